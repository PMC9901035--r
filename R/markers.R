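#' Rank genes per cell type by a one-vs-rest differential-expression score
#'
#' For every cell type in \code{labels}, compares that type's cells against
#' all remaining cells and ranks every gene by a marker score. Four
#' self-contained scores covering the rank-based, parametric, effect-size and
#' similarity families are provided:
#' \describe{
#'   \item{wilcoxon}{rank-sum test; normal approximation with tie correction,
#'     exact enumeration when both groups have at most 8 cells. Score is the
#'     standardized rank-sum statistic (positive = elevated in the type);
#'     two-sided p-values, Benjamini-Hochberg adjusted within the type.}
#'   \item{welch_t}{unequal-variance t test; score is the t statistic,
#'     two-sided BH-adjusted p-values.}
#'   \item{logfc}{difference of group means of log-normalized values; no
#'     p-value.}
#'   \item{cosg}{cosine similarity between the gene's expression vector and
#'     the type's one-hot indicator, penalized by \code{lambda} times the sum
#'     of the gene's squared similarities to the other types; no p-value.}
#' }
#' Genes are sorted by descending score, ties broken by gene id so outputs
#' are deterministic.
#'
#' @param expr a \code{"masi_expr"} with \code{layer = "lognorm"}.
#' @param labels per-cell cell-type labels (length = number of cells).
#' @param method one of \code{"wilcoxon"}, \code{"welch_t"}, \code{"logfc"},
#'   \code{"cosg"}.
#' @param lambda COSG penalty for similarity to other types.
#' @return A \code{"masi_ranked"}: list with \code{method} and \code{types},
#'   a named list of data frames (\code{gene}, \code{score}, \code{p}) sorted
#'   by decreasing score. \code{p} is NA for score-only methods.
#' @export
rank_genes <- function(expr, labels,
                       method = c("wilcoxon", "welch_t", "logfc", "cosg"),
                       lambda = 0.5) {
  stopifnot(inherits(expr, "masi_expr"))
  method <- match.arg(method)
  if (expr$layer != "lognorm")
    stop("rank_genes expects layer 'lognorm'")
  labels <- as.character(labels)
  if (length(labels) != length(expr$cell_ids))
    stop("labels must have one entry per cell")
  sizes <- table(labels)
  if (any(sizes < 2))
    stop("cell types with fewer than 2 cells: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  v <- as.matrix(expr$values)
  types <- sort(unique(labels))
  per_type <- switch(method,
                     wilcoxon = de_wilcoxon(v, labels, types),
                     welch_t  = de_welch(v, labels, types),
                     logfc    = de_logfc(v, labels, types),
                     cosg     = de_cosg(v, labels, types, lambda))
  per_type <- lapply(per_type, function(df) {
    df <- df[order(-df$score, df$gene, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  structure(list(method = method, types = per_type), class = "masi_ranked")
}

#' @exportS3Method print masi_ranked
print.masi_ranked <- function(x, ...) {
  cat(sprintf("masi_ranked [%s]: %d cell types, %d genes\n", x$method,
              length(x$types), nrow(x$types[[1]])))
  invisible(x)
}

de_wilcoxon <- function(v, labels, types) {
  n <- nrow(v)
  rk <- apply(v, 2, rank)                      # ranks shared by every type
  ties <- apply(v, 2, function(col) {
    t <- tabulate(match(col, unique(col)))
    sum(t^3 - t)
  })
  out <- list()
  for (ct in types) {
    grp <- labels == ct
    n1 <- sum(grp); n2 <- n - n1
    r1 <- colSums(rk[grp, , drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - ties / (n * (n - 1))))
    z <- ifelse(sigma > 0, (u - n1 * n2 / 2) / sigma, 0)
    if (n1 <= 8 && n2 <= 8) {
      p <- vapply(seq_len(ncol(v)), function(g)
        suppressWarnings(stats::wilcox.test(v[grp, g], v[!grp, g],
                                            exact = TRUE)$p.value),
        numeric(1))
    } else {
      p <- 2 * stats::pnorm(-abs(z))
    }
    out[[ct]] <- data.frame(gene = colnames(v), score = z,
                            p = stats::p.adjust(p, "BH"),
                            stringsAsFactors = FALSE)
  }
  out
}

de_welch <- function(v, labels, types) {
  out <- list()
  for (ct in types) {
    grp <- labels == ct
    n1 <- sum(grp); n2 <- sum(!grp)
    m1 <- colMeans(v[grp, , drop = FALSE])
    m2 <- colMeans(v[!grp, , drop = FALSE])
    s1 <- colSums(sweep(v[grp, , drop = FALSE], 2, m1)^2) / (n1 - 1)
    s2 <- colSums(sweep(v[!grp, , drop = FALSE], 2, m2)^2) / (n2 - 1)
    se2 <- s1 / n1 + s2 / n2
    # zero pooled variance: infinite t for distinct means, 0 for equal ones
    t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                sign(m1 - m2) * Inf)
    t[se2 == 0 & m1 == m2] <- 0
    df <- ifelse(se2 > 0,
                 se2^2 / (s1^2 / (n1^2 * (n1 - 1)) + s2^2 / (n2^2 * (n2 - 1))),
                 1)
    p <- 2 * stats::pt(-abs(t), df)
    p[is.infinite(t)] <- 0
    out[[ct]] <- data.frame(gene = colnames(v), score = t,
                            p = stats::p.adjust(p, "BH"),
                            stringsAsFactors = FALSE)
  }
  out
}

de_logfc <- function(v, labels, types) {
  out <- list()
  for (ct in types) {
    grp <- labels == ct
    score <- colMeans(v[grp, , drop = FALSE]) - colMeans(v[!grp, , drop = FALSE])
    out[[ct]] <- data.frame(gene = colnames(v), score = score, p = NA_real_,
                            stringsAsFactors = FALSE)
  }
  out
}

de_cosg <- function(v, labels, types, lambda) {
  norms <- sqrt(colSums(v^2))
  h <- vapply(types, function(ct) as.numeric(labels == ct),
              numeric(nrow(v)))                         # cells x types one-hot
  sim <- crossprod(v, h)                                # genes x types
  sim <- sweep(sim, 2, sqrt(colSums(h)), "/")
  sim <- sim / ifelse(norms > 0, norms, 1)
  sim[norms == 0, ] <- 0
  sq <- rowSums(sim^2)
  out <- list()
  for (j in seq_along(types)) {
    score <- sim[, j] - lambda * (sq - sim[, j]^2)
    out[[types[j]]] <- data.frame(gene = colnames(v), score = score,
                                  p = NA_real_, stringsAsFactors = FALSE)
  }
  out
}

#' Robust rank aggregation of ranked marker lists
#'
#' Consensus ranking over several DE outcomes. Per cell type, the candidate
#' set is the union of each method's top \code{top_k} genes. A candidate's
#' normalized rank under method j is its position in that method's full
#' ranking divided by the number of ranked genes, or 1 when it is absent from
#' method j's top-k compilation. With the normalized ranks sorted ascending
#' as r(1) <= ... <= r(m), the gene's rho is
#' \code{min_k BetaCDF(r(k); k, m - k + 1)} -- the smallest probability that
#' the k-th order statistic of m uniforms falls at or below r(k) -- and the
#' final score is the Bonferroni-style \code{min(rho * m, 1)}. Genes are
#' ordered by ascending score and the per-type list truncated to
#' \code{top_k}, with weights attached by [assign_weights()].
#'
#' @param results list of \code{"masi_ranked"} objects covering the same cell
#'   types.
#' @param top_k markers kept per cell type (and per-method compilation size).
#' @return A \code{"masi_markers"}.
#' @export
aggregate_rra <- function(results, top_k = 20) {
  if (length(results) == 0) stop("need at least one ranked result")
  stopifnot(all(vapply(results, inherits, logical(1), "masi_ranked")))
  if (top_k < 1) stop("top_k must be at least 1")
  type_sets <- lapply(results, function(r) sort(names(r$types)))
  if (!all(vapply(type_sets, identical, logical(1), type_sets[[1]])))
    stop("cell-type sets differ between ranked results")
  m <- length(results)
  markers <- list()
  for (ct in type_sets[[1]]) {
    ranked <- lapply(results, function(r) r$types[[ct]]$gene)
    tops <- lapply(ranked, utils::head, top_k)
    cand <- sort(unique(unlist(tops)))
    score <- vapply(cand, function(g) {
      r <- vapply(seq_len(m), function(j) {
        if (g %in% tops[[j]]) match(g, ranked[[j]]) / length(ranked[[j]]) else 1
      }, numeric(1))
      min(rra_rho(r) * m, 1)
    }, numeric(1))
    ord <- order(score, cand, method = "radix")
    markers[[ct]] <- utils::head(cand[ord], top_k)
  }
  assign_weights(masi_markers(markers, weights = list()))
}

#' Lancaster combination of per-method p-values
#'
#' Aggregates only statistically supported markers: per cell type and gene,
#' per-method p-values are combined with the Lancaster statistic
#' \code{T = sum_j Q(1 - p_j; df = w_j)} (Q the chi-square quantile
#' function), whose null distribution is chi-square with \code{sum_j w_j}
#' degrees of freedom. With every weight equal to 2 this reduces to Fisher's
#' method, \code{T = -2 sum_j ln p_j}. Genes whose combined BH-FDR falls
#' below \code{alpha} are retained, ordered by ascending combined p.
#' Score-only methods (no p-values) are dropped with a warning.
#'
#' @param results list of \code{"masi_ranked"} objects.
#' @param alpha FDR threshold in (0, 1).
#' @param weights per-method chi-square degrees of freedom; default 2 each.
#' @return A \code{"masi_markers"}; cell types with no significant gene are
#'   dropped with a warning.
#' @export
aggregate_lancaster <- function(results, alpha = 0.05, weights = NULL) {
  stopifnot(all(vapply(results, inherits, logical(1), "masi_ranked")))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  has_p <- vapply(results, function(r) !all(is.na(r$types[[1]]$p)), logical(1))
  if (any(!has_p)) {
    warning("dropping score-only methods without p-values: ",
            paste(vapply(results[!has_p], `[[`, "", "method"), collapse = ", "))
    results <- results[has_p]
  }
  if (length(results) == 0) stop("no p-value-bearing methods supplied")
  type_sets <- lapply(results, function(r) sort(names(r$types)))
  if (!all(vapply(type_sets, identical, logical(1), type_sets[[1]])))
    stop("cell-type sets differ between ranked results")
  if (is.null(weights)) weights <- rep(2, length(results))
  if (length(weights) != length(results) || any(weights <= 0))
    stop("weights must be positive, one per p-value-bearing method")
  markers <- list()
  for (ct in type_sets[[1]]) {
    pmat <- vapply(results, function(r) {
      df <- r$types[[ct]]
      stats::setNames(df$p, df$gene)[sort(df$gene)]
    }, numeric(nrow(results[[1]]$types[[1]])))
    comb <- apply(pmat, 1, function(p) lancaster_p(p, weights))
    keep <- stats::p.adjust(comb, "BH") < alpha
    if (!any(keep)) next
    genes <- names(comb)[keep]
    ord <- order(comb[keep], genes, method = "radix")
    markers[[ct]] <- genes[ord]
  }
  dropped <- setdiff(type_sets[[1]], names(markers))
  if (length(dropped))
    warning("no significant markers at alpha = ", alpha, " for: ",
            paste(dropped, collapse = ", "))
  if (length(markers) == 0) stop("no cell type retained any significant marker")
  assign_weights(masi_markers(markers, weights = list()))
}

# rho statistic of robust rank aggregation: the smallest Beta order-statistic
# probability P(k-th smallest of m Uniform(0,1) <= r_(k)) over k.
rra_rho <- function(r) {
  m <- length(r)
  r <- sort(r)
  min(stats::pbeta(r, seq_len(m), m - seq_len(m) + 1))
}

# Combined upper-tail p for one gene across methods.
lancaster_p <- function(p, weights) {
  p <- pmin(pmax(p, 0), 1)
  t <- sum(stats::qchisq(p, df = weights, lower.tail = FALSE))
  stats::pchisq(t, df = sum(weights), lower.tail = FALSE)
}

#' Rank-discount weights for a marker table
#'
#' Attaches the rank-based contribution weight to every marker: the 1st
#' marker of a cell type contributes 100% of its expression to that type's
#' score (w = 1 exactly) and the N-th contributes 50%; for ranks i >= 2 the
#' discount is \code{w_i = 1 - (i / N) / 2}. Weights are therefore strictly
#' decreasing from rank 2 on and bounded in [0.5, 1].
#'
#' @param table a \code{"masi_markers"}.
#' @return The same table with \code{weights} populated (replacing any
#'   existing weights).
#' @export
assign_weights <- function(table) {
  stopifnot(inherits(table, "masi_markers"))
  table$weights <- lapply(table$markers, function(g) {
    n <- length(g)
    if (n == 0) stop("cell type with zero markers")
    i <- seq_len(n)
    w <- 1 - (i / n) / 2
    w[1] <- 1
    stats::setNames(w, g)
  })
  table
}
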