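#' Per-cell argmax label (Label 1)
#'
#' The first of the two labels the consensus annotation combines: each cell
#' is assigned the cell type with the maximal score. Ties are broken by
#' column order and flagged.
#'
#' @param scores cells x cell-types score matrix with dimnames.
#' @return List with \code{label} (named character) and \code{tie_flag}
#'   (named logical).
#' @export
label1_argmax <- function(scores) {
  if (ncol(scores) < 1) stop("score matrix needs at least one cell type")
  idx <- max.col(scores, ties.method = "first")
  mx <- scores[cbind(seq_len(nrow(scores)), idx)]
  tie <- rowSums(scores == mx) > 1
  list(label = stats::setNames(colnames(scores)[idx], rownames(scores)),
       tie_flag = stats::setNames(tie, rownames(scores)))
}

#' Over-cluster cells on the score matrix (Label 2 ensemble)
#'
#' Builds a k-nearest-neighbour graph on the cell-type score matrix and runs
#' Louvain community detection at several resolutions, producing one
#' over-clustered partition per (neighbourhood size, resolution) pair. The
#' default grid -- resolutions 3, 5, 7 crossed with neighbourhood sizes 5,
#' 10, 15 -- yields 9 partitions. Cells are processed in a canonical
#' (sorted-id) order so the result does not depend on the input row order.
#'
#' @param scores cells x cell-types score matrix with rownames.
#' @param resolutions Louvain resolution parameters.
#' @param n_neighbors neighbourhood sizes for the kNN graph.
#' @param seed integer seed; each run derives its own sub-seed.
#' @param metric \code{"cosine"} (default) or \code{"euclidean"} kNN metric.
#' @return A \code{"masi_ensemble"}: list of runs, each with
#'   \code{resolution}, \code{n_neighbors} and \code{labels} (named integer
#'   partition over all cells, in the input cell order).
#' @export
overcluster <- function(scores, resolutions = c(3, 5, 7),
                        n_neighbors = c(5, 10, 15), seed = 0,
                        metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  n <- nrow(scores)
  if (n < max(n_neighbors) + 1)
    stop("need at least max(n_neighbors) + 1 = ", max(n_neighbors) + 1,
         " cells, got ", n)
  ids <- rownames(scores)
  ord <- order(ids, method = "radix")
  x <- as.matrix(scores)[ord, , drop = FALSE]
  runs <- list()
  run_i <- 0L
  for (k in n_neighbors) {
    g <- knn_graph(x, k, metric)
    for (res in resolutions) {
      run_i <- run_i + 1L
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv())
      set.seed(as.integer((seed + 7919 * run_i) %% .Machine$integer.max))
      cl <- igraph::cluster_louvain(g, resolution = res)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      memb <- integer(n)
      memb[ord] <- igraph::membership(cl)
      runs[[run_i]] <- list(resolution = res, n_neighbors = k,
                            labels = stats::setNames(memb, ids))
    }
  }
  structure(list(runs = runs), class = "masi_ensemble")
}

# Undirected kNN graph; edge weight = similarity so Louvain favours tight
# neighbourhoods.
knn_graph <- function(x, k, metric) {
  n <- nrow(x)
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(x^2))
    xn <- x / ifelse(nrm > 0, nrm, 1)
    sim <- tcrossprod(xn)
  } else {
    d <- as.matrix(stats::dist(x))
    sim <- 1 / (1 + d)
  }
  diag(sim) <- -Inf
  from <- integer(n * k); to <- integer(n * k); w <- numeric(n * k)
  for (i in seq_len(n)) {
    nb <- order(sim[i, ], decreasing = TRUE)[seq_len(k)]
    idx <- ((i - 1) * k + 1):(i * k)
    from[idx] <- i; to[idx] <- nb; w[idx] <- sim[i, nb]
  }
  w <- pmax(w, 1e-12)                    # Louvain needs positive weights
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Map over-clustered partitions onto argmax labels and take the consensus
#'
#' The consensus step: within every clustering run, each cluster is assigned
#' the majority argmax (Label 1) type among its cells, ties going to the tied
#' type with the higher mean score inside the cluster; every cell thereby
#' receives one mapped label per run. The final per-cell label is the mode of
#' its mapped labels across runs, ties again resolved by the cell's own score
#' for the tied types.
#'
#' @param label1 named per-cell argmax labels (from [label1_argmax()]).
#' @param ensemble a \code{"masi_ensemble"}.
#' @param scores the cells x cell-types score matrix.
#' @return List with \code{label} (named character consensus labels) and
#'   \code{mapped_labels} (cells x runs character matrix).
#' @export
maca_consensus <- function(label1, ensemble, scores) {
  stopifnot(inherits(ensemble, "masi_ensemble"))
  ids <- names(label1)
  if (is.null(ids) || !all(vapply(ensemble$runs, function(r)
    identical(sort(names(r$labels)), sort(ids)), logical(1))))
    stop("label1 and every clustering run must cover the same cells")
  n <- length(ids)
  mapped <- matrix(NA_character_, n, length(ensemble$runs),
                   dimnames = list(ids, NULL))
  for (j in seq_along(ensemble$runs)) {
    part <- ensemble$runs[[j]]$labels[ids]
    for (cl in unique(part)) {
      cells <- ids[part == cl]
      mapped[cells, j] <- majority_label(label1[cells],
                                         scores[cells, , drop = FALSE])
    }
  }
  lab <- vapply(seq_len(n), function(i)
    majority_label(mapped[i, ], scores[i, , drop = FALSE]), character(1))
  list(label = stats::setNames(lab, ids), mapped_labels = mapped)
}

# Majority vote with score-based tie-break: among the most frequent labels,
# pick the one with the highest mean score over the voting cells.
majority_label <- function(labs, score_rows) {
  tab <- table(labs)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  sc <- vapply(top, function(ct)
    mean(score_rows[, ct, drop = TRUE]), numeric(1))
  top[which.max(sc)]
}

#' Cell-type centroids of a score matrix
#'
#' Mean score vector per reference cell type, used by [certainty_score()].
#'
#' @param scores cells x cell-types score matrix.
#' @param labels per-cell reference labels (length = rows of \code{scores}).
#' @return Matrix, one centroid row per reference cell type.
#' @export
compute_centroids <- function(scores, labels) {
  stopifnot(nrow(scores) == length(labels))
  types <- sort(unique(as.character(labels)))
  out <- t(vapply(types, function(ct)
    colMeans(scores[labels == ct, , drop = FALSE]), numeric(ncol(scores))))
  rownames(out) <- types
  out
}

#' Certainty of an assigned label
#'
#' \code{C = 1 - D_1st / D_Nth}, where D_1st is the Euclidean distance from
#' the cell's score vector to the closest reference cell-type centroid and
#' D_Nth the distance to the farthest. A cell squarely of a reference type
#' sits near one centroid and far from an unrelated one (C near 1); a cell
#' of a type unseen in the reference is similarly distant from every
#' centroid (C near 0).
#'
#' @param cell_scores numeric score vector for one cell (or a cells x types
#'   matrix for many).
#' @param centroids centroid matrix from [compute_centroids()] (>= 2 rows).
#' @return Certainty value(s) in [0, 1]; 0 when all distances are equal or
#'   zero.
#' @export
certainty_score <- function(cell_scores, centroids) {
  if (nrow(centroids) < 2)
    stop("certainty needs at least 2 reference centroids")
  x <- if (is.matrix(cell_scores)) cell_scores else
    matrix(cell_scores, 1, dimnames = list(NULL, names(cell_scores)))
  if (!is.null(colnames(x)) && !is.null(colnames(centroids)))
    centroids <- centroids[, colnames(x), drop = FALSE]
  d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(x)), rowSums(centroids^2)) - 2 * tcrossprod(x, centroids)
  d <- sqrt(pmax(d2, 0))
  d1 <- apply(d, 1, min)
  dn <- apply(d, 1, max)
  c_val <- ifelse(dn > 0, 1 - d1 / dn, 0)
  if (is.matrix(cell_scores)) stats::setNames(c_val, rownames(x)) else c_val[[1]]
}

#' Flag low-certainty cells as unassigned
#'
#' Cells whose certainty falls below the threshold are relabelled
#' \code{"unassigned"}, marking probable cell types absent from the
#' reference. The default threshold 0.55 is the midpoint of the 0.5-0.6 band
#' that retrieves unseen types well without discarding seen ones.
#'
#' @param result a \code{"masi_annotation"} with certainties populated.
#' @param threshold certainty threshold in [0, 1].
#' @return The annotation with low-certainty labels replaced.
#' @export
apply_unassigned <- function(result, threshold = 0.55) {
  stopifnot(inherits(result, "masi_annotation"))
  if (!(threshold >= 0 && threshold <= 1))
    stop("threshold must lie in [0, 1]")
  if (all(is.na(result$certainty)))
    stop("certainty scores are not populated; annotate with reference centroids")
  flag <- !is.na(result$certainty) & result$certainty < threshold
  result$label[flag] <- "unassigned"
  result
}

# Consensus annotation of a pre-computed score matrix (shared by the serial
# and per-block paths).
annotate_scores <- function(scores, resolutions, n_neighbors, seed, metric,
                            centroids = NULL) {
  l1 <- label1_argmax(scores)
  ens <- overcluster(scores, resolutions = resolutions,
                     n_neighbors = n_neighbors, seed = seed, metric = metric)
  cons <- maca_consensus(l1$label, ens, scores)
  cert <- if (!is.null(centroids)) certainty_score(scores, centroids)
  else rep(NA_real_, nrow(scores))
  masi_annotation(cell_id = rownames(scores), label = unname(cons$label),
                  certainty = unname(cert), tie_flag = unname(l1$tie_flag),
                  mapped_labels = cons$mapped_labels)
}

#' Annotate cells with a marker table
#'
#' The full per-dataset annotation chain: cell-type scoring
#' ([score_cells()], PlinerScore by default), per-cell argmax labels,
#' Louvain over-clustering on the score matrix, and the cluster-to-label
#' consensus of [maca_consensus()]. When reference centroids are supplied, a
#' certainty score is attached per cell.
#'
#' @param expr a \code{"masi_expr"} (counts are log-normalized
#'   automatically).
#' @param markers a \code{"masi_markers"}.
#' @param mode scoring mode, \code{"pliner"} or \code{"raw"}.
#' @param X suppression percentile for PlinerScore.
#' @param use_weights apply rank-discount marker weights.
#' @param resolutions,n_neighbors clustering grid (default 3/5/7 x 5/10/15).
#' @param metric kNN metric for over-clustering.
#' @param seed integer seed for the clustering runs.
#' @param centroids optional reference centroid matrix for certainty
#'   scoring.
#' @return A \code{"masi_annotation"} data frame with columns
#'   \code{cell_id}, \code{label}, \code{certainty}, \code{tie_flag}; the
#'   per-run mapped labels are in \code{attr(, "mapped_labels")} and the
#'   score matrix in \code{attr(, "scores")}.
#' @export
annotate <- function(expr, markers, mode = "pliner", X = 0.25,
                     use_weights = TRUE, resolutions = c(3, 5, 7),
                     n_neighbors = c(5, 10, 15), metric = "cosine", seed = 0,
                     centroids = NULL) {
  stopifnot(inherits(expr, "masi_expr"))
  if (expr$layer == "counts") expr <- log_normalize(expr)
  scores <- score_cells(expr, markers, mode = mode, X = X,
                        use_weights = use_weights)
  res <- annotate_scores(scores, resolutions, n_neighbors, seed, metric,
                         centroids)
  attr(res, "scores") <- scores
  res
}

#' Annotate in independent mini-batches (parallel-ready)
#'
#' Scales the consensus annotation to large datasets the way the original
#' tool does: per-cell scoring is computed once on the full matrix (so it is
#' identical to the serial path), then cells are shuffled (seeded, based on
#' cell ids) and split into \code{n_batches} contiguous blocks, each
#' annotated independently -- only the over-clustering is per-block. Results
#' are returned in the original cell order. Blocks run on \code{n_workers}
#' processes via \code{parallel::mclapply}.
#'
#' @inheritParams annotate
#' @param n_batches number of independent blocks (1 = serial path).
#' @param n_workers CPU cores for block-level parallelism.
#' @return A \code{"masi_annotation"} covering all cells in input order.
#' @export
annotate_parallel <- function(expr, markers, n_batches = 1, n_workers = 1,
                              seed = 0, mode = "pliner", X = 0.25,
                              use_weights = TRUE, resolutions = c(3, 5, 7),
                              n_neighbors = c(5, 10, 15), metric = "cosine",
                              centroids = NULL) {
  stopifnot(inherits(expr, "masi_expr"))
  n <- length(expr$cell_ids)
  if (n_batches < 1) stop("n_batches must be at least 1")
  if (n_batches > n) stop("n_batches exceeds the number of cells")
  if (expr$layer == "counts") expr <- log_normalize(expr)
  scores <- score_cells(expr, markers, mode = mode, X = X,
                        use_weights = use_weights)
  perm <- seeded_permutation(expr$cell_ids, seed)
  blocks <- split(perm, ceiling(seq_len(n) * n_batches / n))
  parts <- parallel::mclapply(blocks, function(idx)
    annotate_scores(scores[idx, , drop = FALSE], resolutions, n_neighbors,
                    seed, metric, centroids),
    mc.cores = max(1, n_workers))
  df <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)))
  df <- df[match(expr$cell_ids, df$cell_id), , drop = FALSE]
  res <- masi_annotation(df$cell_id, df$label, df$certainty, df$tie_flag)
  attr(res, "scores") <- scores
  res
}
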