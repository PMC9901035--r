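#' Percentile suppression and TF-IDF transform of marker-gene expression
#'
#' The transform behind the PlinerScore variant of cell-type scoring. The
#' matrix is restricted to the requested marker genes; per gene, the
#' X-percentile of its values over all cells (zeros included,
#' linear-interpolation quantile) is taken as a threshold t(g) and values
#' strictly below t(g) are suppressed to zero. Each surviving value is then
#' weighted by the gene's inverse document frequency,
#' \code{idf(g) = ln(1 + n_cells / (1 + n_expressing(g)))}, where
#' \code{n_expressing} counts cells with a positive value after suppression.
#'
#' @param expr a \code{"masi_expr"} with \code{layer = "lognorm"}.
#' @param marker_genes character vector of genes to keep; genes absent from
#'   the matrix are dropped with a warning so mismatched gene panels degrade
#'   gracefully.
#' @param X suppression percentile in [0, 1); \code{X = 0} disables
#'   suppression.
#' @return A \code{"masi_expr"} with \code{layer = "transformed"} restricted
#'   to the retained marker genes.
#' @export
pliner_transform <- function(expr, marker_genes, X = 0.25) {
  stopifnot(inherits(expr, "masi_expr"))
  if (expr$layer != "lognorm")
    stop("pliner_transform expects layer 'lognorm'")
  if (!(X >= 0 && X < 1)) stop("X must lie in [0, 1)")
  marker_genes <- unique(as.character(marker_genes))
  absent <- setdiff(marker_genes, expr$gene_ids)
  if (length(absent)) {
    warning(length(absent), " marker gene(s) absent from the matrix: ",
            paste(utils::head(absent, 5), collapse = ", "))
    marker_genes <- setdiff(marker_genes, absent)
  }
  if (length(marker_genes) == 0)
    stop("none of the marker genes are present in the matrix")
  v <- as.matrix(expr$values[, marker_genes, drop = FALSE])
  n <- nrow(v)
  if (X > 0) {
    thr <- apply(v, 2, stats::quantile, probs = X, names = FALSE)  # type 7
    v[sweep(v, 2, thr, "<")] <- 0
  }
  df <- colSums(v > 0)
  idf <- log(1 + n / (1 + df))
  v <- sweep(v, 2, idf, "*")
  masi_expr(v, cell_ids = expr$cell_ids, gene_ids = marker_genes,
            batch = expr$batch, layer = "transformed")
}

#' Convert an expression matrix into a cell-type score matrix
#'
#' The core conversion of the method: each cell receives one score per
#' reference cell type, the weighted sum of that type's marker expression.
#' In \code{mode = "raw"} the sum runs over the log-normalized values; in
#' \code{mode = "pliner"} (the default annotation chain) the values are first
#' passed through [pliner_transform()]. The resulting cells x cell-types
#' matrix replaces a learned latent space for annotation and integration and
#' never contains negative entries.
#'
#' @param expr a \code{"masi_expr"} with \code{layer = "lognorm"}.
#' @param markers a \code{"masi_markers"}.
#' @param mode \code{"pliner"} or \code{"raw"}.
#' @param X suppression percentile for \code{mode = "pliner"}.
#' @param use_weights apply the rank-discount weights? With
#'   \code{use_weights = FALSE} and \code{mode = "raw"} the score is the
#'   plain unweighted marker sum.
#' @return Numeric matrix, cells x cell types, with cell ids as rownames and
#'   cell-type names as colnames.
#' @export
score_cells <- function(expr, markers, mode = c("pliner", "raw"), X = 0.25,
                        use_weights = TRUE) {
  stopifnot(inherits(expr, "masi_expr"), inherits(markers, "masi_markers"))
  mode <- match.arg(mode)
  if (expr$layer != "lognorm")
    stop("score_cells expects layer 'lognorm'")
  if (length(markers$markers) == 0) stop("empty marker table")
  all_markers <- unique(unlist(markers$markers, use.names = FALSE))
  present <- intersect(all_markers, expr$gene_ids)
  if (length(present) == 0)
    stop("no marker gene of the marker table is present in the matrix")
  if (mode == "pliner") {
    tr <- suppressWarnings(pliner_transform(expr, present, X = X))
    v <- tr$values
  } else {
    v <- as.matrix(expr$values[, present, drop = FALSE])
  }
  types <- names(markers$markers)
  scores <- matrix(0, nrow(v), length(types),
                   dimnames = list(expr$cell_ids, types))
  for (ct in types) {
    g <- markers$markers[[ct]]
    w <- markers$weights[[ct]]
    keep <- g %in% present
    if (!any(keep)) {
      warning("no marker of cell type '", ct,
              "' is present in the matrix; its score column is all zero")
      next
    }
    g <- g[keep]
    w <- if (use_weights) w[keep] else rep(1, sum(keep))
    scores[, ct] <- as.numeric(v[, g, drop = FALSE] %*% w)
  }
  scores
}
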