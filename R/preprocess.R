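#' Log-normalize a count matrix
#'
#' Standard library-size normalization for scRNA-seq: each cell's counts are
#' divided by the cell's total count, multiplied by a scale factor and
#' log-transformed, so entry (c, g) becomes
#' \code{ln(1 + count(c,g) / total(c) * scale)}.
#'
#' @param expr a \code{"masi_expr"} with \code{layer = "counts"}.
#' @param scale positive scale factor (default 10000).
#' @return A \code{"masi_expr"} with \code{layer = "lognorm"}.
#' @export
log_normalize <- function(expr, scale = 10000) {
  stopifnot(inherits(expr, "masi_expr"))
  if (expr$layer != "counts")
    stop("log_normalize expects layer 'counts', got '", expr$layer, "'")
  if (scale <= 0) stop("scale must be positive")
  totals <- Matrix::rowSums(expr$values)
  if (any(totals == 0))
    stop("cells with zero total count: ",
         paste(utils::head(expr$cell_ids[totals == 0], 5), collapse = ", "))
  if (inherits(expr$values, "sparseMatrix")) {
    v <- Matrix::Diagonal(x = scale / totals) %*% expr$values
    v <- methods::as(v, "CsparseMatrix")
    v@x <- log1p(v@x)
  } else {
    v <- log1p(expr$values / totals * scale)
  }
  masi_expr(v, cell_ids = expr$cell_ids, gene_ids = expr$gene_ids,
            batch = expr$batch, layer = "lognorm")
}

#' Mini-batch standardization with non-linear activation
#'
#' The non-learned analogue of a batch-normalization + activation layer used
#' by deep-learning integrators: cells are shuffled (seeded) and split into
#' contiguous mini-batches; within each mini-batch every gene is standardized
#' to mean 0, variance 1 (population variance, with an \code{eps} guard), and
#' a non-linear activation is applied elementwise. The original cell order is
#' restored. This transform is optional and off in the default annotation
#' chain.
#'
#' @param expr a \code{"masi_expr"} with \code{layer = "lognorm"}.
#' @param minibatch_size cells per mini-batch (>= 2); the last batch may be
#'   smaller.
#' @param activation \code{"relu"} or \code{"softplus"}.
#' @param eps variance guard added before taking the square root.
#' @param seed integer seed for the shuffle.
#' @return A \code{"masi_expr"} with \code{layer = "transformed"}.
#' @export
batchnorm_activation <- function(expr, minibatch_size = 256,
                                 activation = c("relu", "softplus"),
                                 eps = 1e-6, seed = 0) {
  stopifnot(inherits(expr, "masi_expr"))
  activation <- match.arg(activation)
  if (expr$layer != "lognorm")
    stop("batchnorm_activation expects layer 'lognorm'")
  if (minibatch_size < 2) stop("minibatch_size must be at least 2")
  n <- length(expr$cell_ids)
  perm <- seeded_permutation(expr$cell_ids, seed)
  v <- as.matrix(expr$values)[perm, , drop = FALSE]
  starts <- seq(1, n, by = minibatch_size)
  for (s in starts) {
    idx <- s:min(s + minibatch_size - 1, n)
    blk <- v[idx, , drop = FALSE]
    mu <- colMeans(blk)
    sd_pop <- sqrt(colMeans(blk^2) - mu^2 + eps)
    v[idx, ] <- sweep(sweep(blk, 2, mu, "-"), 2, sd_pop, "/")
  }
  v <- switch(activation,
              relu = pmax(v, 0),
              softplus = log1p(exp(-abs(v))) + pmax(v, 0))
  v <- v[order(perm), , drop = FALSE]
  masi_expr(v, cell_ids = expr$cell_ids, gene_ids = expr$gene_ids,
            batch = expr$batch, layer = "transformed")
}

# Deterministic permutation of cells that depends only on the cell-id set and
# the seed, not on the incoming order: ids are ranked lexicographically before
# the seeded draw, so permuting the input rows permutes the output
# identically.
seeded_permutation <- function(cell_ids, seed) {
  ord <- order(cell_ids, method = "radix")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  ord[sample.int(length(cell_ids))]
}
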