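#' Fit a marker-assisted annotation model on a labelled reference
#'
#' The main entry point of the package. From a labelled reference dataset it
#' (1) identifies ensemble-ranked cell-type markers via one-vs-rest DE scores
#' aggregated by robust rank aggregation or Lancaster p-value combination
#' (unless a pre-built marker table is supplied), (2) attaches rank-discount
#' weights, (3) converts the reference into its cell-type score matrix, and
#' (4) computes per-type score centroids used later for certainty scoring.
#' The fitted object annotates new data through [predict.masi()].
#'
#' @param x reference expression: a \code{"masi_expr"} (counts or lognorm)
#'   or a cells x genes matrix of counts.
#' @param labels per-cell reference cell-type labels.
#' @param markers optional pre-built \code{"masi_markers"}; skips discovery.
#' @param methods DE scores to ensemble (see [rank_genes()]).
#' @param scheme \code{"top_k_rra"} or \code{"significant_lancaster"}.
#' @param top_k markers per type for the RRA scheme.
#' @param alpha FDR cutoff for the Lancaster scheme.
#' @param lancaster_weights per-method chi-square dfs (default 2 each).
#' @param mode,X,use_weights scoring options (see [score_cells()]).
#' @param scale log-normalization scale factor.
#' @param batch optional per-cell batch labels, stored for evaluation.
#' @return An object of class \code{"masi"}: list with \code{markers},
#'   \code{centroids}, \code{scores} (reference score matrix),
#'   \code{labels}, \code{config}, \code{call}.
#' @seealso [predict.masi()], [annotate()], [evaluate_annotation()]
#' @examples
#' sim <- simulate_multibatch(n_types = 3, n_cells_per_type_per_batch = 40,
#'                            n_batches = 2, n_genes = 120,
#'                            n_markers_per_type = 8, seed = 1)
#' fit <- masi(sim$expr, sim$truth$cell_type, methods = c("logfc", "cosg"))
#' ann <- predict(fit, sim$expr, seed = 1)
#' overall_accuracy(ann$label, sim$truth$cell_type)
#' @export
masi <- function(x, labels, markers = NULL,
                 methods = c("wilcoxon", "welch_t", "logfc", "cosg"),
                 scheme = c("top_k_rra", "significant_lancaster"),
                 top_k = 20, alpha = 0.05, lancaster_weights = NULL,
                 mode = c("pliner", "raw"), X = 0.25, use_weights = TRUE,
                 scale = 10000, batch = NULL) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  if (!inherits(x, "masi_expr"))
    x <- masi_expr(as.matrix(x), batch = batch, layer = "counts")
  if (x$layer == "counts") x <- log_normalize(x, scale = scale)
  labels <- stats::setNames(as.character(labels), x$cell_ids)
  if (is.null(markers)) {
    ranked <- lapply(methods, function(m) rank_genes(x, labels, method = m))
    markers <- if (scheme == "top_k_rra")
      aggregate_rra(ranked, top_k = top_k)
    else
      aggregate_lancaster(ranked, alpha = alpha, weights = lancaster_weights)
  } else {
    stopifnot(inherits(markers, "masi_markers"))
  }
  scores <- score_cells(x, markers, mode = mode, X = X,
                        use_weights = use_weights)
  centroids <- compute_centroids(scores, labels)
  structure(list(markers = markers,
                 centroids = centroids,
                 scores = scores,
                 labels = labels,
                 config = list(methods = methods, scheme = scheme,
                               top_k = top_k, alpha = alpha, mode = mode,
                               X = X, use_weights = use_weights,
                               scale = scale),
                 call = match.call()),
            class = "masi")
}

#' Annotate new data with a fitted model
#'
#' Runs the consensus annotation chain on \code{newdata} using the fitted
#' marker table: cell-type scoring, per-cell argmax labels, Louvain
#' over-clustering of the score matrix, cluster-to-label consensus, and
#' certainty scoring against the reference centroids. With
#' \code{n_batches > 1} cells are annotated in independent blocks (see
#' [annotate_parallel()]).
#'
#' @param object a fitted \code{"masi"}.
#' @param newdata query expression (\code{"masi_expr"} or counts matrix).
#' @param n_batches independent annotation blocks (1 = serial).
#' @param n_workers CPU cores for block-level parallelism.
#' @param resolutions,n_neighbors,metric clustering grid.
#' @param seed seed for clustering.
#' @param unassigned_threshold if non-NULL, cells with certainty below it
#'   are relabelled \code{"unassigned"}.
#' @param ... unused.
#' @return A \code{"masi_annotation"}; the query score matrix is in
#'   \code{attr(, "scores")}.
#' @export
predict.masi <- function(object, newdata, n_batches = 1, n_workers = 1,
                         resolutions = c(3, 5, 7), n_neighbors = c(5, 10, 15),
                         metric = "cosine", seed = 0,
                         unassigned_threshold = NULL, ...) {
  if (!inherits(newdata, "masi_expr"))
    newdata <- masi_expr(as.matrix(newdata), layer = "counts")
  cfg <- object$config
  res <- annotate_parallel(newdata, object$markers, n_batches = n_batches,
                           n_workers = n_workers, seed = seed,
                           mode = cfg$mode, X = cfg$X,
                           use_weights = cfg$use_weights,
                           resolutions = resolutions,
                           n_neighbors = n_neighbors, metric = metric,
                           centroids = object$centroids)
  if (!is.null(unassigned_threshold))
    res <- apply_unassigned(res, unassigned_threshold)
  res
}

#' @exportS3Method print masi
print.masi <- function(x, ...) {
  cat("Marker-assisted annotation model\n")
  cat(sprintf("  reference: %d cells, %d cell types\n",
              length(x$labels), nrow(x$centroids)))
  ns <- vapply(x$markers$markers, length, integer(1))
  cat(sprintf("  markers:   %d types, %d-%d genes per type (%s, %s)\n",
              length(ns), min(ns), max(ns),
              paste(x$config$methods, collapse = "+"), x$config$scheme))
  cat(sprintf("  scoring:   %s (X = %g, weights %s)\n", x$config$mode,
              x$config$X, if (x$config$use_weights) "on" else "off"))
  invisible(x)
}

#' @exportS3Method summary masi
summary.masi <- function(object, ...) {
  print(object)
  cat("\nReference label counts:\n")
  print(table(object$labels))
  cat("\nSelf-annotation of the reference (argmax labels):\n")
  l1 <- label1_argmax(object$scores)
  cat(sprintf("  argmax accuracy vs reference labels: %.3f\n",
              overall_accuracy(l1$label, object$labels)))
  invisible(object)
}

#' Marker weights of a fitted model
#'
#' @param object a fitted \code{"masi"}.
#' @param ... unused.
#' @return Named list (per cell type) of named weight vectors.
#' @export
coef.masi <- function(object, ...) object$markers$weights

#' Plot reference cell-type score centroids
#'
#' Image of the centroid matrix: rows are reference cell types, columns the
#' score dimensions. A crisp diagonal indicates well-separated types.
#'
#' @param x a fitted \code{"masi"}.
#' @param ... passed to [graphics::image()].
#' @export
plot.masi <- function(x, ...) {
  cen <- x$centroids
  graphics::image(seq_len(ncol(cen)), seq_len(nrow(cen)), t(cen),
                  xlab = "score dimension", ylab = "reference cell type",
                  axes = FALSE, main = "cell-type score centroids", ...)
  graphics::axis(1, seq_len(ncol(cen)), colnames(cen), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(cen)), rownames(cen), las = 2, cex.axis = 0.7)
  invisible(x)
}
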