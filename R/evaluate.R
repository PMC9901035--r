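#' Overall annotation accuracy
#'
#' Fraction of cells whose predicted label equals the true label.
#'
#' @param pred,truth equal-length label vectors in the same cell order.
#' @return Accuracy in [0, 1].
#' @export
overall_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth differ in length")
  mean(as.character(pred) == as.character(truth))
}

#' Macro-averaged F1 score
#'
#' F1 (harmonic mean of precision and recall) is computed per cell type
#' present in the truth and averaged without class weights, so minor cell
#' types count as much as dominant ones. An undefined F1 (type never
#' predicted and never recalled) counts as 0.
#'
#' @param pred,truth equal-length label vectors in the same cell order.
#' @return Macro F1 in [0, 1].
#' @export
macro_f1 <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth differ in length")
  pred <- as.character(pred); truth <- as.character(truth)
  f1s <- vapply(sort(unique(truth)), function(ct) {
    tp <- sum(pred == ct & truth == ct)
    fp <- sum(pred == ct & truth != ct)
    fn <- sum(pred != ct & truth == ct)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

#' Rescaled cell-type silhouette score
#'
#' Mean silhouette coefficient of the cells under their cell-type labels
#' (Euclidean distance on the supplied representation -- for this method,
#' the cell-type score matrix), rescaled from [-1, 1] to [0, 1] by
#' \code{(1 + S) / 2}. Higher values mean the representation separates cell
#' types better.
#'
#' @param representation cells x features numeric matrix.
#' @param labels per-cell cell-type labels (>= 2 distinct values).
#' @return Rescaled silhouette in [0, 1].
#' @export
celltype_silhouette <- function(representation, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("silhouette needs at least two distinct labels")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(as.matrix(representation)))
  s <- mean(sil[, "sil_width"])
  (1 + s) / 2
}

#' Batch entropy mixing score
#'
#' Measures how well batches are mixed in local neighbourhoods of a 2-D
#' embedding of the representation. A 2-D UMAP (cosine metric) is computed,
#' \code{n_regions} seed cells are sampled, and each region is the
#' \code{region_size} nearest cells in 2-D. Per region the Shannon entropy
#' of the batch proportions, \code{-sum_i x_i ln x_i} (absent batches
#' contribute 0), is taken; the mean over regions is divided by
#' \code{ln(c)} (c = number of batches) so the score lies in [0, 1], with 1
#' meaning locally uniform batch composition.
#'
#' @param representation cells x features matrix (ignored when
#'   \code{coords} is given).
#' @param batch_labels per-cell batch labels (>= 2 batches).
#' @param n_regions number of sampled seed cells.
#' @param region_size cells per region (<= number of cells).
#' @param seed seed for region sampling (and the UMAP).
#' @param coords optional pre-computed 2-D coordinates, bypassing UMAP.
#' @return Normalized mean regional entropy in [0, 1].
#' @export
batch_entropy_mixing <- function(representation, batch_labels,
                                 n_regions = 50, region_size = 100,
                                 seed = 0, coords = NULL) {
  batch_labels <- as.character(batch_labels)
  batches <- unique(batch_labels)
  if (length(batches) < 2) stop("need at least two batches")
  n <- length(batch_labels)
  if (region_size > n) stop("region_size exceeds the number of cells")
  if (is.null(coords)) {
    coords <- uwot::umap(as.matrix(representation), n_components = 2,
                         metric = "cosine",
                         n_neighbors = min(15, n - 1),
                         min_dist = 0.1, seed = as.integer(seed %% 2^31))
  }
  coords <- as.matrix(coords)
  if (nrow(coords) != n) stop("coords must have one row per cell")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer((seed + 1) %% .Machine$integer.max))
  seeds_idx <- sample.int(n, min(n_regions, n), replace = n_regions > n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  ent <- vapply(seeds_idx, function(i) {
    d2 <- (coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2
    region <- order(d2)[seq_len(region_size)]
    x <- tabulate(factor(batch_labels[region], batches),
                  nbins = length(batches)) / region_size
    x <- x[x > 0]
    -sum(x * log(x))
  }, numeric(1))
  mean(ent) / log(length(batches))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, chance-corrected:
#' \code{ARI = (RI - E[RI]) / (max(RI) - E[RI])}, computed from the
#' contingency table.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return ARI (1 = identical partitions up to relabelling).
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("labelings differ in length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)            # both partitions trivial
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' Normalized mutual information
#'
#' Mutual information between two labelings normalized by the geometric
#' mean of their entropies (\code{sqrt(H(P) H(T))}), bounding the score to
#' [0, 1]; arithmetic-mean normalization is available by flag.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param normalization \code{"geometric"} (default) or \code{"arithmetic"}.
#' @return NMI in [0, 1] (1 when either partition determines the other and
#'   both entropies agree).
#' @export
nmi <- function(labels_a, labels_b,
                normalization = c("geometric", "arithmetic")) {
  if (length(labels_a) != length(labels_b)) stop("labelings differ in length")
  normalization <- match.arg(normalization)
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)            # both partitions trivial
  denom <- if (normalization == "geometric") sqrt(ha * hb) else (ha + hb) / 2
  if (denom == 0) return(0)
  mi / denom
}

#' Evaluation report for an annotation / integration
#'
#' Convenience wrapper computing the full metric suite -- overall accuracy,
#' macro F1, ARI and NMI against the true labels, plus rescaled cell-type
#' silhouette and batch entropy mixing on the supplied representation --
#' and recording what each metric was computed on.
#'
#' @param pred predicted per-cell labels.
#' @param truth true per-cell labels.
#' @param representation optional cells x features matrix (e.g. the
#'   cell-type score matrix) for silhouette / entropy mixing.
#' @param batch optional per-cell batch labels for entropy mixing.
#' @param n_regions,region_size,seed region sampler settings for
#'   [batch_entropy_mixing()].
#' @return A \code{"masi_metrics"} named list; sampler settings and the
#'   representation tag are stored in \code{attr(, "meta")}.
#' @export
evaluate_annotation <- function(pred, truth, representation = NULL,
                                batch = NULL, n_regions = 50,
                                region_size = 100, seed = 0) {
  out <- list(accuracy = overall_accuracy(pred, truth),
              macro_f1 = macro_f1(pred, truth),
              ari = ari(pred, truth),
              nmi = nmi(pred, truth))
  if (!is.null(representation)) {
    out$silhouette <- celltype_silhouette(representation, truth)
    if (!is.null(batch))
      out$entropy_mixing <- batch_entropy_mixing(representation, batch,
                                                 n_regions = n_regions,
                                                 region_size = region_size,
                                                 seed = seed)
  }
  attr(out, "meta") <- list(representation = if (is.null(representation))
    NA_character_ else "supplied",
    n_regions = n_regions, region_size = region_size, seed = seed,
    entropy_normalized = TRUE)
  class(out) <- "masi_metrics"
  out
}

#' @exportS3Method print masi_metrics
print.masi_metrics <- function(x, ...) {
  cat("masi_metrics:\n")
  for (nm in names(x)) cat(sprintf("  %-15s %.4f\n", nm, x[[nm]]))
  invisible(x)
}
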