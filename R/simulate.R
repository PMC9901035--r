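#' Simulate multi-batch scRNA-seq counts with known cell types
#'
#' Generates UMI-like count data from a negative-binomial model with
#' cell-type-specific marker elevation and batch-specific multiplicative
#' distortions, providing ground truth for every stage of the annotation
#' chain. Gene g in a cell of type t and batch b has counts
#' \code{NB(mu = base_mean * f^[g is marker of t] * b(batch, g),
#' size = 1 / nb_dispersion)} with \code{ln b(batch, g) ~ N(0, sigma_b^2)}
#' drawn once per (batch, gene). Marker sets are disjoint across types by
#' default; an \code{overlap} knob shares a leading fraction of each type's
#' markers with the next type to stress the rank-discount weighting.
#' Optional i.i.d. dropout zeroes entries. Deterministic given the seed.
#'
#' @param n_types number of cell types.
#' @param n_cells_per_type_per_batch cells per type in each batch.
#' @param n_batches number of batches.
#' @param n_genes total genes (>= n_types * n_markers_per_type).
#' @param n_markers_per_type marker genes elevated per type.
#' @param fold_change marker elevation factor f (>= 1; 1 = no signal).
#' @param base_mean baseline NB mean per gene.
#' @param nb_dispersion NB dispersion (size = 1/dispersion).
#' @param batch_effect_sd sigma_b, SD of the log-normal batch factor.
#' @param dropout_rate extra i.i.d. dropout probability in [0, 1).
#' @param overlap fraction of each type's markers shared with the next type.
#' @param seed integer seed.
#' @return List with \code{expr} (a counts-layer \code{"masi_expr"} with
#'   batch labels) and \code{truth} (list: \code{cell_type}, \code{batch}
#'   per cell; \code{marker_of} per gene, NA for non-markers).
#' @export
simulate_multibatch <- function(n_types = 5, n_cells_per_type_per_batch = 300,
                                n_batches = 3, n_genes = 1000,
                                n_markers_per_type = 20, fold_change = 4,
                                base_mean = 0.5, nb_dispersion = 0.5,
                                batch_effect_sd = 1, dropout_rate = 0,
                                overlap = 0, seed = 0) {
  if (n_markers_per_type * n_types > n_genes)
    stop("n_markers_per_type * n_types must not exceed n_genes")
  if (fold_change < 1) stop("fold_change must be >= 1")
  if (!(dropout_rate >= 0 && dropout_rate < 1))
    stop("dropout_rate must lie in [0, 1)")
  if (!(overlap >= 0 && overlap < 1)) stop("overlap must lie in [0, 1)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))

  types <- paste0("type", seq_len(n_types))
  batches <- paste0("batch", seq_len(n_batches))
  genes <- sprintf("gene%04d", seq_len(n_genes))
  marker_of <- rep(NA_character_, n_genes)
  marker_sets <- list()
  for (t in seq_len(n_types)) {
    idx <- ((t - 1) * n_markers_per_type + 1):(t * n_markers_per_type)
    marker_of[idx] <- types[t]
    marker_sets[[types[t]]] <- idx
  }
  if (overlap > 0) {
    n_shared <- floor(overlap * n_markers_per_type)
    for (t in seq_len(n_types)) {
      nxt <- if (t == n_types) 1 else t + 1
      marker_sets[[types[t]]] <-
        unique(c(marker_sets[[types[t]]],
                 utils::head(marker_sets[[types[nxt]]], n_shared)))
    }
  }

  cell_type <- rep(rep(types, each = n_cells_per_type_per_batch), n_batches)
  batch <- rep(batches, each = n_types * n_cells_per_type_per_batch)
  n_cells <- length(cell_type)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))

  # batch x gene multiplicative distortion, drawn once
  bfac <- matrix(exp(stats::rnorm(n_batches * n_genes, 0, batch_effect_sd)),
                 n_batches, n_genes, dimnames = list(batches, genes))
  counts <- matrix(0L, n_cells, n_genes, dimnames = list(cell_ids, genes))
  size <- 1 / nb_dispersion
  for (b in seq_len(n_batches)) {
    rows <- which(batch == batches[b])
    mu_gene <- base_mean * bfac[b, ]                  # per-gene baseline
    for (t in seq_len(n_types)) {
      r <- rows[cell_type[rows] == types[t]]
      mu <- mu_gene
      mu[marker_sets[[types[t]]]] <- mu[marker_sets[[types[t]]]] * fold_change
      counts[r, ] <- matrix(stats::rnbinom(length(r) * n_genes, mu = rep(
        mu, each = length(r)), size = size), length(r), n_genes)
    }
  }
  if (dropout_rate > 0) {
    drop <- matrix(stats::runif(n_cells * n_genes) < dropout_rate,
                   n_cells, n_genes)
    counts[drop] <- 0L
  }
  # guard: log-normalization requires positive totals
  empty <- rowSums(counts) == 0
  if (any(empty)) counts[empty, 1] <- 1L

  expr <- masi_expr(counts, cell_ids = cell_ids, gene_ids = genes,
                    batch = batch, layer = "counts")
  truth <- list(cell_type = stats::setNames(cell_type, cell_ids),
                batch = stats::setNames(batch, cell_ids),
                marker_of = stats::setNames(marker_of, genes))
  list(expr = expr, truth = truth)
}

#' Hold one cell type out of the reference
#'
#' Builds the unseen-cell-type experiment: the reference excludes every cell
#' of \code{held_type} while the query keeps the full dataset, so the query
#' contains a type the reference has never seen.
#'
#' @param expr a \code{"masi_expr"}.
#' @param truth ground truth from [simulate_multibatch()] (or any list with
#'   a per-cell \code{cell_type}).
#' @param held_type cell type to exclude from the reference.
#' @return List with \code{reference} (expr subset), \code{reference_labels},
#'   \code{query} (= \code{expr}), \code{query_labels}.
#' @export
hold_out_reference <- function(expr, truth, held_type) {
  stopifnot(inherits(expr, "masi_expr"))
  labels <- truth$cell_type[expr$cell_ids]
  if (!held_type %in% labels)
    stop("unknown cell type: ", held_type)
  keep <- which(labels != held_type)
  list(reference = expr[keep, ],
       reference_labels = labels[keep],
       query = expr,
       query_labels = labels)
}
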