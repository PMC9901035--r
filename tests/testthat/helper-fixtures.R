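# Shared fixtures and independent brute-force oracles.

# Wrap a plain matrix as a log-normalized expression object.
lognorm_expr <- function(mat, batch = NULL) {
  masi_expr(mat, batch = batch, layer = "lognorm")
}

# Hand-built ranked DE result (one method) from ordered gene lists.
make_ranked <- function(method, types) {
  types <- lapply(types, function(df) {
    if (is.character(df))
      df <- data.frame(gene = df, score = rev(seq_along(df)), p = NA_real_,
                       stringsAsFactors = FALSE)
    df
  })
  structure(list(method = method, types = types), class = "masi_ranked")
}

# Small multi-type expression fixture with disjoint one-hot marker blocks:
# cells of type t express exactly that type's marker genes at `value`.
onehot_fixture <- function(n_types = 3, cells_per_type = 4,
                           markers_per_type = 2, value = 2) {
  n_cells <- n_types * cells_per_type
  n_genes <- n_types * markers_per_type
  m <- matrix(0, n_cells, n_genes,
              dimnames = list(sprintf("c%02d", seq_len(n_cells)),
                              sprintf("g%02d", seq_len(n_genes))))
  labels <- rep(paste0("T", seq_len(n_types)), each = cells_per_type)
  for (t in seq_len(n_types)) {
    rows <- which(labels == paste0("T", t))
    cols <- ((t - 1) * markers_per_type + 1):(t * markers_per_type)
    m[rows, cols] <- value
  }
  list(expr = lognorm_expr(m), labels = stats::setNames(labels, rownames(m)),
       markers = masi_markers(split(colnames(m),
                                    rep(paste0("T", seq_len(n_types)),
                                        each = markers_per_type))))
}

# Brute-force ARI by pair enumeration (no contingency shortcut).
brute_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  total <- n11 + n00 + n10 + n01
  exp_idx <- (n11 + n10) * (n11 + n01) / total
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == exp_idx) return(1)
  (n11 - exp_idx) / (max_idx - exp_idx)
}

# Brute-force NMI from cell-by-cell joint counts.
brute_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  joint <- outer(ua, ub, Vectorize(function(x, y) sum(a == x & b == y))) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  mi <- 0
  for (i in seq_along(ua)) for (j in seq_along(ub))
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log(joint[i, j] / (pa[i] * pb[j]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (sqrt(ha * hb) == 0) return(0)
  mi / sqrt(ha * hb)
}

# Brute-force single-run cluster->label majority mapping (ties by mean score).
brute_consensus_single <- function(label1, part, scores) {
  out <- label1
  for (cl in unique(part)) {
    cells <- names(label1)[part == cl]
    tab <- table(label1[cells])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      ms <- vapply(top, function(ct) mean(scores[cells, ct]), numeric(1))
      top <- top[which.max(ms)]
    }
    out[cells] <- top
  }
  out
}
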