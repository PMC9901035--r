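test_that("argmax labelling breaks ties by column order and flags them", {
  s <- rbind(c1 = c(A = 3, B = 1), c2 = c(A = 2, B = 2), c3 = c(A = 0, B = 0))
  l1 <- label1_argmax(s)
  expect_identical(unname(l1$label), c("A", "A", "A"))
  expect_identical(unname(l1$tie_flag), c(FALSE, TRUE, TRUE))
})

test_that("over-clustering yields the full 9-run grid, deterministic, order-invariant", {
  set.seed(10)
  blob <- function(center, n) sweep(matrix(rnorm(n * 3, sd = 0.05), n, 3),
                                    2, center, "+")
  s <- abs(rbind(blob(c(5, 0, 0), 30), blob(c(0, 5, 0), 30)))
  rownames(s) <- sprintf("c%02d", 1:60)
  colnames(s) <- c("A", "B", "C")
  ens <- overcluster(s, seed = 4)
  expect_length(ens$runs, 9)
  for (r in ens$runs) expect_length(r$labels, 60)
  # no cluster spans the two far-separated blobs
  half <- rep(1:2, each = 30)
  for (r in ens$runs)
    expect_true(all(vapply(split(half, r$labels),
                           function(h) length(unique(h)) == 1, logical(1))))
  ens2 <- overcluster(s, seed = 4)
  expect_identical(ens, ens2)
  # permuting the cells permutes the partitions identically
  perm <- sample(60)
  ens3 <- overcluster(s[perm, ], seed = 4)
  for (j in 1:9)
    expect_identical(ens3$runs[[j]]$labels[rownames(s)], ens$runs[[j]]$labels)
  expect_error(overcluster(s[1:10, ], seed = 1), "at least")
})

test_that("cluster-to-label mapping matches the hand-worked majority vote", {
  labs <- stats::setNames(c("A", "A", "B", "B", "B", "B"), paste0("c", 1:6))
  s <- matrix(0.5, 6, 2, dimnames = list(paste0("c", 1:6), c("A", "B")))
  ens <- structure(list(runs = list(list(resolution = 1, n_neighbors = 2,
                                         labels = stats::setNames(
                                           c(0, 0, 0, 1, 1, 1),
                                           paste0("c", 1:6))))),
                   class = "masi_ensemble")
  cons <- maca_consensus(labs, ens, s)
  expect_identical(unname(cons$label), c("A", "A", "A", "B", "B", "B"))
})

test_that("single-run consensus equals the brute-force majority oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    ids <- sprintf("c%03d", seq_len(n))
    types <- c("A", "B", "C")
    s <- matrix(runif(n * 3), n, 3, dimnames = list(ids, types))
    labs <- stats::setNames(types[max.col(s)], ids)
    part <- stats::setNames(sample(1:4, n, replace = TRUE), ids)
    ens <- structure(list(runs = list(list(resolution = 1, n_neighbors = 2,
                                           labels = part))),
                     class = "masi_ensemble")
    cons <- maca_consensus(labs, ens, s)
    expect_identical(cons$label, brute_consensus_single(labs, part, s))
  }
})

test_that("identical runs leave the consensus unchanged (idempotence)", {
  labs <- stats::setNames(c("A", "A", "B", "B"), paste0("c", 1:4))
  s <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2,
              dimnames = list(paste0("c", 1:4), c("A", "B")))
  part <- stats::setNames(c(1, 1, 2, 2), paste0("c", 1:4))
  run <- list(resolution = 1, n_neighbors = 2, labels = part)
  one <- structure(list(runs = list(run)), class = "masi_ensemble")
  three <- structure(list(runs = list(run, run, run)), class = "masi_ensemble")
  expect_identical(maca_consensus(labs, one, s)$label,
                   maca_consensus(labs, three, s)$label)
})

test_that("certainty score follows the centroid-distance contrast", {
  cen <- rbind(A = c(1, 0), B = c(0, 1), C = c(-1, 0))
  colnames(cen) <- c("d1", "d2")
  expect_equal(certainty_score(c(d1 = 1, d2 = 0), cen), 1)       # at a centroid
  expect_equal(certainty_score(c(d1 = 0, d2 = 0), cen), 0)       # equidistant
  cen2 <- rbind(A = c(0, 0), B = c(5, 0))
  colnames(cen2) <- c("d1", "d2")
  expect_equal(certainty_score(c(d1 = 1, d2 = 0), cen2), 0.75)   # 1 - 1/4
  # invariant to translating cell and centroids together
  shift <- c(3, -2)
  expect_equal(certainty_score(c(d1 = 1, d2 = 0) + shift,
                               sweep(cen, 2, -shift)),
               certainty_score(c(d1 = 1, d2 = 0), cen), tolerance = 1e-12)
  expect_error(certainty_score(c(d1 = 1, d2 = 0), cen2[1, , drop = FALSE]),
               "at least 2")
})

test_that("unassigned thresholding flags only low-certainty cells", {
  ann <- masi_annotation(paste0("c", 1:3), c("A", "B", "C"),
                         certainty = c(0.7, 0.3, 0.56))
  out <- apply_unassigned(ann, 0.55)
  expect_identical(out$label, c("A", "unassigned", "C"))
  expect_identical(apply_unassigned(ann, 0)$label, ann$label)
  expect_error(apply_unassigned(ann, 1.2), "0, 1")
  expect_error(apply_unassigned(masi_annotation("c1", "A"), 0.5),
               "not populated")
})

test_that("block-wise annotation preserves cell order and the one-block identity", {
  sim <- simulate_multibatch(n_types = 3, n_cells_per_type_per_batch = 30,
                             n_batches = 2, n_genes = 150,
                             n_markers_per_type = 8, fold_change = 4,
                             batch_effect_sd = 0.5, seed = 2)
  fit <- masi(sim$expr, sim$truth$cell_type, methods = c("logfc", "cosg"),
              top_k = 8)
  serial <- annotate(log_normalize(sim$expr), fit$markers, seed = 9,
                     centroids = fit$centroids)
  one <- annotate_parallel(log_normalize(sim$expr), fit$markers,
                           n_batches = 1, seed = 9, centroids = fit$centroids)
  expect_identical(one$label, serial$label)
  expect_identical(one$certainty, serial$certainty)
  two <- annotate_parallel(log_normalize(sim$expr), fit$markers,
                           n_batches = 2, seed = 9, centroids = fit$centroids)
  expect_identical(two$cell_id, sim$expr$cell_ids)
  expect_error(annotate_parallel(log_normalize(sim$expr), fit$markers,
                                 n_batches = 1e6), "exceeds")
})
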