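test_that("overall accuracy is the plain match rate", {
  expect_equal(overall_accuracy(c("A", "A", "B", "C"), c("A", "A", "B", "B")),
               0.75)
  expect_equal(overall_accuracy(letters[1:5], letters[1:5]), 1)
  expect_equal(overall_accuracy(rep("x", 4), rep("y", 4)), 0)
  expect_error(overall_accuracy("a", c("a", "b")), "length")
})

test_that("macro F1 averages per-type F1 without class weights", {
  expect_equal(macro_f1(c("A", "A", "B", "A"), c("A", "A", "B", "B")), 11 / 15,
               tolerance = 1e-12)
  expect_equal(macro_f1(c("A", "B"), c("A", "B")), 1)
  # a truth class never predicted contributes F1 = 0
  expect_equal(macro_f1(c("A", "A", "A", "A"), c("A", "A", "B", "B")),
               mean(c(2 * 2 / (4 + 2), 0)), tolerance = 1e-12)
})

test_that("silhouette rescaling maps perfect separation to 1 and shuffles near 0.5", {
  x <- rbind(matrix(0, 10, 2), matrix(5, 10, 2)) + 0
  labs <- rep(c("A", "B"), each = 10)
  expect_equal(celltype_silhouette(x, labs), 1, tolerance = 1e-9)
  set.seed(8)
  y <- matrix(rnorm(200), 100, 2)
  rand <- sample(c("A", "B"), 100, replace = TRUE)
  expect_lt(abs(celltype_silhouette(y, rand) - 0.5), 0.1)
  expect_error(celltype_silhouette(x, rep("A", 20)), "two distinct")
})

test_that("regional batch entropy: point masses, exact halves, uniform limit", {
  # two spatially separated single-batch blocks: every region is pure
  coords <- rbind(cbind(1:50 / 1000, 0), cbind(100 + 1:50 / 1000, 0))
  batches <- rep(c("b1", "b2"), each = 50)
  expect_equal(batch_entropy_mixing(NULL, batches, n_regions = 20,
                                    region_size = 40, seed = 1,
                                    coords = coords), 0)
  # perfectly interleaved batches: every region is a 50/50 mix
  coords2 <- cbind(seq_len(100) / 100, 0)
  batches2 <- rep(c("b1", "b2"), 50)
  expect_equal(batch_entropy_mixing(NULL, batches2, n_regions = 10,
                                    region_size = 10, seed = 1,
                                    coords = coords2), 1, tolerance = 1e-12)
  # i.i.d. uniform batches, large regions: near the maximum-entropy limit
  set.seed(12)
  coords3 <- matrix(rnorm(400), 200, 2)
  batches3 <- sample(c("b1", "b2"), 200, replace = TRUE)
  val <- batch_entropy_mixing(NULL, batches3, n_regions = 30,
                              region_size = 150, seed = 2, coords = coords3)
  expect_gt(val, 0.95)
  expect_error(batch_entropy_mixing(NULL, batches3, region_size = 300,
                                    coords = coords3), "region_size")
})

test_that("interleaving batch blocks never decreases entropy mixing", {
  coords <- cbind(seq_len(120) / 10, 0)
  blocked <- rep(c("b1", "b2"), each = 60)
  interleaved <- rep(c("b1", "b2"), 60)
  eb <- batch_entropy_mixing(NULL, blocked, n_regions = 25, region_size = 20,
                             seed = 3, coords = coords)
  ei <- batch_entropy_mixing(NULL, interleaved, n_regions = 25,
                             region_size = 20, seed = 3, coords = coords)
  expect_gte(ei, eb)
})

test_that("the UMAP path produces a score in [0, 1] deterministically", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40 * 3), 40, 3), matrix(rnorm(40 * 3, 4), 40, 3))
  b <- rep(c("b1", "b2"), 40)
  v1 <- batch_entropy_mixing(x, b, n_regions = 10, region_size = 20, seed = 6)
  v2 <- batch_entropy_mixing(x, b, n_regions = 10, region_size = 20, seed = 6)
  expect_identical(v1, v2)
  expect_gte(v1, 0); expect_lte(v1, 1)
})

test_that("ARI and NMI: identity, bijective relabelling, hand example", {
  a <- c(0, 0, 1, 1); b <- c(0, 0, 0, 1)
  expect_equal(ari(a, a), 1)
  expect_equal(nmi(a, a), 1)
  expect_equal(ari(a, c("x", "x", "y", "y")), 1)
  expect_equal(nmi(a, c("x", "x", "y", "y")), 1)
  expect_equal(ari(a, b), brute_ari(a, b), tolerance = 1e-12)
  expect_equal(nmi(a, b), brute_nmi(a, b), tolerance = 1e-12)
})

test_that("ARI agrees with an established independent implementation", {
  set.seed(19)
  for (rep in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to simultaneous cell permutation", {
  set.seed(30)
  pred <- sample(c("A", "B", "C"), 40, replace = TRUE)
  truth <- sample(c("A", "B", "C"), 40, replace = TRUE)
  perm <- sample(40)
  expect_equal(overall_accuracy(pred[perm], truth[perm]),
               overall_accuracy(pred, truth))
  expect_equal(macro_f1(pred[perm], truth[perm]), macro_f1(pred, truth))
  expect_equal(ari(pred[perm], truth[perm]), ari(pred, truth))
  expect_equal(nmi(pred[perm], truth[perm]), nmi(pred, truth))
})

test_that("the report wrapper assembles all metrics with sampler metadata", {
  fx <- onehot_fixture(n_types = 2, cells_per_type = 10, markers_per_type = 2)
  s <- score_cells(fx$expr, fx$markers, mode = "raw")
  rep <- evaluate_annotation(fx$labels, fx$labels, representation = s,
                             batch = rep(c("b1", "b2"), 10),
                             n_regions = 5, region_size = 10, seed = 1)
  expect_named(rep, c("accuracy", "macro_f1", "ari", "nmi", "silhouette",
                      "entropy_mixing"))
  expect_equal(rep$accuracy, 1)
  expect_identical(attr(rep, "meta")$n_regions, 5)
})
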