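test_that("a perfect marker ranks first under every DE score", {
  fx <- onehot_fixture(n_types = 2, cells_per_type = 5, markers_per_type = 1,
                       value = 5)
  for (m in c("wilcoxon", "welch_t", "logfc", "cosg")) {
    r <- rank_genes(fx$expr, fx$labels, method = m)
    expect_identical(r$types$T1$gene[1], "g01")
    expect_identical(r$types$T2$gene[1], "g02")
  }
})

test_that("wilcoxon uses exact enumeration for tiny groups", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1, dimnames = list(paste0("c", 1:6), "g1"))
  e <- lognorm_expr(m)
  labels <- rep(c("A", "B"), each = 3)
  r <- rank_genes(e, labels, method = "wilcoxon")
  # {1,2,3} vs {4,5,6}: 2 of the 20 orderings are as extreme, two-sided
  expect_equal(r$types$A$p[1], 0.1, tolerance = 1e-12)
  expect_equal(r$types$B$p[1], 0.1, tolerance = 1e-12)
})

test_that("wilcoxon normal approximation matches wilcox.test with ties", {
  set.seed(3)
  m <- matrix(round(rexp(40 * 6), 1), 40, 6,
              dimnames = list(paste0("c", 1:40), paste0("g", 1:6)))
  labels <- rep(c("A", "B"), each = 20)
  r <- rank_genes(lognorm_expr(m), labels, method = "wilcoxon")
  for (g in paste0("g", 1:6)) {
    ref <- stats::wilcox.test(m[labels == "A", g], m[labels == "B", g],
                              exact = FALSE, correct = FALSE)$p.value
    row <- r$types$A[r$types$A$gene == g, ]
    expect_equal(2 * stats::pnorm(-abs(row$score)), ref, tolerance = 1e-10)
  }
})

test_that("logfc scores equal mean differences and break ties by gene id", {
  m <- matrix(c(1, 1, 1, 1,   2, 2, 0, 0,   0, 0, 2, 2), 4, 3,
              dimnames = list(paste0("c", 1:4), c("gB", "gA", "gC")))
  r <- rank_genes(lognorm_expr(m), rep(c("X", "Y"), each = 2),
                  method = "logfc")
  x <- r$types$X
  expect_equal(x$score[x$gene == "gB"], 0)          # equal group means
  expect_identical(x$gene[1], "gA")                 # positive score first
  expect_true(which(x$gene == "gB") > 1)
  # tie at score 0 between gB and nothing else here; check lexicographic order
  m2 <- cbind(m, gAA = c(1, 1, 1, 1))
  r2 <- rank_genes(lognorm_expr(m2), rep(c("X", "Y"), each = 2),
                   method = "logfc")
  tied <- r2$types$X$gene[r2$types$X$score == 0]
  expect_identical(tied, sort(tied))
})

test_that("RRA rho matches closed-form Beta order statistics", {
  # single list: Beta(1,1) CDF is the identity, rho preserves order
  expect_equal(masir:::rra_rho(0.37), 0.37, tolerance = 1e-12)
  # m = 2, both normalized ranks 0.25
  expect_equal(masir:::rra_rho(c(0.25, 0.25)),
               min(pbeta(0.25, 1, 2), pbeta(0.25, 2, 1)), tolerance = 1e-12)
  expect_equal(masir:::rra_rho(c(0.25, 0.25)), 0.0625, tolerance = 1e-12)
})

test_that("single-method RRA reproduces the input order; short lists need no padding", {
  r1 <- make_ranked("m1", list(A = c("g3", "g1", "g2")))
  tab <- aggregate_rra(list(r1), top_k = 20)      # top_k > list length
  expect_identical(tab$markers$A, c("g3", "g1", "g2"))
  expect_equal(tab$weights$A[["g3"]], 1)
  tab2 <- aggregate_rra(list(r1), top_k = 2)
  expect_identical(tab2$markers$A, c("g3", "g1"))
})

test_that("RRA is invariant to method order and promotes unanimity", {
  r1 <- make_ranked("m1", list(A = c("g1", "g2", "g3", "g4")))
  r2 <- make_ranked("m2", list(A = c("g1", "g4", "g2", "g3")))
  ab <- aggregate_rra(list(r1, r2), top_k = 3)
  ba <- aggregate_rra(list(r2, r1), top_k = 3)
  expect_identical(ab$markers, ba$markers)
  expect_identical(ab$markers$A[1], "g1")          # first everywhere
  expect_error(aggregate_rra(list(r1, make_ranked("m2", list(B = "g1")))),
               "differ")
})

test_that("Lancaster combination: identity, Fisher closed form, boundaries", {
  expect_equal(masir:::lancaster_p(0.2, 2), 0.2, tolerance = 1e-12)
  expect_equal(masir:::lancaster_p(c(0.1, 0.1), c(2, 2)),
               pchisq(-2 * (log(0.1) + log(0.1)), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(masir:::lancaster_p(c(0.1, 0.1), c(2, 2)), 0.056052,
               tolerance = 1e-4)
  expect_equal(masir:::lancaster_p(c(1, 1, 1), c(2, 2, 2)), 1)
})

test_that("Lancaster aggregation keeps significant genes, drops score-only methods", {
  ps <- c(g1 = 1e-6, g2 = 0.5, g3 = 1e-4)
  mk <- function(method, p) make_ranked(method, list(
    A = data.frame(gene = names(ps), score = -log(p), p = p,
                   stringsAsFactors = FALSE)))
  r1 <- mk("wilcoxon", ps)
  r2 <- mk("welch_t", ps * 2)
  tab <- aggregate_lancaster(list(r1, r2), alpha = 0.05)
  expect_identical(tab$markers$A, c("g1", "g3"))   # ascending combined p
  expect_warning(
    tab2 <- aggregate_lancaster(list(r1, make_ranked("logfc", list(
      A = data.frame(gene = names(ps), score = 1:3, p = NA_real_)))),
      alpha = 0.05),
    "score-only")
  expect_identical(tab2$markers$A, c("g1", "g3"))
  expect_error(suppressWarnings(aggregate_lancaster(list(
    make_ranked("logfc", list(A = data.frame(gene = "g", score = 1,
                                             p = NA_real_)))))),
    "no p-value")
})

test_that("unanimous top genes lead both aggregation schemes", {
  ps1 <- c(g1 = 1e-8, g2 = 0.01, g3 = 0.2, g4 = 0.9)
  ps2 <- c(g1 = 1e-7, g2 = 0.03, g3 = 0.4, g4 = 0.8)
  mk <- function(method, p) make_ranked(method, list(
    A = data.frame(gene = names(sort(p)), score = -log(sort(p)),
                   p = sort(p), stringsAsFactors = FALSE)))
  rs <- list(mk("a", ps1), mk("b", ps2))
  expect_identical(aggregate_rra(rs, top_k = 4)$markers$A[1], "g1")
  expect_identical(aggregate_lancaster(rs, alpha = 0.05)$markers$A[1], "g1")
})

test_that("rank-discount weights hit 100%/75%/50% and decrease within [0.5, 1]", {
  tab <- assign_weights(masi_markers(list(A = paste0("g", 1:10))))
  w <- tab$weights$A
  expect_identical(unname(w[1]), 1)
  expect_equal(unname(w[5]), 0.75, tolerance = 1e-12)
  expect_equal(unname(w[10]), 0.5, tolerance = 1e-12)
  for (n in c(1, 2, 7, 20, 100)) {
    w <- assign_weights(masi_markers(list(A = paste0("g", seq_len(n)))))$weights$A
    expect_identical(unname(w[1]), 1)
    if (n >= 2) {
      expect_equal(unname(w[n]), 0.5, tolerance = 1e-12)
      expect_true(all(diff(w[-1]) < 0))
    }
    expect_true(all(w >= 0.5 & w <= 1))
  }
})
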