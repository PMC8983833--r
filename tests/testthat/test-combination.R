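# Labels, predictor importance, p-value transform, meta-analysis
# combination and the priority rating.

test_that("label assembly applies the phase threshold and seeded control draw", {
  dt <- data.frame(gene = c("A", "B", "C"), drug = c("d1", "d2", "d3"),
                   max_phase = c(1L, 2L, 4L), mechanism = "m", indication = "i")
  universe <- c(LETTERS[1:10], sprintf("g%03d", 1:990))
  ls1 <- assemble_labels(dt, universe, control_ratio = 10L, seed = 3L)
  expect_setequal(ls1$positives, c("B", "C"))
  expect_length(ls1$controls, 20L)
  expect_length(intersect(ls1$positives, ls1$controls), 0L)
  ls2 <- assemble_labels(dt, universe, control_ratio = 10L, seed = 3L)
  expect_identical(ls1$controls, ls2$controls)
  expect_error(assemble_labels(dt, c("B", "C", "X"), control_ratio = 10L),
               "universe too small")
})

test_that("permutation importance finds a perfect feature and ignores noise", {
  withr::with_seed(202, {
    n <- 500L
    genes <- sprintf("g%03d", seq_len(n))
    y <- rbinom(n, 1, 0.3)
    M <- cbind(nGene = runif(n),
               perfect = y + rnorm(n, 0, 0.01),
               noise = runif(n))
    rownames(M) <- genes
    labels <- structure(list(positives = genes[y == 1], controls = genes[y == 0]),
                        class = "label_set")
    imp <- predictor_importance(M, labels, n_trees = 500L, seed = 9L)
    vals <- setNames(imp$importance, imp$predictor)
    expect_gt(vals["perfect"], vals["nGene"])
    expect_gt(vals["perfect"], vals["noise"])
    expect_lt(abs(vals["noise"]), 0.02)

    # permuting rows together with labels leaves importances unchanged
    perm <- sample(n)
    M2 <- M[perm, , drop = FALSE]
    imp2 <- predictor_importance(M2, labels, n_trees = 500L, seed = 9L)
    expect_equal(imp2$importance, imp$importance, tolerance = 1e-12)
  })
})

test_that("a constant predictor column gets zero importance with a warning", {
  withr::with_seed(5, {
    genes <- sprintf("g%02d", 1:60)
    M <- cbind(nGene = runif(60), flat = rep(0.5, 60))
    rownames(M) <- genes
    labels <- structure(list(positives = genes[1:10], controls = genes[11:60]),
                        class = "label_set")
    expect_warning(imp <- predictor_importance(M, labels, n_trees = 100L),
                   "constant")
    expect_equal(imp$importance[imp$predictor == "flat"], 0)
  })
})

test_that("informative-predictor selection keeps the baseline and applies >=", {
  imp <- data.frame(predictor = c("nGene", "cA", "eB"),
                    importance = c(0.05, 0.06, 0.01))
  attr(imp, "baseline") <- "nGene"
  expect_setequal(select_informative(imp), c("nGene", "cA"))

  imp$importance <- c(0.05, 0.01, 0.02)
  expect_identical(select_informative(imp), "nGene")

  imp$importance <- c(0.05, 0.05, 0.01)   # tie kept: "no less important"
  expect_setequal(select_informative(imp), c("nGene", "cA"))
})

test_that("affinity-to-p transform is the descending rank over N", {
  M <- matrix(c(0.5, 0.3, 0.2), ncol = 1, dimnames = list(c("a", "b", "c"), "x"))
  P <- affinity_to_pvalues(M)
  expect_equal(unname(P[, 1]), c(1, 2, 3) / 3)

  M2 <- matrix(c(4, 4, 2, 1), ncol = 1, dimnames = list(letters[1:4], "x"))
  P2 <- affinity_to_pvalues(M2)
  expect_equal(unname(P2[c("a", "b"), 1]), c(1.5, 1.5) / 4)

  M3 <- matrix(c(2, 1, 0, 0), ncol = 1, dimnames = list(letters[1:4], "x"))
  expect_equal(unname(affinity_to_pvalues(M3)[c("c", "d"), 1]), c(1, 1))

  expect_error(affinity_to_pvalues(matrix(1, 3, 1)), "constant")

  # shuffled distinct affinities give p uniform on the i/N grid
  withr::with_seed(8, {
    M4 <- matrix(sample(seq(0.01, 1, length.out = 50)), ncol = 1,
                 dimnames = list(sprintf("g%02d", 1:50), "x"))
    expect_setequal(affinity_to_pvalues(M4)[, 1], (1:50) / 50)
  })
})

test_that("Fisher and logistic match their closed-form references", {
  # frozen reference values computed from the chi-squared / Student-t forms
  expect_equal(fisher_combine(0.5), 0.5, tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.1, 0.1)), 0.0560517018599, tolerance = 1e-10)
  expect_equal(fisher_combine(c(0.01, 0.2, 0.8)), 0.0450561196825, tolerance = 1e-10)
  expect_equal(logistic_combine(0.5), 0.5, tolerance = 1e-10)
  expect_equal(logistic_combine(c(0.01, 0.2, 0.8)), 0.0692608987295, tolerance = 1e-10)
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
})

test_that("order-statistic Q matches the joint order-statistic CDF", {
  expect_equal(orderstat_q(0.2), 0.2)              # k = 1: Q = r1
  expect_equal(orderstat_q(c(0.5, 0.2)), 0.16)     # sorted (0.2, 0.5): 2!(r2 r1 - r1^2/2)
  # against Monte-Carlo joint CDF at a second point
  withr::with_seed(33, {
    U <- matrix(runif(4e5), ncol = 2)
    R <- cbind(pmin(U[, 1], U[, 2]), pmax(U[, 1], U[, 2]))
    r <- c(0.3, 0.7)
    expect_equal(orderstat_q(r), mean(R[, 1] <= r[1] & R[, 2] <= r[2]),
                 tolerance = 0.01)
  })
})

test_that("meta combiners are calibrated under the uniform null", {
  withr::with_seed(44, {
    U <- matrix(runif(3 * 4000), ncol = 3)
    for (f in list(fisher_combine, logistic_combine)) {
      p <- f(U)
      D <- suppressWarnings(ks.test(p, "punif")$statistic)
      expect_lt(D, 0.03)
    }
    p <- orderstat_combine(U, n_null = 50000L, seed = 99L)
    D <- suppressWarnings(ks.test(p, "punif")$statistic)
    expect_lt(D, 0.03)
  })
})

test_that("all combination strategies are monotone in a single predictor", {
  base <- c(0.4, 0.5, 0.6)
  better <- c(0.1, 0.5, 0.6)
  for (m in c("fisher", "logistic", "orderstat")) {
    s0 <- combine_predictors(matrix(base, 1, dimnames = list("g", NULL)), m)$combined_score
    s1 <- combine_predictors(matrix(better, 1, dimnames = list("g", NULL)), m)$combined_score
    expect_gte(s1, s0)
  }
  A0 <- matrix(c(0.2, 0.3, 0.1), 1, dimnames = list("g", NULL))
  A1 <- matrix(c(0.5, 0.3, 0.1), 1, dimnames = list("g", NULL))
  for (m in c("sum", "max", "harmonic")) {
    expect_gte(combine_predictors(A1, m)$combined_score,
               combine_predictors(A0, m)$combined_score)
  }
})

test_that("harmonic sum weights sorted scores by 1/i^2", {
  A <- matrix(c(0.1, 0.4, 0.2), 1, dimnames = list("g", NULL))
  want <- 0.4 / 1 + 0.2 / 4 + 0.1 / 9
  expect_equal(combine_predictors(A, "harmonic")$combined_score, want)
})

test_that("priority rating is min-max on [0,5] with lexicographic tie ranks", {
  pt <- rate_genes(c(x = 10, y = 5, z = 0))
  expect_equal(pt$rating, c(5, 2.5, 0))
  expect_equal(pt$rank, 1:3)
  expect_equal(pt$percentile, c(1, 2, 3) / 3 * 100)

  tie <- rate_genes(c(B = 7, A = 7, C = 1))
  expect_identical(tie$gene[1:2], c("A", "B"))
  expect_error(rate_genes(c(a = 1, b = 1)), "equal")

  withr::with_seed(21, {
    sc <- setNames(rnorm(2000), sprintf("g%04d", 1:2000))
    pt2 <- rate_genes(sc)
    expect_length(top_fraction(pt2, 0.05), 100L)
    expect_false(is.unsorted(-pt2$combined_score))
  })
})
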