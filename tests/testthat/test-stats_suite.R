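test_that("K-S statistic and exact small-sample p match enumeration", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)

  disjoint <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disjoint$D, 1)

  a <- c(1, 3); b <- c(2, 4)
  res <- ks_two_sample(a, b)
  expect_equal(res$D, ks_D_stat(a, b))
  expect_equal(res$p_value, enumerate_ks_p(a, b))

  # random small samples, without and with ties
  set.seed(53)
  for (i in 1:10) {
    a <- sample(1:8, sample(3:6, 1), replace = i > 5)
    b <- sample(1:8, sample(3:6, 1), replace = i > 5)
    res <- ks_two_sample(a, b)
    expect_true(res$exact)
    expect_equal(res$D, ks_D_stat(a, b), tolerance = 1e-12)
    expect_equal(res$p_value, enumerate_ks_p(a, b), tolerance = 1e-9,
                 label = sprintf("case %d", i))
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("the K-S statistic is invariant under monotone transforms", {
  set.seed(59)
  for (i in 1:10) {
    a <- rlnorm(30); b <- rlnorm(25, 0.5)
    d1 <- ks_two_sample(a, b)
    d2 <- ks_two_sample(log10(a), log10(b))
    expect_equal(d1$D, d2$D)
    expect_equal(d1$p_value, d2$p_value)
    expect_true(d1$D >= 0 && d1$D <= 1)
  }
})

test_that("K-S p-values are calibrated under the null", {
  # continuous regime: samples large enough for the asymptotic p
  set.seed(61)
  ps <- vapply(1:1000, function(i) {
    ks_two_sample(rnorm(50), rnorm(50))$p_value
  }, numeric(1))
  expect_gt(mean(ps <= 0.05), 0.02)
  expect_lt(mean(ps <= 0.05), 0.08)
  expect_gt(mean(ps), 0.4)
  # exact small-sample p-values are valid (super-uniform: the discrete
  # null distribution rejects at most at the nominal rate)
  set.seed(62)
  rej <- mean(vapply(1:400, function(i) {
    ks_two_sample(rnorm(10), rnorm(10))$p_value <= 0.05
  }, logical(1)))
  expect_lte(rej, 0.07)
})

test_that("Fisher's exact test matches margin enumeration", {
  expect_equal(fisher_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  tab <- matrix(c(1, 9, 9, 1), 2)
  expect_equal(fisher_2x2(tab), enumerate_fisher_p(tab), tolerance = 1e-12)
  expect_error(fisher_2x2(matrix(c(-1, 2, 3, 4), 2)), "negative")
  expect_error(fisher_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")

  # TE-enrichment-style family: p falls monotonically as the siRNA row
  # drifts below its independence expectation (~26 of 155)
  ps <- vapply(0:25, function(x) {
    fisher_2x2(matrix(c(30, x, 150, 155 - x), 2))
  }, numeric(1))
  expect_true(all(diff(ps) > -1e-12))
})

test_that("ratio analysis partitions pairs, filters targets and runs three K-S tests", {
  set.seed(67)
  n <- 40
  srna <- setNames(c(rlnorm(n, log(50)), rlnorm(n, log(5))),
                   sprintf("m%02d", 1:(2 * n)))
  target <- setNames(rep(rlnorm(n, log(10)), 2), sprintf("t%02d", 1:(2 * n)))
  target[["t01"]] <- 0.005   # below the RPKM floor: excluded
  pairs <- data.frame(srna_id = names(srna), target_id = names(target))
  calls <- data.frame(srna_id = names(srna)[1:n], transcript_id = names(target)[1:n],
                      valid = TRUE)
  res <- ratio_analysis(srna, target, pairs, calls, condition = "light")
  expect_false("t01" %in% res$records$target_id)
  expect_equal(nrow(res$records), 2 * n - 1)
  expect_equal(sort(unique(res$records$degradome_status)), c("minus", "plus"))
  expect_equal(res$records$ratio,
               res$records$srna_abundance / res$records$target_abundance)
  expect_named(res$tests, c("srna", "target", "ratio"))
  # 10x planted sRNA abundance shows up in the sRNA and ratio comparisons
  expect_lt(res$tests$ratio$p_value, 0.01)
  expect_lt(res$tests$srna$p_value, 0.01)

  # an empty stratum drops the comparisons with a warning
  expect_warning(
    empty <- ratio_analysis(srna, target, pairs, calls[0, ], condition = "dark"),
    "stratum")
  expect_length(empty$tests, 0)
})

test_that("fold-change comparison separates shifted groups and rejects tiny ones", {
  set.seed(71)
  ratios <- c(2^rnorm(50, 0, 0.5), 2^rnorm(50, -1, 0.5))
  grouping <- rep(c("minus", "plus"), each = 50)
  res <- fold_change_compare(ratios, grouping)
  expect_lt(res$p_value, 0.01)
  expect_lt(res$mean_plus, res$mean_minus)
  expect_error(fold_change_compare(c(1, 2, 3), c("plus", "minus", "minus")),
               "at least 2")

  # null calibration: matched distributions give a uniform p; 2000
  # simulations keep the Monte Carlo error of the rejection rate below
  # half a percentage point
  set.seed(73)
  rej <- vapply(1:2000, function(i) {
    x <- 2^rnorm(40, 0, 0.5)
    fold_change_compare(x, rep(c("plus", "minus"), 20))$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("profile clustering recovers separated groups and handles degeneracy", {
  set.seed(79)
  blob1 <- matrix(rnorm(25 * 6, 0, 0.2), 25, 6)
  blob2 <- matrix(rnorm(25 * 6, 3, 0.2), 25, 6)
  m <- rbind(blob1, blob2)
  rownames(m) <- sprintf("f%02d", 1:50)
  res <- cluster_profiles(m, k = 2, n_restarts = 10, seed = 3)
  truth <- rep(1:2, each = 25)
  expect_equal(mclust::adjustedRandIndex(res$cluster, truth), 1)
  # deterministic given (seed, restarts)
  res2 <- cluster_profiles(m, k = 2, n_restarts = 10, seed = 3)
  expect_identical(res$cluster, res2$cluster)

  # all-identical profiles collapse to a single centroid with zero inertia
  flat <- matrix(1, 10, 6, dimnames = list(letters[1:10], NULL))
  deg <- cluster_profiles(flat, k = 3)
  expect_equal(deg$k, 1L)
  expect_equal(deg$inertia, 0)
  expect_error(cluster_profiles(m, k = 51), "exceeds")
})

test_that("the packaged light-response table carries 66 anchored profiles", {
  lr <- light_response_profiles()
  expect_equal(dim(lr$log2fc), c(66L, 6L))
  expect_equal(unname(lr$log2fc[, "W0"]), rep(0, 66))
  expect_equal(as.vector(table(lr$cluster)[c("I", "II", "III")]),
               c(1L, 15L, 50L))
  expect_equal(unname(lr$log2fc["miR163", "W24"]), 6.724631)
})
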