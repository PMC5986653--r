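test_that("signed-rank test: forced examples and degenerate input", {
  # 5 pairs, all shifted up: one-sided mass 1/32, doubled
  expect_equal(signed_rank_test(rep(0, 5), 1:5)$p_value, 0.0625)
  expect_warning(res <- signed_rank_test(1:4, 1:4), "all differences")
  expect_equal(res$p_value, 1)
})

test_that("exact signed-rank p equals the sign-pattern enumeration oracle (n <= 12)", {
  set.seed(61)
  for (n in c(1, 2, 3, 5, 8, 12)) {
    for (trial in 1:8) {
      before <- round(runif(n, 0, 10), 1)
      # ties in |d| and zero differences exercised deliberately
      after <- before + sample(c(-2, -1, 0, 1, 1, 2), n, replace = TRUE)
      got <- suppressWarnings(signed_rank_test(before, after))
      expect_equal(got$p_value, signed_rank_enum_p(before, after))
    }
  }
})

test_that("exact signed-rank p matches wilcox.test on tie-free pairs", {
  set.seed(62)
  for (trial in 1:10) {
    n <- sample(4:15, 1)
    before <- rnorm(n)
    after <- before + rnorm(n)
    expect_equal(signed_rank_test(before, after)$p_value,
                 wilcox.test(after, before, paired = TRUE,
                             exact = TRUE)$p.value)
  }
})

test_that("signed-rank detects a planted shift at full binding-site scale", {
  set.seed(63)
  n <- 2723
  before <- rnorm(n, 5, 1)
  after <- before + 0.5  # planted mean shift of 0.5 SD
  expect_lt(signed_rank_test(before, after)$p_value, 0.01)
})

test_that("rank-sum test: complete 5-vs-10 separation gives exactly 2/3003", {
  expect_equal(rank_sum_test(1:5, 6:15)$p_value, 2 / 3003)
  expect_equal(rank_sum_test(rep(3, 4), rep(3, 6))$p_value, 1)
  expect_error(rank_sum_test(numeric(), 1:3), "nonempty")
})

test_that("exact rank-sum p equals the assignment enumeration oracle (n <= 12)", {
  set.seed(64)
  for (n_a in c(1, 2, 3, 5)) for (n_b in c(1, 3, 6)) {
    for (trial in 1:6) {
      a <- sample(1:6, n_a, replace = TRUE)  # heavy ties
      b <- sample(1:6, n_b, replace = TRUE)
      expect_equal(rank_sum_test(a, b)$p_value, rank_sum_enum_p(a, b))
    }
  }
})

test_that("rank-sum p matches wilcox.test exactly (tie-free) and approximately at large n", {
  set.seed(65)
  for (trial in 1:10) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:10, 1))
    expect_equal(rank_sum_test(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
  a <- rnorm(30)
  b <- rnorm(40) + 0.3
  expect_equal(rank_sum_test(a, b)$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
})

test_that("rank tests hold their type-I error under the null", {
  set.seed(66)
  x <- matrix(rnorm(5000 * 15), 5000)
  p <- rank_sum_test_rows(x, 1:5, 6:15)$p_value
  mc <- 3 * sqrt(0.01 * 0.99 / 5000)
  expect_lte(mean(p < 0.01), 0.01 + mc)
  expect_lte(mean(p < 0.005), 0.005 + 3 * sqrt(0.005 * 0.995 / 5000))
})

test_that("BH q values follow the step-up rule", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(67)
  p <- runif(200)
  # reference step-up recomputation
  o <- order(p)
  m <- length(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(bh_fdr(p)[o], pmin(1, q_sorted))
})

test_that("3-SD fold-change rule: forced cases and the single-outlier example", {
  expect_warning(res <- changed_regions_fc_sd(rep(2, 50), rep(4, 50)),
                 "zero spread")
  expect_equal(sum(res$selected), 0)
  # 100 regions with r = 0 plus one with r = 10:
  # m = 10/101, s = sqrt((100*m^2 + (10-m)^2)/100), m + 3s < 10 -> one gain
  control <- rep(0, 101)
  treated <- c(rep(0, 100), 2^10 - 1)
  res <- changed_regions_fc_sd(control, treated, 3, pseudocount = 1)
  m <- 10 / 101
  s <- sqrt((100 * m^2 + (10 - m)^2) / 100)
  expect_equal(attr(res, "center"), m)
  expect_equal(attr(res, "spread"), s)
  expect_equal(sum(res$direction == "gain"), 1)
  expect_equal(sum(res$direction == "loss"), 0)
  expect_equal(which(res$direction == "gain"), 101L)
})

test_that("fold-change calls match brute force, swap to losses, and are scale-equivariant", {
  set.seed(68)
  for (trial in 1:30) {
    n <- 300
    control <- rpois(n, 20) + runif(n)
    treated <- control * 2^rnorm(n, 0, 0.5)
    res <- changed_regions_fc_sd(control, treated, 3, pseudocount = 1)
    expect_equal(res$direction, fc_sd_brute(control, treated, 3, 1))
    swapped <- changed_regions_fc_sd(treated, control, 3, pseudocount = 1)
    expect_equal(res$direction == "gain", swapped$direction == "loss")
    k <- runif(1, 0.1, 10)
    scaled <- changed_regions_fc_sd(k * control, k * treated, 3,
                                    pseudocount = k)
    expect_equal(scaled$direction, res$direction)
  }
})

test_that("median-of-ratios size factors: symmetry, closed form, and the DESeq oracle", {
  raw <- matrix(rpois(200, 50), 100, 2)
  raw[, 2] <- raw[, 1]
  expect_equal(size_factors(raw), c(1, 1), ignore_attr = TRUE)
  raw2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  expect_equal(size_factors(raw2), c(a = 1 / sqrt(2), b = sqrt(2)))
  norm <- sweep(raw2, 2, size_factors(raw2), "/")
  expect_equal(norm[, 1], norm[, 2], ignore_attr = TRUE)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "nonzero")
  set.seed(69)
  m <- matrix(rnbinom(600, mu = 80, size = 10), 100, 6)
  expect_equal(size_factors(m),
               DESeq2::estimateSizeFactorsForMatrix(m),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("NB differential test: null and planted behaviour", {
  raw <- matrix(rep(c(40, 100, 7), each = 6), 3, 6, byrow = TRUE)
  res <- nb_differential_test(raw, rep(c("A", "B"), each = 3))
  expect_equal(res$p_value, rep(1, 3))
  expect_equal(res$log2fc, rep(0, 3))
  expect_error(nb_differential_test(raw, c("A", "B", "B", "B", "B", "B")),
               ">= 2 samples")
  set.seed(70)
  n <- 1000
  planted <- 1:50
  mu <- matrix(100, n, 10)
  mu[planted, 6:10] <- 400  # 4-fold change in the second group
  raw <- matrix(rnbinom(n * 10, mu = mu, size = 1 / 0.05), n, 10)
  res <- nb_differential_test(raw, rep(c("ctl", "hr"), each = 5))
  expect_gte(mean(res$q_value[planted] < 0.01), 0.9)
})

test_that("discriminating-region selection applies the double threshold and direction", {
  res <- data.frame(p_value = rep(1, 5), q_value = rep(1, 5),
                    log2fc = rnorm(5))
  expect_equal(sum(discriminating_regions(res)$selected), 0)
  set.seed(71)
  res <- data.frame(p_value = 10^runif(500, -8, 0))
  res$q_value <- bh_fdr(res$p_value)
  res$log2fc <- rnorm(500)
  th <- differential_thresholds()
  got <- discriminating_regions(res, th, "gain")$selected
  expect_equal(got, res$q_value < 0.01 & res$p_value < 0.0002 & res$log2fc > 0)
  both <- discriminating_regions(res, th, "both")$selected
  loss <- discriminating_regions(res, th, "loss")$selected
  expect_equal(both, got | loss)
})

test_that("threshold constructors validate their bounds", {
  expect_error(differential_thresholds(fdr_max = 0), "\\(0, 1\\]")
  expect_error(differential_thresholds(fc_sd_mult = -1), "> 0")
  expect_silent(differential_thresholds())
})
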