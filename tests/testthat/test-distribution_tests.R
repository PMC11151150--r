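test_that("slope test recovers exact and noisy regressions", {
  x <- c(1, 2, 3, 4, 5)
  res <- suppressWarnings(ols_slope_test(x, x))   # exact fit: se is ~0
  expect_equal(res$slope, 1, tolerance = 1e-12)
  expect_equal(res$t_ratio, 0, tolerance = 1e-8)
  expect_equal(res$df, 3)

  set.seed(91)
  x <- rnorm(200)
  y <- 2 * x + rnorm(200, sd = 0.3)
  res <- ols_slope_test(x, y, null_slope = 1)
  expect_gt(res$t_ratio, 0)
  # normal-equations oracle
  b_or <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(res$slope, b_or, tolerance = 1e-10)
  expect_equal(res$intercept, mean(y) - b_or * mean(x), tolerance = 1e-10)
  expect_error(ols_slope_test(rep(1, 5), rnorm(5)), "constant")
})

test_that("skewness test is zero for symmetric samples and matches the formula chain", {
  sym <- rep(c(-2, -1, 0, 1, 2), 20)
  res <- dagostino_skewness_test(sym)
  expect_equal(res$skew, 0, tolerance = 1e-12)
  expect_equal(res$z, 0, tolerance = 1e-10)

  set.seed(92)
  for (rep in 1:10) {
    x <- exp(rnorm(sample(30:300, 1)))
    res <- dagostino_skewness_test(x)
    oracle <- brute_skewness_z(x)
    expect_equal(res$skew, oracle$skew, tolerance = 1e-10)
    expect_equal(res$z, oracle$z, tolerance = 1e-10)
  }
  expect_error(dagostino_skewness_test(rep(1, 20)), "constant")
  expect_error(dagostino_skewness_test(rnorm(5)), "n >= 9")
})

test_that("ECDF is a right-continuous step reaching one", {
  tab <- ecdf_table(c(1, 2, 3))
  expect_equal(tab$cumfrac[tab$support == 2], 2 / 3)
  expect_equal(tab$cumfrac[nrow(tab)], 1)
  set.seed(93)
  x <- sample(1:20, 100, replace = TRUE)
  tab <- ecdf_table(x)
  q <- seq(0, 21, by = 0.25)
  F <- stats::ecdf(x)
  brute <- vapply(q, function(t) mean(x <= t), numeric(1))
  expect_equal(F(q), brute, tolerance = 1e-15)
  expect_error(ecdf_table(numeric(0)), "empty")
})

test_that("two-sample KS matches brute force and handles ties and disjoint supports", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  set.seed(94)
  for (rep in 1:10) {
    a <- round(rnorm(200), 1)   # heavy ties
    b <- round(rnorm(200, 0.3), 1)
    res <- ks_two_sample(a, b)
    expect_equal(res$D, brute_ks_D(a, b), tolerance = 1e-12)
  }
  # tie-free cross-check against the standard implementation
  a <- rnorm(150)
  b <- rnorm(150, 0.5)
  res <- ks_two_sample(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(res$D, unname(ref$statistic), tolerance = 1e-12)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(95)
  a <- rlnorm(120)
  b <- rlnorm(150, 0.4)
  d0 <- ks_two_sample(a, b)$D
  expect_equal(ks_two_sample(log(a), log(b))$D, d0, tolerance = 1e-15)
  expect_equal(ks_two_sample(a^(1 / 3), b^(1 / 3))$D, d0, tolerance = 1e-15)
})

test_that("centered variance ratio behaves as a scale comparison", {
  a <- c(1, 2, 3, 4, 6)
  res <- variance_ratio_test_centered(a, a)
  expect_equal(res$F, 1)
  expect_equal(res$p, 1)
  b <- 2 * (a - mean(a)) + mean(a)
  expect_equal(variance_ratio_test_centered(a, b)$F, 0.25, tolerance = 1e-12)
  set.seed(96)
  x <- rnorm(50)
  y <- rnorm(70, sd = 1.7)
  res <- variance_ratio_test_centered(x, y)
  expect_equal(res$F, stats::var(x) / stats::var(y), tolerance = 1e-12)
  ref <- stats::var.test(x - mean(x), y - mean(y))
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_error(variance_ratio_test_centered(rep(1, 5), x), "zero variance")
})

test_that("Spearman correlation handles monotone, reversed and tied data", {
  a <- rnorm(30)
  expect_equal(spearman_test(a, exp(a))$rho, 1)
  expect_equal(spearman_test(a, -a)$rho, -1)
  expect_equal(spearman_test(a, exp(a))$p, 0)
  set.seed(97)
  for (rep in 1:10) {
    x <- sample(1:10, 60, replace = TRUE)
    y <- x + sample(1:5, 60, replace = TRUE)
    res <- spearman_test(x, y)
    expect_equal(res$rho, brute_spearman_rho(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
  }
  expect_error(spearman_test(rep(1, 10), rnorm(10)), "constant")
})

test_that("size-distribution comparison covers the three pairs", {
  ct <- simulate_species_table(small_truth(n = 500, seed = 98))
  cmp <- compare_size_distributions(ct$summaries)
  expect_equal(nrow(cmp), 3)
  expect_true(all(cmp$ks_D >= 0 & cmp$ks_D <= 1))
  expect_true(all(abs(cmp$spearman_rho) <= 1))
  # largest stochastically dominates smallest: its mean is higher
  mm <- cmp[cmp$comparison == "minimum vs maximum", ]
  expect_gt(mm$mean_2, mm$mean_1)

  # all-zero-range cohort: identical distributions
  s0 <- ct$summaries
  s0$maxsize_largest <- s0$maxsize_smallest
  s0$log10_largest <- s0$log10_smallest
  s0$log10_mean <- s0$log10_smallest
  s0$maxsize_range <- 0
  cmp0 <- compare_size_distributions(s0)
  expect_equal(cmp0$ks_D, rep(0, 3))
  expect_equal(cmp0$f_stat, rep(1, 3))
  expect_equal(cmp0$spearman_rho, rep(1, 3))
})

test_that("largest-size ECDF lies below the smallest-size ECDF pointwise", {
  ct <- simulate_species_table(small_truth(n = 800, seed = 99))
  s <- ct$summaries
  q <- seq(min(s$log10_smallest) - 1, max(s$log10_largest) + 1, length.out = 200)
  F_small <- stats::ecdf(s$log10_smallest)(q)
  F_large <- stats::ecdf(s$log10_largest)(q)
  expect_true(all(F_large <= F_small + 1e-15))
})

test_that("taxon ranges are computed per level and monotone under merging", {
  ct <- simulate_species_table(small_truth(n = 1500, seed = 100))
  s <- ct$summaries
  ann <- ct$annotations
  tg <- taxon_interspecific_ranges(s, ann, "genus")
  tf <- taxon_interspecific_ranges(s, ann, "family")
  to <- taxon_interspecific_ranges(s, ann, "order")
  ts <- taxon_interspecific_ranges(s, ann, "species")
  expect_true(all(tg$n_members >= 2))
  expect_equal(ts$range, s$maxsize_range)
  # mean interspecific range grows as taxa merge upward
  expect_gte(mean(tf$range), mean(tg$range))
  expect_gte(mean(to$range), mean(tf$range))
  expect_gt(mean(tg$range), mean(s$maxsize_range))

  # a genus spanning three decades
  s2 <- s[1:2, ]
  s2$maxsize_largest <- c(1, 1000)
  ann2 <- ann[1:2, ]
  ann2$genus <- "G1"
  expect_equal(taxon_interspecific_ranges(s2, ann2, "genus")$range, 3)

  # single-species taxa are excluded
  ann3 <- ann2
  ann3$genus <- c("G1", "G2")
  expect_equal(nrow(taxon_interspecific_ranges(s2, ann3, "genus")), 0)
  expect_error(taxon_interspecific_ranges(s, ann[, c("aphia_id", "phylum")], "order"),
               "annotation")
})
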