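emm_fit <- function(n = 900, seed = 61, factors = c("count_class", "habitat"),
                    interactions = NULL) {
  ct <- simulate_species_table(small_truth(n = n, seed = seed))
  dat <- dplyr::inner_join(ct$summaries, ct$annotations, by = "aphia_id")
  args <- list(factors = factors)
  if (!is.null(interactions)) args$interactions <- interactions
  fit_hurdle(dat, spec = do.call(model_spec, args))
}

test_that("marginal means reduce to the inverse-linked prediction in simple cases", {
  fit <- emm_fit(interactions = list())
  em <- estimated_marginal_means(fit, "zero", factors = "habitat",
                                 at = list(log10_smallest = 0))
  # no interactions: each EMM is intercept + habitat dummy + mean count effect
  bz <- fit$zero$coefs
  count_avg <- mean(c(0, bz["count_classc3"], bz["count_classc4_5"],
                      bz["count_classc6plus"]))
  expected <- bz["(Intercept)"] + c(0, bz["habitatpelagic"], bz["habitatunspecified"]) +
    count_avg
  expect_equal(em$table$emmean, unname(expected), tolerance = 1e-10)
  expect_equal(em$table$response, stats::plogis(unname(expected)), tolerance = 1e-10)
})

test_that("marginal means equal an explicit grid-averaging oracle", {
  fit <- emm_fit(seed = 62)
  for (component in c("zero", "conditional")) {
    parts <- sizerange:::component_parts(fit, component)
    em <- estimated_marginal_means(fit, component, factors = "habitat",
                                   at = list(log10_smallest = 0.4))
    design <- parts$design
    for (i in seq_len(nrow(em$table))) {
      h <- em$table$habitat[i]
      grid <- expand.grid(count_class = design$xlev$count_class,
                          stringsAsFactors = FALSE)
      grid$habitat <- h
      grid$log10_smallest <- 0.4
      rows <- sizerange:::design_rows(design, grid)
      preds <- drop(rows %*% parts$coefs)
      expect_equal(em$table$emmean[i], mean(preds), tolerance = 1e-10)
    }
  }
})

test_that("marginal means and SEs agree with the reference-grid engine", {
  skip_if_not_installed("emmeans")
  set.seed(63)
  n <- 500
  dat <- data.frame(x = rnorm(n),
                    g = sample(c("a", "b", "c"), n, replace = TRUE))
  mu <- exp(0.2 + 0.5 * dat$x + ifelse(dat$g == "b", 0.4, ifelse(dat$g == "c", -0.3, 0)))
  dat$y <- rgamma(n, shape = 2, rate = 2 / mu)

  X <- stats::model.matrix(~ x + g, dat)
  fit <- fit_gamma_loglink(X, dat$y)
  # wrap into the minimal structure the EMM code expects
  spec <- model_spec(continuous = "x", factors = "g", interactions = list(),
                     reference_levels = c(g = "a"))
  design <- build_design(dat, spec)
  hf <- structure(list(spec = spec, design = design, design_pos = design,
                       design_data_cont = dat["x"],
                       zero = list(degenerate = TRUE), cond = fit),
                  class = "hurdle_fit")
  em <- estimated_marginal_means(hf, "conditional", factors = "g",
                                 at = list(x = 0.25))

  gl <- stats::glm(y ~ x + g, family = stats::Gamma(link = "log"), data = dat)
  ref <- summary(emmeans::emmeans(gl, "g", at = list(x = 0.25)))
  expect_equal(em$table$emmean, ref$emmean, tolerance = 1e-5)
  # SEs are not compared: the reference engine scales its covariance with a
  # moment dispersion estimate while this fit uses the ML shape and observed
  # information; the grid-averaging oracle test covers the delta rule instead
})

test_that("contrasts are antisymmetric, Tukey-dominated, and exact for m = 2", {
  fit <- emm_fit(seed = 64)
  em <- estimated_marginal_means(fit, "conditional", factors = "habitat")
  ctr <- pairwise_contrasts(em)
  expect_equal(nrow(ctr), 3)
  expect_true(all(ctr$p_adjusted >= ctr$p_unadjusted - 1e-15))

  # two-level case: studentized range with m = 2 reduces to the normal test
  em2 <- estimated_marginal_means(fit, "zero", factors = "habitat")
  tab2 <- em2$table[1:2, ]
  em2$table <- tab2
  em2$cov <- em2$cov[1:2, 1:2]
  ctr2 <- pairwise_contrasts(em2)
  expect_equal(ctr2$p_adjusted, ctr2$p_unadjusted, tolerance = 1e-10)

  # identical means contrast to zero with adjusted p = 1
  em_same <- em2
  em_same$table$emmean <- c(1, 1)
  ctr_same <- pairwise_contrasts(em_same)
  expect_equal(ctr_same$estimate, 0)
  expect_equal(ctr_same$p_adjusted, 1)
})

test_that("Tukey adjustment matches numerical integration of the range tail", {
  fit <- emm_fit(seed = 65, factors = c("count_class", "habitat"))
  em <- estimated_marginal_means(fit, "conditional", factors = "count_class")
  ctr <- pairwise_contrasts(em)
  m <- nrow(em$table)
  for (i in seq_len(nrow(ctr))) {
    expect_equal(ctr$p_adjusted[i],
                 brute_tukey_p(abs(ctr$z[i]) * sqrt(2), m), tolerance = 1e-6)
  }
})

test_that("effect curves evaluate the linear predictor on the grid", {
  fit <- emm_fit(seed = 66)
  grid <- seq(-1, 2, length.out = 7)
  cur <- marginal_effect_curves(fit, "zero", by = "habitat", grid = grid)
  expect_equal(nrow(cur), 7 * 3)
  for (j in seq_len(nrow(cur))) {
    em <- estimated_marginal_means(fit, "zero", factors = "habitat",
                                   at = list(log10_smallest = cur$log10_smallest[j]))
    expect_equal(cur$link[j],
                 em$table$emmean[em$table$habitat == cur$habitat[j]],
                 tolerance = 1e-12)
  }
  expect_error(marginal_effect_curves(fit, "zero", by = "habitat",
                                      grid = numeric(0)), "empty")

  # a positive slope on the continuous term gives monotone P(nonzero) curves
  zc <- sizerange:::default_zero_coefs()
  zc[] <- 0
  zc["(Intercept)"] <- -0.5
  zc["log10_smallest"] <- 1.2
  ct <- simulate_species_table(small_truth(n = 800, seed = 67, zero_coefs = zc))
  dat <- dplyr::inner_join(ct$summaries, ct$annotations, by = "aphia_id")
  fit2 <- fit_hurdle(dat, spec = model_spec(factors = c("count_class", "habitat"),
                                            interactions = list()))
  cur2 <- marginal_effect_curves(fit2, "zero", by = "habitat",
                                 grid = seq(-1, 2, length.out = 10))
  for (h in unique(cur2$habitat)) {
    expect_true(all(diff(cur2$response[cur2$habitat == h]) > 0))
  }
})

test_that("unknown factors and levels are rejected", {
  fit <- emm_fit(seed = 68)
  expect_error(estimated_marginal_means(fit, "zero", factors = "skeleton"),
               "not in the model")
})
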