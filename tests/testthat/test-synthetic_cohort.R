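test_that("simulation is bitwise reproducible from its seed", {
  tr <- small_truth(n = 150)
  a <- simulate_species_table(tr)
  b <- simulate_species_table(tr)
  expect_identical(a$summaries, b$summaries)
  m1 <- simulate_measurements(tr)
  m2 <- simulate_measurements(tr)
  expect_identical(m1$records, m2$records)
  expect_identical(m1$error_ledger, m2$error_ledger)
})

test_that("a saturated negative logit intercept suppresses non-zero ranges", {
  zc <- sizerange:::default_zero_coefs()
  zc[] <- 0
  zc["(Intercept)"] <- -20
  tr <- small_truth(n = 5000, zero_coefs = zc)
  s <- simulate_species_table(tr)$summaries
  expect_lt(mean(s$maxsize_range > 0), 1e-4)
})

test_that("positive ranges follow the stated gamma mean (law of large numbers)", {
  cc <- sizerange:::default_cond_coefs()
  cc[] <- 0
  cc["(Intercept)"] <- log(0.1)
  zc <- sizerange:::default_zero_coefs()
  zc[] <- 0
  zc["(Intercept)"] <- 10   # almost every species non-zero
  tr <- small_truth(n = 20000, cond_coefs = cc, zero_coefs = zc, gamma_shape = 2)
  pos <- simulate_species_table(tr)$summaries$maxsize_range
  pos <- pos[pos > 0]
  se <- sqrt(0.1^2 / 2) / sqrt(length(pos))   # gamma sd = mean/sqrt(shape)
  expect_lt(abs(mean(pos) - 0.1), 3 * se)
})

test_that("frequency vectors are validated", {
  expect_error(simulation_truth(phylum_freqs = c(a = 0, b = 0)), "degenerate|sum")
  expect_error(simulation_truth(count_class_freqs = c(c2 = 0.5, c3 = 0.2,
                                                      c4_5 = 0.2, c6plus = 0.2)),
               "sum to 1")
  expect_error(simulation_truth(gamma_shape = -1))
})

test_that("measurement-level summaries match species-level truth when error-free", {
  tr <- small_truth(n = 400)
  sim <- simulate_measurements(tr)
  s <- summarize_species(sim$records)
  expect_equal(s$maxsize_range, sim$species_truth$maxsize_range, tolerance = 1e-12)
  expect_equal(s$maxsize_smallest, sim$species_truth$maxsize_smallest, tolerance = 1e-12)
  expect_equal(s$maxsize_largest, sim$species_truth$maxsize_largest, tolerance = 1e-12)
  expect_equal(s$maxsize_mean, sim$species_truth$maxsize_mean, tolerance = 1e-12)
  # the species-level table drew the same ranges
  st <- simulate_species_table(tr)$summaries
  expect_equal(s$maxsize_range, st$maxsize_range, tolerance = 1e-12)
  # reports never exceed the true maximum (largest report is an order statistic)
  expect_true(all(sim$records$size_cm <=
                    rep(st$maxsize_largest, st$count) * (1 + 1e-12)))
})

test_that("a forced unit error of three decades pushes every range above 3", {
  tr <- simulation_truth(n_species = 200, seed = 9,
                         error_rates = c(unit_factor_rate = 1,
                                         colony_factor_rate = 0))
  sim <- simulate_measurements(tr)
  # restrict the forced draw to +/- 3 decades via the ledger magnitude
  forced <- sim$error_ledger[abs(sim$error_ledger$factor_log10) == 3, ]
  s <- summarize_species(sim$records)
  hit <- s[s$aphia_id %in% forced$aphia_id, ]
  # a three-decade slip widens the range to at least 3 minus the clean range
  # (the clean range is absorbed when the slip hits an extreme report)
  base <- sim$species_truth$maxsize_range[match(hit$aphia_id,
                                                sim$species_truth$aphia_id)]
  expect_true(all(hit$maxsize_range >= 3 - base - 1e-9))
  expect_gt(mean(hit$maxsize_range >= 3 - 1e-9), 0.6)
  expect_equal(nrow(sim$error_ledger), 200)   # every species hit at rate 1
})

test_that("injected-error count stays inside binomial bounds at rate 0.01", {
  tr <- simulation_truth(n_species = 10000, seed = 12,
                         error_rates = c(unit_factor_rate = 0.01,
                                         colony_factor_rate = 0))
  sim <- simulate_measurements(tr)
  n_err <- nrow(sim$error_ledger)
  bounds <- stats::qbinom(c(0.005, 0.995), 10000, 0.01)
  expect_gte(n_err, bounds[1])
  expect_lte(n_err, bounds[2])
})

test_that("marginal zero fraction matches the integrated expectation", {
  tr <- small_truth(n = 40000, seed = 77)
  s <- simulate_species_table(tr)$summaries
  observed <- mean(s$maxsize_range == 0)
  # numerically integrate the expectation over a fresh covariate draw
  tr2 <- small_truth(n = 200000, seed = 1234)
  cov <- sizerange:::local_seed(99, sizerange:::simulate_covariates(tr2))
  lp <- sizerange:::truth_linear_predictors(cov, tr$zero_coefs, tr$cond_coefs, tr)
  expected <- mean(1 - stats::plogis(lp$eta_zero))
  se <- sqrt(expected * (1 - expected) / 40000)
  expect_lt(abs(observed - expected), 3 * se + 0.003)
})

test_that("simulated positive ranges are right-skewed in the study's regime", {
  tr <- small_truth(n = 12000, seed = 5)
  pos <- simulate_species_table(tr)$summaries$maxsize_range
  pos <- pos[pos > 0]
  g1 <- mean((pos - mean(pos))^3) / stats::sd(pos)^3
  expect_gt(g1, 0)
})

test_that("cohort CSVs round-trip through the ingest path", {
  tr <- small_truth(n = 60)
  sim <- simulate_measurements(tr)
  dir <- tempfile()
  write_cohort(sim, dir)
  rec <- read_measurements(file.path(dir, "measurements.csv"))
  ann <- read_annotations(file.path(dir, "annotations.csv"))
  expect_equal(nrow(rec), nrow(sim$records))
  expect_equal(nrow(ann), tr$n_species)
  s <- summarize_species(rec)
  expect_equal(s$maxsize_range, sim$species_truth$maxsize_range, tolerance = 1e-12)
})
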