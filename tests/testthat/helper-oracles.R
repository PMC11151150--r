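# Independent brute-force oracles used across the suite. Each is deliberately
# naive (direct enumeration, grid search, general-purpose optimization) and
# shares no code with the implementation paths it checks.

# Logistic MLE by general-purpose quasi-Newton on the raw log-likelihood.
oracle_logistic <- function(X, y, start = NULL) {
  if (is.null(start)) start <- numeric(ncol(X))
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log(1 + exp(eta)))
  }
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  opt2 <- stats::optim(opt$par, nll, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-15))
  list(coefs = opt2$par, loglik = -opt2$value)
}

# Gamma log-link MLE: joint optimization over (beta, log shape) by BFGS.
oracle_gamma <- function(X, y, start = NULL) {
  p <- ncol(X)
  if (is.null(start)) start <- c(log(mean(y)), numeric(p - 1), 0)
  nll <- function(th) {
    b <- th[seq_len(p)]
    a <- exp(th[p + 1])
    mu <- exp(drop(X %*% b))
    -sum(stats::dgamma(y, shape = a, rate = a / mu, log = TRUE))
  }
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  opt <- stats::optim(opt$par, nll, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  list(coefs = opt$par[seq_len(p)], shape = exp(opt$par[p + 1]),
       loglik = -opt$value)
}

# Profile-likelihood grid + golden-section polish for an intercept-only gamma
# shape (the mean is the closed-form MLE).
oracle_gamma_shape_profile <- function(y, lower = 1e-3, upper = 1e3) {
  mu <- mean(y)
  prof <- function(a) sum(stats::dgamma(y, shape = a, rate = a / mu, log = TRUE))
  grid <- exp(seq(log(lower), log(upper), length.out = 400))
  vals <- vapply(grid, prof, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

# KS D by brute-force sup over every pooled point.
brute_ks_D <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# Spearman rho by explicit rank-then-Pearson arithmetic.
brute_spearman_rho <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# Step-by-step re-evaluation of the skewness normalizing transformation,
# written independently from published formulas.
brute_skewness_z <- function(x) {
  n <- length(x)
  s3 <- sum((x - mean(x))^3) / n
  s2 <- sum((x - mean(x))^2) / n
  g1 <- s3 / s2^(3 / 2)
  Y <- g1 * sqrt(((n + 1) * (n + 3)) / (6 * (n - 2)))
  b2 <- (3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3)) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- sqrt(2 * (b2 - 1)) - 1
  d <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  list(skew = g1, z = d * asinh(Y / alpha))
}

# Studentized-range tail (df = Inf) by direct numerical integration:
# P(range of m iid N(0,1) > q).
brute_tukey_p <- function(q, m) {
  cdf <- stats::integrate(function(z) {
    m * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q))^(m - 1)
  }, -Inf, Inf, rel.tol = 1e-12)$value
  1 - cdf
}

# Tiny deterministic measurement table for ingest tests.
write_fixture_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# Small cohort shared by several suites: modest n, moderate effects.
small_truth <- function(n = 600, seed = 42, ...) {
  simulation_truth(n_species = n, seed = seed,
                   error_rates = c(unit_factor_rate = 0, colony_factor_rate = 0),
                   ...)
}
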