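# Maximum-likelihood fitters for the two hurdle components. Both use Newton /
# iteratively reweighted least squares with step-halving, a coefficient
# magnitude guard against separation, and explicit convergence flags.

GLM_MAX_ITER <- 200L
GLM_SCORE_TOL <- 1e-8
GLM_LOGLIK_TOL <- 1e-10
LOGIT_GUARD <- 30
SHAPE_GUARD <- 1e6

solve_sym <- function(A, b = NULL) {
  # Cholesky solve with a fallback for near-singular information matrices
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    if (is.null(b)) return(MASS_ginv(A))
    return(MASS_ginv(A) %*% b)
  }
  if (is.null(b)) chol2inv(ch) else backsolve(ch, forwardsolve(t(ch), b))
}

MASS_ginv <- function(A) {
  s <- svd(A)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Logistic regression by Newton iteration
#'
#' Maximum-likelihood logit fit of a binary indicator (here: species has a
#' non-zero size range) on a design matrix. Convergence requires the maximum
#' absolute score below 1e-8 or a relative log-likelihood change below 1e-10;
#' coefficients exceeding 30 in magnitude on the logit scale flag separation
#' as non-convergence rather than returning silent output.
#'
#' @param design A `design_matrix` or a plain numeric matrix.
#' @param y Logical or 0/1 vector (must contain at least one of each).
#' @return List: `coefs` (named), `vcov` (inverse observed information),
#'   `loglik`, `fitted` (probabilities), `converged`, `n_iter`.
#' @export
fit_logistic <- function(design, y) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("logistic fit needs at least one success and one failure")
  }
  p <- ncol(X)
  beta <- numeric(p)
  names(beta) <- colnames(X)
  log1pexp <- function(eta) ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1pexp(eta))
  }
  ll <- loglik(beta)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(GLM_MAX_ITER)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    step <- drop(solve_sym(info, score))
    # step-halving on likelihood decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- beta; ll_new <- ll; break }
    }
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    beta <- cand
    ll <- ll_new
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < GLM_SCORE_TOL || rel_change < GLM_LOGLIK_TOL) {
      converged <- TRUE
      break
    }
  }
  if (any(abs(beta) > LOGIT_GUARD)) converged <- FALSE  # separation guard
  w <- mu * (1 - mu)
  info <- crossprod(X, X * w)
  vcov <- solve_sym(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coefs = beta, vcov = vcov, loglik = ll, fitted = mu,
       converged = converged, n_iter = it)
}

gamma_loglik <- function(y, mu, shape) {
  sum(shape * log(shape) - shape * log(mu) - lgamma(shape) +
        (shape - 1) * log(y) - shape * y / mu)
}

#' Gamma regression with log link, shape by full maximum likelihood
#'
#' Fits the conditional (positive-range) hurdle component: strictly positive
#' responses with mean `exp(X beta)` and a gamma shape parameter estimated
#' jointly by maximum likelihood. The mean coefficients solve the score
#' equations `sum x_ij (y_i / mu_i - 1) = 0` (independent of the shape); the
#' shape is then updated by Newton steps on log(shape) using digamma/trigamma.
#' The observed information is block-diagonal between mean coefficients and
#' shape at the maximum, which the returned covariance exploits.
#'
#' @param design A `design_matrix` or a plain numeric matrix.
#' @param y Strictly positive responses.
#' @return List: `coefs`, `shape`, `vcov` (for the mean coefficients),
#'   `shape_se`, `loglik`, `fitted` (means), `converged`, `n_iter`.
#' @export
fit_gamma_loglink <- function(design, y) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X))
  if (any(y <= 0)) stop("gamma responses must be strictly positive")
  n <- length(y)
  p <- ncol(X)

  # mean model: Newton on the quasi-score sum x (y/mu - 1) = 0
  beta <- c(log(mean(y)), numeric(p - 1))
  names(beta) <- colnames(X)
  qll <- function(b) {          # quasi-likelihood kernel, monotone in the score
    mu <- exp(drop(X %*% b))
    -sum(log(mu) + y / mu)
  }
  qv <- qll(beta)
  conv_beta <- FALSE
  it <- 0L
  for (it in seq_len(GLM_MAX_ITER)) {
    mu <- exp(drop(X %*% beta))
    score <- drop(crossprod(X, y / mu - 1))
    info <- crossprod(X, X * (y / mu))   # observed information / shape
    step <- drop(solve_sym(info, score))
    lam <- 1
    repeat {
      cand <- beta + lam * step
      qn <- qll(cand)
      if (is.finite(qn) && qn >= qv - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- beta; qn <- qv; break }
    }
    rel_change <- abs(qn - qv) / (abs(qv) + 1e-10)
    beta <- cand
    qv <- qn
    mu <- exp(drop(X %*% beta))
    score <- drop(crossprod(X, y / mu - 1))
    if (max(abs(score)) < GLM_SCORE_TOL || rel_change < GLM_LOGLIK_TOL) {
      conv_beta <- TRUE
      break
    }
  }
  mu <- exp(drop(X %*% beta))

  # shape: Newton on log(shape); score n(log a + 1 - psi(a)) + sum(log(y/mu) - y/mu)
  s_const <- sum(log(y / mu) - y / mu)
  shape <- 0.5 / max(mean((y / mu - 1)^2) / 2, 1e-8)   # moment start
  shape <- min(max(shape, 1e-3), 1e3)
  conv_shape <- FALSE
  for (j in seq_len(GLM_MAX_ITER)) {
    sc <- n * (log(shape) + 1 - digamma(shape)) + s_const
    d_sc <- n * (1 / shape - trigamma(shape)) * shape   # d score / d log(shape)
    if (abs(d_sc) < 1e-300) break
    step <- sc / (-d_sc)
    step <- max(min(step, 2), -2)                        # guarded log-scale step
    shape_new <- shape * exp(step)
    if (!is.finite(shape_new) || shape_new <= 0) break
    shape <- shape_new
    if (shape > SHAPE_GUARD) break                        # zero-variance degeneracy
    if (abs(sc) < GLM_SCORE_TOL * n) { conv_shape <- TRUE; break }
  }
  if (shape > SHAPE_GUARD) conv_shape <- FALSE

  ll <- gamma_loglik(y, mu, shape)
  info_beta <- shape * crossprod(X, X * (y / mu))
  vcov <- solve_sym(info_beta)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  info_shape <- n * (trigamma(shape) - 1 / shape)
  shape_se <- if (info_shape > 0) sqrt(1 / info_shape) else NA_real_
  list(coefs = beta, shape = shape, vcov = vcov, shape_se = shape_se,
       loglik = ll, fitted = mu, converged = conv_beta && conv_shape,
       n_iter = it)
}
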