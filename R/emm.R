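# Estimated marginal means, Tukey-adjusted contrasts, and marginal-effect
# curves for hurdle components. EMMs are model predictions on the link scale
# averaged over a reference grid: the requested factors are crossed, every
# non-requested factor is averaged with equal weight over its levels, and
# continuous covariates are fixed (default: their observed mean).

component_parts <- function(fit, component = c("zero", "conditional")) {
  component <- match.arg(component)
  if (component == "zero") {
    if (fit$zero$degenerate) stop("zero component is degenerate for this fit")
    list(coefs = fit$zero$coefs, vcov = fit$zero$vcov,
         invlink = stats::plogis, design = fit$design)
  } else {
    list(coefs = fit$cond$coefs, vcov = fit$cond$vcov,
         invlink = exp, design = fit$design_pos)
  }
}

# L matrix: one row per requested-factor combination, averaging design rows
# over all combinations of the remaining factors with equal weight.
emm_lmatrix <- function(fit, component, factors, at = NULL) {
  parts <- component_parts(fit, component)
  spec <- fit$spec
  unknown <- setdiff(factors, spec$factors)
  if (length(unknown) > 0) stop("factor(s) not in the model: ", paste(unknown, collapse = ", "))
  design <- parts$design

  at_cont <- vapply(spec$continuous, function(cn) {
    if (!is.null(at) && cn %in% names(at)) at[[cn]] else mean(fit$design_data_cont[[cn]])
  }, numeric(1))
  names(at_cont) <- spec$continuous

  req_levels <- design$xlev[factors]
  grid <- expand.grid(req_levels, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) stop("empty reference grid")
  other <- setdiff(spec$factors, factors)
  other_grid <- if (length(other) > 0) {
    expand.grid(design$xlev[other], stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(row.names = 1)
  }
  L <- matrix(0, nrow(grid), length(parts$coefs),
              dimnames = list(NULL, names(parts$coefs)))
  for (i in seq_len(nrow(grid))) {
    nd <- other_grid
    for (f in factors) nd[[f]] <- grid[[f]][i]
    for (cn in spec$continuous) nd[[cn]] <- at_cont[[cn]]
    rows <- design_rows(design, nd)
    L[i, ] <- colMeans(rows)
  }
  list(L = L, grid = tibble::as_tibble(grid), parts = parts, at = at_cont)
}

#' Estimated marginal means for hurdle-component factors
#'
#' @param fit A `hurdle_fit`.
#' @param component `"zero"` (binomial, link = logit, response =
#'   P(range > 0)) or `"conditional"` (gamma, link = log, response = expected
#'   positive range).
#' @param factors Character vector of model factors whose level combinations
#'   form the reference grid.
#' @param at Optional named list fixing continuous covariates; default is the
#'   observed mean over the species entering the model.
#' @return Object of class `emm_result`: tibble of grid levels with `emmean`
#'   (link scale), `se`, and `response` (inverse-linked), plus the averaging
#'   matrix and covariance needed for contrasts.
#' @export
estimated_marginal_means <- function(fit, component = c("zero", "conditional"),
                                     factors, at = NULL) {
  component <- match.arg(component)
  lm_ <- emm_lmatrix(fit, component, factors, at)
  est <- drop(lm_$L %*% lm_$parts$coefs)
  cov_est <- lm_$L %*% lm_$parts$vcov %*% t(lm_$L)
  se <- sqrt(pmax(diag(cov_est), 0))
  out <- lm_$grid
  out$emmean <- est
  out$se <- se
  out$response <- lm_$parts$invlink(est)
  structure(list(table = out, factors = factors, component = component,
                 cov = cov_est, at = lm_$at),
            class = "emm_result")
}

#' @export
print.emm_result <- function(x, ...) {
  cat("estimated marginal means (", x$component, " component), at ",
      paste(names(x$at), signif(x$at, 4), sep = "=", collapse = ", "), "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' All pairwise contrasts among estimated marginal means
#'
#' Differences on the link scale with delta-rule standard errors; the Tukey
#' adjustment evaluates the studentized-range tail with infinite degrees of
#' freedom, `p = P(Q_{m,Inf} >= |z| * sqrt(2))`, where `m` is the number of
#' means. With `m = 2` this reduces to the unadjusted two-sided normal test.
#'
#' @param emms An `emm_result` with at least two rows.
#' @param adjust `"tukey"` or `"none"`.
#' @return Tibble: `contrast, estimate, se, z, p_unadjusted, p_adjusted`.
#' @export
pairwise_contrasts <- function(emms, adjust = c("tukey", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(emms, "emm_result"))
  tab <- emms$table
  m <- nrow(tab)
  if (m < 2) stop("need at least two marginal means to contrast")
  lev <- do.call(paste, c(tab[emms$factors], sep = ":"))
  pairs <- utils::combn(m, 2)
  est <- tab$emmean[pairs[1, ]] - tab$emmean[pairs[2, ]]
  var_d <- diag(emms$cov)[pairs[1, ]] + diag(emms$cov)[pairs[2, ]] -
    2 * emms$cov[cbind(pairs[1, ], pairs[2, ])]
  se <- sqrt(pmax(var_d, 0))
  z <- est / se
  p_un <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (adjust == "tukey") {
    # studentized-range tail dominates the normal tail, but guard the
    # invariant p_adjusted >= p_unadjusted against floating-point residue
    pmax(stats::ptukey(abs(z) * sqrt(2), nmeans = m, df = Inf, lower.tail = FALSE),
         p_un)
  } else {
    p_un
  }
  tibble::tibble(
    contrast = paste(lev[pairs[1, ]], "-", lev[pairs[2, ]]),
    estimate = est, se = se, z = z,
    p_unadjusted = p_un, p_adjusted = p_adj
  )
}

#' Marginal-effect curves over the continuous size term
#'
#' Predictions along a grid of the continuous term, one curve per level of a
#' factor, averaging the remaining factors with equal weight (the same
#' reference-grid rule as the marginal means). For the zero component the
#' curve is P(range > 0); for the conditional component the expected positive
#' range.
#'
#' @param fit A `hurdle_fit`.
#' @param component `"zero"` or `"conditional"`.
#' @param over Continuous model term (default the first one).
#' @param by Factor whose levels index the curves.
#' @param grid Numeric grid for `over`; default 100 equally spaced points over
#'   the observed range.
#' @return Tibble: `by` level, grid value, `link` and `response` predictions.
#' @export
marginal_effect_curves <- function(fit, component = c("zero", "conditional"),
                                   over = NULL, by, grid = NULL) {
  component <- match.arg(component)
  spec <- fit$spec
  if (is.null(over)) over <- spec$continuous[1]
  if (!over %in% spec$continuous) stop("'", over, "' is not a continuous model term")
  if (!by %in% spec$factors) stop("'", by, "' is not a model factor")
  if (is.null(grid)) {
    rng <- range(fit$design_data_cont[[over]])
    grid <- seq(rng[1], rng[2], length.out = 100)
  }
  if (length(grid) == 0) stop("empty prediction grid")
  out <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    at <- stats::setNames(list(grid[i]), over)
    em <- estimated_marginal_means(fit, component, factors = by, at = at)
    tab <- em$table
    out[[i]] <- tibble::tibble(level = tab[[by]], value = grid[i],
                               link = tab$emmean, response = tab$response)
  }
  res <- dplyr::bind_rows(out)
  names(res)[1:2] <- c(by, over)
  res
}
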