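# Distribution-level comparisons of smallest / mean / largest reported
# maximum sizes across species, plus the taxonomic-hierarchy range contrast.

#' OLS regression with a test of the slope against a null value
#'
#' Regresses largest on smallest log10 maximum size across species; the slope
#' test against 1 asks whether small species carry proportionally more
#' disagreement among reports than large ones.
#'
#' @param x,y Paired numeric vectors, `n >= 3`, `x` non-constant.
#' @param null_slope Null value for the slope (default 1).
#' @return List: `slope, intercept, se_slope, t_ratio, df, p_value, adj_r2, n`.
#' @export
ols_slope_test <- function(x, y, null_slope = 1) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  se_slope <- sm$coefficients[2, 2]
  t_ratio <- (slope - null_slope) / se_slope
  df <- n - 2
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       se_slope = se_slope, t_ratio = t_ratio, df = df,
       p_value = 2 * stats::pt(-abs(t_ratio), df),
       adj_r2 = sm$adj.r.squared, n = n)
}

#' D'Agostino test of skewness
#'
#' Sample skewness `g1 = m3 / m2^(3/2)` with the D'Agostino (1970)
#' normalizing transformation to an approximately standard normal `z`,
#' two-sided p. Requires `n >= 9` for the transformation's validity.
#'
#' @param values Numeric vector, non-constant, `n >= 9`.
#' @return List: `skew, z, p, n`.
#' @export
dagostino_skewness_test <- function(values) {
  n <- length(values)
  if (n < 9) stop("skewness test requires n >= 9")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("constant sample: skewness undefined")
  m3 <- mean((values - m)^3)
  g1 <- m3 / m2^1.5
  # D'Agostino (1970) transformation
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  list(skew = g1, z = z, p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Empirical cumulative distribution function as a step table
#'
#' @param values Non-empty numeric vector.
#' @return Tibble with the sorted unique `support` and the right-continuous
#'   `cumfrac` reaching 1 at the maximum.
#' @export
ecdf_table <- function(values) {
  if (length(values) == 0) stop("empty sample")
  support <- sort(unique(values))
  F <- stats::ecdf(values)
  tibble::tibble(support = support, cumfrac = F(support))
}

# Kolmogorov distribution survival function Q(x) = 2 sum (-1)^(k-1) exp(-2 k^2 x^2)
kolmogorov_sf <- function(x) {
  if (x <= 0) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute ECDF difference, evaluated at every
#' pooled jump point (so ties are handled exactly); the p-value is the
#' asymptotic Kolmogorov tail at `sqrt(n_eff) * D` with effective sample size
#' `n_a n_b / (n_a + n_b)`.
#'
#' @param a,b Non-empty numeric samples.
#' @return List: `D, p, n_a, n_b`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  pooled <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pooled)
  Fb <- stats::ecdf(b)(pooled)
  D <- max(abs(Fa - Fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  list(D = D, p = kolmogorov_sf(sqrt(n_eff) * D),
       n_a = length(a), n_b = length(b))
}

#' Variance-ratio F test on mean-centered samples
#'
#' Each sample is centered at its own mean before comparing spreads, so the
#' test is about dispersion only. Two-sided p from the F distribution with
#' `(n_a - 1, n_b - 1)` degrees of freedom.
#'
#' @param a,b Numeric samples with at least 2 values and positive variance.
#' @return List: `F, p, df1, df2`.
#' @export
variance_ratio_test_centered <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per sample")
  va <- stats::var(a - mean(a))
  vb <- stats::var(b - mean(b))
  if (va == 0 || vb == 0) stop("zero variance: F ratio undefined")
  F <- va / vb
  df1 <- length(a) - 1
  df2 <- length(b) - 1
  p <- 2 * min(stats::pf(F, df1, df2), stats::pf(F, df1, df2, lower.tail = FALSE))
  list(F = F, p = min(p, 1), df1 = df1, df2 = df2)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average-tie ranks; p from
#' `t = rho sqrt((n-2)/(1-rho^2))` with `n - 2` degrees of freedom. Perfectly
#' monotone pairs return p = 0.
#'
#' @param a,b Paired numeric vectors, `n >= 3`, neither with constant ranks.
#' @return List: `rho, p, n`.
#' @export
spearman_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3) stop("need at least 3 pairs")
  ra <- rank(a)
  rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) stop("constant ranks: correlation undefined")
  rho <- stats::cor(ra, rb)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Compare the smallest / mean / largest size distributions
#'
#' The three pairwise comparisons among per-species `log10_smallest`,
#' `log10_mean` and `log10_largest`: sample means and SDs, two-sample KS,
#' centered-variance F, and Spearman rank correlation.
#'
#' @param summaries Per-species summary tibble.
#' @return Tibble, one row per comparison.
#' @export
compare_size_distributions <- function(summaries) {
  if (nrow(summaries) == 0) stop("empty summaries")
  samples <- list(minimum = summaries$log10_smallest,
                  mean = summaries$log10_mean,
                  maximum = summaries$log10_largest)
  pairs <- list(c("mean", "minimum"), c("mean", "maximum"), c("minimum", "maximum"))
  rows <- lapply(pairs, function(pr) {
    a <- samples[[pr[1]]]
    b <- samples[[pr[2]]]
    ks <- ks_two_sample(a, b)
    Fres <- if (stats::var(a) > 0 && stats::var(b) > 0) {
      variance_ratio_test_centered(a, b)
    } else {
      list(F = NA_real_, p = NA_real_)
    }
    sp <- spearman_test(a, b)
    tibble::tibble(
      comparison = paste(pr[1], "vs", pr[2]),
      mean_1 = mean(a), sd_1 = stats::sd(a),
      mean_2 = mean(b), sd_2 = stats::sd(b),
      ks_D = ks$D, ks_p = ks$p,
      f_stat = Fres$F, f_p = Fres$p,
      spearman_rho = sp$rho, spearman_p = sp$p
    )
  })
  dplyr::bind_rows(rows)
}

#' Interspecific size ranges per taxon at a taxonomic level
#'
#' For orders, families and genera the range is the log10 ratio between the
#' largest and smallest member species (species size metric:
#' `maxsize_largest` by default, switchable to `maxsize_mean`); at species
#' level it is each species' own within-species range. Taxa with fewer than
#' two member species are excluded.
#'
#' @param summaries Per-species summaries.
#' @param annotations Annotations carrying the taxonomy columns (ignored if
#'   `summaries` already carries them).
#' @param level One of `"order"`, `"family"`, `"genus"`, `"species"`.
#' @param metric `"largest"` or `"mean"`: which per-species size represents
#'   the species in between-species ranges.
#' @return Tibble: `taxon, level, n_members, range`.
#' @export
taxon_interspecific_ranges <- function(summaries, annotations = NULL,
                                       level = c("order", "family", "genus", "species"),
                                       metric = c("largest", "mean")) {
  level <- match.arg(level)
  metric <- match.arg(metric)
  dat <- if (is.null(annotations) || level == "species" ||
             level %in% names(summaries)) summaries else
    dplyr::inner_join(summaries, annotations, by = "aphia_id")
  if (level == "species") {
    return(tibble::tibble(taxon = as.character(dat$aphia_id), level = "species",
                          n_members = dat$count, range = dat$maxsize_range))
  }
  if (!level %in% names(dat)) stop("no '", level, "' annotation column available")
  size <- if (metric == "largest") dat$maxsize_largest else dat$maxsize_mean
  keep <- !is.na(dat[[level]]) & dat[[level]] != ""
  dat <- dat[keep, , drop = FALSE]
  size <- size[keep]
  out <- tibble::tibble(taxon = dat[[level]], size = size) |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(n_members = dplyr::n(),
                     range = log10(max(.data$size)) - log10(min(.data$size)),
                     .groups = "drop") |>
    dplyr::filter(.data$n_members >= 2)
  tibble::tibble(taxon = out$taxon, level = level,
                 n_members = out$n_members, range = out$range)
}
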