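# Synthetic-cohort generator: species-level and measurement-level datasets
# with the statistical structure the analysis assumes, plus ground truth for
# parameter-recovery and error-flag-recall tests.

# Run code under a seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Ground truth for a synthetic cohort
#'
#' Defines the generating process for a cohort of species, each carrying a
#' phylum, habitat, measurement-count class and log10 smallest maximum size,
#' with the range statistic generated by a gamma hurdle: the probability of a
#' non-zero range follows a logit-linear model and positive ranges follow a
#' gamma with log-linear mean, both over the same design as the fitted models
#' (continuous size term, count class, phylum, habitat, and size-by-factor
#' interactions).
#'
#' Defaults are the "paper-like" preset: eight phyla with relative frequencies
#' matching the study cohort, habitat frequencies matching its benthic /
#' pelagic / unspecified split, count-class frequencies with median count 2
#' and 2.8% of species above 5 reports, a marginal zero-range fraction near
#' 0.38, and rare injected gross errors (unit misspecification; colony size
#' recorded against zooid size).
#'
#' @param n_species Number of species.
#' @param phylum_freqs,habitat_freqs,count_class_freqs Named probability
#'   vectors (each sums to 1).
#' @param log10_smallest_dist `c(mean, sd)` of the normal distribution of
#'   log10 smallest maximum size (cm).
#' @param zero_coefs Coefficients of the non-zero-probability component on the
#'   logit scale, named by design column.
#' @param cond_coefs Coefficients of the positive-range mean on the log scale.
#' @param gamma_shape Gamma shape of positive ranges.
#' @param error_rates `c(unit_factor_rate, colony_factor_rate)`: per-species
#'   probabilities of one report being off by a power of ten, or divided by a
#'   colony-vs-zooid factor >= 100.
#' @param seed Integer seed; every simulation from this truth is reproducible.
#' @return Object of class `simulation_truth`.
#' @export
simulation_truth <- function(n_species = 27271,
                             phylum_freqs = NULL,
                             habitat_freqs = NULL,
                             count_class_freqs = NULL,
                             log10_smallest_dist = c(mean = 0.60, sd = 0.89),
                             zero_coefs = NULL,
                             cond_coefs = NULL,
                             gamma_shape = 0.5,
                             error_rates = c(unit_factor_rate = 0.0008,
                                             colony_factor_rate = 0.0008),
                             seed = 1L) {
  if (is.null(phylum_freqs)) {
    counts <- c(Annelida = 379, Arthropoda = 2601, Bryozoa = 237,
                Chordata = 13080, Cnidaria = 707, Echinodermata = 234,
                Mollusca = 9367, Nematoda = 666)
    phylum_freqs <- counts / sum(counts)
  }
  if (is.null(habitat_freqs)) {
    counts <- c(benthic = 21021, pelagic = 5336, unspecified = 914)
    habitat_freqs <- counts / sum(counts)
  }
  if (is.null(count_class_freqs)) {
    count_class_freqs <- c(c2 = 0.60, c3 = 0.25, c4_5 = 0.122, c6plus = 0.028)
  }
  if (is.null(zero_coefs)) zero_coefs <- default_zero_coefs()
  if (is.null(cond_coefs)) cond_coefs <- default_cond_coefs()
  for (v in list(phylum_freqs, habitat_freqs, count_class_freqs)) {
    if (all(v == 0)) stop("degenerate frequency vector: all zero")
    if (abs(sum(v) - 1) > 1e-12) stop("frequency vector must sum to 1")
    if (any(v < 0)) stop("frequencies must be non-negative")
  }
  stopifnot(gamma_shape > 0, all(error_rates >= 0 & error_rates <= 1))
  structure(list(
    n_species = as.integer(n_species),
    phylum_freqs = phylum_freqs, habitat_freqs = habitat_freqs,
    count_class_freqs = count_class_freqs,
    log10_smallest_dist = log10_smallest_dist,
    zero_coefs = zero_coefs, cond_coefs = cond_coefs,
    gamma_shape = gamma_shape, error_rates = error_rates,
    seed = as.integer(seed)
  ), class = "simulation_truth")
}

# Coefficients of the paper-like preset, on the P(nonzero) logit scale.
# Chosen once for qualitative fidelity: zero-range probability rises with
# size, falls with report count, is phylum- and habitat-structured (pelagic
# species have more uniform reports; poorly annotated species fewer); the
# intercept is calibrated so the marginal zero fraction is ~0.38.
default_zero_coefs <- function() {
  c("(Intercept)" = 1.52,
    "log10_smallest" = -0.61,
    "count_classc3" = 0.34, "count_classc4_5" = 0.60, "count_classc6plus" = 0.97,
    "phylumArthropoda" = -0.80, "phylumBryozoa" = 1.20, "phylumChordata" = -0.90,
    "phylumCnidaria" = -0.27, "phylumEchinodermata" = 0.10,
    "phylumMollusca" = -0.92, "phylumNematoda" = -1.20,
    "habitatpelagic" = -0.50, "habitatunspecified" = 0.31,
    "log10_smallest:count_classc3" = 0.00,
    "log10_smallest:count_classc4_5" = 0.08,
    "log10_smallest:count_classc6plus" = 0.00,
    "log10_smallest:phylumArthropoda" = 0.21,
    "log10_smallest:phylumBryozoa" = -0.36,
    "log10_smallest:phylumChordata" = 0.10,
    "log10_smallest:phylumCnidaria" = 0.11,
    "log10_smallest:phylumEchinodermata" = -0.34,
    "log10_smallest:phylumMollusca" = 0.14,
    "log10_smallest:phylumNematoda" = 0.28,
    "log10_smallest:habitatpelagic" = 0.41,
    "log10_smallest:habitatunspecified" = 0.00)
}

# Log-scale mean coefficients for positive ranges: ranges shrink with size,
# grow with report count; annelids / echinoderms / bryozoans high, nematodes
# low; pelagic low, unspecified high.
default_cond_coefs <- function() {
  c("(Intercept)" = -1.35,
    "log10_smallest" = -0.20,
    "count_classc3" = 0.10, "count_classc4_5" = 0.25, "count_classc6plus" = 0.40,
    "phylumArthropoda" = -0.50, "phylumBryozoa" = 0.60, "phylumChordata" = -0.45,
    "phylumCnidaria" = 0.10, "phylumEchinodermata" = 0.20,
    "phylumMollusca" = -0.40, "phylumNematoda" = -0.70,
    "habitatpelagic" = -0.50, "habitatunspecified" = 0.35,
    "log10_smallest:count_classc3" = 0.00,
    "log10_smallest:count_classc4_5" = 0.00,
    "log10_smallest:count_classc6plus" = 0.00,
    "log10_smallest:phylumArthropoda" = 0.00,
    "log10_smallest:phylumBryozoa" = -0.10,
    "log10_smallest:phylumChordata" = 0.00,
    "log10_smallest:phylumCnidaria" = 0.00,
    "log10_smallest:phylumEchinodermata" = 0.00,
    "log10_smallest:phylumMollusca" = 0.00,
    "log10_smallest:phylumNematoda" = 0.00,
    "log10_smallest:habitatpelagic" = 0.15,
    "log10_smallest:habitatunspecified" = -0.10)
}

# The generator's own design spec (matches the best-supported fitted model).
truth_spec <- function() model_spec(factors = c("count_class", "phylum", "habitat"),
                                    label = "phylum+habitat")

draw_counts <- function(count_class, n) {
  count <- integer(n)
  count[count_class == "c2"] <- 2L
  count[count_class == "c3"] <- 3L
  i45 <- count_class == "c4_5"
  count[i45] <- sample(c(4L, 5L), sum(i45), replace = TRUE)
  i6 <- count_class == "c6plus"
  count[i6] <- 6L + stats::rgeom(sum(i6), prob = 0.5)
  count
}

# Linear predictors for arbitrary coefficient vectors over the truth design.
# Factor levels are frozen from the truth's frequency vectors (not from the
# realized draw), so the design is well-defined even when a rare level is
# unobserved in a small cohort.
truth_linear_predictors <- function(covariates, zero_coefs, cond_coefs,
                                    truth = NULL) {
  xlev <- list(
    count_class = count_class_levels(),
    phylum = if (is.null(truth)) sort(unique(as.character(covariates$phylum)), method = "radix")
             else names(truth$phylum_freqs),
    habitat = if (is.null(truth)) c("benthic", "pelagic", "unspecified")
              else names(truth$habitat_freqs)
  )
  df <- as.data.frame(covariates[, c("log10_smallest", "count_class", "phylum", "habitat")])
  for (f in names(xlev)) df[[f]] <- factor(as.character(df[[f]]), levels = xlev[[f]])
  fml <- ~ log10_smallest + count_class + phylum + habitat +
    log10_smallest:count_class + log10_smallest:phylum + log10_smallest:habitat
  X <- stats::model.matrix(fml, df, xlev = xlev)
  stopifnot(identical(colnames(X), names(zero_coefs)),
            identical(colnames(X), names(cond_coefs)))
  list(eta_zero = drop(X %*% zero_coefs), eta_cond = drop(X %*% cond_coefs))
}

simulate_covariates <- function(truth) {
  n <- truth$n_species
  phylum <- sample(names(truth$phylum_freqs), n, replace = TRUE,
                   prob = truth$phylum_freqs)
  habitat <- sample(names(truth$habitat_freqs), n, replace = TRUE,
                    prob = truth$habitat_freqs)
  count_class <- sample(names(truth$count_class_freqs), n, replace = TRUE,
                        prob = truth$count_class_freqs)
  count <- draw_counts(count_class, n)
  log10_smallest <- stats::rnorm(n, truth$log10_smallest_dist[["mean"]],
                                 truth$log10_smallest_dist[["sd"]])
  tibble::tibble(
    aphia_id = seq_len(n),
    species_name = sprintf("Synthetica specios%06d", seq_len(n)),
    phylum = phylum, habitat = habitat,
    count = count, count_class = factor(count_class, levels = count_class_levels()),
    log10_smallest = log10_smallest
  )
}

#' Simulate a species-level cohort from known truth
#'
#' Draws covariates from the stated frequencies, then the range statistic from
#' the hurdle: `P(range > 0)` is the inverse logit of the zero-component
#' linear predictor, and positive ranges are gamma with mean
#' `exp(conditional linear predictor)` and the truth's shape. Summaries are
#' internally consistent (`largest = smallest * 10^range`); fully reproducible
#' from the truth's seed.
#'
#' @param truth A [simulation_truth()].
#' @param seed Optional override of `truth$seed`.
#' @return List: `summaries` (per-species summary tibble), `annotations`
#'   (taxonomy/habitat tibble, with synthetic genus/family/order nesting),
#'   `truth`.
#' @export
simulate_species_table <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (is.null(seed)) seed <- truth$seed
  local_seed(seed, {
    cov <- simulate_covariates(truth)
    lp <- truth_linear_predictors(cov, truth$zero_coefs, truth$cond_coefs, truth)
    p_nonzero <- stats::plogis(lp$eta_zero)
    nonzero <- stats::runif(truth$n_species) < p_nonzero
    mu <- exp(lp$eta_cond)
    range_val <- numeric(truth$n_species)
    range_val[nonzero] <- stats::rgamma(sum(nonzero), shape = truth$gamma_shape,
                                        rate = truth$gamma_shape / mu[nonzero])

    smallest <- 10^cov$log10_smallest
    largest <- smallest * 10^range_val
    log10_mean <- (cov$log10_smallest + log10(largest)) / 2  # geometric midpoint placeholder
    summaries <- tibble::tibble(
      aphia_id = cov$aphia_id, species_name = cov$species_name,
      count = cov$count, count_class = cov$count_class,
      maxsize_smallest = smallest, maxsize_largest = largest,
      maxsize_mean = 10^log10_mean,
      log10_smallest = cov$log10_smallest, log10_largest = log10(largest),
      log10_mean = log10_mean, maxsize_range = range_val
    )
    annotations <- synthetic_taxonomy(cov)
    list(summaries = summaries, annotations = annotations, truth = truth)
  })
}

# Nested synthetic taxonomy: species grouped into genera (~8 species), genera
# into families (~4 genera), families into orders (~5 families), within phylum.
synthetic_taxonomy <- function(cov) {
  genus_idx <- ((cov$aphia_id - 1) %/% 8) + 1
  family_idx <- ((genus_idx - 1) %/% 4) + 1
  order_idx <- ((family_idx - 1) %/% 5) + 1
  tibble::tibble(
    aphia_id = cov$aphia_id,
    phylum = cov$phylum,
    class = paste0(cov$phylum, "_class1"),
    order = sprintf("%s_ord%04d", cov$phylum, order_idx),
    family = sprintf("%s_fam%05d", cov$phylum, family_idx),
    genus = sprintf("%s_gen%06d", cov$phylum, genus_idx),
    habitat = cov$habitat,
    skeleton = synthetic_skeleton(cov$phylum),
    invertebrate = cov$phylum != "Chordata"
  )
}

synthetic_skeleton <- function(phylum) {
  ifelse(phylum == "Chordata", "endoskeleton",
  ifelse(phylum %in% c("Arthropoda", "Echinodermata", "Mollusca"), "exoskeleton",
         "none"))
}

#' Simulate measurement-level reports with injected gross errors
#'
#' Builds on [simulate_species_table()]: per species, the largest and smallest
#' reports anchor the drawn range, and interior reports are exponential
#' decrements from the true maximum on the log10 scale, truncated to the
#' realized range (reports never exceed the true maximum, keeping the largest
#' report an order statistic). Gross errors are then injected: with
#' probability `unit_factor_rate` one report is multiplied or divided by 10,
#' 100 or 1000 (unit misspecification); with probability `colony_factor_rate`
#' one report is divided by a factor >= 100 (an individual-module dimension
#' recorded against a colony size). Injections are recorded in a truth ledger
#' for flag-recall tests.
#'
#' @param truth A [simulation_truth()].
#' @param seed Optional override of `truth$seed`.
#' @param decrement_rate Rate of the truncated-exponential interior decrements
#'   (per log10 unit); larger values cluster interior reports near the
#'   maximum.
#' @return List: `records` (measurement tibble in the ingest schema),
#'   `annotations`, `species_truth` (clean per-species summaries before error
#'   injection), `error_ledger` (one row per injected error:
#'   `aphia_id, error_type, factor_log10, report_index`), `truth`.
#' @export
simulate_measurements <- function(truth, seed = NULL, decrement_rate = 3) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (is.null(seed)) seed <- truth$seed
  cohort <- simulate_species_table(truth, seed = seed)
  s <- cohort$summaries
  n <- nrow(s)
  local_seed(seed + 1L, {
    counts <- s$count
    total <- sum(counts)
    sp_row <- rep.int(seq_len(n), counts)
    idx_in_sp <- sequence(counts)

    # decrements from the true (largest) maximum, in log10 units
    R <- rep.int(s$maxsize_range, counts)
    e <- numeric(total)
    first <- idx_in_sp == 1L               # the true maximum itself
    last <- idx_in_sp == rep.int(counts, counts)  # anchors the smallest report
    e[last] <- R[last]
    interior <- !first & !last
    if (any(interior)) {
      u <- stats::runif(sum(interior))
      lam <- decrement_rate
      Ri <- R[interior]
      # inverse CDF of Exp(lam) truncated to [0, R]
      e[interior] <- ifelse(Ri == 0, 0, -log1p(-u * (1 - exp(-lam * Ri))) / lam)
    }
    size_cm <- rep.int(s$maxsize_largest, counts) * 10^(-e)
    # the smallest anchor must be exact, not subject to rounding of 10^(-e)
    size_cm[last] <- rep.int(s$maxsize_smallest, counts)[last]
    size_cm[first] <- rep.int(s$maxsize_largest, counts)[first]

    # clean per-species truth (before error injection), with the mean taken
    # over the realized reports rather than the species-level placeholder
    clean_records <- tibble::tibble(
      species_name = rep.int(s$species_name, counts),
      aphia_id = rep.int(s$aphia_id, counts),
      size_cm = size_cm)
    species_truth <- summarize_species(clean_records)

    # error injection
    ledger <- list()
    unit_hit <- stats::runif(n) < truth$error_rates[["unit_factor_rate"]]
    colony_hit <- stats::runif(n) < truth$error_rates[["colony_factor_rate"]]
    offsets <- c(0L, cumsum(counts))
    if (any(unit_hit)) {
      ids <- which(unit_hit)
      pick <- offsets[ids] + vapply(counts[ids], function(k) sample.int(k, 1L), integer(1))
      mag <- sample(c(1, 2, 3), length(ids), replace = TRUE)
      sgn <- sample(c(-1, 1), length(ids), replace = TRUE)
      size_cm[pick] <- size_cm[pick] * 10^(sgn * mag)
      ledger[[length(ledger) + 1]] <- tibble::tibble(
        aphia_id = s$aphia_id[ids], error_type = "unit_factor",
        factor_log10 = sgn * mag, report_index = idx_in_sp[pick])
    }
    if (any(colony_hit)) {
      ids <- which(colony_hit)
      pick <- offsets[ids] + vapply(counts[ids], function(k) sample.int(k, 1L), integer(1))
      mag <- stats::runif(length(ids), 2, 3.5)   # divide by 100 .. ~3160
      size_cm[pick] <- size_cm[pick] / 10^mag
      ledger[[length(ledger) + 1]] <- tibble::tibble(
        aphia_id = s$aphia_id[ids], error_type = "colony_factor",
        factor_log10 = -mag, report_index = idx_in_sp[pick])
    }
    error_ledger <- if (length(ledger) > 0) dplyr::bind_rows(ledger) else
      tibble::tibble(aphia_id = integer(), error_type = character(),
                     factor_log10 = numeric(), report_index = integer())

    records <- tibble::tibble(
      species_name = rep.int(s$species_name, counts),
      aphia_id = rep.int(s$aphia_id, counts),
      size_value = size_cm, size_unit = "cm",
      source_id = sprintf("synthetic_source_%02d", idx_in_sp),
      size_cm = size_cm
    )
    list(records = records, annotations = cohort$annotations,
         species_truth = species_truth, species_table = s,
         error_ledger = error_ledger, truth = truth)
  })
}

#' Write a simulated cohort in the ingest CSV schemas
#'
#' Emits `measurements.csv` and `annotations.csv` readable by
#' [read_measurements()] / [read_annotations()], plus `truth.json` holding the
#' generating parameters and the injected-error ledger.
#'
#' @param sim Result of [simulate_measurements()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$records[, c("species_name", "aphia_id", "size_value",
                                   "size_unit", "source_id")],
                   file.path(dir, "measurements.csv"))
  readr::write_csv(sim$annotations, file.path(dir, "annotations.csv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(parameters = unclass(truth), error_ledger = sim$error_ledger),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
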