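# End-to-end orchestration: summarize -> filter -> fit/compare -> post hocs ->
# distribution comparisons -> taxonomic hierarchy -> rank stability -> audit,
# with machine-readable outputs and a reproducibility manifest.

#' Validate a pipeline configuration
#'
#' @param measurements,annotations Paths to ingest CSVs, or `NULL` to
#'   simulate a cohort from `truth`.
#' @param truth A [simulation_truth()] used when no input paths are given.
#' @param out_dir Output directory.
#' @param unit_default Unit assumed for blank unit fields.
#' @param mean_mode Passed to [summarize_species()].
#' @param min_species Phylum-inclusion threshold.
#' @param specs Candidate model list (default [candidate_specs()]).
#' @param n_pairs,seed Rank-stability randomization settings.
#' @param thresholds Audit magnitude thresholds (strictly increasing).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(measurements = NULL, annotations = NULL,
                            truth = NULL, out_dir = "results",
                            unit_default = "cm",
                            mean_mode = "log_arithmetic",
                            min_species = 100,
                            specs = NULL,
                            n_pairs = 1000, seed = 1L,
                            thresholds = c(0.5, 1, 2)) {
  if (is.null(measurements) != is.null(annotations)) {
    stop("provide both measurement and annotation paths, or neither")
  }
  if (!is.null(measurements)) {
    for (p in c(measurements, annotations)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  } else if (is.null(truth)) {
    truth <- simulation_truth(seed = seed)
  }
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (is.null(specs)) specs <- candidate_specs()
  structure(list(measurements = measurements, annotations = annotations,
                 truth = truth, out_dir = out_dir, unit_default = unit_default,
                 mean_mode = mean_mode, min_species = min_species,
                 specs = specs, n_pairs = n_pairs, seed = as.integer(seed),
                 thresholds = thresholds),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [pipeline_config()] (scalar fields
#' only; the truth preset and candidate model set use package defaults).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(pipeline_config)))])
}

pipeline_stage <- function(log, stage, ...) {
  message(sprintf("[%s] %s", stage, paste(..., collapse = " ")))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either ingested CSVs or a simulated cohort, writes
#' CSV/JSON outputs under the configured directory, and records a manifest
#' (configuration digest, seed, package version) so reruns are auditable.
#' Deterministic given config and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result (`summaries`,
#'   `phylum_tally`, `comparison`, `best_fit`, `coef_table`, `emms`,
#'   `contrasts`, `distributions`, `hierarchy`, `rank_stability`, `audit`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$measurements)) {
    pipeline_stage(stage = "ingest", "reading", config$measurements)
    records <- read_measurements(config$measurements, config$unit_default)
    annotations <- read_annotations(config$annotations)
    error_ledger <- NULL
  } else {
    pipeline_stage(stage = "simulate", "paper-like cohort, n =",
                   config$truth$n_species)
    sim <- simulate_measurements(config$truth, seed = config$seed)
    records <- sim$records
    annotations <- sim$annotations
    error_ledger <- sim$error_ledger
  }
  pipeline_stage(stage = "ingest", nrow(records), "measurement records,",
                 nrow(annotations), "annotated species")

  summaries <- summarize_species(records, mean_mode = config$mean_mode)
  filt <- filter_phyla(summaries, annotations, config$min_species)
  dat <- filt$summaries
  pipeline_stage(stage = "summarize", nrow(summaries), "species summarized;",
                 nrow(dat), "retained after phylum filter")
  write_summaries(dat, file.path(out, "species_summaries.csv"))
  readr::write_csv(filt$phylum_tally, file.path(out, "phylum_tally.csv"))

  specs <- lapply(config$specs, adapt_spec_refs, dat = dat)
  estimable <- vapply(specs, function(sp) spec_estimable(sp, dat), logical(1))
  if (!all(estimable)) {
    pipeline_stage(stage = "fit", "dropping non-estimable candidate(s):",
                   paste(vapply(specs[!estimable], function(sp) sp$label,
                                character(1)), collapse = ", "))
    specs <- specs[estimable]
  }
  if (length(specs) == 0) stop("no estimable candidate model for this cohort")
  fits <- lapply(specs, function(sp) fit_hurdle(dat, spec = sp))
  comparison <- compare_models(fits)
  readr::write_csv(comparison, file.path(out, "model_comparison.csv"))
  best <- fits[[which.min(vapply(fits, function(f) f$aicc, numeric(1)))]]
  pipeline_stage(stage = "fit", "best model:", best$spec$label,
                 sprintf("(AICc %.2f)", best$aicc))
  coef_table <- dplyr::bind_rows(
    hurdle_coef_table(best, orientation = "nonzero"),
    hurdle_coef_table(best, orientation = "zero")
  )
  readr::write_csv(coef_table, file.path(out, "best_model_coefficients.csv"))

  post_factors <- intersect(best$spec$factors, c("phylum", "habitat"))
  if (length(post_factors) == 0) post_factors <- best$spec$factors[1]
  emms <- lapply(c(zero = "zero", conditional = "conditional"), function(cmp) {
    lapply(stats::setNames(post_factors, post_factors), function(f) {
      estimated_marginal_means(best, component = cmp, factors = f)
    })
  })
  contrasts <- lapply(emms, function(cmp) lapply(cmp, pairwise_contrasts))
  emm_flat <- dplyr::bind_rows(lapply(names(emms), function(cmp) {
    dplyr::bind_rows(lapply(names(emms[[cmp]]), function(f) {
      tab <- emms[[cmp]][[f]]$table
      tibble::tibble(component = cmp, factor = f,
                     level = tab[[f]], emmean = tab$emmean,
                     se = tab$se, response = tab$response)
    }))
  }))
  readr::write_csv(emm_flat, file.path(out, "marginal_means.csv"))
  ctr_flat <- dplyr::bind_rows(lapply(names(contrasts), function(cmp) {
    dplyr::bind_rows(lapply(names(contrasts[[cmp]]), function(f) {
      dplyr::mutate(contrasts[[cmp]][[f]], component = cmp, factor = f,
                    .before = 1)
    }))
  }))
  readr::write_csv(ctr_flat, file.path(out, "tukey_contrasts.csv"))
  pipeline_stage(stage = "posthoc", nrow(ctr_flat), "Tukey contrasts")

  distributions <- compare_size_distributions(dat)
  readr::write_csv(distributions, file.path(out, "distribution_tests.csv"))

  hierarchy <- dplyr::bind_rows(lapply(c("order", "family", "genus", "species"),
    function(lv) taxon_interspecific_ranges(dat, annotations, lv)))
  readr::write_csv(hierarchy, file.path(out, "taxon_ranges.csv"))
  pipeline_stage(stage = "hierarchy", nrow(hierarchy), "taxon ranges")

  ms <- measurements_by_species(records[records$aphia_id %in% dat$aphia_id, ])
  rs <- rank_stability(ms, n_pairs = config$n_pairs, seed = config$seed)
  jsonlite::write_json(
    list(summary = rs$summary, n_pairs = rs$n_pairs, seed = rs$seed,
         n_species = rs$n_species, rank_convention = rs$rank_convention),
    file.path(out, "rank_stability.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(
    tibble::tibble(pair = seq_len(rs$n_pairs), rho = rs$rho,
                   median_change = rs$median_change,
                   max_change = rs$max_change,
                   largest_mover = rs$largest_mover),
    file.path(out, "rank_stability_pairs.csv"))
  pipeline_stage(stage = "rank_stability",
                 sprintf("mean rho %.4f", rs$summary$mean_rho))

  audit <- flag_extreme_species(dat, records, thresholds = config$thresholds)
  readr::write_csv(audit$species, file.path(out, "audit_extreme_species.csv"))
  readr::write_csv(audit$tallies$disjoint, file.path(out, "audit_tallies.csv"))
  pipeline_stage(stage = "audit", nrow(audit$species), "species flagged at >=",
                 config$thresholds[1], "orders")

  manifest <- list(
    seed = config$seed,
    n_species = nrow(dat),
    n_measurements = nrow(records),
    package_version = as.character(utils::packageVersion("sizerange")),
    config_digest = config_digest(config)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(summaries = dat, phylum_tally = filt$phylum_tally,
                 fits = fits, comparison = comparison, best_fit = best,
                 coef_table = coef_table, emms = emms, contrasts = contrasts,
                 distributions = distributions, hierarchy = hierarchy,
                 rank_stability = rs, audit = audit,
                 error_ledger = error_ledger, manifest = manifest))
}

# A candidate is estimable when each of its factors has >= 2 observed levels
# both overall and within the positive-range subset.
spec_estimable <- function(spec, dat) {
  if ("invertebrate" %in% spec$factors && !"invertebrate" %in% names(dat) &&
      "phylum" %in% names(dat)) {
    dat$invertebrate <- dat$phylum != "Chordata"
  }
  pos <- dat[dat$maxsize_range > 0, , drop = FALSE]
  all(vapply(spec$factors, function(f) {
    length(unique(as.character(dat[[f]]))) >= 2 &&
      identical(sort(unique(as.character(dat[[f]]))),
                sort(unique(as.character(pos[[f]]))))
  }, logical(1)))
}

# When the phylum filter removes a spec's configured reference level (small
# cohorts), fall back to the first observed level in locale-independent sort.
adapt_spec_refs <- function(spec, dat) {
  if ("invertebrate" %in% spec$factors && !"invertebrate" %in% names(dat) &&
      "phylum" %in% names(dat)) {
    dat$invertebrate <- dat$phylum != "Chordata"
  }
  for (f in spec$factors) {
    obs <- unique(as.character(dat[[f]]))
    if (!spec$reference_levels[[f]] %in% obs) {
      spec$reference_levels[[f]] <- sort(obs, method = "radix")[1]
    }
  }
  spec
}

# Content digest of the configuration, independent of environment state.
config_digest <- function(config) {
  x <- config
  x$specs <- vapply(x$specs, function(sp) sp$label, character(1))
  txt <- paste(utils::capture.output(utils::str(x, digits.d = 12)), collapse = "\n")
  # small rolling hash; avoids a digest dependency for a provenance string
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
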