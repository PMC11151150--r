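#' Accepted linear-size unit tokens
#'
#' Sizes are reported as the largest linear dimension (length, height, width,
#' or diameter) and are normalized internally to centimetres.
#'
#' @format Named numeric vector: multiplicative factor to centimetres.
#' @export
SIZE_UNIT_FACTORS <- c(um = 1e-4, mm = 0.1, cm = 1, m = 100)

#' Convert a linear size to centimetres
#'
#' @param size_value Positive numeric vector of sizes.
#' @param size_unit Character vector of unit tokens, one of
#'   `"um"`, `"mm"`, `"cm"`, `"m"` (case-insensitive). Recycled if length 1.
#' @return Numeric vector of sizes in centimetres.
#' @examples
#' to_cm(45.72, "m")   # 4572
#' to_cm(195, "um")    # 0.0195
#' @export
to_cm <- function(size_value, size_unit) {
  unit <- tolower(as.character(size_unit))
  if (length(unit) == 1L) unit <- rep(unit, length(size_value))
  stopifnot(length(unit) == length(size_value))
  bad <- !(unit %in% names(SIZE_UNIT_FACTORS))
  if (any(bad)) {
    stop("unrecognized size unit(s): ", paste(unique(unit[bad]), collapse = ", "),
         "; accepted tokens: ", paste(names(SIZE_UNIT_FACTORS), collapse = ", "))
  }
  unname(as.numeric(size_value) * SIZE_UNIT_FACTORS[unit])
}

#' Read a measurement-level table of reported maximum sizes
#'
#' One row per (species, source) report. All sizes are retained verbatim:
#' no quality control is applied at ingest, so typographical and unit errors
#' in the source literature flow through to the range statistics by design.
#'
#' @param path Path to a UTF-8 CSV with header and required columns
#'   `species_name, aphia_id, size_value, size_unit, source_id`.
#' @param unit_default Unit token assumed when `size_unit` is empty or `NA`.
#' @return A tibble of measurement records with `size_cm` appended.
#' @export
read_measurements <- function(path, unit_default = "cm") {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("species_name", "aphia_id", "size_value", "size_unit", "source_id")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(species_name = character(), aphia_id = integer(),
                          size_value = numeric(), size_unit = character(),
                          source_id = character(), size_cm = numeric()))
  }
  size_num <- suppressWarnings(as.numeric(raw$size_value))
  bad_size <- is.na(size_num) | size_num <= 0
  if (any(bad_size)) {
    stop("non-positive or non-numeric size_value at data row(s): ",
         paste(utils::head(which(bad_size), 10), collapse = ", "))
  }
  aphia <- suppressWarnings(as.integer(raw$aphia_id))
  if (any(is.na(aphia) | aphia <= 0)) {
    stop("aphia_id must be a positive integer; bad row(s): ",
         paste(utils::head(which(is.na(aphia) | aphia <= 0), 10), collapse = ", "))
  }
  unit <- tolower(trimws(raw$size_unit))
  unit[is.na(unit) | unit == ""] <- tolower(unit_default)
  bad_unit <- !(unit %in% names(SIZE_UNIT_FACTORS))
  if (any(bad_unit)) {
    stop("unknown size_unit token(s): ",
         paste(unique(unit[bad_unit]), collapse = ", "),
         "; accepted tokens: ", paste(names(SIZE_UNIT_FACTORS), collapse = ", "))
  }
  tibble::tibble(
    species_name = raw$species_name,
    aphia_id = aphia,
    size_value = size_num,
    size_unit = unit,
    source_id = raw$source_id,
    size_cm = to_cm(size_num, unit)
  )
}

#' Read per-species annotations (taxonomy, habitat, skeleton)
#'
#' @param path CSV with columns `aphia_id, phylum` and optionally
#'   `class, order, family, genus, habitat, skeleton, invertebrate`.
#'   Habitat and skeleton tokens are case-insensitive; empty or unknown
#'   habitat maps to `"unspecified"`.
#' @return A tibble, one row per species.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("aphia_id", "phylum")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("class", "order", "family", "genus")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  habitat <- if ("habitat" %in% names(raw)) tolower(trimws(as.character(raw$habitat))) else rep(NA_character_, nrow(raw))
  habitat[is.na(habitat) | habitat == "" | habitat == "unknown"] <- "unspecified"
  bad_h <- !(habitat %in% c("benthic", "pelagic", "unspecified"))
  if (any(bad_h)) {
    stop("unknown habitat token(s): ", paste(unique(habitat[bad_h]), collapse = ", "))
  }
  skeleton <- if ("skeleton" %in% names(raw)) tolower(trimws(as.character(raw$skeleton))) else rep("none", nrow(raw))
  skeleton[is.na(skeleton) | skeleton == ""] <- "none"
  bad_s <- !(skeleton %in% c("none", "exoskeleton", "endoskeleton"))
  if (any(bad_s)) {
    stop("unknown skeleton token(s): ", paste(unique(skeleton[bad_s]), collapse = ", "))
  }
  out <- tibble::tibble(
    aphia_id = as.integer(raw$aphia_id),
    phylum = as.character(raw$phylum),
    class = as.character(raw$class),
    order = as.character(raw$order),
    family = as.character(raw$family),
    genus = as.character(raw$genus),
    habitat = habitat,
    skeleton = skeleton
  )
  out$invertebrate <- if ("invertebrate" %in% names(raw)) {
    as.logical(raw$invertebrate)
  } else {
    out$phylum != "Chordata"
  }
  out
}

#' Assign the four-level measurement-count category
#'
#' Counts of reports per species are treated as a categorical variable with
#' levels 2, 3, 4-5 and >= 6; treating count as continuous destabilizes the
#' regression because high counts are rare.
#'
#' @param count Integer vector of per-species report counts, all >= 2.
#' @return Factor with levels `c2, c3, c4_5, c6plus`.
#' @export
assign_count_class <- function(count) {
  if (any(count < 2)) stop("count must be >= 2 (species need multiple reports)")
  cls <- ifelse(count == 2, "c2",
         ifelse(count == 3, "c3",
         ifelse(count <= 5, "c4_5", "c6plus")))
  factor(cls, levels = count_class_levels())
}

count_class_levels <- function() c("c2", "c3", "c4_5", "c6plus")

#' Summarize reported maximum sizes per species
#'
#' For each species with at least two reports, computes the smallest, largest
#' and mean reported maximum size (cm), their log10 values, and the range
#' statistic
#' \deqn{range = \log_{10}(largest) - \log_{10}(smallest),}
#' the log-ratio of the most extreme reports, in orders of magnitude. A species
#' whose reports are all identical has range exactly 0.
#'
#' @param records Tibble of measurement records with at least
#'   `aphia_id, species_name, size_cm` (as from [read_measurements()]).
#' @param mean_mode `"log_arithmetic"` (default; mean of log10 sizes, i.e. the
#'   geometric mean on the raw scale) or `"raw_arithmetic"` (arithmetic mean of
#'   cm sizes).
#' @return Tibble with one row per species: `aphia_id, species_name, count,
#'   count_class, maxsize_smallest, maxsize_largest, maxsize_mean,
#'   log10_smallest, log10_largest, log10_mean, maxsize_range`.
#'   Species with fewer than two reports are dropped with a warning.
#' @export
summarize_species <- function(records, mean_mode = c("log_arithmetic", "raw_arithmetic")) {
  mean_mode <- match.arg(mean_mode)
  stopifnot(all(c("aphia_id", "size_cm") %in% names(records)))
  if (any(records$size_cm <= 0)) stop("all sizes must be positive")
  if (!"species_name" %in% names(records)) records$species_name <- NA_character_

  counts <- table(records$aphia_id)
  singletons <- names(counts)[counts < 2]
  if (length(singletons) > 0) {
    warning(length(singletons),
            " species excluded with < 2 size reports (study universe requires >= 2)")
    records <- records[!(as.character(records$aphia_id) %in% singletons), , drop = FALSE]
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(aphia_id = integer(), species_name = character(),
                          count = integer(), count_class = factor(character(), levels = count_class_levels()),
                          maxsize_smallest = numeric(), maxsize_largest = numeric(),
                          maxsize_mean = numeric(), log10_smallest = numeric(),
                          log10_largest = numeric(), log10_mean = numeric(),
                          maxsize_range = numeric()))
  }

  out <- records |>
    dplyr::group_by(.data$aphia_id) |>
    dplyr::summarise(
      species_name = dplyr::first(.data$species_name),
      count = dplyr::n(),
      maxsize_smallest = min(.data$size_cm),
      maxsize_largest = max(.data$size_cm),
      mean_raw = mean(.data$size_cm),
      log10_mean = mean(log10(.data$size_cm)),
      .groups = "drop"
    )
  out$count_class <- assign_count_class(out$count)
  out$log10_smallest <- log10(out$maxsize_smallest)
  out$log10_largest <- log10(out$maxsize_largest)
  if (mean_mode == "log_arithmetic") {
    out$maxsize_mean <- 10^out$log10_mean
  } else {
    out$maxsize_mean <- out$mean_raw
    out$log10_mean <- log10(out$mean_raw)
  }
  # exact zero when all reports are equal; avoids -0.0 / rounding residue
  out$maxsize_range <- ifelse(out$maxsize_smallest == out$maxsize_largest, 0,
                              out$log10_largest - out$log10_smallest)
  out[, c("aphia_id", "species_name", "count", "count_class",
          "maxsize_smallest", "maxsize_largest", "maxsize_mean",
          "log10_smallest", "log10_largest", "log10_mean", "maxsize_range")]
}

#' Restrict the cohort to well-sampled phyla
#'
#' Keeps only species belonging to phyla represented by at least `min_species`
#' species in the input, the inclusion rule used for all regression analyses.
#'
#' @param summaries Per-species summary tibble (see [summarize_species()]).
#' @param annotations Annotation tibble with `aphia_id, phylum` (and
#'   optionally habitat/skeleton for the tally).
#' @param min_species Minimum number of species a phylum must have.
#' @return List with `summaries` (filtered, annotation columns joined) and
#'   `phylum_tally` (per-phylum species counts by habitat and skeleton).
#' @export
filter_phyla <- function(summaries, annotations, min_species = 100) {
  dat <- dplyr::inner_join(summaries, annotations, by = "aphia_id")
  if (nrow(dat) < nrow(summaries)) {
    stop(nrow(summaries) - nrow(dat), " species lack a phylum annotation")
  }
  tally <- dat |>
    dplyr::count(.data$phylum, name = "n_species") |>
    dplyr::arrange(.data$phylum)
  if (all(c("habitat", "skeleton") %in% names(dat))) {
    hab <- dat |>
      dplyr::count(.data$phylum, .data$habitat) |>
      tidyr::pivot_wider(names_from = "habitat", values_from = "n", values_fill = 0L)
    ske <- dat |>
      dplyr::count(.data$phylum, .data$skeleton) |>
      tidyr::pivot_wider(names_from = "skeleton", values_from = "n", values_fill = 0L)
    tally <- tally |>
      dplyr::left_join(hab, by = "phylum") |>
      dplyr::left_join(ske, by = "phylum")
  }
  keep <- tally$phylum[tally$n_species >= min_species]
  list(summaries = dat[dat$phylum %in% keep, , drop = FALSE],
       phylum_tally = tally)
}

magnitude_levels <- function() c("zero", "lt_half", "half_to_one", "one_to_two", "gt_two")

#' Classify a range value into order-of-magnitude bins
#'
#' Bins are disjoint: exactly zero; (0, 0.5); \[0.5, 1); \[1, 2\]; strictly
#' above 2. Interior bins are half-open at the low edge so a range of exactly
#' 0.5 falls in `half_to_one`; `gt_two` requires strict exceedance of two
#' orders of magnitude.
#'
#' @param maxsize_range Numeric vector of range values (>= 0).
#' @return Factor with levels `zero, lt_half, half_to_one, one_to_two, gt_two`.
#' @export
classify_range_magnitude <- function(maxsize_range) {
  if (any(maxsize_range < 0)) stop("maxsize_range must be non-negative")
  cls <- ifelse(maxsize_range == 0, "zero",
         ifelse(maxsize_range < 0.5, "lt_half",
         ifelse(maxsize_range < 1, "half_to_one",
         ifelse(maxsize_range <= 2, "one_to_two", "gt_two"))))
  factor(cls, levels = magnitude_levels())
}

#' Tally range magnitudes, both disjoint and cumulative
#'
#' Reports disjoint bin counts and the cumulative counts of species whose
#' range exceeds half, one and two orders of magnitude, so either reading of
#' "varied by half an order / one order / two orders" can be audited.
#'
#' @param maxsize_range Numeric vector of range values.
#' @return List with `disjoint` (tibble of bin counts and percentages) and
#'   `cumulative` (tibble of threshold exceedance counts and percentages).
#' @export
magnitude_tallies <- function(maxsize_range) {
  cls <- classify_range_magnitude(maxsize_range)
  counts <- as.integer(table(cls))
  disjoint <- tibble::tibble(magnitude_class = magnitude_levels(), n = counts,
                             pct = 100 * counts / length(maxsize_range))
  thr <- c(0.5, 1, 2)
  exceed <- vapply(thr, function(t) sum(maxsize_range > t), integer(1))
  cumulative <- tibble::tibble(threshold = thr, n = exceed,
                               pct = 100 * exceed / length(maxsize_range))
  list(disjoint = disjoint, cumulative = cumulative)
}

#' Write / read per-species summaries
#'
#' CSV round-trip preserves values to full double precision.
#'
#' @param summaries Summary tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  out <- summaries
  out$count_class <- as.character(out$count_class)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$count_class <- factor(out$count_class, levels = count_class_levels())
  out$aphia_id <- as.integer(out$aphia_id)
  out$count <- as.integer(out$count)
  tibble::as_tibble(out)
}
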