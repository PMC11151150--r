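# Rank-stability randomization: repeatedly draw one reported maximum size per
# species, rank all species, and quantify how much the rank order moves.

#' Ragged per-species measurement structure
#'
#' Packs measurement-level records into a flat-value / offset representation
#' so that one draw per species is a single vectorized operation.
#'
#' @param records Measurement tibble with `aphia_id` and `size_cm`.
#' @return Object of class `species_measurements`: `aphia_id`, `values`
#'   (concatenated cm sizes, species-contiguous), `offsets`, `counts`.
#' @export
measurements_by_species <- function(records) {
  stopifnot(all(c("aphia_id", "size_cm") %in% names(records)))
  if (nrow(records) == 0) stop("no measurements")
  ord <- order(records$aphia_id)
  values <- records$size_cm[ord]
  ids <- records$aphia_id[ord]
  counts <- as.integer(table(ids))
  if (any(counts == 0)) stop("species with empty measurement list")
  structure(list(
    aphia_id = unique(ids),
    values = values,
    offsets = c(0L, cumsum(counts))[seq_along(counts)],
    counts = counts
  ), class = "species_measurements")
}

# One uniform draw per species over its recorded reports (duplicates included
# unless distinct_only).
draw_sizes <- function(ms, distinct_only = FALSE) {
  if (distinct_only) {
    vals <- ms$values
    idx <- mapply(function(o, k) {
      d <- unique(vals[(o + 1):(o + k)])
      d[sample.int(length(d), 1L)]
    }, ms$offsets, ms$counts)
    return(as.numeric(idx))
  }
  pick <- ms$offsets + 1L + as.integer(floor(stats::runif(length(ms$counts)) * ms$counts))
  ms$values[pick]
}

#' Draw one body-size ranking
#'
#' Draws a single reported maximum size per species (uniformly over its
#' reports) and ranks species ascending by the drawn size, ties receiving
#' average ranks. Uses the current RNG state; seed externally or via
#' [rank_stability()].
#'
#' @param ms A `species_measurements` structure.
#' @param distinct_only Draw over distinct reported values rather than all
#'   reports (duplicated reports encode report frequency, so the default
#'   keeps them).
#' @return Numeric rank vector aligned with `ms$aphia_id`.
#' @export
draw_ranking <- function(ms, distinct_only = FALSE) {
  stopifnot(inherits(ms, "species_measurements"))
  rank(draw_sizes(ms, distinct_only), ties.method = "average")
}

#' Rank-stability randomization
#'
#' Generates `n_pairs` pairs of body-size rankings, each ranking obtained by
#' independently drawing a single reported maximum per species. For each pair
#' it records the Spearman correlation between the two rank vectors, the
#' median and maximum absolute change in species rank position, and the
#' species attaining the maximum change (ties broken deterministically by the
#' smallest species id).
#'
#' @param ms A `species_measurements` structure with at least 2 species.
#' @param n_pairs Number of ranking pairs (>= 1).
#' @param seed Integer seed; the full result is reproducible.
#' @param distinct_only See [draw_ranking()].
#' @return Object of class `rank_stability_result`: per-pair vectors `rho`,
#'   `median_change`, `max_change`, `largest_mover`; `mover_counts` (times
#'   each species was the largest mover); `summary` (mean rho, median of
#'   medians, max of maxes); `n_pairs`, `seed`, `n_species`.
#' @export
rank_stability <- function(ms, n_pairs = 1000, seed = 1L, distinct_only = FALSE) {
  stopifnot(inherits(ms, "species_measurements"))
  if (length(ms$aphia_id) < 2) stop("need at least 2 species")
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  local_seed(seed, {
    rho <- numeric(n_pairs)
    med_change <- numeric(n_pairs)
    max_change <- numeric(n_pairs)
    mover <- integer(n_pairs)
    for (i in seq_len(n_pairs)) {
      r1 <- draw_ranking(ms, distinct_only)
      r2 <- draw_ranking(ms, distinct_only)
      d <- abs(r1 - r2)
      rho[i] <- if (stats::sd(r1) == 0 || stats::sd(r2) == 0) 1 else stats::cor(r1, r2)
      med_change[i] <- stats::median(d)
      max_change[i] <- max(d)
      mover[i] <- if (max_change[i] > 0) ms$aphia_id[which.max(d)] else NA_integer_
    }
    mover_counts <- table(factor(mover[!is.na(mover)], levels = ms$aphia_id))
    structure(list(
      rho = rho, median_change = med_change, max_change = max_change,
      largest_mover = mover,
      mover_counts = tibble::tibble(aphia_id = ms$aphia_id,
                                    times_largest_mover = as.integer(mover_counts)),
      summary = list(mean_rho = mean(rho),
                     median_of_medians = stats::median(med_change),
                     max_of_maxes = max(max_change)),
      n_pairs = as.integer(n_pairs), seed = as.integer(seed),
      n_species = length(ms$aphia_id),
      rank_convention = "ascending size, ties averaged"
    ), class = "rank_stability_result")
  })
}

#' @export
print.rank_stability_result <- function(x, ...) {
  cat(sprintf("rank stability: %d pairs over %d species (seed %d)\n",
              x$n_pairs, x$n_species, x$seed))
  cat(sprintf("  mean rank correlation %.4f; median displacement %.1f; max %.0f\n",
              x$summary$mean_rho, x$summary$median_of_medians, x$summary$max_of_maxes))
  invisible(x)
}

#' Species most often responsible for the largest rank shift
#'
#' @param result A `rank_stability_result`.
#' @param k Number of species to return.
#' @return Tibble of species sorted by times-largest-mover then mean
#'   displacement; species that never moved are excluded.
#' @export
top_movers <- function(result, k = 10) {
  stopifnot(inherits(result, "rank_stability_result"))
  mc <- result$mover_counts[result$mover_counts$times_largest_mover > 0, , drop = FALSE]
  if (nrow(mc) == 0) return(mc)
  mean_disp <- vapply(mc$aphia_id, function(id) {
    hit <- result$largest_mover == id & !is.na(result$largest_mover)
    if (!any(hit)) 0 else mean(result$max_change[hit])
  }, numeric(1))
  mc$mean_displacement <- mean_disp
  mc <- mc[order(-mc$times_largest_mover, -mc$mean_displacement), ]
  utils::head(mc, k)
}
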