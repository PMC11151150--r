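# Extreme-range audit: order-of-magnitude tallies and advisory cause tags for
# species whose reports disagree grossly. Tags never drop records; the study's
# no-quality-control stance is preserved and a human interprets the flags.

#' Flag species with extreme ranges and suggest causes
#'
#' Every species is binned by [classify_range_magnitude()]; species at or
#' above the lowest threshold appear in the per-species section with an
#' advisory suspected-cause tag:
#' \describe{
#'   \item{unit_error_candidate}{`log10(largest/smallest)` within 5%
#'     (relative) of a whole number of decades `k >= 1`, the signature of a
#'     report off by a factor of 10/100/1000.}
#'   \item{colony_vs_module_candidate}{range above two orders with at least 3
#'     reports, most clustered within half an order of the smallest — the
#'     pattern left when one report is a colony dimension and the rest
#'     measure individual modules (requires `records`).}
#'   \item{unknown}{everything else; includes width-vs-length mixtures, which
#'     have no within-species numeric signature.}
#' }
#'
#' @param summaries Per-species summaries (annotations joined if available;
#'   `phylum`/`habitat` columns are carried through when present).
#' @param records Optional measurement tibble (enables the clustering
#'   heuristic).
#' @param thresholds Strictly increasing magnitude thresholds.
#' @return Object of class `audit_report`: `species` (per-species rows at or
#'   above the lowest threshold), `tallies` (disjoint and cumulative, over all
#'   species), `n_species`.
#' @export
flag_extreme_species <- function(summaries, records = NULL,
                                 thresholds = c(0.5, 1, 2)) {
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  s <- summaries
  s$magnitude_class <- classify_range_magnitude(s$maxsize_range)
  tallies <- magnitude_tallies(s$maxsize_range)

  extreme <- s[s$maxsize_range >= thresholds[1], , drop = FALSE]
  tag <- rep("unknown", nrow(extreme))

  lr <- extreme$maxsize_range
  k <- round(lr)
  unit_cand <- k >= 1 & abs(lr - k) <= 0.05 * k
  tag[unit_cand] <- "unit_error_candidate"

  if (!is.null(records) && nrow(extreme) > 0) {
    cl <- vapply(seq_len(nrow(extreme)), function(i) {
      if (extreme$maxsize_range[i] <= 2 || extreme$count[i] < 3) return(FALSE)
      sz <- records$size_cm[records$aphia_id == extreme$aphia_id[i]]
      near_small <- sum(log10(sz) - log10(min(sz)) <= 0.5)
      near_small >= length(sz) - 1   # all but the colony-scale report
    }, logical(1))
    tag[cl & !unit_cand] <- "colony_vs_module_candidate"
  }
  extreme$suspected_cause <- tag

  keep <- intersect(c("aphia_id", "species_name", "phylum", "habitat", "count",
                      "maxsize_smallest", "maxsize_largest", "maxsize_range",
                      "magnitude_class", "suspected_cause"), names(extreme))
  structure(list(species = extreme[order(-extreme$maxsize_range), keep],
                 tallies = tallies, n_species = nrow(s),
                 thresholds = thresholds),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("extreme-range audit over", x$n_species, "species\n")
  print(x$tallies$disjoint)
  cat("cumulative exceedances:\n")
  print(x$tallies$cumulative)
  cat(nrow(x$species), "species at or above", x$thresholds[1],
      "orders of magnitude\n")
  invisible(x)
}

#' Recall of injected gross errors by the extreme-range flag
#'
#' Fraction of species carrying an injected error of at least `min_decades`
#' decades (per the simulation truth ledger) that the audit flags strictly
#' above two orders of magnitude.
#'
#' @param report An `audit_report`.
#' @param error_ledger Ledger from [simulate_measurements()].
#' @param min_decades Injected-error magnitude that must force a flag.
#' @return List: `recall`, `n_injected`, `n_recovered`.
#' @export
audit_recall <- function(report, error_ledger, min_decades = 2.5) {
  injected <- unique(error_ledger$aphia_id[abs(error_ledger$factor_log10) >= min_decades])
  if (length(injected) == 0) {
    return(list(recall = NA_real_, n_injected = 0L, n_recovered = 0L))
  }
  flagged <- report$species$aphia_id[report$species$magnitude_class == "gt_two"]
  rec <- sum(injected %in% flagged)
  list(recall = rec / length(injected),
       n_injected = length(injected), n_recovered = rec)
}
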