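#' Specify a hurdle regression model
#'
#' The response is the per-species range statistic; both hurdle components use
#' the identical predictor set: a continuous log10 smallest-maximum-size term,
#' categorical terms, and continuous-by-factor interactions.
#'
#' @param continuous Character vector of continuous term names
#'   (default `"log10_smallest"`).
#' @param factors Character vector of factor term names drawn from
#'   `count_class, phylum, habitat, skeleton, invertebrate`.
#' @param interactions List of length-2 character vectors
#'   `c(continuous, factor)`; default: the continuous term crossed with every
#'   factor term (the structure of the study's models).
#' @param reference_levels Named character vector giving the treatment-coding
#'   reference level for each factor; defaults: `count_class = "c2"`,
#'   `phylum = "Annelida"`, `habitat = "benthic"`, `skeleton = "none"`,
#'   `invertebrate = "FALSE"`.
#' @param label Optional display label for model-comparison tables.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(continuous = "log10_smallest",
                       factors = c("count_class", "phylum", "habitat"),
                       interactions = NULL,
                       reference_levels = NULL,
                       label = NULL) {
  defaults <- c(count_class = "c2", phylum = "Annelida", habitat = "benthic",
                skeleton = "none", invertebrate = "FALSE")
  refs <- defaults[factors]
  names(refs) <- factors
  if (!is.null(reference_levels)) {
    refs[names(reference_levels)] <- reference_levels
  }
  if (is.null(interactions)) {
    interactions <- lapply(factors, function(f) c(continuous[1], f))
  }
  for (ia in interactions) {
    if (length(ia) != 2 || !(ia[1] %in% continuous) || !(ia[2] %in% factors)) {
      stop("interaction must pair a declared continuous term with a declared factor: ",
           paste(ia, collapse = ":"))
    }
  }
  if (is.null(label)) label <- paste(factors, collapse = " + ")
  structure(list(response = "maxsize_range", continuous = continuous,
                 factors = factors, interactions = interactions,
                 reference_levels = refs, label = label),
            class = "model_spec")
}

#' The study's candidate model set
#'
#' Seven specifications competing on AICc, each with the continuous size term,
#' the count category, their interaction, and the named grouping factor(s)
#' with their size interactions: phylum + habitat, phylum, skeleton + habitat,
#' invertebrate + habitat, habitat, skeleton, invertebrate.
#'
#' @return Named list of `model_spec` objects.
#' @export
candidate_specs <- function() {
  sets <- list(
    "phylum+habitat"       = c("phylum", "habitat"),
    "phylum"               = "phylum",
    "skeleton+habitat"     = c("skeleton", "habitat"),
    "invertebrate+habitat" = c("invertebrate", "habitat"),
    "habitat"              = "habitat",
    "skeleton"             = "skeleton",
    "invertebrate"         = "invertebrate"
  )
  out <- lapply(names(sets), function(lab) {
    model_spec(factors = c("count_class", sets[[lab]]), label = lab)
  })
  names(out) <- names(sets)
  out
}

# Factor with reference level first, remaining levels in C-locale order.
ref_first_factor <- function(x, ref, term) {
  x <- as.character(x)
  obs <- unique(x)
  if (!ref %in% obs) {
    stop("reference level '", ref, "' for factor '", term, "' not observed in data")
  }
  if (length(obs) < 2) stop("factor '", term, "' is constant; cannot enter the model")
  lev <- c(ref, sort(setdiff(obs, ref), method = "radix"))
  factor(x, levels = lev)
}

spec_formula <- function(spec) {
  terms <- c(spec$continuous, spec$factors,
             vapply(spec$interactions, function(ia) paste(ia, collapse = ":"), character(1)))
  stats::as.formula(paste("~", paste(terms, collapse = " + ")))
}

#' Build a treatment-coded design matrix for a model specification
#'
#' Columns are ordered deterministically: intercept, continuous terms, factor
#' dummies (factors in spec order, levels in locale-independent sort with the
#' reference level dropped), then interaction columns. Interaction columns are
#' elementwise products of the continuous value and the factor dummy.
#'
#' @param data Tibble holding every term of `spec` (per-species summaries
#'   joined with annotations).
#' @param spec A [model_spec()].
#' @return Object of class `design_matrix`: list with `X` (numeric matrix,
#'   rownames = aphia_id where available), `spec`, `formula`, and `xlev`
#'   (observed factor levels, reference first).
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c(spec$continuous, spec$factors)
  missing_terms <- setdiff(need, names(data))
  if (length(missing_terms) > 0) {
    stop("data lack model term(s): ", paste(missing_terms, collapse = ", "))
  }
  df <- as.data.frame(data[, need, drop = FALSE])
  for (f in spec$factors) {
    df[[f]] <- ref_first_factor(df[[f]], spec$reference_levels[[f]], f)
  }
  for (cn in spec$continuous) {
    if (!is.numeric(df[[cn]])) stop("continuous term '", cn, "' is not numeric")
    if (anyNA(df[[cn]])) stop("continuous term '", cn, "' has missing values")
  }
  fml <- spec_formula(spec)
  xlev <- lapply(df[spec$factors], levels)
  X <- stats::model.matrix(fml, df)
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  if ("aphia_id" %in% names(data)) rownames(X) <- as.character(data$aphia_id)
  structure(list(X = X, spec = spec, formula = fml, xlev = xlev),
            class = "design_matrix")
}

# Model-matrix rows for new covariate values, using the levels frozen at fit
# time (so EMM grids and effect curves share the training coding).
design_rows <- function(design, newdata) {
  df <- as.data.frame(newdata)
  for (f in design$spec$factors) {
    bad <- !(as.character(df[[f]]) %in% design$xlev[[f]])
    if (any(bad)) {
      stop("unknown level(s) for factor '", f, "': ",
           paste(unique(df[[f]][bad]), collapse = ", "))
    }
    df[[f]] <- factor(as.character(df[[f]]), levels = design$xlev[[f]])
  }
  stats::model.matrix(design$formula, df, xlev = design$xlev)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("hurdle model spec:", x$label, "\n")
  cat("  ", deparse(spec_formula(x)), "\n")
  cat("  reference levels:",
      paste(names(x$reference_levels), x$reference_levels, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
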