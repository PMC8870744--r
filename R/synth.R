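#' Specify a synthetic patient cohort
#'
#' Describes the generative model behind [simulate_cohort()]: diagnostic
#' categories, per-category per-CAFPA beta distributions, the cohort size and
#' the rate of dual-labeled patients.  The generator mirrors the structure of
#' expert-labeled audiological data sets: each patient carries one or (for a
#' designated comparison pair) two diagnostic-category labels, and the CAFPA
#' profile of a category follows per-CAFPA beta distributions.
#'
#' @param categories Character vector of category labels (>= 1).
#' @param beta_params Named list, one element per category.  Each element is a
#'   list with components `a` and `b`, scalars or length-10 vectors of
#'   strictly positive beta shape parameters (recycled across the ten CAFPAs).
#' @param n_per_category Integer, patients drawn per category (>= 1).
#' @param dual_label_fraction Probability in \[0, 1\] that a patient of the
#'   `dual_pair` categories carries both labels of that pair.
#' @param dual_pair Character vector of two category labels forming the
#'   designated comparison pair for dual labeling; default the first two
#'   categories (ignored when fewer than two categories exist).
#' @param missing_rate Probability that an individual CAFPA value is missing.
#' @param correlation Optional 10 x 10 positive-definite correlation matrix;
#'   when supplied, CAFPAs are coupled through a Gaussian copula while keeping
#'   the per-CAFPA beta marginals.  Default `NULL` (independent CAFPAs).
#' @param seed Integer master seed.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [default_cohort_spec()]
#' @export
cohort_spec <- function(categories, beta_params, n_per_category = 80L,
                        dual_label_fraction = 0.1,
                        dual_pair = NULL, missing_rate = 0,
                        correlation = NULL, seed = 1L) {
  categories <- as.character(categories)
  if (length(categories) < 1L || anyDuplicated(categories))
    stop("categories must be a non-empty set of distinct labels", call. = FALSE)
  if (!is.list(beta_params) || !setequal(names(beta_params), categories))
    stop("beta_params must be a named list with one element per category",
         call. = FALSE)
  shapes <- lapply(categories, function(cat) {
    p <- beta_params[[cat]]
    a <- rep_len(as.numeric(p$a), length(CAFPA_NAMES))
    b <- rep_len(as.numeric(p$b), length(CAFPA_NAMES))
    bad <- which(!is.finite(a) | !is.finite(b) | a <= 0 | b <= 0)
    if (length(bad) > 0L)
      stop("invalid beta parameters (must be > 0) for category '", cat,
           "', CAFPA ", paste(CAFPA_NAMES[bad], collapse = ", "),
           call. = FALSE)
    list(a = setNames(a, CAFPA_NAMES), b = setNames(b, CAFPA_NAMES))
  })
  names(shapes) <- categories
  n_per_category <- as.integer(n_per_category)
  if (is.na(n_per_category) || n_per_category < 1L)
    stop("n_per_category must be >= 1", call. = FALSE)
  if (dual_label_fraction < 0 || dual_label_fraction > 1)
    stop("dual_label_fraction must lie in [0, 1]", call. = FALSE)
  if (is.null(dual_pair) && length(categories) >= 2L)
    dual_pair <- categories[1:2]
  if (!is.null(dual_pair)) {
    dual_pair <- as.character(dual_pair)
    if (length(dual_pair) != 2L || !all(dual_pair %in% categories))
      stop("dual_pair must name two of the spec's categories", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!isTRUE(all.equal(dim(correlation), rep(length(CAFPA_NAMES), 2L))) ||
        !isSymmetric(unname(correlation)))
      stop("correlation must be a symmetric 10 x 10 matrix", call. = FALSE)
  }
  structure(list(categories = categories, shapes = shapes,
                 n_per_category = n_per_category,
                 dual_label_fraction = dual_label_fraction,
                 dual_pair = dual_pair, missing_rate = missing_rate,
                 correlation = correlation, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  categories:        ", paste(x$categories, collapse = ", "), "\n")
  cat("  n per category:    ", x$n_per_category, "\n")
  cat("  dual-label pair:   ",
      if (is.null(x$dual_pair)) "none"
      else paste0(paste(x$dual_pair, collapse = " & "),
                  " (fraction ", x$dual_label_fraction, ")"), "\n")
  cat("  CAFPA correlation: ",
      if (is.null(x$correlation)) "independent" else "Gaussian copula", "\n")
  cat("  seed:              ", x$seed, "\n")
  invisible(x)
}

#' Default synthetic study conditions
#'
#' A three-category cohort shaped like the treatment-recommendation tree of
#' an audiological decision support study: unaided patients (`none`),
#' hearing-aid candidates (`hearing-aid`) and cochlear-implant candidates
#' (`cochlear-implant`), 80 patients per category (240 in total).  Impairment
#' increases from the first to the third category; audibility CAFPAs
#' (CA1--CA4) separate the categories most strongly, supra-threshold CAFPAs
#' (CU1, CU2) somewhat less, and the central/socio-economic CAFPAs (CB, CN,
#' CC, CE) overlap considerably, echoing how expert-estimated CAFPA patterns
#' grow from peripheral to central with impairment severity.  Ten percent of
#' hearing-device patients carry both treatment labels.
#'
#' @param seed Integer master seed.
#' @param n_per_category Patients per category.
#' @return A [cohort_spec()] object.
#' @export
default_cohort_spec <- function(seed = 1L, n_per_category = 80L) {
  #              CA1  CA2  CA3  CA4  CU1  CU2   CB   CN   CC   CE
  none_a <- c(   1.6, 1.6, 1.8, 2.0, 1.8, 1.8, 1.6, 1.5, 1.5, 1.8)
  none_b <- c(   8.0, 8.0, 7.5, 7.0, 7.0, 7.0, 6.5, 6.0, 5.0, 5.5)
  ha_a   <- c(   4.5, 5.0, 5.5, 6.0, 4.5, 5.0, 3.0, 2.8, 2.5, 2.2)
  ha_b   <- c(   5.5, 5.0, 4.5, 4.0, 5.0, 4.5, 5.0, 5.0, 4.5, 4.5)
  ci_a   <- c(   7.5, 8.0, 8.5, 9.0, 7.0, 7.5, 4.5, 4.5, 3.5, 2.8)
  ci_b   <- c(   2.5, 2.2, 2.0, 1.8, 2.8, 2.5, 4.0, 4.0, 4.0, 4.2)
  cohort_spec(
    categories = c("none", "hearing-aid", "cochlear-implant"),
    beta_params = list(
      "none"             = list(a = none_a, b = none_b),
      "hearing-aid"      = list(a = ha_a, b = ha_b),
      "cochlear-implant" = list(a = ci_a, b = ci_b)),
    n_per_category = n_per_category,
    dual_label_fraction = 0.1,
    dual_pair = c("hearing-aid", "cochlear-implant"),
    seed = seed)
}

# Draw an n x 10 CAFPA matrix from per-CAFPA beta marginals, optionally
# coupled by a Gaussian copula.
draw_cafpas <- function(n, a, b, correlation = NULL) {
  k <- length(CAFPA_NAMES)
  if (is.null(correlation)) {
    m <- matrix(rbeta(n * k, rep(a, each = n), rep(b, each = n)), nrow = n)
  } else {
    z <- matrix(rnorm(n * k), nrow = n) %*% chol(correlation)
    u <- pnorm(z)
    m <- matrix(stats::qbeta(u, rep(a, each = n), rep(b, each = n)), nrow = n)
  }
  colnames(m) <- CAFPA_NAMES
  m
}

#' Generate a synthetic patient cohort
#'
#' Draws a seeded cohort from a [cohort_spec()].  Each patient's CAFPAs are
#' drawn independently per CAFPA from the beta distribution of their
#' category (or through the spec's Gaussian copula when configured).  A
#' configurable fraction of patients in the designated comparison pair carry
#' both of that pair's labels; their CAFPAs come from an equal mixture of the
#' two categories' distributions (one mixture component per patient).
#'
#' @param spec A [cohort_spec()] object.
#' @return A data frame with columns `patient_id`, the ten CAFPA columns
#'   `CA1` ... `CE`, and `labels` (`";"`-joined category labels).  The
#'   attribute `"true_category"` records the generating (mixture-component)
#'   category of every patient.
#' @examples
#' cohort <- simulate_cohort(default_cohort_spec(seed = 7, n_per_category = 20))
#' head(cohort)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(stage_seed(spec$seed, "cohort"))
  rows <- lapply(spec$categories, function(cat) {
    sh <- spec$shapes[[cat]]
    n <- spec$n_per_category
    m <- draw_cafpas(n, sh$a, sh$b, spec$correlation)
    labels <- rep(cat, n)
    true_cat <- rep(cat, n)
    if (!is.null(spec$dual_pair) && cat %in% spec$dual_pair &&
        spec$dual_label_fraction > 0) {
      dual <- runif(n) < spec$dual_label_fraction
      other <- setdiff(spec$dual_pair, cat)
      # dual patients: equal mixture over the pair, both labels attached
      comp <- ifelse(runif(n) < 0.5, cat, other)
      sho <- spec$shapes[[other]]
      redraw <- dual & comp == other
      if (any(redraw)) {
        m[redraw, ] <- draw_cafpas(sum(redraw), sho$a, sho$b,
                                   spec$correlation)
        true_cat[redraw] <- other
      }
      labels[dual] <- paste(spec$dual_pair[1], spec$dual_pair[2], sep = ";")
    }
    list(m = m, labels = labels, true_cat = true_cat)
  })
  m <- do.call(rbind, lapply(rows, `[[`, "m"))
  if (spec$missing_rate > 0)
    m[runif(length(m)) < spec$missing_rate] <- NA_real_
  n_tot <- nrow(m)
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n_tot)),
                    m, labels = unlist(lapply(rows, `[[`, "labels")),
                    stringsAsFactors = FALSE)
  attr(out, "true_category") <- unlist(lapply(rows, `[[`, "true_cat"))
  out
}

#' Simulate a measurement battery from CAFPAs
#'
#' Fills measurement columns of a cohort through a configurable noisy linear
#' forward model: each feature is a linear combination of the patient's
#' CAFPAs plus additive Gaussian noise.  This emulates how audiological
#' measurements (audiogram thresholds, speech-test outcomes, loudness
#' scaling, cognitive scores) reflect the underlying functional state.
#'
#' @param cohort A cohort data frame as returned by [simulate_cohort()].
#' @param forward_spec Named list; one element per feature, each a list with
#'   `coef` (named numeric vector of coefficients over CAFPA names, an
#'   optional `"(Intercept)"` entry allowed) and `sd` (non-negative noise
#'   standard deviation).
#' @param seed Integer seed.
#' @return The cohort with one additional numeric column per feature.
#' @examples
#' cohort <- simulate_cohort(default_cohort_spec(seed = 3, n_per_category = 10))
#' fw <- list(ag_4k = list(coef = c(CA4 = 100), sd = 5))
#' cohort <- generate_measurements(cohort, fw, seed = 3)
#' @export
generate_measurements <- function(cohort, forward_spec, seed = 1L) {
  if (length(forward_spec) == 0L) return(cohort)
  if (is.null(names(forward_spec)) || any(names(forward_spec) == ""))
    stop("forward_spec must be a named list of features", call. = FALSE)
  m <- cohort_cafpas(cohort)
  set.seed(stage_seed(seed, "measurements"))
  for (feat in names(forward_spec)) {
    fs <- forward_spec[[feat]]
    cf <- fs$coef
    unknown <- setdiff(setdiff(names(cf), "(Intercept)"), CAFPA_NAMES)
    if (length(unknown) > 0L)
      stop("forward_spec for '", feat, "' references unknown CAFPA(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    icpt <- if ("(Intercept)" %in% names(cf)) cf[["(Intercept)"]] else 0
    cf <- cf[names(cf) %in% CAFPA_NAMES]
    lin <- rep(icpt, nrow(m))
    if (length(cf) > 0L)
      lin <- lin + as.vector(m[, names(cf), drop = FALSE] %*% cf)
    noise_sd <- if (is.null(fs$sd)) 0 else fs$sd
    cohort[[feat]] <- lin + if (noise_sd > 0) rnorm(nrow(m), 0, noise_sd) else 0
  }
  cohort
}

#' Default measurement forward model
#'
#' A compact stand-in for a clinical audiological test battery: audiogram
#' thresholds per frequency band (dB HL, driven by the audibility CAFPAs),
#' a speech reception threshold in noise (driven by audibility and
#' supra-threshold CAFPAs), loudness-scaling slopes, a cognitive screening
#' score (decreasing with CC) and a socio-economic index.  Coefficients and
#' noise scales are in the measurement's natural units.
#'
#' @return A named list suitable for [generate_measurements()].
#' @export
default_forward_spec <- function() {
  list(
    ag_500  = list(coef = c("(Intercept)" = 5, CA1 = 90, CA2 = 10), sd = 6),
    ag_1k   = list(coef = c("(Intercept)" = 5, CA2 = 90, CA1 = 10), sd = 6),
    ag_2k   = list(coef = c("(Intercept)" = 5, CA3 = 90, CA4 = 10), sd = 6),
    ag_4k   = list(coef = c("(Intercept)" = 5, CA4 = 95), sd = 6),
    srt_noise = list(coef = c("(Intercept)" = -7, CU1 = 8, CU2 = 8,
                              CA3 = 4, CA4 = 4, CN = 3), sd = 1.5),
    acalos_slope_low  = list(coef = c("(Intercept)" = 1, CU1 = 2.5), sd = 0.4),
    acalos_slope_high = list(coef = c("(Intercept)" = 1, CU2 = 2.5), sd = 0.4),
    demtect = list(coef = c("(Intercept)" = 17, CC = -9), sd = 1.5),
    swi     = list(coef = c("(Intercept)" = 14, CE = -8), sd = 2),
    age     = list(coef = c("(Intercept)" = 45, CC = 25, CN = 10), sd = 8)
  )
}
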