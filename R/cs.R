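#' Fit a comparison set: per-CAFPA beta training distributions
#'
#' A *comparison set* is an ordered pair of diagnostic categories between
#' which a binary Bayes decision is made.  `cafpa_cs()` fits, for each of the
#' ten CAFPAs and each category, a beta training distribution to the CAFPA
#' values of the cohort patients carrying that category's label, and derives
#' the per-CAFPA classification threshold (the intersection of the two
#' training densities) together with the expected certainty of a
#' single-CAFPA decision.
#'
#' Patients labeled with both categories contribute to both training
#' distributions.  A category may stand for a union of cohort labels (e.g. a
#' "hearing device" category pooling hearing-aid and cochlear-implant
#' patients) via `members`.  Leave-one-out refits are supported through
#' `exclude_patient`, used when classifying a patient who is part of the
#' training cohort.
#'
#' @param cohort Cohort data frame: columns `patient_id`, `CA1` ... `CE`,
#'   `labels` (`";"`-joined category labels).  See [simulate_cohort()].
#' @param categories Character vector of the two category labels, in order.
#' @param members Optional named list mapping a category label to the cohort
#'   labels it pools; defaults to the identity mapping.
#' @param exclude_patient Optional patient id excluded from fitting
#'   (leave-one-out); an id absent from the cohort is a no-op.
#' @param eps Boundary clip for fitting and density evaluation.
#' @param grid_size Grid resolution for threshold search.
#' @return An object of class `cafpa_cs` with components `categories`,
#'   `shapes` (2 x 10 matrices `a` and `b`), `thresholds` (length 10, `NA`
#'   where undefined), `crossings`, `expected_certainty`, `low_certainty`,
#'   `n` (patients per category), `patient_ids` (per category) and `eps`.
#' @examples
#' cohort <- simulate_cohort(default_cohort_spec(seed = 1, n_per_category = 40))
#' cs <- cafpa_cs(cohort, c("hearing-aid", "cochlear-implant"))
#' print(cs)
#' @seealso [predict.cafpa_cs()], [decision_threshold()], [cafpa_tree()]
#' @export
cafpa_cs <- function(cohort, categories, members = NULL,
                     exclude_patient = NULL, eps = .CAFPA_EPS,
                     grid_size = 1001L) {
  categories <- as.character(categories)
  if (length(categories) != 2L || categories[1] == categories[2])
    stop("categories must be an ordered pair of distinct labels",
         call. = FALSE)
  if (is.null(members)) members <- setNames(as.list(categories), categories)
  for (cat in categories)
    if (is.null(members[[cat]]))
      members[[cat]] <- cat
  m <- cohort_cafpas(cohort)
  keep <- rep(TRUE, nrow(cohort))
  if (!is.null(exclude_patient))
    keep <- !(cohort$patient_id %in% exclude_patient)

  k <- length(CAFPA_NAMES)
  a <- b <- matrix(NA_real_, 2L, k, dimnames = list(categories, CAFPA_NAMES))
  methods <- matrix(NA_character_, 2L, k,
                    dimnames = list(categories, CAFPA_NAMES))
  n <- integer(2L)
  ids <- vector("list", 2L)
  for (ci in 1:2) {
    cat <- categories[ci]
    in_cat <- Reduce(`|`, lapply(members[[cat]], has_label, cohort = cohort))
    rows <- which(in_cat & keep)
    if (length(rows) < 3L)
      stop("insufficient data: category '", cat, "' has ", length(rows),
           " contributing patients (need >= 3)", call. = FALSE)
    n[ci] <- length(rows)
    ids[[ci]] <- cohort$patient_id[rows]
    for (j in seq_len(k)) {
      fb <- fit_beta(m[rows, j], eps = eps)
      a[ci, j] <- fb$a; b[ci, j] <- fb$b
      methods[ci, j] <- fb$method
    }
  }

  thresholds <- setNames(rep(NA_real_, k), CAFPA_NAMES)
  crossings <- expcert <- setNames(vector("list", k), CAFPA_NAMES)
  lowcert <- setNames(logical(k), CAFPA_NAMES)
  ec <- setNames(numeric(k), CAFPA_NAMES)
  for (j in seq_len(k)) {
    d1 <- beta_params(a[1, j], b[1, j])
    d2 <- beta_params(a[2, j], b[2, j])
    th <- decision_threshold(d1, d2, grid_size = grid_size, eps = eps)
    thresholds[j] <- as.numeric(th)
    crossings[[j]] <- attr(th, "crossings")
    e <- expected_certainty(d1, d2, grid_size = grid_size, eps = eps)
    ec[j] <- as.numeric(e)
    lowcert[j] <- attr(e, "low_certainty")
  }

  structure(list(categories = categories, members = members,
                 shapes = list(a = a, b = b), fit_methods = methods,
                 thresholds = thresholds, crossings = crossings,
                 expected_certainty = ec, low_certainty = lowcert,
                 n = setNames(n, categories),
                 patient_ids = setNames(ids, categories),
                 eps = eps, grid_size = grid_size, call = match.call()),
            class = "cafpa_cs")
}

# Validate a weight vector over the ten CAFPAs; NULL means uniform.
check_weights <- function(weights) {
  if (is.null(weights)) weights <- uniform_weights()
  if (!is.null(names(weights))) {
    if (!all(CAFPA_NAMES %in% names(weights)))
      stop("named weights must cover all ten CAFPAs", call. = FALSE)
    weights <- weights[CAFPA_NAMES]
  }
  weights <- as.numeric(weights)
  if (length(weights) != length(CAFPA_NAMES))
    stop("weights must have one entry per CAFPA", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  if (all(weights == 0))
    stop("at least one weight must be strictly positive", call. = FALSE)
  setNames(weights, CAFPA_NAMES)
}

#' Uniform CAFPA weights
#'
#' Equal weight on every CAFPA — the baseline weight vector.
#' @return Named numeric vector of ten ones.
#' @export
uniform_weights <- function() setNames(rep(1, length(CAFPA_NAMES)), CAFPA_NAMES)

# Weighted density scores of a CAFPA matrix under both categories.
# Returns n x 2 score matrix plus bookkeeping on dropped (missing) CAFPAs.
cs_scores <- function(object, x, weights) {
  w <- check_weights(weights)
  x <- as_cafpa_matrix(x)
  a <- object$shapes$a; b <- object$shapes$b
  xc <- clip01(x, object$eps)
  n <- nrow(x); k <- ncol(x)
  d1 <- matrix(dbeta(xc, rep(a[1, ], each = n), rep(b[1, ], each = n)), n, k)
  d2 <- matrix(dbeta(xc, rep(a[2, ], each = n), rep(b[2, ], each = n)), n, k)
  act <- matrix(rep(w > 0, each = n), n, k) & !is.na(x)
  if (any(rowSums(act) == 0L))
    stop("cannot classify: all positively weighted CAFPAs missing for row(s) ",
         paste(which(rowSums(act) == 0L), collapse = ", "), call. = FALSE)
  dropped <- is.na(x) & matrix(rep(w > 0, each = n), n, k)
  if (any(dropped))
    warning(sum(dropped), " missing CAFPA value(s) dropped; ",
            "weights renormalized over present CAFPAs", call. = FALSE)
  wm <- matrix(rep(w, each = n), n, k)
  wm[!act] <- 0
  wm <- wm / rowSums(wm) * sum(w)   # renormalize to the original total
  d1[is.na(d1)] <- 0; d2[is.na(d2)] <- 0
  scores <- cbind(rowSums(wm * d1), rowSums(wm * d2))
  colnames(scores) <- object$categories
  list(scores = scores, d1 = d1, d2 = d2, weights = w,
       used = act, dropped = dropped)
}

#' Classify CAFPA vectors within a comparison set
#'
#' The Bayes decision of a fitted comparison set: each patient's score under
#' category *c* is the weighted sum over CAFPAs of the training-density
#' values, \eqn{s_c = \sum_i w_i \, f_{c,i}(x_i)}, and the classified
#' category is the one with the larger score.  The per-decision certainty is
#' the classified score's share of the total, \eqn{s_c / (s_1 + s_2)}.
#'
#' Missing CAFPAs with positive weight are dropped and the weights
#' renormalized over the present ones (with a warning); if every positively
#' weighted CAFPA is missing the patient cannot be classified.  Exact score
#' ties resolve to the first category and are flagged in the `"ties"`
#' attribute.
#'
#' @param object A fitted `cafpa_cs` object.
#' @param newdata CAFPA input: a cohort data frame, a numeric matrix
#'   (patients x 10), or a single length-10 vector.
#' @param weights CAFPA weight vector (non-negative, not all zero);
#'   `NULL` for uniform weights.  Scaling all weights by a positive constant
#'   does not change the classification.
#' @param type `"category"` (default) for the classified labels,
#'   `"score"` for the n x 2 score matrix, `"certainty"` for the n x 2
#'   certainty matrix (rows sum to 1), `"delta"` for per-CAFPA signed
#'   distances to the classification thresholds.
#' @param ... Unused.
#' @return See `type`.  For `"category"`, a character vector with attribute
#'   `"ties"`.
#' @export
predict.cafpa_cs <- function(object, newdata, weights = NULL,
                             type = c("category", "score", "certainty",
                                      "delta"), ...) {
  type <- match.arg(type)
  if (type == "delta") return(delta_pcafpa(object, newdata))
  sc <- cs_scores(object, newdata, weights)
  s <- sc$scores
  if (type == "score") return(s)
  if (type == "certainty") {
    tot <- rowSums(s)
    if (any(tot <= 0))
      stop("degenerate certainty: both scores zero for row(s) ",
           paste(which(tot <= 0), collapse = ", "), call. = FALSE)
    return(s / tot)
  }
  ties <- s[, 1] == s[, 2]
  out <- ifelse(s[, 1] >= s[, 2], object$categories[1], object$categories[2])
  structure(out, ties = ties)
}

#' Single-patient classification with full detail
#'
#' Convenience wrapper around [predict.cafpa_cs()] for one CAFPA vector,
#' returning the classified category together with both combined scores, the
#' per-CAFPA densities under both categories, the certainty pair and which
#' CAFPAs actually entered the decision.
#'
#' @inheritParams predict.cafpa_cs
#' @param cafpas A length-10 CAFPA vector (possibly with `NA`s).
#' @return A list of class `cafpa_classification` with elements `category`,
#'   `scores`, `certainty`, `densities` (2 x 10), `used`, `tie`.
#' @export
classify_cs <- function(object, cafpas, weights = NULL) {
  sc <- cs_scores(object, cafpas, weights)
  s <- sc$scores[1, ]
  dens <- rbind(sc$d1[1, ], sc$d2[1, ])
  dimnames(dens) <- list(object$categories, CAFPA_NAMES)
  tie <- s[1] == s[2]
  structure(list(
    category = if (s[1] >= s[2]) object$categories[1] else object$categories[2],
    scores = s,
    certainty = s / sum(s),
    densities = dens,
    used = setNames(sc$used[1, ], CAFPA_NAMES),
    tie = tie), class = "cafpa_classification")
}

#' @export
print.cafpa_classification <- function(x, ...) {
  cat("Classified category:", x$category, if (x$tie) "(tie)" else "", "\n")
  cat("Scores:   ", paste(sprintf("%s = %.4g", names(x$scores), x$scores),
                          collapse = ", "), "\n")
  cat("Certainty:", paste(sprintf("%s = %.3f", names(x$certainty),
                                  x$certainty), collapse = ", "), "\n")
  invisible(x)
}

#' Certainty pair of a comparison-set decision
#'
#' The certainty of category *c* is its weighted density score divided by
#' the sum of both categories' scores; the two certainties sum to 1.
#'
#' @inheritParams predict.cafpa_cs
#' @param cafpas CAFPA input (vector or matrix).
#' @return An n x 2 matrix of certainties.
#' @export
certainty_cs <- function(object, cafpas, weights = NULL) {
  predict(object, cafpas, weights = weights, type = "certainty")
}

#' Signed distance of CAFPAs to their classification thresholds
#'
#' For each CAFPA, `delta = x - threshold`: negative values lie on the first
#' category's side of the Bayes decision boundary, positive values on the
#' second category's side.  CAFPAs whose threshold is undefined (identical
#' or non-crossing training distributions) yield `NA`.
#'
#' @inheritParams predict.cafpa_cs
#' @param cafpas CAFPA input (vector or matrix).
#' @return An n x 10 matrix of signed differences.
#' @export
delta_pcafpa <- function(object, cafpas) {
  x <- as_cafpa_matrix(cafpas)
  sweep(x, 2L, object$thresholds, `-`)
}

#' @export
print.cafpa_cs <- function(x, ...) {
  cat("Comparison set:", x$categories[1], "vs", x$categories[2], "\n")
  cat("Training patients:", paste(sprintf("%s: %d", names(x$n), x$n),
                                  collapse = ", "), "\n")
  nd <- sum(is.na(x$thresholds))
  cat("Thresholds defined for", sum(!is.na(x$thresholds)), "of 10 CAFPAs",
      if (nd > 0) sprintf("(%d undefined)", nd) else "", "\n")
  invisible(x)
}

#' @export
summary.cafpa_cs <- function(object, ...) {
  tab <- data.frame(
    cafpa = CAFPA_NAMES,
    a1 = object$shapes$a[1, ], b1 = object$shapes$b[1, ],
    a2 = object$shapes$a[2, ], b2 = object$shapes$b[2, ],
    threshold = object$thresholds,
    expected_certainty = object$expected_certainty,
    low_certainty = object$low_certainty,
    row.names = NULL)
  structure(list(categories = object$categories, n = object$n, table = tab),
            class = "summary.cafpa_cs")
}

#' @export
print.summary.cafpa_cs <- function(x, ...) {
  cat("Comparison set:", x$categories[1], "vs", x$categories[2], "\n")
  cat("Training patients:", paste(sprintf("%s: %d", names(x$n), x$n),
                                  collapse = ", "), "\n\n")
  tab <- x$table
  tab[, 2:7] <- round(tab[, 2:7], 3)
  print(tab, row.names = FALSE)
  cat("\n'low_certainty' marks CAFPAs with expected certainty <= 0.65\n")
  invisible(x)
}

#' Coefficients of a fitted comparison set
#'
#' @param object A `cafpa_cs` object.
#' @param ... Unused.
#' @return A 2 x 10 x 2 array: categories x CAFPAs x (a, b).
#' @export
coef.cafpa_cs <- function(object, ...) {
  arr <- array(c(object$shapes$a, object$shapes$b),
               dim = c(2L, length(CAFPA_NAMES), 2L),
               dimnames = list(object$categories, CAFPA_NAMES, c("a", "b")))
  arr
}

#' Simulate CAFPA vectors from fitted training distributions
#'
#' Draws patients from the per-CAFPA beta training distributions of one (or
#' an equal mixture of both) categories of a fitted comparison set.
#'
#' @param object A `cafpa_cs` object.
#' @param nsim Number of CAFPA vectors to draw.
#' @param seed Integer seed.
#' @param category One of the comparison set's categories, or `"mixture"`
#'   (default) for an equal mixture of both.
#' @param ... Unused.
#' @return An `nsim` x 10 matrix of CAFPA values.
#' @export
simulate.cafpa_cs <- function(object, nsim = 1L, seed = NULL,
                              category = "mixture", ...) {
  if (!is.null(seed)) set.seed(seed)
  a <- object$shapes$a; b <- object$shapes$b
  which_cat <- if (identical(category, "mixture")) {
    sample(1:2, nsim, replace = TRUE)
  } else {
    ci <- match(category, object$categories)
    if (is.na(ci)) stop("unknown category '", category, "'", call. = FALSE)
    rep(ci, nsim)
  }
  k <- length(CAFPA_NAMES)
  m <- matrix(rbeta(nsim * k, a[which_cat, ], b[which_cat, ]),
              nrow = nsim, byrow = FALSE)
  colnames(m) <- CAFPA_NAMES
  m
}

#' Plot training distributions and thresholds of a comparison set
#'
#' One panel per CAFPA showing the two categories' beta training densities,
#' the classification threshold (vertical line) and the expected certainty.
#'
#' @param x A `cafpa_cs` object.
#' @param cafpas Subset of CAFPA names to plot (default all ten).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.cafpa_cs <- function(x, cafpas = CAFPA_NAMES, ...) {
  cafpas <- match.arg(cafpas, CAFPA_NAMES, several.ok = TRUE)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(cafpas)),
                       mar = c(3, 3, 2, 0.5), mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(old))
  grid <- seq(x$eps, 1 - x$eps, length.out = 301)
  for (nm in cafpas) {
    j <- match(nm, CAFPA_NAMES)
    y1 <- dbeta(grid, x$shapes$a[1, j], x$shapes$b[1, j])
    y2 <- dbeta(grid, x$shapes$a[2, j], x$shapes$b[2, j])
    graphics::matplot(grid, cbind(y1, y2), type = "l", lty = 1,
                      col = c("#1b7837", "#b2182b"),
                      xlab = nm, ylab = "density",
                      main = sprintf("%s  (E[cert] = %.2f)", nm,
                                     x$expected_certainty[j]), ...)
    if (!is.na(x$thresholds[j]))
      graphics::abline(v = x$thresholds[j], lty = 2)
  }
  invisible(x)
}
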