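#' Enumerate all binary CAFPA weight combinations
#'
#' All non-zero 0/1 weight vectors over `n_cafpas` CAFPAs, in lexicographic
#' order (first CAFPA most significant).  For the full ten-CAFPA layer this
#' yields `2^10 - 1 = 1023` combinations.
#'
#' @param n_cafpas Number of CAFPAs (1 to 20).
#' @return A `(2^n - 1) x n` 0/1 matrix; columns carry CAFPA names when
#'   `n_cafpas` is 10.
#' @examples
#' nrow(enumerate_binary_weights(10))  # 1023
#' @export
enumerate_binary_weights <- function(n_cafpas = 10L) {
  n <- as.integer(n_cafpas)
  if (is.na(n) || n < 1L || n > 20L)
    stop("n_cafpas must be between 1 and 20", call. = FALSE)
  idx <- seq_len(2^n - 1L)
  W <- vapply(seq_len(n),
              function(j) (idx %/% 2^(n - j)) %% 2L,
              numeric(length(idx)))
  W <- matrix(W, nrow = length(idx))
  if (n == length(CAFPA_NAMES)) colnames(W) <- CAFPA_NAMES
  W
}

#' Youden index of a binary classification
#'
#' `Y = Sens + Spec - 1`, where sensitivity is the fraction of patients
#' uniquely labeled with the first category that were classified to it, and
#' specificity the analogue for the second category.  Patients carrying both
#' labels of the comparison set are excluded from the evaluation, as are
#' patients carrying neither.
#'
#' @param predictions Character vector of classified category labels.
#' @param truths Expert label sets: a list of character vectors, or a
#'   character vector of `";"`-joined labels (multi-label allowed).
#' @param comparison_set Ordered pair of category labels.
#' @return The Youden index (can be negative for worse-than-chance
#'   classifiers), with attributes `"sensitivity"`, `"specificity"` and
#'   `"n"` (evaluated patients per category); `NA` with attribute
#'   `"undefined"` when a category has no uniquely labeled patient.
#' @examples
#' youden(c("A", "B", "B"), c("A", "A;B", "B"), c("A", "B"))
#' @export
youden <- function(predictions, truths, comparison_set) {
  if (!is.list(truths)) truths <- split_labels(truths)
  if (length(predictions) != length(truths))
    stop("predictions and truths must be aligned", call. = FALSE)
  c1 <- comparison_set[1]; c2 <- comparison_set[2]
  in1 <- vapply(truths, function(l) c1 %in% l, logical(1))
  in2 <- vapply(truths, function(l) c2 %in% l, logical(1))
  u1 <- in1 & !in2
  u2 <- in2 & !in1
  if (sum(u1) == 0L || sum(u2) == 0L)
    return(structure(NA_real_, undefined = TRUE,
                     n = c(sum(u1), sum(u2))))
  sens <- mean(predictions[u1] == c1)
  spec <- mean(predictions[u2] == c2)
  structure(sens + spec - 1, sensitivity = sens, specificity = spec,
            n = setNames(c(sum(u1), sum(u2)), comparison_set))
}

#' Exhaustive weight search over a comparison set
#'
#' Classifies every eligible cohort patient under every candidate weight
#' vector and scores each vector by the Youden index.  Eligible patients are
#' those carrying at least one of the comparison set's labels; patients
#' carrying both are classified but excluded from the Youden evaluation.
#'
#' When `loo = NULL` (default), training distributions are refitted with the
#' patient held out whenever the classified patient was part of the training
#' cohort, so no patient is evaluated against distributions fitted on their
#' own CAFPAs; `loo = FALSE` forces plain in-sample evaluation and
#' `loo = TRUE` forces the refit for all training patients.
#'
#' @param object A fitted [cafpa_cs()] object.
#' @param cohort The cohort data frame carrying the expert labels (and, by
#'   default, the CAFPAs to classify).
#' @param weights Candidate weight matrix, one row per weight vector
#'   (default [enumerate_binary_weights()] over the ten CAFPAs).
#' @param cafpas Optional matrix of CAFPA values to classify in place of the
#'   cohort's own columns (e.g. model-predicted CAFPAs), aligned with
#'   `cohort` rows.
#' @param loo Leave-one-out switch; see Details.
#' @param source Identifier of the CAFPA source (e.g. `"expert"`,
#'   `"lasso"`), carried into the result.
#' @return An object of class `cafpa_weight_search`: list with `weights`
#'   (the candidate matrix), `youden`, `sensitivity`, `specificity`,
#'   `categories`, `source`, `n_eligible`, `n_unique`.
#' @export
search_weights <- function(object, cohort, weights = enumerate_binary_weights(),
                           cafpas = NULL, loo = NULL, source = "expert") {
  stopifnot(inherits(object, "cafpa_cs"))
  W <- weights
  if (is.null(dim(W))) W <- matrix(W, nrow = 1L)
  if (ncol(W) != length(CAFPA_NAMES))
    stop("weight matrix must have ten columns", call. = FALSE)
  c1 <- object$categories[1]; c2 <- object$categories[2]
  mem1 <- object$members[[c1]]; mem2 <- object$members[[c2]]
  lab <- split_labels(cohort$labels)
  in1 <- vapply(lab, function(l) any(mem1 %in% l), logical(1))
  in2 <- vapply(lab, function(l) any(mem2 %in% l), logical(1))
  eligible <- which(in1 | in2)
  if (length(eligible) == 0L)
    stop("no cohort patient carries a label of this comparison set",
         call. = FALSE)
  x <- if (is.null(cafpas)) cohort_cafpas(cohort) else as_cafpa_matrix(cafpas)
  if (nrow(x) != nrow(cohort))
    stop("cafpas must be aligned with the cohort rows", call. = FALSE)
  x <- x[eligible, , drop = FALSE]
  ids <- cohort$patient_id[eligible]
  trained <- unique(unlist(object$patient_ids))

  n <- length(eligible); k <- length(CAFPA_NAMES)
  xc <- clip01(x, object$eps)
  a <- object$shapes$a; b <- object$shapes$b
  D1 <- matrix(dbeta(xc, rep(a[1, ], each = n), rep(b[1, ], each = n)), n, k)
  D2 <- matrix(dbeta(xc, rep(a[2, ], each = n), rep(b[2, ], each = n)), n, k)
  refit <- if (isTRUE(loo)) ids %in% trained
           else if (is.null(loo)) ids %in% trained
           else rep(FALSE, n)
  if (isTRUE(loo) || is.null(loo)) {
    for (i in which(refit)) {
      fi <- cafpa_cs(cohort, object$categories, members = object$members,
                     exclude_patient = ids[i], eps = object$eps,
                     grid_size = object$grid_size)
      D1[i, ] <- dbeta(xc[i, ], fi$shapes$a[1, ], fi$shapes$b[1, ])
      D2[i, ] <- dbeta(xc[i, ], fi$shapes$a[2, ], fi$shapes$b[2, ])
    }
  }

  S1 <- D1 %*% t(W)              # n x n_weights
  S2 <- D2 %*% t(W)
  pred1 <- S1 >= S2              # ties resolve to the first category
  u1 <- (in1 & !in2)[eligible]
  u2 <- (in2 & !in1)[eligible]
  sens <- colMeans(pred1[u1, , drop = FALSE])
  spec <- colMeans(!pred1[u2, , drop = FALSE])
  y <- if (sum(u1) == 0L || sum(u2) == 0L)
    rep(NA_real_, nrow(W)) else sens + spec - 1

  structure(list(weights = W, youden = y, sensitivity = sens,
                 specificity = spec, categories = object$categories,
                 source = source, n_eligible = n,
                 n_unique = setNames(c(sum(u1), sum(u2)), object$categories),
                 loo_refits = sum(refit)),
            class = "cafpa_weight_search")
}

#' @export
print.cafpa_weight_search <- function(x, ...) {
  cat("Weight search:", x$categories[1], "vs", x$categories[2],
      sprintf("(%s CAFPAs)\n", x$source))
  cat(nrow(x$weights), "weight vectors over", x$n_eligible,
      "patients; uniquely labeled:",
      paste(sprintf("%s: %d", names(x$n_unique), x$n_unique),
            collapse = ", "), "\n")
  if (all(is.na(x$youden))) {
    cat("Youden index undefined (no uniquely labeled patients)\n")
  } else {
    best <- which.max(x$youden)
    cat(sprintf("max Y = %.3f with CAFPAs {%s}\n", x$youden[best],
                paste(CAFPA_NAMES[x$weights[best, ] > 0], collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.data.frame.cafpa_weight_search <- function(x, ...) {
  data.frame(x$weights, youden = x$youden, sensitivity = x$sensitivity,
             specificity = x$specificity, check.names = FALSE)
}

#' Select the Y90 weight combinations
#'
#' Keeps the weight vectors whose Youden index reaches at least a fraction
#' (default 90%) of the maximum over the search — the "Y90" criterion.  A
#' different reference maximum (e.g. the joint maximum over expert and
#' model searches) can be imposed through `reference_max`.
#'
#' @param result A `cafpa_weight_search` object.
#' @param frac Fraction of the maximum (default 0.9).
#' @param reference_max Optional externally supplied maximum Youden index.
#' @return A `cafpa_weight_search` restricted to the selected combinations,
#'   with extra fields `max_youden` and `cutoff`.
#' @export
select_y90 <- function(result, frac = 0.9, reference_max = NULL) {
  stopifnot(inherits(result, "cafpa_weight_search"))
  y <- result$youden
  if (all(is.na(y)))
    stop("empty selection: all Youden indices are undefined", call. = FALSE)
  ymax <- if (is.null(reference_max)) max(y, na.rm = TRUE) else reference_max
  keep <- which(!is.na(y) & y >= frac * ymax)
  out <- result
  out$weights <- result$weights[keep, , drop = FALSE]
  out$youden <- y[keep]
  out$sensitivity <- result$sensitivity[keep]
  out$specificity <- result$specificity[keep]
  out$max_youden <- ymax
  out$cutoff <- frac * ymax
  class(out) <- c("cafpa_y90", class(result))
  out
}

#' @export
print.cafpa_y90 <- function(x, ...) {
  cat(sprintf("Y90 selection (%s, %s vs %s): %d combination(s), Y >= %.3f\n",
              x$source, x$categories[1], x$categories[2],
              nrow(x$weights), x$cutoff))
  invisible(x)
}

# Row-wise keys of a binary weight matrix, for set operations.
weight_keys <- function(W) apply(W > 0, 1L, function(r) paste(as.integer(r),
                                                              collapse = ""))

#' Relative-frequency weights from common high-performing combinations
#'
#' Intersects the selected (Y90) binary combinations of two or more CAFPA
#' sources and turns the relative frequency of each CAFPA among the common
#' combinations into a normalized weight vector.  With an expert source and
#' one model source this yields the *rel-model* weights; with the expert and
#' all model sources, the *rel-all* weights.  When no combination is common
#' to all sources, the single best-performing combination of the designated
#' fallback source is used instead (normalized), and the result flagged.
#'
#' @param selections Named list of two or more [select_y90()] results (or
#'   plain 0/1 weight matrices).
#' @param fallback Name or index of the selection whose best combination is
#'   used when the intersection is empty; default the last one (the model).
#' @return Named numeric weight vector over the ten CAFPAs summing to 1,
#'   with attributes `"fallback"` (logical) and `"n_common"`.
#' @export
derive_rel_weights <- function(selections, fallback = length(selections)) {
  if (length(selections) == 0L)
    stop("selections must contain at least one weight set", call. = FALSE)
  mats <- lapply(selections, function(s) {
    W <- if (inherits(s, "cafpa_weight_search")) s$weights else as.matrix(s)
    if (ncol(W) != length(CAFPA_NAMES))
      stop("weight sets must have ten columns", call. = FALSE)
    W
  })
  keys <- lapply(mats, weight_keys)
  common <- Reduce(intersect, keys)
  if (length(common) > 0L) {
    W <- mats[[1]][match(common, keys[[1]]), , drop = FALSE]
    counts <- colSums(W > 0)
    w <- counts / sum(counts)
    return(structure(setNames(w, CAFPA_NAMES), fallback = FALSE,
                     n_common = length(common)))
  }
  # empty intersection: fall back to the designated source's best combination
  fb <- selections[[fallback]]
  if (!inherits(fb, "cafpa_weight_search"))
    stop("empty intersection and the fallback selection carries no Youden ",
         "indices to pick a best combination from", call. = FALSE)
  best <- which.max(fb$youden)
  w <- fb$weights[best, ]
  w <- w / sum(w)
  structure(setNames(w, CAFPA_NAMES), fallback = TRUE, n_common = 0L)
}
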