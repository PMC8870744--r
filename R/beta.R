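#' Beta shape-parameter pair
#'
#' Light-weight container for the two shape parameters of a beta training
#' distribution (one CAFPA under one diagnostic category).
#'
#' @param a,b Strictly positive shape parameters.
#' @return An object of class `beta_params`.
#' @export
beta_params <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 1L || length(b) != 1L ||
      !is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("beta shape parameters must be finite scalars > 0", call. = FALSE)
  structure(list(a = a, b = b), class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(a = %.4g, b = %.4g)", x$a, x$b))
  if (!is.null(x$method)) cat("  [", x$method, " fit, n = ", x$n, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Beta density of a training distribution at clipped CAFPA values
#'
#' Evaluates the beta probability density at `clip(x, eps, 1 - eps)`.
#' Clipping keeps the density finite when a shape parameter is below 1 and
#' the value sits on the boundary of \[0, 1\].
#'
#' @param params A [beta_params()] object (or list with elements `a`, `b`).
#' @param x Numeric vector of CAFPA values in \[0, 1\].
#' @param eps Boundary clip (default `1e-3`).
#' @return Non-negative density values, same length as `x`.
#' @export
beta_density <- function(params, x, eps = .CAFPA_EPS) {
  if (any(!is.na(x) & (x < 0 | x > 1)))
    stop("CAFPA values must lie in [0, 1]", call. = FALSE)
  dbeta(clip01(x, eps), params$a, params$b)
}

#' Fit a beta training distribution to CAFPA values
#'
#' Maximum-likelihood fit of a beta distribution to values clipped to
#' `[eps, 1 - eps]`, with a method-of-moments start; if the likelihood
#' optimization fails to converge, the method-of-moments estimate itself is
#' returned (recorded in the result's `method` field).
#'
#' @param values Numeric vector of CAFPA values in \[0, 1\]; `NA`s dropped.
#' @param eps Boundary clip applied before fitting.
#' @return A [beta_params()] object with extra fields `method`
#'   (`"mle"` or `"mme"`), `n` and `loglik`.
#' @examples
#' set.seed(1)
#' fit_beta(rbeta(500, 2, 5))
#' @export
fit_beta <- function(values, eps = .CAFPA_EPS) {
  v <- values[is.finite(values)]
  if (any(v < 0 | v > 1))
    stop("CAFPA values must lie in [0, 1]", call. = FALSE)
  if (length(v) < 3L)
    stop("insufficient data: beta fitting needs at least 3 values, got ",
         length(v), call. = FALSE)
  v <- clip01(v, eps)
  if (max(v) - min(v) < .Machine$double.eps^0.5)
    stop("degenerate data: all values identical after clipping", call. = FALSE)
  m <- mean(v); s2 <- var(v)
  # method-of-moments start (always valid since s2 < m (1 - m) on (0, 1))
  k <- m * (1 - m) / s2 - 1
  start <- list(shape1 = max(m * k, 1e-3), shape2 = max((1 - m) * k, 1e-3))
  fit <- tryCatch(
    suppressWarnings(
      fitdistrplus::fitdist(v, "beta", method = "mle", start = start)),
    error = function(e) NULL)
  if (!is.null(fit) && all(is.finite(fit$estimate)) &&
      all(fit$estimate > 0)) {
    out <- beta_params(fit$estimate[["shape1"]], fit$estimate[["shape2"]])
    out$method <- "mle"
    out$loglik <- fit$loglik
  } else {
    out <- beta_params(start$shape1, start$shape2)
    out$method <- "mme"
    out$loglik <- sum(dbeta(v, out$a, out$b, log = TRUE))
  }
  out$n <- length(v)
  out
}

# Refine a sign change of f on [lo, hi] by bisection.
bisect_root <- function(f, lo, hi, tol = 1e-6) {
  flo <- f(lo)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) break
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Bayes decision threshold between two beta training distributions
#'
#' The classification threshold of a comparison set on one CAFPA is the
#' point where the two categories' training densities intersect: values
#' below it classify to the first category, values above to the second.
#' Crossings are located on a uniform grid over `(eps, 1 - eps)` and refined
#' by bisection to `|dx| < 1e-6`.  When the densities cross more than once,
#' the crossing returned is the one where the first distribution dominates
#' below and the second above on the widest surrounding interval; all
#' crossings found are recorded in the `"crossings"` attribute.
#'
#' @param d1,d2 [beta_params()] objects for the first and second category.
#' @param grid_size Number of grid points (>= 101).
#' @param eps Boundary clip.
#' @return The threshold in `(0, 1)`, or `NA` when the distributions are
#'   identical (or never cross on the clipped interval); attributes
#'   `"crossings"` (all sign changes) and `"undefined"` (logical).
#' @examples
#' decision_threshold(beta_params(2, 5), beta_params(5, 2))  # 0.5 by symmetry
#' @export
decision_threshold <- function(d1, d2, grid_size = 1001L, eps = .CAFPA_EPS) {
  if (grid_size < 101L) stop("grid_size must be >= 101", call. = FALSE)
  und <- function(reason) {
    structure(NA_real_, crossings = numeric(0), undefined = TRUE,
              reason = reason)
  }
  if (isTRUE(all.equal(c(d1$a, d1$b), c(d2$a, d2$b))))
    return(und("identical distributions"))
  f <- function(x) dbeta(x, d1$a, d1$b) - dbeta(x, d2$a, d2$b)
  grid <- seq(eps, 1 - eps, length.out = grid_size)
  fg <- f(grid)
  sgn <- sign(fg)
  # collapse exact zeros onto the neighbouring sign to detect true changes
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  crossings <- vapply(idx, function(i) bisect_root(f, grid[i], grid[i + 1]),
                      numeric(1))
  zero_idx <- which(sgn == 0)
  crossings <- sort(unique(c(crossings, grid[zero_idx])))
  if (length(crossings) == 0L) return(und("densities do not cross"))
  # direction at each crossing: want d1 above before, d2 above after
  bounds <- c(eps, crossings, 1 - eps)
  widths <- rep(NA_real_, length(crossings))
  for (i in seq_along(crossings)) {
    left <- (bounds[i] + crossings[i]) / 2
    right <- (crossings[i] + bounds[i + 2]) / 2
    if (f(left) > 0 && f(right) < 0)
      widths[i] <- bounds[i + 2] - bounds[i]
  }
  pick <- if (all(is.na(widths))) {
    # no crossing has the expected orientation (first category below,
    # second above); fall back to the widest-bracketed crossing
    which.max(bounds[seq_along(crossings) + 2] - bounds[seq_along(crossings)])
  } else which.max(widths)
  structure(crossings[pick], crossings = crossings, undefined = FALSE)
}

#' Expected maximum certainty of a single-CAFPA decision
#'
#' How well two training distributions can be told apart at all: the mean,
#' over a uniform grid on the clipped CAFPA axis, of the larger density's
#' share `max(p1, p2) / (p1 + p2)`.  Identical distributions give 0.5
#' (chance); disjoint supports approach 1.  Decisions whose expected
#' certainty is at or below 0.65 are flagged as weakly informative.
#'
#' @inheritParams decision_threshold
#' @return Numeric in \[0.5, 1\] with attribute `"low_certainty"`
#'   (`TRUE` when the value is <= 0.65).
#' @export
expected_certainty <- function(d1, d2, grid_size = 1001L, eps = .CAFPA_EPS) {
  if (grid_size < 101L) stop("grid_size must be >= 101", call. = FALSE)
  grid <- seq(eps, 1 - eps, length.out = grid_size)
  p1 <- dbeta(grid, d1$a, d1$b)
  p2 <- dbeta(grid, d2$a, d2$b)
  val <- mean(pmax(p1, p2) / (p1 + p2))
  structure(val, low_certainty = val <= 0.65)
}
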