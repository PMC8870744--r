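# Internal helpers shared across the package.

# Clip values to [eps, 1 - eps].  Beta densities are evaluated on the open
# interval; clipping keeps scores finite for boundary CAFPAs.
clip01 <- function(x, eps = .CAFPA_EPS) {
  pmin(pmax(x, eps), 1 - eps)
}

# Derive deterministic per-stage sub-seeds from one master seed, so adding a
# stage never perturbs the draws of earlier stages.  Stage names are hashed
# to an offset; the result stays inside the 32-bit integer range.
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483587L) + 1L
}

# Split a ";"-joined label string into a character vector of labels.
split_labels <- function(x) {
  strsplit(as.character(x), ";", fixed = TRUE)
}

# TRUE for each cohort row carrying `label` (possibly among several).
has_label <- function(cohort, label) {
  vapply(split_labels(cohort$labels), function(l) label %in% l, logical(1))
}

# Validate and return the CAFPA matrix of a cohort data frame.
cohort_cafpas <- function(cohort) {
  missing_cols <- setdiff(CAFPA_NAMES, names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing CAFPA columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m <- as.matrix(cohort[, CAFPA_NAMES, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- m[is.finite(m)]
  if (any(bad < 0 | bad > 1))
    stop("CAFPA values must lie in [0, 1]", call. = FALSE)
  m
}

# Coerce a CAFPA input (named/unnamed vector or matrix/data.frame) to an
# n x 10 matrix with the canonical column order.
as_cafpa_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (all(CAFPA_NAMES %in% names(x))) return(cohort_cafpas(x))
    x <- as.matrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x)) && all(CAFPA_NAMES %in% colnames(x)))
    x <- x[, CAFPA_NAMES, drop = FALSE]
  if (ncol(x) != length(CAFPA_NAMES))
    stop("expected ", length(CAFPA_NAMES), " CAFPA values per patient, got ",
         ncol(x), call. = FALSE)
  colnames(x) <- CAFPA_NAMES
  storage.mode(x) <- "double"
  ok <- x[is.finite(x)]
  if (any(ok < 0 | ok > 1))
    stop("CAFPA values must lie in [0, 1]", call. = FALSE)
  x
}
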