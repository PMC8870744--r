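# Shared fixtures, all built in code.

# Construct a cafpa_cs object directly from known beta shapes (bypassing
# fitting), so decision rules and certainties can be checked against
# closed-form values.  a1/b1 and a2/b2 are scalars or length-10 vectors.
make_cs <- function(a1, b1, a2, b2, categories = c("cat1", "cat2"),
                    eps = 1e-3, grid_size = 1001L) {
  k <- length(cafpabayes::CAFPA_NAMES)
  a <- rbind(rep_len(a1, k), rep_len(a2, k))
  b <- rbind(rep_len(b1, k), rep_len(b2, k))
  dimnames(a) <- dimnames(b) <- list(categories, cafpabayes::CAFPA_NAMES)
  thresholds <- numeric(k)
  ec <- numeric(k)
  for (j in seq_len(k)) {
    d1 <- beta_params(a[1, j], b[1, j])
    d2 <- beta_params(a[2, j], b[2, j])
    thresholds[j] <- as.numeric(decision_threshold(d1, d2, grid_size, eps))
    ec[j] <- as.numeric(expected_certainty(d1, d2, grid_size, eps))
  }
  names(thresholds) <- names(ec) <- cafpabayes::CAFPA_NAMES
  structure(list(categories = categories,
                 members = stats::setNames(as.list(categories), categories),
                 shapes = list(a = a, b = b),
                 thresholds = thresholds, crossings = NULL,
                 expected_certainty = ec, low_certainty = ec <= 0.65,
                 n = stats::setNames(c(NA_integer_, NA_integer_), categories),
                 patient_ids = stats::setNames(list(character(0),
                                                    character(0)),
                                               categories),
                 eps = eps, grid_size = grid_size),
            class = "cafpa_cs")
}

# A tree whose root and leaf comparison sets both use identical training
# distributions for their two categories: the uninformative chance case.
make_chance_tree <- function() {
  root <- make_cs(2, 2, 2, 2, categories = c("A", "B"))
  leaf <- make_cs(2, 2, 2, 2, categories = c("C", "D"))
  cafpa_tree(root, leaf)
}

# A strongly separated three-category cohort spec (near-disjoint beta
# supports), used for end-to-end recovery checks.
separated_spec <- function(seed, n_per_category = 60L,
                           dual_label_fraction = 0) {
  cohort_spec(
    categories = c("none", "hearing-aid", "cochlear-implant"),
    beta_params = list(
      "none"             = list(a = 2, b = 50),
      "hearing-aid"      = list(a = 50, b = 50),
      "cochlear-implant" = list(a = 50, b = 2)),
    n_per_category = n_per_category,
    dual_label_fraction = dual_label_fraction,
    dual_pair = c("hearing-aid", "cochlear-implant"),
    seed = seed)
}

# Independent brute-force classifier: weighted density sums computed with
# explicit loops, no shared code with the package internals.
brute_force_classify <- function(x, a, b, w, eps = 1e-3) {
  s <- c(0, 0)
  for (ci in 1:2) {
    for (j in seq_along(x)) {
      xi <- min(max(x[j], eps), 1 - eps)
      s[ci] <- s[ci] + w[j] * stats::dbeta(xi, a[ci, j], b[ci, j])
    }
  }
  if (s[1] >= s[2]) 1L else 2L
}
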