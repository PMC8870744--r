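#' Assemble a tree set from two fitted comparison sets
#'
#' A *tree set* chains two comparison sets into a three-category decision:
#' the root comparison set decides between terminal category A and an
#' intermediate category B; patients classified as B enter the leaf
#' comparison set, which decides between terminal categories C and D.  The
#' canonical example is the treatment-recommendation tree: no hearing
#' device vs hearing device, then hearing aid vs cochlear implant.
#'
#' Certainties are propagated multiplicatively along the tree:
#' `Cert(A) = Cert_root(A)`, `Cert(C) = Cert_root(B) * Cert_leaf(C)`,
#' `Cert(D) = Cert_root(B) * Cert_leaf(D)`; the three terminal certainties
#' sum to 1 by construction.  With completely uninformative training
#' distributions the certainties sit at their chance levels (0.5, 0.25,
#' 0.25).
#'
#' @param root A fitted [cafpa_cs()] for the first-layer decision.
#' @param leaf A fitted [cafpa_cs()] for the second-layer decision, entered
#'   from the root's *second* category.
#' @param root_weights,leaf_weights CAFPA weight vectors used in each
#'   comparison set (`NULL` for uniform).
#' @return An object of class `cafpa_tree` with `terminals`
#'   `c(root$categories[1], leaf$categories)`.
#' @examples
#' cohort <- simulate_cohort(default_cohort_spec(seed = 2, n_per_category = 40))
#' root <- cafpa_cs(cohort, c("none", "hearing-device"),
#'   members = list("hearing-device" = c("hearing-aid", "cochlear-implant")))
#' leaf <- cafpa_cs(cohort, c("hearing-aid", "cochlear-implant"))
#' tree <- cafpa_tree(root, leaf)
#' predict(tree, cohort[1:3, ])
#' @export
cafpa_tree <- function(root, leaf, root_weights = NULL, leaf_weights = NULL) {
  stopifnot(inherits(root, "cafpa_cs"), inherits(leaf, "cafpa_cs"))
  terminals <- c(root$categories[1], leaf$categories)
  if (anyDuplicated(terminals))
    stop("terminal categories must be distinct: ",
         paste(terminals, collapse = ", "), call. = FALSE)
  if (!is.null(root_weights)) root_weights <- check_weights(root_weights)
  if (!is.null(leaf_weights)) leaf_weights <- check_weights(leaf_weights)
  structure(list(root = root, leaf = leaf,
                 root_weights = root_weights, leaf_weights = leaf_weights,
                 terminals = terminals, call = match.call()),
            class = "cafpa_tree")
}

#' @export
print.cafpa_tree <- function(x, ...) {
  cat("CAFPA tree set\n")
  cat("  root:", x$root$categories[1], "vs", x$root$categories[2], "\n")
  cat("  leaf:", x$leaf$categories[1], "vs", x$leaf$categories[2],
      sprintf("(entered from '%s')\n", x$root$categories[2]))
  cat("  terminals:", paste(x$terminals, collapse = ", "), "\n")
  wdesc <- function(w) if (is.null(w)) "uniform"
           else paste(sprintf("%s=%.2g", names(w)[w > 0], w[w > 0]),
                      collapse = " ")
  cat("  root weights:", wdesc(x$root_weights), "\n")
  cat("  leaf weights:", wdesc(x$leaf_weights), "\n")
  invisible(x)
}

#' @export
summary.cafpa_tree <- function(object, ...) {
  cat("Root comparison set\n")
  print(summary(object$root))
  cat("\nLeaf comparison set\n")
  print(summary(object$leaf))
  invisible(object)
}

#' Classify CAFPA vectors through a tree set
#'
#' Runs the root decision, sends patients classified to the root's second
#' category through the leaf decision, and reports the terminal category
#' together with the propagated certainties of *all three* terminals
#' (computed for every patient regardless of the path taken, so the three
#' certainties always sum to 1).
#'
#' @param object A [cafpa_tree()] object.
#' @param newdata CAFPA input: cohort data frame, matrix or length-10
#'   vector.
#' @param ... Unused.
#' @return A data frame with columns `terminal`, one certainty column
#'   `cert_<terminal>` per terminal category, and `root_category`.
#' @export
predict.cafpa_tree <- function(object, newdata, ...) {
  root_cert <- certainty_cs(object$root, newdata, object$root_weights)
  leaf_cert <- certainty_cs(object$leaf, newdata, object$leaf_weights)
  root_cat <- ifelse(root_cert[, 1] >= 0.5, object$root$categories[1],
                     object$root$categories[2])
  leaf_cat <- ifelse(leaf_cert[, 1] >= leaf_cert[, 2],
                     object$leaf$categories[1], object$leaf$categories[2])
  terminal <- ifelse(root_cat == object$root$categories[1],
                     root_cat, leaf_cat)
  cert <- cbind(root_cert[, 1],
                root_cert[, 2] * leaf_cert[, 1],
                root_cert[, 2] * leaf_cert[, 2])
  colnames(cert) <- paste0("cert_", object$terminals)
  out <- data.frame(terminal = terminal, cert,
                    root_category = root_cat,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Confusion matrix between two terminal classifications
#'
#' Cross-tabulates the terminal categories assigned to the same patients by
#' a reference classification (e.g. from expert-estimated CAFPAs) and a test
#' classification (e.g. from model-predicted CAFPAs).  Proportions are
#' normalized within each *reference* column, so each column shows how the
#' reference category's patients were distributed by the test
#' classification.
#'
#' @param reference,test Character vectors of terminal categories, aligned
#'   over the same patients.
#' @param terminals The tree's three terminal categories (fixes row/column
#'   order); default the categories present.
#' @return An object of class `cafpa_confusion`: list with `counts`
#'   (test x reference), `proportions` (column-normalized; `NaN` for empty
#'   reference columns) and `terminals`.
#' @export
cafpa_confusion <- function(reference, test, terminals = NULL) {
  if (length(reference) != length(test))
    stop("reference and test must be aligned", call. = FALSE)
  if (is.null(terminals)) terminals <- sort(unique(c(reference, test)))
  bad <- setdiff(unique(c(reference, test)), terminals)
  if (length(bad) > 0L)
    stop("labels outside the tree's terminal categories: ",
         paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(test, levels = terminals),
                  factor(reference, levels = terminals))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("test", "reference")
  totals <- colSums(counts)
  props <- sweep(counts, 2L, totals, `/`)   # NaN where a column is empty
  structure(list(counts = counts, proportions = props,
                 terminals = terminals), class = "cafpa_confusion")
}

#' @export
print.cafpa_confusion <- function(x, digits = 3, ...) {
  cat("Confusion matrix (test rows x reference columns)\n\ncounts:\n")
  print(x$counts)
  cat("\ncolumn-normalized proportions:\n")
  print(round(x$proportions, digits))
  acc <- accuracy(x)
  if (!is.na(acc)) cat(sprintf("\naccuracy: %.3f\n", acc))
  invisible(x)
}

#' Plot a confusion matrix
#'
#' Heat map of the column-normalized proportions with the raw counts
#' printed in each cell.
#'
#' @param x A [cafpa_confusion()] object.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.cafpa_confusion <- function(x, ...) {
  k <- length(x$terminals)
  p <- x$proportions
  p[!is.finite(p)] <- 0
  graphics::image(1:k, 1:k, t(p[k:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(25, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "reference", ylab = "test",
                  zlim = c(0, 1))
  graphics::axis(1, at = 1:k, labels = x$terminals, tick = FALSE)
  graphics::axis(2, at = k:1, labels = x$terminals, tick = FALSE, las = 2)
  for (i in 1:k) for (j in 1:k)
    graphics::text(j, k + 1 - i, x$counts[i, j],
                   col = if (is.finite(x$proportions[i, j]) &&
                             x$proportions[i, j] > 0.5) "white" else "black")
  graphics::box()
  invisible(x)
}

#' Classification accuracy from a confusion matrix
#'
#' The proportion of agreeing classifications: the trace of the count
#' matrix divided by its grand total.
#'
#' @param confusion A [cafpa_confusion()] object or a square count matrix.
#' @return Accuracy in \[0, 1\]; `NA` when the total count is zero.
#' @export
accuracy <- function(confusion) {
  counts <- if (inherits(confusion, "cafpa_confusion")) confusion$counts
            else as.matrix(confusion)
  if (nrow(counts) != ncol(counts))
    stop("confusion matrix must be square", call. = FALSE)
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  sum(diag(counts)) / total
}
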