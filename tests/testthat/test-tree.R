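test_that("uninformative trees sit exactly at chance-level certainty", {
  tree <- make_chance_tree()
  for (x in list(runif(10), rep(0.1, 10), rep(0.9, 10))) {
    res <- predict(tree, x)
    expect_equal(res$cert_A, 0.5)
    expect_equal(res$cert_C, 0.25)
    expect_equal(res$cert_D, 0.25)
  }
})

test_that("comparison-set certainty is the score share", {
  # single CAFPA, cat1 Beta(2,1) and cat2 Beta(1,2): densities at x = 0.75
  # are 1.5 and 0.5, hence certainty (0.75, 0.25)
  cs <- make_cs(2, 1, 1, 2)
  w <- setNames(c(1, rep(0, 9)), CAFPA_NAMES)
  x <- c(0.75, runif(9))
  cert <- certainty_cs(cs, x, w)
  expect_equal(unname(cert[1, ]), c(0.75, 0.25))

  # identical distributions: (0.5, 0.5) for any input
  cs_id <- make_cs(4, 2, 4, 2)
  expect_equal(unname(certainty_cs(cs_id, runif(10))[1, ]), c(0.5, 0.5))

  # certainty of the classified category is always >= 0.5
  set.seed(31)
  cs_r <- make_cs(runif(10, 0.5, 6), runif(10, 0.5, 6),
                  runif(10, 0.5, 6), runif(10, 0.5, 6))
  for (i in 1:50) {
    x <- runif(10)
    res <- classify_cs(cs_r, x)
    expect_gte(res$certainty[res$category], 0.5)
  }
})

test_that("tree certainties always sum to one", {
  set.seed(42)
  cohort <- simulate_cohort(default_cohort_spec(seed = 42L,
                                                n_per_category = 40L))
  root <- cafpa_cs(cohort, c("none", "hearing-device"),
                   members = list("hearing-device" =
                                    c("hearing-aid", "cochlear-implant")))
  leaf <- cafpa_cs(cohort, c("hearing-aid", "cochlear-implant"))
  tree <- cafpa_tree(root, leaf, root_weights = runif(10),
                     leaf_weights = runif(10))
  x <- matrix(runif(1000 * 10), ncol = 10)
  res <- predict(tree, x)
  sums <- rowSums(res[, paste0("cert_", tree$terminals)])
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(res[, 2:4] > 0 & res[, 2:4] < 1))
})

test_that("well-separated trees classify far inputs with high certainty", {
  cohort <- simulate_cohort(separated_spec(seed = 19L, n_per_category = 50L))
  root <- cafpa_cs(cohort, c("none", "hearing-device"),
                   members = list("hearing-device" =
                                    c("hearing-aid", "cochlear-implant")))
  leaf <- cafpa_cs(cohort, c("hearing-aid", "cochlear-implant"))
  tree <- cafpa_tree(root, leaf)
  res <- predict(tree, rep(0.02, 10))   # deep in 'none' territory
  expect_equal(res$terminal, "none")
  expect_gt(res$cert_none, 0.9)
  res_ci <- predict(tree, rep(0.98, 10))
  expect_equal(res_ci$terminal, "cochlear-implant")
  expect_gt(res_ci$`cert_cochlear-implant`, 0.9)
})

test_that("tree assembly rejects duplicated terminal categories", {
  root <- make_cs(2, 2, 3, 3, categories = c("A", "B"))
  leaf <- make_cs(2, 2, 3, 3, categories = c("A", "D"))
  expect_error(cafpa_tree(root, leaf), "distinct")
})

test_that("confusion matrices count and normalize per reference column", {
  terms <- c("A", "C", "D")
  cm_id <- cafpa_confusion(c("A", "C", "D", "A"), c("A", "C", "D", "A"),
                           terms)
  expect_equal(unname(diag(cm_id$counts)), c(2L, 1L, 1L))
  expect_equal(sum(cm_id$counts) - sum(diag(cm_id$counts)), 0L)

  # hand-enumerated example
  cm <- cafpa_confusion(reference = c("A", "A", "C"),
                        test = c("A", "C", "C"), terms)
  expect_equal(cm$counts["A", "A"], 1L)
  expect_equal(cm$counts["C", "A"], 1L)
  expect_equal(cm$counts["C", "C"], 1L)
  expect_equal(sum(cm$counts), 3L)
  # columns with patients normalize to 1; empty columns are undefined
  expect_equal(colSums(cm$proportions)[c("A", "C")], c(A = 1, C = 1))
  expect_true(all(is.nan(cm$proportions[, "D"])))

  expect_error(cafpa_confusion(c("A", "X"), c("A", "A"), terms),
               "outside the tree")
})

test_that("accuracy is the trace share of the confusion counts", {
  expect_equal(accuracy(diag(c(3, 4, 5))), 1)
  m <- diag(c(10, 10, 10)); m[upper.tri(m)] <- c(10, 10, 5)
  m[lower.tri(m)] <- c(2, 2, 1)
  expect_equal(accuracy(m), 30 / 60)
  off <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  expect_equal(accuracy(off), 0)
  expect_true(is.na(accuracy(matrix(0, 3, 3))))
})

test_that("expected certainty spans chance to near-perfect separation", {
  e_id <- expected_certainty(beta_params(2, 2), beta_params(2, 2))
  expect_equal(as.numeric(e_id), 0.5)
  expect_true(attr(e_id, "low_certainty"))

  e_sep <- expected_certainty(beta_params(50, 2), beta_params(2, 50))
  expect_gt(as.numeric(e_sep), 0.95)
  expect_false(attr(e_sep, "low_certainty"))
  # independent numerical integration oracle (trapezoid-free quadrature)
  f <- function(x) {
    p1 <- dbeta(x, 50, 2); p2 <- dbeta(x, 2, 50)
    pmax(p1, p2) / (p1 + p2)
  }
  oracle <- integrate(f, 1e-3, 1 - 1e-3)$value / (1 - 2e-3)
  expect_equal(as.numeric(e_sep), oracle, tolerance = 1e-3)

  set.seed(12)
  for (i in 1:20) {
    e <- expected_certainty(beta_params(runif(1, 0.5, 9), runif(1, 0.5, 9)),
                            beta_params(runif(1, 0.5, 9), runif(1, 0.5, 9)))
    expect_gte(as.numeric(e), 0.5)
    expect_lte(as.numeric(e), 1)
  }
})

test_that("end-to-end: separable cohorts are recovered almost perfectly", {
  spec <- separated_spec(seed = 71L, n_per_category = 50L)
  cohort <- simulate_cohort(spec)
  root <- cafpa_cs(cohort, c("none", "hearing-device"),
                   members = list("hearing-device" =
                                    c("hearing-aid", "cochlear-implant")))
  leaf <- cafpa_cs(cohort, c("hearing-aid", "cochlear-implant"))
  tree <- cafpa_tree(root, leaf)
  res <- predict(tree, cohort)
  truth <- attr(cohort, "true_category")
  cm <- cafpa_confusion(truth, res$terminal, tree$terminals)
  expect_gt(accuracy(cm), 0.95)
})
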