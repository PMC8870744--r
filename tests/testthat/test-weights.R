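test_that("binary weight enumeration is exhaustive, distinct and non-zero", {
  W10 <- enumerate_binary_weights(10)
  expect_equal(nrow(W10), 1023L)

  W1 <- enumerate_binary_weights(1)
  expect_equal(unname(W1), matrix(1, 1, 1))

  W3 <- enumerate_binary_weights(3)
  expect_equal(nrow(W3), 7L)
  expect_equal(nrow(unique(W3)), 7L)
  expect_true(all(rowSums(W3) > 0))
  expect_true(all(W3 %in% c(0, 1)))
  # lexicographic: first row selects only the last CAFPA
  expect_equal(unname(W3[1, ]), c(0, 0, 1))
  expect_equal(unname(W3[7, ]), c(1, 1, 1))

  expect_error(enumerate_binary_weights(0), "between 1 and 20")
  expect_error(enumerate_binary_weights(21), "between 1 and 20")
})

test_that("youden index reproduces hand-computed values", {
  # perfect classifier
  expect_equal(as.numeric(youden(c("A", "A", "B", "B"),
                                 c("A", "A", "B", "B"), c("A", "B"))), 1)

  # Sens = 0.8 (8/10 category-A correct), Spec = 0.7 (7/10) -> Y = 0.5
  truth <- c(rep("A", 10), rep("B", 10))
  pred <- c(rep("A", 8), "B", "B", rep("B", 7), "A", "A", "A")
  y <- youden(pred, truth, c("A", "B"))
  expect_equal(as.numeric(y), 0.5)
  expect_equal(attr(y, "sensitivity"), 0.8)
  expect_equal(attr(y, "specificity"), 0.7)

  # dual-labeled patients are excluded; all dual -> undefined
  y2 <- youden(c("A", "B"), c("A;B", "A;B"), c("A", "B"))
  expect_true(is.na(y2))
  expect_true(attr(y2, "undefined"))

  # negative values are retained (worse-than-chance classifier)
  expect_equal(as.numeric(youden(c("B", "A"), c("A", "B"), c("A", "B"))), -1)
})

test_that("youden is symmetric under swapping categories and roles", {
  set.seed(8)
  truth <- sample(c("A", "B", "A;B"), 100, replace = TRUE,
                  prob = c(0.45, 0.45, 0.1))
  pred <- sample(c("A", "B"), 100, replace = TRUE)
  y_ab <- youden(pred, truth, c("A", "B"))
  y_ba <- youden(pred, truth, c("B", "A"))
  expect_equal(as.numeric(y_ab), as.numeric(y_ba))
  expect_equal(attr(y_ab, "sensitivity"), attr(y_ba, "specificity"))
})

test_that("adding correctly classified patients never lowers youden", {
  truth <- c(rep("A", 10), rep("B", 10))
  pred <- c(rep("A", 7), rep("B", 3), rep("B", 6), rep("A", 4))
  y0 <- as.numeric(youden(pred, truth, c("A", "B")))
  for (k in c(5, 20, 50)) {
    y1 <- as.numeric(youden(c(pred, rep("A", k), rep("B", k)),
                            c(truth, rep("A", k), rep("B", k)),
                            c("A", "B")))
    expect_gte(y1, y0)
    y0 <- y1
  }
})

test_that("weight search separates separable categories and not chance ones", {
  # near-disjoint supports: some combination reaches Y ~ 1
  spec <- separated_spec(seed = 17L, n_per_category = 40L)
  cohort <- simulate_cohort(spec)
  cs <- cafpa_cs(cohort, c("hearing-aid", "cochlear-implant"))
  sw <- search_weights(cs, cohort, loo = FALSE)
  expect_equal(nrow(sw$weights), 1023L)
  expect_length(sw$youden, 1023L)
  expect_gt(max(sw$youden), 0.99)
  expect_true(all(sw$youden >= -1 & sw$youden <= 1))

  # identical generating distributions: performance at chance
  spec0 <- cohort_spec(
    categories = c("u", "v"),
    beta_params = list(u = list(a = 2, b = 2), v = list(a = 2, b = 2)),
    n_per_category = 400L, dual_label_fraction = 0, seed = 23L)
  cohort0 <- simulate_cohort(spec0)
  cs0 <- cafpa_cs(cohort0, c("u", "v"))
  sw0 <- search_weights(cs0, cohort0, loo = FALSE,
                        weights = enumerate_binary_weights(10)[c(1, 5, 512,
                                                                 1023), ])
  expect_true(all(abs(sw0$youden) < 0.25))
})

test_that("Y90 keeps exactly the combinations within 90% of the maximum", {
  sw <- structure(list(weights = enumerate_binary_weights(2),
                       youden = c(1.0, 0.95, 0.89),
                       sensitivity = rep(NA_real_, 3),
                       specificity = rep(NA_real_, 3),
                       categories = c("A", "B"), source = "expert",
                       n_eligible = 0L, n_unique = c(A = 0L, B = 0L)),
                  class = "cafpa_weight_search")
  sel <- select_y90(sw)
  expect_equal(sel$youden, c(1.0, 0.95))
  expect_equal(nrow(sel$weights), 2L)

  # all equal: everything selected; single entry: itself
  sw$youden <- rep(0.4, 3)
  expect_equal(nrow(select_y90(sw)$weights), 3L)
  sw1 <- sw; sw1$youden <- 0.7
  sw1$weights <- sw$weights[1, , drop = FALSE]
  sw1$sensitivity <- sw1$specificity <- NA_real_
  expect_equal(nrow(select_y90(sw1)$weights), 1L)

  # an externally imposed reference maximum tightens the cut
  sw$youden <- c(0.80, 0.95, 0.50)
  sel_joint <- select_y90(sw, reference_max = 1.0)
  expect_equal(sel_joint$youden, 0.95)

  sw$youden <- rep(NA_real_, 3)
  expect_error(select_y90(sw), "empty selection")
})

test_that("rel weights are normalized CAFPA frequencies over common sets", {
  # single combination {CA1, CA2}: weights (1/2, 1/2, 0, ...)
  W <- matrix(0, 1, 10, dimnames = list(NULL, CAFPA_NAMES))
  W[1, 1:2] <- 1
  w <- derive_rel_weights(list(expert = W))
  expect_equal(as.vector(w), c(0.5, 0.5, rep(0, 8)))
  expect_false(attr(w, "fallback"))

  # sets {A, B} and {B, C}: frequencies over the intersection {B} only
  A <- matrix(c(1, rep(0, 9)), 1)
  B <- matrix(c(1, 1, rep(0, 8)), 1)
  C <- matrix(c(0, 1, 1, rep(0, 7)), 1)
  w2 <- derive_rel_weights(list(expert = rbind(A, B), model = rbind(B, C)))
  expect_equal(as.vector(w2), c(0.5, 0.5, rep(0, 8)))
  expect_equal(attr(w2, "n_common"), 1L)

  # weights sum to 1, zero exactly off the common combinations
  expect_equal(sum(w2), 1)
  expect_true(all(w2[3:10] == 0))

  expect_error(derive_rel_weights(list()), "at least one")
})

test_that("empty intersection falls back to the model's best combination", {
  mk <- function(W, y) structure(
    list(weights = W, youden = y, sensitivity = y, specificity = y,
         categories = c("A", "B"), source = "m", n_eligible = 0L,
         n_unique = c(A = 0L, B = 0L)),
    class = "cafpa_weight_search")
  expert <- mk(matrix(c(1, rep(0, 9)), 1), 0.9)
  model <- mk(rbind(c(0, 1, rep(0, 8)), c(0, 1, 1, rep(0, 7))),
              c(0.8, 0.6))
  w <- derive_rel_weights(list(expert = expert, model = model))
  expect_true(attr(w, "fallback"))
  expect_equal(attr(w, "n_common"), 0L)
  # best model combination is {CA2}, normalized
  expect_equal(as.vector(w), c(0, 1, rep(0, 8)))
  expect_equal(sum(w), 1)
})
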