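test_that("beta_density matches closed-form values", {
  expect_equal(beta_density(beta_params(1, 1), c(0.1, 0.5, 0.9)),
               rep(1, 3))
  expect_equal(beta_density(beta_params(2, 1), 0.5), 1)
  # direct formula as oracle: x (1-x)^4 / B(2, 5)
  x <- 0.2
  expect_equal(beta_density(beta_params(2, 5), x),
               x * (1 - x)^4 / beta(2, 5))
  expect_error(beta_density(beta_params(2, 5), 1.3), "\\[0, 1\\]")
})

test_that("single-CAFPA classification follows the decision threshold", {
  cs <- make_cs(2, 6, 6, 2)
  th <- cs$thresholds["CA1"]
  w <- setNames(c(1, rep(0, 9)), CAFPA_NAMES)
  below <- rep(0.5, 10); below[1] <- th - 0.05
  above <- rep(0.5, 10); above[1] <- th + 0.05
  expect_equal(classify_cs(cs, below, w)$category, "cat1")
  expect_equal(classify_cs(cs, above, w)$category, "cat2")
})

test_that("classification is invariant to positive scaling of weights", {
  cs <- make_cs(c(2, 3, 1, 5, 2, 4, 2, 2, 3, 1), 4, 4, c(2, 2, 3, 1, 5,
                                                         2, 4, 2, 2, 3))
  set.seed(55)
  for (i in 1:50) {
    x <- runif(10)
    w <- runif(10)
    r1 <- classify_cs(cs, x, w)
    r2 <- classify_cs(cs, x, 7.3 * w)
    expect_identical(r1$category, r2$category)
    expect_equal(r2$scores, 7.3 * r1$scores)
    expect_equal(r1$certainty, r2$certainty)
  }
})

test_that("classification agrees with an independent brute-force argmax", {
  set.seed(2024)
  a <- rbind(runif(10, 0.5, 8), runif(10, 0.5, 8))
  b <- rbind(runif(10, 0.5, 8), runif(10, 0.5, 8))
  cs <- make_cs(a[1, ], b[1, ], a[2, ], b[2, ])
  n_agree <- 0L
  n_trials <- 300L
  for (i in seq_len(n_trials)) {
    x <- runif(10)
    w <- sample(0:1, 10, replace = TRUE)
    if (all(w == 0)) w[sample(10, 1)] <- 1
    got <- classify_cs(cs, x, w)$category
    want <- cs$categories[brute_force_classify(x, a, b, w)]
    n_agree <- n_agree + (got == want)
  }
  expect_identical(n_agree, n_trials)
})

test_that("missing CAFPAs are dropped with renormalized weights", {
  cs <- make_cs(2, 6, 6, 2)
  x <- rep(0.2, 10)
  x[3:4] <- NA
  expect_warning(res <- classify_cs(cs, x), "renormalized")
  expect_equal(res$category, "cat1")
  expect_false(any(res$used[3:4]))
  # same decision as simply zeroing the missing CAFPAs' weights
  w <- rep(1, 10); w[3:4] <- 0
  expect_equal(res$certainty,
               classify_cs(cs, ifelse(is.na(x), 0.5, x), w)$certainty)

  all_na <- rep(NA_real_, 10)
  expect_error(classify_cs(cs, all_na), "cannot classify")
})

test_that("exact score ties resolve to the first category and are flagged", {
  cs <- make_cs(2, 2, 2, 2)   # identical distributions: always tied
  res <- classify_cs(cs, runif(10))
  expect_equal(res$category, "cat1")
  expect_true(res$tie)
})

test_that("delta_pcafpa measures signed distance to thresholds", {
  cs <- make_cs(2, 6, 6, 2)
  th <- cs$thresholds
  expect_equal(unname(delta_pcafpa(cs, th)[1, ]), rep(0, 10))

  x <- th + 0.1
  d <- delta_pcafpa(cs, x)[1, ]
  expect_equal(unname(d), rep(0.1, 10), tolerance = 1e-9)
  # consistency: positive delta on a single CAFPA classifies to category 2
  w <- setNames(c(1, rep(0, 9)), CAFPA_NAMES)
  expect_equal(classify_cs(cs, x, w)$category, "cat2")

  # undefined thresholds propagate as NA, no exception
  cs_id <- make_cs(3, 3, 3, 3)
  expect_true(all(is.na(delta_pcafpa(cs_id, runif(10)))))
})

test_that("sign of single-CAFPA delta matches the classified category", {
  cs <- make_cs(c(1.5, 2, 3, 4, 2, 5, 2, 3, 1.2, 2), c(5, 6, 4, 3, 7,
                                                       4, 3, 2, 4, 6),
                c(4, 5, 2, 2, 6, 2, 5, 1.5, 3, 4), c(2, 2, 5, 5, 2,
                                                     6, 2, 4, 1.5, 2))
  # restrict to CAFPAs whose densities cross exactly once with the first
  # category dominating below the crossing: there the sign of the threshold
  # distance fully determines the Bayes decision
  single <- vapply(seq_len(10), function(j) {
    d1 <- beta_params(cs$shapes$a[1, j], cs$shapes$b[1, j])
    d2 <- beta_params(cs$shapes$a[2, j], cs$shapes$b[2, j])
    th <- decision_threshold(d1, d2)
    length(attr(th, "crossings")) == 1L &&
      beta_density(d1, as.numeric(th) / 2) >
        beta_density(d2, as.numeric(th) / 2)
  }, logical(1))
  expect_true(any(single))
  set.seed(99)
  n_checked <- 0L
  for (i in 1:1000) {
    j <- sample(which(single), 1)
    x <- runif(10)
    d <- delta_pcafpa(cs, x)[1, j]
    if (is.na(d) || d == 0) next
    w <- rep(0, 10); w[j] <- 1
    got <- classify_cs(cs, x, w)$category
    want <- if (d > 0) "cat2" else "cat1"
    expect_identical(got, want)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 900)
})

test_that("scores stay finite for boundary CAFPA values", {
  cs <- make_cs(0.6, 0.7, 5, 0.5)  # shapes < 1: densities unbounded at 0/1
  res <- classify_cs(cs, c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1))
  expect_true(all(is.finite(res$scores)))
})
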