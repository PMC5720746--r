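test_that("beta posterior has the conjugate closed form", {
  e <- usage_estimate("x_thorax", "teaching", 0, 10, 0.5, 0.5)
  expect_equal(e$rate, 0)
  expect_equal(e$beta_a, 0.5)
  expect_equal(e$beta_b, 10.5)
  expect_equal(e$beta_a / (e$beta_a + e$beta_b), 0.5 / 11)
  # never-used modality: the interval's lower bound sits above 0 only
  # through prior mass
  expect_gt(e$ci_low, 0)
  expect_lt(e$ci_low, 0.01)

  e <- usage_estimate("mr_brain", "teaching", 37, 212)
  expect_equal(round(100 * e$rate, 1), 17.5)
  expect_equal(e$beta_a, 37.5)
  expect_equal(e$beta_b, 175.5)
  expect_true(e$ci_low <= e$rate && e$rate <= e$ci_high)

  e <- usage_estimate("sex_male", "teaching", 136, 214)
  expect_equal(round(100 * e$rate, 1), 63.6)
})

test_that("posterior mean lies strictly between prior mean and empirical rate", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:500, 1)
    k <- sample(0:n, 1)
    a <- stats::runif(1, 0.1, 5); b <- stats::runif(1, 0.1, 5)
    e <- usage_estimate("m", "h", k, n, a, b)
    post_mean <- e$beta_a / (e$beta_a + e$beta_b)
    prior_mean <- a / (a + b)
    rate <- k / n
    if (abs(rate - prior_mean) > 1e-12) {
      expect_true(post_mean > min(rate, prior_mean) &&
                  post_mean < max(rate, prior_mean))
    }
  }
})

test_that("estimate_usage counts flags per hospital with evaluable denominators", {
  co <- make_small_cohort()
  e <- estimate_usage(co, "x_thorax")
  expect_equal(sort(e$hospital), c("academic", "teaching"))
  expect_equal(e$count[e$hospital == "teaching"], 2L)
  expect_equal(e$denominator[e$hospital == "teaching"], 3L)
  # the NA flag shrinks the evaluable denominator
  ect <- estimate_usage(co, "ct")
  expect_equal(ect$denominator[ect$hospital == "teaching"], 2L)
  expect_error(estimate_usage(co, "not_a_modality"), "not in the registry")
})

test_that("chi-squared matches the direct Pearson formula", {
  # balanced table: no association
  t0 <- chi2_independence(matrix(c(50, 50, 50, 50), 2))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(t0$df, 1L)

  # the between-hospital brain-MRI table, against the hand-evaluated oracle
  tab <- rbind(c(37, 175), c(47, 105))
  t1 <- chi2_independence(tab)
  expect_equal(t1$statistic, pearson_oracle(37, 175, 47, 105),
               tolerance = 1e-12)
  expect_equal(t1$statistic, 9.0462, tolerance = 1e-4)
  expect_lt(t1$p_value, 0.01)

  # doubling every cell doubles the statistic at fixed proportions
  t2 <- chi2_independence(2 * tab)
  expect_equal(t2$statistic, 2 * t1$statistic, tolerance = 1e-12)

  # Yates correction shrinks a non-null statistic
  expect_lt(chi2_independence(tab, correct = TRUE)$statistic, t1$statistic)
})

test_that("chi-squared agrees with the brute-force oracle on random small tables", {
  set.seed(17)
  for (i in 1:200) {
    repeat {
      cells <- as.integer(stats::rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
      tab <- matrix(cells, 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    got <- chi2_independence(tab)
    expect_equal(got$statistic,
                 pearson_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
    expect_true(got$p_value > 0 && got$p_value <= 1)
  }
})

test_that("degenerate margins and malformed tables are rejected", {
  expect_error(chi2_independence(matrix(c(0, 0, 5, 3), 2, byrow = TRUE)),
               "row margin 1")
  expect_error(chi2_independence(matrix(c(0, 4, 0, 3), 2, byrow = TRUE)),
               "column margin 1")
  expect_error(chi2_independence(matrix(1:6, 2)), "2x2")
  expect_error(chi2_independence(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("usage_table is one row per modality and invariant to row order", {
  co <- make_small_cohort()
  ut <- usage_table(co)
  expect_equal(nrow(ut), 19L)
  expect_equal(ut$count_teaching[ut$modality_id == "bronchoscopy"], 2L)
  # never-used modality: rate 0 in both hospitals
  expect_equal(ut$rate_teaching[ut$modality_id == "alk"], 0)
  expect_equal(ut$rate_academic[ut$modality_id == "alk"], 0)

  perm <- co[rev(seq_len(nrow(co))), ]
  class(perm) <- c("dx_cohort", class(perm))
  attr(perm, "registry") <- default_registry()
  expect_equal(as.data.frame(usage_table(perm)), as.data.frame(ut))

  one_hosp <- co[co$hospital == "teaching", ]
  class(one_hosp) <- c("dx_cohort", class(one_hosp))
  attr(one_hosp, "registry") <- default_registry()
  expect_error(usage_table(one_hosp), "two hospitals")
})

test_that("usage tables export with percentage formatting", {
  ut <- usage_table(make_small_cohort())
  path <- withr::local_tempfile(fileext = ".csv")
  write_usage_table(ut, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 19L)
  expect_equal(back$rate_teaching[back$modality_id == "x_thorax"],
               round(100 * ut$rate_teaching[ut$modality_id == "x_thorax"], 1))
})
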