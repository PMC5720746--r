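test_that("the default pathway holds all 19 modalities in 4 ordered stages", {
  pw <- make_reference_pathway()
  expect_equal(pw$start, "suspicion of lung cancer")
  expect_equal(pw$stages, c("imaging", "invasive", "functional", "molecular"))
  expect_setequal(pw$terminal, c("TNM stage", "no malignancy"))
  by_stage <- table(pw$registry$stage)
  expect_equal(sum(by_stage), 19L)
  expect_equal(as.integer(by_stage[c("imaging", "invasive", "functional",
                                     "molecular")]), c(7L, 5L, 5L, 2L))
})

test_that("build_pathway reports estimate gaps by modality", {
  u <- reference_usage()
  u <- u[u$modality_id != "pet_ct" | u$hospital != "academic", ]
  est <- usage_estimate(u$modality_id, u$hospital, u$count, u$denominator)
  expect_error(build_pathway(default_registry(), est),
               "hospital 'academic'.*pet_ct")
})

test_that("expected cost composes unit cost and probability exactly", {
  reg <- modality_registry("x_thorax", "X-thorax", "imaging")
  est <- usage_estimate("x_thorax", c("teaching", "academic"),
                        c(10, 0), c(10, 10))
  pw <- build_pathway(reg, est)
  bi <- expected_cost(pw, default_tariffs())
  expect_equal(bi$per_patient[["teaching"]], 43.66)
  expect_equal(bi$per_patient[["academic"]], 0)
  bi_n <- expected_cost(pw, default_tariffs(), n = c(teaching = 100, academic = 50))
  expect_equal(bi_n$cohort_total[["teaching"]], 4366)
})

test_that("expected cost is linear in modality sets and monotone in p and c", {
  pw <- make_reference_pathway()
  tt <- default_tariffs()
  full <- expected_cost(pw, tt)
  # linearity: contributions partition the total
  for (h in names(full$per_patient)) {
    ch <- full$contributions[full$contributions$hospital == h, ]
    imaging_ids <- pw$registry$modality_id[pw$registry$stage == "imaging"]
    part <- sum(ch$contribution[ch$modality_id %in% imaging_ids]) +
      sum(ch$contribution[!ch$modality_id %in% imaging_ids])
    expect_equal(part, full$per_patient[[h]])
    expect_true(all(ch$contribution >= 0))
  }
  # monotonicity in p: raise one probability
  est2 <- pw$estimates
  i <- which(est2$modality_id == "ecg" & est2$hospital == "teaching")
  est2$rate[i] <- min(1, est2$rate[i] + 0.2)
  up <- expected_cost(build_pathway(pw$registry, est2), tt)
  expect_gt(up$per_patient[["teaching"]], full$per_patient[["teaching"]])
  expect_equal(up$per_patient[["academic"]], full$per_patient[["academic"]])
  # monotonicity in c and basis ordering: hospital costs never exceed tariffs
  hc <- expected_cost(pw, tt, cost_basis = "hospital_cost")
  expect_true(all(hc$per_patient <= full$per_patient))
})

test_that("unmapped modalities are excluded with a message, or error without a table entry", {
  pw <- make_reference_pathway()
  map <- default_tariff_mapping()
  map <- map[names(map) != "bone_scintigraphy"]
  expect_message(bi <- expected_cost(pw, default_tariffs(), mapping = map),
                 "bone_scintigraphy")
  expect_equal(bi$excluded, "bone_scintigraphy")
  bad_map <- default_tariff_mapping()
  bad_map[["bone_scintigraphy"]] <- "no_such_row"
  expect_error(expected_cost(pw, default_tariffs(), mapping = bad_map),
               "no_such_row")
})

test_that("observed cost sums used-modality tariffs per patient in exact cents", {
  co <- make_small_cohort()
  # silence the never-used columns: patient 3 uses bronchoscopy only
  oc <- observed_cost(co, default_tariffs())
  costs <- oc$per_patient
  p3 <- costs$cost[costs$patient_id == "p03"]
  expect_equal(p3, 370.71)
  p2 <- costs$cost[costs$patient_id == "p02"]  # x_thorax only
  expect_equal(p2, 43.66)
  p1 <- costs$cost[costs$patient_id == "p01"]  # x_thorax + bronch + mr_brain
  expect_equal(p1, 43.66 + 370.71 + 218.29)
})

test_that("cohort mean observed cost equals expected cost at empirical rates", {
  co <- generate_cohort(default_config(seed = 21))
  est <- do.call(rbind, lapply(default_registry()$modality_id,
                               function(m) estimate_usage(co, m)))
  pw <- build_pathway(default_registry(), est)
  bi <- expected_cost(pw, default_tariffs())
  oc <- observed_cost(co, default_tariffs())
  expect_equal(oc$mean_cost[["teaching"]], bi$per_patient[["teaching"]],
               tolerance = 1e-12)
  expect_equal(oc$mean_cost[["academic"]], bi$per_patient[["academic"]],
               tolerance = 1e-12)
})

test_that("PSA is seeded, reproducible and consistent with the plug-in cost", {
  pw <- make_reference_pathway()
  tt <- default_tariffs()
  expect_error(run_psa(pw, tt, draws = 0), "draws")

  a <- run_psa(pw, tt, draws = 500, seed = 99)
  b <- run_psa(pw, tt, draws = 500, seed = 99)
  expect_identical(a$costs, b$costs)
  expect_false(identical(a$costs, run_psa(pw, tt, draws = 500, seed = 100)$costs))
  expect_equal(nrow(a$costs), 500L)
  s <- a$summary
  expect_true(all(s$ci_low <= s$mean & s$mean <= s$ci_high))

  # with near-degenerate posteriors one draw already sits on E[C]
  est <- pw$estimates
  scale <- 1e6
  est$beta_a <- est$rate * scale
  est$beta_b <- (1 - est$rate) * scale
  est$beta_a[est$beta_a == 0] <- 1e-3  # keep shapes positive
  tight <- run_psa(build_pathway(pw$registry, est), tt, draws = 1, seed = 4)
  plug <- expected_cost(pw, tt)
  for (h in names(plug$per_patient)) {
    expect_equal(unname(tight$costs[1, h]), plug$per_patient[[h]],
                 tolerance = 5e-3)
  }
})

test_that("PSA mean converges to the posterior-mean cost by linearity", {
  pw <- make_reference_pathway()
  tt <- default_tariffs()
  psa <- run_psa(pw, tt, draws = 4000, seed = 12)
  # E[C] under the posterior means (a/(a+b)), the PSA's true expectation
  est <- pw$estimates
  est$rate <- est$beta_a / (est$beta_a + est$beta_b)
  target <- expected_cost(build_pathway(pw$registry, est), tt)
  for (h in names(target$per_patient)) {
    mc_se <- psa$summary$sd[psa$summary$hospital == h] / sqrt(psa$draws)
    expect_lt(abs(psa$summary$mean[psa$summary$hospital == h] -
                  target$per_patient[[h]]), 3 * mc_se)
  }
})
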