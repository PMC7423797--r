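test_that("CICR correction allocates event mass by hazard share", {
  ## single cause: plain exponential reduction
  out <- cicr_correct(c(a = 0.01, b = 0, c = 0), 1)
  expect_equal(unname(out), c(1 - exp(-0.01), 0, 0))
  ## symmetric causes split the exact exponential mass equally
  out <- cicr_correct(c(0.01, 0.01, 0.01), 0.9)
  expect_equal(out, rep((1 / 3) * (1 - exp(-0.03)) * 0.9, 3))
  expect_equal(sum(out) <= 0.9, TRUE)
  expect_equal(cicr_correct(c(0, 0, 0), 0.5), c(0, 0, 0))
  expect_error(cicr_correct(c(-0.01, 0.02), 1), ">= 0")
  ## literal first-order form agrees for small hazards, exceeds for large
  expect_equal(cicr_correct(c(x = 1e-5), 1, method = "literal")[["x"]],
               cicr_correct(c(x = 1e-5), 1)[["x"]], tolerance = 1e-4)
  expect_gt(sum(cicr_correct(c(2, 2), 1, method = "literal")), 1)
})

test_that("zero hazards leave the cohort untouched", {
  zero <- stats::setNames(rep(0, 9), age_bands())
  ts <- transition_set(zero, NULL, NULL, NULL, zero)
  tr <- run_cohort(subgroup_profile("70-74"), FALSE, ts, horizon = 24,
                   effects = unit_effects())
  expect_equal(tr$states[, "alive_no_rec"], rep(1, 25))
  expect_equal(max(abs(1 - rowSums(tr$states))), 0)
  sm <- summarize_trace(tr, c(12, 24))
  expect_equal(sm$recurrences, c(0, 0))
  expect_equal(sm$rfs_rounded, c(1000, 1000))
})

test_that("single-risk Gompertz cohort matches the closed form to 1e-9", {
  ts <- single_risk_transitions()
  tr <- run_cohort(subgroup_profile("50-54"), FALSE, ts, horizon = 120,
                   effects = unit_effects())
  H <- gompertz_cumhaz(0:120, -0.016, 0.004)
  expect_lt(max(abs(tr$cum_rec - (1 - exp(-H)))), 1e-9)
  expect_lt(max(abs(tr$states[, "alive_no_rec"] - exp(-H))), 1e-9)
  ## 60-month spot value and the defective-distribution limit
  expect_equal(tr$cum_rec[61], 1 - exp(-0.25 * (1 - exp(-0.96))),
               tolerance = 1e-9)
  tr_long <- run_cohort(subgroup_profile("50-54"), FALSE, ts,
                        horizon = 600, effects = unit_effects())
  expect_equal(tr_long$cum_rec[601], 1 - exp(-0.25), tolerance = 1e-4)
  ## per-1,000 reporting of the same quantity
  sm <- summarize_trace(tr, 60)
  expect_equal(sm$recurrences, 1000 * (1 - exp(-0.25 * (1 - exp(-0.96)))))
  expect_equal(sm$recurrences_rounded, 143)
})

test_that("mass is conserved to 1e-12 at every cycle under the full
          registry", {
  ts <- load_default_parameters("updated_2015")
  for (sg in list(subgroup_profile("90-95", "GE10", "pT4", "left",
                                   "MSSmut"),
                  subgroup_profile("50-54", "LT10", "pT3", "right",
                                   "MSI"))) {
    tr <- run_cohort(sg, treated = TRUE, ts, horizon = 600)
    expect_lt(max(abs(1 - rowSums(tr$states))), 1e-12)
    expect_true(all(tr$states >= 0))
    expect_true(all(diff(tr$cum_rec) >= 0))
    for (st in c("dead_90dm", "dead_doc", "dead_dcc"))
      expect_true(all(diff(tr$states[, st]) >= -1e-15))
  }
})

test_that("a protective treatment hazard ratio shifts recurrence mass to
          competing death", {
  ts <- load_default_parameters("updated_2015")
  sg <- subgroup_profile("70-74", "LT10", "pT4", "left", "MSSmut")
  untr <- run_cohort(sg, FALSE, ts, horizon = 120)
  trt <- run_cohort(sg, TRUE, ts, horizon = 120, regimen_hr = 0.73)
  expect_true(all(trt$cum_rec[-1] < untr$cum_rec[-1]))
  expect_true(all(trt$states[-1, "dead_dcc"] <=
                    untr$states[-1, "dead_dcc"]))
  expect_lt(trt$states[121, "dead_dcc"], untr$states[121, "dead_dcc"])
  ## competing-risk displacement: with post-recurrence other-cause death
  ## switched off, keeping more patients recurrence-free must (weakly)
  ## increase other-cause deaths
  ts0 <- ts
  ts0$rec_doc_by_age[] <- 0
  untr0 <- run_cohort(sg, FALSE, ts0, horizon = 120)
  trt0 <- run_cohort(sg, TRUE, ts0, horizon = 120, regimen_hr = 0.73)
  expect_true(all(trt0$states[, "dead_doc"] >=
                    untr0$states[, "dead_doc"] - 1e-15))
  ## regimen_hr = 1 is a no-op
  null_trt <- run_cohort(sg, TRUE, ts, horizon = 60, regimen_hr = 1)
  base <- run_cohort(sg, FALSE, ts, horizon = 60)
  expect_equal(null_trt$states, base$states)
})

test_that("dropping the competing-risk correction changes 5-year
          mortality by the documented amount", {
  ts <- load_default_parameters("updated_2015")
  sg <- subgroup_profile("80-84", "LT10", "pT4", "left", "MSSmut")
  exact <- run_cohort(sg, FALSE, ts, horizon = 60)
  naive <- run_cohort(sg, FALSE, ts, horizon = 60,
                      cicr_method = "literal")
  dead_cols <- c("dead_90dm", "dead_doc", "dead_dcc")
  d_exact <- sum(exact$states[61, dead_cols])
  d_naive <- sum(naive$states[61, dead_cols])
  ## regression value: naive independent probabilities overstate 5-year
  ## all-cause mortality by ~5.9 per 1,000 in this high-risk subgroup
  expect_equal(d_naive - d_exact, 0.005878, tolerance = 1e-3)
  expect_gt(d_naive, d_exact)
})

test_that("recurrence mass entering the final tunnel is held with frozen
          hazard", {
  zero <- stats::setNames(rep(0, 9), age_bands())
  ts <- transition_set(zero, NULL,
                       parametric_survival_model("gompertz", 0, 0.05),
                       parametric_survival_model("loglogistic", 1.17,
                                                 1e6),  # ~no death
                       zero)
  tr <- run_cohort(subgroup_profile("50-54"), FALSE, ts, horizon = 6,
                   effects = unit_effects())
  expect_lt(max(abs(1 - rowSums(tr$states))), 1e-12)
  ## all recurrence mass is still alive in the tunnels
  expect_equal(sum(tr$tunnel), unname(tr$states[7, "rec"]))
  expect_equal(tr$cum_rec[7], unname(tr$states[7, "rec"]),
               tolerance = 1e-6)
})

test_that("trace summaries and exports are consistent", {
  ts <- load_default_parameters("updated_2015")
  tr <- run_cohort(subgroup_profile("70-74"), FALSE, ts, horizon = 60)
  sm <- summarize_trace(tr, c(12, 36, 60))
  expect_true(all(diff(sm$recurrences) >= 0))
  expect_true(all(diff(sm$dcc_deaths) >= 0))
  expect_true(all(sm$recurrences_rounded == floor(sm$recurrences + 0.5)))
  expect_equal(sm$os, 1000 - sm$dcc_deaths - sm$doc_deaths -
                 sm$deaths_90dm)
  expect_error(summarize_trace(tr, 61), "horizon")
  long <- trace_to_long(tr)
  expect_equal(nrow(long), 61 * 5)
  expect_equal(sum(long$mass[long$cycle == 60]), 1, tolerance = 1e-12)
})
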