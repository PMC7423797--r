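test_that("cohort weights combine independent marginals over 216 cells", {
  comp <- build_cohort_weights()
  expect_equal(nrow(comp), 216)
  expect_equal(sum(comp$weight), 1, tolerance = 1e-12)
  expect_true(all(comp$weight >= 0))
  ## marginal recovery
  expect_equal(sum(comp$weight[comp$pt_stage == "pT4"]), 214 / 2221)
  expect_equal(sum(comp$weight[comp$lymph_nodes == "GE10"]), 946 / 2144)
  expect_equal(sum(comp$weight[comp$sidedness == "left"]), 987 / 2238)
  bm <- tapply(comp$weight, comp$biomarker, sum)
  expect_equal(as.numeric(bm[c("MSI", "MSSdwt", "MSSmut")]),
               c(28, 39, 36) / 103, tolerance = 1e-12)
  expect_equal(as.numeric(round(bm[c("MSI", "MSSdwt", "MSSmut")], 4)),
               c(0.2718, 0.3786, 0.3495))
  ## pT4 & MSS cell mass (either MSS class)
  w_pt4_mss <- sum(comp$weight[comp$pt_stage == "pT4" &
                                 comp$biomarker != "MSI"])
  expect_equal(w_pt4_mss, (214 / 2221) * (75 / 103))
  expect_equal(w_pt4_mss, 0.0699, tolerance = 5e-3)
  ## age-band weights follow the truncated normal
  aw <- tapply(comp$weight, comp$age_band, sum)[age_bands()]
  cdf <- pnorm(age_band_breaks(), 70.7, 10.9)
  expect_equal(as.numeric(aw), diff(cdf) / (cdf[10] - cdf[1]),
               tolerance = 1e-12)
  expect_error(build_cohort_weights(pt4_prev = 1.2), "\\[0, 1\\]")
  expect_error(build_cohort_weights(biomarker_prev = c(0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("degenerate marginals collapse to a single cell", {
  comp <- build_cohort_weights(pt4_prev = 1, ge10_nodes_prev = 1,
                               left_prev = 1, age_mean = 72,
                               age_sd = 1e-3,
                               biomarker_prev = c(0, 0, 1))
  expect_equal(max(comp$weight), 1, tolerance = 1e-12)
  top <- comp[which.max(comp$weight), ]
  expect_equal(top$age_band, "70-74")
  expect_equal(top$pt_stage, "pT4")
  expect_equal(top$biomarker, "MSSmut")
})

test_that("allocation rules implement the four example strategies", {
  g <- subgroup_grid()
  sg <- function(pt, bm) g[g$pt_stage == pt & g$biomarker == bm, ][1, ]
  expect_equal(allocate("A_full_nvmo", sg("pT4", "MSSmut")), 1)
  expect_equal(allocate("A_full_nvmo", sg("pT4", "MSSdwt")), 1)
  expect_equal(allocate("A_full_nvmo", sg("pT3", "MSSmut")), 0)
  expect_equal(allocate("A_full_nvmo", sg("pT4", "MSI")), 0)
  expect_equal(allocate("B_observed", sg("pT4", "MSSdwt")), 0.21)
  expect_equal(allocate("B_observed", sg("pT3", "MSI")), 0.04)
  expect_equal(allocate("B_observed", sg("pT4", "MSI")), 0.04)
  expect_equal(allocate("C_biomarker", sg("pT3", "MSSmut")), 1)
  expect_equal(allocate("C_biomarker", sg("pT4", "MSSdwt")), 0)
  expect_equal(unique(allocate("D_none", g)), 0)
  expect_error(allocate("E_everything", g))
})

test_that("the DIAG-REC multiplier is the biomarker HR times the regimen
          HR", {
  sg <- subgroup_profile("70-74", biomarker = "MSI")
  expect_equal(effective_rec_hazard_multiplier(sg, FALSE), 0.247)
  sgm <- subgroup_profile("70-74", biomarker = "MSSmut")
  expect_equal(effective_rec_hazard_multiplier(sgm, TRUE,
                                               regimen_hr = 0.73),
               1.528 * 0.73)
  sgd <- subgroup_profile("70-74", biomarker = "MSSdwt")
  expect_equal(effective_rec_hazard_multiplier(sgd, FALSE,
                                               effects = unit_effects()),
               1)
})

test_that("a universally-applied null regimen reproduces the no-treatment
          strategy", {
  ts <- load_default_parameters("updated_2015")
  comp <- build_cohort_weights()
  d <- evaluate_strategy("D_none", comp, ts, at_months = c(24, 60),
                         horizon = 60)
  all_null <- make_strategy("all", function(sg) rep(1, nrow(sg)),
                            regimen_hr = 1)
  nul <- evaluate_strategy(all_null, comp, ts, at_months = c(24, 60),
                           horizon = 60)
  expect_equal(nul$summary$recurrences, d$summary$recurrences,
               tolerance = 1e-12)
  expect_equal(nul$summary$dcc_deaths, d$summary$dcc_deaths,
               tolerance = 1e-12)
  expect_equal(d$fraction_treated, 0)
  expect_equal(nul$fraction_treated, 1)
})

test_that("strategies order 5-year colon-cancer deaths C <= A <= B <= D
          and treat the expected fractions", {
  ts <- load_default_parameters("updated_2015")
  comp <- build_cohort_weights()
  res <- lapply(strategy_names(), evaluate_strategy, composition = comp,
                transitions = ts, at_months = 60, horizon = 60)
  names(res) <- strategy_names()
  dcc <- vapply(res, function(r) r$summary$dcc_deaths, 0)
  expect_lt(dcc[["C_biomarker"]], dcc[["A_full_nvmo"]])
  expect_lt(dcc[["A_full_nvmo"]], dcc[["B_observed"]])
  expect_lt(dcc[["B_observed"]], dcc[["D_none"]])
  rec <- vapply(res, function(r) r$summary$recurrences, 0)
  expect_true(all(rec[c("C_biomarker", "A_full_nvmo", "B_observed")] <
                    rec[["D_none"]]))
  ## treated fractions
  w_pt4_mss <- sum(comp$weight[comp$pt_stage == "pT4" &
                                 comp$biomarker != "MSI"])
  expect_equal(res$A_full_nvmo$fraction_treated, w_pt4_mss)
  expect_equal(res$D_none$fraction_treated, 0)
  expect_equal(res$C_biomarker$fraction_treated,
               sum(comp$weight[comp$biomarker == "MSSmut"]))
  expect_equal(res$B_observed$fraction_treated,
               0.21 * w_pt4_mss + 0.04 * (1 - w_pt4_mss))
})

test_that("strategy evaluation is linear in the cohort composition", {
  ts <- load_default_parameters("updated_2015")
  c1 <- build_cohort_weights()
  c2 <- build_cohort_weights(pt4_prev = 0.3, age_mean = 62)
  mix <- c1
  mix$weight <- 0.5 * c1$weight + 0.5 * c2$weight
  r1 <- evaluate_strategy("B_observed", c1, ts, at_months = 60,
                          horizon = 60)
  r2 <- evaluate_strategy("B_observed", c2, ts, at_months = 60,
                          horizon = 60)
  rmix <- evaluate_strategy("B_observed", mix, ts, at_months = 60,
                            horizon = 60)
  for (col in c("recurrences", "dcc_deaths", "doc_deaths", "os"))
    expect_equal(rmix$summary[[col]],
                 0.5 * r1$summary[[col]] + 0.5 * r2$summary[[col]],
                 tolerance = 1e-9)
})
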