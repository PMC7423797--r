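## Cohort construction from marginal distributions, treatment-allocation
## strategies, treatment-effect application and population-level
## aggregation across the 216 subgroup cells.

#' Build cohort weights from independent marginal distributions
#'
#' Constructs the 216-cell cohort composition as the product of independent
#' marginals: age-band weights are the probability mass of a
#' `Normal(age_mean, age_sd)` truncated to `[50, 95)` falling in each
#' 5-year band (renormalized), crossed with the pT-stage, nodal-category,
#' sidedness and biomarker prevalences. Defaults are the registry cohort
#' marginals with unknowns excluded (pT4 214/2221, >= 10 nodes evaluated
#' 946/2144, left-sided 987/2238, age mean 70.7 sd 10.9) and the external
#' biomarker cohort fractions (MSI/MSSdwt/MSSmut = 28/39/36 of 103).
#' Independence of biomarker status from the clinical factors is an
#' explicit modeling assumption.
#'
#' @param pt4_prev,ge10_nodes_prev,left_prev Marginal prevalences in
#'   `[0, 1]`.
#' @param age_mean,age_sd Age distribution parameters in years.
#' @param biomarker_prev Numeric vector of three fractions (MSI, MSSdwt,
#'   MSSmut) summing to 1.
#' @return An object of class `cohort_composition`: the 216-row
#'   [subgroup_grid()] with a `weight` column summing to 1.
#' @export
build_cohort_weights <- function(pt4_prev = 214 / 2221,
                                 ge10_nodes_prev = 946 / 2144,
                                 left_prev = 987 / 2238,
                                 age_mean = 70.7, age_sd = 10.9,
                                 biomarker_prev = c(MSI = 28, MSSdwt = 39,
                                                    MSSmut = 36) / 103) {
  prev <- c(pt4_prev, ge10_nodes_prev, left_prev, biomarker_prev)
  if (any(prev < 0 | prev > 1))
    stop("prevalences must lie in [0, 1]")
  if (abs(sum(biomarker_prev) - 1) > 1e-8)
    stop("biomarker fractions must sum to 1")
  stopifnot(age_sd > 0)

  edges <- age_band_breaks()  # 50, 55, ..., 95
  cdf <- stats::pnorm(edges, age_mean, age_sd)
  age_w <- diff(cdf) / (cdf[length(cdf)] - cdf[1])
  names(age_w) <- age_bands()

  g <- subgroup_grid(biomarker = TRUE)
  bm <- stats::setNames(as.numeric(biomarker_prev), biomarker_levels())
  w <- age_w[g$age_band] *
    ifelse(g$lymph_nodes == "GE10", ge10_nodes_prev, 1 - ge10_nodes_prev) *
    ifelse(g$pt_stage == "pT4", pt4_prev, 1 - pt4_prev) *
    ifelse(g$sidedness == "left", left_prev, 1 - left_prev) *
    bm[g$biomarker]
  g$weight <- as.numeric(w)
  class(g) <- c("cohort_composition", "data.frame")
  g
}

#' Treated fraction of a subgroup under a named allocation strategy
#'
#' The four example strategies: `"A_full_nvmo"` treats every pT4 patient
#' with a microsatellite-stable tumor (MSSdwt or MSSmut); `"B_observed"`
#' reflects observed guideline adherence (21% of pT4 & MSS patients, 4% of
#' everyone else); `"C_biomarker"` treats all MSSmut patients regardless of
#' pT stage; `"D_none"` treats no one.
#'
#' @param strategy_name One of `"A_full_nvmo"`, `"B_observed"`,
#'   `"C_biomarker"`, `"D_none"`.
#' @param subgroup A [subgroup_profile()] or a data.frame of subgroup rows
#'   (vectorized).
#' @return Treated fraction(s) in `[0, 1]`.
#' @export
allocate <- function(strategy_name, subgroup) {
  strategy_name <- match.arg(strategy_name, strategy_names())
  if (!is.data.frame(subgroup)) subgroup <- as.data.frame(
    subgroup[c("age_band", "lymph_nodes", "pt_stage", "sidedness",
               "biomarker")], stringsAsFactors = FALSE)
  mss <- subgroup$biomarker %in% c("MSSdwt", "MSSmut")
  high_risk <- subgroup$pt_stage == "pT4" & mss
  switch(strategy_name,
         A_full_nvmo = ifelse(high_risk, 1, 0),
         B_observed = ifelse(high_risk, 0.21, 0.04),
         C_biomarker = ifelse(subgroup$biomarker == "MSSmut", 1, 0),
         D_none = rep(0, nrow(subgroup)))
}

#' @rdname allocate
#' @export
strategy_names <- function() {
  c("A_full_nvmo", "B_observed", "C_biomarker", "D_none")
}

#' Define a treatment-allocation strategy
#'
#' @param name A strategy name from [strategy_names()], or any label when a
#'   custom `treated_fraction` function is supplied.
#' @param treated_fraction Optional function mapping a data.frame of
#'   subgroup rows to treated fractions in `[0, 1]`; defaults to
#'   [allocate()] with `name`.
#' @param regimen_hr Hazard ratio of the allocated regimen on the DIAG-REC
#'   transition (default 0.73, FOLFOX vs no adjuvant treatment; 0.78
#'   selects fluoropyrimidine monotherapy).
#' @return An object of class `strategy`.
#' @export
make_strategy <- function(name, treated_fraction = NULL,
                          regimen_hr = 0.73) {
  stopifnot(regimen_hr > 0)
  if (is.null(treated_fraction)) {
    name <- match.arg(name, strategy_names())
    treated_fraction <- function(sg) allocate(name, sg)
  }
  s <- list(name = name, treated_fraction = treated_fraction,
            regimen_hr = regimen_hr)
  class(s) <- "strategy"
  s
}

#' Effective hazard multiplier on the DIAG-REC transition
#'
#' The biomarker hazard ratio of the subgroup, times the regimen hazard
#' ratio if the arm is treated. Applied multiplicatively to the DIAG-REC
#' Gompertz hazard at every cycle.
#'
#' @inheritParams run_cohort
#' @return A positive scalar multiplier.
#' @export
effective_rec_hazard_multiplier <- function(subgroup, treated = FALSE,
                                            effects = effect_registry(),
                                            regimen_hr = 0.73) {
  hr <- effects$hr_biomarker[[subgroup$biomarker]]
  if (isTRUE(treated)) hr <- hr * regimen_hr
  hr
}

#' Evaluate a treatment-allocation strategy at population level
#'
#' Splits each of the 216 subgroup cells into a treated and an untreated
#' arm according to the strategy's allocated fraction, runs the cohort
#' engine per arm, and aggregates the weighted outcomes per 1,000 patients.
#'
#' @param strategy A [make_strategy()] object or a name from
#'   [strategy_names()].
#' @param composition A [build_cohort_weights()] composition.
#' @param transitions A [transition_set()]; the default uses the updated
#'   pT4 coefficient.
#' @param effects An [effect_registry()].
#' @param at_months Months at which to tabulate outcomes.
#' @param horizon Number of cycles to run (default `max(at_months)`).
#' @param ... Passed on to [run_cohort()] (e.g. `cicr_method`,
#'   `treatment_model`).
#' @return An object of class `strategy_result`: list with `summary` (the
#'   [summarize_trace()] table of the aggregate cohort), `curves`
#'   (per-cycle per-1,000 state occupancies and cumulative outcomes),
#'   `fraction_treated`, `strategy`, and the aggregate `trace`.
#' @export
evaluate_strategy <- function(strategy,
                              composition = build_cohort_weights(),
                              transitions = load_default_parameters(),
                              effects = effect_registry(),
                              at_months = c(12, 36, 60),
                              horizon = max(at_months), ...) {
  if (is.character(strategy)) strategy <- make_strategy(strategy)
  stopifnot(inherits(strategy, "strategy"),
            inherits(composition, "data.frame"),
            abs(sum(composition$weight) - 1) < 1e-8)

  frac <- strategy$treated_fraction(composition)
  stopifnot(all(frac >= -1e-12 & frac <= 1 + 1e-12))
  frac <- pmin(pmax(frac, 0), 1)

  agg_states <- NULL
  agg_cum_rec <- NULL
  for (i in seq_len(nrow(composition))) {
    w <- composition$weight[i]
    if (w <= 0) next
    sg <- as.list(composition[i, c("age_band", "lymph_nodes", "pt_stage",
                                   "sidedness", "biomarker")])
    arms <- list()
    if (frac[i] < 1)
      arms <- c(arms, list(list(wt = w * (1 - frac[i]), treated = FALSE)))
    if (frac[i] > 0)
      arms <- c(arms, list(list(wt = w * frac[i], treated = TRUE)))
    for (arm in arms) {
      tr <- run_cohort(sg, treated = arm$treated, transitions = transitions,
                       effects = effects, horizon = horizon,
                       regimen_hr = strategy$regimen_hr, ...)
      if (is.null(agg_states)) {
        agg_states <- tr$states * arm$wt
        agg_cum_rec <- tr$cum_rec * arm$wt
      } else {
        agg_states <- agg_states + tr$states * arm$wt
        agg_cum_rec <- agg_cum_rec + tr$cum_rec * arm$wt
      }
    }
  }

  agg <- list(states = agg_states, cum_rec = agg_cum_rec,
              horizon = horizon)
  class(agg) <- "cohort_trace"
  curves <- data.frame(cycle = 0:horizon,
                       1000 * agg_states,
                       cum_recurrences = 1000 * agg_cum_rec)
  res <- list(summary = summarize_trace(agg, at_months),
              curves = curves,
              fraction_treated = sum(composition$weight * frac),
              strategy = strategy,
              trace = agg)
  class(res) <- "strategy_result"
  res
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy %s: %.1f%% of cohort treated (regimen HR %.2f)>\n",
              x$strategy$name, 100 * x$fraction_treated,
              x$strategy$regimen_hr))
  print(x$summary[, c("month", "recurrences_rounded", "dcc_deaths_rounded",
                      "doc_deaths_rounded", "rfs_rounded", "os_rounded")])
  invisible(x)
}
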