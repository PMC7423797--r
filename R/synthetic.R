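## Patient-level synthetic data generator. Emulates the statistical
## structure the fitting and validation modules assume: covariate-dependent
## Gompertz / log-logistic event times, competing events, right censoring.
## Also serves as the Monte-Carlo oracle for the cohort engine: all three
## competing transitions out of diagnosis (including 90-day mortality,
## drawn as a latent event time with piecewise-constant hazard over months
## 1-3) are independent latent times, which is the patient-level law
## equivalent to the engine's cause-specific-hazard CICR correction.

#' Simulate patient-level survival records
#'
#' Per patient: draws a subgroup cell from the cohort composition, a
#' treatment indicator from the allocation strategy (if any), independent
#' latent times for 90-day mortality, other-cause death and recurrence by
#' inverse-CDF sampling (the defective recurrence Gompertz yields infinite
#' times for the cured fraction), and — if recurrence comes first — a
#' post-recurrence death time from the log-logistic model, classified as
#' other-cause vs colon-cancer death via the monthly age-band other-cause
#' probability. Right censoring is administrative plus uniform dropout.
#' Fully reproducible given `seed`.
#'
#' @param n Number of patients.
#' @param transitions A [transition_set()].
#' @param composition A [build_cohort_weights()] composition.
#' @param effects An [effect_registry()].
#' @param strategy `NULL` (no one treated), a [make_strategy()] object or a
#'   name from [strategy_names()].
#' @param censoring `NULL` for complete follow-up, or a list with
#'   `admin_months` (administrative censoring) and `dropout_max` (uniform
#'   dropout on `(0, dropout_max)`); default 60 and 120 months.
#' @param seed Integer seed (set via [set.seed()] when non-`NULL`).
#' @param return_latent If `TRUE`, return the wide per-patient latent
#'   table instead of long-format records (used as a Monte-Carlo oracle).
#' @return Long-format records: one row per transition outcome with
#'   columns `id`, `transition` (`diag_90dm`, `diag_doc`, `diag_rec`,
#'   `rec_death`), `time_months`, `event`, `cause` (for `rec_death`
#'   events: `doc` or `dcc`), the subgroup columns and `treated`.
#'   Competing events are censored cause-specifically.
#' @export
simulate_patients <- function(n, transitions = load_default_parameters(),
                              composition = build_cohort_weights(),
                              effects = effect_registry(), strategy = NULL,
                              censoring = list(admin_months = 60,
                                               dropout_max = 120),
                              seed = NULL, return_latent = FALSE) {
  stopifnot(n >= 1)
  if (!is.null(censoring)) {
    if (!(censoring$admin_months > 0) || !(censoring$dropout_max > 0))
      stop("censoring bounds must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.character(strategy)) strategy <- make_strategy(strategy)

  idx <- sample.int(nrow(composition), n, replace = TRUE,
                    prob = composition$weight)
  sg <- composition[idx, c("age_band", "lymph_nodes", "pt_stage",
                           "sidedness", "biomarker")]
  rownames(sg) <- NULL
  band <- sg$age_band

  treated <- rep(FALSE, n)
  regimen_hr <- 0.73
  if (!is.null(strategy)) {
    frac <- strategy$treated_fraction(sg)
    treated <- stats::runif(n) < frac
    regimen_hr <- strategy$regimen_hr
  }

  ## latent 90-day mortality: constant hazard over months 0-3, none after
  q90 <- p90dm_to_monthly(transitions$p90dm_by_age[band])
  h90 <- -log(1 - q90)
  t90 <- ifelse(h90 > 0, -log(stats::runif(n)) / h90, Inf)
  t90[t90 > 3] <- Inf

  t_doc <- rep(Inf, n)
  if (!is.null(transitions$diag_doc)) {
    m <- transitions$diag_doc
    t_doc <- sample_event_time("gompertz", m$shape, m$rate_or_scale,
                               lp = unname(m$coefficients[band]),
                               u = stats::runif(n))
  }

  t_rec <- rep(Inf, n)
  if (!is.null(transitions$diag_rec)) {
    m <- transitions$diag_rec
    lp <- rec_linear_predictor(m, sg)
    mult <- effects$hr_biomarker[sg$biomarker] *
      ifelse(treated, regimen_hr, 1)
    t_rec <- sample_event_time("gompertz", m$shape, m$rate_or_scale,
                               lp = lp + log(unname(mult)),
                               u = stats::runif(n))
  }

  first <- pmin(t90, t_doc, t_rec)
  type <- rep("none", n)
  type[is.finite(first) & first == t90] <- "p90"
  type[is.finite(first) & first == t_doc] <- "doc"
  type[is.finite(first) & first == t_rec] <- "rec"

  ## post-recurrence death time and cause (drawn for every patient to keep
  ## the random-number stream independent of the realized history)
  t_death_rec <- rep(Inf, n)
  cause_rec <- rep(NA_character_, n)
  if (!is.null(transitions$rec_death)) {
    m <- transitions$rec_death
    u_d <- stats::runif(n)
    u_c <- stats::runif(n)
    t_death_rec <- sample_event_time(m$family, m$shape, m$rate_or_scale,
                                     lp = unname(m$coefficients[band]),
                                     u = u_d)
    k <- pmax(1, ceiling(t_death_rec))
    lp <- unname(m$coefficients[band])
    s_prev <- model_survival_vec(m, k - 1, lp)
    s_now <- model_survival_vec(m, k, lp)
    q_death <- ifelse(s_prev <= 0, 1, 1 - s_now / s_prev)
    q_doc <- transitions$rec_doc_by_age[band]
    p_doc <- ifelse(q_death > 0, pmin(1, q_doc / q_death), 1)
    cause_rec <- ifelse(u_c < p_doc, "doc", "dcc")
  }

  cens <- if (is.null(censoring)) rep(Inf, n) else
    pmin(censoring$admin_months,
         stats::runif(n, 0, censoring$dropout_max))

  latent <- data.frame(id = seq_len(n), sg, treated = treated,
                       t90 = t90, t_doc = t_doc, t_rec = t_rec,
                       first = first, first_type = type,
                       t_death_after_rec = t_death_rec,
                       cause_after_rec = cause_rec, censor = cens,
                       stringsAsFactors = FALSE)
  if (return_latent) return(latent)
  latent_to_records(latent)
}

## cause-specifically censored long-format records from the latent table
latent_to_records <- function(latent) {
  n <- nrow(latent)
  obs <- pmin(latent$first, latent$censor)
  sgcols <- c("age_band", "lymph_nodes", "pt_stage", "sidedness",
              "biomarker")
  row_for <- function(transition, time, event, cause = NA_character_,
                      keep = rep(TRUE, n)) {
    data.frame(id = latent$id[keep], transition = transition,
               time_months = time[keep], event = as.integer(event[keep]),
               cause = if (length(cause) == 1) rep(cause, sum(keep)) else
                 cause[keep],
               latent[keep, sgcols], treated = latent$treated[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row_for("diag_90dm", pmin(obs, 3),
            latent$first_type == "p90" & latent$first <= latent$censor),
    row_for("diag_doc", obs,
            latent$first_type == "doc" & latent$first <= latent$censor),
    row_for("diag_rec", obs,
            latent$first_type == "rec" & latent$first <= latent$censor))
  rec_obs <- latent$first_type == "rec" & latent$first <= latent$censor
  if (any(rec_obs)) {
    t_left <- latent$censor - latent$first  # follow-up after recurrence
    died <- latent$t_death_after_rec <= t_left
    out <- rbind(out, row_for(
      "rec_death", pmin(latent$t_death_after_rec, t_left), died,
      cause = ifelse(died, latent$cause_after_rec, NA_character_),
      keep = rec_obs))
  }
  rownames(out) <- NULL
  out[order(out$id, out$transition), ]
}

## DIAG-REC clinical linear predictor for a data.frame of subgroup rows
rec_linear_predictor <- function(model, sg) {
  cf <- model$coefficients
  pick <- function(level) if (level %in% names(cf)) cf[[level]] else 0
  ifelse(sg$lymph_nodes == "GE10", pick("GE10"), 0) +
    ifelse(sg$pt_stage == "pT4", pick("pT4"), 0) +
    ifelse(sg$sidedness == "left", pick("left"), 0)
}

model_survival_vec <- function(model, t, lp) {
  switch(model$family,
    gompertz = gompertz_survival(t, model$shape, model$rate_or_scale, lp),
    loglogistic = loglogistic_survival_vec(t, model$shape,
                                           model$rate_or_scale, lp),
    weibull = weibull_survival(t, model$shape, model$rate_or_scale, lp),
    lognormal = lognormal_survival(t, model$shape, model$rate_or_scale,
                                   lp))
}

loglogistic_survival_vec <- function(t, shape, scale, lp) {
  1 / (1 + (t / (scale * exp(lp)))^shape)
}

#' Simulate a shifted external-validation cohort
#'
#' Simulates a cohort under multiplicatively shifted DIAG-REC regression
#' coefficients (e.g. the pT4 log hazard ratio times 1.36), to exercise the
#' recalibration workflow: refit the transition on the shifted cohort,
#' compare coefficients, recover the shift factor.
#'
#' @inheritParams simulate_patients
#' @param shift Named numeric vector of positive multipliers applied to
#'   DIAG-REC coefficients (names must exist in the coefficient map).
#' @return As [simulate_patients()].
#' @export
make_external_validation_set <- function(n,
                                         transitions =
                                           load_default_parameters(
                                             "original_2002_2008"),
                                         shift = c(pT4 = 1.36), ...) {
  if (length(shift)) {
    if (any(shift <= 0)) stop("shift multipliers must be positive")
    unknown <- setdiff(names(shift),
                       names(transitions$diag_rec$coefficients))
    if (length(unknown))
      stop("unknown coefficients in shift: ",
           paste(unknown, collapse = ", "))
    transitions$diag_rec$coefficients[names(shift)] <-
      transitions$diag_rec$coefficients[names(shift)] * shift
  }
  simulate_patients(n, transitions = transitions, ...)
}
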