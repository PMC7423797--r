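## Deterministic Markov cohort engine: monthly cycles, five clinical states
## (alive without recurrence, recurrence, 90-day mortality, death other
## causes, colon cancer death), recurrence tunnel states indexed by months
## since recurrence, and a discrete-time cumulative-incidence competing-risk
## (CICR) correction for the three competing transitions out of diagnosis.

#' Competing-risk allocation of one cycle's event mass
#'
#' Splits the mass leaving the at-risk state in one cycle among competing
#' causes from their cause-specific cumulative-hazard increments. The
#' default (`method = "exponential"`) transfers
#' `(dH_k / dH_tot) * (1 - exp(-dH_tot)) * survival_prev` to cause `k`,
#' which never exceeds the available mass; `method = "literal"` uses the
#' first-order product `dH_k * survival_prev` (the textbook
#' hazard-times-survivor form, which the exponential form reduces to for
#' small monthly hazards), available for sensitivity analysis.
#'
#' @param hazard_increments Named non-negative numeric vector of per-cause
#'   cumulative-hazard increments over the cycle.
#' @param survival_prev Probability mass still at risk at the start of the
#'   cycle, in `[0, 1]`.
#' @param method `"exponential"` (default) or `"literal"`.
#' @return Per-cause mass transferred this cycle (same names as
#'   `hazard_increments`); the sum never exceeds `survival_prev` under the
#'   exponential method.
#' @export
cicr_correct <- function(hazard_increments, survival_prev,
                         method = c("exponential", "literal")) {
  method <- match.arg(method)
  if (any(hazard_increments < 0)) stop("hazard increments must be >= 0")
  stopifnot(survival_prev >= 0, survival_prev <= 1)
  dh_tot <- sum(hazard_increments)
  if (dh_tot <= 0) return(hazard_increments * 0)
  if (method == "exponential") {
    (hazard_increments / dh_tot) * (-expm1(-dh_tot)) * survival_prev
  } else {
    hazard_increments * survival_prev
  }
}

#' Run the Markov cohort model for one subgroup arm
#'
#' Simulates a cohort of unit mass starting in the diagnosis state. Each
#' cycle, mass leaves the recurrence-free state through three competing
#' transitions combined by [cicr_correct()]: 90-day mortality (a constant
#' monthly probability during cycles 1-3, entered as the hazard increment
#' `-log(1 - q)`), other-cause death (Gompertz with age-band coefficient),
#' and recurrence (Gompertz with nodal/pT/sidedness coefficients, times the
#' biomarker hazard ratio and, if `treated`, the regimen hazard ratio).
#' Recurrence mass then moves through tunnel states indexed by months since
#' recurrence; tunnel `k` loses mass to other-cause death at the constant
#' monthly age-band probability and to colon-cancer death at the
#' post-recurrence log-logistic monthly death probability minus the
#' other-cause probability, floored at zero. Mass reaching the last tunnel
#' stays there with its hazard frozen.
#'
#' @param subgroup A [subgroup_profile()] (or a one-row slice of
#'   [subgroup_grid()]).
#' @param treated Logical: does this arm receive adjuvant chemotherapy?
#' @param transitions A [transition_set()].
#' @param effects An [effect_registry()].
#' @param horizon Number of monthly cycles (default 600, i.e. 50 years,
#'   effectively lifelong).
#' @param regimen_hr Hazard ratio of the adjuvant regimen on DIAG-REC
#'   (default 0.73, FOLFOX vs no adjuvant treatment).
#' @param treatment_model `"hazard"` (default): the regimen hazard ratio
#'   multiplies the DIAG-REC hazard level (proportional hazards);
#'   `"shape"`: it multiplies the Gompertz shape parameter instead
#'   (alternative reading, kept for sensitivity analysis).
#' @param cicr_method Passed to [cicr_correct()].
#' @param early_stop Stop cycling once alive (non-absorbed) mass falls
#'   below this threshold (default `1e-9`); remaining cycles keep the last
#'   state.
#' @return An object of class `cohort_trace`: a list with `states` (a
#'   `(horizon + 1) x 5` matrix with columns `alive_no_rec`, `rec`,
#'   `dead_90dm`, `dead_doc`, `dead_dcc`), `cum_rec` (cumulative
#'   recurrence entries per cycle), `tunnel` (final tunnel occupancy),
#'   `subgroup` and `treated`.
#' @export
run_cohort <- function(subgroup, treated = FALSE,
                       transitions = load_default_parameters(),
                       effects = effect_registry(), horizon = 600,
                       regimen_hr = 0.73,
                       treatment_model = c("hazard", "shape"),
                       cicr_method = c("exponential", "literal"),
                       early_stop = 1e-9) {
  treatment_model <- match.arg(treatment_model)
  cicr_method <- match.arg(cicr_method)
  stopifnot(horizon >= 1)
  if (is.data.frame(subgroup)) subgroup <- as.list(subgroup[1, ])
  validate_subgroup(subgroup)
  band <- subgroup$age_band
  t_grid <- 0:horizon

  ## cycle hazard increments out of the recurrence-free state
  dh90 <- numeric(horizon)
  q90 <- p90dm_to_monthly(transitions$p90dm_by_age[[band]])
  dh90[seq_len(min(3, horizon))] <- -log(1 - q90)

  dh_doc <- numeric(horizon)
  if (!is.null(transitions$diag_doc)) {
    m <- transitions$diag_doc
    H <- gompertz_cumhaz(t_grid, m$shape, m$rate_or_scale,
                         model_lp(m, subgroup))
    dh_doc <- diff(H)
  }

  dh_rec <- numeric(horizon)
  if (!is.null(transitions$diag_rec)) {
    m <- transitions$diag_rec
    mult <- effective_rec_hazard_multiplier(subgroup, treated, effects,
                                            regimen_hr)
    shape <- m$shape
    if (treatment_model == "shape" && treated) {
      shape <- m$shape * regimen_hr
      mult <- mult / regimen_hr  # regimen acts on the shape, not the level
    }
    H <- gompertz_cumhaz(t_grid, shape, m$rate_or_scale,
                         model_lp(m, subgroup))
    dh_rec <- diff(H) * mult
  }

  ## post-recurrence monthly probabilities by months-since-recurrence k
  q_doc <- transitions$rec_doc_by_age[[band]]
  q_death <- numeric(horizon)
  if (!is.null(transitions$rec_death)) {
    m <- transitions$rec_death
    s <- model_survival(m, t_grid, model_lp(m, subgroup))
    q_death <- ifelse(s[-length(s)] <= 0, 1, 1 - s[-1] / s[-length(s)])
  }
  q_dcc <- pmax(0, q_death - q_doc)
  q_doc_k <- pmin(q_doc, 1)  # constant in k

  states <- matrix(0, nrow = horizon + 1, ncol = 5,
                   dimnames = list(NULL, c("alive_no_rec", "rec",
                                           "dead_90dm", "dead_doc",
                                           "dead_dcc")))
  states[1, "alive_no_rec"] <- 1
  cum_rec <- numeric(horizon + 1)
  tunnel <- numeric(horizon)  # tunnel[k]: mass k months after recurrence
  alive <- 1
  d90 <- doc <- dcc <- 0

  for (t in seq_len(horizon)) {
    moved <- cicr_correct(c(p90 = dh90[t], doc = dh_doc[t],
                            rec = dh_rec[t]),
                          alive, method = cicr_method)
    alive <- alive - sum(moved)
    d90 <- d90 + moved[["p90"]]
    doc <- doc + moved[["doc"]]

    ## tunnel transitions for mass already in recurrence
    doc_loss <- tunnel * q_doc_k
    dcc_loss <- tunnel * q_dcc
    doc <- doc + sum(doc_loss)
    dcc <- dcc + sum(dcc_loss)
    remaining <- tunnel - doc_loss - dcc_loss
    tunnel <- c(0, remaining[-length(remaining)])
    tunnel[length(tunnel)] <- tunnel[length(tunnel)] +
      remaining[length(remaining)]  # frozen final tunnel
    tunnel[1] <- moved[["rec"]]
    cum_rec[t + 1] <- cum_rec[t] + moved[["rec"]]

    states[t + 1, ] <- c(alive, sum(tunnel), d90, doc, dcc)
    if (alive + sum(tunnel) < early_stop && t < horizon) {
      idx <- (t + 2):(horizon + 1)
      states[idx, ] <- rep(states[t + 1, ], each = length(idx))
      cum_rec[idx] <- cum_rec[t + 1]
      break
    }
  }

  out <- list(states = states, cum_rec = cum_rec, tunnel = tunnel,
              subgroup = subgroup, treated = treated, horizon = horizon)
  class(out) <- "cohort_trace"
  out
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort trace: %d cycles, %s, %s>\n", x$horizon,
              paste(unlist(x$subgroup), collapse = "/"),
              if (x$treated) "treated" else "untreated"))
  print(utils::tail(summarize_trace(x, c(12, 36, min(60, x$horizon))), 3))
  invisible(x)
}

#' Summarize a cohort trace at selected months
#'
#' Reports, per 1,000 patients: cumulative recurrences, colon-cancer
#' deaths, other-cause deaths, 90-day deaths, recurrence-free survival
#' (alive without recurrence) and overall survival. Counts are also given
#' rounded half-up to integers as in report tables; the unrounded values
#' are retained.
#'
#' @param trace A `cohort_trace` from [run_cohort()], or an aggregated
#'   trace from [evaluate_strategy()].
#' @param at_months Integer vector of months, each `<=` the trace horizon.
#' @return A data.frame with one row per requested month.
#' @export
summarize_trace <- function(trace, at_months = c(12, 36, 60)) {
  stopifnot(all(at_months >= 0), all(at_months <= trace$horizon))
  i <- at_months + 1
  s <- trace$states
  per1000 <- function(x) 1000 * x
  out <- data.frame(
    month = at_months,
    recurrences = per1000(trace$cum_rec[i]),
    dcc_deaths = per1000(s[i, "dead_dcc"]),
    doc_deaths = per1000(s[i, "dead_doc"]),
    deaths_90dm = per1000(s[i, "dead_90dm"]),
    rfs = per1000(s[i, "alive_no_rec"]),
    os = per1000(s[i, "alive_no_rec"] + s[i, "rec"]))
  for (col in c("recurrences", "dcc_deaths", "doc_deaths", "deaths_90dm",
                "rfs", "os"))
    out[[paste0(col, "_rounded")]] <- round_half_up(out[[col]])
  rownames(out) <- NULL
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Export a cohort trace as a tidy table
#'
#' @param trace A `cohort_trace`.
#' @return A long data.frame with columns `cycle`, `state`, `mass`.
#' @export
trace_to_long <- function(trace) {
  s <- trace$states
  data.frame(cycle = rep(0:trace$horizon, times = ncol(s)),
             state = rep(colnames(s), each = nrow(s)),
             mass = as.vector(s))
}
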