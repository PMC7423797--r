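## Independent oracles used across tests.

## Harrell's concordance by brute-force pair enumeration (O(n^2)).
harrell_c_bruteforce <- function(time, event, risk) {
  conc <- disc <- tied <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || event[i] != 1 || time[i] >= time[j]) next
      d <- risk[i] - risk[j]
      if (d > 0) conc <- conc + 1
      else if (d < 0) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / (conc + disc + tied)
}

## Cumulative hazard by adaptive numerical integration of a hazard function.
numeric_cumhaz <- function(hazard_fn, t) {
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    stats::integrate(hazard_fn, 0, tt, rel.tol = 1e-10)$value
  }, 0)
}

## Right-censored survival records from a sampling function; lp may be a
## per-subject vector. Used for fitting-recovery tests.
make_records <- function(n, family, shape, scale, lp = 0, censor_max = 120,
                         seed = 1, covariates = NULL) {
  set.seed(seed)
  lp <- rep(lp, length.out = n)
  t <- sample_event_time(family, shape, scale, lp, u = runif(n))
  cens <- runif(n, 0, censor_max)
  out <- data.frame(time_months = pmin(t, cens),
                    event = as.integer(t <= cens))
  if (!is.null(covariates)) out <- cbind(out, covariates)
  out[is.finite(out$time_months), , drop = FALSE]
}

## Discrete-month state occupancies from a latent patient table, using the
## engine's bookkeeping convention (events land in the cycle containing
## their continuous time; post-recurrence death months count from the
## recurrence month).
occupancy_from_latent <- function(lat, month) {
  m_first <- ceiling(lat$first)
  rec_m <- ifelse(lat$first_type == "rec", m_first, Inf)
  death_m <- rec_m + pmax(1, ceiling(lat$t_death_after_rec))
  c(alive_no_rec = mean(m_first > month),
    rec = mean(rec_m <= month & death_m > month),
    dead_90dm = mean(lat$first_type == "p90" & m_first <= month),
    dead_doc = mean((lat$first_type == "doc" & m_first <= month) |
                      (rec_m <= month & death_m <= month &
                         lat$cause_after_rec == "doc")),
    dead_dcc = mean(rec_m <= month & death_m <= month &
                      lat$cause_after_rec == "dcc"))
}

## Effect registry with all biomarker hazard ratios neutralized.
unit_effects <- function() {
  e <- effect_registry()
  e$hr_biomarker[] <- 1
  e
}

## A transition set with only the DIAG-REC transition active.
single_risk_transitions <- function(shape = -0.016, rate = 0.004) {
  zero <- stats::setNames(rep(0, 9), age_bands())
  transition_set(p90dm_by_age = zero,
                 diag_doc = NULL,
                 diag_rec = parametric_survival_model("gompertz", shape,
                                                      rate),
                 rec_death = NULL,
                 rec_doc_by_age = zero)
}
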