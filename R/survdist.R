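## Parametric survival mathematics for the four candidate families used in
## health-economic transition modeling: Gompertz, Weibull, log-normal and
## log-logistic. Pure math layer, no I/O.
##
## Conventions:
##  * Gompertz: hazard h(t) = rate * exp(lp) * exp(shape * t). Covariates act
##    proportionally on the hazard (lp = log hazard ratio). shape < 0 gives a
##    defective distribution with cure fraction exp(-rate*e^lp/|shape|).
##  * Log-logistic: S(t) = 1 / (1 + (t / (scale * exp(lp)))^shape). Covariates
##    act on the scale (accelerated failure time, lp = log time ratio).
##  * Weibull (AFT): S(t) = exp(-(t / (scale * exp(lp)))^shape).
##  * Log-normal: S(t) = 1 - pnorm((log t - (log scale + lp)) / shape).
## Time is measured in months throughout.

#' Gompertz hazard
#'
#' @param t Time in months (vectorized, `t >= 0`).
#' @param shape Per-month log-hazard slope; may be negative (decreasing
#'   hazard, defective distribution).
#' @param rate Baseline hazard per month at `t = 0`; must be positive.
#' @param lp Linear predictor on the log-hazard-ratio scale (default 0).
#' @return Hazard per month, `rate * exp(lp) * exp(shape * t)`.
#' @export
gompertz_hazard <- function(t, shape, rate, lp = 0) {
  check_rate(rate)
  stopifnot(all(t >= 0))
  rate * exp(lp) * exp(shape * t)
}

#' Gompertz cumulative hazard
#'
#' Closed form `(rate * e^lp / shape) * (e^(shape t) - 1)`, continuous in
#' `shape` at 0 where it reduces to the exponential `rate * e^lp * t`.
#'
#' @inheritParams gompertz_hazard
#' @return Cumulative hazard at `t`.
#' @export
gompertz_cumhaz <- function(t, shape, rate, lp = 0) {
  check_rate(rate)
  stopifnot(all(t >= 0))
  r <- rate * exp(lp)
  if (abs(shape) < 1e-12) return(r * t)
  (r / shape) * expm1(shape * t)
}

#' @rdname gompertz_cumhaz
#' @export
gompertz_survival <- function(t, shape, rate, lp = 0) {
  exp(-gompertz_cumhaz(t, shape, rate, lp))
}

#' Log-logistic survival function
#'
#' `S(t) = 1 / (1 + (t / (scale * e^lp))^shape)`; the effective scale
#' `scale * e^lp` is the median survival time.
#'
#' @param t Time in months, `t >= 0`.
#' @param shape Unitless shape parameter, `> 0`.
#' @param scale Scale parameter in months, `> 0`.
#' @param lp Linear predictor on the log-time-ratio scale (default 0).
#' @return Survival probability in `[0, 1]`.
#' @export
loglogistic_survival <- function(t, shape, scale, lp = 0) {
  stopifnot(shape > 0, scale > 0)
  if (any(t < 0)) stop("t must be non-negative")
  1 / (1 + (t / (scale * exp(lp)))^shape)
}

#' @rdname loglogistic_survival
#' @export
loglogistic_hazard <- function(t, shape, scale, lp = 0) {
  stopifnot(shape > 0, scale > 0)
  a <- scale * exp(lp)
  (shape / a) * (t / a)^(shape - 1) / (1 + (t / a)^shape)
}

#' Weibull (accelerated failure time) survival function
#'
#' @inheritParams loglogistic_survival
#' @return Survival probability.
#' @export
weibull_survival <- function(t, shape, scale, lp = 0) {
  stopifnot(shape > 0, scale > 0)
  exp(-(t / (scale * exp(lp)))^shape)
}

#' Log-normal survival function
#'
#' Parameterized by `scale = exp(meanlog)` and `shape = sdlog`, so the
#' linear predictor acts multiplicatively on the time scale as in the other
#' accelerated-failure-time families.
#'
#' @inheritParams loglogistic_survival
#' @return Survival probability.
#' @export
lognormal_survival <- function(t, shape, scale, lp = 0) {
  stopifnot(shape > 0, scale > 0)
  stats::pnorm((log(pmax(t, 0)) - (log(scale) + lp)) / shape,
               lower.tail = FALSE)
}

#' Monthly transition probability from a survival function
#'
#' Converts a survival curve to the per-cycle conditional event probability
#' `q(t) = 1 - S(t) / S(t - 1)` over the half-open month `(t-1, t]`. When
#' `S(t - 1) = 0` the state is treated as absorbed and `q = 1` by
#' convention.
#'
#' @param survival_at A function of time returning `S(t)`, with `S(0) = 1`
#'   and non-increasing.
#' @param t Cycle index (vectorized, `t >= 1`).
#' @return Conditional event probability per cycle.
#' @export
monthly_event_probability <- function(survival_at, t) {
  stopifnot(all(t >= 1))
  s_prev <- survival_at(t - 1)
  s_now <- survival_at(t)
  q <- ifelse(s_prev <= 0, 1, 1 - s_now / s_prev)
  pmin(pmax(q, 0), 1)
}

#' Inverse-CDF event-time sampling
#'
#' Returns the time `t` solving `S(t) = u`. For a defective Gompertz
#' (negative shape) the cumulative hazard is bounded by
#' `rate * e^lp / |shape|`; draws beyond the achievable event mass return
#' `Inf` (the cure fraction).
#'
#' @param family One of `"gompertz"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`.
#' @param shape,rate_or_scale Family parameters (Gompertz: shape and
#'   baseline rate; AFT families: shape and scale).
#' @param lp Linear predictor (log hazard ratio for Gompertz, log time
#'   ratio otherwise); vectorized.
#' @param u Uniform(0,1) draws (vectorized, strictly inside (0,1)).
#' @return Event times in months (possibly `Inf` for defective Gompertz).
#' @export
sample_event_time <- function(family, shape, rate_or_scale, lp = 0, u) {
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0, 1)")
  family <- match.arg(family,
                      c("gompertz", "weibull", "lognormal", "loglogistic"))
  h <- -log(u)  # target cumulative hazard
  switch(family,
    gompertz = {
      check_rate(rate_or_scale)
      r <- rate_or_scale * exp(lp)
      if (abs(shape) < 1e-12) {
        h / r
      } else {
        arg <- 1 + shape * h / r
        t <- ifelse(arg > 0, log(pmax(arg, .Machine$double.xmin)) / shape,
                    Inf)
        t
      }
    },
    weibull = {
      stopifnot(shape > 0, all(rate_or_scale > 0))
      rate_or_scale * exp(lp) * h^(1 / shape)
    },
    lognormal = {
      stopifnot(shape > 0, all(rate_or_scale > 0))
      exp(stats::qnorm(1 - u) * shape + log(rate_or_scale) + lp)
    },
    loglogistic = {
      stopifnot(shape > 0, all(rate_or_scale > 0))
      rate_or_scale * exp(lp) * ((1 - u) / u)^(1 / shape)
    })
}

check_rate <- function(rate) {
  if (any(rate <= 0)) stop("Gompertz rate must be positive")
  invisible(rate)
}
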