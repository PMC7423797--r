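## Discrimination and calibration metrics for censored survival
## predictions: Uno's inverse-probability-of-censoring-weighted concordance
## and the Greenwood-D'Agostino-Nam (GND) calibration chi-square over
## predicted-risk groups at a landmark time.

#' Uno's censoring-adjusted concordance statistic
#'
#' Inverse-probability-of-censoring-weighted concordance over pairs with
#' the earlier time an observed event before the truncation time `tau`.
#' Computed via [survival::concordance()] with `timewt = "n/G2"` (the Uno
#' weighting, with the censoring distribution estimated by reverse
#' Kaplan-Meier) and `ymax = tau`. The statistic is invariant under any
#' strictly monotone transform of the predicted risks.
#'
#' @param time,event Follow-up time in months and event indicator
#'   (1 = event, 0 = censored).
#' @param risk Predicted risk (higher = earlier expected event); any
#'   monotone risk score works, e.g. a model's predicted event probability
#'   by the landmark time.
#' @param tau Truncation time in months.
#' @return A list with `c`, `se`, `ci` (95% normal interval) and
#'   `n_pairs` (comparable pairs).
#' @export
uno_c <- function(time, event, risk, tau = 36) {
  stopifnot(length(time) == length(event), length(time) == length(risk),
            all(event %in% c(0, 1)), tau > 0)
  fit <- survival::concordance(survival::Surv(time, event) ~ risk,
                               reverse = TRUE, timewt = "n/G2",
                               ymax = tau)
  n_pairs <- sum(fit$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0)
    stop("no comparable pairs before tau")
  se <- sqrt(fit$var)
  list(c = as.numeric(fit$concordance), se = se,
       ci = as.numeric(fit$concordance) + c(-1, 1) * 1.96 * se,
       n_pairs = n_pairs)
}

#' Greenwood-D'Agostino-Nam calibration test
#'
#' Groups subjects by quantiles of predicted risk (deciles by default,
#' ties assigned to the lower group), compares the Kaplan-Meier observed
#' event risk at the landmark time `tau` with the mean predicted risk in
#' each group, and forms the chi-square statistic
#' `sum((obs - exp)^2 / var)` with the Greenwood variance of the
#' Kaplan-Meier estimate. The reference distribution uses one degree of
#' freedom per (post-merge) group: with externally fixed predictions the
#' per-group deviations are independent, so the statistic is chi-square on
#' `g` degrees of freedom, not the `g - 1` of the
#' development-data Hosmer-Lemeshow convention. The chi-square reference
#' is asymptotic in the group size; groups should be large enough to carry
#' at least a handful of expected events each. Groups with no observed
#' events before `tau` are merged with their neighbor (with a message).
#'
#' @inheritParams uno_c
#' @param risk Model-predicted event probability by `tau`, in `[0, 1]`.
#' @param n_groups Number of risk groups (default 10).
#' @return A list with `statistic`, `df`, `p_value` and `table` (the
#'   per-group calibration table: group, n, events, observed KM risk, mean
#'   predicted risk, Greenwood variance, chi-square contribution).
#' @export
gnd_test <- function(time, event, risk, tau = 36, n_groups = 10) {
  stopifnot(length(time) == length(event), length(time) == length(risk),
            all(event %in% c(0, 1)), all(risk >= 0 & risk <= 1))
  if (n_groups < 2)
    stop("need at least 2 risk groups for a calibration comparison")
  qs <- stats::quantile(risk, probs = seq(0, 1, length.out = n_groups + 1),
                        type = 7)
  breaks <- unique(qs)
  if (length(breaks) < 3)
    stop("predicted risks are too tied to form groups")
  grp <- cut(risk, breaks = breaks, include.lowest = TRUE, labels = FALSE,
             right = TRUE)

  groups <- sort(unique(grp))
  ev_before_tau <- function(g) sum(event[grp %in% g & time <= tau])
  ## merge event-free groups into their lower neighbor
  membership <- as.list(groups)
  i <- 1
  while (i <= length(membership)) {
    if (ev_before_tau(membership[[i]]) == 0 && length(membership) > 1) {
      j <- if (i == 1) 2 else i - 1
      message("merging risk group with zero events into neighbor")
      membership[[j]] <- c(membership[[j]], membership[[i]])
      membership[[i]] <- NULL
    } else i <- i + 1
  }
  if (length(membership) < 2)
    stop("fewer than 2 groups remain after merging; cannot test")

  rows <- lapply(seq_along(membership), function(k) {
    sel <- grp %in% membership[[k]]
    sf <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    sm <- summary(sf, times = tau, extend = TRUE)
    obs <- 1 - sm$surv
    v <- sm$std.err^2  # Greenwood variance of S(tau), same for 1 - S
    data.frame(group = k, n = sum(sel),
               events = sum(event[sel] & time[sel] <= tau),
               observed_km = obs, predicted_mean = mean(risk[sel]),
               variance = v,
               contribution = (obs - mean(risk[sel]))^2 / v)
  })
  tab <- do.call(rbind, rows)
  stat <- sum(tab$contribution)
  df <- nrow(tab)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab)
}

#' Write a per-group calibration table
#'
#' @param gnd A result of [gnd_test()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_calibration_table <- function(gnd, path) {
  utils::write.csv(gnd$table, path, row.names = FALSE)
  invisible(path)
}
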