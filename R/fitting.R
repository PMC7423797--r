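## Model-development workflow: censored maximum-likelihood fitting of the
## four candidate families with covariates (via flexsurv), AIC-based family
## selection, and forward covariate selection with Wald tests at the
## AIC-equivalent threshold p < 0.157 (|z| ~ sqrt(2)).

FLEXSURV_DIST <- c(gompertz = "gompertz", weibull = "weibull",
                   loglogistic = "llogis", lognormal = "lnorm")

#' Fit a parametric survival model to right-censored records
#'
#' Maximum-likelihood fitting of one candidate family with covariates,
#' delegated to [flexsurv::flexsurvreg()]. Covariates act on the location
#' parameter: multiplicatively on the Gompertz rate (proportional hazards)
#' and on the scale of the accelerated-failure-time families. Records with
#' a missing value in any requested covariate are excluded (complete-case
#' analysis).
#'
#' @param records A data.frame with columns `time_months` (> 0), `event`
#'   (1 = event, 0 = censored) and any covariate columns.
#' @param family One of `"gompertz"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`.
#' @param covariates Character vector of covariate column names (treated as
#'   factors with their first observed level, or their existing factor
#'   reference level, as reference).
#' @return An object of class `fit_result`: list with `model` (a
#'   [parametric_survival_model()]), `loglik`, `aic`, `n`, `n_events`,
#'   `standard_errors` (on the estimation scale: log rate/scale/shape for
#'   positive parameters), `wald_p` (two-sided, per coefficient) and the
#'   underlying `flexsurv` fit as `fit`.
#' @export
fit_parametric <- function(records, family = "gompertz",
                           covariates = character()) {
  family <- match.arg(family, names(FLEXSURV_DIST))
  records <- check_records(records, covariates)
  if (sum(records$event) < 2)
    stop("need at least 2 events to fit a survival model")
  if (length(unique(records$time_months[records$event == 1])) < 2)
    stop("need at least 2 distinct event times")

  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    if (length(covariates)) paste(covariates, collapse = " + ") else "1"))
  dist <- FLEXSURV_DIST[[family]]
  fit <- tryCatch(
    flexsurv::flexsurvreg(fml, data = records, dist = dist),
    error = function(e) stop("fit failed for family '", family, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(fit$opt$convergence) || fit$opt$convergence != 0)
    stop("optimizer did not converge for family '", family, "'")

  res <- fit$res.t  # estimation scale (log for positive parameters)
  base_pars <- rownames(res) %in% fit$dlist$pars
  coefs <- res[!base_pars, , drop = FALSE]
  pars <- fit$res[rownames(fit$res) %in% fit$dlist$pars, "est"]
  shape <- switch(family,
                  gompertz = pars[["shape"]],
                  weibull = pars[["shape"]],
                  loglogistic = pars[["shape"]],
                  lognormal = pars[["sdlog"]])
  loc <- switch(family,
                gompertz = pars[["rate"]],
                weibull = pars[["scale"]],
                loglogistic = pars[["scale"]],
                lognormal = exp(pars[["meanlog"]]))
  coef_vec <- stats::setNames(coefs[, "est"], clean_coef_names(
    rownames(coefs), covariates, records))

  wald_p <- if (nrow(coefs))
    stats::setNames(2 * stats::pnorm(-abs(coefs[, "est"] / coefs[, "se"])),
                    names(coef_vec))
  else stats::setNames(numeric(0), character(0))

  out <- list(model = parametric_survival_model(family, shape, loc,
                                                coef_vec),
              loglik = fit$loglik, aic = fit$AIC, n = nrow(records),
              n_events = sum(records$event),
              standard_errors = stats::setNames(res[, "se"], rownames(res)),
              wald_p = wald_p, fit = fit, covariates = covariates)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<%s fit: n = %d (%d events), loglik = %.2f, AIC = %.2f>\n",
              x$model$family, x$n, x$n_events, x$loglik, x$aic))
  print(x$model)
  invisible(x)
}

check_records <- function(records, covariates = character()) {
  stopifnot(is.data.frame(records))
  need <- c("time_months", "event", covariates)
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  if (any(records$time_months <= 0, na.rm = TRUE))
    stop("time_months must be positive")
  if (!all(records$event %in% c(0, 1)))
    stop("event must be 0 or 1")
  if (length(covariates)) {
    cc <- stats::complete.cases(records[, covariates, drop = FALSE])
    records <- records[cc, , drop = FALSE]
  }
  ## canonical reference levels for the model's own covariates; other
  ## covariates keep R's default (alphabetical) factor coding
  canonical <- list(age_band = age_bands(),
                    lymph_nodes = lymph_node_levels(),
                    pt_stage = pt_stage_levels(),
                    sidedness = sidedness_levels(),
                    biomarker = biomarker_levels())
  for (col in intersect(names(canonical), covariates))
    records[[col]] <- droplevels(factor(records[[col]],
                                        levels = canonical[[col]]))
  records
}

## strip the covariate-name prefix from factor coefficient labels, e.g.
## "pt_stagepT4" -> "pT4", so coefficients are keyed by level
clean_coef_names <- function(nms, covariates, records) {
  for (cv in covariates) {
    lev <- unique(as.character(records[[cv]]))
    hit <- startsWith(nms, cv) & nms != cv
    nms[hit] <- sub(paste0("^", cv), "", nms[hit])
  }
  nms
}

#' Select a distribution family by AIC
#'
#' Fits each candidate family and returns the one with the lowest AIC (ties
#' broken by listed order). The per-family AIC table is returned alongside
#' to support the visual-inspection step of model development, which is a
#' human judgment and not automated here. Families that fail to fit are
#' excluded with a warning.
#'
#' @inheritParams fit_parametric
#' @param families Character vector of at least two candidate families.
#' @return A list with `family` (the selected name), `aic_table` (a
#'   data.frame of family, loglik, aic ordered as listed) and `fits` (the
#'   successful [fit_parametric()] results, named by family).
#' @export
select_family <- function(records, families = c("gompertz", "weibull",
                                                "lognormal", "loglogistic"),
                          covariates = character()) {
  stopifnot(length(families) >= 2)
  fits <- list()
  for (f in families) {
    fit <- tryCatch(fit_parametric(records, f, covariates),
                    error = function(e) {
                      warning("family '", f, "' excluded: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (!is.null(fit)) fits[[f]] <- fit
  }
  if (!length(fits)) stop("no family could be fitted")
  aic <- vapply(fits, `[[`, 0, "aic")
  tab <- data.frame(family = names(fits),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    aic = aic, row.names = NULL)
  list(family = names(fits)[which.min(aic)], aic_table = tab, fits = fits)
}

#' Two-sided Wald test
#'
#' `p = 2 * pnorm(-|estimate / se|)`. The covariate-selection threshold
#' p < 0.157 corresponds to `|z| ~ sqrt(2)`, the AIC-equivalent inclusion
#' rule.
#'
#' @param estimate Point estimate.
#' @param se Standard error, `> 0`.
#' @return Two-sided p-value.
#' @export
wald_test <- function(estimate, se) {
  if (any(se <= 0)) stop("standard error must be positive")
  2 * stats::pnorm(-abs(estimate / se))
}

#' Forward covariate selection with Wald tests
#'
#' Starting from the intercept-only model, repeatedly refits the model with
#' each remaining candidate added, computes the candidate's Wald p-value
#' (a joint chi-square Wald test across its coefficients for multi-level
#' factors), adds the candidate with the smallest p-value if it falls below
#' `alpha`, and stops otherwise. All parameters are refitted at each step.
#' Deterministic given the data.
#'
#' @inheritParams fit_parametric
#' @param candidate_covariates Character vector of candidate covariate
#'   columns.
#' @param alpha Inclusion threshold on the two-sided Wald p-value (default
#'   0.157).
#' @return A list with `selected` (covariates in inclusion order), `steps`
#'   (a data.frame logging each evaluation) and `fit` (the final
#'   [fit_parametric()] result, or `NULL` if nothing was selected).
#' @export
forward_select <- function(records, family = "gompertz",
                           candidate_covariates = character(),
                           alpha = 0.157) {
  selected <- character()
  steps <- data.frame(step = integer(), candidate = character(),
                      p = numeric(), included = logical())
  final_fit <- NULL
  remaining <- candidate_covariates
  step <- 0
  while (length(remaining)) {
    step <- step + 1
    ps <- vapply(remaining, function(cv) {
      fit <- tryCatch(fit_parametric(records, family, c(selected, cv)),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      covariate_wald_p(fit, cv, records)
    }, 0)
    if (all(is.na(ps))) break
    best <- which.min(ps)
    include <- ps[best] < alpha
    steps <- rbind(steps, data.frame(step = step,
                                     candidate = remaining[best],
                                     p = ps[best], included = include))
    if (!include) break
    selected <- c(selected, remaining[best])
    final_fit <- fit_parametric(records, family, selected)
    remaining <- remaining[-best]
  }
  list(selected = selected, steps = steps, fit = final_fit)
}

## Wald p-value for one covariate in a fit_result: single-coefficient
## normal test, or joint chi-square test for multi-level factors.
covariate_wald_p <- function(fit_result, covariate, records) {
  fs <- fit_result$fit
  idx <- which(startsWith(rownames(fs$res.t), covariate) &
                 !(rownames(fs$res.t) %in% fs$dlist$pars))
  if (!length(idx)) return(NA_real_)
  est <- fs$res.t[idx, "est"]
  if (length(idx) == 1)
    return(wald_test(est, fs$res.t[idx, "se"]))
  v <- fs$cov[idx, idx, drop = FALSE]
  stat <- drop(t(est) %*% solve(v, est))
  stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
}
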