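---
title: "A Markov cohort model of adjuvant chemotherapy in stage II colon cancer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov cohort model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coloncohort)
```

This vignette documents the model implemented by `coloncohort`: its
structure and assumptions, the parameters that matter and their defaults,
the numerical choices, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the design was
genuinely open.

## Model structure and assumptions

The model is a deterministic Markov cohort simulation with a one-month
cycle and five clinical states: diagnosis (alive, recurrence-free after
surgical resection), 90-day mortality, recurrence, death from other
causes (DOC) and death from colon cancer (DCC). Key structural
assumptions:

* **Colon-cancer death only follows recurrence.** There is no direct
  diagnosis-to-DCC transition; if recurrences are under-ascertained in
  registry data the model correspondingly understates disease-specific
  mortality.
* **Three competing exits from diagnosis.** 90-day mortality, other-cause
  death and recurrence compete; their cause-specific hazards are combined
  each cycle with the cumulative-incidence competing-risk (CICR)
  correction (below).
* **Tunnel states carry post-recurrence time-dependence.** A Markov
  chain is memoryless, so time since recurrence is encoded by a sequence
  of tunnel sub-states, one per month since recurrence. Post-recurrence
  death follows a log-logistic model in months since recurrence; its DOC
  component is a constant monthly age-band probability (assumed equal to
  the other-cause mortality of recurrence-free patients, because the
  source data record only overall survival after recurrence), and the DCC
  component is the remainder, floored at zero.
* **Age is frozen at the baseline band.** Subgroup hazards use the age
  band at diagnosis throughout; patients surviving past the oldest band
  keep the 90–95 coefficients. This mirrors how the transition models
  were estimated (age at diagnosis as a covariate) and avoids
  extrapolating age effects.
* **Homogeneous treatment effect.** The regimen hazard ratio on the
  recurrence transition is the same in every subgroup; predictive
  (effect-modifying) biomarker interactions are out of scope.

## Parameterization

The packaged registry (`load_default_parameters()`) stores the published
point estimates:

| Transition | Family | Parameters |
|---|---|---|
| DIAG-90DM | — | 90-day probability per age band, 0.028–0.333 |
| DIAG-DOC | Gompertz | shape 0.010/month, calibrated baseline rate, age-band log-HRs 0–3.315 |
| DIAG-REC | Gompertz | shape −0.016/month, rate 0.004/month, log-HRs: ≥10 nodes −0.519, pT4 1.081, left-sided 0.505 |
| REC-DEATH | log-logistic | shape 1.17, scale 1,390 months, age-band log time ratios −3.439 … −6.059 |
| REC-DOC | — | monthly probability per age band, 0.000–0.006 |

Conventions worth stating:

* Gompertz covariates act **proportionally on the hazard** (they
  multiply the rate); log-logistic covariates act on the **time scale**
  (accelerated failure time, multiplying the scale). These are the
  natural parameterizations of the fitting software the estimates
  originate from, and `fit_parametric()` uses the same ones.
* The DIAG-REC shape is negative, so the recurrence distribution is
  *defective*: the cumulative hazard is bounded by
  `rate·exp(lp)/0.016`, leaving a cured fraction. For the reference
  subgroup that bound is 0.25, i.e. a lifetime recurrence risk of
  `1 − exp(−0.25) ≈ 22%` before competing mortality.
* **90-day mortality** enters as a constant monthly probability over the
  first three cycles solving `1 − (1 − q)³ = p90` — the complement rule
  rather than `p90/3` — because per-cycle probabilities compose
  multiplicatively in a Markov chain.
* **The DIAG-DOC baseline rate is calibrated, not copied.** The source
  table prints it as 0.000 (CI 0.000; 0.001) — unusable at three
  decimals. Since the model assumes post-recurrence other-cause mortality
  equals that of recurrence-free patients, the printed monthly REC-DOC
  probabilities identify the rate:
  `calibrate_doc_baseline_rate()` minimizes
  `Σ (r·exp(β_age) − p_age)²`, giving `r ≈ 2.288e-4` per month (inside
  the printed CI); this value is stored explicitly in the packaged
  registry so results do not depend on re-running the calibration. The
  printed REC-DOC column is treated as the hazard level at `t = 0`; the
  alternative reading (a column evaluated at some typical time since
  diagnosis) would only rescale `r` by a few percent.
* **Model versions.** `"original_2002_2008"` is the registry exactly as
  published; `"updated_2015"` multiplies the DIAG-REC pT4 coefficient by
  1.36 (1.081 → 1.470), the external-validation re-estimate. Strategy
  evaluation defaults to the updated version, since the strategy analyses
  postdate the update; the original is selectable everywhere.
* **Effect registry.** Biomarker hazard ratios MSI 0.247, MSSdwt 0.880,
  MSSmut 1.528 multiply the DIAG-REC hazard directly, as printed, without
  renormalizing the population-average hazard to one; with the default
  biomarker mix the population mean multiplier is ≈ 0.93, a mild downward
  shift that is accepted as part of the published parameterization.
  Treatment: fluoropyrimidine vs none 0.78, FOLFOX vs fluoropyrimidine
  0.94, product 0.73 (two decimals) — the default regimen effect.
  The treatment ratio multiplies the **hazard level**, not the Gompertz
  shape: multiplying the negative shape by 0.73 would slow the hazard's
  time-decay (raising late hazards) rather than lower its level, which
  contradicts a proportional-hazards treatment effect; the shape reading
  is nevertheless available via `treatment_model = "shape"` for
  sensitivity analysis.

## The engine's numerics

* **CICR transfer.** Cause `k` receives
  `(ΔH_k/ΔH_tot)·(1 − exp(−ΔH_tot))·S(t−1)` per cycle. This exact
  exponential form never moves more mass than is available; the literal
  hazard-times-survivor product (`cicr_method = "literal"`) agrees to
  first order for small monthly hazards and is kept for sensitivity
  analysis (in a high-risk 80–84 subgroup it overstates 5-year all-cause
  mortality by ≈ 6 per 1,000).
* **Horizon and early stop.** Default 600 cycles (50 years, effectively
  lifelong); cycling stops early when alive mass falls below `1e-9`.
  Mass is conserved to better than `1e-12` per cycle (regression-tested).
* **Tunnel cap.** Tunnels extend to the horizon; mass reaching the final
  tunnel is held there with its hazard frozen at the last value. The cap
  is an implementation choice — no published value exists.
* **Floors.** The monthly DCC probability is
  `max(0, q_death(k) − q_doc)`; the floor can bind at very old ages in
  late tunnels where the constant DOC probability exceeds the waning
  log-logistic death probability.
* **No half-cycle correction.** Reported outcomes are cumulative event
  counts, not life-years; a half-cycle option belongs to a future
  cost-effectiveness layer.
* **Reporting.** `summarize_trace()` scales to a cohort of 1,000 and
  rounds half-up for report tables while retaining unrounded values;
  cumulative recurrence is *cumulative incidence of entering the
  recurrence state*, not recurrence-state prevalence.

## Cohort composition and strategies

`build_cohort_weights()` builds the 216-cell composition as a product of
independent marginals: age bands from a Normal(70.7, 10.9) truncated to
[50, 95) (patients under 50 are outside the modeled population, so the
youngest band is 50–54), pT4 214/2221, ≥10 evaluated nodes 946/2144,
left-sided 987/2238 (registry marginals excluding unknowns — the model
has no unknown level), and biomarker fractions 28/39/36 of 103 from the
external biomarker cohort. Independence — in particular of biomarker
status from clinical factors — is an explicit assumption; the true joint
distribution is not published, so population-level absolute counts
inherit this approximation.

The four packaged strategies: **A** treats all pT4 & microsatellite-stable
patients ("MSS" includes both the double-wild-type and mutated classes);
**B** treats 21% of those and 4% of everyone else (observed adherence);
**C** treats all MSS-mutated patients regardless of pT stage; **D** treats
no one. Custom rules are a function from subgroup rows to treated
fractions.

On the default cohort the engine predicts, per 1,000 patients at five
years, 149/146/143/131 recurrences and 97/96/93/85 colon-cancer deaths
for D/B/A/C — reproducing the published strategy ordering and the ≈11%
relative mortality reduction of the biomarker strategy versus observed
adherence, while running 15–23 recurrences per 1,000 above the published
absolute counts. That offset is within the parametric uncertainty of the
registry itself: the DIAG-REC baseline rate is published to a single
significant digit (0.004, CI 0.003–0.005), and ±12.5% on that hazard
alone moves five-year recurrences by roughly ±17 per 1,000, before the
unknown joint cohort distribution is considered. The package deliberately
keeps the printed values rather than tuning any of them to match
downstream counts.

## Fitting and validation

`fit_parametric()` delegates censored maximum likelihood to
`flexsurv::flexsurvreg` (positive parameters optimized on the log scale),
returning the model in this package's parameterization plus standard
errors and per-coefficient Wald p-values; records missing a requested
covariate are dropped (complete-case). `select_family()` compares
Gompertz, Weibull, log-normal and log-logistic by AIC — all four are
implemented even though the final model uses only two, because the
development workflow tests all four — and returns the AIC table for the
accompanying visual-inspection step, which is human judgment and not
automated. `forward_select()` adds, at each step, the candidate with the
smallest Wald p-value (a joint chi-square test for multi-level factors),
refitting all parameters, until no candidate reaches `p < 0.157` — the
AIC-equivalent threshold `|z| ≈ √2`.

`uno_c()` wraps `survival::concordance(timewt = "n/G2", ymax = tau)`
(inverse-probability-of-censoring-weighted concordance); tests verify it
against a brute-force pair enumeration in the uncensored case. The
Greenwood–D'Agostino–Nam calibration test (`gnd_test()`) is implemented
here: predicted-risk deciles (empirical quantiles, ties to the lower
group, event-free groups merged), Kaplan–Meier observed risk at the
landmark (default 36 months) versus mean predicted risk, Greenwood
variance, chi-square with **one degree of freedom per group** — with
externally fixed predictions the group deviations are independent, so
`g` df is the calibrated reference (the `g − 1` convention belongs to
development-data goodness-of-fit testing, where calibration-in-the-large
is constrained by estimation). The chi-square reference is asymptotic in
group size; deciles should carry at least a handful of events each
(property tests use ~400 subjects per decile).

The published concordance and calibration values themselves are
reproducible only with the original registry records, which are not
public; the validation machinery is therefore exercised on synthetic
data.

## The synthetic-data generator

`simulate_patients()` draws, per patient: a subgroup cell; independent
latent times for 90-day mortality (piecewise-constant hazard on months
1–3), other-cause death (Gompertz) and recurrence (defective Gompertz,
with an explicit cured fraction) by inverse-CDF sampling; a log-logistic
post-recurrence death time classified as DOC vs DCC via the monthly
age-band probability; and right censoring (administrative at 60 months
plus uniform dropout on (0, 120) — loosely emulating a registry with
~4.5-year median follow-up, without claiming to reproduce it). The
independent-latent-time construction is the patient-level law equivalent
to the engine's cause-specific-hazard CICR correction, which is what
makes the generator a valid Monte-Carlo oracle for the engine (the
engine-vs-micro-simulation property test holds all five state
occupancies within three binomial standard errors at one million
patients). Two deliberate approximations: within-cycle variation of
hazard ratios is ignored by the engine's monthly discretization (second
order, cancels within cycles), and when the constant DOC probability
exceeds the log-logistic monthly death probability (very old ages, late
tunnels) the engine's total death probability exceeds the generator's
log-logistic one — the affected mass is negligible.

What the generator does **not** emulate: registry quirks such as
under-reported recurrences, missing covariates (records are complete
unless you blank them), cohort heterogeneity between biomarker sources,
or dependence between censoring and covariates. Passing tests on
synthetic data therefore demonstrate internal consistency of the
machinery, not fidelity of any refit to real registry behavior.

Problem sizes used by the property tests — chosen as the smallest giving
stable sampling distributions: parameter recovery at 20,000 patients;
noise-inclusion rate of forward selection over 1,000 replicates of 200
patients; calibration-null uniformity over 500 replicates of 4,000;
engine-vs-simulation agreement at 10⁶.

## Known limitations

* Absolute population-level counts depend on the printed single-digit
  baseline recurrence rate and the independence approximation of the
  cohort composition (see above); relative strategy contrasts are much
  more stable.
* No costs, utilities, QALYs or probabilistic sensitivity analysis;
  the engine's determinism and speed (a full 216-cell strategy evaluation
  runs in under a second) are intended to make a future probabilistic
  layer feasible.
* Treatment-effect heterogeneity, direct diagnosis-to-DCC mortality and
  age progression across bands are structurally excluded.
* The micro-simulation path exists as a test oracle, not as a primary
  engine.
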