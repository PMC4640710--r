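---
title: "Lagged versus temporal-proximity models of dynamic violence risk factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lagged versus temporal-proximity models of dynamic violence risk factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(proxrisk)
```

## The scientific problem

Structured professional judgement (SPJ) instruments such as the HCR-20^v3^
(20 risk items: 10 historical, 5 clinical, 5 risk-management) and the SAPROF
(17 protective items) are validated almost exclusively by *prediction*: items
rated in one period are tested as statistical predictors of violence in the
following period, usually summarised by the AUC. Dynamic items, however,
fluctuate: a risk state present in the past six months may have resolved by the
time the outcome window opens. A *lagged* (predictive) analysis can therefore
miss factors that genuinely drive violence while they are present. The
competing *temporal-proximity* (causal) analysis associates item ratings and
violence measured within the same six-month window, at the price of losing
strict temporal ordering.

`proxrisk` implements both designs over the same longitudinal panel — subjects
nested in NHS Trusts, rated at baseline, 6 and 12 months, with a binary
"any violence" outcome for each of the two 6-month follow-up windows — along
with the three analysis stages used to compare them:

1. **Clustered discrimination.** Per-item AUC, the rank statistic
   $P(s_\text{case} > s_\text{control}) + \tfrac12 P(\text{tie})
   = (D + 1)/2$ for Somers' $D$, with a delete-one-subject (cluster) jackknife
   standard error so the two windows contributed by a subject are never
   treated as independent. Protective items give AUC < 0.5.
2. **Multilevel association.** Random-intercept logistic regression of the
   window outcome on each item (windows within subjects, optionally within
   Trusts), adjusted for baseline age, gender, ethnicity and primary
   diagnosis, reported as adjusted odds ratios per rating point.
3. **Explanatory-variable attenuation.** Candidate explanatory factors must be
   associated (at $\alpha < 0.05$) with both the outcome — independently, in a
   joint "Model 0" multilevel fit — and the other factors (pairwise Spearman
   tests). Each base factor's model is then refit adding the explanatory
   variables singly and jointly, and the attenuation is quantified on the
   log-odds scale as
   $$100 \times \frac{\beta_\text{unadjusted} - \beta_\text{adjusted}}
   {\beta_\text{unadjusted}},$$
   with values above 100 when the adjusted odds ratio crosses 1. Only the log
   scale reproduces the published worked examples: an adjusted odds ratio of
   1.59 against a baseline of 3.56 gives
   `pct_change(log(3.56), log(1.59))` = 63.48.

Because the underlying patient data were collected without individual consent
and are not public, every stage is driven by a synthetic cohort whose
generator is itself first-class, tested code.

## The synthetic cohort generator

`generate_cohort(sim_config())` emulates the published study conditions: 409
subjects in 26 Trusts; baseline, 6- and 12-month waves with monotone
missing-at-random dropout (retention 0.95, then 0.89 of those retained,
matching the published 387/409 and 344 completions); age 37.8 (SD 9.7), 11.1%
female, 60.1/25.4/6.2/8.3% white/black/South Asian/mixed-other ethnicity,
80.9% schizophrenia-spectrum diagnoses; window violence prevalences 14.0% and
12.5%.

**Latent dynamics.** Each dynamic item carries a standard-normal latent value
evolving across waves as an AR(1) process with autocorrelation `rho`, cut at
`item_thresholds` into the ordinal 0/1/2 rating. This is the simplest
structure in which items "change and fluctuate" at a tunable speed: `rho = 0`
gives fresh states every wave, `rho` near 1 freezes them (and makes the lagged
and proximity designs coincide). The default `rho = 0.35` was chosen so that
the ratio of lagged to proximity log-odds effects roughly matches the
published contrast (e.g. violent ideation 1.58 vs 6.98); a 6-month gap
spanning discharge from secure care plausibly carries low item persistence.
Historical items are drawn once and held fixed.

**Causal wiring.** Within each side (risk: C/R items; protective: SAPROF),
items share a per-wave latent factor. The three proximal risk items (violent
ideation or intent, instability, stress or coping) and the proximal protective
item (self-control) load on it with `lambda_proximal = 0.75`; distal items
load so that the distal-proximal latent correlation is exactly
`delta_distal = 0.45` (hence distal-distal correlations of ~0.36 and
proximal-proximal of ~0.56, in the range of the published inter-item Spearman
summaries). Violence in a window depends *only* on the proximal item scores at
the wave closing that window, with per-point log-odds
`gamma_proximal = (1.2, 0.9, 1.1, -1.3)`, plus subject (SD 0.8) and Trust
(SD 0.3) random intercepts. Distal items have no direct path to the outcome,
so conditioning on the proximal scores blocks their association exactly — the
known ground truth against which the attenuation stage is validated. The
gamma defaults were set so that marginal single-item odds ratios land in the
published 2-8 (risk) and 0.2-0.6 (protective) ranges.

**Calibration.** The intercept `baseline_logit = -3.97` and second-window
offset `-0.20` were frozen once by Monte-Carlo root-finding
(`calibrate_baseline_logit()`, 200,000 subjects over 500 Trusts so that
Trust-level noise averages out) against the 14.0%/12.5% prevalence targets
under the default effects. The per-item rating thresholds (0.25, 1.30, giving
roughly 60/30/10% of ratings 0/1/2) are an arbitrary calibration: per-item
rating prevalences were never published, and nothing downstream is sensitive
to them beyond the effective effect size per rating point.

**What the generator does not emulate.** Real item ratings are clinician
judgements with rater effects and instrument-specific marginal distributions;
real violence is measured by interview plus police records with its own
misclassification; real dropout need not be missing at random; and the true
causal graph of risk states is certainly denser than
distal → proximal → violence. Passing tests therefore demonstrate that the
*statistical machinery* recovers known structure under the study's design —
not that the published point estimates are correct.

## Model fitting choices

Mixed models are estimated by `lme4::glmer`. The 2-level model (windows within
subjects) uses adaptive Gauss-Hermite quadrature, default 7 nodes; on this
design 7 nodes agree with 15 and 25 to four decimals. The 3-level model
(windows within subjects within Trusts) has two nested random intercepts, for
which `glmer` supports only the Laplace approximation; this is the documented
fallback.

The quadrature choice matters more than usual here. With at most two binary
observations per subject and ~14% prevalence, the Laplace approximation is
unreliable for the *subject-level* variance — in simulations it inflated
`var_subject` severalfold and conditional log-odds by 15-25%, with Wald
coverage dropping to ~0.85, while 7-node quadrature recovered both (coverage
~0.95). Consequences adopted throughout:

* single-estimand checks (parameter recovery, null calibration, degenerate
  limits) use the 2-level AGQ fit — the Trust variance (0.09 on the default
  configuration) is negligible and is absorbed into the subject level;
* the 3-level tables keep the published architecture but their variance
  components should be read with the Laplace caveat;
* attenuation percentages are ratios of coefficients from fits sharing the
  same approximation, so the multiplicative Laplace inflation largely cancels;
  adjusted null effects are unbiased either way.

A related numerical note: the AGQ-approximated log-likelihood is *not*
monotone in the node count — Laplace typically overstates it — so the package
treats "more nodes" as "more accurate", verified by stabilisation (7 vs 15
nodes) rather than by monotonicity. The optimizer is `nloptwrap` (BOBYQA),
which reached the same optima as the alternatives at a fraction of the cost on
the widest model fitted (17 fixed effects).

Other conventions: Wald inference throughout, matching the OR / 95% CI / P
reporting style; exposures enter as numeric 0/1/2 per rating point
(`exposure_coding = "categorical"` switches to factors — the published coding
was not stated); ethnicity is collapsed to four categories and diagnosis to
two (reference: white, schizophrenia-spectrum, male) to avoid empty cells at
n = 409; the significance level is 0.05 everywhere; AUC confidence intervals
are normal-theory on the AUC scale, truncated to [0, 1], and two intervals are
called distinct only when disjoint (touching endpoints count as overlapping).
An optional window fixed effect (`include_window = TRUE`) absorbs the secular
difference between the two follow-up windows; recovery analyses use it so the
fitted model nests the generator exactly.

## Degenerate inputs and edge behaviour

* `n_subjects = 0` yields an empty panel that still carries the full item
  catalogue; empty panels are rejected by the summary and design builders with
  explicit errors.
* AUC is undefined without at least one case and one control; with a single
  discordant subject cluster the point estimate is returned with missing
  inference and a warning. Leave-one-cluster replicates that lose the last
  case (or control) are dropped from the jackknife with a warning.
* Constant items: excluded (and listed) by the Spearman summary; reported as
  failed rows, with the remaining items still fitted, in the per-item tables.
* `pct_change` is an error when the baseline coefficient is 0; an empty
  explanatory set returns an all-zero ledger by construction.
* A base factor that is itself an explanatory variable is set aside with a
  message rather than adjusted for itself.

## Problem sizes used by the test-suite simulations

Monte-Carlo checks run at sizes chosen to make their statistical claims sharp
at desk scale: null calibration uses 1,000 replicates of a 409-subject cohort
(the study's own size; both the cluster-jackknife AUC test and the multilevel
Wald test must reject in 3-7% of replicates at the 5% level); parameter
recovery uses 50 replicates at 400 subjects (Wald coverage of the generating
log-odds pooled over the four proximal effects, and the lagged-vs-proximity
attenuation contrast); the explanatory-variable recovery uses three
1,000-subject cohorts (mean Model-4 attenuation of significant distal factors
in [80, 120] with adjusted intervals covering 1). The pipeline determinism
check compares every results table byte-for-byte across two runs from the same
configuration and seed.

## Known limitations

* No mediation estimands: temporal ordering within a window is unavailable by
  design, so the attenuation procedure identifies explanatory variables, not
  mediators.
* No random slopes, GEE alternatives, or likelihood-ratio inference; no
  windows finer than 6 months.
* The 3-level variance components inherit the Laplace caveat above.
* The generator's independence of the risk and protective sides, and of the
  historical items from everything else, is a deliberate simplification; real
  instruments correlate across scales.
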