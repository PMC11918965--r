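---
title: "Methods: sequential trial emulation for vaccination and mental-health symptoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential trial emulation for vaccination and mental-health symptoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttevax)
```

## The estimation problem

`ttevax` estimates the observational analog of the intention-to-treat (ITT)
effect of COVID-19 vaccination (receipt of at least one dose) on
moderate-to-severe symptoms of anxiety and depression, from a longitudinal
survey cohort assessed roughly quarterly. Because vaccine uptake is strongly
confounded and rolled out over calendar time, a naive comparison of
vaccinated versus unvaccinated responses is uninterpretable. The package
instead emulates a *sequence of nonrandomized trials*: each assessment wave
from December 2020 through December 2021 opens a "trial" in which every
participant who completed that wave's assessment and reported vaccination
status is assigned to an arm.

* A participant still unvaccinated at the wave contributes an *unvaccinated
  person-trial* with time zero equal to the month of assessment completion.
  They may re-enter at every later wave until vaccinated.
* A participant first reporting vaccination at the wave contributes exactly
  one *vaccinated person-trial*, with time zero the month of the first dose,
  and then exits the sequence. A participant already vaccinated at the first
  wave enters once, as a vaccinated person-trial.

The outcome of a person-trial is the GAD-7 (anxiety) or PHQ-8 (depression)
total at the earliest assessment 2 to 5 whole months after time zero
(typically 3, the assessment cadence), dichotomized at the conventional
moderate-to-severe cut of 10. Effects are estimated separately for doses
begun before versus on/after 2021-04-19, the date all US adults became
vaccine-eligible ("preuniversal" versus "universal" era); the era of an
unvaccinated person-trial is the era of its time-zero month.

The analysis model is a pooled logistic regression over the stack of
person-trials of one era,

$$\operatorname{logit} \Pr(Y_{it} = 1) = \beta_0 + \beta_1 A_{it} +
  \gamma^{\top} L_{it},$$

where $A_{it}$ is the arm of person $i$ in trial $t$ and $L_{it}$ the
covariate snapshot as of time zero. Because a participant can contribute up
to five person-trials, standard errors come from a cluster-robust (CR0)
sandwich estimator $A^{-1} B A^{-1}$ with scores summed within participant;
$\exp(\beta_1)$ is reported as the adjusted odds ratio. Heterogeneity of
$\beta_1$ across eras is tested with the Wald statistic
$W = (\hat\beta_{\text{pre}} - \hat\beta_{\text{uni}})^2 /
(\widehat{\operatorname{var}}_{\text{pre}} +
\widehat{\operatorname{var}}_{\text{uni}})$ against $\chi^2_1$.

## Key decisions and their rationale

**Time-zero and era granularity.** Assessment calendars and time zero are
handled at month resolution (months are encoded as the first of the month),
but era assignment is date-based: a vaccinated person-trial uses the exact
reported first-dose date against the cutoff; an unvaccinated person-trial,
which has only a month, uses the month's midpoint (day 15). With the default
quarterly calendar no trial month straddles the cutoff, so the midpoint rule
is inert, but it keeps behaviour defined for arbitrary calendars.

**Outcome window.** The follow-up score is taken from the earliest
assessment whose lag from time zero is 2–5 whole months. The lower bound
keeps a vaccinated participant's *reporting* assessment usable as the
outcome when the dose occurred early in the preceding inter-wave gap; the
upper bound stops a skipped wave from linking an outcome half a year away.
Earliest-match wins on ties.

**Covariate snapshots.** Baseline covariates (age band, gender,
race/ethnicity, income, education, children in household, exposure risk,
susceptibility, healthcare access) are frozen at enrollment. Time-updated
covariates (employment, food insecurity, housing instability) and the
severity-at-time-zero indicators use the most recent measure at or before
time zero, with severity additionally skipping missing measures. A
vaccinated entry whose first-dose date is missing cannot be placed in time
or era and is dropped with a warning; a participant with no assessment at or
before time zero is a data error.

**Partially answered screeners** are treated as missing totals — items are
never prorated. Missingness is handled once, at the score level, by the
imputation engine.

**Imputation model.** Missing outcome totals are imputed on the continuous
score scale (then rounded, clipped to the instrument range, and
re-dichotomized), so a single set of completed data serves both the binary
models and the linear mixed models. The default engine is type-1
predictive-mean matching: screener totals are bounded, integer-valued and
strongly bimodal around the severity threshold, and a fully parametric
normal draw (available as `method = "norm"`) has so much residual spread on
such a distribution that it systematically overstates threshold crossings —
enough to visibly attenuate the pooled log-OR at 7% missingness. Matching
instead reuses observed totals, preserving the empirical score
distribution; the donor pool includes *all* observations tied at the
matching distance, since with categorical predictors a literal nearest-five
rule would collapse to an arbitrary handful of donors. The default
predictor set is the
sociodemographic/auxiliary list (age, race/ethnicity, gender, income,
education, employment, food insecurity, housing instability, children in
household, healthcare access, plus enrollment anxiety for the GAD-7 model
and enrollment depression for the PHQ-8 model). On top of that list the
default adds treatment, era, and their interaction: an imputation model that
omits the exposure is uncongenial with the era-stratified analysis model and
biases the pooled effect toward the null. Set `include_treatment = FALSE`
for the purely auxiliary model. `m = 20` imputations by default —
comfortable for the ~7% missingness the design anticipates — with
per-imputation seeds `seed + i`.

**Rubin pooling.** Estimates are pooled on the log-OR / coefficient scale:
$\bar q = m^{-1}\sum q_i$, $T = W + (1 + 1/m)B$, with confidence intervals
from a $t$ distribution on Barnard–Rubin degrees of freedom (classic Rubin
df when the complete-data df is taken as infinite, the default). With
$m = 1$, or when no cell is missing, the single estimate passes through
unchanged; `run_full_analysis()` detects a fully observed outcome and skips
the MI loop entirely, so the no-missingness pipeline is *bitwise* identical
to the complete-data analysis rather than identical up to floating-point
rearrangement.

**Variance estimation.** CR0 (no small-sample correction) is the default,
matching the large number of participant clusters this design produces;
`cr_type = "CR1"` applies the $G/(G-1)$ factor. Point estimates never depend
on the variance choice. Quasi-separation is fatal when it involves the
treatment coefficient and a warning when confined to a sparse nuisance cell.

**Stratification rather than interaction.** Era-specific effects come from
separate fits per era rather than an era-by-treatment interaction model;
with a fully stratified adjustment this is the same estimand, and it mirrors
how the results are reported. The Wald test consumes the two stratum
estimates directly.

**Descriptive tables** (prevalences with Wald binomial intervals, crude
odds ratios with Woolf intervals) are computed from the first completed
dataset. The closed-form 2×2 odds ratio and the model-based pooled OR are
both exposed and are not interchangeable: published tables in this
literature sometimes print model-based ORs beside raw counts, and the two
need not agree.

## What the synthetic generator emulates

`simulate_cohort()` draws a cohort with the statistical structure the
analysis assumes, so that every downstream stage is testable without any
external data:

* six quarterly waves, December 2020 through March 2022 (the last wave is
  outcome-only);
* baseline covariates with marginals typical of a large online US adult
  cohort (e.g. 21% with elevated susceptibility to severe COVID-19, 58%
  college graduates);
* an absorbing first-dose process evaluated at each of the five trial
  waves, with per-wave log-odds intercepts `qlogis(c(0.10, 0.45, 0.18,
  0.08, 0.05))` concentrating uptake before the cutoff (roughly 80% of
  vaccinated person-trials fall in the preuniversal era, as in the
  motivating cohort) and covariate coefficients linking uptake to
  susceptibility and education;
* GAD-7/PHQ-8 totals generated by first drawing the moderate-to-severe
  class from the logistic outcome model — intercept solved numerically so
  the untreated marginal prevalence hits its target (defaults 0.25 anxiety,
  0.27 depression), era-specific treatment log-ORs defaulting to log(0.79)
  and log(1.23) — and then drawing an integer total uniformly within the
  class's score range. The estimand lives on the dichotomized scale; the
  within-class distribution is deliberately simple.
* outcome missingness at a 7% marginal rate, MCAR or MAR (logistic in
  observed covariates with the intercept solved to hit the marginal rate),
  applied to waves after the first. Enrollment scores stay complete because
  the design conditions on confounder-complete records and uses enrollment
  severity as an imputation predictor.

First-dose dates fall inside the wave month in which uptake occurs. This
makes the generator's treatment status for every wave's score exactly
consistent with the ITT arm the trial builder assigns — a dose occurring
mid-gap between waves, which would contaminate the unvaccinated arm's
follow-up under ITT, is not modelled by default. Real cohorts do have such
contamination (and attrition, which the generator only offers through an
optional geometric `retention` parameter, default off), so passing recovery
tests here demonstrates the estimator is correct under its own assumptions,
not that the published estimates are right. Per-wave scores are
conditionally independent given covariates and treatment; within-person
outcome correlation beyond covariates is therefore absent by default, which
is the conservative case for checking cluster-robust interval calibration
(the test suite additionally checks the sandwich against a cluster bootstrap
on data with a genuine participant random intercept).

## Verification strategy and problem sizes

The test suite validates each stage against an independent oracle: the
trial builder against a literal per-participant timeline walker on dozens
of small random cohorts; the pooled logistic against the closed-form
ln(ad/bc) on random 2×2 tables (agreement to 1e-8, which is why the IRLS
deviance tolerance is set to 1e-12); the CR0 sandwich against both a
hand-rolled score computation and a 1,000-resample cluster bootstrap (within
10%); Rubin's rules against hand-evaluated combinations; and the full
pipeline against its own generative truth — 200 replicate cohorts of 2,000
participants with 7% MAR missingness and m = 10 imputations, requiring the
mean pooled log-OR within 3 Monte-Carlo SEs of the true era-specific value
and 92–98% CI coverage, plus 500 null replicates bounding the Wald test's
size between 3% and 7%. These sizes were chosen to give each check real
statistical teeth while keeping a full run desk-scale. The published
marginal counts shipped in `inst/extdata` let the descriptive machinery be
checked exactly against printed percentages.

## Limitations

* The adjusted odds ratios of the motivating study are not reproducible
  from this package alone: they require the original cohort. The package
  reproduces every count-derived descriptive exactly and demonstrates
  estimator correctness by simulation.
* Per-protocol analyses, dose–response, censoring weights, and
  survey-weighted generalization are out of scope; the exposure is strictly
  "at least one dose".
* The imputation engine assumes confounder-complete records (it refuses
  incomplete predictors) and imputes outcomes only.
* Logistic non-collapsibility means the conditional log-OR targeted by the
  adjusted model differs in general from the marginal one; comparisons of
  crude and adjusted ORs should keep that in mind.
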