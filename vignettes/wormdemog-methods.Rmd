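---
title: "Demographic analysis of worm lifespan screens: models and methods"
author: "wormdemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic analysis of worm lifespan screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormdemog)
```

This vignette documents the statistical machinery of `wormdemog`: the
mortality model and its conventions, the estimation choices, what the
synthetic cohorts emulate (and do not), and the limitations a user should
know before trusting the output on real assay data.

## The data and the day convention

A lifespan assay scores each worm once per day by gentle prodding, so the
raw datum is a final observation day plus a status (death, or censoring for
worms lost at transfer, bagged, or still alive at the end of observation).
Day 1 is the first day of adulthood; the age interval `x` covers the
half-open interval `(x-1, x]`. A worm whose true (continuous) death time is
`t` is therefore recorded on day `ceiling(t)`: death is observed at the
first inspection after it occurs.

From one stratum (a condition, pooling or splitting replicates) the
lifetable tallies, per day `x`:

- `Nx`: worms entering the interval (censored worms count for their final
  day and leave the risk set afterwards — no actuarial half-interval
  correction);
- `dx`, `cx`: deaths and censorings in the interval;
- `qx = dx / Nx`: interval probability of death;
- `mx = -log(1 - qx)`: force of mortality;
- `km`: the product-limit (Kaplan–Meier) survival after day `x`.

Days with `qx = 1` make `mx` infinite; they are flagged (`mx_defined =
FALSE`) and excluded from any regression on log-mortality. Mean lifespan is
the area under the Kaplan–Meier step curve up to the last observed day (the
restricted mean). This is the standard censoring-consistent summary: with no
censoring it reduces exactly to the arithmetic mean of death days, and with
censoring it neither discards censored worms nor pretends they died.

## The Gompertz–Makeham model

Age-specific mortality is modelled as

$$M(x) = M_0 e^{G x} + M_\infty,$$

with $M_0$ the initial mortality rate (IMR, the hazard extrapolated to the
start of adulthood — "frailty"), $G$ the demographic rate of aging (RoA,
the slope of log-mortality against age) and $M_\infty$ an age-independent
background term. Integrating the hazard gives the survival function

$$S(x) = \exp\!\left[\frac{M_0}{G}\left(1 - e^{G x}\right) - M_\infty x\right],$$

which is the form implemented (`gm_survival()`); it is the exact integral
of the hazard above, verified in the tests against adaptive quadrature to
1e-8. At $G = 0$ the analytic limit $\exp[-(M_0 + M_\infty)x]$ is used.
Derived summaries are the median ($S(x) = 0.5$), the "maximum" lifespan
defined as the age at 1% estimated survival ($S(x) = 0.01$; a model
quantile, deliberately not the oldest observed death), and the mean
$\int_0^\infty S$, computed by adaptive quadrature with an analytic tail
bound ($S(T)/M(T)$, valid because the hazard is non-decreasing).

## Fitting

`fit_gm()` minimises the unweighted sum of squared deviations between the
model survival and the Kaplan–Meier estimate at each observed day. Choices
that matter:

- **Fit target.** The KM curve (not raw death fractions) so censoring is
  handled by the risk sets. Points after the day the curve first reaches
  exactly 0 are dropped: the model never reaches 0, and a run of exact
  zeros would overweight the tail.
- **Parameter box.** $M_0 \in [10^{-8}, 1]$, $G \in [0, 2]$,
  $M_\infty \in [0, 1]$ per day — generous envelopes for daily worm
  mortality. $M_0$ is optimised on the log10 scale for conditioning.
- **Initialisation.** Ordinary linear regression of $\log m_x$ on $x$ over
  days with $0 < q_x < 1$ (Gompertz log-linearity) gives starting
  $(\log M_0, G)$; $M_\infty$ starts at 0. The bounded PORT optimiser
  (`nlminb`, objective tolerance 1e-10) is restarted from three
  deterministically jittered starts and the lowest-RSS solution kept, so
  fits are reproducible without a random-number stream.
- **Failure modes.** Non-convergence is reported as a flag on the fit, not
  an exception; a curve with no decline below 0.9, or fewer than 4 distinct
  days, is rejected as non-identifiable.

Noiseless curves are recovered to relative error below 1e-4. On sampled
cohorts the acceptance script measures the estimator's behaviour at the
screen's working scale (single cohorts of 300 worms on the daily grid): the
RoA is recovered essentially unbiased (median relative bias ~3%, within
±30% of truth in >99% of runs), while the fitted $M_0$ is median-biased
downward on the order of 10–15%. The cause is structural: at a few hundred
worms the data barely constrain early-age hazard, and the non-negative
Makeham term absorbs part of it, trading off against $M_0$ (the two
estimates are strongly anticorrelated). Averaging per-replicate fits, as
the reporting convention does, and interpreting $M_0$ changes as ratios
between arms (both arms carry the same bias) keeps the comparisons
meaningful; absolute single-cohort $M_0$ values should be read with this
caveat. Bias shrinks steadily with cohort size (75 → 150 → 300).

**Per-replicate vs pooled fitting.** Whether to fit each replicate
experiment and average, or fit the pooled curve, is genuinely open;
`fit_gm_replicates()` fits per replicate and summarises mean ± sd across
experiments (matching the usual presentation of IMR/RoA), while pooled
fitting is available by passing the pooled KM curve to `fit_gm()` directly.

## Comparisons and demographic classification

- **Log-rank** (`logrank_test()`, via `survival::survdiff`) compares two
  survival distributions on the shared day grid; it is the reported
  survival comparison, with Holm (Bonferroni step-down) adjustment applied
  across all gene comparisons of a run — the family is the run.
- **Student t-tests** (`two_sample_t()`, pooled variance) compare
  reproductive lifespans, brood sizes, developmental times, and
  per-replicate fitted parameters.
- **Classification** (`classify_demographic_group()`): IMR and RoA effects
  are two-sample t-tests on the per-replicate fitted parameters at
  $\alpha$ (default 0.05), with direction from the means; the lifespan
  axis is the supplied combined-experiment comparison. Patterns map to
  Group 1 (RoA↓, lifespan↑), Group 2 (IMR↓, lifespan↑), Group 3
  (IMR↓, RoA↑, lifespan unchanged) and Group 4 (no effects); anything
  else — e.g. IMR up — is reported as unclassified rather than forced into
  a group, because only those four patterns are biologically established.

One design choice deserves emphasis: the classification's lifespan axis is
the **mean** lifespan, so the pipeline feeds it `mean_lifespan_test()` — a
t-test on per-individual death days — rather than the log-rank p-value.
The log-rank responds to any distributional difference: a Group-3-style
inactivation (lower IMR, higher RoA, unchanged mean) shifts the *shape* of
the survival curve while leaving its mean in place, and at pooled sizes of
several hundred worms per arm the log-rank rejects essentially always,
which would misread "mean lifespan unchanged" as a lifespan effect. The
log-rank remains the reported survival-curve comparison; classification
tests the axis it actually claims. With three tests each at
$\alpha = 0.05$, a truly null gene is called Group 4 at most ~86% of the
time ($0.95^3$) — the residual is the cost of the per-axis error rate, not
a defect of the data.

## Reproductive-lifespan screening

`self_rls()` scores the self-fertilising reproductive lifespan with the
first day of reproduction indexed as 1 (RLS = last − first nonzero day
+ 1); `mated_cessation_day()` returns the absolute last day of live progeny
production, which feeds KM/log-rank as a reproductive "survival" event.
Interior zero-count days do not terminate the span — worms are transferred
until no progeny are scored for at least two consecutive days, so a one-day
gap is part of the span.

`call_hit()` implements the screen rule: extension of pooled mean RLS above
the threshold (default 25%) **and** a significant t-test within every
replicate experiment (default 3) — "scored positive three times". The
all-replicate rule makes the null hit rate roughly $\alpha^3$-scale
(empirically below 1%), at the cost of conjunctive power: with a true 30%
extension and per-replicate power 0.9, the hit rate is slightly below the
naive $0.9^3 = 0.73$ because the pooled-extension threshold also has to
clear 25%. Screens of this design do not usually record whether the
threshold was applied to the replicate mean or to each replicate
individually; the pooled-mean threshold plus all-replicate significance is
the documented default here.

`classify_epistasis()` is a pure truth table over the three wet-lab flags
(does the inactivation still extend RLS in daf-2, daf-16, sma-2
backgrounds); it classifies supplied flags and never infers them from
survival data. Genes extending in both daf-2 and daf-16 are
IIS-independent; crossing that with the sma-2 flag yields the four pathway
classes (independent of both, TGF-β-specific, IIS-specific, both
pathways).

## The synthetic cohorts

The generator reproduces the statistical skeleton the analysis assumes:

- **Lifetimes** are drawn exactly from the GM distribution by
  inverse-transform sampling (closed form when $M_\infty = 0$; otherwise
  bracketed bisection on the strictly increasing cumulative hazard,
  tolerance 1e-10 days).
- **Daily scoring** applies the ceiling rule above.
- **Censoring** is an independent per-day geometric loss process — a
  declared stand-in for worms lost at transfer, since published lifetables
  report censored counts but not their mechanism — plus administrative
  censoring at the observation horizon.
- **Progeny schedules** draw a cessation day per individual (fixed, rounded
  normal, or shifted Poisson), then Poisson daily counts around a mean
  schedule up to cessation and exactly zero after.
- **Reproducibility**: one integer seed expands deterministically into
  independent substreams for lifetimes, censoring and progeny, so each
  stage can be regenerated in isolation.

Default simulation conditions mirror the assay design: ~100 worms per
condition per experiment (300 for the estimation studies, where parameter
recovery is the question), three independent replicate experiments, daily
scoring, wild-type-like mortality around $M_0 \approx 0.004$/day,
$G \approx 0.25$/day, and ~7 reproductive days for controls.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: plate- or experimenter-level batch effects
(replicates are exchangeable here), non-GM mortality shapes (late-life
deceleration, heterogeneity/frailty mixtures), informative censoring
(matricidal bagging correlates with reproduction), day-to-day scoring
error, and developmental or temperature-shift biology. Test sizes
(200-cohort recovery studies, 1000-pair log-rank calibration, 100-run
classification studies, 300-run screen simulations) were chosen as the
smallest designs whose Monte-Carlo error is well below the effect margins
being asserted.

## Numerical conventions and edge cases

- `qx = 1` days: `mx = Inf`, flagged, excluded from log-mortality
  regression; the KM curve simply reaches 0.
- Degenerate flat survival (no deaths): explicit non-identifiability error
  from `fit_gm`; empty strata: explicit empty-cohort error.
- Two constant equal samples in `two_sample_t()`: p = 1 by convention.
- Ties in the log-rank are handled by the standard risk-set computation on
  the shared day grid.
- All file outputs use fixed column orders so identical configurations
  produce byte-identical CSVs.

## Known limitations

- The $M_0$/$M_\infty$ weak identifiability described above: single-cohort
  IMR estimates at n ≈ 300 are median-biased low by ~10–15%; ratios
  between arms and replicate averages are the supported use.
- Mean lifespans are restricted means (area under KM up to the last
  observed day); with heavy late censoring they under-state the true mean.
- The epistasis module classifies supplied flags; it does not propagate
  uncertainty in the flags themselves.
- Confidence intervals on fitted GM parameters are not provided beyond the
  replicate standard deviation; no interval-censored likelihood or model
  selection (Gompertz vs GM vs Weibull vs logistic) is attempted.
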