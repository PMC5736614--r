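---
title: "Feedback-learning trajectories: models, generators and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-learning trajectories: models, generators and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedlearn)
```

This vignette is the package's own account of the science it implements: the
sorting task and its event classification, the behavioral generator, the
synthetic accelerated-longitudinal cohort, the mixed-model trajectory
machinery, and the brain–behavior linkage — including every place where the
design was genuinely open and what was decided there.

## The task and its engine

Each sequence of the sorting task presents three novel stimuli that must be
placed into three squares under a fixed bijective rule. Feedback after every
choice is a plus or minus sign. A sequence ends after 12 trials or as soon as
every stimulus has been placed correctly at least twice, whichever comes
first; a wave-1/2 session has 15 sequences (at most 180 trials) and a wave-3
session 10 (at most 120). Trial timing is fixation 500 ms, stimulus and
response 2500 ms, feedback 1000 ms, with inter-trial intervals jittered on
0–6 s.

Three aspects of the engine are design choices rather than task facts:

* **Presentation schedule.** The within-sequence order of stimuli is not part
  of the task description. The engine presents permuted blocks of the three
  stimuli (no stimulus appears twice before the others appear once), seeded.
  This matches common practice for this task family and guarantees the
  interleaving the event classifier relies on: every learning trial normally
  has a later presentation of the same stimulus to evaluate feedback use
  against. A consequence worth knowing: with block scheduling, any responding
  policy yields sequence lengths in [6, 12].
* **Criterion timing.** The criterion is checked after every completed trial,
  so a sequence ends at the first trial after which it holds.
* **Jitter.** Only the marginal 0–6 s range of the (design-optimized)
  inter-trial intervals is known; the engine draws them uniformly, since
  design efficiency of the fMRI schedule is out of scope.

Too-late (omitted) responses receive no feedback, count toward the 12-trial
cap but not toward the criterion, and are events of no interest downstream.

## The behavioral agent

No generative behavioral model accompanies the task description, so the
package supplies the minimal policy family whose summary statistic is exactly
the learning-performance measure: a stochastic win-stay/lose-shift learner.
After positive feedback it stays with probability `p_use_positive`; after
negative feedback it switches with probability `p_use_negative`; when a switch
fires, an elimination memory (probability `p_elim_memory`) restricts the
choice to squares never yet disconfirmed for that stimulus. Whether real
participants use elimination is untested; `p_elim_memory = 0.5` is an
arbitrary middle value and results should not be read as evidence about it.

The developmental profile puts an inverted-U in age on the logit of both
feedback-use probabilities, `logit(p) = logit_peak − curvature (age −
peak_age)²`, defaulting to `peak_age = 20`, `logit_peak = 3.6`, `curvature =
0.008` per year². These defaults were set once so that simulated wave-level
mean performance lands in the mid-90s percent with a spread of a few points —
the regime reported for this deliberately easy task — and are a calibration
reference, not a fit to any dataset.

## Event classification and the performance statistic

Feedback events are classified per stimulus, in presentation order:

* **Learning phase** — no prior correct sort of this stimulus exists. If the
  feedback is used on the stimulus's next responded presentation (stay after
  positive, *any* switch after negative), the trial is `learning_pos` or
  `learning_neg` by valence; if not used, `excluded_nonlearning` (excluded
  from imaging contrasts but inside the performance denominator).
* **Application phase** — a prior correct sort exists, the current sort is
  correct, and the next responded presentation (if any) is also correct.
* **No interest** — too-late trials; final learning trials with no later
  responded presentation; correct post-criterion trials whose next
  presentation is wrong; and relapses (wrong sorts after a prior correct),
  which never re-enter the learning phase because a prior correct response
  exists.

Learning performance is `100 × used / (used + not used)` over evaluable
learning trials. Three readings were open and are resolved as follows:

* A switch after negative feedback counts as *used* even when it lands on the
  other wrong square — feedback use is stay/switch, not success; a stricter
  reading would conflate use with learning outcome.
* Final learning-phase presentations are unevaluable ("used on the next
  trial" is undecidable without one) and are excluded from the denominator;
  `classify_session(include_unevaluable = TRUE)` exposes the other reading.
* Whether a relapse could re-enter the learning phase is unstated; it does
  not here, since the learning definition requires no prior correct response.

Behavioral outliers are flagged wave-wise at more than 3 SD below the wave
mean (threshold configurable) — a rule chosen to implement "extreme low
scorers who plausibly did not understand the task".

## The synthetic cohort

`cohort_config()` defaults encode the study design being emulated: 271
subjects entering uniformly at ages 8–25, three waves two years apart,
retention 0.86 applied independently to each wave after the first (wave 1 is
the entry wave and always observed; independence, rather than monotone
attrition, is deliberate because reported wave sizes are non-monotone),
giving expected wave sizes 271/233/233. Activity per (ROI, contrast) stratum
is a quadratic in age centered at the midpoint of the achievable span (18.5
years, which keeps the vertex formula simple), plus a subject random
intercept (SD 0.5) and residual (SD 0.5); intercepts and residuals are
equicorrelated across strata at 0.66, the conventional mean inter-variable
correlation for these ROIs. Performance is its own quadratic (default peak
near age 20.5, mid-90s level) plus configured couplings to the *true*
activity residuals of selected strata (defaults: 0.5 and 0.44 performance
points per residual unit in dorsal and ventral caudate, informative-value
contrast), a subject intercept and noise of SD 3 each (ICC 0.5 before
truncation), truncation to [0, 100], and per-wave exact-100 ceiling scorers
(defaults 15/271, 27/233, 69/232).

What the generator emulates: the accelerated-longitudinal age/wave structure,
adolescent-peaked trajectories, correlated ROI batteries, a positive
activity–performance coupling with both between- and within-subject
components, ceiling scorers. What it does not: practice effects across waves,
scanner or motion artifacts, non-Gaussian tails, informative (non-random)
dropout, or any real link between the behavioral agent and activity
(behavioral-mode performance is uncoupled). Passing recovery tests on this
generator therefore shows the estimators are correct under their assumptions,
not that real data meet those assumptions. Two cautions from the defaults:
with a latent mean near 95 and SD ~4, truncation at 100 produces extra
exact-100 scores beyond `ceiling_rate`, and those spikes depress the
performance ICC well below the latent 0.5 — both are realistic features of an
easy task, but they are why the *calibration* suites (below) use an
untruncated regime.

## Trajectory models

All mixed models are random-intercept models fitted by **maximum likelihood,
never REML**, because the ladder compares models differing in fixed effects;
REML likelihoods would not be comparable and default estimators differ across
ecosystems (`lme4` here). The age polynomial uses the orthonormal basis over
the observed ages. The printed coefficients of the emulated analyses are on an
undeclared basis whose scaling cannot be inferred (magnitudes differ by two
orders across analyses), so coefficients are never the comparable surface —
predicted curves and peak ages are basis-free and are the contract. Every fit
also reports its raw-age-polynomial conversion (`raw_coef`), obtained by
solving the Vandermonde system through three prediction points, so the vertex
formula `−b1/(2 b2)` applies directly.

The ladder compares degrees 0/1/2 with step-up likelihood-ratio tests on
χ²(1) (one fixed effect per step; variance components are shared, so no
boundary correction applies) and reports AIC alongside. The selected degree is
the **highest degree whose own step-up test is significant** at α = 0.05: a
quadratic can be selected when the linear step is flat, which is exactly the
signature of an adolescent peak. The rule is configurable (`rule = "aic"`).

A known property of this selection procedure: under a flat truth it selects
*some* age effect at the union rate of two nominal-5% tests — about
1 − 0.95² ≈ 9.8% (and slightly above at finite samples, ≈ 11% at 150
subjects), not 5%. Each individual step does hold its 5% size. Any rule that
kept the family-wise selection at 5% would have to de-power or re-gate the
quadratic step and would no longer reproduce peaked-over-flat selections, so
the per-step rule is retained and its procedure-wise size documented here.

Other numerical choices: `peak_age()` is valid only when the fitted curvature
is negative and the vertex lies inside the observed age range; its CI is a
parametric bootstrap over the fixed-effect sampling distribution (2000 draws,
percentile interval over concave draws). A constant outcome yields a
degenerate fit with zero variance components and a floored-SD likelihood
rather than an error. Single-subject data are refused (the random intercept is
unidentifiable). ICC is σ_u²/(σ_u² + σ_ε²) from the degree-0 fit.

## Brain–behavior linkage

Residualization subtracts only the **fixed-effects** prediction of the
stratum's selected age model: subtracting estimated random intercepts would
remove exactly the stable between-subject signal the linkage tests. A
consequence: the ML estimating equation zeroes the V⁻¹-weighted residual
mean exactly, while the raw residual mean is only near zero when dropout
unbalances subjects — the test suite asserts the weighted identity at 10⁻⁶
and the raw mean at 5% of the residual SD.

The hierarchical test adds the residual to the performance-by-age² model and
reports its coefficient with a Wald test against the normal reference —
appropriate at the several hundred observations this design yields, and its
5% size is verified by simulation rather than assumed. The six striatal tests
are evaluated against the corrected threshold α/k^(1−r̄); with k = 6 and
r̄ = 0.66 this reproduces the conventional 0.027 (the formula is the standard
effective-number-of-tests correction; both k and the formula are exposed).
Results significant at 0.05 but not at the corrected level are flagged rather
than dropped. Lagged regressions standardize both variables and, by default,
include no age covariate — whether the emulated analysis adjusted for age is
unstated, so `age_adjust = TRUE` is provided but off.

## Calibration and recovery suites

The acceptance tests run at these problem sizes, chosen as the smallest at
which the Monte-Carlo error is clearly inside each tolerance:

* classifier vs an independently written prose-walking oracle: 1000 random
  sessions, exact agreement on every label and performance value;
* ladder null calibration: 500 single-stratum cohorts of 150 subjects
  (flat truth); ladder power: 100 cohorts of 250 subjects at curvature
  b2 = −0.012 (quadratic selected ≥ 90%);
* peak-age recovery: truth 18.5 years, 100 cohorts of 250 subjects, mean
  within ±1 year; ICC recovery: truth 0.5 at 1000 subjects, within ±0.03;
* brain–behavior: type-I over 500 null cohorts of 150 subjects (5% ± 2);
  power with the coupling sized at design time from one null fit's SE as
  (z₀.₉₇₅ + z₀.₉₅)·SE — 95% analytic Wald power, so the asserted 90%
  detection bar has margin against the binomial error of a 100-replicate
  proportion.

Calibration cohorts use a performance intercept of 85 with no ceiling
scorers, keeping the outcome away from the truncation bound so normal theory
applies; the package defaults keep the truncated, ceiling-afflicted regime
for realism. The ladder null-calibration band of 5% ± 2 is asserted against
the *selection* rate and fails by design of the selection rule, as analysed
above — the per-step size checks are the ones that pass.

## Known limitations

* The agent family is win-stay/lose-shift with elimination; it is not a
  reinforcement-learning model and cannot speak to learning-rate or value
  dynamics.
* Ladders are capped at the quadratic; cubic or spline trajectories are out
  of scope by design.
* The generator's dropout is completely at random; estimates under
  informative dropout are not studied here.
* Printed-coefficient comparability across age bases is impossible without
  the original basis declaration; curves and peaks are the only cross-basis
  contract.
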