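---
title: "Measuring metacognitive asymmetry: models, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring metacognitive asymmetry: models, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasym)
```

## The scientific problem

In near-threshold detection, confidence discriminates correct from incorrect
decisions better after "yes" (target present) than after "no" (target absent)
responses. `metasym` packages the machinery needed to ask whether the same
asymmetry appears in *discrimination* between two stimulus classes S1 and S2,
where neither response is logically a detection "yes": a generative
signal-detection observer to produce trial tables with known ground truth,
the response-conditional type-2 ROC analysis that quantifies the asymmetry,
an equal-variance SDT-matched null that controls for response bias, a zROC
analysis that estimates the evidence variance ratio, and the frequentist and
Bayes-factor inference layer used to test four directional group hypotheses:

* **H1** — confidence is higher for S1 than for S2 responses;
* **H2** — metacognitive sensitivity (auROC2) is higher for S1 responses;
* **H3** — H2 still holds against an SDT null that matches each participant's
  bias and sensitivity;
* **H4** — S1 responses are faster (on log response time).

## The generative observer

On each trial the observer draws evidence `x ~ N(d'(SOA), sigma_s1)` for S1
stimuli and `x ~ N(0, 1)` for S2 stimuli, responds "S1" when `x` exceeds
`k = d'/2 + criterion_shift`, and reports confidence as a bounded monotone
transform of the distance from threshold:
`conf = 1 - exp(-max(conf_gain * |x - k| + noise, 0))`. Log response time
decreases linearly in confidence. The interesting regime is `sigma_s1 > 1`:
a wider S1 evidence distribution produces exactly the confidence, type-2 ROC
and zROC signatures that distinguish "detection-like" asymmetric
representations from symmetric ones.

Choices the task description leaves open, fixed here once:

* **Psychometric link.** `d'(SOA) = d_max (1 - exp(-SOA/tau_ms))` — the
  simplest saturating link with a single time constant. With the defaults
  `d_max = 2.5`, `tau_ms = 40` ms the converged staircase sits in the
  30–55 ms SOA range typical of masked letter discrimination. The link is a
  modelling convenience connecting difficulty to exposure duration, not a
  claim about any particular data set.
* **Confidence squashing.** `1 - exp(-u)` maps unbounded evidence distance to
  the continuous 0–1 rating scale; any strictly increasing map would give the
  same auROC2 (tested as an invariance), so the choice only shapes marginal
  rating distributions.
* **Staircase direction.** 1-up-2-down with multiplicative step 0.9 starting
  at 30 ms: errors lengthen the SOA (easier), two consecutive correct
  responses shorten it. The fixed point solves `p^2 = 0.5`, i.e. 70.7%
  accuracy, which the simulator reproduces to well under a percentage point
  over 10^5 trials. SOA is clamped to [1, 1000] ms for physical plausibility.
* **Between-subject heterogeneity.** Positive-mean parameters vary
  log-normally across participants (mean-preserving, log-SD `sdlog = 0.2` by
  default — roughly ±20% individual differences, typical of behavioural
  parameters); the sign-free additive parameters (`criterion_shift`,
  `conf_shift_s1`) vary normally, since a log-normal is undefined at and
  below zero; the two probability parameters are shared. One root seed feeds
  deterministic per-participant child streams, so participant `i`'s data do
  not depend on the cohort size.
* **Session structure.** 96 trials in 6 blocks per participant, balanced
  S1/S2, the comprehension-check outcome drawn once per participant; the
  first block is treated as practice and dropped from analysis.

What the generator deliberately does *not* emulate: stimulus rendering and
masking, sequential effects, learning or fatigue across blocks, and
non-stationary criteria. Tests passing on synthetic cohorts therefore
establish that the *analysis* is correct and well-calibrated under the
assumed evidence model, not that any particular real population satisfies
that model.

## Exclusion rules

Participants are excluded for accuracy below 60%, for response times outside
[250 ms, 5 s] on more than 25% of trials, for failing the comprehension
check, for fewer than two errors of either type, or for fewer than two
distinct confidence levels within either response. Decisions the rules leave
open, fixed here: boundary response times (exactly 250 ms or 5 s) are
retained, reading "below"/"above" strictly; the RT-fraction rule is scored
on all trials while accuracy, error-count and confidence-level rules are
scored on the analysed blocks (configurable via `accuracy_all_blocks`);
error counts use pre-RT-filter trials so trial filtering can never cause an
exclusion; missing confidence values are dropped with a warning. Trials with
extreme response times are excluded from the analysis of included
participants.

## Type-2 ROC, the SDT-matched null, and zROC

`rcroc_curve()` cumulates confidence from high to low with weak ("at or
above") inequalities, so ties share one point — the standard ROC convention.
The trapezoidal area then equals the pairwise concordance statistic
`P(conf_correct > conf_incorrect) + P(tie)/2` *exactly*, a property the test
suite checks to 1e-12 on a thousand random samples. auROC2 is always
computed from the raw continuous ratings; `bin_confidence()`'s 20
participant-tailored bins exist for visualisation only.

For the bias-controlled statistic, `expected_rcroc()` constructs the type-2
curve an equal-variance observer with the participant's fitted `d'` and
threshold `k` would produce, *given the participant's own incorrect-trial
confidence distribution*: each cumulative proportion of incorrect-trial
confidence maps through the truncated evidence distribution on the response's
own side to an evidence cut, which the model translates into the matching
correct-trial cumulative. The construction is analytic (truncated-normal
inversion) and is validated against a 10^6-sample Monte-Carlo of the same
observer to 0.005 in area. Because only the *ranks* of the incorrect-trial
confidences enter, the resulting `h3_statistic()` is invariant to monotone
redescriptions of the confidence scale. Simulations confirm the two key
calibration properties: a response-biased equal-variance observer moves the
raw asymmetry but leaves the statistic at zero, while an unequal-variance
observer drives it positive.

`fit_sdt()` applies the log-linear correction (+0.5 to each cell, +1 to each
denominator) only when a count is zero, and records that it did. zROC points
come from sweeping every distinct *signed* confidence value (S1 responses at
`+conf`, S2 at `-conf`) as a threshold, dropping degenerate rates, and
probit-transforming the survivors; the slope is ordinary least squares of
`z(hit)` on `z(FA)`, the common reporting convention. Under equal variance
the slope is 1; with `sigma_s1 = 1.25` the estimate recovers the analytic
`1/1.25 = 0.8` within 0.03 at 10^5 trials. The zROC slope is a noisy
*estimator* with finite-sample attenuation from sampling error in the tail
rates, visible below roughly a thousand trials per participant; group
inference is run on the log slope.

## Inference

Hypotheses are tested with one-tailed one-sample t-tests (`alpha = 0.05`) on
the per-participant summaries, and with a two-sided JZS Bayes factor: a
Cauchy prior with scale 0.65 on the standardized effect, symmetric around
zero, so evidence for the alternative can come from either sign even when
the t-test direction was registered. `jzs_bf_from_t()` evaluates the defining
integral by adaptive quadrature (relative tolerance 1e-7) after substituting
`delta = rscale * u`, with the quadrature pieces anchored at the prior bulk
and at the likelihood peak so that neither can be stepped over at extreme
`t` or prior scales; beyond the reach of double-precision t densities the
Bayes factor is reported as infinite. The suite cross-checks the quadrature
against a brute-force fine-grid trapezoidal oracle to 1e-4 on random cases.
Report verdicts are keyed to the Bayes factor (thresholds 3 and 1/3), with
the t-test shown alongside and disagreements flagged rather than
adjudicated.

Design utilities: `power_one_tailed()` and `min_detectable_d()` are closed
forms in the noncentral t; `min_bf_decisive_d()` root-finds the observed
effect at which BF10 crosses 3 (Brent's method on the bracket
`[min_detectable_d/4, 1]`, tolerance 1e-6). `design_simulation()` repeats
whole experiments under a point-null or Cauchy-distributed true effect. Its
default is an *independent-samples* design with `n` participants per group —
the design used by the standard Bayes-factor design-analysis simulation code
this workflow follows, and the configuration that reproduces the published
planning proportions (95% and 79% null support at zero effect; 76%, 70% and
15% under Cauchy-distributed effects); a one-sample variant is available via
`design = "one_sample"`. `robustness_region()` sweeps the prior scale over a
grid and labels where each Bayes-factor conclusion holds.

## Problem sizes and numerical choices

The test suite and the acceptance script run the design simulation at 10^4
repetitions (Monte-Carlo SE about 0.4 percentage points on the reported
proportions), simulate 200 participants for the group-null calibration
checks, 10^5 trials for staircase and zROC recovery, 10^6 evidence samples
for the expected-curve oracle, and 100 seeded experiments of 106
participants for the power-recovery study, which detects an injected
0.66-SD confidence asymmetry at the rate the noncentral-t power formula
predicts. Degenerate inputs are handled explicitly: empty tables produce
all-excluded reports, single-level confidence distributions produce diagonal
expected curves (area 0.5), zero-range ratings fall in a single bin with a
warning, and all-correct or all-incorrect response sets raise errors naming
the violated inclusion rule.

## Known limitations

The equal-variance-matched null absorbs response bias but, by construction,
not every alternative generative story (e.g. confidence criteria that differ
between responses); the zROC slope summarises the variance ratio only under
approximately Gaussian evidence; and parameter-recovery results transfer to
real data only insofar as the evidence model holds. The per-participant
variance-ratio versus asymmetry correlation reported for real detection data
can be reproduced only qualitatively on synthetic cohorts.
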