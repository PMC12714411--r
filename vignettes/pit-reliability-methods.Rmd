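---
title: "Reliability analysis of Pavlovian-to-instrumental transfer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability analysis of Pavlovian-to-instrumental transfer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Pavlovian-to-instrumental transfer (PIT) tasks measure how passively
conditioned cues bias independently learned instrumental behaviour. Two
behavioural parameters summarize the transfer:

* the **interference PIT effect** — the error-rate difference between
  incongruent and congruent transfer trials (a cue whose valence conflicts
  with the required action pushes responses toward errors), and
* the **motivational PIT effect** — the slope of the button-press count on
  the monetary value of the background cue, in a Poisson mixed model of
  response vigour.

Before such parameters can be used for individual-differences research
(e.g. as risk markers), their *reliability* must be established: how much
of the between-subject variance is stable signal rather than trial-level
noise (split-half), and how stable subjects' scores are across sessions
(test–retest). `pitrel` implements the complete reliability machinery, a
generative simulator of the task with known ground truth to validate it
against, and a counterpart analysis for first-level neural maps.

## The task simulator

`simulate_study()` emulates the three-phase design:

1. **Instrumental training**: at least 60 trials; the phase stops as soon
   as accuracy over the last 16 consecutive trials reaches 80%, with a
   hard cap at 120 trials. The specification of the task fixes only this
   stopping rule, so the accuracy trajectory is a package design choice:
   a saturating exponential `accuracy(t) = A - (A - 0.5) exp(-t / tau)`
   rising from chance toward an asymptote `A` (default: derived from the
   subject's baseline error trait), with `tau = 16` trials. Any form
   rising from 0.5 to an asymptote would serve; the exponential is the
   standard single-parameter learning curve.
2. **Pavlovian conditioning**: 80 passive trials, 16 for each conditioned
   stimulus, with monetary values −2, −1, 0, +1, +2 euros.
3. **Transfer (PIT)**: 90 trials under nominal extinction, 3 s each, the
   conditioned stimulus leading by 0.6 s (2.4-s response window). The ten
   cue-value × required-action cells are allocated equally (9 trials
   each) in randomized order; the source design does not state the
   allocation, and equal cells guarantee that stratified splits keep both
   congruency classes populated.

The generative behavioural model per subject \(i\), session \(s\):

* error probability: \(\mathrm{logit}\, p_{err} = \alpha_{is} +
  \gamma_{is}\,[\text{incongruent}]\);
* button presses: \(y \sim \mathrm{Poisson}\!\big(\exp(b_{0,is} +
  b_{1,is}\,\mathrm{value} + b_{go}\,[\text{collect}] + u_{cue}^{pav} +
  u_{cue}^{instr})\big)\).

Traits \((\alpha, \gamma, b_0, b_1)\) are drawn per subject from bivariate
normals whose session-1/session-2 correlation is `rho_trait`; setting it
to 1 encodes the classical stable-true-score assumption, lower values
inject genuine trait change, which is what separates test–retest
stability from internal consistency. Crossed cue intercepts (5 Pavlovian
stimuli, 4 instrumental shell exemplars) are population-level draws.

Decisions the task description leaves open, fixed here once:

* **Omissions** count as errors with zero presses; the scoring of
  non-responses is not specified in the source design.
* **Neutral trials** (value 0) belong to neither congruency class.
* **Press counts are uncapped** by the response window (default rates
  make >10 presses rare); a cap is configurable via `press_cap`.
* Seeds are mandatory arguments everywhere and recorded in the manifest;
  the package never relies on hidden RNG state.

Default population values (means/SDs of the trait distributions) were
chosen once as plausible for this family of tasks: baseline error ≈ 8%
(`mu_alpha = qlogis(0.08)`, `sd_alpha = 0.8`), an incongruency shift of
1 logit (`sd_gamma = 1`), press intercept 0.5 log-units with a
collect-vs-reject effect of 1.5 (≈1.6 vs 7.4 presses), motivational slope
0.2 per euro (`sd_b1 = 0.1`), cue-intercept SDs 0.05 and `rho_trait
= 0.7`. They are conditions of simulation studies, not estimates of any
particular sample.

## Split-half reliability

`split_half_reliability()` follows the permutation scheme: for each of
`n_perm` permutations (default 5000) every subject's trials are split
into stratified halves (by cue value × required action; plain random
splits can empty a congruency class), the effect is computed per half,
and the across-subject Pearson correlation between halves is corrected
for halved test length with Spearman–Brown, \(r_{SB} = 2r/(1+r)\). The
corrected coefficients are Fisher-z transformed, averaged, and
back-transformed. Degenerate permutations with \(|r| = 1\) are clipped to
\(1 - 10^{-12}\) before `atanh`, with a logged count.

Under the classical test-theory model (observed effect = true score +
independent error), the Spearman–Brown-corrected split-half coefficient
estimates \(\sigma_T^2 / (\sigma_T^2 + \sigma_e^2)\) for the full-length
measure. The acceptance suite verifies this identity against an oracle
that computes \(\sigma_T^2\) directly from the simulator's latent traits
and \(\sigma_e^2\) from the binomial error variance of the 36 + 36
non-neutral trials, across three trait regimes spanning true
reliabilities of roughly 0.90, 0.74 and 0.83 — the excellent-to-good
range in which behavioural PIT measures operate. Below roughly 0.6 the
finite-sample realization noise of a 300-subject cohort exceeds ±0.03,
so such regimes cannot discriminate a correct estimator from a biased
one at this cohort size and are not used.

Inside the permutation loop the motivational effect is the per-subject
Poisson regression slope (`two_stage_motivational()`); refitting the full
mixed model per half and permutation would cost hours at 5000
permutations. The mixed model remains the estimator for session-level
effect tables.

## Test–retest statistics

`icc_agreement()` computes the single-measurement, absolute-agreement,
two-way model ICC — ICC(A,1) in McGraw–Wong terms — from the two-way
ANOVA mean squares,

\[ \mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
\frac{k}{n}(MS_C - MS_E)}, \]

with the F-based 95% confidence interval. The mean squares come from
`stats::aov`; the formula and CI are implemented in the package and
oracle-tested against a from-first-principles sums-of-squares
computation. Absolute agreement penalizes systematic between-session
shifts, so the shift-insensitive Pearson correlation is reported
alongside, and `paired_t_test()` quantifies mean change. Negative ICCs
are reported as computed — truncating at zero would bias aggregate
summaries. For single measurements the agreement point estimate is
identical under the two-way random and two-way mixed models, so the
distinction is carried only in the model label.

`classify_reliability()` maps coefficients onto the two standard
guideline schemes (poor/moderate/good/excellent at 0.5/0.75/0.9, and the
more liberal poor/fair/good/excellent at 0.4/0.6/0.75), with bin edges
inclusive for the higher category since the printed guidelines are
ambiguous at the boundaries.

## Neural reliability

The synthetic path replaces the HRF-convolved time-series GLM (out of
scope here) with a *trial-amplitude* linear model: each transfer trial
contributes one amplitude per voxel, generated as the sum over signal
components (onset, incongruent, congruent, cue value, log presses,
value × log presses) of the trial's regressor value times the
subject-session beta field, plus i.i.d. Gaussian noise. Beta fields are
group ROI amplitudes plus subject deviations (correlated `rho_trait`
across sessions) and session deviations, constant within each ROI so that
they survive ROI averaging. The toy geometry is a 20×20×12 grid with four
disjoint 4×4×4 boxes labelled amygdala, VS, lPFC and dmPFC; the real-data
path substitutes user NIfTI masks and pre-estimated beta maps.

First-level estimation (`estimate_first_level()`) is per-voxel OLS with
`df = n_trials − rank(X)`; the interference design has 10 cue × action
indicators and the motivational design one onset column plus three
mean-centred, deliberately *non-orthogonalized* parametric modulators
(value × log-presses, value, log-presses; `log(presses + 1)` because zero
presses occur). Contrasts: incongruent and congruent cell means, their
difference, and the four motivational-model columns.

Reliability of the maps is assessed three ways, mirroring the behavioural
logic: ROI ICCs on unweighted mean betas (split-half per session via
`split_half_neural()`, and across sessions), voxel-wise ICC maps
(`voxelwise_icc()`, degenerate voxels stored as NaN and excluded), and
per-subject Jaccard overlap of thresholded t maps
(`threshold_map()` + `jaccard()`) at uncorrected p < 0.05, 0.01, 0.001.
Thresholding is two-sided on |t| by default (the tail convention is not
fixed by the source method; a positive-tail option exists). When both of
a subject's thresholded maps are empty the Jaccard coefficient is
undefined and excluded from the group mean with a count — scoring it 0 or
1 would reward or punish empty maps. Group overlap is the arithmetic mean
of individual coefficients.

The default amplitudes make the incongruent and congruent responses
large and strongly shared (a common onset-component subject deviation)
while their difference carries little distinct between-subject signal.
This reproduces, as a property, the characteristic finding that
difference contrasts are far less reliable than their constituents: the
shared variance cancels in the subtraction while estimation noise adds.

## Problem sizes and numerical choices

The test suite runs everything at reduced but informative scales, chosen
as the smallest sizes at which the Monte-Carlo error of each check is
several times smaller than its tolerance: 300-subject cohorts with 500
permutations for the classical-test-theory and ICC recovery checks, 40
replicates of 100 subjects × 90 trials for mixed-model slope recovery,
a 12×12×6 grid with 3×3×3 ROIs for neural checks, and 100 simulations of
20 subjects for the difference-contrast ordering property. The full
pipeline example below the defaults (119 subjects, 5000 permutations,
full grid) runs in tens of minutes; the reduced configuration in the
README runs in well under a minute.

Other numerical conventions: ICC degeneracy (zero total variance) is an
explicit error for scalars and NaN for voxel maps; rank-deficient designs
fall back to the SVD pseudoinverse with adjusted df and a warning; t
statistics at voxels with zero residual variance are NaN; paired t with
zero-variance nonzero-mean differences reports an infinite statistic
rather than failing.

## Known limitations

* The neural generator has no haemodynamics, autocorrelation, motion, or
  spatial smoothness; passing tests validate the reliability statistics
  and their implementation, not robustness to fMRI preprocessing
  artefacts.
* Wald confidence intervals for the fixed motivational slope undercover
  (≈80–90% rather than 95%) under the default crossed design: cue value
  is a deterministic function of the five Pavlovian stimuli, so the
  cue-intercept variance rests on five levels, is estimated poorly, and
  often shrinks to zero, deflating the slope SE. This is a known
  small-level-count property of mixed models, inherited by any analysis
  of this design, and worth remembering when interpreting slope CIs.
* Split-half coefficients for the motivational effect use unshrunken
  per-subject slopes; shrinkage-based alternatives would correlate the
  halves through the shared prior and overstate reliability.
* With 3-year retest intervals the ICC conflates measurement error with
  genuine trait change; the simulator makes this explicit through
  `rho_trait`, and the recovered ICC approximates `rho_trait` times the
  session reliability.
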