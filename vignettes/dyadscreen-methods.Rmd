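---
title: "Screening for ASD from caregiver-child interaction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for ASD from caregiver-child interaction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dyadscreen)
```

# The analysis problem

Early screening for autism spectrum disorder (ASD) in preschool children can
be built on how a child and their familiar caregiver actually interact during
a few minutes of free play, rather than on questionnaires or lengthy expert
assessment. The analysis this package implements takes three inputs:

1. **micro-coded behavioral annotations** of a 3–5 minute caregiver–child
   free-play session, coded in 1-second steps with a small vocabulary of
   interaction states (`bid`, `respond`, `engage`, plus passive codes);
2. **the child's multichannel EEG**, recorded simultaneously;
3. **a participant roster** with diagnostic group (ASD with developmental
   delay, ASD without developmental delay, typically developing), sex, age,
   IQ, and — for the ASD groups — clinical severity scores (CARS total,
   ADOS-CSS).

From the annotations it derives five behavioral indicators; from the EEG it
derives theta- and alpha-band power spectral density (PSD); and it then runs
the full statistical surface of a screening study: group comparisons,
sex-adjusted contrasts, partial correlations between behavior and brain, and
ROC screening accuracy with Youden-optimal cutoffs.

Because the underlying clinical video/EEG data are not publicly available,
the package also ships a fully specified synthetic cohort generator,
calibrated so that its group-level structure matches the published group
parameters. The generator makes every stage of the pipeline testable, end to
end, under known ground truth.

# Behavioral coding and the five indicators

## Coding model

A coded session is a set of events, each an interval `[onset, offset)` in
0-based seconds attributed to one actor (`child` or `caregiver`) with one
code. Sessions are rasterized into 1-second frames: a frame takes an actor's
state when an event covers at least 50% of the frame (ties at exactly 50%
count), with precedence `engage > respond > bid > idle` when several codes
qualify. The 50% rule and the precedence order are package conventions — the
published description fixes only the 1-s stepping — and are applied uniformly
to real annotation files and simulated sessions alike.

## Episode segmentation

Interaction episodes are reconstructed from the frame stream:

* an episode opens at the first `bid` frame of either actor (caregiver wins a
  simultaneous tie);
* it is **answered** when the other actor shows `respond`/`engage` within the
  response window (default 3 s);
* an answered episode closes after `gap_close` (default 2 s) consecutive
  frames with neither actor in `respond`/`engage`, counted from the first
  answer frame; its end is the first frame of the closing run;
* an unanswered episode ends with the opening bid run or the response window,
  whichever is first;
* a bid by the other actor inside an open episode does not open a new episode
  (it re-initiates the exchange); bids after closure open new episodes.

The window and gap defaults are chosen to be meaningful at 1-s coding
granularity and are configurable.

## The indicators

With `active = {respond, engage}` frames:

| Indicator | Definition |
|---|---|
| SIC | proportion of frames with the child in `bid`, `respond`, or `engage` |
| IT  | proportion of frames with *both* actors simultaneously in `respond`/`engage` |
| RSC | answered caregiver-initiated episodes / all caregiver-initiated episodes |
| GIS | proportion of frames inside caregiver-initiated episodes (unanswered bids included) |
| CIS | same for child-initiated episodes |

Frames covered by a re-initiating bid count toward **both** GIS and CIS; this
double attribution is the minimal rule under which group-level GIS + CIS can
exceed 1, as the published group means do. RSC is *undefined*, not zero, for
a session in which the caregiver never initiated — a zero would fabricate a
response deficit.

Two structural facts about these definitions matter for calibration. First,
mutual-interaction frames require the child to be active, so IT ≤ SIC always;
a group mean pattern with IT above SIC is therefore not attainable under
these definitions and the published IT values are treated as emergent rather
than as calibration targets. Second, GIS + CIS + idle time is bounded, so GIS
and CIS cannot be calibrated jointly to arbitrary values; the package
calibrates SIC (all three groups), TD CIS and TD RSC, and lets IT and GIS
follow.

Before model fitting, indicator proportions and PSD values are square-root
transformed (the *analysis scale*) to stabilize distributions; report tables
carry both scales.

# EEG processing

## Preprocessing chain

`preprocess()` applies, in order: a zero-phase 0.5–45 Hz bandpass plus 50 Hz
notch; exclusion of the montage's "skirt" channels (the outermost ring of a
high-density net, most exposed to muscle artifact — 46 of 128 channels in the
full profile, leaving 82 for analysis); robust bad-channel detection (log-RMS
outliers beyond 4 robust SDs, with the spread estimate floored so
near-identical channels are never flagged) and inverse-distance interpolation
over the 4 nearest neighbors; segmentation into 1-s epochs; epoch rejection
by peak-to-peak amplitude (150 µV) and sample-to-sample jump (100 µV); blink
removal by regressing every channel on a 0.3–4 Hz low-passed frontal-pair
template; and re-referencing to the mastoid average. Every removal and
interpolation is logged in the returned object.

Two deliberate substitutions for manual steps: visual artifact inspection and
ICA, which are not reproducible as specified, are replaced by the thresholded
rejection plus template blink regression above. The preprocessing surface is
parameterized (`params`) so an independent-component step can be slotted in
upstream without changing any downstream code.

## Filtering realization

Zero-phase filtering is implemented in the frequency domain: the signal
spectrum is multiplied by the one-pass squared magnitude response
|H(f)|² of the 4th-order Butterworth bandpass and the Q = 30 IIR notch. This
is exactly the transfer function of forward–backward (filtfilt) application,
with no edge transients, exact linearity, and a DC gain of identically zero;
it differs from a bilinear-transform digital filtfilt only near Nyquist
(tested against `signal::filtfilt`). It is also fast: two packed FFTs per
pair of channels.

## PSD and band summaries

`compute_psd()` is the bare-FFT estimator: per 1-s epoch and channel, the
DFT magnitude squared with periodogram normalization `2|X(f)|²/(N·fs)`
(one-sided, DC and Nyquist not doubled), which for 1-s epochs gives a 1 Hz
grid in µV²/Hz; epochs are then averaged. A rectangular window is the
default, matching the bare-FFT description; a Hann option exists behind a
flag. A unit-amplitude sine therefore lands `A²/2 = 0.5` µV²/Hz in its bin,
and the one-sided integral reproduces the signal variance (Parseval — both
are test oracles).

`band_power()` averages PSD bins inside theta (4–7 Hz) and alpha (8–13 Hz),
endpoints inclusive, per channel, and reports the unweighted grand mean over
retained channels. Averaging (rather than summing) bins is a convention; the
calibration absorbs the constant.

# The synthetic cohort generator

The generator is a test harness with matched first moments and correlation
signs — not a mechanistic claim about dyadic interaction. Everything hangs on
a latent social trait per child, standardized to TD mean 0, SD 1; the ASD
group trait means are negative and set by calibration (the study's published
tables give no latent scale).

## Dyadic sessions: a semi-Markov interaction process

While the dyad is idle, caregiver and child bids compete as Poisson processes
with rates λ_cg = `cg_rate`·exp(−`cg_rate_slope`·trait) (caregivers of
lower-trait children initiate more) and λ_ch = `ch_rate`·exp(`ch_rate_slope`·
trait). A bid is answered with probability plogis(`resp_intercept` +
`resp_slope`·trait) after an Exponential(1 s) latency truncated at the 3-s
timeout; the answer is a 1-s `respond` event followed by a mutual `engage`
episode with Gamma(shape 2) duration whose mean is `engage_mean`·
exp(`engage_mean_slope`·trait). Unanswered bids close after the timeout.
Latency and timeout are not published; the values chosen make 1-s coding
meaningful. Sessions default to 180 s (the lower end of the published 3–5 min
range, matching the EEG profile below).

## EEG: structured signal plus realistic artifacts

Each channel is synthesized in the frequency domain (Hermitian random
spectra, so the expected one-sided PSD equals the target shape exactly):
a 1/f background (9 µV RMS over the analysis band), Gaussian spectral bumps
for theta (5.5 ± 0.75 Hz) and alpha (10 ± 1 Hz) whose RMS amplitude is
`amp`·exp(−`coupling`·trait) times a per-subject log-normal variability
multiplier (SD 0.25, set from the plausible published group SEs), 50 Hz line
noise, frontally weighted half-sine blink transients (0.2/s, ~120 µV), and
occasional broadband motion bursts (0.02/s, ~300 µV) that the epoch rejection
is expected to catch. Mastoid channels carry attenuated signal (gain 0.3) so
mastoid re-referencing removes little oscillatory power. The negative
`coupling` link is what induces the negative behavior–PSD partial
correlations at the population level; setting it to zero is the package's
null-coupling control.

Two profiles exist: `desk` (32-channel 10–20-style cap, 128 Hz, 180 s; the
default, sized so a full 85-child cohort simulates in well under a minute per
replicate on one CPU) and `full` (128-channel geodesic-style net at 1000 Hz,
mimicking the lab recording; its outer ring of 46 channels is the documented
default skirt list, config-overridable, since the exact identities of the
excluded channels are not published).

## Roster and severity

Sex is per-group Bernoulli with the published female counts (4/23, 1/17,
22/45); note the published abstract's 70.6%-male figure is inconsistent with
those counts — the generator follows the counts. Age and IQ are truncated
normals with published means and SDs reconstructed as SE·√n (IQ truncated to
[20, 160], age to [3, 5]; full-scale IQ respects the diagnostic FSIQ < 70
boundary of the ASD-with-DD group). Severity is linked to the trait as
CARS = 30 − a·trait + ε; the slope a ≈ 3.1 reproduces the published ASD group
CARS means at the calibrated trait means, and SD(ε) = 5 is a realistic
clinical spread (the published CARS SEs imply implausible SDs on a 15–60
scale and were not used). ADOS-CSS uses a deliberately weak trait link, since
the two ASD groups' published means are nearly identical, and is rounded and
clipped to 1–10.

## Calibration

`calibrate_generator()` performs the documented univariate search: each
target (a group mean of an indicator on the raw scale, or an analysis-scale
band PSD group mean) is linked to one parameter, and targets are swept in
order with a secant iteration per parameter (common random numbers across
evaluations), repeating the sweep because parameters interact. The shipped
defaults in `default_config()` are the result of this calibration against
the published TD and ASD-group parameters: engagement mean and child bid
rate for TD SIC and CIS, response intercept for TD RSC, the ASD trait means
for the ASD SIC means, band amplitudes for the TD band PSDs, and band
couplings for the ASD-with-DD band PSDs. Infeasible targets (proportions
outside [0, 1]) fail before any simulation; non-convergence raises an error
that carries the best-found configuration.

# Statistics

* **Group comparisons** (`compare_groups`): one-way ANOVA F/p, plus a linear
  model `value ~ group + sex` with TD as reference whose group coefficients
  are the sex-adjusted mean differences (t-based p, Bonferroni over the
  pairwise contrasts); Wilcoxon rank-sum p per contrast (exact for small
  groups without ties). Models are fitted on the analysis scale; group means
  are reported on both scales.
* **Partial Pearson correlation** (`partial_pearson`): residualize both
  variables on an intercept plus covariates by least squares, correlate
  residuals; t = r·sqrt(df/(1−r²)) with df = n − 2 − k, two-sided p. With no
  covariates this is exactly plain Pearson (a test oracle, as is the
  single-covariate closed form).
* **Bonferroni** (`bonferroni_adjust`): threshold mode α/m and p-value mode
  min(1, m·p); the indicator-by-band correlation family has m = 10, giving
  the 0.005 family threshold.
* **ROC** (`roc_analysis`): thresholds at midpoints of sorted unique scores
  plus infinities; automatic orientation (scores negated, and the flip
  recorded, when the raw AUC is below 0.5 — low raw indicator values mark the
  ASD class); AUC by trapezoid, equal to the tie-corrected Mann–Whitney
  U/(n₁n₂); the operating cutoff maximizes Youden's J with ties broken toward
  higher specificity, a deliberate screening-context choice (false positives
  are the known weakness of the most sensitive indicators). Both the AUC and
  the cutoff-level accuracy are reported side by side and labelled
  distinctly, because a published "accuracy" column alongside
  sensitivity/specificity is ambiguous between the two.

`run_study()` wires everything into one deterministic run — roster, sessions,
EEG, indicators, band powers, and the six result tables (demographics, group
comparisons, ROC over the three contrasts, behavior–PSD partial correlations
controlling sex and sex + verbal IQ, severity correlations per ASD group on
both scales, and sex-stratified correlations) — and `export_report()` writes
CSV/JSON tables, ROC and group figures, and a markdown summary. Every random
draw site takes a named sub-seed derived from the master seed
(`derive_seed`), so adding a draw site never perturbs existing streams, and
reruns with the same config and seed are bit-identical.

# Numerical choices and edge cases

* Times are 0-based seconds with half-open `[onset, offset)` intervals.
* RSC of a caregiver-silent session is `NA` with a `rsc_defined = FALSE`
  flag; statistics drop undefined values.
* All scores tied in a ROC gives AUC 0.5 and an undefined-cutoff flag.
* Constant values in a group comparison or zero residual variance in a
  partial correlation raise errors rather than returning NaN.
* The bad-channel spread estimate is floored (MAD ≥ 0.05 on log-RMS) so
  degenerate near-identical channel sets never self-reject.
* Proportion calibration targets outside [0, 1] fail fast.

# Problem sizes used by the shipped checks

The package's own verification simulations are sized for a single CPU: the
calibrated-recovery checks use 20 replicate cohorts of 85 children (desk EEG
profile); the acceptance script averages the behavioral and TD-EEG
quantities over 20 replicates and the behavior–EEG partial correlation over
24 replicates; the null-coupling control runs 50 replicate cohorts with
coupling set to zero and 60-s recordings (under the null, the family-wise
error of the correlation tests does not depend on recording length). These
sizes are the package's chosen study conditions for its own tests, stated
here so they can be scaled up by anyone with more hardware.

# What passing tests do and do not show

The generator reproduces the *group-level structure* the analysis consumes:
group means of the attainable indicators and band powers, their between-child
spread, the sign and rough magnitude of the behavior–PSD coupling, and the
severity links. It does not claim to reproduce real micro-dynamics of play
(turn-taking rhythms, affect, gaze), real EEG nonstationarity, or annotation
noise from human coders; and the published IT/GIS means are structurally
outside the declared indicator definitions (see above). Green tests
therefore validate the pipeline's correctness and its behavior under a
faithful-by-construction cohort — they are not clinical validation on real
children.

# Known limitations

* EAF (ELAN) input is read-only and requires a user-supplied tier-to-actor
  mapping; EDF input is not supported — EEG enters as a delimited matrix with
  a JSON sidecar.
* The blink regression removes a fraction of genuine low-frequency frontal
  signal along with blinks; this is the standard cost of template regression.
* The exact published indicator formulas and the full coding vocabulary live
  in an unavailable supplement; the definitions here are declared
  reconstructions used consistently throughout.
* Youden cutoffs estimated and evaluated on the same sample are optimistic
  in finite samples; the screening accuracies of a single simulated cohort
  should be read accordingly.
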