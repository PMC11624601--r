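---
title: "Methods: sustained processing negativity in source-space auditory MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sustained processing negativity in source-space auditory MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spnpipe)
```

## The scientific problem

Vowels are acoustic patterns: a set of spectral peaks (formants) riding on a
common periodic amplitude envelope (the fundamental frequency, f0, perceived
as pitch). When the auditory cortex detects such a pattern it produces a
*sustained processing negativity* (SPN): a negative shift of source current,
beginning before 100 ms after sound onset and lasting several hundred
milliseconds, measured as the difference between responses to a patterned
test sound and a control sound with neither periodicity nor formant
constancy. `spnpipe` implements an end-to-end analysis of this response in
source-space MEG for a two-group (typically developing vs autism spectrum
disorder) child cohort, together with its linkage to words-in-noise (WiN)
performance: stimulus synthesis, a synthetic cohort generator, source
timecourse conditioning, spatiotemporal threshold-free cluster enhancement
(TFCE) permutation statistics, most-significant-source timecourse analysis,
the adjusted SPN measure (SPNadj), P3a-like peak detection, and the
subject-level statistics (partial correlations, Fisher Z comparisons,
Benjamini-Hochberg FDR).

Everything downstream of source estimation is in scope; MEG acquisition,
artifact suppression, head modelling and the inverse solution are upstream of
this pipeline, which starts from per-subject source-current timecourses.

## Stimuli

Four stimulus classes are synthesized as sums of four formant trains of
damped sinusoids over 812 ms with 10 ms raised-cosine ramps:

* **periodic vowel** — pulses on an exact 12 ms grid (f0 = 83.3 Hz), carrier
  fixed at the vowel's formant frequencies;
* **non-periodic vowel** — onsets jittered i.i.d. uniformly within ±6 ms per
  pulse and formant;
* **periodic non-vowel** — 12 ms grid, but every pulse's carrier drawn from a
  per-formant set of eight candidate frequencies;
* **non-periodic non-vowel** — both manipulations; the control condition.

Choices where the acoustic construction is not fully determined:

* *Damping constant.* The decay of each damped sinusoid is exponential with a
  3 ms half-life (a quarter period): pulses decay essentially fully before
  the next onset while keeping clear formant peaks. Configurable via
  `stimulus_spec(half_life = )`.
* *Formant table.* Formant centre frequencies for /a e i o u/ follow a
  standard adult-male table, clipped into the per-formant randomization bands
  (F1 270--1300, F2 850--2260, F3 1750--3000, F4 3300--5500 Hz); fully
  configurable.
* *Randomization set.* The eight candidate carriers per formant are
  log-spaced across each band (membership of the original set is not
  recoverable); configurable via `stimulus_spec(carrier_sets = )`.
* *Jitter convention.* Jitter is drawn independently per pulse and per
  formant; jittered onsets are clipped to the stimulus window rather than
  wrapped. Pulse phase at onset is 0.
* The full 812 ms train is synthesized directly (no concatenation seam), at
  44100 Hz.

The WiN maskers are 1 s of pink noise (PSD slope -3 dB/octave), stationary
(ST) or amplitude-modulated (AM) by a 10 Hz sinusoid starting at phase 0,
with 1 ms edge smoothing; the masker starts 75 ms before word onset and its
RMS realizes the requested SNR against a unit-RMS word.

## The synthetic cohort generator

The generator (`cohort_config()`, `simulate_evoked()`,
`simulate_win_behavior()`) defines the study conditions under which every
downstream guarantee is tested. Per subject and condition each vertex trace
is

> subject gain x regional gain x [ P100m bump + sustained plateau
> (+ P3a bump) ] + smoothed noise,

with these defaults (arbitrary source-current units):

| parameter | default | meaning |
|---|---|---|
| `n_td`, `n_asd` | 39 / 35 | group sizes |
| `epochs_mean` | 231 (range 130--350) | averaged epochs per condition; noise SD scales as `noise_sd0 / sqrt(n_epochs)` |
| `p100_amp`, `p100_lat` | 25 a.u., 100 ms (SD 20 ms) | positive P100m transient |
| `sustained_amp` | -14 / -13 / -12 / -8 | plateau amplitude for periodic vowel / non-periodic vowel / periodic non-vowel / control; differential responses are -4 to -6 a.u. |
| `sustained_rise`, `sustained_fall` | 60--140 ms, 600--750 ms | raised-cosine onset (negativity present before 100 ms) and decay |
| `region_gain` | A1 1, A4 0.85, pINS 0.7, other STG+ 0.6, outside 0.05 | auditory responses concentrate in the STG+ band |
| `deficit_mean`, `deficit_sd` | 0.45, 0.25 (truncated at 0) | per-subject fraction of the vowel-specific increment lost in ASD |
| `deficit_regions`, `deficit_window` | A4 + pINS, 150--450 ms (10 ms edges) | where and when the group deficit lives |
| `p3a_amp`, `p3a_lat` | 6 a.u., 300 ms (SD 45 ms) | left-hemisphere positive bump for vowel conditions; scaled x1.6 in ASD for periodic vowels |
| `noise_sd0` | 20 | trace SD about 1.3 a.u. at 231 epochs |
| `noise_smooth_ms` | 8 | Gaussian temporal autocorrelation length of the noise |

Sizing rationale, chosen once: the deficit magnitude (45% of the vowel
increment) and its spread put the window-mean group effect near Cohen's
d of about 1 and the per-point group t near 3.5 at the full cohort size, i.e.
an effect that is clearly detectable yet of the same order as the group
effects such cohorts produce; the behavioral link (`beta_spn_am = -0.25`
logits per latent-SPN unit, AM noise only) yields a partial Spearman
correlation near -0.5 at n = 26. The psychometric slope (0.45 logits/dB)
places the -9 dB stationary-noise condition at the floor for roughly half
the subjects, the reason that condition is excluded from the WiNst/WiNam
summaries. The 160-word inventory contains 10 over-easy and 8 over-hard
words, so the default exclusion thresholds (pooled accuracy > 0.95 at the
hardest retained SNR, or < 0.05 at the easiest) remove 18 words. Each
subject hears every word exactly once in one random (SNR x noise type) cell,
as in the testing procedure the scores are modelled on; unassigned cells are
missing values.

What the generator deliberately does **not** emulate: realistic cortical
geometry (a planar grid per hemisphere stands in for the mesh), spatially
correlated noise and inverse-solution point spread (noise is independent
across vertices), 1/f MEG noise spectra (the noise is Gaussian with a
single temporal correlation length), condition-correlated single-trial
variability, and any lexical structure in the WiN task beyond per-word
difficulty. Passing tests therefore demonstrate that the *statistics and
estimators* behave as claimed under a known ground truth -- not that the
generator reproduces real MEG data.

## Preprocessing

Source orientations on a folded cortex are sign-ambiguous.
`align_polarity()` chooses per-vertex sign flips, per subject and
hemisphere, from the leading left singular vector of the condition-averaged
vertex-by-time matrix; the remaining global sign is fixed by requiring the
ROI-mean 50--150 ms (P100m) window to be positive. The singular-vector rule
was preferred over flipping by correlation with the ROI mean because it is
*exactly idempotent* (flips computed on already-aligned data are all +1),
while iterated correlation flipping changes the reference as it flips. After
alignment the 300--800 ms ROI mean is checked for negativity; subjects
failing either window are reported in the `"flagged"` attribute, never
silently accepted.

`baseline_crop_resample()` subtracts the per-trace mean over -200--0 ms
(half-open), applies a zero-phase 4th-order Butterworth anti-alias filter at
`0.4 * fs_out`, and decimates to the half-open analysis window (default
0--800 ms at 500 Hz, 400 samples). Time conventions throughout: half-open
intervals, milliseconds, 0-based sample times.

## TFCE and its permutation tests

For a statistic map h(p) over vertices x time, TFCE integrates
`e(h)^E * h^H` over thresholds, with E = 0.5, H = 2, start h0 = 0 and step
dh = 0.4; `e(h)` is the extent of the supra-threshold (`stat >= h`)
spatiotemporal connected component containing p (spatial neighbours at the
same sample, plus the same vertex at adjacent samples; components never span
hemispheres). Numerical conventions:

* the integral is a left-Riemann sum at `h0 + k*dh` up to the map maximum,
  plus a final partial step of width `max - h_last` at the maximum itself;
* two-sided maps are enhanced separately per sign and recombined with sign;
* the C++ core processes thresholds in descending order with an incremental
  union-find and offset-carrying path compression, and is checked against a
  literal threshold-loop + flood-fill oracle to 1e-10 in the tests.

The one-sample test (test-minus-control difference maps) builds its null by
random whole-subject sign flips -- enumerated exhaustively when `2^n` does
not exceed the requested permutation count -- and the two-sample test
(group comparison of differential responses, pooled-variance t) by label
shuffling. Hemispheres are processed disjointly with a shared permutation
schedule. The corrected p-value of a point is the proportion of permutations
whose maximum |TFCE| *anywhere in the analysed map* reaches that point's
observed |TFCE| (with the `>=` tie convention and the `(1 + b)/(1 + m)`
estimator, so p is never 0). Correcting within each hemisphere separately
would double the family and inflate the family-wise error to about 10%; the
combined max-statistic null keeps it at the nominal 5%, which the test suite
verifies on 200 null cohorts. A pointwise exceedance variant is available
behind `tfce_params(p_type = "pointwise")` for comparison; the max-statistic
rule is the default because only it provides family-wise control.

## Post-cluster analysis

`select_most_significant_sources()` takes, per hemisphere, the significant
cluster with the largest total enhanced mass, restricts it to the STG+
auditory band, averages each source's corrected p over the cluster's full
temporal extent (one shared extent, not per-source extents), and keeps
sources strictly below the cluster-wide mean of those averages. Ties (all
averages equal) therefore select nothing -- the degenerate case is
documented rather than patched. Per-source group contrasts
(pointwise Welch t, Benjamini-Hochberg across the 400 timepoints, p < 0.05)
yield maximal significant runs; the group-difference window is the mean of
per-source first and last significant times. The pipeline requires runs of
at least 5 samples (20 ms at 250 Hz, about 2.5 noise correlation lengths):
with temporally smoothed noise, isolated FDR survivors come in runs of 2--4
samples and would otherwise drag the window ends outward; the default of the
standalone functions remains 1 sample.

SPNadj is the residual of the per-subject test-condition window mean after
ordinary least squares on the control-condition window mean and the square
root of the mean epoch count, fitted within the sample entering the
subsequent correlation (the ASD subsample), so the residuals are exactly
orthogonal to both nuisance variables in that sample.

## P3a-like detection

Traces (including the baseline) are low-passed at 10 Hz (zero-phase
4th-order Butterworth; reflection-padded filtering). The candidate peak is
the largest local maximum in 200--400 ms; its amplitude is the peak minus
the mean of the nearest local minima before and after (searched in 0--800
ms; a side with no local minimum falls back to that side's minimum value).
The peak counts as present only when *both* peak-to-minimum margins reach
the trace's noise floor, taken as the RMS of the raw (unfiltered) baseline
about its mean. Computing the floor on the *filtered* baseline would make
margins and floor scale identically and pin the pure-noise false-detection
rate near 50%; the raw-baseline floor keeps the comparison "low-passed peak
vs full-band noise", preserves invariance to constant offsets, and gives
the detector sensitivity >= 0.9 at false-detection <= 0.1 on constructed
traces.

## Subject-level statistics

The normality-gated comparison runs Shapiro-Wilk on both samples and picks
Mann-Whitney (tie-corrected normal approximation, with Z and eta^2 = Z^2/N)
when either deviates at p < 0.05, otherwise the t-test. Partial correlations
are residual-residual correlations (rank-transformed first for Spearman),
with t on n-2-k degrees of freedom; a variable fully explained by the
covariates yields r = 0 rather than an error, while collinear covariates are
an error. Fisher Z comparisons use the standard independent-samples formula
and Steiger's statistic for dependent overlapping correlations. The
Group x Type interaction uses a seeded permutation test on per-subject
AM-minus-ST difference scores, which is exactly the random-intercept
interaction for two within-subject levels; a full mixed-model fit is out of
scope. Benjamini-Hochberg decisions use the step-up rule (reject at adjusted
p <= q). The 2x2 occurrence chi-square is Pearson's without continuity
correction.

## Problem sizes and calibration experiments

The packaged experiments run at desk scale, chosen as the smallest sizes at
which each claim is still a meaningful Monte-Carlo statement:

* *Family-wise error*: 500 null cohorts (10 + 10 subjects, links and
  condition differences zeroed), 50 vertices/hemisphere, 25 Hz analysis
  rate (a 100 x 20 spatiotemporal map), 500 permutations; both tests must
  land in 0.05 +/- 0.03. Calibration under exchangeability is
  size-independent, so the coarse map only reduces compute; the replicate
  count keeps the Monte-Carlo error of the estimate (SE ~ 0.01) well inside
  the band.
* *Deficit recovery*: 50 cohorts at the full 39 + 35 size, 250 Hz, 500
  permutations, non-periodic vowel condition (whose P3a term has no group
  scaling, so the only group difference is the injected deficit): the
  deficit must be detected with the recovered window within +/-30 ms of
  150--450 ms in >= 80% of replicates, and the selected sources must stay
  inside A4/pINS in >= 90%. The window is computed from the selected
  sources of both hemispheres pooled.
* *Behavioral linkage*: 100 cohorts of 26 ASD subjects; the WiNam partial
  Spearman correlation (controlling age and IQ) must recover the negative
  sign in > 90% of replicates while the WiNst correlation stays at the
  nominal rejection rate.

The full-scale profile (`pipeline_config(profile = "full")`) uses 5000
permutations.

## Known limitations

* The surrogate source space is a planar grid; adjacency-driven behaviour on
  a real cortical mesh (variable vertex degree, curvature) is not exercised.
* Independent vertex noise understates the spatial spread of real
  inverse-solution noise, so the spatial specificity measured here is
  optimistic relative to real data.
* The permutation engine holds the whole subject-by-point matrix in memory;
  at the full 4098-vertices-per-hemisphere resolution a run is possible but
  slow on one core.
* The WiN model treats words as exchangeable given a scalar difficulty; no
  phonetic structure links specific words to the SPN.
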