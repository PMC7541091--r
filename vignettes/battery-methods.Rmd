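---
title: "Methods: adaptive psychoacoustics, simulated listeners, and test-retest analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive psychoacoustics, simulated listeners, and test-retest analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audbattery)
```

# What the package models

`audbattery` is a simulation and analysis toolkit for a battery of ten
suprathreshold auditory assessments of the kind used to probe central
auditory function beyond the audiogram: three temporal-fine-structure tests
(temporal gap detection, diotic and dichotic frequency-modulation
detection), three modulation-sensitivity tests (temporal, spectral, and
spectro-temporal modulation detection in broadband noise), two tone-in-noise
tests (a 2-kHz tone masked by noise with and without a spectral notch), and
two speech-on-speech tests (keyword identification with colocated or
spatially separated maskers, whose difference is the spatial release from
masking).

The package contains everything needed to exercise such a battery end to
end without human listeners: calibrated stimulus synthesis, the adaptive
procedures, parametric simulated observers, a session runner, a two-session
synthetic cohort generator, and the reliability pipeline (Bland-Altman
limits of agreement, paired statistics, composite z-scores, Cronbach's
alpha).

# The adaptive procedure

Eight of the ten assessments adjust a single stimulus parameter with a
two-stage, two-down one-up transformed staircase with unequal step sizes.
After two consecutive correct responses the parameter takes one "down" step
toward harder; after any error it takes one "up" step toward easier, with
the up step larger than the down step by a ratio $r$ (2:1 in the standard
condition, 1.5:1 in the headphone/noise-styled conditions). On the
exponential scale the steps are multiplicative and the ratio acts on the
exponent (up factor $=$ down factor$^r$); on the linear (dB) scale it acts
additively. Stage 1 uses large steps until the third reversal; stage 2 uses
steps 1/5 the size (exponent 1/5 on the exponential scale) and ends the
track at its sixth reversal. The threshold is the geometric mean of the six
stage-2 reversal values, in the parameter's native units, for every
staircase assessment regardless of scale.

The drift-balance equilibrium of this rule is where the expected step
displacement vanishes. A down-move requires two consecutive correct
responses (probability $p^2$ per renewal), so
$p^{*} = \left(\frac{r}{1+r}\right)^{1/n}$ for an $n$-down/1-up rule, giving
81.65% correct for $n=2, r=2$, 77.46% for $n=2, r=1.5$, and 79.37% for a
3-down/1-up rule with equal steps. `convergence_target()` evaluates this
closed form and the Monte-Carlo drift-balance property is tested against a
constant-probability responder.

**Reversal-value convention.** Whether the logged reversal value is the
parameter value *before* or *after* the direction-changing step is not fixed
by the procedure description and materially affects short tracks. We ran a
sensitivity study over the four combinations of {stage-switch timing} x
{pre/post-step logging} with simulated logistic observers: with only six
stage-2 reversals, pre-step logging biases the percent-correct at the mean
estimated threshold 1.5-2.5 percentage points below the asymptotic target,
while post-step logging (the value the track turns back from) realizes the
asymptotic target within a percentage point. The package therefore logs
post-step values; with many reversals the two conventions agree to within
one stage-2 step.

The speech-on-speech tests instead use a fixed 20-trial progressive track:
the target stays at 65 dB SPL while the two maskers rise from 55 to
73 dB SPL in 2-dB steps every two trials, two trials at each of ten
target-to-masker ratios (TMR, +10 dB down to -8 dB). The TMR threshold is
$10 - (\text{number correct})$ dB, so all-incorrect scores +10 and
all-correct -10; spatial release is the colocated-minus-separated threshold
difference, spanning -20 to +20 dB.

# Stimulus synthesis

All synthesizers emit calibrated stereo buffers at 44.1 kHz; a single
calibration offset maps digital RMS to dB SPL (default: 0 dBFS RMS maps to
100 dB SPL, which keeps the battery's 45-80 dB SPL levels at least 20 dB
below full scale). Level-setting is pure scaling and fails rather than
clips, because silent saturation would corrupt modulation depths.

Choices the procedure descriptions leave open, fixed once here:

* **Ramps.** The 4-ms gap-test tone bursts carry full raised-cosine (Hann)
  envelopes; all other stimuli get 10-ms raised-cosine on/off ramps. This
  limits spectral splatter without materially changing the nominal
  durations.
* **Gap definition.** The gap is measured between the zero-envelope offset
  of burst 1 and the onset of burst 2, which makes a 0-ms gap two contiguous
  bursts (8 ms total).
* **FM.** The instantaneous frequency is
  $f(t) = f_c + d\sin(2\pi \cdot 2\,t + \varphi_0)$ with the carrier drawn
  uniformly from 460-550 Hz per stimulus (so the task cannot be solved by a
  pitch cue) and $\varphi_0$ drawn per stimulus to prevent onset-phase cues.
  The dichotic variant sign-inverts the modulator in the right ear, sweeping
  the interaural phase difference at the 2-Hz rate.
* **Modulated noise.** The carrier is flat-spectrum noise over 0.4-8 kHz
  built in the frequency domain from every FFT bin in band (the maximum
  component count the sampling rate allows) with Rayleigh amplitudes and
  uniform phases. Modulation is a per-component gain on the logarithmic
  amplitude scale, $G(t,x) = M \sin(2\pi(f_m t \pm \Omega x) + \varphi)$ dB
  with $x = \log_2(f/400\,\mathrm{Hz})$, so the depth $M$ is mid-to-peak by
  construction. Temporal-only modulation is applied as a time-domain dB
  envelope and spectral-only modulation as static per-component gains (both
  algebraically identical to the general per-component form); joint
  spectro-temporal modulation uses a compiled per-component sum. The ripple
  drifts upward or downward in frequency according to the trial's assigned
  direction.
* **Notched noise.** The masker is 10,000 sinusoids with log-uniform
  frequencies (split across the two notch flanks in proportion to their
  logarithmic widths) and per-component power proportional to $1/f$,
  yielding the -3 dB/octave power slope; the notch band 1.6-2.4 kHz contains
  no components at all. The 2-kHz, 45-dB SPL target is synthesized
  separately so trial assembly can mix it into any interval.
* **Speech-on-speech audio is schematic.** The coordinate-response-measure
  speech corpus and HRTF spatialization are external assets; SRM trials are
  represented as structured records (call sign, color/number keywords from
  the 4 x 8 grid, levels, azimuths 0 or +/-45 degrees) with labelled
  tone-complex placeholder audio. All psychometric behaviour on these tests
  enters through the observer model in TMR.
* **Regeneration.** Stimulus noise is drawn fresh per call (per trial),
  matching between-trial stimulus generation.

Fidelity is verified by measurement oracles that avoid the synthesis code:
instantaneous frequency from the analytic signal for FM depth and IPD,
short-window dB envelopes for temporal depth, per-bin spectra for spectral
depth, band power for the notch, and octave-band power for the masker
slope.

# Simulated observers

An observer answers two-cue 2AFC trials through a logistic psychometric
function on the track's adaptation domain ($\log_2$ of the native parameter
for exponential tracks, dB for linear ones):
$p(x) = \gamma + (1-\gamma-\lambda)F\!\big(\delta(x-\alpha)/\beta\big)$,
with guess rate $\gamma$ (0.5 for 2AFC, 1/32 for the keyword grid), lapse
rate $\lambda$ (default 0.02; 0 in analytic tests), and $\delta = \pm 1$
encoding whether larger parameter values are easier (gap, depth, TMR) or
harder (masker level). The logistic on the adaptation domain matches the
multiplicative step geometry of the exponential tracks. `observer_point()`
inverts the function analytically, which places a track's convergence point
for a known observer; parameter-recovery tests verify that simulated-track
thresholds land on it across a wide threshold range.

# Analysis pipeline

Native thresholds are transformed for analysis: log2 units for the
temporal-fine-structure tests, TMR (45 dB SPL target level minus masker
level) for the tone-in-noise tests, and pass-through for modulation depths
and speech TMRs. Modulation depths measured mid-to-peak on the log-amplitude
scale convert to the older $20\log_{10} m$ convention through
$20 \log_{10}\!\big((10^{M/10}-1)/(10^{M/10}+1)\big)$, a strictly
increasing, always-negative map verified against a brute-force envelope
oracle to 1e-9. Because the map is concave, converting a cohort's mean depth
always yields a value at or above the mean of the per-subject conversions
(a Jensen gap), so the two orders of operation are both provided and must
not be mixed when comparing cohorts.

Outlier rejection is a single pass per assessment and condition: values
deviating more than 3 sample SDs from the mean (computed with the candidate
included) are excluded; a value at exactly 3 SD is kept. The pass is
deliberately not iterated, since re-estimating the SD after exclusion would
change counts.

Test-retest agreement uses Bland-Altman limits of agreement: the bias is
the mean session-2-minus-session-1 difference (negative = improvement for
threshold-type measures), the 95% limits are bias +/- 1.96 SD of the paired
differences, and the same pairs yield the Pearson correlation, paired
t-test, and paired Cohen's d (bias / SD of differences; chosen as the
consistent companion of the paired t). Composite scores z-score each
assessment against its own mean and SD, average the z-scores per subject,
and summarise internal consistency with Cronbach's alpha; the ten
assessments (not the derived spatial-release metric) feed the composite.
P-values are two-sided and uncorrected.

# The synthetic cohort

`cohort_presets()` fixes the generative model: per assessment, subject
thresholds are Normal(mean, between-SD) in analysis units, sessions add
Normal(0, within-SD) noise plus a systematic session-2 shift, and an
equicorrelated general-ability factor (default correlation 0.3) links the
ten assessments. The preset means, spreads, session shifts, and
reliability-implied between/within split are shaped to resemble a young
normal-hearing cohort so that default simulations look like real normative
data; they are presets for simulation, not empirical claims. Optional
outlier contamination displaces a randomly chosen session by more than 3
between-subject SDs, mimicking inattentive single sessions.

Two measurement models are provided. `"direct"` reports the session's true
threshold location, so the within-subject SD is exactly the measurement
spread - this is the mode used to validate the reliability pipeline
(injected session bias is recovered within its own confidence interval, and
the limits-of-agreement width matches $2 \times 1.96 \times \sqrt{2}\sigma$).
`"tracks"` runs the full battery - screening, practice, shuffled blocks,
staircases and progressive tracks - per subject and session with observers
whose convergence points sit at the session's threshold, adding realistic
adaptive-track estimation noise on top.

What the generator does *not* emulate: learning curves within a session,
attention drift, headphone or room acoustics, non-Gaussian threshold tails,
or any dependence of lapse rate on difficulty. Passing recovery tests
therefore shows the pipeline's statistics are correct, not that real
listeners behave this simply.

# Numerical choices and problem sizes

* Staircase starts: the published values (gap 20 ms; FM 6 and 3 Hz; masker
  35 dB SPL). The modulation tests' start depth is not published; 6 dB is
  used - clearly suprathreshold against ~1-1.5 dB typical thresholds and
  nine stage-1 steps above them.
* Practice trials are presented at the start value stepped four stage-1
  up-steps easier, clamped to the bounds - reproducibly easy without being
  degenerate.
* Target-interval assignment is uniform over positions 2 and 3.
* Convergence checks use 500 simulated tracks; reliability recovery uses
  200 replicate cohorts of 150 subjects in direct mode; track-level cohort
  tests use small cohorts (3-20 subjects). These sizes give Monte-Carlo
  error comfortably inside the asserted tolerances while keeping the full
  suite fast.
* Degenerate inputs fail loudly: silent buffers and clipping in
  level-setting, zero-variance composite columns (named in the error),
  unfinished tracks, nonpositive values under log transforms (excluded with
  a reason), and out-of-range adaptive parameters.

# Known limitations

* Observers respond to the trial's nominal parameter value, not to the
  rendered audio; stimulus fidelity and psychometrics are verified
  separately, so a defect that changed the audio without changing the
  parameter would not alter simulated thresholds.
* The spatial speech task is modelled at the TMR/keyword level only.
* The staircase reversal-logging convention is fixed to post-step values
  (see above); published thresholds obtained under a pre-step convention
  would differ by a fraction of one stage-2 step.
* Cronbach's alpha and the between-assessment correlation structure depend
  entirely on the preset shared-ability factor; the default 0.3 is a
  plausible, not an estimated, value.
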