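# audbattery

Simulation and analysis of a suprathreshold auditory psychophysics battery
in R.

Clinical audiometry measures audibility; it says little about the central
auditory abilities — temporal fine structure coding, spectro-temporal
modulation sensitivity, hearing a target in competition — that drive
real-world listening complaints in people with normal audiograms.
Portable tablet-based batteries of rapid adaptive tests address this, but
validating their procedures (do the staircases converge where theory says?
is a 20-trial progressive track scored correctly? how reliable is a
two-session protocol?) requires running the whole pipeline many times,
which is impractical with human listeners. `audbattery` implements such a
battery end to end with *simulated* listeners: calibrated stimulus
synthesis, the adaptive procedures, parametric psychometric observers, a
session runner, a synthetic two-session cohort generator, and the
test-retest reliability analysis.

The package is for hearing scientists and psychometricians who want to
study or extend this class of test battery: to verify procedure
implementations against closed-form targets, to power-analyse test-retest
designs, or to prototype analysis pipelines on realistic synthetic cohorts.

## The battery

Ten assessments in three families, each a two-cue two-alternative
forced-choice task (four intervals; the first and last are standards, the
target hides in interval 2 or 3) unless noted:

| family | assessments | adaptive parameter |
|---|---|---|
| temporal fine structure | temporal gap, diotic FM, dichotic FM | gap (ms), modulation depth (Hz) |
| modulation sensitivity | TM (4 Hz), SM (2 cyc/oct), STM (both) | log-scale depth *M* (dB) |
| targets in competition | tone in noise (no-notch, notch), speech-on-speech (colocated, separated) | masker level (dB SPL); fixed TMR schedule |

The staircase assessments use a two-stage two-down one-up rule with
unequal steps (up:down ratio *r* of 2:1 or 1.5:1); the threshold is the
geometric mean of the six second-stage reversals. The rule's asymptotic
target is the drift-balance equilibrium

> p\* = (r / (1 + r))^(1/n)

— 81.7% correct for 2-down/1-up with 2:1 steps, 77.5% for 1.5:1, versus
79.4% for a classic 3-down/1-up with equal steps. The speech tests use a
20-trial progressive track over ten target-to-masker ratios (+10 … −8 dB)
scored as `10 − n_correct` dB; colocated-minus-separated thresholds give
the spatial release from masking. Test-retest agreement is summarised with
Bland-Altman limits of agreement (bias ± 1.96 SD of session differences),
paired statistics, and composite z-scores with Cronbach's α.

## Worked example

```r
library(audbattery)

convergence_target(2, 2)        # asymptotic % correct, 2-down/1-up, 2:1 steps
#> [1] 81.64966

## one adaptive track on a simulated listener (thresholds in native Hz)
set.seed(42)
cfg <- staircase_config("exponential", start = 6, step1 = 2^(1/2),
                        minimum = 0, maximum = 10000)
obs <- simulated_observer(alpha = 1, beta = 0.5, lambda = 0.02,
                          scale = "exponential")
res <- simulate_track(obs, cfg)
res$threshold                   # geometric mean of the 6 stage-2 reversals
#> [1] 2.93148
nrow(staircase_history(res$track))   # trials to completion
#> [1] 39

## a two-session synthetic cohort through the reliability pipeline
set.seed(7)
dataset <- simulate_study(cohort_config(n_subjects = 80), mode = "direct")
report  <- test_retest_report(to_analysis_units(dataset))
report
#> Test-retest reliability report
#>     assessment   bias loa_low loa_high     units    r     t     d df
#>    dichotic_fm  0.114   -1.97     2.19 log2 (Hz) 0.55  0.96  0.11 79
#>      diotic_fm -0.097   -1.63     1.44 log2 (Hz) 0.48 -1.11 -0.12 79
#>            gap -0.119   -3.35     3.11 log2 (ms) 0.42 -0.65 -0.07 79
#>       no_notch -1.531   -5.90     2.84  TMR (dB) 0.40 -6.14 -0.69 79
#>          notch -0.118   -7.41     7.17  TMR (dB) 0.41 -0.28 -0.03 79
#>             sm -0.210   -1.72     1.30    M (dB) 0.56 -2.43 -0.27 79
#>  srm_colocated -0.287   -4.77     4.20  TMR (dB) 0.39 -1.12 -0.13 79
#>  srm_separated -0.839   -5.95     4.28  TMR (dB) 0.69 -2.87 -0.32 79
#>            stm -0.047   -1.34     1.24    M (dB) 0.30 -0.64 -0.07 79
#>             tm -0.100   -1.48     1.28    M (dB) 0.59 -1.27 -0.14 79
#>      composite -0.170   -0.84     0.50         z 0.73 -4.44 -0.50 79
#> Composite Cronbach's alpha: 0.68
```

Reading the report: `bias` is the mean session-2-minus-session-1
difference in analysis units (negative = better second-session thresholds),
`loa_low`/`loa_high` bound the region holding ~95% of within-subject
session differences, and the composite row shows that averaging z-scores
across the ten tests is more reliable (r = 0.73) than any single test —
the expected behaviour when a shared ability links the assessments.

Stimuli can be rendered to WAV (`synth_gap()`, `synth_fm()`,
`synth_modulated_noise()`, `synth_notched_noise()`, `write_wav()`), or from
the shell via `inst/scripts/synth-stimulus.R`; a full cohort simulation CLI
is in `inst/scripts/simulate-cohort.R`.

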