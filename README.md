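# rhythmtag

EEG frequency-tagging analysis of neural entrainment to musical rhythm,
with a ground-truth synthetic-EEG generator.

When a listener hears a rhythm built from isochronous 333 ms slots, the
EEG develops steady-state evoked potentials (SS-EPs): narrow spectral
peaks at the 3 Hz beat frequency and at the meter frequencies produced by
perceptual grouping of beats — duple 3/2 = 1.5 Hz, triple 3/3 = 1 Hz,
quadruple 3/4 = 0.75 Hz. Because these frequencies are imposed by the
stimulus, entrainment can be quantified directly from the amplitude
spectrum of trial-averaged EEG. `rhythmtag` implements the full chain used
in infant rhythm-entrainment studies:

* **Stimuli** — six-beat ambiguous (`x.xxx.`) and twelve-slot quadruple
  rhythm patterns, pure-tone synthesis with 10 ms ramps, analytic-signal
  (Hilbert) envelopes, amplitude-calibrated envelope spectra, and
  automatic derivation of the stimulus-present / stimulus-absent
  frequency sets.
* **Synthetic cohorts** — multi-channel recordings containing
  trial-locked sinusoidal SS-EPs, a slow frontal ERP transient ~175 ms
  after each tone, 1/f background noise and artifact bursts, with
  per-subject group structure (music classes, parent music training) and
  full ground truth.
* **Preprocessing** — zero-phase 0.5–20 Hz Butterworth filtering,
  resampling to 200 Hz, threshold-based artifact attenuation,
  common-average referencing, per-epoch baseline-corrected trial
  averaging.
* **SS-EP extraction** — per-channel FFT, noise-floor subtraction using
  the mean of the bins at ±3–5 bin offsets, channel averaging, 3-bin peak
  picking, noise-floor statistics, z-score outlier screening.
* **ERP analysis** — tone-locked epochs (−100 to 300 ms), frontal channel
  groups by hemisphere, grand-average peak latency, ±50 ms area under the
  curve.
* **Statistics** — paired t with Bonferroni correction, mixed-design
  ANOVA with Greenhouse–Geisser correction (`tidy()`/`glance()`
  methods), Pearson correlations, and a one-call cohort report.

Results are tibbles throughout and chain with the pipe; result types have
`autoplot()` methods.

## Worked example

Simulate a scaled-down two-group cohort in which infants enrolled in music
classes have selectively larger duple-meter (1.5 Hz) SS-EPs, then run the
full analysis:

```r
library(rhythmtag)

fs <- frequencies_of_interest(
  stimulus_spectrum(pattern_sixbeat(), repetitions = 17))
fs
#> <frequency_set>
#>   beat:    3 Hz
#>   meter:   duple 1.5 Hz, triple 1 Hz, quadruple 0.75 Hz
#>   present: 1, 1.5, 2, 2.5, 3
#>   absent:  0.75, 1.25, 1.75, 2.25, 2.75

cfg <- cohort_config(
  "exp1", seed = 42, n_trials = 2L, n_channels = 8L, rate_hz = 500,
  erp_amp_uv = 0, noise_level_uv = scaled_noise_level(20, 2, 8),
  groups = list(
    list(name = "music_class", n = 8L, music_classes = TRUE,
         parent_trained = FALSE),
    list(name = "no_class", n = 8L, music_classes = FALSE,
         parent_trained = FALSE)))

cohort <- simulate_cohort(cfg, process = function(rec, truth, meta) {
  pre <- preprocess_recording(rec)
  avg <- epoch_average(pre, trial_onsets(pre), 0, 33000, 900, 1000, 1000)
  ssep_subject(avg, fs, subject_id = meta$subject_id)
})
tb <- dplyr::left_join(cohort$meta,
                       purrr::map_dfr(cohort$subjects, \(s) s$result),
                       by = "subject_id")

rep <- build_report(tb, related_hz = c(1, 1.5, 3),
                    between = "music_classes")
dplyr::select(rep$anova_group_by_freq, effect, F, df1_gg, df2_gg, p_gg)
#> # A tibble: 3 × 5
#>   effect          F df1_gg df2_gg     p_gg
#>   <chr>       <dbl>  <dbl>  <dbl>    <dbl>
#> 1 between      1.74   1      14   2.09e- 1
#> 2 within      36.6    3.09   43.3 4.41e-12
#> 3 interaction 11.2    3.09   43.3 1.26e- 5
rep$flags
#> # A tibble: 1 × 2
#>   interaction_significant duple_contrast_significant
#>   <lgl>                   <lgl>
#> 1 TRUE                    TRUE
```

The group × frequency interaction is significant with
Greenhouse–Geisser-corrected degrees of freedom, and the Bonferroni
post-hoc contrast localizes the group difference to the 1.5 Hz duple bin
(t(14) = 9.58: simulated music-class mean 0.83 µV vs 0.44 µV), with no
other tagged frequency flagged — i.e. the analysis recovers exactly the
selective effect that was built into the cohort.

`run_pipeline(run_config("exp1", ...), out_dir)` wraps the same chain (plus
the ERP stage and report CSVs) into a deterministic run directory with a
manifest; `inst/cli/rhythmtag.R` is a thin command-line wrapper around it.

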