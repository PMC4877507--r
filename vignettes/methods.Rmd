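---
title: "Frequency-tagged EEG analysis of rhythm entrainment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged EEG analysis of rhythm entrainment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

When a listener hears a periodic rhythm, neural populations entrain to the
stimulus: the EEG develops narrow-band components — steady-state evoked
potentials (SS-EPs) — at exactly the frequencies the stimulus imposes. For a
rhythm built from 333 ms slots (180 beats per minute) the beat frequency is
3 Hz; perceptual grouping of beats into twos, threes or fours adds *meter*
frequencies at 1.5, 1 and 0.75 Hz. Because these frequencies are known in
advance, stimulus-driven activity can be read directly off the EEG amplitude
spectrum — the *frequency-tagging* approach. The package implements that
analysis end to end for infant-style recordings, together with a transient
event-related potential (ERP) analysis of the slow frontal positivity evoked
by individual tones, and the group statistics used to relate both measures
to a cohort's musical background.

No public infant dataset accompanies this problem, so the package also
contains a first-class synthetic-EEG generator with known ground truth.
Every stage of the chain is validated against that ground truth; what such
validation does and does not establish about real infant data is discussed
at the end.

## Stimuli

A `rhythm_pattern()` is an ordered vector of binary slots at a common
inter-onset interval (IOI), a carrier frequency and a linear ramp time.
Two presets are provided:

* `pattern_sixbeat()` — `x.xxx.` over six 333 ms slots (2 s): a
  metrically ambiguous rhythm, interpretable as duple (1.5 Hz) or triple
  (1 Hz) grouping of the 3 Hz beat.
* `pattern_twelvebeat()` — `xxxxx.xxxx..` over twelve slots (4 s): an
  unambiguous quadruple-meter rhythm (0.75 Hz). Only the periodicity
  structure of this arrangement matters for the analysis; it was chosen so
  that every 0.25 Hz envelope harmonic between 0.75 and 3 Hz carries
  energy and so that the first slot is a tone following a silence. Any
  12-slot arrangement can be supplied instead.

Two IOI conventions are supported because 333 ms and 1/3 s differ at the
millisecond level over long sequences: the default is the exact 1/3 s slot
(180 bpm exactly, so the twelve-slot pattern lasts 4 s), with the literal
0.333 s print convention (3.996 s) available via `ioi_seconds = 0.333`.

`synthesize()` renders tones as linearly ramped sinusoids (990 Hz, 10 ms
rise/fall by default). The carrier phase is continuous across adjacent tone
slots by default, so runs of tones merge smoothly; a `reset` mode restarts
the phase at each slot. Because each slot is ramped independently, the
amplitude envelope dips to zero at every slot boundary either way, which is
what puts (weak) energy at the 3 Hz beat frequency itself.

The envelope is extracted as the modulus of the analytic signal
(`hilbert_envelope()`, frequency-domain construction), decimated to the
200 Hz analysis rate shared with the EEG, and Fourier-transformed with an
amplitude-calibrated single-sided spectrum: a sinusoid of amplitude A on an
exact bin reports amplitude A, and the resolution is the reciprocal of the
window duration. `frequencies_of_interest()` then scans the 0.5–3 Hz band
for bins exceeding 2% of the in-band maximum. That threshold is derived
from the harmonic structure of the two patterns: the weakest harmonic that
must be detected (the ramp-borne 3 Hz component of the six-beat envelope,
and the 2.75 Hz harmonic of the twelve-slot envelope) sits at 5–9% of the
maximum, while off-harmonic bins are below 1e-5 of it, so 2% separates the
two regimes with an order of magnitude on either side. The 0.5 Hz
pattern-repetition fundamental is excluded (it coincides with the
high-pass corner), and the stimulus-absent control grid is the set of
midpoints between consecutive detected harmonics.

## Synthetic EEG

`simulate_subject()` builds a channels × samples matrix as the sum of four
components:

1. **SS-EP components** — pure sinusoids at each tagged frequency,
   phase-locked to trial onsets. Per-subject amplitudes are drawn from
   group-level normal distributions truncated at zero (defaults around
   0.2–0.6 µV, SD 0.15 µV, chosen as plausible infant SS-EP magnitudes;
   no physiological calibration is claimed and all values are
   config-exposed). Sinusoids make ground-truth amplitude per bin
   well-defined. Each component has a smooth cosine scalp profile that is
   zero-mean across channels with unit mean absolute value — zero-mean so
   that common-average referencing leaves it untouched (as for real
   dipolar scalp fields), unit mean-|gain| so that the channel-averaged
   spectral amplitude equals the true amplitude.
2. **ERP transients** — a half-cosine positive bump (default 8 µV peak,
   160 ms wide) peaking 175 ms after every tone onset, with a
   frontal-positive/posterior-negative zero-mean topography scaled so the
   frontal-row mean is exactly 1. Note that a transient repeated at every
   tone onset is itself periodic with the pattern, so it contributes
   deterministic energy at the tagged harmonics — as overlapping auditory
   responses do in real recordings.
3. **1/f background noise** — per-channel pink noise (`pink_noise()`,
   spectral exponent 1, default 20 µV SD), generated by frequency-domain
   shaping of white Gaussian noise.
4. **Artifact bursts** — Poisson-placed rectangular excursions (default
   0.5/trial, 400 µV, 200 ms) on random single channels. This exercises
   the artifact attenuator; it is not a model of infant movement.

Events mark trial starts and tone onsets with their slot number, which is
what the ERP onset selectors consume. A master seed derives per-subject
seeds deterministically, so an identical `cohort_config()` reproduces an
identical cohort bit for bit.

The `exp1` preset encodes the ambiguous-rhythm study conditions (34 s
trials of 17 pattern repetitions, 32 trials, cohort of 13 music-class vs
46 no-class infants, and a selective duple-frequency amplitude boost —
factor 1.8 — in the music-class group); the `exp2` preset encodes the
quadruple-rhythm conditions (36 s trials of 9 repetitions, 14 trials,
parent-trained vs untrained groups of 16 and 17 — the split is an
assumption, only the total of 33 is constrained — and an overall 1.4×
amplitude scaling in the trained group). The default channel count is 32
(124 available by config) for tractability; the montage is an abstract
front-to-back row layout with hemispheric labels, not a head model.

## Preprocessing

The chain is `eeg_bandpass()` → `eeg_resample()` →
`attenuate_artifacts()` → `rereference_common_average()` →
`epoch_average()`, in that order.

* **Filtering.** 4th-order Butterworth high-pass (0.5 Hz) and low-pass
  (20 Hz), each applied forward and backward (`signal::filtfilt`) after
  mean removal. Zero phase is mandatory because every later stage depends
  on phase-locked averaging; the effective magnitude response is the
  squared Butterworth response. A consequence worth knowing: at 0.75 Hz
  the squared high-pass response is ≈0.96, so quadruple-meter amplitudes
  are attenuated ~4% by the filters themselves.
* **Resampling** to 200 Hz. Integer factors use a zero-phase 8th-order
  Butterworth anti-alias low-pass at 0.8× the new Nyquist followed by
  subsampling; non-integer ratios use Fourier-domain resampling. This
  in-package implementation exists because the off-the-shelf polyphase
  resampler available to us showed percent-level passband amplitude
  ripple, which would have consumed the entire SS-EP recovery error
  budget. Event indices are remapped by the rate ratio with half-up
  rounding.
* **Artifact attenuation.** A deliberately transparent threshold rule:
  runs of samples exceeding 200 µV are widened by a 10 ms guard and
  replaced by linear interpolation. It stands on its own as a simple,
  inspectable attenuator; it is not a reimplementation of any published
  artifact-removal algorithm.
* **Common-average reference**, subtracting the instantaneous channel
  mean.
* **Epoch averaging.** Trial epochs are extracted relative to each trial
  onset, baseline-corrected per epoch over 900–1000 ms, averaged, and the
  first second discarded (onset transients; entrainment needs several
  cycles). Baseline correction is per-epoch — whether it should instead
  use the continuous record is genuinely underdetermined, and the
  per-epoch choice is flagged here as a design decision. Onsets too close
  to the recording edge are skipped with a warning.

## SS-EP extraction

Per channel, the averaged waveform is Fourier-transformed
(amplitude-calibrated, resolution = 1/duration). The local noise floor is
removed per bin by subtracting the mean amplitude of the neighbouring bins
at offsets ±3–5 (about ±0.09–0.15 Hz); the symmetric neighbourhood cancels
any locally linear background exactly. Corrected amplitudes may be
negative and are *not* clipped — clipping would bias noise-only spectra
upward and destroy the zero-centred null that the unbiasedness tests rely
on. The corrected spectra are averaged across all channels (avoiding
electrode selection), and amplitudes of interest are read off as the
maximum over a 3-bin band centred on the bin nearest each tagged
frequency. A target exactly midway between two bins centres on the
lower-frequency bin — a documented, deterministic tie-break. Edge bins
that cannot be corrected are `NA`, and peak-picking refuses bands touching
them. The noise floor per subject is the mean of the same 3-bin measure
over the stimulus-absent frequencies, and subjects are screened by
z-scoring the mean tagged amplitude (|z| > 3 excluded, flagged but never
dropped from tables). Corrected (not raw) amplitudes feed the screening
score.

### Window alignment and scalloping

The order of stages follows the natural reading of the processing chain:
per-channel FFT → per-channel noise subtraction → channel averaging →
peak picking.

One numerical subtlety deserves emphasis. A 34 s trial epoch that discards
its first second retains 33 s, giving 0.0303 Hz bins — and then 1.5 and
2.5 Hz fall exactly *between* bins (49.5 and 82.5 cycles), where
rectangular-window scalloping caps the 3-bin maximum at ~64% of the true
amplitude. The presets keep those printed windows for fidelity, but every
quantitative simulation study in the package (recovery, null calibration,
power) analyses a window retaining 32 s (1000–33000 ms), whose 0.03125 Hz
grid contains every multiple of 0.25 Hz exactly. With bin-centred
components the chain is amplitude-exact; recovery claims are made under
that alignment, and off-grid scalloping is a documented limitation of the
printed-window configuration.

## ERP analysis

Tone-locked epochs span −100 to 300 ms with a −100–0 ms baseline. Two
onset-selection rules are provided, because "the first tone" of a pattern
is ambiguous for patterns with several silences: `pattern_start` (slot 1
of each repetition) and `post_silence` (every tone whose preceding slot is
silent). Epoch counts follow from the layout: 32 trials × 17 six-beat
patterns gives 544 pattern-start epochs; 14 × 9 twelve-slot patterns gives
126.

Waveforms are averaged over frontal channel groups — the frontal row of
the simulated montage split by hemisphere, a required config input in real
use since no montage-independent definition exists. The peak latency is
located as the largest-magnitude sample of the across-subject grand
average within 50–300 ms (ties to the earliest sample; the lower edge
avoids baseline edge effects), and each subject's response magnitude is
the signed trapezoidal area under the curve over ±50 ms around that grand
latency (µV·ms; a rectified option exists). Signed area matches a
dominantly positive deflection. Because the 20 Hz low-pass flattens the
transient's peak, single-subject argmax latencies jitter by a sample or
two; the grand-average latency — the quantity the procedure actually
uses — is stable and recovers the configured 175 ms exactly in the test
scenarios.

## Group statistics

* `paired_t_bonferroni()` — two-sided paired t with `min(1, m·p)`
  family-wise correction.
* `mixed_anova_gg()` — one between × one within mixed-design ANOVA,
  fitted as a multivariate linear model with type-III sum-to-zero
  contrasts (via `car::Anova`), reporting Greenhouse–Geisser ε and
  ε-corrected degrees of freedom and p-values for within-subject effects.
  With two within levels sphericity is trivial and ε = 1 exactly. The
  test suite cross-checks F, ε and p against an independent from-scratch
  sums-of-squares computation to 1e-8.
* `pearson_r()` — sample correlation with t-based p.
* `build_report()` — the full battery over a cohort table: tagged vs
  noise-floor paired t-tests (Bonferroni over the tagged family),
  beat/meter-related vs unrelated contrast, group × frequency ANOVA with
  per-frequency post-hoc contrasts at a family-wise α of 0.10 (the
  convention for that five-test family; configurable), group × hemisphere
  ANOVA on ERP areas, and correlations with parent-training years and
  listening hours. Outliers are flagged, excluded from statistics, and
  retained in every written table.

## Scaled simulation studies

Validation studies must fit a desk-scale compute budget. Two scalings are
used, both decided from first principles rather than tuned:

* **Problem size.** Group-level studies run at 2 trials × 8 channels ×
  500 Hz with 8 + 8 (power) or 4 + 4 (null) subjects; recovery studies
  use single subjects or 20-subject batches at the same size; the
  noise-bias study uses 50 single-subject seeds.
* **Noise.** The SE of a channel- and trial-averaged amplitude scales as
  noise/√(trials × channels). Running 2 × 8 instead of 32 × 124 would
  multiply measurement error ~18-fold and test a regime the full-scale
  design never operates in. `scaled_noise_level()` therefore divides the
  noise level by √(budget ratio), preserving the full-scale per-subject
  measurement SE. Type-I calibration is noise-level-independent, so null
  studies are unaffected by this choice; it matters only for power.
  Group-study scenarios also set the ERP transient amplitude to zero so
  that tagged-bin amplitudes coincide with the sinusoidal ground truth
  (with the transient on, its pattern-locked harmonics mix into the same
  bins, which is realistic but makes "true amplitude" ill-defined).

The α-calibration check uses the uncorrected interaction p-value against
a binomial band around the nominal level — under the simulated compound
symmetry the uncorrected F-test is exact, while the Greenhouse–Geisser
version is slightly conservative at small n and is checked against the
upper bound only.

## Known limitations

* The generator's components are stylized: sinusoidal SS-EPs, a single
  ERP bump shape, spatially smooth topographies, no head model, no
  eye-blink/ECG taxonomy, rectangular artifacts. Passing recovery and
  calibration tests shows the *analysis chain* is correct and unbiased
  under its own assumptions; it cannot show that real infant EEG
  satisfies those assumptions.
* Amplitude scales are plausible, not calibrated to any dataset.
* The quadruple-meter (0.75 Hz) component sits on the shoulder of the
  0.5 Hz high-pass; its ~4% filter attenuation is inherent to the printed
  filter settings, which is why sub-percent recovery claims are made for
  the ≥1 Hz tagged set.
* The analytic-signal envelope of a ramped 990 Hz tone sequence carries a
  carrier–envelope intermodulation floor of ~4e-6 (relative to the
  largest harmonic) in the envelope spectrum, which bounds how clean the
  off-harmonic bins can be.
* Recordings serialize as CSV + JSON sidecar only; no binary EEG
  container is written.
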