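# Rhythm-pattern construction, tone synthesis, envelope extraction and the
# stimulus-side frequency derivations.

test_that("pattern construction validates and reports durations", {
  p <- rhythm_pattern(c(1, 0, 1, 1, 1, 0), 1 / 3, 990, 0.010)
  expect_s3_class(p, "rhythm_pattern")
  expect_equal(pattern_duration(p), 2)
  expect_equal(pattern_repetition_hz(p), 0.5)

  p1 <- rhythm_pattern(1, 0.333, 990, 0.010)
  expect_equal(pattern_duration(p1), 0.333)

  # literal-IOI convention: 12 slots of 0.333 s
  p12 <- pattern_twelvebeat(ioi_seconds = 0.333)
  expect_equal(pattern_duration(p12), 3.996)

  expect_error(rhythm_pattern(integer(0)), "at least one slot")
  expect_error(rhythm_pattern(c(1, 0), ioi_seconds = 0.1,
                              ramp_seconds = 0.06), "do not fit")
})

test_that("synthesis produces ramped tones of exact total duration", {
  p <- pattern_sixbeat()
  s <- synthesize(p, rate_hz = 8000, repetitions = 17)
  expect_equal(length(s$samples), 34 * 8000)

  # silence synthesizes to zeros
  sil <- synthesize(rhythm_pattern(c(0, 0), carrier_hz = 100),
                    rate_hz = 1000, repetitions = 3)
  expect_true(all(sil$samples == 0))

  # un-ramped full slot: RMS of a sinusoid is peak / sqrt(2)
  tone <- synthesize(rhythm_pattern(1, ioi_seconds = 1, carrier_hz = 100,
                                    ramp_seconds = 0),
                     rate_hz = 8000)
  expect_equal(sqrt(mean(tone$samples^2)), 1 / sqrt(2), tolerance = 1e-3)

  # duration exact to one sample for awkward rates, several repetitions
  for (reps in c(1, 5, 9)) {
    s2 <- synthesize(pattern_twelvebeat(), rate_hz = 5000,
                     repetitions = reps)
    expect_equal(length(s2$samples), round(reps * 4 * 5000))
  }

  expect_error(synthesize(p, rate_hz = 2000), ">= 4 x carrier")
})

test_that("hilbert envelope recovers instantaneous amplitude", {
  rate <- 2000
  t <- seq(0, 2, by = 1 / rate)[-1]
  x <- audio_signal(3 * sin(2 * pi * 100 * t), rate)
  env <- hilbert_envelope(x)
  inner <- env$samples[200:3800]
  expect_true(all(abs(inner - 3) / 3 < 0.01))
  expect_true(all(env$samples >= 0))

  z <- hilbert_envelope(audio_signal(rep(0, 100) + 0, 100))
  expect_true(all(z$samples == 0))

  # slow raised-cosine modulator, checked against the quadrature-pair oracle
  m <- 1 + 0.5 * cos(2 * pi * 2 * t)
  am <- audio_signal(m * sin(2 * pi * 200 * t), rate)
  got <- hilbert_envelope(am)$samples
  want <- oracle_quadrature_envelope(m, 200, rate)
  idx <- 500:(length(t) - 500)
  expect_lt(max(abs(got[idx] - want[idx])), 0.01)

  # amplitude linearity: envelope(c x) = c envelope(x)
  for (c_ in c(0.5, 2, 7)) {
    scaled <- hilbert_envelope(audio_signal(c_ * am$samples, rate))
    expect_equal(scaled$samples, c_ * got, tolerance = 1e-12)
  }
})

test_that("amplitude spectrum is amplitude-calibrated with 1/duration bins", {
  rate <- 200
  t <- seq(0, 34, by = 1 / rate)[-1]
  sp <- amplitude_spectrum(audio_signal(sin(2 * pi * 1.5 * t), rate))
  expect_equal(attr(sp, "resolution_hz"), 1 / 34)
  k <- which.min(abs(sp$frequency_hz - 1.5))
  expect_equal(sp$amplitude[k], 1, tolerance = 1e-9)
  expect_lt(max(sp$amplitude[-k]), 1e-9)

  const <- amplitude_spectrum(audio_signal(rep(2.5, 400), 100))
  expect_equal(const$amplitude[1], 2.5)
  expect_lt(max(const$amplitude[-1]), 1e-12)
})

test_that("envelope energy sits on pattern-repetition harmonics only", {
  for (pat in list(pattern_sixbeat(), pattern_twelvebeat())) {
    reps <- if (pattern_duration(pat) == 2) 17 else 9
    sp <- stimulus_spectrum(pat, repetitions = reps)
    rep_hz <- pattern_repetition_hz(pat)
    harmonic <- abs(sp$frequency_hz / rep_hz -
                      round(sp$frequency_hz / rep_hz)) < 1e-9
    off <- sp$amplitude[!harmonic & sp$frequency_hz > 0.1 &
                          sp$frequency_hz < 20]
    # carrier-envelope intermodulation in the Hilbert envelope leaves a
    # ~4e-6 leakage floor even over whole-pattern windows
    expect_lt(max(off) / max(sp$amplitude[harmonic]), 1e-5)
    # the six-beat envelope carries energy at 1, 1.5, 2 and 2.5 Hz
    if (pattern_duration(pat) == 2) {
      for (f in c(1, 1.5, 2, 2.5)) {
        expect_gt(sp$amplitude[which.min(abs(sp$frequency_hz - f))],
                  0.02 * max(sp$amplitude[sp$frequency_hz >= 0.5]))
      }
    }
  }
})

test_that("metric frequencies divide the beat exactly", {
  expect_equal(metric_frequency(3, 2), 1.5)
  expect_equal(metric_frequency(3, 3), 1)
  expect_equal(metric_frequency(3, 4), 0.75)
  for (f in c(2.4, 3, 5)) expect_equal(metric_frequency(f, 1), f)
  for (g in 1:6) expect_equal(metric_frequency(3, g) * g, 3)
  expect_error(metric_frequency(3, 0), "integer >= 1")
})

test_that("frequency sets derived from the stimulus match both experiments", {
  fs1 <- exp1_freqset()
  expect_equal(fs1$stimulus_present_hz, c(1, 1.5, 2, 2.5, 3))
  expect_equal(fs1$stimulus_absent_hz, c(0.75, 1.25, 1.75, 2.25, 2.75))
  expect_equal(unname(fs1$meter_hz["duple"]), 1.5)

  fs2 <- exp2_freqset()
  expect_equal(fs2$stimulus_present_hz,
               c(0.75, 1, 1.25, 1.5, 1.75, 2, 2.25, 2.5, 2.75, 3))
  expect_equal(fs2$stimulus_absent_hz,
               c(0.625, 0.875, 1.125, 1.375, 1.625, 1.875, 2.125,
                 2.375, 2.625, 2.875))
  expect_true(length(intersect(fs2$stimulus_present_hz,
                               fs2$stimulus_absent_hz)) == 0)

  # an all-zero spectrum yields empty sets
  zero <- amplitude_spectrum(audio_signal(rep(0, 2000) + 0, 100))
  fz <- frequencies_of_interest(zero)
  expect_length(fz$stimulus_present_hz, 0)
  expect_length(fz$stimulus_absent_hz, 0)
})

test_that("wav export writes a well-formed 16-bit PCM file", {
  s <- synthesize(pattern_sixbeat(), rate_hz = 8000, repetitions = 1)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(s, path)
  hdr <- readBin(path, "raw", 44)
  expect_equal(rawToChar(hdr[1:4]), "RIFF")
  expect_equal(rawToChar(hdr[9:12]), "WAVE")
  expect_equal(file.size(path), 44 + 2 * length(s$samples))
})
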