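# SS-EP extraction: per-channel spectra, neighbour-bin noise subtraction,
# channel averaging, 3-bin peak picking, noise floor and outlier screening.

flat_spectrum <- function(values, res = 1 / 32) {
  rhythmtag:::new_amp_spectrum((seq_along(values) - 1) * res, values, res,
                               noise_corrected = FALSE)
}

test_that("per-channel spectra are calibrated with 1/duration resolution", {
  rate <- 200
  n <- 33 * rate
  t <- (seq_len(n) - 1) / rate
  data <- rbind(4 * sin(2 * pi * 3 * t), rnorm(n, sd = 0.1))
  avg <- rhythmtag:::new_averaged_waveform(data, rate, 1000, 4, c("A", "B"))
  sp <- spectrum_per_channel(avg)
  expect_equal(attr(sp, "resolution_hz"), 1 / 33)
  a_chan <- dplyr::filter(sp, channel == "A")
  k <- which.min(abs(a_chan$frequency_hz - 3))
  expect_equal(a_chan$amplitude[k], 4, tolerance = 0.01)

  zero <- rhythmtag:::new_averaged_waveform(matrix(0, 1, n), rate, 0, 1, "A")
  expect_true(all(spectrum_per_channel(zero)$amplitude == 0))

  short <- rhythmtag:::new_averaged_waveform(matrix(0, 1, 399), rate, 0, 1,
                                             "A")
  expect_error(spectrum_per_channel(short), "too short")
})

test_that("neighbour-bin subtraction removes flat and linear backgrounds", {
  flat <- flat_spectrum(rep(2, 50))
  corr <- subtract_noise(flat)
  valid <- !is.na(corr$amplitude)
  expect_equal(sum(!valid), 10)             # 5 bins at each edge
  expect_true(all(abs(corr$amplitude[valid]) < 1e-12))

  peaked <- rep(2, 50); peaked[25] <- 10
  corr2 <- subtract_noise(flat_spectrum(peaked))
  expect_equal(corr2$amplitude[25], 8)

  ramp <- flat_spectrum(seq(0, 4.9, by = 0.1))
  corr3 <- subtract_noise(ramp)
  ok <- !is.na(corr3$amplitude)
  expect_true(all(abs(corr3$amplitude[ok]) < 1e-12))

  expect_true(attr(corr, "noise_corrected"))
  expect_error(subtract_noise(corr), "already")
  expect_error(subtract_noise(flat_spectrum(rep(1, 10))), "too short")
})

test_that("channel averaging equals the bin-wise mean", {
  res <- 1 / 32
  set.seed(41)
  vals <- matrix(runif(3 * 40), 3)
  sp <- purrr::map_dfr(1:3, function(ch) {
    tibble::tibble(channel = paste0("E", ch),
                   frequency_hz = (0:39) * res,
                   amplitude = vals[ch, ])
  })
  class(sp) <- c("channel_spectra", class(sp))
  attr(sp, "resolution_hz") <- res
  attr(sp, "noise_corrected") <- FALSE
  avg <- average_across_channels(sp)
  expect_equal(avg$amplitude, colMeans(vals))

  # identical channels -> unchanged; (x, -x) -> zero
  sp2 <- sp
  sp2$amplitude <- rep(vals[1, ], 3)
  expect_equal(average_across_channels(sp2)$amplitude, vals[1, ])
  sp3 <- sp[sp$channel != "E3", ]
  sp3$amplitude <- c(vals[1, ], -vals[1, ])
  class(sp3) <- class(sp)
  attr(sp3, "resolution_hz") <- res
  attr(sp3, "noise_corrected") <- FALSE
  expect_true(all(abs(average_across_channels(sp3)$amplitude) < 1e-12))
})

test_that("3-bin peak picking captures shifted peaks and breaks ties down", {
  res <- 1 / 32
  vals <- rep(0, 200)
  vals[97] <- 5                      # bin 97 = 3 Hz exactly
  sp <- flat_spectrum(vals, res)
  expect_equal(peak_amplitude(sp, 3), 5)
  vals2 <- rep(0, 200); vals2[98] <- 7   # one bin above the target
  expect_equal(peak_amplitude(flat_spectrum(vals2, res), 3), 7)

  # a target exactly midway between bins centres on the lower bin:
  # with bins at k*0.03125 Hz, 3.015625 Hz sits between bins 97 and 98
  vals3 <- rep(0, 200); vals3[96] <- 2
  expect_equal(peak_amplitude(flat_spectrum(vals3, res), 3 + res / 2), 2)
  vals4 <- rep(0, 200); vals4[99] <- 2
  expect_equal(peak_amplitude(flat_spectrum(vals4, res), 3 + res / 2), 0)

  expect_error(peak_amplitude(sp, 50), "outside")
  corr <- subtract_noise(flat_spectrum(rep(1, 200), res))
  expect_error(peak_amplitude(corr, res * 2), "edge bins")
})

test_that("noise floor averages peak amplitudes at absent frequencies", {
  expect_length(exp1_freqset()$stimulus_absent_hz, 5)
  expect_length(exp2_freqset()$stimulus_absent_hz, 10)

  res <- 1 / 32
  vals <- rep(0, 200)
  vals[round(c(0.75, 1.25, 1.75) / res) + 1] <- c(1, 2, 3)
  sp <- flat_spectrum(vals, res)
  expect_equal(noise_floor(sp, c(0.75, 1.25, 1.75)), 2)
  expect_equal(noise_floor(sp, c(2.25, 2.75)), 0)
  expect_error(noise_floor(sp, numeric(0)), "nonempty")
})

test_that("z-score screening excludes exactly the gross outlier", {
  expect_true(all(zscore_exclude(rep(1, 10))))
  set.seed(17)
  scores <- c(rnorm(59, 1, 0.1), 10)
  mask <- zscore_exclude(scores)
  expect_equal(which(!mask), 60)
  expect_true(all(zscore_exclude(scores, cutoff = Inf)))
  expect_error(zscore_exclude(c(1, 2)), ">= 3 subjects")
})

test_that("tagged amplitudes exceed unrelated ones in a beat/meter cohort", {
  fs1 <- exp1_freqset()
  cfg <- scaled_exp1_config(seed = 12, n_per_group = c(3L, 3L),
                            effect_factor = 1)
  cfg$ssep_mean_uv <- c("1" = 0.5, "1.5" = 0.5, "3" = 0.5)  # no 2, 2.5 Hz
  tb <- ssep_cohort_table(cfg, fs1)
  related <- rowMeans(tb[, c("ssep_1", "ssep_1.5", "ssep_3")])
  unrelated <- rowMeans(tb[, c("ssep_2", "ssep_2.5")])
  expect_gt(mean(related), mean(unrelated))
})
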