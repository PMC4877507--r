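# Filtering, resampling, artifact attenuation, common-average referencing
# and epoch averaging.

make_rec <- function(data, rate = 1000, events = NULL) {
  eeg_recording(data, rate, events = events)
}

test_that("band-pass rejects DC, keeps 3 Hz, attenuates 40 Hz", {
  rate <- 1000
  t <- seq(0, 40, by = 1 / rate)[-1]
  rec <- make_rec(rbind(100 + 0 * t,
                        sin(2 * pi * 3 * t),
                        sin(2 * pi * 40 * t)), rate)
  out <- eeg_bandpass(rec)
  mid <- (10 * rate):(30 * rate)
  expect_lt(abs(mean(out$data[1, ])), 1e-3 * 100)
  gain3 <- max(abs(out$data[2, mid]))
  expect_lt(abs(gain3 - 1), 0.05)

  # compare against the analytic magnitude response of the cascaded design
  h <- function(flt, f) {
    z <- exp(-1i * 2 * pi * f / rate)
    abs(sum(flt$b * z^(seq_along(flt$b) - 1)) /
          sum(flt$a * z^(seq_along(flt$a) - 1)))
  }
  hp <- signal::butter(4, 0.5 / 500, "high")
  lp <- signal::butter(4, 20 / 500, "low")
  expected3 <- (h(hp, 3) * h(lp, 3))^2   # forward-backward squares the gain
  expect_equal(gain3, expected3, tolerance = 0.01)

  gain40 <- max(abs(out$data[3, mid]))
  expected40 <- (h(hp, 40) * h(lp, 40))^2
  expect_equal(gain40, expected40, tolerance = 0.05)
  expect_lt(20 * log10(gain40), -20)

  expect_error(eeg_bandpass(rec, 20, 0.5), "high_pass_hz < low_pass_hz")
})

test_that("resampling scales counts, remaps events, keeps in-band tones", {
  rate <- 1000
  t <- seq(0, 34, by = 1 / rate)[-1]
  rec <- make_rec(rbind(sin(2 * pi * 3 * t), cos(2 * pi * 5 * t)), rate,
                  events = tibble::tibble(sample = c(1L, 17001L, 34000L),
                                          code = "trial_start"))
  out <- eeg_resample(rec, 200)
  expect_equal(ncol(out$data), 6800)
  expect_equal(out$rate_hz, 200)
  expect_equal(out$events$sample, c(1L, 3401L, 6800L))
  mid <- 1000:5800
  expect_lt(abs(max(abs(out$data[1, mid])) - 1), 0.01)

  expect_identical(eeg_resample(rec, 1000), rec)
  expect_error(eeg_resample(rec, 2000), "exceeds")

  # non-integer ratio path
  rec5 <- make_rec(matrix(sin(2 * pi * 3 * seq(0, 20, by = 1 / 500))[-1],
                          nrow = 1), 500)
  out5 <- eeg_resample(rec5, 200)
  expect_equal(ncol(out5$data), 4000)
  expect_lt(abs(max(abs(out5$data[1, 800:3200])) - 1), 0.01)
})

test_that("artifact attenuation interpolates flagged runs only", {
  rate <- 500
  n <- 5000
  clean <- matrix(rnorm(2 * n, sd = 10), 2, n)
  rec <- make_rec(clean, rate)
  expect_equal(attenuate_artifacts(rec, 200)$data, clean, ignore_attr = TRUE)

  burst <- clean
  burst[1, 2000:2100] <- 500
  out <- attenuate_artifacts(make_rec(burst, rate), 200)
  expect_true(all(abs(out$data[1, 2000:2100]) <= 200))
  expect_equal(out$data[2, ], clean[2, ], ignore_attr = TRUE)  # other channel untouched
  guard <- round(0.010 * rate)
  untouched <- c(1:(2000 - guard - 1), (2100 + guard + 1):n)
  expect_equal(out$data[1, untouched], clean[1, untouched], ignore_attr = TRUE)

  expect_error(attenuate_artifacts(rec, -5), "threshold_uv")
})

test_that("artifact attenuation improves SS-EP recovery under bursts", {
  fs1 <- exp1_freqset()
  cfg <- scaled_exp1_config(seed = 3, n_trials = 2L, n_channels = 4L)
  cfg$noise_level_uv <- 0
  cfg$artifact_rate_per_trial <- 1
  sub <- simulate_subject(cfg, seed = 3)
  truth <- sub$truth$ssep_amp_uv

  run_chain <- function(rec, attenuate) {
    pre <- eeg_resample(eeg_bandpass(rec), 200)
    if (attenuate) pre <- attenuate_artifacts(pre, 200)
    pre <- rereference_common_average(pre)
    avg <- epoch_average(pre, trial_onsets(pre), 0, 33000, 900, 1000, 1000)
    row <- ssep_subject(avg, fs1)
    unlist(row[paste0("ssep_", names(truth))])
  }
  err_with <- abs(run_chain(sub$recording, TRUE) - truth) / truth
  err_without <- abs(run_chain(sub$recording, FALSE) - truth) / truth
  expect_lt(mean(err_with), mean(err_without))
})

test_that("common-average referencing zeroes the per-sample channel mean", {
  rec <- make_rec(matrix(rnorm(5 * 400, mean = 3), 5, 400), 100)
  out <- rereference_common_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  # idempotent on already-referenced data; symmetric pair unchanged
  expect_equal(rereference_common_average(out)$data, out$data)
  v <- rnorm(300)
  sym <- make_rec(rbind(v, -v), 100)
  expect_equal(rereference_common_average(sym)$data, sym$data,
               ignore_attr = TRUE)
  expect_error(rereference_common_average(make_rec(matrix(v, 1), 100)),
               ">= 2 channels")
})

test_that("epoch averaging obeys the baseline and averaging laws", {
  rate <- 200
  epoch <- sin(2 * pi * 3 * seq(0, 2, by = 1 / rate)[-1]) + 2
  x <- rep(epoch, 5)
  rec <- make_rec(rbind(x, 2 * x), rate)
  onsets <- seq(1, by = length(epoch), length.out = 5)
  avg <- epoch_average(rec, onsets, 0, 2000)
  expect_equal(avg$n_epochs_averaged, 5)
  expect_equal(avg$data[1, ], epoch, ignore_attr = TRUE)

  # baseline window mean of the average is zero after per-epoch correction
  avg_b <- epoch_average(rec, onsets, 0, 2000, 0, 500)
  expect_lt(abs(mean(avg_b$data[1, 1:(rate / 2)])), 1e-12)

  # residual noise shrinks as 1/sqrt(N)
  ratio <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      n_ep <- 16
      noise <- rnorm(n_ep * 400)
      r <- make_rec(matrix(rep(epoch[1:400], n_ep) + noise, 1), rate)
      a <- epoch_average(r, seq(1, by = 400, length.out = n_ep), 0, 2000)
      sd(a$data[1, ] - epoch[1:400]) * sqrt(n_ep)
    })
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.2)

  # onsets beyond the edge are skipped with a warning; none usable errors
  expect_warning(epoch_average(rec, c(1, length(x) - 10), 0, 2000),
                 "Skipped 1")
  expect_error(suppressWarnings(epoch_average(rec, length(x) - 10, 0, 2000)),
               "No usable epochs")
})

test_that("referencing and epoching commute on artifact-free input", {
  fs1 <- exp1_freqset()
  cfg <- scaled_exp1_config(seed = 8, n_trials = 2L, n_channels = 4L)
  cfg$artifact_rate_per_trial <- 0
  rec <- simulate_subject(cfg, seed = 8)$recording
  base <- eeg_resample(eeg_bandpass(rec), 200)

  avg_then_ref <- epoch_average(rereference_common_average(base),
                                trial_onsets(base), 0, 33000, 900, 1000,
                                1000)
  a <- ssep_subject(avg_then_ref, fs1)

  ref_last <- epoch_average(base, trial_onsets(base), 0, 33000, 900, 1000,
                            1000)
  ref_last$data <- sweep(ref_last$data, 2, colMeans(ref_last$data))
  b <- ssep_subject(ref_last, fs1)
  expect_equal(as.numeric(a[-1]), as.numeric(b[-1]), tolerance = 1e-9)
})
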