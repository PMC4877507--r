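#' Define a rhythmic tone pattern
#'
#' A rhythm pattern is an ordered sequence of isochronous slots, each either
#' carrying a pure tone (`1`) or silent (`0`). Slots share one inter-onset
#' interval (IOI), one carrier frequency and one linear rise/fall ramp time.
#' The default parameters describe a 180-beats-per-minute sequence of 990 Hz
#' tones with 10 ms ramps, i.e. a 3 Hz beat.
#'
#' Two IOI conventions are supported: the exact `1/3` s slot (180 bpm exactly,
#' the default) and the literal `0.333` s print convention, under which a
#' 12-slot pattern lasts 3.996 s rather than 4 s.
#'
#' @param onset_flags Integer/logical vector, one element per slot; `1`/`TRUE`
#'   marks a tone, `0`/`FALSE` a silence.
#' @param ioi_seconds Inter-onset interval of one slot in seconds.
#' @param carrier_hz Pure-tone carrier frequency in Hz.
#' @param ramp_seconds Linear rise and fall time in seconds; the rise and the
#'   fall together must fit inside one slot.
#' @return An object of class `rhythm_pattern`.
#' @examples
#' p <- rhythm_pattern(c(1, 0, 1, 1, 1, 0))
#' pattern_duration(p)        # 2 s
#' pattern_repetition_hz(p)   # 0.5 Hz
#' @export
rhythm_pattern <- function(onset_flags, ioi_seconds = 1 / 3,
                           carrier_hz = 990, ramp_seconds = 0.010) {
  if (length(onset_flags) == 0) {
    abort("`onset_flags` must contain at least one slot.")
  }
  flags <- as.integer(as.logical(onset_flags))
  if (anyNA(flags)) abort("`onset_flags` must be 0/1 or logical.")
  assert_scalar_num(ioi_seconds, "ioi_seconds", lower = 0, allow_zero = FALSE)
  assert_scalar_num(carrier_hz, "carrier_hz", lower = 0, allow_zero = FALSE)
  assert_scalar_num(ramp_seconds, "ramp_seconds", lower = 0)
  if (2 * ramp_seconds > ioi_seconds) {
    abort(sprintf(
      "Rise + fall ramps (2 x %g s) do not fit in one %g s slot.",
      ramp_seconds, ioi_seconds))
  }
  structure(
    list(onset_flags = flags, ioi_seconds = ioi_seconds,
         carrier_hz = carrier_hz, ramp_seconds = ramp_seconds),
    class = "rhythm_pattern")
}

#' @export
print.rhythm_pattern <- function(x, ...) {
  cat("<rhythm_pattern> ", paste(ifelse(x$onset_flags == 1, "x", "."),
                                 collapse = ""), "\n", sep = "")
  cat(sprintf("  %d slots, IOI %.4g s, carrier %g Hz, ramps %g s (%.4g s total)\n",
              length(x$onset_flags), x$ioi_seconds, x$carrier_hz,
              x$ramp_seconds, pattern_duration(x)))
  invisible(x)
}

#' Pattern duration and repetition frequency
#'
#' @param pattern A [rhythm_pattern()].
#' @return Duration in seconds, or its reciprocal (the pattern repetition
#'   frequency in Hz).
#' @export
pattern_duration <- function(pattern) {
  stopifnot(inherits(pattern, "rhythm_pattern"))
  length(pattern$onset_flags) * pattern$ioi_seconds
}

#' @rdname pattern_duration
#' @export
pattern_repetition_hz <- function(pattern) 1 / pattern_duration(pattern)

#' Six-beat ambiguous-meter pattern
#'
#' The tone-silence-tone-tone-tone-silence sequence: a 2 s, six-slot pattern
#' at 3 Hz beat rate whose meter can be heard as duple (1.5 Hz) or triple
#' (1 Hz).
#'
#' @inheritParams rhythm_pattern
#' @return A [rhythm_pattern()].
#' @export
pattern_sixbeat <- function(ioi_seconds = 1 / 3) {
  rhythm_pattern(c(1, 0, 1, 1, 1, 0), ioi_seconds = ioi_seconds)
}

#' Twelve-slot quadruple-meter pattern
#'
#' A 12-slot pattern (4 s at the exact-IOI convention) with an unambiguous
#' quadruple grouping of the 3 Hz beat (meter frequency 0.75 Hz). The exact
#' slot arrangement is a documented package default chosen so that every
#' 0.25 Hz envelope harmonic from 0.75 to 3 Hz carries energy and the first
#' slot is a tone following a silence; any 12-slot flag vector can be supplied
#' instead via [rhythm_pattern()].
#'
#' @inheritParams rhythm_pattern
#' @return A [rhythm_pattern()].
#' @export
pattern_twelvebeat <- function(ioi_seconds = 1 / 3) {
  rhythm_pattern(c(1, 1, 1, 1, 1, 0, 1, 1, 1, 1, 0, 0),
                 ioi_seconds = ioi_seconds)
}

#' Synthesize a rhythm pattern as an audio signal
#'
#' Tone slots carry a linearly ramped sinusoid at the carrier frequency;
#' silent slots are zero. With `phase_mode = "continuous"` the carrier phase
#' advances through the whole signal (adjacent tones join smoothly); with
#' `"reset"` the phase restarts at every tone slot.
#'
#' @param pattern A [rhythm_pattern()].
#' @param rate_hz Sampling rate; must be at least four times the carrier.
#' @param repetitions Number of times the pattern is repeated back to back.
#' @param phase_mode `"continuous"` (default) or `"reset"`.
#' @param amplitude Peak amplitude of the tones (arbitrary units).
#' @return An `audio_signal`: a list with `samples` and `rate_hz`.
#' @examples
#' s <- synthesize(pattern_sixbeat(), rate_hz = 8000, repetitions = 17)
#' length(s$samples) / s$rate_hz  # 34 s
#' @export
synthesize <- function(pattern, rate_hz = 44100, repetitions = 1,
                       phase_mode = c("continuous", "reset"),
                       amplitude = 1) {
  stopifnot(inherits(pattern, "rhythm_pattern"))
  phase_mode <- match.arg(phase_mode)
  assert_count(repetitions, "repetitions")
  if (rate_hz < 4 * pattern$carrier_hz) {
    abort(sprintf("rate_hz (%g) must be >= 4 x carrier (%g Hz).",
                  rate_hz, 4 * pattern$carrier_hz))
  }
  n_slots <- length(pattern$onset_flags)
  # Slot boundaries on the sample grid; cumulative rounding keeps total
  # duration exact to one sample.
  total_slots <- n_slots * repetitions
  flags <- rep(pattern$onset_flags, repetitions)
  edges <- round_half_up((0:total_slots) * pattern$ioi_seconds * rate_hz)
  n_total <- edges[total_slots + 1L]
  env <- numeric(n_total)
  ramp_n <- round_half_up(pattern$ramp_seconds * rate_hz)
  for (s in seq_len(total_slots)) {
    if (flags[s] == 0) next
    i0 <- edges[s] + 1L
    i1 <- edges[s + 1L]
    len <- i1 - i0 + 1L
    e <- rep(1, len)
    rn <- min(ramp_n, floor(len / 2))
    if (rn > 0) {
      e[seq_len(rn)] <- seq(0, 1, length.out = rn + 1L)[-1L]
      e[(len - rn + 1L):len] <- rev(seq(0, 1, length.out = rn + 1L)[-1L])
    }
    env[i0:i1] <- e
  }
  t <- (seq_len(n_total) - 1) / rate_hz
  if (phase_mode == "continuous") {
    carrier <- sin(2 * pi * pattern$carrier_hz * t)
  } else {
    carrier <- numeric(n_total)
    for (s in seq_len(total_slots)) {
      if (flags[s] == 0) next
      idx <- (edges[s] + 1L):edges[s + 1L]
      carrier[idx] <- sin(2 * pi * pattern$carrier_hz *
                            (t[idx] - t[idx[1]]))
    }
  }
  audio_signal(amplitude * env * carrier, rate_hz)
}

#' Construct an audio signal
#'
#' @param samples Numeric vector of samples (arbitrary units).
#' @param rate_hz Sampling rate in Hz.
#' @return An object of class `audio_signal`.
#' @export
audio_signal <- function(samples, rate_hz) {
  if (length(samples) == 0) abort("`samples` must be nonempty.")
  if (!all(is.finite(samples))) abort("`samples` must be finite.")
  assert_scalar_num(rate_hz, "rate_hz", lower = 0, allow_zero = FALSE)
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.4g s)\n",
              length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz))
  invisible(x)
}

#' Instantaneous-amplitude envelope via the analytic signal
#'
#' Returns the modulus of the analytic signal (frequency-domain Hilbert
#' construction), i.e. a time-varying estimate of the instantaneous amplitude,
#' at the same length and rate as the input.
#'
#' @param signal An [audio_signal()].
#' @return An [audio_signal()] holding the non-negative envelope.
#' @export
hilbert_envelope <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  audio_signal(Mod(analytic_signal(signal$samples)), signal$rate_hz)
}

#' Resample an audio signal
#'
#' Zero-phase downsampling (see Details in [eeg_resample()]); used to bring a
#' high-rate stimulus envelope onto the 200 Hz analysis grid shared with the
#' EEG spectra.
#'
#' @param signal An [audio_signal()].
#' @param target_hz New sampling rate; must not exceed the original.
#' @return An [audio_signal()] at `target_hz`.
#' @export
resample_audio <- function(signal, target_hz) {
  stopifnot(inherits(signal, "audio_signal"))
  assert_scalar_num(target_hz, "target_hz", lower = 0, allow_zero = FALSE)
  audio_signal(resample_vector(signal$samples, signal$rate_hz, target_hz),
               target_hz)
}

#' Meter frequency from beat frequency and grouping
#'
#' Beats grouped in `grouping` produce a metrical periodicity at
#' `beat_hz / grouping`: duple grouping of a 3 Hz beat gives 1.5 Hz, triple
#' 1 Hz, quadruple 0.75 Hz.
#'
#' @param beat_hz Beat frequency in Hz.
#' @param grouping Positive integer number of beats per metrical cycle.
#' @return The meter frequency in Hz.
#' @export
metric_frequency <- function(beat_hz, grouping) {
  assert_scalar_num(beat_hz, "beat_hz")
  assert_count(grouping, "grouping")
  beat_hz / grouping
}

#' Write an audio signal as a 16-bit PCM WAV file
#'
#' Samples are scaled by `scale` (default: the maximum absolute sample, so
#' full scale) and quantized to 16 bits.
#'
#' @param signal An [audio_signal()].
#' @param path Output file path.
#' @param scale Value mapped to full scale; defaults to `max(abs(samples))`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, scale = NULL) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  scale <- scale %||% max(abs(x), 1e-12)
  pcm <- as.integer(pmax(-32767, pmin(32767, round(x / scale * 32767))))
  rate <- as.integer(round(signal$rate_hz))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
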