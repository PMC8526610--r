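# Acoustics: calibrated SPL extraction, distance standardisation, mean
# spectra and the high/low train-noise frequency grouping.

#' Minimal PCM WAV input/output
#'
#' Reads and writes mono (or first-channel) RIFF/WAVE files with 16- or 24-bit
#' integer PCM samples, returning amplitudes scaled to [-1, 1]. Covers the
#' fixtures this package synthesizes; not a general-purpose audio library.
#'
#' @param path File path.
#' @return `read_wav()`: list with `wave` (numeric) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  abort_unless(identical(riff, "RIFF"), "not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  abort_unless(identical(readChar(con, 4, useBytes = TRUE), "WAVE"),
               "not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "raw", sz)
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  abort_unless(!is.null(fmt) && !is.null(data_raw), "missing fmt/data chunk")
  u16 <- function(off) sum(as.integer(fmt[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(fmt[off + 1:4]) * 256^(0:3))
  n_chan <- u16(2); rate <- u32(4); bits <- u16(14)
  abort_unless(bits %in% c(16L, 24L), "only 16/24-bit PCM supported")
  bytes <- bits / 8
  m <- matrix(as.integer(data_raw), nrow = bytes)
  val <- colSums(m * 256^(0:(bytes - 1)))
  full <- 2^bits
  val[val >= full / 2] <- val[val >= full / 2] - full
  if (n_chan > 1) val <- val[seq(1, length(val), by = n_chan)]
  list(wave = val / (full / 2), sample_rate = rate)
}

#' @rdname read_wav
#' @param wave Numeric vector in [-1, 1].
#' @param sample_rate Samples per second.
#' @param bits Bit depth, 16 or 24.
#' @export
write_wav <- function(wave, sample_rate, path, bits = 16) {
  abort_unless(bits %in% c(16, 24), "only 16/24-bit PCM supported")
  abort_unless(max(abs(wave)) <= 1, "wave must be within [-1, 1]")
  bytes <- bits / 8
  full <- 2^bits
  val <- round(wave * (full / 2 - 1))
  val[val < 0] <- val[val < 0] + full
  m <- vapply(0:(bytes - 1), function(b) (val %/% 256^b) %% 256,
              numeric(length(val)))
  data_raw <- as.raw(t(m))
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + length(data_raw))
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(1); w16(1); w32(sample_rate); w32(sample_rate * bytes)
  w16(bytes); w16(bits)
  writeChar("data", con, eos = NULL); w32(length(data_raw))
  writeBin(data_raw, con)
  invisible(path)
}

#' Compute an (uncalibrated) SPL curve from a waveform
#'
#' RMS intensity in sliding windows of length `3.2 / min_pitch` seconds,
#' stepped by `0.8 / min_pitch` seconds, converted to dB. With the default
#' minimum pitch of 5 Hz the step is 0.16 s, i.e. 6.25 readings per second —
#' adequate temporal resolution at modest data volume. Readings are relative
#' to an arbitrary gain until [calibrate_spl()] anchors them to a reference
#' tone of known level.
#'
#' @param wave Numeric waveform (or a list with `wave`/`sample_rate` as
#'   returned by [read_wav()] / [simulate_calibration_audio()]).
#' @param sample_rate Samples per second (ignored when `wave` carries its own).
#' @param min_pitch Minimum pitch, Hz; sets window (3.2/min_pitch) and step
#'   (0.8/min_pitch).
#' @return A tibble of class `spl_curve` with columns `time_s` (window
#'   centre), `spl_db`; attributes `step_s`, `calibrated`, `offset_db`.
#' @export
compute_spl_curve <- function(wave, sample_rate = NULL, min_pitch = 5) {
  if (is.list(wave)) {
    sample_rate <- wave$sample_rate
    wave <- wave$wave
  }
  abort_unless(length(wave) > 0, "empty waveform")
  abort_unless(min_pitch > 0, "min_pitch must be > 0")
  win_s <- 3.2 / min_pitch
  step_s <- 0.8 / min_pitch
  win_n <- round(win_s * sample_rate)
  step_n <- round(step_s * sample_rate)
  abort_unless(win_n <= length(wave),
               "analysis window (%.2f s) longer than waveform", win_s)
  starts <- seq(1L, length(wave) - win_n + 1L, by = step_n)
  # O(n) sliding RMS via cumulative sum of squares
  cs <- c(0, cumsum(wave^2))
  ms <- (cs[starts + win_n] - cs[starts]) / win_n
  spl <- 10 * log10(pmax(ms, 1e-300))
  out <- tibble::tibble(
    time_s = (starts - 1 + win_n / 2) / sample_rate,
    spl_db = spl
  )
  structure(out, step_s = step_s, calibrated = FALSE, offset_db = 0,
            class = c("spl_curve", class(out)))
}

#' Calibrate an SPL curve against a reference tone
#'
#' The field protocol inserts a tone of known level (94 dB SPL at 1 kHz) at
#' the start of each recording. The calibration offset is the difference
#' between that known level and the mean uncalibrated reading over the tone
#' segment; all readings are shifted by it. A pressure-domain multiplication
#' factor and a dB-domain additive offset are the same operation.
#'
#' @param curve An `spl_curve` from [compute_spl_curve()].
#' @param ref_segment Two-element numeric, start/end (s) of the reference-tone
#'   segment.
#' @param ref_level_db Known tone level, dB SPL (default 94).
#' @return The curve shifted onto the calibrated scale (`calibrated = TRUE`,
#'   `offset_db` recorded).
#' @export
calibrate_spl <- function(curve, ref_segment, ref_level_db = 94) {
  abort_unless(inherits(curve, "spl_curve"), "curve must be an spl_curve")
  sel <- curve$time_s >= ref_segment[1] & curve$time_s <= ref_segment[2]
  abort_unless(sum(sel) >= 3, "reference segment covers fewer than 3 readings")
  offset <- ref_level_db - mean(curve$spl_db[sel])
  out <- dplyr::mutate(curve, spl_db = .data$spl_db + offset)
  attr(out, "step_s") <- attr(curve, "step_s")
  attr(out, "calibrated") <- TRUE
  attr(out, "offset_db") <- attr(curve, "offset_db") + offset
  class(out) <- class(curve)
  out
}

#' Maximum SPL over a train pass
#'
#' The highest calibrated reading between the pass start and end times padded
#' by `pad` seconds either side (track joins or curvature occasionally place
#' the loudest moment slightly before or after the train is level with the
#' detector), clipped to the curve extent.
#'
#' @param curve A calibrated `spl_curve`.
#' @param pass_start,pass_end Pass timing, seconds.
#' @param pad Padding either side, seconds (default 5).
#' @return Maximum SPL, dB.
#' @export
max_spl <- function(curve, pass_start, pass_end, pad = 5) {
  abort_unless(inherits(curve, "spl_curve"), "curve must be an spl_curve")
  abort_unless(isTRUE(attr(curve, "calibrated")),
               "max_spl needs a calibrated curve; run calibrate_spl() first")
  sel <- curve$time_s >= pass_start - pad & curve$time_s <= pass_end + pad
  abort_unless(any(sel), "pass window lies entirely outside the curve")
  max(curve$spl_db[sel])
}

#' Standardise SPL to a reference distance
#'
#' Spherical-spreading correction `SPL2 = SPL1 - 20 * log10(r2 / r1)`: the
#' level measured at `r1` metres projected to `r2` metres from the source
#' (+20 dB per tenfold decrease in distance).
#'
#' @param spl_db Measured SPL, dB.
#' @param r1 Measurement distance, metres (> 0).
#' @param r2 Target distance, metres (default 1).
#' @return Corrected SPL, dB.
#' @export
correct_distance <- function(spl_db, r1, r2 = 1) {
  abort_unless(all(r1 > 0) && all(r2 > 0), "distances must be > 0")
  spl_db - 20 * log10(r2 / r1)
}

#' Mean magnitude spectrum of a waveform segment
#'
#' Welch-style averaged magnitude spectrum: Hann-windowed frames of
#' `window` samples with 50% overlap, magnitudes averaged across frames and
#' normalised to unit maximum.
#'
#' @param wave Numeric segment (or list with `wave`/`sample_rate`).
#' @param sample_rate Samples per second.
#' @param window Frame length in samples (default 1024).
#' @return A tibble of class `train_spectrum`: `freq_hz`, `amplitude` (0-1).
#' @export
mean_spectrum <- function(wave, sample_rate = NULL, window = 1024) {
  if (is.list(wave)) {
    sample_rate <- wave$sample_rate
    wave <- wave$wave
  }
  abort_unless(length(wave) >= window,
               "segment shorter than one analysis window (%d samples)", window)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / (window + 1))
  starts <- seq(1L, length(wave) - window + 1L, by = window %/% 2)
  frames <- vapply(starts, function(s)
    Mod(fft(wave[s:(s + window - 1)] * hann))[1:(window %/% 2)],
    numeric(window %/% 2))
  amp <- rowMeans(frames)
  out <- tibble::tibble(
    freq_hz = (seq_len(window %/% 2) - 1) * sample_rate / window,
    amplitude = amp / max(amp)
  )
  structure(out, class = c("train_spectrum", class(out)))
}

#' Classify a site's train-noise frequency group
#'
#' Site mean spectra fall into two groups: a gradual decline in energy across
#' 5-20 kHz ("low"), or multiple distinct harmonic peaks above 5 kHz from
#' wheel squeal/flanging on curved or defective track ("high"). The original
#' assignment was by visual inspection; here it is an explicit heuristic: the
#' site mean spectrum (with an optional bootstrap CI over passes) is scanned
#' for local maxima above `min_freq` whose level exceeds a smoothed spectral
#' envelope by at least `prominence_db`; two or more such peaks give "high".
#'
#' @param site_spectra List of `train_spectrum` tibbles (one per pass), all on
#'   the same frequency grid, or a single spectrum.
#' @param min_freq Only peaks above this frequency (Hz) count (default 5000).
#' @param prominence_db Required height above the smoothed envelope, dB
#'   (default 6).
#' @param n_boot Bootstrap replicates for the CI of the mean spectrum
#'   (0 = none).
#' @param seed Seed for the bootstrap.
#' @return List of class `freq_group`: `group` ("high"/"low"), `n_peaks`,
#'   `peaks` (tibble `freq_hz`, `prominence_db`), `mean_spectrum` (tibble with
#'   `amplitude` and, if bootstrapped, `lo`/`hi`).
#' @export
classify_frequency_group <- function(site_spectra, min_freq = 5000,
                                     prominence_db = 6, n_boot = 0,
                                     seed = 1L) {
  if (inherits(site_spectra, "train_spectrum")) site_spectra <- list(site_spectra)
  abort_unless(length(site_spectra) >= 1, "need at least one spectrum")
  freqs <- site_spectra[[1]]$freq_hz
  for (s in site_spectra) {
    abort_unless(isTRUE(all.equal(s$freq_hz, freqs)),
                 "spectra have mismatched frequency bins")
  }
  amps <- vapply(site_spectra, function(s) s$amplitude, numeric(length(freqs)))
  mean_amp <- rowMeans(amps)
  mean_amp <- mean_amp / max(mean_amp)
  spec_db <- 20 * log10(pmax(mean_amp, 1e-12))

  # smoothed envelope: running median then moving average, ~1 kHz scale
  bw <- max(3L, round(1000 / (freqs[2] - freqs[1])))
  if (bw %% 2 == 0) bw <- bw + 1L
  env <- stats::runmed(spec_db, bw)
  env <- stats::filter(env, rep(1 / bw, bw), sides = 2)
  env[is.na(env)] <- spec_db[is.na(env)]
  prom <- spec_db - as.numeric(env)

  n <- length(freqs)
  is_peak <- c(FALSE, spec_db[2:(n - 1)] > spec_db[1:(n - 2)] &
                 spec_db[2:(n - 1)] >= spec_db[3:n], FALSE)
  hit <- is_peak & freqs > min_freq & prom >= prominence_db
  peaks <- tibble::tibble(freq_hz = freqs[hit], prominence_db = prom[hit])
  # collapse peaks closer than 300 Hz to one
  if (nrow(peaks) > 1) {
    grp <- cumsum(c(TRUE, diff(peaks$freq_hz) > 300))
    peaks <- peaks |>
      dplyr::mutate(grp = grp) |>
      dplyr::group_by(.data$grp) |>
      dplyr::slice_max(.data$prominence_db, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(-"grp")
  }

  ms <- tibble::tibble(freq_hz = freqs, amplitude = mean_amp)
  if (n_boot > 0 && ncol(amps) > 1) {
    bands <- with_seed(seed, {
      reps <- replicate(n_boot, {
        idx <- sample.int(ncol(amps), replace = TRUE)
        rowMeans(amps[, idx, drop = FALSE])
      })
      apply(reps, 1, quantile, probs = c(0.025, 0.975))
    })
    ms$lo <- bands[1, ]
    ms$hi <- bands[2, ]
  }
  structure(list(
    group = if (nrow(peaks) >= 2) "high" else "low",
    n_peaks = nrow(peaks),
    peaks = peaks,
    mean_spectrum = ms
  ), class = "freq_group")
}

#' @export
print.freq_group <- function(x, ...) {
  cat(sprintf("Train-noise frequency group: %s (%d prominent peak%s > 5 kHz)\n",
              x$group, x$n_peaks, if (x$n_peaks == 1) "" else "s"))
  invisible(x)
}

#' Plot an SPL curve
#'
#' @param object An `spl_curve`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.spl_curve <- function(object, ...) {
  lab <- if (isTRUE(attr(object, "calibrated"))) "SPL (dB re 20 µPa)"
         else "Uncalibrated level (dB)"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$spl_db)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = lab) +
    ggplot2::theme_minimal()
}

#' Plot a mean spectrum
#'
#' @param object A `train_spectrum`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.train_spectrum <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$freq_hz / 1000, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Frequency (kHz)", y = "Normalised amplitude") +
    ggplot2::theme_minimal()
}
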