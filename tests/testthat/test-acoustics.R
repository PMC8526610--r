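# SPL curves, calibration, distance standardisation, spectra, grouping.

test_that("SPL sampling density follows the minimum-pitch convention", {
  sr <- 48000
  wave <- sin(2 * pi * 1000 * (0:(5 * sr - 1)) / sr)
  cur <- compute_spl_curve(wave, sr, min_pitch = 5)
  expect_equal(attr(cur, "step_s"), 0.16)
  expect_equal(1 / attr(cur, "step_s"), 6.25)
  expect_equal(median(diff(cur$time_s)), 0.16)
  # min_pitch scales both window and step
  cur2 <- compute_spl_curve(wave, sr, min_pitch = 10)
  expect_equal(attr(cur2, "step_s"), 0.08)
})

test_that("a stationary sine gives a flat curve; scaling shifts it in dB", {
  sr <- 48000
  wave <- 0.1 * sin(2 * pi * 1000 * (0:(5 * sr - 1)) / sr)
  cur <- compute_spl_curve(wave, sr)
  expect_lt(max(cur$spl_db) - min(cur$spl_db), 0.1)
  cur2 <- compute_spl_curve(2 * wave, sr)
  expect_equal(cur2$spl_db - cur$spl_db,
               rep(20 * log10(2), nrow(cur)), tolerance = 1e-9)
})

test_that("calibration is an additive shift anchored to the reference tone", {
  sr <- 48000
  wave <- 0.05 * sin(2 * pi * 1000 * (0:(12 * sr - 1)) / sr)
  cur <- compute_spl_curve(wave, sr)
  cal <- calibrate_spl(cur, c(1, 9), ref_level_db = 94)
  expect_true(attr(cal, "calibrated"))
  expect_equal(mean(cal$spl_db[cal$time_s >= 1 & cal$time_s <= 9]), 94)
  # a curve already reading the reference level gets offset zero
  cal2 <- calibrate_spl(cal, c(1, 9), ref_level_db = 94)
  expect_equal(attr(cal2, "offset_db"), attr(cal, "offset_db"))
  # pure additive shift: every reading moves by exactly the offset
  expect_equal(cal$spl_db, cur$spl_db + attr(cal, "offset_db"))
  expect_error(calibrate_spl(cur, c(1, 1.1)), "fewer than 3")
})

test_that("max SPL uses the +/- 5 s padded window", {
  sr <- 8000
  n <- 60 * sr
  wave <- numeric(n) + 1e-4
  peak_at <- function(t0) {
    w <- wave
    idx <- (t0 * sr):((t0 + 1) * sr)
    w[idx] <- 0.5 * sin(2 * pi * 1000 * idx / sr)
    w
  }
  # pass nominally 20-30 s; peak 3 s after pass end is captured by the pad
  cur <- compute_spl_curve(peak_at(33), sr)
  cal <- calibrate_spl(cur, c(1, 9), ref_level_db = 94)
  tone_level <- 94  # flat reference level everywhere except the peak
  expect_gt(max_spl(cal, 20, 30), tone_level + 20)
  # peak 7 s after pass end falls outside the pad
  cur2 <- calibrate_spl(compute_spl_curve(peak_at(37), sr), c(1, 9), 94)
  expect_lt(max_spl(cur2, 20, 30), tone_level + 1)
  expect_error(max_spl(cur2, 500, 510), "outside")
  expect_error(max_spl(compute_spl_curve(peak_at(33), sr), 20, 30),
               "calibrated")
})

test_that("distance correction is spherical spreading", {
  expect_equal(correct_distance(100, 10, 10), 100)
  expect_equal(correct_distance(100, 10, 1), 120)
  expect_equal(correct_distance(107.3, 10.6, 1), 107.3 + 20 * log10(10.6))
  # antisymmetry under swapping the two distances
  d1 <- correct_distance(90, 4, 9) - 90
  d2 <- correct_distance(90, 9, 4) - 90
  expect_equal(d1, -d2)
  expect_error(correct_distance(100, 0), "> 0")
})

test_that("full calibration round trip recovers a known pass peak", {
  aud <- simulate_calibration_audio(
    passes = tibble::tibble(start_s = 20, end_s = 26),
    peak_spl_db = 107.3, seed = 5)
  cal <- calibrate_spl(compute_spl_curve(aud), c(1, 9), 94)
  got <- max_spl(cal, 20, 26)
  expect_lt(abs(got - 107.3), 0.5)
  # distance standardisation of the recovered maximum
  expect_equal(correct_distance(got, 10.6), got + 20 * log10(10.6))
})

test_that("mean spectrum finds tones, flat noise, and harmonic stacks", {
  sr <- 48000
  t <- (0:(2 * sr - 1)) / sr
  sp <- mean_spectrum(0.2 * sin(2 * pi * 1000 * t), sr)
  expect_equal(sp$freq_hz[which.max(sp$amplitude)], 1000, tolerance = 50)
  set.seed(3)
  spn <- mean_spectrum(rnorm(4 * sr) * 0.05, sr)
  mid <- spn$amplitude[spn$freq_hz > 2000 & spn$freq_hz < 20000]
  expect_lt(sd(mid) / mean(mid), 0.2)
  harm <- 0.1 * (sin(2 * pi * 6000 * t) + sin(2 * pi * 9000 * t) +
                   sin(2 * pi * 12000 * t))
  sph <- mean_spectrum(harm, sr)
  top3 <- sph$freq_hz[order(sph$amplitude, decreasing = TRUE)[1:3]]
  expect_equal(sort(round(top3, -2)), c(6000, 9000, 12000))
  expect_error(mean_spectrum(numeric(10), sr), "window")
})

test_that("frequency grouping separates squeal sites from broadband sites", {
  sr <- 48000
  passes <- tibble::tibble(start_s = c(15, 40), end_s = c(21, 46))
  lo <- simulate_calibration_audio(passes = passes, peak_spl_db = 105,
                                   seed = 6)
  hi <- simulate_calibration_audio(passes = passes, peak_spl_db = 105,
                                   squeal = TRUE, seed = 6)
  spec_of <- function(aud, i) {
    idx <- (passes$start_s[i] * sr):(passes$end_s[i] * sr)
    mean_spectrum(aud$wave[idx], sr)
  }
  g_lo <- classify_frequency_group(list(spec_of(lo, 1), spec_of(lo, 2)),
                                   n_boot = 50)
  g_hi <- classify_frequency_group(list(spec_of(hi, 1), spec_of(hi, 2)))
  expect_identical(g_lo$group, "low")
  expect_identical(g_hi$group, "high")
  expect_gte(g_hi$n_peaks, 2)
  expect_true(all(g_hi$peaks$freq_hz > 5000))
  expect_true(all(c("lo", "hi") %in% names(g_lo$mean_spectrum)))
  expect_error(
    classify_frequency_group(list(spec_of(lo, 1),
                                  mean_spectrum(rnorm(2048), 8000))),
    "mismatched")
})

test_that("a single weak bump stays in the low group", {
  freqs <- seq(0, 24000, by = 46.875)
  amp <- exp(-freqs / 8000)
  bump <- amp + 0.3 * amp * exp(-(freqs - 7000)^2 / (2 * 200^2))
  sp <- tibble::tibble(freq_hz = freqs, amplitude = bump / max(bump))
  class(sp) <- c("train_spectrum", class(sp))
  expect_identical(classify_frequency_group(list(sp))$group, "low")
})

test_that("WAV files round-trip at 16 and 24 bit", {
  sr <- 8000
  wave <- 0.3 * sin(2 * pi * 440 * (0:(sr - 1)) / sr)
  for (bits in c(16, 24)) {
    f <- withr::local_tempfile(fileext = ".wav")
    write_wav(wave, sr, f, bits = bits)
    r <- read_wav(f)
    expect_identical(r$sample_rate, sr)
    expect_lt(max(abs(r$wave - wave)), 2^-(bits - 2))
  }
})
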