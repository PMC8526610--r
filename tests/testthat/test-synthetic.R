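# Synthetic generator: train schedules, suppressed point process, audio truth.

test_that("train schedule handles the zero-rate case and rejects saturation", {
  cfg <- site_config(trains_per_hour = 0)
  expect_identical(nrow(simulate_train_schedule(cfg, seed = 1)), 0L)
  expect_error(simulate_train_schedule(site_config(trains_per_hour = 500)),
               "overlap")
})

test_that("schedule count is Poisson around rate x duration", {
  cfg <- site_config(trains_per_hour = 6, recording_duration = 3600)
  counts <- vapply(1:1000, function(s)
    nrow(simulate_train_schedule(cfg, seed = s)), numeric(1))
  # dropped coincident arrivals shave a little off the mean; 3 SE band on 6
  se <- sqrt(6 / 1000)
  expect_lt(abs(mean(counts) - 6), 3 * se)
  expect_gt(var(counts) / mean(counts), 0.8)  # near-Poisson dispersion
})

test_that("schedule physical fields are internally consistent", {
  cfg <- site_config(trains_per_hour = 10)
  sch <- simulate_train_schedule(cfg, seed = 42)
  expect_true(all(diff(sch$start_s) >= 0))
  expect_true(all(sch$end_s > sch$start_s))
  expect_equal(sch$length_m, sch$n_cars * 21)
  # duration = length / speed: speed recomputed from the other two fields
  expect_equal(sch$speed_kmh,
               (sch$length_m / (sch$end_s - sch$start_s)) * 3.6)
  # a 12-car train at the default 21 m mean car length is 252 m
  expect_equal(unique(sch$length_m[sch$n_cars == 12]), 252)
})

test_that("same seed gives bit-identical outputs", {
  cfg <- site_config(trains_per_hour = 8)
  expect_identical(simulate_train_schedule(cfg, seed = 7),
                   simulate_train_schedule(cfg, seed = 7))
  sch <- simulate_train_schedule(cfg, seed = 7)
  expect_identical(simulate_bat_calls(sch, cfg, seed = 9),
                   simulate_bat_calls(sch, cfg, seed = 9))
  aud1 <- simulate_calibration_audio(seed = 3)
  aud2 <- simulate_calibration_audio(seed = 3)
  expect_identical(aud1$wave, aud2$wave)
})

test_that("zero baseline rate yields no events", {
  cfg <- site_config(baseline_rate = 0)
  expect_identical(nrow(simulate_bat_calls(tibble::tibble(), cfg)), 0L)
})

test_that("with constant rate and no trains, inter-event times are exponential", {
  cfg <- site_config(trains_per_hour = 0, baseline_rate = 200,
                     site_effect_sd = 0, time_trend = 0)
  sup <- suppression_config(factor_s = 1, dispersion_theta = Inf)
  empty_sched <- simulate_train_schedule(site_config(trains_per_hour = 0))
  ps <- vapply(1:5, function(s) {
    calls <- simulate_bat_calls(empty_sched, cfg, sup, seed = s,
                                site_effect = 0)
    gaps <- diff(calls$time_s)
    suppressWarnings(stats::ks.test(gaps, "pexp", 200 / 3600)$p.value)
  }, numeric(1))
  expect_gte(sum(ps > 0.01), 4)
})

test_that("no suppression leaves post-train and baseline rates equal", {
  r <- empirical_suppression_ratio(150, factor_s = 1, duration_tau = 120,
                                   seed = 100)
  expect_lt(abs(r - 1), 0.07)
})

test_that("post-train / baseline rate ratio recovers the suppression factor", {
  r <- empirical_suppression_ratio(500, factor_s = 0.5, duration_tau = 120,
                                   seed = 200)
  expect_lt(abs(r - 0.5), 0.05)
})

test_that("suppression factor is recovered across the (s, tau) grid", {
  grid <- expand.grid(s = c(0.3, 0.5, 0.8), tau = c(30, 120, 480))
  for (i in seq_len(nrow(grid))) {
    s <- grid$s[i]; tau <- grid$tau[i]
    # short windows collect few events, so boost the baseline rate there
    rate <- if (tau < 60) 400 else 153 / 3.5
    r <- empirical_suppression_ratio(150, factor_s = s, duration_tau = tau,
                                     baseline_rate = rate,
                                     seed = 300 + i)
    expect_lt(abs(r - s), 0.06)
  }
})

test_that("exponential-recovery option suppresses less than the step window", {
  r_step <- empirical_suppression_ratio(100, factor_s = 0.5,
                                        duration_tau = 120, seed = 400)
  cfg <- site_config(site_effect_sd = 0, time_trend = 0)
  sup_exp <- suppression_config(factor_s = 0.5, duration_tau = 120,
                                recovery = "exponential",
                                dispersion_theta = Inf)
  sched <- simulate_train_schedule(cfg, seed = 1)
  expect_s3_class(simulate_bat_calls(sched, cfg, sup_exp, seed = 2),
                  "tbl_df")
  # step factor at tau/2 after a pass end is s; exponential has recovered
  f_exp <- railbat:::suppression_factor_at(60, 0,
                                           sup_exp)
  expect_gt(f_exp, 0.5)
  expect_lt(f_exp, 1)
  expect_lt(abs(r_step - 0.5), 0.07)
})

test_that("calibration audio without passes is tone followed by silence", {
  aud <- simulate_calibration_audio(tone_duration = 2, duration_s = 4,
                                    seed = 1)
  sr <- aud$sample_rate
  expect_gt(sqrt(mean(aud$wave[1:(1.9 * sr)]^2)), 0)
  expect_identical(unique(aud$wave[(2.1 * sr):(4 * sr - 1)]), 0)
})

test_that("clipping levels are rejected", {
  expect_error(simulate_calibration_audio(ref_level_db = 135), "clip")
  expect_error(
    simulate_calibration_audio(
      passes = tibble::tibble(start_s = 15, end_s = 20),
      peak_spl_db = 129),
    "clip")
})

test_that("interval-count emulator recovers its own generating model", {
  d <- simulate_interval_counts(n_gaps = 2000, seed = 11)
  expect_identical(nrow(d), 6000L)
  f <- fit_nb(d, terms = c("category", "nightly_total",
                           "time_since_start_h"))
  co <- tidy(f)
  expect_lt(abs(co$estimate[co$term == "categoryafter"] + 0.78), 0.08)
  expect_lt(abs(co$estimate[co$term == "nightly_total"] - 0.004), 0.001)
  expect_lt(abs(f$theta - 8), 2)
})
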