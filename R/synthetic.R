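# Synthetic study generator: train schedules, bat-pass point processes with
# post-train suppression, covariates, and calibration audio with known truth.

#' Site configuration for the synthetic generator
#'
#' Defaults reproduce the study conditions of the trackside survey the package
#' models: 3.5 h recordings at wooded rail-side sites, a mean of 8.6 train
#' passes per hour (site means spanning 1.7-19.3), a baseline of 153 bat
#' passes per 3.5 h recording, and a positive within-night activity trend.
#'
#' @param site_id Character site label.
#' @param trains_per_hour Mean train passes per hour (>= 0).
#' @param n_tracks Number of tracks (1 or 2). Overlapping passes can only
#'   occur at two-track sites.
#' @param detector_train_distance Distance (m) from detector to the near side
#'   of passing trains, one value per track (recycled).
#' @param baseline_rate Baseline bat-pass rate, passes per hour (lambda0).
#' @param site_effect_sd Standard deviation of the log-scale site/night random
#'   intercept.
#' @param time_trend Log-rate slope per hour since recording start.
#' @param recording_duration Recording length in seconds (default 12600 = 3.5 h).
#' @return A list of class `site_config`.
#' @export
site_config <- function(site_id = "S01",
                        trains_per_hour = 8.6,
                        n_tracks = 2,
                        detector_train_distance = 10.6,
                        baseline_rate = 153 / 3.5,
                        site_effect_sd = 0.5,
                        time_trend = 0.41,
                        recording_duration = 12600) {
  abort_unless(trains_per_hour >= 0, "trains_per_hour must be >= 0")
  abort_unless(baseline_rate >= 0, "baseline_rate must be >= 0")
  abort_unless(recording_duration > 0, "recording_duration must be > 0")
  abort_unless(n_tracks %in% c(1L, 2L), "n_tracks must be 1 or 2")
  abort_unless(all(detector_train_distance > 0),
               "detector_train_distance must be > 0")
  structure(list(
    site_id = site_id,
    trains_per_hour = trains_per_hour,
    n_tracks = as.integer(n_tracks),
    detector_train_distance = rep_len(detector_train_distance, n_tracks),
    baseline_rate = baseline_rate,
    site_effect_sd = site_effect_sd,
    time_trend = time_trend,
    recording_duration = recording_duration
  ), class = "site_config")
}

#' Post-train suppression configuration
#'
#' The disturbance signal the whole pipeline estimates: after each train pass
#' the bat-pass rate is multiplied by `factor_s` for `duration_tau` seconds
#' (rectangular window anchored at pass end), then recovers fully. Defaults
#' encode the headline effect the analysis is designed to detect: activity
#' roughly halved for two minutes after each pass.
#'
#' Count overdispersion is induced by a gamma frailty multiplier drawn per
#' `frailty_block_s`-second block of the night, giving block counts a negative
#' binomial (NB2) distribution with shape `dispersion_theta`. Set
#' `dispersion_theta = Inf` for a pure (equidispersed) Poisson process.
#'
#' @param factor_s Multiplicative rate factor in (0, 1] applied after each pass.
#' @param duration_tau Seconds the factor applies after pass end (>= 0).
#' @param dispersion_theta NB2 shape of the per-block gamma frailty (> 0, may
#'   be `Inf`).
#' @param frailty_block_s Block length (s) over which one frailty draw applies.
#' @param recovery Either `"step"` (rectangular window, default) or
#'   `"exponential"`: rate factor `1 - (1 - s) * exp(-(t - end)/tau)` after the
#'   most recent pass end.
#' @return A list of class `suppression_config`.
#' @export
suppression_config <- function(factor_s = 0.5,
                               duration_tau = 120,
                               dispersion_theta = 2,
                               frailty_block_s = 30,
                               recovery = c("step", "exponential")) {
  abort_unless(factor_s > 0 && factor_s <= 1, "factor_s must be in (0, 1]")
  abort_unless(duration_tau >= 0, "duration_tau must be >= 0")
  abort_unless(dispersion_theta > 0, "dispersion_theta must be > 0")
  abort_unless(frailty_block_s > 0, "frailty_block_s must be > 0")
  structure(list(
    factor_s = factor_s,
    duration_tau = duration_tau,
    dispersion_theta = dispersion_theta,
    frailty_block_s = frailty_block_s,
    recovery = match.arg(recovery)
  ), class = "suppression_config")
}

#' Train schedule configuration
#'
#' @param mean_car_length Mean carriage length in metres (default 21, the mean
#'   over the rolling-stock models operating on the surveyed lines).
#' @param car_count_range Integer vector of possible carriage counts.
#' @param speed_range Two-element numeric, min/max speed in km/h.
#' @param pass_overlap_prob Probability that a pass coincides with an
#'   opposite-track pass at a two-track site (study rate: 36/1144).
#' @return A list of class `train_schedule_config`.
#' @export
train_schedule_config <- function(mean_car_length = 21,
                                  car_count_range = 1:12,
                                  speed_range = c(60, 160),
                                  pass_overlap_prob = 36 / 1144) {
  abort_unless(mean_car_length > 0, "mean_car_length must be > 0")
  abort_unless(length(car_count_range) >= 1 && all(car_count_range >= 1),
               "car_count_range must be non-empty positive integers")
  abort_unless(length(speed_range) == 2 && all(speed_range > 0),
               "speed_range must be two positive values")
  abort_unless(pass_overlap_prob >= 0 && pass_overlap_prob <= 1,
               "pass_overlap_prob must be a probability")
  structure(list(
    mean_car_length = mean_car_length,
    car_count_range = as.integer(car_count_range),
    speed_range = sort(as.numeric(speed_range)),
    pass_overlap_prob = pass_overlap_prob
  ), class = "train_schedule_config")
}

# evaluate expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a night's train schedule
#'
#' Train arrivals follow a homogeneous Poisson process at the site's mean rate,
#' with a minimum headway of one pass duration: an arrival that would start
#' while the previous train is still passing either becomes a coincident
#' opposite-track (overlapping) pass, with probability
#' `tcfg$pass_overlap_prob` at two-track sites, or is dropped. Pass duration is
#' length / speed, with length = carriage count x mean carriage length.
#'
#' @param cfg A [site_config()].
#' @param tcfg A [train_schedule_config()].
#' @param seed Integer seed; the schedule is reproducible bit-for-bit.
#' @return A tibble with one row per train pass: `train_id`, `start_s`,
#'   `end_s`, `track`, `n_cars`, `length_m`, `speed_kmh`, `overlap`.
#' @export
simulate_train_schedule <- function(cfg, tcfg = train_schedule_config(),
                                    seed = 1L) {
  abort_unless(inherits(cfg, "site_config"), "cfg must be a site_config")
  abort_unless(inherits(tcfg, "train_schedule_config"),
               "tcfg must be a train_schedule_config")
  # mean pass duration implied by the schedule config, seconds
  mean_dur <- mean(tcfg$car_count_range) * tcfg$mean_car_length /
    (mean(tcfg$speed_range) / 3.6)
  abort_unless(cfg$trains_per_hour / 3600 * mean_dur < 0.5,
               paste("trains_per_hour = %g is too high: passes of ~%.1f s",
                     "cannot be placed without near-total overlap"),
               cfg$trains_per_hour, mean_dur)

  empty <- tibble::tibble(
    train_id = integer(), start_s = numeric(), end_s = numeric(),
    track = integer(), n_cars = integer(), length_m = numeric(),
    speed_kmh = numeric(), overlap = logical()
  )
  if (cfg$trains_per_hour == 0) return(empty)

  with_seed(seed, {
    dur <- cfg$recording_duration
    n <- rpois(1, cfg$trains_per_hour / 3600 * dur)
    starts <- sort(runif(n, 0, dur))
    n_cars <- sample(tcfg$car_count_range, n, replace = TRUE)
    length_m <- n_cars * tcfg$mean_car_length
    speed_kmh <- runif(n, tcfg$speed_range[1], tcfg$speed_range[2])
    ends <- starts + length_m / (speed_kmh / 3.6)
    track <- sample.int(cfg$n_tracks, n, replace = TRUE)
    overlap <- rep(FALSE, n)
    keep <- rep(TRUE, n)
    prev <- 1L
    for (i in seq_len(n)[-1]) {
      if (starts[i] < ends[prev]) {
        if (cfg$n_tracks == 2 && runif(1) < tcfg$pass_overlap_prob) {
          track[i] <- 3L - track[prev]
          overlap[i] <- TRUE
          overlap[prev] <- TRUE
          prev <- if (ends[i] > ends[prev]) i else prev
        } else {
          keep[i] <- FALSE
        }
      } else {
        prev <- i
      }
    }
    tibble::tibble(
      train_id = seq_len(sum(keep)),
      start_s = starts[keep], end_s = ends[keep], track = track[keep],
      n_cars = n_cars[keep], length_m = length_m[keep],
      speed_kmh = speed_kmh[keep], overlap = overlap[keep]
    )
  })
}

# suppression factor at times t given pass end times (step or exponential)
suppression_factor_at <- function(t, pass_ends, sup) {
  if (length(pass_ends) == 0 || sup$factor_s == 1) return(rep(1, length(t)))
  pass_ends <- sort(pass_ends)
  idx <- findInterval(t, pass_ends)  # most recent pass end at or before t
  f <- rep(1, length(t))
  has_prev <- idx > 0
  dt <- t[has_prev] - pass_ends[idx[has_prev]]
  if (sup$recovery == "step") {
    fs <- ifelse(dt < sup$duration_tau, sup$factor_s, 1)
  } else {
    fs <- 1 - (1 - sup$factor_s) * exp(-dt / max(sup$duration_tau, 1e-9))
  }
  f[has_prev] <- fs
  f
}

#' Simulate bat-call timestamps around a train schedule
#'
#' Events are drawn from an inhomogeneous Poisson process with rate
#' `lambda(t) = lambda0 * exp(site_effect + time_trend * t) * m(t)`, where
#' `m(t)` is the post-train suppression factor, realised by thinning against a
#' per-block envelope rate. A gamma frailty per block induces NB2
#' overdispersion of block counts (see [suppression_config()]).
#'
#' @param schedule A train schedule tibble from [simulate_train_schedule()]
#'   (may have zero rows).
#' @param cfg A [site_config()].
#' @param sup A [suppression_config()].
#' @param seed Integer seed.
#' @param site_effect Optional fixed log-scale intercept offset; if `NULL`
#'   (default) one draw from `N(0, site_effect_sd^2)` is made.
#' @param species_prob Probability a pass is a common (vs soprano) pipistrelle;
#'   the study proportion 5798/6255 by default.
#' @param buzz_prob Probability a pass carries a feeding buzz.
#' @return A tibble of call events sorted by time: `time_s`, `species`
#'   (`"common_pipistrelle"` / `"soprano_pipistrelle"`), `feeding_buzz`.
#' @export
simulate_bat_calls <- function(schedule, cfg, sup = suppression_config(),
                               seed = 1L, site_effect = NULL,
                               species_prob = 5798 / 6255,
                               buzz_prob = 0.05) {
  abort_unless(inherits(cfg, "site_config"), "cfg must be a site_config")
  abort_unless(inherits(sup, "suppression_config"),
               "sup must be a suppression_config")
  if (nrow(schedule) > 0) {
    abort_unless(!is.unsorted(schedule$start_s), "schedule must be sorted")
  }
  empty <- tibble::tibble(time_s = numeric(), species = character(),
                          feeding_buzz = logical())
  if (cfg$baseline_rate == 0) return(empty)

  with_seed(seed, {
    T_end <- cfg$recording_duration
    eff <- if (is.null(site_effect)) rnorm(1, 0, cfg$site_effect_sd) else site_effect
    lam0 <- cfg$baseline_rate / 3600  # per second
    trend <- cfg$time_trend / 3600    # per second on the log scale
    pass_ends <- sort(schedule$end_s)

    edges <- unique(c(seq(0, T_end, by = sup$frailty_block_s), T_end))
    n_blk <- length(edges) - 1
    frailty <- if (is.finite(sup$dispersion_theta)) {
      rgamma(n_blk, shape = sup$dispersion_theta, rate = sup$dispersion_theta)
    } else rep(1, n_blk)

    times <- vector("list", n_blk)
    for (b in seq_len(n_blk)) {
      lo <- edges[b]; hi <- edges[b + 1]
      # envelope: trend evaluated at its block maximum, suppression <= 1
      lam_max <- lam0 * exp(eff + trend * if (trend > 0) hi else lo) * frailty[b]
      n_cand <- rpois(1, lam_max * (hi - lo))
      if (n_cand == 0) next
      tc <- runif(n_cand, lo, hi)
      lam_t <- lam0 * exp(eff + trend * tc) * frailty[b] *
        suppression_factor_at(tc, pass_ends, sup)
      keep <- runif(n_cand) < lam_t / lam_max
      times[[b]] <- tc[keep]
    }
    tt <- sort(unlist(times))
    tibble::tibble(
      time_s = tt,
      species = dplyr::if_else(runif(length(tt)) < species_prob,
                               "common_pipistrelle", "soprano_pipistrelle"),
      feeding_buzz = runif(length(tt)) < buzz_prob
    )
  })
}

#' Simulate one survey night (trains, calls, covariates)
#'
#' @inheritParams simulate_train_schedule
#' @inheritParams simulate_bat_calls
#' @param night_id Character night label.
#' @return A list with tibbles `trains`, `calls` and a one-row `night` table
#'   (`night_id`, `site_id`, `trains_per_hour`, mean weather values).
#' @export
simulate_night <- function(cfg, sup = suppression_config(),
                           tcfg = train_schedule_config(), seed = 1L,
                           night_id = "N01", site_effect = NULL) {
  trains <- simulate_train_schedule(cfg, tcfg, seed = seed)
  calls <- simulate_bat_calls(trains, cfg, sup, seed = seed + 1L,
                              site_effect = site_effect)
  weather <- with_seed(seed + 2L, {
    tibble::tibble(
      wind = pmin(pmax(rnorm(1, 7, 3), 0), 15),       # km/h, protocol cap
      temperature = pmax(rnorm(1, 15, 3), 10),        # deg C, protocol floor
      humidity = pmin(pmax(rnorm(1, 80, 8), 40), 100) # %
    )
  })
  night <- dplyr::bind_cols(
    tibble::tibble(night_id = night_id, site_id = cfg$site_id,
                   trains_per_hour = cfg$trains_per_hour,
                   recording_duration = cfg$recording_duration),
    weather
  )
  list(trains = trains, calls = calls, night = night)
}

#' Simulate a multi-site, multi-night study
#'
#' Site mean train rates are spread evenly across the observed study range
#' (1.7-19.3 trains per hour by default) and each site contributes
#' `nights_per_site` nights with a shared site random intercept.
#'
#' @param n_sites Number of sites.
#' @param nights_per_site Nights recorded per site.
#' @param rate_range Two-element range of site mean trains per hour.
#' @param sup A [suppression_config()].
#' @param tcfg A [train_schedule_config()].
#' @param seed Integer seed.
#' @param ... Further arguments passed to [site_config()] (e.g.
#'   `baseline_rate`, `site_effect_sd`, `recording_duration`).
#' @return A list of tibbles: `calls` and `trains` (keyed by `night_id`),
#'   `nights` (one row per night with covariates), `sites`.
#' @export
simulate_study <- function(n_sites = 12, nights_per_site = 2,
                           rate_range = c(1.7, 19.3),
                           sup = suppression_config(),
                           tcfg = train_schedule_config(),
                           seed = 1L, ...) {
  abort_unless(n_sites >= 1, "n_sites must be >= 1")
  rates <- if (n_sites == 1) mean(rate_range) else
    seq(rate_range[1], rate_range[2], length.out = n_sites)
  site_ids <- sprintf("S%02d", seq_len(n_sites))
  site_effects <- with_seed(seed, rnorm(n_sites, 0, 1))

  out_calls <- list(); out_trains <- list(); out_nights <- list()
  k <- 0L
  for (i in seq_len(n_sites)) {
    cfg <- site_config(site_id = site_ids[i], trains_per_hour = rates[i], ...)
    eff <- site_effects[i] * cfg$site_effect_sd
    for (j in seq_len(nights_per_site)) {
      k <- k + 1L
      nid <- sprintf("%s_n%d", site_ids[i], j)
      nt <- simulate_night(cfg, sup, tcfg, seed = seed + 13L * k,
                           night_id = nid, site_effect = eff)
      out_calls[[k]] <- dplyr::mutate(nt$calls, night_id = nid, .before = 1)
      out_trains[[k]] <- dplyr::mutate(nt$trains, night_id = nid, .before = 1)
      out_nights[[k]] <- nt$night
    }
  }
  list(
    calls = dplyr::bind_rows(out_calls),
    trains = dplyr::bind_rows(out_trains),
    nights = dplyr::bind_rows(out_nights),
    sites = tibble::tibble(site_id = site_ids, trains_per_hour = rates)
  )
}

#' Simulate a gap-level interval-count table for estimator studies
#'
#' A fast emulator of the analysis table produced by [assemble_dataset()],
#' drawing interval counts directly from the NB2 count model rather than from
#' the underlying point process. Intended for parameter-recovery and
#' type-I-error studies of the screening / AICc-averaging chain, where the
#' quantity under test is the estimator, so intervals are populated richly
#' enough that count noise does not dominate (see the methods vignette).
#'
#' @param n_gaps Number of qualifying inter-train gaps.
#' @param mean_before Expected count in a `before` interval at covariate means.
#' @param theta NB2 dispersion of interval counts.
#' @param beta_after,beta_between True log incidence-rate contrasts of the
#'   `after` and `between` categories against `before`.
#' @param beta_nightly,beta_time,beta_wind True coefficients of the centred
#'   nightly total, time since start (h), and wind (km/h) covariates.
#' @param n_nights Number of nights the gaps are spread across.
#' @param seed Integer seed.
#' @return A tibble with one row per interval: `gap_id`, `night_id`,
#'   `category` (factor, reference `"before"`), `count`, `nightly_total`,
#'   `time_since_start_h`, `wind`.
#' @export
simulate_interval_counts <- function(n_gaps = 900, mean_before = 8, theta = 8,
                                     beta_after = -0.78, beta_between = 0,
                                     beta_nightly = 0.004, beta_time = 0.41,
                                     beta_wind = 0, n_nights = 24, seed = 1L) {
  abort_unless(n_gaps >= 1, "n_gaps must be >= 1")
  with_seed(seed, {
    night_id <- sprintf("n%02d", sample.int(n_nights, n_gaps, replace = TRUE))
    nightly <- setNames(pmax(rnorm(n_nights, 153, 80), 5), sprintf("n%02d", 1:n_nights))
    wind_n <- setNames(pmin(pmax(rnorm(n_nights, 7, 3), 0), 15), names(nightly))
    time_h <- runif(n_gaps, 0, 3.5)
    cats <- c("before", "between", "after")
    grid <- tidyr::expand_grid(gap = seq_len(n_gaps), category = cats)
    nid_row <- night_id[grid$gap]
    nightly_row <- unname(nightly[nid_row]) - 153
    time_row <- time_h[grid$gap] - 1.75
    wind_row <- unname(wind_n[nid_row]) - 7
    eta <- log(mean_before) +
      ifelse(grid$category == "after", beta_after,
             ifelse(grid$category == "between", beta_between, 0)) +
      beta_nightly * nightly_row + beta_time * time_row + beta_wind * wind_row
    tibble::tibble(
      gap_id = grid$gap,
      night_id = nid_row,
      category = factor(grid$category, levels = cats),
      count = rnbinom(nrow(grid), size = theta, mu = exp(eta)),
      nightly_total = nightly_row,
      time_since_start_h = time_row,
      wind = wind_row
    )
  })
}

#' Synthesize a calibration recording with known SPL ground truth
#'
#' Builds a mono waveform opening with a pure reference tone whose true SPL is
#' `ref_level_db` (the field protocol inserts a 1 kHz, 94 dB calibrator tone at
#' the start of each recording), followed by band-limited noise bursts at the
#' supplied train-pass times whose true peak SPLs are returned in a
#' ground-truth table. Amplitude maps to SPL via
#' `spl = full_scale_db + 20*log10(rms)`, so a full-scale sine corresponds to
#' `full_scale_db - 3.01` dB; a requested level that would clip is an error.
#'
#' @param passes Tibble with `start_s`, `end_s` of each train pass (may be
#'   empty). Passes must start after the tone ends.
#' @param peak_spl_db True peak SPL per pass, dB (recycled).
#' @param ref_level_db True SPL of the opening reference tone, dB (default 94).
#' @param tone_freq Reference tone frequency, Hz (default 1000).
#' @param tone_duration Tone length, s.
#' @param duration_s Total recording length, s; default covers the last pass
#'   plus 10 s.
#' @param sample_rate Samples per second (default 48000; must be at least 4x
#'   `tone_freq`).
#' @param full_scale_db SPL assigned to a unit-RMS signal.
#' @param noise_band Two-element passband (Hz) of the burst noise.
#' @param squeal If `TRUE`, add harmonic "squeal" tones at 6/9/12 kHz to each
#'   burst, emulating wheel-rail noise on curved or defective track (the
#'   high-frequency site group).
#' @param seed Integer seed for the noise.
#' @return A list: `wave` (numeric vector in [-1, 1]), `sample_rate`, `truth`
#'   (tibble `start_s`, `end_s`, `true_peak_spl_db`), `tone` (tibble `start_s`,
#'   `end_s`, `level_db`, `freq_hz`).
#' @export
simulate_calibration_audio <- function(passes = tibble::tibble(start_s = numeric(),
                                                               end_s = numeric()),
                                       peak_spl_db = 107.3,
                                       ref_level_db = 94, tone_freq = 1000,
                                       tone_duration = 10, duration_s = NULL,
                                       sample_rate = 48000,
                                       full_scale_db = 130,
                                       noise_band = c(200, 8000),
                                       squeal = FALSE, seed = 1L) {
  abort_unless(sample_rate >= 4 * tone_freq,
               "sample_rate must be at least 4x tone_freq")
  n_pass <- nrow(passes)
  peak_spl_db <- rep_len(peak_spl_db, max(n_pass, 1L))
  if (is.null(duration_s)) {
    duration_s <- if (n_pass) max(passes$end_s) + 10 else tone_duration + 5
  }
  if (n_pass) {
    abort_unless(all(passes$start_s > tone_duration),
                 "passes must start after the reference tone ends")
    abort_unless(all(passes$end_s + 5 <= duration_s),
                 "duration_s too short for the last pass (+5 s tail)")
  }
  rms_for <- function(db) 10^((db - full_scale_db) / 20)
  tone_amp <- sqrt(2) * rms_for(ref_level_db)
  abort_unless(tone_amp <= 1,
               "ref_level_db %.1f dB clips at full_scale_db %.1f dB",
               ref_level_db, full_scale_db)
  # burst crest factor ~4 for band-limited gaussian noise
  abort_unless(all(4 * rms_for(peak_spl_db[seq_len(n_pass)]) <= 1),
               "a pass peak SPL clips at full_scale_db %.1f dB", full_scale_db)

  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  wave <- numeric(n)
  tone_idx <- t < tone_duration
  wave[tone_idx] <- tone_amp * sin(2 * pi * tone_freq * t[tone_idx])

  if (n_pass) {
    wave <- with_seed(seed, {
      for (i in seq_len(n_pass)) {
        s0 <- passes$start_s[i]; s1 <- passes$end_s[i]
        i0 <- max(1L, floor(s0 * sample_rate) + 1L)
        i1 <- min(n, ceiling(s1 * sample_rate))
        m <- i1 - i0 + 1L
        noise <- band_limited_noise(m, sample_rate, noise_band)
        # raised-cosine rise/fall with a flat plateau >= 1.5 s at peak RMS
        tp <- (seq_len(m) - 1) / sample_rate
        dur <- (m - 1) / sample_rate
        ramp <- max(0.25, min(1, (dur - 1.5) / 2))
        env <- rep(1, m)
        rise <- tp < ramp
        fall <- tp > dur - ramp
        env[rise] <- 0.5 - 0.5 * cos(pi * tp[rise] / ramp)
        env[fall] <- 0.5 - 0.5 * cos(pi * (dur - tp[fall]) / ramp)
        burst <- rms_for(peak_spl_db[i]) * env * noise
        if (squeal) {
          sq <- rowSums(sapply(c(6000, 9000, 12000), function(f)
            sin(2 * pi * f * tp + runif(1, 0, 2 * pi))))
          burst <- burst + 0.25 * rms_for(peak_spl_db[i]) * env * sq
        }
        wave[i0:i1] <- wave[i0:i1] + burst
      }
      wave
    })
  }
  abort_unless(max(abs(wave)) <= 1, "synthesized waveform clipped")
  list(
    wave = wave,
    sample_rate = sample_rate,
    truth = tibble::tibble(
      start_s = passes$start_s, end_s = passes$end_s,
      true_peak_spl_db = peak_spl_db[seq_len(n_pass)]
    ),
    tone = tibble::tibble(start_s = 0, end_s = tone_duration,
                          level_db = ref_level_db, freq_hz = tone_freq)
  )
}

# unit-RMS gaussian noise restricted to [band[1], band[2]] Hz via FFT masking
band_limited_noise <- function(n, sample_rate, band) {
  x <- rnorm(n)
  spec <- fft(x)
  freqs <- (seq_len(n) - 1) * sample_rate / n
  freqs <- pmin(freqs, sample_rate - freqs)  # two-sided
  mask <- freqs >= band[1] & freqs <= band[2]
  x <- Re(fft(spec * mask, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}
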