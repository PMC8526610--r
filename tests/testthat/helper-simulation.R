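# Shared simulation helpers for the test suite.

# total length of the union of [s, e] intervals (independent re-derivation,
# also used to slice suppressed vs baseline time)
union_intervals <- function(starts, ends) {
  if (length(starts) == 0) return(matrix(numeric(), ncol = 2))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]
  res <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > tail(out_e, 1)) {
      out_s <- c(out_s, starts[i]); out_e <- c(out_e, ends[i])
    } else {
      out_e[length(out_e)] <- max(out_e[length(out_e)], ends[i])
    }
  }
  cbind(out_s, out_e)
}

in_any_interval <- function(t, ivals) {
  if (nrow(ivals) == 0) return(rep(FALSE, length(t)))
  idx <- findInterval(t, ivals[, 1])
  idx > 0 & t < ivals[pmax(idx, 1), 2]
}

# pooled post-train vs baseline empirical rate ratio over many simulated
# nights; trend and site effect off so both regions share one true rate
empirical_suppression_ratio <- function(n_nights, factor_s, duration_tau,
                                        trains_per_hour = 8.6,
                                        baseline_rate = 153 / 3.5,
                                        theta = Inf, seed = 1L) {
  cfg <- site_config(trains_per_hour = trains_per_hour,
                     baseline_rate = baseline_rate,
                     site_effect_sd = 0, time_trend = 0)
  sup <- suppression_config(factor_s = factor_s, duration_tau = duration_tau,
                            dispersion_theta = theta)
  ev_s <- 0; len_s <- 0; ev_b <- 0; len_b <- 0
  for (i in seq_len(n_nights)) {
    sched <- simulate_train_schedule(cfg, seed = seed + 2L * i)
    calls <- simulate_bat_calls(sched, cfg, sup, seed = seed + 2L * i + 1L,
                                site_effect = 0)
    if (nrow(sched) == 0) next
    P <- union_intervals(sched$start_s, sched$end_s)
    W <- union_intervals(sched$end_s,
                         pmin(sched$end_s + duration_tau,
                              cfg$recording_duration))
    WP <- union_intervals(c(P[, 1], W[, 1]), c(P[, 2], W[, 2]))
    len_P <- sum(P[, 2] - P[, 1])
    len_WP <- sum(WP[, 2] - WP[, 1])
    len_s <- len_s + (len_WP - len_P)                      # |W \ P|
    len_b <- len_b + (cfg$recording_duration - len_WP)     # baseline
    t <- calls$time_s
    in_P <- in_any_interval(t, P)
    in_W <- in_any_interval(t, W)
    ev_s <- ev_s + sum(in_W & !in_P)
    ev_b <- ev_b + sum(!in_W & !in_P)
  }
  (ev_s / len_s) / (ev_b / len_b)
}

# one no-suppression replicate: simulated nights -> interval counts table
simulate_null_intervals <- function(n_nights, d = 30, trains_per_hour = 8.6,
                                    theta = 2, seed = 1L) {
  cfg <- site_config(trains_per_hour = trains_per_hour,
                     site_effect_sd = 0, time_trend = 0)
  sup <- suppression_config(factor_s = 1, dispersion_theta = theta)
  out <- vector("list", n_nights)
  for (i in seq_len(n_nights)) {
    sched <- simulate_train_schedule(cfg, seed = seed + 2L * i)
    calls <- simulate_bat_calls(sched, cfg, sup, seed = seed + 2L * i + 1L,
                                site_effect = 0)
    gaps <- build_gaps(sched)
    iv <- make_intervals(gaps, d)
    if (nrow(iv) == 0) next
    passes <- tibble::tibble(start_s = calls$time_s)
    out[[i]] <- count_passes(iv, passes)
  }
  dplyr::bind_rows(out)
}
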