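# Event processing: bat-pass segmentation, train physical estimates,
# inter-train gaps, and CSV interfaces for call/train logs.

#' Segment call detections into bat passes
#'
#' A bat pass is any call or series of calls separated from other calls by
#' more than one second. The rule is strict: a gap of exactly 1.000 s keeps
#' calls in the same pass. Species streams are segmented independently, so
#' passes of different species may overlap in time. A pass carries a feeding
#' buzz if any constituent call does.
#'
#' @param calls Tibble of call detections with columns `time_s` (seconds from
#'   recording start, sorted within species), `species`, `feeding_buzz`
#'   (logical). A `night_id` column, if present, is treated as an additional
#'   grouping key and carried through.
#' @param max_gap_s Maximum within-pass call separation, seconds (default 1).
#' @return Tibble of passes: grouping keys, `species`, `start_s`, `end_s`,
#'   `n_calls`, `feeding_buzz`, ordered by start time within group.
#' @export
segment_passes <- function(calls, max_gap_s = 1) {
  abort_unless(all(c("time_s", "species") %in% names(calls)),
               "calls needs columns time_s and species")
  if (!"feeding_buzz" %in% names(calls)) calls$feeding_buzz <- FALSE
  keys <- intersect(c("night_id", "species"), names(calls))
  if (nrow(calls) == 0) {
    return(tibble::tibble(!!!setNames(
      lapply(keys, function(k) character()), keys),
      start_s = numeric(), end_s = numeric(), n_calls = integer(),
      feeding_buzz = logical()))
  }
  grouped <- dplyr::group_by(calls, dplyr::across(dplyr::all_of(keys)))
  chk <- dplyr::summarise(grouped, bad = is.unsorted(.data$time_s),
                          .groups = "drop")
  abort_unless(!any(chk$bad), "call times must be sorted within each stream")
  out <- dplyr::reframe(
    grouped,
    {
      t <- .data$time_s
      fb <- .data$feeding_buzz
      pass <- cumsum(c(TRUE, diff(t) > max_gap_s))
      tibble::tibble(
        start_s = as.numeric(tapply(t, pass, min)),
        end_s = as.numeric(tapply(t, pass, max)),
        n_calls = as.integer(tabulate(pass)),
        feeding_buzz = as.logical(tapply(fb, pass, any))
      )
    }
  )
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(keys, "start_s"))))
}

#' Estimate train length from carriage count
#'
#' Night-time footage rarely reveals the rolling-stock model, but the carriage
#' count is always discernible, so length is estimated as count x mean
#' carriage length (21 m over the models operating on the surveyed lines).
#'
#' @param n_cars Integer carriage count(s), >= 1.
#' @param mean_car_length Mean carriage length, metres.
#' @return Estimated length(s), metres.
#' @export
estimate_train_length <- function(n_cars, mean_car_length = 21) {
  abort_unless(all(n_cars >= 1), "n_cars must be >= 1")
  abort_unless(mean_car_length > 0, "mean_car_length must be > 0")
  n_cars * mean_car_length
}

#' Estimate train speed from length and pass duration
#'
#' `speed (km/h) = (length_m / duration_s) * 3.6`.
#'
#' @param length_m Train length, metres.
#' @param duration_s Pass duration, seconds (> 0).
#' @return Speed(s), km/h.
#' @export
estimate_train_speed <- function(length_m, duration_s) {
  abort_unless(all(duration_s > 0), "duration_s must be > 0")
  (length_m / duration_s) * 3.6
}

#' Annotate a train log with physical estimates
#'
#' Adds `length_m` and `speed_kmh` columns derived from carriage counts and
#' pass durations.
#'
#' @param trains Tibble with `start_s`, `end_s`, `n_cars`.
#' @inheritParams estimate_train_length
#' @return The input with `length_m` and `speed_kmh` columns (re)computed.
#' @export
annotate_trains <- function(trains, mean_car_length = 21) {
  dplyr::mutate(
    trains,
    length_m = estimate_train_length(.data$n_cars, mean_car_length),
    speed_kmh = estimate_train_speed(.data$length_m, .data$end_s - .data$start_s)
  )
}

#' Build inter-train gaps from a train log
#'
#' An inter-train gap is the train-free span between the end of one train pass
#' and the start of the next. Gaps adjacent to an overlap-flagged pass
#' (coincident opposite-track trains, a qualitatively different stimulus) are
#' excluded, as are the unbounded spans between the recording boundaries and
#' the first/last train, which lack one anchoring train. Same-track trains
#' that overlap in time are malformed input and rejected.
#'
#' @param trains Tibble with `start_s`, `end_s`, and optionally `track` and
#'   `overlap` (both assumed single-track / `FALSE` when absent), time-sorted.
#'   A `night_id` column, if present, partitions the log.
#' @param recording_window Unused for gap construction (boundary spans are
#'   always excluded) but validated: passes must lie within it when supplied.
#' @return Tibble of gaps: optional `night_id`, `gap_id`, `start_s`, `end_s`,
#'   `duration_s`, `bounded` (always `TRUE` for returned rows).
#' @export
build_gaps <- function(trains, recording_window = NULL) {
  abort_unless(all(c("start_s", "end_s") %in% names(trains)),
               "trains needs columns start_s and end_s")
  if (!"overlap" %in% names(trains)) trains$overlap <- FALSE
  if (!"track" %in% names(trains)) trains$track <- 1L
  if (!is.null(recording_window)) {
    abort_unless(all(trains$start_s >= recording_window[1] &
                       trains$end_s <= recording_window[2]),
                 "train passes fall outside the recording window")
  }
  one_night <- function(tr) {
    tr <- dplyr::arrange(tr, .data$start_s)
    abort_unless(all(tr$end_s > tr$start_s), "train passes need end_s > start_s")
    for (trk in unique(tr$track)) {
      sub <- tr[tr$track == trk, ]
      if (nrow(sub) > 1) {
        abort_unless(all(sub$start_s[-1] >= head(sub$end_s, -1)),
                     "overlapping same-track train passes are malformed input")
      }
    }
    n <- nrow(tr)
    if (n < 2) {
      return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                            duration_s = numeric(), bounded = logical()))
    }
    g_start <- tr$end_s[-n]
    g_end <- tr$start_s[-1]
    ok <- g_end > g_start &                       # no coincident passes between
      !tr$overlap[-n] & !tr$overlap[-1]           # neither anchor overlapped
    # a gap interior must be train-free: any pass inside invalidates it
    for (i in which(ok)) {
      inside <- tr$start_s < g_end[i] & tr$end_s > g_start[i]
      if (any(inside)) ok[i] <- FALSE
    }
    tibble::tibble(start_s = g_start[ok], end_s = g_end[ok],
                   duration_s = g_end[ok] - g_start[ok],
                   bounded = rep(TRUE, sum(ok)))
  }
  if ("night_id" %in% names(trains)) {
    out <- trains |>
      dplyr::group_by(.data$night_id) |>
      dplyr::group_modify(~ one_night(.x)) |>
      dplyr::ungroup()
  } else {
    out <- one_night(trains)
  }
  dplyr::mutate(out, gap_id = dplyr::row_number(),
                .before = "start_s")
}

# ---- CSV / config interfaces -------------------------------------------------

#' Read and write bat-call and train logs
#'
#' Fixed schemas, times in decimal seconds from recording start, half-open
#' `[start, end)` interval convention. Call logs: `timestamp_s`, `species`,
#' `feeding_buzz`; train logs: `start_s`, `end_s`, `track`, `n_cars`,
#' `overlap`, with an optional leading `night_id` in both.
#'
#' @param path File path.
#' @name event_io
#' @return `read_call_log()` returns a call tibble with the column names used
#'   throughout the package (`time_s`, `species`, `feeding_buzz`);
#'   `read_train_log()` a train tibble.
NULL

#' @rdname event_io
#' @export
read_call_log <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  abort_unless(all(c("timestamp_s", "species", "feeding_buzz") %in% names(x)),
               "call log needs columns timestamp_s, species, feeding_buzz")
  dplyr::rename(x, time_s = "timestamp_s") |>
    dplyr::mutate(feeding_buzz = as.logical(.data$feeding_buzz))
}

#' @rdname event_io
#' @param calls Call tibble (`time_s`, `species`, `feeding_buzz`).
#' @export
write_call_log <- function(calls, path) {
  calls |>
    dplyr::rename(timestamp_s = "time_s") |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname event_io
#' @export
read_train_log <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  abort_unless(all(c("start_s", "end_s", "track", "n_cars", "overlap") %in%
                     names(x)),
               "train log needs columns start_s, end_s, track, n_cars, overlap")
  dplyr::mutate(x, overlap = as.logical(.data$overlap),
                track = as.integer(.data$track),
                n_cars = as.integer(.data$n_cars))
}

#' @rdname event_io
#' @param trains Train tibble.
#' @export
write_train_log <- function(trains, path) {
  readr::write_csv(trains, path)
  invisible(path)
}

#' Read or write a site configuration as YAML
#'
#' @param path File path.
#' @return A [site_config()].
#' @export
read_site_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(site_config, x)
}

#' @rdname read_site_config
#' @param cfg A [site_config()].
#' @export
write_site_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
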