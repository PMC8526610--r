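# Interval analysis: before/after/between windows within qualifying
# inter-train gaps, their bat-pass counts and covariates.

#' Cut a gap into before / after / between intervals
#'
#' A gap qualifies for interval duration `d` when it is at least `3 d` long
#' (so the three windows fit without touching each other's roles):
#' `after` = the first `d` seconds of the gap (just after a train has passed),
#' `before` = the last `d` seconds (just before the next train arrives), and
#' `between` = `d` seconds centred at the gap midpoint, the activity baseline
#' maximally distant from both trains. All intervals are half-open
#' `[start, end)` and pairwise disjoint by construction.
#'
#' @param gaps Gap tibble from [build_gaps()] (columns `gap_id`, `start_s`,
#'   `end_s`, `duration_s`; optional `night_id` carried through).
#' @param d Interval duration, seconds (one of 30/60/120/240/480 in the core
#'   analysis; any positive value is accepted).
#' @return Tibble with three rows per qualifying gap (zero for others):
#'   carried keys, `gap_id`, `gap_duration_s`, `category` (factor
#'   before/between/after, reference `"before"`), `start_s`, `end_s`.
#' @export
make_intervals <- function(gaps, d) {
  abort_unless(d > 0, "d must be > 0")
  keep <- gaps[gaps$duration_s >= 3 * d, , drop = FALSE]
  keys <- intersect("night_id", names(gaps))
  if (nrow(keep) == 0) {
    return(tibble::tibble(!!!setNames(lapply(keys, function(k) character()),
                                      keys),
                          gap_id = integer(), gap_duration_s = numeric(),
                          category = factor(character(),
                                            levels = c("before", "between",
                                                       "after")),
                          start_s = numeric(), end_s = numeric()))
  }
  mid <- (keep$start_s + keep$end_s) / 2
  per_gap <- tibble::tibble(
    after_start = keep$start_s,
    between_start = mid - d / 2,
    before_start = keep$end_s - d
  )
  out <- keep |>
    dplyr::select(dplyr::all_of(keys), "gap_id",
                  gap_duration_s = "duration_s") |>
    dplyr::bind_cols(per_gap) |>
    tidyr::pivot_longer(cols = dplyr::ends_with("_start"),
                        names_to = "category", values_to = "start_s") |>
    dplyr::mutate(
      category = factor(sub("_start$", "", .data$category),
                        levels = c("before", "between", "after")),
      end_s = .data$start_s + d
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "gap_id"))),
                   .data$start_s)
  out
}

#' Count bat passes starting within an interval
#'
#' A pass is assigned to the interval containing its start time, half-open
#' `[start, end)`, so every pass lands in at most one interval.
#'
#' @param intervals Interval tibble from [make_intervals()].
#' @param passes Bat-pass tibble from [segment_passes()] (needs `start_s`;
#'   `night_id` respected when present in both; `species` filtered when
#'   `species` is given).
#' @param species Optional character vector of species to keep (default: all
#'   pooled).
#' @return `intervals` with a `bat_count` column.
#' @export
count_passes <- function(intervals, passes, species = NULL) {
  if (!is.null(species) && "species" %in% names(passes)) {
    passes <- passes[passes$species %in% species, , drop = FALSE]
  }
  if (nrow(intervals) == 0) {
    intervals$bat_count <- integer()
    return(intervals)
  }
  by_night <- "night_id" %in% names(intervals) && "night_id" %in% names(passes)
  count_one <- function(iv, ps) {
    if (nrow(ps) == 0 || nrow(iv) == 0) {
      iv$bat_count <- integer(nrow(iv))
      return(iv)
    }
    t <- sort(ps$start_s)
    # passes with start in [s, e): (# t < e) - (# t < s)
    iv$bat_count <- as.integer(
      findInterval(iv$end_s, t, left.open = TRUE) -
        findInterval(iv$start_s, t, left.open = TRUE)
    )
    iv
  }
  if (by_night) {
    intervals |>
      dplyr::group_by(.data$night_id) |>
      dplyr::group_modify(function(iv, key)
        count_one(iv, passes[passes$night_id == key$night_id, , drop = FALSE])) |>
      dplyr::ungroup()
  } else {
    count_one(intervals, passes)
  }
}

#' Assemble the interval analysis table
#'
#' Runs the full event-processing chain for each night — segment calls into
#' passes, build inter-train gaps, cut qualifying gaps into
#' before/between/after intervals of duration `d`, count passes per interval —
#' and attaches the candidate covariates: nightly bat-pass total (passes
#' within inter-train gaps over the recording), time since recording start
#' (hours, at interval start), gap duration, site train density, and any
#' per-night weather columns present in `nights`.
#'
#' @param calls Call tibble (`night_id`, `time_s`, `species`, `feeding_buzz`),
#'   or a pre-segmented pass tibble (`start_s` present, `time_s` absent).
#' @param trains Train tibble (`night_id`, `start_s`, `end_s`, `track`,
#'   `overlap`).
#' @param nights Night tibble (`night_id`, `site_id`, `trains_per_hour`, plus
#'   covariates such as `wind`, `humidity`, `temperature`).
#' @param d Interval duration, seconds.
#' @param species Optional species filter; default pools both pipistrelle
#'   species.
#' @return Tibble, one row per interval: identifiers, `category`, `bat_count`,
#'   `gap_duration`, `time_since_start_h`, `nightly_total`, `trains_per_hour`
#'   and the night covariates. Rows with missing covariates are flagged
#'   (`covariates_complete`), never dropped. Warns when no gap qualifies.
#' @export
assemble_dataset <- function(calls, trains, nights, d = 30, species = NULL) {
  abort_unless("night_id" %in% names(trains) && "night_id" %in% names(nights),
               "trains and nights need a night_id column")
  passes <- if ("time_s" %in% names(calls)) segment_passes(calls) else calls
  gaps <- build_gaps(trains)
  intervals <- make_intervals(gaps, d)
  if (nrow(intervals) == 0) {
    warning(sprintf("no inter-train gap of >= %g s qualifies at d = %g s",
                    3 * d, d))
  }
  counted <- count_passes(intervals, passes, species = species)

  # nightly total: passes starting within any inter-train gap that night
  gap_totals <- count_gap_passes(gaps, passes, species = species)

  out <- counted |>
    dplyr::left_join(gap_totals, by = "night_id") |>
    dplyr::left_join(nights, by = "night_id") |>
    dplyr::mutate(
      gap_duration = .data$gap_duration_s,
      time_since_start_h = .data$start_s / 3600
    )
  covar_cols <- intersect(c("nightly_total", "wind", "humidity", "temperature",
                            "gap_duration", "trains_per_hour"), names(out))
  out$covariates_complete <- stats::complete.cases(out[, covar_cols])
  if (any(!out$covariates_complete)) {
    warning(sprintf("%d interval row(s) have missing covariates (flagged)",
                    sum(!out$covariates_complete)))
  }
  dplyr::relocate(out, dplyr::any_of(c("night_id", "site_id")), "gap_id",
                  "category", "bat_count")
}

# nightly totals of passes starting inside inter-train gaps
count_gap_passes <- function(gaps, passes, species = NULL) {
  if (!is.null(species) && "species" %in% names(passes)) {
    passes <- passes[passes$species %in% species, , drop = FALSE]
  }
  if (!"night_id" %in% names(gaps)) {
    gaps$night_id <- "all"
    passes$night_id <- "all"
  }
  purrr::map_dfr(unique(gaps$night_id), function(nid) {
    g <- gaps[gaps$night_id == nid, , drop = FALSE]
    p <- passes[passes$night_id == nid, , drop = FALSE]
    n_in <- if (nrow(p) == 0 || nrow(g) == 0) 0L else {
      sum(vapply(p$start_s, function(s)
        any(s >= g$start_s & s < g$end_s), logical(1)))
    }
    tibble::tibble(night_id = nid, nightly_total = as.integer(n_in))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
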