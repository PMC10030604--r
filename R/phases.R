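#' Gravity-phase schedule
#'
#' An ordered set of labelled, non-overlapping time intervals with g-levels,
#' plus a safety margin trimmed from both ends of every phase before any
#' rate is computed. Phases listed in `split_first_last` are analyzed as
#' two sub-windows (the first and last `split_len` seconds), the standard
#' way adaptation is probed within long hypergravity/post phases.
#'
#' @param phases data frame with columns `label`, `start`, `end`, `g_level`.
#' @param safety_margin seconds trimmed at both ends of each analyzed
#'   window.
#' @param platform free-text platform tag (e.g. "drop_tower", "centrifuge").
#' @param split_first_last character vector of phase labels analyzed as
#'   first/last sub-windows.
#' @param split_len sub-window length in seconds (default 60).
#' @return A tibble of class `phase_schedule` with the margin and platform
#'   stored as attributes.
#' @export
phase_schedule <- function(phases, safety_margin = 0, platform = "custom",
                           split_first_last = character(0), split_len = 60) {
  phases <- tibble::as_tibble(phases)
  check_that(
    "`phases` needs columns label, start, end, g_level" =
      all(c("label", "start", "end", "g_level") %in% names(phases)),
    "phase labels must be unique" = !anyDuplicated(phases$label),
    "phases must have positive duration" = all(phases$end > phases$start),
    "phases must be time-ordered and non-overlapping" =
      all(diff(as.vector(rbind(phases$start, phases$end))) >= 0),
    "`safety_margin` must be non-negative" = safety_margin >= 0,
    "every phase must be longer than twice the safety margin" =
      all(phases$end - phases$start > 2 * safety_margin)
  )
  structure(
    phases,
    class = c("phase_schedule", class(phases)),
    safety_margin = safety_margin,
    platform = platform,
    split_first_last = split_first_last,
    split_len = split_len
  )
}

#' Margin-trimmed analysis windows of a schedule
#'
#' Each phase is shrunk symmetrically by the safety margin; phases flagged
#' for first/last splitting yield two sub-windows (suffixes `1` and `2`).
#' All windows are half-open `[start, end)`.
#'
#' @param schedule a [phase_schedule()].
#' @param margin override of the schedule's safety margin (seconds).
#' @return tibble with columns `phase`, `start`, `end`, `g_level`.
#' @export
analysis_windows <- function(schedule, margin = NULL) {
  m <- margin %||% attr(schedule, "safety_margin")
  split_phases <- attr(schedule, "split_first_last") %||% character(0)
  split_len <- attr(schedule, "split_len") %||% 60
  rows <- purrr::pmap(
    list(schedule$label, schedule$start, schedule$end, schedule$g_level),
    function(label, start, end, g) {
      dur <- end - start
      check_that("safety margin must be below half of every phase duration" =
                   2 * m < dur)
      if (label %in% split_phases) {
        sl <- min(split_len, dur / 2)
        check_that("split length must exceed twice the margin" = sl > 2 * m)
        w_start <- c(start + m, end - sl + m)
        w_end <- c(start + sl - m, end - m)
        tibble::tibble(
          phase = paste0(label, c("1", "2")),
          start = w_start,
          end = w_end,
          g_level = g
        )
      } else {
        tibble::tibble(phase = label, start = start + m, end = end - m,
                       g_level = g)
      }
    }
  )
  dplyr::bind_rows(rows)
}

#' Mean firing rate in a half-open window
#'
#' @param spike_times numeric vector of spike times (s).
#' @param start,end window bounds; spikes in `[start, end)` are counted.
#' @return rate in Hz.
#' @export
firing_rate <- function(spike_times, start, end) {
  check_that("window must have positive length" = end > start)
  sum(spike_times >= start & spike_times < end) / (end - start)
}

#' Build the unit-by-phase firing/burst rate table
#'
#' For every curated unit and every margin-trimmed analysis window,
#' computes the mean firing rate and the burst rate (bursts detected on the
#' unit's full train with [detect_bursts()]; a burst is attributed to the
#' window containing its start).
#'
#' @param spikes tibble with columns `unit_id`, `time` (one row per spike),
#'   e.g. from [simulate_experiment()] or [sort_recording()].
#' @param schedule a [phase_schedule()].
#' @param burst_params a [burst_params()] parameter set.
#' @return A tibble of class `phase_rate_table` with columns `unit_id`,
#'   `phase`, `firing_rate`, `burst_rate`, and the schedule and analysis
#'   windows stored as attributes.
#' @export
build_rate_table <- function(spikes, schedule, burst_params = gravimea::burst_params()) {
  check_that(
    "`spikes` needs columns unit_id, time" =
      all(c("unit_id", "time") %in% names(spikes))
  )
  win <- analysis_windows(schedule)
  units <- unique(spikes$unit_id)
  rows <- purrr::map(units, function(u) {
    t_u <- sort(spikes$time[spikes$unit_id == u])
    bursts <- detect_bursts(t_u, burst_params)
    tibble::tibble(
      unit_id = u,
      phase = win$phase,
      firing_rate = purrr::map2_dbl(win$start, win$end,
                                    ~ firing_rate(t_u, .x, .y)),
      burst_rate = purrr::map2_dbl(win$start, win$end,
                                   ~ burst_rate(bursts, .x, .y))
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    class = c("phase_rate_table", class(out)),
    windows = win,
    schedule = schedule,
    filtered = FALSE,
    log10 = FALSE
  )
}

# keep phase_rate_table attributes through a transformation of its data
restamp_table <- function(data, template, ...) {
  dots <- list(...)
  out <- structure(
    data,
    class = c("phase_rate_table", class(tibble::as_tibble(data))),
    windows = attr(template, "windows"),
    schedule = attr(template, "schedule"),
    filtered = attr(template, "filtered"),
    log10 = attr(template, "log10"),
    burst_units = attr(template, "burst_units")
  )
  for (nm in names(dots)) attr(out, nm) <- dots[[nm]]
  out
}

#' Remove units that are silent in any analyzed phase
#'
#' Units without a single spike in one of the analyzed windows are removed
#' from the whole analysis (all phases), the standard guard against
#' artifactual units. The burst-rate analysis is additionally restricted to
#' units with at least one burst in every phase; their ids are stored in
#' the `burst_units` attribute and used by [rate_matrix()].
#'
#' @param table a [build_rate_table()] result.
#' @return The filtered `phase_rate_table`.
#' @export
filter_silent_units <- function(table) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(table)[c("unit_id", "phase", "firing_rate")],
                             names_from = "phase", values_from = "firing_rate")
  keep <- wide$unit_id[apply(wide[-1] > 0, 1, all)]
  if (length(keep) == 0) {
    rlang::abort("all units are silent in at least one phase; nothing to analyze",
                 class = "gravimea_empty_result")
  }
  out <- dplyr::filter(tibble::as_tibble(table), .data$unit_id %in% keep)
  out <- out[order(match(out$unit_id, unique(table$unit_id))), ]
  bw <- tidyr::pivot_wider(out[c("unit_id", "phase", "burst_rate")],
                           names_from = "phase", values_from = "burst_rate")
  burst_units <- bw$unit_id[apply(bw[-1] > 0, 1, all)]
  restamp_table(out, table, filtered = TRUE, burst_units = burst_units)
}

#' Log-transform a rate table
#'
#' Firing and bursting rates are lognormally distributed across units, so
#' statistics run on `log10` rates. Requires [filter_silent_units()] first
#' so every firing rate is positive.
#'
#' @param table a filtered `phase_rate_table`.
#' @return The table with `firing_rate` and `burst_rate` replaced by their
#'   `log10` (burst rates only for burst-complete units; others become
#'   `NA`).
#' @export
log_transform <- function(table) {
  if (!isTRUE(attr(table, "filtered")) || any(table$firing_rate <= 0)) {
    rlang::abort("log_transform requires filter_silent_units() first (all rates > 0)",
                 class = "gravimea_invalid_state")
  }
  burst_units <- attr(table, "burst_units") %||% character(0)
  out <- dplyr::mutate(
    tibble::as_tibble(table),
    firing_rate = log10(.data$firing_rate),
    burst_rate = ifelse(.data$unit_id %in% burst_units, log10(.data$burst_rate), NA_real_)
  )
  restamp_table(out, table, log10 = TRUE)
}

#' Units x phases rate matrix for statistics
#'
#' @param table a `phase_rate_table`.
#' @param measure `"firing"` or `"burst"`; the burst matrix is restricted
#'   to burst-complete units when the table has been filtered.
#' @return numeric matrix, units (rows, named) x phases (columns, named).
#' @export
rate_matrix <- function(table, measure = c("firing", "burst")) {
  measure <- match.arg(measure)
  col <- paste0(measure, "_rate")
  dat <- tibble::as_tibble(table)[c("unit_id", "phase", col)]
  if (measure == "burst" && !is.null(attr(table, "burst_units"))) {
    dat <- dplyr::filter(dat, .data$unit_id %in% attr(table, "burst_units"))
  }
  wide <- tidyr::pivot_wider(dat, names_from = "phase", values_from = all_of(col))
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$unit_id
  m
}
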