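#' Interval (MaxInterval) burst-detection parameters
#'
#' The five-parameter interval algorithm: a burst opens at an ISI of at
#' most `max_isi_start`, extends while ISIs stay at or below
#' `max_isi_end`, candidate bursts closer than `min_ibi` are merged, and
#' candidates shorter than `min_duration` or with fewer than `min_spikes`
#' spikes are discarded. Defaults are the standard 20 / 100 / 100 ms,
#' 20 ms, 2-spike set.
#'
#' @param max_isi_start maximum ISI starting a burst (s, default 0.020).
#' @param max_isi_end maximum ISI continuing a burst (s, default 0.100).
#' @param min_ibi minimum inter-burst interval (s, default 0.100).
#' @param min_duration minimum burst duration (s, default 0.020).
#' @param min_spikes minimum spikes per burst (default 2).
#' @return list of class `burst_params`.
#' @export
burst_params <- function(max_isi_start = 0.020, max_isi_end = 0.100,
                         min_ibi = 0.100, min_duration = 0.020,
                         min_spikes = 2) {
  check_that(
    "all burst parameters must be positive" =
      all(c(max_isi_start, max_isi_end, min_ibi, min_duration) > 0),
    "`max_isi_start` must not exceed `max_isi_end`" =
      max_isi_start <= max_isi_end,
    "`min_spikes` must be at least 2" = min_spikes >= 2
  )
  structure(
    list(max_isi_start = max_isi_start, max_isi_end = max_isi_end,
         min_ibi = min_ibi, min_duration = min_duration,
         min_spikes = min_spikes),
    class = "burst_params"
  )
}

#' Detect bursts in a spike train
#'
#' Sequential MaxInterval scan: (1) a candidate burst opens at spike `i`
#' when `ISI(i, i+1) <= max_isi_start`; (2) it extends while subsequent
#' ISIs are at most `max_isi_end`; (3) candidates whose start-minus-end
#' gap is below `min_ibi` are merged; (4) candidates failing the duration
#' or spike-count minima are discarded — in that order.
#'
#' @param spike_times strictly increasing numeric vector (s).
#' @param params a [burst_params()].
#' @return tibble with columns `start`, `end`, `n_spikes` (possibly
#'   zero rows).
#' @export
detect_bursts <- function(spike_times, params = burst_params()) {
  if (is.unsorted(spike_times, strictly = TRUE)) {
    rlang::abort("`spike_times` must be strictly increasing",
                 class = "gravimea_invalid_input")
  }
  empty <- tibble::tibble(start = numeric(0), end = numeric(0),
                          n_spikes = integer(0))
  n <- length(spike_times)
  if (n < 2) return(empty)
  isi <- diff(spike_times)

  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n - 1L) {
    if (isi[i] <= params$max_isi_start) {
      j <- i + 1L
      while (j <= n - 1L && isi[j] <= params$max_isi_end) j <- j + 1L
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(starts) == 0) return(empty)

  # (3) merge candidates separated by less than min_ibi
  k <- 1L
  m_starts <- starts[1]; m_ends <- ends[1]
  for (c in seq_along(starts)[-1]) {
    gap <- spike_times[starts[c]] - spike_times[m_ends[k]]
    if (gap < params$min_ibi) {
      m_ends[k] <- ends[c]
    } else {
      k <- k + 1L
      m_starts[k] <- starts[c]; m_ends[k] <- ends[c]
    }
  }

  # (4) duration and spike-count filters
  out <- tibble::tibble(
    start = spike_times[m_starts],
    end = spike_times[m_ends],
    n_spikes = m_ends - m_starts + 1L
  )
  dplyr::filter(out, .data$end - .data$start >= params$min_duration,
                .data$n_spikes >= params$min_spikes)
}

#' Burst rate in a half-open window
#'
#' Bursts are attributed to the window containing their start (a burst
#' straddling a phase edge counts once, in its start window).
#'
#' @param bursts tibble from [detect_bursts()].
#' @param start,end window bounds (s); `end > start`.
#' @return rate in Hz.
#' @export
burst_rate <- function(bursts, start, end) {
  check_that("window must have positive length" = end > start)
  sum(bursts$start >= start & bursts$start < end) / (end - start)
}
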