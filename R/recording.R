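#' MEA recording container
#'
#' A minimal container for raw or preprocessed extracellular voltage data:
#' a channels x time matrix in microvolts plus sampling metadata. Standard
#' 60-electrode MEA chips record 60 channels at 25 kHz; both are
#' configurable.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_ids character or integer channel labels; defaults to
#'   `1:nrow(samples)`.
#' @param layout optional tibble with columns `channel_id`, `row`, `col`
#'   giving electrode grid positions (see [mea_layout()]).
#' @param t0 time of the first sample in seconds (default 0).
#'
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(samples, sampling_rate, channel_ids = NULL,
                          layout = NULL, t0 = 0) {
  check_that(
    "`samples` must be a numeric matrix" = is.matrix(samples) && is.numeric(samples),
    "`sampling_rate` must be a single positive number" =
      is.numeric(sampling_rate) && length(sampling_rate) == 1 && sampling_rate > 0,
    "`samples` must be finite" = all(is.finite(samples)),
    "`t0` must be a single finite number" =
      is.numeric(t0) && length(t0) == 1 && is.finite(t0)
  )
  channel_ids <- channel_ids %||% seq_len(nrow(samples))
  check_that(
    "`channel_ids` must match the number of rows of `samples`" =
      length(channel_ids) == nrow(samples)
  )
  structure(
    list(
      samples = samples,
      sampling_rate = sampling_rate,
      channel_ids = channel_ids,
      layout = layout,
      t0 = t0
    ),
    class = "mea_recording"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "<mea_recording> %d channels x %d samples @ %g Hz (%.2f s, t0 = %g s)\n",
    nrow(x$samples), ncol(x$samples), x$sampling_rate,
    ncol(x$samples) / x$sampling_rate, x$t0
  ))
  invisible(x)
}

#' @export
dim.mea_recording <- function(x) dim(x$samples)

#' Standard MEA electrode layout
#'
#' The common 60-electrode layout: an 8 x 8 grid with the four corner
#' positions absent.
#'
#' @return A tibble with columns `channel_id`, `row`, `col` (60 rows).
#' @export
mea_layout <- function() {
  grid <- expand.grid(row = 1:8, col = 1:8)
  corner <- (grid$row %in% c(1, 8)) & (grid$col %in% c(1, 8))
  grid <- grid[!corner, , drop = FALSE]
  tibble::tibble(
    channel_id = seq_len(nrow(grid)),
    row = grid$row,
    col = grid$col
  )
}

# time axis of a recording, in seconds
recording_times <- function(rec) {
  rec$t0 + (seq_len(ncol(rec$samples)) - 1L) / rec$sampling_rate
}
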