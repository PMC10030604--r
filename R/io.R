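#' Write / read a recording in the open binary format
#'
#' The on-disk format is a little-endian int16 payload of
#' channel-interleaved frames (all channels at sample 1, then sample 2,
#' ...) at a calibration of `uv_per_lsb` microvolts per least significant
#' bit (default 0.1, covering +-3276.7 uV with quantization well below
#' electrode noise), plus a JSON sidecar `<path>.json` carrying
#' `n_channels`, `sampling_rate_hz`, `uv_per_lsb`, `channel_ids`,
#' `layout`, `t0_s`, `provenance` and a format `version`.
#'
#' @param rec an [mea_recording()].
#' @param path payload path (the sidecar gets `.json` appended).
#' @param uv_per_lsb calibration in uV per LSB (default 0.1).
#' @param provenance free-form provenance list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, uv_per_lsb = 0.1, provenance = list()) {
  check_that(
    "`rec` must be an mea_recording" = inherits(rec, "mea_recording"),
    "samples must be finite" = all(is.finite(rec$samples))
  )
  q <- round(rec$samples / uv_per_lsb)
  if (max(abs(q)) > 32767) {
    rlang::abort("samples exceed the int16 range at this calibration",
                 class = "gravimea_calibration_error")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  # column-major write of the channels x time matrix = channel-interleaved frames
  writeBin(as.integer(q), con, size = 2L, endian = "little")
  sidecar <- list(
    version = 1L,
    n_channels = nrow(rec$samples),
    n_samples = ncol(rec$samples),
    sampling_rate_hz = rec$sampling_rate,
    uv_per_lsb = uv_per_lsb,
    channel_ids = rec$channel_ids,
    layout = rec$layout,
    t0_s = rec$t0,
    provenance = provenance
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param path payload path written by [write_recording()].
#' @export
read_recording <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    rlang::abort(sprintf("recording payload or sidecar missing at %s", path),
                 class = "gravimea_invalid_input")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$version) || meta$version != 1L) {
    rlang::abort(sprintf("unknown recording format version: %s",
                         meta$version %||% "<missing>"),
                 class = "gravimea_invalid_input")
  }
  check_that(
    "sidecar n_channels must be a positive count" =
      is.numeric(meta$n_channels) && meta$n_channels >= 1,
    "sidecar sampling_rate_hz must be positive" =
      is.numeric(meta$sampling_rate_hz) && meta$sampling_rate_hz > 0,
    class = "gravimea_invalid_input"
  )
  n_int16 <- file.size(path) / 2
  expected <- meta$n_channels * meta$n_samples
  if (n_int16 != expected) {
    rlang::abort(
      sprintf("payload holds %g frames but the sidecar declares %g (%d channels x %d samples)",
              n_int16 / meta$n_channels, meta$n_samples,
              meta$n_channels, meta$n_samples),
      class = "gravimea_invalid_input"
    )
  }
  con <- file(path, "rb")
  on.exit(close(con))
  q <- readBin(con, integer(), n = expected, size = 2L, signed = TRUE,
               endian = "little")
  samples <- matrix(q * meta$uv_per_lsb, nrow = meta$n_channels)
  layout <- if (!is.null(meta$layout)) tibble::as_tibble(meta$layout)
  mea_recording(samples, meta$sampling_rate_hz,
                channel_ids = meta$channel_ids, layout = layout,
                t0 = meta$t0_s %||% 0)
}

#' Export curated spike trains to tidy CSV
#'
#' One row per spike, columns `unit_id`, `channel_id`, `time_s`, sorted
#' by unit then time.
#'
#' @param spikes tibble with columns `unit_id`, `channel_id`, `time`
#'   (e.g. `sort_recording()$spikes`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_spike_trains <- function(spikes, path) {
  out <- tibble::tibble(
    unit_id = spikes$unit_id,
    channel_id = spikes$channel_id %||% NA,
    time_s = spikes$time
  )
  out <- dplyr::arrange(out, .data$unit_id, .data$time_s)
  if (nrow(out) == 0) {
    rlang::warn("no curated spikes; writing a header-only file")
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_spike_trains
#' @export
import_spike_trains <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(unit_id = as.character(df$unit_id),
                 channel_id = df$channel_id, time = df$time_s)
}

#' Export a rate table to tidy CSV
#'
#' @param table a `phase_rate_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_rate_table <- function(table, path) {
  out <- tibble::as_tibble(table)
  names(out)[names(out) == "firing_rate"] <- "firing_rate_hz"
  names(out)[names(out) == "burst_rate"] <- "burst_rate_hz"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
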