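#' Biphasic extracellular spike template
#'
#' A trough-dominant biphasic waveform: 0.2 ms lead-in, 0.3 ms negative
#' half-sine trough (3/4 of the amplitude), 0.5 ms positive half-sine
#' rebound (1/4 of the amplitude), then a zero tail; 1.6 ms total.
#' `amplitude` is trough-to-peak.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param amplitude trough-to-peak amplitude in uV.
#' @return numeric vector (uV) with attribute `trough_index`.
#' @export
spike_template <- function(sampling_rate, amplitude = 30.5) {
  check_that("`amplitude` must be positive" = amplitude > 0)
  ms <- function(x) max(1L, round(x * 1e-3 * sampling_rate))
  lead <- ms(0.2); trough <- ms(0.3); rebound <- ms(0.5)
  total <- ms(1.6)
  tail <- max(0L, total - lead - trough - rebound)
  w <- c(
    rep(0, lead),
    -0.75 * amplitude * sin(pi * seq_len(trough) / (trough + 1)),
    0.25 * amplitude * sin(pi * seq_len(rebound) / (rebound + 1)),
    rep(0, tail)
  )
  structure(w, trough_index = lead + which.min(w[lead + seq_len(trough)]))
}

#' Render a synthetic recording from ground truth
#'
#' Each ground-truth spike is rendered as a biphasic template on the
#' unit's electrode; independent Gaussian noise of `noise_sigma` is added
#' to every channel, plus an optional sinusoidal common-mode artifact
#' identical on all channels. The result must be representable as int16 at
#' the 0.1 uV/LSB calibration used by [write_recording()].
#'
#' @param config a [synth_config()].
#' @param truth a [make_ground_truth()] result (its `config` is ignored in
#'   favor of `config`).
#' @param duration seconds to render (default: full schedule length).
#' @param t0 start time of the rendered window (default 0).
#' @param seed integer seed for the noise streams.
#' @return An [mea_recording()].
#' @export
render_recording <- function(config, truth, duration = NULL, t0 = 0, seed = 1) {
  fs <- config$sampling_rate
  duration <- duration %||% max(truth$schedule$end)
  n_samp <- round(duration * fs)
  ch_ids <- truth$channels$channel_id
  n_ch <- length(ch_ids)

  per_ch <- table(truth$units$channel_id)
  if (any(per_ch > config$max_units_per_channel)) {
    rlang::abort(
      sprintf("more than %d units assigned to one electrode; reduce n_units or empty_channel_fraction",
              config$max_units_per_channel),
      class = "gravimea_invalid_parameter"
    )
  }

  set.seed(derive_seed(seed, 7L))
  samples <- matrix(rnorm(n_ch * n_samp, sd = config$noise_sigma),
                    nrow = n_ch, ncol = n_samp)
  if (config$common_mode$amplitude > 0) {
    t <- (seq_len(n_samp) - 1L) / fs + t0
    cm <- config$common_mode$amplitude *
      sin(2 * pi * config$common_mode$frequency * t)
    samples <- sweep(samples, 2, cm, `+`)
  }

  for (i in seq_len(nrow(truth$units))) {
    u <- truth$units[i, ]
    tpl <- spike_template(fs, u$amplitude)
    tr_idx <- attr(tpl, "trough_index")
    row <- match(u$channel_id, ch_ids)
    st <- truth$spikes$time[truth$spikes$unit_id == u$unit_id]
    st <- st[st >= t0 & st < t0 + duration]
    idx0 <- round((st - t0) * fs) + 1L - (tr_idx - 1L)
    for (k in idx0) {
      lo <- max(1L, k); hi <- min(n_samp, k + length(tpl) - 1L)
      if (hi < lo) next
      samples[row, lo:hi] <- samples[row, lo:hi] + tpl[(lo - k + 1L):(hi - k + 1L)]
    }
  }

  if (max(abs(samples)) > 32767 * 0.1) {
    rlang::abort("rendered amplitudes exceed the int16 range at 0.1 uV/LSB",
                 class = "gravimea_calibration_error")
  }
  mea_recording(samples, fs, channel_ids = ch_ids,
                layout = config$layout, t0 = t0)
}
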