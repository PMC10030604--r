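#' Build ground truth for a synthetic experiment
#'
#' Samples per-unit baseline rates, subgroup labels, amplitudes and
#' electrode assignments, derives per-segment true rates from the preset's
#' phase modulation, and generates ground-truth spike trains.
#'
#' Subgroups are the baseline-rate terciles (`low`, `mid`, `high`); each
#' high unit is independently assigned an `up` or `down` response
#' direction, encoding the mixed behavior of high-firing units under
#' microgravity. Modulation entries given as `target_hz` are converted to
#' subgroup-wide factors `target / geometric-mean(subgroup baseline)` so
#' the within-subgroup rate spread is preserved.
#'
#' @param config a [synth_config()].
#' @param schedule a [phase_schedule()].
#' @param modulation modulation tibble as returned by [make_preset()], or
#'   `NULL` for no phase effects.
#' @param seed integer root seed; all sub-streams derive from it.
#' @return list of class `mea_ground_truth` with elements `units`
#'   (tibble: unit_id, channel_id, subgroup, baseline_rate, amplitude),
#'   `channels` (tibble: channel_id, has_unit), `rates` (tibble: unit_id,
#'   segment, start, end, rate), `spikes` (tibble: unit_id, time),
#'   `config`, `schedule`.
#' @export
make_ground_truth <- function(config, schedule, modulation = NULL, seed = 1) {
  set.seed(derive_seed(seed, 1L))
  n <- config$n_units
  rates <- sample_unit_rates(n, config$rate_lognormal_mu,
                             config$rate_lognormal_sigma)
  amplitude <- rlnorm(n, log(config$amplitude_mu), config$amplitude_sigma)

  r_rank <- rank(rates, ties.method = "first")
  subgroup <- ifelse(r_rank <= n / 3, "low",
                     ifelse(r_rank <= 2 * n / 3, "mid", "high"))
  direction <- ifelse(subgroup == "high",
                      ifelse(runif(n) < 0.5, "up", "down"), "none")

  # electrode assignment: units fill the non-empty channels round-robin
  n_empty <- round(config$empty_channel_fraction * config$n_channels)
  ch_ids <- config$layout$channel_id[seq_len(config$n_channels)]
  empty_ch <- if (n_empty > 0) sample(ch_ids, n_empty) else integer(0)
  occupied <- setdiff(ch_ids, empty_ch)
  channel_id <- rep_len(occupied, n)

  units <- tibble::tibble(
    unit_id = sprintf("u%03d", seq_len(n)),
    channel_id = channel_id,
    subgroup = subgroup,
    direction = direction,
    baseline_rate = rates,
    amplitude = amplitude
  )
  occupied_mask <- ch_ids %in% channel_id
  channels <- tibble::tibble(channel_id = ch_ids, has_unit = occupied_mask)

  seg <- generation_segments(schedule)
  unit_rates <- unit_segment_rates(units, seg, modulation)

  spikes <- purrr::map(seq_len(n), function(i) {
    prof <- dplyr::filter(unit_rates, .data$unit_id == units$unit_id[i])
    set.seed(derive_seed(seed, 100L + i))
    t <- generate_spike_train(
      data.frame(start = prof$start, end = prof$end, rate = prof$rate),
      duration = max(schedule$end), refractory = config$refractory,
      burst = config$burst
    )
    tibble::tibble(unit_id = units$unit_id[i], time = t)
  })
  spikes <- dplyr::bind_rows(spikes)

  structure(
    list(units = units, channels = channels, rates = unit_rates,
         spikes = spikes, config = config, schedule = schedule),
    class = "mea_ground_truth"
  )
}

# Per-unit true rate on every generation segment, applying subgroup
# modulation factors (or rate targets) where defined.
unit_segment_rates <- function(units, segments, modulation) {
  key <- ifelse(units$subgroup == "high",
                paste0("high_", units$direction), units$subgroup)
  gm <- tapply(units$baseline_rate, key, function(x) exp(mean(log(x))))
  rows <- purrr::pmap(
    list(segments$segment, segments$start, segments$end),
    function(seg_label, s, e) {
      fac <- rep(1, nrow(units))
      if (!is.null(modulation)) {
        mod <- modulation[modulation$segment == seg_label, , drop = FALSE]
        for (j in seq_len(nrow(mod))) {
          sel <- key == mod$subgroup[j]
          if (!any(sel)) next
          f <- if (!is.na(mod$factor[j])) mod$factor[j]
               else mod$target_hz[j] / gm[[mod$subgroup[j]]]
          fac[sel] <- f
        }
      }
      tibble::tibble(unit_id = units$unit_id, segment = seg_label,
                     start = s, end = e, rate = units$baseline_rate * fac)
    }
  )
  dplyr::bind_rows(rows)
}

#' True mean rate of a unit over an arbitrary window
#'
#' Time-weighted average of the piecewise-constant ground-truth rate.
#'
#' @param truth a [make_ground_truth()] result.
#' @param unit_id unit identifier.
#' @param start,end window in seconds.
#' @return rate in Hz.
#' @export
true_rate <- function(truth, unit_id, start, end) {
  seg <- truth$rates[truth$rates$unit_id == unit_id, , drop = FALSE]
  ov <- pmax(0, pmin(seg$end, end) - pmax(seg$start, start))
  sum(ov * seg$rate) / (end - start)
}

#' Simulate a full gravity-protocol experiment at the spike-train level
#'
#' Convenience wrapper: build the preset, generate ground truth, and
#' return everything needed for the downstream analysis chain (rate table,
#' statistics) without rendering voltage traces.
#'
#' @param name preset name, see [make_preset()].
#' @param seed integer root seed.
#' @param scale time-compression factor, see [make_preset()].
#' @param modulate logical; `FALSE` removes all phase effects (null
#'   experiment).
#' @param ... overrides passed to [synth_config()].
#' @return list with `truth`, `spikes`, `schedule`, `config`.
#' @export
simulate_experiment <- function(name = "drop", seed = 1, scale = 1,
                                modulate = TRUE, ...) {
  preset <- make_preset(name, scale = scale, ...)
  truth <- make_ground_truth(preset$config, preset$schedule,
                             modulation = if (modulate) preset$modulation,
                             seed = seed)
  list(truth = truth, spikes = truth$spikes, schedule = preset$schedule,
       config = preset$config)
}
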