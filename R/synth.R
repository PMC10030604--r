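#' Synthetic recording configuration
#'
#' Parameters of the ground-truth MEA simulator. Defaults emulate the
#' statistical structure of cultured human neural networks on standard
#' 60-electrode chips: lognormal baseline firing rates with a median of
#' 3 Hz, biphasic extracellular waveforms of ~30.5 uV trough-to-peak,
#' ~4 uV Gaussian electrode noise, a fraction of electrodes without any
#' neuron, and burst-structured spike trains.
#'
#' @param n_channels number of electrodes (default 60).
#' @param sampling_rate sampling rate in Hz (default 25000).
#' @param layout electrode grid tibble, see [mea_layout()].
#' @param n_units number of simulated units (default 63).
#' @param empty_channel_fraction fraction of electrodes carrying no unit
#'   (default 0.2); empty channels contain noise only and serve as the
#'   false-positive control.
#' @param rate_lognormal_mu,rate_lognormal_sigma natural-log parameters of
#'   the baseline firing-rate distribution (defaults `log(3)` and 0.5, i.e.
#'   median 3 Hz).
#' @param amplitude_mu median trough-to-peak spike amplitude in uV
#'   (default 30.5); per-unit amplitudes are lognormal around this median.
#' @param amplitude_sigma lognormal sigma of amplitudes (default 0.2).
#' @param noise_sigma per-channel Gaussian noise SD in uV (default 4).
#' @param refractory absolute refractory period in seconds (default 0.002).
#' @param burst burst-structure parameters from [burst_structure()], or
#'   `NULL` for purely tonic (Poisson-with-refractory) trains.
#' @param common_mode list with `amplitude` (uV) and `frequency` (Hz) of a
#'   sinusoidal artifact added identically to every channel; amplitude 0
#'   disables it.
#' @param max_units_per_channel maximum units rendered on one electrode
#'   (default 2; the in-repo sorter resolves up to 3).
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 60,
                         sampling_rate = 25000,
                         layout = mea_layout(),
                         n_units = 63,
                         empty_channel_fraction = 0.2,
                         rate_lognormal_mu = log(3),
                         rate_lognormal_sigma = 0.5,
                         amplitude_mu = 30.5,
                         amplitude_sigma = 0.2,
                         noise_sigma = 4,
                         refractory = 0.002,
                         burst = burst_structure(),
                         common_mode = list(amplitude = 0, frequency = 50),
                         max_units_per_channel = 2) {
  check_that(
    "`n_channels` must be a positive count" = n_channels >= 1,
    "`sampling_rate` must be positive" = sampling_rate > 0,
    "`n_units` must be a positive count" = n_units >= 1,
    "`empty_channel_fraction` must be in [0, 1)" =
      empty_channel_fraction >= 0 && empty_channel_fraction < 1,
    "`rate_lognormal_sigma` must be non-negative" = rate_lognormal_sigma >= 0,
    "`amplitude_mu` must be positive" = amplitude_mu > 0,
    "`noise_sigma` must be non-negative" = noise_sigma >= 0,
    "`refractory` must be positive" = refractory > 0
  )
  if (!is.null(burst)) {
    check_that(
      "`refractory` must be below the intra-burst ISI mean" =
        refractory < burst$intra_isi_mean
    )
  }
  structure(
    list(
      n_channels = n_channels, sampling_rate = sampling_rate, layout = layout,
      n_units = n_units, empty_channel_fraction = empty_channel_fraction,
      rate_lognormal_mu = rate_lognormal_mu,
      rate_lognormal_sigma = rate_lognormal_sigma,
      amplitude_mu = amplitude_mu, amplitude_sigma = amplitude_sigma,
      noise_sigma = noise_sigma, refractory = refractory, burst = burst,
      common_mode = common_mode, max_units_per_channel = max_units_per_channel
    ),
    class = "synth_config"
  )
}

#' Burst-structure parameters for the spike-train generator
#'
#' Spike trains are a superposition of a tonic renewal process and a
#' two-state burst process: burst onsets arrive as a Poisson process,
#' burst lengths are geometric, intra-burst ISIs are refractory-shifted
#' exponentials. `burst_fraction` sets the fraction of each unit's mean
#' rate delivered by the burst process.
#'
#' @param intra_isi_mean mean intra-burst inter-spike interval in seconds
#'   (default 0.008).
#' @param len_mean mean number of spikes per burst (default 5, geometric).
#' @param burst_fraction fraction of the unit rate carried by bursts
#'   (default 0.15).
#' @return list of class `burst_structure`.
#' @export
burst_structure <- function(intra_isi_mean = 0.008, len_mean = 5,
                            burst_fraction = 0.15) {
  check_that(
    "`intra_isi_mean` must be positive" = intra_isi_mean > 0,
    "`len_mean` must be >= 1" = len_mean >= 1,
    "`burst_fraction` must be in [0, 1]" =
      burst_fraction >= 0 && burst_fraction <= 1
  )
  structure(
    list(intra_isi_mean = intra_isi_mean, len_mean = len_mean,
         burst_fraction = burst_fraction),
    class = "burst_structure"
  )
}

#' Sample lognormal baseline firing rates
#'
#' Firing rates of cortical-type units are lognormally distributed; this
#' draws per-unit baseline rates with median `exp(mu)`.
#'
#' @param n number of units.
#' @param mu,sigma natural-log location and scale (log-Hz).
#' @param seed optional integer seed.
#' @return numeric vector of `n` positive rates (Hz).
#' @export
sample_unit_rates <- function(n, mu = log(3), sigma = 0.5, seed = NULL) {
  check_that(
    "`n` must be a positive count" = is.numeric(n) && length(n) == 1 && n >= 1,
    "`sigma` must be non-negative" = is.numeric(sigma) && sigma >= 0
  )
  if (!is.null(seed)) set.seed(seed)
  rlnorm(n, meanlog = mu, sdlog = sigma)
}

# tonic renewal train: refractory-shifted exponential ISIs with mean 1/rate,
# on [0, duration). Exact target rate for rate < 1/refractory.
tonic_train <- function(rate, duration, refractory) {
  if (rate <= 0) return(numeric(0))
  shift <- min(refractory, 0.5 / rate)
  exp_mean <- 1 / rate - shift
  n_guess <- ceiling(rate * duration + 6 * sqrt(rate * duration) + 25)
  isi <- shift + rexp(n_guess, rate = 1 / exp_mean)
  t <- cumsum(isi) - isi[1] * runif(1) # random phase of the first spike
  t[t >= 0 & t < duration]
}

# burst-process train: Poisson burst onsets, geometric lengths,
# shifted-exponential intra-burst ISIs.
burst_train <- function(rate, duration, refractory, bs) {
  if (rate <= 0) return(numeric(0))
  onset_rate <- rate / bs$len_mean
  n_b <- rpois(1, onset_rate * duration)
  if (n_b == 0) return(numeric(0))
  starts <- sort(runif(n_b, 0, duration))
  p <- 1 / bs$len_mean
  len <- 1L + rgeom(n_b, p)
  m <- sum(len)
  isi <- refractory + rexp(m, rate = 1 / (bs$intra_isi_mean - refractory))
  first <- cumsum(c(1L, len[-n_b]))
  isi[first] <- 0
  cs <- cumsum(isi)
  off <- cs - rep(cs[first], len)
  t <- rep(starts, len) + off
  t[t < duration]
}

#' Generate a spike train with a piecewise-constant rate profile
#'
#' Produces a strictly increasing spike-time vector on `[0, duration)`
#' following the given per-segment firing rates, with an absolute
#' refractory period and optional burst structure.
#'
#' @param rate_profile either a single non-negative rate (Hz) or a data
#'   frame with columns `start`, `end`, `rate` tiling `[0, duration)`.
#' @param duration total duration in seconds.
#' @param refractory absolute refractory period in seconds.
#' @param burst `NULL` or a [burst_structure()].
#' @param seed optional integer seed.
#' @return numeric vector of spike times in seconds.
#' @export
generate_spike_train <- function(rate_profile, duration, refractory = 0.002,
                                 burst = NULL, seed = NULL) {
  check_that("`duration` must be positive" = duration > 0,
             "`refractory` must be positive" = refractory > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(rate_profile) && length(rate_profile) == 1) {
    rate_profile <- data.frame(start = 0, end = duration, rate = rate_profile)
  }
  check_that(
    "`rate_profile` needs columns start, end, rate" =
      all(c("start", "end", "rate") %in% names(rate_profile)),
    "rates must be non-negative" = all(rate_profile$rate >= 0),
    "segments must have positive length" =
      all(rate_profile$end > rate_profile$start)
  )
  phi <- if (is.null(burst)) 0 else burst$burst_fraction
  times <- numeric(0)
  for (i in seq_len(nrow(rate_profile))) {
    r <- rate_profile$rate[i]
    s <- rate_profile$start[i]
    len <- min(rate_profile$end[i], duration) - s
    if (len <= 0 || r <= 0) next
    seg <- tonic_train((1 - phi) * r, len, refractory)
    if (phi > 0) {
      seg <- c(seg, burst_train(phi * r, len, refractory, burst))
    }
    times <- c(times, s + sort(seg))
  }
  times <- sort(times)
  # greedy refractory thinning across merged processes / segment boundaries
  while (length(times) >= 2) {
    gap <- diff(times)
    bad <- which(gap < refractory)
    if (length(bad) == 0) break
    # drop the second spike of the first violating pair in each chain
    drop <- bad[c(TRUE, diff(bad) > 1)] + 1L
    times <- times[-drop]
  }
  times
}
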