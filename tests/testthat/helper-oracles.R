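# Independent oracles and small simulation helpers shared across tests.

# Brute-force MaxInterval burst detector: enumerate maximal runs of ISIs
# <= max_isi_end, open each candidate at the first ISI <= max_isi_start
# inside the run, then merge candidates closer than min_ibi, then apply the
# duration and spike-count filters. Independent of the package's sequential
# scan.
brute_force_bursts <- function(times, p) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  n <- length(times)
  if (n < 2) return(empty)
  isi <- diff(times)
  r <- rle(isi <= p$max_isi_end)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  cand_s <- integer(0); cand_e <- integer(0)
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    run <- idx_start[j]:idx_end[j]
    first <- run[which(isi[run] <= p$max_isi_start)[1]]
    if (is.na(first)) next
    cand_s <- c(cand_s, first)
    cand_e <- c(cand_e, idx_end[j] + 1L)
  }
  if (length(cand_s) == 0) return(empty)
  # merge
  ms <- cand_s[1]; me <- cand_e[1]
  for (c in seq_along(cand_s)[-1]) {
    if (times[cand_s[c]] - times[me[length(me)]] < p$min_ibi) {
      me[length(me)] <- cand_e[c]
    } else {
      ms <- c(ms, cand_s[c]); me <- c(me, cand_e[c])
    }
  }
  out <- data.frame(start = times[ms], end = times[me],
                    n_spikes = me - ms + 1L)
  out[out$end - out$start >= p$min_duration & out$n_spikes >= p$min_spikes, ,
      drop = FALSE]
}

# random spike train with mixed ISI scales (burst-like, intermediate, slow)
random_train <- function(max_spikes = 50) {
  n <- sample(0:max_spikes, 1)
  if (n == 0) return(numeric(0))
  scale <- sample(c(0.006, 0.04, 0.4), n, replace = TRUE)
  cumsum(rexp(n, 1 / scale) + 1e-5)
}

# greedy +-tol matching of detected against true spike times
match_spikes <- function(truth_t, det_t, tol = 0.001) {
  if (length(truth_t) == 0 || length(det_t) == 0) {
    return(c(recall = NA_real_, precision = NA_real_, tp = 0))
  }
  tp <- 0
  det <- sort(det_t)
  for (tt in sort(truth_t)) {
    if (length(det) == 0) break
    j <- which.min(abs(det - tt))
    if (abs(det[j] - tt) <= tol) {
      tp <- tp + 1
      det <- det[-j]
    }
  }
  c(recall = tp / length(truth_t), precision = tp / length(det_t), tp = tp)
}

# subjects x conditions fixture for the RM-ANOVA oracle tests
anova_fixture <- function() {
  matrix(c(
    3.1, 4.2, 5.0, 3.6,
    2.7, 3.9, 4.1, 3.0,
    3.8, 5.1, 6.2, 4.4,
    1.9, 2.8, 3.5, 2.2,
    4.4, 5.9, 6.8, 5.1,
    3.3, 4.6, 5.2, 3.9
  ), nrow = 6, byrow = TRUE)
}

# independent RM-ANOVA oracle: aov() error strata for F / MS_error,
# eigenvalues of the double-centered covariance for epsilon
anova_oracle <- function(y) {
  n <- nrow(y); k <- ncol(y)
  df <- data.frame(y = as.vector(y),
                   subj = factor(rep(seq_len(n), k)),
                   cond = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ cond + Error(subj / cond), data = df))
  tab <- tab[["Error: subj:cond"]][[1]]
  s <- stats::cov(y)
  cc <- s - outer(rowMeans(s), rep(1, k)) - outer(rep(1, k), colMeans(s)) + mean(s)
  ev <- eigen(cc, symmetric = TRUE)$values
  eps <- sum(ev)^2 / ((k - 1) * sum(ev^2))
  F <- tab["cond", "F value"]
  list(F = F, ms_error = tab["Residuals", "Mean Sq"], epsilon = eps,
       p_gg = stats::pf(F, eps * (k - 1), eps * (k - 1) * (n - 1),
                        lower.tail = FALSE))
}

# small rendered-recording scenario used by sorting tests
small_sorting_scenario <- function(seed, n_channels = 30, n_units = 8,
                                   duration = 10, fs = 10000) {
  cfg <- synth_config(n_channels = n_channels, sampling_rate = fs,
                      n_units = n_units, empty_channel_fraction = 0.2,
                      amplitude_sigma = 0, amplitude_mu = 40, noise_sigma = 4)
  sch <- phase_schedule(
    data.frame(label = "baseline", start = 0, end = duration, g_level = 1),
    safety_margin = 0.15
  )
  truth <- make_ground_truth(cfg, sch, seed = seed)
  list(config = cfg, schedule = sch, truth = truth,
       recording = render_recording(cfg, truth, seed = seed))
}
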