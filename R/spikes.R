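#' Robust noise scale of a voltage trace
#'
#' Median-absolute-deviation estimate of the noise standard deviation,
#' `median(|x - median(x)|) / 0.6745`, which is insensitive to the spikes
#' riding on the noise and underlies the detection threshold.
#'
#' @param trace numeric vector (uV), at least 1000 samples.
#' @return noise sigma in uV.
#' @export
estimate_noise_sigma <- function(trace) {
  check_that("`trace` must have at least 1000 samples" = length(trace) >= 1000,
             class = "gravimea_invalid_input")
  median(abs(trace - median(trace))) / 0.6745
}

#' Detect negative-going threshold crossings
#'
#' Spikes are detected where the trace drops below `-threshold_multiplier
#' * sigma`, aligned to the local trough within one dead time; no two
#' detections occur within `dead_time` of each other.
#'
#' @param trace numeric vector (uV), typically high-pass filtered and
#'   referenced.
#' @param sampling_rate Hz.
#' @param sigma noise scale in uV (e.g. from [estimate_noise_sigma()]).
#' @param threshold_multiplier detection threshold in units of sigma
#'   (default 4.5).
#' @param dead_time minimum separation between detections in seconds
#'   (default 0.001).
#' @param t0 time of the first sample (s).
#' @param edge_exclusion seconds at each end of the trace excluded from
#'   detection (filter-transient guard; default 0.05).
#' @return numeric vector of spike times (s).
#' @export
detect_spikes <- function(trace, sampling_rate, sigma,
                          threshold_multiplier = 4.5, dead_time = 0.001,
                          t0 = 0, edge_exclusion = 0.05) {
  check_that("`sigma` must be positive" = sigma > 0)
  thr <- -threshold_multiplier * sigma
  below <- trace < thr
  if (!any(below)) return(numeric(0))
  onset <- which(below & !c(FALSE, below[-length(below)]))
  half <- max(1L, round(dead_time * sampling_rate))
  troughs <- integer(0)
  last <- -Inf
  for (i in onset) {
    win <- i:min(length(trace), i + half)
    tr <- win[which.min(trace[win])]
    if (tr - last < half) next
    troughs <- c(troughs, tr)
    last <- tr
  }
  guard <- round(edge_exclusion * sampling_rate)
  troughs <- troughs[troughs > guard & troughs <= length(trace) - guard]
  t0 + (troughs - 1L) / sampling_rate
}

#' Extract waveform snippets and cluster them into units
#'
#' Snippets around each detected spike are projected onto their first
#' three principal components and partitioned with k-means; the number of
#' clusters (1..`max_k`) is selected by the mean silhouette width (a split
#' must reach `min_silhouette` to beat the single-cluster solution). Every
#' spike is assigned to exactly one unit; each unit's template is its mean
#' snippet.
#'
#' @param trace numeric vector (uV).
#' @param sampling_rate Hz.
#' @param spike_times detected spike times (s), trough-aligned.
#' @param sigma noise scale (uV), for the SNR quality metric.
#' @param channel_id electrode label carried into the output.
#' @param pre,post snippet window around the trough in seconds
#'   (defaults 0.6 ms / 1.0 ms).
#' @param max_k maximum clusters per channel (default 3).
#' @param min_silhouette minimum mean silhouette width to accept a
#'   multi-cluster split (default 0.5).
#' @param refractory ISI-violation window in seconds (default 0.0015).
#' @param t0 time of the first trace sample (s).
#' @return tibble with one row per unit: `unit_id`, `channel_id`,
#'   `n_spikes`, `snr`, `isi_violation_rate`, and list-columns
#'   `spike_times`, `template`.
#' @export
extract_and_cluster <- function(trace, sampling_rate, spike_times, sigma,
                                channel_id = 1L, pre = 0.0006, post = 0.001,
                                max_k = 3, min_silhouette = 0.5,
                                refractory = 0.0015, t0 = 0) {
  check_that("at least one spike is required" = length(spike_times) >= 1,
             class = "gravimea_invalid_input")
  n_pre <- round(pre * sampling_rate)
  n_post <- round(post * sampling_rate)
  idx <- round((spike_times - t0) * sampling_rate) + 1L
  keep <- idx - n_pre >= 1 & idx + n_post <= length(trace)
  idx <- idx[keep]
  spike_times <- spike_times[keep]
  if (length(idx) == 0) return(unit_tibble_empty())

  snips <- t(vapply(idx, function(i) trace[(i - n_pre):(i + n_post)],
                    numeric(n_pre + n_post + 1L)))
  labels <- cluster_snippets(snips, max_k, min_silhouette)
  labels <- merge_similar_clusters(snips, labels)

  rows <- purrr::map(sort(unique(labels)), function(lab) {
    sel <- labels == lab
    tpl <- colMeans(snips[sel, , drop = FALSE])
    st <- sort(spike_times[sel])
    tibble::tibble(
      unit_id = sprintf("ch%s_u%d", channel_id, lab),
      channel_id = channel_id,
      n_spikes = sum(sel),
      snr = compute_snr(tpl, sigma),
      isi_violation_rate = isi_violation_rate(st, refractory),
      spike_times = list(st),
      template = list(tpl)
    )
  })
  dplyr::bind_rows(rows)
}

unit_tibble_empty <- function() {
  tibble::tibble(unit_id = character(0), channel_id = integer(0),
                 n_spikes = integer(0), snr = numeric(0),
                 isi_violation_rate = numeric(0),
                 spike_times = list(), template = list())
}

# Merge clusters whose mean templates are the same waveform up to a small
# alignment shift (trough-alignment jitter fragments one unit into shifted
# copies); similarity = best cross-correlation over +-3 sample shifts, with
# a compatible trough-to-peak amplitude.
merge_similar_clusters <- function(snips, labels, min_corr = 0.9,
                                   min_amp_ratio = 0.6, max_shift = 3L) {
  repeat {
    labs <- sort(unique(labels))
    if (length(labs) < 2) return(labels)
    tpls <- lapply(labs, function(l) colMeans(snips[labels == l, , drop = FALSE]))
    merged <- FALSE
    for (a in seq_along(labs)[-length(labs)]) {
      for (b in seq(a + 1L, length(labs))) {
        if (templates_similar(tpls[[a]], tpls[[b]], min_corr, min_amp_ratio,
                              max_shift)) {
          labels[labels == labs[b]] <- labs[a]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(labels)
  }
}

templates_similar <- function(t1, t2, min_corr, min_amp_ratio, max_shift) {
  a1 <- max(t1) - min(t1); a2 <- max(t2) - min(t2)
  if (min(a1, a2) / max(a1, a2) < min_amp_ratio) return(FALSE)
  n <- length(t1)
  best <- -1
  for (s in -max_shift:max_shift) {
    i1 <- max(1, 1 + s):min(n, n + s)
    i2 <- i1 - s
    if (length(i1) < 3) next
    if (sd(t1[i1]) == 0 || sd(t2[i2]) == 0) next
    best <- max(best, stats::cor(t1[i1], t2[i2]))
  }
  best >= min_corr
}

# PCA + k-means with silhouette model selection; returns integer labels
cluster_snippets <- function(snips, max_k, min_silhouette) {
  n <- nrow(snips)
  if (n < 4) return(rep(1L, n))
  pcs <- prcomp(snips, center = TRUE)$x
  pcs <- pcs[, seq_len(min(3L, ncol(pcs))), drop = FALSE]
  best <- rep(1L, n); best_sil <- min_silhouette
  d <- dist(pcs)
  for (k in 2:min(max_k, n - 1L)) {
    km <- tryCatch(kmeans(pcs, centers = k, nstart = 5, iter.max = 50),
                   error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < k) next
    sil <- mean(cluster::silhouette(km$cluster, d)[, 3])
    if (sil > best_sil) {
      best <- km$cluster
      best_sil <- sil
    }
  }
  as.integer(best)
}

#' Interspike-interval violation rate
#'
#' Fraction of consecutive ISIs strictly below the refractory bound; a
#' contamination measure (a well-isolated unit cannot fire twice within
#' its refractory period). Returns 0 for fewer than two spikes.
#'
#' @param spike_times numeric vector (s).
#' @param refractory refractory bound in seconds (default 0.0015).
#' @return proportion in \[0, 1\].
#' @export
isi_violation_rate <- function(spike_times, refractory = 0.0015) {
  check_that("`refractory` must be non-negative" = refractory >= 0)
  if (length(spike_times) < 2) return(0)
  isi <- diff(sort(spike_times))
  mean(isi < refractory)
}

#' Template signal-to-noise ratio
#'
#' Trough-to-peak amplitude of the template divided by the channel noise
#' scale.
#'
#' @param template numeric waveform (uV).
#' @param sigma noise scale (uV), > 0.
#' @return dimensionless SNR.
#' @export
compute_snr <- function(template, sigma) {
  check_that("`sigma` must be positive" = sigma > 0)
  (max(template) - min(template)) / sigma
}

#' Curate sorted units by quality
#'
#' Keeps units with ISI violation rate at most `max_isi_violation`, SNR at
#' least `min_snr`, and at least `min_spikes` spikes (very sparse clusters
#' are indistinguishable from chance threshold crossings). Rejected units
#' are attached as the `rejected` attribute with the failed rule.
#'
#' @param units tibble from [extract_and_cluster()].
#' @param max_isi_violation maximum tolerated ISI violation rate
#'   (default 0.2).
#' @param min_snr minimum SNR (default 5).
#' @param min_spikes minimum spike count (default 5).
#' @return The accepted subset, same columns.
#' @export
curate_units <- function(units, max_isi_violation = 0.2, min_snr = 5,
                         min_spikes = 5) {
  ok_isi <- units$isi_violation_rate <= max_isi_violation
  ok_snr <- units$snr >= min_snr
  ok_n <- units$n_spikes >= min_spikes
  reason <- dplyr::case_when(
    !ok_isi ~ "isi_violation",
    !ok_snr ~ "snr",
    !ok_n ~ "min_spikes",
    TRUE ~ NA_character_
  )
  accepted <- units[ok_isi & ok_snr & ok_n, , drop = FALSE]
  rejected <- units[!(ok_isi & ok_snr & ok_n), , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[!(ok_isi & ok_snr & ok_n)]
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Waveform metrics of a template
#'
#' Trough-to-peak amplitude and the half width of the trough lobe (time
#' spent below half the trough depth), the two template parameters
#' compared across gravity phases.
#'
#' @param template numeric waveform (uV).
#' @param sampling_rate Hz.
#' @return tibble with `amplitude` (uV) and `half_width` (ms).
#' @export
waveform_metrics <- function(template, sampling_rate) {
  trough <- min(template)
  if (trough >= 0) {
    rlang::abort("template has no trough (no negative deflection)",
                 class = "gravimea_invalid_input")
  }
  amplitude <- max(template) - trough
  below <- template < trough / 2
  # linear-interpolated width of the contiguous lobe around the trough
  ti <- which.min(template)
  left <- ti
  while (left > 1 && below[left - 1]) left <- left - 1
  right <- ti
  while (right < length(template) && below[right + 1]) right <- right + 1
  cross <- function(i1, i2) {
    # fractional samples where the template crosses trough/2 between i1, i2
    if (i1 < 1 || i2 > length(template) || i1 == i2) return(0)
    v1 <- template[i1]; v2 <- template[i2]
    if (v1 == v2) return(0)
    abs((trough / 2 - v2) / (v1 - v2))
  }
  width_samples <- (right - left) + cross(left - 1L, left) + cross(right + 1L, right)
  tibble::tibble(amplitude = amplitude,
                 half_width = width_samples / sampling_rate * 1000)
}

#' Sort a preprocessed recording into curated units
#'
#' Runs per-channel noise estimation, threshold detection, snippet
#' clustering, and quality curation; the transparent in-repo replacement
#' for an external spike sorter, adequate at standard MEA electrode pitch
#' where a unit appears on a single electrode.
#'
#' @param rec a preprocessed [mea_recording()].
#' @param threshold_multiplier,dead_time see [detect_spikes()].
#' @param max_isi_violation,min_snr,min_spikes see [curate_units()].
#' @param max_k,min_silhouette see [extract_and_cluster()].
#' @return list with `units` (curated unit tibble), `all_units` (before
#'   curation), `spikes` (tidy tibble `unit_id`, `channel_id`, `time` of
#'   curated units), `detections` (tibble `channel_id`, `time`), and
#'   `counts` (per-stage bookkeeping).
#' @export
sort_recording <- function(rec, threshold_multiplier = 4.5, dead_time = 0.001,
                           max_isi_violation = 0.2, min_snr = 5,
                           min_spikes = 5, max_k = 3, min_silhouette = 0.5) {
  all_units <- list()
  detections <- list()
  for (i in seq_len(nrow(rec$samples))) {
    ch <- rec$channel_ids[i]
    trace <- rec$samples[i, ]
    sigma <- estimate_noise_sigma(trace)
    if (sigma <= 0) next
    st <- detect_spikes(trace, rec$sampling_rate, sigma,
                        threshold_multiplier = threshold_multiplier,
                        dead_time = dead_time, t0 = rec$t0)
    if (length(st) == 0) next
    detections[[length(detections) + 1L]] <-
      tibble::tibble(channel_id = ch, time = st)
    all_units[[length(all_units) + 1L]] <-
      extract_and_cluster(trace, rec$sampling_rate, st, sigma,
                          channel_id = ch, max_k = max_k,
                          min_silhouette = min_silhouette, t0 = rec$t0)
  }
  all_units <- if (length(all_units)) dplyr::bind_rows(all_units) else unit_tibble_empty()
  detections <- if (length(detections)) dplyr::bind_rows(detections) else
    tibble::tibble(channel_id = integer(0), time = numeric(0))
  curated <- curate_units(all_units, max_isi_violation = max_isi_violation,
                          min_snr = min_snr, min_spikes = min_spikes)
  spikes <- if (nrow(curated) > 0) {
    tidyr::unnest(curated[c("unit_id", "channel_id", "spike_times")],
                  cols = "spike_times") |>
      dplyr::rename(time = "spike_times")
  } else {
    tibble::tibble(unit_id = character(0), channel_id = integer(0),
                   time = numeric(0))
  }
  list(
    units = curated, all_units = all_units, spikes = spikes,
    detections = detections,
    counts = tibble::tibble(
      stage = c("detected_spikes", "sorted_spikes", "curated_spikes",
                "sorted_units", "curated_units"),
      n = c(nrow(detections), sum(all_units$n_spikes), sum(curated$n_spikes),
            nrow(all_units), nrow(curated))
    )
  )
}
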