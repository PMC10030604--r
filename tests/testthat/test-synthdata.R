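test_that("sample_unit_rates follows the lognormal specification", {
  # degenerate sigma: all rates exactly the median
  expect_equal(sample_unit_rates(5, mu = log(3), sigma = 0, seed = 1),
               rep(3, 5))
  # large-sample median close to exp(mu)
  r <- sample_unit_rates(10000, mu = log(3), sigma = 0.5, seed = 42)
  expect_true(all(r > 0))
  expect_lt(abs(median(r) - 3) / 3, 0.05)
  # determinism
  expect_identical(sample_unit_rates(100, seed = 7),
                   sample_unit_rates(100, seed = 7))
  expect_error(sample_unit_rates(0), class = "gravimea_invalid_parameter")
  expect_error(sample_unit_rates(5, sigma = -1),
               class = "gravimea_invalid_parameter")
})

test_that("generate_spike_train respects rate profile and refractory period", {
  expect_identical(generate_spike_train(0, duration = 100, seed = 1),
                   numeric(0))
  # homogeneous 3 Hz over 600 s: count within 3 * sqrt(1800) of 1800
  t <- generate_spike_train(3, duration = 600, seed = 11)
  expect_lt(abs(length(t) - 1800), 3 * sqrt(1800))
  expect_true(all(diff(t) >= 0.002))
  expect_true(all(t >= 0 & t < 600))
  # with burst structure: refractory still holds, bursts are detectable
  tb <- generate_spike_train(5, duration = 300, seed = 12,
                             burst = burst_structure(burst_fraction = 0.5))
  expect_true(all(diff(tb) >= 0.002))
  expect_gt(nrow(detect_bursts(tb)), 0)
  # piecewise profile: per-segment empirical rates near targets
  prof <- data.frame(start = c(0, 100), end = c(100, 200), rate = c(2, 10))
  tp <- generate_spike_train(prof, duration = 200, seed = 13)
  r1 <- sum(tp < 100) / 100; r2 <- sum(tp >= 100) / 100
  expect_lt(abs(r1 - 2), 4 * sqrt(2 / 100))
  expect_lt(abs(r2 - 10), 4 * sqrt(10 / 100))
  expect_error(generate_spike_train(-1, duration = 10),
               class = "gravimea_invalid_parameter")
})

test_that("ground-truth trains track programmed rates at Poisson tolerance", {
  # long phases (>= 30 s analyzed) across seeds: |emp - true| <= 4*sqrt(r/T)
  bad <- 0; total <- 0
  for (seed in 1:20) {
    sim <- simulate_experiment("drop", seed = seed, scale = 0.1, n_units = 20)
    win <- analysis_windows(sim$schedule)
    win <- win[win$end - win$start >= 30, ]
    for (u in unique(sim$spikes$unit_id)) {
      tu <- sim$spikes$time[sim$spikes$unit_id == u]
      for (i in seq_len(nrow(win))) {
        r <- true_rate(sim$truth, u, win$start[i], win$end[i])
        emp <- firing_rate(tu, win$start[i], win$end[i])
        total <- total + 1
        bad <- bad + (abs(emp - r) > 4 * sqrt(r / (win$end[i] - win$start[i])))
      }
    }
  }
  expect_gte(1 - bad / total, 0.99)
})

test_that("ground truth satisfies its structural invariants", {
  sim <- simulate_experiment("drop", seed = 5, scale = 0.1)
  sp <- sim$spikes
  for (u in unique(sp$unit_id)) {
    tu <- sp$time[sp$unit_id == u]
    expect_true(!is.unsorted(tu, strictly = TRUE))
    if (length(tu) > 1) expect_true(all(diff(tu) >= sim$config$refractory))
  }
  expect_equal(nrow(sim$truth$units), 63)
  expect_setequal(unique(sim$truth$units$subgroup), c("low", "mid", "high"))
  # determinism: same seed, bit-identical truth
  sim2 <- simulate_experiment("drop", seed = 5, scale = 0.1)
  expect_identical(sim$spikes, sim2$spikes)
  expect_identical(sim$truth$rates, sim2$truth$rates)
})

test_that("drop preset encodes the reported effect directions", {
  sim <- simulate_experiment("drop", seed = 9, scale = 0.1)
  units <- sim$truth$units
  r <- sim$truth$rates
  ug <- r[r$segment == "microgravity", ]
  bl <- r[r$segment == "baseline", ]
  m <- merge(merge(units, ug, by = "unit_id"), bl, by = "unit_id",
             suffixes = c(".ug", ".bl"))
  low <- m[m$subgroup == "low", ]
  expect_true(all(low$rate.ug > low$rate.bl))
  # microgravity factor on low units is exactly 4/3 (3 -> 4 Hz)
  expect_equal(low$rate.ug / low$rate.bl, rep(4 / 3, nrow(low)))
  high <- m[m$subgroup == "high", ]
  frac_up <- mean(high$rate.ug > high$rate.bl)
  expect_gt(frac_up, 0.2); expect_lt(frac_up, 0.8)
})

test_that("presets reproduce the protocol schedules", {
  drop <- make_preset("drop", scale = 1)
  expect_equal(drop$schedule$end - drop$schedule$start, c(600, 4.7, 5, 600))
  expect_equal(attr(drop$schedule, "safety_margin"), 0.15)
  cf <- make_preset("centrifuge_6g", scale = 1)
  d <- cf$schedule$end - cf$schedule$start
  names(d) <- cf$schedule$label
  expect_equal(unname(d[c("ramp_up", "hyperg", "ramp_down")]), c(30, 300, 30))
  expect_equal(attr(cf$schedule, "safety_margin"), 2)
  expect_equal(cf$schedule$g_level[cf$schedule$label == "hyperg"], 6)
  # scaling: long phases compressed, sub-10 s phases untouched
  ds <- make_preset("drop", scale = 0.1)$schedule
  expect_equal(ds$end - ds$start, c(60, 4.7, 5, 60))
  expect_error(make_preset("unknown"), class = "gravimea_invalid_parameter")
  expect_error(make_preset("drop", scale = 0),
               class = "gravimea_invalid_parameter")
})

test_that("render_recording places templates, noise and common mode correctly", {
  fs <- 10000
  cfg <- synth_config(n_channels = 4, sampling_rate = fs, n_units = 1,
                      empty_channel_fraction = 0.5, noise_sigma = 0,
                      amplitude_sigma = 0, amplitude_mu = 30)
  sch <- phase_schedule(data.frame(label = "b", start = 0, end = 2, g_level = 1),
                        safety_margin = 0)
  truth <- make_ground_truth(cfg, sch, seed = 2)
  # one spike only
  truth$spikes <- truth$spikes[1, ]
  rec <- render_recording(cfg, truth, seed = 2)
  row <- match(truth$units$channel_id[1], rec$channel_ids)
  tpl <- spike_template(fs, 30)
  idx <- round(truth$spikes$time[1] * fs) + 1L - (attr(tpl, "trough_index") - 1L)
  expect_equal(rec$samples[row, idx:(idx + length(tpl) - 1)], as.numeric(tpl))
  off_rows <- setdiff(seq_len(nrow(rec$samples)), row)
  expect_true(all(rec$samples[off_rows, ] == 0))
  expect_equal(sum(rec$samples[row, ] != 0), sum(tpl != 0))

  # common mode appears as the channel-wise median
  cfg_cm <- synth_config(n_channels = 10, sampling_rate = fs, n_units = 2,
                         empty_channel_fraction = 0.5, noise_sigma = 0,
                         amplitude_sigma = 0,
                         common_mode = list(amplitude = 15, frequency = 50))
  truth_cm <- make_ground_truth(cfg_cm, sch, seed = 3)
  rec_cm <- render_recording(cfg_cm, truth_cm, seed = 3)
  tt <- (seq_len(ncol(rec_cm$samples)) - 1) / fs
  expected <- 15 * sin(2 * pi * 50 * tt)
  med <- apply(rec_cm$samples, 2, median)
  expect_lt(max(abs(med - expected)), 1e-9)

  # empty channels: noise only, std within 5% of noise_sigma over 10 s
  cfg_n <- synth_config(n_channels = 10, sampling_rate = fs, n_units = 2,
                        empty_channel_fraction = 0.5, noise_sigma = 4,
                        amplitude_sigma = 0)
  sch10 <- phase_schedule(data.frame(label = "b", start = 0, end = 10,
                                     g_level = 1), safety_margin = 0)
  truth_n <- make_ground_truth(cfg_n, sch10, seed = 4)
  rec_n <- render_recording(cfg_n, truth_n, seed = 4)
  empty_rows <- which(!truth_n$channels$has_unit)
  for (i in empty_rows[1:2]) {
    expect_lt(abs(sd(rec_n$samples[i, ]) - 4) / 4, 0.05)
  }

  # int16 calibration guard
  cfg_big <- synth_config(n_channels = 4, sampling_rate = fs, n_units = 1,
                          empty_channel_fraction = 0.5, noise_sigma = 0,
                          amplitude_sigma = 0, amplitude_mu = 5000)
  truth_big <- make_ground_truth(cfg_big, sch, seed = 5)
  expect_error(render_recording(cfg_big, truth_big, seed = 5),
               class = "gravimea_calibration_error")
})

test_that("synth_config validates its invariants", {
  expect_error(synth_config(noise_sigma = -1),
               class = "gravimea_invalid_parameter")
  expect_error(synth_config(refractory = 0.01,
                            burst = burst_structure(intra_isi_mean = 0.008)),
               class = "gravimea_invalid_parameter")
  expect_error(synth_config(empty_channel_fraction = 1),
               class = "gravimea_invalid_parameter")
})
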