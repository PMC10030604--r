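test_that("RM-ANOVA handles degenerate and two-condition designs exactly", {
  # rows constant across conditions: F = 0, p = 1
  y <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 4)
  a <- rm_anova_gg(y)
  expect_equal(a$F, 0)
  expect_equal(a$p_gg, 1)
  # k = 2: epsilon exactly 1 and F equals the squared paired t statistic
  set.seed(81)
  y2 <- matrix(rnorm(24), ncol = 2)
  a2 <- rm_anova_gg(y2)
  expect_equal(a2$epsilon_gg, 1)
  tt <- t.test(y2[, 1], y2[, 2], paired = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p_gg, tt$p.value, tolerance = 1e-10)
  expect_error(rm_anova_gg(matrix(c(1, NA, 2, 3), 2)))
  expect_error(rm_anova_gg(matrix(1:4, ncol = 1)))
})

test_that("RM-ANOVA matches the frozen fixture oracle to 6 decimals", {
  y <- anova_fixture()
  a <- rm_anova_gg(y)
  # frozen values computed with the independent aov()/eigenvalue oracle
  expect_equal(a$F, 123.8093322607, tolerance = 1e-9)
  expect_equal(a$epsilon_gg, 0.4569924579, tolerance = 1e-9)
  expect_equal(a$p_gg, 7.334739e-06, tolerance = 1e-6)
  expect_equal(a$ms_error, 0.034527777778, tolerance = 1e-9)
  # and agrees with the oracle recomputed live
  o <- anova_oracle(y)
  expect_equal(a$F, o$F, tolerance = 1e-10)
  expect_equal(a$epsilon_gg, o$epsilon, tolerance = 1e-10)
  expect_equal(a$ms_error, o$ms_error, tolerance = 1e-10)
  expect_equal(a$p_gg, o$p_gg, tolerance = 1e-10)
  g <- glance(a)
  expect_equal(g$statistic, a$F)
  expect_equal(g$epsilon_gg, a$epsilon_gg)
})

test_that("GG epsilon respects its bounds", {
  set.seed(82)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    y <- matrix(rnorm(10 * k), ncol = k)
    eps <- rm_anova_gg(y)$epsilon_gg
    expect_gte(eps, 1 / (k - 1))
    expect_lte(eps, 1)
  }
})

test_that("Tukey pairwise comparisons match the fixture oracle", {
  y <- anova_fixture()
  colnames(y) <- paste0("c", 1:4)
  a <- rm_anova_gg(y)
  tk <- tukey_pairwise(y, a)
  # frozen q values from the oracle computation
  expect_equal(tk$q, c(16.038469, 25.485787, 6.591152, 9.447318, 9.447318,
                       18.894635), tolerance = 1e-6)
  expect_equal(tk$p_adj,
               ptukey(tk$q, 4, 15, lower.tail = FALSE), tolerance = 1e-12)
  # identical condition means: q = 0, p = 1
  yc <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 4)
  ac <- rm_anova_gg(yc)
  tc <- tukey_pairwise(yc, ac)
  expect_true(all(tc$q == 0))
  expect_true(all(tc$p_adj == 1))
  # k = 2: Tukey p equals the paired comparison p (no multiplicity)
  set.seed(83)
  y2 <- matrix(rnorm(30), ncol = 2)
  a2 <- rm_anova_gg(y2)
  t2 <- tukey_pairwise(y2, a2)
  tt <- t.test(y2[, 1], y2[, 2], paired = TRUE)
  expect_equal(t2$p_adj, tt$p.value, tolerance = 1e-10)
  # antisymmetry of differences
  expect_equal(t2$mean_diff, mean(y2[, 2]) - mean(y2[, 1]))
})

test_that("Friedman test handles concordance, ties and matches stats::friedman.test", {
  # perfect concordance: n = 10, k = 3 -> statistic n(k-1) = 20
  y <- matrix(rep(c(1, 2, 3), each = 10), ncol = 3) + rep(1:10, 3) * 0
  f <- friedman_test(y)
  expect_equal(f$statistic, 20)
  # constant rows: statistic 0
  expect_equal(friedman_test(matrix(5, 4, 3))$statistic, 0)
  # textbook 4x3 example with ties: exact match to the reference routine
  m <- matrix(c(2.5, 3.1, 2.2, 4.4, 4.1, 4.0, 3.3, 3.3, 3.1, 5.0, 5.8, 5.2),
              nrow = 4, byrow = TRUE)
  f2 <- friedman_test(m)
  ref <- stats::friedman.test(m)
  expect_equal(f2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(f2$p.value, ref$p.value, tolerance = 1e-12)
  # random cross-check including ties
  set.seed(84)
  for (i in 1:20) {
    mm <- matrix(sample(1:4, 24, TRUE), ncol = 4)
    expect_equal(friedman_test(mm)$statistic,
                 unname(stats::friedman.test(mm)$statistic), tolerance = 1e-12)
  }
})

test_that("Friedman test is invariant to monotone within-subject transforms", {
  set.seed(85)
  y <- matrix(rlnorm(40), ncol = 4)
  f1 <- friedman_test(y)
  f2 <- friedman_test(log(y))
  f3 <- friedman_test(y^3)
  expect_equal(f1$statistic, f2$statistic)
  expect_equal(f1$statistic, f3$statistic)
})

test_that("ROUT flags gross outliers and spares clean data", {
  flag <- rout_outliers(c(0, 0, 0, 0, 0, 100))
  expect_equal(which(flag), 6L)
  expect_true(all(!rout_outliers(rep(3.5, 10))))
  expect_warning(f3 <- rout_outliers(c(1, 2, 3)), "at least 4")
  expect_true(all(!f3))
  # clean Gaussian n = 20: nothing flagged in >= 95% of samples
  set.seed(86)
  none <- replicate(300, !any(rout_outliers(rnorm(20))))
  expect_gte(mean(none), 0.95)
  # a planted shift outlier in Gaussian noise is caught
  set.seed(87)
  x <- c(rnorm(30), 25)
  expect_true(rout_outliers(x)[31])
})

test_that("density profiles normalize and find the population modes", {
  set.seed(88)
  r <- rnorm(200, 3, 0.3)
  d <- density_profile(r)
  step <- d$rate[2] - d$rate[1]
  integral <- sum((d$density[-1] + d$density[-nrow(d)]) / 2) * step
  expect_lt(abs(integral - 1), 1e-3)
  expect_lt(abs(d$rate[which.max(d$density)] - 3), 0.5)
  # two separated clusters at 8 and 20 Hz give two local maxima nearby
  r2 <- c(rnorm(150, 8, 0.8), rnorm(150, 20, 0.8))
  d2 <- density_profile(r2)
  y <- d2$density
  peaks <- which(y > dplyr::lag(y, default = 0) & y > dplyr::lead(y, default = 0))
  peaks <- peaks[y[peaks] > 0.2 * max(y)]
  expect_equal(length(peaks), 2)
  expect_lt(abs(d2$rate[peaks[1]] - 8), 1)
  expect_lt(abs(d2$rate[peaks[2]] - 20), 1)
  # degenerate input falls back to the minimum bandwidth
  dd <- density_profile(rep(2, 10))
  expect_equal(attr(dd, "bandwidth"), 0.1)
  expect_error(density_profile(3))
})

test_that("subgroup deltas rank, slice and break ties deterministically", {
  tab <- tibble::tibble(
    unit_id = sprintf("u%02d", 1:9),
    phase = "a", firing_rate = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
    burst_rate = 0
  )
  tab <- dplyr::bind_rows(tab, dplyr::mutate(tab, phase = "b",
                                             firing_rate = firing_rate + 1))
  d <- subgroup_deltas(tab, "a", "b", k = 3)
  expect_equal(d$unit_id[d$subgroup == "low"], sprintf("u%02d", 1:3))
  expect_equal(d$unit_id[d$subgroup == "mid"], sprintf("u%02d", 4:6))
  expect_equal(d$unit_id[d$subgroup == "high"], sprintf("u%02d", 7:9))
  expect_true(all(d$sign == 1))
  # k = 1 on a 3-unit table returns the three units themselves
  t3 <- tab[tab$unit_id %in% c("u01", "u05", "u09"), ]
  d3 <- subgroup_deltas(t3, "a", "b", k = 1)
  expect_equal(sort(d3$unit_id), c("u01", "u05", "u09"))
  # ties at the median rank broken by unit id
  tt <- tibble::tibble(unit_id = sprintf("u%02d", 1:5), phase = "a",
                       firing_rate = c(1, 2, 2, 2, 3), burst_rate = 0)
  tt <- dplyr::bind_rows(tt, dplyr::mutate(tt, phase = "b"))
  d5 <- subgroup_deltas(tt, "a", "b", k = 1)
  expect_equal(d5$unit_id[d5$subgroup == "mid"], "u03")
  expect_error(subgroup_deltas(tab, "a", "b", k = 4))
})

test_that("drop-preset subgroup deltas show the planted low-unit increase", {
  sim <- simulate_experiment("drop", seed = 19, scale = 0.1)
  tab <- filter_silent_units(build_rate_table(sim$spikes, sim$schedule))
  d <- subgroup_deltas(tab, "baseline", "microgravity", k = 10)
  # ground truth: every low unit increases; verify on true rates
  tr <- sim$truth$rates
  for (u in d$unit_id[d$subgroup == "low"]) {
    expect_gt(tr$rate[tr$unit_id == u & tr$segment == "microgravity"],
              tr$rate[tr$unit_id == u & tr$segment == "baseline"])
  }
})

test_that("type-I error of the GG ANOVA is calibrated on null log-rate data", {
  set.seed(89)
  rej <- replicate(400, {
    subj <- rnorm(20, 0, 0.4)
    y <- exp(log(3) + outer(subj, rep(1, 4)) + matrix(rnorm(80, 0, 0.3), 20))
    rm_anova_gg(log10(y))$p_gg < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})
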