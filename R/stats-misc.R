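#' Friedman test (non-parametric repeated-measures ANOVA)
#'
#' Within-subject mid-ranks with the standard tie correction:
#' `chi^2_F = 12 * sum_j (R_j - n(k+1)/2)^2 / (n k (k+1) - T/(k-1))`
#' where `R_j` are rank column sums and `T = sum over subjects of
#' sum(t^3 - t)` over tie groups; p from the chi-square distribution with
#' `k - 1` degrees of freedom.
#'
#' @param data numeric matrix or data frame, subjects x conditions.
#' @return list of class `friedman_test` with `statistic`, `df`,
#'   `p.value`, `n`, `k`.
#' @export
friedman_test <- function(data) {
  y <- as.matrix(data)
  check_that(
    "`data` must be numeric without missing cells" = is.numeric(y) && !anyNA(y),
    "at least 2 subjects are required" = nrow(y) >= 2,
    "at least 2 conditions are required" = ncol(y) >= 2
  )
  n <- nrow(y); k <- ncol(y)
  ranks <- t(apply(y, 1, rank)) # mid-ranks for ties
  rj <- colSums(ranks)
  tie_term <- sum(apply(y, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  stat <- if (denom <= 0) 0 else 12 * sum((rj - n * (k + 1) / 2)^2) / denom
  structure(
    list(statistic = stat, df = k - 1,
         p.value = pchisq(stat, df = k - 1, lower.tail = FALSE),
         n = n, k = k),
    class = "friedman_test"
  )
}

#' @export
print.friedman_test <- function(x, ...) {
  cat(sprintf("Friedman test: chi-squared = %.4g, df = %d, p = %.4g (n = %d, k = %d)\n",
              x$statistic, x$df, x$p.value, x$n, x$k))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.friedman_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 n = x$n, k = x$k)
}

#' ROUT outlier detection for a location model
#'
#' Robust outlier detection at FDR rate `Q`: residuals from the median
#' are scaled by the RSDR (the 68.27th percentile of absolute residuals
#' with the small-sample correction `n / (n - 1.5)`), converted to
#' two-tailed t-type p-values (`df = n - 1`), and flagged by
#' Benjamini-Hochberg step-up at rate `Q` — the ROUT construction applied
#' to a constant model, as appropriate for scalar waveform parameters.
#'
#' @param values numeric vector, `n >= 4` for any detection.
#' @param Q FDR rate (default 0.01, i.e. 1 percent).
#' @return logical outlier mask the length of `values` (with attribute
#'   `p` of per-point p-values). For `n < 4` a warning is raised and no
#'   point is flagged.
#' @export
rout_outliers <- function(values, Q = 0.01) {
  check_that("`Q` must be in (0, 1)" = Q > 0 && Q < 1)
  n <- length(values)
  if (n < 4) {
    rlang::warn("ROUT needs at least 4 values; nothing flagged")
    return(structure(rep(FALSE, n), p = rep(NA_real_, n)))
  }
  res <- values - median(values)
  rsdr <- unname(quantile(abs(res), 0.6827, type = 7)) * n / (n - 1.5)
  if (rsdr <= 0) {
    # degenerate scale: only points off the median can be outliers
    rsdr <- max(.Machine$double.eps * max(abs(values), 1), 1e-300)
  }
  p <- 2 * pt(-abs(res) / rsdr, df = n - 1)
  flag <- stats::p.adjust(p, method = "BH") <= Q
  structure(flag, p = p)
}

#' Firing-rate density profile
#'
#' Gaussian kernel density of unit firing rates on a linear Hz grid
#' `[0, grid_max]`, Scott bandwidth (`sd(x) * n^(-1/5)`), clipped to the
#' grid support and renormalized to integrate to 1; the standard display
#' of how the population's rate distribution shifts between gravity
#' phases.
#'
#' @param rates numeric vector of rates (Hz), at least 2 finite values.
#' @param grid_max upper edge of the evaluation grid (default 30 Hz).
#' @param n_grid number of grid points (default 512).
#' @param min_bandwidth lower bandwidth bound in Hz for degenerate
#'   (all-identical) samples (default 0.1).
#' @return tibble of class `density_profile` with columns `rate`,
#'   `density`; bandwidth stored as attribute `bandwidth`.
#' @export
density_profile <- function(rates, grid_max = 30, n_grid = 512,
                            min_bandwidth = 0.1) {
  rates <- rates[is.finite(rates)]
  check_that("at least 2 finite rates are required" = length(rates) >= 2,
             "`grid_max` must be positive" = grid_max > 0)
  bw <- sd(rates) * length(rates)^(-1 / 5)
  if (!is.finite(bw) || bw < min_bandwidth) bw <- min_bandwidth
  d <- density(rates, bw = bw, from = 0, to = grid_max, n = n_grid)
  dens <- pmax(d$y, 0)
  step <- d$x[2] - d$x[1]
  area <- sum((dens[-1] + dens[-length(dens)]) / 2) * step
  dens <- dens / area
  out <- tibble::tibble(rate = d$x, density = dens)
  structure(out, class = c("density_profile", class(out)), bandwidth = bw)
}

#' Paired subgroup rate changes between two phases
#'
#' Ranks units by their firing rate in the reference phase and returns the
#' `k` lowest, the `k` highest, and the `k` centered on the median rank,
#' each with their paired reference/target rates and the sign of change —
#' the per-unit view of how low-, mid- and high-firing subpopulations
#' react to a gravity phase. Rank ties are broken by ascending unit id.
#'
#' @param table a `phase_rate_table` (linear rates).
#' @param ref_phase,target_phase phase labels present in the table.
#' @param k subgroup size (default 10).
#' @return tibble with columns `subgroup`, `unit_id`, `ref_rate`,
#'   `target_rate`, `change` (target - ref), `sign`.
#' @export
subgroup_deltas <- function(table, ref_phase, target_phase, k = 10) {
  dat <- tibble::as_tibble(table)
  check_that(
    "phases must be present in the table" =
      all(c(ref_phase, target_phase) %in% dat$phase)
  )
  wide <- tidyr::pivot_wider(dat[c("unit_id", "phase", "firing_rate")],
                             names_from = "phase", values_from = "firing_rate")
  check_that("table must contain at least 3 * k units" = nrow(wide) >= 3 * k)
  ord <- order(wide[[ref_phase]], wide$unit_id)
  wide <- wide[ord, ]
  n <- nrow(wide)
  mid_lo <- floor((n - k) / 2) + 1L
  sel <- list(
    low = seq_len(k),
    mid = seq(mid_lo, mid_lo + k - 1L),
    high = seq(n - k + 1L, n)
  )
  rows <- purrr::imap(sel, function(idx, nm) {
    tibble::tibble(
      subgroup = nm,
      unit_id = wide$unit_id[idx],
      ref_rate = wide[[ref_phase]][idx],
      target_rate = wide[[target_phase]][idx]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$change <- out$target_rate - out$ref_rate
  out$sign <- sign(out$change)
  out
}
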