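#' Repeated-measures one-way ANOVA with Geisser-Greenhouse correction
#'
#' Classical within-subject decomposition on a complete subjects x
#' conditions matrix: `F = MS_condition / MS_error` with uncorrected
#' degrees of freedom `(k - 1)` and `(k - 1)(n - 1)`. Sphericity
#' violations are corrected by the Geisser-Greenhouse epsilon computed
#' from the double-centered condition covariance matrix `C`:
#' `epsilon = tr(C)^2 / ((k - 1) tr(C^2))`, bounded in
#' `[1/(k - 1), 1]`; the reported p-value uses epsilon-scaled degrees of
#' freedom.
#'
#' @param data numeric matrix or data frame, subjects in rows, conditions
#'   in columns, no missing cells.
#' @return object of class `rm_anova_gg`: list with `F`, `df_num`,
#'   `df_den`, `epsilon_gg`, `p_uncorrected`, `p_gg`, `grand_mean`,
#'   `condition_means`, `ms_error`, `n`, `k`.
#' @export
rm_anova_gg <- function(data) {
  y <- as.matrix(data)
  check_that(
    "`data` must be numeric" = is.numeric(y),
    "`data` must have no missing cells" = !anyNA(y),
    "at least 3 subjects are required" = nrow(y) >= 3,
    "at least 2 conditions are required" = ncol(y) >= 2
  )
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  cond_means <- colMeans(y)
  subj_means <- rowMeans(y)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_num <- k - 1
  df_den <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df_num
  ms_err <- ss_err / df_den
  f <- if (ms_err <= 0) {
    if (ms_cond <= 0) 0 else Inf
  } else ms_cond / ms_err

  # Geisser-Greenhouse epsilon from the double-centered covariance
  s <- stats::cov(y)
  cm <- diag(k) - matrix(1 / k, k, k)
  cc <- cm %*% s %*% cm
  tr <- sum(diag(cc))
  tr2 <- sum(cc * cc) # tr(C %*% C) for symmetric C
  eps <- if (tr2 <= 0) 1 else tr^2 / ((k - 1) * tr2)
  eps <- min(1, max(1 / (k - 1), eps))

  p_unc <- if (f == 0) 1 else pf(f, df_num, df_den, lower.tail = FALSE)
  p_gg <- if (f == 0) 1 else pf(f, eps * df_num, eps * df_den, lower.tail = FALSE)

  structure(
    list(F = f, df_num = df_num, df_den = df_den, epsilon_gg = eps,
         p_uncorrected = p_unc, p_gg = p_gg, grand_mean = grand,
         condition_means = cond_means, ms_error = ms_err, n = n, k = k),
    class = "rm_anova_gg"
  )
}

#' @export
print.rm_anova_gg <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures one-way ANOVA (n = %d subjects, k = %d conditions)\n",
    x$n, x$k))
  cat(sprintf("  F(%g, %g) = %.4g, Geisser-Greenhouse epsilon = %.4f\n",
              x$df_num, x$df_den, x$F, x$epsilon_gg))
  cat(sprintf("  p (GG-corrected) = %.4g, p (uncorrected) = %.4g\n",
              x$p_gg, x$p_uncorrected))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @exportS3Method generics::glance
glance.rm_anova_gg <- function(x, ...) {
  tibble::tibble(
    statistic = x$F, df_num = x$df_num, df_den = x$df_den,
    epsilon_gg = x$epsilon_gg, p.value = x$p_gg,
    p.value.uncorrected = x$p_uncorrected, ms_error = x$ms_error,
    n = x$n, k = x$k
  )
}

#' @exportS3Method generics::tidy
tidy.rm_anova_gg <- function(x, ...) {
  tibble::tibble(
    condition = names(x$condition_means) %||% as.character(seq_len(x$k)),
    estimate = unname(x$condition_means)
  )
}

#' Tukey pairwise comparisons after a repeated-measures ANOVA
#'
#' For every condition pair, the studentized range statistic
#' `q = |mean_i - mean_j| / sqrt(MS_error / n)` with the RM-ANOVA error
#' term; adjusted p-values from the studentized range distribution with
#' `k` groups and the uncorrected error degrees of freedom (the
#' sphericity correction applies to the omnibus test only).
#'
#' @param data the subjects x conditions matrix the ANOVA was fitted on.
#' @param anova the matching [rm_anova_gg()] fit.
#' @return tibble of class `tukey_pairwise`: `condition_1`, `condition_2`,
#'   `mean_diff`, `q`, `p_adj`.
#' @export
tukey_pairwise <- function(data, anova) {
  y <- as.matrix(data)
  check_that(
    "`anova` must be an rm_anova_gg fit" = inherits(anova, "rm_anova_gg"),
    "`data` must match the fitted matrix" =
      nrow(y) == anova$n && ncol(y) == anova$k,
    "at least 2 subjects are required" = nrow(y) >= 2
  )
  k <- anova$k; n <- anova$n
  means <- unname(colMeans(y))
  labs <- colnames(y) %||% as.character(seq_len(k))
  se <- sqrt(anova$ms_error / n)
  pairs <- utils::combn(k, 2)
  out <- tibble::tibble(
    condition_1 = labs[pairs[1, ]],
    condition_2 = labs[pairs[2, ]],
    mean_diff = means[pairs[2, ]] - means[pairs[1, ]],
    q = abs(means[pairs[2, ]] - means[pairs[1, ]]) / se,
    p_adj = ptukey(abs(means[pairs[2, ]] - means[pairs[1, ]]) / se,
                   nmeans = k, df = anova$df_den, lower.tail = FALSE)
  )
  if (anova$ms_error <= 0) {
    out$q <- ifelse(abs(out$mean_diff) > 0, Inf, 0)
    out$p_adj <- ifelse(abs(out$mean_diff) > 0, 0, 1)
  }
  class(out) <- c("tukey_pairwise", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.tukey_pairwise <- function(x, ...) {
  tibble::as_tibble(x)
}
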