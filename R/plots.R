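#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_violin geom_point
#'   labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a firing-rate density profile
#'
#' @param object a [density_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.density_profile <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$rate, y = .data$density)) +
    geom_line() +
    labs(x = "Firing rate (Hz)", y = "Density") +
    theme_minimal()
}

#' Violin plot of a phase rate table
#'
#' One violin per analyzed phase, on log10 rates (the scale the
#' statistics run on).
#'
#' @param object a `phase_rate_table`.
#' @param measure `"firing"` or `"burst"`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phase_rate_table <- function(object, measure = c("firing", "burst"), ...) {
  measure <- match.arg(measure)
  col <- paste0(measure, "_rate")
  dat <- tibble::as_tibble(object)
  dat <- dat[is.finite(dat[[col]]) & dat[[col]] > 0, ]
  phases <- attr(object, "windows")$phase
  dat$phase <- factor(dat$phase, levels = phases)
  y <- if (isTRUE(attr(object, "log10"))) dat[[col]] else log10(dat[[col]])
  dat$log_rate <- y
  ggplot(dat, aes(x = .data$phase, y = .data$log_rate)) +
    geom_violin(draw_quantiles = c(0.25, 0.5, 0.75)) +
    geom_point(alpha = 0.4, shape = 17) +
    labs(x = NULL, y = sprintf("log10 %s rate (Hz)", measure)) +
    theme_minimal()
}

#' Paired-lines plot of subgroup rate changes
#'
#' @param deltas a [subgroup_deltas()] result.
#' @param ref_label,target_label axis labels for the two phases.
#' @return a ggplot.
#' @export
plot_subgroup_deltas <- function(deltas, ref_label = "reference",
                                 target_label = "target") {
  long <- tidyr::pivot_longer(deltas, c("ref_rate", "target_rate"),
                              names_to = "which", values_to = "rate")
  long$which <- factor(long$which, levels = c("ref_rate", "target_rate"),
                       labels = c(ref_label, target_label))
  ggplot(long, aes(x = .data$which, y = .data$rate, group = .data$unit_id)) +
    geom_line(alpha = 0.6) +
    geom_point() +
    facet_wrap(~subgroup, scales = "free_y") +
    labs(x = NULL, y = "Firing rate (Hz)") +
    theme_minimal()
}
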