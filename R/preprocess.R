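#' Zero-phase Butterworth high-pass filter
#'
#' Removes the local-field/DC band before spike detection. The filter is
#' designed with [signal::butter()] and applied forward-backward
#' (zero-phase), so spike times are not shifted; the magnitude response is
#' consequently the square of the single-pass Butterworth response. Each
#' channel is reflect-padded (odd reflection, three filter lengths) before
#' filtering to suppress edge transients.
#'
#' @param rec an [mea_recording()].
#' @param order filter order (default 2).
#' @param cutoff high-pass cutoff in Hz (default 100).
#' @return The filtered [mea_recording()].
#' @export
butterworth_highpass <- function(rec, order = 2, cutoff = 100) {
  fs <- rec$sampling_rate
  check_that(
    "`cutoff` must be positive and below the Nyquist frequency" =
      cutoff > 0 && cutoff < fs / 2,
    "`order` must be a positive integer" = order >= 1
  )
  bw <- signal::butter(order, cutoff / (fs / 2), type = "high")
  filtered <- t(apply(rec$samples, 1, filtfilt_padded, b = bw$b, a = bw$a,
                      pad = 3L * ceiling(fs / cutoff)))
  out <- rec
  out$samples <- filtered
  out
}

# forward-backward IIR filtering with odd-reflection padding
filtfilt_padded <- function(x, b, a, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

# direct-form IIR: FIR numerator via one-sided convolution, recursive
# denominator via stats::filter (both C routines)
iir_filter <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1L), x), b, method = "convolution",
                     sides = 1)
  v <- v[-seq_len(nb - 1L)]
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

#' Common median referencing
#'
#' Subtracts the across-channel median from every channel at each sample,
#' cancelling artifacts shared by all electrodes (movement, supply noise,
#' platform interference). Requires at least two channels.
#'
#' @param rec an [mea_recording()].
#' @return The referenced [mea_recording()].
#' @export
common_median_reference <- function(rec) {
  if (nrow(rec$samples) < 2) {
    rlang::abort("common median referencing needs at least 2 channels",
                 class = "gravimea_invalid_input")
  }
  med <- matrixStats::colMedians(rec$samples)
  out <- rec
  out$samples <- sweep(rec$samples, 2, med, `-`)
  out
}

#' Standard preprocessing chain
#'
#' High-pass filter then common median referencing, the denoising chain
#' applied before spike detection.
#'
#' @param rec an [mea_recording()].
#' @param order,cutoff see [butterworth_highpass()].
#' @param cmr apply common median referencing (default TRUE).
#' @return preprocessed [mea_recording()].
#' @export
preprocess_recording <- function(rec, order = 2, cutoff = 100, cmr = TRUE) {
  out <- butterworth_highpass(rec, order = order, cutoff = cutoff)
  if (cmr && nrow(out$samples) >= 2) out <- common_median_reference(out)
  out
}
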