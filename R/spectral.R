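#' Sigmoid band weights
#'
#' Frequency-domain bandpass weights built from paired logistic flanks:
#' `w(f) = sigma((f - f_lo)/h) * sigma((f_hi - f)/h)` with `sigma` the
#' logistic function and `h` the flank half-width. Weights are 0.5 at each
#' band edge, saturate to 1 deep inside the band and to 0 far outside, and
#' are symmetric about the band center.
#'
#' @param freqs sorted non-negative frequencies, Hz.
#' @param f_lo,f_hi band edges, Hz (0 < f_lo < f_hi).
#' @param halfwidth flank half-width, Hz (> 0; 1.5 for broadband gamma).
#' @return weights in \[0, 1\], same length as `freqs`.
#' @export
sigmoid_band_weights <- function(freqs, f_lo, f_hi, halfwidth = 1.5) {
  if (!(f_lo > 0 && f_hi > f_lo)) stop("need 0 < f_lo < f_hi")
  if (halfwidth <= 0) stop("halfwidth must be > 0")
  if (is.unsorted(freqs)) stop("freqs must be sorted")
  if (any(freqs < 0)) stop("freqs must be non-negative")
  stats::plogis((freqs - f_lo) / halfwidth) *
    stats::plogis((f_hi - freqs) / halfwidth)
}

#' Frequency-domain bandpass Hilbert envelope
#'
#' Analytic-amplitude extraction in one pass: FFT, zero the negative
#' frequencies and double the positive ones (analytic-signal construction),
#' multiply by the sigmoid band weights, inverse FFT, take the magnitude.
#' The result is the instantaneous envelope of the band-limited signal and
#' is linear in the input amplitude. No zero-padding: the FFT length is the
#' signal length, and the flank width stays fixed in Hz regardless of
#' length.
#'
#' @param x numeric vector (one channel) or channels x samples matrix.
#' @param fs sampling rate, Hz; requires `f_hi < fs/2`.
#' @param f_lo,f_hi,halfwidth band spec as in [sigmoid_band_weights()].
#' @return envelope, same shape as `x`, non-negative.
#' @export
hilbert_bandpass_amplitude <- function(x, fs, f_lo = 70, f_hi = 150,
                                       halfwidth = 1.5) {
  if (f_hi >= fs / 2) stop("f_hi must be below Nyquist (fs/2)")
  one <- is.null(dim(x))
  if (one) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n < 4 * fs / f_lo) stop("signal too short for the requested band")
  f <- (seq_len(n) - 1) * fs / n
  pos <- f > 0 & f < fs / 2
  gain <- numeric(n)
  gain[pos] <- 2 * sigmoid_band_weights(f[pos], f_lo, f_hi, halfwidth)
  gain[1] <- sigmoid_band_weights(0, f_lo, f_hi, halfwidth)   # DC, ~0
  if (n %% 2 == 0)   # Nyquist bin kept single
    gain[n / 2 + 1] <- sigmoid_band_weights(fs / 2, f_lo, f_hi, halfwidth)
  X <- t(stats::mvfft(t(x)))
  X <- sweep(X, 2, gain, "*")
  env <- Mod(t(stats::mvfft(t(X), inverse = TRUE))) / n
  if (one) env[1, ] else env
}

#' Zero-phase band-limited voltage
#'
#' The band-limited signal itself (not its envelope): the FFT is multiplied
#' by the sigmoid band weights applied symmetrically to positive and
#' negative frequencies, then inverted. Zero-phase by construction.
#'
#' @inheritParams hilbert_bandpass_amplitude
#' @return filtered signal, same shape as `x`.
#' @export
bandlimit_voltage <- function(x, fs, f_lo = 70, f_hi = 150,
                              halfwidth = 1.5) {
  if (f_hi >= fs / 2) stop("f_hi must be below Nyquist (fs/2)")
  one <- is.null(dim(x))
  if (one) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  f <- (seq_len(n) - 1) * fs / n
  f_phys <- ifelse(f > fs / 2, fs - f, f)    # fold to physical frequency
  gain <- sigmoid_band_weights_unsorted(f_phys, f_lo, f_hi, halfwidth)
  X <- t(stats::mvfft(t(x)))
  X <- sweep(X, 2, gain, "*")
  y <- Re(t(stats::mvfft(t(X), inverse = TRUE))) / n
  if (one) y[1, ] else y
}

# internal: weights without the sorted-input guard (folded axes)
sigmoid_band_weights_unsorted <- function(freqs, f_lo, f_hi, halfwidth) {
  stats::plogis((freqs - f_lo) / halfwidth) *
    stats::plogis((f_hi - freqs) / halfwidth)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing: each output sample is the center
#' value of the polynomial of order `order` fit to the surrounding frame.
#' The frame length in ms is converted to samples and rounded to the
#' nearest odd count (151 ms at 2 kHz gives 302, rounded to 301 samples).
#' The first and last half-frame are edge-contaminated and should not enter
#' statistics windows; [edge_samples()] reports how many.
#'
#' @param x numeric vector or channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param order polynomial order (default 3).
#' @param frame_ms frame length, ms (default 151).
#' @return smoothed series, same shape.
#' @export
savgol_smooth <- function(x, fs, order = 3, frame_ms = 151) {
  n_frame <- sg_frame_samples(frame_ms, fs)
  if (n_frame < order + 2) stop("frame shorter than order + 2 samples")
  if (is.null(dim(x))) return(signal::sgolayfilt(x, p = order, n = n_frame))
  t(apply(x, 1, signal::sgolayfilt, p = order, n = n_frame))
}

#' @rdname savgol_smooth
#' @return `sg_frame_samples` returns the odd frame length in samples.
#' @export
sg_frame_samples <- function(frame_ms, fs) {
  n <- round(frame_ms * fs / 1000)
  if (n %% 2 == 0) n <- n - 1L   # 302 -> 301
  as.integer(max(n, 3L))
}

#' @rdname savgol_smooth
#' @return `edge_samples` returns the number of edge-contaminated samples
#'   at each end of a smoothed series.
#' @export
edge_samples <- function(frame_ms, fs) (sg_frame_samples(frame_ms, fs) - 1L) %/% 2L

#' Multiband amplitude spectrogram
#'
#' Stacks [hilbert_bandpass_amplitude()] over log-spaced center frequencies
#' with proportional bandwidth (center +/- 10% by default). If a baseline
#' sample window is given, each row is expressed as percent change from its
#' own baseline mean (per-frequency normalization).
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate, Hz.
#' @param center_freqs band centers, Hz (default 24 log-spaced 2..200,
#'   clipped below Nyquist).
#' @param rel_bandwidth half-bandwidth as a fraction of center (default
#'   0.1).
#' @param baseline_samples optional integer index vector for baseline
#'   normalization.
#' @param halfwidth sigmoid flank half-width, Hz.
#' @return list with `amplitude` (freq x time matrix) and `center_freqs`.
#' @export
spectrogram <- function(x, fs, center_freqs = NULL, rel_bandwidth = 0.1,
                        baseline_samples = NULL, halfwidth = 1.5) {
  if (is.null(center_freqs))
    center_freqs <- exp(seq(log(2), log(200), length.out = 24))
  center_freqs <- center_freqs[center_freqs * (1 + rel_bandwidth) < fs / 2]
  amp <- matrix(0, length(center_freqs), length(x))
  for (i in seq_along(center_freqs)) {
    cf <- center_freqs[i]
    hw <- min(halfwidth, cf * rel_bandwidth / 3)  # keep flanks inside band
    amp[i, ] <- hilbert_bandpass_amplitude(
      x, fs, cf * (1 - rel_bandwidth), cf * (1 + rel_bandwidth), hw)
  }
  if (!is.null(baseline_samples)) {
    b <- rowMeans(amp[, baseline_samples, drop = FALSE])
    amp <- 100 * sweep(sweep(amp, 1, b), 1, b, "/")
  }
  list(amplitude = amp, center_freqs = center_freqs)
}

#' Zero-phase ERP band-pass filter (0.1-50 Hz)
#'
#' Zero-phase Butterworth band-pass realized as a cascade of a
#' second-order high-pass at `f_lo` and a fourth-order low-pass at `f_hi`,
#' each applied forward-backward; the cascade is numerically robust at the
#' very low 0.1 Hz corner, where a directly designed narrow band-pass is
#' ill-conditioned.
#'
#' @param x numeric vector or channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi corners, Hz (defaults 0.1 and 50).
#' @return filtered signal, same shape.
#' @export
erp_filter <- function(x, fs, f_lo = 0.1, f_hi = 50) {
  n <- if (is.null(dim(x))) length(x) else ncol(x)
  if (n < 10 * fs / f_lo * 0.1)   # need ~1 period of the high-pass corner
    stop("signal too short for the ", f_lo, " Hz corner")
  hp <- signal::butter(2, f_lo / (fs / 2), type = "high")
  lp <- signal::butter(4, f_hi / (fs / 2), type = "low")
  run <- function(v) signal::filtfilt(lp, signal::filtfilt(hp, v))
  if (is.null(dim(x))) run(x) else t(apply(x, 1, run))
}
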