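#' Common-average re-referencing
#'
#' Subtracts, at every sample, the mean over all included channels from each
#' included channel. Excluded channels are left untouched. After the
#' operation the per-sample mean across included channels is zero, and the
#' operation is idempotent.
#'
#' @param rec a `seeg_recording` with at least 2 included channels.
#' @return the re-referenced `seeg_recording` (`reference` set to
#'   "common-average").
#' @export
common_average_rereference <- function(rec) {
  inc <- which(rec$channels$include)
  if (length(inc) < 2)
    stop("common-average reference requires >= 2 included channels")
  avg <- colMeans(rec$data[inc, , drop = FALSE])
  rec$data[inc, ] <- sweep(rec$data[inc, , drop = FALSE], 2, avg)
  rec$reference <- "common-average"
  rec
}

#' Remove line noise with zero-phase Butterworth band-stops
#'
#' Applies a forward-backward (zero-phase) second-order Butterworth
#' band-stop around each harmonic of `base_hz`, per channel. Default stop
#' half-width is 2 Hz.
#'
#' @param rec a `seeg_recording`.
#' @param base_hz line frequency (60 in North America).
#' @param n_harmonics harmonics to remove, including the base.
#' @param stop_halfwidth half-width of each stop band, Hz.
#' @return the filtered `seeg_recording`.
#' @export
notch_line_noise <- function(rec, base_hz = 60, n_harmonics = 3,
                             stop_halfwidth = 2) {
  nyq <- rec$fs / 2
  if (base_hz - stop_halfwidth <= 0) stop("stop band overlaps DC")
  if (base_hz * n_harmonics + stop_halfwidth >= nyq)
    stop("stop band overlaps Nyquist; reduce n_harmonics")
  for (k in seq_len(n_harmonics)) {
    fk <- base_hz * k
    lo <- fk - stop_halfwidth
    hi <- fk + stop_halfwidth
    bf <- signal::butter(2, c(lo, hi) / nyq, type = "stop")
    for (ci in seq_len(nrow(rec$data)))
      rec$data[ci, ] <- signal::filtfilt(bf, rec$data[ci, ])
  }
  rec
}

# band power via periodogram, summed over [f_lo, f_hi]
band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  p <- Mod(X)^2 / n
  sum(p[half & f >= f_lo & f <= f_hi])
}

#' Flag channels with excessive line noise
#'
#' Computes each channel's power in a 4 Hz band around `base_hz`, then a
#' robust z-score (median/MAD across channels) of log power; channels above
#' the threshold are flagged for exclusion.
#'
#' @param rec a `seeg_recording`.
#' @param line_power_z_threshold robust-z threshold (> 0; default 5).
#' @param base_hz line frequency.
#' @return an `exclusion_report` list with `channels` (data.frame: label,
#'   statistic, reason) and `trials` (empty here).
#' @export
detect_bad_channels <- function(rec, line_power_z_threshold = 5,
                                base_hz = 60) {
  if (line_power_z_threshold <= 0) stop("threshold must be > 0")
  lp <- apply(rec$data, 1, band_power, fs = rec$fs,
              f_lo = base_hz - 2, f_hi = base_hz + 2)
  lp <- log(lp + .Machine$double.eps)
  z <- (lp - stats::median(lp)) / (stats::mad(lp) + .Machine$double.eps)
  bad <- which(z > line_power_z_threshold)
  structure(list(
    channels = data.frame(label = rec$channels$label[bad],
                          statistic = z[bad],
                          reason = rep("line-noise power", length(bad))),
    trials = data.frame(trial = integer(0), statistic = numeric(0),
                        reason = character(0)),
    threshold = line_power_z_threshold), class = "exclusion_report")
}

#' Reject artifact-contaminated trials
#'
#' For raw-voltage epochs, computes per channel a robust scale (median
#' absolute deviation over all trials and samples) and flags any trial
#' whose peak absolute amplitude on any channel exceeds
#' `amplitude_z_threshold` robust SDs, the automated surrogate for visual
#' inspection of inter-ictal spikes.
#'
#' @param epochs an `epoch_set` in microvolt units (see [epoch()]).
#' @param amplitude_z_threshold threshold in robust SDs (> 0; default 5).
#' @return an `exclusion_report` with the `trials` slot filled.
#' @export
reject_trials <- function(epochs, amplitude_z_threshold = 5) {
  if (amplitude_z_threshold <= 0) stop("threshold must be > 0")
  d <- epochs$data   # trials x channels x time
  nt <- dim(d)[1]; nc <- dim(d)[2]
  stat <- numeric(nt)
  scale_c <- numeric(nc)
  center_c <- numeric(nc)
  for (ci in seq_len(nc)) {
    v <- as.vector(d[, ci, ])
    center_c[ci] <- stats::median(v)
    scale_c[ci] <- stats::mad(v) + .Machine$double.eps
  }
  for (ti in seq_len(nt)) {
    z <- abs(sweep(sweep(matrix(d[ti, , ], nc), 1, center_c), 1, scale_c,
                   "/"))
    stat[ti] <- max(z)
  }
  bad <- which(stat > amplitude_z_threshold)
  structure(list(
    channels = data.frame(label = character(0), statistic = numeric(0),
                          reason = character(0)),
    trials = data.frame(trial = bad, statistic = stat[bad],
                        reason = rep("artifact amplitude", length(bad))),
    threshold = amplitude_z_threshold), class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("exclusion_report: %d channels, %d trials excluded (threshold %g)\n",
              nrow(x$channels), nrow(x$trials), x$threshold))
  invisible(x)
}

#' Apply an exclusion report to a recording
#' @param rec a `seeg_recording`.
#' @param report an `exclusion_report`.
#' @return the recording with `include` flags cleared for flagged channels.
#' @export
apply_exclusions <- function(rec, report) {
  rec$channels$include[rec$channels$label %in% report$channels$label] <- FALSE
  rec
}
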