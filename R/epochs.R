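#' Event-locked epoching
#'
#' Slices a continuous signal (raw voltage or envelope) into trials x
#' channels x time epochs, aligned to stimulus or speech onset with
#' nearest-sample precision. Windows are half-open in samples: a window of
#' L ms at sampling rate fs contains exactly `round(L*fs/1000)` samples.
#' Trials whose window falls outside the recording (or whose alignment
#' event is missing, e.g. speech onset in a listening task) are dropped and
#' reported in the `dropped` attribute.
#'
#' @param x channels x samples matrix, or a `seeg_recording` (its included
#'   channels are used).
#' @param events an `event_table`.
#' @param align "stimulus" or "speech".
#' @param window_ms length-2 window relative to the alignment event.
#' @param fs sampling rate, Hz (taken from the recording if given one).
#' @param units unit tag carried on the result ("uV" or "envelope").
#' @param channel_info optional channel metadata data.frame.
#' @return an `epoch_set`: list with `data` (trials x channels x time),
#'   `time_ms`, `align`, `units`, `fs`, `events` (retained trials),
#'   `channel_info`, `dropped`.
#' @export
epoch <- function(x, events, align = c("stimulus", "speech"),
                  window_ms = c(-2000, 2000), fs = NULL, units = "uV",
                  channel_info = NULL) {
  align <- match.arg(align)
  if (inherits(x, "seeg_recording")) {
    fs <- x$fs
    channel_info <- x$channels[x$channels$include, , drop = FALSE]
    x <- x$data[x$channels$include, , drop = FALSE]
  }
  if (is.null(fs)) stop("fs required when x is a plain matrix")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  anchor <- if (align == "speech") {
    if (!"speech_onset_ms" %in% names(events) ||
        all(is.na(events$speech_onset_ms)))
      stop("speech alignment requested but speech_onset_ms is absent; ",
           "align to the stimulus onset instead")
    events$speech_onset_ms
  } else events$stim_onset_ms
  ws <- window_samples(window_ms, fs)
  n_time <- ws[2] - ws[1]
  n <- ncol(x)
  keep <- logical(nrow(events))
  idx0 <- integer(nrow(events))
  for (tr in seq_len(nrow(events))) {
    if (is.na(anchor[tr])) next
    a <- round(anchor[tr] * fs / 1000) + 1L      # nearest sample, 1-based
    if (a + ws[1] >= 1 && a + ws[2] - 1 <= n) {
      keep[tr] <- TRUE
      idx0[tr] <- a + ws[1]
    }
  }
  kept <- which(keep)
  if (!length(kept)) stop("no trial window lies inside the recording")
  d <- array(0, dim = c(length(kept), nrow(x), n_time))
  for (j in seq_along(kept))
    d[j, , ] <- x[, idx0[kept[j]] + seq_len(n_time) - 1L, drop = FALSE]
  structure(list(
    data = d,
    time_ms = window_ms[1] + (seq_len(n_time) - 1) * 1000 / fs,
    align = align, units = units, fs = fs,
    events = events[kept, , drop = FALSE],
    channel_info = channel_info,
    dropped = setdiff(seq_len(nrow(events)), kept)),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "epoch_set: %d trials x %d channels x %d samples (%s-aligned, %s), %.0f..%.0f ms\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$align, x$units,
    min(x$time_ms), max(x$time_ms)))
  if (length(x$dropped))
    cat(sprintf("  dropped trials: %d\n", length(x$dropped)))
  invisible(x)
}

#' Baseline percent-change normalization
#'
#' Converts envelope epochs to percent change from baseline:
#' `100 * (x - B) / B`, where `B` is the mean envelope over the baseline
#' window, pooled across trials, per channel. The baseline window is
#' defined relative to the *stimulus* onset; when the epochs under analysis
#' are speech-aligned, pass the matching stimulus-aligned envelope epochs
#' as `baseline_epochs` so the baseline is taken pre-stimulus.
#'
#' @param epochs an `epoch_set` with `units == "envelope"`.
#' @param baseline_ms length-2 baseline window (ms; default -500..-100).
#' @param baseline_epochs optional stimulus-aligned `epoch_set` supplying
#'   the baseline (defaults to `epochs` itself).
#' @return the `epoch_set` in percent-change units, with a `baseline`
#'   vector attribute (per-channel B).
#' @export
percent_change <- function(epochs, baseline_ms = c(-500, -100),
                           baseline_epochs = NULL) {
  if (!identical(epochs$units, "envelope"))
    stop("percent_change expects envelope units, got: ", epochs$units)
  src <- if (is.null(baseline_epochs)) epochs else baseline_epochs
  bidx <- which(src$time_ms >= baseline_ms[1] & src$time_ms < baseline_ms[2])
  if (!length(bidx)) stop("baseline window lies outside the epoch")
  nc <- dim(epochs$data)[2]
  B <- vapply(seq_len(nc),
              function(ci) mean(src$data[, ci, bidx]), 0)
  if (any(B <= 0))
    stop("non-positive baseline envelope; data corrupted upstream")
  for (ci in seq_len(nc))
    epochs$data[, ci, ] <- 100 * (epochs$data[, ci, ] - B[ci]) / B[ci]
  epochs$units <- "percent-change"
  epochs$baseline <- B
  epochs$baseline_ms <- baseline_ms
  epochs
}

#' Hierarchical group time course
#'
#' Two-stage averaging that equalizes subjects: electrode traces are first
#' averaged within each subject, then the subject means are averaged. This
#' keeps densely sampled subjects from dominating the group trace. SE is
#' across subjects.
#'
#' @param traces electrodes x time matrix (e.g. per-electrode mean percent
#'   change).
#' @param subject_ids character/factor, one per electrode row.
#' @param time_ms optional time axis carried through.
#' @return a `group_timecourse`: list with `subject_means` (subjects x
#'   time), `mean`, `se`, `n_subjects`, `time_ms`.
#' @export
group_timecourse <- function(traces, subject_ids, time_ms = NULL) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  if (nrow(traces) != length(subject_ids))
    stop("one subject id per electrode row required")
  sid <- factor(subject_ids)
  sm <- vapply(levels(sid),
               function(s) colMeans(traces[sid == s, , drop = FALSE]),
               numeric(ncol(traces)))
  sm <- if (is.matrix(sm)) t(sm) else matrix(sm, ncol = 1)
  ns <- nlevels(sid)
  se <- if (ns >= 2) apply(sm, 2, stats::sd) / sqrt(ns)
        else rep(NA_real_, ncol(traces))
  structure(list(subject_means = sm, mean = colMeans(sm), se = se,
                 n_subjects = ns, time_ms = time_ms),
            class = "group_timecourse")
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure at level `q`: with ordered p-values `p(1) <= ... <=
#' p(m)`, find the largest k with `p(k) <= k*q/m`; all p-values up to
#' `p(k)` are significant.
#'
#' @param pvals p-values in \[0,1\].
#' @param q FDR level.
#' @return logical mask, same length (empty input gives empty mask).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Per-timepoint activation significance
#'
#' One-tailed (activation above zero) one-sample t-test across subject
#' means at each time point, corrected over timepoints with BH-FDR.
#' Zero-variance timepoints are assigned p = 0.5 when the mean is zero
#' (and 0 or 1 by sign otherwise) and flagged.
#'
#' @param group a `group_timecourse` with >= 3 subjects.
#' @param q FDR level (default 0.05).
#' @return list with `mask` (logical per timepoint), `p`, `t`,
#'   `degenerate` (flag vector).
#' @export
timepoint_significance <- function(group, q = 0.05) {
  sm <- group$subject_means
  ns <- nrow(sm)
  if (ns < 3) stop("per-timepoint t-tests require >= 3 subjects")
  m <- colMeans(sm)
  s <- apply(sm, 2, stats::sd)
  degen <- s < .Machine$double.eps
  tt <- ifelse(degen, 0, m / (s / sqrt(ns)))
  p <- stats::pt(tt, df = ns - 1, lower.tail = FALSE)
  p[degen] <- ifelse(abs(m[degen]) < .Machine$double.eps, 0.5,
                     ifelse(m[degen] > 0, 0, 1))
  list(mask = bh_fdr(p, q), p = p, t = tt, degenerate = degen)
}

#' Electrode window z-score against baseline
#'
#' Per trial, the mean over the analysis window and over the baseline
#' window are taken; the z-score is the difference of their across-trial
#' means divided by the across-trial SD of the baseline means. p-values are
#' two-tailed normal. With fewer than 5 trials the estimate is flagged
#' unstable; all-zero (degenerate) data return z = 0, non-significant, with
#' a warning.
#'
#' @param epochs an `epoch_set` (envelope or percent-change units).
#' @param window_ms analysis window, ms.
#' @param baseline_ms baseline window, ms.
#' @param baseline_epochs optional `epoch_set` supplying the baseline
#'   window samples (e.g. stimulus-aligned when `epochs` is
#'   speech-aligned).
#' @return data.frame, one row per channel: channel, z, p, n_trials,
#'   unstable.
#' @export
window_zscore <- function(epochs, window_ms, baseline_ms = c(-500, -100),
                          baseline_epochs = NULL) {
  src <- if (is.null(baseline_epochs)) epochs else baseline_epochs
  widx <- which(epochs$time_ms >= window_ms[1] &
                epochs$time_ms < window_ms[2])
  bidx <- which(src$time_ms >= baseline_ms[1] & src$time_ms < baseline_ms[2])
  if (!length(widx) || !length(bidx))
    stop("window and baseline must lie inside their epochs")
  nt <- dim(epochs$data)[1]; nc <- dim(epochs$data)[2]
  out <- data.frame(channel = seq_len(nc), z = NA_real_, p = NA_real_,
                    n_trials = nt, unstable = nt < 5)
  for (ci in seq_len(nc)) {
    wm <- apply(epochs$data[, ci, widx, drop = FALSE], 1, mean)
    bm <- apply(src$data[, ci, bidx, drop = FALSE], 1, mean)
    sb <- stats::sd(bm)
    if (!is.finite(sb) || sb < .Machine$double.eps) {
      if (all(abs(c(wm, bm)) < .Machine$double.eps)) {
        warning("all-zero data in window_zscore; returning z = 0")
        out$z[ci] <- 0; out$p[ci] <- 1
      } else {
        out$z[ci] <- sign(mean(wm) - mean(bm)) * Inf
        out$p[ci] <- 0
      }
    } else {
      out$z[ci] <- (mean(wm) - mean(bm)) / sb
      out$p[ci] <- 2 * stats::pnorm(-abs(out$z[ci]))
    }
  }
  if (!is.null(epochs$channel_info) &&
      nrow(epochs$channel_info) == nc)
    out$label <- epochs$channel_info$label
  out
}

#' Paired Wilcoxon signed-rank contrast
#'
#' Two-sided Wilcoxon signed-rank test on paired per-subject means. Zeros
#' are dropped (Wilcoxon's convention); the exact distribution is used for
#' up to 25 non-zero pairs, the normal approximation above. Tied magnitudes
#' at n <= 12 are handled by exact sign-flip enumeration on average ranks. If every pair
#' is tied the test is degenerate and p = 1 is returned with a warning.
#'
#' @param a,b paired numeric vectors (one value per subject).
#' @return list with `p`, `statistic`, `n_effective`.
#' @export
wilcoxon_contrast <- function(a, b = NULL) {
  if (is.null(b)) b <- rep(0, length(a))
  if (length(a) != length(b)) stop("unpaired lengths")
  d <- a - b
  d <- d[d != 0]
  nz <- length(d)
  if (nz == 0) {
    warning("all paired differences are zero; degenerate contrast, p = 1")
    return(list(p = 1, statistic = NA_real_, n_effective = 0L))
  }
  ties <- anyDuplicated(abs(d)) > 0
  if (ties && nz <= 12) {
    # tied magnitudes at small n: exact sign-flip enumeration on average
    # ranks (wilcox.test would fall back to the normal approximation)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    flips <- as.matrix(expand.grid(rep(list(c(0, 1)), nz)))
    W_null <- as.vector(flips %*% r)
    mu <- sum(r) / 2
    p <- min(1, mean(abs(W_null - mu) >= abs(W - mu) - 1e-9))
    return(list(p = p, statistic = W, n_effective = nz))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    d, exact = nz <= 25, correct = TRUE))
  list(p = unname(wt$p.value), statistic = unname(wt$statistic),
       n_effective = nz)
}

#' Group event-related potential
#'
#' Trial-averages ERP-filtered raw epochs per electrode, smooths each
#' average (Savitzky-Golay, third order, 151 ms), then applies the same
#' hierarchical subject averaging and per-timepoint significance machinery
#' as the gamma analysis.
#'
#' @param epochs an `epoch_set` of ERP-filtered raw voltage.
#' @param subject_ids one subject id per channel.
#' @param sg_frame_ms Savitzky-Golay frame, ms.
#' @param sg_order polynomial order.
#' @return a `group_timecourse`.
#' @export
compute_erp <- function(epochs, subject_ids, sg_frame_ms = 151,
                        sg_order = 3) {
  nc <- dim(epochs$data)[2]
  avg <- t(vapply(seq_len(nc),
                  function(ci) colMeans(epochs$data[, ci, , drop = FALSE][, 1, ]),
                  numeric(dim(epochs$data)[3])))
  sm <- savgol_smooth(avg, epochs$fs, order = sg_order,
                      frame_ms = sg_frame_ms)
  group_timecourse(sm, subject_ids, time_ms = epochs$time_ms)
}

#' Per-electrode mean time course from an epoch set
#' @param epochs an `epoch_set`.
#' @return channels x time matrix of trial means.
#' @export
electrode_means <- function(epochs) {
  nc <- dim(epochs$data)[2]
  t(vapply(seq_len(nc),
           function(ci) colMeans(epochs$data[, ci, , drop = FALSE][, 1, ]),
           numeric(dim(epochs$data)[3])))
}
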