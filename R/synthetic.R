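#' Ground-truth specification for synthetic sEEG
#'
#' Bundles the regional effect structure, background spectrum and behavioral
#' timing that [simulate_recording()] and [simulate_events()] realize.
#'
#' @param effects data.frame with one row per active region:
#'   `region` (integer parcellation label), `amplitude` (gamma envelope
#'   increase, % of baseline), `latency_ms` (effect onset relative to the
#'   alignment event), `duration_ms` (> 0), `jitter` (per-trial
#'   multiplicative amplitude jitter fraction in \[0,1)), `align`
#'   ("stimulus" or "speech").
#' @param one_over_f_exponent exponent of the 1/f background power spectrum
#'   (power ~ f^-exponent; default 1).
#' @param line_hz line-noise base frequency (default 60).
#' @param line_amp_uv line-noise amplitude in microvolts (default 5).
#' @param n_harmonics number of harmonics including the base (default 3);
#'   harmonic k has amplitude `line_amp_uv / k`.
#' @param baseline_gamma_scale multiplier on the resting 70-150 Hz
#'   component of the 1/f background (default 1 = the natural 1/f level).
#' @param background_uv RMS of the 1/f background, microvolts (default 20).
#' @param rt_mean_ms,rt_sd_ms behavioral response-time mean and SD (ms);
#'   defaults 978 and 221 (word reading).
#' @param spike_rate_per_min rate of inter-ictal-like biphasic spike
#'   artifacts injected per channel (default 0 = none).
#' @param spike_amp_uv spike peak amplitude (default 300).
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(effects = NULL,
                         one_over_f_exponent = 1,
                         line_hz = 60, line_amp_uv = 5, n_harmonics = 3,
                         baseline_gamma_scale = 1, background_uv = 20,
                         rt_mean_ms = 978, rt_sd_ms = 221,
                         spike_rate_per_min = 0, spike_amp_uv = 300) {
  if (is.null(effects))
    effects <- data.frame(region = integer(0), amplitude = numeric(0),
                          latency_ms = numeric(0), duration_ms = numeric(0),
                          jitter = numeric(0), align = character(0))
  req <- c("region", "amplitude", "latency_ms", "duration_ms", "jitter", "align")
  if (!all(req %in% names(effects)))
    stop("effects must have columns: ", paste(req, collapse = ", "))
  if (any(effects$amplitude < 0)) stop("effect amplitude must be >= 0")
  if (any(effects$duration_ms <= 0)) stop("effect duration must be > 0")
  if (any(effects$jitter < 0 | effects$jitter >= 1))
    stop("jitter fraction must lie in [0, 1)")
  if (!all(effects$align %in% c("stimulus", "speech")))
    stop("effect align must be 'stimulus' or 'speech'")
  structure(list(effects = effects,
                 one_over_f_exponent = one_over_f_exponent,
                 line_hz = line_hz, line_amp_uv = line_amp_uv,
                 n_harmonics = n_harmonics,
                 baseline_gamma_scale = baseline_gamma_scale,
                 background_uv = background_uv,
                 rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
                 spike_rate_per_min = spike_rate_per_min,
                 spike_amp_uv = spike_amp_uv),
            class = "ground_truth")
}

#' Place linear sEEG probes on a synthetic mesh
#'
#' Each probe is a straight line of equally spaced contacts entering the
#' surface at a random vertex and advancing inward along a jittered surface
#' normal, emulating stereotactic depth-electrode trajectories. Contacts are
#' labeled with the parcellation region of the nearest mesh vertex.
#'
#' @param mesh a `surface_mesh`.
#' @param n_patients,probes_per_patient,contacts_per_probe counts.
#' @param pitch_mm center-to-center contact spacing; clinical probes with
#'   2.0 mm contacts and 1.5-2.43 mm gaps give 3.5-4.43 mm (default 3.5).
#' @param seed RNG seed.
#' @param max_depth_mm maximum distance of a contact from the surface
#'   (probe truncated if it would exceed it; default 30).
#' @return an `electrode_table` data.frame: patient, probe, contact, x, y,
#'   z (mm), region, include.
#' @export
place_electrodes <- function(mesh, n_patients, probes_per_patient,
                             contacts_per_probe, pitch_mm = 3.5, seed = 1L,
                             max_depth_mm = 30) {
  if (pitch_mm <= 0) stop("pitch_mm must be > 0")
  if (contacts_per_probe < 2 || contacts_per_probe > 20)
    stop("contacts_per_probe out of plausible range (2..20)")
  depth_needed <- (contacts_per_probe - 1) * pitch_mm
  if (depth_needed > 2 * mesh$radius_mm)
    stop("mesh too small to host the requested probe length")
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  v <- mesh$vertices
  rows <- list()
  for (p in seq_len(n_patients)) {
    for (pr in seq_len(probes_per_patient)) {
      entry <- v[sample.int(nrow(v), 1L), ]
      inward <- -entry / sqrt(sum(entry^2))       # sphere normal points out
      jitter <- stats::rnorm(3, 0, 0.15)
      dir <- inward + jitter
      dir <- dir / sqrt(sum(dir^2))
      if (sum(dir * inward) < 0.5) dir <- inward  # keep trajectory inward
      k <- 0:(contacts_per_probe - 1)
      pos <- sweep(outer(k * pitch_mm, dir), 2, entry, "+")
      # keep contacts within max_depth_mm of the surface (radial depth)
      depth <- mesh$radius_mm - sqrt(rowSums(pos^2))
      keep <- depth <= max_depth_mm & depth >= -1
      pos <- pos[keep, , drop = FALSE]
      if (!nrow(pos)) next
      reg <- mesh$labels[nearest_node(pos, mesh)]
      rows[[length(rows) + 1L]] <- data.frame(
        patient = sprintf("P%02d", p), probe = sprintf("pr%02d", pr),
        contact = which(keep),
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        region = reg, include = TRUE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$label <- paste(tab$patient, tab$probe, tab$contact, sep = "-")
  class(tab) <- c("electrode_table", "data.frame")
  tab
}

#' Simulate a behavioral event table
#'
#' Stimulus onsets at a fixed inter-trial interval; speech onsets at
#' stimulus onset plus a truncated-normal response time (floor 200 ms).
#' Listening tasks have no speech onset (`speech_onset_ms = NA`): epochs
#' must be aligned to the stimulus. A configurable fraction of trials is
#' flagged as incorrect or non-modal responses to exercise trial filtering.
#'
#' @param task task name ("reading", "naming", "listening", ...).
#' @param n_trials number of trials (>= 1).
#' @param rt_mean,rt_sd response time mean and SD, ms (reading: 978/221;
#'   naming: 1192/245).
#' @param iti inter-stimulus interval, ms (default 3000).
#' @param seed RNG seed.
#' @param start_ms time of first stimulus onset (default 5000, leaving a
#'   pre-stimulus margin for baselines).
#' @param p_error fraction of trials flagged not-correct/non-modal
#'   (default 0).
#' @param rt_floor_ms truncation floor for RT draws (default 200).
#' @return an `event_table` data.frame: trial, task, condition,
#'   stim_onset_ms, speech_onset_ms, rt_ms, correct, modal_response.
#' @export
simulate_events <- function(task, n_trials, rt_mean = 978, rt_sd = 221,
                            iti = 3000, seed = 1L, start_ms = 5000,
                            p_error = 0, rt_floor_ms = 200) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (rt_mean <= 0) stop("rt_mean must be > 0")
  if (rt_sd < 0) stop("rt_sd must be >= 0")
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  stim <- start_ms + (seq_len(n_trials) - 1) * iti
  if (identical(task, "listening")) {
    rt <- rep(NA_real_, n_trials)
  } else {
    rt <- stats::rnorm(n_trials, rt_mean, rt_sd)
    while (any(bad <- rt < rt_floor_ms))     # redraw below the floor
      rt[bad] <- stats::rnorm(sum(bad), rt_mean, rt_sd)
  }
  err <- stats::runif(n_trials) < p_error
  ev <- data.frame(trial = seq_len(n_trials), task = task,
                   condition = task,
                   stim_onset_ms = stim,
                   speech_onset_ms = stim + rt,
                   rt_ms = rt,
                   correct = !err, modal_response = !err)
  class(ev) <- c("event_table", "data.frame")
  ev
}

# raised-cosine ramp (ramp_ms) to plateau effect gain profile, per trial
effect_profile <- function(t_ms, onset_ms, duration_ms, ramp_ms = 50) {
  g <- numeric(length(t_ms))
  rel <- t_ms - onset_ms
  up <- rel >= 0 & rel < ramp_ms
  g[up] <- 0.5 * (1 - cos(pi * rel[up] / ramp_ms))
  plateau <- rel >= ramp_ms & rel < duration_ms - ramp_ms
  g[plateau] <- 1
  down <- rel >= duration_ms - ramp_ms & rel < duration_ms
  g[down] <- 0.5 * (1 - cos(pi * (duration_ms - rel[down]) / ramp_ms))
  g
}

# 1/f^(exponent/2) amplitude-shaped Gaussian noise, unit RMS
one_over_f_noise <- function(n, fs, exponent) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]      # fold to physical frequency
  shape <- c(0, f[-1]^(-exponent / 2))     # kill DC
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

# smallest integer >= n with no prime factor beyond 5
next_fast_len <- function(n) {
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# split a signal into its 70-150 Hz component and the remainder by FFT
# masking with soft (logistic) band edges; the two parts sum exactly to
# the input, so the resting spectrum is untouched by the decomposition
fft_band_split <- function(x, fs, f_lo = 70, f_hi = 150, hw = 1.5) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f_phys <- ifelse(f > fs / 2, fs - f, f)
  w <- stats::plogis((f_phys - f_lo) / hw) * stats::plogis((f_hi - f_phys) / hw)
  inb <- Re(stats::fft(stats::fft(x) * w, inverse = TRUE)) / n
  list(inband = inb, outband = x - inb)
}

#' Simulate a raw multichannel sEEG recording
#'
#' Each channel is 1/f-shaped Gaussian background plus line noise with
#' harmonics. The 70-150 Hz component of the background — a broadband
#' noise carrier with random phase across trials — is multiplied, on each
#' trial, by `1 + A/100` (raised-cosine onset and offset ramps) in the
#' region's effect window; the remainder of the spectrum is untouched, so
#' a resting channel has an exactly 1/f spectrum. Channels in regions with
#' no specified effect carry a flat gamma envelope. Because the effect is
#' multiplicative on the band component, the injected amplitude `A` is the
#' expected baseline-normalized percent change of the gamma envelope,
#' which calibrates the downstream analysis.
#'
#' @param electrodes an `electrode_table` from [place_electrodes()].
#' @param events an `event_table` from [simulate_events()].
#' @param truth a [ground_truth()] object.
#' @param fs sampling rate, Hz (>= 500 to resolve 150 Hz; 2000 in clinical
#'   practice).
#' @param seed RNG seed.
#' @param margin_ms extra recording time after the last event (default
#'   4000).
#' @return a `seeg_recording` (see [seeg_recording()]).
#' @export
simulate_recording <- function(electrodes, events, truth, fs = 2000,
                               seed = 1L, margin_ms = 4000) {
  if (fs < 500) stop("fs must be >= 500 Hz to resolve the 150 Hz band edge")
  t_end <- max(events$stim_onset_ms,
               events$speech_onset_ms, na.rm = TRUE) + margin_ms
  # pad to a 5-smooth length: FFTs of the recording (and of envelopes
  # derived from it) stay O(n log n) instead of hitting large prime sizes
  n <- next_fast_len(ceiling(t_end * fs / 1000))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  nch <- nrow(electrodes)
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  line <- numeric(n)
  for (k in seq_len(truth$n_harmonics)) {
    fk <- truth$line_hz * k
    if (fk < fs / 2)
      line <- line + (truth$line_amp_uv / k) * sin(2 * pi * fk * t_ms / 1000)
  }
  data <- matrix(0, nch, n)
  for (ci in seq_len(nch)) {
    bg <- truth$background_uv *
      one_over_f_noise(n, fs, truth$one_over_f_exponent)
    parts <- fft_band_split(bg, fs)
    gain <- rep(1, n)
    eff <- truth$effects[truth$effects$region == electrodes$region[ci], ,
                         drop = FALSE]
    for (ei in seq_len(nrow(eff))) {
      anchor <- if (eff$align[ei] == "speech") events$speech_onset_ms
                else events$stim_onset_ms
      for (tr in seq_len(nrow(events))) {
        if (is.na(anchor[tr])) next
        a_tr <- eff$amplitude[ei] *
          (1 + eff$jitter[ei] * stats::runif(1, -1, 1))
        onset <- anchor[tr] + eff$latency_ms[ei]
        idx <- which(t_ms >= onset - 1 & t_ms < onset + eff$duration_ms[ei] + 1)
        if (!length(idx)) next
        gain[idx] <- gain[idx] + (a_tr / 100) *
          effect_profile(t_ms[idx], onset, eff$duration_ms[ei])
      }
    }
    x <- parts$outband + truth$baseline_gamma_scale * parts$inband * gain +
      line
    if (truth$spike_rate_per_min > 0) {
      n_spikes <- stats::rpois(1, truth$spike_rate_per_min * t_end / 60000)
      if (n_spikes > 0) {
        at <- sort(stats::runif(n_spikes, 0.05, 0.95)) * n
        x <- x + inject_spikes(n, fs, round(at), truth$spike_amp_uv)
      }
    }
    data[ci, ] <- x
  }
  seeg_recording(data, fs, channels = electrodes, reference = "original")
}

# biphasic inter-ictal-like transient: derivative-of-Gaussian, ~60 ms wide
inject_spikes <- function(n, fs, centers, amp) {
  w <- round(0.03 * fs)
  tt <- seq(-3, 3, length.out = 2 * w + 1)
  shape <- -tt * exp(-tt^2 / 2)
  shape <- amp * shape / max(abs(shape))
  out <- numeric(n)
  for (c0 in centers) {
    idx <- (c0 - w):(c0 + w)
    ok <- idx >= 1 & idx <= n
    out[idx[ok]] <- out[idx[ok]] + shape[ok]
  }
  out
}
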