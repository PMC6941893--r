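#' Simulate a two-task speech study with a known regional dissociation
#'
#' Builds a multi-subject synthetic study emulating the qualitative
#' regional dissociation reported for speech production: a
#' "posterior-insula-like" region (`pi`) responds more strongly during
#' speech production than listening, a "superior-temporal-like" region
#' (`stg`) responds more strongly during listening, and a
#' "frontal-opercular-like" region (`fo`) is active only before
#' articulation. Each subject receives two contacts near the centroid of
#' each region; a reading task (speech-aligned effects) and a listening
#' task (stimulus-aligned effects, no speech onset) are simulated per
#' subject, then run through the standard envelope pipeline
#' (notch, Hilbert band amplitude, Savitzky-Golay, epoching,
#' baseline percent change).
#'
#' Effect amplitudes (reading: pi 50%, stg 20%, fo 40% pre-articulatory;
#' listening: stg 60%, pi 5%) are qualitative stand-ins at roughly the
#' magnitudes seen in intracranial gamma responses.
#'
#' @param mesh a `surface_mesh` with at least 3 regions.
#' @param n_subjects subjects (default 6; paired tests need >= 6 for a
#'   two-sided exact p below 0.05).
#' @param n_trials trials per task (default 15).
#' @param fs sampling rate (default 500 Hz).
#' @param seed RNG seed.
#' @return list with speech-aligned and stimulus-aligned percent-change
#'   epochs per task (`reading_speech`, `reading_stim`, `listening_stim`),
#'   the `electrodes` table, and `regions` (labels for pi, stg, fo).
#' @export
simulate_speech_study <- function(mesh, n_subjects = 6, n_trials = 15,
                                  fs = 500, seed = 1L) {
  if (length(unique(mesh$labels)) < 3)
    stop("need a mesh with at least 3 regions")
  regions <- list(pi = 1L, stg = 2L, fo = 3L)
  el <- region_electrodes(mesh, unlist(regions), n_subjects, seed)
  truth_read <- ground_truth(effects = data.frame(
    region = c(regions$pi, regions$stg, regions$fo),
    amplitude = c(50, 20, 40),
    latency_ms = c(0, 0, -450),
    duration_ms = c(400, 400, 400),
    jitter = 0.1,
    align = "speech"))
  truth_listen <- ground_truth(effects = data.frame(
    region = c(regions$stg, regions$pi),
    amplitude = c(60, 5),
    latency_ms = c(100, 100),
    duration_ms = c(500, 500),
    jitter = 0.1,
    align = "stimulus"))
  ev_read <- simulate_events("reading", n_trials, iti = 3000,
                             seed = seed + 1L)
  ev_listen <- simulate_events("listening", n_trials, iti = 3000,
                               seed = seed + 2L)
  rec_read <- notch_line_noise(
    simulate_recording(el, ev_read, truth_read, fs = fs, seed = seed + 3L))
  rec_listen <- notch_line_noise(
    simulate_recording(el, ev_listen, truth_listen, fs = fs,
                       seed = seed + 4L))
  env_pipeline <- function(rec, events, align) {
    env <- savgol_smooth(hilbert_bandpass_amplitude(rec$data, fs), fs)
    stim <- epoch(env, events, "stimulus", c(-800, 1500), fs = fs,
                  units = "envelope", channel_info = rec$channels)
    stim_pc <- attach_vertices(percent_change(stim, c(-500, -100)), mesh)
    if (align == "stimulus") return(list(stim = stim_pc, speech = NULL))
    sp <- epoch(env, events, "speech", c(-800, 1200), fs = fs,
                units = "envelope", channel_info = rec$channels)
    # baseline stays pre-stimulus even for speech-aligned responses
    sp_pc <- attach_vertices(
      percent_change(sp, c(-500, -100), baseline_epochs = stim), mesh)
    list(stim = stim_pc, speech = sp_pc)
  }
  read_ep <- env_pipeline(rec_read, ev_read, "speech")
  listen_ep <- env_pipeline(rec_listen, ev_listen, "stimulus")
  list(reading_speech = read_ep$speech, reading_stim = read_ep$stim,
       listening_stim = listen_ep$stim, electrodes = el, regions = regions,
       mesh = mesh, fs = fs)
}

# two contacts per subject near each requested region centroid, with a
# small seeded tangential scatter so subjects differ
region_electrodes <- function(mesh, region_labels, n_subjects, seed) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  rows <- list()
  for (reg in region_labels) {
    members <- which(mesh$labels == reg)
    cen <- members[which.min(colSums(
      as.matrix(stats::dist(mesh$vertices[members, ]))))]
    for (p in seq_len(n_subjects)) {
      for (k in 1:2) {
        pos <- mesh$vertices[cen, ] + stats::rnorm(3, 0, 1.5)
        rows[[length(rows) + 1L]] <- data.frame(
          patient = sprintf("P%02d", p), probe = sprintf("r%02d", reg),
          contact = k, x = pos[1], y = pos[2], z = pos[3],
          region = reg, include = TRUE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$label <- paste(tab$patient, tab$probe, tab$contact, sep = "-")
  class(tab) <- c("electrode_table", "data.frame")
  tab
}

# per-subject mean percent change over a window for channels of one region
subject_region_means <- function(epochs, region, window_ms) {
  info <- epochs$channel_info
  cis <- which(info$region == region)
  widx <- which(epochs$time_ms >= window_ms[1] &
                epochs$time_ms < window_ms[2])
  vals <- vapply(cis, function(ci) mean(epochs$data[, ci, widx]), 0)
  tapply(vals, info$patient[cis], mean)
}

#' Task-contrast outcomes of a simulated speech study
#'
#' Computes the three qualitative signatures on a study from
#' [simulate_speech_study()]: (1) production-vs-listening paired contrast
#' in the `pi` region, (2) the reverse contrast in `stg` (both over the
#' 200-600 ms post-onset window), (3) pre-articulatory activation
#' (-500..-100 ms before speech onset) present in `fo` but not in `pi` or
#' `stg`, plus MEMA maps for the reading post-articulatory window and the
#' listening post-stimulus window.
#'
#' @param study result of [simulate_speech_study()].
#' @param cfg an [analysis_config()].
#' @param extent optional precomputed [cluster_extent_threshold()] result
#'   shared across studies on the same mesh.
#' @param dist_matrix optional precomputed geodesic distances.
#' @return list with per-region contrasts (difference of per-subject
#'   means, Wilcoxon p), pre-articulatory group means, and the two map
#'   significant-vertex sets.
#' @export
dissociation_outcomes <- function(study, cfg = analysis_config(),
                                  extent = NULL, dist_matrix = NULL) {
  post <- cfg$window_post_ms
  pre <- cfg$window_pre_ms
  regions <- study$regions
  pi_prod <- subject_region_means(study$reading_speech, regions$pi, post)
  pi_lis <- subject_region_means(study$listening_stim, regions$pi, post)
  stg_prod <- subject_region_means(study$reading_speech, regions$stg, post)
  stg_lis <- subject_region_means(study$listening_stim, regions$stg, post)
  pre_means <- lapply(regions, function(r)
    mean(subject_region_means(study$reading_speech, r, pre)))
  if (is.null(dist_matrix)) dist_matrix <- geodesic_distances(study$mesh)
  map_read <- mema_window_analysis(study$reading_speech, study$mesh, post,
                                   cfg, "static", extent = extent,
                                   dist_matrix = dist_matrix)
  map_listen <- mema_window_analysis(study$listening_stim, study$mesh, post,
                                     cfg, "static", extent = extent,
                                     dist_matrix = dist_matrix)
  list(
    pi_diff = mean(pi_prod - pi_lis),
    pi_p = wilcoxon_contrast(pi_prod, pi_lis)$p,
    stg_diff = mean(stg_prod - stg_lis),
    stg_p = wilcoxon_contrast(stg_prod, stg_lis)$p,
    pre_means = pre_means,
    sig_read = attr(map_read, "significant_vertices"),
    sig_listen = attr(map_listen, "significant_vertices"))
}

#' Did a study reproduce the three dissociation signatures?
#'
#' TRUE when production > listening in `pi`, listening > production in
#' `stg`, pre-articulatory activation above 10% only in `fo`, the reading
#' map recovers `pi` activity, and the listening map recovers `stg`
#' without `pi` (whose listening response sits below the 10% floor).
#'
#' @param out result of [dissociation_outcomes()].
#' @param study the study the outcomes came from.
#' @return logical scalar.
#' @export
dissociation_reproduced <- function(out, study) {
  labs <- study$mesh$labels
  out$pi_diff > 0 &&
    out$stg_diff < 0 &&
    out$pre_means$fo > 10 &&
    out$pre_means$pi < 10 &&
    out$pre_means$stg < 10 &&
    any(labs[out$sig_read] == study$regions$pi) &&
    any(labs[out$sig_listen] == study$regions$stg) &&
    !any(labs[out$sig_listen] == study$regions$pi)
}
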