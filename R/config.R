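#' Analysis configuration
#'
#' Central container for the pipeline's numeric constants. Defaults are the
#' standard broadband-gamma analysis settings: 70-150 Hz band with 1.5 Hz
#' sigmoid flanks, third-order Savitzky-Golay smoothing over 151 ms,
#' baseline -500..-100 ms before stimulus onset, per-timepoint FDR q = 0.05,
#' surface maps at corrected alpha 0.01 with 5000 Monte-Carlo iterations,
#' 3 mm FWHM geodesic smoothing, at least 3 patients coverage and a 10%
#' absolute effect floor (15% in movie mode, 150 ms windows at 10 ms step).
#'
#' @param band_lo,band_hi band edges, Hz.
#' @param flank_hw sigmoid flank half-width, Hz.
#' @param sg_order,sg_frame_ms Savitzky-Golay order and frame length (ms;
#'   converted to the nearest odd sample count).
#' @param baseline_ms length-2 baseline window (ms relative to stimulus).
#' @param window_pre_ms,window_post_ms analysis windows (ms relative to
#'   speech onset).
#' @param fdr_q per-timepoint / per-electrode FDR level.
#' @param mema_alpha corrected alpha for surface maps.
#' @param mema_iters Monte-Carlo iterations for the cluster-extent null.
#' @param fwhm_mm geodesic Gaussian smoothing FWHM, mm.
#' @param min_patients coverage mask floor.
#' @param assignment_radius_mm geodesic radius within which electrodes
#'   contribute to a vertex's estimate.
#' @param coverage_radius_mm geodesic recording-zone radius for the
#'   patient coverage count.
#' @param effect_floor,movie_effect_floor absolute group-effect floors (%).
#' @param movie_width_ms,movie_step_ms sliding-window movie geometry.
#' @param notch_hz,notch_harmonics,notch_halfwidth_hz line-noise band-stop
#'   settings.
#' @param seed default RNG seed for stochastic stages.
#' @return a validated `analysis_config` list.
#' @export
analysis_config <- function(band_lo = 70, band_hi = 150, flank_hw = 1.5,
                            sg_order = 3, sg_frame_ms = 151,
                            baseline_ms = c(-500, -100),
                            window_pre_ms = c(-500, -100),
                            window_post_ms = c(200, 600),
                            fdr_q = 0.05,
                            mema_alpha = 0.01, mema_iters = 5000,
                            fwhm_mm = 3, min_patients = 3,
                            assignment_radius_mm = 10,
                            coverage_radius_mm = 10,
                            effect_floor = 10, movie_effect_floor = 15,
                            movie_width_ms = 150, movie_step_ms = 10,
                            notch_hz = 60, notch_harmonics = 3,
                            notch_halfwidth_hz = 2,
                            seed = 1L) {
  cfg <- list(band_lo = band_lo, band_hi = band_hi, flank_hw = flank_hw,
              sg_order = sg_order, sg_frame_ms = sg_frame_ms,
              baseline_ms = baseline_ms,
              window_pre_ms = window_pre_ms,
              window_post_ms = window_post_ms,
              fdr_q = fdr_q, mema_alpha = mema_alpha,
              mema_iters = mema_iters, fwhm_mm = fwhm_mm,
              min_patients = min_patients,
              assignment_radius_mm = assignment_radius_mm,
              coverage_radius_mm = coverage_radius_mm,
              effect_floor = effect_floor,
              movie_effect_floor = movie_effect_floor,
              movie_width_ms = movie_width_ms,
              movie_step_ms = movie_step_ms,
              notch_hz = notch_hz, notch_harmonics = notch_harmonics,
              notch_halfwidth_hz = notch_halfwidth_hz, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$band_lo > 0, cfg$band_hi > cfg$band_lo, cfg$flank_hw > 0,
            cfg$sg_order >= 1, cfg$sg_frame_ms > 0,
            length(cfg$baseline_ms) == 2,
            cfg$baseline_ms[1] < cfg$baseline_ms[2],
            cfg$window_pre_ms[1] < cfg$window_pre_ms[2],
            cfg$window_post_ms[1] < cfg$window_post_ms[2],
            cfg$fdr_q > 0, cfg$fdr_q < 1,
            cfg$mema_alpha > 0, cfg$mema_alpha < 1,
            cfg$mema_iters >= 100, cfg$fwhm_mm > 0,
            cfg$min_patients >= 1, cfg$assignment_radius_mm > 0,
            cfg$coverage_radius_mm > 0,
            cfg$movie_width_ms > 0, cfg$movie_step_ms > 0)
  invisible(TRUE)
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the package defaults.
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

# ms pair -> half-open sample index window relative to an anchor sample.
# A window of L ms at fs contains exactly round(L*fs/1000) samples.
window_samples <- function(window_ms, fs) {
  i0 <- round(window_ms[1] * fs / 1000)
  n <- round((window_ms[2] - window_ms[1]) * fs / 1000)
  c(i0, i0 + n)   # half-open [i0, i1)
}
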