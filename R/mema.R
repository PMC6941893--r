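#' Nearest mesh vertex for electrode coordinates
#'
#' Assigns each coordinate to the Euclidean-closest mesh vertex; ties break
#' to the lowest vertex index.
#'
#' @param coords length-3 vector or n x 3 matrix of mm coordinates.
#' @param mesh a `surface_mesh`.
#' @return integer vertex indices (1-based).
#' @export
nearest_node <- function(coords, mesh) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  v <- mesh$vertices
  if (!nrow(v)) stop("empty mesh")
  vapply(seq_len(nrow(coords)), function(i) {
    d2 <- (v[, 1] - coords[i, 1])^2 + (v[, 2] - coords[i, 2])^2 +
      (v[, 3] - coords[i, 3])^2
    which.min(d2)          # which.min returns the first (lowest) index
  }, 0L)
}

#' Geodesic Gaussian smoothing on a mesh
#'
#' Smooths a per-vertex field with Gaussian weights
#' `exp(-d^2 / (2 sigma^2))`, `sigma = fwhm / 2.355`, where `d` is the
#' geodesic (shortest-path) distance along mesh edges. Weights are
#' normalized to unit sum per target vertex, so constant fields are fixed
#' points. `NA` entries are treated as unobserved: they get smoothed
#' estimates from their observed neighbors and contribute no weight.
#' Disconnected components smooth independently (infinite distances get
#' zero weight).
#'
#' @param values numeric per-vertex field (may contain NA).
#' @param mesh a `surface_mesh`.
#' @param fwhm_mm full-width at half-maximum, mm.
#' @param dist_matrix optional precomputed geodesic distance matrix
#'   (n x n), to amortize Dijkstra across calls.
#' @param cutoff_sigmas truncate the kernel beyond this many sigmas
#'   (default 4).
#' @return smoothed field, same length.
#' @export
geodesic_gaussian_smooth <- function(values, mesh, fwhm_mm = 3,
                                     dist_matrix = NULL,
                                     cutoff_sigmas = 4) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be > 0")
  if (is.null(dist_matrix)) dist_matrix <- geodesic_distances(mesh)
  sigma <- fwhm_mm / 2.355
  W <- exp(-dist_matrix^2 / (2 * sigma^2))
  W[dist_matrix > cutoff_sigmas * sigma] <- 0
  obs <- !is.na(values)
  W[, !obs] <- 0
  rs <- rowSums(W)
  out <- as.vector(W[, obs, drop = FALSE] %*% values[obs]) / rs
  out[rs == 0] <- NA_real_
  out
}

#' Smoothing operator matrix
#'
#' The row-normalized geodesic Gaussian kernel as an explicit matrix, for
#' repeated application to many fields (Monte-Carlo null simulation).
#' @inheritParams geodesic_gaussian_smooth
#' @return n x n matrix with unit row sums.
#' @export
smoothing_matrix <- function(mesh, fwhm_mm = 3, dist_matrix = NULL,
                             cutoff_sigmas = 4) {
  if (is.null(dist_matrix)) dist_matrix <- geodesic_distances(mesh)
  sigma <- fwhm_mm / 2.355
  W <- exp(-dist_matrix^2 / (2 * sigma^2))
  W[dist_matrix > cutoff_sigmas * sigma] <- 0
  W / rowSums(W)
}

# REML estimate of the between-subject variance tau^2 for a random-effects
# meta-analysis; DerSimonian-Laird fallback on non-convergence.
reml_tau2 <- function(y, v, tol = 1e-10, max_iter = 200) {
  n <- length(y)
  tau2 <- max(stats::var(y) - mean(v), 0) + 1e-12   # moment start
  for (i in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    new <- (sum(w^2 * ((y - mu)^2 - v)) + sum(w^2) / sum(w)) / sum(w^2)
    new <- max(new, 0)
    if (abs(new - tau2) < tol * (1 + tau2)) return(new)
    tau2 <- new
  }
  # DerSimonian-Laird fallback
  vf <- pmax(v, 1e-12)
  wf <- 1 / vf
  muf <- sum(wf * y) / sum(wf)
  Q <- sum(wf * (y - muf)^2)
  max(0, (Q - (n - 1)) / (sum(wf) - sum(wf^2) / sum(wf)))
}

#' Surface-based mixed-effects multilevel fit
#'
#' Per-vertex two-level random-effects model combining within-subject
#' effect estimates and variances across subjects: the group effect is the
#' inverse-variance-weighted mean with weights `1/(v_i + tau^2)`, the
#' between-subject variance `tau^2` estimated by REML (DerSimonian-Laird on
#' non-convergence); `t = effect / SE` with `n - 1` degrees of freedom.
#' When all within-subject variances are zero the fit reduces exactly to
#' the one-sample t-test on the subject estimates. Vertices with a single
#' subject carry that estimate with the test flagged undefined.
#'
#' @param estimates data.frame with columns `subject`, `vertex`, `effect`
#'   (BGA % change), `var` (within-subject variance of the estimate, >= 0).
#' @param n_vertices total vertices in the map (for the output frame).
#' @return a `mema_map`: data.frame, one row per contributing vertex:
#'   vertex, effect, se, tau2, t, df, p, n_subjects; class carries
#'   print/summary/coef methods. Attribute `n_vertices` records the map
#'   size.
#' @export
mema_fit <- function(estimates, n_vertices = max(estimates$vertex)) {
  req <- c("subject", "vertex", "effect", "var")
  if (!all(req %in% names(estimates)))
    stop("estimates needs columns: ", paste(req, collapse = ", "))
  if (any(estimates$var < 0)) stop("variances must be >= 0")
  rows <- lapply(split(estimates, estimates$vertex), function(d) {
    y <- d$effect; v <- d$var; n <- nrow(d)
    if (n == 1L)
      return(data.frame(vertex = d$vertex[1], effect = y, se = NA_real_,
                        tau2 = NA_real_, t = NA_real_, df = 0L,
                        p = NA_real_, n_subjects = 1L))
    tau2 <- reml_tau2(y, v)
    w <- 1 / (v + tau2)
    if (!all(is.finite(w))) {        # all variances zero and tau2 zero
      w <- rep(1, n)
      tau2 <- 0
    }
    mu <- sum(w * y) / sum(w)
    se <- sqrt(1 / sum(w))
    tt <- if (se > 0) mu / se else 0
    data.frame(vertex = d$vertex[1], effect = mu, se = se, tau2 = tau2,
               t = tt, df = n - 1L,
               p = 2 * stats::pt(-abs(tt), df = n - 1), n_subjects = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("mema_map", "data.frame"),
            n_vertices = n_vertices)
}

#' @export
print.mema_map <- function(x, ...) {
  cat(sprintf("mema_map: %d of %d vertices with estimates; %d testable (>= 2 subjects)\n",
              nrow(x), attr(x, "n_vertices"), sum(x$n_subjects >= 2)))
  if ("significant" %in% names(x))
    cat(sprintf("  significant vertices: %d\n", sum(x$significant)))
  NextMethod()
}

#' @export
summary.mema_map <- function(object, ...) {
  cat("Surface-based mixed-effects map\n")
  cat(sprintf("  vertices with estimates : %d / %d\n", nrow(object),
              attr(object, "n_vertices")))
  cat(sprintf("  group effect (%%)       : median %.2f, range [%.2f, %.2f]\n",
              stats::median(object$effect), min(object$effect),
              max(object$effect)))
  ok <- object$n_subjects >= 2
  if (any(ok))
    cat(sprintf("  tau^2 (between-subject) : median %.3f\n",
                stats::median(object$tau2[ok])))
  if ("significant" %in% names(object))
    cat(sprintf("  significant vertices    : %d\n",
                sum(object$significant)))
  invisible(object)
}

#' @export
coef.mema_map <- function(object, ...) {
  stats::setNames(object$effect, object$vertex)
}

#' Label connected supra-threshold clusters
#'
#' Edge-connected components of the vertex set where `mask` is TRUE.
#' @param mask logical per-vertex vector.
#' @param mesh a `surface_mesh`.
#' @return integer vector: 0 outside the mask, cluster id (1..k) inside.
#' @export
label_clusters <- function(mask, mesh) {
  out <- integer(length(mask))
  idx <- which(mask)
  if (!length(idx)) return(out)
  g <- mesh_graph(mesh)
  sub <- igraph::induced_subgraph(g, idx)
  comp <- igraph::components(sub)
  out[idx] <- comp$membership
  out
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates white noise on the mesh vertices, smooths it with the same
#' geodesic Gaussian kernel as the data, standardizes the smoothed map,
#' thresholds at the vertex-level alpha (two-sided), and records the
#' largest edge-connected supra-threshold cluster. The returned minimum
#' cluster extent is the `(1 - fwer_alpha)` quantile of that null maximum,
#' so requiring observed clusters to reach it controls the family-wise
#' error rate at `fwer_alpha` for smoothness-matched noise.
#'
#' @param mesh a `surface_mesh`.
#' @param fwhm_mm smoothing FWHM, mm.
#' @param vertex_alpha vertex-level threshold (default 0.01).
#' @param fwer_alpha family-wise level (default 0.01).
#' @param n_iter Monte-Carlo iterations (5000 default; >= 100 enforced).
#' @param seed RNG seed.
#' @param dist_matrix optional precomputed geodesic distances.
#' @return list with `threshold` (minimum cluster size, vertices),
#'   `null_max_sizes`, and the settings.
#' @export
cluster_extent_threshold <- function(mesh, fwhm_mm = 3, vertex_alpha = 0.01,
                                     fwer_alpha = 0.01, n_iter = 5000,
                                     seed = 1L, dist_matrix = NULL) {
  if (n_iter < 100) stop("n_iter must be >= 100")
  nv <- nrow(mesh$vertices)
  if (nv < 4) stop("degenerate mesh")
  S <- smoothing_matrix(mesh, fwhm_mm, dist_matrix)
  g <- mesh_graph(mesh)
  zc <- stats::qnorm(1 - vertex_alpha / 2)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  max_sizes <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    z <- as.vector(S %*% stats::rnorm(nv))
    z <- (z - mean(z)) / stats::sd(z)
    idx <- which(abs(z) > zc)
    if (!length(idx)) next
    sub <- igraph::induced_subgraph(g, idx)
    max_sizes[it] <- max(igraph::components(sub)$csize)
  }
  thr <- as.integer(stats::quantile(max_sizes, 1 - fwer_alpha, type = 1)) + 1L
  list(threshold = thr, null_max_sizes = max_sizes,
       vertex_alpha = vertex_alpha, fwer_alpha = fwer_alpha,
       fwhm_mm = fwhm_mm, n_iter = n_iter)
}

#' Patient coverage mask
#'
#' A patient contributes coverage at a vertex if any of their electrodes,
#' mapped to its nearest node, lies within `radius_mm` geodesic distance of
#' that vertex. The mask requires at least `min_patients`.
#'
#' @param electrodes an electrode table (columns patient, x, y, z).
#' @param mesh a `surface_mesh`.
#' @param radius_mm geodesic recording-zone radius (default 10).
#' @param min_patients coverage floor (default 3).
#' @param dist_matrix optional precomputed geodesic distances.
#' @return list with `count` (patients per vertex) and `mask` (logical).
#' @export
coverage_mask <- function(electrodes, mesh, radius_mm = 10,
                          min_patients = 3, dist_matrix = NULL) {
  if (radius_mm <= 0) stop("radius_mm must be > 0")
  nv <- nrow(mesh$vertices)
  count <- integer(nv)
  if (nrow(electrodes)) {
    nodes <- nearest_node(as.matrix(electrodes[, c("x", "y", "z")]), mesh)
    if (is.null(dist_matrix)) {
      un <- sort(unique(nodes))
      D <- geodesic_distances(mesh, from = un)
      rowidx <- match(nodes, un)
    } else {
      D <- dist_matrix
      rowidx <- nodes
    }
    for (p in unique(electrodes$patient)) {
      rows <- rowidx[electrodes$patient == p]
      within <- apply(D[rows, , drop = FALSE] <= radius_mm, 2, any)
      count <- count + within
    }
  }
  list(count = count, mask = count >= min_patients)
}

#' Per-subject per-vertex window estimates
#'
#' Each electrode is indexed to its nearest mesh node; a vertex then
#' collects, per subject, every electrode whose node lies within the
#' geodesic assignment radius. The subject-vertex effect is the mean of
#' the pooled per-trial window means (electrodes within a subject averaged
#' as a fixed effect) and its variance the squared standard error of that
#' pooled mean. Vertices with no electrode in range are absent (sparse).
#'
#' @param epochs percent-change `epoch_set` whose `channel_info` carries
#'   `patient` and `vertex` (see [attach_vertices()]).
#' @param window_ms analysis window, ms.
#' @param mesh a `surface_mesh`.
#' @param radius_mm geodesic assignment radius (default 10).
#' @param dist_matrix optional precomputed geodesic distances.
#' @return data.frame: subject, vertex, effect, var, n_electrodes.
#' @export
node_estimates <- function(epochs, window_ms, mesh, radius_mm = 10,
                           dist_matrix = NULL) {
  info <- epochs$channel_info
  if (is.null(info) || !all(c("vertex", "patient") %in% names(info)))
    stop("epochs$channel_info needs 'vertex' and 'patient' columns")
  widx <- which(epochs$time_ms >= window_ms[1] &
                epochs$time_ms < window_ms[2])
  if (!length(widx)) stop("window outside epoch")
  if (is.null(dist_matrix)) dist_matrix <- geodesic_distances(mesh)
  nc <- dim(epochs$data)[2]
  trial_means <- vapply(seq_len(nc), function(ci)
    apply(epochs$data[, ci, widx, drop = FALSE], 1, mean),
    numeric(dim(epochs$data)[1]))      # trials x channels
  trial_means <- matrix(trial_means, ncol = nc)
  nv <- nrow(mesh$vertices)
  rows <- list()
  for (vx in seq_len(nv)) {
    near <- which(dist_matrix[info$vertex, vx] <= radius_mm)
    if (!length(near)) next
    for (p in unique(info$patient[near])) {
      cis <- near[info$patient[near] == p]
      pooled <- as.vector(trial_means[, cis])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = p, vertex = vx, effect = mean(pooled),
        var = stats::var(pooled) / length(pooled),
        n_electrodes = length(cis))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Window MEMA map with smoothing, cluster correction and masks
#'
#' The full population-map stage for one analysis window: per-subject
#' per-vertex estimates (electrodes averaged within subject), per-vertex
#' mixed-effects fit, geodesic Gaussian smoothing of the effect and test
#' maps, supra-threshold clustering against the Monte-Carlo extent
#' threshold (static mode) or uncorrected vertex threshold (movie mode),
#' and the coverage and absolute-effect-floor masks.
#'
#' @param epochs percent-change `epoch_set` whose `channel_info` includes
#'   `patient` and `vertex` (add with [attach_vertices()]).
#' @param mesh a `surface_mesh`.
#' @param window_ms analysis window.
#' @param cfg an [analysis_config()].
#' @param mode "static" (cluster-corrected, 10% floor) or "movie"
#'   (uncorrected, 15% floor).
#' @param extent optional precomputed [cluster_extent_threshold()] result
#'   (computed here if absent in static mode).
#' @param dist_matrix optional precomputed geodesic distances.
#' @return a `mema_map` with added per-vertex columns `effect_smoothed`,
#'   `cluster`, `coverage`, `significant`, and attributes `window_ms`,
#'   `mode`, `extent_threshold`.
#' @export
mema_window_analysis <- function(epochs, mesh, window_ms,
                                 cfg = analysis_config(),
                                 mode = c("static", "movie"),
                                 extent = NULL, dist_matrix = NULL) {
  mode <- match.arg(mode)
  if (is.null(dist_matrix)) dist_matrix <- geodesic_distances(mesh)
  est <- node_estimates(epochs, window_ms, mesh,
                        radius_mm = cfg$assignment_radius_mm,
                        dist_matrix = dist_matrix)
  fit <- mema_fit(est, n_vertices = nrow(mesh$vertices))
  nv <- nrow(mesh$vertices)
  eff <- rep(NA_real_, nv); eff[fit$vertex] <- fit$effect
  pv <- rep(NA_real_, nv); pv[fit$vertex] <- fit$p
  eff_s <- geodesic_gaussian_smooth(eff, mesh, cfg$fwhm_mm, dist_matrix)
  cov <- coverage_mask(epochs$channel_info, mesh,
                       radius_mm = cfg$coverage_radius_mm,
                       min_patients = cfg$min_patients,
                       dist_matrix = dist_matrix)
  floor_pct <- if (mode == "movie") cfg$movie_effect_floor else cfg$effect_floor
  supra <- !is.na(pv) & pv < cfg$mema_alpha
  clust <- label_clusters(supra, mesh)
  if (mode == "static") {
    if (is.null(extent))
      extent <- cluster_extent_threshold(
        mesh, cfg$fwhm_mm, vertex_alpha = cfg$mema_alpha,
        fwer_alpha = cfg$mema_alpha, n_iter = cfg$mema_iters,
        seed = cfg$seed, dist_matrix = dist_matrix)
    sizes <- tabulate(clust)
    big <- clust > 0 & sizes[pmax(clust, 1L)] >= extent$threshold
  } else big <- supra
  sig <- big & !is.na(eff_s) & abs(eff_s) > floor_pct & cov$mask
  fit$effect_smoothed <- eff_s[fit$vertex]
  fit$cluster <- clust[fit$vertex]
  fit$coverage <- cov$count[fit$vertex]
  fit$significant <- sig[fit$vertex]
  attr(fit, "window_ms") <- window_ms
  attr(fit, "mode") <- mode
  attr(fit, "extent_threshold") <- if (mode == "static") extent$threshold
                                   else NA_integer_
  attr(fit, "significant_vertices") <- which(sig)
  fit
}

#' Sliding-window MEMA movie
#'
#' Runs [mema_window_analysis()] in movie mode over overlapping windows
#' (150 ms width, 10 ms step by default) spanning `span_ms`.
#'
#' @inheritParams mema_window_analysis
#' @param span_ms length-2 overall time span; windows fit fully inside.
#' @return list of `mema_map`s, one per window, with a `windows` attribute
#'   (matrix of window starts/ends).
#' @export
mema_movie <- function(epochs, mesh, span_ms, cfg = analysis_config(),
                       dist_matrix = NULL) {
  if (is.null(dist_matrix)) dist_matrix <- geodesic_distances(mesh)
  starts <- seq(span_ms[1], span_ms[2] - cfg$movie_width_ms,
                by = cfg$movie_step_ms)
  frames <- lapply(starts, function(s)
    mema_window_analysis(epochs, mesh, c(s, s + cfg$movie_width_ms), cfg,
                         mode = "movie", dist_matrix = dist_matrix))
  attr(frames, "windows") <- cbind(start = starts,
                                   end = starts + cfg$movie_width_ms)
  frames
}

#' Number of sliding-movie frames in a span
#' @param span_ms length-2 span (ms).
#' @param width_ms,step_ms window geometry (150 / 10 default).
#' @return integer frame count: `floor((span - width)/step) + 1`.
#' @export
movie_frame_count <- function(span_ms, width_ms = 150, step_ms = 10) {
  as.integer(floor((diff(span_ms) - width_ms) / step_ms) + 1)
}

#' Attach nearest-vertex indices to epoch channel metadata
#' @param epochs an `epoch_set` whose `channel_info` has x, y, z columns.
#' @param mesh a `surface_mesh`.
#' @return the `epoch_set` with `channel_info$vertex` filled.
#' @export
attach_vertices <- function(epochs, mesh) {
  info <- epochs$channel_info
  if (is.null(info)) stop("epochs carry no channel metadata")
  epochs$channel_info$vertex <-
    nearest_node(as.matrix(info[, c("x", "y", "z")]), mesh)
  epochs
}
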