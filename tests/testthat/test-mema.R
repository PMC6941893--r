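test_that("nearest-node assignment matches the exhaustive scan and tie rule", {
  m <- fixture_mesh()
  # coordinates exactly at vertices map to themselves
  picks <- c(1L, 57L, 162L)
  expect_identical(nearest_node(m$vertices[picks, ], m), picks)
  set.seed(20)
  pts <- matrix(rnorm(60, 0, 15), ncol = 3)
  expect_identical(nearest_node(pts, m),
                   as.integer(oracle_nearest(pts, m$vertices)))
  # equidistant tie: midpoint of an edge returns the lower vertex index
  e <- c(m$faces[1, 1], m$faces[1, 2])
  mid <- colMeans(m$vertices[e, ])
  expect_equal(nearest_node(mid, m), min(e))
  expect_error(nearest_node(c(Inf, 0, 0), m), "finite")
})

test_that("geodesic Gaussian smoothing fixes constants and matches the kernel", {
  m <- fixture_mesh()
  D <- fixture_dist()
  const <- rep(3.3, nrow(m$vertices))
  expect_equal(geodesic_gaussian_smooth(const, m, 3, D), const)
  # unit impulse: smoothed values proportional to the Gaussian kernel
  fwhm <- 8
  sigma <- fwhm / 2.355
  imp <- numeric(nrow(m$vertices)); imp[10] <- 1
  sm <- geodesic_gaussian_smooth(imp, m, fwhm, D)
  k <- exp(-D[, 10]^2 / (2 * sigma^2))
  k[D[, 10] > 4 * sigma] <- 0
  direct <- k / rowSums(exp(-D^2 / (2 * sigma^2)) * (D <= 4 * sigma))
  expect_equal(sm, direct, tolerance = 1e-12)
  # fwhm -> 0 limit approaches the identity map
  set.seed(21)
  x <- rnorm(nrow(m$vertices))
  expect_equal(geodesic_gaussian_smooth(x, m, 1e-3, D), x, tolerance = 1e-9)
  expect_error(geodesic_gaussian_smooth(x, m, 0, D), "fwhm")
})

test_that("smoothing changes the global mean only within a bounded asymmetry", {
  m <- fixture_mesh()
  D <- fixture_dist()
  set.seed(22)
  x <- rnorm(nrow(m$vertices), 5, 2)
  sm <- geodesic_gaussian_smooth(x, m, 6, D)
  expect_lt(abs(mean(sm) - mean(x)), 0.05 * sd(x))
})

test_that("the mixed-effects fit reduces to the one-sample t-test at zero variance", {
  set.seed(23)
  y <- rnorm(9, 25, 6)
  est <- data.frame(subject = paste0("s", 1:9), vertex = 1, effect = y,
                    var = 0)
  f <- mema_fit(est)
  tt <- t.test(y)
  expect_equal(f$t, unname(tt$statistic), tolerance = 1e-6)
  expect_equal(f$p, tt$p.value, tolerance = 1e-6)
  expect_equal(f$effect, mean(y), tolerance = 1e-10)
  # tau^2 = 0 reduces to the fixed-effect inverse-variance mean
  v <- runif(9, 1, 2)
  y2 <- rep(10, 9) + rnorm(9, 0, 1e-4)   # tiny dispersion, tau2 -> 0
  f2 <- mema_fit(data.frame(subject = 1:9, vertex = 1, effect = y2,
                            var = v))
  w <- 1 / (v + f2$tau2)
  expect_equal(f2$effect, sum(w * y2) / sum(w), tolerance = 1e-10)
})

test_that("REML between-subject variance agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(24)
  for (i in 1:5) {
    y <- rnorm(10, 20, 8)
    v <- runif(10, 0.5, 4)
    f <- mema_fit(data.frame(subject = 1:10, vertex = 1, effect = y,
                             var = v))
    mref <- metafor::rma(yi = y, vi = v, method = "REML")
    expect_equal(f$tau2, mref$tau2, tolerance = 1e-4)
    expect_equal(f$effect, as.numeric(mref$beta), tolerance = 1e-6)
  }
})

test_that("single-subject vertices carry the estimate with the test disabled", {
  est <- data.frame(subject = c("a", "a", "b"), vertex = c(1, 2, 2),
                    effect = c(12, 5, 7), var = c(1, 1, 1))
  f <- mema_fit(est)
  one <- f[f$vertex == 1, ]
  expect_equal(one$effect, 12)
  expect_true(is.na(one$p))
  expect_equal(one$n_subjects, 1)
  # all variances zero with unequal estimates: dispersion goes to tau2
  f2 <- mema_fit(data.frame(subject = 1:4, vertex = 1,
                            effect = c(1, 5, 9, 13), var = 0))
  expect_gt(f2$tau2, 0)
  expect_true(is.finite(f2$t))
})

test_that("parameter recovery: mu = 30, tau = 10, n = 12, 500 replicates", {
  set.seed(25)
  mus <- numeric(500)
  cover <- logical(500)
  for (r in 1:500) {
    v <- runif(12, 4, 25)
    y <- rnorm(12, 30, 10) + rnorm(12, 0, sqrt(v))
    f <- mema_fit(data.frame(subject = 1:12, vertex = 1, effect = y,
                             var = v))
    mus[r] <- f$effect
    half <- qt(0.975, f$df) * f$se
    cover[r] <- abs(f$effect - 30) <= half
  }
  expect_equal(mean(mus), 30, tolerance = 1.5 / 30)
  expect_equal(mean(cover), 0.95, tolerance = 0.03 / 0.95)
})

test_that("cluster labeling agrees with brute-force flood fill", {
  m <- fixture_mesh()
  set.seed(26)
  for (i in 1:20) {
    mask <- runif(nrow(m$vertices)) < 0.3
    got <- label_clusters(mask, m)
    want <- oracle_clusters(mask, m$faces, nrow(m$vertices))
    expect_equal(max(got), max(want))
    # same partition up to label permutation
    expect_equal(length(unique(got[mask])), length(unique(want[mask])))
    for (cl in unique(got[mask]))
      expect_equal(length(unique(want[got == cl])), 1)
  }
})

test_that("cluster-extent thresholds are monotone in alpha and smoothness", {
  m <- fixture_mesh()
  D <- fixture_dist()
  t05 <- cluster_extent_threshold(m, 3, 0.05, 0.05, n_iter = 300, seed = 1,
                                  dist_matrix = D)
  t01 <- cluster_extent_threshold(m, 3, 0.05, 0.01, n_iter = 300, seed = 1,
                                  dist_matrix = D)
  expect_gte(t01$threshold, t05$threshold)
  s3 <- cluster_extent_threshold(m, 3, 0.05, 0.05, n_iter = 300, seed = 2,
                                 dist_matrix = D)
  s12 <- cluster_extent_threshold(m, 12, 0.05, 0.05, n_iter = 300, seed = 2,
                                  dist_matrix = D)
  expect_gte(s12$threshold, s3$threshold)   # smoother noise, bigger clusters
  expect_error(cluster_extent_threshold(m, 3, 0.05, 0.05, n_iter = 10),
               "n_iter")
})

test_that("coverage counts match a brute-force distance scan", {
  m <- fixture_mesh()
  D <- fixture_dist()
  empty <- coverage_mask(data.frame(patient = character(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0)), m)
  expect_false(any(empty$mask))
  # three patients at one vertex
  v1 <- m$vertices[5, ]
  el3 <- data.frame(patient = c("a", "b", "c"),
                    x = v1[1], y = v1[2], z = v1[3])
  cv3 <- coverage_mask(el3, m, radius_mm = 10, min_patients = 3,
                       dist_matrix = D)
  expect_true(cv3$mask[5])
  # random electrodes versus independent scan
  el <- place_electrodes(m, 5, 2, 6, 3.5, seed = 27)
  cv <- coverage_mask(el, m, radius_mm = 10, min_patients = 3,
                      dist_matrix = D)
  nodes <- nearest_node(as.matrix(el[, c("x", "y", "z")]), m)
  want <- integer(nrow(m$vertices))
  for (vx in seq_len(nrow(m$vertices))) {
    pats <- unique(el$patient[D[nodes, vx] <= 10])
    want[vx] <- length(pats)
  }
  expect_equal(cv$count, want)
})

test_that("movie frame counts follow the sliding-window formula", {
  expect_equal(movie_frame_count(c(-500, 600)), 96)
  expect_equal(movie_frame_count(c(0, 150)), 1)
  expect_equal(movie_frame_count(c(0, 1000), 150, 50), 18)
})

test_that("the static map recovers an injected region and leaves the pre-window empty", {
  s <- fixture_study()
  D <- fixture_dist()
  cfg <- analysis_config(mema_iters = 300)
  map <- mema_window_analysis(s$epochs_pct, s$mesh, c(250, 550), cfg,
                              "static", dist_matrix = D)
  cov <- coverage_mask(s$electrodes, s$mesh, cfg$coverage_radius_mm,
                       cfg$min_patients, dist_matrix = D)
  sig <- attr(map, "significant_vertices")
  truth_v <- which(s$mesh$labels == s$region & cov$mask)
  dice <- 2 * length(intersect(sig, truth_v)) /
    (length(sig) + length(truth_v))
  expect_gte(dice, 0.8)
  pre <- mema_window_analysis(s$epochs_pct, s$mesh, c(-500, -100), cfg,
                              "static", dist_matrix = D)
  expect_length(attr(pre, "significant_vertices"), 0)
  expect_output(print(map), "mema_map")
  expect_output(summary(map), "mixed-effects")
  expect_true(is.numeric(coef(map)))
})

test_that("movie mode applies the uncorrected threshold and 15% floor", {
  s <- fixture_study()
  D <- fixture_dist()
  cfg <- analysis_config(mema_iters = 300)
  frames <- mema_movie(s$epochs_pct, s$mesh, c(100, 700), cfg,
                       dist_matrix = D)
  expect_length(frames, movie_frame_count(c(100, 700)))
  # effect window frames light up inside the true region
  mid <- frames[[30]]   # window ~390..540 ms, inside the plateau
  sig_mid <- attr(mid, "significant_vertices")
  expect_gt(length(sig_mid), 0)
  expect_true(mean(s$mesh$labels[sig_mid] == s$region) > 0.8)
  expect_true(all(abs(mid$effect_smoothed[mid$significant]) > 15))
})
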