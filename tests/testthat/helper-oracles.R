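# Independent brute-force oracles used to validate the fast implementations.
# These deliberately avoid the code paths they check.

# time-domain FIR bandpass (windowed sinc) + quadrature demodulation,
# both by direct convolution (stats::filter, method = "convolution")
oracle_fir_quadrature_envelope <- function(x, fs, f_lo = 70, f_hi = 150,
                                           n_taps = 401) {
  stopifnot(n_taps %% 2 == 1)
  m <- (n_taps - 1) / 2
  k <- -m:m
  sinc <- function(f) ifelse(k == 0, 2 * f / fs, sin(2 * pi * f * k / fs) /
                               (pi * k))
  h_bp <- (sinc(f_hi) - sinc(f_lo)) * (0.54 - 0.46 * cos(2 * pi *
                                                           (k + m) / (n_taps - 1)))
  xf <- stats::filter(x, h_bp, method = "convolution", sides = 2)
  fc <- (f_lo + f_hi) / 2
  t <- (seq_along(x) - 1) / fs
  z <- xf * exp(-2i * pi * fc * t)
  h_lp <- sinc((f_hi - f_lo) / 2 + 5) * (0.54 - 0.46 * cos(2 * pi *
                                                             (k + m) / (n_taps - 1)))
  zr <- stats::filter(Re(z), h_lp, method = "convolution", sides = 2)
  zi <- stats::filter(Im(z), h_lp, method = "convolution", sides = 2)
  2 * sqrt(zr^2 + zi^2)
}

# plain analytic-signal envelope (no band weighting) of an already
# band-limited trace
oracle_analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  } else h[2:((n + 1) / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE)) / n
}

# sliding least-squares polynomial fit, value at window center
oracle_savgol <- function(x, order, frame) {
  m <- (frame - 1) / 2
  out <- x
  for (i in (m + 1):(length(x) - m)) {
    idx <- (i - m):(i + m)
    fit <- stats::lm.fit(outer(idx - i, 0:order, "^"), x[idx])
    out[i] <- fit$coefficients[1]
  }
  out
}

# literal BH step-up
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  mask <- logical(m)
  if (length(k)) mask[o[seq_len(max(k))]] <- TRUE
  mask
}

# per-channel loop common average over included channels
oracle_car <- function(data, include) {
  out <- data
  inc <- which(include)
  for (s in seq_len(ncol(data))) {
    mu <- mean(data[inc, s])
    for (ci in inc) out[ci, s] <- data[ci, s] - mu
  }
  out
}

# exhaustive nearest-vertex scan
oracle_nearest <- function(coords, vertices) {
  apply(coords, 1, function(p) {
    d <- sqrt(colSums((t(vertices) - p)^2))
    which(d == min(d))[1]
  })
}

# flood fill over the vertex adjacency of a mask
oracle_clusters <- function(mask, faces, nv) {
  adj <- vector("list", nv)
  for (r in seq_len(nrow(faces))) {
    tri <- faces[r, ]
    for (a in tri) for (b in tri) if (a != b)
      adj[[a]] <- union(adj[[a]], b)
  }
  lab <- integer(nv)
  cur <- 0L
  for (v in which(mask)) {
    if (lab[v]) next
    cur <- cur + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[u]) next
      lab[u] <- cur
      stack <- c(stack, Filter(function(w) mask[w] && !lab[w], adj[[u]]))
    }
  }
  lab
}

# exact two-sided signed-rank p by enumerating all sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_null <- as.matrix(signs) %*% r
  mu <- sum(r) / 2
  p <- mean(abs(W_null - mu) >= abs(W_obs - mu) - 1e-9)
  min(1, p)
}

# shared small fixtures (built once per test run)
fixture_mesh <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- seegamma::make_mesh(2, 4, seed = 2)
    m
  }
})

fixture_dist <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- seegamma::geodesic_distances(fixture_mesh())
    d
  }
})

# one modest multi-patient simulated study, reused by epoch/MEMA tests:
# 12 patients x 4 probes x 6 contacts at 500 Hz, 20 reading trials, a 60%
# gamma increase at +200..+600 ms post-stimulus in the largest region
fixture_study <- local({
  s <- NULL
  function() {
    if (!is.null(s)) return(s)
    fs <- 500
    mesh <- fixture_mesh()
    el <- seegamma::place_electrodes(mesh, 12, 4, 6, 3.5, seed = 5)
    reg <- as.integer(names(which.max(table(el$region))))
    truth <- seegamma::ground_truth(effects = data.frame(
      region = reg, amplitude = 60, latency_ms = 200, duration_ms = 400,
      jitter = 0.1, align = "stimulus"))
    ev <- seegamma::simulate_events("reading", 20, iti = 2200, seed = 6)
    rec <- seegamma::simulate_recording(el, ev, truth, fs = fs, seed = 7)
    env <- seegamma::savgol_smooth(
      seegamma::hilbert_bandpass_amplitude(rec$data, fs), fs)
    ep <- seegamma::epoch(env, ev, "stimulus", c(-800, 1200), fs = fs,
                          units = "envelope", channel_info = rec$channels)
    pc <- seegamma::attach_vertices(
      seegamma::percent_change(ep, c(-500, -100)), mesh)
    s <<- list(mesh = mesh, electrodes = el, region = reg, truth = truth,
               events = ev, recording = rec, epochs_pct = pc, fs = fs)
    s
  }
})
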