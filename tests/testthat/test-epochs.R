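make_epochs <- function(d, fs, t0_ms, units = "envelope") {
  n_time <- dim(d)[3]
  structure(list(data = d, fs = fs,
                 time_ms = t0_ms + (seq_len(n_time) - 1) * 1000 / fs,
                 align = "stimulus", units = units, dropped = integer(0)),
            class = "epoch_set")
}

test_that("epoch windows are half-open with exact sample counts", {
  fs <- 2000
  ev <- data.frame(trial = 1, task = "reading", stim_onset_ms = 1000,
                   speech_onset_ms = 1900)
  x <- matrix(rnorm(2 * 3 * fs), 2)
  ep <- epoch(x, ev, "stimulus", c(-100, 100), fs = fs)
  expect_equal(dim(ep$data)[3], 400)    # 200 ms at 2 kHz
  expect_equal(ep$time_ms[1], -100)
  expect_equal(diff(ep$time_ms)[1], 0.5)
  # constant channel stays constant
  xc <- matrix(5, 1, 3 * fs)
  epc <- epoch(xc, ev, "stimulus", c(-100, 100), fs = fs)
  expect_true(all(epc$data == 5))
  # out-of-range trials are dropped and reported
  ev2 <- rbind(ev, data.frame(trial = 2, task = "reading",
                              stim_onset_ms = 5950, speech_onset_ms = NA))
  ep2 <- epoch(x, ev2, "stimulus", c(-100, 100), fs = fs)
  expect_equal(dim(ep2$data)[1], 1)
  expect_equal(ep2$dropped, 2)
})

test_that("a synthetic gamma burst is recovered at its injected latency", {
  fs <- 500
  el <- place_electrodes(fixture_mesh(), 1, 1, 2, 3.5, seed = 5)
  reg <- el$region[1]
  truth <- ground_truth(effects = data.frame(
    region = reg, amplitude = 120, latency_ms = 300, duration_ms = 200,
    jitter = 0, align = "speech"))
  ev <- simulate_events("reading", 40, iti = 2500, seed = 2)
  rec <- simulate_recording(el, ev, truth, fs = fs, seed = 3)
  env <- savgol_smooth(hilbert_bandpass_amplitude(rec$data, fs), fs)
  ep <- epoch(env, ev, "speech", c(-500, 1000), fs = fs,
              units = "envelope")
  avg <- colMeans(ep$data[, 1, ])
  peak_ms <- ep$time_ms[which.max(avg)]
  # effect plateau spans 300..500 ms; smoothing tolerance ~75 ms each side
  expect_gt(peak_ms, 300 - 80)
  expect_lt(peak_ms, 500 + 80)
})

test_that("percent change is exact arithmetic on constructed envelopes", {
  fs <- 100
  n_time <- 200
  B <- 3
  d <- array(B, dim = c(10, 1, n_time))
  ep <- make_epochs(d, fs, -1000)
  pc <- percent_change(ep, c(-500, -100))
  expect_true(all(abs(pc$data) < 1e-12))
  d2 <- d
  d2[, , 150:200] <- 2 * B
  ep2 <- make_epochs(d2, fs, -1000)
  pc2 <- percent_change(ep2, c(-500, -100))
  expect_equal(unique(as.vector(pc2$data[, , 150:200])), 100)
  # unit discipline and corrupted baselines
  expect_error(percent_change(make_epochs(d, fs, -1000, units = "uV")),
               "envelope")
  dz <- array(0, dim = c(2, 1, n_time))
  expect_error(percent_change(make_epochs(dz, fs, -1000)), "baseline")
})

test_that("injected effect amplitude is recovered by the envelope pipeline", {
  fs <- 500
  el <- place_electrodes(fixture_mesh(), 1, 1, 2, 3.5, seed = 5)[1, ]
  truth <- ground_truth(effects = data.frame(
    region = el$region, amplitude = 50, latency_ms = 200,
    duration_ms = 400, jitter = 0, align = "stimulus"),
    line_amp_uv = 0)
  ev <- simulate_events("reading", 200, iti = 2200, seed = 6)
  rec <- simulate_recording(el, ev, truth, fs = fs, seed = 7)
  env <- savgol_smooth(hilbert_bandpass_amplitude(rec$data, fs), fs)
  ep <- epoch(env, ev, "stimulus", c(-800, 1200), fs = fs,
              units = "envelope")
  pc <- percent_change(ep, c(-500, -100))
  w <- which(ep$time_ms >= 300 & ep$time_ms < 500)   # effect plateau
  recovered <- mean(pc$data[, 1, w])
  expect_equal(recovered, 50, tolerance = 5 / 50)
})

test_that("group averaging is hierarchical, not pooled", {
  traces <- rbind(rep(0, 5), rep(100, 5), rep(50, 5))
  g <- group_timecourse(traces, c("A", "A", "B"))
  expect_equal(g$mean, rep(50, 5))     # not (0+100+50)/3
  expect_equal(g$n_subjects, 2)
  same <- group_timecourse(rbind(rep(7, 4), rep(7, 4), rep(7, 4)),
                           c("A", "B", "C"))
  expect_equal(same$se, rep(0, 4))
  # duplicating a subject's full electrode set changes nothing, and
  # duplicating one electrode of A leaves B's contribution untouched
  dup_all <- group_timecourse(rbind(traces, traces[1:2, ]),
                              c("A", "A", "B", "A", "A"))
  expect_equal(dup_all$mean, g$mean)
  dup_one <- group_timecourse(rbind(traces, rep(0, 5)),
                              c("A", "A", "B", "A"))
  expect_equal(dup_one$subject_means[2, ], rep(50, 5))
  expect_equal(dup_one$n_subjects, 2)
})

test_that("across-subject SE scales as sigma over root n", {
  set.seed(10)
  sigma <- 8
  n_sub <- 10
  ses <- replicate(300, {
    traces <- matrix(rnorm(n_sub, 0, sigma), n_sub, 1)
    group_timecourse(traces, paste0("s", 1:n_sub))$se
  })
  expect_equal(mean(ses), sigma / sqrt(n_sub), tolerance = 0.05)
})

test_that("BH-FDR reproduces the worked step-up example and the brute-force rule", {
  mask <- bh_fdr(c(0.001, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(mask, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(mask), 3)
  expect_false(any(bh_fdr(rep(1, 10), 0.05)))
  m <- 20
  expect_true(all(bh_fdr(rep(0.05 / m, m), 0.05)))  # boundary case
  expect_length(bh_fdr(numeric(0)), 0)
  set.seed(11)
  for (i in 1:1000) {
    len <- sample(1:500, 1)
    p <- runif(len)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(bh_fdr(p, q), oracle_bh(p, q))
  }
})

test_that("timepoint significance flags plateaus and spares baselines", {
  set.seed(12)
  n_sub <- 8
  n_time <- 100
  sm <- matrix(rnorm(n_sub * n_time, 0, 0.5), n_sub)
  sm[, 40:70] <- sm[, 40:70] + 50
  g <- structure(list(subject_means = sm, mean = colMeans(sm),
                      n_subjects = n_sub), class = "group_timecourse")
  res <- timepoint_significance(g, 0.05)
  expect_true(all(res$mask[45:65]))
  expect_false(any(res$mask[1:35]))
  two <- structure(list(subject_means = sm[1:2, ], n_subjects = 2),
                   class = "group_timecourse")
  expect_error(timepoint_significance(two), ">= 3 subjects")
})

test_that("window z-scores match the closed-form definition", {
  fs <- 100
  set.seed(13)
  n_tr <- 60
  n_time <- 300
  d <- array(rnorm(n_tr * n_time, 10, 1), dim = c(n_tr, 1, n_time))
  ep <- make_epochs(d, fs, -1500)
  ws <- window_zscore(ep, c(200, 600), c(-500, -100))
  widx <- which(ep$time_ms >= 200 & ep$time_ms < 600)
  bidx <- which(ep$time_ms >= -500 & ep$time_ms < -100)
  wm <- apply(d[, 1, widx], 1, mean)
  bm <- apply(d[, 1, bidx], 1, mean)
  expect_equal(ws$z, (mean(wm) - mean(bm)) / sd(bm), tolerance = 1e-12)
  expect_equal(ws$p, 2 * pnorm(-abs(ws$z)), tolerance = 1e-12)
  # +2 baseline-SD shift lands near z = 2
  d2 <- d
  d2[, , ep$time_ms >= 200 & ep$time_ms < 600] <-
    d2[, , ep$time_ms >= 200 & ep$time_ms < 600] + 2 * sd(bm)
  z2 <- window_zscore(make_epochs(d2, fs, -1500), c(200, 600),
                      c(-500, -100))$z
  expect_equal(z2, ws$z + 2, tolerance = 1e-9)
  # degenerate all-zero input is guarded
  dz <- array(0, dim = c(10, 1, n_time))
  expect_warning(wz <- window_zscore(make_epochs(dz, fs, -1500),
                                     c(200, 600), c(-500, -100)),
                 "all-zero")
  expect_equal(wz$z, 0)
  expect_equal(wz$p, 1)
})

test_that("window z-scores are small and conservative under the null", {
  # z measures the shift in baseline-SD units: under the null its spread
  # is ~sqrt(2/n_trials), so normal-tail p-values are conservative
  set.seed(14)
  n_tr <- 30
  zs <- replicate(200, {
    d <- array(rnorm(n_tr * 250, 5, 1), dim = c(n_tr, 1, 250))
    window_zscore(make_epochs(d, 100, -1500), c(200, 600),
                  c(-500, -100))$z
  })
  expect_lt(abs(mean(zs)), 0.1)
  expect_equal(sd(zs), sqrt(2 / n_tr), tolerance = 0.2)
  ps <- 2 * pnorm(-abs(zs))
  expect_lt(mean(ps < 0.05), 0.05)   # conservative false-positive rate
})

test_that("the paired Wilcoxon test matches exact enumeration", {
  # n = 6, all positive differences: two-sided p = 2/64
  a <- c(1.2, 0.8, 2.1, 0.5, 1.7, 0.9)
  b <- rep(0, 6)
  res <- wilcoxon_contrast(a, b)
  expect_equal(res$p, 2 / 64)
  expect_equal(res$p, oracle_signed_rank_p(a - b))
  # random paired data agree with the enumeration oracle
  set.seed(15)
  for (i in 1:20) {
    d <- round(rnorm(7), 2)
    d <- d[d != 0]
    if (length(d) < 3) next
    expect_equal(wilcoxon_contrast(d, rep(0, length(d)))$p,
                 oracle_signed_rank_p(d), tolerance = 1e-12)
  }
  # symmetry under swapping conditions
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(wilcoxon_contrast(x, y)$p, wilcoxon_contrast(y, x)$p)
  # degenerate: identical conditions
  expect_warning(resz <- wilcoxon_contrast(x, x), "degenerate")
  expect_equal(resz$p, 1)
  expect_error(wilcoxon_contrast(1:3, 1:4), "unpaired")
})

test_that("ERPs capture evoked deflections but not phase-random gamma", {
  fs <- 500
  n_tr <- 60
  n_time <- 500   # -400..+600 ms
  t_ms <- seq(-400, by = 2, length.out = n_time)
  set.seed(16)
  # evoked: deflection at +100 ms, identical phase across trials
  wave <- 10 * exp(-((t_ms - 100)^2) / (2 * 30^2))
  d <- array(NA_real_, dim = c(n_tr, 3, n_time))
  for (ci in 1:3) for (tr in seq_len(n_tr))
    d[tr, ci, ] <- wave + rnorm(n_time, 0, 2)
  ep <- make_epochs(d, fs, -400, units = "uV")
  g <- compute_erp(ep, c("A", "A", "B"))
  expect_lt(abs(g$time_ms[which.max(g$mean)] - 100), 10)
  # induced: gamma bursts with random phase average out
  d2 <- array(NA_real_, dim = c(n_tr, 3, n_time))
  burst_gain <- 1 + 3 * exp(-((t_ms - 100)^2) / (2 * 50^2))
  for (ci in 1:3) for (tr in seq_len(n_tr))
    d2[tr, ci, ] <- bandlimit_voltage(rnorm(n_time), fs) * burst_gain
  g2 <- compute_erp(make_epochs(d2, fs, -400, units = "uV"),
                    c("A", "A", "B"))
  expect_lt(max(abs(g2$mean)), 0.2 * max(g$mean))
  # zero in, zero out
  g0 <- compute_erp(make_epochs(array(0, dim = c(5, 2, n_time)), fs, -400,
                                units = "uV"), c("A", "B"))
  expect_true(all(g0$mean == 0))
})
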