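test_that("filter_positions removes exactly the implausibly fast samples", {
  t <- seq(0, 1.98, by = 0.02)
  x <- seq(0, 99, by = 1)        # 50 cm/s steady
  tr <- trajectory(t, x, rep(0, 100), rep(0, 100))
  expect_identical(filter_positions(tr), tr)
  # one teleporting sample
  x2 <- x; x2[50] <- x[50] + 16   # centred-difference speed ~400 cm/s
  tr2 <- trajectory(t, x2, rep(0, 100), rep(0, 100))
  f2 <- filter_positions(tr2)
  expect_length(f2$t, 99)
  expect_false(t[50] %in% f2$t)
  # mixed trace agrees with a per-sample loop oracle (a sample is kept
  # unless both of its adjacent-interval speeds exceed the cut-off)
  set.seed(1)
  xr <- cumsum(rnorm(300, 0, 3)); yr <- cumsum(rnorm(300, 0, 3))
  tt <- seq(0, by = 0.02, length.out = 300)
  tr3 <- trajectory(tt, xr, yr, rep(0, 300))
  keep <- logical(300)
  for (i in 1:300) {
    sp <- c()
    if (i > 1) sp <- c(sp, sqrt((xr[i] - xr[i - 1])^2 +
                                  (yr[i] - yr[i - 1])^2) / 0.02)
    if (i < 300) sp <- c(sp, sqrt((xr[i + 1] - xr[i])^2 +
                                    (yr[i + 1] - yr[i])^2) / 0.02)
    keep[i] <- min(sp) <= 200
  }
  expect_equal(filter_positions(tr3)$t, tt[keep])
})

test_that("rate maps conserve dwell and spikes and handle degenerate input", {
  s <- bvc_baseline_session()
  for (m in list(s$map, compute_rate_map(s$traj, s$spikes, smooth = FALSE))) {
    expect_equal(sum(m$dwell), length(s$traj$t) * 0.02)
    expect_equal(sum(m$counts), length(s$spikes))
  }
  m0 <- compute_rate_map(s$traj, numeric(0))
  expect_equal(m0$peak_rate, 0)
  expect_true(all(m0$rate[m0$visited] == 0))
  expect_error(trajectory(numeric(0), numeric(0), numeric(0), numeric(0)))
  expect_error(trajectory(c(1, 1), c(0, 0), c(0, 0), c(0, 0)), "increasing")
})

test_that("smoothing preserves constants and matches the convolution oracle", {
  # spikes exactly proportional to dwell: one spike at every sample time
  t <- seq(0, 59.98, by = 0.02)
  set.seed(2)
  tr <- trajectory(t, runif(3000, -20, 20), runif(3000, -20, 20),
                   rep(0, 3000))
  m <- compute_rate_map(tr, t + 1e-4, bin_size = 5)
  expect_equal(m$rate[m$visited], rep(50, sum(m$visited)), tolerance = 1e-9)

  # sparse map vs the double-loop renormalised boxcar oracle
  s <- bvc_baseline_session()
  sub <- trajectory(s$traj$t[1:2000], s$traj$x[1:2000], s$traj$y[1:2000],
                    s$traj$hd[1:2000])
  spk <- s$spikes[s$spikes < sub$t[2000]]
  msm <- compute_rate_map(sub, spk)
  mraw <- compute_rate_map(sub, spk, smooth = FALSE)
  oracle <- oracle_boxcar_rate(mraw$counts, mraw$dwell)
  expect_equal(msm$rate[msm$visited], oracle[mraw$visited], tolerance = 1e-12)
})

test_that("doubling the spike train doubles unsmoothed rates exactly", {
  s <- bvc_baseline_session()
  m1 <- compute_rate_map(s$traj, s$spikes, smooth = FALSE)
  m2 <- compute_rate_map(s$traj, sort(c(s$spikes, s$spikes)), smooth = FALSE)
  expect_equal(m2$rate[m2$visited], 2 * m1$rate[m1$visited])
})

test_that("barrier-aware smoothing does not pool dwell across the barrier", {
  # synthetic scene: heavy dwell and zero spikes south of an east-west
  # barrier, light dwell and brisk firing north of it
  env_b <- insert_barrier(square_env(), c(0, 0), 0)
  t <- seq(0, by = 0.02, length.out = 8000)
  set.seed(3)
  xs <- runif(8000, -24, 24)
  north <- rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), length.out = 8000)
  ys <- ifelse(north, runif(8000, 1.6, 12), runif(8000, -12, -1.6))
  tr <- trajectory(t, xs, ys, rep(0, 8000))
  spk <- sort(t[north]) + 1e-4     # fires only north of the barrier
  plain <- compute_rate_map(tr, spk)
  aware <- compute_rate_map(tr, spk, env = env_b)
  side <- pi / 2
  bins <- bvctools:::abutting_bins(aware, env_b, side)
  expect_gt(length(bins), 10)
  # north-side true rate is 50 Hz; the plain map is diluted by the heavy
  # south-side dwell, the barrier-aware map is not
  expect_true(all(aware$rate[bins] > 45))
  expect_lt(mean(plain$rate[bins]), 25)
})

test_that("polar maps respect the circular boxcar and rotation equivariance", {
  n <- 6000
  t <- seq(0, by = 0.02, length.out = n)
  set.seed(4)
  hd <- runif(n, 0, 2 * pi)
  tr <- trajectory(t, rep(0, n), rep(0, n), hd)
  # spikes only while hd is in bin 10 (centred 57 deg)
  k <- 10
  in_k <- floor(hd / (pi / 30)) + 1 == k
  pm <- compute_polar_map(tr, t[in_k] + 1e-4)
  nz <- which(pm$rate > 0)
  expect_setequal(nz, ((k - 1 + (-2:2)) %% 60) + 1)
  expect_equal(sum(pm$counts), sum(in_k))
  expect_equal(sum(pm$dwell), n * 0.02)
  # rotating all headings by 60 degrees rotates the map by 10 bins
  tr_rot <- trajectory(t, tr$x, tr$y, hd + pi / 3)
  pm_rot <- compute_polar_map(tr_rot, t[in_k] + 1e-4)
  expect_equal(pm_rot$rate, pm$rate[((seq_len(60) - 1 - 10) %% 60) + 1],
               tolerance = 1e-12)
})

test_that("a heading-independent cell yields a flat polar map", {
  s <- bvc_baseline_session()
  r <- s$polar$rate
  expect_lt(max(r) / min(r), 2)
})

test_that("windowed maps partition the trial", {
  s <- bvc_baseline_session()
  dur <- length(s$traj$t) * 0.02
  full <- windowed_rate_map(s$traj, s$spikes, 0, dur + 1)
  expect_equal(full$rate, s$map$rate)
  w1 <- windowed_rate_map(s$traj, s$spikes, 0, dur / 2, smooth = FALSE)
  w2 <- windowed_rate_map(s$traj, s$spikes, dur / 2, dur + 1, smooth = FALSE)
  expect_equal(sum(w1$dwell) + sum(w2$dwell), length(s$traj$t) * 0.02)
  expect_equal(sum(w1$counts) + sum(w2$counts), length(s$spikes))
  expect_error(windowed_rate_map(s$traj, s$spikes, -10, -5), "samples")
})
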