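test_that("simulated trajectories are deterministic, confined and well sampled", {
  env <- circle_env()
  tr <- simulate_trajectory(env, duration = 60, seed = 5)
  expect_length(tr$t, 60 * 50)
  expect_equal(diff(tr$t), rep(0.02, length(tr$t) - 1))
  tr2 <- simulate_trajectory(env, duration = 60, seed = 5)
  expect_identical(tr, tr2)
  expect_false(identical(tr, simulate_trajectory(env, 60, seed = 6)))
  # confined to the clearance-eroded floor
  expect_true(all(sqrt(tr$x^2 + tr$y^2) <= 70 + 1e-9))
  expect_true(all(instantaneous_speed(tr) <= 200))
  expect_error(simulate_trajectory(env, 60, 1, wall_clearance = 80),
               "clearance")
})

test_that("a full trial covers nearly all reachable 3 cm bins", {
  tr <- long_circle_traj()
  m <- compute_rate_map(tr, numeric(0), bin_size = 3, smooth = FALSE)
  cen <- bvctools:::ratemap_bin_centres(m)
  reachable <- sqrt(rowSums(cen^2)) < 70
  vis <- as.vector(m$visited)
  expect_gt(sum(vis & reachable) / sum(reachable), 0.95)
  # occupancy roughly uniform: coarse interior bins within 5x of each other
  mc <- compute_rate_map(tr, numeric(0), bin_size = 15, smooth = FALSE)
  cc <- bvctools:::ratemap_bin_centres(mc)
  interior <- sqrt((abs(cc[, 1]) + 7.5)^2 + (abs(cc[, 2]) + 7.5)^2) < 70
  d <- as.vector(mc$dwell)[interior]
  expect_lt(max(d) / min(d), 5)
})

test_that("bvc_rate has the right tuning geometry and normalisation", {
  env <- circle_env()
  p <- bvc_params(d_pref = 8, phi_pref = -pi / 2)   # south-tuned, proximal
  # nothing at the preferred distance near the centre
  expect_lt(bvc_rate(p, env, 0, 0), 0.05 * p$a_max)
  # 8 cm north of the southernmost wall point: at the field maximum
  expect_equal(bvc_rate(p, env, 0, -67), p$a_max, tolerance = 0.02)
  # peak of the rate surface lies within 2*sigma0 of d_pref from the south
  # wall along the north-south axis
  ys <- seq(-74, 0, by = 0.5)
  r <- bvc_rate(p, env, rep(0, length(ys)), ys)
  y_peak <- ys[which.max(r)]
  expect_lt(abs((y_peak + 75) - p$d_pref), 2 * p$sigma0)
  # deterministic
  expect_identical(bvc_rate(p, env, 10, -40), bvc_rate(p, env, 10, -40))
})

test_that("hd_rate is a circular Gaussian with the expected integral", {
  p <- hd_params(mu = 1, kappa = 6, a_max = 12)
  expect_equal(hd_rate(p, 1), 12)
  expect_lt(hd_rate(p, 1 + pi), 1e-4 * 12)
  # quadrature of the tuning curve vs the von Mises closed form
  th <- seq(0, 2 * pi, length.out = 20001)[-1]
  num <- sum(hd_rate(p, th)) * (2 * pi / 20000)
  expect_equal(num, p$a_max * exp(-p$kappa) * 2 * pi *
                 besselI(p$kappa, 0), tolerance = 1e-6)
})

test_that("boundary_off_rate inverts its BVC and responds to a barrier", {
  env <- circle_env()
  bvc <- bvc_params(d_pref = 8, phi_pref = -pi / 2)
  off0 <- boundary_off_params(baseline = 8, suppression = 0, bvc = bvc)
  xs <- c(0, 20, -30, 0); ys <- c(0, 10, -20, -60)
  expect_equal(boundary_off_rate(off0, env, xs, ys), rep(8, 4))
  off1 <- boundary_off_params(baseline = 8, suppression = 1, bvc = bvc)
  expect_equal(boundary_off_rate(off1, env, 0, -67), 0, tolerance = 0.05)
  # inserting a barrier creates a low-rate zone on the predicted (north) side
  env_b <- insert_barrier(env, c(0, 0), 0)
  before <- boundary_off_rate(off1, env, 0, 9.5)
  after <- boundary_off_rate(off1, env_b, 0, 9.5)
  expect_gt(before, 0.9 * 8)
  expect_lt(after, 0.4 * 8)
})

test_that("generate_spikes is a seeded inhomogeneous Poisson thinning", {
  t <- seq(0, 1000 - 0.02, by = 0.02)
  tr <- trajectory(t, 10 * cos(t), 10 * sin(t), t %% (2 * pi))
  f5 <- constant_rate_fn(5)
  sp <- generate_spikes(f5, tr, seed = 3)
  expect_true(!is.unsorted(sp))
  expect_lt(abs(length(sp) - 5000), 3 * sqrt(5000))
  expect_identical(sp, generate_spikes(f5, tr, seed = 3))
  expect_length(generate_spikes(constant_rate_fn(0), tr, seed = 3), 0)
  expect_error(generate_spikes(function(x, y, hd) rep(-1, length(x)), tr, 1),
               "negative")
})

test_that("spike counts match the time-integral of the rate across seeds", {
  env <- circle_env()
  p <- bvc_params(d_pref = 8, phi_pref = pi / 2)
  tr <- simulate_trajectory(env, duration = 120, seed = 9)
  fn <- bvc_rate_fn(p, env)
  expected <- sum(fn(tr$x, tr$y, tr$hd)) * 0.02
  counts <- vapply(1:30, function(s) length(generate_spikes(fn, tr, seed = s)),
                   numeric(1))
  # mean of 30 Poisson counts: within 4 standard errors of the integral
  expect_lt(abs(mean(counts) - expected), 4 * sqrt(expected / 30))
})
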