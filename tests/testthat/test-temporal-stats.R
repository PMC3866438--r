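test_that("global mean rate is spikes over trial length", {
  expect_equal(global_mean_rate(seq_len(5000), 1000), 5)
  expect_equal(global_mean_rate(numeric(0), 600), 0)
})

test_that("extract_runs segments fast epochs like a per-sample oracle", {
  n <- 3000
  t <- seq(0, by = 0.02, length.out = n)
  # constant 20 cm/s: one run spanning the trial
  tr_fast <- trajectory(t, 20 * t, rep(0, n), rep(0, n))
  runs <- extract_runs(tr_fast)
  expect_equal(nrow(runs), 1)
  expect_equal(unname(runs[1, 2] - runs[1, 1]), n * 0.02)
  # constant 2 cm/s: nothing
  tr_slow <- trajectory(t, 2 * t, rep(0, n), rep(0, n))
  expect_equal(nrow(extract_runs(tr_slow)), 0)
  # square-wave speed: 1 s fast / 0.3 s slow, checked against an oracle
  period <- rep(c(rep(20, 50), rep(0, 15)), length.out = n)
  x <- cumsum(period) * 0.02
  tr_sq <- trajectory(t, x, rep(0, n), rep(0, n))
  runs_sq <- extract_runs(tr_sq)
  spd <- instantaneous_speed(tr_sq)
  # per-sample loop oracle
  oracle_starts <- numeric(0); cur <- NA
  for (i in seq_len(n)) {
    if (spd[i] > 5 && is.na(cur)) cur <- i
    if (spd[i] <= 5 && !is.na(cur)) {
      if ((i - cur) * 0.02 >= 0.5) oracle_starts <- c(oracle_starts, t[cur])
      cur <- NA
    }
  }
  if (!is.na(cur) && (n + 1 - cur) * 0.02 >= 0.5)
    oracle_starts <- c(oracle_starts, t[cur])
  expect_equal(unname(runs_sq[, 1]), oracle_starts)
  expect_gt(nrow(runs_sq), 10)
})

test_that("autocorrelogram counts ordered pairs and matches the O(N^2) oracle", {
  acg <- spike_autocorrelogram(c(1, 1.102))
  expect_equal(sum(acg$counts), 1)
  expect_equal(acg$counts[26], 1)         # 102 ms lag -> bin (0.100, 0.104]
  expect_length(acg$counts, 125)
  expect_error(spike_autocorrelogram(1), "2 spikes")

  set.seed(6)
  spikes <- sort(runif(400, 0, 20))
  acg2 <- spike_autocorrelogram(spikes)
  expect_equal(acg2$counts, oracle_acg(spikes))
  # conservation: total = number of ordered pairs within the window
  n_pairs <- sum(outer(spikes, spikes, function(a, b) b - a) > 0 &
                   outer(spikes, spikes, function(a, b) b - a) <= 0.5)
  expect_equal(sum(acg2$counts), n_pairs)

  # periodic 8 Hz train: mass only at 125 ms multiples
  per <- seq(0, 20, by = 0.125)
  acg3 <- spike_autocorrelogram(per)
  hot <- c(32, 63, 94, 125)               # bins holding 125, 250, 375, 500 ms
  expect_equal(sum(acg3$counts[-hot]), 0)
  expect_true(all(acg3$counts[hot[1:3]] > 0))
})

test_that("run restriction drops spikes outside running epochs", {
  runs <- cbind(t0 = c(0, 10), t1 = c(2, 12))
  sp <- c(0.5, 1.0, 5, 9, 10.5, 11.9, 13)
  acg <- spike_autocorrelogram(sp, runs)
  expect_equal(acg$n_spikes, 4)
})

test_that("theta scoring localises the modulation frequency and tracks depth", {
  n <- 600 / 0.02
  t <- seq(0, by = 0.02, length.out = n)
  tr <- trajectory(t, 30 * cos(0.5 * t), 30 * sin(0.5 * t), rep(0, n))
  runs <- extract_runs(tr)
  f8 <- constant_rate_fn(8)
  score_at <- function(depth, seed) {
    sp <- generate_spikes(f8, tr, seed = seed,
                          theta = if (depth > 0) list(f0 = 8, depth = depth))
    theta_modulation_score(spike_autocorrelogram(sp, runs))
  }
  th <- score_at(0.8, 41)
  expect_gte(th$peak_freq, 7.5)
  expect_lte(th$peak_freq, 8.5)
  # score grows with modulation depth (averaged over seeds)
  mean_score <- function(depth) mean(vapply(1:10, function(s)
    score_at(depth, 50 + s)$score, numeric(1)))
  s0 <- mean_score(0); s4 <- mean_score(0.4); s8 <- mean_score(0.8)
  expect_gt(s4, s0)
  expect_gt(s8, s4)
  expect_gt(s8 / s0, 3)
})

test_that("the theta score is invariant to time translation", {
  sp <- with(list(), {
    set.seed(9)
    sort(runif(2000, 0, 300)) })
  # impose 8 Hz structure by jittering spikes toward theta phase peaks
  sp <- sp + 0.02 * sin(2 * pi * 8 * sp)
  sc1 <- theta_modulation_score(spike_autocorrelogram(sort(sp)))
  sc2 <- theta_modulation_score(spike_autocorrelogram(sort(sp + 123.456)))
  expect_equal(sc1$score, sc2$score, tolerance = 1e-9)
  expect_equal(sc1$peak_freq, sc2$peak_freq)
})
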