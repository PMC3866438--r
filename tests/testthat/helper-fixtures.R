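# Shared fixtures, memoised so expensive simulations run once per suite.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

circle_env <- function() fixture("circle", make_standard_environment("walled_circle"))
square_env <- function() fixture("square", make_standard_environment("walled_square"))

# Full-length foraging trajectory in the walled circle.
long_circle_traj <- function(seed = 11)
  fixture(paste0("traj1620_", seed),
          simulate_trajectory(circle_env(), duration = 1620, seed = seed))

# A complete simulated baseline session for a south-tuned short-range BVC.
bvc_baseline_session <- function() fixture("bvc_base", {
  env <- circle_env()
  pars <- bvc_params(d_pref = 8, phi_pref = -pi / 2)
  traj <- filter_positions(long_circle_traj())
  spikes <- generate_spikes(bvc_rate_fn(pars, env), traj, seed = 21)
  list(env = env, pars = pars, traj = traj, spikes = spikes,
       map = compute_rate_map(traj, spikes),
       polar = compute_polar_map(traj, spikes))
})

# Simulate one cell through baseline + barrier trials and classify it.
# type: "bvc", "hd" or "off".  Returns classification, boundary-off
# coverage, matched-bin stats and ground truth.
run_cell_session <- function(type, phi, seed, duration = 1620, d_pref = 8) {
  env <- circle_env()
  pars <- switch(type,
    bvc = bvc_params(d_pref = d_pref, phi_pref = phi),
    hd = hd_params(mu = phi),
    off = boundary_off_params(bvc = bvc_params(d_pref = d_pref,
                                               phi_pref = phi)))
  env_b <- insert_barrier(env, c(0, 0), phi + pi / 2)
  traj <- filter_positions(simulate_trajectory(env, duration, seed = seed))
  traj_b <- filter_positions(simulate_trajectory(env_b, duration,
                                                 seed = seed + 1))
  fn <- function(e) switch(type, bvc = bvc_rate_fn(pars, e),
                           hd = hd_rate_fn(pars),
                           off = boundary_off_rate_fn(pars, e))
  spikes <- generate_spikes(fn(env), traj, seed = seed + 2)
  spikes_b <- generate_spikes(fn(env_b), traj_b, seed = seed + 3)
  map <- compute_rate_map(traj, spikes)
  map_b <- compute_rate_map(traj_b, spikes_b, env = env_b)
  cls <- classify_bvc(map, map_b, env, env_b)
  off <- tryCatch(
    boundary_off_coverage(map, map_b, env_b, wrap_angle(phi + pi)),
    error = function(e) NULL)
  info <- matched_bin_stats(traj, spikes, env)
  list(type = type, phi = phi, params = pars, cls = cls, off = off,
       info = info, map = map, map_b = map_b, env = env, env_b = env_b,
       traj = traj, spikes = spikes)
}

wrap_angle <- bvctools:::wrap_angle

# ---- independent oracles ----------------------------------------------------

# Ray-segment / ray-circle first-hit distance, written independently of the
# package's vectorised implementation.
oracle_ray_distance <- function(env, p, theta) {
  u <- c(cos(theta), sin(theta))
  best <- Inf
  if (!is.null(env$arc)) {
    R <- env$arc$radius
    b <- sum(p * u)
    disc <- b^2 + R^2 - sum(p^2)
    if (disc >= 0) {
      for (t in c(-b - sqrt(disc), -b + sqrt(disc)))
        if (t > 1e-9) best <- min(best, t)
    }
  }
  segs <- env$segments
  for (k in seq_len(nrow(segs))) {
    a <- c(segs$x0[k], segs$y0[k]); d <- c(segs$x1[k], segs$y1[k]) - a
    den <- u[1] * d[2] - u[2] * d[1]
    if (abs(den) < 1e-14) next
    w <- a - p
    t <- (w[1] * d[2] - w[2] * d[1]) / den
    s <- (w[1] * u[2] - w[2] * u[1]) / den
    if (t > 1e-9 && s >= 0 && s <= 1) best <- min(best, t)
  }
  best
}

# Direct 5x5 renormalised boxcar over visited bins (double loop).
oracle_boxcar_rate <- function(counts, dwell, k = 2) {
  nr <- nrow(counts); nc <- ncol(counts)
  visited <- dwell > 0
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!visited[i, j]) next
    cs <- 0; ds <- 0
    for (ii in max(1, i - k):min(nr, i + k))
      for (jj in max(1, j - k):min(nc, j + k))
        if (visited[ii, jj]) { cs <- cs + counts[ii, jj]; ds <- ds + dwell[ii, jj] }
    out[i, j] <- cs / ds
  }
  out
}

# O(N^2) pairwise autocorrelogram.
oracle_acg <- function(spikes, window = 0.5, bin = 0.004) {
  n_bins <- round(window / bin)
  counts <- numeric(n_bins)
  for (i in seq_along(spikes)) for (j in seq_along(spikes)) {
    if (j <= i) next
    lag <- spikes[j] - spikes[i]
    if (lag > 0 && lag <= window) {
      idx <- ceiling(lag / bin)
      counts[idx] <- counts[idx] + 1
    }
  }
  counts
}

# Construct a bvc_ratemap object directly from matrices (synthetic map
# fixture; indices: rate[ix, iy], edges on multiples of bin_size).
make_test_map <- function(rate, bin_size = 3, x0 = NULL, y0 = NULL,
                          dwell = NULL, counts = NULL, smoothed = TRUE) {
  nx <- nrow(rate); ny <- ncol(rate)
  if (is.null(x0)) x0 <- -nx %/% 2
  if (is.null(y0)) y0 <- -ny %/% 2
  if (is.null(dwell)) dwell <- matrix(1, nx, ny)
  if (is.null(counts)) counts <- rate * dwell
  visited <- dwell > 0
  structure(list(
    bin_size = bin_size,
    xedges = (x0:(x0 + nx)) * bin_size,
    yedges = (y0:(y0 + ny)) * bin_size,
    dwell = dwell, counts = counts, rate = rate, visited = visited,
    smoothed = smoothed, smooth_mode = "counts_dwell",
    peak_rate = max(rate[visited], na.rm = TRUE),
    n_spikes = sum(counts), duration = sum(dwell)),
    class = "bvc_ratemap")
}
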