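#' Parameter sets for the generative firing models
#'
#' @description
#' `bvc_params()` parameterises a boundary vector cell: the cell responds
#' whenever a boundary lies near a preferred distance `d_pref` in a
#' preferred allocentric direction `phi_pref`, independently of the
#' animal's heading.  The radial tuning width grows linearly with the
#' preferred distance, `sigma_rad = sigma0 * (d_pref / beta + 1)`, so
#' distal fields are broader than proximal ones.
#'
#' `hd_params()` parameterises a head direction cell: a circular-Gaussian
#' (von Mises shaped) tuning curve over allocentric heading, independent
#' of location.
#'
#' `boundary_off_params()` parameterises a boundary-off cell: firing at a
#' uniform baseline everywhere except in the zone where the associated BVC
#' would fire, where it is suppressed.
#'
#' @param d_pref Preferred boundary distance, cm.
#' @param phi_pref Preferred allocentric direction, radians
#'   counter-clockwise from east.
#' @param sigma0 Radial tuning width at zero preferred distance, cm.
#' @param beta Distance-broadening constant, cm.
#' @param sigma_ang Angular tuning width, radians.
#' @param a_max Peak firing rate, Hz (the maximum of the rate surface over
#'   the environment).
#' @return A parameter list of class `bvc_params`, `hd_params` or
#'   `boundary_off_params`.
#' @export
bvc_params <- function(d_pref = 8, phi_pref = -pi / 2, sigma0 = 12,
                       beta = 180, sigma_ang = 0.2, a_max = 10) {
  stopifnot(d_pref >= 0, sigma0 > 0, beta > 0, sigma_ang > 0, a_max > 0)
  structure(list(d_pref = d_pref, phi_pref = phi_pref, sigma0 = sigma0,
                 beta = beta, sigma_ang = sigma_ang, a_max = a_max),
            class = "bvc_params")
}

#' @rdname bvc_params
#' @param mu Preferred heading, radians.
#' @param kappa Concentration of the heading tuning (larger = sharper).
#' @export
hd_params <- function(mu = 0, kappa = 4, a_max = 10) {
  stopifnot(kappa > 0, a_max > 0)
  structure(list(mu = mu, kappa = kappa, a_max = a_max),
            class = "hd_params")
}

#' @rdname bvc_params
#' @param baseline Baseline firing rate, Hz.
#' @param suppression Fractional suppression inside the BVC zone, in
#'   `[0, 1]`; 1 silences the cell at the BVC's rate maximum.
#' @param bvc The `bvc_params` of the suppressing boundary input.
#' @export
boundary_off_params <- function(baseline = 8, suppression = 1,
                                bvc = bvc_params()) {
  stopifnot(baseline > 0, suppression >= 0, suppression <= 1,
            inherits(bvc, "bvc_params"))
  structure(list(baseline = baseline, suppression = suppression, bvc = bvc),
            class = "boundary_off_params")
}

# ---- BVC rate surface -------------------------------------------------------

# Unnormalised BVC response at positions (x, y): the boundary-distance
# profile dist(theta) is sampled on `n_dirs` rays (1 degree steps by
# default) and weighted by Gaussian tuning in distance and in wrapped
# angular offset from phi_pref.
bvc_response <- function(params, env, x, y, n_dirs = 360) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  thetas <- (seq_len(n_dirs) - 0.5) * (2 * pi / n_dirs)
  sigma_rad <- params$sigma0 * (params$d_pref / params$beta + 1)
  ang_w <- exp(-ang_diff(thetas, params$phi_pref)^2 / (2 * params$sigma_ang^2))
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / n_dirs))
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    m <- length(idx)
    d <- ray_distances(env,
                       rep(x[idx], each = n_dirs),
                       rep(y[idx], each = n_dirs),
                       rep(thetas, times = m))
    g <- exp(-(d - params$d_pref)^2 / (2 * sigma_rad^2)) *
      rep(ang_w, times = m)
    g[!is.finite(d)] <- 0   # open directions contribute nothing
    out[idx] <- colSums(matrix(g, nrow = n_dirs))
  }
  out * (2 * pi / n_dirs)
}

.rate_cache <- new.env(parent = emptyenv())

env_signature <- function(env) {
  paste(env$name, env$floor$type,
        paste(unlist(env$floor[-1]), collapse = ","),
        if (is.null(env$arc)) "" else paste(env$arc$radius, env$arc$kind),
        paste(round(as.matrix(env$segments[, 1:4]), 6), collapse = ","),
        if (is.null(env$barrier)) "" else
          paste(round(unlist(env$barrier), 6), collapse = ","),
        sep = "|")
}

# Grid of floor-interior points used for normalisation and lookup tables.
floor_grid <- function(env, res = 2) {
  r <- floor_circumradius(env)
  gx <- seq(-r + res / 2, r - res / 2, by = res)
  pts <- expand.grid(x = gx, y = gx)
  keep <- point_in_floor(env, pts$x, pts$y)
  list(x = pts$x[keep], y = pts$y[keep], res = res, gx = gx, keep = keep)
}

# Environment-wide maximum of the unnormalised response (memoised).
bvc_norm_const <- function(params, env, res = 2) {
  key <- paste(paste(round(unlist(params), 8), collapse = ","),
               env_signature(env), res, sep = "#")
  if (!is.null(.rate_cache[[key]])) return(.rate_cache[[key]])
  g <- floor_grid(env, res)
  m <- max(bvc_response(params, env, g$x, g$y))
  .rate_cache[[key]] <- m
  m
}

#' Firing rate of a simulated boundary vector cell
#'
#' The BVC rate at a position integrates, over all allocentric directions,
#' a Gaussian in the boundary distance along each direction (centred on
#' the preferred distance, width increasing with preferred distance) times
#' a Gaussian in the wrapped angular offset from the preferred direction.
#' The surface is normalised so that its maximum over the environment
#' equals `a_max`; firing is independent of the animal's heading.
#'
#' @param params A [bvc_params()] object.
#' @param env A `bvc_environment`.
#' @param x,y Position coordinates, cm (vectorised).
#' @return Rate(s) in Hz.
#' @export
bvc_rate <- function(params, env, x, y) {
  stopifnot(inherits(params, "bvc_params"), inherits(env, "bvc_environment"))
  if (!all(point_in_floor(env, x, y)))
    stopf("some positions are outside the floor of '%s'", env$name)
  params$a_max * bvc_response(params, env, x, y) / bvc_norm_const(params, env)
}

#' Firing rate of a simulated head direction cell
#'
#' Circular-Gaussian tuning over allocentric heading:
#' `a_max * exp(kappa * (cos(hd - mu) - 1))`, maximal at `mu` and
#' independent of location.
#'
#' @param params An [hd_params()] object.
#' @param hd Head direction(s), radians.
#' @return Rate(s) in Hz.
#' @export
hd_rate <- function(params, hd) {
  stopifnot(inherits(params, "hd_params"))
  params$a_max * exp(params$kappa * (cos(hd - params$mu) - 1))
}

#' Firing rate of a simulated boundary-off cell
#'
#' A boundary-off cell fires at a uniform baseline everywhere except in
#' the zone where its associated BVC fires, where the rate is reduced in
#' proportion to the BVC's normalised rate:
#' `baseline * (1 - suppression * bvc_rate / a_max)`, floored at zero.
#'
#' @param params A [boundary_off_params()] object.
#' @inheritParams bvc_rate
#' @return Rate(s) in Hz.
#' @export
boundary_off_rate <- function(params, env, x, y) {
  stopifnot(inherits(params, "boundary_off_params"))
  rel <- bvc_rate(params$bvc, env, x, y) / params$bvc$a_max
  pmax(params$baseline * (1 - params$suppression * rel), 0)
}

# ---- rate-function factories ------------------------------------------------

#' Rate functions for spike generation
#'
#' @description
#' These factories return a vectorised rate function `f(x, y, hd)` (Hz)
#' suitable for [generate_spikes()].  `bvc_rate_fn()` and
#' `boundary_off_rate_fn()` pre-evaluate the rate surface on a fine grid
#' and look positions up by nearest grid node, so that spike generation
#' along a long trajectory does not re-integrate the boundary profile at
#' every sample.
#'
#' @param params Parameters of the matching class.
#' @param env A `bvc_environment`.
#' @param res Lookup grid resolution, cm.
#' @return A function `(x, y, hd) -> Hz`.
#' @export
bvc_rate_fn <- function(params, env, res = 2) {
  rate_lookup_fn(function(gx, gy) bvc_rate(params, env, gx, gy), env, res)
}

#' @rdname bvc_rate_fn
#' @export
boundary_off_rate_fn <- function(params, env, res = 2) {
  rate_lookup_fn(function(gx, gy) boundary_off_rate(params, env, gx, gy),
                 env, res)
}

#' @rdname bvc_rate_fn
#' @export
hd_rate_fn <- function(params) {
  force(params)
  function(x, y, hd) hd_rate(params, hd)
}

#' @rdname bvc_rate_fn
#' @param rate Constant rate, Hz.
#' @export
constant_rate_fn <- function(rate) {
  force(rate)
  function(x, y, hd) rep_len(rate, max(length(x), length(hd)))
}

rate_lookup_fn <- function(surface, env, res) {
  g <- floor_grid(env, res)
  nx <- length(g$gx)
  vals <- rep(0, nx * nx)
  vals[g$keep] <- surface(g$x, g$y)
  x0 <- g$gx[1]
  function(x, y, hd) {
    ix <- pmin(pmax(round((x - x0) / res), 0), nx - 1)
    iy <- pmin(pmax(round((y - x0) / res), 0), nx - 1)
    vals[iy * nx + ix + 1]
  }
}

# ---- trajectory simulation --------------------------------------------------

#' Construct a trajectory object
#'
#' Time-stamped head positions and head directions sampled at 50 Hz, the
#' common currency of every analysis stage.
#'
#' @param t Sample times, s (strictly increasing, nominally 0.02 s steps).
#' @param x,y Head position, cm.
#' @param hd Head direction, radians allocentric.
#' @return An object of class `bvc_trajectory`.
#' @export
trajectory <- function(t, x, y, hd) {
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, length(hd) == n, n >= 1)
  if (n > 1 && any(diff(t) <= 0))
    stopf("trajectory times must be strictly increasing")
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 hd = as.numeric(hd)), class = "bvc_trajectory")
}

#' @export
print.bvc_trajectory <- function(x, ...) {
  cat(sprintf("<bvc_trajectory> %d samples, %.1f s, x [%.1f, %.1f], y [%.1f, %.1f] cm\n",
              length(x$t), diff(range(x$t)) + TRACK_DT,
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Simulate a random-foraging trajectory
#'
#' Generates a smooth random walk at 50 Hz confined to the floor eroded by
#' `wall_clearance` (the head of a foraging animal stays several
#' centimetres from the wall).  Heading evolves by bounded Gaussian
#' angular increments; speed follows a positive autocorrelated process
#' around `speed_mean`; steps that would leave the eroded floor (or enter
#' a barrier footprint) steer the heading back toward the interior.
#' Deterministic given `seed`.
#'
#' @param env A `bvc_environment`.
#' @param duration Trial duration, s.  The default of 1620 s (27 min)
#'   matches the trial length assumed throughout the analyses.
#' @param seed Integer seed.
#' @param speed_mean Mean running speed, cm/s.
#' @param wall_clearance Minimum head distance from the perimeter, cm.
#' @param barrier_clearance Minimum head distance from an inserted
#'   barrier, cm.  Zero by default: animals investigate a free-standing
#'   barrier closely and the tracked head position can reach its faces,
#'   which gives the bins directly abutting the barrier the dwell the
#'   field-repetition criterion relies on.
#' @param turn_sd Heading diffusion, rad per sqrt(s).
#' @return A `bvc_trajectory` with `duration * 50` samples.
#' @export
simulate_trajectory <- function(env, duration = 1620, seed = 1,
                                speed_mean = 18, wall_clearance = 5,
                                barrier_clearance = 0, turn_sd = 1.2) {
  stopifnot(inherits(env, "bvc_environment"), duration > 0)
  if (wall_clearance < 0 || wall_clearance >= floor_inradius(env))
    stopf("wall_clearance must be in [0, floor inradius)")
  n <- round(duration / TRACK_DT)
  dt <- TRACK_DT
  with_seed(seed, {
    turn <- rnorm(n, 0, turn_sd * sqrt(dt))
    spd_z <- rnorm(n, 0, 1)
    hd_jit <- rnorm(n, 0, 0.15)
    x <- numeric(n); y <- numeric(n); h <- numeric(n); s <- numeric(n)
    h[1] <- runif(1, -pi, pi)
    s[1] <- speed_mean
    # start at a random interior point
    repeat {
      p <- runif(2, -floor_circumradius(env), floor_circumradius(env))
      if (point_in_floor(env, p[1], p[2], wall_clearance, barrier_clearance)) break
    }
    x[1] <- p[1]; y[1] <- p[2]
    tau_s <- 1; sd_s <- 0.45 * speed_mean
    for (i in 2:n) {
      h[i] <- h[i - 1] + turn[i]
      s[i] <- abs(s[i - 1] + (speed_mean - s[i - 1]) * dt / tau_s +
                    sd_s * sqrt(dt) * spd_z[i])
      px <- x[i - 1] + s[i] * dt * cos(h[i])
      py <- y[i - 1] + s[i] * dt * sin(h[i])
      if (!point_in_floor(env, px, py, wall_clearance, barrier_clearance)) {
        # steer away from the blocked direction in growing increments,
        # preferring the side the current turn already favours; small
        # deflections first, which makes the animal skirt along walls and
        # barriers rather than bounce off them
        sgn <- if (turn[i] >= 0) 1 else -1
        moved <- FALSE
        for (dth in sgn * c(1, -1, 2, -2, 3, -3, 4, -4, 5, -5, 6) * (pi / 6)) {
          hh <- h[i] + dth
          qx <- x[i - 1] + s[i] * dt * cos(hh)
          qy <- y[i - 1] + s[i] * dt * sin(hh)
          if (point_in_floor(env, qx, qy, wall_clearance, barrier_clearance)) {
            h[i] <- hh; px <- qx; py <- qy; moved <- TRUE
            break
          }
        }
        if (!moved) { px <- x[i - 1]; py <- y[i - 1] }
      }
      x[i] <- px; y[i] <- py
    }
    trajectory(t = (seq_len(n) - 1) * dt, x = x, y = y,
               hd = wrap_angle(h + hd_jit))
  })
}

# ---- spike generation -------------------------------------------------------

#' Generate an inhomogeneous-Poisson spike train along a trajectory
#'
#' Spikes are generated by thinning: candidate spikes are drawn from a
#' homogeneous Poisson process at the trajectory-wide maximum rate and
#' kept with probability `rate(t) / rate_max`, where the rate at a
#' candidate time is the rate function evaluated at the temporally nearest
#' position sample.  With `theta` supplied the rate is multiplied by
#' `1 + depth * cos(2 * pi * f0 * t)`, evaluated in continuous time, so
#' theta rhythmicity is not quantised to the 20 ms tracking interval.
#' Deterministic given `seed`.
#'
#' @param rate_fn A vectorised function `(x, y, hd) -> Hz` (see
#'   [bvc_rate_fn()] and friends).
#' @param traj A `bvc_trajectory`.
#' @param seed Integer seed.
#' @param theta Optional list `list(f0 = Hz, depth = 0..1)` for theta
#'   modulation of the rate.
#' @return Sorted numeric vector of spike times, s.
#' @export
generate_spikes <- function(rate_fn, traj, seed = 1, theta = NULL) {
  stopifnot(inherits(traj, "bvc_trajectory"))
  lam <- rate_fn(traj$x, traj$y, traj$hd)
  if (any(lam < 0)) stopf("rate function returned negative rates")
  depth <- 0; f0 <- 0
  if (!is.null(theta)) {
    depth <- theta$depth; f0 <- theta$f0
    stopifnot(depth >= 0, depth <= 1, f0 > 0)
  }
  t0 <- traj$t[1]
  t1 <- traj$t[length(traj$t)] + TRACK_DT
  lam_max <- max(lam) * (1 + depth)
  if (lam_max == 0) return(numeric(0))
  with_seed(seed, {
    n_cand <- rpois(1, lam_max * (t1 - t0))
    if (n_cand == 0) return(numeric(0))
    tc <- sort(runif(n_cand, t0, t1))
    idx <- pmin(pmax(round((tc - t0) / TRACK_DT) + 1, 1), length(traj$t))
    rate_t <- lam[idx] * (1 + depth * cos(2 * pi * f0 * tc))
    tc[runif(n_cand) < rate_t / lam_max]
  })
}
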