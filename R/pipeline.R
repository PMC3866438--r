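#' Simulate and write a complete synthetic recording session
#'
#' Generates a baseline trajectory, and for every cell an
#' appropriately-oriented barrier trial (barrier perpendicular to the
#' cell's preferred direction, as in the experimental protocol), spike
#' trains for both trials, and a JSON manifest tying the files together
#' with the ground-truth generator parameters and all seeds.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; every per-cell seed derives from it.
#' @param env_name Baseline environment name (see
#'   [make_standard_environment()]).
#' @param n_bvc,n_hd,n_off Numbers of simulated BVC, head direction and
#'   boundary-off cells.
#' @param duration Trial duration, s.
#' @return The manifest (invisibly), also written to
#'   `file.path(dir, "manifest.json")`.
#' @export
simulate_session <- function(dir, seed = 1, env_name = "walled_circle",
                             n_bvc = 3, n_hd = 1, n_off = 0,
                             duration = 1620) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  env <- make_standard_environment(env_name)
  base_traj <- simulate_trajectory(env, duration = duration, seed = seed)
  traj_path <- "baseline_trajectory.tsv"
  write_trajectory(base_traj, file.path(dir, traj_path))
  cells <- list()
  types <- c(rep("bvc", n_bvc), rep("hd", n_hd), rep("boundary_off", n_off))
  phis <- with_seed(seed + 7919L, stats::runif(length(types), -pi, pi))
  for (k in seq_along(types)) {
    type <- types[k]
    cseed <- (seed + 1000L * k) %% .Machine$integer.max
    id <- sprintf("%s_%02d", type, k)
    phi <- phis[k]
    pars <- switch(type,
      bvc = bvc_params(d_pref = 8, phi_pref = phi),
      hd = hd_params(mu = phi),
      boundary_off = boundary_off_params(bvc = bvc_params(d_pref = 8,
                                                          phi_pref = phi)))
    rate_base <- switch(type,
      bvc = bvc_rate_fn(pars, env),
      hd = hd_rate_fn(pars),
      boundary_off = boundary_off_rate_fn(pars, env))
    # barrier trial: barrier at the centre, long axis perpendicular to the
    # (simulated experimenter's) presumed preferred direction
    orient <- wrap_angle(phi + pi / 2)
    env_b <- insert_barrier(env, centre = c(0, 0), orientation = orient)
    traj_b <- simulate_trajectory(env_b, duration = duration,
                                  seed = cseed + 1L)
    rate_b <- switch(type,
      bvc = bvc_rate_fn(pars, env_b),
      hd = hd_rate_fn(pars),
      boundary_off = boundary_off_rate_fn(pars, env_b))
    f_base <- sprintf("%s_baseline_spikes.txt", id)
    f_btraj <- sprintf("%s_barrier_trajectory.tsv", id)
    f_bspk <- sprintf("%s_barrier_spikes.txt", id)
    write_spikes(generate_spikes(rate_base, base_traj, seed = cseed + 2L),
                 file.path(dir, f_base))
    write_trajectory(traj_b, file.path(dir, f_btraj))
    write_spikes(generate_spikes(rate_b, traj_b, seed = cseed + 3L),
                 file.path(dir, f_bspk))
    cells[[k]] <- list(
      id = id, type = type, params = unclass(pars), seed = cseed,
      baseline_spikes = f_base,
      barrier = list(centre = c(0, 0), orientation = orient),
      barrier_trajectory = f_btraj, barrier_spikes = f_bspk)
  }
  manifest <- list(environment = env_name, seed = seed, duration = duration,
                   baseline_trajectory = traj_path, cells = cells)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a session manifest
#'
#' @param path Path to a `manifest.json` written by [simulate_session()]
#'   (or hand-authored in the same schema).
#' @return The manifest as a nested list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

cell_params_from_manifest <- function(cell) {
  p <- cell$params
  switch(cell$type,
    bvc = bvc_params(p$d_pref, p$phi_pref, p$sigma0, p$beta, p$sigma_ang,
                     p$a_max),
    hd = hd_params(p$mu, p$kappa, p$a_max),
    boundary_off = boundary_off_params(p$baseline, p$suppression,
      bvc_params(p$bvc$d_pref, p$bvc$phi_pref, p$bvc$sigma0, p$bvc$beta,
                 p$bvc$sigma_ang, p$bvc$a_max)))
}

#' Run the full analysis pipeline over a session
#'
#' For every cell in the manifest: speed-filters the trajectories, builds
#' the baseline and barrier rate maps and the polar map, runs the
#' field-repetition classification, the matched-bin information
#' statistics, the temporal statistics (global mean rate and theta
#' score), and windowed rate maps for the trial thirds.  A failure in any
#' cell is recorded as an error entry and the run continues.  Finally, if
#' the session environment is circular, a Monte Carlo null for the mean
#' field-peak distance of the session's eligible cells is computed.
#'
#' @param manifest A manifest list (see [read_manifest()]) or a path to
#'   `manifest.json`.
#' @param dir Directory the manifest's relative paths resolve against;
#'   defaults to the manifest file's directory when `manifest` is a path.
#' @param config Named list of overrides: `bin_size`, `rate_frac`,
#'   `cover_frac`, `mc_reps`, `mc_R`, `mc_seed`.
#' @return An object of class `bvc_report`: per-cell result entries plus
#'   session-level Monte Carlo summary.
#' @export
run_pipeline <- function(manifest, dir = ".", config = list()) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  cfg <- utils::modifyList(list(bin_size = 3, rate_frac = 0.4,
                                cover_frac = 0.5, mc_reps = 1e5,
                                mc_R = NULL, mc_seed = 1), config)
  env <- make_standard_environment(manifest$environment)
  base_traj <- filter_positions(
    read_trajectory(file.path(dir, manifest$baseline_trajectory)))
  cells <- list()
  peak_dists <- numeric(0)
  for (cell in manifest$cells) {
    res <- tryCatch({
      spikes_b <- read_spikes(file.path(dir, cell$baseline_spikes))
      env_b <- insert_barrier(env,
                              centre = unlist(cell$barrier$centre),
                              orientation = cell$barrier$orientation)
      traj_b <- filter_positions(
        read_trajectory(file.path(dir, cell$barrier_trajectory)))
      spikes_bar <- read_spikes(file.path(dir, cell$barrier_spikes))
      map_base <- compute_rate_map(base_traj, spikes_b,
                                   bin_size = cfg$bin_size)
      map_bar <- compute_rate_map(traj_b, spikes_bar,
                                  bin_size = cfg$bin_size, env = env_b)
      polar <- compute_polar_map(base_traj, spikes_b)
      cls <- classify_bvc(map_base, map_bar, env, env_b,
                          rate_frac = cfg$rate_frac,
                          cover_frac = cfg$cover_frac)
      info <- matched_bin_stats(base_traj, spikes_b, env)
      dur <- length(base_traj$t) * TRACK_DT
      gmr <- global_mean_rate(spikes_b, dur)
      runs <- extract_runs(base_traj)
      theta <- tryCatch({
        acg <- spike_autocorrelogram(spikes_b, runs)
        theta_modulation_score(acg)
      }, error = function(e) NULL)
      thirds <- lapply(0:2, function(k)
        windowed_rate_map(base_traj, spikes_b, k * dur / 3,
                          (k + 1) * dur / 3, bin_size = cfg$bin_size))
      if (cls$eligible && env$floor$type == "disk")
        peak_dists <- c(peak_dists, cls$peak$dist_centre)
      list(id = cell$id, type = cell$type, error = NULL,
           eligible = cls$eligible, is_bvc = cls$is_bvc,
           reason = cls$reason,
           predicted_side = if (!is.null(cls$predicted)) cls$predicted$label,
           coverage_pct = if (!is.null(cls$coverage)) cls$coverage$coverage,
           peak_rate_hz = map_base$peak_rate,
           peak_position_cm = if (!is.null(cls$peak)) cls$peak$position,
           peak_dist_centre_cm = if (!is.null(cls$peak)) cls$peak$dist_centre,
           directional_peak_rate_hz = polar$peak_rate,
           loc_info_bits_s = info$loc_info, dir_info_bits_s = info$dir_info,
           loc_selectivity = info$loc_selectivity,
           dir_selectivity = info$dir_selectivity,
           global_mean_rate_hz = gmr,
           theta_peak_hz = if (!is.null(theta)) theta$peak_freq,
           theta_score = if (!is.null(theta)) theta$score,
           window_peak_rates_hz = vapply(thirds, function(m) m$peak_rate,
                                         numeric(1)))
    }, error = function(e) list(id = cell$id, type = cell$type,
                                error = conditionMessage(e)))
    cells[[length(cells) + 1]] <- res
  }
  mc <- NULL
  if (length(peak_dists) >= 2 && env$floor$type == "disk") {
    R <- if (is.null(cfg$mc_R)) env$floor$radius else cfg$mc_R
    null <- mc_field_peak_null(n = length(peak_dists), R = R,
                               seed = cfg$mc_seed, reps = cfg$mc_reps)
    obs <- mean(peak_dists)
    mc <- list(n = length(peak_dists), R = R, reps = null$reps,
               observed_mean_cm = obs, null_mean_cm = null$null_mean,
               null_median_cm = null$null_median,
               null_p95_cm = null$null_p95,
               percentile = percentile_of(null, obs))
  }
  structure(list(environment = manifest$environment,
                 n_cells = length(cells), cells = cells,
                 monte_carlo = mc, config = cfg),
            class = "bvc_report")
}

#' @export
print.bvc_report <- function(x, ...) {
  cat(sprintf("<bvc_report> %s, %d cells\n", x$environment, x$n_cells))
  for (cl in x$cells) {
    if (!is.null(cl$error))
      cat(sprintf("  %s [%s]: ERROR %s\n", cl$id, cl$type, cl$error))
    else
      cat(sprintf("  %s [%s]: %s%s\n", cl$id, cl$type,
                  if (isTRUE(cl$is_bvc)) "BVC" else "not BVC",
                  sprintf(" (%s)", cl$reason)))
  }
  if (!is.null(x$monte_carlo))
    cat(sprintf(
      "  mean peak distance %.2f cm; %.1fth percentile of null (n = %d, R = %.0f cm)\n",
      x$monte_carlo$observed_mean_cm, x$monte_carlo$percentile,
      x$monte_carlo$n, x$monte_carlo$R))
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report A `bvc_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
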