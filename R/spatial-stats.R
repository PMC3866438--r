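#' Locational or directional selectivity
#'
#' Peak firing rate of a map divided by the cell's global mean rate.
#'
#' @param map A `bvc_ratemap` or `bvc_polarmap`.
#' @param global_mean_rate Global mean rate, Hz (spike count / trial
#'   length; see [global_mean_rate()]).
#' @return Dimensionless selectivity (>= 1 whenever the cell fired).
#' @export
selectivity <- function(map, global_mean_rate) {
  if (!is.numeric(global_mean_rate) || global_mean_rate <= 0)
    stopf("global mean rate must be positive")
  map$peak_rate / global_mean_rate
}

#' Skaggs spatial information rate
#'
#' `I = sum_i p_i * lambda_i * log2(lambda_i / lambda_bar)` in bits per
#' second, where `p_i` is the occupancy probability of visited bin `i`,
#' `lambda_i` its firing rate and `lambda_bar = sum_i p_i * lambda_i` the
#' occupancy-weighted mean rate; `0 * log 0 = 0`.
#'
#' @param map A `bvc_ratemap` or `bvc_polarmap` (typically unsmoothed for
#'   corrected comparisons).
#' @return Information rate, bits/s (>= 0).
#' @export
information_rate <- function(map) {
  dwell <- as.numeric(map$dwell)
  rate <- as.numeric(map$rate)
  keep <- dwell > 0 & !is.na(rate)
  p <- dwell[keep] / sum(dwell[keep])
  lam <- rate[keep]
  lbar <- sum(p * lam)
  if (lbar <= 0) return(0)
  terms <- p * lam * log2(lam / lbar)
  terms[lam == 0] <- 0
  max(sum(terms), 0)
}

#' Matched-bin locational vs directional statistics
#'
#' Compares locational and directional signalling while correcting for
#' the bin-number dependence of information measures: the locational map
#' is rebuilt unsmoothed at a coarse bin size chosen so that the number
#' of visited locational bins is close to the 60 directional bins, and
#' the polar map is used unsmoothed.  Default coarse bin sizes follow the
#' standard environments (18.5 cm in the 150 cm circle, 14 cm in the
#' 100 cm square); for other floors the bin size is searched so the
#' visited-bin count is nearest 60.
#'
#' @param traj A speed-filtered `bvc_trajectory`.
#' @param spikes Spike times, s.
#' @param env The `bvc_environment` (used to pick the coarse bin size).
#' @param loc_bin Optional explicit coarse locational bin size, cm.
#' @return An object of class `bvc_infostats`: locational and directional
#'   information rates (bits/s) and selectivities, the bin sizes used,
#'   and the visited locational bin count.
#' @export
matched_bin_stats <- function(traj, spikes, env, loc_bin = NULL) {
  stopifnot(inherits(traj, "bvc_trajectory"))
  if (is.null(loc_bin)) {
    loc_bin <- if (env$floor$type == "disk" &&
                   isTRUE(all.equal(env$floor$radius, 75))) 18.5
    else if (env$floor$type == "rect" && env$floor$hx == 50 &&
             env$floor$hy == 50) 14
    else {
      cand <- seq(5, floor_inradius(env), by = 0.5)
      counts <- vapply(cand, function(b)
        sum(compute_rate_map(traj, numeric(0), bin_size = b,
                             smooth = FALSE)$visited), numeric(1))
      cand[which.min(abs(counts - 60))]
    }
  }
  loc <- compute_rate_map(traj, spikes, bin_size = loc_bin, smooth = FALSE)
  dir <- compute_polar_map(traj, spikes, smooth = FALSE)
  n_vis <- sum(loc$visited)
  if (n_vis < 10)
    stopf("only %d visited locational bins; too few for matched-bin stats", n_vis)
  gmr <- length(spikes) / (length(traj$t) * TRACK_DT)
  structure(list(
    loc_info = information_rate(loc),
    dir_info = information_rate(dir),
    loc_selectivity = if (gmr > 0) selectivity(loc, gmr) else NA_real_,
    dir_selectivity = if (gmr > 0) selectivity(dir, gmr) else NA_real_,
    loc_bin_cm = loc_bin, dir_bin_deg = 360 / dir$n_bins,
    n_loc_bins = n_vis, n_dir_bins = dir$n_bins,
    global_mean_rate = gmr, corrected = TRUE), class = "bvc_infostats")
}

#' @export
print.bvc_infostats <- function(x, ...) {
  cat(sprintf(
    "<bvc_infostats> corrected information: locational %.3f, directional %.3f bits/s\n",
    x$loc_info, x$dir_info))
  cat(sprintf("  bins: %d locational (%.1f cm), %d directional (%.0f deg)\n",
              x$n_loc_bins, x$loc_bin_cm, x$n_dir_bins, x$dir_bin_deg))
  invisible(x)
}

#' Monte Carlo null for the mean field-peak distance from the centre
#'
#' Null hypothesis: the `n` field peaks are uniformly distributed over the
#' disk of radius `R`.  Each replicate draws `n` points uniformly in the
#' disk (radius by inverse CDF, `r = R * sqrt(u)`, exact and
#' rejection-free) and records the mean distance to the centre;
#' `reps` replicates (default 10^6) form the null population.
#' Convergence is checked by requiring that the mean, median and 95th
#' percentile move by less than one unit in the `tol`-th decimal place
#' between the first half of the replicates and the full sample.
#'
#' @param n Number of field peaks per replicate.
#' @param R Disk radius, cm.  For the unwalled circular platform the
#'   behaviourally defined radius is 81 cm.
#' @param seed Integer seed.
#' @param reps Number of replicates.
#' @param tol Decimal places for the convergence check.
#' @return An object of class `bvc_mc_null`: the sorted null sample and
#'   its mean, median and 95th percentile, plus a `converged` flag.
#' @export
mc_field_peak_null <- function(n = 15, R = 81, seed = 1, reps = 1e6,
                               tol = 2) {
  stopifnot(n >= 1, R > 0, reps >= 2)
  reps <- as.integer(reps)
  means <- with_seed(seed, {
    out <- numeric(reps)
    chunk <- max(1L, min(reps, as.integer(2e6 / n)))
    done <- 0L
    while (done < reps) {
      m <- min(chunk, reps - done)
      r <- R * sqrt(matrix(runif(m * n), nrow = n))
      out[done + seq_len(m)] <- colMeans(r)
      done <- done + m
    }
    out
  })
  stat <- function(v) c(mean = mean(v), median = stats::median(v),
                        p95 = unname(stats::quantile(v, 0.95)))
  full <- stat(means)
  half <- stat(means[seq_len(reps %/% 2L)])
  converged <- all(abs(full - half) < 10^(-tol))
  structure(list(n = n, R = R, reps = reps, seed = seed,
                 null = sort(means),
                 null_mean = full[["mean"]], null_median = full[["median"]],
                 null_p95 = full[["p95"]], converged = converged, tol = tol),
            class = "bvc_mc_null")
}

#' @export
print.bvc_mc_null <- function(x, ...) {
  cat(sprintf(
    "<bvc_mc_null> n = %d peaks in disk R = %.1f cm, %d replicates%s\n",
    x$n, x$R, x$reps, if (x$converged) " (converged)" else " (NOT converged)"))
  cat(sprintf("  null mean %.2f, median %.2f, 95th pct %.2f cm\n",
              x$null_mean, x$null_median, x$null_p95))
  invisible(x)
}

#' Percentile of an observed mean peak distance within the null
#'
#' `100 *` fraction of null replicates strictly below the observed value.
#'
#' @param null A `bvc_mc_null`.
#' @param observed Observed mean distance to centre, cm.
#' @return Percentile in `[0, 100]`.
#' @export
percentile_of <- function(null, observed) {
  stopifnot(inherits(null, "bvc_mc_null"))
  100 * sum(null$null < observed) / length(null$null)
}
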