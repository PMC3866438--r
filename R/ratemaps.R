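#' Instantaneous speed along a trajectory
#'
#' Centred-difference speed at each sample (one-sided at the ends), cm/s.
#'
#' @param traj A `bvc_trajectory`.
#' @return Numeric vector of speeds, cm/s.
#' @export
instantaneous_speed <- function(traj) {
  n <- length(traj$t)
  if (n < 2) return(rep(0, n))
  lo <- c(1, 1:(n - 1)); hi <- c(2:n, n)
  sqrt((traj$x[hi] - traj$x[lo])^2 + (traj$y[hi] - traj$y[lo])^2) /
    (traj$t[hi] - traj$t[lo])
}

#' Discard implausibly fast position samples
#'
#' Samples faster than `max_speed` (default 200 cm/s, i.e. 2 m/s) are
#' removed: such jumps come from tracking artefacts (head flicks, light
#' reflections) rather than locomotion.  A sample's speed is taken as the
#' *smaller* of its two adjacent-interval speeds, so an isolated
#' teleported sample flags itself (it is far from both neighbours) while
#' its well-tracked neighbours survive; a genuinely fast stretch exceeds
#' the cut-off on every interval and is removed whole.
#'
#' @param traj A `bvc_trajectory` with at least 2 samples.
#' @param max_speed Speed cut-off, cm/s.
#' @return The filtered `bvc_trajectory`.
#' @export
filter_positions <- function(traj, max_speed = 200) {
  stopifnot(inherits(traj, "bvc_trajectory"), length(traj$t) >= 2)
  n <- length(traj$t)
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) / diff(traj$t)
  v <- pmin(c(step[1], step), c(step, step[n - 1]))
  keep <- v <= max_speed
  trajectory(traj$t[keep], traj$x[keep], traj$y[keep], traj$hd[keep])
}

# Index of the temporally nearest trajectory sample for each spike.
nearest_sample <- function(spike_t, traj_t) {
  i <- findInterval(spike_t, traj_t)
  i[i < 1] <- 1
  n <- length(traj_t)
  up <- i < n & (spike_t - traj_t[i]) > (traj_t[pmin(i + 1, n)] - spike_t)
  i[up] <- i[up] + 1
  i
}

# Moving-window sum of a matrix with an all-ones (2k+1) x (2k+1) kernel,
# zero padding outside the matrix.
boxcar_sum <- function(m, k = 2) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (dx in -k:k) {
    rs <- max(1, 1 + dx):min(nr, nr + dx)
    rd <- max(1, 1 - dx):min(nr, nr - dx)
    for (dy in -k:k)
      out[rd, max(1, 1 - dy):min(nc, nc - dy)] <-
        out[rd, max(1, 1 - dy):min(nc, nc - dy)] +
        m[rs, max(1, 1 + dy):min(nc, nc + dy)]
  }
  out
}

# Recompute smoothed rates for bins whose 5 x 5 window overlaps the
# barrier, excluding window members on the far side of the barrier (the
# straight line between the two bin centres crosses the footprint).
barrier_aware_rates <- function(rate, counts, dwell, visited, smooth_mode,
                                env, bin_size, xedges, yedges, k = 2) {
  b <- env$barrier
  u <- c(cos(b$orientation), sin(b$orientation))
  cx <- (xedges[-length(xedges)] + xedges[-1]) / 2
  cy <- (yedges[-length(yedges)] + yedges[-1]) / 2
  nr <- length(cx); nc <- length(cy)
  # local barrier frame; a centre-to-centre segment crosses the footprint
  # iff it intersects the axis-aligned rectangle in this frame
  to_local <- function(px, py) {
    dx <- px - b$centre[1]; dy <- py - b$centre[2]
    cbind(dx * u[1] + dy * u[2], -dx * u[2] + dy * u[1])
  }
  reach <- k * bin_size + sqrt(2) * bin_size
  # shrink the footprint infinitesimally so a bin centre lying exactly on
  # a face is treated as being on that side, not inside the barrier
  hl <- b$length / 2 - 1e-6; ht <- b$thickness / 2 - 1e-6
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!visited[i, j]) next
      p <- to_local(cx[i], cy[j])
      if (abs(p[1]) > hl + reach || abs(p[2]) > ht + reach) next
      is <- max(1, i - k):min(nr, i + k)
      js <- max(1, j - k):min(nc, j + k)
      cs <- 0; ds <- 0; rs <- 0; nv <- 0L
      for (ii in is) for (jj in js) {
        if (!visited[ii, jj]) next
        q <- to_local(cx[ii], cy[jj])
        if (bin_touches_segment(-hl, hl, -ht, ht, p, q)) next
        nv <- nv + 1L
        cs <- cs + counts[ii, jj]; ds <- ds + dwell[ii, jj]
        rs <- rs + counts[ii, jj] / dwell[ii, jj]
      }
      rate[i, j] <- if (nv == 0L) NA_real_
      else if (smooth_mode == "counts_dwell") {
        if (ds > 0) cs / ds else NA_real_
      } else rs / nv
    }
  }
  rate
}

#' Locational firing rate map
#'
#' Bins the floor into square bins (default 3 cm, the resolution of the
#' standard maps), accumulates dwell time and spike counts, and divides to
#' obtain rates on visited bins.  Spikes are assigned to the bin of the
#' temporally nearest position sample.  With `smooth = TRUE` a 5 x 5 bin
#' boxcar is applied before the division; by default counts and dwell are
#' smoothed separately (numerically stable at low occupancy), with
#' `smooth_mode = "rate"` the ratio itself is smoothed instead.  In both
#' cases the kernel is renormalised over the visited bins inside the
#' window, so rates at the map border are not diluted by unvisited bins.
#'
#' The bin grid is anchored so that bin edges fall on integer multiples of
#' `bin_size` from the environment origin (the origin is always at a bin
#' corner).
#'
#' When `env` carries an inserted barrier, smoothing is additionally
#' barrier-aware: a neighbouring bin is excluded from the window whenever
#' the straight line between the two bin centres crosses the barrier
#' footprint.  The animal cannot cross the barrier and boundary-driven
#' firing differs sharply on its two sides, so pooling across it would
#' dilute the rate in exactly the peri-barrier bins the field-repetition
#' criterion inspects - the same rationale as the renormalisation at the
#' perimeter.
#'
#' @param traj A (speed-filtered) `bvc_trajectory`.
#' @param spikes Sorted numeric vector of spike times, s.
#' @param bin_size Bin side, cm.
#' @param smooth Apply the 5 x 5 boxcar?
#' @param smooth_mode `"counts_dwell"` (default) or `"rate"`.
#' @param env Optional `bvc_environment`; supply the barrier-trial
#'   environment so smoothing does not pool across the barrier.
#' @return An object of class `bvc_ratemap`: bin edges, raw `dwell` (s),
#'   raw `counts`, `rate` (Hz, `NA` on unvisited bins), `visited` mask,
#'   `peak_rate` and bookkeeping fields.
#' @export
compute_rate_map <- function(traj, spikes, bin_size = 3, smooth = TRUE,
                             smooth_mode = c("counts_dwell", "rate"),
                             env = NULL) {
  stopifnot(inherits(traj, "bvc_trajectory"))
  smooth_mode <- match.arg(smooth_mode)
  if (length(traj$t) == 0) stopf("empty trajectory")
  spikes <- as.numeric(spikes)
  ix <- floor(traj$x / bin_size)
  iy <- floor(traj$y / bin_size)
  x0 <- min(ix); x1 <- max(ix); y0 <- min(iy); y1 <- max(iy)
  nx <- x1 - x0 + 1L; ny <- y1 - y0 + 1L
  flat <- (ix - x0) + nx * (iy - y0) + 1L
  dwell <- matrix(tabulate(flat, nbins = nx * ny) * TRACK_DT, nx, ny)
  counts <- matrix(0, nx, ny)
  if (length(spikes)) {
    si <- nearest_sample(spikes, traj$t)
    counts <- matrix(tabulate(flat[si], nbins = nx * ny), nx, ny)
  }
  visited <- dwell > 0
  if (smooth) {
    v <- boxcar_sum(visited * 1)
    if (smooth_mode == "counts_dwell") {
      counts_sm <- boxcar_sum(counts) / pmax(v, 1)
      dwell_sm <- boxcar_sum(dwell) / pmax(v, 1)
      rate <- ifelse(visited & dwell_sm > 0, counts_sm / dwell_sm, NA_real_)
    } else {
      raw <- ifelse(visited, counts / dwell, 0)
      rate <- ifelse(visited, boxcar_sum(raw) / pmax(v, 1), NA_real_)
    }
    if (!is.null(env) && !is.null(env$barrier))
      rate <- barrier_aware_rates(rate, counts, dwell, visited, smooth_mode,
                                  env, bin_size,
                                  (x0:(x1 + 1L)) * bin_size,
                                  (y0:(y1 + 1L)) * bin_size)
  } else {
    rate <- ifelse(visited, counts / dwell, NA_real_)
  }
  structure(list(
    bin_size = bin_size,
    xedges = (x0:(x1 + 1L)) * bin_size,
    yedges = (y0:(y1 + 1L)) * bin_size,
    dwell = dwell, counts = counts, rate = rate, visited = visited,
    smoothed = smooth, smooth_mode = if (smooth) smooth_mode else NA_character_,
    peak_rate = if (any(visited)) max(rate[visited], na.rm = TRUE) else 0,
    n_spikes = length(spikes),
    duration = length(traj$t) * TRACK_DT), class = "bvc_ratemap")
}

#' @export
print.bvc_ratemap <- function(x, ...) {
  cat(sprintf(
    "<bvc_ratemap> %.3g cm bins, %d x %d grid, %d visited, peak %.2f Hz%s\n",
    x$bin_size, nrow(x$rate), ncol(x$rate), sum(x$visited), x$peak_rate,
    if (x$smoothed) " (smoothed)" else " (unsmoothed)"))
  invisible(x)
}

# Bin-centre coordinates of a rate map as an (nx*ny) x 2 matrix (column-major
# over the rate matrix).
ratemap_bin_centres <- function(map) {
  cx <- (map$xedges[-length(map$xedges)] + map$xedges[-1]) / 2
  cy <- (map$yedges[-length(map$yedges)] + map$yedges[-1]) / 2
  cbind(rep(cx, times = length(cy)), rep(cy, each = length(cx)))
}

#' Directional firing polar map
#'
#' Bins head direction into 6 degree bins (60 bins tiling the circle),
#' accumulates dwell and spike counts, and smooths each bin with the two
#' bins on either side (a circular 5-bin boxcar over counts and dwell
#' separately) before dividing.
#'
#' @inheritParams compute_rate_map
#' @param n_bins Number of directional bins.
#' @param smooth Apply the circular 5-bin boxcar?
#' @return An object of class `bvc_polarmap` with bin centres (radians in
#'   `[0, 2pi)`), `dwell`, `counts`, `rate` and `peak_rate`.
#' @export
compute_polar_map <- function(traj, spikes, n_bins = 60, smooth = TRUE) {
  stopifnot(inherits(traj, "bvc_trajectory"))
  if (length(traj$t) == 0) stopf("empty trajectory")
  spikes <- as.numeric(spikes)
  width <- 2 * pi / n_bins
  bin_of <- function(a) floor((a %% (2 * pi)) / width) %% n_bins + 1L
  dwell <- tabulate(bin_of(traj$hd), nbins = n_bins) * TRACK_DT
  counts <- rep(0, n_bins)
  if (length(spikes)) {
    si <- nearest_sample(spikes, traj$t)
    counts <- tabulate(bin_of(traj$hd[si]), nbins = n_bins)
  }
  visited <- dwell > 0
  if (smooth) {
    circ_box <- function(v) {
      out <- v
      for (d in c(-2, -1, 1, 2)) out <- out + v[(seq_along(v) - 1 + d) %% n_bins + 1]
      out
    }
    vis_n <- circ_box(visited * 1)
    counts_sm <- circ_box(counts) / pmax(vis_n, 1)
    dwell_sm <- circ_box(dwell) / pmax(vis_n, 1)
    rate <- ifelse(visited & dwell_sm > 0, counts_sm / dwell_sm, NA_real_)
  } else {
    rate <- ifelse(visited, counts / dwell, NA_real_)
  }
  structure(list(
    n_bins = n_bins, bin_width = width,
    centres = (seq_len(n_bins) - 0.5) * width,
    dwell = dwell, counts = counts, rate = rate, visited = visited,
    smoothed = smooth,
    peak_rate = if (any(visited)) max(rate[visited], na.rm = TRUE) else 0,
    n_spikes = length(spikes),
    duration = length(traj$t) * TRACK_DT), class = "bvc_polarmap")
}

#' @export
print.bvc_polarmap <- function(x, ...) {
  cat(sprintf("<bvc_polarmap> %d bins of %.1f deg, peak %.2f Hz%s\n",
              x$n_bins, x$bin_width * 180 / pi, x$peak_rate,
              if (x$smoothed) " (smoothed)" else " (unsmoothed)"))
  invisible(x)
}

#' Rate map restricted to a time window
#'
#' Recomputes the locational rate map from the samples and spikes falling
#' in `[t0, t1)`, e.g. for the first minute of a trial or for 9-minute
#' trial segments.
#'
#' @inheritParams compute_rate_map
#' @param t0,t1 Window limits, s (`t0 < t1`).
#' @param ... Passed to [compute_rate_map()].
#' @return A `bvc_ratemap`.
#' @export
windowed_rate_map <- function(traj, spikes, t0, t1, ...) {
  stopifnot(inherits(traj, "bvc_trajectory"), t0 < t1)
  keep <- traj$t >= t0 & traj$t < t1
  if (!any(keep)) stopf("no trajectory samples in [%g, %g)", t0, t1)
  sub <- trajectory(traj$t[keep], traj$x[keep], traj$y[keep], traj$hd[keep])
  compute_rate_map(sub, spikes[spikes >= t0 & spikes < t1], ...)
}
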