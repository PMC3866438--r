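#' Global mean firing rate
#'
#' Number of spikes divided by the trial length in seconds.
#'
#' @param spikes Spike times, s.
#' @param duration Trial length, s.
#' @return Rate, Hz.
#' @export
global_mean_rate <- function(spikes, duration) {
  stopifnot(duration > 0)
  length(spikes) / duration
}

#' Extract running intervals from a trajectory
#'
#' Maximal intervals during which the instantaneous speed exceeds
#' `speed_min` (default 5 cm/s), kept only when at least `min_length`
#' (default 0.5 s) long.  Theta-modulation analysis is restricted to
#' spikes inside these runs, when the animal is locomoting and the theta
#' rhythm is engaged.
#'
#' @param traj A speed-filtered `bvc_trajectory`.
#' @param speed_min Speed threshold, cm/s.
#' @param min_length Minimum run length, s.
#' @return A two-column matrix of interval start and end times
#'   (half-open `[t0, t1)`), possibly with zero rows.
#' @export
extract_runs <- function(traj, speed_min = 5, min_length = 0.5) {
  stopifnot(inherits(traj, "bvc_trajectory"))
  fast <- instantaneous_speed(traj) > speed_min
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths * TRACK_DT >= min_length
  cbind(t0 = traj$t[starts[keep]],
        t1 = traj$t[ends[keep]] + TRACK_DT)
}

# Restrict spikes to a set of [t0, t1) intervals.
spikes_in_runs <- function(spikes, runs) {
  if (is.null(runs) || nrow(runs) == 0) return(numeric(0))
  keep <- rep(FALSE, length(spikes))
  for (i in seq_len(nrow(runs)))
    keep <- keep | (spikes >= runs[i, 1] & spikes < runs[i, 2])
  spikes[keep]
}

#' Spike-train autocorrelogram
#'
#' Histogram of all ordered spike-time differences in `(0, window]`
#' (default 500 ms) at `bin` resolution (default 4 ms, placing the
#' spectral Nyquist frequency at exactly 125 Hz).  The zero-lag bin is
#' excluded by construction.  If `runs` is supplied, spikes outside the
#' running intervals are dropped first.
#'
#' @param spikes Sorted spike times, s.
#' @param runs Optional run intervals from [extract_runs()].
#' @param window Maximum lag, s.
#' @param bin Lag bin width, s.
#' @return An object of class `bvc_acg`: `lags` (bin centres, s),
#'   `counts`, `bin`, `window` and `n_spikes` used.
#' @export
spike_autocorrelogram <- function(spikes, runs = NULL, window = 0.5,
                                  bin = 0.004) {
  spikes <- sort(as.numeric(spikes))
  if (!is.null(runs)) spikes <- spikes_in_runs(spikes, runs)
  n <- length(spikes)
  if (n < 2) stopf("need at least 2 spikes (after run restriction)")
  n_bins <- round(window / bin)
  counts <- numeric(n_bins)
  # sliding window over the sorted train: pairs (i, j > i) within `window`
  hi <- findInterval(spikes + window, spikes)
  for (i in seq_len(n - 1)) {
    if (hi[i] <= i) next
    lag <- spikes[(i + 1):hi[i]] - spikes[i]
    idx <- ceiling(lag / bin)
    idx <- idx[idx >= 1 & idx <= n_bins]
    if (length(idx)) {
      tb <- tabulate(idx, nbins = n_bins)
      counts <- counts + tb
    }
  }
  structure(list(lags = (seq_len(n_bins) - 0.5) * bin, counts = counts,
                 bin = bin, window = window, n_spikes = n),
            class = "bvc_acg")
}

#' @export
print.bvc_acg <- function(x, ...) {
  cat(sprintf("<bvc_acg> %d lag bins of %.0f ms, %d spikes, %d pairs\n",
              length(x$counts), x$bin * 1000, x$n_spikes, sum(x$counts)))
  invisible(x)
}

#' Theta-modulation score of an autocorrelogram
#'
#' The mean-subtracted autocorrelogram is zero-padded (to at least
#' `pad_s` seconds, giving a frequency resolution well below 1 Hz) and
#' transformed to a power spectrum (squared modulus of the discrete
#' Fourier transform; no taper by default).  The spectral peak is located
#' within the theta range (6-12 Hz) and the score is the mean power in a
#' 2 Hz band centred on that peak divided by the mean power over the
#' whole spectrum (0-125 Hz).
#'
#' @param acg A `bvc_acg` from [spike_autocorrelogram()].
#' @param theta_range Frequency range searched for the peak, Hz.
#' @param band_width Width of the band around the peak, Hz.
#' @param pad_s Minimum padded length, s.
#' @param taper Optional taper applied to the mean-subtracted
#'   autocorrelogram before the transform: `"none"` (default) or
#'   `"hann"`.
#' @return An object of class `bvc_thetascore`: `peak_freq` (Hz),
#'   `band_power`, `total_power`, `score`, and the spectrum (`freq`,
#'   `power`).
#' @export
theta_modulation_score <- function(acg, theta_range = c(6, 12),
                                   band_width = 2, pad_s = 4,
                                   taper = c("none", "hann")) {
  stopifnot(inherits(acg, "bvc_acg"))
  taper <- match.arg(taper)
  y <- acg$counts - mean(acg$counts)
  if (taper == "hann")
    y <- y * (0.5 - 0.5 * cos(2 * pi * seq_along(y) / (length(y) + 1)))
  n_pad <- max(2^ceiling(log2(pad_s / acg$bin)), length(y))
  y <- c(y, rep(0, n_pad - length(y)))
  pw <- Mod(stats::fft(y))^2
  freq <- (seq_along(pw) - 1) / (n_pad * acg$bin)
  nyquist <- 1 / (2 * acg$bin)
  keep <- freq <= nyquist
  freq <- freq[keep]; pw <- pw[keep]
  total <- mean(pw)
  if (total <= 0) stopf("autocorrelogram spectrum has zero power")
  in_theta <- freq >= theta_range[1] & freq <= theta_range[2]
  pk <- freq[in_theta][which.max(pw[in_theta])]
  in_band <- freq >= pk - band_width / 2 & freq <= pk + band_width / 2
  band <- mean(pw[in_band])
  structure(list(peak_freq = pk, band_power = band, total_power = total,
                 score = band / total, freq = freq, power = pw),
            class = "bvc_thetascore")
}

#' @export
print.bvc_thetascore <- function(x, ...) {
  cat(sprintf("<bvc_thetascore> theta peak %.2f Hz, score %.2f\n",
              x$peak_freq, x$score))
  invisible(x)
}
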