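#' Locational field peak of a rate map
#'
#' The bin centre of the maximal (smoothed) rate.  Exact ties are broken
#' deterministically by the lowest flat bin index (x index varying
#' fastest).
#'
#' @param map A `bvc_ratemap` with at least one visited bin of nonzero rate.
#' @param env The `bvc_environment` the map was recorded in.
#' @return An object of class `bvc_fieldpeak`: `position` (cm), `rate`
#'   (Hz, equal to the map's locational peak rate) and `dist_centre`
#'   (distance of the peak from the environment centre, cm).
#' @export
field_peak <- function(map, env) {
  stopifnot(inherits(map, "bvc_ratemap"), inherits(env, "bvc_environment"))
  r <- map$rate
  r[!map$visited | is.na(r)] <- -Inf
  if (!any(is.finite(r)) || max(r) <= 0)
    stopf("rate map has no positive rate; no field peak")
  i <- which.max(r)   # first maximum in column-major (flat) order
  pos <- ratemap_bin_centres(map)[i, ]
  structure(list(position = pos, rate = max(r),
                 dist_centre = sqrt(sum(pos^2))),
            class = "bvc_fieldpeak")
}

#' @export
print.bvc_fieldpeak <- function(x, ...) {
  cat(sprintf("<bvc_fieldpeak> (%.1f, %.1f) cm, %.2f Hz, %.1f cm from centre\n",
              x$position[1], x$position[2], x$rate, x$dist_centre))
  invisible(x)
}

#' Is a field peak in the outer portion of a circular environment?
#'
#' The outer portion is the annulus between the perimeter and the circle
#' at 75% of the radial distance; the boundary is inclusive.
#'
#' @param peak A `bvc_fieldpeak`.
#' @param env A circular `bvc_environment`.
#' @param fraction Radial fraction defining the inner edge of the outer
#'   portion.
#' @return `TRUE` or `FALSE`.
#' @export
outer_portion <- function(peak, env, fraction = 0.75) {
  stopifnot(inherits(peak, "bvc_fieldpeak"), inherits(env, "bvc_environment"))
  if (env$floor$type != "disk")
    stopf("outer portion is defined for circular environments only")
  peak$dist_centre >= fraction * env$floor$radius
}

#' Predicted barrier side for a boundary-responsive cell
#'
#' Infers the cell's preferred allocentric direction from the location of
#' its baseline firing field (the direction from the field to the nearest
#' perimeter point: a field hugging the south wall implies a preferred
#' direction of south) and returns the side of a barrier on which field
#' repetition is predicted - the side facing opposite the preferred
#' direction, so that an animal on that side has the barrier at the
#' preferred direction.  The field is located by the rate-weighted
#' centroid of the bins at or above half the peak rate, which is far less
#' sensitive to bin-level noise than the single maximal bin.
#'
#' @param baseline_map A `bvc_ratemap` from the baseline (no-barrier) trial.
#' @param env The baseline `bvc_environment`.
#' @return An object of class `bvc_predicted_side`: `phi_pref` (estimated
#'   preferred direction, radians), `side` (direction from the barrier
#'   centre toward the predicted side, radians, `= phi_pref + pi`
#'   wrapped), `label` (compass label of `side`) and `peak`.
#' @export
predicted_side <- function(baseline_map, env) {
  peak <- field_peak(baseline_map, env)
  r <- as.numeric(baseline_map$rate)
  w <- ifelse(is.na(r) | r < 0.5 * peak$rate, 0, r)
  cen <- ratemap_bin_centres(baseline_map)
  p <- c(sum(w * cen[, 1]), sum(w * cen[, 2])) / sum(w)
  phi <- if (env$floor$type == "disk") {
    if (sqrt(sum(p^2)) < 1e-9)
      stopf("field peak at the environment centre; preferred direction undefined")
    atan2(p[2], p[1])
  } else {
    # nearest wall of the rectangle
    gaps <- c(env$floor$hx - p[1], p[1] + env$floor$hx,   # E, W
              env$floor$hy - p[2], p[2] + env$floor$hy)   # N, S
    if (abs(max(gaps) - min(gaps)) < 1e-9)
      stopf("field peak equidistant from all walls; preferred direction undefined")
    c(0, pi, pi / 2, -pi / 2)[which.min(gaps)]
  }
  side <- wrap_angle(phi + pi)
  labels <- c("east", "north-east", "north", "north-west",
              "west", "south-west", "south", "south-east")
  lab <- labels[(round(side / (pi / 4)) %% 8) + 1]
  structure(list(phi_pref = phi, side = side, label = lab, peak = peak),
            class = "bvc_predicted_side")
}

#' @export
print.bvc_predicted_side <- function(x, ...) {
  cat(sprintf(
    "<bvc_predicted_side> preferred direction %.1f deg; predicted side: %s (%.1f deg)\n",
    x$phi_pref * 180 / pi, x$label, x$side * 180 / pi))
  invisible(x)
}

# Does the axis-aligned square bin [bx0,bx1]x[by0,by1] touch the segment
# (p0, p1)?  Closed test: contact at an edge counts.
bin_touches_segment <- function(bx0, bx1, by0, by1, p0, p1) {
  d <- p1 - p0
  # clip the segment parameter to the slab of each axis (Liang-Barsky)
  t0 <- 0; t1 <- 1
  for (ax in 1:2) {
    lo <- c(bx0, by0)[ax]; hi <- c(bx1, by1)[ax]
    if (abs(d[ax]) < 1e-12) {
      if (p0[ax] < lo - 1e-9 || p0[ax] > hi + 1e-9) return(FALSE)
    } else {
      ta <- (lo - p0[ax]) / d[ax]; tb <- (hi - p0[ax]) / d[ax]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
      if (t0 > t1 + 1e-9) return(FALSE)
    }
  }
  TRUE
}

# Bins of `map` directly abutting the barrier face on the side `side`
# (radians): visited bins whose square touches the 50 cm face segment and
# whose centre lies on the predicted side of the face.  Returns flat indices.
abutting_bins <- function(map, env, side) {
  b <- env$barrier
  if (is.null(b)) stopf("environment contains no barrier")
  u <- c(cos(b$orientation), sin(b$orientation))
  v <- c(-u[2], u[1])
  # outward normal of the predicted face
  nrm <- if (sum(v * c(cos(side), sin(side))) >= 0) v else -v
  # the face segment, displaced infinitesimally to the predicted side, so
  # that a bin abuts iff its square covers floor arbitrarily close to the
  # face on that side (bins merely tangent from the barrier side drop out)
  f_mid <- b$centre + nrm * (b$thickness / 2 + 1e-4)
  p0 <- f_mid - u * (b$length / 2)
  p1 <- f_mid + u * (b$length / 2)
  centres <- ratemap_bin_centres(map)
  h <- map$bin_size / 2
  rel <- sweep(centres, 2, f_mid)
  perp <- as.vector(rel %*% nrm)
  along <- as.vector(rel %*% u)
  # bins whose centre lies strictly inside the footprint are barrier bins,
  # not abutting floor bins
  inside_fp <- abs(perp + b$thickness / 2 + 1e-4) < b$thickness / 2 - 1e-6 &
    abs(along) <= b$length / 2
  on_side <- perp + b$thickness / 2 + 1e-4 > 0   # centre on the predicted half
  cand <- which(as.vector(map$visited) & !inside_fp & on_side &
                  abs(perp) < h * 3 & abs(along) <= b$length / 2 + h * 2)
  keep <- vapply(cand, function(i)
    bin_touches_segment(centres[i, 1] - h, centres[i, 1] + h,
                        centres[i, 2] - h, centres[i, 2] + h, p0, p1),
    logical(1))
  cand[keep]
}

#' Barrier coverage: the field-repetition criterion
#'
#' Measures how much of the predicted side of an inserted barrier is
#' covered by firing: among the visited bins directly abutting the
#' predicted 50 cm face (bins whose square touches the face within the
#' barrier's extent), the percentage whose rate is at least 40% of the
#' map's locational peak rate.  A cell is classified as a BVC when the
#' coverage reaches 50% or more.
#'
#' @param barrier_map A `bvc_ratemap` from the barrier trial.
#' @param env_with_barrier The barrier-trial `bvc_environment` (must carry
#'   a barrier).
#' @param side Predicted side: a `bvc_predicted_side` or an angle in
#'   radians (direction from the barrier centre toward the predicted side).
#' @param rate_frac Fraction of the locational peak defining "firing"
#'   (default 0.4).
#' @param cover_frac Fraction of abutting bins required (default 0.5).
#' @return An object of class `bvc_coverage`: `side`, `bins` (flat indices
#'   of abutting bins), `threshold` (Hz), `n_abutting`, `n_above`,
#'   `coverage` (percent) and `is_bvc`.
#' @export
barrier_coverage <- function(barrier_map, env_with_barrier, side,
                             rate_frac = 0.4, cover_frac = 0.5) {
  stopifnot(inherits(barrier_map, "bvc_ratemap"))
  if (inherits(side, "bvc_predicted_side")) side <- side$side
  bins <- abutting_bins(barrier_map, env_with_barrier, side)
  if (length(bins) == 0)
    stopf("no visited bins abut the predicted barrier side")
  thr <- rate_frac * barrier_map$peak_rate
  above <- sum(barrier_map$rate[bins] >= thr, na.rm = TRUE)
  coverage <- 100 * above / length(bins)
  structure(list(side = side, bins = bins, threshold = thr,
                 n_abutting = length(bins), n_above = above,
                 coverage = coverage,
                 is_bvc = coverage >= 100 * cover_frac),
            class = "bvc_coverage")
}

#' @export
print.bvc_coverage <- function(x, ...) {
  cat(sprintf(
    "<bvc_coverage> %d/%d abutting bins >= %.2f Hz: %.0f%% -> %s\n",
    x$n_above, x$n_abutting, x$threshold, x$coverage,
    if (isTRUE(x$is_bvc)) "BVC criterion met" else "criterion not met"))
  invisible(x)
}

#' Inverse (boundary-off) barrier criterion
#'
#' A boundary-off cell fires everywhere except where its associated BVC
#' would fire, so barrier insertion should elicit an additional region of
#' *low* firing on the predicted side.  The criterion mirrors
#' [barrier_coverage()] with the inequality inverted: the percentage of
#' abutting bins whose rate is at or below `rate_frac` (default 40%) of
#' the median visited-bin rate, flagged when it reaches `cover_frac`.
#' The paper-style field-repetition criterion gives no formula for
#' boundary-off cells; this low-rate threshold is this package's own
#' operationalisation and both fractions are configurable.
#'
#' @inheritParams barrier_coverage
#' @param baseline_map Unused by the default criterion but accepted so the
#'   two coverage operators share a calling convention.
#' @return A `bvc_coverage` object whose `is_bvc` field flags the
#'   boundary-off criterion instead.
#' @export
boundary_off_coverage <- function(baseline_map, barrier_map,
                                  env_with_barrier, side,
                                  rate_frac = 0.4, cover_frac = 0.5) {
  stopifnot(inherits(barrier_map, "bvc_ratemap"))
  if (inherits(side, "bvc_predicted_side")) side <- side$side
  bins <- abutting_bins(barrier_map, env_with_barrier, side)
  if (length(bins) == 0)
    stopf("no visited bins abut the predicted barrier side")
  med <- stats::median(barrier_map$rate[barrier_map$visited], na.rm = TRUE)
  thr <- rate_frac * med
  below <- sum(barrier_map$rate[bins] <= thr, na.rm = TRUE)
  coverage <- 100 * below / length(bins)
  structure(list(side = side, bins = bins, threshold = thr,
                 n_abutting = length(bins), n_above = below,
                 coverage = coverage,
                 is_bvc = coverage >= 100 * cover_frac),
            class = "bvc_coverage")
}

# Fraction of the map's firing (dwell-weighted rate mass) carried by bins
# within `band` cm of the floor perimeter.
perimeter_rate_fraction <- function(map, env, band) {
  centres <- ratemap_bin_centres(map)
  d_perim <- if (env$floor$type == "disk") {
    env$floor$radius - sqrt(rowSums(centres^2))
  } else {
    pmin(env$floor$hx - abs(centres[, 1]), env$floor$hy - abs(centres[, 2]))
  }
  w <- as.numeric(map$dwell) * ifelse(is.na(as.numeric(map$rate)), 0,
                                      as.numeric(map$rate))
  tot <- sum(w[map$visited])
  if (tot <= 0) return(0)
  sum(w[map$visited & d_perim <= band]) / tot
}

#' Classify a cell by barrier-elicited field repetition
#'
#' Composes the full classification procedure: (1) eligibility - the cell
#' must fire at or near the perimeter in the baseline trial, meaning its
#' baseline field peak lies in the outer portion of a circular floor (or
#' within two bin widths of a wall for rectangular floors) *and* at least
#' half of its firing mass is concentrated in the outer band of the
#' environment (a diffusely firing cell with a peak that happens to fall
#' near a wall is not a perimeter-firing cell); (2) the predicted barrier
#' side from the baseline peak; (3) barrier coverage on the barrier trial.
#' An ineligible cell yields a `"not eligible"` outcome, not an error.
#'
#' @param baseline_map,barrier_map Smoothed `bvc_ratemap`s from the
#'   baseline and barrier trials.
#' @param env,env_with_barrier The matching environments.
#' @param rate_frac,cover_frac Criterion fractions, see
#'   [barrier_coverage()].
#' @param perimeter_mass_frac Minimum fraction of firing mass in the
#'   outer band required for eligibility.
#' @return An object of class `bvc_classification`: `eligible`, `is_bvc`,
#'   `coverage` (a `bvc_coverage` or `NULL`), `predicted` (a
#'   `bvc_predicted_side` or `NULL`), `peak` and `reason`.
#' @export
classify_bvc <- function(baseline_map, barrier_map, env, env_with_barrier,
                         rate_frac = 0.4, cover_frac = 0.5,
                         perimeter_mass_frac = 0.5) {
  stopifnot(inherits(baseline_map, "bvc_ratemap"),
            inherits(barrier_map, "bvc_ratemap"))
  res <- list(eligible = FALSE, is_bvc = FALSE, coverage = NULL,
              predicted = NULL, peak = NULL, reason = "")
  peak <- tryCatch(field_peak(baseline_map, env), error = function(e) NULL)
  if (is.null(peak)) {
    res$reason <- "not eligible: baseline map has no field peak"
    return(structure(res, class = "bvc_classification"))
  }
  res$peak <- peak
  near_perim <- if (env$floor$type == "disk") {
    outer_portion(peak, env)
  } else {
    d <- min(env$floor$hx - abs(peak$position[1]),
             env$floor$hy - abs(peak$position[2]))
    d <= 2 * baseline_map$bin_size
  }
  if (!near_perim) {
    res$reason <- "not eligible: baseline field peak is not at/near the perimeter"
    return(structure(res, class = "bvc_classification"))
  }
  band <- 0.25 * floor_inradius(env)
  mass <- perimeter_rate_fraction(baseline_map, env, band)
  if (mass < perimeter_mass_frac) {
    res$reason <- sprintf(
      "not eligible: only %.0f%% of firing mass lies near the perimeter", 100 * mass)
    return(structure(res, class = "bvc_classification"))
  }
  res$eligible <- TRUE
  pred <- predicted_side(baseline_map, env)
  res$predicted <- pred
  cov <- barrier_coverage(barrier_map, env_with_barrier, pred,
                          rate_frac = rate_frac, cover_frac = cover_frac)
  res$coverage <- cov
  res$is_bvc <- cov$is_bvc
  res$reason <- sprintf("%.0f%% barrier coverage on the %s side",
                        cov$coverage, pred$label)
  structure(res, class = "bvc_classification")
}

#' @export
print.bvc_classification <- function(x, ...) {
  verdict <- if (!x$eligible) "not eligible"
  else if (x$is_bvc) "BVC" else "not a BVC"
  cat(sprintf("<bvc_classification> %s - %s\n", verdict, x$reason))
  invisible(x)
}
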