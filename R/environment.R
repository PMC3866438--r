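#' Testing-environment geometry
#'
#' An environment is a 2-D floor region (origin at the floor centre,
#' x east, y north, all lengths in cm) plus a set of boundary elements.
#' Boundary elements are either `"wall"` (a vertical surface) or `"drop"`
#' (the edge of an elevated platform).  The perimeter of circular floors is
#' stored analytically as an arc; all other boundaries are line segments.
#' Wall height and platform elevation are descriptive metadata only: every
#' geometric query is two-dimensional.
#'
#' @section Standard environments:
#' \describe{
#'   \item{`walled_circle`}{150 cm diameter disk, walled perimeter.}
#'   \item{`walled_square`}{100 x 100 cm square, walled perimeter.}
#'   \item{`unwalled_circle`}{155 cm diameter elevated platform, drop perimeter.}
#'   \item{`together`}{three 50 x 50 cm platforms pushed together into a
#'     150 x 50 cm rectangle, drop perimeter.}
#'   \item{`apart`}{the same three platforms separated by two 10 cm
#'     traversable gaps.  The floor is modelled as the connected
#'     170 x 50 cm union (animals cross the gaps), with every platform edge
#'     present as a drop element, including the four edges facing the gaps.}
#' }
#'
#' @param name One of `"walled_circle"`, `"walled_square"`,
#'   `"unwalled_circle"`, `"together"`, `"apart"`.
#' @return An object of class `bvc_environment`: a list with elements
#'   `name`, `floor` (disk or rectangle descriptor), `arc` (analytic
#'   circular perimeter or `NULL`), `segments` (data frame of segment
#'   boundary elements with columns `x0, y0, x1, y1, kind, role`),
#'   `barrier` (see [insert_barrier()]) and `metadata`.
#' @examples
#' env <- make_standard_environment("walled_circle")
#' boundary_distance(env, c(0, 0), 0)  # 75 cm in every direction
#' @export
make_standard_environment <- function(name) {
  name <- match.arg(name,
    c("walled_circle", "walled_square", "unwalled_circle", "together", "apart"))
  seg <- function(x0, y0, x1, y1, kind)
    data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1, kind = kind,
               role = rep("perimeter", length(x0)), stringsAsFactors = FALSE)
  rect_segments <- function(hx, hy, kind)
    seg(c(-hx,  hx,  hx, -hx), c(-hy, -hy,  hy,  hy),
        c( hx,  hx, -hx, -hx), c(-hy,  hy,  hy, -hy), kind)
  env <- switch(name,
    walled_circle = list(
      floor = list(type = "disk", radius = 75),
      arc = list(radius = 75, kind = "wall"),
      segments = seg(numeric(0), numeric(0), numeric(0), numeric(0), character(0)),
      metadata = list(wall_height_cm = 50)),
    walled_square = list(
      floor = list(type = "rect", hx = 50, hy = 50),
      arc = NULL,
      segments = rect_segments(50, 50, "wall"),
      metadata = list(wall_height_cm = 50)),
    unwalled_circle = list(
      floor = list(type = "disk", radius = 77.5),
      arc = list(radius = 77.5, kind = "drop"),
      segments = seg(numeric(0), numeric(0), numeric(0), numeric(0), character(0)),
      metadata = list(elevation_cm = 30)),
    together = list(
      floor = list(type = "rect", hx = 75, hy = 25),
      arc = NULL,
      segments = rect_segments(75, 25, "drop"),
      metadata = list(elevation_cm = 30)),
    apart = {
      # three 50 x 50 platforms centred at x = -60, 0, +60 with 10 cm gaps;
      # the traversable floor is the 170 x 50 bounding rectangle and every
      # platform edge (12 segments) is a drop element
      centres <- c(-60, 0, 60)
      segs <- do.call(rbind, lapply(centres, function(cx)
        seg(cx + c(-25, 25, 25, -25), c(-25, -25, 25, 25),
            cx + c(25, 25, -25, -25), c(-25, 25, 25, -25), "drop")))
      internal <- abs(pmax(abs(segs$x0), abs(segs$x1))) < 85 &
        segs$x0 == segs$x1
      segs$role[internal] <- "gap_edge"
      list(floor = list(type = "rect", hx = 85, hy = 25),
           arc = NULL, segments = segs,
           metadata = list(elevation_cm = 30, gap_cm = 10))
    })
  structure(c(env, list(name = name, barrier = NULL)),
            class = "bvc_environment")
}

#' @export
print.bvc_environment <- function(x, ...) {
  fl <- if (x$floor$type == "disk")
    sprintf("disk, radius %.1f cm", x$floor$radius)
  else sprintf("rectangle, %.0f x %.0f cm", 2 * x$floor$hx, 2 * x$floor$hy)
  cat(sprintf("<bvc_environment> %s\n  floor: %s\n", x$name, fl))
  if (!is.null(x$arc))
    cat(sprintf("  perimeter: circular %s, radius %.1f cm\n",
                x$arc$kind, x$arc$radius))
  if (nrow(x$segments))
    cat(sprintf("  segments: %d (%s)\n", nrow(x$segments),
                paste(sprintf("%d %s", table(x$segments$kind),
                              names(table(x$segments$kind))), collapse = ", ")))
  if (!is.null(x$barrier))
    cat(sprintf("  barrier: centre (%.1f, %.1f), orientation %.2f rad\n",
                x$barrier$centre[1], x$barrier$centre[2], x$barrier$orientation))
  invisible(x)
}

# Corner coordinates of the barrier rectangle (counter-clockwise).
barrier_corners <- function(barrier) {
  u <- c(cos(barrier$orientation), sin(barrier$orientation))   # long axis
  v <- c(-u[2], u[1])                                          # normal
  hl <- barrier$length / 2
  ht <- barrier$thickness / 2
  rbind(barrier$centre + hl * u + ht * v,
        barrier$centre - hl * u + ht * v,
        barrier$centre - hl * u - ht * v,
        barrier$centre + hl * u - ht * v)
}

#' Insert an upright barrier into an environment
#'
#' Adds a free-standing barrier (by default 50 cm long and 3 cm thick, the
#' dimensions of the experimental barrier) as four wall elements: two long
#' faces and two short end faces.  The floor region is unchanged apart from
#' the barrier footprint, which becomes unreachable.
#'
#' @param env A `bvc_environment`.
#' @param centre Barrier centre, cm; default the environment centre.
#' @param orientation Orientation of the barrier's long axis, radians
#'   counter-clockwise from east.
#' @param length,thickness Barrier dimensions, cm.
#' @return A new `bvc_environment` with the barrier's wall elements added
#'   and a `barrier` descriptor recorded.
#' @examples
#' env <- insert_barrier(make_standard_environment("walled_square"),
#'                       centre = c(0, 0), orientation = 0)
#' @export
insert_barrier <- function(env, centre = c(0, 0), orientation = 0,
                           length = 50, thickness = 3) {
  stopifnot(inherits(env, "bvc_environment"))
  if (!is.null(env$barrier))
    stopf("environment already contains a barrier")
  barrier <- list(centre = as.numeric(centre), orientation = orientation,
                  length = length, thickness = thickness)
  corners <- barrier_corners(barrier)
  # the barrier must sit strictly inside the floor, clear of the perimeter
  inside <- point_in_floor(env, corners[, 1], corners[, 2])
  if (!all(inside))
    stopf("barrier extends outside the floor of '%s'", env$name)
  if (env$floor$type == "disk") {
    if (max(sqrt(rowSums(corners^2))) >= env$floor$radius)
      stopf("barrier touches the perimeter of '%s'", env$name)
  }
  idx <- c(1, 2, 3, 4)
  faces <- data.frame(
    x0 = corners[idx, 1], y0 = corners[idx, 2],
    x1 = corners[c(2, 3, 4, 1), 1], y1 = corners[c(2, 3, 4, 1), 2],
    kind = "wall",
    role = c("barrier_face", "barrier_end", "barrier_face", "barrier_end"),
    stringsAsFactors = FALSE)
  env$segments <- rbind(env$segments, faces)
  env$barrier <- barrier
  env
}

# Vectorised point-in-floor test; `clearance` erodes the floor, and points
# within `barrier_clearance` of the barrier footprint are excluded as well.
point_in_floor <- function(env, x, y, clearance = 0,
                           barrier_clearance = clearance) {
  inside <- if (env$floor$type == "disk") {
    x^2 + y^2 < (env$floor$radius - clearance)^2
  } else {
    abs(x) < env$floor$hx - clearance & abs(y) < env$floor$hy - clearance
  }
  if (!is.null(env$barrier)) {
    b <- env$barrier
    dx <- x - b$centre[1]; dy <- y - b$centre[2]
    u <- c(cos(b$orientation), sin(b$orientation))
    lx <- dx * u[1] + dy * u[2]
    ly <- -dx * u[2] + dy * u[1]
    in_barrier <- abs(lx) <= b$length / 2 + barrier_clearance &
      abs(ly) <= b$thickness / 2 + barrier_clearance
    inside <- inside & !in_barrier
  }
  inside
}

# Inradius of the floor (largest centred disk).
floor_inradius <- function(env) {
  if (env$floor$type == "disk") env$floor$radius
  else min(env$floor$hx, env$floor$hy)
}

# Circumradius of the floor (distance to the farthest floor point).
floor_circumradius <- function(env) {
  if (env$floor$type == "disk") env$floor$radius
  else sqrt(env$floor$hx^2 + env$floor$hy^2)
}

# Distance from each ray (px, py, theta) to the first boundary element,
# vectorised over rays.  Inf where no element is hit.
ray_distances <- function(env, px, py, theta) {
  n <- max(length(px), length(py), length(theta))
  px <- rep_len(px, n); py <- rep_len(py, n); theta <- rep_len(theta, n)
  ux <- cos(theta); uy <- sin(theta)
  best <- rep(Inf, n)
  if (!is.null(env$arc)) {
    # ray-circle intersection from a point inside the circle
    R <- env$arc$radius
    b <- px * ux + py * uy
    disc <- b^2 + R^2 - (px^2 + py^2)
    best <- -b + sqrt(pmax(disc, 0))
  }
  segs <- env$segments
  if (nrow(segs)) {
    for (k in seq_len(nrow(segs))) {
      ax <- segs$x0[k]; ay <- segs$y0[k]
      dx <- segs$x1[k] - ax; dy <- segs$y1[k] - ay
      denom <- ux * dy - uy * dx
      wx <- ax - px; wy <- ay - py
      t <- (wx * dy - wy * dx) / denom
      s <- (wx * uy - wy * ux) / denom
      hit <- is.finite(t) & t > 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
      upd <- hit & t < best
      best[upd] <- t[upd]
    }
  }
  best
}

#' Distance to the nearest boundary along an allocentric ray
#'
#' Distance from a position inside the floor, along the ray at allocentric
#' direction `direction`, to the first boundary element (perimeter wall or
#' drop, or a barrier face).  This is the geometric primitive of the BVC
#' receptive-field model: the cell's input at a position is the set of
#' boundary distances over all directions.
#'
#' @param env A `bvc_environment`.
#' @param position Numeric length-2, cm.
#' @param direction Allocentric direction(s), radians counter-clockwise
#'   from east; may be a vector.
#' @return Distance(s) in cm; `NA` if the ray escapes (possible only in
#'   open configurations).
#' @export
boundary_distance <- function(env, position, direction) {
  stopifnot(inherits(env, "bvc_environment"), length(position) == 2)
  if (!point_in_floor(env, position[1], position[2]))
    stopf("position (%.1f, %.1f) is outside the floor of '%s'",
          position[1], position[2], env$name)
  d <- ray_distances(env, position[1], position[2], direction)
  d[!is.finite(d)] <- NA_real_
  d
}
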