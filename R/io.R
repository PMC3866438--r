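#' Read and write trajectories and spike trains
#'
#' @description
#' Trajectories are tab-delimited text with a header line `t x y hd`
#' (seconds, cm, cm, radians) and one sample per row.  Spike trains are
#' plain text with one spike time (seconds) per line.  Readers validate
#' the files and report the offending line on failure.
#'
#' @param traj A `bvc_trajectory`.
#' @param path File path.
#' @return `read_trajectory()` a `bvc_trajectory`; `read_spikes()` a
#'   sorted numeric vector; the writers return `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "bvc_trajectory"))
  df <- data.frame(t = traj$t, x = traj$x, y = traj$y, hd = traj$hd)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("t", "x", "y", "hd")
  if (!all(need %in% names(df)))
    stopf("%s: expected columns t, x, y, hd (got: %s)", path,
          paste(names(df), collapse = ", "))
  for (col in need) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]]))
      stopf("%s: non-numeric or missing values in column '%s' (line %d)",
            path, col, which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1] + 1L)
  }
  nm <- which(diff(df$t) <= 0)
  if (length(nm))
    stopf("%s: time not strictly increasing at line %d", path, nm[1] + 2L)
  trajectory(df$t, df$x, df$y, df$hd)
}

#' @rdname write_trajectory
#' @param spikes Sorted spike times, s.
#' @export
write_spikes <- function(spikes, path) {
  writeLines(format(as.numeric(spikes), digits = 10, trim = TRUE,
                    scientific = FALSE), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(numeric(0))
  v <- suppressWarnings(as.numeric(lines))
  if (anyNA(v))
    stopf("%s: non-numeric spike time at line %d", path, which(is.na(v))[1])
  if (any(v < 0))
    stopf("%s: negative spike time at line %d", path, which(v < 0)[1])
  if (is.unsorted(v))
    stopf("%s: spike times not sorted (line %d)", path,
          which(diff(v) < 0)[1] + 1L)
  v
}

#' Write a rate map as a delimited text grid
#'
#' The grid is written row per y-bin (south to north), preceded by header
#' comment lines recording the bin size, grid origin and peak rate.
#' Unvisited bins are written as `NA`.
#'
#' @param map A `bvc_ratemap`.
#' @param path File path.
#' @export
write_rate_map <- function(map, path) {
  stopifnot(inherits(map, "bvc_ratemap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# bin_size_cm: %g", map$bin_size),
    sprintf("# origin_cm: %g %g", map$xedges[1], map$yedges[1]),
    sprintf("# peak_rate_hz: %g", map$peak_rate),
    sprintf("# smoothed: %s", map$smoothed)), con)
  utils::write.table(t(map$rate), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
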