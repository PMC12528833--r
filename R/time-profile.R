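#' Inverted-Gaussian time profile
#'
#' Generates the schedule of inter-sample time intervals that gives simulated
#' paths a bell-shaped speed profile. With path points indexed
#' \code{0 .. n_points - 1}, the k-th of the \code{n_points - 1} intervals is
#' attributed to its midpoint index \code{x_k = k - 0.5} and receives
#' duration proportional to \code{C - g(x_k)}, where
#' \code{g(x) = exp(-0.5 * ((x - mu) / sigma)^2)} and
#' \code{C = max(g) + 0.1} keeps every interval positive. Intervals are
#' normalised so they sum exactly to \code{total_duration}. Short intervals
#' near \code{mu} (the profile midpoint) mean the path is traversed fastest
#' mid-movement.
#'
#' Evaluating \code{g} at interval midpoints (rather than at either bounding
#' sample index) makes the interval schedule exactly symmetric about the
#' midpoint when \code{mu = (n_points - 1) / 2}, matching the symmetric
#' differencing convention used for velocities.
#'
#' @param n_points number of path samples (default 501, giving 500 intervals).
#' @param mu Gaussian centre in sample-index units (default
#'   \code{(n_points - 1) / 2}, i.e. 250 at the default size).
#' @param sigma Gaussian width in sample-index units (default 75).
#' @param total_duration total movement duration (s), default 1.
#' @return an object of class \code{time_profile}: list with \code{n_points},
#'   \code{mu}, \code{sigma}, \code{C}, \code{intervals} (length
#'   \code{n_points - 1}, s) and \code{timestamps} (length \code{n_points},
#'   starting at 0, s).
#' @examples
#' pr <- make_time_profile()
#' sum(pr$intervals)          # exactly 1 s
#' @export
make_time_profile <- function(n_points = 501L, mu = (n_points - 1) / 2,
                              sigma = 75, total_duration = 1) {
  stopifnot(is.numeric(n_points), length(n_points) == 1L, n_points >= 3,
            is.numeric(mu), is.finite(mu),
            is.numeric(sigma), sigma > 0,
            is.numeric(total_duration), total_duration > 0)
  n_points <- as.integer(n_points)
  x <- seq_len(n_points - 1L) - 0.5          # interval midpoints, index units
  g <- exp(-0.5 * ((x - mu) / sigma)^2)
  C <- max(g) + 0.1
  raw <- C - g
  intervals <- raw / sum(raw) * total_duration
  # force the sum to be exact despite rounding in the normalisation
  intervals <- intervals * (total_duration / sum(intervals))
  structure(
    list(n_points = n_points, mu = mu, sigma = sigma, C = C,
         total_duration = total_duration,
         intervals = intervals,
         timestamps = c(0, cumsum(intervals))),
    class = "time_profile")
}

#' @export
print.time_profile <- function(x, ...) {
  cat(sprintf("<inverted-Gaussian time profile: %d points, mu = %.1f, sigma = %.1f, %.3f s>\n",
              x$n_points, x$mu, x$sigma, x$total_duration))
  invisible(x)
}

#' Attach a time profile to an untimed path
#'
#' @param path a two-column matrix of ordered path points with exactly
#'   \code{profile$n_points} rows.
#' @param profile a \code{\link{make_time_profile}} object.
#' @param space the space tag for the resulting \code{\link{trajectory}}.
#' @return a \code{\link{trajectory}} sampled at the profile's timestamps.
#' @export
time_path <- function(path, profile, space = c("hand", "joint")) {
  space <- match.arg(space)
  stopifnot(inherits(profile, "time_profile"), is.matrix(path), ncol(path) == 2L)
  if (nrow(path) != profile$n_points)
    stop(sprintf("path has %d points but the profile expects %d",
                 nrow(path), profile$n_points))
  trajectory(profile$timestamps, path[, 1L], path[, 2L], space = space)
}
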