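#' Simulate a straight or parabolically curved path
#'
#' Builds an untimed path between two points whose signed normalised
#' deviation (see \code{\link{trajectory_deviation}}) equals \code{deviation}
#' exactly. In the chord frame (origin at \code{start}, x along the chord of
#' length l), the path is the parabola
#' \deqn{y(x) = 4 d l (x/l)(1 - x/l)}
#' whose apex sits at perpendicular offset \code{d * l} from the chord
#' midpoint, sampled at \code{n_points} equal steps in x. Positive
#' \code{deviation} places the apex on the right of the chord in the
#' direction of movement, negative on the left, matching the sign convention
#' of the deviation metric. \code{deviation = 0} gives the straight segment.
#'
#' @param start,end numeric length-2 endpoints (same units as the space the
#'   path lives in; the construction is purely planar).
#' @param deviation signed normalised deviation (a.u.).
#' @param n_points number of samples (>= 3).
#' @return a \code{n_points} x 2 matrix of path points.
#' @export
simulate_path <- function(start, end, deviation, n_points = 501L) {
  stopifnot(is.numeric(start), length(start) == 2L,
            is.numeric(end), length(end) == 2L,
            is.numeric(deviation), length(deviation) == 1L, is.finite(deviation),
            n_points >= 3L)
  parabolic_point(start, end, deviation, seq(0, 1, length.out = n_points))
}

# evaluate the parabolic path at arbitrary chord fractions s in [0, 1]
parabolic_point <- function(start, end, deviation, s) {
  chord <- end - start
  l <- sqrt(sum(chord^2))
  if (l <= 0) stop("coincident endpoints: cannot orient a path")
  u <- chord / l                       # unit chord direction
  r <- c(u[2L], -u[1L])                # unit right normal (in movement direction)
  y <- 4 * deviation * l * s * (1 - s)
  cbind(start[1L] + s * chord[1L] + y * r[1L],
        start[2L] + s * chord[2L] + y * r[2L])
}

#' Jitter a target point uniformly within its logical radius
#'
#' Draws a point uniformly from the closed disk of radius \code{radius}
#' around \code{target}, emulating the invisible target-acceptance zone of
#' the task (1 cm by default). Uses the current R random-number stream, so
#' results are reproducible under \code{set.seed}.
#'
#' @param target numeric length-2 centre (m).
#' @param radius disk radius (m), > 0.
#' @return numeric length-2 point.
#' @export
jitter_endpoint <- function(target, radius = 0.01) {
  stopifnot(is.numeric(target), length(target) == 2L, radius > 0)
  r <- radius * sqrt(stats::runif(1L))
  a <- stats::runif(1L, 0, 2 * pi)
  target + r * c(cos(a), sin(a))
}
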