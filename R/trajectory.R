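#' Timestamped planar trajectory
#'
#' A trajectory is a data frame with columns \code{t} (s, strictly
#' increasing), \code{u} and \code{v} (the two plane coordinates), carrying a
#' \code{space} attribute: \code{"hand"} (u, v in metres) or \code{"joint"}
#' (u = shoulder angle, v = elbow angle, rad).
#'
#' @param t numeric, strictly increasing times (s), length >= 2.
#' @param u,v plane coordinates, same length as \code{t}.
#' @param space \code{"hand"} or \code{"joint"}.
#' @return a data frame of class \code{trajectory}.
#' @export
trajectory <- function(t, u, v, space = c("hand", "joint")) {
  space <- match.arg(space)
  stopifnot(length(t) >= 2L, length(u) == length(t), length(v) == length(t),
            all(is.finite(t)), all(is.finite(u)), all(is.finite(v)))
  if (any(diff(t) <= 0)) stop("trajectory time stamps must be strictly increasing")
  structure(data.frame(t = t, u = u, v = v),
            space = space, class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<%s-space trajectory: %d samples, %.3f s, from (%.4g, %.4g) to (%.4g, %.4g)>\n",
              trajectory_space(x), nrow(x), x$t[nrow(x)] - x$t[1],
              x$u[1], x$v[1], x$u[nrow(x)], x$v[nrow(x)]))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a \code{trajectory}.
#' @export
trajectory_space <- function(traj) {
  sp <- attr(traj, "space")
  if (is.null(sp)) stop("object has no trajectory space tag")
  sp
}

#' Signed normalised trajectory deviation
#'
#' The deviation of a path from straightness: the maximum perpendicular
#' distance of the path from the chord joining its first and last points,
#' normalised by the chord length. The measure is dimensionless (a.u.) and
#' applies identically in hand space and joint space. The sign encodes the
#' side of the chord on which the maximising sample lies, in the direction of
#' movement: left is negative, right is positive. Ties between samples of
#' equal perpendicular distance are broken toward the earlier sample.
#'
#' @param traj a \code{\link{trajectory}}, any data frame with columns
#'   \code{u}, \code{v}, or a two-column matrix of path points (ordered).
#' @return signed scalar deviation (a.u.).
#' @export
trajectory_deviation <- function(traj) {
  p <- as_path_matrix(traj)
  if (nrow(p) < 3L) stop("trajectory deviation needs at least 3 samples")
  s <- p[1L, ]
  e <- p[nrow(p), ]
  l <- sqrt(sum((e - s)^2))
  if (l <= 0) stop("degenerate chord: start and end coincide")
  ux <- (e[1L] - s[1L]) / l
  uy <- (e[2L] - s[2L]) / l
  # z-component of chord-direction x (point - start): positive = left side
  cross <- ux * (p[, 2L] - s[2L]) - uy * (p[, 1L] - s[1L])
  i <- which.max(abs(cross))          # which.max takes the earliest tie
  -cross[i] / l                        # left of chord => negative deviation
}

as_path_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2L, is.numeric(x))
    return(unname(x))
  }
  if (is.data.frame(x) && all(c("u", "v") %in% names(x)))
    return(cbind(x$u, x$v))
  stop("expected a trajectory, a data frame with columns u/v, or a 2-column matrix")
}
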