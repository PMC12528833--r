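#' Two-link planar arm geometry
#'
#' Builds the rigid-body description of a two-link planar arm as mounted in a
#' planar exoskeleton: upper-arm and forearm segment lengths, segment masses,
#' and the moments of inertia obtained by approximating each segment as a
#' rigid rod with its mass concentrated at the distal end (I = m * L^2).
#'
#' The angle convention follows the exoskeleton's configuration: the hand
#' position is
#' \deqn{X_h - X_s = L_2 \cos(\theta_e - \theta_s) + L_1 \cos(\theta_s)}
#' \deqn{Y_h - Y_s = L_2 \sin(\theta_e - \theta_s) + L_1 \sin(\theta_s)}
#' so \code{theta_s} is the absolute direction of the upper arm and
#' \code{theta_e - theta_s} the absolute direction of the forearm.
#'
#' @param L1,L2 upper-arm and forearm lengths (m); must be positive.
#' @param m1,m2 upper-arm and forearm masses (kg); must be non-negative.
#' @param shoulder numeric length-2, shoulder position (m).
#' @param ik_branch inverse-kinematics branch: \code{"open"} selects the
#'   solution with \code{theta_e - 2 * theta_s} in (0, pi) (elbow opened to
#'   the left of the upper arm, the configuration of a right arm in the
#'   exoskeleton); \code{"closed"} selects the mirrored solution.
#' @return an object of class \code{arm_geometry}.
#' @examples
#' geom <- arm_geometry()
#' forward_kinematics(geom, 0, 0)   # fully extended along +x: (0.36, 0)
#' @export
arm_geometry <- function(L1 = 0.13, L2 = 0.23, m1 = 0.220, m2 = 0.090,
                         shoulder = c(0, 0),
                         ik_branch = c("open", "closed")) {
  ik_branch <- match.arg(ik_branch)
  stopifnot(is.numeric(L1), is.numeric(L2), length(L1) == 1L, length(L2) == 1L,
            is.finite(L1), is.finite(L2), L1 > 0, L2 > 0,
            is.numeric(m1), is.numeric(m2), m1 >= 0, m2 >= 0,
            is.numeric(shoulder), length(shoulder) == 2L, all(is.finite(shoulder)))
  structure(
    list(L1 = L1, L2 = L2, m1 = m1, m2 = m2,
         Is = m1 * L1^2, Ie = m2 * L2^2,
         shoulder = as.numeric(shoulder), ik_branch = ik_branch),
    class = "arm_geometry")
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat("Two-link planar arm geometry\n")
  cat(sprintf("  segments : L1 = %.3f m (%.3f kg), L2 = %.3f m (%.3f kg)\n",
              x$L1, x$m1, x$L2, x$m2))
  cat(sprintf("  inertia  : Is = %.5f, Ie = %.5f kg m^2 (rigid-rod, I = m L^2)\n",
              x$Is, x$Ie))
  cat(sprintf("  shoulder : (%.3f, %.3f) m; IK branch: %s\n",
              x$shoulder[1], x$shoulder[2], x$ik_branch))
  invisible(x)
}

#' Forward kinematics of the two-link arm
#'
#' Maps shoulder/elbow angles to the Cartesian hand position using the
#' exoskeleton convention (see \code{\link{arm_geometry}}). Vectorised over
#' angles.
#'
#' @param geom an \code{\link{arm_geometry}}.
#' @param theta_s,theta_e shoulder and elbow angles (rad), equal length.
#' @return a numeric matrix with columns \code{x}, \code{y} (m).
#' @export
forward_kinematics <- function(geom, theta_s, theta_e) {
  stopifnot(inherits(geom, "arm_geometry"),
            length(theta_s) == length(theta_e),
            all(is.finite(theta_s)), all(is.finite(theta_e)))
  x <- geom$shoulder[1] + geom$L2 * cos(theta_e - theta_s) + geom$L1 * cos(theta_s)
  y <- geom$shoulder[2] + geom$L2 * sin(theta_e - theta_s) + geom$L1 * sin(theta_s)
  cbind(x = x, y = y)
}

#' Inverse kinematics of the two-link arm
#'
#' Recovers the joint angles that place the hand at a given Cartesian
#' position, on the branch selected by \code{geom$ik_branch}. The target must
#' lie inside the reachable annulus \code{[|L1 - L2|, L1 + L2]} around the
#' shoulder (a slack of \code{tol} metres is allowed at both rims before the
#' cosine argument is clamped).
#'
#' @param geom an \code{\link{arm_geometry}}.
#' @param x,y hand position coordinates (m), equal length; vectorised.
#' @param tol reachability slack (m).
#' @return a numeric matrix with columns \code{theta_s}, \code{theta_e} (rad)
#'   satisfying \code{forward_kinematics} to machine precision.
#' @export
inverse_kinematics <- function(geom, x, y, tol = 1e-9) {
  stopifnot(inherits(geom, "arm_geometry"), length(x) == length(y),
            all(is.finite(x)), all(is.finite(y)))
  dx <- x - geom$shoulder[1]
  dy <- y - geom$shoulder[2]
  r <- sqrt(dx^2 + dy^2)
  r_lo <- abs(geom$L1 - geom$L2)
  r_hi <- geom$L1 + geom$L2
  bad <- r < r_lo - tol | r > r_hi + tol
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "unreachable target: point %d at distance %.6f m from the shoulder lies outside [%.6f, %.6f]",
      i, r[i], r_lo, r_hi))
  }
  cg <- (r^2 - geom$L1^2 - geom$L2^2) / (2 * geom$L1 * geom$L2)
  cg <- pmin(1, pmax(-1, cg))          # |cg| can exceed 1 by O(tol) only
  gamma <- acos(cg)                    # elbow opening angle, in [0, pi]
  if (geom$ik_branch == "closed") gamma <- -gamma
  theta_s <- atan2(dy, dx) -
    atan2(geom$L2 * sin(gamma), geom$L1 + geom$L2 * cos(gamma))
  # canonical wrap to (-pi, pi]: the forward map is 2*pi-periodic in theta_s
  theta_s <- theta_s - 2 * pi * ceiling((theta_s - pi) / (2 * pi))
  theta_e <- 2 * theta_s + gamma
  cbind(theta_s = theta_s, theta_e = theta_e)
}

#' Angular velocities of a joint-space trajectory
#'
#' Interval-centred finite differences: for a joint trajectory with n samples
#' the result has n - 1 rows, each velocity attributed to the midpoint of its
#' time interval. Non-uniform sampling is honoured through the actual time
#' steps.
#'
#' @param traj a joint-space trajectory: data frame with columns \code{t}
#'   (s, strictly increasing), \code{u} (shoulder angle, rad) and \code{v}
#'   (elbow angle, rad); see \code{\link{trajectory}}.
#' @return data frame with columns \code{t} (interval midpoints, s),
#'   \code{omega_s} and \code{omega_e} (rad/s).
#' @export
angular_velocities <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("t", "u", "v") %in% names(traj)),
            nrow(traj) >= 2L)
  dt <- diff(traj$t)
  if (any(dt <= 0)) stop("trajectory time stamps must be strictly increasing")
  data.frame(t = traj$t[-nrow(traj)] + dt / 2,
             omega_s = diff(traj$u) / dt,
             omega_e = diff(traj$v) / dt)
}

#' Kinetic energy of a joint-velocity series
#'
#' The sampled kinetic-energy cost of a movement: the sum over time points of
#' the rotational energies of the two segments,
#' \deqn{KE = \sum_t \left( \tfrac12 I_s \omega_s^2 + \tfrac12 I_e \omega_e^2 \right).}
#' This is a discrete proxy (units J per sample, summed), not a time
#' integral; its absolute scale depends on the number of samples, which is
#' why landscape analyses fix a common time profile.
#'
#' @param vel data frame with columns \code{omega_s}, \code{omega_e} (rad/s),
#'   e.g. from \code{\link{angular_velocities}}.
#' @param geom an \code{\link{arm_geometry}}.
#' @return non-negative scalar (J).
#' @export
kinetic_energy <- function(vel, geom) {
  stopifnot(is.data.frame(vel), all(c("omega_s", "omega_e") %in% names(vel)),
            inherits(geom, "arm_geometry"),
            all(is.finite(vel$omega_s)), all(is.finite(vel$omega_e)))
  sum(0.5 * geom$Is * vel$omega_s^2 + 0.5 * geom$Ie * vel$omega_e^2)
}

#' Observed kinetic energy of a recorded submovement
#'
#' Thin delegation to \code{\link{kinetic_energy}} for velocities recorded by
#' the exoskeleton (or produced by the synthetic generator) at 1 kHz.
#'
#' @inheritParams kinetic_energy
#' @return non-negative scalar (J).
#' @export
observed_ke <- function(vel, geom) kinetic_energy(vel, geom)
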