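#' Symmetric grid of deviation levels
#'
#' The deviation levels at which KE landscapes are evaluated. The default is
#' 33 equally spaced levels spanning -0.5 to 0.5 a.u. (32 levels around the
#' straight trajectory plus the straight trajectory itself); the grid must be
#' strictly increasing, symmetric about 0 and contain exactly one 0.
#'
#' @param min,max grid end points (a.u.), \code{min = -max} required.
#' @param n odd number of levels.
#' @return numeric vector of class \code{deviation_grid}.
#' @export
deviation_grid <- function(min = -0.5, max = 0.5, n = 33L) {
  stopifnot(is.numeric(min), is.numeric(max), min < max, n >= 3L)
  levels <- seq(min, max, length.out = n)
  if (sum(levels == 0) != 1L)
    stop("deviation grid must contain exactly one 0 level (use an odd n with min = -max)")
  if (max(abs(levels + rev(levels))) > 1e-12)
    stop("deviation grid must be symmetric about 0")
  structure(levels, class = "deviation_grid")
}

# fast KE of a timed joint path without intermediate data frames
ke_of_joint_path <- function(ts, us, vs, geom) {
  dt <- diff(ts)
  sum(0.5 * geom$Is * (diff(us) / dt)^2 + 0.5 * geom$Ie * (diff(vs) / dt)^2)
}

#' Kinetic-energy landscape of one submovement
#'
#' Simulates trajectories at every deviation level of \code{grid} between the
#' two target centres of a submovement, times them with the inverted-Gaussian
#' profile, transforms them to joint space where needed, and records the mean
#' and standard deviation of the kinetic energy per level.
#'
#' With \code{n_replicates > 0}, each level is simulated that many times with
#' start and end points jittered independently and uniformly within the
#' logical radius of their targets (emulating endpoint scatter); the
#' deviation is defined relative to the jittered chord. With
#' \code{n_replicates = 0} the exact target centres are used once per level
#' and \code{sd_ke} is 0.
#'
#' For \code{space = "hand"} the parabolic path is drawn in hand space and
#' converted point-by-point to joint angles by
#' \code{\link{inverse_kinematics}}; for \code{space = "joint"} the (jittered)
#' endpoints are converted to joint angles first and the parabola is drawn
#' directly in the shoulder-elbow angle plane, so a level-0 path is straight
#' in joint space.
#'
#' @param start,end hand-space target centres (m).
#' @param space \code{"hand"} or \code{"joint"}: the space in which deviation
#'   is imposed.
#' @param geom an \code{\link{arm_geometry}}.
#' @param grid a \code{\link{deviation_grid}}.
#' @param n_replicates jittered replicates per level (default 100; 0 turns
#'   jitter off).
#' @param profile a \code{\link{make_time_profile}} object.
#' @param jitter_radius logical target radius (m), default 0.01.
#' @param submovement_id identifier stored with the landscape.
#' @return a data frame of class \code{ke_landscape} with columns
#'   \code{deviation}, \code{mean_ke}, \code{sd_ke}, and attributes
#'   \code{submovement_id}, \code{space}, \code{n_replicates}.
#' @export
build_ke_landscape <- function(start, end, space = c("hand", "joint"), geom,
                               grid = deviation_grid(),
                               n_replicates = 100L,
                               profile = make_time_profile(),
                               jitter_radius = 0.01,
                               submovement_id = NA_character_) {
  space <- match.arg(space)
  stopifnot(inherits(geom, "arm_geometry"), inherits(profile, "time_profile"),
            n_replicates >= 0L)
  levels <- as.numeric(grid)
  ts <- profile$timestamps
  n <- profile$n_points
  nrep <- max(1L, as.integer(n_replicates))
  jitter_on <- n_replicates > 0L

  one_ke <- function(s_pt, e_pt, d, level_label) {
    if (space == "hand") {
      path <- simulate_path(s_pt, e_pt, d, n)
      jp <- tryCatch(inverse_kinematics(geom, path[, 1L], path[, 2L]),
                     error = function(e) stop(sprintf(
                       "deviation level %g: %s", level_label, conditionMessage(e)),
                       call. = FALSE))
      ke_of_joint_path(ts, jp[, 1L], jp[, 2L], geom)
    } else {
      jse <- tryCatch(inverse_kinematics(geom, c(s_pt[1L], e_pt[1L]),
                                         c(s_pt[2L], e_pt[2L])),
                      error = function(e) stop(sprintf(
                        "deviation level %g: %s", level_label, conditionMessage(e)),
                        call. = FALSE))
      path <- simulate_path(jse[1L, ], jse[2L, ], d, n)
      ke_of_joint_path(ts, path[, 1L], path[, 2L], geom)
    }
  }

  # one endpoint draw per replicate, shared across all levels (common random
  # numbers): the landscape is a function of level differences, and paired
  # endpoints keep replicate scatter out of the level-to-level derivative
  s_pts <- lapply(seq_len(nrep), function(r)
    if (jitter_on) jitter_endpoint(start, jitter_radius) else start)
  e_pts <- lapply(seq_len(nrep), function(r)
    if (jitter_on) jitter_endpoint(end, jitter_radius) else end)

  mean_ke <- sd_ke <- numeric(length(levels))
  for (i in seq_along(levels)) {
    kes <- numeric(nrep)
    for (r in seq_len(nrep))
      kes[r] <- one_ke(s_pts[[r]], e_pts[[r]], levels[i], levels[i])
    mean_ke[i] <- mean(kes)
    sd_ke[i] <- if (jitter_on && nrep > 1L) stats::sd(kes) else 0
  }
  new_ke_landscape(levels, mean_ke, sd_ke, submovement_id, space,
                   if (jitter_on) nrep else 0L)
}

new_ke_landscape <- function(levels, mean_ke, sd_ke, submovement_id, space,
                             n_replicates) {
  stopifnot(length(mean_ke) == length(levels), length(sd_ke) == length(levels),
            all(is.finite(mean_ke)), all(mean_ke >= 0))
  structure(data.frame(deviation = as.numeric(levels), mean_ke = mean_ke,
                       sd_ke = sd_ke),
            submovement_id = submovement_id, space = space,
            n_replicates = n_replicates,
            class = c("ke_landscape", "data.frame"))
}

#' @export
print.ke_landscape <- function(x, ...) {
  cat(sprintf("<KE landscape: submovement %s, %s space, %d levels [%g, %g], %d replicates/level>\n",
              attr(x, "submovement_id"), attr(x, "space"), nrow(x),
              min(x$deviation), max(x$deviation), attr(x, "n_replicates")))
  cat(sprintf("  mean KE range: %.4g .. %.4g J; argmin at deviation %g\n",
              min(x$mean_ke), max(x$mean_ke), x$deviation[which.min(x$mean_ke)]))
  invisible(x)
}

#' KE landscapes for every submovement of a task layout
#'
#' Convenience wrapper over \code{\link{build_ke_landscape}} looping over the
#' submovement catalogue of a \code{\link{task_layout}}.
#'
#' @param layout a \code{\link{task_layout}}.
#' @inheritParams build_ke_landscape
#' @return a named list of \code{ke_landscape} objects keyed by
#'   submovement id.
#' @export
build_landscapes <- function(layout, geom, space = c("hand", "joint"),
                             grid = deviation_grid(), n_replicates = 100L,
                             profile = make_time_profile(),
                             jitter_radius = layout$logical_radius) {
  space <- match.arg(space)
  cat_df <- submovement_catalog(layout)
  out <- vector("list", nrow(cat_df))
  names(out) <- cat_df$submovement_id
  for (i in seq_len(nrow(cat_df))) {
    out[[i]] <- build_ke_landscape(
      start = c(cat_df$sx[i], cat_df$sy[i]), end = c(cat_df$ex[i], cat_df$ey[i]),
      space = space, geom = geom, grid = grid, n_replicates = n_replicates,
      profile = profile, jitter_radius = jitter_radius,
      submovement_id = cat_df$submovement_id[i])
  }
  out
}

# linear-interpolation resampling of a path to n points equally spaced in
# cumulative arclength
resample_by_arclength <- function(path, n) {
  stopifnot(is.matrix(path), ncol(path) == 2L, nrow(path) >= 2L)
  seg <- sqrt(diff(path[, 1L])^2 + diff(path[, 2L])^2)
  arc <- c(0, cumsum(seg))
  if (arc[length(arc)] <= 0) stop("degenerate path: zero total arclength")
  keep <- c(TRUE, seg > 0)             # drop duplicated points for interpolation
  arc_k <- arc[keep]
  grid <- seq(0, arc[length(arc)], length.out = n)
  cbind(stats::approx(arc_k, path[keep, 1L], xout = grid)$y,
        stats::approx(arc_k, path[keep, 2L], xout = grid)$y)
}

#' Model-estimated KE of an observed hand trajectory
#'
#' Estimates the kinetic energy an observed hand path would require under the
#' canonical bell-shaped speed profile: the path's shape is kept but its own
#' timing discarded. The shape is resampled to the profile's number of points
#' at equal arclength steps (linear interpolation), re-timed with the
#' profile's timestamps, converted to joint space through
#' \code{\link{inverse_kinematics}}, and its KE computed from the resulting
#' joint velocities.
#'
#' @param hand_traj a hand-space \code{\link{trajectory}} (or any data frame
#'   with columns \code{u}, \code{v} in metres); its time stamps are ignored.
#' @param geom an \code{\link{arm_geometry}}.
#' @param profile a \code{\link{make_time_profile}} object.
#' @return scalar KE (J).
#' @export
estimate_ke_for_observed_shape <- function(hand_traj, geom,
                                           profile = make_time_profile()) {
  stopifnot(inherits(geom, "arm_geometry"), inherits(profile, "time_profile"))
  path <- resample_by_arclength(as_path_matrix(hand_traj), profile$n_points)
  jp <- inverse_kinematics(geom, path[, 1L], path[, 2L])
  ke_of_joint_path(profile$timestamps, jp[, 1L], jp[, 2L], geom)
}
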