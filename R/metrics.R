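#' Trial record
#'
#' Container for one successful trial of the sequential reaching task:
#' identifiers, the ordered target labels (centre plus the three sequence
#' targets), the times at which the hand reached each of those targets, and
#' the time-aligned kinematic streams sampled at 1 kHz.
#'
#' @param session_id,trial_id,sequence_id identifiers.
#' @param targets character length-4: \code{"C"} then the three sequence
#'   targets.
#' @param events numeric length-4: target-reach times (s), strictly
#'   increasing, within the stream's time range.
#' @param streams data frame with columns \code{t} (s), \code{x}, \code{y}
#'   (hand position, m), \code{theta_s}, \code{theta_e} (rad),
#'   \code{omega_s}, \code{omega_e} (rad/s) and \code{speed} (hand speed,
#'   m/s).
#' @return an object of class \code{trial_record}.
#' @export
trial_record <- function(session_id, trial_id, sequence_id, targets, events,
                         streams) {
  stopifnot(is.character(targets), length(targets) == 4L,
            is.numeric(events), length(events) == 4L, !is.unsorted(events, strictly = TRUE),
            is.data.frame(streams),
            all(c("t", "x", "y", "theta_s", "theta_e",
                  "omega_s", "omega_e", "speed") %in% names(streams)))
  if (events[1L] < streams$t[1L] || events[4L] > streams$t[nrow(streams)])
    stop("event times fall outside the recorded stream")
  structure(list(session_id = session_id, trial_id = trial_id,
                 sequence_id = sequence_id, targets = targets,
                 events = events, streams = streams),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial %s/%s (sequence %s): %s, %d samples, %.2f s>\n",
              x$session_id, x$trial_id, x$sequence_id,
              paste(x$targets, collapse = " > "), nrow(x$streams),
              diff(range(x$streams$t))))
  invisible(x)
}

#' Section a trial into its three submovements
#'
#' Slices the trial streams into the three point-to-point reaches between
#' consecutive target-reach events. Each slice starts at the movement onset
#' detected (\code{\link{detect_movement_onset}}) within the window between
#' reaching the start target and reaching the next target, and ends at the
#' next-target reach. Submovement ids are keyed by the (start, end) target
#' pair, so identical pairs from different sequences share an id.
#'
#' @param trial a \code{\link{trial_record}}.
#' @param threshold onset speed threshold (m/s).
#' @param min_supra_ms minimum supra-threshold duration (ms).
#' @return list of 3 elements, each a list with \code{submovement_id},
#'   \code{onset} (s), \code{hand} and \code{joint}
#'   (\code{\link{trajectory}} objects) and \code{vel} (data frame
#'   \code{t}, \code{omega_s}, \code{omega_e} of the recorded velocities over
#'   the slice).
#' @export
section_submovements <- function(trial, threshold = 0.02, min_supra_ms = 50) {
  stopifnot(inherits(trial, "trial_record"))
  st <- trial$streams
  out <- vector("list", 3L)
  for (i in 1:3) {
    win <- st$t >= trial$events[i] & st$t <= trial$events[i + 1L]
    if (sum(win) < 3L)
      stop(sprintf("submovement %d: window between events %g and %g contains too few samples",
                   i, trial$events[i], trial$events[i + 1L]))
    w <- st[win, , drop = FALSE]
    onset <- detect_movement_onset(data.frame(t = w$t, speed = w$speed),
                                   threshold, min_supra_ms)
    sl <- w[w$t >= onset, , drop = FALSE]
    out[[i]] <- list(
      submovement_id = paste(trial$targets[i], trial$targets[i + 1L], sep = ">"),
      onset = onset,
      hand = trajectory(sl$t, sl$x, sl$y, space = "hand"),
      joint = trajectory(sl$t, sl$theta_s, sl$theta_e, space = "joint"),
      vel = data.frame(t = sl$t, omega_s = sl$omega_s, omega_e = sl$omega_e))
  }
  out
}

#' Spatial variability of a bundle of trajectories
#'
#' Aligns trajectories at their onsets, computes the mean path on a regular
#' time grid (default every 10 ms), and at each grid time the scatter of the
#' individual trajectories around the mean path, measured as the root mean
#' square Euclidean distance to the mean point. The series is truncated at
#' the duration of the shortest trajectory so every trajectory contributes at
#' every grid time.
#'
#' @param trajs list of >= 2 trajectories (data frames with \code{t},
#'   \code{u}, \code{v}), each starting at its movement onset.
#' @param step_ms grid step (ms), default 10.
#' @return data frame with columns \code{t} (s since onset) and \code{sd}
#'   (same units as the trajectory coordinates).
#' @export
spatial_variability <- function(trajs, step_ms = 10) {
  if (!is.list(trajs) || length(trajs) < 2L)
    stop("spatial variability needs at least two trajectories")
  dur <- vapply(trajs, function(x) x$t[nrow(x)] - x$t[1L], numeric(1L))
  grid <- seq(0, min(dur), by = step_ms / 1000)
  us <- vapply(trajs, function(x)
    stats::approx(x$t - x$t[1L], x$u, xout = grid)$y, numeric(length(grid)))
  vs <- vapply(trajs, function(x)
    stats::approx(x$t - x$t[1L], x$v, xout = grid)$y, numeric(length(grid)))
  us <- matrix(us, nrow = length(grid))
  vs <- matrix(vs, nrow = length(grid))
  mu_u <- rowMeans(us)
  mu_v <- rowMeans(vs)
  data.frame(t = grid,
             sd = sqrt(rowMeans((us - mu_u)^2 + (vs - mu_v)^2)))
}
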