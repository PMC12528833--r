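# evaluate code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic study generator
#'
#' Parameters of the emulated multi-session reaching study. Defaults encode
#' the task's stated structure: 120-trial sessions organised as 3 blocks of
#' 40 trials (5 trials per sequence per block), ~840 ms movements, a 1.5 s
#' movement timeout (draws are clamped well inside it), 250 ms centre holds
#' and 150--200 ms target holds, endpoint scatter inside the 1 cm logical
#' radius.
#'
#' Per-submovement deviation means drift across sessions from
#' \code{deviation_initial} toward \code{deviation_target} by the factor
#' \code{1 - drift_rate} per session (exponential approach); both can be
#' scalars or named vectors keyed by submovement id.
#'
#' @param n_sessions number of sessions.
#' @param trials_per_session trials per session; must be a multiple of
#'   40 (one block = 5 trials of each of the 8 sequences).
#' @param deviation_initial,deviation_target initial and asymptotic mean
#'   signed hand deviation (a.u.), scalar or named per submovement.
#' @param drift_rate per-session approach rate in [0, 1]; 0 = stationary.
#' @param trial_sd trial-to-trial SD of the drawn deviation (a.u.).
#' @param duration_mean,duration_sd movement duration law (s); draws are
#'   clamped to [0.4, 1.4] s, inside the task's 1.5 s timeout.
#' @param speed_noise_sd multiplicative Gaussian noise SD on the time-profile
#'   intervals (renormalised to the drawn duration); 0 disables.
#' @param hold_noise_sd SD of the smooth positional jitter during holds (m),
#'   interpolated from 50 ms knots so hold speeds stay far below onset
#'   thresholds.
#' @param center_hold_s centre-target hold duration (s).
#' @param target_hold_s length-2 range of the peripheral-target hold (s),
#'   drawn uniformly.
#' @param seed integer seed driving all randomness of the study.
#' @return an object of class \code{generator_config}.
#' @export
generator_config <- function(n_sessions = 20L, trials_per_session = 120L,
                             deviation_initial = 0, deviation_target = 0,
                             drift_rate = 0.15, trial_sd = 0.05,
                             duration_mean = 0.84, duration_sd = 0.08,
                             speed_noise_sd = 0.05, hold_noise_sd = 1.5e-4,
                             center_hold_s = 0.25,
                             target_hold_s = c(0.15, 0.20),
                             seed = 1L) {
  stopifnot(n_sessions >= 1L, trials_per_session >= 40L,
            trials_per_session %% 40L == 0L,
            drift_rate >= 0, drift_rate <= 1, trial_sd > 0,
            duration_mean > 0, duration_sd >= 0,
            duration_mean + 3 * duration_sd < 1.5,   # task timeout
            speed_noise_sd >= 0, hold_noise_sd >= 0,
            center_hold_s > 0, length(target_hold_s) == 2L,
            all(target_hold_s > 0), target_hold_s[1] <= target_hold_s[2])
  structure(list(n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 deviation_initial = deviation_initial,
                 deviation_target = deviation_target,
                 drift_rate = drift_rate, trial_sd = trial_sd,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 speed_noise_sd = speed_noise_sd, hold_noise_sd = hold_noise_sd,
                 center_hold_s = center_hold_s, target_hold_s = target_hold_s,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator config: %d sessions x %d trials, drift %.2f, trial SD %.3f a.u., seed %d>\n",
              x$n_sessions, x$trials_per_session, x$drift_rate, x$trial_sd, x$seed))
  invisible(x)
}

# smooth positional jitter for hold segments: Gaussian knots every 50 ms,
# pinned to 0 at both ends, linearly interpolated to the 1 ms grid
smooth_hold_noise <- function(m, sd) {
  if (sd <= 0 || m < 2L) return(matrix(0, m, 2L))
  knots <- unique(c(seq(1L, m, by = 50L), m))
  val <- cbind(stats::rnorm(length(knots), 0, sd),
               stats::rnorm(length(knots), 0, sd))
  val[1L, ] <- 0
  val[nrow(val), ] <- 0
  if (length(knots) < 2L) return(matrix(0, m, 2L))
  cbind(stats::approx(knots, val[, 1L], xout = seq_len(m))$y,
        stats::approx(knots, val[, 2L], xout = seq_len(m))$y)
}

# one movement segment resampled to the 1 kHz grid; returns positions for
# t = 1..m ms after the segment start (the start sample belongs to the
# preceding segment). Chord progress over time is interpolated with a
# monotone (Hyman) spline so the resampled speed profile is smooth — real
# kinematic recordings are smooth at the millisecond scale, and the backward
# acceleration search of the onset detector relies on that.
movement_block <- function(from, to, deviation, duration_s, speed_noise_sd,
                           n_shape = 501L) {
  m <- max(2L, round(duration_s * 1000))
  d_s <- m / 1000
  prof <- make_time_profile(n_shape, total_duration = d_s)
  iv <- prof$intervals
  if (speed_noise_sd > 0) {
    # smooth multiplicative envelope: Gaussian log-factors at 11 knots over
    # the movement, interpolated across intervals, then renormalised so the
    # drawn duration is preserved
    knots <- seq(1L, length(iv), length.out = 11L)
    env <- stats::approx(knots, stats::rnorm(11L, 0, speed_noise_sd),
                         xout = seq_along(iv))$y
    iv <- iv * exp(env)
    iv <- iv / sum(iv) * d_s
  }
  tau <- c(0, cumsum(iv))
  tau[length(tau)] <- d_s                      # guard against rounding
  s_of_t <- stats::splinefun(tau, seq(0, 1, length.out = n_shape),
                             method = "hyman")
  s_grid <- pmin(1, pmax(0, s_of_t(seq_len(m) / 1000)))
  parabolic_point(from, to, deviation, s_grid)
}

# truncated-normal draw by rejection (falls back to clamping after 100 tries)
rtrunc_norm <- function(mean, sd, lo, hi) {
  for (i in 1:100) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

# central differences on a uniform grid, one-sided at the ends
cdiff <- function(z, dt) {
  n <- length(z)
  d <- numeric(n)
  d[1L] <- (z[2L] - z[1L]) / dt
  d[n] <- (z[n] - z[n - 1L]) / dt
  if (n > 2L) d[2:(n - 1L)] <- (z[3:n] - z[1:(n - 2L)]) / (2 * dt)
  d
}

#' Generate one synthetic trial
#'
#' Emulates one successful trial: the hand starts at a jittered point inside
#' the centre target's logical radius, holds there (smooth low-amplitude
#' positional noise), then performs the three submovements of the sequence.
#' Each movement is a parabolic path with a deviation drawn from the
#' submovement's current Gaussian law, traversed under a duration-scaled
#' inverted-Gaussian time profile with multiplicative interval noise, and
#' resampled at 1 kHz. Endpoints are jittered uniformly within the logical
#' radius; each movement starts where the previous one actually ended. Joint
#' streams follow by inverse kinematics; velocities and hand speed by
#' central differences.
#'
#' Randomness comes from the current R RNG stream: seed control belongs to
#' the caller (see \code{\link{generate_study}}).
#'
#' @param layout a \code{\link{task_layout}}.
#' @param geom an \code{\link{arm_geometry}}.
#' @param sequence character length-3: the trial's peripheral targets.
#' @param config a \code{\link{generator_config}}.
#' @param mean_dev named numeric: current mean deviation per submovement id
#'   (missing ids default to 0).
#' @param session_id,trial_id,sequence_id identifiers.
#' @return a \code{\link{trial_record}} whose attribute \code{"truth"} is a
#'   data frame with the drawn \code{deviation} and \code{duration} per
#'   submovement.
#' @export
generate_trial <- function(layout, geom, sequence, config, mean_dev = numeric(),
                           session_id = "S01", trial_id = 1L,
                           sequence_id = NA_integer_) {
  stopifnot(inherits(layout, "task_layout"), inherits(geom, "arm_geometry"),
            inherits(config, "generator_config"),
            is.character(sequence), length(sequence) == 3L)
  targets <- c("C", sequence)
  ids <- paste(targets[1:3], targets[2:4], sep = ">")

  p0 <- jitter_endpoint(layout$center, layout$logical_radius)
  blocks <- list(matrix(p0, 1L, 2L))
  event_idx <- 1L                       # sample index (1-based) of each reach

  hold_samples <- function(n) n         # readability only
  add_hold <- function(point, n) {
    noise <- smooth_hold_noise(n, config$hold_noise_sd)
    blocks[[length(blocks) + 1L]] <<- cbind(point[1L] + noise[, 1L],
                                            point[2L] + noise[, 2L])
  }

  m_center <- hold_samples(round(config$center_hold_s * 1000))
  add_hold(p0, m_center)

  truth <- data.frame(submovement_id = ids, deviation = NA_real_,
                      duration = NA_real_)
  cur <- p0
  for (i in 1:3) {
    dev_mean <- if (ids[i] %in% names(mean_dev)) mean_dev[[ids[i]]] else 0
    d <- rtrunc_norm(dev_mean, config$trial_sd, -0.5, 0.5)
    dur <- min(max(stats::rnorm(1L, config$duration_mean, config$duration_sd),
                   0.4), 1.4)
    e_pt <- jitter_endpoint(target_position(layout, targets[i + 1L]),
                            layout$logical_radius)
    mb <- movement_block(cur, e_pt, d, dur, config$speed_noise_sd)
    blocks[[length(blocks) + 1L]] <- mb
    truth$deviation[i] <- d
    truth$duration[i] <- nrow(mb) / 1000
    cur <- e_pt
    n_so_far <- sum(vapply(blocks, nrow, integer(1L)))
    event_idx <- c(event_idx, n_so_far)
    if (i < 3L)
      add_hold(cur, hold_samples(round(stats::runif(
        1L, config$target_hold_s[1L], config$target_hold_s[2L]) * 1000)))
  }

  pos <- do.call(rbind, blocks)
  n <- nrow(pos)
  t <- (seq_len(n) - 1L) / 1000
  jp <- inverse_kinematics(geom, pos[, 1L], pos[, 2L])
  vx <- cdiff(pos[, 1L], 0.001)
  vy <- cdiff(pos[, 2L], 0.001)
  streams <- data.frame(t = t, x = pos[, 1L], y = pos[, 2L],
                        theta_s = jp[, 1L], theta_e = jp[, 2L],
                        omega_s = cdiff(jp[, 1L], 0.001),
                        omega_e = cdiff(jp[, 2L], 0.001),
                        speed = sqrt(vx^2 + vy^2))
  tr <- trial_record(session_id = session_id, trial_id = trial_id,
                     sequence_id = sequence_id, targets = targets,
                     events = t[event_idx], streams = streams)
  attr(tr, "truth") <- truth
  tr
}

#' Behavioural metrics of one trial
#'
#' Sections a trial into its submovements and returns one deviation record
#' per submovement: the signed normalised deviation in hand and joint space
#' and the observed kinetic energy of the recorded velocities over the slice.
#'
#' @param trial a \code{\link{trial_record}}.
#' @param geom an \code{\link{arm_geometry}}.
#' @param threshold onset speed threshold (m/s).
#' @return data frame with columns \code{session_id}, \code{trial_id},
#'   \code{submovement_id}, \code{hand_dev}, \code{joint_dev}, \code{ke_J}.
#' @export
measure_trial <- function(trial, geom, threshold = 0.02) {
  slices <- section_submovements(trial, threshold = threshold)
  do.call(rbind, lapply(slices, function(s)
    data.frame(session_id = trial$session_id, trial_id = trial$trial_id,
               submovement_id = s$submovement_id,
               hand_dev = trajectory_deviation(s$hand),
               joint_dev = trajectory_deviation(s$joint),
               ke_J = observed_ke(s$vel, geom))))
}

#' Generate a multi-session synthetic study
#'
#' Runs the generator over \code{config$n_sessions} sessions. Each session
#' consists of \code{trials_per_session / 40} blocks of 40 trials (5 per
#' sequence, order shuffled within block). Per-submovement deviation means
#' drift from \code{deviation_initial} toward \code{deviation_target}
#' (exponential approach at \code{drift_rate} per session). All randomness
#' descends from \code{config$seed}; the caller's RNG state is restored.
#'
#' Ground truth is recorded at two levels: per session and submovement, the
#' true mean deviation and the KE of the noiseless parabolic path at that
#' deviation between exact target centres (canonical 501-point, 1 s
#' profile); and per trial, the drawn deviation and duration.
#'
#' @param config a \code{\link{generator_config}}.
#' @param layout a \code{\link{task_layout}}.
#' @param geom an \code{\link{arm_geometry}}.
#' @param process optional function applied to each \code{trial_record} as it
#'   is generated (e.g. \code{\link{measure_trial}} partial); when supplied,
#'   only its row-bound results are kept and full streams are discarded —
#'   essential for large studies.
#' @return list of class \code{kelscape_study}: \code{trials} (list of
#'   \code{trial_record}, or NULL when \code{process} is used),
#'   \code{records} (row-bound \code{process} output, or NULL),
#'   \code{truth_session}, \code{truth_trials}, \code{config}.
#' @export
generate_study <- function(config, layout = default_layout("E"),
                           geom = arm_geometry(), process = NULL) {
  stopifnot(inherits(config, "generator_config"))
  cat_df <- submovement_catalog(layout)
  ids <- cat_df$submovement_id
  expand <- function(x) {
    if (length(x) == 1L && is.null(names(x))) return(stats::setNames(rep(x, length(ids)), ids))
    out <- stats::setNames(rep(0, length(ids)), ids)
    out[intersect(names(x), ids)] <- x[intersect(names(x), ids)]
    out
  }
  initial <- expand(config$deviation_initial)
  target <- expand(config$deviation_target)
  n_blocks <- config$trials_per_session %/% 40L
  profile <- make_time_profile()

  with_seed(config$seed, {
    trials <- if (is.null(process)) vector("list", config$n_sessions * config$trials_per_session)
    records <- if (!is.null(process)) vector("list", config$n_sessions * config$trials_per_session)
    truth_trials <- vector("list", length(trials %||% records))
    truth_session <- vector("list", config$n_sessions)
    k <- 0L
    for (s in seq_len(config$n_sessions)) {
      session_id <- sprintf("S%03d", s)
      mean_dev <- target + (initial - target) * (1 - config$drift_rate)^(s - 1L)
      ke_true <- vapply(seq_along(ids), function(i) {
        path <- simulate_path(c(cat_df$sx[i], cat_df$sy[i]),
                              c(cat_df$ex[i], cat_df$ey[i]),
                              mean_dev[[ids[i]]], profile$n_points)
        jp <- inverse_kinematics(geom, path[, 1L], path[, 2L])
        ke_of_joint_path(profile$timestamps, jp[, 1L], jp[, 2L], geom)
      }, numeric(1L))
      truth_session[[s]] <- data.frame(session_id = session_id,
                                       submovement_id = ids,
                                       mean_dev = unname(mean_dev),
                                       mean_ke_J = ke_true)
      seq_order <- unlist(lapply(seq_len(n_blocks), function(b)
        sample(rep(seq_along(layout$sequences), 5L))))
      for (j in seq_along(seq_order)) {
        k <- k + 1L
        tr <- generate_trial(layout, geom, layout$sequences[[seq_order[j]]],
                             config, mean_dev, session_id = session_id,
                             trial_id = k, sequence_id = seq_order[j])
        tt <- attr(tr, "truth")
        tt$session_id <- session_id
        tt$trial_id <- k
        truth_trials[[k]] <- tt
        if (is.null(process)) trials[[k]] <- tr
        else records[[k]] <- process(tr)
      }
    }
    structure(list(trials = trials,
                   records = if (!is.null(process)) do.call(rbind, records),
                   truth_session = do.call(rbind, truth_session),
                   truth_trials = do.call(rbind, truth_trials),
                   config = config),
              class = "kelscape_study")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kelscape_study <- function(x, ...) {
  cat(sprintf("<synthetic study: %d sessions x %d trials (seed %d), %s>\n",
              x$config$n_sessions, x$config$trials_per_session, x$config$seed,
              if (is.null(x$records)) "streams kept" else
                sprintf("%d processed records", nrow(x$records))))
  invisible(x)
}
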