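#' Early/late session summary per submovement
#'
#' Compares the first \code{n_edge} and the last \code{n_edge} sessions of a
#' study: for each submovement, per-session means of \code{field} are
#' averaged over the early and late session blocks (mean of per-session
#' means, not pooled trials) and their difference reported as late - early.
#'
#' @param records data frame with columns \code{session_id},
#'   \code{submovement_id} and the column named by \code{field}.
#' @param n_edge sessions per edge block, default 10.
#' @param field name of the value column (e.g. \code{"hand_dev"},
#'   \code{"joint_dev"}, \code{"ke_J"}).
#' @return data frame with columns \code{submovement_id}, \code{early},
#'   \code{late}, \code{diff}.
#' @export
early_late_summary <- function(records, n_edge = 10L, field = "hand_dev") {
  stopifnot(is.data.frame(records),
            all(c("session_id", "submovement_id", field) %in% names(records)))
  sessions <- sort(unique(records$session_id))
  if (length(sessions) < 2L * n_edge)
    stop(sprintf("need at least %d sessions for n_edge = %d, got %d",
                 2L * n_edge, n_edge, length(sessions)))
  early_set <- sessions[seq_len(n_edge)]
  late_set <- sessions[seq.int(length(sessions) - n_edge + 1L, length(sessions))]
  per <- stats::aggregate(records[[field]],
                          by = list(session_id = records$session_id,
                                    submovement_id = records$submovement_id),
                          FUN = mean)
  ids <- sort(unique(per$submovement_id))
  early <- late <- numeric(length(ids))
  for (i in seq_along(ids)) {
    p <- per[per$submovement_id == ids[i], ]
    early[i] <- mean(p$x[p$session_id %in% early_set])
    late[i] <- mean(p$x[p$session_id %in% late_set])
  }
  data.frame(submovement_id = ids, early = early, late = late,
             diff = late - early)
}

#' Linear session trend of kinetic energy
#'
#' Ordinary least squares of per-session mean KE on session index, reporting
#' the slope and the Pearson correlation coefficient. A constant series has
#' an undefined correlation; it is reported as 0 with a warning.
#'
#' @param ke numeric vector of per-session mean KE (J), in session order;
#'   length >= 3.
#' @return list with \code{slope} (J per session) and \code{r}.
#' @export
ke_session_trend <- function(ke) {
  stopifnot(is.numeric(ke), all(is.finite(ke)))
  if (length(ke) < 3L) stop("session trend needs at least 3 sessions")
  idx <- seq_along(ke)
  if (stats::sd(ke) == 0) {
    warning("constant KE series: correlation undefined, reported as 0")
    return(list(slope = 0, r = 0))
  }
  fit <- stats::lm.fit(cbind(1, idx), ke)
  list(slope = unname(fit$coefficients[2L]), r = stats::cor(idx, ke))
}

#' Fit a variability ellipse to deviation pairs
#'
#' Summarises the scatter of (joint deviation, hand deviation) pairs by the
#' 1-SD ellipse of their covariance: axes along the covariance eigenvectors,
#' semi-axis lengths equal to the square roots of the eigenvalues, and the
#' angle of the major axis relative to the horizontal (joint-deviation) axis
#' in degrees, mapped to [-90, 90). Collinear input yields a zero minor axis
#' and a warning; fully degenerate input (no scatter at all) is an error.
#'
#' @param points matrix or data frame with two columns: joint deviation
#'   (horizontal) and hand deviation (vertical), >= 3 rows.
#' @return an object of class \code{ellipse_fit}: list with \code{center},
#'   \code{semi_axes} (major, minor), \code{angle_deg}, \code{degenerate}.
#' @export
fit_deviation_ellipse <- function(points) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 2L, nrow(p) >= 3L, all(is.finite(p)))
  cv <- stats::cov(p)
  eg <- eigen(cv, symmetric = TRUE)    # eigenvalues in decreasing order
  if (eg$values[1L] <= 1e-300)
    stop("degenerate covariance: points have no scatter")
  degenerate <- eg$values[2L] <= 1e-12 * eg$values[1L]
  if (degenerate)
    warning("degenerate covariance: points are (nearly) collinear; minor axis ~ 0")
  v <- eg$vectors[, 1L]
  ang <- atan2(v[2L], v[1L]) * 180 / pi
  if (ang >= 90) ang <- ang - 180
  if (ang < -90) ang <- ang + 180
  structure(list(center = colMeans(p),
                 semi_axes = sqrt(pmax(eg$values, 0)),
                 angle_deg = ang, degenerate = degenerate),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<deviation ellipse: centre (%.3g, %.3g), semi-axes %.3g / %.3g, major axis %.1f deg%s>\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
              x$angle_deg, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Cosine k-means classification of submovements
#'
#' Clusters submovements by the direction of their mean (joint deviation,
#' hand deviation) vector using k-means under the cosine distance
#' \code{1 - cos(x, c)} (observations are scale-invariant: only direction
#' matters). Lloyd iterations with \code{n_init} random restarts; centroids
#' are means of the unit-normalised members. Labels are canonicalised so that
#' class 1 is the cluster whose centroid has the smallest absolute
#' joint-deviation component (the "straight-in-joint-space" class).
#'
#' @param x matrix or data frame with two columns (joint deviation, hand
#'   deviation), one row per submovement; no zero rows.
#' @param k number of classes, default 2.
#' @param n_init random restarts, default 10.
#' @param max_iter Lloyd iteration cap.
#' @return integer vector of class labels in 1..k with attribute
#'   \code{centroids} (k x 2) and attribute \code{degenerate} flagging
#'   single-direction input (all labels 1).
#' @export
cluster_submovement_classes <- function(x, k = 2L, n_init = 10L,
                                        max_iter = 100L) {
  p <- as.matrix(x)
  stopifnot(ncol(p) == 2L, all(is.finite(p)), k >= 1L)
  nrm <- sqrt(rowSums(p^2))
  if (any(nrm == 0)) stop("zero deviation vector: direction undefined")
  xn <- p / nrm
  n <- nrow(xn)
  if (n < k) stop("fewer observations than classes")
  # degenerate: every observation points the same way
  if (max(1 - xn %*% xn[1L, ]) < 1e-12) {
    warning("all submovements share one direction: single effective cluster")
    return(structure(rep(1L, n), centroids = xn[1L, , drop = FALSE],
                     degenerate = TRUE))
  }
  best <- NULL
  best_cost <- Inf
  for (init in seq_len(n_init)) {
    cen <- xn[sample.int(n, k), , drop = FALSE]
    lab <- integer(n)
    for (it in seq_len(max_iter)) {
      cn <- cen / sqrt(rowSums(cen^2))
      sim <- xn %*% t(cn)
      new_lab <- max.col(sim, ties.method = "first")
      for (j in seq_len(k)) {           # re-seed empty clusters at the worst fit
        if (!any(new_lab == j)) {
          far <- which.min(sim[cbind(seq_len(n), new_lab)])
          new_lab[far] <- j
        }
      }
      if (identical(new_lab, lab)) break
      lab <- new_lab
      cen <- do.call(rbind, lapply(seq_len(k), function(j)
        colMeans(xn[lab == j, , drop = FALSE])))
    }
    cn <- cen / sqrt(rowSums(cen^2))
    cost <- sum(1 - (xn * cn[lab, , drop = FALSE]) %*% c(1, 1))
    if (cost < best_cost) {
      best_cost <- cost
      best <- list(lab = lab, cen = cen)
    }
  }
  ord <- order(abs(best$cen[, 1L]) / sqrt(rowSums(best$cen^2)))
  relabel <- match(seq_len(k), ord)
  structure(relabel[best$lab],
            centroids = best$cen[ord, , drop = FALSE], degenerate = FALSE)
}
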