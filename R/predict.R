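#' Effective deviation range
#'
#' The behaviourally relevant span of hand deviations for one subject: the
#' central \code{coverage} empirical quantile range (default the central 98%,
#' i.e. the [1%, 99%] quantiles) of all hand-trajectory deviations pooled
#' across submovements and sessions.
#'
#' @param deviations numeric vector of pooled signed hand deviations (a.u.),
#'   length >= 100.
#' @param coverage central coverage fraction, default 0.98.
#' @return list of class \code{effective_range} with \code{lo}, \code{hi},
#'   \code{coverage}, \code{degenerate} (TRUE when the range has zero width).
#' @export
effective_deviation_range <- function(deviations, coverage = 0.98) {
  stopifnot(is.numeric(deviations), coverage > 0, coverage < 1)
  deviations <- deviations[is.finite(deviations)]
  if (length(deviations) < 100L)
    stop("effective range needs at least 100 deviation values")
  tail_p <- (1 - coverage) / 2
  q <- unname(stats::quantile(deviations, c(tail_p, 1 - tail_p)))
  degenerate <- q[2L] <= q[1L]
  if (degenerate)
    warning("degenerate effective range: zero width")
  structure(list(lo = q[1L], hi = q[2L], coverage = coverage,
                 degenerate = degenerate),
            class = "effective_range")
}

#' @rdname effective_deviation_range
#' @param lo,hi explicit range bounds (a.u.), \code{lo < hi}; use when the
#'   range is stipulated rather than estimated from pooled deviations.
#' @export
effective_range <- function(lo, hi, coverage = 0.98) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
  structure(list(lo = lo, hi = hi, coverage = coverage, degenerate = FALSE),
            class = "effective_range")
}

#' @export
print.effective_range <- function(x, ...) {
  cat(sprintf("<effective deviation range: [%.3f, %.3f] a.u. (central %g%%)%s>\n",
              x$lo, x$hi, 100 * x$coverage, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

in_range_idx <- function(landscape, range) {
  which(landscape$deviation >= range$lo - 1e-12 &
          landscape$deviation <= range$hi + 1e-12)
}

#' KE-variability threshold for the landscape slope
#'
#' The typical fluctuation of modeled KE within the behaviourally relevant
#' deviations: the standard deviation (population form, dividing by the
#' count) of the landscape's mean KE over the grid levels that fall inside
#' the effective range. This value is used directly as the threshold on the
#' absolute first derivative of the landscape.
#'
#' @param landscape a \code{\link{build_ke_landscape}} object.
#' @param range an \code{\link{effective_deviation_range}}.
#' @return scalar threshold (J per unit deviation).
#' @export
kels_threshold <- function(landscape, range) {
  stopifnot(inherits(landscape, "ke_landscape"), inherits(range, "effective_range"))
  idx <- in_range_idx(landscape, range)
  if (length(idx) < 2L)
    stop("effective range overlaps fewer than 2 landscape levels")
  ke <- landscape$mean_ke[idx]
  sqrt(mean((ke - mean(ke))^2))
}

#' Safe-range (KE-LS) prediction for one submovement
#'
#' Identifies the "safe KE range": the longest contiguous stretch of grid
#' levels inside the effective range where the absolute first derivative of
#' the modeled KE with respect to deviation stays below \code{threshold}.
#' The derivative is estimated by central differences on the (possibly
#' non-uniform) grid, one-sided at the grid edges. Ties between equally long
#' stretches are broken toward the stretch with the lower mean KE, then
#' toward the stretch whose centre is nearer 0. The KE-LS point prediction
#' is the median grid level of the safe range (for an even-length run, the
#' lower-middle level, keeping predictions on-grid).
#'
#' When every in-range level has a derivative at or above the threshold (a
#' landscape that is steep and monotone throughout the effective range, which
#' can genuinely occur), there is no safe range. The default is an error;
#' \code{fallback = "flattest"} instead degenerates the safe range to the
#' single in-range level with the smallest absolute derivative and flags the
#' prediction (\code{degenerate = TRUE}), which keeps multi-submovement
#' pipelines running.
#'
#' @param landscape a \code{\link{build_ke_landscape}} object.
#' @param threshold slope threshold (J per a.u.), e.g. from
#'   \code{\link{kels_threshold}}.
#' @param range an \code{\link{effective_deviation_range}}.
#' @param fallback behaviour when no level qualifies: \code{"error"}
#'   (default) or \code{"flattest"}.
#' @return list of class \code{kels_prediction} with \code{safe_range}
#'   (length-2), \code{kels_pred}, \code{threshold_used},
#'   \code{submovement_id}, \code{degenerate}.
#' @export
kels_predict <- function(landscape, threshold, range,
                         fallback = c("error", "flattest")) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(landscape, "ke_landscape"), is.numeric(threshold),
            inherits(range, "effective_range"))
  lev <- landscape$deviation
  ke <- landscape$mean_ke
  n <- length(lev)
  deriv <- numeric(n)
  deriv[1L] <- (ke[2L] - ke[1L]) / (lev[2L] - lev[1L])
  deriv[n] <- (ke[n] - ke[n - 1L]) / (lev[n] - lev[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    deriv[i] <- (ke[i + 1L] - ke[i - 1L]) / (lev[i + 1L] - lev[i - 1L])
  }
  idx <- in_range_idx(landscape, range)
  if (length(idx) == 0L) stop("effective range overlaps no landscape levels")
  ok <- abs(deriv[idx]) < threshold
  degenerate <- !any(ok)
  if (degenerate) {
    if (fallback == "error")
      stop("no landscape level has |dKE/ddev| below the threshold")
    ok[which.min(abs(deriv[idx]))] <- TRUE
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  len <- runs$lengths[cand]
  best <- cand[len == max(len)]
  if (length(best) > 1L) {              # tie: lower mean KE wins
    mk <- vapply(best, function(b)
      mean(ke[idx[starts[b]:ends[b]]]), numeric(1L))
    best <- best[mk == min(mk)]
    if (length(best) > 1L) {            # still tied: centre nearest 0
      ctr <- vapply(best, function(b)
        abs(mean(lev[idx[c(starts[b], ends[b])]])), numeric(1L))
      best <- best[which.min(ctr)]
    } else best <- best[1L]
  }
  sel <- idx[starts[best[1L]]:ends[best[1L]]]
  run_lev <- lev[sel]
  m <- length(run_lev)
  kels_pred <- run_lev[ceiling(m / 2)]  # lower-middle for even m
  structure(list(safe_range = c(run_lev[1L], run_lev[m]),
                 kels_pred = kels_pred, threshold_used = threshold,
                 submovement_id = attr(landscape, "submovement_id"),
                 degenerate = degenerate),
            class = "kels_prediction")
}

#' @export
print.kels_prediction <- function(x, ...) {
  cat(sprintf("<KE-LS prediction (%s): safe range [%g, %g], median %g a.u. (threshold %.4g J/a.u.)>\n",
              x$submovement_id, x$safe_range[1], x$safe_range[2],
              x$kels_pred, x$threshold_used))
  invisible(x)
}

#' Minimum-KE prediction
#'
#' The deviation level at which the landscape's mean KE is smallest. Ties are
#' broken toward the smallest absolute deviation, and between equal absolute
#' values toward the negative level.
#'
#' @param landscape a \code{\link{build_ke_landscape}} object.
#' @return scalar deviation (a.u.).
#' @export
minke_predict <- function(landscape) {
  stopifnot(inherits(landscape, "ke_landscape"), nrow(landscape) >= 1L)
  i <- which(landscape$mean_ke == min(landscape$mean_ke))
  if (length(i) > 1L) {
    lev <- landscape$deviation[i]
    lev <- lev[order(abs(lev), lev)]    # smallest |dev|, negative first
    return(lev[1L])
  }
  landscape$deviation[i]
}

#' Resampled RMSE comparison of prediction methods
#'
#' Evaluates competing per-submovement deviation predictions against the
#' observed (late-session) mean deviations by repeated random k-fold
#' partitioning: in each repeat the submovements are shuffled and split into
#' \code{n_folds} near-equal folds, and the RMSE of each method is computed
#' on every fold (identical partitions across methods within a repeat),
#' yielding \code{n_folds * n_repeats} RMSE values per method.
#'
#' @param preds named list of numeric prediction vectors, all aligned with
#'   \code{observed} (e.g. \code{list(kels = ..., minke = ..., zero = ...)}).
#' @param observed numeric vector of observed late-session mean deviations.
#' @param n_folds folds per repeat, default 5.
#' @param n_repeats repeats, default 20.
#' @return data frame with columns \code{method}, \code{repeat_id},
#'   \code{fold}, \code{rmse}.
#' @export
compare_predictions <- function(preds, observed, n_folds = 5L, n_repeats = 20L) {
  stopifnot(is.list(preds), length(preds) >= 1L, !is.null(names(preds)),
            all(vapply(preds, length, integer(1L)) == length(observed)))
  n <- length(observed)
  if (n < n_folds) stop("fewer submovements than folds")
  res <- vector("list", n_repeats)
  fold_of <- rep(seq_len(n_folds), length.out = n)
  for (rep_i in seq_len(n_repeats)) {
    perm <- sample.int(n)
    assign_f <- integer(n)
    assign_f[perm] <- fold_of
    rows <- expand.grid(method = names(preds), fold = seq_len(n_folds),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows$repeat_id <- rep_i
    rows$rmse <- mapply(function(m, f) {
      e <- preds[[m]][assign_f == f] - observed[assign_f == f]
      sqrt(mean(e^2))
    }, rows$method, rows$fold)
    res[[rep_i]] <- rows
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("method", "repeat_id", "fold", "rmse")]
}

#' Predicted versus observed change in deviation
#'
#' For each submovement the predicted change is the KE-LS prediction minus
#' the early-session median deviation; the function correlates these with the
#' observed changes (late minus early) and reports the Pearson correlation
#' and the OLS slope of observed on predicted.
#'
#' @param early_median numeric vector of early-session median deviations.
#' @param kels_pred numeric vector of KE-LS predictions, same length.
#' @param observed_change numeric vector of observed deviation changes
#'   (late - early), same length.
#' @return list with \code{r}, \code{slope}, \code{predicted_change}.
#' @export
predicted_vs_observed_change <- function(early_median, kels_pred,
                                         observed_change) {
  stopifnot(length(early_median) >= 3L,
            length(kels_pred) == length(early_median),
            length(observed_change) == length(early_median))
  predicted <- kels_pred - early_median
  if (stats::sd(predicted) == 0 || stats::sd(observed_change) == 0)
    stop("degenerate variance: predicted or observed changes are constant")
  fit <- stats::lm.fit(cbind(1, predicted), observed_change)
  list(r = stats::cor(predicted, observed_change),
       slope = unname(fit$coefficients[2L]),
       predicted_change = predicted)
}
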