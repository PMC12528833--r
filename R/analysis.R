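#' Run the full landscape-and-prediction analysis on a synthetic study
#'
#' End-to-end pipeline in the order of the underlying analysis: (1) generate
#' the synthetic study and reduce every trial to deviation records
#' (\code{\link{measure_trial}}); (2) build jittered hand-space KE landscapes
#' for every submovement; (3) derive the subject's effective deviation range
#' from the pooled observed hand deviations, the per-submovement slope
#' thresholds, and the KE-LS, minimum-KE and zero-deviation predictions;
#' (4) summarise observed deviations into early/late session means and
#' compare the three predictors against late-session behaviour with the
#' repeated 5-fold RMSE procedure and the predicted-versus-observed change
#' correlation; (5) per-submovement KE session trends and the cosine k-means
#' submovement classes.
#'
#' All randomness descends from \code{config$seed} (study) and fixed offsets
#' of it (landscape jitter, fold resampling, k-means restarts); reruns with
#' the same configuration are identical.
#'
#' @param config a \code{\link{generator_config}}.
#' @param layout a \code{\link{task_layout}}.
#' @param geom an \code{\link{arm_geometry}}.
#' @param grid a \code{\link{deviation_grid}}.
#' @param n_replicates jittered replicates per landscape level.
#' @param profile a \code{\link{make_time_profile}} object.
#' @param coverage effective-range coverage, default 0.98.
#' @param n_folds,n_repeats RMSE resampling design, default 5 x 20.
#' @param n_edge sessions per early/late block; default 10, reduced to
#'   \code{n_sessions \%/\% 2} for short studies.
#' @param onset_threshold onset speed threshold (m/s).
#' @param out_dir optional directory: when given, the deviation, landscape,
#'   prediction and RMSE tables are written there as CSV.
#' @return list of class \code{kelscape_report} with elements
#'   \code{records}, \code{landscapes}, \code{effective_range},
#'   \code{predictions} (data frame), \code{summary} (early/late means),
#'   \code{rmse}, \code{change} (predicted-vs-observed correlation),
#'   \code{trends}, \code{classes}, \code{truth_session}, \code{config}.
#' @export
run_full_analysis <- function(config, layout = default_layout("E"),
                              geom = arm_geometry(),
                              grid = deviation_grid(), n_replicates = 100L,
                              profile = make_time_profile(),
                              coverage = 0.98, n_folds = 5L, n_repeats = 20L,
                              n_edge = min(10L, config$n_sessions %/% 2L),
                              onset_threshold = 0.02, out_dir = NULL) {
  study <- generate_study(config, layout, geom,
                          process = function(tr) measure_trial(tr, geom, onset_threshold))
  records <- study$records

  landscapes <- with_seed(config$seed + 1000L,
    build_landscapes(layout, geom, space = "hand", grid = grid,
                     n_replicates = n_replicates, profile = profile))

  eff <- effective_deviation_range(records$hand_dev, coverage)

  ids <- names(landscapes)
  preds <- do.call(rbind, lapply(ids, function(id) {
    ls <- landscapes[[id]]
    thr <- kels_threshold(ls, eff)
    kp <- kels_predict(ls, thr, eff, fallback = "flattest")
    data.frame(submovement_id = id, kels_pred = kp$kels_pred,
               safe_lo = kp$safe_range[1L], safe_hi = kp$safe_range[2L],
               minke_pred = minke_predict(ls), zero_pred = 0,
               threshold_used = thr)
  }))

  summ <- early_late_summary(records, n_edge = n_edge, field = "hand_dev")
  summ <- summ[match(ids, summ$submovement_id), ]
  sessions <- sort(unique(records$session_id))
  early_set <- sessions[seq_len(n_edge)]
  early_median <- vapply(ids, function(id)
    stats::median(records$hand_dev[records$submovement_id == id &
                                     records$session_id %in% early_set]),
    numeric(1L))

  rmse <- with_seed(config$seed + 2000L,
    compare_predictions(list(kels = preds$kels_pred, minke = preds$minke_pred,
                             zero = preds$zero_pred),
                        observed = summ$late,
                        n_folds = n_folds, n_repeats = n_repeats))

  change <- predicted_vs_observed_change(early_median, preds$kels_pred,
                                         summ$diff)

  per_sess_ke <- stats::aggregate(records$ke_J,
    by = list(session_id = records$session_id,
              submovement_id = records$submovement_id), FUN = mean)
  trends <- do.call(rbind, lapply(ids, function(id) {
    ke <- per_sess_ke$x[per_sess_ke$submovement_id == id][
      order(per_sess_ke$session_id[per_sess_ke$submovement_id == id])]
    tr <- ke_session_trend(ke)
    data.frame(submovement_id = id, slope = tr$slope, r = tr$r)
  }))

  mean_dirs <- cbind(
    joint = vapply(ids, function(id)
      mean(records$joint_dev[records$submovement_id == id]), numeric(1L)),
    hand = vapply(ids, function(id)
      mean(records$hand_dev[records$submovement_id == id]), numeric(1L)))
  classes <- with_seed(config$seed + 3000L,
                       cluster_submovement_classes(mean_dirs))

  report <- structure(
    list(records = records, landscapes = landscapes, effective_range = eff,
         predictions = preds, summary = summ, rmse = rmse, change = change,
         trends = trends,
         classes = data.frame(submovement_id = ids,
                              class = as.integer(classes)),
         truth_session = study$truth_session, config = config),
    class = "kelscape_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_kelscape_table(records, file.path(out_dir, "deviations.csv"),
                         "deviations")
    write_kelscape_table(as_landscape_table(landscapes),
                         file.path(out_dir, "landscape.csv"), "landscape")
    write_kelscape_table(preds, file.path(out_dir, "predictions.csv"),
                         "predictions")
    write_kelscape_table(rmse, file.path(out_dir, "rmse.csv"), "rmse")
  }
  report
}

#' @export
print.kelscape_report <- function(x, ...) {
  cat("Kinetic-energy landscape analysis report\n")
  cat(sprintf("  study     : %d sessions x %d trials (seed %d), %d deviation records\n",
              x$config$n_sessions, x$config$trials_per_session,
              x$config$seed, nrow(x$records)))
  cat(sprintf("  eff range : [%.3f, %.3f] a.u.\n",
              x$effective_range$lo, x$effective_range$hi))
  cat(sprintf("  change    : predicted-vs-observed r = %.3f, slope = %.3f\n",
              x$change$r, x$change$slope))
  mr <- tapply(x$rmse$rmse, x$rmse$method, mean)
  cat("  mean RMSE :", paste(sprintf("%s = %.4f", names(mr), mr),
                             collapse = ", "), "\n")
  invisible(x)
}
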