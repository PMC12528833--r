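#' Delimited-text table schemas
#'
#' All tables the package reads and writes are plain UTF-8 CSV with a header
#' row and '.' decimal separator. Units are fixed: metres, radians, seconds,
#' joules, and dimensionless a.u. for normalised deviations.
#'
#' Known types and their required columns:
#' \describe{
#'   \item{trajectories}{\code{t_s}, \code{u}, \code{v}, \code{space},
#'     \code{trial_id}, \code{submovement_id}; \code{t_s} must be strictly
#'     increasing within each (trial, submovement) group.}
#'   \item{events}{\code{trial_id}, \code{slot}, \code{submovement_id},
#'     \code{reach_time_s}.}
#'   \item{deviations}{\code{session_id}, \code{trial_id},
#'     \code{submovement_id}, \code{hand_dev}, \code{joint_dev}, \code{ke_J}.}
#'   \item{landscape}{\code{submovement_id}, \code{space}, \code{deviation},
#'     \code{mean_ke_J}, \code{sd_ke_J}, \code{n_replicates}.}
#'   \item{predictions}{\code{submovement_id}, \code{kels_pred},
#'     \code{safe_lo}, \code{safe_hi}, \code{minke_pred}, \code{zero_pred},
#'     \code{threshold_used}.}
#'   \item{rmse}{\code{method}, \code{repeat_id}, \code{fold}, \code{rmse}.}
#' }
#'
#' @name table_schemas
NULL

kelscape_schemas <- list(
  trajectories = c("t_s", "u", "v", "space", "trial_id", "submovement_id"),
  events = c("trial_id", "slot", "submovement_id", "reach_time_s"),
  deviations = c("session_id", "trial_id", "submovement_id",
                 "hand_dev", "joint_dev", "ke_J"),
  landscape = c("submovement_id", "space", "deviation",
                "mean_ke_J", "sd_ke_J", "n_replicates"),
  predictions = c("submovement_id", "kels_pred", "safe_lo", "safe_hi",
                  "minke_pred", "zero_pred", "threshold_used"),
  rmse = c("method", "repeat_id", "fold", "rmse"))

check_schema <- function(x, type) {
  req <- kelscape_schemas[[type]]
  if (is.null(req)) stop("unknown table type: ", type)
  missing <- setdiff(req, names(x))
  if (length(missing))
    stop(sprintf("%s table is missing required column(s): %s",
                 type, paste(missing, collapse = ", ")))
  extra <- setdiff(names(x), req)
  if (length(extra))
    warning(sprintf("%s table has unknown column(s) (preserved): %s",
                    type, paste(extra, collapse = ", ")))
  if (type == "trajectories") {
    key <- paste(x$trial_id, x$submovement_id)
    bad <- tapply(x$t_s, key, function(t) any(diff(t) <= 0))
    if (any(unlist(bad)))
      stop("trajectories table: t_s not strictly increasing in group(s): ",
           paste(names(bad)[unlist(bad)], collapse = ", "))
  }
  invisible(x)
}

#' Write an analysis table
#'
#' @param x data frame conforming to one of the \link{table_schemas}.
#' @param path output file path.
#' @param type schema name (see \link{table_schemas}).
#' @return \code{path}, invisibly.
#' @export
write_kelscape_table <- function(x, path, type) {
  check_schema(x, type)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate an analysis table
#'
#' @param path input file path.
#' @param type schema name (see \link{table_schemas}).
#' @return the validated data frame; unknown extra columns are preserved
#'   with a warning, missing required columns are an error.
#' @export
read_kelscape_table <- function(path, type) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(x, type)
  x
}

#' Flatten a list of KE landscapes to the landscape table schema
#'
#' @param landscapes named list of \code{\link{build_ke_landscape}} objects.
#' @return data frame in the \code{landscape} schema of
#'   \link{table_schemas}.
#' @export
as_landscape_table <- function(landscapes) {
  do.call(rbind, lapply(landscapes, function(ls)
    data.frame(submovement_id = attr(ls, "submovement_id"),
               space = attr(ls, "space"),
               deviation = ls$deviation,
               mean_ke_J = ls$mean_ke, sd_ke_J = ls$sd_ke,
               n_replicates = attr(ls, "n_replicates"),
               row.names = NULL)))
}
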