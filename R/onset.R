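#' Detect movement onset from a hand-speed stream
#'
#' Three-step onset detector. (1) Find contiguous segments where speed
#' exceeds \code{threshold}. (2) Reject segments that stay above threshold
#' for less than \code{min_supra_ms} (noise blips). (3) From the threshold
#' crossing of the first surviving segment, walk backwards to the most recent
#' zero-crossing of acceleration from non-positive to positive — the foot of
#' the speed bell — and report that sample's time. If acceleration is
#' positive all the way back to the start of the stream, the first sample is
#' returned with a warning.
#'
#' @param speed data frame with columns \code{t} (s, strictly increasing) and
#'   \code{speed} (m/s), spanning at least 100 ms.
#' @param threshold speed threshold (m/s), > 0. Task-specific: tune per
#'   dataset (the synthetic generator's default regime works with 0.05 m/s).
#' @param min_supra_ms minimum supra-threshold duration (ms), default 50.
#' @return onset time (s).
#' @export
detect_movement_onset <- function(speed, threshold, min_supra_ms = 50) {
  stopifnot(is.data.frame(speed), all(c("t", "speed") %in% names(speed)),
            is.numeric(threshold), threshold > 0)
  t <- speed$t
  v <- speed$speed
  if (length(t) < 2L || (t[length(t)] - t[1L]) < 0.1)
    stop("speed stream must span at least 100 ms")
  if (any(diff(t) <= 0)) stop("speed stream time stamps must be strictly increasing")

  supra <- v > threshold
  runs <- rle(supra)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  cand <- cand[t[ends[cand]] - t[starts[cand]] >= min_supra_ms / 1000 - 1e-12]
  if (length(cand) == 0L)
    stop(sprintf("no movement onset: speed never stays above %.3g m/s for >= %g ms",
                 threshold, min_supra_ms))
  crossing <- starts[cand[1L]]

  acc <- diff(v) / diff(t)             # acc[k] over interval [k, k+1]
  k <- crossing - 1L
  while (k >= 1L && acc[k] > 0) k <- k - 1L
  if (k < 1L && acc[1L] > 0) {
    warning("no acceleration zero-crossing before the threshold crossing; onset set to the first sample")
    return(t[1L])
  }
  t[k + 1L]
}
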