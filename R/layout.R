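#' Hexagonal reaching-task layout
#'
#' The workspace geometry of the sequential reaching task: a central target
#' surrounded by six targets at the vertices of a (non-regular) hexagon, an
#' invisible target-acceptance disk of \code{logical_radius} around every
#' target, and a set of ordered three-target sequences. Targets are named
#' \code{"C"} (centre) and \code{"T1"} .. \code{"T6"} counter-clockwise from
#' the top (\code{T1} top, \code{T4} bottom, \code{T2}/\code{T3} right side,
#' \code{T5}/\code{T6} left side).
#'
#' @param center numeric length-2 centre-target position (m), in shoulder
#'   coordinates.
#' @param center_to_top distance from the centre to the top and bottom
#'   vertices (m).
#' @param center_to_side distance from the centre to the four oblique side
#'   vertices (m).
#' @param logical_radius target-acceptance radius (m).
#' @param sequences list of character vectors of length 3 naming the
#'   peripheral targets of each sequence, in order.
#' @return an object of class \code{task_layout}.
#' @export
task_layout <- function(center = c(0, 0.25),
                        center_to_top = 0.036, center_to_side = 0.045,
                        logical_radius = 0.01,
                        sequences = default_sequences()) {
  stopifnot(is.numeric(center), length(center) == 2L,
            center_to_top > 0, center_to_side > 0, logical_radius > 0,
            is.list(sequences), length(sequences) >= 1L)
  ang <- c(T1 = 90, T2 = 30, T3 = -30, T4 = -90, T5 = -150, T6 = 150) * pi / 180
  rad <- c(T1 = center_to_top, T2 = center_to_side, T3 = center_to_side,
           T4 = center_to_top, T5 = center_to_side, T6 = center_to_side)
  vertices <- cbind(x = center[1L] + rad * cos(ang),
                    y = center[2L] + rad * sin(ang))
  rownames(vertices) <- names(ang)
  if (anyDuplicated(round(vertices, 12))) stop("hexagon vertices must be distinct")
  ok <- vapply(sequences, function(s)
    is.character(s) && length(s) == 3L && all(s %in% rownames(vertices)),
    logical(1L))
  if (!all(ok)) stop("each sequence must name 3 valid peripheral targets")
  structure(list(center = as.numeric(center), vertices = vertices,
                 logical_radius = logical_radius, sequences = sequences,
                 center_to_top = center_to_top, center_to_side = center_to_side),
            class = "task_layout")
}

#' @export
print.task_layout <- function(x, ...) {
  cat(sprintf("<task layout: hexagon + centre at (%.3f, %.3f) m, top %.1f cm, side %.1f cm,\n",
              x$center[1], x$center[2], 100 * x$center_to_top, 100 * x$center_to_side))
  cat(sprintf("  logical radius %.1f cm, %d sequences, %d unique submovements>\n",
              100 * x$logical_radius, length(x$sequences),
              nrow(submovement_catalog(x))))
  invisible(x)
}

#' Default sequence set
#'
#' A reconstruction of the task's eight three-target sequences. The exact
#' target orders used with the animals are not published; this canonical set
#' is chosen so that the 24 directed (start, end) pairs across all sequence
#' slots (including the initial centre-to-target reach) collapse to 19
#' unique submovements, the structure all downstream analyses assume. It can
#' be replaced through the \code{sequences} argument of
#' \code{\link{task_layout}}.
#'
#' @return list of 8 character triples.
#' @export
default_sequences <- function() {
  list(c("T1", "T2", "T3"), c("T2", "T4", "T6"), c("T3", "T5", "T1"),
       c("T4", "T3", "T6"), c("T5", "T6", "T2"), c("T6", "T1", "T4"),
       c("T1", "T4", "T3"), c("T2", "T3", "T1"))
}

#' Monkey-like default layouts
#'
#' Two preset layouts matching the published workspace scales: profile
#' \code{"E"} uses 3.6 cm centre-to-top and 4.5 cm centre-to-side distances,
#' profile \code{"J"} uses 4 cm and 5 cm.
#'
#' @param profile \code{"E"} or \code{"J"}.
#' @param ... passed on to \code{\link{task_layout}}.
#' @return a \code{\link{task_layout}}.
#' @export
default_layout <- function(profile = c("E", "J"), ...) {
  profile <- match.arg(profile)
  if (profile == "E")
    task_layout(center_to_top = 0.036, center_to_side = 0.045, ...)
  else
    task_layout(center_to_top = 0.040, center_to_side = 0.050, ...)
}

#' Target position by name
#'
#' @param layout a \code{\link{task_layout}}.
#' @param name \code{"C"} or one of \code{"T1"} .. \code{"T6"}.
#' @return numeric length-2 position (m).
#' @export
target_position <- function(layout, name) {
  stopifnot(inherits(layout, "task_layout"), is.character(name), length(name) == 1L)
  if (name == "C") return(layout$center)
  if (!name %in% rownames(layout$vertices)) stop("unknown target: ", name)
  as.numeric(layout$vertices[name, ])
}

#' Catalogue of unique submovements
#'
#' Enumerates the directed (start, end) target pairs over all sequence slots
#' — centre to first target, first to second, second to third — and collapses
#' identical pairs occurring in different sequences into one submovement, the
#' fundamental unit of all analyses. Ids are \code{"start>end"}.
#'
#' @param layout a \code{\link{task_layout}}.
#' @return data frame with columns \code{submovement_id}, \code{start},
#'   \code{end}, \code{sx}, \code{sy}, \code{ex}, \code{ey}, in order of
#'   first occurrence.
#' @export
submovement_catalog <- function(layout) {
  stopifnot(inherits(layout, "task_layout"))
  pairs <- do.call(rbind, lapply(layout$sequences, function(s) {
    nodes <- c("C", s)
    cbind(start = nodes[1:3], end = nodes[2:4])
  }))
  id <- paste(pairs[, "start"], pairs[, "end"], sep = ">")
  keep <- !duplicated(id)
  out <- data.frame(submovement_id = id[keep],
                    start = pairs[keep, "start"], end = pairs[keep, "end"],
                    stringsAsFactors = FALSE)
  sp <- t(vapply(out$start, function(n) target_position(layout, n), numeric(2L)))
  ep <- t(vapply(out$end, function(n) target_position(layout, n), numeric(2L)))
  out$sx <- sp[, 1L]; out$sy <- sp[, 2L]
  out$ex <- ep[, 1L]; out$ey <- ep[, 2L]
  rownames(out) <- NULL
  out
}
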