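#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule records, for each reconstructed frame, its start time and
#' duration in minutes since injection. Frame mid-times (`mid_min`) are the
#' nominal sampling times used when a frame is treated as a point measurement.
#'
#' @param start_min Frame start times, minutes since injection, strictly
#'   increasing.
#' @param duration_min Frame durations in minutes, all positive. Frames may be
#'   contiguous or gapped but must not overlap out of order.
#' @return A tibble of class `frame_schedule` with columns `start_min`,
#'   `duration_min`, `mid_min`, `end_min`.
#' @examples
#' frame_schedule(c(0, 1, 2), c(1, 1, 2))
#' default_frame_schedule()
#' @export
frame_schedule <- function(start_min, duration_min) {
  if (length(start_min) != length(duration_min))
    abort("start_min and duration_min must have equal length")
  if (length(start_min) < 1L) abort("schedule needs at least one frame")
  if (any(!is.finite(start_min)) || any(!is.finite(duration_min)))
    abort("schedule times must be finite")
  if (any(duration_min <= 0)) abort("frame durations must be positive")
  if (any(diff(start_min) <= 0))
    abort("frame start times must be strictly increasing")
  out <- tibble(
    start_min = as.numeric(start_min),
    duration_min = as.numeric(duration_min),
    mid_min = as.numeric(start_min) + as.numeric(duration_min) / 2,
    end_min = as.numeric(start_min) + as.numeric(duration_min)
  )
  class(out) <- c("frame_schedule", class(out))
  out
}

#' Default 60-minute dynamic FLT schedule
#'
#' A conventional variable-length framing for a one-hour liver acquisition:
#' 6 x 10 s, 8 x 15 s, 6 x 60 s, 5 x 120 s, 8 x 300 s (33 frames, 59 min).
#' The framing is a simulator/config default, not a claim about any particular
#' scanner protocol.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur_s <- c(rep(10, 6), rep(15, 8), rep(60, 6), rep(120, 5), rep(300, 8))
  dur <- dur_s / 60
  frame_schedule(start_min = cumsum(c(0, dur[-length(dur)])),
                 duration_min = dur)
}

#' Read/write a frame schedule as sidecar JSON
#'
#' The sidecar format is a JSON object
#' `{"frame_start_min": [...], "frame_duration_min": [...]}`.
#'
#' @param path File path.
#' @param schedule A [frame_schedule()].
#' @return `read_frame_schedule()` returns a [frame_schedule()];
#'   `write_frame_schedule()` returns `path` invisibly.
#' @export
read_frame_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$frame_start_min) || is.null(x$frame_duration_min))
    abort("timing JSON must contain frame_start_min and frame_duration_min")
  frame_schedule(x$frame_start_min, x$frame_duration_min)
}

#' @rdname read_frame_schedule
#' @export
write_frame_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  jsonlite::write_json(
    list(frame_start_min = schedule$start_min,
         frame_duration_min = schedule$duration_min),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}
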