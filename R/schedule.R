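#' Frame schedule
#'
#' An acquisition frame schedule: frame start times and durations.  All
#' internal computation in leupet uses minutes; schedules printed in seconds
#' (the usual convention for PET protocols) are converted at construction.
#'
#' @param start numeric vector of frame start times.
#' @param dur numeric vector of frame durations, same length as `start`.
#' @param unit unit of `start` and `dur`: `"s"` (default) or `"min"`.
#'
#' @return An object of class `frame_schedule`: a list with elements
#'   `start`, `dur`, `mid`, `end` (all minutes) and `n` (number of frames).
#' @export
#' @examples
#' fs <- default_frame_schedule()
#' fs$n                      # 42
#' sum(fs$dur)               # 90 minutes
frame_schedule <- function(start, dur, unit = c("s", "min")) {
  unit <- match.arg(unit)
  start <- as.numeric(start)
  dur <- as.numeric(dur)
  if (length(start) != length(dur) || length(start) == 0L)
    stop("'start' and 'dur' must be non-empty vectors of equal length")
  if (unit == "s") {
    start <- start / 60
    dur <- dur / 60
  }
  if (any(dur <= 0)) stop("frame durations must be positive")
  if (any(diff(start) <= 0)) stop("frame start times must be strictly increasing")
  end <- start + dur
  if (any(start[-1] < end[-length(end)] - 1e-9))
    stop("frames must not overlap")
  structure(
    list(start = start, dur = dur, mid = start + dur / 2, end = end,
         n = length(start)),
    class = "frame_schedule"
  )
}

#' @describeIn frame_schedule The standard 90-min leucine PET protocol:
#'   42 frames of 16 x 15 s, 4 x 30 s, 4 x 60 s, 4 x 150 s and 14 x 300 s.
#' @export
default_frame_schedule <- function() {
  dur_s <- c(rep(15, 16), rep(30, 4), rep(60, 4), rep(150, 4), rep(300, 14))
  frame_schedule(start = cumsum(c(0, dur_s[-length(dur_s)])), dur = dur_s,
                 unit = "s")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.5g to %.5g min (total %.5g min)\n",
              x$n, x$start[1], x$end[x$n], sum(x$dur)))
  invisible(x)
}

#' Read / write a frame schedule as delimited text
#'
#' The table has two columns, `start_s` and `dur_s` (seconds), one row per
#' frame.
#'
#' @param path file path.
#' @param schedule a [frame_schedule()].
#' @param unit time unit used in the file, `"s"` (default) or `"min"`.
#' @return `read_frame_schedule` returns a [frame_schedule()];
#'   `write_frame_schedule` returns `path` invisibly.
#' @export
read_frame_schedule <- function(path, unit = c("s", "min")) {
  unit <- match.arg(unit)
  tab <- utils::read.table(path, header = TRUE)
  cols <- if (unit == "s") c("start_s", "dur_s") else c("start_min", "dur_min")
  if (!all(cols %in% names(tab)))
    stop("schedule table must have columns ", paste(cols, collapse = ", "))
  frame_schedule(tab[[cols[1]]], tab[[cols[2]]], unit = unit)
}

#' @rdname read_frame_schedule
#' @export
write_frame_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  utils::write.table(
    data.frame(start_s = schedule$start * 60, dur_s = schedule$dur * 60),
    path, row.names = FALSE, quote = FALSE, sep = "\t"
  )
  invisible(path)
}
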