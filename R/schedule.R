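#' Exposure schedule for a multi-frame plate experiment
#'
#' The plate is exposed for `duration_min` starting at each `start_min`,
#' then exchanged; the default reproduces the dynamic acquisition used for
#' the epidermal model: 45-min exposures starting every 60 min from 0 to
#' 360 min (seven frames over 405 min).
#'
#' @param start_min Frame start times in minutes, strictly increasing.
#' @param duration_min Frame durations in minutes (> 0); recycled to the
#'   number of frames.
#' @return A data frame of class `exposure_schedule` with columns
#'   `start_min`, `duration_min` and `mid_min` (frame midpoints).
#' @export
exposure_schedule <- function(start_min = seq(0, 360, by = 60),
                              duration_min = 45) {
  if (!is.numeric(start_min) || length(start_min) == 0L ||
      any(!is.finite(start_min)))
    stop_input("'start_min' must be finite numeric")
  if (!is.numeric(duration_min) || any(!is.finite(duration_min)) ||
      any(duration_min <= 0))
    stop_input("'duration_min' must be > 0")
  duration_min <- rep_len(duration_min, length(start_min))
  if (is.unsorted(start_min, strictly = TRUE))
    stop_input("'start_min' must be strictly increasing")
  ends <- start_min + duration_min
  if (length(start_min) > 1 &&
      any(ends[-length(ends)] > start_min[-1] + 1e-9))
    stop_input("schedule frames overlap: frame ends %s exceed next starts",
               paste(signif(ends[-length(ends)], 6), collapse = ", "))
  structure(data.frame(start_min = as.numeric(start_min),
                       duration_min = as.numeric(duration_min),
                       mid_min = as.numeric(start_min + duration_min / 2)),
            class = c("exposure_schedule", "data.frame"))
}

as_exposure_schedule <- function(x) {
  if (inherits(x, "exposure_schedule")) return(x)
  if (is.list(x) && !is.null(x$start_min))
    return(exposure_schedule(x$start_min, x$duration_min %||% 45))
  stop_input("cannot interpret object of class '%s' as an exposure schedule",
             class(x)[1])
}

#' Multi-frame PSL image stack
#'
#' @param frames List of 2-D numeric matrices of PSL values, one per frame,
#'   all the same shape.
#' @param schedule An [exposure_schedule()] with one row per frame.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, schedule, pixel_size_um = 350) {
  schedule <- as_exposure_schedule(schedule)
  if (!is.list(frames) || length(frames) == 0L ||
      !all(vapply(frames, is.matrix, logical(1))))
    stop_input("'frames' must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_input("all frames must have the same shape")
  if (length(frames) != nrow(schedule))
    stop_input("stack has %d frames but schedule has %d",
               length(frames), nrow(schedule))
  check_scalar(pixel_size_um, "pixel_size_um")
  structure(list(frames = frames, schedule = schedule,
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("PSL image stack:", length(x$frames), "frames of", d[1], "x", d[2],
      "px (", x$pixel_size_um, "um/px )\n")
  cat("  frame starts (min):",
      paste(x$schedule$start_min, collapse = ", "), "\n")
  invisible(x)
}
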