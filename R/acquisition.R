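#' Acquisition configuration
#'
#' Describes one contrast-enhanced SRUS acquisition. Defaults mirror the
#' clinical protocol the package emulates: a 6-second breath-hold acquired at
#' 500 frames per second (3000 frames), imaging depth standardized to 3 cm at
#' a mechanical index of 0.116 (the latter two are inert metadata for the
#' computations), with maps accumulated on a 25 micrometre super-resolution
#' grid over a 20 x 20 mm field of view.
#'
#' @param frame_rate Frames per second (default 500).
#' @param duration Acquisition length in seconds (default 6).
#' @param n_frames Frame count; must equal `round(frame_rate * duration)`.
#' @param pixel_size Super-resolution pixel pitch in micrometres (default 25).
#' @param field_of_view Numeric length-2, width and height of the imaging
#'   plane in mm (default `c(20, 20)`).
#' @param depth_label Imaging depth in cm (metadata, default 3).
#' @param mechanical_index Acoustic MI (metadata, default 0.116).
#' @return An object of class `acquisition_config`.
#' @export
#' @examples
#' acq <- acquisition_config()
#' acq$n_frames  # 3000
acquisition_config <- function(frame_rate = 500, duration = 6,
                               n_frames = round(frame_rate * duration),
                               pixel_size = 25, field_of_view = c(20, 20),
                               depth_label = 3, mechanical_index = 0.116) {
  stopifnot_scalar_pos(frame_rate, "frame_rate")
  stopifnot_scalar_pos(duration, "duration")
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  if (length(field_of_view) != 2L || any(!is.finite(field_of_view)) ||
      any(field_of_view <= 0)) {
    stop("`field_of_view` must be two positive lengths (mm)", call. = FALSE)
  }
  if (n_frames != round(frame_rate * duration)) {
    stop("`n_frames` must equal round(frame_rate * duration)", call. = FALSE)
  }
  structure(list(frame_rate = frame_rate, duration = duration,
                 n_frames = as.integer(n_frames), pixel_size = pixel_size,
                 field_of_view = as.numeric(field_of_view),
                 depth_label = depth_label,
                 mechanical_index = mechanical_index),
            class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("SRUS acquisition: %g fps x %g s = %d frames, %g um pixels, FOV %g x %g mm\n",
              x$frame_rate, x$duration, x$n_frames, x$pixel_size,
              x$field_of_view[1], x$field_of_view[2]))
  invisible(x)
}
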