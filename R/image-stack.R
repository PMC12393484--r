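#' Photon-count image stack
#'
#' A light container for a fluorescence-fluctuation acquisition: a
#' rows x cols x frames array of non-negative photon counts plus the
#' acquisition metadata the downstream analyses need.
#'
#' @param data numeric array, `rows x cols x frames`, non-negative counts.
#' @param pixel_size pixel size in micrometres.
#' @param dwell_time pixel dwell time in microseconds (optional).
#' @param frame_interval frame interval in seconds (optional).
#' @param allow_negative permit negative values (detrended fluctuation
#'   stacks are real-valued); acquisitions must be non-negative counts.
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, pixel_size, dwell_time = NULL,
                        frame_interval = NULL, allow_negative = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a rows x cols x frames array.")
  }
  if (!allow_negative && any(data < 0)) {
    abort("counts must be non-negative.")
  }
  assert_scalar_num(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  structure(
    list(data = data, pixel_size = pixel_size,
         dwell_time = dwell_time, frame_interval = frame_interval),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d pixels, %d frames\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel size: %g um", x$pixel_size))
  if (!is.null(x$dwell_time)) cat(sprintf(", dwell: %g us", x$dwell_time))
  if (!is.null(x$frame_interval)) {
    cat(sprintf(", frame interval: %g s", x$frame_interval))
  }
  cat("\n  counts: [", min(x$data), ",", max(x$data), "]\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[3]

# rows*cols x frames matrix view (pixels as rows), used by the moment code
stack_matrix <- function(stack) {
  d <- dim(stack$data)
  matrix(stack$data, nrow = d[1] * d[2], ncol = d[3])
}
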