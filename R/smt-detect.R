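#' Tracking parameter sets
#'
#' Bundles the linking/analysis parameters used throughout the tracking
#' module. `smt_preset()` returns the two acquisition presets: `"fast"`
#' (20 ms frames, max expected D 3 um^2/s, box 7 — displacement and bound
#' fraction) and `"slow"` (500 ms frames, max expected D 0.33 um^2/s,
#' box 9 — residence times). Both allow a one-frame blinking gap and at
#' most 3 linking competitors, and exclude cells with fewer than 500
#' trajectories.
#'
#' @param d_max maximum expected diffusion coefficient, um^2/s.
#' @param blink_frames gap allowance in frames (>= 0).
#' @param max_competitors candidate links considered per detection (>= 1).
#' @param box_size detection window in pixels (odd).
#' @param dt frame interval, seconds.
#' @param min_tracks_per_cell per-cell trajectory floor for mobility stats.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(d_max = 3, blink_frames = 1, max_competitors = 3,
                            box_size = 7, dt = 0.02,
                            min_tracks_per_cell = 500) {
  assert_scalar_num(d_max, "d_max", lower = 0, strict_lower = TRUE)
  assert_scalar_num(blink_frames, "blink_frames", lower = 0)
  assert_scalar_num(max_competitors, "max_competitors", lower = 1)
  assert_scalar_num(box_size, "box_size", lower = 1)
  assert_scalar_num(dt, "dt", lower = 0, strict_lower = TRUE)
  structure(list(d_max = d_max, blink_frames = as.integer(blink_frames),
                 max_competitors = as.integer(max_competitors),
                 box_size = as.integer(box_size), dt = dt,
                 min_tracks_per_cell = as.integer(min_tracks_per_cell)),
            class = "tracking_params")
}

#' @rdname tracking_params
#' @param preset `"fast"` or `"slow"`.
#' @export
smt_preset <- function(preset = c("fast", "slow")) {
  switch(match.arg(preset),
    fast = tracking_params(d_max = 3, blink_frames = 1, max_competitors = 3,
                           box_size = 7, dt = 0.02),
    slow = tracking_params(d_max = 0.33, blink_frames = 1, max_competitors = 3,
                           box_size = 9, dt = 0.5)
  )
}

#' Detect single-molecule localizations in an image stack
#'
#' A simple local-maximum detector: pixels above `intensity_threshold` that
#' are maxima of their `box_size` x `box_size` neighbourhood are refined to
#' sub-pixel positions by an intensity-weighted centroid within the box.
#' Positions are returned in micrometres using the stack's pixel size.
#'
#' @param stack an [image_stack].
#' @param box_size odd window size in pixels.
#' @param intensity_threshold minimum peak intensity (counts).
#' @return A tibble `frame, x_um, y_um, intensity` sorted by frame. x runs
#'   along columns, y along rows, origin at pixel (1,1) = (0,0) um.
#' @export
detect_localizations <- function(stack, box_size = 7, intensity_threshold) {
  stopifnot(inherits(stack, "image_stack"))
  assert_scalar_num(box_size, "box_size", lower = 3)
  if (box_size %% 2 == 0) abort("`box_size` must be odd.")
  assert_scalar_num(intensity_threshold, "intensity_threshold")
  h <- (box_size - 1L) / 2L
  d <- dim(stack$data)
  out <- vector("list", d[3])
  for (f in seq_len(d[3])) {
    img <- stack$data[, , f]
    peaks <- which(img >= intensity_threshold, arr.ind = TRUE)
    if (!nrow(peaks)) next
    keep <- logical(nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      r <- peaks[i, 1]; c <- peaks[i, 2]
      rr <- max(1, r - h):min(d[1], r + h)
      cc <- max(1, c - h):min(d[2], c + h)
      nb <- img[rr, cc]
      # strict maximum vs neighbours; ties broken by first (row-major) position
      keep[i] <- img[r, c] == max(nb) &&
        which.max(nb) == (match(c, cc) - 1L) * length(rr) + match(r, rr)
    }
    peaks <- peaks[keep, , drop = FALSE]
    if (!nrow(peaks)) next
    loc <- matrix(0, nrow(peaks), 3)
    for (i in seq_len(nrow(peaks))) {
      r <- peaks[i, 1]; c <- peaks[i, 2]
      rr <- max(1, r - h):min(d[1], r + h)
      cc <- max(1, c - h):min(d[2], c + h)
      nb <- img[rr, cc]
      w <- sum(nb)
      loc[i, ] <- c(sum(cc * colSums(nb)) / w, sum(rr * rowSums(nb)) / w, w)
    }
    out[[f]] <- tibble(frame = f, x_um = (loc[, 1] - 1) * stack$pixel_size,
                       y_um = (loc[, 2] - 1) * stack$pixel_size,
                       intensity = loc[, 3])
  }
  res <- bind_rows(out)
  if (!nrow(res)) {
    return(tibble(frame = integer(), x_um = double(), y_um = double(),
                  intensity = double()))
  }
  arrange(res, .data$frame)
}
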