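#' Remove slow intensity drift from a stack (moving-average detrend)
#'
#' Subtracts a centered boxcar moving average from each pixel's intensity
#' trace and adds the pixel's global temporal mean back, removing slow
#' drift (cell movement, photobleaching) while preserving the first moment
#' exactly. Because subtracting a `w`-frame local mean also removes `1/w` of
#' the genuine fluctuation variance, the deviations are rescaled by
#' `sqrt(w_t / (w_t - 1))` (with `w_t` the actual, edge-truncated window
#' size at frame `t`) so that the fluctuation variance — and hence the
#' apparent brightness — is preserved.
#'
#' @param stack an [image_stack].
#' @param window moving-average window in frames, `2 <= window < n_frames`.
#' @return An [image_stack] of identical dimensions.
#' @export
detrend_stack <- function(stack, window = 10) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  assert_scalar_num(window, "window", lower = 2)
  if (window >= nf) abort("`window` must be smaller than the frame count.")
  window <- as.integer(window)

  m <- stack_matrix(stack)
  # centered boxcar: frames t - floor((w-1)/2) .. t + ceiling((w-1)/2)
  lo <- pmax(1L, seq_len(nf) - (window - 1L) %/% 2L)
  hi <- pmin(nf, seq_len(nf) + window %/% 2L)
  w_t <- hi - lo + 1L

  cs <- matrix(0, nrow(m), nf)
  acc <- numeric(nrow(m))
  for (t in seq_len(nf)) {
    acc <- acc + m[, t]
    cs[, t] <- acc
  }
  px_mean <- cs[, nf] / nf

  out <- matrix(0, nrow(m), nf)
  for (t in seq_len(nf)) {
    ma <- (cs[, hi[t]] - (if (lo[t] > 1L) cs[, lo[t] - 1L] else 0)) / w_t[t]
    out[, t] <- (m[, t] - ma) * sqrt(w_t[t] / (w_t[t] - 1))
  }
  # re-center so each pixel's temporal mean is preserved exactly
  out <- out - rowMeans(out) + px_mean

  image_stack(array(out, dim(stack$data)), pixel_size = stack$pixel_size,
              dwell_time = stack$dwell_time,
              frame_interval = stack$frame_interval, allow_negative = TRUE)
}

#' Per-pixel moment (Number & Brightness) maps
#'
#' For every pixel of a fluctuation stack computes the temporal mean
#' (first moment), the unbiased temporal variance (second moment), the
#' apparent brightness `B = var/mean` and the apparent number
#' `N = mean^2/var`. On a photon-counting detector, mobile particles of
#' molecular brightness `epsilon` give `B = epsilon + 1`; immobile or empty
#' pixels give `B` near the shot-noise value 1. Pixels with zero mean have
#' undefined brightness and are flagged `NA`.
#'
#' @param stack an [image_stack] with >= 2 frames.
#' @return A `brightness_map`: matrices `B`, `mean_F`, `var_F`,
#'   `n_apparent`, plus `n_frames` and `pixel_size`. Use [tidy()] for a
#'   per-pixel tibble.
#' @export
brightness_map <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  if (nf < 2) abort("brightness analysis needs at least 2 frames.")
  m <- stack_matrix(stack)
  mu <- rowMeans(m)
  v <- (rowSums(m * m) - nf * mu^2) / (nf - 1)
  v <- pmax(v, 0) # guard tiny negative rounding
  B <- ifelse(mu > 0, v / mu, NA_real_)
  n_app <- ifelse(mu > 0 & v > 0, mu^2 / v, NA_real_)

  d <- dim(stack$data)[1:2]
  structure(list(
    B = matrix(B, d[1], d[2]),
    mean_F = matrix(mu, d[1], d[2]),
    var_F = matrix(v, d[1], d[2]),
    n_apparent = matrix(n_app, d[1], d[2]),
    n_frames = nf,
    pixel_size = stack$pixel_size
  ), class = "brightness_map")
}

#' @export
print.brightness_map <- function(x, ...) {
  cat(sprintf("<brightness_map> %d x %d pixels from %d frames\n",
              nrow(x$B), ncol(x$B), x$n_frames))
  cat(sprintf("  median B (defined pixels): %.4f\n",
              median(x$B, na.rm = TRUE)))
  invisible(x)
}

#' @rdname brightness_map
#' @param x a `brightness_map`.
#' @param ... unused.
#' @method tidy brightness_map
#' @export
tidy.brightness_map <- function(x, ...) {
  d <- dim(x$B)
  tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    mean_F = as.vector(x$mean_F),
    var_F = as.vector(x$var_F),
    B = as.vector(x$B),
    n_apparent = as.vector(x$n_apparent)
  )
}

#' Calibrate brightness cursors from a monomer control
#'
#' Estimates the monomeric molecular brightness from a brightness map of a
#' monomer-control acquisition as `epsilon = median(B) - 1` (the median is
#' robust to bright aggregates; the 1 is the photon-counting detector
#' contribution), extrapolates the expected brightness of higher-order
#' species `B_s = s * epsilon + 1` for s = 1, 2, 4, and builds ordered
#' cursor intervals that assign a brightness value to a class:
#' `background` below `B_1 - epsilon/2`, `monomer` up to the 1-2 midpoint,
#' `dimer` up to the 2-4 midpoint, `oligomer` above.
#'
#' @param bmap a [brightness_map] of the monomer control.
#' @param mask optional logical matrix selecting pixels (e.g. the nucleus);
#'   default all pixels. At least 100 defined-B pixels are required.
#' @return An `oligomer_cursors` object: `epsilon`, `levels` (named vector
#'   of expected B per stoichiometry), and `bounds`, a tibble of ordered,
#'   disjoint class intervals.
#' @export
calibrate_monomer <- function(bmap, mask = NULL) {
  stopifnot(inherits(bmap, "brightness_map"))
  b <- bmap$B
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(b))) abort("`mask` dimensions must match the map.")
    b <- b[mask]
  }
  b <- b[!is.na(b)]
  if (length(b) < 100) {
    abort("monomer calibration needs at least 100 defined-B pixels.")
  }
  med <- median(b)
  if (med <= 1) {
    abort(sprintf(
      "calibration failure: median B = %.4f <= 1 (no fluctuation signal above shot noise).",
      med))
  }
  cursors_from_epsilon(med - 1)
}

#' Build cursor intervals from a known monomer brightness
#'
#' @param epsilon monomeric molecular brightness (counts/molecule/dwell, > 0).
#' @return An `oligomer_cursors` object (see [calibrate_monomer]).
#' @export
cursors_from_epsilon <- function(epsilon) {
  assert_scalar_num(epsilon, "epsilon", lower = 0, strict_lower = TRUE)
  levels <- c(`1` = epsilon + 1, `2` = 2 * epsilon + 1, `4` = 4 * epsilon + 1)
  b1 <- levels[["1"]]; b2 <- levels[["2"]]; b4 <- levels[["4"]]
  bounds <- tibble(
    class = factor(c("background", "monomer", "dimer", "oligomer"),
                   levels = c("background", "monomer", "dimer", "oligomer")),
    lower = c(-Inf, b1 - epsilon / 2, (b1 + b2) / 2, (b2 + b4) / 2),
    upper = c(b1 - epsilon / 2, (b1 + b2) / 2, (b2 + b4) / 2, Inf)
  )
  structure(list(epsilon = epsilon, levels = levels, bounds = bounds),
            class = "oligomer_cursors")
}

#' @export
print.oligomer_cursors <- function(x, ...) {
  cat(sprintf("<oligomer_cursors> epsilon = %.4f\n", x$epsilon))
  cat(sprintf("  expected B: monomer %.3f, dimer %.3f, tetramer %.3f\n",
              x$levels[["1"]], x$levels[["2"]], x$levels[["4"]]))
  print(x$bounds)
  invisible(x)
}

#' Classify pixels into oligomeric-state classes
#'
#' Assigns every masked, defined-brightness pixel to the cursor interval
#' containing its apparent brightness and summarises the per-class pixel
#' fractions. Fractions over all classified pixels sum to 1; `fraction_species`
#' renormalizes over the monomer/dimer/oligomer classes only, excluding
#' background pixels (those below the monomer lower bound).
#'
#' @param bmap a [brightness_map].
#' @param cursors an `oligomer_cursors` object.
#' @param mask optional logical matrix of pixels to classify (e.g. the
#'   nucleus); default all pixels.
#' @return An `oligomer_fractions` object: `fractions` tibble
#'   (`class, n, fraction, fraction_species`), `class_map` (factor-coded
#'   integer matrix, NA outside mask/defined pixels) and `n_pixels_used`.
#' @export
classify_pixels <- function(bmap, cursors, mask = NULL) {
  stopifnot(inherits(bmap, "brightness_map"), inherits(cursors, "oligomer_cursors"))
  b <- bmap$B
  use <- !is.na(b)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(b))) abort("`mask` dimensions must match the map.")
    use <- use & mask
  }
  if (!any(use)) abort("empty mask: no pixels to classify.")

  # intervals are [lower, upper): cut at the three finite upper bounds
  cls <- matrix(NA_integer_, nrow(b), ncol(b))
  cls[use] <- cut(b[use], breaks = c(-Inf, cursors$bounds$upper[-4], Inf),
                  labels = FALSE, right = FALSE)

  lv <- levels(cursors$bounds$class)
  counts <- tabulate(cls[use], nbins = 4L)
  n_used <- sum(counts)
  n_species <- sum(counts[-1])
  fractions <- tibble(
    class = factor(lv, levels = lv),
    n = counts,
    fraction = counts / n_used,
    fraction_species = c(NA, if (n_species > 0) counts[-1] / n_species else rep(NA, 3))
  )
  structure(list(fractions = fractions, class_map = cls,
                 n_pixels_used = n_used),
            class = "oligomer_fractions")
}

#' @export
print.oligomer_fractions <- function(x, ...) {
  cat(sprintf("<oligomer_fractions> %d pixels classified\n", x$n_pixels_used))
  print(x$fractions)
  invisible(x)
}

#' @rdname classify_pixels
#' @param x an `oligomer_fractions` object.
#' @param ... unused.
#' @method tidy oligomer_fractions
#' @export
tidy.oligomer_fractions <- function(x, ...) x$fractions
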