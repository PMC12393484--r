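#' Simulate a fluorescence-fluctuation (N&B) image stack
#'
#' Generates a photon-count stack with the statistical structure that
#' moment-based brightness analysis assumes: in every pixel and frame the
#' number of molecules of each species in the focal volume is Poisson with
#' mean `N_s`, and the photons detected from `n` molecules of stoichiometry
#' `s` are Poisson with mean `n * s * epsilon`. For a pure species the
#' apparent brightness (variance/mean) of such a compound process is exactly
#' `1 + s * epsilon`, which is what the brightness analysis exploits.
#'
#' Photobleaching is modelled as a loss of fluorescent molecules: the
#' occupancy mean is multiplied by a ramp that decays by `bleach_fraction`
#' over the acquisition (linearly by default, exponentially on request).
#' Per-molecule brightness is unaffected, so a moving-average detrend can
#' restore the brightness estimate.
#'
#' @param epsilon true molecular brightness of the monomer, photon counts per
#'   molecule per dwell time.
#' @param species a data frame with columns `s` (stoichiometry, integer >= 1)
#'   and `N` (mean occupancy, molecules per focal volume). An empty frame
#'   yields an all-zero stack.
#' @param n_frames number of frames (>= 2).
#' @param shape `c(rows, cols)` of each frame.
#' @param bleach_fraction fractional intensity decay over the acquisition,
#'   in `[0, 1)`.
#' @param bleach_mode `"linear"` (default) or `"exponential"` decay shape.
#' @param pixel_size,dwell_time metadata stored on the stack (um, us).
#' @param seed integer seed; `NULL` uses the session RNG.
#' @return A list with class `ffs_sim`: `stack` (an [image_stack]) and
#'   `truth` (epsilon, the species mix, bleach settings and the expected
#'   apparent brightness `1 + s * epsilon` per species).
#' @examples
#' sim <- simulate_ffs_stack(0.5, data.frame(s = 1, N = 2),
#'                           n_frames = 50, shape = c(32, 32), seed = 1)
#' mean(sim$stack$data)
#' @export
simulate_ffs_stack <- function(epsilon,
                               species = data.frame(s = 1, N = 2),
                               n_frames = 100,
                               shape = c(256, 256),
                               bleach_fraction = 0,
                               bleach_mode = c("linear", "exponential"),
                               pixel_size = 0.041,
                               dwell_time = 12.5,
                               seed = NULL) {
  assert_scalar_num(epsilon, "epsilon", lower = 0, strict_lower = TRUE)
  assert_scalar_num(n_frames, "n_frames", lower = 2)
  assert_scalar_num(bleach_fraction, "bleach_fraction", lower = 0, upper = 1 - 1e-12)
  bleach_mode <- match.arg(bleach_mode)
  if (length(shape) != 2L || any(shape < 1)) {
    abort("`shape` must be c(rows, cols) with positive entries.")
  }
  species <- as.data.frame(species)
  if (nrow(species)) {
    assert_columns(species, c("s", "N"), "`species`")
    if (any(species$s < 1) || any(species$s != round(species$s))) {
      abort("stoichiometries `s` must be integers >= 1.")
    }
    if (any(species$N < 0)) abort("occupancies `N` must be >= 0.")
  }
  n_frames <- as.integer(n_frames)
  npx <- as.double(shape[1]) * shape[2]
  if (npx * n_frames > 2^28) {
    abort("requested stack exceeds the supported size (2^28 pixel-frames).")
  }
  expected_peak <- if (nrow(species)) sum(species$N * species$s) * epsilon else 0
  if (expected_peak > 6e4) {
    abort("expected counts overflow the 16-bit count range; reduce N, s or epsilon.")
  }

  ramp <- switch(bleach_mode,
    linear = 1 - bleach_fraction * (seq_len(n_frames) - 1) / max(1, n_frames - 1),
    exponential = (1 - bleach_fraction)^((seq_len(n_frames) - 1) / max(1, n_frames - 1))
  )

  counts <- with_seed_or_current(seed, {
    total <- matrix(0, nrow = npx, ncol = n_frames)
    ramp_px <- rep(ramp, each = npx) # pixel-frame expansion, frames vary slowest
    for (i in seq_len(nrow(species))) {
      occ <- rpois(npx * n_frames, lambda = species$N[i] * ramp_px)
      total <- total + matrix(
        rpois(npx * n_frames, lambda = occ * species$s[i] * epsilon),
        nrow = npx
      )
    }
    total
  })

  stack <- image_stack(
    array(counts, dim = c(shape[1], shape[2], n_frames)),
    pixel_size = pixel_size, dwell_time = dwell_time
  )
  truth <- list(
    epsilon = epsilon,
    species = as_tibble(species),
    expected_brightness = if (nrow(species)) 1 + species$s * epsilon else numeric(),
    bleach_fraction = bleach_fraction,
    bleach_mode = bleach_mode,
    seed = seed
  )
  structure(list(stack = stack, truth = truth), class = "ffs_sim")
}
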