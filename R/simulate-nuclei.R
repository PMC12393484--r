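#' Simulate textured single-nucleus crops
#'
#' Produces labelled single-nucleus image crops and masks for the texture
#' phenotyping pipeline: each nucleus is an elliptical mask filled with a
#' smoothed Gaussian random field whose correlation length is set per
#' condition (`texture_scale`, pixels), rescaled to a fixed [0, 1] intensity
#' range. Larger correlation lengths give coarser, blotchier chromatin-like
#' texture; equal scales across conditions make them statistically
#' indistinguishable.
#'
#' @param conditions character vector of condition labels.
#' @param texture_scale correlation length in pixels, one per condition
#'   (recycled if scalar); must be > 0.
#' @param n_per_condition crops per condition.
#' @param shape `c(rows, cols)` of each crop; must exceed the nucleus
#'   ellipse (axes are drawn at 55-80% of the crop).
#' @param seed integer seed; `NULL` uses the session RNG.
#' @return A list with class `nuclei_sim`: `crops` (list of matrices),
#'   `masks` (list of logical matrices), and `cells`, a tibble with
#'   `cell_id` and `condition` in crop order.
#' @examples
#' sim <- simulate_nuclei_images(c("fine", "coarse"), c(2, 8),
#'                               n_per_condition = 3, shape = c(48, 48),
#'                               seed = 1)
#' length(sim$crops)
#' @export
simulate_nuclei_images <- function(conditions,
                                   texture_scale,
                                   n_per_condition = 30,
                                   shape = c(64, 64),
                                   seed = NULL) {
  conditions <- as.character(conditions)
  texture_scale <- rep_len(texture_scale, length(conditions))
  if (any(texture_scale <= 0)) abort("`texture_scale` must be > 0.")
  assert_scalar_num(n_per_condition, "n_per_condition", lower = 1)
  if (length(shape) != 2L || any(shape < 16)) {
    abort("`shape` must be c(rows, cols), each >= 16 pixels.")
  }
  if (any(shape < 4 * max(texture_scale))) {
    abort("crop shape too small for the requested nucleus/texture scale.")
  }

  n <- as.integer(n_per_condition)
  with_seed_or_current(seed, {
    crops <- list(); masks <- list()
    cells <- tibble(cell_id = character(), condition = character())
    idx <- 0L
    for (ci in seq_along(conditions)) {
      for (k in seq_len(n)) {
        idx <- idx + 1L
        # elliptical nucleus, mildly variable axes and orientation
        a <- runif(1, 0.55, 0.8) * shape[1] / 2
        b <- runif(1, 0.55, 0.8) * shape[2] / 2
        th <- runif(1, 0, pi)
        rr <- matrix(seq_len(shape[1]) - (shape[1] + 1) / 2, shape[1], shape[2])
        cc <- matrix(seq_len(shape[2]) - (shape[2] + 1) / 2, shape[1], shape[2],
                     byrow = TRUE)
        u <- rr * cos(th) + cc * sin(th)
        v <- -rr * sin(th) + cc * cos(th)
        mask <- (u / a)^2 + (v / b)^2 <= 1

        field <- matrix(rnorm(prod(shape)), shape[1], shape[2])
        field <- EBImage::gblur(field, sigma = texture_scale[ci])
        rng <- range(field[mask])
        img <- (field - rng[1]) / max(rng[2] - rng[1], 1e-12)
        img[!mask] <- 0
        img[img < 0] <- 0; img[img > 1] <- 1

        crops[[idx]] <- img
        masks[[idx]] <- mask
        cells <- bind_rows(cells, tibble(
          cell_id = sprintf("%s_%03d", conditions[ci], k),
          condition = conditions[ci]
        ))
      }
    }
    names(crops) <- cells$cell_id
    names(masks) <- cells$cell_id
    structure(list(crops = crops, masks = masks, cells = cells,
                   truth = list(conditions = conditions,
                                texture_scale = texture_scale, seed = seed)),
              class = "nuclei_sim")
  })
}
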