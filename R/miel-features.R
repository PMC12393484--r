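#' Extract per-cell texture and intensity features
#'
#' Computes, for each single-nucleus crop, 13 gray-level co-occurrence
#' (Haralick) features averaged over the 4 directions at pixel distances
#' {1, 2, 4, 8} on 64-level quantized masked intensities (52 texture
#' features), plus the mean, SD, skewness and kurtosis of the masked
#' intensity. Intensities are rescaled to the masked range before
#' quantization, so the texture features are invariant to affine intensity
#' scaling. Constant-intensity crops yield defined values (the degenerate
#' co-occurrence features are set to 0).
#'
#' @param crops list of numeric matrices (one channel per call; run per
#'   channel and join for multi-channel data).
#' @param masks list of logical/0-1 matrices, same lengths and shapes.
#' @param cells optional tibble with `cell_id` and `condition` in crop
#'   order (e.g. from [simulate_nuclei_images]); defaults to sequential ids.
#' @param nbins gray levels for quantization (default 64).
#' @param distances co-occurrence pair distances in pixels.
#' @return A tibble: `cell_id, condition`, 13 x length(distances) Haralick
#'   columns (`h.<name>.d<distance>`), then `int_mean, int_sd, int_skew,
#'   int_kurt`. Deterministic column order; one row per crop.
#' @export
extract_features <- function(crops, masks, cells = NULL, nbins = 64,
                             distances = c(1, 2, 4, 8)) {
  if (length(crops) != length(masks)) {
    abort("`crops` and `masks` must have the same length.")
  }
  if (!length(crops)) abort("no crops supplied.")
  if (is.null(cells)) {
    cells <- tibble(cell_id = sprintf("cell_%04d", seq_along(crops)),
                    condition = "all")
  }
  assert_columns(cells, c("cell_id", "condition"), "`cells`")
  if (nrow(cells) != length(crops)) {
    abort("`cells` must have one row per crop.")
  }

  hnames <- unlist(lapply(distances, function(d) {
    sprintf("h.%s.d%d", glcm_feature_names, d)
  }))
  rows <- purrr::map(seq_along(crops), function(i) {
    img <- crops[[i]]
    mask <- masks[[i]] > 0
    if (!identical(dim(img), dim(mask))) {
      abort(sprintf("crop/mask shape mismatch for crop %d.", i))
    }
    if (!any(mask)) abort(sprintf("empty mask for crop %d.", i))
    vals <- img[mask]
    q <- quantize_masked(img, mask, nbins)
    h <- unlist(lapply(distances, function(d) {
      haralick_at_distance(q, d, nbins)
    }))
    names(h) <- hnames

    mu <- mean(vals); s <- stats::sd(vals)
    if (s > 0) {
      z <- (vals - mu) / s
      sk <- mean(z^3); ku <- mean(z^4) - 3
    } else {
      sk <- 0; ku <- 0
    }
    c(h, int_mean = mu, int_sd = s, int_skew = sk, int_kurt = ku)
  })

  feats <- do.call(rbind, rows)
  bind_cols(cells[, c("cell_id", "condition")], as_tibble(feats))
}
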