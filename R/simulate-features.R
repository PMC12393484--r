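#' Simulate a per-cell feature table
#'
#' Draws per-cell feature vectors for several experimental conditions from
#' multivariate Gaussians that share a covariance but whose means are shifted
#' by `effect_size` standard-deviation units along a fixed, seeded random
#' unit direction per condition. This emulates the per-cell texture-feature
#' tables the population-phenotyping pipeline consumes, with a controllable
#' separation between conditions.
#'
#' @param conditions character vector of condition labels (>= 1; >= 2 when
#'   `effect_size > 0`, since a single shifted condition is untestable).
#' @param n_cells_per_condition cells per condition (>= 2).
#' @param n_features number of features.
#' @param effect_size mean shift between conditions, in SD units.
#' @param within_sd per-feature SD (scalar or length `n_features`).
#' @param correlation common pairwise correlation between features in
#'   `[0, 1)`; 0 gives independent features.
#' @param seed integer seed; `NULL` uses the session RNG.
#' @return A list with class `feature_sim`: `cells`, a tibble with
#'   `cell_id`, `condition` and feature columns `f_001...`, and `truth`
#'   holding the condition mean vectors and parameters.
#' @examples
#' sim <- simulate_feature_table(c("ctrl", "treated"), 50, n_features = 10,
#'                               effect_size = 2, seed = 1)
#' dplyr::count(sim$cells, condition)
#' @export
simulate_feature_table <- function(conditions = c("A", "B"),
                                   n_cells_per_condition = 100,
                                   n_features = 20,
                                   effect_size = 1,
                                   within_sd = 1,
                                   correlation = 0,
                                   seed = NULL) {
  conditions <- as.character(conditions)
  if (!length(conditions)) abort("at least one condition is required.")
  if (effect_size > 0 && length(conditions) < 2) {
    abort("`effect_size` > 0 requires at least 2 conditions.")
  }
  assert_scalar_num(n_cells_per_condition, "n_cells_per_condition", lower = 2)
  assert_scalar_num(n_features, "n_features", lower = 1)
  assert_scalar_num(effect_size, "effect_size", lower = 0)
  assert_scalar_num(correlation, "correlation", lower = 0, upper = 1 - 1e-9)
  if (!length(within_sd) %in% c(1L, n_features) || any(within_sd <= 0)) {
    abort("`within_sd` must be a positive scalar or one value per feature.")
  }

  n_features <- as.integer(n_features)
  n <- as.integer(n_cells_per_condition)
  sds <- rep_len(within_sd, n_features)

  with_seed_or_current(seed, {
    # fixed random unit direction per condition (near-orthogonal in high
    # dimension, so between-condition separation ~ effect_size * sqrt(2))
    dirs <- matrix(rnorm(length(conditions) * n_features), ncol = n_features)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    means <- effect_size * dirs * rep(sds, each = length(conditions))

    # equicorrelated Gaussian via common + idiosyncratic components
    rho <- correlation
    draws <- purrr::map(seq_along(conditions), function(ci) {
      z <- matrix(rnorm(n * n_features), nrow = n)
      if (rho > 0) {
        common <- rnorm(n)
        z <- sqrt(rho) * matrix(common, n, n_features) + sqrt(1 - rho) * z
      }
      sweep(z, 2, sds, `*`) + matrix(means[ci, ], n, n_features, byrow = TRUE)
    })

    cells <- bind_cols(
      tibble(
        cell_id = sprintf("cell_%05d", seq_len(n * length(conditions))),
        condition = rep(conditions, each = n)
      ),
      as_tibble(do.call(rbind, draws),
                .name_repair = ~ sprintf("f_%03d", seq_len(n_features)))
    )

    structure(list(
      cells = cells,
      truth = list(condition_means = means, directions = dirs, sds = sds,
                   effect_size = effect_size, correlation = rho, seed = seed)
    ), class = "feature_sim")
  })
}
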