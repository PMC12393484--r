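#' Per-trajectory diffusion coefficients from short-lag MSD
#'
#' For each trajectory the time-averaged mean squared displacement is
#' computed at lags 1..min(4, L-1) frame intervals (displacements are
#' collected over every position pair separated by the lag, so blink-bridged
#' gaps contribute at the correct lag), and a least-squares line
#' `MSD(tau) = 4 D tau dt + b` is fitted. The free intercept absorbs the
#' static localization-error offset `4 sigma_loc^2`; a through-origin fit is
#' available with `intercept = FALSE`. Non-positive fitted slopes are floored
#' at `d_floor` so that `log10(D)` is always defined; floored trajectories
#' are flagged and always classify as confined.
#'
#' @param trajectories tibble `track_id, frame, x_um, y_um` (optionally
#'   `cell_id`).
#' @param dt frame interval, seconds.
#' @param max_lag largest lag in frames (default 4, the short-lag fit).
#' @param intercept fit a free intercept (default) or force through origin.
#' @param d_floor replacement for non-positive slopes, um^2/s.
#' @return A tibble `track_id (, cell_id), n_pos, D, log10_D, floored`;
#'   trajectories with fewer than 3 positions are dropped with a warning.
#' @export
diffusion_coefficients <- function(trajectories, dt, max_lag = 4,
                                   intercept = TRUE, d_floor = 1e-4) {
  assert_columns(trajectories, c("track_id", "frame", "x_um", "y_um"),
                 "`trajectories`")
  assert_scalar_num(dt, "dt", lower = 0, strict_lower = TRUE)
  assert_scalar_num(max_lag, "max_lag", lower = 1)
  has_cell <- "cell_id" %in% names(trajectories)

  trajectories <- arrange(trajectories, .data$track_id, .data$frame)
  idx <- split(seq_len(nrow(trajectories)), trajectories$track_id)
  short <- vapply(idx, length, integer(1)) < 3L
  if (any(short)) {
    warn(sprintf("%d trajectories with < 3 positions dropped.", sum(short)))
    idx <- idx[!short]
  }
  if (!length(idx)) {
    abort("no trajectory has the 3 positions required for an MSD fit.")
  }

  fr <- trajectories$frame; xx <- trajectories$x_um; yy <- trajectories$y_um
  fit_one <- function(rows) {
    f <- fr[rows]; x <- xx[rows]; y <- yy[rows]
    L <- length(rows)
    lags <- seq_len(min(max_lag, f[L] - f[1]))
    msd <- rep(NA_real_, length(lags))
    for (g in lags) {
      # all position pairs separated by exactly g frames (gap-aware)
      j <- match(f + g, f)
      ok <- !is.na(j)
      if (any(ok)) {
        msd[g] <- mean((x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2)
      }
    }
    ok <- !is.na(msd)
    tau <- lags[ok]; msd <- msd[ok]
    if (length(msd) < 2L && intercept) return(c(NA_real_, L))
    slope <- if (intercept) {
      # closed-form simple least squares (2-4 points)
      tm <- mean(tau); mm <- mean(msd)
      sum((tau - tm) * (msd - mm)) / sum((tau - tm)^2)
    } else {
      sum(tau * msd) / sum(tau * tau)
    }
    c(slope / (4 * dt), L)
  }

  res <- vapply(idx, fit_one, numeric(2))
  D_raw <- unname(res[1, ])
  floored <- is.na(D_raw) | D_raw <= 0
  D <- ifelse(floored, d_floor, D_raw)

  out <- tibble(
    track_id = unname(trajectories$track_id[vapply(idx, `[`, numeric(1), 1L)]),
    n_pos = as.integer(res[2, ]),
    D = D,
    log10_D = log10(D),
    floored = floored
  )
  if (has_cell) {
    out$cell_id <- trajectories$cell_id[vapply(idx, `[`, numeric(1), 1L)]
    out <- select(out, "track_id", "cell_id", dplyr::everything())
  }
  out
}

#' Mobility threshold from a control-condition diffusion profile
#'
#' Locates the boundary between the confined (chromatin-bound) and
#' non-confined (diffusing) trajectory populations on the log10 diffusion
#' profile of a control condition: a Gaussian kernel density (Silverman
#' bandwidth) is computed, and the threshold is the density minimum between
#' the two highest modes. If the profile is unimodal, a two-component
#' Gaussian mixture is fitted and the decision boundary between its
#' components is used instead. The same threshold is then applied to every
#' condition.
#'
#' @param log10_D numeric vector of log10 diffusion coefficients from the
#'   control condition (>= 500 values, the per-cell trajectory floor).
#' @param min_n minimum number of values required.
#' @return A scalar threshold on the log10 D scale, with attributes
#'   `method` (`"kde_minimum"` or `"gmm_boundary"`) and `modes`.
#' @export
mobility_threshold <- function(log10_D, min_n = 500) {
  log10_D <- log10_D[is.finite(log10_D)]
  if (length(log10_D) < min_n) {
    abort(sprintf("mobility_threshold needs >= %d values (got %d).",
                  min_n, length(log10_D)))
  }
  if (stats::sd(log10_D) < 1e-12) {
    abort("degenerate diffusion profile: all values identical.")
  }
  den <- density(log10_D, bw = "nrd0", n = 1024)
  y <- den$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) >= 2L) {
    top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
    between <- seq(top2[1], top2[2])
    thr <- den$x[between[which.min(y[between])]]
    return(structure(thr, method = "kde_minimum",
                     modes = den$x[top2]))
  }
  # unimodal fallback: two-component Gaussian mixture decision boundary
  mclustBIC <- mclust::mclustBIC # Mclust resolves this in the caller frame
  fit <- mclust::Mclust(log10_D, G = 2, modelNames = "V", verbose = FALSE)
  p <- fit$parameters
  mu <- p$mean; sig <- sqrt(p$variance$sigmasq); w <- p$pro
  grid <- seq(min(mu), max(mu), length.out = 2048)
  post_diff <- w[1] * stats::dnorm(grid, mu[1], sig[1]) -
               w[2] * stats::dnorm(grid, mu[2], sig[2])
  cross <- which(diff(sign(post_diff)) != 0)
  thr <- if (length(cross)) grid[cross[1] + 1L] else mean(mu)
  structure(thr, method = "gmm_boundary", modes = sort(mu))
}

#' Classify trajectory mobility and summarise per cell
#'
#' A trajectory is confined when `log10(D)` falls below the threshold
#' (floored trajectories always are). Per cell the confined and
#' non-confined fractions and their ratio are computed; cells with fewer
#' than `min_tracks_per_cell` trajectories are excluded from the summary
#' and reported in the `excluded` attribute.
#'
#' @param d_table output of [diffusion_coefficients]; needs a `cell_id`
#'   column (a single implicit cell is assumed if absent).
#' @param threshold log10-D boundary from [mobility_threshold].
#' @param min_tracks_per_cell per-cell trajectory floor (default 500).
#' @return A tibble `cell_id, n_tracks, confined_fraction,
#'   nonconfined_fraction, ratio_nonconfined_confined`, with excluded cells
#'   in `attr(, "excluded")`. The per-trajectory classification is in
#'   `attr(, "trajectories")`.
#' @export
classify_mobility <- function(d_table, threshold, min_tracks_per_cell = 500) {
  assert_columns(d_table, c("track_id", "log10_D"), "`d_table`")
  if (!"cell_id" %in% names(d_table)) d_table$cell_id <- "cell_1"
  thr <- as.numeric(threshold)

  per_traj <- mutate(d_table,
                     confined = .data$log10_D < thr | .data$floored)
  per_cell <- per_traj |>
    group_by(.data$cell_id) |>
    summarise(
      n_tracks = dplyr::n(),
      confined_fraction = mean(.data$confined),
      nonconfined_fraction = mean(!.data$confined),
      .groups = "drop"
    ) |>
    mutate(ratio_nonconfined_confined =
             .data$nonconfined_fraction /
             ifelse(.data$confined_fraction > 0, .data$confined_fraction, NA))

  keep <- per_cell$n_tracks >= min_tracks_per_cell
  out <- per_cell[keep, ]
  attr(out, "excluded") <- per_cell[!keep, c("cell_id", "n_tracks")]
  attr(out, "trajectories") <- per_traj
  attr(out, "threshold") <- thr
  out
}
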