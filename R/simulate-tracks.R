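#' Simulate single-molecule trajectories
#'
#' Draws 2-D Brownian trajectories from a mixture of diffusive populations,
#' adds Gaussian localization error, and drops frames to mimic fluorophore
#' blinking. Each track belongs to exactly one population (no within-track
#' state switching). Blinking never removes two consecutive frames, matching
#' a linker gap allowance of one frame, and never removes the first or last
#' frame of a track.
#'
#' @param populations data frame with columns `D` (diffusion coefficient,
#'   um^2/s, >= 0) and `weight` (mixture weights summing to 1).
#' @param sigma_loc localization error SD per axis, um.
#' @param dt frame interval, seconds.
#' @param n_tracks number of tracks.
#' @param mean_track_len mean track length in frames (lengths are
#'   `min_track_len` plus a geometric tail, mimicking stochastic bleaching).
#' @param p_blink per-frame missed-detection probability.
#' @param n_frames acquisition length in frames; track start frames are
#'   uniform over the acquisition (molecules appear and photobleach
#'   throughout), which sets the molecule density per frame to roughly
#'   `n_tracks * mean_track_len / n_frames`.
#' @param fov `c(width, height)` of the field of view, um; track starting
#'   points are uniform in the field.
#' @param min_track_len shortest track emitted (default 5 frames so lag-1..4
#'   displacement statistics exist).
#' @param seed integer seed; `NULL` uses the session RNG.
#' @return A list with class `track_sim`:
#'   * `localizations`: tibble `frame, x_um, y_um, intensity` — the observed,
#'     noisy detections without identities (blinked frames removed);
#'   * `trajectories`: the same detections with `track_id` attached (the
#'     ground-truth linking);
#'   * `truth`: tibble of true (noise-free, no-blink) positions with
#'     `track_id, frame, x_um, y_um, D, population`, plus the parameters.
#' @examples
#' sim <- simulate_tracks(data.frame(D = 2, weight = 1), sigma_loc = 0.03,
#'                        dt = 0.02, n_tracks = 10, seed = 1)
#' head(sim$trajectories)
#' @export
simulate_tracks <- function(populations = data.frame(D = c(0.05, 2.5),
                                                     weight = c(0.4, 0.6)),
                            sigma_loc = 0.03,
                            dt = 0.02,
                            n_tracks = 500,
                            mean_track_len = 20,
                            p_blink = 0,
                            n_frames = 6000,
                            fov = c(20, 20),
                            min_track_len = 5,
                            seed = NULL) {
  populations <- as.data.frame(populations)
  assert_columns(populations, c("D", "weight"), "`populations`")
  if (any(populations$D < 0)) abort("all `D` must be >= 0.")
  if (abs(sum(populations$weight) - 1) > 1e-6) {
    abort("population weights must sum to 1.")
  }
  assert_scalar_num(dt, "dt", lower = 0, strict_lower = TRUE)
  assert_scalar_num(sigma_loc, "sigma_loc", lower = 0)
  assert_scalar_num(p_blink, "p_blink", lower = 0, upper = 1)
  assert_scalar_num(n_tracks, "n_tracks", lower = 1)
  if (mean_track_len < min_track_len) {
    abort("`mean_track_len` must be >= `min_track_len`.")
  }

  with_seed_or_current(seed, {
    n_tracks <- as.integer(n_tracks)
    pop <- sample.int(nrow(populations), n_tracks, replace = TRUE,
                      prob = populations$weight)
    tail_mean <- mean_track_len - min_track_len
    len <- as.integer(min_track_len) + if (tail_mean > 0) {
      rgeom(n_tracks, prob = 1 / (tail_mean + 1))
    } else {
      integer(n_tracks)
    }

    total <- sum(len)
    id <- rep.int(seq_len(n_tracks), len)
    start <- sample.int(max(1L, as.integer(n_frames)), n_tracks,
                        replace = TRUE)
    pos <- sequence(len) # within-track index
    frame <- pos + (start - 1L)[id]
    step_sd <- sqrt(2 * populations$D[pop] * dt)[id]
    # first position of each track replaces the step with a uniform start
    first <- pos == 1L
    dx <- rnorm(total, sd = step_sd); dy <- rnorm(total, sd = step_sd)
    dx[first] <- runif(n_tracks, 0, fov[1])
    dy[first] <- runif(n_tracks, 0, fov[2])
    x <- ave(dx, id, FUN = cumsum)
    y <- ave(dy, id, FUN = cumsum)

    truth <- tibble(
      track_id = id, frame = frame, x_um = x, y_um = y,
      population = pop[id], D = populations$D[pop][id]
    )

    obs_x <- x + rnorm(total, sd = sigma_loc)
    obs_y <- y + rnorm(total, sd = sigma_loc)

    # blinking: drop interior frames, never two consecutive per track
    drop <- runif(total) < p_blink & !first & pos != len[id]
    if (any(drop)) {
      prev_same <- c(FALSE, id[-1] == id[-total])
      run2 <- drop & prev_same & c(FALSE, drop[-total])
      drop[run2] <- FALSE
    }

    keep <- !drop
    trajectories <- tibble(
      track_id = id[keep], frame = frame[keep],
      x_um = obs_x[keep], y_um = obs_y[keep]
    )
    localizations <- tibble(
      frame = trajectories$frame,
      x_um = trajectories$x_um, y_um = trajectories$y_um,
      intensity = 1
    ) |> arrange(.data$frame)

    structure(list(
      localizations = localizations,
      trajectories = trajectories,
      truth = list(
        positions = truth,
        populations = as_tibble(populations),
        sigma_loc = sigma_loc, dt = dt, p_blink = p_blink,
        track_lengths = len, seed = seed
      )
    ), class = "track_sim")
  })
}
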