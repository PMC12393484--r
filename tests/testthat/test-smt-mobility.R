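# diffusion estimation and mobility classification

test_that("the MSD line fit reproduces the hand-computed fixture", {
  # positions (0,0), (1,0), (2,0) um: MSD(1) = 1, MSD(2) = 4
  fix <- tibble::tibble(track_id = 1L, frame = 1:3,
                        x_um = c(0, 1, 2), y_um = 0)
  d <- diffusion_coefficients(fix, dt = 0.02)
  # least squares through (1,1), (2,4): slope 3, intercept -1
  expect_equal(d$D, 3 / (4 * 0.02))
  d0 <- diffusion_coefficients(fix, dt = 0.02, intercept = FALSE)
  # through-origin slope (1*1 + 2*4)/(1 + 4) = 1.8
  expect_equal(d0$D, 1.8 / (4 * 0.02))
})

test_that("a stationary molecule is floored and classified confined", {
  fix <- tibble::tibble(track_id = 1L, frame = 1:6, x_um = 1, y_um = 2)
  d <- diffusion_coefficients(fix, dt = 0.02)
  expect_true(d$floored)
  expect_equal(d$D, 1e-4)
  cm <- classify_mobility(d, threshold = -1, min_tracks_per_cell = 1)
  expect_equal(cm$confined_fraction, 1)
  expect_equal(cm$ratio_nonconfined_confined, 0)
})

test_that("trajectories shorter than three positions are dropped with a warning", {
  fix <- tibble::tibble(track_id = c(1L, 1L, 2L, 2L, 2L), frame = c(1:2, 1:3),
                        x_um = c(0, 1, 0, 1, 2), y_um = 0)
  expect_warning(d <- diffusion_coefficients(fix, dt = 0.02), "dropped")
  expect_identical(nrow(d), 1L)
  short <- tibble::tibble(track_id = 1L, frame = 1:2, x_um = 0:1, y_um = 0)
  expect_warning(expect_error(diffusion_coefficients(short, dt = 0.02),
                              "3 positions"))
})

test_that("the estimator recovers the simulated diffusion coefficient", {
  sim <- simulate_tracks(data.frame(D = 2, weight = 1), sigma_loc = 0.03,
                         dt = 0.02, n_tracks = 1500, mean_track_len = 20,
                         p_blink = 0, seed = 31)
  d <- diffusion_coefficients(sim$trajectories, dt = 0.02)
  expect_lt(abs(median(d$D) / 2 - 1), 0.15)
})

test_that("the KDE threshold sits at the analytic minimum of a balanced bimodal", {
  set.seed(32)
  mu <- c(-1.3, 0.3); sd0 <- 0.35
  v <- c(rnorm(4000, mu[1], sd0), rnorm(4000, mu[2], sd0))
  thr <- mobility_threshold(v)
  expect_identical(attr(thr, "method"), "kde_minimum")
  dens <- function(x) 0.5 * dnorm(x, mu[1], sd0) + 0.5 * dnorm(x, mu[2], sd0)
  analytic <- optimize(dens, interval = mu)$minimum
  expect_lt(abs(as.numeric(thr) - analytic), 0.15)
  expect_gt(as.numeric(thr), mu[1]); expect_lt(as.numeric(thr), mu[2])
})

test_that("a unimodal profile falls back to the mixture decision boundary", {
  set.seed(33)
  v <- rnorm(1500, 0, 0.4)
  thr <- mobility_threshold(v)
  expect_identical(attr(thr, "method"), "gmm_boundary")
  modes <- attr(thr, "modes")
  expect_gte(as.numeric(thr), modes[1])
  expect_lte(as.numeric(thr), modes[2])
})

test_that("thresholding is deterministic and input-validated", {
  set.seed(34)
  v <- c(rnorm(600, -1), rnorm(600, 0.5))
  expect_identical(mobility_threshold(v), mobility_threshold(v))
  expect_error(mobility_threshold(v[1:100]), ">= 500")
  expect_error(mobility_threshold(rep(0.5, 600)), "degenerate")
})

test_that("cells under the trajectory floor are excluded and reported", {
  d <- tibble::tibble(
    track_id = 1:999,
    cell_id = rep(c("cell_a", "cell_b"), c(499, 500)),
    log10_D = rnorm(999), floored = FALSE
  )
  out <- classify_mobility(d, threshold = 0, min_tracks_per_cell = 500)
  expect_identical(out$cell_id, "cell_b")
  excl <- attr(out, "excluded")
  expect_identical(excl$cell_id, "cell_a")
  expect_identical(excl$n_tracks, 499L)
  expect_equal(out$confined_fraction + out$nonconfined_fraction, 1)
})

test_that("confined fractions are recovered across mixture weights", {
  # one mid-grid weight here; the full grid runs in the acceptance suite
  w <- 0.4
  sim <- simulate_tracks(data.frame(D = c(0.05, 2.5), weight = c(w, 1 - w)),
                         sigma_loc = 0.03, dt = 0.02, n_tracks = 1200,
                         mean_track_len = 20, p_blink = 0, seed = 35)
  d <- diffusion_coefficients(sim$trajectories, dt = 0.02)
  thr <- mobility_threshold(d$log10_D)
  cm <- classify_mobility(d, thr, min_tracks_per_cell = 500)
  expect_lt(abs(cm$confined_fraction - w), 0.10)
})
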