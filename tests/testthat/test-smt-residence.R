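# residence-time two-exponential fitting

test_that("single-exponential data yields a negligible long fraction", {
  sim <- simulate_dwells(tau_short = 1, tau_long = 12, frac_long = 0,
                         n_dwells = 2000, t_max = 250, dt = 0.5, seed = 41)
  fit <- suppressWarnings(residence_analysis(sim$dwells, dt = 0.5))
  # either the long component vanishes or it collapses onto the short one
  expect_true(fit$frac_long < 0.05 || fit$ratio_long_short < 1.2)
})

test_that("all mixture parameters are recovered within 20%", {
  sim <- simulate_dwells(1, 12, 0.3, n_dwells = 2000, t_max = 250, dt = 0.5,
                         seed = 42)
  fit <- residence_analysis(sim$dwells, dt = 0.5)
  expect_lt(abs(fit$tau_short / 1 - 1), 0.2)
  expect_lt(abs(fit$tau_long / 12 - 1), 0.2)
  expect_lt(abs(fit$frac_long / 0.3 - 1), 0.2)
  expect_true(fit$converged)
  expect_identical(nrow(tidy(fit)), 4L)
})

test_that("the MLE attains the brute-force grid-search likelihood optimum", {
  sim <- simulate_dwells(1, 12, 0.3, n_dwells = 200, t_max = 250, dt = 0.5,
                         seed = 43)
  fit <- residence_analysis(sim$dwells, dt = 0.5)
  t_obs <- sim$dwells$duration_s; cens <- sim$dwells$censored

  # independent brute-force likelihood: coarse grid, then Nelder-Mead polish
  # of the grid optimum with optim (a different optimizer than the fit path)
  grid <- expand.grid(tau_s = seq(0.4, 3, length.out = 25),
                      tau_l = seq(4, 30, length.out = 25),
                      f = seq(0.05, 0.8, length.out = 16))
  ll <- mapply(function(a, b, f) residence_loglik(t_obs, cens, a, b, f, 0.5),
               grid$tau_s, grid$tau_l, grid$f)
  top <- grid[which.max(ll), ]
  polish <- optim(
    c(log(top$tau_s), log(top$tau_l - top$tau_s), qlogis(top$f)),
    function(th) -residence_loglik(t_obs, cens, exp(th[1]),
                                   exp(th[1]) + exp(th[2]),
                                   plogis(th[3]), 0.5),
    method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-14)
  )
  expect_lt(abs(fit$loglik - (-polish$value)), 1e-6)
})

test_that("degenerate dwell tables are rejected", {
  same <- tibble::tibble(duration_s = rep(0.5, 200), censored = FALSE)
  expect_error(residence_analysis(same, dt = 0.5), "identical")
  few <- tibble::tibble(duration_s = seq(0.5, 5, by = 0.5), censored = FALSE)
  expect_error(residence_analysis(few, dt = 0.5), ">= 100")
})

test_that("the opt-in photobleaching correction adjusts both time scales", {
  sim <- simulate_dwells(1, 10, 0.3, n_dwells = 1000, t_max = 250, dt = 0.5,
                         seed = 44)
  fit <- residence_analysis(sim$dwells, dt = 0.5, k_bleach = 0.05)
  expect_equal(fit$tau_long_corrected,
               1 / (1 / fit$tau_long - 0.05), tolerance = 1e-12)
  expect_gt(fit$tau_long_corrected, fit$tau_long)
})

test_that("the continuous likelihood path fits finely sampled dwells", {
  sim <- simulate_dwells(1, 12, 0.3, n_dwells = 3000, t_max = 500, dt = 0.001,
                         seed = 45)
  fit <- residence_analysis(sim$dwells, dt = NULL)
  expect_lt(abs(fit$tau_long / 12 - 1), 0.2)
})
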