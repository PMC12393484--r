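#' Simulate chromatin-binding dwell times
#'
#' Draws residence durations from a two-exponential mixture — a short
#' component (target search) and a long component (stable, regulation-
#' associated binding) — then discretizes them to whole frames of length
#' `dt` (observed residence times are frame counts times the frame interval)
#' and right-censors events that survive into the final frame of the
#' observation window.
#'
#' An event is recorded as censored when its discretized duration reaches
#' `t_max`; at `t_max = dt` every event is censored at one frame.
#'
#' @param tau_short,tau_long mean dwell times (s) of the two components,
#'   `tau_long > tau_short > 0`.
#' @param frac_long mixture fraction of the long component, in `[0, 1]`.
#' @param n_dwells number of events.
#' @param t_max observation limit, seconds (right-censoring); must be
#'   >= `dt`.
#' @param dt frame interval, seconds.
#' @param seed integer seed; `NULL` uses the session RNG.
#' @return A list with class `dwell_sim`: `dwells`, a tibble with
#'   `duration_s` (multiples of `dt`) and `censored`, and `truth` with the
#'   generating parameters.
#' @examples
#' sim <- simulate_dwells(1, 12, 0.3, n_dwells = 100, t_max = 250,
#'                        dt = 0.5, seed = 1)
#' table(sim$dwells$censored)
#' @export
simulate_dwells <- function(tau_short = 1,
                            tau_long = 12,
                            frac_long = 0.3,
                            n_dwells = 1000,
                            t_max = 250,
                            dt = 0.5,
                            seed = NULL) {
  assert_scalar_num(tau_short, "tau_short", lower = 0, strict_lower = TRUE)
  assert_scalar_num(tau_long, "tau_long", lower = tau_short, strict_lower = TRUE)
  assert_scalar_num(frac_long, "frac_long", lower = 0, upper = 1)
  assert_scalar_num(n_dwells, "n_dwells", lower = 1)
  assert_scalar_num(dt, "dt", lower = 0, strict_lower = TRUE)
  if (t_max < dt) abort("`t_max` must be >= `dt`.")

  with_seed_or_current(seed, {
    n_dwells <- as.integer(n_dwells)
    is_long <- runif(n_dwells) < frac_long
    u <- rexp(n_dwells, rate = 1) * ifelse(is_long, tau_long, tau_short)
    k <- pmax(1, ceiling(u / dt))
    k_max <- floor(t_max / dt + 1e-9)
    censored <- k >= k_max
    k[censored] <- k_max
    structure(list(
      dwells = tibble(duration_s = k * dt, censored = censored),
      truth = list(tau_short = tau_short, tau_long = tau_long,
                   frac_long = frac_long, t_max = t_max, dt = dt,
                   component_long = is_long, seed = seed)
    ), class = "dwell_sim")
  })
}
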