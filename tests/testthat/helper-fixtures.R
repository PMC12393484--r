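# shared fixture builders (all generated in code; no files)

# a brightness_map with a prescribed B matrix (mean/var layers consistent
# with an arbitrary mean level), for cursor-classification tests
make_bmap <- function(B, mean_level = 10) {
  structure(list(
    B = B,
    mean_F = matrix(mean_level, nrow(B), ncol(B)),
    var_F = B * mean_level,
    n_apparent = ifelse(B > 0, mean_level / B, NA_real_),
    n_frames = 100L,
    pixel_size = 0.041
  ), class = "brightness_map")
}

# fraction of ground-truth consecutive-observation links reproduced by the
# linker, plus the fraction among gate-feasible links
link_recovery <- function(sim, params) {
  linked <- link_trajectories(sim$localizations, params)
  truth <- dplyr::arrange(sim$trajectories, track_id, frame)
  key <- function(df) paste(round(df$x_um, 9), round(df$y_um, 9), df$frame)
  map <- stats::setNames(linked$track_id, key(linked))
  tid <- unname(map[key(truth)])
  n <- nrow(truth)
  same <- truth$track_id[-1] == truth$track_id[-n]
  rec <- tid[-1] == tid[-n]
  gap <- truth$frame[-1] - truth$frame[-n]
  d2 <- (truth$x_um[-1] - truth$x_um[-n])^2 +
    (truth$y_um[-1] - truth$y_um[-n])^2
  feasible <- d2 <= 4 * params$d_max * params$dt * gap
  list(
    overall = mean(rec[same]),
    feasible = mean(rec[same & feasible]),
    n_links = sum(same),
    conserved = nrow(linked) == nrow(sim$localizations)
  )
}

# brute-force two-pass per-pixel moments (oracle for brightness_map)
brute_moments <- function(arr) {
  d <- dim(arr)
  mu <- v <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      tr <- arr[i, j, ]
      mu[i, j] <- mean(tr)
      v[i, j] <- sum((tr - mean(tr))^2) / (length(tr) - 1)
    }
  }
  list(mean = mu, var = v, B = ifelse(mu > 0, v / mu, NA_real_))
}
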