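#' Link localizations into trajectories
#'
#' Deterministic multi-target linking in the spirit of MTT-style trackers:
#' frames are processed in order, and detections are matched to active
#' tracks by greedily accepting the candidate pair with the smallest squared
#' displacement. A track that last appeared `g` frames before the current
#' one (a blinking gap of `g - 1`) may capture a detection within the gating
#' radius `r(g-1) = sqrt(4 * d_max * dt * g)`, the displacement a molecule
#' at the maximum expected diffusion coefficient would plausibly make over
#' `g` frame intervals. Each detection considers at most `max_competitors`
#' nearest candidate tracks. Unmatched detections start new tracks; tracks
#' silent for more than `blink_frames` frames are closed. Every input
#' localization ends up in exactly one trajectory.
#'
#' @param localizations tibble with `frame, x_um, y_um` (e.g. from
#'   [detect_localizations] or [read_table]), sorted by frame.
#' @param params a [tracking_params] object.
#' @return A tibble `track_id, frame, x_um, y_um`, frames strictly
#'   increasing within a track, gaps at most `blink_frames + 1`.
#' @export
link_trajectories <- function(localizations, params = smt_preset("fast")) {
  stopifnot(inherits(params, "tracking_params"))
  assert_columns(localizations, c("frame", "x_um", "y_um"), "`localizations`")
  n <- nrow(localizations)
  if (!n) {
    return(tibble(track_id = integer(), frame = integer(),
                  x_um = double(), y_um = double()))
  }
  if (is.unsorted(localizations$frame)) {
    abort("`localizations` must be sorted by frame.")
  }
  if (!all(is.finite(localizations$x_um)) || !all(is.finite(localizations$y_um))) {
    abort("non-finite coordinates in `localizations`.")
  }

  frame <- as.integer(localizations$frame)
  x <- localizations$x_um; y <- localizations$y_um
  track_of <- integer(n)

  # active track state (parallel vectors): last row index, last frame
  act_last <- integer(0); act_frame <- integer(0); act_id <- integer(0)
  next_id <- 1L
  # squared gating radius per gap g = 0..blink_frames
  gate2 <- 4 * params$d_max * params$dt * (seq_len(params$blink_frames + 1L))
  # note: for a track last seen at f-1 matching frame f, g = 0, radius^2 = gate2[1]

  rows_by_frame <- split(seq_len(n), frame)
  for (fr_chr in names(rows_by_frame)) {
    f <- as.integer(fr_chr)
    rows <- rows_by_frame[[fr_chr]]

    # drop tracks beyond the blink allowance
    alive <- (f - act_frame - 1L) <= params$blink_frames
    act_last <- act_last[alive]; act_frame <- act_frame[alive]
    act_id <- act_id[alive]

    assigned_det <- rep(FALSE, length(rows))
    if (length(act_id)) {
      gap <- f - act_frame # frame intervals spanned, >= 1
      d2 <- outer(x[rows], x[act_last], `-`)^2 +
            outer(y[rows], y[act_last], `-`)^2
      d2[d2 > matrix(gate2[gap], length(rows), length(act_id), byrow = TRUE)] <- Inf
      # per-detection truncation to the max_competitors nearest candidates
      if (ncol(d2) > params$max_competitors) {
        for (i in seq_len(nrow(d2))) {
          ord <- order(d2[i, ])
          d2[i, ord[-seq_len(params$max_competitors)]] <- Inf
        }
      }
      cand <- which(is.finite(d2), arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d2[cand], cand[, 1], cand[, 2])
        used_tr <- rep(FALSE, length(act_id))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (assigned_det[i] || used_tr[j]) next
          assigned_det[i] <- TRUE; used_tr[j] <- TRUE
          track_of[rows[i]] <- act_id[j]
          act_last[j] <- rows[i]; act_frame[j] <- f
        }
      }
    }
    # unmatched detections start new tracks
    new <- which(!assigned_det)
    if (length(new)) {
      ids <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
      track_of[rows[new]] <- ids
      act_last <- c(act_last, rows[new])
      act_frame <- c(act_frame, rep(f, length(new)))
      act_id <- c(act_id, ids)
    }
  }

  tibble(track_id = track_of, frame = frame, x_um = x, y_um = y) |>
    arrange(.data$track_id, .data$frame)
}
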