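#' Bootstrap optimization of the condensation number
#'
#' Determines the smallest pool size `n` that yields robust condition
#' discrimination. For every candidate `n` and every iteration, 80% of each
#' condition's cells (by count) are resampled with replacement, the
#' resampled cells are condensed into disjoint pools of `n`, and a
#' PCA + linear-SVM classifier with a stratified train/test split records
#' its test accuracy. The optimal condensation number is the smallest
#' candidate achieving at least `accuracy_criterion` in at least
#' `success_quantile` of the iterations (`NA` when no candidate qualifies).
#'
#' Conditions are expected to be pre-selected for separability (e.g. in
#' PCA space); the bootstrap allows a single test center per condition,
#' since large pool sizes can leave very few centers.
#'
#' @param tbl per-cell feature tibble (`cell_id`, `condition`, features),
#'   typically z-scored.
#' @param candidate_ns candidate pool sizes; every candidate must leave at
#'   least 2 centers per condition in the 80% sample.
#' @param iterations bootstrap iterations per candidate.
#' @param sample_frac fraction of each condition's cell count resampled
#'   with replacement per iteration.
#' @param accuracy_criterion per-iteration accuracy target.
#' @param success_quantile required fraction of passing iterations.
#' @param n_components,train_frac classifier settings (see
#'   [fit_classify]).
#' @param seed integer seed; iteration draws are deterministic in
#'   (candidate, iteration).
#' @return A `bootstrap_report`: `accuracy` (tibble `candidate_n,
#'   iteration, accuracy`), `summary` (tibble `candidate_n, frac_pass,
#'   mean_accuracy`), `optimal_n` (or `NA`), and the settings. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
bootstrap_condensation <- function(tbl, candidate_ns = c(5, 10, 20, 40, 60),
                                   iterations = 1000, sample_frac = 0.8,
                                   accuracy_criterion = 0.95,
                                   success_quantile = 0.95,
                                   n_components = 4, train_frac = 0.8,
                                   seed = 1) {
  assert_columns(tbl, c("cell_id", "condition"), "`tbl`")
  fcols <- feature_columns(tbl)
  conds <- sort(unique(tbl$condition))
  if (length(conds) < 2) abort("bootstrap needs >= 2 conditions.")
  counts <- table(tbl$condition)
  n_sample <- floor(sample_frac * counts)
  candidate_ns <- sort(as.integer(candidate_ns))
  bad <- candidate_ns[candidate_ns > floor(min(n_sample) / 2)]
  if (length(bad)) {
    abort(sprintf(
      "candidate n too large for the %g%% sample (need >= 2 pools per condition): %s",
      100 * sample_frac, paste(bad, collapse = ", ")))
  }

  rows_by_cond <- split(seq_len(nrow(tbl)), tbl$condition)
  x <- as.matrix(tbl[, fcols])

  res <- vector("list", length(candidate_ns) * iterations)
  k <- 0L
  for (ci in seq_along(candidate_ns)) {
    n <- candidate_ns[ci]
    for (it in seq_len(iterations)) {
      k <- k + 1L
      acc <- with_seed_or_current(derive_seed(seed, ci * 1000003L + it), {
        centers_list <- list(); labs <- character()
        for (cond in conds) {
          draw <- sample(rows_by_cond[[cond]], n_sample[[cond]],
                         replace = TRUE)
          n_pools <- length(draw) %/% n
          pools <- matrix(draw[seq_len(n_pools * n)], nrow = n)
          cm <- t(apply(pools, 2, function(rws) colMeans(x[rws, , drop = FALSE])))
          centers_list[[cond]] <- cm
          labs <- c(labs, rep(cond, n_pools))
        }
        centers <- as_tibble(do.call(rbind, centers_list),
                             .name_repair = ~ fcols)
        centers$condition <- labs
        fit <- classify_once(centers, fcols, n_components, train_frac,
                             min_test = 1L)
        mean(fit$truth == fit$pred)
      })
      res[[k]] <- tibble(candidate_n = n, iteration = it, accuracy = acc)
    }
  }
  accuracy <- bind_rows(res)

  summary <- accuracy |>
    group_by(.data$candidate_n) |>
    summarise(frac_pass = mean(.data$accuracy >= accuracy_criterion),
              mean_accuracy = mean(.data$accuracy), .groups = "drop")
  qualifying <- summary$candidate_n[summary$frac_pass >= success_quantile]
  optimal_n <- if (length(qualifying)) min(qualifying) else NA_integer_

  structure(list(
    accuracy = accuracy, summary = summary, optimal_n = optimal_n,
    settings = list(candidate_ns = candidate_ns, iterations = iterations,
                    sample_frac = sample_frac,
                    accuracy_criterion = accuracy_criterion,
                    success_quantile = success_quantile,
                    n_components = n_components, train_frac = train_frac,
                    seed = seed)
  ), class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("<bootstrap_report> %d candidates x %d iterations\n",
              length(x$settings$candidate_ns), x$settings$iterations))
  print(x$summary)
  cat("optimal condensation number:",
      if (is.na(x$optimal_n)) "none" else x$optimal_n, "\n")
  invisible(x)
}

#' @rdname bootstrap_condensation
#' @param x a `bootstrap_report`.
#' @param ... unused.
#' @method tidy bootstrap_report
#' @export
tidy.bootstrap_report <- function(x, ...) x$summary

#' @rdname bootstrap_condensation
#' @method glance bootstrap_report
#' @export
glance.bootstrap_report <- function(x, ...) {
  tibble(optimal_n = x$optimal_n,
         iterations = x$settings$iterations,
         accuracy_criterion = x$settings$accuracy_criterion,
         success_quantile = x$settings$success_quantile)
}
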