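#' Z-score a feature table
#'
#' Normalizes every feature column to zero mean and unit SD across all
#' cells. Zero-variance features are dropped with a warning. The per-feature
#' parameters are attached (`attr(, "zscore_params")`) and can be reapplied
#' to held-out data via the `params` argument, which reproduces the stored
#' transform exactly.
#'
#' @param tbl feature tibble with id columns (`cell_id`, `condition`) and
#'   numeric feature columns (>= 2 rows).
#' @param params optional stored parameter tibble (`feature, mean, sd`)
#'   from a previous call.
#' @return The transformed tibble with `zscore_params` attached.
#' @export
zscore_features <- function(tbl, params = NULL) {
  if (nrow(tbl) < 2) abort("z-scoring needs at least 2 cells.")
  fcols <- feature_columns(tbl)
  if (!length(fcols)) abort("no numeric feature columns found.")

  if (is.null(params)) {
    mu <- vapply(tbl[fcols], mean, numeric(1))
    s <- vapply(tbl[fcols], stats::sd, numeric(1))
    drop <- s <= 0 | !is.finite(s)
    if (all(drop)) abort("all feature columns have zero variance.")
    if (any(drop)) {
      warn(sprintf("dropping %d zero-variance feature(s): %s",
                   sum(drop), paste(fcols[drop], collapse = ", ")))
    }
    params <- tibble(feature = fcols[!drop], mean = mu[!drop], sd = s[!drop])
  } else {
    assert_columns(params, c("feature", "mean", "sd"), "`params`")
    missing <- setdiff(params$feature, fcols)
    if (length(missing)) {
      abort(sprintf("table lacks feature(s) in `params`: %s",
                    paste(missing, collapse = ", ")))
    }
  }

  out <- tbl[, c(setdiff(names(tbl), fcols), params$feature)]
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    out[[f]] <- (out[[f]] - params$mean[i]) / params$sd[i]
  }
  attr(out, "zscore_params") <- params
  out
}

#' Condense cells into population centers
#'
#' Within each condition, cells are randomly permuted (seeded) and
#' partitioned into `floor(N/n)` disjoint pools of exactly `n` cells;
#' remainder cells are discarded and counted. Each center is the unweighted
#' mean feature vector of its pool and becomes one population-level data
#' point.
#'
#' @param tbl feature tibble (typically z-scored) with `cell_id`,
#'   `condition` and feature columns.
#' @param n pool size (condensation number); every condition needs >= n
#'   cells.
#' @param seed integer seed for the permutation; `NULL` uses the session
#'   RNG.
#' @return A tibble `center_id, condition, pool_size`, then the feature
#'   columns; pool membership in `attr(, "members")`, discarded counts in
#'   `attr(, "discarded")`.
#' @export
condense_cells <- function(tbl, n, seed = NULL) {
  assert_columns(tbl, c("cell_id", "condition"), "`tbl`")
  assert_scalar_num(n, "n", lower = 1)
  n <- as.integer(n)
  fcols <- feature_columns(tbl)
  counts <- table(tbl$condition)
  if (any(counts < n)) {
    abort(sprintf("condition(s) with fewer than n = %d cells: %s", n,
                  paste(names(counts)[counts < n], collapse = ", ")))
  }

  with_seed_or_current(seed, {
    members <- list()
    discarded <- integer()
    centers <- list()
    cid <- 0L
    for (cond in sort(unique(tbl$condition))) {
      sub <- tbl[tbl$condition == cond, ]
      perm <- sample.int(nrow(sub))
      n_pools <- nrow(sub) %/% n
      discarded[cond] <- nrow(sub) - n_pools * n
      for (p in seq_len(n_pools)) {
        cid <- cid + 1L
        rows <- perm[((p - 1L) * n + 1L):(p * n)]
        id <- sprintf("center_%04d", cid)
        members[[id]] <- sub$cell_id[rows]
        centers[[id]] <- c(
          list(center_id = id, condition = cond, pool_size = n),
          as.list(colMeans(sub[rows, fcols]))
        )
      }
    }
    out <- bind_rows(centers)
    attr(out, "members") <- members
    attr(out, "discarded") <- discarded
    out
  })
}

# internal: one stratified train/test split + PCA + linear SVM, returning
# test-set predictions. min_test = 2 enforces the reporting contract; the
# bootstrap stage relaxes it to 1.
classify_once <- function(centers, fcols, n_components, train_frac,
                          min_test = 2L) {
  conds <- unique(centers$condition)
  tr_rows <- integer(); te_rows <- integer()
  for (cond in conds) {
    rows <- which(centers$condition == cond)
    n_te <- round(length(rows) * (1 - train_frac))
    n_te <- max(n_te, 1L)
    if (n_te < min_test) {
      abort(sprintf(
        "condition '%s' has %d test center(s) at train_frac = %g; need >= %d.",
        cond, n_te, train_frac, min_test))
    }
    if (length(rows) - n_te < 1L) {
      abort(sprintf("condition '%s' has no training centers left.", cond))
    }
    te <- sample(rows, n_te)
    te_rows <- c(te_rows, te)
    tr_rows <- c(tr_rows, setdiff(rows, te))
  }
  x <- as.matrix(centers[, fcols])
  if (length(fcols) < n_components) {
    abort(sprintf("need >= %d features for %d principal components.",
                  n_components, n_components))
  }
  pca <- prcomp(x[tr_rows, , drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pca$rotation))
  sc_tr <- pca$x[, seq_len(k), drop = FALSE]
  sc_te <- predict(pca, x[te_rows, , drop = FALSE])[, seq_len(k), drop = FALSE]
  y_tr <- factor(centers$condition[tr_rows], levels = sort(conds))
  fit <- e1071::svm(x = sc_tr, y = y_tr, kernel = "linear", cost = 1,
                    scale = FALSE)
  pred <- predict(fit, sc_te)
  list(truth = factor(centers$condition[te_rows], levels = sort(conds)),
       pred = pred, pca = pca, svm = fit)
}

#' Classify condensed centers (PCA + linear SVM)
#'
#' Fits the population-phenotyping classifier: PCA (4 components by
#' default) on the training centers, then a linear SVM on the component
#' scores, with a stratified 80/20 train/test split. Accuracy and the
#' confusion matrix are computed on the test set and averaged over
#' `repeats` seeded splits (set `repeats = 1` for a single literal split).
#' Confusion-matrix rows are percentages and sum to 100.
#'
#' @param centers output of [condense_cells] (>= 2 conditions, >= 5 centers
#'   per condition; the default split needs enough centers for 2 test
#'   centers each).
#' @param n_components retained principal components.
#' @param train_frac training fraction of each condition.
#' @param repeats number of seeded splits averaged.
#' @param seed integer seed.
#' @param on_pcs classify on PC scores (default) or on raw z-scored
#'   features.
#' @return A `miel_fit`: `report` (overall `accuracy`, `confusion` matrix
#'   in %, `per_repeat` accuracies) and `model` (PCA + SVM refitted on all
#'   centers, split seed). Methods: [tidy()], [glance()], [autoplot()].
#' @export
fit_classify <- function(centers, n_components = 4, train_frac = 0.8,
                         repeats = 20, seed = 1, on_pcs = TRUE) {
  assert_columns(centers, c("condition"), "`centers`")
  fcols <- feature_columns(centers)
  conds <- sort(unique(centers$condition))
  if (length(conds) < 2) abort("classification needs >= 2 conditions.")
  tab <- table(centers$condition)
  if (any(tab < 5)) {
    abort(sprintf("condition(s) with fewer than 5 centers: %s",
                  paste(names(tab)[tab < 5], collapse = ", ")))
  }

  k <- length(conds)
  conf_sum <- matrix(0, k, k, dimnames = list(true = conds, predicted = conds))
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    res <- with_seed_or_current(derive_seed(seed, r), {
      if (on_pcs) {
        classify_once(centers, fcols, n_components, train_frac)
      } else {
        classify_once(centers, fcols, length(fcols), train_frac)
      }
    })
    cm <- unclass(table(res$truth, res$pred))
    conf_sum <- conf_sum + sweep(cm, 1, pmax(rowSums(cm), 1), `/`) * 100
    acc[r] <- mean(res$truth == res$pred)
  }
  confusion <- conf_sum / repeats

  model <- with_seed_or_current(derive_seed(seed, 0), {
    x <- as.matrix(centers[, fcols])
    pca <- prcomp(x, center = TRUE, scale. = FALSE)
    kk <- if (on_pcs) min(n_components, ncol(pca$rotation)) else ncol(x)
    sc <- if (on_pcs) pca$x[, seq_len(kk), drop = FALSE] else x
    list(
      pca = pca, n_components = kk,
      explained_variance = (pca$sdev^2 / sum(pca$sdev^2))[seq_len(kk)],
      svm = e1071::svm(x = sc, y = factor(centers$condition, levels = conds),
                       kernel = "linear", cost = 1, scale = FALSE),
      on_pcs = on_pcs, seed = seed
    )
  })

  structure(list(
    report = list(accuracy = mean(acc), confusion = confusion,
                  per_repeat = acc, repeats = repeats),
    model = model,
    conditions = conds
  ), class = "miel_fit")
}

#' @export
print.miel_fit <- function(x, ...) {
  cat(sprintf("<miel_fit> %d conditions, accuracy %.1f%% over %d splits\n",
              length(x$conditions), 100 * x$report$accuracy,
              x$report$repeats))
  print(round(x$report$confusion, 1))
  invisible(x)
}

#' @rdname fit_classify
#' @param x a `miel_fit`.
#' @param ... unused.
#' @method tidy miel_fit
#' @export
tidy.miel_fit <- function(x, ...) {
  cm <- x$report$confusion
  as_tibble(as.data.frame.table(cm, responseName = "percent")) |>
    dplyr::rename(true = 1, predicted = 2)
}

#' @rdname fit_classify
#' @method glance miel_fit
#' @export
glance.miel_fit <- function(x, ...) {
  tibble(accuracy = x$report$accuracy, repeats = x$report$repeats,
         n_conditions = length(x$conditions),
         n_components = x$model$n_components)
}

#' Distance matrices and dispersion of condensed centers
#'
#' Computes the pairwise Euclidean distance matrix between all centers, the
#' condition-level distance matrix (mean distance over all cross-condition
#' center pairs; diagonal = within-condition mean), and the per-condition
#' dispersion (mean within-condition pair distance). Conditions with a
#' single center have undefined dispersion and are flagged `NA` with a
#' warning.
#'
#' @param centers output of [condense_cells] (or any tibble with
#'   `condition` and feature columns; >= 2 centers).
#' @return A list: `center_dist` (matrix), `condition_dist` (matrix),
#'   `dispersion` (tibble `condition, dispersion, n_centers`).
#' @export
distance_analysis <- function(centers) {
  assert_columns(centers, "condition", "`centers`")
  fcols <- feature_columns(centers)
  if (nrow(centers) < 2) abort("distance analysis needs >= 2 centers.")
  x <- as.matrix(centers[, fcols])
  ids <- if ("center_id" %in% names(centers)) centers$center_id
         else sprintf("center_%04d", seq_len(nrow(centers)))
  dmat <- as.matrix(dist(x))
  dimnames(dmat) <- list(ids, ids)

  conds <- sort(unique(centers$condition))
  cmat <- matrix(NA_real_, length(conds), length(conds),
                 dimnames = list(conds, conds))
  for (i in seq_along(conds)) {
    for (j in seq_along(conds)) {
      ri <- centers$condition == conds[i]
      rj <- centers$condition == conds[j]
      block <- dmat[ri, rj, drop = FALSE]
      cmat[i, j] <- if (i == j) {
        if (sum(ri) < 2) NA_real_ else mean(block[lower.tri(block)])
      } else {
        mean(block)
      }
    }
  }
  singles <- conds[table(centers$condition)[conds] < 2]
  if (length(singles)) {
    warn(sprintf("dispersion undefined for single-center condition(s): %s",
                 paste(singles, collapse = ", ")))
  }
  dispersion <- tibble(
    condition = conds,
    dispersion = diag(cmat),
    n_centers = as.integer(table(centers$condition)[conds])
  )
  list(center_dist = dmat, condition_dist = cmat, dispersion = dispersion)
}

#' Project points onto the first two discriminant factors
#'
#' Computes linear discriminant axes on the feature columns (within-class
#' covariance regularized by a ridge term so singular covariances are
#' handled) and projects every row onto the first two discriminant factors
#' for plotting. Axis signs are fixed by the convention that the loading of
#' largest magnitude on each axis is positive.
#'
#' @param tbl tibble with `condition` and feature columns (centers or
#'   cells), >= 2 conditions.
#' @param ridge ridge fraction added to the within-class covariance
#'   diagonal.
#' @return A tibble with the id columns of `tbl` plus `DF1`, `DF2`.
#' @export
discriminant_scatter <- function(tbl, ridge = 1e-3) {
  assert_columns(tbl, "condition", "`tbl`")
  fcols <- feature_columns(tbl)
  conds <- unique(tbl$condition)
  if (length(conds) < 2) abort("discriminant projection needs >= 2 conditions.")
  x <- as.matrix(tbl[, fcols])
  p <- ncol(x)

  mu <- colMeans(x)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (cond in conds) {
    xc <- x[tbl$condition == cond, , drop = FALSE]
    mc <- colMeans(xc)
    if (nrow(xc) > 1) {
      Sw <- Sw + crossprod(sweep(xc, 2, mc)) # (n_c - 1) * cov
    }
    Sb <- Sb + nrow(xc) * tcrossprod(mc - mu)
  }
  Sw <- Sw / max(1, nrow(x) - length(conds))
  Sw <- Sw + ridge * mean(diag(Sw)) * diag(p) + 1e-12 * diag(p)

  e <- eigen(solve(Sw, Sb))
  W <- Re(e$vectors[, 1:2, drop = FALSE])
  # sign convention: largest-|loading| entry positive
  for (j in 1:2) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  proj <- x %*% W
  idcols <- intersect(c("cell_id", "center_id", "condition"), names(tbl))
  bind_cols(tbl[, idcols], tibble(DF1 = proj[, 1], DF2 = proj[, 2]))
}
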