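# MIEL population phenotyping: normalization, condensation, classification

make_cells <- function(n = 60, effect = 2, seed = 1, conditions = c("a", "b"),
                       p = 10) {
  simulate_feature_table(conditions, n, n_features = p, effect_size = effect,
                         seed = seed)$cells
}

test_that("z-scoring gives zero-mean unit-SD columns and reusable parameters", {
  cells <- make_cells()
  z <- zscore_features(cells)
  fcols <- grep("^f_", names(z), value = TRUE)
  expect_true(all(abs(colMeans(z[fcols])) < 1e-9))
  expect_true(all(abs(vapply(z[fcols], sd, numeric(1)) - 1) < 1e-9))

  params <- attr(z, "zscore_params")
  z2 <- zscore_features(cells, params = params)
  expect_equal(as.data.frame(z2[fcols]), as.data.frame(z[fcols]),
               tolerance = 1e-12)
})

test_that("constant features are dropped with a warning; all-constant errors", {
  cells <- make_cells()
  cells$f_001 <- 5
  expect_warning(z <- zscore_features(cells), "f_001")
  expect_false("f_001" %in% names(z))
  flat <- cells[, 1:3]; flat$f_x <- 1
  expect_error(suppressWarnings(zscore_features(flat)), "zero variance")
})

test_that("condensation partitions cells into exact disjoint pools", {
  cells <- make_cells(n = 10, effect = 0, conditions = c("a", "b"))
  cen <- condense_cells(cells, 3, seed = 2)
  expect_identical(nrow(cen), 6L) # 3 pools per condition
  expect_true(all(cen$pool_size == 3))
  expect_identical(unname(attr(cen, "discarded")), c(1L, 1L))
  members <- attr(cen, "members")
  expect_false(anyDuplicated(unlist(members)) > 0)

  # brute-force mean oracle: every center equals the column mean of its pool
  fcols <- grep("^f_", names(cells), value = TRUE)
  for (id in names(members)) {
    pool <- cells[cells$cell_id %in% members[[id]], fcols]
    expect_equal(unlist(cen[cen$center_id == id, fcols]),
                 colMeans(pool), tolerance = 1e-12)
  }
})

test_that("pool size one returns the cells themselves", {
  cells <- make_cells(n = 4)
  cen <- condense_cells(cells, 1, seed = 3)
  fcols <- grep("^f_", names(cells), value = TRUE)
  expect_identical(nrow(cen), nrow(cells))
  expect_equal(sort(cen$f_001), sort(cells$f_001), tolerance = 1e-12)
  expect_error(condense_cells(cells, 5), "fewer than")
})

test_that("classification separates strong conditions and reports % rows summing to 100", {
  cells <- zscore_features(make_cells(n = 300, effect = 3, seed = 4))
  cen <- condense_cells(cells, 20, seed = 5)
  fit <- fit_classify(cen, repeats = 5, seed = 6)
  expect_gte(fit$report$accuracy, 0.95)
  expect_true(all(abs(rowSums(fit$report$confusion) - 100) < 0.5))
  expect_identical(dim(fit$report$confusion), c(2L, 2L))
  expect_equal(sum(tidy(fit)$percent), 200, tolerance = 0.5)
})

test_that("indistinguishable duplicate conditions classify at chance", {
  base <- make_cells(n = 400, effect = 0, seed = 7, conditions = c("a", "b"))
  z <- zscore_features(base)
  cen <- condense_cells(z, 10, seed = 8)
  fit <- fit_classify(cen, repeats = 10, seed = 9)
  # 99% binomial band around 0.5 with ~16 test decisions per repeat,
  # averaged over 10 repeats: use the conservative single-repeat band
  expect_gt(fit$report$accuracy, 0.5 - 2.576 * sqrt(0.25 / 16))
  expect_lt(fit$report$accuracy, 0.5 + 2.576 * sqrt(0.25 / 16))
})

test_that("too few test centers raise an error naming the condition", {
  cells <- make_cells(n = 60, effect = 1, seed = 10)
  z <- zscore_features(cells)
  cen <- condense_cells(z, 10, seed = 11) # 6 centers per condition
  expect_error(fit_classify(cen, repeats = 1, seed = 12), "'a'|'b'")
})

test_that("distance analysis matches hand and brute-force oracles", {
  cen <- tibble::tibble(
    center_id = c("c1", "c2"), condition = c("p", "q"),
    f_001 = c(0, 3), f_002 = c(0, 4)
  )
  expect_warning(da <- distance_analysis(cen), "single-center")
  expect_equal(da$center_dist["c1", "c2"], 5)

  cells <- zscore_features(make_cells(n = 30, effect = 1, seed = 13))
  cen2 <- condense_cells(cells, 5, seed = 14)
  da2 <- distance_analysis(cen2)
  fcols <- grep("^f_", names(cen2), value = TRUE)
  x <- as.matrix(cen2[, fcols])
  brute <- matrix(0, nrow(x), nrow(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(x))) {
      brute[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    }
  }
  expect_equal(unname(da2$center_dist), brute, tolerance = 1e-12)
  expect_true(isSymmetric(da2$center_dist))
  expect_true(all(diag(da2$center_dist) == 0))

  # permutation invariance of the condition-level matrix
  perm <- sample(nrow(cen2))
  da3 <- distance_analysis(cen2[perm, ])
  expect_equal(da3$condition_dist, da2$condition_dist, tolerance = 1e-12)
})

test_that("discriminant projection returns two factors separating strong conditions", {
  cells <- zscore_features(make_cells(n = 150, effect = 4, seed = 15))
  sc <- discriminant_scatter(cells)
  expect_true(all(c("DF1", "DF2") %in% names(sc)))
  expect_identical(nrow(sc), nrow(cells))
  byc <- split(sc$DF1, sc$condition)
  sep <- abs(mean(byc$a) - mean(byc$b)) /
    sqrt((var(byc$a) + var(byc$b)) / 2)
  expect_gt(sep, 5)

  null <- zscore_features(make_cells(n = 200, effect = 0, seed = 16))
  sc0 <- discriminant_scatter(null)
  byc0 <- split(sc0$DF1, null$condition)
  sep0 <- abs(mean(byc0$a) - mean(byc0$b)) /
    sqrt((var(byc0$a) + var(byc0$b)) / 2)
  expect_lt(sep0, 1)
})

test_that("direction-averaged features are invariant to a 90-degree rotation", {
  sim <- simulate_nuclei_images("x", 3, n_per_condition = 1,
                                shape = c(48, 48), seed = 17)
  rot90 <- function(m) t(m)[, nrow(m):1]
  crops <- list(sim$crops[[1]], rot90(sim$crops[[1]]))
  masks <- list(sim$masks[[1]], rot90(sim$masks[[1]]))
  ft <- extract_features(crops, masks,
                         tibble::tibble(cell_id = c("o", "r"),
                                        condition = "x"))
  fcols <- setdiff(names(ft), c("cell_id", "condition"))
  expect_equal(unlist(ft[1, fcols]), unlist(ft[2, fcols]), tolerance = 1e-6)
})

test_that("constant crops produce defined features and row counts are conserved", {
  crops <- list(matrix(0.5, 32, 32), matrix(runif(1024), 32, 32))
  masks <- list(matrix(TRUE, 32, 32), matrix(TRUE, 32, 32))
  ft <- extract_features(crops, masks)
  expect_identical(nrow(ft), 2L)
  expect_false(anyNA(ft[setdiff(names(ft), "condition")]))
  expect_identical(ft$int_sd[1], 0)
  expect_error(extract_features(crops[1], list(matrix(FALSE, 32, 32))),
               "empty mask")
})
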