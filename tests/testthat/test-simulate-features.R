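# per-cell feature-table and nucleus-crop simulators

test_that("feature table has the requested shape and labels", {
  sim <- simulate_feature_table(c("a", "b", "c"), 100, n_features = 20,
                                effect_size = 1, seed = 1)
  expect_identical(nrow(sim$cells), 300L)
  expect_identical(sum(grepl("^f_", names(sim$cells))), 20L)
  expect_true(all(table(sim$cells$condition) == 100))
})

test_that("zero effect size gives indistinguishable condition means", {
  sim <- simulate_feature_table(c("a", "b"), 2000, n_features = 5,
                                effect_size = 0, seed = 2)
  fcols <- grep("^f_", names(sim$cells), value = TRUE)
  ma <- colMeans(sim$cells[sim$cells$condition == "a", fcols])
  mb <- colMeans(sim$cells[sim$cells$condition == "b", fcols])
  # SE of a mean difference at n = 2000 per arm is sqrt(2/2000) ~ 0.032
  expect_lt(max(abs(ma - mb)), 4 * sqrt(2 / 2000))
})

test_that("a large effect is linearly separable at the single-cell level", {
  sim <- simulate_feature_table(c("a", "b"), 200, n_features = 20,
                                effect_size = 3, seed = 3)
  fcols <- grep("^f_", names(sim$cells), value = TRUE)
  train <- sim$cells[c(1:150, 201:350), ]
  test <- sim$cells[c(151:200, 351:400), ]
  fit <- e1071::svm(x = as.matrix(train[fcols]), y = factor(train$condition),
                    kernel = "linear", cost = 1, scale = FALSE)
  acc <- mean(predict(fit, as.matrix(test[fcols])) == test$condition)
  expect_gte(acc, 0.95)
})

test_that("effect size requires at least two conditions", {
  expect_error(simulate_feature_table("only", 10, effect_size = 1),
               "2 conditions")
})

test_that("nucleus crops come with one mask each and chosen counts", {
  sim <- simulate_nuclei_images(c("x", "y"), c(2, 4), n_per_condition = 6,
                                shape = c(48, 48), seed = 4)
  expect_length(sim$crops, 12)
  expect_length(sim$masks, 12)
  expect_identical(sum(sim$cells$condition == "x"), 6L)
  expect_true(all(vapply(sim$crops, function(x) all(x >= 0 & x <= 1),
                         logical(1))))
})

test_that("texture correlation length separates co-occurrence homogeneity", {
  sim <- simulate_nuclei_images(c("fine", "coarse"), c(2, 8),
                                n_per_condition = 10, shape = c(64, 64),
                                seed = 5)
  ft <- extract_features(sim$crops, sim$masks, sim$cells)
  idm <- split(ft$h.idm.d1, ft$condition)
  pooled_sd <- sqrt((var(idm$fine) + var(idm$coarse)) / 2)
  effect <- abs(mean(idm$coarse) - mean(idm$fine)) / pooled_sd
  expect_gt(effect, 1)
})

test_that("a crop smaller than the texture scale is rejected", {
  expect_error(
    simulate_nuclei_images("x", 10, n_per_condition = 1, shape = c(24, 24)),
    "too small"
  )
})
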