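test_that("bagged forest learns separable data and is seed-deterministic", {
  ds <- make_separable_dataset()
  fit <- train_forest(ds, forest_config(n_trees = 50, seed = 3))
  expect_lte(fit$oob_error, 0.05)
  expect_equal(mean(predict(fit, ds) != ds$labels), 0)

  fit2 <- train_forest(ds, forest_config(n_trees = 50, seed = 3))
  probe <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(predict(fit, probe), predict(fit2, probe))
  expect_identical(fit$oob_error_by_ntrees, fit2$oob_error_by_ntrees)
})

test_that("coin-flip labels give chance-level OOB error", {
  set.seed(9)
  X <- matrix(rnorm(200 * 3), 200, dimnames = list(NULL, c("x", "y", "z")))
  y <- rbinom(200, 1, 0.5)
  fit <- train_forest(labeled_dataset(X, y), forest_config(seed = 5))
  expect_gte(fit$oob_error, 0.35)
  expect_lte(fit$oob_error, 0.65)
})

test_that("prediction follows majority vote with documented edge behaviour", {
  ds <- make_separable_dataset()
  # single-tree forest: ensemble prediction equals that tree's prediction
  fit1 <- train_forest(ds, forest_config(n_trees = 1, seed = 7))
  pred_tree <- hemigait:::rf_predict_cpp(fit1$trees, ds$matrix)[, 1]
  expect_identical(predict(fit1, ds), as.integer(pred_tree))

  # permutation equivariance
  fit <- train_forest(ds, forest_config(n_trees = 25, seed = 7))
  perm <- sample(nrow(ds$matrix))
  expect_identical(predict(fit, ds$matrix[perm, ]),
                   predict(fit, ds$matrix)[perm])

  # attribute mismatch is an error; names may arrive in any order
  m <- ds$matrix[, c("b", "a")]
  expect_identical(predict(fit, m), predict(fit, ds$matrix))
  expect_error(predict(fit, ds$matrix[, "a", drop = FALSE]),
               class = "hemigait_validation_error")

  expect_error(train_forest(labeled_dataset(ds$matrix, rep(1, 40))),
               class = "hemigait_degenerate_error")
  expect_error(forest_config(n_trees = 51), class = "hemigait_validation_error")
})

test_that("bootstrap resamples have the expected unique fraction", {
  ds <- make_separable_dataset(n_per_class = 50)
  frac <- vapply(1:30, function(s) {
    fit <- hemigait:::rf_fit_cpp(ds$matrix, ds$labels, 20L, 1L, 1L, s)
    mean(colSums(fit$inbag > 0) / nrow(ds$matrix))
  }, numeric(1))
  expect_equal(mean(frac), 1 - exp(-1), tolerance = 0.02)
})

test_that("OOB error declines (or plateaus) with more trees on separable data", {
  ds <- make_separable_dataset()
  curves <- sapply(1:20, function(s) {
    train_forest(ds, forest_config(n_trees = 50, seed = s))$oob_error_by_ntrees
  })
  avg <- rowMeans(curves)
  expect_lte(avg[50], avg[1])
  # smooth trend: no late increase beyond Monte-Carlo noise
  expect_lte(max(avg[25:50]), avg[5] + 0.02)
})

test_that("the error surface behaves like the training error picture", {
  ds <- make_planted_dataset()
  surf <- error_curves(ds, c("planted", "noise01", "noise02"), max_trees = 20,
                       cfg = forest_config(seed = 4))
  expect_equal(dim(surf), c(3, 20))
  expect_true(all(surf >= 0 & surf <= 1, na.rm = TRUE))
  expect_lte(surf[2, 20], surf[1, 1])

  # pure-noise attributes beyond the informative prefix do not help
  reps <- sapply(1:20, function(s) {
    s1 <- error_curves(ds, "planted", max_trees = 15,
                       cfg = forest_config(seed = s))[1, 15]
    s3 <- error_curves(ds, c("planted", "noise03", "noise04"), max_trees = 15,
                       cfg = forest_config(seed = s))[3, 15]
    c(s1, s3)
  })
  expect_gte(mean(reps[2, ]) + 0.02, mean(reps[1, ]))
})

test_that("stratified splitting preserves class ratios and subject grouping", {
  set.seed(41)
  n_h <- 40; n_n <- 30
  X <- matrix(rnorm((n_h + n_n) * 2), n_h + n_n,
              dimnames = list(NULL, c("a", "b")))
  y <- rep(c(1, 0), c(n_h, n_n))
  subj <- paste0("S", rep(1:35, each = 2))
  ds <- labeled_dataset(X, y, subject_ids = subj)

  sp <- stratified_split(ds, 0.75, seed = 2, group_by_subject = FALSE)
  expect_equal(sum(sp$test$labels == 1), 10)
  expect_true(sum(sp$test$labels == 0) %in% c(7, 8))

  spg <- stratified_split(ds, 0.75, seed = 2, group_by_subject = TRUE)
  expect_length(intersect(spg$train$subject_ids, spg$test$subject_ids), 0)

  sp1 <- stratified_split(ds, 1.0, seed = 2)
  expect_length(sp1$test$labels, 0)
  expect_length(sp1$train$labels, 70)

  expect_identical(stratified_split(ds, 0.75, seed = 9)$train$subject_ids,
                   stratified_split(ds, 0.75, seed = 9)$train$subject_ids)
  expect_error(stratified_split(labeled_dataset(X, rep(1, 70)), 0.75),
               class = "hemigait_degenerate_error")
})

test_that("k-fold cross-validation partitions rows and averages fold metrics", {
  ds <- make_separable_dataset(n_per_class = 4)  # n = 8, k = 4
  rep4 <- kfold_cv(ds, k = 4, cfg = forest_config(n_trees = 10), seed = 3)
  expect_equal(sort(as.vector(table(rep4$fold_assignment))), rep(2L, 4))
  # every row validated exactly once: fold sizes partition the data
  expect_length(rep4$fold_assignment, 8)

  dsep <- make_separable_dataset(n_per_class = 16)
  rep_sep <- kfold_cv(dsep, k = 4, cfg = forest_config(n_trees = 25), seed = 3)
  expect_equal(rep_sep$mean_metrics$ac, 100)
  expect_equal(rep_sep$error, 0)

  expect_identical(kfold_cv(dsep, 4, forest_config(), seed = 5)$fold_assignment,
                   kfold_cv(dsep, 4, forest_config(), seed = 5)$fold_assignment)
})

test_that("the ensemble agrees with an established bagging implementation", {
  skip_if_not_installed("randomForest")
  ds <- make_separable_dataset(n_per_class = 25)
  ours <- train_forest(ds, forest_config(n_trees = 50, seed = 1))
  set.seed(1)
  ref <- randomForest::randomForest(ds$matrix, factor(ds$labels), ntree = 50)
  # both backends should find this trivial structure: OOB errors both ~0
  expect_lte(ours$oob_error, 0.05)
  expect_lte(mean(ref$err.rate[50, "OOB"]), 0.05)
  probe <- ds$matrix + matrix(rnorm(50 * 2, 0, 0.05), 50)
  expect_equal(mean(predict(ours, probe) !=
                      as.integer(as.character(predict(ref, probe)))), 0,
               tolerance = 0.05)
})
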