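test_that("stratified folds preserve class proportions within one study", {
  labels <- rep(0:3, times = c(991, 296, 23, 24))   # a realistic cohort mix
  folds <- make_stratified_folds(labels, k = 5, seed = 3)
  # test sets partition the studies
  test_all <- sort(unlist(lapply(folds, `[[`, "test_ids")))
  expect_identical(test_all, seq_along(labels))
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    counts <- table(factor(labels[f$test_ids], levels = 0:3))
    # 24 grade-3 studies over 5 folds: every fold holds 4 or 5
    expect_true(counts[["3"]] %in% 4:5)
    expect_true(counts[["2"]] %in% 4:5)
  }
  # per-class test counts differ by at most one across folds
  for (cl in 0:3) {
    per_fold <- vapply(folds, function(f) sum(labels[f$test_ids] == cl),
                       numeric(1))
    expect_lte(diff(range(per_fold)), 1)
  }
})

test_that("fold shuffling is seeded but stratification is seed-invariant", {
  labels <- rep(0:1, times = c(30, 10))
  f1 <- make_stratified_folds(labels, k = 5, seed = 1)
  f2 <- make_stratified_folds(labels, k = 5, seed = 2)
  expect_false(identical(lapply(f1, `[[`, "test_ids"),
                         lapply(f2, `[[`, "test_ids")))
  count_of <- function(fs) lapply(fs, function(f)
    as.vector(table(factor(labels[f$test_ids], levels = 0:1))))
  expect_identical(count_of(f1), count_of(f2))
  # ten studies of one class over five folds: two per fold
  f3 <- make_stratified_folds(rep(1L, 10), k = 5, seed = 1)
  expect_true(all(vapply(f3, function(f) length(f$test_ids), numeric(1)) == 2))
  expect_error(make_stratified_folds(labels, k = 1), ">= 2")
  expect_warning(make_stratified_folds(rep(0:1, c(3, 12)), k = 5, seed = 1),
                 "fewer members")
})

test_that("inverse-frequency class weights satisfy the mass identity", {
  labels <- rep(0:3, times = c(991, 296, 23, 24))
  w <- compute_class_weights(labels)
  expect_equal(unname(w), c(0.337, 1.127, 14.500, 13.896), tolerance = 1e-3)
  counts <- c(991, 296, 23, 24)
  expect_lt(abs(sum(w * counts) - length(labels)), 1e-9)
  # minority weights dominate majority weights
  expect_true(all(w[3:4] > w[1:2]))
  expect_equal(unname(compute_class_weights(rep(0:3, each = 7))), rep(1, 4))
  expect_error(compute_class_weights(c(0, 0, 1), classes = 0:2), "empty class")
})

test_that("task relabeling implements the clinical dichotomies", {
  expect_identical(relabel_for_task(0:3, "four_class"), 0:3)
  expect_identical(relabel_for_task(0:3, "pos_vs_neg"), c(0L, 0L, 1L, 1L))
  expect_identical(relabel_for_task(0:3, "grade3_vs_rest"), c(0L, 0L, 0L, 1L))
  expect_error(relabel_for_task(c(1, 4), "four_class"), "0..3")
  expect_error(relabel_for_task(0:3, "bogus"))
})

test_that("augmentation yields multiplier x n seeded images with inherited labels", {
  set.seed(20)
  imgs <- replicate(1066, matrix(runif(64), 8, 8), simplify = FALSE)
  labels <- sample(0:3, 1066, replace = TRUE)
  cfg <- augmentation_config(multiplier = 5, seed = 7)
  aug <- augment_training_set(imgs, labels, cfg)
  expect_length(aug$images, 5330)
  expect_identical(aug$labels, labels[aug$source])
  aug2 <- augment_training_set(imgs, labels, cfg)
  expect_identical(aug$images[[17]], aug2$images[[17]])
  none <- augment_training_set(imgs, labels,
                               augmentation_config(multiplier = 0))
  expect_length(none$images, 0)
})

test_that("zero-range augmentation is the exact identity", {
  set.seed(21)
  imgs <- replicate(3, matrix(runif(32 * 32), 32, 32), simplify = FALSE)
  cfg <- augmentation_config(shift_range = 0, rotation_range = 0,
                             zoom_range = 0, multiplier = 2, seed = 1)
  aug <- augment_training_set(imgs, c(0L, 1L, 2L), cfg)
  for (i in seq_along(aug$images))
    expect_equal(aug$images[[i]], imgs[[aug$source[i]]], tolerance = 1e-12)
})

test_that("augmented content stays within the configured geometric ranges", {
  # a centered bright square shifted by at most 10% + zoom slack
  img <- matrix(0, 64, 64); img[29:36, 29:36] <- 1
  cfg <- augmentation_config(multiplier = 20, seed = 3)
  aug <- augment_training_set(list(img), 1L, cfg)
  for (m in aug$images) {
    expect_identical(dim(m), c(64L, 64L))
    com <- which(m == max(m), arr.ind = TRUE)[1, ]
    # center of an 8px square can move ~6.4px by shift + a few px by zoom
    expect_true(all(abs(com - 32.5) < 14))
  }
})

test_that("training reduces loss on a separable two-class phantom problem", {
  iv <- rbind(c(0, 0.1), c(0, 0.1), c(1.5, 2), c(1.5, 2))
  studies <- generate_dataset(40, c(0.5, 0, 0, 0.5), seed = 31,
                              base_config = phantom_config(grade_intervals = iv))
  pp <- preprocess_studies(studies)
  imgs <- lapply(pp$images, resample_area, 32, 32)
  y <- relabel_for_task(pp$meta$grade, "grade3_vs_rest")
  stats <- compute_norm_stats(imgs)
  xn <- lapply(imgs, zscore_apply, stats = stats)
  # independent oracle: logistic regression on mean cardiac-window intensity
  feat <- vapply(xn, function(m) mean(m[10:26, 6:20]), numeric(1))
  fit0 <- suppressWarnings(glm(y ~ feat, family = binomial))
  expect_equal(mean((predict(fit0, type = "response") > 0.5) == y), 1)
  spec <- model_spec("linear", n_classes = 2, input_size = 32,
                     filter_plan = c(8, 16, 32, 64), stem_filters = 8,
                     init_seed = 1)
  cfg <- train_config(epochs = 10, batch_size = 4, initial_lr = 1e-3,
                      clip_norm = 1, lr_factor = 1, restore_best = TRUE,
                      seed = 2)
  fit <- train_model(build_model(spec), xn, y, weights = rep(1, 2), cfg = cfg)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  probs <- predict(fit$net, xn)
  expect_gte(mean((max.col(probs) - 1) == y), 0.95)
})

test_that("the learning-rate schedule is non-increasing and floored", {
  set.seed(12)
  imgs <- replicate(30, matrix(rnorm(64), 8, 8), simplify = FALSE)
  y <- sample(0:1, 30, replace = TRUE)
  spec <- model_spec("linear", n_classes = 2, input_size = 8,
                     filter_plan = c(2, 2, 2, 2), stem_filters = 2,
                     dropout = 0)
  # zero class weights freeze the network, so the validation loss can never
  # improve and the plateau rule must fire every `lr_patience` epochs
  cfg <- train_config(epochs = 16, batch_size = 8, initial_lr = 1e-4,
                      lr_patience = 2, lr_factor = 0.1, min_lr = 1e-7,
                      seed = 5)
  fit <- train_model(build_model(spec), imgs, y, weights = c(0, 0), cfg = cfg)
  lrs <- fit$history$lr
  expect_true(all(diff(lrs) <= 0))
  expect_true(all(lrs >= 1e-7))
  expect_lt(tail(lrs, 1), 1e-4)   # reductions fired
  expect_equal(min(lrs), 1e-7)    # and bottomed out at the floor
})

test_that("all-zero class weights freeze the parameters", {
  set.seed(13)
  imgs <- replicate(12, matrix(rnorm(64), 8, 8), simplify = FALSE)
  y <- rep(0:1, 6)
  spec <- model_spec("linear", n_classes = 2, input_size = 8,
                     filter_plan = c(2, 2, 2, 2), stem_filters = 2,
                     dropout = 0)
  net <- build_model(spec)
  fit <- train_model(net, imgs, y, weights = c(0, 0),
                     cfg = train_config(epochs = 2, batch_size = 4, seed = 3))
  expect_equal(fit$net$layers$stem$W, net$layers$stem$W)
  expect_equal(fit$net$layers$head$W, net$layers$head$W)
  expect_true(all(abs(fit$history$loss) < 1e-12))
})

test_that("weighted loss with unit weights equals the unweighted loss", {
  ns <- asNamespace("scintigrade")
  set.seed(14)
  probs <- matrix(runif(40), 4, 10)
  probs <- sweep(probs, 2, colSums(probs), "/")
  y <- sample(0:3, 10, replace = TRUE)
  lw <- ns$nn_loss_grad(probs, y, rep(1, 4))
  plain <- mean(-log(probs[cbind(y + 1, 1:10)]))
  expect_equal(lw$loss, plain, tolerance = 1e-12)
})

test_that("evaluation metrics match their definitions and the AUC oracle", {
  # 3-example hand case: perfect ranking and argmax agreement
  probs <- cbind(1 - c(0.9, 0.4, 0.6), c(0.9, 0.4, 0.6))
  rep <- evaluation_report(probs, c(1L, 0L, 1L), task = "pos_vs_neg")
  expect_equal(rep$auc, 1)
  expect_equal(rep$accuracy, 1)
  # constant scores: chance-level ranking
  flat <- evaluation_report(matrix(0.5, 10, 2), rep(0:1, 5))
  expect_equal(flat$auc, 0.5)
  # random prediction sets against the brute-force concordance oracle
  set.seed(15)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    s <- round(runif(n), 2)          # coarse scores force ties
    rep_i <- evaluation_report(cbind(1 - s, s), y)
    expect_equal(rep_i$auc, oracle_auc(y, s), tolerance = 1e-12)
  }
  # single-class test set: NA AUC with a warning
  expect_warning(one <- evaluation_report(matrix(0.5, 4, 2), rep(1L, 4)),
                 "single class")
  expect_true(is.na(one$auc))
})

test_that("confusion-derived identities hold on random four-class reports", {
  set.seed(16)
  n <- 200L
  probs <- matrix(runif(4 * n), n, 4)
  probs <- probs / rowSums(probs)
  y <- sample(0:3, n, replace = TRUE)
  rep <- evaluation_report(probs, y)
  expect_identical(sum(rep$confusion), n)
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / n)
  expect_equal(unname(rowSums(rep$confusion)),
               as.vector(table(factor(y, levels = 0:3))))
  # micro-averaged recall equals total accuracy for the multi-class task
  micro_recall <- sum(diag(rep$confusion)) / sum(rep$confusion)
  expect_equal(micro_recall, rep$accuracy)
  # per-class definitions
  for (k in 1:4) {
    tp <- rep$confusion[k, k]
    expect_equal(rep$precision[[k]], tp / sum(rep$confusion[, k]))
    expect_equal(rep$recall[[k]], tp / sum(rep$confusion[k, ]))
  }
})

test_that("cross-validation pools disjoint out-of-fold predictions without leakage", {
  set.seed(17)
  # small synthetic images whose mean encodes the grade
  n <- 48L
  y <- rep(0:3, each = 12)
  imgs <- lapply(y, function(g) matrix(rnorm(256, mean = g), 16, 16))
  spec <- model_spec("linear", input_size = 16, filter_plan = c(2, 2, 2, 2),
                     stem_filters = 2)
  cv <- run_cross_validation(
    imgs, y, spec, "four_class", k = 4,
    train_cfg = train_config(epochs = 2, batch_size = 8, initial_lr = 1e-3,
                             clip_norm = 1),
    aug_cfg = augmentation_config(multiplier = 1), seed = 9,
    keep_models = TRUE)
  # every study predicted exactly once, confusion totals match
  expect_false(anyNA(cv$pooled_probs))
  expect_identical(sum(cv$report$confusion), n)
  expect_identical(sort(unlist(lapply(cv$folds, `[[`, "test_ids"))), 1:n)
  # leakage guard: each fold's stored stats equal stats recomputed from its
  # training images alone
  for (f in seq_along(cv$models)) {
    tr <- cv$folds[[f]]$train_ids
    expect_equal(cv$models[[f]]$stats$mean, compute_norm_stats(imgs[tr])$mean)
  }
  # binary task relabels and reports two classes
  cv2 <- run_cross_validation(
    imgs, y, spec, "pos_vs_neg", k = 4,
    train_cfg = train_config(epochs = 1, batch_size = 8),
    aug_cfg = augmentation_config(multiplier = 0), seed = 9)
  expect_identical(ncol(cv2$pooled_probs), 2L)
  expect_identical(cv2$predictions$true, as.integer(y >= 2))
})

test_that("subgroup reports split by metastasis flag and cover all studies", {
  set.seed(18)
  n <- 40L
  probs <- matrix(runif(2 * n), n, 2); probs <- probs / rowSums(probs)
  y <- sample(0:1, n, replace = TRUE); y[1:2] <- 0:1
  cv <- structure(list(pooled_probs = probs,
                       predictions = data.frame(true = y,
                                                has_metastases = rep(c(TRUE, FALSE),
                                                                     n / 2)),
                       task = "pos_vs_neg"),
                  class = "cv_result")
  sub <- subgroup_report(cv)
  expect_identical(sub$metastases$n + sub$no_metastases$n, n)
  # all-false flags: the no-metastasis report equals the overall report
  cv$predictions$has_metastases <- rep(FALSE, n)
  expect_warning(sub2 <- subgroup_report(cv), "empty subgroup")
  overall <- evaluation_report(probs, y, task = "pos_vs_neg")
  expect_equal(sub2$no_metastases$auc, overall$auc)
  expect_equal(sub2$no_metastases$accuracy, overall$accuracy)
  expect_true(is.na(sub2$metastases$auc))
})
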