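# ROC / precision / recall evaluation, pooled cross-validation, and the
# bone-metastasis subgroup analysis.

# Binary ROC-AUC on the positive-class score. Explicit levels and direction
# so pROC never auto-orients (auto-orientation would silently report
# max(AUC, 1 - AUC)).
auc_binary <- function(labels, scores) {
  if (length(unique(labels)) < 2L) {
    warning("AUC undefined: test set contains a single class")
    return(NA_real_)
  }
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Macro-averaged one-vs-rest AUC over the classes that have both positives
# and negatives in the test set.
auc_macro_ovr <- function(labels, probs) {
  K <- ncol(probs)
  aucs <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    bin <- as.integer(labels == k - 1L)
    if (length(unique(bin)) == 2L)
      aucs[k] <- auc_binary(bin, probs[, k])
  }
  if (all(is.na(aucs))) {
    warning("AUC undefined: no class has both positives and negatives")
    return(NA_real_)
  }
  mean(aucs, na.rm = TRUE)
}

#' Evaluation report from predicted probabilities
#'
#' Computes AUC (binary ROC-AUC for two-class tasks, macro-averaged
#' one-vs-rest for the four-class task), total accuracy, per-class precision
#' and recall, and the confusion matrix. Precision/recall with an empty
#' denominator are reported as `NA`, never silently as zero.
#'
#' @param probs N x K matrix of class probabilities.
#' @param labels 0-based integer true labels.
#' @param task Task label stored in the report.
#' @param subgroup Optional subgroup label (`"all"`, `"metastases"`,
#'   `"no_metastases"`).
#' @return An object of class `evaluation_report`.
#' @export
evaluation_report <- function(probs, labels, task = "four_class",
                              subgroup = "all") {
  probs <- as.matrix(probs)
  K <- ncol(probs)
  n <- nrow(probs)
  stopifnot(length(labels) == n)
  pred <- max.col(probs, ties.method = "first") - 1L
  classes <- 0:(K - 1L)
  confusion <- table(factor(labels, levels = classes),
                     factor(pred, levels = classes))
  confusion <- matrix(as.integer(confusion), K, K,
                      dimnames = list(true = classes, predicted = classes))
  tp <- diag(confusion)
  precision <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), NA_real_)
  recall <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), NA_real_)
  names(precision) <- names(recall) <- classes
  auc <- if (n == 0L) NA_real_
         else if (K == 2L) auc_binary(labels, probs[, 2L])
         else auc_macro_ovr(labels, probs)
  structure(list(task = task, subgroup = subgroup, n = n, auc = auc,
                 accuracy = if (n > 0) sum(tp) / n else NA_real_,
                 precision = precision, recall = recall,
                 confusion = confusion),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> task=%s subgroup=%s n=%d\n",
              x$task, x$subgroup, x$n))
  cat(sprintf("  AUC %.3f  accuracy %.3f\n", x$auc, x$accuracy))
  for (cl in names(x$precision))
    cat(sprintf("  class %s: precision %.3f recall %.3f\n", cl,
                x$precision[[cl]], x$recall[[cl]]))
  invisible(x)
}

#' Evaluate a trained network on a test set
#'
#' @param net Trained `scinti_network`.
#' @param test_images List of normalized image matrices or an (H, W, 1, N)
#'   array.
#' @param test_labels 0-based task labels.
#' @param task Task label for the report.
#' @return An [evaluation_report()].
#' @export
evaluate_model <- function(net, test_images, test_labels,
                           task = "four_class") {
  probs <- predict(net, test_images)
  evaluation_report(probs, test_labels, task = task)
}

#' Stratified cross-validated training and evaluation
#'
#' For each fold: fit normalization statistics on the training images alone,
#' augment the training set, compute class weights, build a fresh network,
#' train, and predict the held-out fold. The headline report is computed on
#' the out-of-fold predictions pooled over all folds; per-fold reports are
#' retained.
#'
#' @param images List of 128 x 128 log-count matrices (e.g.
#'   `preprocess_studies()$images`).
#' @param labels Integer Perugini grades 0..3, parallel to `images`.
#' @param spec A [model_spec()]; `n_classes` and `input_size` are aligned
#'   with `task` and `input_size` automatically.
#' @param task Classification task, see [relabel_for_task()].
#' @param k Number of folds.
#' @param train_cfg A [train_config()].
#' @param aug_cfg An [augmentation_config()].
#' @param seed Master seed for fold assignment and per-fold derived seeds.
#' @param input_size Optional working resolution: images (already
#'   log-transformed) are area-averaged down to this size before
#'   normalization and training. `NULL` keeps 128.
#' @param has_metastases Optional logical vector for the subgroup analysis,
#'   stored with the predictions.
#' @param ids Optional study identifiers.
#' @param keep_models Retain each fold's trained network (memory permitting).
#' @return A `cv_result`: pooled `report`, `fold_reports`, `predictions`
#'   data frame (id, task, true label, fold, class probabilities), fold
#'   assignment, and optionally `models`.
#' @export
run_cross_validation <- function(images, labels, spec,
                                 task = c("four_class", "pos_vs_neg",
                                          "grade3_vs_rest"),
                                 k = 5L, train_cfg = train_config(),
                                 aug_cfg = augmentation_config(),
                                 seed = 1L, input_size = NULL,
                                 has_metastases = NULL, ids = NULL,
                                 keep_models = FALSE) {
  task <- match.arg(task)
  n <- length(images)
  ids <- ids %||% seq_len(n)
  y_task <- relabel_for_task(labels, task)
  K <- task_n_classes(task)
  spec$n_classes <- K
  if (!is.null(input_size) && input_size != dim(images[[1]])[1]) {
    images <- lapply(images, resample_area, input_size, input_size)
  }
  spec$input_size <- as.integer(dim(images[[1]])[1])
  folds <- make_stratified_folds(labels, k = k, seed = seed)
  pooled <- matrix(NA_real_, n, K)
  fold_of <- integer(n)
  fold_reports <- vector("list", k)
  models <- if (keep_models) vector("list", k) else NULL
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train_ids
    te <- folds[[f]]$test_ids
    fold_of[te] <- f - 1L
    fold_seed <- (seed * 1000L + f) %% .Machine$integer.max
    # normalization statistics from this fold's training images only
    stats <- compute_norm_stats(images[tr])
    aug <- if (aug_cfg$multiplier > 0) {
      acfg <- aug_cfg; acfg$seed <- fold_seed
      augment_training_set(images[tr], y_task[tr], acfg)
    } else list(images = list(), labels = integer(0))
    train_imgs <- c(images[tr], aug$images)
    train_lbls <- c(y_task[tr], aug$labels)
    train_norm <- lapply(train_imgs, zscore_apply, stats = stats)
    weights <- if (train_cfg$class_weighting == "inverse_frequency")
      compute_class_weights(y_task[tr], classes = 0:(K - 1L))
    else rep(1, K)
    fspec <- spec; fspec$init_seed <- fold_seed + 1L
    net <- build_model(fspec)
    tcfg <- train_cfg; tcfg$seed <- fold_seed + 2L
    fit <- train_model(net, train_norm, train_lbls, weights, tcfg)
    test_norm <- lapply(images[te], zscore_apply, stats = stats)
    probs <- predict(fit$net, test_norm)
    pooled[te, ] <- probs
    fold_reports[[f]] <- evaluation_report(probs, y_task[te], task = task)
    if (keep_models) models[[f]] <- list(net = fit$net, stats = stats,
                                         history = fit$history,
                                         test_ids = te)
  }
  predictions <- data.frame(id = ids, task = task, true = y_task,
                            fold = fold_of)
  for (j in seq_len(K))
    predictions[[paste0("p", j - 1L)]] <- pooled[, j]
  if (!is.null(has_metastases)) predictions$has_metastases <- has_metastases
  structure(list(report = evaluation_report(pooled, y_task, task = task),
                 fold_reports = fold_reports, predictions = predictions,
                 pooled_probs = pooled, task = task, spec = spec,
                 folds = folds, models = models),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d folds, %d studies (pooled out-of-fold)\n",
              x$task, length(x$fold_reports), nrow(x$predictions)))
  print(x$report)
  invisible(x)
}

#' Metastasis subgroup evaluation
#'
#' Recomputes the pooled evaluation report separately for studies with and
#' without bone metastases, with identical metric definitions, to check
#' whether skeletal lesions disturb the cardiac-uptake classification.
#'
#' @param cv A `cv_result` from [run_cross_validation()].
#' @param has_metastases Logical vector parallel to the studies; taken from
#'   the predictions if it was supplied to the cross-validation.
#' @return `list(metastases = ..., no_metastases = ...)` of
#'   [evaluation_report()]s (an empty subgroup yields an NA report with a
#'   warning).
#' @export
subgroup_report <- function(cv, has_metastases = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  flags <- has_metastases %||% cv$predictions$has_metastases
  if (is.null(flags)) stop("no metastasis flags available")
  stopifnot(length(flags) == nrow(cv$predictions))
  one <- function(sel, label) {
    if (!any(sel)) {
      warning("empty subgroup: ", label)
      return(structure(list(task = cv$task, subgroup = label, n = 0L,
                            auc = NA_real_, accuracy = NA_real_,
                            precision = NA_real_, recall = NA_real_,
                            confusion = NULL),
                       class = "evaluation_report"))
    }
    evaluation_report(cv$pooled_probs[sel, , drop = FALSE],
                      cv$predictions$true[sel], task = cv$task,
                      subgroup = label)
  }
  list(metastases = one(flags, "metastases"),
       no_metastases = one(!flags, "no_metastases"))
}
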