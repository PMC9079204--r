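# Cross-validation machinery: stratified folds, randomized affine
# augmentation, inverse-frequency class weights, task relabeling, and the
# Adam training loop with reduce-on-plateau learning-rate scheduling.

#' Stratified k-fold assignment
#'
#' Splits each class's (shuffled) members as evenly as possible over k folds,
#' rotating which folds receive the remainders, so per-class test counts
#' differ by at most one study between folds. Classes with fewer members than
#' folds are spread one-per-fold over as many folds as possible, with a
#' warning.
#'
#' @param labels Integer class labels, one per study.
#' @param k Number of folds (>= 2).
#' @param seed Shuffling seed; assignments are deterministic given it.
#' @param ids Optional study identifiers (default positional indices).
#' @return A list of k folds, each `list(fold_id, train_ids, test_ids)`;
#'   test sets partition the studies.
#' @export
make_stratified_folds <- function(labels, k = 5L, seed = 1L, ids = NULL) {
  if (k < 2L) stop("k must be >= 2")
  ids <- ids %||% seq_along(labels)
  stopifnot(length(ids) == length(labels))
  classes <- sort(unique(labels))
  small <- classes[tabulate(match(labels, classes)) < k]
  if (length(small) > 0)
    warning("class(es) ", paste(small, collapse = ", "),
            " have fewer members than folds; spreading one per fold")
  fold_of <- integer(length(labels))
  offset <- 0L
  with_seed(seed, {
    for (cl in classes) {
      members <- which(labels == cl)
      members <- members[sample.int(length(members))]
      n_c <- length(members)
      base <- n_c %/% k; extra <- n_c %% k
      sizes <- rep(base, k)
      if (extra > 0) sizes[(offset + 0:(extra - 1L)) %% k + 1L] <-
          sizes[(offset + 0:(extra - 1L)) %% k + 1L] + 1L
      offset <- offset + extra
      fold_of[members] <- rep(seq_len(k), times = sizes)
    }
  })
  lapply(seq_len(k), function(f)
    list(fold_id = f - 1L,
         train_ids = ids[fold_of != f],
         test_ids = ids[fold_of == f]))
}

#' Augmentation configuration
#'
#' Randomized affine augmentation: shifts up to ±`shift_range` of the image
#' size in both axes, rotations up to ±`rotation_range` degrees, and scaling
#' within ±`zoom_range`, applied with bilinear interpolation and zero fill.
#'
#' @param shift_range Fraction of the image size (default 0.10).
#' @param rotation_range Degrees (default 20).
#' @param zoom_range Fractional scale range (default 0.20).
#' @param multiplier Augmented images generated per training image (default
#'   5, so a 1066-image training fold yields 5330 augmented images).
#' @param seed RNG seed.
#' @return An `augmentation_config` object.
#' @export
augmentation_config <- function(shift_range = 0.1, rotation_range = 20,
                                zoom_range = 0.2, multiplier = 5L,
                                seed = 1L) {
  if (shift_range < 0 || rotation_range < 0 || zoom_range < 0)
    stop("augmentation ranges must be non-negative")
  if (multiplier < 0) stop("multiplier must be >= 0")
  structure(list(shift_range = shift_range, rotation_range = rotation_range,
                 zoom_range = zoom_range, multiplier = as.integer(multiplier),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

# Inverse affine coefficient vector for cg_warp_affine: rotation by theta
# (degrees) and isotropic scale about the image center, then translation by
# (tr, tc) pixels.
affine_coeffs <- function(H, W, theta, scale, tr, tc) {
  th <- theta * pi / 180
  cs <- cos(th) / scale; sn <- sin(th) / scale
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  c(cs, sn, cr - (cs * (cr + tr) + sn * (cc + tc)),
    -sn, cs, cc - (-sn * (cr + tr) + cs * (cc + tc)))
}

#' Generate randomized augmented copies of a training set
#'
#' Draws `multiplier * n` source images uniformly (with replacement) and
#' applies an independent random shift / rotation / zoom to each; labels are
#' inherited from the source image. With all ranges zero the transform is the
#' identity and augmented images equal their sources exactly.
#'
#' @param images List of image matrices.
#' @param labels Labels parallel to `images`.
#' @param cfg An [augmentation_config()].
#' @return `list(images, labels, source)` of length `multiplier * n` each.
#' @export
augment_training_set <- function(images, labels, cfg) {
  stopifnot(inherits(cfg, "augmentation_config"))
  n <- length(images)
  if (n == 0L) stop("empty training set")
  total <- cfg$multiplier * n
  out <- vector("list", total)
  src <- integer(total)
  with_seed(cfg$seed, {
    for (i in seq_len(total)) {
      s <- sample.int(n, 1L)
      img <- images[[s]]
      m <- affine_coeffs(nrow(img), ncol(img),
                         theta = runif(1, -cfg$rotation_range, cfg$rotation_range),
                         scale = 1 + runif(1, -cfg$zoom_range, cfg$zoom_range),
                         tr = runif(1, -cfg$shift_range, cfg$shift_range) * nrow(img),
                         tc = runif(1, -cfg$shift_range, cfg$shift_range) * ncol(img))
      out[[i]] <- cg_warp_affine(img, m)
      src[i] <- s
    }
  })
  list(images = out, labels = labels[src], source = src)
}

#' Inverse-frequency class weights
#'
#' `w_c = n / (n_classes * n_c)`: minority classes (Perugini grades 2 and 3
#' in a realistic cohort) receive proportionally larger misclassification
#' penalties, and the weights satisfy `sum_c w_c * n_c = n`.
#'
#' @param labels Integer labels.
#' @param classes Declared classes (default the sorted observed labels).
#'   Every declared class must be present.
#' @return Named numeric vector of weights, one per class.
#' @export
compute_class_weights <- function(labels, classes = sort(unique(labels))) {
  counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  if (any(counts == 0))
    stop("empty class: ", paste(classes[counts == 0], collapse = ", "))
  w <- length(labels) / (length(classes) * counts)
  names(w) <- classes
  w
}

#' Relabel grades for a classification task
#'
#' `four_class` is the identity; `pos_vs_neg` maps grade >= 2 to the positive
#' class (the clinically positive-for-ATTR reading); `grade3_vs_rest` singles
#' out high-grade uptake.
#'
#' @param labels Integer Perugini grades in 0..3.
#' @param task One of `"four_class"`, `"pos_vs_neg"`, `"grade3_vs_rest"`.
#' @return Integer labels (0..3 or 0/1).
#' @export
relabel_for_task <- function(labels,
                             task = c("four_class", "pos_vs_neg",
                                      "grade3_vs_rest")) {
  task <- match.arg(task)
  if (!all(labels %in% 0:3)) stop("labels must be Perugini grades 0..3")
  switch(task,
    four_class = as.integer(labels),
    pos_vs_neg = as.integer(labels >= 2L),
    grade3_vs_rest = as.integer(labels == 3L))
}

task_n_classes <- function(task) if (task == "four_class") 4L else 2L

#' Training configuration
#'
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 128).
#' @param initial_lr,min_lr Adam learning-rate schedule bounds (defaults
#'   1e-4 and 1e-7).
#' @param lr_patience Epochs without validation-loss improvement before the
#'   learning rate is reduced (default 2).
#' @param lr_factor Multiplicative reduction factor (default 0.1).
#' @param validation_fraction Fraction of the training data held out for
#'   validation, stratified (default 0.10).
#' @param class_weighting `"inverse_frequency"` or `"none"`.
#' @param clip_norm Optional global L2 gradient-norm ceiling per batch;
#'   `NULL` (default) disables clipping. Useful for stabilizing short
#'   high-learning-rate runs.
#' @param restore_best Return the weights from the epoch with the lowest
#'   validation loss instead of the final epoch (checkpoint-style); protects
#'   short runs against late training collapse.
#' @param restarts Maximum number of fresh re-initializations when a run
#'   fails to converge (best validation loss still above 0.5 log K, i.e.
#'   closer to the uniform predictor than to a fitted model): multi-start
#'   optimization in the spirit of `kmeans(nstart =)`, keeping the best
#'   attempt by validation loss. 0 (default) disables restarts. Only the
#'   validation split is consulted.
#' @param seed RNG seed for shuffling, dropout and the validation split.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 50L, batch_size = 128L, initial_lr = 1e-4,
                         min_lr = 1e-7, lr_patience = 2L, lr_factor = 0.1,
                         validation_fraction = 0.1,
                         class_weighting = c("inverse_frequency", "none"),
                         clip_norm = NULL, restore_best = FALSE,
                         restarts = 0L, seed = 1L) {
  class_weighting <- match.arg(class_weighting)
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)")
  if (min_lr > initial_lr) stop("min_lr must not exceed initial_lr")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, min_lr = min_lr,
                 lr_patience = as.integer(lr_patience),
                 lr_factor = lr_factor,
                 validation_fraction = validation_fraction,
                 class_weighting = class_weighting,
                 clip_norm = clip_norm,
                 restore_best = isTRUE(restore_best),
                 restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Stratified validation split: per class, round(n_c * fraction) members
# (at least one overall).
validation_split <- function(labels, fraction) {
  val <- integer(0)
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    nv <- round(length(members) * fraction)
    if (nv > 0) val <- c(val, members[sample.int(length(members), nv)])
  }
  if (length(val) == 0L) val <- sample.int(length(labels), 1L)
  sort(val)
}

# Scale all gradients so their global L2 norm does not exceed `max_norm`.
clip_gradients <- function(grads, max_norm) {
  ss <- 0
  for (g in grads) for (p in g) if (!is.null(p)) ss <- ss + sum(p^2)
  nrm <- sqrt(ss)
  if (is.finite(nrm) && nrm > max_norm) {
    sc <- max_norm / nrm
    for (nm in names(grads)) for (p in names(grads[[nm]]))
      if (!is.null(grads[[nm]][[p]]))
        grads[[nm]][[p]] <- grads[[nm]][[p]] * sc
  }
  grads
}

adam_init <- function(net) {
  st <- list()
  for (nm in names(net$layers)) {
    lay <- net$layers[[nm]]
    for (p in intersect(c("W", "b", "gamma", "beta"), names(lay))) {
      st[[paste0(nm, ".", p)]] <- list(m = lay[[p]] * 0, v = lay[[p]] * 0)
    }
  }
  st
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  for (nm in names(grads)) {
    for (p in names(grads[[nm]])) {
      g <- grads[[nm]][[p]]
      if (is.null(g)) next
      key <- paste0(nm, ".", p)
      s <- state[[key]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      net$layers[[nm]][[p]] <- net$layers[[nm]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[key]] <- s
    }
  }
  list(net = net, state = state)
}

#' Train a network
#'
#' Minimizes class-weighted sparse categorical cross-entropy with Adam. A
#' stratified `validation_fraction` of the training data guides a
#' reduce-on-plateau schedule: when the validation loss has not improved for
#' `lr_patience` consecutive epochs the learning rate is multiplied by
#' `lr_factor`, floored at `min_lr`. The validation loss itself is
#' unweighted.
#'
#' @param net A freshly built `scinti_network`.
#' @param train_images List of normalized image matrices (or an
#'   (H, W, 1, N) array).
#' @param train_labels 0-based integer task labels.
#' @param weights Per-class weight vector (see [compute_class_weights()]);
#'   `NULL` for uniform weights.
#' @param cfg A [train_config()].
#' @return `list(net, history)` with per-epoch training loss, validation
#'   loss and learning rate.
#' @export
train_model <- function(net, train_images, train_labels, weights = NULL,
                        cfg = train_config()) {
  x <- as_image_batch(train_images, net$input_shape[1])
  y <- as.integer(train_labels)
  n <- dim(x)[4]
  if (n == 0L) stop("empty training set")
  stopifnot(length(y) == n)
  K <- net$n_classes
  wvec <- rep(1, K)
  if (!is.null(weights)) {
    stopifnot(length(weights) == K)
    wvec <- as.numeric(weights)
  }
  restarts <- cfg$restarts %||% 0L
  net0 <- net
  history <- NULL
  with_seed(cfg$seed, {
    val_ix <- validation_split(y, cfg$validation_fraction)
    tr_ix <- setdiff(seq_len(n), val_ix)
    xval <- x[, , , val_ix, drop = FALSE]; yval <- y[val_ix]
    overall_best <- Inf; overall_net <- NULL
    for (attempt in 0:restarts) {
      if (attempt > 0L) {
        # multi-start: the previous attempt stalled near the uniform
        # predictor; draw a fresh initialization and try again
        net <- nn_init(net0, (cfg$seed + 7919L * attempt) %% .Machine$integer.max)
      }
      attempt_hist <- data.frame(epoch = integer(0), loss = numeric(0),
                                 val_loss = numeric(0), lr = numeric(0))
      lr <- cfg$initial_lr
      best_val <- Inf; wait <- 0L
      best_net <- NULL
      state <- adam_init(net)
      t <- 0L
      for (epoch in seq_len(cfg$epochs)) {
        ord <- tr_ix[sample.int(length(tr_ix))]
        losses <- c()
        for (start in seq(1L, length(ord), by = cfg$batch_size)) {
          ix <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
          fw <- nn_forward(net, x[, , , ix, drop = FALSE], training = TRUE)
          lg <- nn_loss_grad(fw$out, y[ix], wvec)
          pg <- nn_backward(net, fw, lg$dz)
          if (!is.null(cfg$clip_norm)) pg <- clip_gradients(pg, cfg$clip_norm)
          t <- t + 1L
          up <- adam_step(net, pg, state, lr, t)
          net <- up$net; state <- up$state
          losses <- c(losses, lg$loss)
        }
        pv <- nn_predict_probs(net, xval)
        val_loss <- mean(-log(pmax(pv[cbind(seq_along(yval), yval + 1L)], 1e-12)))
        attempt_hist <- rbind(attempt_hist,
                              data.frame(epoch = epoch, loss = mean(losses),
                                         val_loss = val_loss, lr = lr))
        if (val_loss < best_val) {
          best_val <- val_loss; wait <- 0L
          if (cfg$restore_best) best_net <- net
        } else {
          wait <- wait + 1L
          if (wait >= cfg$lr_patience) {
            lr <- max(lr * cfg$lr_factor, cfg$min_lr)
            wait <- 0L
          }
        }
      }
      if (cfg$restore_best && !is.null(best_net)) net <- best_net
      attempt_hist$attempt <- attempt
      history <- rbind(history, attempt_hist)
      if (best_val < overall_best) {
        overall_best <- best_val; overall_net <- net
      }
      # done once an attempt clearly escapes the uniform-predictor plateau
      # (converged attempts sit far below log K; stalled ones just under it)
      if (overall_best < 0.5 * log(K) || attempt == restarts) break
    }
    if (restarts > 0L && !is.null(overall_net)) net <- overall_net
  })
  list(net = net, history = history)
}
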