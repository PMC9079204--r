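#' Declarative model specification
#'
#' Describes a network before it is built: the architecture family, the number
#' of output classes (4 for Perugini grading, 2 for the binary detection
#' tasks), the square input size, the convolutional filter plan and the head
#' configuration. The default filter plan (stem 16; blocks 16/32/64/128) is
#' chosen so that the two custom models total about one million trainable
#' parameters.
#'
#' @param family One of `"linear"`, `"residual"`, `"vgg16"`, `"resnet50"`,
#'   `"inceptionv3"`, `"mobilenet"`. `"linear"` is the plain stacked-conv
#'   model; `"residual"` adds parameter-free skip connections; the remaining
#'   four are canonical comparison backbones with a replaced classification
#'   head.
#' @param n_classes Number of softmax outputs, 2 or 4.
#' @param input_size Side length of the square single-channel input in pixels
#'   (default 128, the size produced by the preprocessing crop).
#' @param filter_plan Integer vector of length 4: filters in each of the four
#'   convolution blocks (custom families only).
#' @param stem_filters Filters in the stem convolution preceding the blocks.
#' @param dropout Dropout fraction before the dense head.
#' @param pool_stride Stride of the 2x2 average-pooling layers in the custom
#'   families. The default 2 halves the spatial grid after every block
#'   (128 -> 64 -> 32 -> 16 -> 8); stride 1 is available but inflates the
#'   flattened feature count enormously.
#' @param init_seed Seed for the uniform fan-in weight initialization.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("linear", "residual", "vgg16", "resnet50",
                                  "inceptionv3", "mobilenet"),
                       n_classes = 4L, input_size = 128L,
                       filter_plan = c(16L, 32L, 64L, 128L),
                       stem_filters = 16L, dropout = 0.2, pool_stride = 2L,
                       init_seed = 42L) {
  family <- match.arg(family)
  n_classes <- as.integer(n_classes)
  if (!n_classes %in% c(2L, 4L))
    stop("n_classes must be 2 or 4")
  if (length(filter_plan) != 4L || any(filter_plan <= 0))
    stop("filter_plan must be four positive filter counts")
  if (stem_filters <= 0) stop("stem_filters must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(family = family, n_classes = n_classes,
                 input_size = as.integer(input_size),
                 filter_plan = as.integer(filter_plan),
                 stem_filters = as.integer(stem_filters),
                 dropout = dropout, pool_stride = as.integer(pool_stride),
                 init_seed = as.integer(init_seed)),
            class = "model_spec")
}

#' Build a network from a specification
#'
#' Dispatches to [build_linear()], [build_residual()] or [build_pretrained()]
#' according to `spec$family`.
#'
#' @param spec A [model_spec()].
#' @param ... Passed on to the family-specific builder.
#' @return A `scinti_network` handle.
#' @export
build_model <- function(spec, ...) {
  switch(spec$family,
    linear = build_linear(spec),
    residual = build_residual(spec),
    build_pretrained(spec, ...))
}

custom_backbone <- function(spec, residual) {
  net <- nn_new(c(spec$input_size, spec$input_size, 1L), spec$family,
                spec$n_classes)
  net <- nn_conv(net, "stem", spec$stem_filters, k = 3L, act = "relu")
  entry <- "stem"
  for (blk in 1:4) {
    f <- spec$filter_plan[blk]
    for (j in 1:6) {
      nm <- sprintf("block%d_conv%d", blk, j)
      if (!residual) {
        net <- nn_conv(net, nm, f, k = 3L, act = "relu")
      } else if (j %% 2L == 1L) {
        net <- nn_conv(net, nm, f, k = 3L, act = "relu")
      } else {
        # even conv: linear pre-activation; the skip lands here. The skip
        # source is the output two conv layers back (the block input for the
        # first skip), zero-padded in channels when the block widens.
        net <- nn_conv(net, nm, f, k = 3L, act = "none")
        src <- if (j == 2L) entry else sprintf("block%d_add%d", blk, j - 2L)
        net <- nn_add(net, sprintf("block%d_add%d", blk, j),
                      inputs = c(nm, src), act = "relu")
      }
    }
    net <- nn_pool(net, sprintf("pool%d", blk), mode = "avg", k = 2L,
                   stride = spec$pool_stride)
    entry <- sprintf("pool%d", blk)
  }
  net <- nn_flatten(net, "flatten")
  net <- nn_dropout(net, "dropout", rate = spec$dropout)
  net <- nn_dense(net, "head", spec$n_classes, act = "softmax")
  net$spec <- spec
  nn_init(net, spec$init_seed)
}

#' Build the plain stacked-convolution ("Linear") model
#'
#' One stem convolution followed by four convolution blocks of six 3x3
#' convolutions (stride 1, ReLU, same padding) and a 2x2 average pooling each,
#' then flatten, dropout and a softmax head.
#'
#' @param spec A [model_spec()] with `family = "linear"`.
#' @return A `scinti_network`.
#' @export
build_linear <- function(spec) {
  stopifnot(spec$family == "linear")
  custom_backbone(spec, residual = FALSE)
}

#' Build the skip-connection ("Residual") model
#'
#' Identical topology and parameter count to [build_linear()], with three
#' identity skip connections per block: the output two convolution layers
#' back is added to the pre-activation of every second convolution, and ReLU
#' is applied to the sum. Skips are parameter-free; where the block widens,
#' the skip tensor is zero-padded in channels.
#'
#' @param spec A [model_spec()] with `family = "residual"`.
#' @return A `scinti_network`.
#' @export
build_residual <- function(spec) {
  stopifnot(spec$family == "residual")
  custom_backbone(spec, residual = TRUE)
}

#' Count trainable parameters
#'
#' Sums every trainable scalar: convolution and dense weights and biases,
#' depthwise-convolution weights, and batch-norm scale/shift. Pooling,
#' flatten, dropout, concatenation and skip additions contribute nothing.
#'
#' @param net A `scinti_network`.
#' @return Integer-valued count.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "scinti_network"))
  total <- 0
  for (lay in net$layers) {
    total <- total + switch(lay$type,
      conv = length(lay$W) + if (lay$use_bias) length(lay$b) else 0L,
      dwconv = length(lay$W) + length(lay$b),
      dense = length(lay$W) + length(lay$b),
      bn = length(lay$gamma) + length(lay$beta),
      0L)
  }
  total
}

#' Layer registry of a network
#'
#' @param net A `scinti_network`.
#' @return A data frame with one row per layer: semantic `name`, `type`, and
#'   the output shape as a string.
#' @export
layer_registry <- function(net) {
  data.frame(
    name = names(net$layers),
    type = vapply(net$layers, function(l) l$type, character(1)),
    output = vapply(net$layers, function(l)
      paste(l$out_shape, collapse = "x"), character(1)),
    row.names = NULL)
}

#' Class probabilities for a batch of images
#'
#' @param object A trained `scinti_network`.
#' @param images A single matrix, an (H, W, 1, N) array, or a list of
#'   matrices matching the network input size.
#' @param ... Unused.
#' @return An N x n_classes matrix of softmax probabilities (rows sum to 1).
#' @export
predict.scinti_network <- function(object, images, ...) {
  nn_predict_probs(object, as_image_batch(images, object$input_shape[1]))
}

#' @export
print.scinti_network <- function(x, ...) {
  cat(sprintf("<scinti_network> family=%s, input=%dx%dx%d, classes=%d\n",
              x$family, x$input_shape[1], x$input_shape[2], x$input_shape[3],
              x$n_classes))
  cat(sprintf("  layers: %d (%d conv), trainable parameters: %s\n",
              length(x$layers),
              sum(vapply(x$layers, function(l) l$type == "conv", logical(1))),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# Stack heterogeneous image input into an (H, W, 1, N) array.
as_image_batch <- function(images, size) {
  if (is.list(images)) {
    arr <- array(0, c(size, size, 1L, length(images)))
    for (i in seq_along(images)) arr[, , 1L, i] <- images[[i]]
    arr
  } else if (is.matrix(images)) {
    array(images, c(dim(images), 1L, 1L))
  } else images
}

# ---- canonical comparison backbones ----------------------------------------

#' Build a canonical comparison backbone with a replaced head
#'
#' Constructs VGG16, ResNet50, InceptionV3 or MobileNet (v1) to the published
#' architecture, drops the original classifier and attaches the same
#' flatten / dropout / softmax head used by the custom models. The
#' single-channel scintigraphy input is replicated to three channels by a
#' parameter-free layer. Weights are randomly initialized (uniform fan-in,
#' seeded); ImageNet checkpoints, when available on disk, can be applied to a
#' built network via [load_network()] weight files.
#'
#' @param spec A [model_spec()] whose family names one of the four backbones.
#' @param head `"replace"` (default) for the scintigraphy head of width
#'   `spec$n_classes`; `"original"` rebuilds the published ImageNet
#'   classifier (1000 classes, canonical input size) — useful for
#'   architecture-fidelity checks such as VGG16's 138,357,544 trainable
#'   parameters.
#' @param init Draw initial weights (default). `FALSE` leaves parameters at
#'   zero, which halves the peak memory of building the very large ImageNet
#'   heads when only structure or parameter counts are needed.
#' @return A `scinti_network`.
#' @export
build_pretrained <- function(spec, head = c("replace", "original"),
                             init = TRUE) {
  head <- match.arg(head)
  builder <- switch(spec$family,
    vgg16 = build_vgg16, resnet50 = build_resnet50,
    inceptionv3 = build_inceptionv3, mobilenet = build_mobilenet,
    stop("unknown pretrained family: ", spec$family))
  net <- builder(spec, head)
  if (init) net <- nn_init(net, spec$init_seed)
  net
}

attach_head <- function(net, spec, head) {
  if (head == "replace") {
    net <- nn_flatten(net, "flatten")
    net <- nn_dropout(net, "dropout", rate = spec$dropout)
    net <- nn_dense(net, "head", spec$n_classes, act = "softmax")
  } else {
    s <- nn_shape_of(net, nn_last(net))
    net <- nn_pool(net, "global_pool", mode = "avg", k = s[1], stride = s[1])
    net <- nn_flatten(net, "flatten")
    net <- nn_dense(net, "head", 1000L, act = "softmax")
    net$n_classes <- 1000L
  }
  net
}

pretrained_input <- function(spec, head, canonical) {
  size <- if (head == "original") canonical else spec$input_size
  nn_rep3(nn_new(c(size, size, 1L), spec$family,
                 spec$n_classes), "rep3")
}

build_vgg16 <- function(spec, head) {
  net <- pretrained_input(spec, head, 224L)
  plan <- list(c(64, 64), c(128, 128), c(256, 256, 256),
               c(512, 512, 512), c(512, 512, 512))
  for (b in seq_along(plan)) {
    for (j in seq_along(plan[[b]]))
      net <- nn_conv(net, sprintf("b%d_conv%d", b, j), plan[[b]][j],
                     k = 3L, act = "relu")
    net <- nn_pool(net, sprintf("b%d_pool", b), mode = "max", k = 2L,
                   stride = 2L)
  }
  if (head == "original") {
    net <- nn_flatten(net, "flatten")
    net <- nn_dense(net, "fc1", 4096L, act = "relu")
    net <- nn_dropout(net, "drop1", rate = 0.5)
    net <- nn_dense(net, "fc2", 4096L, act = "relu")
    net <- nn_dropout(net, "drop2", rate = 0.5)
    net <- nn_dense(net, "head", 1000L, act = "softmax")
    net$n_classes <- 1000L
  } else {
    net <- attach_head(net, spec, "replace")
  }
  net$spec <- spec
  net
}

conv_bn <- function(net, name, filters, k = 3L, stride = 1L, pad = "same",
                    act = "relu", input = NULL) {
  net <- nn_conv(net, paste0(name, "_conv"), filters, k = k, stride = stride,
                 pad = pad, act = "none", use_bias = FALSE, input = input)
  nn_bn(net, paste0(name, "_bn"), act = act)
}

build_resnet50 <- function(spec, head) {
  net <- pretrained_input(spec, head, 224L)
  net <- conv_bn(net, "stem", 64L, k = 7L, stride = 2L)
  net <- nn_pool(net, "stem_pool", mode = "max", k = 3L, stride = 2L,
                 pad = "same")
  widths <- c(64L, 128L, 256L, 512L); reps <- c(3L, 4L, 6L, 3L)
  for (st in 1:4) {
    for (u in seq_len(reps[st])) {
      stride <- if (st > 1L && u == 1L) 2L else 1L
      inp <- nn_last(net)
      base <- sprintf("s%d_u%d", st, u)
      net <- conv_bn(net, paste0(base, "_a"), widths[st], k = 1L, input = inp)
      net <- conv_bn(net, paste0(base, "_b"), widths[st], k = 3L,
                     stride = stride)
      net <- conv_bn(net, paste0(base, "_c"), widths[st] * 4L, k = 1L,
                     act = "none")
      main <- nn_last(net)
      if (u == 1L) {
        net <- conv_bn(net, paste0(base, "_proj"), widths[st] * 4L, k = 1L,
                       stride = stride, act = "none", input = inp)
        short <- nn_last(net)
      } else short <- inp
      net <- nn_add(net, paste0(base, "_add"), inputs = c(main, short),
                    act = "relu")
    }
  }
  net <- attach_head(net, spec, head)
  net$spec <- spec
  net
}

build_mobilenet <- function(spec, head) {
  net <- pretrained_input(spec, head, 224L)
  net <- conv_bn(net, "stem", 32L, k = 3L, stride = 2L, act = "relu6")
  plan <- list(c(64L, 1L), c(128L, 2L), c(128L, 1L), c(256L, 2L),
               c(256L, 1L), c(512L, 2L), c(512L, 1L), c(512L, 1L),
               c(512L, 1L), c(512L, 1L), c(512L, 1L), c(1024L, 2L),
               c(1024L, 1L))
  for (i in seq_along(plan)) {
    base <- sprintf("dw%d", i)
    net <- nn_dwconv(net, paste0(base, "_dw"), k = 3L, stride = plan[[i]][2],
                     act = "none")
    net <- nn_bn(net, paste0(base, "_dwbn"), act = "relu6")
    net <- conv_bn(net, paste0(base, "_pw"), plan[[i]][1], k = 1L,
                   act = "relu6")
  }
  net <- attach_head(net, spec, head)
  net$spec <- spec
  net
}

build_inceptionv3 <- function(spec, head) {
  net <- pretrained_input(spec, head, 299L)
  net <- conv_bn(net, "stem1", 32L, k = 3L, stride = 2L, pad = "valid")
  net <- conv_bn(net, "stem2", 32L, k = 3L, pad = "valid")
  net <- conv_bn(net, "stem3", 64L, k = 3L)
  net <- nn_pool(net, "stem_pool1", mode = "max", k = 3L, stride = 2L)
  net <- conv_bn(net, "stem4", 80L, k = 1L, pad = "valid")
  net <- conv_bn(net, "stem5", 192L, k = 3L, pad = "valid")
  net <- nn_pool(net, "stem_pool2", mode = "max", k = 3L, stride = 2L)
  inception_a <- function(net, base, pool_features) {
    inp <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b1"), 64L, k = 1L, input = inp)
    b1 <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b2a"), 48L, k = 1L, input = inp)
    net <- conv_bn(net, paste0(base, "_b2b"), 64L, k = 5L)
    b2 <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b3a"), 64L, k = 1L, input = inp)
    net <- conv_bn(net, paste0(base, "_b3b"), 96L, k = 3L)
    net <- conv_bn(net, paste0(base, "_b3c"), 96L, k = 3L)
    b3 <- nn_last(net)
    net <- nn_pool(net, paste0(base, "_pool"), mode = "avg", k = 3L,
                   stride = 1L, pad = "same", input = inp)
    net <- conv_bn(net, paste0(base, "_b4"), pool_features, k = 1L)
    b4 <- nn_last(net)
    nn_concat(net, paste0(base, "_out"), c(b1, b2, b3, b4))
  }
  inception_b <- function(net, base) {
    inp <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b1"), 384L, k = 3L, stride = 2L,
                   pad = "valid", input = inp)
    b1 <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b2a"), 64L, k = 1L, input = inp)
    net <- conv_bn(net, paste0(base, "_b2b"), 96L, k = 3L)
    net <- conv_bn(net, paste0(base, "_b2c"), 96L, k = 3L, stride = 2L,
                   pad = "valid")
    b2 <- nn_last(net)
    net <- nn_pool(net, paste0(base, "_pool"), mode = "max", k = 3L,
                   stride = 2L, input = inp)
    nn_concat(net, paste0(base, "_out"), c(b1, b2, nn_last(net)))
  }
  inception_c <- function(net, base, c7) {
    inp <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b1"), 192L, k = 1L, input = inp)
    b1 <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b2a"), c7, k = 1L, input = inp)
    net <- conv_bn(net, paste0(base, "_b2b"), c7, k = c(1L, 7L))
    net <- conv_bn(net, paste0(base, "_b2c"), 192L, k = c(7L, 1L))
    b2 <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b3a"), c7, k = 1L, input = inp)
    net <- conv_bn(net, paste0(base, "_b3b"), c7, k = c(7L, 1L))
    net <- conv_bn(net, paste0(base, "_b3c"), c7, k = c(1L, 7L))
    net <- conv_bn(net, paste0(base, "_b3d"), c7, k = c(7L, 1L))
    net <- conv_bn(net, paste0(base, "_b3e"), 192L, k = c(1L, 7L))
    b3 <- nn_last(net)
    net <- nn_pool(net, paste0(base, "_pool"), mode = "avg", k = 3L,
                   stride = 1L, pad = "same", input = inp)
    net <- conv_bn(net, paste0(base, "_b4"), 192L, k = 1L)
    nn_concat(net, paste0(base, "_out"), c(b1, b2, b3, nn_last(net)))
  }
  inception_d <- function(net, base) {
    inp <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b1a"), 192L, k = 1L, input = inp)
    net <- conv_bn(net, paste0(base, "_b1b"), 320L, k = 3L, stride = 2L,
                   pad = "valid")
    b1 <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b2a"), 192L, k = 1L, input = inp)
    net <- conv_bn(net, paste0(base, "_b2b"), 192L, k = c(1L, 7L))
    net <- conv_bn(net, paste0(base, "_b2c"), 192L, k = c(7L, 1L))
    net <- conv_bn(net, paste0(base, "_b2d"), 192L, k = 3L, stride = 2L,
                   pad = "valid")
    b2 <- nn_last(net)
    net <- nn_pool(net, paste0(base, "_pool"), mode = "max", k = 3L,
                   stride = 2L, input = inp)
    nn_concat(net, paste0(base, "_out"), c(b1, b2, nn_last(net)))
  }
  inception_e <- function(net, base) {
    inp <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b1"), 320L, k = 1L, input = inp)
    b1 <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b2a"), 384L, k = 1L, input = inp)
    b2stem <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b2b"), 384L, k = c(1L, 3L),
                   input = b2stem)
    b2a <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b2c"), 384L, k = c(3L, 1L),
                   input = b2stem)
    net <- nn_concat(net, paste0(base, "_b2out"), c(b2a, nn_last(net)))
    b2 <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b3a"), 448L, k = 1L, input = inp)
    net <- conv_bn(net, paste0(base, "_b3b"), 384L, k = 3L)
    b3stem <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b3c"), 384L, k = c(1L, 3L),
                   input = b3stem)
    b3a <- nn_last(net)
    net <- conv_bn(net, paste0(base, "_b3d"), 384L, k = c(3L, 1L),
                   input = b3stem)
    net <- nn_concat(net, paste0(base, "_b3out"), c(b3a, nn_last(net)))
    b3 <- nn_last(net)
    net <- nn_pool(net, paste0(base, "_pool"), mode = "avg", k = 3L,
                   stride = 1L, pad = "same", input = inp)
    net <- conv_bn(net, paste0(base, "_b4"), 192L, k = 1L)
    nn_concat(net, paste0(base, "_out"), c(b1, b2, b3, nn_last(net)))
  }
  net <- inception_a(net, "mixed0", 32L)
  net <- inception_a(net, "mixed1", 64L)
  net <- inception_a(net, "mixed2", 64L)
  net <- inception_b(net, "mixed3")
  net <- inception_c(net, "mixed4", 128L)
  net <- inception_c(net, "mixed5", 160L)
  net <- inception_c(net, "mixed6", 160L)
  net <- inception_c(net, "mixed7", 192L)
  net <- inception_d(net, "mixed8")
  net <- inception_e(net, "mixed9")
  net <- inception_e(net, "mixed10")
  net <- attach_head(net, spec, head)
  net$spec <- spec
  net
}

#' Save / load a network
#'
#' Weights and the generating [model_spec()] are serialized together, so a
#' checkpoint is self-describing; the spec is additionally written as a JSON
#' sidecar for inspection without R.
#'
#' @param net A `scinti_network`.
#' @param path File path for the checkpoint (`.rds`).
#' @return `save_network` returns `path` invisibly; `load_network` returns
#'   the restored network.
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  if (!is.null(net$spec))
    jsonlite::write_json(unclass(net$spec), paste0(path, ".json"),
                         auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "scinti_network"))
  net
}
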