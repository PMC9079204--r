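# Internal CNN engine.
#
# A network is a directed acyclic graph of named layers stored in topological
# order. Activations are R arrays with dim (H, W, C, N); dense-stage
# activations are matrices (features x N). Convolutions run through the
# RcppArmadillo im2col kernels in src/kernels.cpp; everything else is
# vectorized R. Gradients are validated against numerical differentiation in
# the test suite.

nn_new <- function(input_shape, family, n_classes) {
  structure(
    list(layers = list(), registry = character(0),
         input_shape = input_shape, family = family, n_classes = n_classes),
    class = "scinti_network")
}

# TF-style padding arithmetic. Returns c(out, pad_before) for one axis.
nn_pad1 <- function(size, k, stride, pad) {
  if (pad == "same") {
    out <- ceiling(size / stride)
    total <- max((out - 1L) * stride + k - size, 0L)
    c(out, total %/% 2L)
  } else {
    c(floor((size - k) / stride) + 1L, 0L)
  }
}

nn_shape_of <- function(net, name) {
  if (name == "input") net$input_shape else net$layers[[name]]$out_shape
}

nn_add_layer <- function(net, layer) {
  if (is.null(layer$input)) layer$input <- nn_last(net)
  stopifnot(is.null(net$layers[[layer$name]]))
  net$layers[[layer$name]] <- layer
  net
}

nn_last <- function(net) {
  if (length(net$layers) == 0L) "input" else names(net$layers)[length(net$layers)]
}

# ---- layer constructors (compute shapes and allocate parameters) -----------

nn_conv <- function(net, name, filters, k = 3L, stride = 1L, pad = "same",
                    act = "relu", use_bias = TRUE, input = NULL) {
  input <- input %||% nn_last(net)
  s <- nn_shape_of(net, input)
  k <- as.integer(rep(k, length.out = 2L))  # c(kh, kw)
  ph <- nn_pad1(s[1], k[1], stride, pad); pw <- nn_pad1(s[2], k[2], stride, pad)
  lay <- list(name = name, type = "conv", input = input, k = k,
              stride = as.integer(stride), act = act, use_bias = use_bias,
              pad_top = ph[2], pad_left = pw[2],
              in_shape = s, out_shape = c(ph[1], pw[1], filters),
              W = array(0, c(k[1], k[2], s[3], filters)), b = numeric(filters))
  nn_add_layer(net, lay)
}

nn_dwconv <- function(net, name, k = 3L, stride = 1L, pad = "same",
                      act = "relu", input = NULL) {
  input <- input %||% nn_last(net)
  s <- nn_shape_of(net, input)
  ph <- nn_pad1(s[1], k, stride, pad); pw <- nn_pad1(s[2], k, stride, pad)
  lay <- list(name = name, type = "dwconv", input = input, k = as.integer(k),
              stride = as.integer(stride), act = act,
              pad_top = ph[2], pad_left = pw[2],
              in_shape = s, out_shape = c(ph[1], pw[1], s[3]),
              W = array(0, c(k, k, s[3])), b = numeric(s[3]))
  nn_add_layer(net, lay)
}

nn_bn <- function(net, name, act = "relu", eps = 1e-3, input = NULL) {
  input <- input %||% nn_last(net)
  s <- nn_shape_of(net, input)
  C <- s[3]
  lay <- list(name = name, type = "bn", input = input, act = act, eps = eps,
              in_shape = s, out_shape = s,
              gamma = rep(1, C), beta = numeric(C),
              moving_mean = numeric(C), moving_var = rep(1, C))
  nn_add_layer(net, lay)
}

nn_pool <- function(net, name, mode = "avg", k = 2L, stride = 2L,
                    pad = "valid", input = NULL) {
  input <- input %||% nn_last(net)
  s <- nn_shape_of(net, input)
  ph <- nn_pad1(s[1], k, stride, pad); pw <- nn_pad1(s[2], k, stride, pad)
  lay <- list(name = name, type = "pool", input = input, mode = mode,
              k = as.integer(k), stride = as.integer(stride),
              pad_top = ph[2], pad_left = pw[2],
              in_shape = s, out_shape = c(ph[1], pw[1], s[3]))
  nn_add_layer(net, lay)
}

# Element-wise sum of two feature maps followed by an activation. When the
# second (skip) input has fewer channels it is zero-padded to match: a
# parameter-free projection, so residual and plain variants always count the
# same number of trainable parameters.
nn_add <- function(net, name, inputs, act = "relu") {
  s1 <- nn_shape_of(net, inputs[1]); s2 <- nn_shape_of(net, inputs[2])
  stopifnot(all(s1[1:2] == s2[1:2]), s2[3] <= s1[3])
  lay <- list(name = name, type = "add", input = inputs, act = act,
              skip_channels = s2[3], in_shape = s1, out_shape = s1)
  nn_add_layer(net, lay)
}

nn_concat <- function(net, name, inputs) {
  shapes <- lapply(inputs, nn_shape_of, net = net)
  hw <- shapes[[1]][1:2]
  stopifnot(all(vapply(shapes, function(s) all(s[1:2] == hw), logical(1))))
  chans <- vapply(shapes, function(s) s[3], numeric(1))
  lay <- list(name = name, type = "concat", input = inputs, channels = chans,
              out_shape = c(hw, sum(chans)))
  nn_add_layer(net, lay)
}

nn_rep3 <- function(net, name = "rep3", input = NULL) {
  input <- input %||% nn_last(net)
  s <- nn_shape_of(net, input)
  stopifnot(s[3] == 1L)
  lay <- list(name = name, type = "rep3", input = input,
              in_shape = s, out_shape = c(s[1:2], 3L))
  nn_add_layer(net, lay)
}

nn_flatten <- function(net, name = "flatten", input = NULL) {
  input <- input %||% nn_last(net)
  s <- nn_shape_of(net, input)
  lay <- list(name = name, type = "flatten", input = input,
              in_shape = s, out_shape = prod(s))
  nn_add_layer(net, lay)
}

nn_dropout <- function(net, name = "dropout", rate = 0.2, input = NULL) {
  input <- input %||% nn_last(net)
  s <- nn_shape_of(net, input)
  lay <- list(name = name, type = "dropout", input = input, rate = rate,
              in_shape = s, out_shape = s)
  nn_add_layer(net, lay)
}

nn_dense <- function(net, name, units, act = "none", input = NULL) {
  input <- input %||% nn_last(net)
  f <- nn_shape_of(net, input)
  stopifnot(length(f) == 1L)
  lay <- list(name = name, type = "dense", input = input, act = act,
              in_shape = f, out_shape = as.integer(units),
              W = matrix(0, f, units), b = numeric(units))
  nn_add_layer(net, lay)
}

# ---- initialization --------------------------------------------------------

# Uniform fan-in initialization: W ~ U(-sqrt(6/fan_in), +sqrt(6/fan_in)),
# biases zero. Deterministic given `seed`.
nn_init <- function(net, seed = 1L) {
  with_seed(seed, {
    for (nm in names(net$layers)) {
      lay <- net$layers[[nm]]
      if (lay$type %in% c("conv", "dwconv", "dense")) {
        fan_in <- switch(lay$type,
          conv = prod(dim(lay$W)[1:3]),
          dwconv = lay$k^2,
          dense = lay$in_shape)
        lim <- sqrt(6 / fan_in)
        net$layers[[nm]]$W[] <- runif(length(lay$W), -lim, lim)
      }
    }
  })
  net
}

# ---- forward ---------------------------------------------------------------

nn_act <- function(x, act) {
  switch(act,
    none = x,
    relu = cg_relu(x),
    relu6 = pmin(pmax(x, 0), 6),
    softmax = {
      z <- sweep(x, 2, apply(x, 2, max), "-")
      e <- exp(z)
      sweep(e, 2, colSums(e), "/")
    },
    stop("unknown activation: ", act))
}

nn_as_batch <- function(x, input_shape) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  stopifnot(all(dim(x)[1:3] == input_shape))
  x
}

# Returns list(out, cache, aux). `cache` maps layer name -> post-activation
# output; `aux` holds dropout masks and batch-norm batch statistics.
nn_forward <- function(net, x, training = FALSE, upto = NULL) {
  x <- nn_as_batch(x, net$input_shape)
  N <- dim(x)[4]
  cache <- list(input = x)
  aux <- list()
  for (lay in net$layers) {
    xin <- cache[[if (length(lay$input) > 1L) lay$input[1] else lay$input]]
    out <- switch(lay$type,
      conv = {
        y <- cg_conv_fwd(xin, dim(xin),
                         lay$W, dim(lay$W), lay$b,
                         lay$stride, lay$pad_top, lay$pad_left,
                         lay$out_shape[1], lay$out_shape[2])
        dim(y) <- c(lay$out_shape, N)
        nn_act(y, lay$act)
      },
      dwconv = {
        y <- cg_dwconv_fwd(xin, dim(xin),
                           lay$W, dim(lay$W), lay$b,
                           lay$stride, lay$pad_top, lay$pad_left,
                           lay$out_shape[1], lay$out_shape[2])
        dim(y) <- c(lay$out_shape, N)
        nn_act(y, lay$act)
      },
      bn = {
        C <- lay$out_shape[3]
        xm <- aperm(xin, c(1, 2, 4, 3)); dim(xm) <- c(length(xin) / C, C)
        if (training) {
          mu <- colMeans(xm)
          va <- colMeans(xm^2) - mu^2
          aux[[lay$name]] <- list(mean = mu, var = va)
        } else {
          mu <- lay$moving_mean; va <- lay$moving_var
        }
        y <- sweep(sweep(xm, 2, mu, "-"), 2, sqrt(va + lay$eps), "/")
        y <- sweep(sweep(y, 2, lay$gamma, "*"), 2, lay$beta, "+")
        dim(y) <- c(lay$out_shape[1], lay$out_shape[2], N, C)
        nn_act(aperm(y, c(1, 2, 4, 3)), lay$act)
      },
      pool = {
        y <- cg_pool_fwd(xin, dim(xin), lay$k, lay$stride,
                         lay$pad_top, lay$pad_left,
                         lay$out_shape[1], lay$out_shape[2],
                         if (lay$mode == "avg") 0L else 1L)
        dim(y) <- c(lay$out_shape, N)
        y
      },
      add = {
        a <- cache[[lay$input[1]]]; b <- cache[[lay$input[2]]]
        if (lay$skip_channels < lay$out_shape[3]) {
          bp <- array(0, dim(a))
          bp[, , seq_len(lay$skip_channels), ] <- b
          b <- bp
        }
        nn_act(a + b, lay$act)
      },
      concat = {
        y <- array(0, c(lay$out_shape, N))
        off <- 0L
        for (i in seq_along(lay$input)) {
          ci <- lay$channels[i]
          y[, , off + seq_len(ci), ] <- cache[[lay$input[i]]]
          off <- off + ci
        }
        y
      },
      rep3 = {
        y <- array(0, c(lay$out_shape, N))
        for (j in 1:3) y[, , j, ] <- xin
        y
      },
      flatten = { dim(xin) <- c(lay$out_shape, N); xin },
      dropout = {
        if (training && lay$rate > 0) {
          mask <- (runif(length(xin)) >= lay$rate) / (1 - lay$rate)
          dim(mask) <- dim(xin)
          aux[[lay$name]] <- mask
          xin * mask
        } else xin
      },
      dense = nn_act(crossprod(lay$W, xin) + lay$b, lay$act),
      stop("unknown layer type: ", lay$type))
    cache[[lay$name]] <- out
    if (!is.null(upto) && lay$name == upto) break
  }
  last <- if (is.null(upto)) nn_last(net) else upto
  list(out = cache[[last]], cache = cache, aux = aux)
}

# ---- backward --------------------------------------------------------------

nn_act_grad <- function(dout, out, act) {
  switch(act,
    none = dout,
    relu = cg_relu_bwd(dout, out),
    relu6 = dout * (out > 0 & out < 6),
    stop("no closed activation gradient for: ", act))
}

# Backpropagation from a gradient injected at the final dense layer's
# pre-activation (for a softmax head this is `probs - onehot`, scaled by the
# per-sample loss weights). Returns per-layer parameter gradients.
nn_backward <- function(net, fw, d_head_z) {
  layers <- net$layers
  consumers <- list()
  grads <- list()
  pgrads <- list()
  nms <- names(layers)
  head_nm <- nms[length(nms)]
  grads[[head_nm]] <- d_head_z        # pre-activation gradient at the head
  for (i in rev(seq_along(layers))) {
    lay <- layers[[i]]
    nm <- lay$name
    dout <- grads[[nm]]
    if (is.null(dout)) next
    dz <- if (nm == head_nm) dout
          else if (!is.null(lay$act)) nn_act_grad(dout, fw$cache[[nm]], lay$act)
          else dout
    push <- function(target, g) {
      grads[[target]] <<- if (is.null(grads[[target]])) g else grads[[target]] + g
    }
    xin_nm <- if (length(lay$input) > 1L) lay$input[1] else lay$input
    xin <- fw$cache[[xin_nm]]
    switch(lay$type,
      conv = {
        r <- cg_conv_bwd(xin, dim(xin), lay$W,
                         dim(lay$W), dz, lay$stride,
                         lay$pad_top, lay$pad_left,
                         lay$out_shape[1], lay$out_shape[2])
        dx <- r$dx; dim(dx) <- dim(xin)
        dW <- r$dw; dim(dW) <- dim(lay$W)
        pgrads[[nm]] <- list(W = dW, b = if (lay$use_bias) r$db else NULL)
        push(xin_nm, dx)
      },
      dwconv = {
        r <- cg_dwconv_bwd(xin, dim(xin), lay$W,
                           dim(lay$W), dz, lay$stride,
                           lay$pad_top, lay$pad_left,
                           lay$out_shape[1], lay$out_shape[2])
        dx <- r$dx; dim(dx) <- dim(xin)
        dW <- r$dw; dim(dW) <- dim(lay$W)
        pgrads[[nm]] <- list(W = dW, b = r$db)
        push(xin_nm, dx)
      },
      bn = {
        C <- lay$out_shape[3]
        st <- fw$aux[[nm]]
        if (is.null(st)) st <- list(mean = lay$moving_mean, var = lay$moving_var)
        to2d <- function(a) { a <- aperm(a, c(1, 2, 4, 3)); dim(a) <- c(length(a) / C, C); a }
        xm <- to2d(xin); dm <- to2d(dz)
        m <- nrow(xm)
        xhat <- sweep(sweep(xm, 2, st$mean, "-"), 2, sqrt(st$var + lay$eps), "/")
        dgamma <- colSums(dm * xhat)
        dbeta <- colSums(dm)
        dxhat <- sweep(dm, 2, lay$gamma, "*")
        inv <- 1 / sqrt(st$var + lay$eps)
        dx2 <- sweep(dxhat - matrix(colMeans(dxhat), m, C, byrow = TRUE) -
                       sweep(xhat, 2, colMeans(dxhat * xhat), "*"),
                     2, inv, "*")
        dim(dx2) <- c(lay$out_shape[1], lay$out_shape[2], dim(xin)[4], C)
        pgrads[[nm]] <- list(gamma = dgamma, beta = dbeta)
        push(xin_nm, aperm(dx2, c(1, 2, 4, 3)))
      },
      pool = {
        dx <- cg_pool_bwd(xin, dim(xin), dz,
                          lay$k, lay$stride, lay$pad_top, lay$pad_left,
                          lay$out_shape[1], lay$out_shape[2],
                          if (lay$mode == "avg") 0L else 1L)
        dim(dx) <- dim(xin)
        push(xin_nm, dx)
      },
      add = {
        push(lay$input[1], dz)
        if (lay$skip_channels < lay$out_shape[3]) {
          push(lay$input[2], dz[, , seq_len(lay$skip_channels), , drop = FALSE])
        } else push(lay$input[2], dz)
      },
      concat = {
        off <- 0L
        for (j in seq_along(lay$input)) {
          cj <- lay$channels[j]
          push(lay$input[j], dz[, , off + seq_len(cj), , drop = FALSE])
          off <- off + cj
        }
      },
      rep3 = {
        push(xin_nm, dz[, , 1, , drop = FALSE] + dz[, , 2, , drop = FALSE] +
                     dz[, , 3, , drop = FALSE])
      },
      flatten = { dim(dz) <- dim(xin); push(xin_nm, dz) },
      dropout = {
        mask <- fw$aux[[nm]]
        push(xin_nm, if (is.null(mask)) dz else dz * mask)
      },
      dense = {
        pgrads[[nm]] <- list(W = xin %*% t(dz), b = rowSums(dz))
        push(xin_nm, lay$W %*% dz)
      })
  }
  pgrads
}

# ---- loss ------------------------------------------------------------------

# Class-weighted sparse categorical cross-entropy on softmax outputs.
# labels are 0-based integers; weights is a per-class vector (length K).
nn_loss_grad <- function(probs, labels, weights) {
  N <- ncol(probs); K <- nrow(probs)
  idx <- cbind(labels + 1L, seq_len(N))
  w <- weights[labels + 1L]
  p <- pmax(probs[idx], 1e-12)
  loss <- mean(w * -log(p))
  onehot <- matrix(0, K, N)
  onehot[idx] <- 1
  dz <- sweep(probs - onehot, 2, w / N, "*")
  list(loss = loss, dz = dz)
}

nn_predict_probs <- function(net, x, batch_size = 64L) {
  x <- nn_as_batch(x, net$input_shape)
  N <- dim(x)[4]
  out <- matrix(NA_real_, N, net$n_classes)
  for (start in seq(1L, N, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, N)
    fw <- nn_forward(net, x[, , , ix, drop = FALSE], training = FALSE)
    out[ix, ] <- t(fw$out)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate an expression under a temporary, restored RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
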