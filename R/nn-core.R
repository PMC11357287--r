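# Minimal neural-network core used by the embedding models.
#
# Layers are plain lists with `init`, `fwd` and `bwd` closures operating on
# batch-rows matrices. Two layer types cover every architecture here:
#
#   - dense:  out = act(X W + b)
#   - sconv:  a convolution expressed as a structured sparse linear map;
#     the (out, in, tap) index triplets encode the weight sharing, so the
#     same machinery runs the forward pass, the input gradient and the
#     kernel gradient, and the transposed map gives the mirrored
#     deconvolution layer for free.
#
# Gradients are averaged over the batch. Optimization is Adam with
# bias-corrected moments. All randomness flows through local_rng streams,
# so training is bit-reproducible for a fixed seed in serial execution.

act_fun <- function(name) {
  switch(name,
    linear = list(f = function(x) x, df = function(x, y) 1),
    relu = list(f = function(x) pmax(x, 0), df = function(x, y) (x > 0) * 1),
    sigmoid = list(
      f = function(x) 1 / (1 + exp(-x)),
      df = function(x, y) y * (1 - y)
    ),
    stop("unknown activation: ", name)
  )
}

layer_dense <- function(n_in, n_out, act = "linear") {
  a <- act_fun(act)
  list(
    type = "dense", n_in = n_in, n_out = n_out, act = act,
    init = function(rng) {
      sd <- sqrt(2 / (n_in + n_out))
      list(W = matrix(rng$rnorm(n_in * n_out, sd = sd), n_in, n_out),
           b = rep(0, n_out))
    },
    fwd = function(p, X) {
      pre <- X %*% p$W + matrix(p$b, nrow(X), n_out, byrow = TRUE)
      out <- a$f(pre)
      list(out = out, cache = list(X = X, pre = pre, out = out))
    },
    bwd = function(p, cache, gout) {
      gpre <- gout * a$df(cache$pre, cache$out)
      list(
        gin = gpre %*% t(p$W),
        gpar = list(W = crossprod(cache$X, gpre), b = colSums(gpre))
      )
    }
  )
}

# Index structure of a stride-2, pad-1 convolution flattened to a linear
# map between (h*w*ch) vectors, channel-fastest ordering.
conv_structure <- function(in_h, in_w, in_ch, out_ch, kernel = 3,
                           stride = 2, pad = 1) {
  out_h <- (in_h + 2 * pad - kernel) %/% stride + 1
  out_w <- (in_w + 2 * pad - kernel) %/% stride + 1
  grid <- expand.grid(
    kx = seq_len(kernel) - 1, ky = seq_len(kernel) - 1,
    ic = seq_len(in_ch) - 1, oc = seq_len(out_ch) - 1,
    ox = seq_len(out_w) - 1, oy = seq_len(out_h) - 1
  )
  iy <- grid$oy * stride - pad + grid$ky
  ix <- grid$ox * stride - pad + grid$kx
  ok <- iy >= 0 & iy < in_h & ix >= 0 & ix < in_w
  grid <- grid[ok, ]
  iy <- iy[ok]
  ix <- ix[ok]
  list(
    out_idx = with(grid, oy * out_w * out_ch + ox * out_ch + oc + 1),
    in_idx = iy * in_w * in_ch + ix * in_ch + grid$ic + 1,
    tap_idx = with(grid, ((oc * in_ch + ic) * kernel + ky) * kernel +
                     kx + 1),
    out_channel = grid$oc + 1,
    n_taps = out_ch * in_ch * kernel * kernel,
    n_in = in_h * in_w * in_ch, n_out = out_h * out_w * out_ch,
    in_dim = c(in_h, in_w, in_ch), out_dim = c(out_h, out_w, out_ch),
    in_ch = in_ch, out_ch = out_ch
  )
}

layer_sconv <- function(structure, act = "linear", transpose = FALSE) {
  a <- act_fun(act)
  s <- structure
  if (transpose) {
    # swap roles: output of the map is the convolution's input space
    out_idx <- s$in_idx
    in_idx <- s$out_idx
    n_in <- s$n_out
    n_out <- s$n_in
    ch_of_out <- rep(seq_len(s$in_ch),
                     length.out = 0) # filled below per index
    out_channel <- ((out_idx - 1) %% s$in_ch) + 1
    n_bias <- s$in_ch
  } else {
    out_idx <- s$out_idx
    in_idx <- s$in_idx
    n_in <- s$n_in
    n_out <- s$n_out
    out_channel <- s$out_channel
    n_bias <- s$out_ch
  }
  tap_idx <- s$tap_idx
  fanin <- length(tap_idx) / n_out
  bias_of_out_full <- integer(n_out)
  bias_of_out_full[out_idx] <- out_channel
  # outputs never touched keep channel from position parity
  if (any(bias_of_out_full == 0)) {
    bias_of_out_full[bias_of_out_full == 0] <-
      ((which(bias_of_out_full == 0) - 1) %% n_bias) + 1
  }
  list(
    type = "sconv", n_in = n_in, n_out = n_out, act = act,
    init = function(rng) {
      sd <- sqrt(2 / fanin)
      list(w = rng$rnorm(s$n_taps, sd = sd), b = rep(0, n_bias))
    },
    fwd = function(p, X) {
      C <- Matrix::sparseMatrix(i = out_idx, j = in_idx,
                                x = p$w[tap_idx],
                                dims = c(n_out, n_in))
      pre <- as.matrix(Matrix::tcrossprod(X, C)) +
        matrix(p$b[bias_of_out_full], nrow(X), n_out, byrow = TRUE)
      out <- a$f(pre)
      list(out = out, cache = list(X = X, pre = pre, out = out))
    },
    bwd = function(p, cache, gout) {
      gpre <- gout * a$df(cache$pre, cache$out)
      C <- Matrix::sparseMatrix(i = out_idx, j = in_idx,
                                x = p$w[tap_idx],
                                dims = c(n_out, n_in))
      gin <- as.matrix(gpre %*% C)
      # kernel gradient: sum over batch and over shared positions
      ent <- rowSums(t(gpre)[out_idx, , drop = FALSE] *
                       t(cache$X)[in_idx, , drop = FALSE])
      gw <- as.numeric(rowsum(ent, tap_idx)[as.character(seq_len(s$n_taps)), 1])
      gw[is.na(gw)] <- 0
      gb <- as.numeric(rowsum(colSums(gpre), bias_of_out_full))
      list(gin = gin, gpar = list(w = gw, b = gb))
    }
  )
}

stack_init <- function(layers, rng) lapply(layers, function(l) l$init(rng))

stack_fwd <- function(layers, params, X) {
  caches <- vector("list", length(layers))
  out <- X
  for (i in seq_along(layers)) {
    r <- layers[[i]]$fwd(params[[i]], out)
    out <- r$out
    caches[[i]] <- r$cache
  }
  list(out = out, caches = caches)
}

stack_bwd <- function(layers, params, caches, gout) {
  gpars <- vector("list", length(layers))
  g <- gout
  for (i in rev(seq_along(layers))) {
    r <- layers[[i]]$bwd(params[[i]], caches[[i]], g)
    g <- r$gin
    gpars[[i]] <- r$gpar
  }
  list(gin = g, gpars = gpars)
}

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list")
}

# params and grads share their nesting; state holds first/second moments
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p
      out_s <- s
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p
        out_s[[nm]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    m <- beta1 * s$m + (1 - beta1) * g
    v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = list(m = m, v = v))
  }
  walk(params, grads, state)
}

minibatches <- function(n, batch_size, rng) {
  ord <- rng$sample_int(n, n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}
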