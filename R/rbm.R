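#' Restricted Boltzmann machine energy
#'
#' Energy of a joint visible/hidden configuration,
#' `E(v, h) = -sum_i v_i a_i - sum_j h_j b_j - sum_ij v_i W_ij h_j` for
#' Bernoulli visible units. Gaussian visible units add the standard
#' quadratic self-energy `sum_i (v_i - a_i)^2 / 2` in place of the linear
#' visible-bias term.
#'
#' @param params an `rbm_params` object (see [rbm_train_cd()]) or any list
#'   with `W`, `a`, `b`, `visible_type`.
#' @param v visible vector.
#' @param h hidden vector.
#' @return A single real value.
#' @export
rbm_energy <- function(params, v, h) {
  stopifnot(length(v) == length(params$a), length(h) == length(params$b))
  interaction <- as.numeric(t(v) %*% params$W %*% h)
  if (identical(params$visible_type, "gaussian")) {
    sum((v - params$a)^2) / 2 - sum(params$b * h) - interaction
  } else {
    -sum(params$a * v) - sum(params$b * h) - interaction
  }
}

#' Train a restricted Boltzmann machine with CD-1
#'
#' Single-step contrastive divergence with minibatches. The first layer of
#' a deep belief network uses Gaussian visible units (the spectral features
#' are real-valued); deeper layers are Bernoulli-Bernoulli. Training is
#' deterministic given `seed`, and the reconstruction mean-squared error
#' after training is checked against its value at initialization.
#'
#' @param X numeric matrix, one row per training vector.
#' @param hidden number of hidden units (>= 1).
#' @param epochs training epochs (default 100).
#' @param seed integer seed.
#' @param learning_rate CD-1 step size (default 0.01).
#' @param batch_size minibatch size (default 64).
#' @param visible_type `"gaussian"` or `"bernoulli"`.
#' @param momentum velocity coefficient, ramped from 0.5 to its final
#'   value after five epochs (default 0.9).
#' @param weight_decay L2 penalty on the weights (default 2e-4).
#' @return An object of class `rbm_params`: list with `W`
#'   (visible x hidden), `a`, `b`, `visible_type`, and the training curve
#'   `recon_mse` (per epoch, epoch 0 first).
#' @export
rbm_train_cd <- function(X, hidden, epochs = 100, seed = 1,
                         learning_rate = 0.01, batch_size = 64,
                         visible_type = c("gaussian", "bernoulli"),
                         momentum = 0.9, weight_decay = 2e-4) {
  X <- as.matrix(X)
  visible_type <- match.arg(visible_type)
  if (hidden < 1) stop("hidden must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  n <- nrow(X)
  d <- ncol(X)
  rng <- local_rng(seed)
  W <- matrix(rng$rnorm(d * hidden, sd = 0.01), d, hidden)
  a <- rep(0, d)
  b <- rep(0, hidden)
  vW <- W * 0
  va <- a * 0
  vb <- b * 0
  sig <- function(x) 1 / (1 + exp(-x))

  recon_mse <- function() {
    hm <- sig(X %*% W + matrix(b, n, hidden, byrow = TRUE))
    vm <- hm %*% t(W) + matrix(a, n, d, byrow = TRUE)
    if (visible_type == "bernoulli") vm <- sig(vm)
    mean((X - vm)^2)
  }
  curve <- recon_mse()

  for (ep in seq_len(epochs)) {
    mom <- if (ep <= 5) 0.5 else momentum
    for (idx in minibatches(n, batch_size, rng)) {
      v0 <- X[idx, , drop = FALSE]
      B <- nrow(v0)
      h0p <- sig(v0 %*% W + matrix(b, B, hidden, byrow = TRUE))
      h0 <- (matrix(rng$runif(B * hidden), B, hidden) < h0p) * 1
      v1 <- h0 %*% t(W) + matrix(a, B, d, byrow = TRUE)
      if (visible_type == "bernoulli") v1 <- sig(v1)
      h1p <- sig(v1 %*% W + matrix(b, B, hidden, byrow = TRUE))
      vW <- mom * vW + learning_rate *
        ((crossprod(v0, h0p) - crossprod(v1, h1p)) / B - weight_decay * W)
      va <- mom * va + learning_rate * colMeans(v0 - v1)
      vb <- mom * vb + learning_rate * colMeans(h0p - h1p)
      W <- W + vW
      a <- a + va
      b <- b + vb
      if (!all(is.finite(W))) stop("non-finite RBM parameters at epoch ", ep)
    }
    curve <- c(curve, recon_mse())
  }
  structure(
    list(W = W, a = a, b = b, visible_type = visible_type,
         hidden = hidden, recon_mse = curve, seed = seed),
    class = "rbm_params"
  )
}

#' @export
print.rbm_params <- function(x, ...) {
  cat(sprintf(
    "<rbm_params> %d x %d (%s visible), recon MSE %.4g -> %.4g\n",
    nrow(x$W), ncol(x$W), x$visible_type,
    x$recon_mse[1], x$recon_mse[length(x$recon_mse)]
  ))
  invisible(x)
}

#' Train a deep belief network greedily
#'
#' Stacks RBMs trained layer by layer: each layer's mean hidden activations
#' become the next layer's training data. The first layer is
#' Gaussian-Bernoulli, the rest Bernoulli-Bernoulli.
#'
#' @param X numeric matrix, one row per training vector.
#' @param layer_sizes hidden-layer widths (default 512, 128, 32; the last
#'   is the latent dimension).
#' @param epochs epochs for the first layer; unless `epochs` is given as
#'   a vector (recycled per layer), each deeper layer trains twice as
#'   long as the one below it — deeper layers see far smaller inputs, so
#'   the extra sweeps are cheap, and the narrow top layer is the slowest
#'   to become a useful code.
#' @param seed integer seed.
#' @param learning_rate per-layer CD-1 step sizes, recycled to the number
#'   of layers. The default uses 0.001 for the Gaussian-visible first
#'   layer (real-valued inputs need a much smaller step than binary
#'   ones) and 0.005 for the Bernoulli layers.
#' @param n_restarts number of independently seeded training runs; the
#'   stack with the lowest input-space reconstruction error (encode
#'   through the stack, decode through the transposed weights) is kept.
#'   Greedy CD occasionally converges to a code that reconstructs the
#'   data poorly and scrambles its geometry; selecting on the training
#'   objective filters those runs out, exactly as best-of-restarts
#'   selection does for k-means. Default 3.
#' @param ... passed to [rbm_train_cd()].
#' @return An object of class `dbn_model`: list of `rbm_params`, with the
#'   winning restart's input-space `recon_mse`.
#' @export
dbn_train <- function(X, layer_sizes = c(512, 128, 32), epochs = 200,
                      seed = 1,
                      learning_rate = c(0.001, rep(0.005, length(layer_sizes) - 1)),
                      n_restarts = 3, ...) {
  X <- as.matrix(X)
  lr <- rep_len(learning_rate, length(layer_sizes))
  ep <- if (length(epochs) > 1) {
    rep_len(epochs, length(layer_sizes))
  } else {
    epochs * 2^(seq_along(layer_sizes) - 1)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    seed_r <- if (r == 1) seed else derive_seed(seed, paste0("restart", r))
    stack <- vector("list", length(layer_sizes))
    cur <- X
    for (i in seq_along(layer_sizes)) {
      vt <- if (i == 1) "gaussian" else "bernoulli"
      stack[[i]] <- rbm_train_cd(
        cur, hidden = layer_sizes[i], epochs = ep[i],
        seed = derive_seed(seed_r, paste0("rbm", i)), visible_type = vt,
        learning_rate = lr[i], ...
      )
      cur <- dbn_encode(stack[i], cur)
    }
    mse <- dbn_recon_mse(stack, X)
    if (is.null(best) || mse < best$recon_mse) {
      best <- list(stack = stack, recon_mse = mse, restart = r)
    }
  }
  structure(list(stack = best$stack, layer_sizes = layer_sizes,
                 seed = seed, recon_mse = best$recon_mse,
                 restart = best$restart),
            class = "dbn_model")
}

# input-space reconstruction through the unrolled stack: sigmoid encoder,
# transposed-weight decoder with visible biases (linear at the bottom for
# the Gaussian layer)
dbn_recon_mse <- function(stack, X) {
  sig <- function(x) 1 / (1 + exp(-x))
  h <- X
  for (r in stack) {
    h <- sig(h %*% r$W + matrix(r$b, nrow(h), ncol(r$W), byrow = TRUE))
  }
  v <- h
  for (i in rev(seq_along(stack))) {
    r <- stack[[i]]
    v <- v %*% t(r$W) + matrix(r$a, nrow(v), nrow(r$W), byrow = TRUE)
    if (i > 1) v <- sig(v)
  }
  mean((X - v)^2)
}

#' Encode data through a DBN stack
#'
#' Deterministic forward pass of mean hidden activations through each RBM
#' in turn.
#'
#' @param stack a `dbn_model`, or a plain list of `rbm_params`.
#' @param X numeric matrix, rows are inputs to the first layer.
#' @return Latent matrix with `nrow(X)` rows and last-layer width columns.
#' @export
dbn_encode <- function(stack, X) {
  if (inherits(stack, "dbn_model")) stack <- stack$stack
  out <- as.matrix(X)
  for (rbm in stack) {
    if (ncol(out) != nrow(rbm$W)) {
      stop("layer shape mismatch: input has ", ncol(out),
           " columns, layer expects ", nrow(rbm$W))
    }
    out <- 1 / (1 + exp(-(out %*% rbm$W +
                            matrix(rbm$b, nrow(out), ncol(rbm$W),
                                   byrow = TRUE))))
  }
  out
}
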