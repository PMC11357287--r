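#' Analytic Gaussian KL divergence to the standard-normal prior
#'
#' `KL(N(mu, diag(exp(logvar))) || N(0, I)) = 0.5 * sum(mu^2 + exp(logvar)
#' - 1 - logvar)`, the closed form used by the variational autoencoder
#' objective. Zero exactly when `mu = 0, logvar = 0`; `mu^2/2` for unit
#' variance.
#'
#' @param mu posterior mean vector (or matrix, rows = samples).
#' @param logvar posterior log-variance, same shape as `mu`.
#' @return Per-sample KL (vector if `mu` is a matrix).
#' @export
gaussian_kl <- function(mu, logvar = 0 * mu) {
  if (is.matrix(mu)) {
    0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
  } else {
    0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)
  }
}

#' Assemble a standardized training dataset from feature matrices
#'
#' Stacks per-molecule spectral feature matrices into a single
#' observations-by-features matrix and standardizes each feature to zero
#' mean and unit variance (constant features are left centred). The
#' standardization statistics are kept so reconstructions can be mapped
#' back to the original scale.
#'
#' @param features list of [build_feature_matrix()] results, or a numeric
#'   matrix (rows = molecules).
#' @return An object of class `feature_dataset`: list with `X`
#'   (standardized matrix), `mean`, `sd`, `ids`, and the matrix dimensions
#'   `h`, `w` of the unflattened features (when known).
#' @export
feature_dataset <- function(features) {
  if (is.matrix(features)) {
    X <- features
    ids <- rownames(X) %||% paste0("mol_", seq_len(nrow(X)))
    h <- NA_integer_
    w <- NA_integer_
  } else {
    stopifnot(length(features) > 0)
    h <- nrow(features[[1]]$matrix)
    w <- ncol(features[[1]]$matrix)
    X <- t(vapply(features, function(f) as.numeric(f$matrix),
                  numeric(h * w)))
    ids <- vapply(features, function(f) f$molecule_id, character(1))
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  structure(
    list(X = Xs, mean = mu, sd = sdev, ids = ids,
         h = h, w = w, d = ncol(X)),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d molecules x %d features\n",
              nrow(x$X), x$d))
  invisible(x)
}

build_ae_layers <- function(kind, d, latent_dim, h, w, hidden = 256) {
  if (kind == "cae") {
    if (is.na(h) || is.na(w)) {
      stop("convolutional autoencoder needs the 2-D feature shape")
    }
    s1 <- conv_structure(h, w, 1, 8)
    h2 <- s1$out_dim[1]; w2 <- s1$out_dim[2]
    s2 <- conv_structure(h2, w2, 8, 16)
    flat <- prod(s2$out_dim)
    list(
      enc = list(layer_sconv(s1, act = "relu"),
                 layer_sconv(s2, act = "relu"),
                 layer_dense(flat, latent_dim)),
      dec = list(layer_dense(latent_dim, flat, act = "relu"),
                 layer_sconv(s2, act = "relu", transpose = TRUE),
                 layer_sconv(s1, act = "linear", transpose = TRUE))
    )
  } else {
    list(
      enc = list(layer_dense(d, hidden, act = "relu"),
                 layer_dense(hidden, latent_dim)),
      dec = list(layer_dense(latent_dim, hidden, act = "relu"),
                 layer_dense(hidden, d))
    )
  }
}

#' Train an autoencoder-family embedding model
#'
#' Three architectures over the standardized feature matrices:
#' \describe{
#'   \item{cae}{convolutional autoencoder: two stride-2 convolutions
#'     (kernel 3) and a dense bottleneck, mirrored transposed-convolution
#'     decoder, squared-error reconstruction loss.}
#'   \item{vae}{variational autoencoder: dense trunk with Gaussian
#'     mean/log-variance heads, reparameterized sampling, loss =
#'     reconstruction + analytic KL to the standard-normal prior
#'     (negative ELBO).}
#'   \item{aae}{adversarial autoencoder: deterministic dense autoencoder
#'     plus a discriminator matching the latent distribution to a
#'     standard-normal prior; reconstruction, discriminator and
#'     encoder-fooling steps alternate each minibatch.}
#' }
#' Training is deterministic given `seed` (serial execution); the loss
#' curve is recorded per epoch with the value at initialization first.
#'
#' @param data a [feature_dataset()].
#' @param kind `"cae"`, `"vae"` or `"aae"`.
#' @param latent_dim latent dimension (default 32).
#' @param epochs training epochs (default 30).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size minibatch size (default 16).
#' @param seed integer seed.
#' @return An object of class `encoder_decoder` with the trained
#'   parameters, the architecture description and `loss_curve` (and for
#'   VAE additionally `recon_curve` and `kl_curve`; for AAE the
#'   discriminator).
#' @export
train_autoencoder <- function(data, kind = c("cae", "vae", "aae"),
                              latent_dim = 32, epochs = 30,
                              learning_rate = 1e-3, batch_size = 16,
                              seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(data, "feature_dataset"))
  X <- data$X
  d <- ncol(X)
  if (latent_dim >= d) stop("latent_dim must be smaller than input dim")
  rng <- local_rng(derive_seed(seed, paste0("ae_", kind)))

  arch <- build_ae_layers(kind, d, latent_dim, data$h, data$w)
  model <- list(
    kind = kind, latent_dim = latent_dim, d = d, h = data$h, w = data$w,
    enc_layers = arch$enc, dec_layers = arch$dec,
    enc_params = stack_init(arch$enc, rng),
    dec_params = stack_init(arch$dec, rng),
    seed = seed
  )
  if (kind == "vae") {
    trunk_out <- arch$enc[[length(arch$enc)]]$n_in
    # replace the last encoder layer with mu / logvar heads
    model$enc_layers <- arch$enc[-length(arch$enc)]
    model$enc_params <- model$enc_params[-length(arch$enc)]
    model$mu_layer <- layer_dense(trunk_out, latent_dim)
    model$logvar_layer <- layer_dense(trunk_out, latent_dim)
    model$mu_params <- model$mu_layer$init(rng)
    model$logvar_params <- model$logvar_layer$init(rng)
  }
  if (kind == "aae") {
    model$disc_layers <- list(layer_dense(latent_dim, 64, act = "relu"),
                              layer_dense(64, 1, act = "sigmoid"))
    model$disc_params <- stack_init(model$disc_layers, rng)
  }

  trainer <- switch(kind, cae = , aae = train_deterministic_ae,
                    vae = train_vae)
  trainer(model, X, epochs = epochs, lr = learning_rate,
          batch_size = batch_size, rng = rng)
}

recon_loss_full <- function(model, X) {
  Z <- encode_latent(model, X, standardized = TRUE)
  Xhat <- stack_fwd(model$dec_layers, model$dec_params, Z)$out
  mean(rowSums((X - Xhat)^2))
}

train_deterministic_ae <- function(model, X, epochs, lr, batch_size, rng,
                                   lambda = 0, centroids = NULL,
                                   labels = NULL) {
  n <- nrow(X)
  opt_e <- adam_init(model$enc_params)
  opt_d <- adam_init(model$dec_params)
  if (model$kind == "aae") {
    opt_disc <- adam_init(model$disc_params)
  }
  t_step <- 0
  curve <- recon_loss_full(model, X)
  adv_eps <- 1e-7
  for (ep in seq_len(epochs)) {
    for (idx in minibatches(n, batch_size, rng)) {
      xb <- X[idx, , drop = FALSE]
      B <- nrow(xb)
      fe <- stack_fwd(model$enc_layers, model$enc_params, xb)
      z <- fe$out
      fd <- stack_fwd(model$dec_layers, model$dec_params, z)
      gxhat <- 2 * (fd$out - xb) / B
      bd <- stack_bwd(model$dec_layers, model$dec_params, fd$caches, gxhat)
      gz <- bd$gin
      if (lambda > 0) {
        gz <- gz + lambda * 2 * (z - centroids[labels[idx], , drop = FALSE]) / B
      }
      be <- stack_bwd(model$enc_layers, model$enc_params, fe$caches, gz)
      t_step <- t_step + 1
      se <- adam_step(model$enc_params, be$gpars, opt_e, lr, t_step)
      model$enc_params <- se$p; opt_e <- se$s
      sd_ <- adam_step(model$dec_params, bd$gpars, opt_d, lr, t_step)
      model$dec_params <- sd_$p; opt_d <- sd_$s

      if (model$kind == "aae") {
        # discriminator step on balanced prior/posterior batches
        zp <- matrix(rng$rnorm(B * model$latent_dim), B)
        zf <- stack_fwd(model$enc_layers, model$enc_params, xb)$out
        fdp <- stack_fwd(model$disc_layers, model$disc_params, zp)
        fdf <- stack_fwd(model$disc_layers, model$disc_params, zf)
        dp <- pmin(pmax(fdp$out, adv_eps), 1 - adv_eps)
        df_ <- pmin(pmax(fdf$out, adv_eps), 1 - adv_eps)
        g_dp <- -1 / dp / B
        g_df <- 1 / (1 - df_) / B
        bdp <- stack_bwd(model$disc_layers, model$disc_params, fdp$caches, g_dp)
        bdf <- stack_bwd(model$disc_layers, model$disc_params, fdf$caches, g_df)
        gd <- mapply(function(g1, g2) mapply(`+`, g1, g2, SIMPLIFY = FALSE),
                     bdp$gpars, bdf$gpars, SIMPLIFY = FALSE)
        sdisc <- adam_step(model$disc_params, gd, opt_disc, lr, t_step)
        model$disc_params <- sdisc$p; opt_disc <- sdisc$s

        # encoder fooling step: minimize -log D(enc(x))
        fe2 <- stack_fwd(model$enc_layers, model$enc_params, xb)
        fdisc <- stack_fwd(model$disc_layers, model$disc_params, fe2$out)
        dfool <- pmin(pmax(fdisc$out, adv_eps), 1 - adv_eps)
        g_fool <- -1 / dfool / B
        bdisc <- stack_bwd(model$disc_layers, model$disc_params,
                           fdisc$caches, g_fool)
        be2 <- stack_bwd(model$enc_layers, model$enc_params, fe2$caches,
                         bdisc$gin)
        se2 <- adam_step(model$enc_params, be2$gpars, opt_e, lr, t_step)
        model$enc_params <- se2$p; opt_e <- se2$s
      }
    }
    loss <- recon_loss_full(model, X)
    if (!is.finite(loss)) stop("non-finite loss at epoch ", ep)
    curve <- c(curve, loss)
  }
  model$loss_curve <- curve
  class(model) <- "encoder_decoder"
  model
}

train_vae <- function(model, X, epochs, lr, batch_size, rng, lambda = 0,
                      centroids = NULL, labels = NULL) {
  n <- nrow(X)
  opt <- list(
    enc = adam_init(model$enc_params),
    mu = adam_init(model$mu_params),
    lv = adam_init(model$logvar_params),
    dec = adam_init(model$dec_params)
  )
  t_step <- 0
  full_losses <- function() {
    ft <- stack_fwd(model$enc_layers, model$enc_params, X)
    mu <- model$mu_layer$fwd(model$mu_params, ft$out)$out
    lv <- model$logvar_layer$fwd(model$logvar_params, ft$out)$out
    xhat <- stack_fwd(model$dec_layers, model$dec_params, mu)$out
    recon <- mean(rowSums((X - xhat)^2))
    kl <- mean(gaussian_kl(mu, lv))
    c(recon = recon, kl = kl)
  }
  l0 <- full_losses()
  recon_curve <- l0["recon"]
  kl_curve <- l0["kl"]
  for (ep in seq_len(epochs)) {
    for (idx in minibatches(n, batch_size, rng)) {
      xb <- X[idx, , drop = FALSE]
      B <- nrow(xb)
      ft <- stack_fwd(model$enc_layers, model$enc_params, xb)
      fmu <- model$mu_layer$fwd(model$mu_params, ft$out)
      flv <- model$logvar_layer$fwd(model$logvar_params, ft$out)
      mu <- fmu$out
      lv <- pmin(pmax(flv$out, -10), 10)
      sigma <- exp(0.5 * lv)
      eps <- matrix(rng$rnorm(B * model$latent_dim), B)
      z <- mu + eps * sigma
      fd <- stack_fwd(model$dec_layers, model$dec_params, z)
      gxhat <- 2 * (fd$out - xb) / B
      bd <- stack_bwd(model$dec_layers, model$dec_params, fd$caches, gxhat)
      gz <- bd$gin
      if (lambda > 0) {
        gz <- gz + lambda * 2 * (z - centroids[labels[idx], , drop = FALSE]) / B
      }
      gmu <- gz + mu / B
      glv <- gz * eps * 0.5 * sigma + 0.5 * (exp(lv) - 1) / B
      bmu <- model$mu_layer$bwd(model$mu_params, fmu$cache, gmu)
      blv <- model$logvar_layer$bwd(model$logvar_params, flv$cache, glv)
      bt <- stack_bwd(model$enc_layers, model$enc_params, ft$caches,
                      bmu$gin + blv$gin)
      t_step <- t_step + 1
      s1 <- adam_step(model$enc_params, bt$gpars, opt$enc, lr, t_step)
      model$enc_params <- s1$p; opt$enc <- s1$s
      s2 <- adam_step(model$mu_params, bmu$gpar, opt$mu, lr, t_step)
      model$mu_params <- s2$p; opt$mu <- s2$s
      s3 <- adam_step(model$logvar_params, blv$gpar, opt$lv, lr, t_step)
      model$logvar_params <- s3$p; opt$lv <- s3$s
      s4 <- adam_step(model$dec_params, bd$gpars, opt$dec, lr, t_step)
      model$dec_params <- s4$p; opt$dec <- s4$s
    }
    l <- full_losses()
    if (!all(is.finite(l))) stop("non-finite loss at epoch ", ep)
    recon_curve <- c(recon_curve, l["recon"])
    kl_curve <- c(kl_curve, l["kl"])
  }
  model$recon_curve <- unname(recon_curve)
  model$kl_curve <- unname(kl_curve)
  model$loss_curve <- unname(recon_curve + kl_curve)
  class(model) <- "encoder_decoder"
  model
}

#' @export
print.encoder_decoder <- function(x, ...) {
  cat(sprintf("<encoder_decoder> %s, latent %d, loss %.4g -> %.4g\n",
              x$kind, x$latent_dim, x$loss_curve[1],
              x$loss_curve[length(x$loss_curve)]))
  invisible(x)
}

#' Encode data into the latent space
#'
#' Deterministic encoding: mean activations for a DBN, the encoder output
#' for CAE/AAE, and the posterior mean for a VAE.
#'
#' @param model a trained `dbn_model` or `encoder_decoder`.
#' @param X data matrix on the standardized feature scale (rows =
#'   molecules), or a [feature_dataset()].
#' @param standardized internal flag; data passed as a matrix is assumed
#'   already standardized.
#' @return Latent matrix `Z`.
#' @export
encode_latent <- function(model, X, standardized = TRUE) {
  if (inherits(X, "feature_dataset")) X <- X$X
  if (inherits(model, "dbn_model")) {
    return(dbn_encode(model, X))
  }
  trunk <- stack_fwd(model$enc_layers, model$enc_params, X)$out
  if (model$kind == "vae") {
    model$mu_layer$fwd(model$mu_params, trunk)$out
  } else {
    trunk
  }
}

#' Joint reconstruction + clustering fine-tuning
#'
#' Alternates gradient epochs on the combined loss `L_recon + lambda *
#' L_cluster` (the k-means within-cluster sum of squares of the latent
#' points around their assigned centroids) with centroid/label updates.
#' With `lambda = 0` the procedure reduces exactly to reconstruction-only
#' training. The joint loss is tracked across outer iterations and the
#' procedure stops when it stops decreasing (tolerance `1e-6`) or at the
#' iteration cap.
#'
#' @param model a trained `encoder_decoder` (all three autoencoder kinds).
#' @param data the [feature_dataset()] used for training.
#' @param assignment a [kmeans_fit()] on the current latent space.
#' @param lambda nonnegative clustering weight (default 0.1).
#' @param outer_steps maximum outer iterations (default 10).
#' @param epochs_per_step gradient epochs between centroid updates.
#' @param learning_rate,batch_size,seed as in [train_autoencoder()].
#' @param update_assignment if `FALSE`, labels and centroids stay fixed
#'   (useful to probe the pull of the cluster term).
#' @return The updated model, with `joint_loss_curve` attached.
#' @export
joint_finetune <- function(model, data, assignment, lambda = 0.1,
                           outer_steps = 10, epochs_per_step = 1,
                           learning_rate = 1e-3, batch_size = 16,
                           seed = 1, update_assignment = TRUE) {
  if (lambda < 0) stop("lambda must be nonnegative")
  stopifnot(inherits(model, "encoder_decoder"))
  X <- data$X
  labels <- assignment$labels
  centroids <- assignment$centroids
  rng <- local_rng(derive_seed(seed, "joint"))
  trainer <- if (model$kind == "vae") train_vae else train_deterministic_ae
  joint_curve <- numeric(0)
  prev <- Inf
  for (step in seq_len(outer_steps)) {
    model <- trainer(model, X, epochs = epochs_per_step,
                     lr = learning_rate, batch_size = batch_size,
                     rng = rng, lambda = lambda, centroids = centroids,
                     labels = labels)
    class(model) <- "encoder_decoder"
    Z <- encode_latent(model, X)
    if (update_assignment) {
      d2 <- outer(rowSums(Z^2), rowSums(centroids^2), "+") -
        2 * Z %*% t(centroids)
      labels <- max.col(-d2, ties.method = "first")
      for (k in seq_len(nrow(centroids))) {
        if (sum(labels == k) > 0) {
          centroids[k, ] <- colMeans(Z[labels == k, , drop = FALSE])
        }
      }
    }
    recon <- recon_loss_full_any(model, X)
    lcl <- mean(rowSums((Z - centroids[labels, , drop = FALSE])^2))
    joint <- recon + lambda * lcl
    joint_curve <- c(joint_curve, joint)
    if (is.finite(prev) && prev - joint <= 1e-6 * max(abs(prev), 1)) break
    prev <- joint
  }
  model$joint_loss_curve <- joint_curve
  model$joint_labels <- labels
  model$joint_centroids <- centroids
  model
}

#' Save and load embedding models
#'
#' Checkpoints a trained embedder (`dbn_model` or `encoder_decoder`) as a
#' serialized R object with a JSON sidecar describing the architecture,
#' seed and training curve.
#'
#' @param model a trained embedding model.
#' @param path checkpoint path (an `.rds` file); the sidecar is written
#'   next to it as `<path>.json`.
#' @return `path` (invisibly) for `save_embedder`; the model for
#'   `load_embedder`.
#' @export
save_embedder <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(
    kind = if (inherits(model, "dbn_model")) "dbn" else model$kind,
    latent_dim = if (inherits(model, "dbn_model")) {
      utils::tail(model$layer_sizes, 1)
    } else {
      model$latent_dim
    },
    seed = model$seed,
    training_curve = if (inherits(model, "dbn_model")) {
      lapply(model$stack, function(r) r$recon_mse)
    } else {
      model$loss_curve
    }
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_embedder
#' @export
load_embedder <- function(path) {
  readRDS(path)
}

recon_loss_full_any <- function(model, X) {
  Z <- encode_latent(model, X)
  Xhat <- stack_fwd(model$dec_layers, model$dec_params, Z)$out
  mean(rowSums((X - Xhat)^2))
}
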