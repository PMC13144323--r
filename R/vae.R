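# Convolutional variational autoencoder for 128x128 nucleus
# projections, implemented directly in base R linear algebra: 3x3
# convolutions via im2col gather + BLAS matrix products, spatial batch
# normalization, leaky-rectifier activations, nearest-neighbor
# upsampling in the decoder, Adam optimization, and the
# reparameterization trick. Activations for a batch of B images of
# H x W pixels and C channels are stored as (B*H*W) x C matrices with
# pixels in R's column-major order, image-major rows.

#' VAE training configuration
#'
#' Architecture and optimization settings. The encoder and decoder each
#' cascade 4 convolution + batch-normalization + activation layers;
#' encoder convolutions are 3x3 stride 2 with channel widths
#' `channels`, the decoder mirrors them with nearest-neighbor 2x
#' upsampling. The loss is `mean squared reconstruction error +
#' lambda * KL(posterior || N(0, I))`; mean (not summed) squared error
#' keeps the validation tolerance scale per-pixel.
#'
#' @param latent_dim latent dimensionality of the chromatin descriptor.
#' @param channels encoder channel widths, innermost last (length 4).
#' @param lambda KL weight.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param tol stop when validation reconstruction MSE drops below this.
#' @param epochs_per_condition the training set rotates between disease
#'   conditions after this many epochs.
#' @param leaky_slope negative-side slope of the activation.
#' @param seed RNG seed (weight init, shuffling, reparameterization).
#' @return A `vae_config` object.
#' @export
vae_config <- function(latent_dim = 32, channels = c(32, 64, 128, 256),
                       lambda = 1.0, lr = 1e-3, batch_size = 16,
                       max_epochs = 600, tol = 1e-5,
                       epochs_per_condition = 20, leaky_slope = 0.2,
                       seed = 1) {
  stopifnot(length(channels) == 4, latent_dim >= 1)
  structure(
    list(latent_dim = as.integer(latent_dim), channels = as.integer(channels),
         lambda = lambda, lr = lr, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), tol = tol,
         epochs_per_condition = as.integer(epochs_per_condition),
         leaky_slope = leaky_slope, seed = as.integer(seed)),
    class = "vae_config"
  )
}

#' VAE loss with closed-form KL term
#'
#' `recon_term` is the mean squared error between reconstruction and
#' input; `kl_term` is the closed-form KL divergence of the diagonal
#' Gaussian posterior from the standard normal prior, summed over
#' latent dimensions and averaged over the batch:
#' `0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)`.
#'
#' @param x input pixels (vector or matrix, batch in rows).
#' @param reconstruction decoder output, same shape as `x`.
#' @param mu,logvar posterior means and log-variances (batch in rows).
#' @param lambda KL weight.
#' @return list with `total`, `recon_term`, `kl_term`.
#' @export
vae_loss <- function(x, reconstruction, mu, logvar, lambda = 1) {
  if (!all(is.finite(x)) || !all(is.finite(reconstruction)) ||
      !all(is.finite(mu)) || !all(is.finite(logvar)))
    stop("non-finite inputs to vae_loss")
  stopifnot(length(x) == length(reconstruction), length(mu) == length(logvar))
  recon <- mean((reconstruction - x)^2)
  mu <- rbind(mu); logvar <- rbind(logvar)
  kl_per <- 0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
  kl <- mean(kl_per)
  list(total = recon + lambda * kl, recon_term = recon, kl_term = kl)
}

# ---- im2col / upsample index machinery ------------------------------------

# gather indices for a 3x3 convolution with pad 1: one column of input
# linear indices per kernel position (0 = zero pad)
conv_index <- function(H, W, stride) {
  Ho <- (H + 2 - 3) %/% stride + 1
  Wo <- (W + 2 - 3) %/% stride + 1
  ox <- rep(seq_len(Ho), times = Wo)
  oy <- rep(seq_len(Wo), each = Ho)
  G <- matrix(0L, Ho * Wo, 9L)
  k <- 0L
  for (ky in 0:2) for (kx in 0:2) {
    k <- k + 1L
    ux <- (ox - 1L) * stride + kx
    uy <- (oy - 1L) * stride + ky
    ok <- ux >= 1 & ux <= H & uy >= 1 & uy <= W
    G[ok, k] <- ux[ok] + (uy[ok] - 1L) * H
  }
  list(G = G, Ho = Ho, Wo = Wo)
}

# extend a one-image gather index column over a batch; 0 (pad) maps to
# the appended zero row npad
batch_index <- function(Gk, np_in, B, npad) {
  out <- rep(Gk, times = B) +
    rep((seq_len(B) - 1L) * np_in, each = length(Gk))
  out[rep(Gk == 0L, times = B)] <- npad
  out
}

# weight layout: row (k - 1) * Cin + cin maps kernel position k, input
# channel cin to the output channels in columns
conv_forward <- function(A, W, b, Gmat, np_in, B) {
  Cin <- ncol(A)
  npo <- nrow(Gmat)
  npo_total <- npo * B
  npad <- nrow(A) + 1L
  Apad <- rbind(A, 0)
  P <- matrix(0, npo_total, 9L * Cin)
  Gk_list <- vector("list", 9L)
  for (k in 1:9) {
    Gk <- batch_index(Gmat[, k], np_in, B, npad)
    Gk_list[[k]] <- Gk
    P[, ((k - 1L) * Cin + 1L):(k * Cin)] <- Apad[Gk, , drop = FALSE]
  }
  out <- P %*% W
  out <- out + rep(b, each = npo_total)
  list(out = out, P = P, Gk_list = Gk_list)
}

conv_backward <- function(dOut, cache, W, n_in, Cin) {
  dW <- crossprod(cache$P, dOut)
  db <- colSums(dOut)
  dP <- dOut %*% t(W)
  dA <- matrix(0, n_in, Cin)
  # for a fixed kernel offset the output -> input pixel map is
  # injective, so each block scatters without accumulation conflicts
  for (k in 1:9) {
    Gk <- cache$Gk_list[[k]]
    ok <- Gk <= n_in
    ii <- Gk[ok]
    dA[ii, ] <- dA[ii, , drop = FALSE] +
      dP[ok, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
  }
  list(dA = dA, dW = dW, db = db)
}

upsample_index <- function(H, W) {
  ox <- rep(seq_len(2L * H), times = 2L * W)
  oy <- rep(seq_len(2L * W), each = 2L * H)
  ceiling(ox / 2) + (ceiling(oy / 2) - 1L) * H
}

# ---- batch norm and activations -------------------------------------------

bn_forward <- function(A, gamma, beta, buf, training, momentum = 0.1,
                       eps = 1e-5) {
  if (training) {
    m <- colMeans(A)
    v <- colMeans(A^2) - m^2
    buf$mean <- (1 - momentum) * buf$mean + momentum * m
    buf$var <- (1 - momentum) * buf$var + momentum * v
  } else {
    m <- buf$mean
    v <- buf$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(A, 2, m), 2, inv, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, inv = inv, buf = buf)
}

bn_backward <- function(dOut, cache, gamma) {
  n <- nrow(dOut)
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  t1 <- sweep(dOut, 2, dbeta / n)
  t2 <- sweep(cache$xhat, 2, dgamma / n, "*")
  dx <- sweep((t1 - t2), 2, gamma * cache$inv, "*")
  list(dA = dx, dgamma = dgamma, dbeta = dbeta)
}

lrelu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}
lrelu_grad <- function(d, x, slope) {
  neg <- x < 0
  d[neg] <- slope * d[neg]
  d
}

# ---- model construction ---------------------------------------------------

new_param <- function(dim, scale, env) {
  matrix(rnorm(prod(dim), 0, scale), dim[1], dim[2])
}

#' Initialize an untrained VAE model
#'
#' @param config a [vae_config()].
#' @param input_size FOV side length in pixels.
#' @return A `vae_model` environment holding parameters, normalization
#'   buffers, optimizer state, and the training log.
#' @export
vae_init <- function(config, input_size = 128) {
  ch <- config$channels
  L <- config$latent_dim
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$input_size <- input_size
  sizes <- input_size / c(1, 2, 4, 8)       # encoder input sizes per layer
  model$sizes <- sizes
  inner <- input_size / 16                  # spatial size at the bottleneck
  model$inner <- inner
  cin <- c(1, ch[1], ch[2], ch[3])
  p <- list()
  with_seed(config$seed, {
    for (l in 1:4) {
      p[[paste0("enc_conv", l, "_W")]] <-
        new_param(c(9 * cin[l], ch[l]), sqrt(2 / (9 * cin[l])))
      p[[paste0("enc_conv", l, "_b")]] <- rep(0, ch[l])
      p[[paste0("enc_bn", l, "_gamma")]] <- rep(1, ch[l])
      p[[paste0("enc_bn", l, "_beta")]] <- rep(0, ch[l])
    }
    flat <- inner * inner * ch[4]
    p$fc_mu_W <- new_param(c(flat, L), sqrt(1 / flat))
    p$fc_mu_b <- rep(0, L)
    p$fc_lv_W <- new_param(c(flat, L), sqrt(1 / flat))
    p$fc_lv_b <- rep(0, L)
    p$dec_fc_W <- new_param(c(L, flat), sqrt(1 / L))
    p$dec_fc_b <- rep(0, flat)
    p$dec_bn0_gamma <- rep(1, ch[4])
    p$dec_bn0_beta <- rep(0, ch[4])
    dcin <- c(ch[4], ch[3], ch[2], ch[1])
    dcout <- c(ch[3], ch[2], ch[1], 1)
    for (l in 1:4) {
      p[[paste0("dec_conv", l, "_W")]] <-
        new_param(c(9 * dcin[l], dcout[l]), sqrt(2 / (9 * dcin[l])))
      p[[paste0("dec_conv", l, "_b")]] <- rep(0, dcout[l])
      if (l < 4) {
        p[[paste0("dec_bn", l, "_gamma")]] <- rep(1, dcout[l])
        p[[paste0("dec_bn", l, "_beta")]] <- rep(0, dcout[l])
      }
    }
  })
  model$params <- p
  bn_buf <- function(C) list(mean = rep(0, C), var = rep(1, C))
  model$bufs <- list(
    enc_bn1 = bn_buf(ch[1]), enc_bn2 = bn_buf(ch[2]),
    enc_bn3 = bn_buf(ch[3]), enc_bn4 = bn_buf(ch[4]),
    dec_bn0 = bn_buf(ch[4]),
    dec_bn1 = bn_buf(ch[3]), dec_bn2 = bn_buf(ch[2]), dec_bn3 = bn_buf(ch[1])
  )
  model$adam <- list(
    m = lapply(p, function(x) x * 0),
    v = lapply(p, function(x) x * 0),
    t = 0
  )
  # index caches per spatial size
  model$idx <- list(
    enc = lapply(1:4, function(l) conv_index(sizes[l], sizes[l], 2L)),
    dec = lapply(1:4, function(l) {
      s <- inner * 2^l
      conv_index(s, s, 1L)
    }),
    up = lapply(1:4, function(l) {
      s <- inner * 2^(l - 1)
      upsample_index(s, s)
    })
  )
  model$log <- data.frame(epoch = integer(0), condition = character(0),
                          train_total = numeric(0), val_recon = numeric(0))
  class(model) <- "vae_model"
  model
}

# ---- forward / backward ---------------------------------------------------

# X: (B*np) x 1 pixel matrix; returns caches for backprop
vae_forward <- function(model, X, B, training = TRUE, eps_z = NULL) {
  p <- model$params
  cfg <- model$config
  sl <- cfg$leaky_slope
  cache <- list(B = B)
  A <- X
  cin <- 1L
  for (l in 1:4) {
    ix <- model$idx$enc[[l]]
    np_in <- model$sizes[l]^2
    cv <- conv_forward(A, p[[paste0("enc_conv", l, "_W")]],
                       p[[paste0("enc_conv", l, "_b")]], ix$G, np_in, B)
    bn <- bn_forward(cv$out, p[[paste0("enc_bn", l, "_gamma")]],
                     p[[paste0("enc_bn", l, "_beta")]],
                     model$bufs[[paste0("enc_bn", l)]], training)
    if (training) model$bufs[[paste0("enc_bn", l)]] <- bn$buf
    act <- lrelu(bn$out, sl)
    cache[[paste0("enc", l)]] <- list(conv = cv, bn = bn, pre_act = bn$out,
                                      n_in = B * np_in, cin = cin)
    A <- act
    cin <- cfg$channels[l]
  }
  np_inner <- model$inner^2
  flat <- np_inner * cfg$channels[4]
  Z3 <- A
  dim(Z3) <- c(np_inner, B, cfg$channels[4])
  F1 <- aperm(Z3, c(2, 1, 3))
  dim(F1) <- c(B, flat)
  mu <- sweep(F1 %*% p$fc_mu_W, 2, p$fc_mu_b, "+")
  lv <- sweep(F1 %*% p$fc_lv_W, 2, p$fc_lv_b, "+")
  lv <- pmin(pmax(lv, -10), 10)  # numeric guard on log-variance
  if (is.null(eps_z)) eps_z <- matrix(0, B, cfg$latent_dim)
  z <- mu + exp(lv / 2) * eps_z
  cache$F1 <- F1
  cache$mu <- mu; cache$lv <- lv; cache$eps_z <- eps_z; cache$z <- z

  # decoder
  D0 <- sweep(z %*% p$dec_fc_W, 2, p$dec_fc_b, "+")  # B x flat
  dim(D0) <- c(B, np_inner, cfg$channels[4])
  D0 <- aperm(D0, c(2, 1, 3))
  dim(D0) <- c(np_inner * B, cfg$channels[4])
  bn0 <- bn_forward(D0, p$dec_bn0_gamma, p$dec_bn0_beta,
                    model$bufs$dec_bn0, training)
  if (training) model$bufs$dec_bn0 <- bn0$buf
  A <- lrelu(bn0$out, sl)
  cache$dec0 <- list(bn = bn0, pre_act = bn0$out, D0 = D0)
  dcin <- c(cfg$channels[4], cfg$channels[3], cfg$channels[2], cfg$channels[1])
  for (l in 1:4) {
    s_in <- model$inner * 2^(l - 1)
    np_in <- s_in^2
    U <- model$idx$up[[l]]
    Ufull <- rep(U, times = B) + rep((seq_len(B) - 1L) * np_in, each = length(U))
    Aup <- A[Ufull, , drop = FALSE]
    ix <- model$idx$dec[[l]]
    np_up <- (2L * s_in)^2
    cv <- conv_forward(Aup, p[[paste0("dec_conv", l, "_W")]],
                       p[[paste0("dec_conv", l, "_b")]], ix$G, np_up, B)
    if (l < 4) {
      bn <- bn_forward(cv$out, p[[paste0("dec_bn", l, "_gamma")]],
                       p[[paste0("dec_bn", l, "_beta")]],
                       model$bufs[[paste0("dec_bn", l)]], training)
      if (training) model$bufs[[paste0("dec_bn", l)]] <- bn$buf
      out <- lrelu(bn$out, sl)
    } else {
      bn <- NULL
      out <- 1 / (1 + exp(-cv$out))
    }
    cache[[paste0("dec", l)]] <- list(conv = cv, Ufull = Ufull,
                                      bn = bn, pre_act = if (l < 4) bn$out else NULL,
                                      n_up = B * np_up, n_in = B * np_in,
                                      cin = dcin[l], out = out)
    A <- out
  }
  cache$recon <- A
  cache
}

vae_backward <- function(model, X, cache) {
  p <- model$params
  cfg <- model$config
  sl <- cfg$leaky_slope
  B <- cache$B
  g <- list()
  y <- cache$recon
  n_pix <- length(y)
  dA <- 2 * (y - X) / n_pix              # d(recon MSE)/dy
  dA <- dA * y * (1 - y)                  # through the sigmoid
  dcin <- c(cfg$channels[4], cfg$channels[3], cfg$channels[2], cfg$channels[1])
  for (l in 4:1) {
    cc <- cache[[paste0("dec", l)]]
    if (l < 4) {
      dA <- lrelu_grad(dA, cc$pre_act, sl)
      bb <- bn_backward(dA, cc$bn, p[[paste0("dec_bn", l, "_gamma")]])
      g[[paste0("dec_bn", l, "_gamma")]] <- bb$dgamma
      g[[paste0("dec_bn", l, "_beta")]] <- bb$dbeta
      dA <- bb$dA
    }
    cb <- conv_backward(dA, cc$conv, p[[paste0("dec_conv", l, "_W")]],
                        cc$n_up, cc$cin)
    g[[paste0("dec_conv", l, "_W")]] <- cb$dW
    g[[paste0("dec_conv", l, "_b")]] <- cb$db
    # back through upsample: sum gradients of the 4 children; every
    # input index occurs in Ufull, so rowsum's sorted rows are 1..n_in
    dA <- rowsum(cb$dA, group = cc$Ufull, reorder = TRUE)
    dimnames(dA) <- NULL
  }
  dA <- lrelu_grad(dA, cache$dec0$pre_act, sl)
  bb <- bn_backward(dA, cache$dec0$bn, p$dec_bn0_gamma)
  g$dec_bn0_gamma <- bb$dgamma
  g$dec_bn0_beta <- bb$dbeta
  dD0 <- bb$dA                             # (np_inner*B) x C4
  np_inner <- model$inner^2
  flat <- np_inner * cfg$channels[4]
  dim(dD0) <- c(np_inner, B, cfg$channels[4])
  dD0 <- aperm(dD0, c(2, 1, 3))
  dim(dD0) <- c(B, flat)
  g$dec_fc_W <- crossprod(cache$z, dD0)
  g$dec_fc_b <- colSums(dD0)
  dz <- dD0 %*% t(p$dec_fc_W)

  # KL gradients plus reparameterization path
  lam <- cfg$lambda
  dmu <- dz + lam * cache$mu / B
  dlv <- dz * cache$eps_z * exp(cache$lv / 2) * 0.5 +
    lam * 0.5 * (exp(cache$lv) - 1) / B
  g$fc_mu_W <- crossprod(cache$F1, dmu)
  g$fc_mu_b <- colSums(dmu)
  g$fc_lv_W <- crossprod(cache$F1, dlv)
  g$fc_lv_b <- colSums(dlv)
  dF1 <- dmu %*% t(p$fc_mu_W) + dlv %*% t(p$fc_lv_W)
  dim(dF1) <- c(B, np_inner, cfg$channels[4])
  dF1 <- aperm(dF1, c(2, 1, 3))
  dim(dF1) <- c(np_inner * B, cfg$channels[4])
  dA <- dF1
  for (l in 4:1) {
    cc <- cache[[paste0("enc", l)]]
    dA <- lrelu_grad(dA, cc$pre_act, sl)
    bb <- bn_backward(dA, cc$bn, p[[paste0("enc_bn", l, "_gamma")]])
    g[[paste0("enc_bn", l, "_gamma")]] <- bb$dgamma
    g[[paste0("enc_bn", l, "_beta")]] <- bb$dbeta
    cb <- conv_backward(bb$dA, cc$conv, p[[paste0("enc_conv", l, "_W")]],
                        cc$n_in, cc$cin)
    g[[paste0("enc_conv", l, "_W")]] <- cb$dW
    g[[paste0("enc_conv", l, "_b")]] <- cb$db
    dA <- cb$dA
  }
  g
}

adam_step <- function(model, grads) {
  st <- model$adam
  st$t <- st$t + 1
  lr <- model$config$lr
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * gr
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * gr^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  model$adam <- st
  invisible(model)
}

# assemble the (B*np) x 1 pixel matrix for FOVs ids from a (H,W,N) array
fov_batch <- function(fovs, ids) {
  matrix(as.vector(fovs[, , ids, drop = FALSE]), ncol = 1)
}

#' Train the VAE with condition-switching schedule
#'
#' The training set rotates between disease conditions (fixed order:
#' the sorted unique condition labels, or `condition_order`) every
#' `epochs_per_condition` epochs; validation reconstruction loss is
#' evaluated on the full validation split each epoch, and training
#' stops when it drops below `config$tol` or at `config$max_epochs`.
#'
#' @param fovs `(H, W, N)` array of preprocessed FOVs in `[0, 1]`.
#' @param condition length-`N` condition labels.
#' @param split length-`N` factor with levels train/val/test (e.g. from
#'   [make_splits()]); `NULL` generates one with the default fractions.
#' @param config a [vae_config()].
#' @param condition_order optional explicit rotation order.
#' @return The trained `vae_model`; its `log` field holds per-epoch
#'   active condition, training loss, and validation reconstruction
#'   loss.
#' @export
train_vae <- function(fovs, condition, split = NULL, config = vae_config(),
                      condition_order = NULL) {
  stopifnot(length(dim(fovs)) == 3, dim(fovs)[3] == length(condition))
  if (length(unique(condition)) < 2)
    stop("training requires at least 2 conditions")
  if (is.null(split)) {
    split <- make_splits(dim(fovs)[3], seed = derive_seed(config$seed, "split"))
  }
  conds <- if (is.null(condition_order)) sort(unique(condition)) else condition_order
  model <- vae_init(config, input_size = dim(fovs)[1])
  np <- model$input_size^2
  train_idx <- which(split == "train")
  val_idx <- which(split == "val")
  if (length(val_idx) == 0) val_idx <- train_idx
  val_recon <- function() {
    tot <- 0
    for (chunk in split(val_idx, ceiling(seq_along(val_idx) / config$batch_size))) {
      Xb <- fov_batch(fovs, chunk)
      cc <- vae_forward(model, Xb, length(chunk), training = FALSE)
      tot <- tot + sum((cc$recon - Xb)^2)
    }
    tot / (length(val_idx) * np)
  }
  log <- model$log
  for (epoch in seq_len(config$max_epochs)) {
    active <- conds[((epoch - 1) %/% config$epochs_per_condition) %% length(conds) + 1]
    ids <- train_idx[condition[train_idx] == active]
    if (length(ids) == 0) ids <- train_idx
    ids <- with_seed(derive_seed(config$seed, paste0("shuffle_", epoch)),
                     sample(ids))
    ep_loss <- 0
    nb <- 0
    for (chunk in split(ids, ceiling(seq_along(ids) / config$batch_size))) {
      B <- length(chunk)
      Xb <- fov_batch(fovs, chunk)
      eps_z <- with_seed(
        derive_seed(config$seed, paste0("eps_", epoch, "_", nb)),
        matrix(rnorm(B * config$latent_dim), B, config$latent_dim)
      )
      cc <- vae_forward(model, Xb, B, training = TRUE, eps_z = eps_z)
      ls <- vae_loss(Xb, cc$recon, cc$mu, cc$lv, config$lambda)
      if (!is.finite(ls$total))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      grads <- vae_backward(model, Xb, cc)
      adam_step(model, grads)
      ep_loss <- ep_loss + ls$total
      nb <- nb + 1
    }
    vr <- val_recon()
    log <- rbind(log, data.frame(epoch = epoch, condition = active,
                                 train_total = ep_loss / max(1, nb),
                                 val_recon = vr))
    model$log <- log
    if (vr < config$tol) break
  }
  model
}

#' Encode FOVs into latent chromatin descriptors
#'
#' Returns the posterior mean per FOV (deterministic at inference;
#' batch normalization uses running statistics).
#'
#' @param fovs `(H, W, N)` array in `[0, 1]`.
#' @param model trained `vae_model`.
#' @return `N x latent_dim` matrix Z.
#' @export
encode <- function(fovs, model) {
  stopifnot(inherits(model, "vae_model"), length(dim(fovs)) == 3)
  if (dim(fovs)[1] != model$input_size)
    stop("FOV size does not match the model input size")
  n <- dim(fovs)[3]
  bs <- model$config$batch_size
  out <- matrix(NA_real_, n, model$config$latent_dim)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / bs))) {
    cc <- vae_forward(model, fov_batch(fovs, chunk), length(chunk),
                      training = FALSE)
    out[chunk, ] <- cc$mu
  }
  out
}
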