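# Beta-variational autoencoder over 64 x 64 x 3 cell crops.
#
# Architecture: a convolutional encoder (3x3 kernels, stride 2, ReLU) whose
# filter counts are configurable (default 32, 64, 128, 256, 512), a 64-d
# Gaussian latent (posterior mean and log-variance heads), and a mirrored
# decoder of transposed convolutions with a linear output layer. The
# objective is pixelwise squared reconstruction error (summed over pixels,
# averaged over the batch) plus beta times the KL divergence from the
# standard-normal prior, with beta annealed per batch by a linear schedule.

#' KL-weight annealing schedule
#'
#' Beta starts at `beta_start` and increases by `beta_step` every training
#' batch until it reaches `beta_max`, where it stays for the rest of
#' training.
#'
#' @param beta_start,beta_step,beta_max Schedule parameters; defaults 0.001,
#'   0.001 per batch, and 2.
#' @return A list of class `beta_schedule`.
#' @export
beta_schedule <- function(beta_start = 0.001, beta_step = 0.001, beta_max = 2) {
  if (!(beta_start > 0 && beta_start <= beta_max)) {
    stop_input("need 0 < beta_start <= beta_max")
  }
  if (beta_step <= 0) stop_input("beta_step must be > 0")
  structure(list(beta_start = beta_start, beta_step = beta_step,
                 beta_max = beta_max), class = "beta_schedule")
}

#' Beta at a given training batch
#'
#' `beta = min(beta_max, beta_start + batch_index * beta_step)`; batch 0
#' returns `beta_start`. Values within 1e-12 of the ceiling snap to
#' `beta_max` exactly, so the plateau value is exact despite the accumulated
#' floating-point increments.
#'
#' @param batch_index Zero-based training batch index.
#' @param schedule A [beta_schedule()].
#' @return Numeric beta.
#' @export
beta_at <- function(batch_index, schedule = beta_schedule()) {
  if (any(batch_index < 0)) stop_input("batch_index must be >= 0")
  v <- schedule$beta_start + batch_index * schedule$beta_step
  ifelse(v >= schedule$beta_max - 1e-12, schedule$beta_max, v)
}

#' Beta-VAE training configuration
#'
#' Defaults follow the full-scale training recipe: five encoder layers of
#' 32/64/128/256/512 filters, latent dimension 64, batch size 16, Adam with
#' learning rate 5e-4, at most 100 epochs with early stopping on a 10%
#' validation split (patience 10). Tests and desk-scale runs pass smaller
#' `encoder_filters` / `max_epochs`.
#'
#' @param encoder_filters Integer vector of filter counts, one per stride-2
#'   encoder layer; the decoder mirrors it. Length L must satisfy
#'   `64 %% 2^L == 0`.
#' @param latent_dim Latent dimension (>= 1).
#' @param batch_size,learning_rate,max_epochs Optimizer settings.
#' @param patience,min_delta,validation_fraction Early-stopping settings;
#'   `validation_fraction` must lie in (0, 0.5).
#' @param seed Integer seed covering initialization, the train/validation
#'   split, shuffling, and the reparameterization noise.
#' @return A list of class `vae_config`.
#' @export
vae_config <- function(encoder_filters = c(32, 64, 128, 256, 512),
                       latent_dim = 64, batch_size = 16,
                       learning_rate = 5e-4, max_epochs = 100,
                       patience = 10, min_delta = 0,
                       validation_fraction = 0.1, seed = 1L) {
  if (length(encoder_filters) < 1 || any(encoder_filters < 1) ||
      64 %% 2^length(encoder_filters) != 0) {
    stop_input("encoder_filters must be positive with length L such that 64 %% 2^L == 0")
  }
  check_scalar_num(latent_dim, "latent_dim", 1)
  check_scalar_num(batch_size, "batch_size", 1)
  check_scalar_num(learning_rate, "learning_rate")
  check_scalar_num(max_epochs, "max_epochs", 1)
  if (learning_rate <= 0) stop_input("learning_rate must be > 0")
  if (validation_fraction <= 0 || validation_fraction >= 0.5) {
    stop_input("validation_fraction must lie in (0, 0.5)")
  }
  structure(list(encoder_filters = as.integer(encoder_filters),
                 latent_dim = as.integer(latent_dim),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "vae_config")
}

vae_arch <- function(config) {
  f <- config$encoder_filters
  L <- length(f)
  ch_enc <- c(3L, f)
  ch_dec <- c(rev(f), 3L)
  side <- 64L %/% 2L^L
  list(L = L, ch_enc = ch_enc, ch_dec = ch_dec, side = side,
       ss = side * side, flat = side * side * f[L],
       latent = config$latent_dim)
}

vae_init_params <- function(arch) {
  p <- list()
  for (l in seq_len(arch$L)) {
    p[[paste0("Wc", l)]] <- he_init(9L * arch$ch_enc[l], arch$ch_enc[l + 1],
                                    9L * arch$ch_enc[l])
    p[[paste0("bc", l)]] <- numeric(arch$ch_enc[l + 1])
  }
  p$Wmu <- he_init(arch$flat, arch$latent, arch$flat)
  p$bmu <- numeric(arch$latent)
  p$Wlv <- 0.01 * he_init(arch$flat, arch$latent, arch$flat)
  p$blv <- numeric(arch$latent)
  p$Wd <- he_init(arch$latent, arch$flat, arch$latent)
  p$bd <- numeric(arch$flat)
  for (l in seq_len(arch$L)) {
    p[[paste0("Wt", l)]] <- he_init(9L * arch$ch_dec[l + 1], arch$ch_dec[l],
                                    9L * arch$ch_dec[l])
    p[[paste0("bt", l)]] <- numeric(arch$ch_dec[l + 1])
  }
  p
}

LV_CLAMP <- 8

vae_encode_batch <- function(params, X, B, arch, keep_cache = FALSE) {
  L <- arch$L
  A <- X
  caches <- if (keep_cache) vector("list", L) else NULL
  side <- 64L
  for (l in seq_len(L)) {
    g <- conv_geom(side, side, B)
    cf <- conv_fwd(A, params[[paste0("Wc", l)]], params[[paste0("bc", l)]], g)
    Anew <- relu_fwd(cf$Y)
    if (keep_cache) caches[[l]] <- list(P = cf$P, A_out = Anew, g = g)
    A <- Anew
    side <- side %/% 2L
  }
  Fm <- nn_flatten(A, arch$ss, arch$ch_enc[L + 1], B)
  mu <- Fm %*% params$Wmu + rep(params$bmu, each = B)
  lv <- Fm %*% params$Wlv + rep(params$blv, each = B)
  lv_clamped <- pmin(pmax(lv, -LV_CLAMP), LV_CLAMP)
  list(mu = mu, lv = lv_clamped, lv_raw = lv, F = Fm, caches = caches)
}

vae_decode_batch <- function(params, z, B, arch, keep_cache = FALSE) {
  L <- arch$L
  G <- z %*% params$Wd + rep(params$bd, each = B)
  D0 <- relu_fwd(G)
  A <- nn_unflatten(D0, arch$ss, arch$ch_dec[1], B)
  side <- arch$side
  acts <- if (keep_cache) vector("list", L) else NULL
  ins <- if (keep_cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    g <- conv_geom(2L * side, 2L * side, B)
    if (keep_cache) ins[[l]] <- A
    Y <- convT_fwd(A, params[[paste0("Wt", l)]], params[[paste0("bt", l)]], g)
    A <- if (l < L) relu_fwd(Y) else Y
    if (keep_cache) acts[[l]] <- A
    side <- 2L * side
  }
  list(Xhat = A, G = G, D0 = D0, ins = ins, acts = acts)
}

# One training step: forward, loss, full backward pass. Returns grads in the
# same named layout as params.
vae_step <- function(params, X, B, arch, beta, eps_z) {
  enc <- vae_encode_batch(params, X, B, arch, keep_cache = TRUE)
  sig <- exp(0.5 * enc$lv)
  z <- enc$mu + sig * eps_z
  dec <- vae_decode_batch(params, z, B, arch, keep_cache = TRUE)
  resid <- dec$Xhat - X
  recon <- sum(resid^2) / B
  kl <- sum(-0.5 * (1 + enc$lv - enc$mu^2 - exp(enc$lv))) / B
  loss <- recon + beta * kl
  if (!is.finite(loss)) {
    stop_input("non-finite training loss (recon = %g, kl = %g); lower the learning rate", recon, kl)
  }

  grads <- list()
  L <- arch$L

  # Decoder chain (last layer linear, others ReLU).
  dY <- 2 * resid / B
  side <- 64L
  dA <- dY
  for (l in rev(seq_len(L))) {
    g <- conv_geom(side, side, B)
    if (l < L) dA <- relu_bwd(dA, dec$acts[[l]])
    bw <- convT_bwd(dA, dec$ins[[l]], params[[paste0("Wt", l)]], g)
    grads[[paste0("Wt", l)]] <- bw$dW
    grads[[paste0("bt", l)]] <- bw$db
    dA <- bw$dX
    side <- side %/% 2L
  }
  dD0 <- nn_flatten(dA, arch$ss, arch$ch_dec[1], B)
  dG <- relu_bwd(dD0, dec$D0)
  grads$Wd <- crossprod(z, dG)
  grads$bd <- colSums(dG)
  dz <- tcrossprod(dG, params$Wd)

  dmu <- dz + beta * enc$mu / B
  dlv <- dz * eps_z * 0.5 * sig + beta * 0.5 * (exp(enc$lv) - 1) / B
  dlv[enc$lv_raw < -LV_CLAMP | enc$lv_raw > LV_CLAMP] <- 0

  grads$Wmu <- crossprod(enc$F, dmu)
  grads$bmu <- colSums(dmu)
  grads$Wlv <- crossprod(enc$F, dlv)
  grads$blv <- colSums(dlv)
  dF <- tcrossprod(dmu, params$Wmu) + tcrossprod(dlv, params$Wlv)
  dA <- nn_unflatten(dF, arch$ss, arch$ch_enc[L + 1], B)

  side <- arch$side
  for (l in rev(seq_len(L))) {
    g <- conv_geom(2L * side, 2L * side, B)
    dA <- relu_bwd(dA, enc$caches[[l]]$A_out)
    bw <- conv_bwd(dA, enc$caches[[l]]$P, params[[paste0("Wc", l)]], g,
                   need_dA = l > 1L)
    grads[[paste0("Wc", l)]] <- bw$dW
    grads[[paste0("bc", l)]] <- bw$db
    dA <- bw$dA
    side <- 2L * side
  }

  list(grads = grads[names(params)], recon = recon, kl = kl, loss = loss)
}

# Stack selected crops into the (4096*B) x 3 matrix layout.
batch_matrix <- function(arr, idx) {
  B <- length(idx)
  X <- matrix(0, 4096L * B, 3L)
  for (ch in 1:3) X[, ch] <- as.vector(arr[, , ch, idx, drop = FALSE])
  X
}

vae_eval_loss <- function(params, arr, idx, arch, beta, batch_size) {
  recon <- 0
  kl <- 0
  n <- length(idx)
  for (start in seq(1, n, by = batch_size)) {
    ix <- idx[start:min(start + batch_size - 1, n)]
    B <- length(ix)
    X <- batch_matrix(arr, ix)
    enc <- vae_encode_batch(params, X, B, arch)
    dec <- vae_decode_batch(params, enc$mu, B, arch)   # posterior mean, no noise
    recon <- recon + sum((dec$Xhat - X)^2)
    kl <- kl + sum(-0.5 * (1 + enc$lv - enc$mu^2 - exp(enc$lv)))
  }
  c(recon = recon / n, kl = kl / n, total = recon / n + beta * kl / n)
}

#' Fit the beta-VAE to a set of crops
#'
#' Trains with Adam on mini-batches; beta follows the per-batch annealing
#' schedule; validation loss (reconstruction of the posterior mean plus
#' beta * KL) drives early stopping, and the best-validation weights are
#' restored. All randomness (initialization, split, shuffling,
#' reparameterization noise) derives from `config$seed`, so identical calls
#' give identical models.
#'
#' @param crops A `crop_set`, list of `chc_crop`s, or a 64 x 64 x 3 x n
#'   array. Crops should already be normalized (see [normalize_crops()]).
#' @param config A [vae_config()].
#' @param schedule A [beta_schedule()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `chc_vae` with elements `params`, `config`,
#'   `schedule`, `arch`, `history` (per-epoch data frame), `best_epoch`,
#'   `epochs_trained`.
#' @export
vae_fit <- function(crops, config = vae_config(), schedule = beta_schedule(),
                    verbose = FALSE) {
  stopifnot(inherits(config, "vae_config"), inherits(schedule, "beta_schedule"))
  arr <- crops_to_array(crops)
  n <- dim(arr)[4]
  if (n < 2 * config$batch_size) {
    stop_input("need at least 2 * batch_size = %d crops, got %d",
               2 * config$batch_size, n)
  }
  arch <- vae_arch(config)
  with_seed(config$seed, {
    params <- vae_init_params(arch)
    opt <- adam_init(params)
    n_val <- max(1L, floor(config$validation_fraction * n))
    val_idx <- sample(n, n_val)
    train_idx <- setdiff(seq_len(n), val_idx)

    history <- NULL
    best_val <- Inf
    best_params <- params
    best_epoch <- 0L
    wait <- 0L
    kglobal <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      order <- sample(train_idx)
      tr_recon <- 0
      tr_kl <- 0
      n_seen <- 0
      for (start in seq(1, length(order), by = config$batch_size)) {
        ix <- order[start:min(start + config$batch_size - 1, length(order))]
        B <- length(ix)
        beta <- beta_at(kglobal, schedule)
        X <- batch_matrix(arr, ix)
        eps_z <- matrix(stats::rnorm(B * arch$latent), B, arch$latent)
        st <- vae_step(params, X, B, arch, beta, eps_z)
        upd <- adam_step(params, st$grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
        tr_recon <- tr_recon + st$recon * B
        tr_kl <- tr_kl + st$kl * B
        n_seen <- n_seen + B
        kglobal <- kglobal + 1L
      }
      beta_now <- beta_at(kglobal - 1L, schedule)
      val <- vae_eval_loss(params, arr, val_idx, arch, beta_now,
                           config$batch_size)
      history <- rbind(history, data.frame(
        epoch = epoch, beta = beta_now,
        train_recon = tr_recon / n_seen, train_kl = tr_kl / n_seen,
        train_total = tr_recon / n_seen + beta_now * tr_kl / n_seen,
        val_recon = unname(val["recon"]), val_kl = unname(val["kl"]),
        val_total = unname(val["total"])
      ))
      if (verbose) {
        message(sprintf("epoch %3d  beta %.3f  train %.2f  val %.2f",
                        epoch, beta_now, utils::tail(history$train_total, 1),
                        utils::tail(history$val_total, 1)))
      }
      if (val["total"] < best_val - config$min_delta) {
        best_val <- val["total"]
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }

    structure(list(params = best_params, config = config, schedule = schedule,
                   arch = arch, history = history, best_epoch = best_epoch,
                   epochs_trained = nrow(history),
                   n_train = length(train_idx), n_val = n_val),
              class = "chc_vae")
  })
}

#' @export
print.chc_vae <- function(x, ...) {
  cat(sprintf("<chc_vae> encoder filters (%s), latent %d\n",
              paste(x$config$encoder_filters, collapse = ", "),
              x$config$latent_dim))
  cat(sprintf("  trained %d epochs (best %d), final val loss %.4g\n",
              x$epochs_trained, x$best_epoch,
              x$history$val_total[x$epochs_trained]))
  invisible(x)
}

#' @export
summary.chc_vae <- function(object, ...) {
  print(object)
  cat("  last epochs:\n")
  print(utils::tail(object$history[, c("epoch", "beta", "train_total",
                                       "val_total")], 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.chc_vae <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_total, h$val_total), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss (recon + beta * KL)", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Predict method: latent posterior means or reconstructions
#'
#' @param object A fitted `chc_vae`.
#' @param crops Crops in any accepted container.
#' @param type `"latent"` for the n x latent_dim posterior-mean matrix,
#'   `"reconstruction"` for the decoded posterior means (64 x 64 x 3 x n).
#' @param ... Unused.
#' @export
predict.chc_vae <- function(object, crops, type = c("latent", "reconstruction"),
                            ...) {
  type <- match.arg(type)
  arr <- crops_to_array(crops)
  n <- dim(arr)[4]
  arch <- object$arch
  bs <- object$config$batch_size
  mu_all <- matrix(0, n, arch$latent)
  rec_all <- if (type == "reconstruction") array(0, dim = dim(arr)) else NULL
  for (start in seq(1, n, by = bs)) {
    ix <- start:min(start + bs - 1, n)
    B <- length(ix)
    X <- batch_matrix(arr, ix)
    enc <- vae_encode_batch(object$params, X, B, arch)
    mu_all[ix, ] <- enc$mu
    if (type == "reconstruction") {
      dec <- vae_decode_batch(object$params, enc$mu, B, arch)
      for (j in seq_len(B)) {
        block <- (j - 1L) * 4096L + seq_len(4096L)
        rec_all[, , , ix[j]] <- array(dec$Xhat[block, ], c(64L, 64L, 3L))
      }
    }
  }
  if (type == "latent") mu_all else rec_all
}

#' Simulate crops from the fitted generative model
#'
#' Draws latent vectors from the standard-normal prior and decodes them.
#'
#' @param object A fitted `chc_vae`.
#' @param nsim Number of crops to simulate.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A 64 x 64 x 3 x nsim array.
#' @export
simulate.chc_vae <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    z <- matrix(stats::rnorm(nsim * object$arch$latent), nsim,
                object$arch$latent)
    dec <- vae_decode_batch(object$params, z, nsim, object$arch)
    out <- array(0, dim = c(64L, 64L, 3L, nsim))
    for (j in seq_len(nsim)) {
      block <- (j - 1L) * 4096L + seq_len(4096L)
      out[, , , j] <- array(dec$Xhat[block, ], c(64L, 64L, 3L))
    }
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Encode crops into an embedding set
#'
#' Computes posterior-mean embeddings for every crop, carrying phase labels
#' and per-crop morphology features, row-aligned.
#'
#' @param model A fitted `chc_vae`.
#' @param crops A `crop_set` or list of `chc_crop` objects.
#' @return A list of class `embedding_set`: `matrix` (n x latent_dim),
#'   `phase`, `features` (see [crop_features()]), `umap` (`NULL` until
#'   [embed_umap()] is run).
#' @export
encode <- function(model, crops) {
  stopifnot(inherits(model, "chc_vae"))
  m <- predict(model, crops, type = "latent")
  structure(list(matrix = m, phase = crop_phases(crops),
                 features = crop_features(crops), umap = NULL),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d crops x %d latent dims (%s)%s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s: %d", names(table(x$phase)), table(x$phase)),
                    collapse = ", "),
              if (is.null(x$umap)) "" else ", UMAP attached"))
  invisible(x)
}
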