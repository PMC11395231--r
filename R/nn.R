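# Minimal convolutional-network core used by the beta-VAE.
#
# All convolutions are 3x3, stride 2, with (0, 1) edge padding, so each layer
# exactly halves an even spatial size. A batch of feature maps is stored as a
# dense matrix with (H * W * B) rows (spatial index column-major, images in
# contiguous blocks) and C columns. Convolution is im2col + GEMM; the
# scatter-add in the backward data pass (and in the transposed-convolution
# forward pass, which is its mirror) is a precomputed sparse-matrix product.
# Geometry (gather indices and scatter matrix) is cached per (H, W, batch).

.geom_cache <- new.env(parent = emptyenv())

conv_geom <- function(H, W, B) {
  key <- paste(H, W, B, sep = "_")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  Ho <- H %/% 2L
  Wo <- W %/% 2L
  np <- Ho * Wo
  oy <- rep(seq_len(Ho), times = Wo)
  ox <- rep(seq_len(Wo), each = Ho)
  idx0 <- matrix(0L, np, 9L)
  j <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      j <- j + 1L
      rr <- 2L * (oy - 1L) + dy + 1L
      cc <- 2L * (ox - 1L) + dx + 1L
      ok <- rr <= H & cc <= W
      idx0[, j] <- ifelse(ok, (cc - 1L) * H + rr, 0L)
    }
  }
  base <- idx0[rep(seq_len(np), B), , drop = FALSE]
  off <- rep.int((seq_len(B) - 1L) * (H * W), rep.int(np, B))
  IDX <- base + off
  IDX[base == 0L] <- H * W * B + 1L   # shared zero-pad row
  idxvec <- as.integer(IDX)
  S <- Matrix::sparseMatrix(i = idxvec, j = seq_along(idxvec), x = 1,
                            dims = c(H * W * B + 1L, length(idxvec)))
  g <- list(H = H, W = W, B = B, Ho = Ho, Wo = Wo, npb = np * B,
            idxvec = idxvec, S = S)
  .geom_cache[[key]] <- g
  g
}

# Gather patches: A is (H*W*B) x Cin -> (Ho*Wo*B) x (9*Cin), column (c-1)*9+j.
nn_im2col <- function(A, g) {
  Apad <- rbind(A, 0)
  P <- Apad[g$idxvec, , drop = FALSE]
  dim(P) <- c(g$npb, 9L * ncol(A))
  P
}

# Scatter-add the patch-space matrix M ((Ho*Wo*B) x (9*C)) back to image
# space ((H*W*B) x C).
nn_scatter <- function(M, g, C) {
  dim(M) <- c(g$npb * 9L, C)
  out <- as.matrix(g$S %*% M)
  out[-nrow(out), , drop = FALSE]
}

# Strided convolution: Y = im2col(A) %*% W + b. Returns Y and the patch
# matrix for the backward pass.
conv_fwd <- function(A, W, b, g) {
  P <- nn_im2col(A, g)
  Y <- P %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, P = P)
}

conv_bwd <- function(dY, P, W, g, need_dA = TRUE) {
  dW <- crossprod(P, dY)
  db <- colSums(dY)
  dA <- NULL
  if (need_dA) {
    dA <- nn_scatter(tcrossprod(dY, W), g, nrow(W) / 9L)
  }
  list(dW = dW, db = db, dA = dA)
}

# Transposed (fractionally strided) convolution, the mirror of conv_fwd: maps
# (Hi*Wi*B) x Cin to (2Hi*2Wi*B) x Cout using the geometry of the underlying
# stride-2 convolution from the large side to the small side. Weight shape is
# (9*Cout) x Cin.
convT_fwd <- function(X, W, b, g) {
  Y <- nn_scatter(tcrossprod(X, W), g, nrow(W) / 9L)
  Y + rep(b, each = nrow(Y))
}

convT_bwd <- function(dY, X, W, g) {
  P <- nn_im2col(dY, g)
  dW <- crossprod(P, X)
  db <- colSums(dY)
  dX <- P %*% W
  list(dW = dW, db = db, dX = dX)
}

relu_fwd <- function(Z) {
  Z[Z < 0] <- 0
  Z
}

relu_bwd <- function(dA, A) {
  dA[A <= 0] <- 0
  dA
}

# (ss*B) x C feature maps <-> B x (ss*C) flat rows (column (c-1)*ss + s).
nn_flatten <- function(A, ss, C, B) {
  arr <- array(A, c(ss, B, C))
  t(matrix(aperm(arr, c(1, 3, 2)), ncol = B))
}

nn_unflatten <- function(F, ss, C, B) {
  arr <- array(t(F), c(ss, C, B))
  matrix(aperm(arr, c(1, 3, 2)), nrow = ss * B, ncol = C)
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}
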