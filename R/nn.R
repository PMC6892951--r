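# Internal convolutional-network engine.
#
# The network is small enough (two 1-D convolution layers of 20 filters
# over 15 peptide positions, a 64-unit dense layer, a sigmoid output) that
# dense base-R matrix algebra is the natural backend: convolutions are
# im2col matrix products, and batches are a few hundred rows at most.
#
# Tensors are arrays (n, channels, positions). im2col flattens windows so
# that row (i-1)*W + w holds window w of example i, and the column block
# for kernel offset o spans ((o-1)*C+1):(o*C).

im2col <- function(X, k) {
  d <- dim(X)
  n <- d[1]; C <- d[2]; L <- d[3]
  W <- L - k + 1L
  out <- matrix(0, n * W, C * k)
  for (o in seq_len(k)) {
    sl <- X[, , o:(o + W - 1L), drop = FALSE]          # n x C x W
    out[, ((o - 1L) * C + 1L):(o * C)] <-
      matrix(aperm(sl, c(3L, 1L, 2L)), n * W, C)        # row = (i-1)*W + w
  }
  out
}

col2im <- function(dXc, n, C, L, k) {
  W <- L - k + 1L
  dX <- array(0, c(n, C, L))
  for (o in seq_len(k)) {
    dm <- dXc[, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
    dX[, , o:(o + W - 1L)] <- dX[, , o:(o + W - 1L), drop = FALSE] +
      aperm(array(dm, c(W, n, C)), c(2L, 3L, 1L))
  }
  dX
}

# max pool over the position axis of an (n*W, F) activation matrix whose
# rows are ordered w-fastest-within-example; returns pooled (P, n, F)
# array plus the argmax offsets needed for the backward pass
pool_forward <- function(A, n, W, p) {
  FF <- ncol(A)
  P <- W %/% p
  arr <- array(A, c(W, n, FF))
  best <- arr[seq(1L, by = p, length.out = P), , , drop = FALSE]
  which_o <- array(1L, c(P, n, FF))
  if (p > 1L) for (o in 2:p) {
    cand <- arr[seq(o, by = p, length.out = P), , , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    which_o[upd] <- o
  }
  list(out = best, argmax = which_o, W = W, p = p)
}

# geometry implied by a config and an input channel count; errors early
# when kernel/pool sizes do not fit the 15-position axis
cnn_geometry <- function(config, C) {
  k <- config$kernel_size; p <- config$pool_size
  L0 <- 15L
  L1 <- L0 - k + 1L
  if (L1 < 1L) stop("kernel size ", k, " too large for the 15-position axis",
                    call. = FALSE)
  P1 <- L1 %/% p
  if (P1 < 1L) stop("pool size ", p, " too large after the first convolution",
                    call. = FALSE)
  L2 <- P1 - k + 1L
  if (L2 < 1L) stop("kernel size ", k, " too large for the second convolution",
                    call. = FALSE)
  P2 <- L2 %/% p
  if (P2 < 1L) stop("pool size ", p, " too large after the second convolution",
                    call. = FALSE)
  list(C = C, k = k, p = p, L0 = L0, L1 = L1, P1 = P1, L2 = L2, P2 = P2,
       flat = P2 * config$filters)
}

cnn_init <- function(config, C) {
  g <- cnn_geometry(config, C)
  FF <- config$filters
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  list(
    W1 = he(C * g$k, FF),          b1 = numeric(FF),
    W2 = he(FF * g$k, FF),         b2 = numeric(FF),
    W3 = he(g$flat, config$dense_units), b3 = numeric(config$dense_units),
    W4 = he(config$dense_units, 1L),     b4 = numeric(1L)
  )
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

cnn_forward <- function(params, X, g, config, train = FALSE) {
  n <- dim(X)[1]
  Xc1 <- im2col(X, g$k)                               # (n*L1, C*k)
  Z1 <- sweep(Xc1 %*% params$W1, 2L, params$b1, "+")
  A1 <- relu(Z1)
  pl1 <- pool_forward(A1, n, g$L1, g$p)               # (P1, n, F)
  X2 <- aperm(pl1$out, c(2L, 3L, 1L))                 # (n, F, P1)
  Xc2 <- im2col(X2, g$k)                              # (n*L2, F*k)
  Z2 <- sweep(Xc2 %*% params$W2, 2L, params$b2, "+")
  A2 <- relu(Z2)
  pl2 <- pool_forward(A2, n, g$L2, g$p)               # (P2, n, F)
  Xf <- matrix(aperm(pl2$out, c(2L, 1L, 3L)), n, g$flat)
  Z3 <- sweep(Xf %*% params$W3, 2L, params$b3, "+")
  A3 <- relu(Z3)
  if (train && config$dropout > 0) {
    mask <- (matrix(stats::runif(length(A3)), nrow(A3)) >= config$dropout) /
      (1 - config$dropout)
    A3d <- A3 * mask
  } else {
    mask <- NULL
    A3d <- A3
  }
  Z4 <- sweep(A3d %*% params$W4, 2L, params$b4, "+")
  p <- sigmoid(Z4)
  list(p = as.numeric(p),
       cache = list(X = X, Xc1 = Xc1, Z1 = Z1, pl1 = pl1, X2 = X2,
                    Xc2 = Xc2, Z2 = Z2, pl2 = pl2, Xf = Xf, Z3 = Z3,
                    A3d = A3d, mask = mask, n = n))
}

# gradient of mean binary cross-entropy wrt every parameter
cnn_backward <- function(params, fw, y, g) {
  ca <- fw$cache
  n <- ca$n
  dZ4 <- matrix((fw$p - y) / n, n, 1L)
  gW4 <- crossprod(ca$A3d, dZ4); gb4 <- colSums(dZ4)
  dA3 <- dZ4 %*% t(params$W4)
  if (!is.null(ca$mask)) dA3 <- dA3 * ca$mask
  dZ3 <- dA3 * (ca$Z3 > 0)
  gW3 <- crossprod(ca$Xf, dZ3); gb3 <- colSums(dZ3)
  dXf <- dZ3 %*% t(params$W3)                          # (n, flat)
  dP2 <- aperm(array(dXf, c(n, g$P2, ncol(params$W2))), c(2L, 1L, 3L))
  dA2 <- unpool(dP2, ca$pl2, n)                        # (n*L2, F)
  dZ2 <- dA2 * (ca$Z2 > 0)
  gW2 <- crossprod(ca$Xc2, dZ2); gb2 <- colSums(dZ2)
  dXc2 <- dZ2 %*% t(params$W2)
  dX2 <- col2im(dXc2, n, ncol(params$W1), g$P1, g$k)   # (n, F, P1)
  dP1 <- aperm(dX2, c(3L, 1L, 2L))                     # (P1, n, F)
  dA1 <- unpool(dP1, ca$pl1, n)                        # (n*L1, F)
  dZ1 <- dA1 * (ca$Z1 > 0)
  gW1 <- crossprod(ca$Xc1, dZ1); gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

# scatter pooled gradients back to the (n*W, F) pre-pool activation matrix
unpool <- function(dP, pool, n) {
  d <- dim(dP)
  P <- d[1]; FF <- d[3]
  dA <- array(0, c(pool$W, n, FF))
  base <- seq(0L, by = pool$p, length.out = P)
  for (o in seq_len(pool$p)) {
    mask <- pool$argmax == o
    contrib <- array(0, d)
    contrib[mask] <- dP[mask]
    dA[base + o, , ] <- dA[base + o, , , drop = FALSE] + contrib
  }
  matrix(dA, pool$W * n, FF)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# full training loop: seeded init, shuffled mini-batches, optional
# validation split with early stopping on validation loss
cnn_train <- function(X, y, config) {
  n <- dim(X)[1]
  C <- dim(X)[2]
  g <- cnn_geometry(config, C)
  with_seed(config$seed, {
    params <- cnn_init(config, C)
    state <- adam_init(params)
    val_n <- floor(n * config$validation_fraction)
    perm <- sample.int(n)
    val_idx <- if (val_n >= 2L) perm[seq_len(val_n)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    Xtr <- X[tr_idx, , , drop = FALSE]; ytr <- y[tr_idx]
    Xva <- X[val_idx, , , drop = FALSE]; yva <- y[val_idx]
    ntr <- length(tr_idx)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    epochs_run <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(ntr)
      starts <- seq(1L, ntr, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, ntr)]
        fw <- cnn_forward(params, Xtr[idx, , , drop = FALSE], g, config,
                          train = TRUE)
        loss <- bce_loss(fw$p, ytr[idx])
        if (!is.finite(loss))
          stop("training failure: non-finite loss at epoch ", epoch,
               call. = FALSE)
        ep_loss <- ep_loss + loss * length(idx)
        gr <- cnn_backward(params, fw, ytr[idx], g)
        upd <- adam_step(params, gr, state, config$learning_rate)
        params <- upd$params; state <- upd$state
      }
      ep_loss <- ep_loss / ntr
      vl <- if (length(val_idx))
        bce_loss(cnn_forward(params, Xva, g, config)$p, yva) else NA_real_
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss,
                                           val_loss = vl))
      epochs_run <- epoch
      if (length(val_idx)) {
        if (vl < best$loss - 1e-6) {
          best <- list(loss = vl, params = params, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$patience) break
        }
      }
    }
    if (length(val_idx) && is.finite(best$loss)) params <- best$params
    list(params = params, geometry = g, history = history,
         epochs_run = epochs_run,
         best_epoch = if (length(val_idx)) best$epoch else epochs_run)
  })
}
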