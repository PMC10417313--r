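# Internal neural-network engine for the 1D-CNN classifiers: leaky-ReLU
# convolutions (compiled in src/), size-2 max pooling, flatten, dropout,
# dense layers, single sigmoid output, binary cross-entropy and Adam.
# Gradients are verified against finite differences in the test suite.

leaky_relu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

leaky_grad <- function(x, slope) ifelse(x < 0, slope, 1)

# Max pooling (pool size 2, stride 2).  Odd trailing element is dropped,
# matching floor(L/2) output lengths.  Ties keep the first element.
maxpool_fwd <- function(A) {
  L <- dim(A)[1]; L2 <- L %/% 2L
  odd <- seq(1L, 2L * L2, 2L)
  a1 <- A[odd, , , drop = FALSE]
  a2 <- A[odd + 1L, , , drop = FALSE]
  keep1 <- a1 >= a2
  list(out = a1 * keep1 + a2 * !keep1, keep1 = keep1, L_in = L)
}

maxpool_bwd <- function(dOut, pool) {
  d <- dim(dOut)
  dA <- array(0, c(pool$L_in, d[2], d[3]))
  odd <- seq(1L, 2L * d[1], 2L)
  dA[odd, , ] <- dOut * pool$keep1
  dA[odd + 1L, , ] <- dOut * !pool$keep1
  dA
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

# He-normal initialisation of all weights; biases start at zero.
# Must be called inside an RNG context (see train_model).
init_cnn_params <- function(arch) {
  nb <- length(arch$conv_filters)
  conv <- vector("list", nb)
  cin <- 1L
  for (i in seq_len(nb)) {
    k <- arch$conv_kernels[i]; f <- arch$conv_filters[i]
    conv[[i]] <- list(W = he_init(k * cin, f, fan_in = k * cin),
                      b = numeric(f), k = k, cin = cin, f = f)
    cin <- f
  }
  sh <- architecture_shapes(arch)
  list(conv = conv,
       W1 = he_init(sh$flatten, arch$dense_units, fan_in = sh$flatten),
       b1 = numeric(arch$dense_units),
       W2 = he_init(arch$dense_units, 1L, fan_in = arch$dense_units),
       b2 = 0)
}

# Forward pass.  X: n x input_length matrix.  With training = TRUE dropout
# masks are drawn from the current RNG stream.  Returns logits and, when
# want_cache, every intermediate needed for backprop / Grad-CAM.
forward_cnn <- function(params, arch, X, training = FALSE, want_cache = FALSE) {
  B <- nrow(X); slope <- arch$leaky_slope
  A <- array(t(X), dim = c(ncol(X), 1L, B))
  cache <- if (want_cache) list(blocks = vector("list", length(params$conv)))
  for (i in seq_along(params$conv)) {
    ly <- params$conv[[i]]
    Z <- conv1d_forward(A, ly$W, ly$b, ly$k)
    Aact <- leaky_relu(Z, slope)
    pool <- maxpool_fwd(Aact)
    if (want_cache) cache$blocks[[i]] <- list(input = A, Z = Z, pool = pool)
    A <- pool$out
  }
  d <- dim(A)                               # (L_final, C_final, B)
  flat <- t(matrix(A, d[1] * d[2], B))      # flat index = (ch-1)*L + pos
  keep <- 1 - arch$dropout_rate
  if (training && arch$dropout_rate > 0) {
    m1 <- matrix(rbinom(length(flat), 1L, keep) / keep, nrow(flat))
  } else m1 <- 1
  flat_d <- flat * m1
  H <- sweep(flat_d %*% params$W1, 2, params$b1, `+`)
  A1 <- leaky_relu(H, slope)
  if (training && arch$dropout_rate > 0) {
    m2 <- matrix(rbinom(length(A1), 1L, keep) / keep, nrow(A1))
  } else m2 <- 1
  A1d <- A1 * m2
  logits <- drop(A1d %*% params$W2) + params$b2
  if (!want_cache) return(list(logits = logits))
  cache$final_dim <- d
  c(list(logits = logits, flat = flat, m1 = m1, flat_d = flat_d, H = H,
         A1 = A1, m2 = m2, A1d = A1d), cache)
}

# Numerically stable binary cross-entropy on logits.
bce_loss <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Full backward pass; returns gradients in the same structure as params.
backward_cnn <- function(params, arch, X, y, fw) {
  B <- nrow(X); slope <- arch$leaky_slope
  dlogit <- matrix((sigmoid(fw$logits) - y) / B, ncol = 1)
  gW2 <- t(fw$A1d) %*% dlogit
  gb2 <- sum(dlogit)
  dA1 <- (dlogit %*% t(params$W2)) * fw$m2
  dH <- dA1 * leaky_grad(fw$H, slope)
  gW1 <- t(fw$flat_d) %*% dH
  gb1 <- colSums(dH)
  dflat <- (dH %*% t(params$W1)) * fw$m1
  d <- fw$final_dim
  dA <- array(t(dflat), dim = d)
  grads <- vector("list", length(params$conv))
  for (i in rev(seq_along(params$conv))) {
    ly <- params$conv[[i]]; blk <- fw$blocks[[i]]
    dAct <- maxpool_bwd(dA, blk$pool)
    dZ <- dAct * leaky_grad(blk$Z, slope)
    bw <- conv1d_backward(blk$input, ly$W, dZ, ly$k)
    grads[[i]] <- list(W = bw$dW, b = as.numeric(bw$db))
    dA <- bw$dX
  }
  list(conv = grads, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

# --- Adam ----------------------------------------------------------------

adam_new <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (i in seq_along(params$conv)) {
    for (nm in c("W", "b")) {
      r <- upd(params$conv[[i]][[nm]], grads$conv[[i]][[nm]],
               state$m$conv[[i]][[nm]], state$v$conv[[i]][[nm]])
      params$conv[[i]][[nm]] <- r$p
      state$m$conv[[i]][[nm]] <- r$m; state$v$conv[[i]][[nm]] <- r$v
    }
  }
  for (nm in c("W1", "b1", "W2", "b2")) {
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  list(params = params, state = state)
}
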