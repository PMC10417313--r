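# The network engine is verified against independent oracles: a naive
# direct-summation convolution and central finite differences of the loss.

naive_conv1d <- function(X, W, b, k) {
  # X: L x Cin; W: (k*Cin) x Cout; same padding, stride 1
  L <- nrow(X); Cin <- ncol(X); Cout <- ncol(W)
  pl <- (k - 1) %/% 2
  Y <- matrix(0, L, Cout)
  for (i in seq_len(L)) for (f in seq_len(Cout)) {
    acc <- b[f]
    for (c in seq_len(Cin)) for (j in seq_len(k)) {
      src <- i + (j - 1) - pl
      if (src >= 1 && src <= L)
        acc <- acc + X[src, c] * W[(c - 1) * k + j, f]
    }
    Y[i, f] <- acc
  }
  Y
}

test_that("compiled convolution matches direct summation", {
  set.seed(11)
  for (k in c(3L, 4L, 9L)) {
    L <- 13L; Cin <- 2L; Cout <- 3L; B <- 2L
    X <- array(rnorm(L * Cin * B), c(L, Cin, B))
    W <- matrix(rnorm(k * Cin * Cout), k * Cin, Cout)
    b <- rnorm(Cout)
    Y <- mrsinet:::conv1d_forward(X, W, b, k)
    for (s in seq_len(B))
      expect_equal(Y[, , s], naive_conv1d(X[, , s, drop = TRUE], W, b, k),
                   tolerance = 1e-12)
  }
})

test_that("convolution backward pass matches finite differences", {
  set.seed(12)
  L <- 10L; Cin <- 2L; Cout <- 3L; k <- 4L; B <- 2L
  X <- array(rnorm(L * Cin * B), c(L, Cin, B))
  W <- matrix(rnorm(k * Cin * Cout), k * Cin, Cout)
  b <- rnorm(Cout)
  R <- array(rnorm(L * Cout * B), c(L, Cout, B))   # random projection
  loss <- function(X, W, b) sum(mrsinet:::conv1d_forward(X, W, b, k) * R)
  bw <- mrsinet:::conv1d_backward(X, W, R, k)
  eps <- 1e-6
  num <- function(get, set) {
    p0 <- get()
    vapply(seq_along(p0), function(i) {
      pp <- p0; pp[i] <- pp[i] + eps; lp <- set(pp)
      pm <- p0; pm[i] <- pm[i] - eps; lm <- set(pm)
      (lp - lm) / (2 * eps)
    }, numeric(1))
  }
  gW <- num(function() W, function(p) loss(X, matrix(p, nrow(W)), b))
  expect_equal(as.numeric(bw$dW), gW, tolerance = 1e-6)
  gb <- num(function() b, function(p) loss(X, W, p))
  expect_equal(as.numeric(bw$db), gb, tolerance = 1e-6)
  gX <- num(function() as.numeric(X),
            function(p) loss(array(p, dim(X)), W, b))
  expect_equal(as.numeric(bw$dX), gX, tolerance = 1e-6)
})

test_that("end-to-end network gradients match finite differences", {
  arch <- cnn_architecture(c(16L, 16L), c(3L, 3L), 64L, dropout_rate = 0,
                           input_length = 16L)
  set.seed(13)
  params <- mrsinet:::init_cnn_params(arch)
  X <- matrix(rnorm(3 * 16), 3, 16)
  y <- c(1, 0, 1)
  fw <- mrsinet:::forward_cnn(params, arch, X, want_cache = TRUE)
  gr <- mrsinet:::backward_cnn(params, arch, X, y, fw)
  loss_with <- function(p) {
    f <- mrsinet:::forward_cnn(p, arch, X)
    mrsinet:::bce_loss(f$logits, y)
  }
  eps <- 1e-6
  check_tensor <- function(getp, setp, analytic, n_probe = 12) {
    p0 <- getp(params)
    idx <- sample(seq_along(p0), min(n_probe, length(p0)))
    for (i in idx) {
      pp <- params; v <- p0; v[i] <- v[i] + eps; pp <- setp(pp, v)
      pm <- params; v <- p0; v[i] <- v[i] - eps; pm <- setp(pm, v)
      expect_equal(analytic[i], (loss_with(pp) - loss_with(pm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
  check_tensor(function(p) p$W1,
               function(p, v) { p$W1 <- matrix(v, nrow(p$W1)); p },
               as.numeric(gr$W1))
  check_tensor(function(p) p$W2,
               function(p, v) { p$W2 <- matrix(v, nrow(p$W2)); p },
               as.numeric(gr$W2))
  for (blk in 1:2) {
    check_tensor(function(p) p$conv[[blk]]$W,
                 function(p, v) {
                   p$conv[[blk]]$W <- matrix(v, nrow(p$conv[[blk]]$W)); p
                 },
                 as.numeric(gr$conv[[blk]]$W))
    check_tensor(function(p) p$conv[[blk]]$b,
                 function(p, v) { p$conv[[blk]]$b <- v; p },
                 as.numeric(gr$conv[[blk]]$b))
  }
})

test_that("max pooling halves length, keeps the larger element and routes gradients", {
  A <- array(c(3, 1, 2, 5, 7, 7, 9, 4, 0, 6), c(10, 1, 1))
  p <- mrsinet:::maxpool_fwd(A)
  expect_equal(as.numeric(p$out), c(3, 5, 7, 9, 6))  # ties keep the first
  dOut <- array(1:5, c(5, 1, 1))
  dA <- mrsinet:::maxpool_bwd(dOut, p)
  expect_equal(as.numeric(dA), c(1, 0, 0, 2, 3, 0, 4, 0, 0, 5))
  # odd input length drops the trailing element
  A2 <- array(1:7, c(7, 1, 1))
  expect_equal(dim(mrsinet:::maxpool_fwd(A2)$out)[1], 3L)
})
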