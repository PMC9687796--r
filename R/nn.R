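# Minimal neural-network primitives used by the Siamese scorers: dense and
# 1-D convolution layers (im2col), max-pooling, seeded Glorot-uniform
# initialization and the RMSprop update. Everything operates on batches
# (rows = pairs) through base matrix algebra, so forward/backward passes are
# plain BLAS calls and fully deterministic under a seed.

.relu <- function(x) pmax(x, 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))

# column-broadcast bias add: Z is (B x F), b length F
.addb <- function(Z, b) Z + rep(b, each = nrow(Z))

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# ---- 1-D convolution, kernel 3, "same" padding, via im2col ----------------
# X is an array (B, L, Cin); W is (3*Cin, Cout), rows ordered (tap, channel);
# returns list(Y = (B, L, Cout) array, Xcol = im2col matrix kept for backward).
.conv1d_fwd <- function(X, W, b) {
  d <- dim(X); B <- d[1]; L <- d[2]; Cin <- d[3]
  Cout <- ncol(W)
  Xpad <- array(0, c(B, L + 2L, Cin))
  Xpad[, 2:(L + 1L), ] <- X
  Xcol <- matrix(0, B * L, 3L * Cin)
  for (k in 1:3) {
    blk <- Xpad[, k:(k + L - 1L), , drop = FALSE]
    dim(blk) <- c(B * L, Cin)
    Xcol[, ((k - 1L) * Cin + 1L):(k * Cin)] <- blk
  }
  Y <- .addb(Xcol %*% W, b)
  dim(Y) <- c(B, L, Cout)
  list(Y = Y, Xcol = Xcol, dims = c(B, L, Cin))
}

# dY is (B, L, Cout); returns grads and dX (B, L, Cin)
.conv1d_bwd <- function(dY, W, Xcol, dims) {
  B <- dims[1]; L <- dims[2]; Cin <- dims[3]
  Cout <- ncol(W)
  dYm <- dY; dim(dYm) <- c(B * L, Cout)
  dW <- crossprod(Xcol, dYm)
  db <- colSums(dYm)
  dXcol <- tcrossprod(dYm, W)           # (B*L, 3*Cin)
  dXpad <- array(0, c(B, L + 2L, Cin))
  for (k in 1:3) {
    blk <- dXcol[, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
    dim(blk) <- c(B, L, Cin)
    dXpad[, k:(k + L - 1L), ] <- dXpad[, k:(k + L - 1L), , drop = FALSE] + blk
  }
  list(dW = dW, db = db, dX = dXpad[, 2:(L + 1L), , drop = FALSE])
}

# ---- max pooling, size 2, stride 2 ----------------------------------------
.pool2_fwd <- function(X) {
  d <- dim(X); L <- d[2]
  odd <- X[, seq(1L, L, 2L), , drop = FALSE]
  even <- X[, seq(2L, L, 2L), , drop = FALSE]
  mask <- odd >= even                    # ties routed to the first element
  list(Y = pmax(odd, even), mask = mask, L = L)
}

.pool2_bwd <- function(dY, pool) {
  d <- dim(dY)
  dX <- array(0, c(d[1], pool$L, d[3]))
  dX[, seq(1L, pool$L, 2L), ] <- dY * pool$mask
  dX[, seq(2L, pool$L, 2L), ] <- dY * (1 - pool$mask)
  dX
}

# ---- RMSprop ---------------------------------------------------------------
.rmsprop_step <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state[[nm]] <- rho * state[[nm]] + (1 - rho) * g^2
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state[[nm]]) + eps)
  }
  list(params = params, state = state)
}

.zero_like <- function(params) lapply(params, function(p) p * 0)
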