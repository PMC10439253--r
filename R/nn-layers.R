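## Minimal neural-network primitives on batched (B, H, W, C) arrays.
## Convolutions use im2col + BLAS matrix products; every layer has an
## explicit backward pass so gradients can be verified by finite
## differences and reused for Grad-CAM / guided backpropagation.

## weight matrix layout: rows indexed by (kernel offset block, input channel)
conv_init <- function(k, cin, cout) {
  fan_in <- k * k * cin
  list(W = matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                  fan_in, cout),
       b = numeric(cout))
}

dense_init <- function(din, dout) {
  list(W = matrix(stats::rnorm(din * dout, 0, sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

conv_fwd <- function(X, par, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(X); B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  Cout <- ncol(par$W)
  if (pad > 0L) {
    Xp <- array(0, c(B, H + 2L * pad, Wd + 2L * pad, Cin))
    Xp[, pad + seq_len(H), pad + seq_len(Wd), ] <- X
  } else Xp <- X
  dp <- dim(Xp)
  Ho <- (dp[2] - k) %/% stride + 1L
  Wo <- (dp[3] - k) %/% stride + 1L
  ri <- seq.int(1L, by = stride, length.out = Ho)
  ci <- seq.int(1L, by = stride, length.out = Wo)
  ## linear indices into Xp for the (kr = kc = 1) window, laid out as the
  ## column-major vector of a (B, Ho, Wo, Cin) slice; other kernel offsets
  ## are constant shifts of this index set
  idx0 <- as.vector(outer(outer(outer(seq_len(B), (ri - 1L) * B, "+"),
                                (ci - 1L) * (B * dp[2]), "+"),
                          (seq_len(Cin) - 1L) * (B * dp[2] * dp[3]), "+"))
  M <- matrix(0, B * Ho * Wo, k * k * Cin)
  blk <- 0L
  for (kc in seq_len(k)) for (kr in seq_len(k)) {
    sh <- (kr - 1L) * B + (kc - 1L) * (B * dp[2])
    M[, blk * Cin + seq_len(Cin)] <- Xp[idx0 + sh]
    blk <- blk + 1L
  }
  Y <- M %*% par$W
  Y <- sweep(Y, 2, par$b, "+")
  dim(Y) <- c(B, Ho, Wo, Cout)
  list(Y = Y, M = M, in_dim = d, pad_dim = dp, k = k, stride = stride,
       pad = pad, idx0 = idx0)
}

conv_bwd <- function(cache, par, dY) {
  d <- cache$in_dim; dp <- cache$pad_dim
  B <- d[1]; Cin <- d[4]
  Ho <- dim(dY)[2]; Wo <- dim(dY)[3]; Cout <- dim(dY)[4]
  dYm <- dY; dim(dYm) <- c(B * Ho * Wo, Cout)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, par$W)
  dXp <- numeric(prod(dp))
  blk <- 0L
  for (kc in seq_len(cache$k)) for (kr in seq_len(cache$k)) {
    sh <- (kr - 1L) * B + (kc - 1L) * (B * dp[2])
    ii <- cache$idx0 + sh
    dXp[ii] <- dXp[ii] + dM[, blk * Cin + seq_len(Cin)]
    blk <- blk + 1L
  }
  dim(dXp) <- dp
  dX <- if (cache$pad > 0L)
    dXp[, cache$pad + seq_len(d[2]), cache$pad + seq_len(d[3]), ,
        drop = FALSE]
  else dXp
  list(dX = dX, dW = dW, db = db)
}

relu_fwd <- function(X) list(Y = pmax(X, 0), X = X)

## guided = TRUE additionally suppresses negative upstream gradients
## (guided backpropagation's rectifier rule)
relu_bwd <- function(cache, dY, guided = FALSE) {
  g <- dY * (cache$X > 0)
  if (guided) g <- g * (dY > 0)
  g
}

dense_fwd <- function(X, par) {
  Y <- X %*% par$W
  list(Y = sweep(Y, 2, par$b, "+"), X = X)
}

dense_bwd <- function(cache, par, dY) {
  list(dX = tcrossprod(dY, par$W), dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

## global average pool (B,H,W,C) -> (B,C)
gap_fwd <- function(X) {
  d <- dim(X)
  A <- aperm(X, c(2, 3, 1, 4))
  dim(A) <- c(d[2] * d[3], d[1] * d[4])
  list(Y = matrix(colMeans(A), d[1], d[4]), in_dim = d)
}

gap_bwd <- function(cache, dY) {
  d <- cache$in_dim
  g <- array(rep(as.vector(dY) / (d[2] * d[3]), each = d[2] * d[3]),
             c(d[2], d[3], d[1], d[4]))
  aperm(g, c(3, 1, 2, 4))
}

## nearest-neighbour 2x spatial upsampling
up2_fwd <- function(X) {
  d <- dim(X)
  list(Y = X[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), ,
             drop = FALSE],
       in_dim = d)
}

up2_bwd <- function(cache, dY) {
  d <- cache$in_dim
  r1 <- seq.int(1L, 2L * d[2], 2L); c1 <- seq.int(1L, 2L * d[3], 2L)
  dY[, r1, c1, , drop = FALSE] + dY[, r1 + 1L, c1, , drop = FALSE] +
    dY[, r1, c1 + 1L, , drop = FALSE] + dY[, r1 + 1L, c1 + 1L, , drop = FALSE]
}

se_init <- function(c_in, reduction) {
  cr <- max(1L, c_in %/% reduction)
  list(W1 = matrix(stats::rnorm(c_in * cr, 0, sqrt(2 / c_in)), c_in, cr),
       b1 = numeric(cr),
       W2 = matrix(stats::rnorm(cr * c_in, 0, sqrt(2 / cr)), cr, c_in),
       b2 = numeric(c_in))
}

## squeeze-and-excitation: per-channel global average -> two-layer
## perceptron with sigmoid gate -> channel rescaling
se_fwd <- function(X, par) {
  gp <- gap_fwd(X)
  z1 <- sweep(gp$Y %*% par$W1, 2, par$b1, "+")
  a1 <- pmax(z1, 0)
  z2 <- sweep(a1 %*% par$W2, 2, par$b2, "+")
  g <- 1 / (1 + exp(-z2))                       # (B, C)
  d <- dim(X)
  gx <- aperm(array(rep(as.vector(g), each = d[2] * d[3]),
                    c(d[2], d[3], d[1], d[4])), c(3, 1, 2, 4))
  list(Y = X * gx, X = X, gp = gp, z1 = z1, a1 = a1, g = g, gx = gx)
}

se_bwd <- function(cache, par, dY, guided = FALSE) {
  d <- dim(cache$X)
  dX <- dY * cache$gx
  ## gradient into the gate: sum over space of dY * X per (batch, channel)
  A <- aperm(dY * cache$X, c(2, 3, 1, 4))
  dim(A) <- c(d[2] * d[3], d[1] * d[4])
  dg <- matrix(colSums(A), d[1], d[4])
  dz2 <- dg * cache$g * (1 - cache$g)
  da1 <- tcrossprod(dz2, par$W2)
  dz1 <- da1 * (cache$z1 > 0)
  if (guided) dz1 <- dz1 * (da1 > 0)
  ds <- tcrossprod(dz1, par$W1)                 # grad wrt channel means
  dX <- dX + gap_bwd(cache$gp, ds)
  list(dX = dX,
       dW1 = crossprod(cache$gp$Y, dz1), db1 = colSums(dz1),
       dW2 = crossprod(cache$a1, dz2), db2 = colSums(dz2))
}
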