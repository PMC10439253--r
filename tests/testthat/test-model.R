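test_that("squeeze-and-excitation gates rescale channels exactly", {
  set.seed(11)
  par <- se_init(4L, 2L)
  X <- array(rnorm(2 * 5 * 5 * 4), c(2, 5, 5, 4))
  ## force the sigmoid into saturation: gate = 1 -> identity
  sat <- par; sat$W2[] <- 0; sat$b2[] <- 50
  expect_equal(se_fwd(X, sat)$Y, X, tolerance = 1e-12)
  ## gate = 0 for one channel zeroes it
  off <- par; off$W2[] <- 0; off$b2 <- c(50, 50, -50, 50)
  Y <- se_fwd(X, off)$Y
  expect_equal(max(abs(Y[, , , 3])), 0, tolerance = 1e-10)
  expect_equal(Y[, , , 1], X[, , , 1], tolerance = 1e-10)
  ## random weights: output(c) = input(c) * gate(c), checked against a
  ## scalar reimplementation
  fw <- se_fwd(X, par)
  for (b in 1:2) {
    s <- vapply(1:4, function(ch) mean(X[b, , , ch]), 0)
    a1 <- pmax(s %*% par$W1 + par$b1, 0)
    g <- 1 / (1 + exp(-(a1 %*% par$W2 + par$b2)))
    for (ch in 1:4)
      expect_equal(fw$Y[b, , , ch], X[b, , , ch] * g[ch], tolerance = 1e-12)
  }
})

test_that("weight initialization is a pure function of the seed", {
  m1 <- hrr_model(hrr_tiny_config(), seed = 42)
  m2 <- hrr_model(hrr_tiny_config(), seed = 42)
  m3 <- hrr_model(hrr_tiny_config(), seed = 43)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("forward pass emits probabilities and is batch-consistent", {
  m <- hrr_model(hrr_tiny_config(), seed = 1)
  set.seed(2)
  B <- 5L
  x <- array(runif(B * 64 * 64 * 3), c(B, 64, 64, 3))
  rad <- matrix(rnorm(B * 361), B, 361)
  p <- hrr_forward(m, x, rad)$p
  expect_length(p, B)
  expect_true(all(p > 0 & p < 1))
  ## duplicated case scores identically within one batch
  x2 <- x; x2[2, , , ] <- x[1, , , ]
  rad2 <- rad; rad2[2, ] <- rad[1, ]
  p2 <- hrr_forward(m, x2, rad2)$p
  expect_equal(p2[1], p2[2], tolerance = 1e-12)
  ## wrong radiomics length
  expect_error(hrr_forward(m, x, rad[, 1:100]), "dimension mismatch")
})

test_that("tiny preset is small and fast enough for CPU work", {
  m <- hrr_model(hrr_tiny_config(), seed = 1)
  expect_lt(n_parameters(m), 200000)
  x <- array(runif(64 * 64 * 3), c(1, 64, 64, 3))
  rad <- matrix(0, 1, 361)
  hrr_forward(m, x, rad)  # warm up
  t0 <- proc.time()[["elapsed"]]
  hrr_forward(m, x, rad)
  expect_lt(proc.time()[["elapsed"]] - t0, 0.1)
})

test_that("ablations remove exactly the intended pathway", {
  m <- hrr_model(hrr_tiny_config(), seed = 3)
  set.seed(4)
  x <- array(runif(3 * 64 * 64 * 3), c(3, 64, 64, 3))
  rad <- matrix(rnorm(3 * 361), 3, 361)
  ## no_radiomics: output unchanged under permuted radiomics
  mnr <- ablate(m, "no_radiomics")
  p1 <- hrr_forward(mnr, x, rad)$p
  p2 <- hrr_forward(mnr, x, rad[c(3, 1, 2), ])$p
  expect_equal(p1, p2, tolerance = 1e-12)
  ## the full model does depend on radiomics
  q1 <- hrr_forward(m, x, rad)$p
  q2 <- hrr_forward(m, x, rad[c(3, 1, 2), ])$p
  expect_false(isTRUE(all.equal(q1, q2, tolerance = 1e-6)))
  ## no_se equals forward with all gates forced to 1
  mns <- ablate(m, "no_se")
  msat <- m
  force_gate <- function(se) { se$W2[] <- 0; se$b2[] <- 50; se }
  msat$params$stage1_se <- force_gate(msat$params$stage1_se)
  msat$params$blocks <- lapply(msat$params$blocks, function(b) {
    b$hi_se <- force_gate(b$hi_se); b$lo_se <- force_gate(b$lo_se); b
  })
  expect_equal(hrr_forward(mns, x, rad)$p, hrr_forward(msat, x, rad)$p,
               tolerance = 1e-10)
  expect_error(ablate(m, "no_everything"), "unknown")
})

test_that("analytic gradients match finite differences on sampled weights", {
  set.seed(42)
  cfg <- hrr_tiny_config(input_size = 32L)
  m <- hrr_model(cfg, seed = 7)
  B <- 3L
  x <- array(runif(B * 32 * 32 * 3), c(B, 32, 32, 3))
  rad <- matrix(rnorm(B * 361), B, 361)
  y <- c(1, 0, 1)
  loss_of <- function(model) {
    p <- hrr_forward(model, x, rad)$p
    pt <- ifelse(y == 1, p, 1 - p)
    mean(focal_loss(pt))
  }
  fw <- hrr_forward(m, x, rad, keep_cache = TRUE)
  pt <- ifelse(y == 1, fw$p, 1 - fw$p)
  dz <- dlrs:::.focal_grad(pt) * (2 * y - 1) * fw$p * (1 - fw$p)
  bk <- hrr_backward(m, fw$cache, dz)
  theta <- unlist(m$params)
  grad <- unlist(bk$grads)
  expect_length(grad, length(theta))
  n_check <- max(50L, round(0.01 * length(theta)))
  set.seed(1)
  idx <- sample(length(theta), n_check)
  h <- 1e-5
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    mp <- m; mp$params <- relist(tp, m$params)
    mm <- m; mm$params <- relist(tm, m$params)
    (loss_of(mp) - loss_of(mm)) / (2 * h)
  }, 0)
  rel <- abs(num - grad[idx]) / pmax(abs(grad[idx]), 1e-6)
  expect_lt(max(rel), 1e-4)
})
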