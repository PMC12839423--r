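test_that("an MSLA branch reduces to ReLU at zero weights and matches a direct oracle", {
  set.seed(1)
  br <- nn_msla_branch(8, 3)
  x <- array(rnorm(16 * 16 * 8 * 1), c(16, 16, 8, 1))
  br$children$dw$params$weight[] <- 0
  expect_equal(br$forward(x), pmax(x, 0))
  # shape contract
  set.seed(2)
  br2 <- nn_msla_branch(8, 5)
  expect_equal(dim(br2$forward(x)), dim(x))
  # random weights against the naive sliding-window convolution
  set.seed(3)
  br3 <- nn_msla_branch(4, 7)
  x3 <- array(rnorm(10 * 10 * 4), c(10, 10, 4, 1))
  ref <- droughtvision:::conv2d_direct(x3, br3$children$dw$params$weight,
                                       NULL, 7L, 1L, 3L, 4L)
  expect_equal(br3$forward(x3), pmax(ref + x3, 0), tolerance = 1e-5)
})

test_that("linear attention normalizes softmaxes and matches the naive order", {
  set.seed(4)
  for (trial in 1:10) {
    n <- sample(2:32, 1); d <- sample(c(4, 8, 16), 1)
    tok <- matrix(rnorm(n * d), n, d)
    params <- list(wq = matrix(rnorm(d * d), d), wk = matrix(rnorm(d * d), d),
                   wv = matrix(rnorm(d * d), d), wo = diag(d), heads = 1L)
    la <- linear_attention(tok, params)
    A <- droughtvision:::softmax_rows(tok %*% params$wq)
    B <- droughtvision:::softmax_cols(tok %*% params$wk)
    V <- tok %*% params$wv
    expect_equal(rowSums(A), rep(1, n), tolerance = 1e-9)
    expect_equal(colSums(B), rep(1, d), tolerance = 1e-9)
    # associativity: phi_q(Q) (phi_k(K)^T V) == (phi_q(Q) phi_k(K)^T) V
    naive <- (A %*% t(B)) %*% V
    expect_equal(la$out, naive, tolerance = 1e-5)
    # outputs are convex combinations of the global context rows
    ctx <- crossprod(B, V)
    for (j in seq_len(d)) {
      expect_true(all(la$out[, j] >= min(ctx[, j]) - 1e-9))
      expect_true(all(la$out[, j] <= max(ctx[, j]) + 1e-9))
    }
  }
  # single token: output is its own projected value vector
  d <- 4
  tok1 <- matrix(rnorm(d), 1, d)
  params <- list(wq = diag(d), wk = diag(d), wv = matrix(rnorm(d * d), d),
                 wo = diag(d), heads = 1L)
  la1 <- linear_attention(tok1, params)
  expect_equal(la1$out, tok1 %*% params$wv, tolerance = 1e-9)
  expect_error(linear_attention(tok1, utils::modifyList(params, list(heads = 3L))),
               "divisible")
})

test_that("MSLA preserves shape and is linear in the fusion gates", {
  set.seed(5)
  m <- nn_msla(32)
  x <- array(rnorm(2 * 32 * 8 * 8), c(8, 8, 32, 2))
  y <- m$forward(x)
  expect_equal(dim(y), dim(x))
  # zero branch gates and zero fusion bias kill the output entirely
  m$params$w[] <- 0
  m$children$fuse$params$bias[] <- 0
  expect_equal(m$forward(x), array(0, dim(x)))
  expect_error(nn_msla(6), "divisible")
})

test_that("MSLA forward equals a straight-line re-composition from its parameters", {
  set.seed(6)
  m <- nn_msla(8)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))
  got <- m$forward(x)
  # independent single-function recomposition
  cb <- 2L
  outs <- array(0, c(4, 4, 8, 1))
  kernels <- c(3L, 5L, 7L, 9L)
  for (i in 1:4) {
    chs <- (i - 1L) * cb + seq_len(cb)
    xb <- x[, , chs, , drop = FALSE]
    z <- droughtvision:::conv2d_direct(
      xb, m$children[[i]]$children$dw$params$weight, NULL,
      kernels[i], 1L, kernels[i] %/% 2L, cb)
    xbar <- pmax(z + xb, 0)
    tok <- matrix(xbar, 16, cb)
    A <- droughtvision:::softmax_rows(tok %*% m$params[[paste0("attn", i, "_wq")]])
    B <- droughtvision:::softmax_cols(tok %*% m$params[[paste0("attn", i, "_wk")]])
    V <- tok %*% m$params[[paste0("attn", i, "_wv")]]
    O <- (A %*% crossprod(B, V)) %*% m$params[[paste0("attn", i, "_wo")]]
    outs[, , chs, 1] <- array(O, c(4, 4, cb)) * m$params$w[i]
  }
  fuse_w <- m$children$fuse$params$weight
  fuse_b <- m$children$fuse$params$bias
  ref <- droughtvision:::conv2d_direct(outs, fuse_w, fuse_b, 1L, 1L, 0L, 1L)
  expect_equal(got, ref, tolerance = 1e-5)
})

test_that("CMUNeXt preserves shape and spatial constancy", {
  set.seed(7)
  blk <- nn_cmunext(64, depth = 1)
  x <- array(rnorm(8 * 8 * 64), c(8, 8, 64, 1))
  expect_equal(dim(blk$forward(x)), dim(x))
  # the pointwise stages are spatially invariant: with the depthwise kernel
  # silenced, a per-channel-constant input stays spatially constant
  xc <- array(rep(rnorm(16), each = 36), c(6, 6, 16, 1))
  blk2 <- nn_cmunext(16, depth = 1)
  blk2$children[[1]]$children$dw$params$weight[] <- 0
  y <- blk2$forward(xc)
  spatial_sd <- apply(y, 3, stats::sd)
  expect_true(all(spatial_sd < 1e-9))
  # depth argument stacks units
  expect_equal(count_parameters(nn_cmunext(16, depth = 2)),
               2 * count_parameters(nn_cmunext(16, depth = 1)))
})

test_that("CMUNeXt forward equals an independent staged recomposition", {
  set.seed(8)
  blk <- nn_cmunext(8, depth = 1)
  u <- blk$children[[1]]
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))
  got <- blk$forward(x)
  gelu <- function(z) z * stats::pnorm(z)
  bn <- function(z, gamma, beta) {
    mu <- apply(z, 3, mean)
    v <- apply(z, 3, function(a) mean((a - mean(a))^2))
    sweep(sweep(sweep(sweep(z, 3, mu), 3, sqrt(v + 1e-5), "/"),
                3, gamma, "*"), 3, beta, "+")
  }
  z1 <- droughtvision:::conv2d_direct(x, u$children$dw$params$weight, NULL,
                                      7L, 1L, 3L, 8L) + x
  f1 <- bn(gelu(z1), u$children$bn1$params$gamma, u$children$bn1$params$beta)
  z2 <- droughtvision:::conv2d_direct(f1, u$children$pw1$params$weight, NULL,
                                      1L, 1L, 0L, 1L)
  f2 <- bn(gelu(z2), u$children$bn2$params$gamma, u$children$bn2$params$beta)
  z3 <- droughtvision:::conv2d_direct(f2, u$children$pw2$params$weight, NULL,
                                      1L, 1L, 0L, 1L)
  ref <- bn(gelu(z3), u$children$bn3$params$gamma, u$children$bn3$params$beta)
  expect_equal(got, ref, tolerance = 1e-5)
})

test_that("count_parameters reproduces the printed conv-block rows", {
  expect_equal(count_parameters(nn_conv_block(3, 16, 3, 2)), 464L)
  expect_equal(count_parameters(nn_conv_block(16, 32, 3, 2, 1, 2)), 2368L)
  expect_equal(count_parameters(nn_conv_block(64, 64, 3, 2, 1, 4)), 9344L)
  expect_equal(count_parameters(nn_conv_block(128, 64, 1, 1)), 8320L)
  expect_equal(count_parameters(nn_conv_block(64, 64, 3, 2)), 36992L)
  expect_equal(count_parameters(nn_conv_block(128, 128, 3, 2)), 147712L)
  # depthwise-separable and downsample conventions
  expect_equal(count_parameters(nn_dsconv(128, 128, 3, 2)), 17792L)
  expect_equal(count_parameters(nn_dsconv(128, 256, 3, 2)), 34432L)
  expect_equal(count_parameters(nn_downsample_conv(128)), 33280L)
  expect_equal(count_parameters(nn_fullpad_tunnel()), 1L)
  expect_equal(count_parameters(droughtvision:::nn_upsample()), 0L)
  expect_equal(count_parameters(droughtvision:::nn_concat()), 0L)
})

test_that("residual paths keep gradients alive at zero branch weights", {
  set.seed(9)
  br <- nn_msla_branch(4, 3)
  br$children$dw$params$weight[] <- 0
  droughtvision:::zero_grads(br)
  x <- array(abs(rnorm(6 * 6 * 4)), c(6, 6, 4, 1))  # positive: ReLU active
  y <- br$forward(x)
  dx <- br$backward(array(1, dim(y)))
  expect_true(sum(abs(dx)) > 0)
})

test_that("module backward passes match finite differences on a small block", {
  set.seed(10)
  blk <- nn_conv_block(3, 4, 3, 2)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  droughtvision:::zero_grads(blk)
  y <- blk$forward(x)
  dy <- array(rnorm(length(y)), dim(y))
  dx <- blk$backward(dy)
  eps <- 1e-6
  for (probe in sample(length(x), 5)) {
    xp <- x; xp[probe] <- xp[probe] + eps
    xm <- x; xm[probe] <- xm[probe] - eps
    num <- (sum(blk$forward(xp) * dy) - sum(blk$forward(xm) * dy)) / (2 * eps)
    expect_equal(dx[probe], num, tolerance = 1e-4)
  }
  # weight gradient check
  droughtvision:::zero_grads(blk)
  blk$forward(x); blk$backward(dy)
  w <- blk$children$conv$params$weight
  for (probe in sample(length(w), 5)) {
    blk$children$conv$params$weight[probe] <- w[probe] + eps
    up <- sum(blk$forward(x) * dy)
    blk$children$conv$params$weight[probe] <- w[probe] - eps
    dn <- sum(blk$forward(x) * dy)
    blk$children$conv$params$weight[probe] <- w[probe]
    expect_equal(blk$children$conv$grads$weight[probe], (up - dn) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("MSLA end-to-end gradient matches finite differences", {
  set.seed(11)
  m <- nn_msla(8)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))
  droughtvision:::zero_grads(m)
  y <- m$forward(x)
  dy <- array(rnorm(length(y)), dim(y))
  dx <- m$backward(dy)
  eps <- 1e-6
  for (probe in sample(length(x), 6)) {
    xp <- x; xp[probe] <- xp[probe] + eps
    xm <- x; xm[probe] <- xm[probe] - eps
    num <- (sum(m$forward(xp) * dy) - sum(m$forward(xm) * dy)) / (2 * eps)
    expect_equal(dx[probe], num, tolerance = 1e-3)
  }
})
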