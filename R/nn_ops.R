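#' Feature-map tensor operations
#'
#' Feature maps are 4-D numeric arrays with dimensions
#' `height x width x channels x batch`. Convolutions are computed by
#' offset-slice patch extraction (im2col) followed by a BLAS matrix
#' multiplication; every operation has a matching hand-derived backward pass
#' so small detectors can be trained on the CPU without an external
#' autodifferentiation framework.
#'
#' @name nn-ops
NULL

#' Construct a feature map
#'
#' @param data numeric array `H x W x C x N` (or anything reshapeable).
#' @param dims optional dimensions when `data` is a plain vector.
#' @return the array with class `feature_map`.
#' @export
feature_map <- function(data, dims = NULL) {
  if (!is.null(dims)) dim(data) <- dims
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("a feature map is a 4-D array (H, W, C, N)")
  if (any(!is.finite(data))) stop("feature map contains non-finite values")
  class(data) <- c("feature_map", class(data))
  data
}

zero_pad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  out[p + seq_len(d[1L]), p + seq_len(d[2L]), , ] <- x
  out
}

conv_out_len <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

# Grouped 2-D convolution, forward.
#   x: (H, W, Cin, N); weight: (k*k*Cin/g, Cout) with rows ordered
#   channel-fastest: row = (kj-1)*k*cg + (ki-1)*cg + c_in_within_group.
# Three execution paths share one contract: a reshape+GEMM fast path for
# pointwise (1x1, stride 1, ungrouped) convolutions, k^2 fused multiply-adds
# for depthwise convolutions (groups == c_in == c_out), and the general
# im2col route otherwise.
conv2d_forward <- function(x, weight, bias = NULL, k, stride = 1L, pad = NULL,
                           groups = 1L, keep_patches = FALSE) {
  d <- dim(x)
  if (is.null(pad)) pad <- k %/% 2L
  cin <- d[3L]; n <- d[4L]
  cout <- ncol(weight)
  cg_in <- cin %/% groups; cg_out <- cout %/% groups
  if (cg_in * groups != cin || cg_out * groups != cout)
    stop("channel mismatch: channels not divisible by groups")
  if (k == 1L && stride == 1L && pad == 0L && groups == 1L) {
    xm <- aperm(x, c(1, 2, 4, 3))
    dim(xm) <- c(d[1L] * d[2L] * n, cin)
    O <- xm %*% weight
    if (!is.null(bias)) O <- O + rep(bias, each = nrow(O))
    dim(O) <- c(d[1L], d[2L], n, cout)
    return(aperm(O, c(1, 2, 4, 3)))
  }
  xp <- zero_pad(x, pad)
  ho <- conv_out_len(d[1L], k, stride, pad)
  wo <- conv_out_len(d[2L], k, stride, pad)
  ri0 <- seq.int(1L, by = stride, length.out = ho)
  ci0 <- seq.int(1L, by = stride, length.out = wo)
  if (groups == cin && cg_out == 1L) {        # depthwise
    out <- array(0, c(ho, wo, cin, n))
    for (kj in seq_len(k)) for (ki in seq_len(k)) {
      wv <- weight[(kj - 1L) * k + ki, ]      # one scalar per channel
      sl <- xp[ri0 + (ki - 1L), ci0 + (kj - 1L), , , drop = FALSE]
      out <- out + sl * rep(wv, each = ho * wo)
    }
    if (!is.null(bias)) out <- out + rep(bias, each = ho * wo)
    return(out)
  }
  out <- array(0, c(ho, wo, cout, n))
  Pcache <- if (keep_patches) vector("list", groups) else NULL
  for (g in seq_len(groups)) {
    chs <- (g - 1L) * cg_in + seq_len(cg_in)
    P <- matrix(0, ho * wo * n, k * k * cg_in)
    for (kj in seq_len(k)) for (ki in seq_len(k)) {
      sl <- aperm(xp[ri0 + (ki - 1L), ci0 + (kj - 1L), chs, , drop = FALSE],
                  c(1, 2, 4, 3))
      dim(sl) <- c(ho * wo * n, cg_in)
      P[, (kj - 1L) * k * cg_in + (ki - 1L) * cg_in + seq_len(cg_in)] <- sl
    }
    if (keep_patches) Pcache[[g]] <- P
    W <- weight[, (g - 1L) * cg_out + seq_len(cg_out), drop = FALSE]
    O <- P %*% W                      # (ho*wo*n) x cg_out
    dim(O) <- c(ho, wo, n, cg_out)
    out[, , (g - 1L) * cg_out + seq_len(cg_out), ] <- aperm(O, c(1, 2, 4, 3))
  }
  if (!is.null(bias))
    out <- out + aperm(array(bias, c(cout, ho, wo, n)), c(2, 3, 1, 4))
  if (keep_patches) attr(out, "patches") <- Pcache
  out
}

# Backward pass: returns list(dx, dweight, dbias). Recomputes patches from x.
conv2d_backward <- function(dy, x, weight, k, stride = 1L, pad = NULL,
                            groups = 1L, bias = FALSE, patches = NULL,
                            need_dx = TRUE) {
  d <- dim(x)
  if (is.null(pad)) pad <- k %/% 2L
  cin <- d[3L]; n <- d[4L]
  cout <- ncol(weight)
  cg_in <- cin %/% groups; cg_out <- cout %/% groups
  if (k == 1L && stride == 1L && pad == 0L && groups == 1L) {
    xm <- aperm(x, c(1, 2, 4, 3)); dim(xm) <- c(d[1L] * d[2L] * n, cin)
    dym <- aperm(dy, c(1, 2, 4, 3)); dim(dym) <- c(d[1L] * d[2L] * n, cout)
    dW <- crossprod(xm, dym)
    dxm <- dym %*% t(weight)
    dim(dxm) <- c(d[1L], d[2L], n, cin)
    db <- if (bias) colSums(dym) else NULL
    return(list(dx = aperm(dxm, c(1, 2, 4, 3)), dweight = dW, dbias = db))
  }
  ho <- dim(dy)[1L]; wo <- dim(dy)[2L]
  if (groups == cin && cg_out == 1L) {        # depthwise
    xp <- zero_pad(x, pad)
    ri0 <- seq.int(1L, by = stride, length.out = ho)
    ci0 <- seq.int(1L, by = stride, length.out = wo)
    dxp <- if (need_dx) array(0, dim(xp)) else NULL
    dW <- matrix(0, nrow(weight), ncol(weight))
    for (kj in seq_len(k)) for (ki in seq_len(k)) {
      wv <- weight[(kj - 1L) * k + ki, ]
      sl <- xp[ri0 + (ki - 1L), ci0 + (kj - 1L), , , drop = FALSE]
      prod <- dy * sl
      dim(prod) <- c(ho * wo, cin * n)
      dW[(kj - 1L) * k + ki, ] <- rowSums(matrix(colSums(prod), cin, n))
      if (need_dx)
        dxp[ri0 + (ki - 1L), ci0 + (kj - 1L), , ] <-
          dxp[ri0 + (ki - 1L), ci0 + (kj - 1L), , , drop = FALSE] +
          dy * rep(wv, each = ho * wo)
    }
    dx <- if (!need_dx) NULL
    else if (pad > 0L) dxp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), , ,
                           drop = FALSE] else dxp
    db <- if (bias) apply(dy, 3L, sum) else NULL
    return(list(dx = dx, dweight = dW, dbias = db))
  }
  need_patch_build <- is.null(patches)
  xp <- if (need_patch_build) zero_pad(x, pad) else NULL
  ho <- dim(dy)[1L]; wo <- dim(dy)[2L]
  ri0 <- seq.int(1L, by = stride, length.out = ho)
  ci0 <- seq.int(1L, by = stride, length.out = wo)
  dxp <- if (need_dx) array(0, c(d[1L] + 2L * pad, d[2L] + 2L * pad,
                                 d[3L], d[4L])) else NULL
  dW <- matrix(0, nrow(weight), ncol(weight))
  for (g in seq_len(groups)) {
    chs <- (g - 1L) * cg_in + seq_len(cg_in)
    P <- if (need_patch_build) {
      Pg <- matrix(0, ho * wo * n, k * k * cg_in)
      for (kj in seq_len(k)) for (ki in seq_len(k)) {
        sl <- aperm(xp[ri0 + (ki - 1L), ci0 + (kj - 1L), chs, , drop = FALSE],
                    c(1, 2, 4, 3))
        dim(sl) <- c(ho * wo * n, cg_in)
        Pg[, (kj - 1L) * k * cg_in + (ki - 1L) * cg_in + seq_len(cg_in)] <- sl
      }
      Pg
    } else patches[[g]]
    dOg <- aperm(dy[, , (g - 1L) * cg_out + seq_len(cg_out), , drop = FALSE],
                 c(1, 2, 4, 3))
    dim(dOg) <- c(ho * wo * n, cg_out)
    W <- weight[, (g - 1L) * cg_out + seq_len(cg_out), drop = FALSE]
    dW[, (g - 1L) * cg_out + seq_len(cg_out)] <- crossprod(P, dOg)
    if (need_dx) {
      dP <- dOg %*% t(W)             # (ho*wo*n) x (k*k*cg_in)
      for (kj in seq_len(k)) for (ki in seq_len(k)) {
        blk <- dP[, (kj - 1L) * k * cg_in + (ki - 1L) * cg_in + seq_len(cg_in),
                  drop = FALSE]
        dim(blk) <- c(ho, wo, n, cg_in)
        dxp[ri0 + (ki - 1L), ci0 + (kj - 1L), chs, ] <-
          dxp[ri0 + (ki - 1L), ci0 + (kj - 1L), chs, , drop = FALSE] +
          aperm(blk, c(1, 2, 4, 3))
      }
    }
  }
  dx <- if (!need_dx) NULL
  else if (pad > 0L) dxp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), , ,
                         drop = FALSE]
  else dxp
  db <- if (bias) apply(dy, 3L, sum) else NULL
  list(dx = dx, dweight = dW, dbias = db)
}

# Direct (naive) convolution for oracle checks: same contract, no im2col.
conv2d_direct <- function(x, weight, bias = NULL, k, stride = 1L, pad = NULL,
                          groups = 1L) {
  d <- dim(x)
  if (is.null(pad)) pad <- k %/% 2L
  xp <- zero_pad(x, pad)
  cin <- d[3L]; n <- d[4L]; cout <- ncol(weight)
  cg_in <- cin %/% groups; cg_out <- cout %/% groups
  ho <- conv_out_len(d[1L], k, stride, pad)
  wo <- conv_out_len(d[2L], k, stride, pad)
  out <- array(0, c(ho, wo, cout, n))
  for (b in seq_len(n)) for (oc in seq_len(cout)) {
    g <- (oc - 1L) %/% cg_out + 1L
    chs <- (g - 1L) * cg_in + seq_len(cg_in)
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      acc <- 0
      for (c in seq_along(chs)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
        wrow <- (kj - 1L) * k * cg_in + (ki - 1L) * cg_in + c
        acc <- acc + xp[(i - 1L) * stride + ki, (j - 1L) * stride + kj,
                        chs[c], b] * weight[wrow, oc]
      }
      out[i, j, oc, b] <- acc + if (is.null(bias)) 0 else bias[oc]
    }
  }
  out
}

# ---- batch normalization ----------------------------------------------

# Per-channel sums of an (H, W, C, N) array without permuting or copying it:
# treat the data as an (H*W) x (C*N) matrix, column-sum, fold the batch.
channel_sums <- function(a, hw, c, n) {
  rowSums(matrix(.colSums(a, hw, c * n), c, n))
}

# Expand a length-C vector so elementwise arithmetic recycles it over the
# (H*W, C, N) layout.
per_channel <- function(v, hw) rep(v, each = hw)

batchnorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1L] * d[2L]; c <- d[3L]; n <- d[4L]
  m <- hw * n
  mu <- channel_sums(x, hw, c, n) / m
  xc <- x - per_channel(mu, hw)
  var <- channel_sums(xc^2, hw, c, n) / m
  invstd <- 1 / sqrt(var + eps)
  xhat <- xc * per_channel(invstd, hw)
  y <- xhat * per_channel(gamma, hw) + per_channel(beta, hw)
  list(y = y, xhat = xhat, invstd = invstd, m = m)
}

batchnorm_backward <- function(dy, cache, gamma) {
  d <- dim(dy)
  hw <- d[1L] * d[2L]; c <- d[3L]; n <- d[4L]
  m <- cache$m
  xhat <- cache$xhat
  dgamma <- channel_sums(dy * xhat, hw, c, n)
  dbeta <- channel_sums(dy, hw, c, n)
  dxc <- dy - per_channel(dbeta / m, hw) - xhat * per_channel(dgamma / m, hw)
  dx <- dxc * per_channel(gamma * cache$invstd, hw)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations -------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))
silu <- function(x) x * sigmoid(x)
silu_grad <- function(x) { s <- sigmoid(x); s * (1 + x * (1 - s)) }
relu <- function(x) pmax(x, 0)
relu_grad <- function(x) as.numeric(x > 0)
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

act_fun <- function(kind) switch(kind, silu = silu, relu = relu, gelu = gelu,
                                 identity = identity)
act_grad <- function(kind) switch(kind, silu = silu_grad, relu = relu_grad,
                                  gelu = gelu_grad, identity = function(x) 1)

# ---- resampling --------------------------------------------------------

upsample_nearest <- function(x, scale = 2L) {
  d <- dim(x)
  ri <- rep(seq_len(d[1L]), each = scale)
  ci <- rep(seq_len(d[2L]), each = scale)
  x[ri, ci, , , drop = FALSE]
}

upsample_nearest_backward <- function(dy, scale = 2L) {
  d <- dim(dy)
  h <- d[1L] %/% scale; w <- d[2L] %/% scale
  out <- array(0, c(h, w, d[3L], d[4L]))
  for (i in seq_len(scale)) for (j in seq_len(scale)) {
    out <- out + dy[seq.int(i, by = scale, length.out = h),
                    seq.int(j, by = scale, length.out = w), , , drop = FALSE]
  }
  out
}

avgpool2 <- function(x) {
  d <- dim(x)
  h <- d[1L] %/% 2L; w <- d[2L] %/% 2L
  out <- array(0, c(h, w, d[3L], d[4L]))
  for (i in 1:2) for (j in 1:2) {
    out <- out + x[seq.int(i, by = 2L, length.out = h),
                   seq.int(j, by = 2L, length.out = w), , , drop = FALSE]
  }
  out / 4
}

avgpool2_backward <- function(dy) {
  upsample_nearest(dy, 2L) / 4
}

# ---- softmax helpers (stabilized; used by linear attention) -----------

softmax_rows <- function(s) {
  m <- Reduce(pmax, lapply(seq_len(ncol(s)), function(j) s[, j]))
  e <- exp(s - m)
  e / (rowSums(e) + 1e-12)
}

softmax_cols <- function(s) {
  m <- apply(s, 2L, max)
  e <- exp(sweep(s, 2L, m))
  sweep(e, 2L, colSums(e) + 1e-12, `/`)
}

softmax_rows_backward <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

softmax_cols_backward <- function(p, dp) {
  p * sweep(dp, 2L, colSums(dp * p))
}
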