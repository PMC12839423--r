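#' Network blocks with forward/backward passes
#'
#' Every block is a mutable module environment with `$forward(x)` and
#' `$backward(dy)` closures, named parameter arrays in `$params`, matching
#' gradient accumulators in `$grads`, and nested blocks in `$children`.
#' Convolution blocks follow the convention of convolution WITHOUT bias
#' followed by batch normalization with learnable scale and shift (2
#' parameters per channel; running statistics are not trainable and are not
#' counted).
#'
#' @name nn-blocks
NULL

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- list()
  m$grads <- list()
  m$children <- list()
  class(m) <- "nn_module"
  m
}

#' @export
print.nn_module <- function(x, ...) {
  cat(sprintf("<%s: %s trainable parameters>\n", x$type,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable scalars in a module
#'
#' Counts convolution weights, optional biases and batch-norm scale/shift,
#' recursively over nested blocks; batch-norm running statistics are
#' excluded. Can also count directly from a Table-style block spec via
#' [build_block()].
#'
#' @param module an `nn_module`.
#' @return integer count.
#' @examples
#' count_parameters(nn_conv_block(3, 16, 3, 2))   # 464
#' @export
count_parameters <- function(module) {
  stopifnot(inherits(module, "nn_module"))
  own <- sum(vapply(module$params, length, numeric(1)))
  sub <- sum(vapply(module$children, count_parameters, numeric(1)))
  as.integer(own + sub)
}

# depth-first walk over all modules (self + descendants)
module_walk <- function(module, fn) {
  fn(module)
  for (ch in module$children) module_walk(ch, fn)
  invisible(NULL)
}

zero_grads <- function(module) {
  module_walk(module, function(m) {
    m$grads <- lapply(m$params, function(p) p * 0)  # shape-preserving zeros
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# He-uniform initialization for a fan-in
init_weight <- function(nrow, ncol, fan_in) {
  bound <- sqrt(6 / fan_in)
  matrix(stats::runif(nrow * ncol, -bound, bound), nrow, ncol)
}

# ---- primitive modules -------------------------------------------------

#' Bare 2-D convolution module
#'
#' @param c_in,c_out channel counts; `c_in` divisible by `groups`.
#' @param k kernel side; `stride`, `pad` (default `k %/% 2`), `groups` as in
#'   the usual convolution contract; `bias` adds one scalar per output
#'   channel.
#' @return an `nn_module`.
#' @keywords internal
nn_conv2d <- function(c_in, c_out, k, stride = 1L, pad = NULL, groups = 1L,
                      bias = FALSE) {
  if (c_in %% groups != 0 || c_out %% groups != 0)
    stop("channel mismatch: c_in and c_out must be divisible by groups")
  if (is.null(pad)) pad <- k %/% 2L
  m <- new_module("conv2d")
  cg <- c_in %/% groups
  m$k <- as.integer(k); m$stride <- as.integer(stride)
  m$pad <- as.integer(pad); m$groups <- as.integer(groups)
  m$c_in <- c_in; m$c_out <- c_out
  m$params$weight <- init_weight(k * k * cg, c_out, fan_in = k * k * cg)
  if (bias) m$params$bias <- numeric(c_out)
  m$need_input_grad <- TRUE
  m$forward <- function(x) {
    m$cache_x <- x
    out <- conv2d_forward(x, m$params$weight, m$params$bias, m$k, m$stride,
                          m$pad, m$groups, keep_patches = TRUE)
    m$cache_P <- attr(out, "patches")
    attr(out, "patches") <- NULL
    out
  }
  m$backward <- function(dy) {
    bk <- conv2d_backward(dy, m$cache_x, m$params$weight, m$k, m$stride,
                          m$pad, m$groups, bias = !is.null(m$params$bias),
                          patches = m$cache_P, need_dx = m$need_input_grad)
    m$grads$weight <- m$grads$weight + bk$dweight
    if (!is.null(bk$dbias)) m$grads$bias <- m$grads$bias + bk$dbias
    m$cache_x <- NULL
    m$cache_P <- NULL
    bk$dx
  }
  m
}

nn_batchnorm <- function(c) {
  m <- new_module("batchnorm")
  m$params$gamma <- rep(1, c)
  m$params$beta <- rep(0, c)
  m$forward <- function(x) {
    fw <- batchnorm_forward(x, m$params$gamma, m$params$beta)
    m$cache <- fw[c("xhat", "invstd", "m")]
    fw$y
  }
  m$backward <- function(dy) {
    bk <- batchnorm_backward(dy, m$cache, m$params$gamma)
    m$grads$gamma <- m$grads$gamma + bk$dgamma
    m$grads$beta <- m$grads$beta + bk$dbeta
    m$cache <- NULL
    bk$dx
  }
  m
}

nn_activation <- function(kind) {
  m <- new_module(paste0("act_", kind))
  f <- act_fun(kind); g <- act_grad(kind)
  m$forward <- function(x) { m$cache_x <- x; f(x) }
  m$backward <- function(dy) { dx <- dy * g(m$cache_x); m$cache_x <- NULL; dx }
  m
}

nn_sequential <- function(...) {
  m <- new_module("sequential")
  m$children <- list(...)
  m$forward <- function(x) {
    for (ch in m$children) x <- ch$forward(x)
    x
  }
  m$backward <- function(dy) {
    for (ch in rev(m$children)) dy <- ch$backward(dy)
    dy
  }
  m
}

#' Standard convolution block: conv (no bias) + batch norm + SiLU
#'
#' The block whose trainable-scalar count is
#' `c_in/groups * k^2 * c_out + 2 * c_out`.
#'
#' @param c_in,c_out,k,stride,pad,groups convolution geometry; `pad` defaults
#'   to `k %/% 2` (same padding for odd kernels).
#' @param act activation kind (default `"silu"`).
#' @return an `nn_module`.
#' @examples
#' count_parameters(nn_conv_block(16, 32, 3, 2, 1, 2))  # 2368
#' @export
nn_conv_block <- function(c_in, c_out, k = 1L, stride = 1L, pad = NULL,
                          groups = 1L, act = "silu") {
  m <- new_module("conv_block")
  m$children <- list(conv = nn_conv2d(c_in, c_out, k, stride, pad, groups),
                     bn = nn_batchnorm(c_out),
                     act = nn_activation(act))
  m$forward <- function(x)
    m$children$act$forward(m$children$bn$forward(m$children$conv$forward(x)))
  m$backward <- function(dy)
    m$children$conv$backward(m$children$bn$backward(m$children$act$backward(dy)))
  m
}

#' Depthwise-separable convolution block
#'
#' Depthwise `k x k` convolution (one filter per channel, no bias, no
#' normalization) followed by a pointwise 1x1 convolution with batch norm and
#' SiLU; parameter count `c_in*k^2 + c_in*c_out + 2*c_out`.
#'
#' @inheritParams nn_conv_block
#' @return an `nn_module`.
#' @export
nn_dsconv <- function(c_in, c_out, k = 3L, stride = 1L) {
  m <- new_module("dsconv")
  m$children <- list(
    dw = nn_conv2d(c_in, c_in, k, stride, groups = c_in),
    pw = nn_conv_block(c_in, c_out, 1L))
  m$forward <- function(x) m$children$pw$forward(m$children$dw$forward(x))
  m$backward <- function(dy) m$children$dw$backward(m$children$pw$backward(dy))
  m
}

# ---- multi-scale linear attention (MSLA) ------------------------------

#' One MSLA depthwise branch: `ReLU(dwconv_k(X) + X)`
#'
#' Same-padded depthwise convolution of one channel block with residual
#' addition and ReLU. The four branches of MSLA use kernels 3, 5, 7, 9.
#'
#' @param channels branch channel count.
#' @param kernel odd kernel side, one of 3/5/7/9 in the full block.
#' @return an `nn_module`.
#' @export
nn_msla_branch <- function(channels, kernel) {
  if (kernel %% 2L != 1L) stop("branch kernel must be odd")
  m <- new_module("msla_branch")
  m$children <- list(dw = nn_conv2d(channels, channels, kernel,
                                    groups = channels))
  m$forward <- function(x) {
    z <- m$children$dw$forward(x) + x
    m$cache_z <- z
    relu(z)
  }
  m$backward <- function(dy) {
    dz <- dy * relu_grad(m$cache_z)
    m$cache_z <- NULL
    m$children$dw$backward(dz) + dz
  }
  m
}

#' Linear attention over a token sequence
#'
#' Computes, per head, `O = phi_q(Q) (phi_k(K)^T V)` with `phi_q` a row-wise
#' softmax over `Q` and `phi_k` a column-wise softmax over `K`; the global
#' context `phi_k(K)^T V` is a `d x d` matrix, so no `N x N` attention matrix
#' is ever materialized. Heads are concatenated and linearly mapped.
#'
#' @param tokens `N x d` matrix.
#' @param params list with projection matrices `wq`, `wk`, `wv`, `wo` (each
#'   `d x d`) and `heads`.
#' @return list with `out` (`N x d`) and a cache for the backward pass.
#' @export
linear_attention <- function(tokens, params) {
  d <- ncol(tokens)
  h <- params$heads %||% 1L
  if (d %% h != 0) stop("token width not divisible by head count")
  dh <- d %/% h
  Q <- tokens %*% params$wq
  K <- tokens %*% params$wk
  V <- tokens %*% params$wv
  O <- matrix(0, nrow(tokens), d)
  hc <- vector("list", h)
  for (i in seq_len(h)) {
    ix <- (i - 1L) * dh + seq_len(dh)
    A <- softmax_rows(Q[, ix, drop = FALSE])
    B <- softmax_cols(K[, ix, drop = FALSE])
    ctx <- crossprod(B, V[, ix, drop = FALSE])   # dh x dh global context
    O[, ix] <- A %*% ctx
    hc[[i]] <- list(A = A, B = B, ctx = ctx)
  }
  out <- O %*% params$wo
  list(out = out,
       cache = list(tokens = tokens, Q = Q, K = K, V = V, O = O, heads = hc,
                    h = h, dh = dh))
}

linear_attention_backward <- function(dout, params, cache) {
  tokens <- cache$tokens
  dO <- dout %*% t(params$wo)
  dwo <- crossprod(cache$O, dout)
  dQ <- matrix(0, nrow(tokens), ncol(tokens))
  dK <- dQ; dV <- dQ
  for (i in seq_len(cache$h)) {
    ix <- (i - 1L) * cache$dh + seq_len(cache$dh)
    hc <- cache$heads[[i]]
    dOi <- dO[, ix, drop = FALSE]
    dA <- dOi %*% t(hc$ctx)
    dctx <- crossprod(hc$A, dOi)
    dB <- cache$V[, ix, drop = FALSE] %*% t(dctx)
    dV[, ix] <- hc$B %*% dctx
    dQ[, ix] <- softmax_rows_backward(hc$A, dA)
    dK[, ix] <- softmax_cols_backward(hc$B, dB)
  }
  dwq <- crossprod(tokens, dQ)
  dwk <- crossprod(tokens, dK)
  dwv <- crossprod(tokens, dV)
  dtokens <- dQ %*% t(params$wq) + dK %*% t(params$wk) + dV %*% t(params$wv)
  list(dtokens = dtokens, dwq = dwq, dwk = dwk, dwv = dwv, dwo = dwo)
}

#' Multi-scale linear attention block
#'
#' Splits the input into four channel blocks; each passes through a
#' depthwise branch ([nn_msla_branch()]) with kernel 3/5/7/9, is flattened to
#' a token sequence (one token per spatial position) and run through
#' [linear_attention()], then reshaped back. The four branch outputs,
#' individually scaled by learnable weights `w1..w4` (initialized to 1), are
#' concatenated along channels and fused by a 1x1 convolution. Shape
#' preserving for any input with `channels` divisible by 4.
#'
#' @param channels input/output channel count, divisible by 4.
#' @param heads attention heads per branch (default 1, head dim =
#'   `channels/4`).
#' @return an `nn_module`.
#' @export
nn_msla <- function(channels, heads = 1L) {
  if (channels < 4L || channels %% 4L != 0L)
    stop("MSLA needs channels divisible by 4")
  cb <- channels %/% 4L
  m <- new_module("msla")
  kernels <- c(3L, 5L, 7L, 9L)
  branches <- lapply(kernels, function(k) nn_msla_branch(cb, k))
  names(branches) <- paste0("branch", 1:4)
  m$children <- c(branches, list(fuse = nn_conv2d(channels, channels, 1L,
                                                  bias = TRUE)))
  m$params$w <- rep(1, 4)
  for (i in 1:4) {
    ap <- list(
      wq = init_weight(cb, cb, cb), wk = init_weight(cb, cb, cb),
      wv = init_weight(cb, cb, cb), wo = init_weight(cb, cb, cb),
      heads = heads)
    m$params[[paste0("attn", i, "_wq")]] <- ap$wq
    m$params[[paste0("attn", i, "_wk")]] <- ap$wk
    m$params[[paste0("attn", i, "_wv")]] <- ap$wv
    m$params[[paste0("attn", i, "_wo")]] <- ap$wo
  }
  m$heads <- as.integer(heads)
  m$cb <- cb
  m$forward <- function(x) {
    d <- dim(x)
    n <- d[4L]
    outs <- array(0, c(d[1L], d[2L], 4L * cb, n))
    m$cache <- list(dims = d, attn = vector("list", 4L))
    for (i in 1:4) {
      chs <- (i - 1L) * cb + seq_len(cb)
      xb <- x[, , chs, , drop = FALSE]
      xb <- m$children[[i]]$forward(xb)
      ac <- vector("list", n)
      ob <- array(0, dim(xb))
      ap <- list(wq = m$params[[paste0("attn", i, "_wq")]],
                 wk = m$params[[paste0("attn", i, "_wk")]],
                 wv = m$params[[paste0("attn", i, "_wv")]],
                 wo = m$params[[paste0("attn", i, "_wo")]],
                 heads = m$heads)
      for (b in seq_len(n)) {
        tok <- xb[, , , b]
        dim(tok) <- c(d[1L] * d[2L], cb)
        la <- linear_attention(tok, ap)
        ac[[b]] <- la$cache
        dim(la$out) <- c(d[1L], d[2L], cb)
        ob[, , , b] <- la$out
      }
      m$cache$attn[[i]] <- ac
      m$cache[[paste0("ob", i)]] <- ob
      outs[, , chs, ] <- m$params$w[i] * ob
    }
    m$children$fuse$forward(outs)
  }
  m$backward <- function(dy) {
    douts <- m$children$fuse$backward(dy)
    d <- m$cache$dims
    n <- d[4L]
    dx <- array(0, d)
    for (i in 1:4) {
      chs <- (i - 1L) * cb + seq_len(cb)
      dob_scaled <- douts[, , chs, , drop = FALSE]
      ob <- m$cache[[paste0("ob", i)]]
      m$grads$w[i] <- m$grads$w[i] + sum(dob_scaled * ob)
      dob <- m$params$w[i] * dob_scaled
      ap <- list(wq = m$params[[paste0("attn", i, "_wq")]],
                 wk = m$params[[paste0("attn", i, "_wk")]],
                 wv = m$params[[paste0("attn", i, "_wv")]],
                 wo = m$params[[paste0("attn", i, "_wo")]],
                 heads = m$heads)
      dxb <- array(0, c(d[1L], d[2L], cb, n))
      for (b in seq_len(n)) {
        dtok <- dob[, , , b]
        dim(dtok) <- c(d[1L] * d[2L], cb)
        bk <- linear_attention_backward(dtok, ap, m$cache$attn[[i]][[b]])
        for (nm in c("wq", "wk", "wv", "wo")) {
          key <- paste0("attn", i, "_", nm)
          m$grads[[key]] <- m$grads[[key]] + bk[[paste0("d", nm)]]
        }
        dt <- bk$dtokens
        dim(dt) <- c(d[1L], d[2L], cb)
        dxb[, , , b] <- dt
      }
      dx[, , chs, ] <- m$children[[i]]$backward(dxb)
    }
    m$cache <- NULL
    dx
  }
  m
}

# ---- CMUNeXt block -----------------------------------------------------

#' CMUNeXt block: residual large-kernel depthwise stage + pointwise MLP
#'
#' One unit computes `f' = BN(GELU(dwconv_k(f) + f))`, then
#' `f'' = BN(GELU(pw(C -> E)))`, then `f_out = BN(GELU(pw(E -> C)))`; the
#' depthwise stage integrates long-range spatial structure per channel, the
#' 1x1 pointwise pair expands to a wider channel space and compresses back.
#' `depth` units are stacked. Shape preserving.
#'
#' @param channels channel count C.
#' @param depth number of stacked units (Table-style third argument).
#' @param kernel depthwise kernel side (default 7).
#' @param expansion expansion factor E/C (default 4).
#' @return an `nn_module`.
#' @export
nn_cmunext <- function(channels, depth = 1L, kernel = 7L, expansion = 4L) {
  e <- channels * expansion
  unit <- function() {
    u <- new_module("cmunext_unit")
    u$children <- list(
      dw = nn_conv2d(channels, channels, kernel, groups = channels),
      bn1 = nn_batchnorm(channels),
      pw1 = nn_conv2d(channels, e, 1L),
      bn2 = nn_batchnorm(e),
      pw2 = nn_conv2d(e, channels, 1L),
      bn3 = nn_batchnorm(channels))
    u$forward <- function(x) {
      z1 <- u$children$dw$forward(x) + x
      u$cz1 <- z1
      f1 <- u$children$bn1$forward(gelu(z1))
      z2 <- u$children$pw1$forward(f1)
      u$cz2 <- z2
      f2 <- u$children$bn2$forward(gelu(z2))
      z3 <- u$children$pw2$forward(f2)
      u$cz3 <- z3
      u$children$bn3$forward(gelu(z3))
    }
    u$backward <- function(dy) {
      dz3 <- u$children$bn3$backward(dy) * gelu_grad(u$cz3)
      df2 <- u$children$pw2$backward(dz3)
      dz2 <- u$children$bn2$backward(df2) * gelu_grad(u$cz2)
      df1 <- u$children$pw1$backward(dz2)
      dz1 <- u$children$bn1$backward(df1) * gelu_grad(u$cz1)
      u$cz1 <- u$cz2 <- u$cz3 <- NULL
      u$children$dw$backward(dz1) + dz1
    }
    u
  }
  units <- lapply(seq_len(depth), function(i) unit())
  do.call(nn_sequential, units)
}

# ---- C3k2 with MSLA interior ------------------------------------------

#' C3k2-style block with a multi-scale linear attention interior
#'
#' A 1x1 convolution expands the input to two hidden chunks; the second chunk
#' passes through a residual MSLA unit; the three streams (both chunks plus
#' the attended one) are concatenated and projected by a second 1x1
#' convolution.
#'
#' @param c_in,c_out channel counts.
#' @param n interior repeats (Table-style; 1 throughout the printed layout).
#' @param c3k shortcut-flag argument kept for Table compatibility (the
#'   interior is always the MSLA unit here).
#' @param e hidden-width fraction: hidden = `round(c_out * e)`, forced to a
#'   multiple of 4 for the MSLA split.
#' @return an `nn_module`.
#' @export
nn_c3k2_msla <- function(c_in, c_out, n = 1L, c3k = FALSE, e = 0.5) {
  ch <- as.integer(round(c_out * e))
  ch <- max(4L, (ch %/% 4L) * 4L)
  m <- new_module("c3k2_msla")
  interior <- lapply(seq_len(n), function(i) nn_msla(ch))
  names(interior) <- paste0("msla", seq_len(n))
  m$children <- c(list(cv1 = nn_conv_block(c_in, 2L * ch, 1L)),
                  interior,
                  list(cv2 = nn_conv_block(3L * ch, c_out, 1L)))
  m$ch <- ch; m$n <- n
  m$forward <- function(x) {
    y <- m$children$cv1$forward(x)
    ch <- m$ch
    y2 <- y[, , ch + seq_len(ch), , drop = FALSE]
    z <- y2
    for (i in seq_len(m$n)) z <- m$children[[paste0("msla", i)]]$forward(z) + z
    d <- dim(y)
    out <- array(0, c(d[1L], d[2L], 3L * ch, d[4L]))
    out[, , seq_len(2L * ch), ] <- y
    out[, , 2L * ch + seq_len(ch), ] <- z
    m$children$cv2$forward(out)
  }
  m$backward <- function(dy) {
    dcat <- m$children$cv2$backward(dy)
    ch <- m$ch
    dy12 <- dcat[, , seq_len(2L * ch), , drop = FALSE]
    dz <- dcat[, , 2L * ch + seq_len(ch), , drop = FALSE]
    for (i in rev(seq_len(m$n)))
      dz <- m$children[[paste0("msla", i)]]$backward(dz) + dz
    dy12[, , ch + seq_len(ch), ] <- dy12[, , ch + seq_len(ch), , drop = FALSE] + dz
    m$children$cv1$backward(dy12)
  }
  m
}

# ---- assembly helper modules ------------------------------------------

#' Gated feature merge with a single learnable scalar
#'
#' `out = x1 + g * x2` with `g` initialized to 0; exactly one trainable
#' parameter, and the identity path guarantees gradient flow at
#' initialization.
#'
#' @return an `nn_module` whose `forward` takes a list of two same-shape
#'   feature maps.
#' @export
nn_fullpad_tunnel <- function() {
  m <- new_module("fullpad_tunnel")
  m$params$gate <- 0
  m$forward <- function(xs) {
    m$cache_x2 <- xs[[2L]]
    xs[[1L]] + m$params$gate * xs[[2L]]
  }
  m$backward <- function(dy) {
    m$grads$gate <- m$grads$gate + sum(dy * m$cache_x2)
    dx2 <- m$params$gate * dy
    m$cache_x2 <- NULL
    list(dy, dx2)
  }
  m
}

#' Channel-doubling downsample block
#'
#' Stride-2 average pooling (parameter free) followed by a 1x1
#' conv-batchnorm block doubling the channels: `c^2*2 + 4c` parameters.
#'
#' @param c input channel count (output has `2c`).
#' @return an `nn_module`.
#' @export
nn_downsample_conv <- function(c) {
  m <- new_module("downsample_conv")
  m$children <- list(pw = nn_conv_block(c, 2L * c, 1L))
  m$forward <- function(x) m$children$pw$forward(avgpool2(x))
  m$backward <- function(dy) avgpool2_backward(m$children$pw$backward(dy))
  m
}

nn_upsample <- function(scale = 2L) {
  m <- new_module("upsample")
  m$scale <- as.integer(scale)
  m$forward <- function(x) upsample_nearest(x, m$scale)
  m$backward <- function(dy) upsample_nearest_backward(dy, m$scale)
  m
}

nn_concat <- function() {
  m <- new_module("concat")
  m$forward <- function(xs) {
    m$cache_ch <- vapply(xs, function(x) dim(x)[3L], integer(1))
    d1 <- dim(xs[[1L]])
    out <- array(0, c(d1[1L], d1[2L], sum(m$cache_ch), d1[4L]))
    at <- 0L
    for (x in xs) {
      out[, , at + seq_len(dim(x)[3L]), ] <- x
      at <- at + dim(x)[3L]
    }
    out
  }
  m$backward <- function(dy) {
    at <- 0L
    out <- vector("list", length(m$cache_ch))
    for (i in seq_along(m$cache_ch)) {
      out[[i]] <- dy[, , at + seq_len(m$cache_ch[i]), , drop = FALSE]
      at <- at + m$cache_ch[i]
    }
    out
  }
  m
}

#' Cross-scale aggregation block
#'
#' Package-defined stand-in for the hypergraph correlation-enhancement stage:
#' three pyramid inputs (strides 8/16/32) are brought to the middle scale
#' (average pooling / nearest upsampling), concatenated, projected by a 1x1
#' conv block, and modulated by a global channel gate (squeeze-excitation
#' style) that redistributes globally pooled evidence across channels.
#'
#' @param ch_in length-3 channel counts of the three inputs.
#' @param c_out output channels (at the middle scale).
#' @return an `nn_module` taking a list of three feature maps.
#' @export
nn_hyperace <- function(ch_in, c_out) {
  m <- new_module("hyperace")
  ctot <- sum(ch_in)
  cr <- max(8L, c_out %/% 4L)
  m$children <- list(cat = nn_concat(),
                     proj = nn_conv_block(ctot, c_out, 1L),
                     sq1 = nn_conv2d(c_out, cr, 1L, bias = TRUE),
                     sq2 = nn_conv2d(cr, c_out, 1L, bias = TRUE))
  m$forward <- function(xs) {
    m$cache_dims <- lapply(xs, dim)
    z <- list(avgpool2(xs[[1L]]), xs[[2L]], upsample_nearest(xs[[3L]], 2L))
    y <- m$children$proj$forward(m$children$cat$forward(z))
    d <- dim(y)
    # global average pool -> bottleneck -> sigmoid gate per channel
    gp <- apply(y, c(3L, 4L), mean)
    dim(gp) <- c(1L, 1L, d[3L], d[4L])
    m$cache_gp_in <- gp
    h <- m$children$sq1$forward(gp)
    m$cache_h <- h
    gate <- stats::plogis(m$children$sq2$forward(relu(h)))
    m$cache_y <- y
    m$cache_gate <- gate
    y * aperm(array(gate[1L, 1L, , ], c(d[3L], d[4L], d[1L], d[2L])), c(3, 4, 1, 2))
  }
  m$backward <- function(dy) {
    d <- dim(m$cache_y)
    gate_full <- aperm(array(m$cache_gate[1L, 1L, , ], c(d[3L], d[4L], d[1L], d[2L])),
                       c(3, 4, 1, 2))
    dy_y <- dy * gate_full
    dgate <- apply(dy * m$cache_y, c(3L, 4L), sum)
    dim(dgate) <- c(1L, 1L, d[3L], d[4L])
    dsig <- dgate * m$cache_gate * (1 - m$cache_gate)
    dh <- m$children$sq2$backward(dsig) * relu_grad(m$cache_h)
    dgp <- m$children$sq1$backward(dh)
    # spread the pooled gradient back over positions
    dy_y <- dy_y + aperm(array(dgp[1L, 1L, , ] / (d[1L] * d[2L]),
                               c(d[3L], d[4L], d[1L], d[2L])), c(3, 4, 1, 2))
    dz <- m$children$cat$backward(m$children$proj$backward(dy_y))
    m$cache_y <- m$cache_gate <- m$cache_h <- m$cache_gp_in <- NULL
    list(avgpool2_backward(dz[[1L]]), dz[[2L]],
         upsample_nearest_backward(dz[[3L]], 2L))
  }
  m
}

#' Residual aggregation block (A2C2f-style stand-in)
#'
#' Package-defined stand-in for the area-attention aggregation block of the
#' base network: 1x1 projection, `n` residual 3x3 conv units, 1x1 output
#' projection.
#'
#' @param c_in,c_out channel counts; `n` residual units.
#' @return an `nn_module`.
#' @export
nn_a2c2f <- function(c_in, c_out, n = 1L) {
  ch <- max(16L, c_out %/% 2L)
  m <- new_module("a2c2f")
  units <- lapply(seq_len(n), function(i) nn_conv_block(ch, ch, 3L))
  names(units) <- paste0("unit", seq_len(n))
  m$children <- c(list(cv1 = nn_conv_block(c_in, ch, 1L)), units,
                  list(cv2 = nn_conv_block(ch, c_out, 1L)))
  m$n <- n
  m$forward <- function(x) {
    z <- m$children$cv1$forward(x)
    for (i in seq_len(m$n)) z <- m$children[[paste0("unit", i)]]$forward(z) + z
    m$children$cv2$forward(z)
  }
  m$backward <- function(dy) {
    dz <- m$children$cv2$backward(dy)
    for (i in rev(seq_len(m$n)))
      dz <- m$children[[paste0("unit", i)]]$backward(dz) + dz
    m$children$cv1$backward(dz)
  }
  m
}

#' Anchor-free detection head
#'
#' Per pyramid scale: a 3x3 conv block followed by a biased 1x1 convolution
#' emitting `4 + n_classes` maps (box offsets `tx, ty` and log-sizes
#' `tw, th`, then class logits).
#'
#' @param nc number of classes.
#' @param ch_in channel counts of the incoming scales.
#' @return an `nn_module` taking/returning a list of feature maps.
#' @export
nn_detect <- function(nc, ch_in) {
  m <- new_module("detect")
  m$nc <- as.integer(nc)
  heads <- list()
  for (i in seq_along(ch_in)) {
    heads[[paste0("stem", i)]] <- nn_conv_block(ch_in[i], ch_in[i], 3L)
    heads[[paste0("out", i)]] <- nn_conv2d(ch_in[i], 4L + nc, 1L, bias = TRUE)
  }
  m$children <- heads
  m$forward <- function(xs) {
    lapply(seq_along(xs), function(i)
      m$children[[paste0("out", i)]]$forward(
        m$children[[paste0("stem", i)]]$forward(xs[[i]])))
  }
  m$backward <- function(dys) {
    lapply(seq_along(dys), function(i)
      m$children[[paste0("stem", i)]]$backward(
        m$children[[paste0("out", i)]]$backward(dys[[i]])))
  }
  m
}
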