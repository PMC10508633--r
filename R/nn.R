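# Minimal convolutional-network engine used by the adversarial model.
#
# Tensors are numeric arrays with dim c(C, H, W) (channel fastest). All
# convolutions go through precomputed im2col gather indices plus BLAS matrix
# multiplies; transposed convolution reuses the same index map in the scatter
# direction. Everything is deterministic given the R RNG state.

.im2col_cache <- new.env(parent = emptyenv())

# gather-index matrix (C*k*k) x (Ho*Wo) into a (C,H,W) vector; 0 marks padding
im2col_idx <- function(C, H, W, k, stride, pad) {
  key <- paste(C, H, W, k, stride, pad, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (W + 2 * pad - k) %/% stride + 1L
  oh <- rep(seq_len(Ho), times = Wo)
  ow <- rep(seq_len(Wo), each = Ho)
  h0 <- (oh - 1L) * stride - pad
  w0 <- (ow - 1L) * stride - pad
  kk <- expand.grid(c = seq_len(C), kh = seq_len(k), kw = seq_len(k))
  hh <- outer(kk$kh, h0, "+")
  ww <- outer(kk$kw, w0, "+")
  cc <- matrix(kk$c, nrow(kk), Ho * Wo)
  inside <- hh >= 1 & hh <= H & ww >= 1 & ww <= W
  idx <- ifelse(inside, cc + C * (hh - 1) + C * H * (ww - 1), 0L)
  storage.mode(idx) <- "integer"
  out <- list(idx = idx, Ho = Ho, Wo = Wo, n_in = C * H * W)
  assign(key, out, envir = .im2col_cache)
  out
}

im2col <- function(x, cache) {
  cpp_gather(x, cache$idx)
}

col2im <- function(cols, cache) {
  cpp_scatter_add(cols, cache$idx, cache$n_in)
}

nn_init_conv <- function(c_in, c_out, k = 4) {
  list(W = matrix(stats::rnorm(c_out * c_in * k * k, 0, 0.02), c_out),
       b = numeric(c_out))
}

# transposed conv stores the weight of the *equivalent* forward conv
# (mapping the larger output back to the input): rows c_in, cols c_out*k*k
nn_init_tconv <- function(c_in, c_out, k = 4) {
  list(W = matrix(stats::rnorm(c_in * c_out * k * k, 0, 0.02), c_in),
       b = numeric(c_out))
}

nn_init_bn <- function(c) {
  list(gamma = stats::rnorm(c, 1, 0.02), beta = numeric(c))
}

conv_fwd <- function(par, x, k, stride, pad) {
  d <- dim(x)
  cache <- im2col_idx(d[1], d[2], d[3], k, stride, pad)
  X <- im2col(x, cache)
  out <- par$W %*% X + par$b
  list(out = array(out, c(nrow(par$W), cache$Ho, cache$Wo)),
       ctx = list(X = X, cache = cache, dims = d))
}

conv_bwd <- function(par, dout, ctx) {
  dmat <- matrix(dout, nrow(par$W))
  dW <- tcrossprod(dmat, ctx$X)
  db <- rowSums(dmat)
  dx <- col2im(crossprod(par$W, dmat), ctx$cache)
  list(dW = dW, db = db, dx = array(dx, ctx$dims))
}

tconv_fwd <- function(par, x, k = 4, stride = 2, pad = 1) {
  d <- dim(x)
  c_out <- length(par$b)
  Ho <- d[2] * stride
  Wo <- d[3] * stride
  cache <- im2col_idx(c_out, Ho, Wo, k, stride, pad)
  xmat <- matrix(x, d[1])
  cols <- crossprod(par$W, xmat)          # (c_out*k*k) x (H*W)
  y <- array(col2im(cols, cache), c(c_out, Ho, Wo))
  y <- y + rep(par$b, times = Ho * Wo)    # dim 1 is channels
  list(out = y, ctx = list(xmat = xmat, cache = cache, dims = d))
}

tconv_bwd <- function(par, dout, ctx) {
  dcols <- im2col(dout, ctx$cache)
  dx <- par$W %*% dcols
  dW <- tcrossprod(ctx$xmat, dcols)
  db <- rowSums(matrix(dout, dim(dout)[1]))
  list(dW = dW, db = db, dx = array(dx, ctx$dims))
}

bn_fwd <- function(par, x, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  mu <- rowMeans(xm)
  v <- rowMeans(xm^2) - mu^2
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * istd
  y <- par$gamma * xhat + par$beta
  list(out = array(y, d), ctx = list(xhat = xhat, istd = istd, dims = d))
}

bn_bwd <- function(par, dout, ctx) {
  d <- ctx$dims
  dy <- matrix(dout, d[1])
  m <- ncol(dy)
  dgamma <- rowSums(dy * ctx$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * par$gamma
  dx <- (ctx$istd / m) * (m * dxhat - rowSums(dxhat) -
                            ctx$xhat * rowSums(dxhat * ctx$xhat))
  list(dgamma = dgamma, dbeta = dbeta, dx = array(dx, d))
}

lrelu_fwd <- function(x, slope = 0.2) {
  out <- cpp_lrelu(x, slope)
  dim(out) <- dim(x)
  list(out = out, ctx = list(x = x, slope = slope))
}
lrelu_bwd <- function(dout, ctx) {
  dx <- cpp_lrelu_grad(dout, ctx$x, ctx$slope)
  dim(dx) <- dim(dout)
  dx
}

relu_fwd <- function(x) {
  out <- cpp_lrelu(x, 0)
  dim(out) <- dim(x)
  list(out = out, ctx = list(x = x, slope = 0))
}
relu_bwd <- function(dout, ctx) lrelu_bwd(dout, ctx)

tanh_fwd <- function(x) {
  y <- tanh(x)
  list(out = y, ctx = y)
}
tanh_bwd <- function(dout, ctx) dout * (1 - ctx^2)

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(out = y, ctx = y)
}
sigmoid_bwd <- function(dout, ctx) dout * ctx * (1 - ctx)

dropout_fwd <- function(x, p = 0.5, active = TRUE) {
  if (!active) return(list(out = x, ctx = NULL))
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  list(out = x * mask, ctx = array(mask, dim(x)))
}
dropout_bwd <- function(dout, ctx) {
  if (is.null(ctx)) dout else dout * ctx
}

# --- Adam over nested parameter lists ------------------------------------
#
# Parameter blocks are updated *in place* through the compiled kernel: the
# nested lists handed to adam_step_inplace alias the network's own matrices,
# so the caller's network is updated without reassembling the tree. The
# bias correction is folded into the step size
# (lr_t = lr * sqrt(1 - beta2^t) / (1 - beta1^t)).

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step_inplace <- function(params, grads, state, lr, beta1 = 0.5,
                              beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  lr_t <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- if (!is.null(names(p)) && all(nzchar(names(p)))) names(p)
              else seq_along(p)
      for (k in keys) walk(p[[k]], g[[k]], m[[k]], v[[k]])
    } else {
      cpp_adam_update(p, g, m, v, lr_t, beta1, beta2, eps)
    }
    invisible(NULL)
  }
  walk(params, grads, state$m, state$v)
  state
}
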