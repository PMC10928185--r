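# Low-level tensor operations for the network engine. Activations are
# 4-D arrays (H, W, C, N) or plain matrices (N, d). Convolution is
# computed as a sum over kernel offsets of shifted-slice matrix
# products, so BLAS does the heavy lifting; the backward pass is the
# exact adjoint of each forward step.

pad_hw <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

crop_hw <- function(x, pad, h, w) {
  if (pad == 0) return(x)
  x[pad + seq_len(h), pad + seq_len(w), , , drop = FALSE]
}

conv_out_len <- function(l, k, stride, pad) (l + 2 * pad - k) %/% stride + 1L

# x: (H,W,Cin,N); w: (kh,kw,Cin,Cout); b: length Cout
conv_forward <- function(x, w, b, stride = 1L, pad = 0L) {
  d <- dim(x); kh <- dim(w)[1]; kw <- dim(w)[2]
  cin <- dim(w)[3]; cout <- dim(w)[4]; n <- d[4]
  stopifnot(d[3] == cin)
  ho <- conv_out_len(d[1], kh, stride, pad)
  wo <- conv_out_len(d[2], kw, stride, pad)
  if (ho < 1 || wo < 1) stop("input too small for this convolution")
  xp <- pad_hw(x, pad)
  acc <- matrix(rep(b, each = ho * wo * n), ho * wo * n, cout)
  for (di in seq_len(kh)) {
    rows <- seq.int(di, by = stride, length.out = ho)
    for (dj in seq_len(kw)) {
      cols <- seq.int(dj, by = stride, length.out = wo)
      xs <- xp[rows, cols, , , drop = FALSE]
      m <- matrix(aperm(xs, c(1, 2, 4, 3)), nrow = ho * wo * n)
      acc <- acc + m %*% matrix(w[di, dj, , ], nrow = cin)
    }
  }
  out <- aperm(array(acc, c(ho, wo, n, cout)), c(1, 2, 4, 3))
  list(out = out, cache = list(xp = xp, dims = d))
}

conv_backward <- function(dout, w, stride, pad, cache) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  do_dims <- dim(dout); ho <- do_dims[1]; wo <- do_dims[2]; n <- do_dims[4]
  xp <- cache$xp; d <- cache$dims
  dmat <- matrix(aperm(dout, c(1, 2, 4, 3)), nrow = ho * wo * n)
  db <- colSums(dmat)
  dw <- array(0, dim(w))
  dxp <- array(0, dim(xp))
  for (di in seq_len(kh)) {
    rows <- seq.int(di, by = stride, length.out = ho)
    for (dj in seq_len(kw)) {
      cols <- seq.int(dj, by = stride, length.out = wo)
      xs <- xp[rows, cols, , , drop = FALSE]
      m <- matrix(aperm(xs, c(1, 2, 4, 3)), nrow = ho * wo * n)
      dw[di, dj, , ] <- crossprod(m, dmat)
      dm <- tcrossprod(dmat, matrix(w[di, dj, , ], nrow = cin))
      dxs <- aperm(array(dm, c(ho, wo, n, cin)), c(1, 2, 4, 3))
      dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] + dxs
    }
  }
  list(dx = crop_hw(dxp, pad, d[1], d[2]), dw = dw, db = db)
}

# Channel-wise batch normalization over (H, W, N).
bn_forward <- function(x, gamma, beta, state, train, eps = 1e-5,
                       momentum = 0.1) {
  d <- dim(x); C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)  # (H*W*N) x C
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * v
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  sd_c <- sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, sd_c, "/")
  ym <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  out <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(out = out, state = state,
       cache = list(xhat = xhat, sd = sd_c, dims = d, train = train))
}

bn_backward <- function(dout, gamma, cache) {
  d <- cache$dims; C <- d[3]
  dym <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, "*")
  if (cache$train) {
    m <- nrow(dym)
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
    dxm <- sweep(t1 - t2, 2, cache$sd, "/")
  } else {
    dxm <- sweep(dxhat, 2, cache$sd, "/")
  }
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  ho <- conv_out_len(d[1], k, stride, pad)
  wo <- conv_out_len(d[2], k, stride, pad)
  # zero padding: harmless here because pooling follows a ReLU
  xp <- pad_hw(x, pad)
  out <- array(-Inf, c(ho, wo, d[3], d[4]))
  amax <- array(0L, c(ho, wo, d[3], d[4]))
  off <- 0L
  for (di in seq_len(k)) {
    rows <- seq.int(di, by = stride, length.out = ho)
    for (dj in seq_len(k)) {
      off <- off + 1L
      cols <- seq.int(dj, by = stride, length.out = wo)
      xs <- xp[rows, cols, , , drop = FALSE]
      better <- xs > out
      out[better] <- xs[better]
      amax[better] <- off
    }
  }
  list(out = out, cache = list(amax = amax, dims = d, k = k,
                               stride = stride, pad = pad,
                               hw = c(ho, wo)))
}

maxpool_backward <- function(dout, cache) {
  d <- cache$dims; k <- cache$k; stride <- cache$stride; pad <- cache$pad
  ho <- cache$hw[1]; wo <- cache$hw[2]
  dxp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  off <- 0L
  for (di in seq_len(k)) {
    rows <- seq.int(di, by = stride, length.out = ho)
    for (dj in seq_len(k)) {
      off <- off + 1L
      cols <- seq.int(dj, by = stride, length.out = wo)
      sel <- dout * (cache$amax == off)
      dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] + sel
    }
  }
  crop_hw(dxp, pad, d[1], d[2])
}

# Global average pooling (H,W,C,N) -> (N,C) matrix.
gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])  # (H*W*N) x C
  # rows are (h,w) fastest then n: reshape to (H*W, N, C) and average.
  a <- array(m, c(d[1] * d[2], d[4], d[3]))
  out <- apply(a, c(2, 3), mean)
  dim(out) <- c(d[4], d[3])
  list(out = out, cache = d)
}

gap_backward <- function(dout, dims) {
  scale <- 1 / (dims[1] * dims[2])
  a <- array(0, c(dims[1] * dims[2], dims[4], dims[3]))
  for (cc in seq_len(dims[3])) {
    a[, , cc] <- matrix(rep(dout[, cc] * scale, each = dims[1] * dims[2]),
                        nrow = dims[1] * dims[2])
  }
  aperm(array(a, c(dims[1], dims[2], dims[4], dims[3])), c(1, 2, 4, 3))
}

# Adaptive average pooling to a g x g grid (torch-style band edges).
adaptive_avgpool <- function(x, g) {
  d <- dim(x)
  out <- array(0, c(g, g, d[3], d[4]))
  hb <- floor((0:g) * d[1] / g); wb <- floor((0:g) * d[2] / g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    sl <- x[(hb[i] + 1):hb[i + 1], (wb[j] + 1):wb[j + 1], , , drop = FALSE]
    out[i, j, , ] <- apply(sl, c(3, 4), mean)
  }
  out
}

# Nearest-neighbour 2x upsampling.
upsample_forward <- function(x) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = 2)
  ci <- rep(seq_len(d[2]), each = 2)
  list(out = x[ri, ci, , , drop = FALSE], cache = d)
}

upsample_backward <- function(dout, dims) {
  odd_r <- seq(1, dims[1] * 2, 2); odd_c <- seq(1, dims[2] * 2, 2)
  dout[odd_r, odd_c, , , drop = FALSE] +
    dout[odd_r, odd_c + 1, , , drop = FALSE] +
    dout[odd_r + 1, odd_c, , , drop = FALSE] +
    dout[odd_r + 1, odd_c + 1, , , drop = FALSE]
}

dense_forward <- function(x, w, b) {
  list(out = sweep(x %*% w, 2, b, "+"), cache = x)
}

dense_backward <- function(dout, w, x) {
  list(dx = tcrossprod(dout, w), dw = crossprod(x, dout),
       db = colSums(dout))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# Bilinear resize of a single-channel matrix to (h, w).
bilinear_resize <- function(m, h, w) {
  hi <- nrow(m); wi <- ncol(m)
  if (hi == h && wi == w) return(m)
  ys <- (seq_len(h) - 0.5) * hi / h + 0.5
  xs <- (seq_len(w) - 0.5) * wi / w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), hi); y1 <- pmin(y0 + 1, hi)
  x0 <- pmin(pmax(floor(xs), 1), wi); x1 <- pmin(x0 + 1, wi)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  cc <- m[y1, x0, drop = FALSE]; dd <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, h, w); wx <- matrix(fx, h, w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx +
    cc * wy * (1 - wx) + dd * wy * wx
}
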