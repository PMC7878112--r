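# Internal neural-network primitives: 'same'-padded 2D convolution via
# im2col + GEMM, batch normalization, ReLU, 2x2 max pooling, and fully
# connected layers, each with a hand-derived backward pass. Activations are
# 4D arrays (height, width, channels, batch). Kept deliberately small: just
# the pieces the residual image classifier needs.

# 'same' padding for kernel k and stride s: output ceil(H/s), extra pixel on
# the bottom/right when the total padding is odd.
conv_out_len <- function(len, stride) as.integer(ceiling(len / stride))

conv_pad <- function(len, k, stride) {
  out <- conv_out_len(len, stride)
  total <- max((out - 1L) * stride + k - len, 0L)
  c(lo = total %/% 2L, hi = total - total %/% 2L)
}

# Gather-index matrix for im2col on a single padded image.
# Column order is (kernel row, kernel col, channel), matching the
# column-major flattening of a (k, k, C_in, C_out) weight array.
im2col_index <- function(h, w, c_in, k, stride) {
  ph <- conv_pad(h, k, stride); pw <- conv_pad(w, k, stride)
  hp <- h + sum(ph); wp <- w + sum(pw)
  oh <- conv_out_len(h, stride); ow <- conv_out_len(w, stride)
  oi <- rep(seq_len(oh), times = ow)          # output row varies fastest
  oj <- rep(seq_len(ow), each = oh)
  pos0 <- (oi - 1L) * stride + 1L + ((oj - 1L) * stride) * hp
  di <- rep(0:(k - 1), times = k)
  dj <- rep(0:(k - 1), each = k)
  off <- as.vector(outer(di + dj * hp,
                         (seq_len(c_in) - 1L) * hp * wp, "+"))
  idx <- outer(pos0, off, "+")
  storage.mode(idx) <- "integer"
  list(idx = idx, hp = hp, wp = wp, ph = ph, pw = pw, oh = oh, ow = ow,
       P = oh * ow, K = k * k * c_in)
}

pad_batch <- function(x, ph, pw) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + sum(ph), d[2] + sum(pw), d[3], d[4]))
  out[ph[1] + seq_len(d[1]), pw[1] + seq_len(d[2]), , ] <- x
  out
}

# Forward convolution. W: (k, k, C_in, C_out); b: length C_out.
# Returns list(out, cols, geom) — cols retained for the backward pass.
conv_forward <- function(x, W, b, stride, geom = NULL) {
  d <- dim(x); k <- dim(W)[1]; c_out <- dim(W)[4]
  if (is.null(geom)) geom <- im2col_index(d[1], d[2], d[3], k, stride)
  B <- d[4]
  xp <- pad_batch(x, geom$ph, geom$pw)
  plane <- geom$hp * geom$wp * d[3]
  cols <- matrix(0, B * geom$P, geom$K)
  for (b_i in seq_len(B)) {
    cols[(b_i - 1L) * geom$P + seq_len(geom$P), ] <-
      xp[as.vector(geom$idx) + (b_i - 1L) * plane]
  }
  Wm <- matrix(W, nrow = geom$K, ncol = c_out)
  y <- cols %*% Wm
  y <- sweep(y, 2, b, "+")
  out <- array(0, dim = c(geom$oh, geom$ow, c_out, B))
  for (b_i in seq_len(B)) {
    out[, , , b_i] <- y[(b_i - 1L) * geom$P + seq_len(geom$P), ]
  }
  list(out = out, cols = cols, geom = geom, in_dim = d)
}

conv_backward <- function(dout, cache, W) {
  geom <- cache$geom; d <- cache$in_dim
  k <- dim(W)[1]; c_in <- dim(W)[3]; c_out <- dim(W)[4]
  B <- d[4]
  dy <- matrix(0, B * geom$P, c_out)
  for (b_i in seq_len(B)) {
    dy[(b_i - 1L) * geom$P + seq_len(geom$P), ] <-
      matrix(dout[, , , b_i], geom$P, c_out)
  }
  Wm <- matrix(W, nrow = geom$K, ncol = c_out)
  dW <- crossprod(cache$cols, dy)
  dim(dW) <- dim(W)
  db <- colSums(dy)
  dcols <- dy %*% t(Wm)
  # scatter back: for each of the k*k kernel offsets the P x C_in index
  # block is injective, so accumulation needs only k*k vectorized passes
  plane <- geom$hp * geom$wp * c_in
  dxp <- array(0, dim = c(geom$hp, geom$wp, c_in, B))
  for (b_i in seq_len(B)) {
    dslice <- numeric(plane)
    rows <- (b_i - 1L) * geom$P + seq_len(geom$P)
    for (o in seq_len(k * k)) {
      sel <- o + (k * k) * (seq_len(c_in) - 1L)
      ii <- geom$idx[, sel]
      dslice[ii] <- dslice[ii] + dcols[rows, sel]
    }
    dxp[, , , b_i] <- dslice
  }
  dx <- dxp[geom$ph[1] + seq_len(d[1]), geom$pw[1] + seq_len(d[2]), , ,
            drop = FALSE]
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# Batch normalization over (height, width, batch) per channel.
bn_forward <- function(x, gamma, beta, running, train, eps = 1e-5,
                       momentum = 0.1) {
  d <- dim(x); C <- d[3]
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], C)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv_sd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(y) <- c(d[1], d[2], d[4], C)
  y <- aperm(y, c(1, 2, 4, 3))
  list(out = y, xhat = xhat, inv_sd = inv_sd, running = running, dims = d)
}

bn_backward <- function(dout, cache, gamma) {
  d <- cache$dims; C <- d[3]; N <- d[1] * d[2] * d[4]
  dym <- aperm(dout, c(1, 2, 4, 3))
  dim(dym) <- c(N, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, "*")
  # dx = inv_sd/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dxm <- sweep(
    N * dxhat - matrix(s1, N, C, byrow = TRUE) -
      cache$xhat * matrix(s2, N, C, byrow = TRUE),
    2, cache$inv_sd / N, "*"
  )
  dim(dxm) <- c(d[1], d[2], d[4], C)
  dx <- aperm(dxm, c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, mask = mask)
}

relu_backward <- function(dout, cache) {
  dout[!cache$mask] <- 0
  dout
}

# 2x2 max pooling, stride 2. Odd trailing rows/columns are dropped.
maxpool_forward <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  x <- x[seq_len(2L * h2), seq_len(2L * w2), , , drop = FALSE]
  odd_r <- seq(1L, 2L * h2, by = 2L); evn_r <- odd_r + 1L
  s1 <- x[odd_r, , , , drop = FALSE]; s2 <- x[evn_r, , , , drop = FALSE]
  m1 <- s1 >= s2
  y1 <- s2; y1[m1] <- s1[m1]
  odd_c <- seq(1L, 2L * w2, by = 2L); evn_c <- odd_c + 1L
  t1 <- y1[, odd_c, , , drop = FALSE]; t2 <- y1[, evn_c, , , drop = FALSE]
  m2 <- t1 >= t2
  y <- t2; y[m2] <- t1[m2]
  list(out = y, m1 = m1, m2 = m2, in_dim = d, h2 = h2, w2 = w2)
}

maxpool_backward <- function(dout, cache) {
  d <- cache$in_dim; h2 <- cache$h2; w2 <- cache$w2
  dy1 <- array(0, dim = c(h2, 2L * w2, d[3], d[4]))
  odd_c <- seq(1L, 2L * w2, by = 2L)
  dy1[, odd_c, , ] <- dout * cache$m2
  dy1[, odd_c + 1L, , ] <- dout * (!cache$m2)
  dx <- array(0, dim = d)
  odd_r <- seq(1L, 2L * h2, by = 2L)
  dx[odd_r, seq_len(2L * w2), , ] <- dy1 * cache$m1
  dx[odd_r + 1L, seq_len(2L * w2), , ] <- dy1 * (!cache$m1)
  dx
}

fc_forward <- function(x, W, b) {
  y <- x %*% W
  list(out = sweep(y, 2, b, "+"), x = x)
}

fc_backward <- function(dout, cache, W) {
  list(dx = dout %*% t(W), dW = crossprod(cache$x, dout), db = colSums(dout))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
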