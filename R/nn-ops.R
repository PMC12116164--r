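# Tensor primitives for the segmentation network.
#
# Layout convention: activations are 4-D double arrays (N, H, W, C); weights
# of a k x k convolution are (k, k, in_c, out_c). Convolutions are computed
# as a single BLAS matrix product on an im2col patch matrix whose gather
# indices are cached per input shape, which keeps the training loop fast in
# plain R.

conv_out_len <- function(n, k, stride, dilation, pad) {
  eff <- (k - 1L) * dilation + 1L
  as.integer(floor((n + 2L * pad - eff) / stride) + 1L)
}

# Gather-index set for im2col. Returns list(li, dims): `li` is a
# (P x K*C) index matrix into the zero-padded input plane of one sample,
# with columns ordered kernel-row fastest, then kernel-col, then channel —
# matching the vectorization order of a (k, k, C, out) weight array.
im2col_indices <- function(h, w, c, k, stride, dilation, pad) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  oh <- conv_out_len(h, k, stride, dilation, pad)
  ow <- conv_out_len(w, k, stride, dilation, pad)
  if (oh < 1L || ow < 1L) stop_bad_arg("feature map too small for this convolution")
  rows0 <- (seq_len(oh) - 1L) * stride + 1L
  cols0 <- (seq_len(ow) - 1L) * stride + 1L
  pr <- rep(rows0, times = ow)          # p = i' + (j'-1)*oh, i' fastest
  pc <- rep(cols0, each = oh)
  p_n <- oh * ow
  li_ab <- matrix(0L, p_n, k * k)
  for (b in 0:(k - 1L)) for (a in 0:(k - 1L)) {
    li_ab[, a + b * k + 1L] <- (pr + a * dilation) + (pc + b * dilation - 1L) * hp
  }
  plane <- hp * wp
  li <- matrix(0L, p_n, k * k * c)
  for (ch in 0:(c - 1L)) {
    li[, ch * k * k + seq_len(k * k)] <- li_ab + ch * plane
  }
  list(li = li, hp = hp, wp = wp, oh = oh, ow = ow)
}

pad_nhwc <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

conv2d_forward <- function(x, W, b, stride = 1L, dilation = 1L, pad = NULL,
                           idx = NULL) {
  d <- dim(x); k <- dim(W)[1]; in_c <- dim(W)[3]; out_c <- dim(W)[4]
  if (d[4] != in_c) stop_bad_arg("input channels (", d[4], ") do not match kernel (", in_c, ")")
  if (is.null(pad)) pad <- dilation * (k - 1L) %/% 2L
  if (is.null(idx)) idx <- im2col_indices(d[2], d[3], in_c, k, stride, dilation, pad)
  xp <- pad_nhwc(x, pad)
  n <- d[1]
  dim(xp) <- c(n, length(xp) / n)                    # N x (Hp*Wp*C), no copy
  M <- xp[, as.vector(idx$li), drop = FALSE]         # N x (P*K*C) gather
  p_n <- idx$oh * idx$ow; kc <- ncol(idx$li)
  dim(M) <- c(n * p_n, kc)                           # (N*P) x (K*C), no copy
  Wmat <- W
  dim(Wmat) <- c(kc, out_c)
  out <- M %*% Wmat
  if (!is.null(b)) out <- out + rep(b, each = n * p_n)
  y <- out
  dim(y) <- c(n, idx$oh, idx$ow, out_c)
  list(y = y, cache = list(M = M, idx = idx, in_dim = d, pad = pad,
                           stride = stride, dilation = dilation))
}

conv2d_backward <- function(dy, W, cache) {
  d <- cache$in_dim; idx <- cache$idx
  n <- d[1]; k <- dim(W)[1]; in_c <- dim(W)[3]; out_c <- dim(W)[4]
  p_n <- idx$oh * idx$ow
  dY <- dy
  dim(dY) <- c(n * p_n, out_c)
  Wmat <- W
  dim(Wmat) <- c(k * k * in_c, out_c)
  gW <- crossprod(cache$M, dY)
  dim(gW) <- dim(W)
  gb <- colSums(dY)
  dM <- tcrossprod(dY, Wmat)                          # (N*P) x (K*C)
  hp <- idx$hp; wp <- idx$wp
  dxp_mat <- matrix(0, n, hp * wp * in_c)
  kk <- k * k
  plane_off <- (0:(in_c - 1L)) * (hp * wp)
  for (ab in seq_len(kk)) {
    cols_m <- ab + (0:(in_c - 1L)) * kk                # columns of dM for this offset
    dm <- dM[, cols_m, drop = FALSE]                   # (N*P) x C
    dim(dm) <- c(n, p_n * in_c)                        # N x (P*C), no copy
    tcols <- as.vector(outer(idx$li[, ab], plane_off, "+"))
    dxp_mat[, tcols] <- dxp_mat[, tcols] + dm
  }
  dxp <- dxp_mat
  dim(dxp) <- c(n, hp, wp, in_c)
  pad <- cache$pad
  dx <- if (pad > 0L) dxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE] else dxp
  list(dx = dx, gW = gW, gb = gb)
}

batchnorm_forward <- function(x, gamma, beta, running_mean, running_var,
                              training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); c_n <- d[4]; m <- prod(d[1:3])
  xm <- x
  dim(xm) <- c(m, c_n)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = m)
    v <- colSums(xc^2) / m
    new_mean <- (1 - momentum) * running_mean + momentum * mu
    new_var <- (1 - momentum) * running_var + momentum * v * m / max(1, m - 1)
  } else {
    mu <- running_mean; v <- running_var
    xc <- xm - rep(mu, each = m)
    new_mean <- running_mean; new_var <- running_var
  }
  istd <- 1 / sqrt(v + eps)
  y <- xc * rep(gamma * istd, each = m) + rep(beta, each = m)
  dim(y) <- d
  list(y = y,
       cache = list(xc = xc, istd = istd, dims = d, training = training),
       running_mean = new_mean, running_var = new_var)
}

batchnorm_backward <- function(dy, gamma, cache) {
  d <- cache$dims; m <- prod(d[1:3]); c_n <- d[4]
  dym <- dy
  dim(dym) <- c(m, c_n)
  xhat <- cache$xc * rep(cache$istd, each = m)
  ggamma <- colSums(dym * xhat)
  gbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = m)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dxm <- (dxhat - rep(s1 / m, each = m) - xhat * rep(s2 / m, each = m)) *
      rep(cache$istd, each = m)
  } else {
    dxm <- dxhat * rep(cache$istd, each = m)
  }
  dim(dxm) <- d
  list(dx = dxm, ggamma = ggamma, gbeta = gbeta)
}

# Bilinear interpolation matrix mapping `n_in` samples to `n_out`, with
# half-pixel center alignment.
bilinear_matrix <- function(n_in, n_out) {
  Wm <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (o in seq_len(n_out)) {
    src <- (o - 0.5) * scale + 0.5   # in 1-based pixel-center coordinates
    i0 <- floor(src); t <- src - i0
    i0 <- min(max(i0, 1), n_in); i1 <- min(i0 + 1, n_in)
    if (i1 == i0) t <- 0
    Wm[o, i0] <- Wm[o, i0] + (1 - t)
    Wm[o, i1] <- Wm[o, i1] + t
  }
  Wm
}

# y[n,o,q,c] = sum_{h,w} Rm[o,h] Cm[q,w] x[n,h,w,c]
bilinear_resize <- function(x, rm, cm) {
  d <- dim(x)
  x1 <- aperm(x, c(2, 1, 3, 4))                     # H, N, W, C
  y1 <- rm %*% matrix(x1, nrow = d[2])              # oh x (N*W*C)
  oh <- nrow(rm)
  y1 <- array(y1, c(oh, d[1], d[3], d[4]))
  y2 <- aperm(y1, c(3, 2, 1, 4))                    # W, N, oh, C
  y2 <- cm %*% matrix(y2, nrow = d[3])              # ow x (N*oh*C)
  ow <- nrow(cm)
  aperm(array(y2, c(ow, d[1], oh, d[4])), c(2, 3, 1, 4))
}

bilinear_forward <- function(x, oh, ow) {
  d <- dim(x)
  rm <- bilinear_matrix(d[2], oh)
  cm <- bilinear_matrix(d[3], ow)
  list(y = bilinear_resize(x, rm, cm), cache = list(rm = rm, cm = cm, in_dim = d))
}

bilinear_backward <- function(dy, cache) {
  bilinear_resize(dy, t(cache$rm), t(cache$cm))
}

global_pool_forward <- function(x) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1] * d[2] * d[3], ncol = d[4])
  grp <- rep(seq_len(d[1]), times = d[2] * d[3])
  y <- rowsum(xm, grp) / (d[2] * d[3])              # N x C
  list(y = array(y, c(d[1], 1L, 1L, d[4])), cache = list(in_dim = d))
}

global_pool_backward <- function(dy, cache) {
  d <- cache$in_dim
  dym <- matrix(dy, nrow = d[1], ncol = d[4]) / (d[2] * d[3])
  grp <- rep(seq_len(d[1]), times = d[2] * d[3])
  array(dym[grp, , drop = FALSE], d)
}

# Pixel-wise softmax cross-entropy, mean over all pixels.
softmax_ce <- function(logits, labels) {
  d <- dim(logits); m <- prod(d[1:3]); k <- d[4]
  lm <- matrix(logits, nrow = m, ncol = k)
  lab <- as.integer(labels) + 1L
  if (any(lab < 1L | lab > k)) stop_bad_arg("label out of range [0, n_classes)")
  mx <- do.call(pmax, lapply(seq_len(k), function(j) lm[, j]))
  ex <- exp(lm - mx)
  se <- rowSums(ex)
  p <- ex / se
  picked <- p[cbind(seq_len(m), lab)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  g <- p
  g[cbind(seq_len(m), lab)] <- g[cbind(seq_len(m), lab)] - 1
  list(loss = loss, grad = array(g / m, d))
}
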