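# CBAM and ECA attention blocks, as trainable layers and as standalone
# functional operators.

#' Adaptive ECA kernel size
#'
#' The 1-D channel-attention kernel length adapts to the channel count:
#' `k` is the nearest odd integer to `|log2(C)/gamma + b/gamma|` (computed as
#' floor, bumped up to the next odd number), never below 1.
#'
#' @param n_channels Number of channels C.
#' @param gamma,b Mapping coefficients (defaults 2 and 1).
#' @return Odd integer kernel size.
#' @export
eca_kernel_size <- function(n_channels, gamma = 2, b = 1) {
  t <- abs(log2(n_channels) / gamma + b / gamma)
  k <- floor(t)
  if (k %% 2 == 0) k <- k + 1
  max(1L, as.integer(k))
}

make_cbam <- function(c_n, reduction = 16L) {
  if (c_n < reduction) stop_bad_arg("channels (", c_n, ") < reduction (", reduction, ")")
  if (c_n %% reduction != 0) stop_bad_arg("channels must be divisible by reduction")
  cr <- c_n %/% reduction
  e <- new_layer("cbam", c_n = c_n, reduction = as.integer(reduction), cr = cr)
  add_param(e, "W1", matrix(stats::rnorm(c_n * cr, 0, sqrt(2 / c_n)), c_n, cr))
  add_param(e, "b1", numeric(cr))
  add_param(e, "W2", matrix(stats::rnorm(cr * c_n, 0, sqrt(2 / cr)), cr, c_n))
  add_param(e, "b2", numeric(c_n))
  add_param(e, "Wsp", array(stats::rnorm(7 * 7 * 2, 0, sqrt(2 / 98)), c(7, 7, 2, 1)))
  add_param(e, "bsp", 0)
  e
}

# shared-MLP helper: returns output and backward closure inputs
cbam_mlp <- function(e, v) {
  h1 <- sweep(v %*% e$W1, 2, e$b1, "+")
  a1 <- h1 * (h1 > 0)
  list(out = sweep(a1 %*% e$W2, 2, e$b2, "+"), a1 = a1, mask = h1 > 0, v = v)
}

cbam_layer_forward <- function(e, x, training = FALSE) {
  d <- dim(x); n <- d[1]; hh <- d[2]; ww <- d[3]; c_n <- d[4]
  if (c_n != e$c_n) stop_bad_arg("CBAM channel mismatch")
  arr <- array(x, c(n, hh * ww, c_n))
  avg <- apply(arr, c(1, 3), sum) / (hh * ww)          # N x C
  mx_idx <- matrix(0L, n, c_n)
  mx <- matrix(0, n, c_n)
  for (i in seq_len(n)) {
    m <- arr[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = c_n)
    idx <- max.col(t(m), ties.method = "first")
    mx_idx[i, ] <- idx
    mx[i, ] <- m[cbind(idx, seq_len(c_n))]
  }
  pa <- cbam_mlp(e, avg)
  pm <- cbam_mlp(e, mx)
  z <- pa$out + pm$out
  mc <- 1 / (1 + exp(-z))                              # channel gain, N x C
  x1 <- x * aperm(array(mc, c(n, c_n, hh, ww)), c(1, 3, 4, 2))

  x1m <- matrix(x1, nrow = n * hh * ww, ncol = c_n)
  savg <- rowMeans(x1m)
  sm_idx <- max.col(x1m, ties.method = "first")
  smax <- x1m[cbind(seq_len(nrow(x1m)), sm_idx)]
  smap <- array(c(savg, smax), c(n, hh, ww, 2))
  cv <- conv2d_forward(smap, e$Wsp, e$bsp)
  ms_logit <- cv$y                                     # N x H x W x 1
  ms <- 1 / (1 + exp(-ms_logit))
  y <- x1 * as.vector(ms)                              # broadcast over channels

  e$cache <- list(d = d, x = x, mc = mc, ms = ms, x1 = x1, pa = pa, pm = pm,
                  mx_idx = mx_idx, sm_idx = sm_idx, conv_cache = cv$cache)
  y
}

cbam_layer_backward <- function(e, dy) {
  cc <- e$cache
  d <- cc$d; n <- d[1]; hh <- d[2]; ww <- d[3]; c_n <- d[4]
  npix <- n * hh * ww
  ms_v <- as.vector(cc$ms)

  dx1 <- dy * ms_v
  dms <- array(rowSums(matrix(dy * cc$x1, nrow = npix, ncol = c_n)),
               c(n, hh, ww, 1))
  dms_logit <- dms * cc$ms * (1 - cc$ms)
  cb <- conv2d_backward(dms_logit, e$Wsp, cc$conv_cache)
  e$g_Wsp <- e$g_Wsp + cb$gW
  e$g_bsp <- e$g_bsp + cb$gb
  dsmap <- cb$dx                                       # N x H x W x 2
  dsavg <- as.vector(dsmap[, , , 1])
  dsmax <- as.vector(dsmap[, , , 2])
  dx1m <- matrix(dx1, nrow = npix, ncol = c_n)
  dx1m <- dx1m + dsavg / c_n
  dx1m[cbind(seq_len(npix), cc$sm_idx)] <-
    dx1m[cbind(seq_len(npix), cc$sm_idx)] + dsmax
  dx1 <- array(dx1m, c(n, hh, ww, c_n))

  mc_b <- aperm(array(cc$mc, c(n, c_n, hh, ww)), c(1, 3, 4, 2))
  dx <- dx1 * mc_b
  # gain gradient: sum over spatial of dx1 * x
  dmc <- apply(array(dx1 * cc$x, c(n, hh * ww, c_n)), c(1, 3), sum)
  dz <- dmc * cc$mc * (1 - cc$mc)

  back_mlp <- function(path, dz) {
    da1 <- dz %*% t(e$W2)
    dh1 <- da1 * path$mask
    e$g_W2 <- e$g_W2 + crossprod(path$a1, dz)
    e$g_b2 <- e$g_b2 + colSums(dz)
    e$g_W1 <- e$g_W1 + crossprod(path$v, dh1)
    e$g_b1 <- e$g_b1 + colSums(dh1)
    dh1 %*% t(e$W1)
  }
  davg <- back_mlp(cc$pa, dz)                          # N x C
  dmxv <- back_mlp(cc$pm, dz)

  # average-pool path: spread evenly
  davg_b <- aperm(array(davg / (hh * ww), c(n, c_n, hh, ww)), c(1, 3, 4, 2))
  dx <- dx + davg_b
  # max-pool path: route to the argmax pixel of each (sample, channel)
  dmax_arr <- array(0, c(n, hh * ww, c_n))
  for (i in seq_len(n)) {
    dmax_arr[i, , ][cbind(cc$mx_idx[i, ], seq_len(c_n))] <- dmxv[i, ]
  }
  dx + array(dmax_arr, c(n, hh, ww, c_n))
}

make_eca <- function(c_n, gamma = 2, b = 1) {
  k <- eca_kernel_size(c_n, gamma, b)
  e <- new_layer("eca", c_n = c_n, k = k, gamma = gamma, b = b)
  add_param(e, "w", stats::rnorm(k, 0, sqrt(1 / k)))
  e
}

eca_layer_forward <- function(e, x, training = FALSE) {
  d <- dim(x); n <- d[1]; c_n <- d[4]
  if (c_n != e$c_n) stop_bad_arg("ECA channel mismatch")
  hw <- d[2] * d[3]
  s <- rowsum(matrix(x, nrow = n * hw, ncol = c_n), rep(seq_len(n), times = hw))
  s <- s / hw                                          # N x C channel descriptor
  k <- e$k; half <- (k - 1L) %/% 2L
  sp <- cbind(matrix(0, n, half), s, matrix(0, n, half))
  z <- matrix(0, n, c_n)
  for (j in seq_len(k)) z <- z + e$w[j] * sp[, j:(j + c_n - 1L), drop = FALSE]
  g <- 1 / (1 + exp(-z))                               # N x C gains
  y <- x * aperm(array(g, c(n, c_n, d[2], d[3])), c(1, 3, 4, 2))
  e$cache <- list(d = d, x = x, s = s, sp = sp, g = g)
  y
}

eca_layer_backward <- function(e, dy) {
  cc <- e$cache
  d <- cc$d; n <- d[1]; c_n <- d[4]; hw <- d[2] * d[3]
  g_b <- aperm(array(cc$g, c(n, c_n, d[2], d[3])), c(1, 3, 4, 2))
  dx <- dy * g_b
  dg <- apply(array(dy * cc$x, c(n, hw, c_n)), c(1, 3), sum)
  dz <- dg * cc$g * (1 - cc$g)
  k <- e$k; half <- (k - 1L) %/% 2L
  dsp <- matrix(0, n, c_n + 2L * half)
  for (j in seq_len(k)) {
    e$g_w[j] <- e$g_w[j] + sum(dz * cc$sp[, j:(j + c_n - 1L), drop = FALSE])
    dsp[, j:(j + c_n - 1L)] <- dsp[, j:(j + c_n - 1L)] + e$w[j] * dz
  }
  ds <- dsp[, half + seq_len(c_n), drop = FALSE] / hw
  dx + aperm(array(ds, c(n, c_n, d[2], d[3])), c(1, 3, 4, 2))
}

as_nhwc <- function(x) {
  if (length(dim(x)) == 3L) array(x, c(1L, dim(x))) else x
}

#' Convolutional block attention (CBAM) applied to a feature map
#'
#' Applies sequential channel and spatial gating: the channel gain is the
#' sigmoid of a shared two-layer MLP evaluated on the global average- and
#' max-pooled channel descriptors (summed), and the spatial gain is the
#' sigmoid of a 7x7 convolution over the stacked channel-wise mean and max
#' maps of the channel-gated input. Both gains lie strictly in (0, 1), so
#' the output never exceeds the input in magnitude and the shape is
#' preserved.
#'
#' @param x Feature map, `H x W x C` or `N x H x W x C`.
#' @param weights Optional weight list from [cbam_weights()]; random
#'   He-initialized weights are drawn otherwise (seeded externally).
#' @param reduction Channel reduction ratio of the MLP bottleneck.
#' @return Gated array of the same shape, with attributes `channel_gain`
#'   (`N x C`) and `spatial_gain` (`N x H x W`).
#' @export
cbam <- function(x, weights = NULL, reduction = 16L) {
  x4 <- as_nhwc(x)
  c_n <- dim(x4)[4]
  e <- make_cbam(c_n, reduction)
  if (!is.null(weights)) for (nm in names(weights)) assign(nm, weights[[nm]], envir = e)
  y <- cbam_layer_forward(e, x4, training = FALSE)
  out <- if (length(dim(x)) == 3L) array(y, dim(x)) else y
  attr(out, "channel_gain") <- e$cache$mc
  attr(out, "spatial_gain") <- array(e$cache$ms, dim(x4)[1:3])
  out
}

#' CBAM weight set
#'
#' @param n_channels Channel count of the feature map.
#' @param reduction MLP bottleneck reduction ratio.
#' @param seed Optional seed for reproducible random weights.
#' @return List with `W1`, `b1`, `W2`, `b2` (shared MLP) and `Wsp`, `bsp`
#'   (7x7 spatial convolution).
#' @export
cbam_weights <- function(n_channels, reduction = 16L, seed = NULL) {
  build <- function() {
    e <- make_cbam(n_channels, reduction)
    list(W1 = e$W1, b1 = e$b1, W2 = e$W2, b2 = e$b2, Wsp = e$Wsp, bsp = e$bsp)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Efficient channel attention (ECA) applied to a feature map
#'
#' Gates each channel by the sigmoid of a length-k 1-D convolution over the
#' global-average channel descriptor, with k adapted to the channel count
#' (see [eca_kernel_size()]).
#'
#' @param x Feature map, `H x W x C` or `N x H x W x C`.
#' @param weights Optional numeric kernel of length [eca_kernel_size()].
#' @param gamma,b Kernel-size mapping coefficients.
#' @return Gated array of the same shape with attribute `channel_gain`.
#' @export
eca <- function(x, weights = NULL, gamma = 2, b = 1) {
  x4 <- as_nhwc(x)
  c_n <- dim(x4)[4]
  e <- make_eca(c_n, gamma, b)
  if (!is.null(weights)) {
    if (length(weights) != e$k) {
      stop_bad_arg("ECA kernel must have length ", e$k, " for ", c_n, " channels")
    }
    e$w <- as.numeric(weights)
  }
  y <- eca_layer_forward(e, x4, training = FALSE)
  out <- if (length(dim(x)) == 3L) array(y, dim(x)) else y
  attr(out, "channel_gain") <- e$cache$g
  out
}
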