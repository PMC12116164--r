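# Layer objects. Each primitive layer is an environment with parameter
# arrays (plus gradient `g_*` and momentum `v_*` buffers), a forward cache,
# and a `type` tag dispatched by layer_forward()/layer_backward().
# Containers hold `children`. Weight init is He-normal, driven by the RNG
# state at build time.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$param_names <- character(0)
  class(e) <- "nn_layer"
  e
}

add_param <- function(e, name, value) {
  assign(name, value, envir = e)
  assign(paste0("g_", name), value * 0, envir = e)
  assign(paste0("v_", name), value * 0, envir = e)
  e$param_names <- c(e$param_names, name)
}

make_conv <- function(in_c, out_c, k = 3L, stride = 1L, dilation = 1L,
                      bias = TRUE) {
  e <- new_layer("conv", k = as.integer(k), stride = as.integer(stride),
                 dilation = as.integer(dilation), in_c = in_c, out_c = out_c,
                 use_bias = bias, idx_cache = NULL, idx_key = "")
  sd <- sqrt(2 / (k * k * in_c))
  add_param(e, "W", array(stats::rnorm(k * k * in_c * out_c, 0, sd),
                          c(k, k, in_c, out_c)))
  if (bias) add_param(e, "b", numeric(out_c))
  e
}

make_bn <- function(c_n) {
  e <- new_layer("bn", c_n = c_n, running_mean = numeric(c_n),
                 running_var = rep(1, c_n), momentum = 0.1)
  add_param(e, "gamma", rep(1, c_n))
  add_param(e, "beta", numeric(c_n))
  e
}

make_relu <- function() new_layer("relu")

make_seq <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1]]) && !inherits(ch[[1]], "nn_layer")) ch <- ch[[1]]
  new_layer("seq", children = ch)
}

# y = x + children(x); caller must ensure matching shapes
make_residual <- function(inner) new_layer("residual", children = list(inner))

# Image-pooling branch of ASPP: global pool -> 1x1 conv -> BN -> ReLU ->
# broadcast back to the input resolution.
make_aspp_pool <- function(in_c, out_c) {
  new_layer("aspp_pool",
            children = list(make_conv(in_c, out_c, k = 1L, bias = FALSE),
                            make_bn(out_c)))
}

make_upsample <- function(factor = NULL, target = NULL) {
  new_layer("upsample", factor = factor, target = target)
}

layer_forward <- function(e, x, training = FALSE) {
  switch(e$type,
    conv = {
      d <- dim(x)
      key <- paste(d, collapse = "x")
      if (!identical(e$idx_key, key)) {
        pad <- e$dilation * (e$k - 1L) %/% 2L
        e$idx_cache <- im2col_indices(d[2], d[3], e$in_c, e$k, e$stride,
                                      e$dilation, pad)
        e$idx_key <- key
        e$pad <- pad
      }
      r <- conv2d_forward(x, e$W, if (e$use_bias) e$b else NULL,
                          e$stride, e$dilation, e$pad, e$idx_cache)
      e$cache <- r$cache
      r$y
    },
    bn = {
      r <- batchnorm_forward(x, e$gamma, e$beta, e$running_mean, e$running_var,
                             training, e$momentum)
      if (training) {
        e$running_mean <- r$running_mean
        e$running_var <- r$running_var
      }
      e$cache <- r$cache
      r$y
    },
    relu = {
      e$cache <- x > 0
      x * e$cache
    },
    seq = {
      for (ch in e$children) x <- layer_forward(ch, x, training)
      x
    },
    residual = {
      e$in_x <- x
      x + layer_forward(e$children[[1]], x, training)
    },
    aspp_pool = {
      d <- dim(x)
      e$in_dim <- d
      r <- global_pool_forward(x)
      e$pool_cache <- r$cache
      y <- layer_forward(e$children[[1]], r$y, training)
      y <- layer_forward(e$children[[2]], y, training)
      e$relu_cache <- y > 0
      y <- y * e$relu_cache
      # broadcast 1x1 back to H x W
      array(rep(as.vector(y), each = 1), c(d[1], 1, 1, dim(y)[4]))[, rep(1, d[2]), rep(1, d[3]), , drop = FALSE]
    },
    upsample = {
      d <- dim(x)
      oh <- if (!is.null(e$target)) e$target[1] else d[2] * e$factor
      ow <- if (!is.null(e$target)) e$target[2] else d[3] * e$factor
      r <- bilinear_forward(x, oh, ow)
      e$cache <- r$cache
      r$y
    },
    cbam = cbam_layer_forward(e, x, training),
    eca = eca_layer_forward(e, x, training),
    stop_bad_arg("unknown layer type: ", e$type)
  )
}

layer_backward <- function(e, dy) {
  switch(e$type,
    conv = {
      r <- conv2d_backward(dy, e$W, e$cache)
      e$g_W <- e$g_W + r$gW
      if (e$use_bias) e$g_b <- e$g_b + r$gb
      r$dx
    },
    bn = {
      r <- batchnorm_backward(dy, e$gamma, e$cache)
      e$g_gamma <- e$g_gamma + r$ggamma
      e$g_beta <- e$g_beta + r$gbeta
      r$dx
    },
    relu = dy * e$cache,
    seq = {
      for (ch in rev(e$children)) dy <- layer_backward(ch, dy)
      dy
    },
    residual = dy + layer_backward(e$children[[1]], dy),
    aspp_pool = {
      d <- e$in_dim
      # collapse the broadcast: sum over spatial positions
      dym <- matrix(dy, nrow = d[1] * d[2] * d[3], ncol = dim(dy)[4])
      grp <- rep(seq_len(d[1]), times = d[2] * d[3])
      dpool <- array(rowsum(dym, grp), c(d[1], 1L, 1L, dim(dy)[4]))
      dpool <- dpool * e$relu_cache
      dpool <- layer_backward(e$children[[2]], dpool)
      dpool <- layer_backward(e$children[[1]], dpool)
      global_pool_backward(dpool, e$pool_cache)
    },
    upsample = bilinear_backward(dy, e$cache),
    cbam = cbam_layer_backward(e, dy),
    eca = eca_layer_backward(e, dy),
    stop_bad_arg("unknown layer type: ", e$type)
  )
}

# Flat list of parameter-bearing primitive layers in a layer tree.
collect_layers <- function(e) {
  if (is.null(e)) return(list())
  kids <- if (!is.null(e$children)) e$children else list()
  c(list(e), unlist(lapply(kids, collect_layers), recursive = FALSE))
}

layer_param_count <- function(layers) {
  sum(vapply(layers, function(e) {
    sum(vapply(e$param_names, function(nm) length(get(nm, envir = e)), 0))
  }, 0))
}

sgd_step <- function(layers, lr, momentum = 0.9) {
  for (e in layers) {
    for (nm in e$param_names) {
      g <- get(paste0("g_", nm), envir = e)
      v <- momentum * get(paste0("v_", nm), envir = e) + g
      assign(paste0("v_", nm), v, envir = e)
      assign(nm, get(nm, envir = e) - lr * v, envir = e)
    }
  }
}

zero_grads <- function(layers) {
  for (e in layers) {
    for (nm in e$param_names) {
      g <- get(paste0("g_", nm), envir = e)
      assign(paste0("g_", nm), g * 0, envir = e)
    }
  }
}
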