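#' Segmentation model configuration
#'
#' Describes a DeepLabv3+-style encoder-decoder with optional dual attention:
#' a small residual encoder with output stride 16, atrous spatial pyramid
#' pooling (ASPP) over the encoder output, and a decoder that fuses the
#' stride-4 low-level feature path. When `use_cbam` is on, a CBAM block
#' transforms the encoder's final feature map before ASPP; when `use_eca` is
#' on, an ECA block transforms the low-level path immediately before the
#' decoder concatenation.
#'
#' @param n_classes Number of output classes (>= 2; default 5).
#' @param input_size Input side length in pixels; must be divisible by 16.
#' @param aspp_rates Dilation rates of the parallel ASPP branches.
#' @param use_cbam,use_eca Attention toggles.
#' @param cbam_reduction CBAM channel-bottleneck ratio (default 16).
#' @param eca_gamma,eca_b ECA kernel-size coefficients (defaults 2 and 1).
#' @param channels Named list of widths: `stem`, `enc1`, `enc2`, `enc3`
#'   (encoder stages at strides 2/4/8/16), `aspp`, `low`, `decoder`.
#' @return A `model_config` list.
#' @export
model_config <- function(n_classes = 5L, input_size = 128L,
                         aspp_rates = c(2L, 4L, 6L),
                         use_cbam = TRUE, use_eca = TRUE,
                         cbam_reduction = 16L, eca_gamma = 2, eca_b = 1,
                         channels = NULL) {
  if (n_classes < 2L) stop_bad_arg("`n_classes` must be >= 2")
  if (length(aspp_rates) == 0L) stop_bad_arg("`aspp_rates` must be nonempty")
  if (cbam_reduction < 1L) stop_bad_arg("`cbam_reduction` must be >= 1")
  if (input_size %% 16L != 0L) {
    stop_bad_arg("`input_size` must be divisible by the encoder stride (16)")
  }
  ch <- utils::modifyList(
    list(stem = 12L, enc1 = 16L, enc2 = 24L, enc3 = 32L,
         aspp = 24L, low = 12L, decoder = 32L),
    channels %||% list())
  if (use_cbam && ch$enc3 %% cbam_reduction != 0) {
    stop_bad_arg("encoder output channels must be divisible by cbam_reduction")
  }
  structure(list(n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 aspp_rates = as.integer(aspp_rates),
                 use_cbam = isTRUE(use_cbam), use_eca = isTRUE(use_eca),
                 cbam_reduction = as.integer(cbam_reduction),
                 eca_gamma = eca_gamma, eca_b = eca_b, channels = ch),
            class = "model_config")
}

# encoder stage: strided conv + BN + ReLU, then a residual unit
make_stage <- function(in_c, out_c) {
  make_seq(
    make_conv(in_c, out_c, k = 3L, stride = 2L, bias = FALSE), make_bn(out_c),
    make_relu(),
    make_residual(make_seq(make_conv(out_c, out_c, k = 3L, bias = FALSE),
                           make_bn(out_c))),
    make_relu()
  )
}

#' Build the attention-augmented DeepLabv3+ model
#'
#' @param config A [model_config()].
#' @param seed Seed for weight initialization.
#' @return An `orchard_segnet` environment holding all layers.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  ch <- config$channels
  with_seed(seed, {
    m <- new.env(parent = emptyenv())
    m$config <- config
    m$stem <- make_seq(make_conv(3L, ch$stem, k = 3L, stride = 2L, bias = FALSE),
                       make_bn(ch$stem), make_relu())
    m$enc1 <- make_stage(ch$stem, ch$enc1)   # stride 4, low-level tap
    m$enc2 <- make_stage(ch$enc1, ch$enc2)   # stride 8
    m$enc3 <- make_stage(ch$enc2, ch$enc3)   # stride 16
    m$cbam <- if (config$use_cbam) make_cbam(ch$enc3, config$cbam_reduction) else NULL
    m$aspp_branches <- c(
      list(make_seq(make_conv(ch$enc3, ch$aspp, k = 1L, bias = FALSE),
                    make_bn(ch$aspp), make_relu())),
      lapply(config$aspp_rates, function(r) {
        make_seq(make_conv(ch$enc3, ch$aspp, k = 3L, dilation = r, bias = FALSE),
                 make_bn(ch$aspp), make_relu())
      }),
      list(make_aspp_pool(ch$enc3, ch$aspp))
    )
    n_br <- length(m$aspp_branches)
    m$aspp_proj <- make_seq(make_conv(n_br * ch$aspp, ch$aspp, k = 1L, bias = FALSE),
                            make_bn(ch$aspp), make_relu())
    m$up4 <- make_upsample(factor = 4L)
    m$eca <- if (config$use_eca) make_eca(ch$enc1, config$eca_gamma, config$eca_b) else NULL
    m$low_proj <- make_seq(make_conv(ch$enc1, ch$low, k = 1L, bias = FALSE),
                           make_bn(ch$low), make_relu())
    m$decoder <- make_seq(make_conv(ch$aspp + ch$low, ch$decoder, k = 3L, bias = FALSE),
                          make_bn(ch$decoder), make_relu())
    m$classifier <- make_conv(ch$decoder, config$n_classes, k = 1L)
    m$up_final <- make_upsample(factor = 4L)
    class(m) <- "orchard_segnet"
    m
  })
}

model_layers <- function(m) {
  roots <- list(m$stem, m$enc1, m$enc2, m$enc3, m$cbam, m$aspp_proj,
                m$eca, m$low_proj, m$decoder, m$classifier)
  roots <- c(roots, m$aspp_branches)
  unlist(lapply(Filter(Negate(is.null), roots), collect_layers),
         recursive = FALSE)
}

#' Total trainable parameter count
#'
#' @param model An `orchard_segnet`.
#' @return Integer number of scalar parameters.
#' @export
count_parameters <- function(model) layer_param_count(model_layers(model))

#' Enumerate the attention blocks of a model
#'
#' Introspection over the architecture: reports each inserted attention
#' module and its position in the network.
#'
#' @param model An `orchard_segnet`.
#' @return Data frame with columns `block`, `position`, `n_parameters`.
#' @export
attention_blocks <- function(model) {
  rows <- list()
  if (!is.null(model$cbam)) {
    rows[[length(rows) + 1L]] <- data.frame(
      block = "CBAM", position = "encoder output, before ASPP",
      n_parameters = layer_param_count(list(model$cbam)))
  }
  if (!is.null(model$eca)) {
    rows[[length(rows) + 1L]] <- data.frame(
      block = "ECA", position = "low-level path, before decoder concatenation",
      n_parameters = layer_param_count(list(model$eca)))
  }
  if (length(rows) == 0L) {
    return(data.frame(block = character(0), position = character(0),
                      n_parameters = integer(0)))
  }
  do.call(rbind, rows)
}

# Full forward pass; returns logits and keeps all caches for backward.
model_forward <- function(m, x, training = FALSE) {
  d <- dim(x)
  if (d[2] %% 16L != 0L || d[3] %% 16L != 0L) {
    stop_bad_arg("input spatial size must be divisible by 16")
  }
  s <- layer_forward(m$stem, x, training)
  l1 <- layer_forward(m$enc1, s, training)
  l2 <- layer_forward(m$enc2, l1, training)
  l3 <- layer_forward(m$enc3, l2, training)
  t3 <- if (!is.null(m$cbam)) layer_forward(m$cbam, l3, training) else l3
  branches <- lapply(m$aspp_branches, function(br) layer_forward(br, t3, training))
  m$branch_channels <- vapply(branches, function(y) dim(y)[4], 0L)
  z <- array(unlist(lapply(branches, as.vector), use.names = FALSE),
             c(dim(branches[[1]])[1:3], sum(m$branch_channels)))
  z <- layer_forward(m$aspp_proj, z, training)
  zu <- layer_forward(m$up4, z, training)
  ll <- if (!is.null(m$eca)) layer_forward(m$eca, l1, training) else l1
  ll <- layer_forward(m$low_proj, ll, training)
  m$dec_channels <- c(dim(zu)[4], dim(ll)[4])
  dd <- array(c(as.vector(zu), as.vector(ll)),
              c(dim(zu)[1:3], sum(m$dec_channels)))
  dd <- layer_forward(m$decoder, dd, training)
  logits <- layer_forward(m$classifier, dd, training)
  layer_forward(m$up_final, logits, training)
}

model_backward <- function(m, dlogits) {
  dl <- layer_backward(m$up_final, dlogits)
  dd <- layer_backward(m$classifier, dl)
  dd <- layer_backward(m$decoder, dd)
  ch <- m$dec_channels
  dzu <- dd[, , , seq_len(ch[1]), drop = FALSE]
  dll <- dd[, , , ch[1] + seq_len(ch[2]), drop = FALSE]
  dll <- layer_backward(m$low_proj, dll)
  dl1_low <- if (!is.null(m$eca)) layer_backward(m$eca, dll) else dll
  dz <- layer_backward(m$up4, dzu)
  dz <- layer_backward(m$aspp_proj, dz)
  bc <- m$branch_channels
  off <- 0L
  dt3 <- NULL
  for (i in seq_along(m$aspp_branches)) {
    dpart <- dz[, , , off + seq_len(bc[i]), drop = FALSE]
    off <- off + bc[i]
    dbr <- layer_backward(m$aspp_branches[[i]], dpart)
    dt3 <- if (is.null(dt3)) dbr else dt3 + dbr
  }
  dl3 <- if (!is.null(m$cbam)) layer_backward(m$cbam, dt3) else dt3
  dl2 <- layer_backward(m$enc3, dl3)
  dl1 <- layer_backward(m$enc2, dl2)
  dl1 <- dl1 + dl1_low
  ds <- layer_backward(m$enc1, dl1)
  dx <- layer_backward(m$stem, ds)
  invisible(dx)
}

#' Predict a label mask for an image
#'
#' Runs the model in inference mode and takes the per-pixel argmax of the
#' class logits; exact ties break toward the lowest label id.
#'
#' @param model An `orchard_segnet`.
#' @param image `H x W x 3` array with values in 0-255 (or a `seg_scene`).
#' @return `H x W` integer label matrix.
#' @export
predict_mask <- function(model, image) {
  if (inherits(image, "seg_scene")) image <- image$image
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop_bad_arg("`image` must be H x W x 3")
  x <- array(as.numeric(image) / 255, c(1L, d))
  logits <- model_forward(model, x, training = FALSE)
  lm <- matrix(logits, nrow = d[1] * d[2], ncol = dim(logits)[4])
  lab <- max.col(lm, ties.method = "first") - 1L
  matrix(lab, d[1], d[2])
}

#' @export
print.orchard_segnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<orchard_segnet> %d classes, input %d, CBAM=%s ECA=%s, %d parameters\n",
              cfg$n_classes, cfg$input_size, cfg$use_cbam, cfg$use_eca,
              count_parameters(x)))
  ab <- attention_blocks(x)
  if (nrow(ab) > 0) print(ab)
  invisible(x)
}
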