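# Shared fixtures, built in code at test time.

make_test_scenes <- function(n = 8L, size = 128L, seed0 = 100L) {
  lapply(seq_len(n), function(i) {
    generate_scene(scene_spec(size, size,
                              stage = if (i %% 2 == 1) "flowering" else "young_fruit",
                              seed = seed0 + i))
  })
}

tiny_model_config <- function(n_classes = 3L, input_size = 16L) {
  model_config(n_classes = n_classes, input_size = input_size,
               aspp_rates = c(1L, 2L),
               channels = list(stem = 4L, enc1 = 4L, enc2 = 6L, enc3 = 8L,
                               aspp = 4L, low = 4L, decoder = 6L),
               cbam_reduction = 4L)
}

# Independent ray-casting point-in-polygon (even-odd rule), used as the
# zonal-statistics oracle.
ray_cast_inside <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly_y[i] > py) != (poly_y[j] > py)) {
      xint <- poly_x[i] + (py - poly_y[i]) / (poly_y[j] - poly_y[i]) *
        (poly_x[j] - poly_x[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force per-pixel confusion tally, the metrics oracle.
brute_force_metrics <- function(preds, truths, k) {
  conf <- matrix(0, k, k)
  for (i in seq_along(preds)) {
    p <- preds[[i]]; t <- truths[[i]]
    for (r in seq_len(nrow(p))) for (cc in seq_len(ncol(p))) {
      conf[t[r, cc] + 1, p[r, cc] + 1] <- conf[t[r, cc] + 1, p[r, cc] + 1] + 1
    }
  }
  tp <- diag(conf); rs <- rowSums(conf); cs <- colSums(conf)
  pa <- sum(tp) / sum(conf)
  acc <- mean((tp / rs)[rs > 0])
  un <- rs + cs - tp
  iou <- ifelse(un > 0, tp / un, NA_real_)
  list(pa = pa, acc_class = acc, iou = iou, miou = mean(iou[un > 0]), conf = conf)
}
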