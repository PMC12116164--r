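#' Training configuration for the segmentation network
#'
#' Defaults mirror the field-scale regime (300 epochs, batch size 8,
#' learning rate 0.01, 4:1 train/test split); desk-scale runs shrink epochs
#' and image size, not the regime's structure. The learning rate follows a
#' polynomial decay (the standard schedule for this architecture family) and
#' can be held constant instead.
#'
#' @param epochs Number of passes over the training scenes (default 300).
#' @param batch_size Scenes per gradient step (default 8).
#' @param learning_rate Initial SGD learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param split_ratio Train:test ratio used by [split_scenes()] (default 4:1).
#' @param val_fraction Fraction of the training scenes held out for the
#'   validation loss curve (default 0.1; with few scenes this may floor to
#'   zero, in which case the validation loss equals the training loss).
#' @param lr_schedule `"poly"` (default) or `"constant"`.
#' @param poly_power Exponent of the polynomial decay (default 0.9).
#' @param seed Integer seed controlling shuffling and the validation split.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 300L, batch_size = 8L, learning_rate = 0.01,
                         momentum = 0.9, split_ratio = c(4, 1),
                         val_fraction = 0.1,
                         lr_schedule = c("poly", "constant"),
                         poly_power = 0.9, seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  check_scalar_number(epochs, "epochs", lower = 1)
  check_scalar_number(batch_size, "batch_size", lower = 1)
  check_scalar_number(learning_rate, "learning_rate", lower = 0)
  check_scalar_number(val_fraction, "val_fraction", lower = 0, upper = 0.5)
  if (length(split_ratio) != 2L || any(split_ratio <= 0)) {
    stop_bad_arg("`split_ratio` must be two positive numbers")
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 split_ratio = split_ratio, val_fraction = val_fraction,
                 lr_schedule = lr_schedule, poly_power = poly_power,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split scenes into training and test sets
#'
#' @param scenes List of `seg_scene` objects.
#' @param ratio Two positive numbers, train:test (default 4:1).
#' @param seed Integer seed.
#' @return List with `train` and `test` scene lists.
#' @export
split_scenes <- function(scenes, ratio = c(4, 1), seed = 1L) {
  n <- length(scenes)
  if (n < 2L) stop_bad_arg("need at least 2 scenes")
  n_train <- min(max(1L, round(n * ratio[1] / sum(ratio))), n - 1L)
  idx <- with_seed(seed, sample.int(n))
  list(train = scenes[sort(idx[seq_len(n_train)])],
       test = scenes[sort(idx[seq(n_train + 1, n)])])
}

scenes_to_tensors <- function(scenes, n_classes) {
  d <- dim(scenes[[1]]$image)
  n <- length(scenes)
  x <- array(0, c(n, d[1], d[2], 3L))
  y <- array(0L, c(n, d[1], d[2]))
  for (i in seq_len(n)) {
    si <- scenes[[i]]
    if (!identical(dim(si$image), d)) stop_bad_arg("scenes must share dimensions")
    if (any(si$mask < 0 | si$mask >= n_classes)) {
      stop_bad_arg("scene ", i, " has labels outside [0, n_classes)")
    }
    x[i, , , ] <- si$image / 255
    y[i, , ] <- si$mask
  }
  list(x = x, y = y)
}

batch_loss <- function(model, x, y, training) {
  logits <- model_forward(model, x, training = training)
  softmax_ce(logits, y)
}

#' Train the segmentation network
#'
#' Optimizes pixel-wise cross-entropy with SGD + momentum over the scenes.
#' A fraction of the scenes is held out for the validation loss curve; the
#' model itself is updated only on the training portion. Deterministic given
#' the config seed (up to floating-point reduction order).
#'
#' @param model An `orchard_segnet` from [build_model()] (updated in place).
#' @param scenes List of at least 2 `seg_scene` objects with equal sizes.
#' @param tc A [train_config()].
#' @param stop_miou Optional early-stop target: every `check_every` epochs the
#'   training-set mIoU is evaluated (inference mode) and training stops once
#'   it is reached.
#' @param check_every Epoch interval of the early-stop check (default 25).
#' @return A `seg_training` list: the `model`, a `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`), and `n_steps` taken.
#' @export
train_segmenter <- function(model, scenes, tc = train_config(),
                            stop_miou = NULL, check_every = 25L) {
  stopifnot(inherits(model, "orchard_segnet"), inherits(tc, "train_config"))
  if (length(scenes) < 2L) stop_bad_arg("need at least 2 scenes to train")
  n_classes <- model$config$n_classes
  layers <- model_layers(model)

  with_seed(tc$seed, {
    n <- length(scenes)
    n_val <- floor(tc$val_fraction * n)
    idx <- sample.int(n)
    val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx, val_idx)
    tens <- scenes_to_tensors(scenes, n_classes)
    n_tr <- length(tr_idx)
    bs <- min(tc$batch_size, n_tr)
    n_batches <- ceiling(n_tr / bs)
    total_steps <- tc$epochs * n_batches

    history <- data.frame(epoch = seq_len(tc$epochs), train_loss = NA_real_,
                          val_loss = NA_real_)
    step <- 0L
    for (ep in seq_len(tc$epochs)) {
      ord <- tr_idx[sample.int(n_tr)]
      ep_loss <- 0
      for (bi in seq_len(n_batches)) {
        sel <- ord[((bi - 1L) * bs + 1L):min(bi * bs, n_tr)]
        xb <- tens$x[sel, , , , drop = FALSE]
        yb <- tens$y[sel, , , drop = FALSE]
        r <- batch_loss(model, xb, yb, training = TRUE)
        zero_grads(layers)
        model_backward(model, r$grad)
        lr_t <- if (tc$lr_schedule == "poly") {
          tc$learning_rate * (1 - step / total_steps)^tc$poly_power
        } else tc$learning_rate
        sgd_step(layers, lr_t, tc$momentum)
        step <- step + 1L
        ep_loss <- ep_loss + r$loss * length(sel)
      }
      history$train_loss[ep] <- ep_loss / n_tr
      history$val_loss[ep] <- if (length(val_idx) > 0) {
        xv <- tens$x[val_idx, , , , drop = FALSE]
        yv <- tens$y[val_idx, , , drop = FALSE]
        batch_loss(model, xv, yv, training = FALSE)$loss
      } else history$train_loss[ep]
      if (!is.null(stop_miou) && ep %% check_every == 0L && ep < tc$epochs) {
        miou <- evaluate_model(model, scenes[tr_idx])$miou
        if (miou >= stop_miou) {
          history <- history[seq_len(ep), , drop = FALSE]
          break
        }
      }
    }
    structure(list(model = model, history = history, n_steps = step),
              class = "seg_training")
  })
}

#' Evaluate a model on a list of scenes
#'
#' Predicts a mask for every scene and scores the predictions against the
#' ground-truth masks.
#'
#' @param model An `orchard_segnet`.
#' @param scenes List of `seg_scene` objects.
#' @return A `seg_metrics` object.
#' @export
evaluate_model <- function(model, scenes) {
  preds <- lapply(scenes, function(s) predict_mask(model, s$image))
  truths <- lapply(scenes, `[[`, "mask")
  evaluate_segmentation(preds, truths, model$config$n_classes)
}

# Snapshot / restore of all trainable state, in deterministic layer order.
model_state <- function(model) {
  lapply(model_layers(model), function(e) {
    st <- lapply(e$param_names, function(nm) get(nm, envir = e))
    names(st) <- e$param_names
    if (e$type == "bn") {
      st$running_mean <- e$running_mean
      st$running_var <- e$running_var
    }
    st
  })
}

set_model_state <- function(model, state) {
  layers <- model_layers(model)
  if (length(layers) != length(state)) stop_bad_arg("state does not match architecture")
  for (i in seq_along(layers)) {
    e <- layers[[i]]
    for (nm in e$param_names) assign(nm, state[[i]][[nm]], envir = e)
    if (e$type == "bn") {
      e$running_mean <- state[[i]]$running_mean
      e$running_var <- state[[i]]$running_var
    }
  }
  invisible(model)
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS file holding the parameter state; the model
#' configuration is written alongside as a JSON sidecar so the architecture
#' can be rebuilt before the state is restored.
#'
#' @param model An `orchard_segnet`.
#' @param path Checkpoint path (`.rds`); the sidecar gets `.json` appended.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  cfg <- model$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "channels")],
                       paste0(path, ".json"), auto_unbox = TRUE)
  saveRDS(list(config = cfg, state = model_state(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  cfg <- obj$config
  class(cfg) <- "model_config"
  model <- build_model(cfg, seed = 1L)
  set_model_state(model, obj$state)
  model
}
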