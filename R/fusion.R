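#' Aggregate raw SPAD readings to a plot value
#'
#' Field protocol: six leaf readings per tree (two per canopy layer); the tree
#' value is the mean of its six readings and the plot value the mean over
#' trees.
#'
#' @param spad Either a numeric matrix with one row per tree and six columns,
#'   or a data frame with columns `tree` and `spad` (six rows per tree).
#' @return Plot-level SPAD value (scalar).
#' @export
aggregate_spad <- function(spad) {
  if (is.data.frame(spad)) {
    per_tree <- split(spad$spad, spad$tree)
    n <- vapply(per_tree, length, 0L)
    if (any(n != 6L)) stop_bad_arg("each tree must have exactly 6 SPAD readings")
    return(mean(vapply(per_tree, mean, 0)))
  }
  spad <- as.matrix(spad)
  if (ncol(spad) != 6L) stop_bad_arg("expected 6 readings per tree (6 columns)")
  mean(rowMeans(spad))
}

#' Plot yield from harvest sampling averages
#'
#' The per-tree yield is the average fruit count times the average single
#' fruit weight; the plot yield multiplies by the number of trees in the plot
#' (default 20, i.e. two rows of ten).
#'
#' @param avg_fruit_count Mean fruits per tree (>= 0).
#' @param avg_fruit_weight_kg Mean single-fruit weight in kg (>= 0).
#' @param n_trees Trees per plot (default 20).
#' @return Plot yield in kg.
#' @export
compute_plot_yield <- function(avg_fruit_count, avg_fruit_weight_kg, n_trees = 20) {
  check_scalar_number(avg_fruit_count, "avg_fruit_count", lower = 0)
  check_scalar_number(avg_fruit_weight_kg, "avg_fruit_weight_kg", lower = 0)
  check_scalar_number(n_trees, "n_trees", lower = 0)
  avg_fruit_count * avg_fruit_weight_kg * n_trees
}

#' Sample Pearson correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 3), each with nonzero
#'   variance.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_bad_arg("`x` and `y` must have equal length")
  if (length(x) < 3L) stop_bad_arg("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_bad_arg("correlation undefined: zero variance")
  }
  stats::cor(x, y)
}

#' Correlation of every feature with yield
#'
#' @param records Data frame with feature columns and `yield_kg`.
#' @param features Feature names (default: the ten standard plot features).
#' @return Named vector of Pearson correlations with yield.
#' @export
yield_correlations <- function(records, features = PLOT_FEATURES) {
  vapply(features, function(f) pearson_r(records[[f]], records$yield_kg), 0)
}

#' Aliases between index symbols and short feature names
#'
#' The fused feature table names selected vegetation indices by short
#' aliases: `d1` = DVI, `d2` = GDVI, `d3` = GEVI, `k1` = VARI.
#'
#' @return Named character vector, alias -> index symbol.
#' @export
index_aliases <- function() {
  c(d1 = "DVI", d2 = "GDVI", d3 = "GEVI", k1 = "VARI")
}

#' Default Pearson screening rules
#'
#' Per-group absolute-correlation rules: SPAD and multispectral indices pass
#' at |r| > 0.6, structural ratios at |r| > 0.7, and only the single
#' best-correlated visible index is taken. `exclude` removes features by name
#' regardless of their correlation (the default excludes GNDVI, which is kept
#' out of the fused set even when it passes the multispectral threshold).
#'
#' @return List of group rules understood by [select_features()].
#' @export
default_screening_rules <- function() {
  list(
    spad = list(features = c("s1", "s2"), rule = "threshold", value = 0.6),
    structural = list(features = c("f1", "f2", "f3", "f4"),
                      rule = "threshold", value = 0.7),
    multispectral = list(features = c("DVI", "GDVI", "EVI", "GEVI", "NDVI",
                                      "GNDVI", "GRVI", "RVI", "d1", "d2", "d3"),
                         rule = "threshold", value = 0.6),
    visible = list(features = c("VARI", "ExR", "ExG", "GLI", "NDI", "MGRVI",
                                "ExGR", "RGBVI", "k1"),
                   rule = "top1"),
    exclude = "GNDVI"
  )
}

#' Screen features by Pearson correlation with yield
#'
#' Applies per-group rules to a correlation table: `threshold` keeps group
#' members with `|r|` above the group value, `top1` keeps the single member
#' with the largest `|r|`. Features named in `rules$exclude` are dropped
#' last. Features absent from the table are ignored; a table feature that
#' belongs to no group is an error.
#'
#' @param corr Named numeric vector of correlations (feature -> r).
#' @param rules Group rules, see [default_screening_rules()].
#' @return Character vector of selected feature names, ordered by group.
#' @export
select_features <- function(corr, rules = default_screening_rules()) {
  if (length(corr) == 0L) stop_bad_arg("empty correlation table")
  groups <- rules[setdiff(names(rules), "exclude")]
  known <- unlist(lapply(groups, `[[`, "features"), use.names = FALSE)
  orphan <- setdiff(names(corr), known)
  if (length(orphan) > 0) {
    stop_bad_arg("feature(s) in no screening group: ", paste(orphan, collapse = ", "))
  }
  selected <- character(0)
  for (g in groups) {
    members <- intersect(g$features, names(corr))
    if (length(members) == 0L) next
    r <- abs(corr[members])
    picked <- switch(g$rule,
      threshold = members[r > g$value],
      top1 = members[which.max(r)],
      stop_bad_arg("unknown rule: ", g$rule)
    )
    selected <- c(selected, picked)
  }
  setdiff(selected, rules$exclude %||% character(0))
}

#' Feature set definitions A-G
#'
#' The nested combinations of the three feature sources: SPAD (`A`),
#' structural ratios (`B`), selected vegetation indices (`C`), and their
#' unions `D = A+B`, `E = B+C`, `F = A+C`, `G = A+B+C`.
#'
#' @param id One of `"A"`..`"G"`.
#' @return Ordered character vector of column names.
#' @export
feature_set_columns <- function(id) {
  a <- c("s1", "s2"); b <- c("f1", "f2", "f3", "f4"); cc <- c("d1", "d2", "d3", "k1")
  switch(toupper(id),
    A = a, B = b, C = cc,
    D = c(a, b), E = c(b, cc), F = c(a, cc), G = c(a, b, cc),
    stop_bad_arg("unknown feature set id: ", id)
  )
}

#' Build a feature matrix and target vector
#'
#' @param records Data frame of plot records including `yield_kg`.
#' @param spec A feature-set id (`"A"`..`"G"`) or a character vector of
#'   column names.
#' @return List: `X` (numeric matrix, columns in spec order), `y` (yield),
#'   `columns`.
#' @export
build_feature_matrix <- function(records, spec) {
  cols <- if (length(spec) == 1L && toupper(spec) %in% LETTERS[1:7]) {
    feature_set_columns(spec)
  } else as.character(spec)
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    stop_bad_arg("missing feature column(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(records[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop_bad_arg("non-finite feature values")
  list(X = X, y = records$yield_kg, columns = cols)
}

#' Shuffle-split records into train and test sets
#'
#' Seeded random shuffle; the training size is `floor(0.7 m + 0.5)`
#' (round-half-up) and the test set the remainder. The two parts are
#' disjoint and exhaustive.
#'
#' @param records Data frame (>= 10 rows).
#' @param train_frac Training fraction (default 0.7, the 7:3 split).
#' @param seed Integer seed.
#' @return List with data frames `train` and `test`.
#' @export
split_records <- function(records, train_frac = 0.7, seed = 1L) {
  m <- nrow(records)
  if (m < 10L) stop_bad_arg("need at least 10 records to split")
  check_scalar_number(train_frac, "train_frac", lower = 0.05, upper = 0.95)
  n_train <- floor(train_frac * m + 0.5)
  idx <- with_seed(seed, sample.int(m))
  list(train = records[sort(idx[seq_len(n_train)]), , drop = FALSE],
       test = records[sort(idx[(n_train + 1):m]), , drop = FALSE])
}

# z-score standardization fitted on the training matrix only
fit_scaler <- function(X) {
  mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

# 5-fold CV selection of the PLS component count on the training split.
select_pls_ncomp <- function(X, y, max_comp, folds = 5L) {
  m <- nrow(X)
  fold_id <- rep(seq_len(folds), length.out = m)[sample.int(m)]
  press <- numeric(max_comp)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sum(tr) <= max_comp || sum(!tr) == 0) next
    fit <- mixOmics::pls(X[tr, , drop = FALSE], y[tr], ncomp = max_comp,
                         mode = "regression", scale = TRUE)
    pr <- predict(fit, newdata = X[!tr, , drop = FALSE])$predict
    for (k in seq_len(max_comp)) press[k] <- press[k] + sum((pr[, 1, k] - y[!tr])^2)
  }
  which.min(press)
}

#' Fit a yield regressor and predict both splits
#'
#' Fits one of the four supported model families and returns train/test
#' predictions. Features are z-score standardized (fitted on the training
#' split) for KNN, PLS and SVM; the random forest uses unscaled features.
#' Defaults: KNN `k = 5`; PLS components chosen by 5-fold cross-validation on
#' the training split over `1..min(p, n-1)`; RF 500 trees; SVM with a radial
#' kernel, `epsilon = 0.01`, and `cost`/`gamma` grid-searched by 5-fold
#' cross-validation on the training split. All hyperparameters can be
#' overridden via `hyperparams`.
#'
#' @param model_name `"KNN"`, `"PLS"`, `"RF"` or `"SVM"`.
#' @param train,test Lists from [build_feature_matrix()].
#' @param hyperparams Named list of overrides (`k`, `ncomp`, `ntree`,
#'   `nodesize`, `cost`, `gamma`, `epsilon`, `cost_grid`, `gamma_grid`).
#' @param seed Integer seed (controls CV folds and the forest).
#' @return List: `model_name`, `pred_train`, `pred_test`, `details` (fitted
#'   object plus, for PLS, raw-scale `coefficients` and `intercept`).
#' @export
fit_and_predict <- function(model_name, train, test, hyperparams = list(),
                            seed = 1L) {
  model_name <- toupper(model_name)
  if (!model_name %in% c("KNN", "PLS", "RF", "SVM")) {
    stop_bad_arg("unknown model: ", model_name)
  }
  X_tr <- train$X; y_tr <- train$y
  X_te <- test$X
  if (!all(is.finite(X_tr)) || !all(is.finite(X_te))) stop_bad_arg("non-finite features")
  p <- ncol(X_tr); n <- nrow(X_tr)
  hp <- hyperparams
  details <- list()

  with_seed(seed, {
    if (model_name == "RF") {
      fit <- randomForest::randomForest(
        x = X_tr, y = y_tr,
        ntree = hp$ntree %||% 500L,
        nodesize = hp$nodesize %||% 5L)
      pred_tr <- as.vector(stats::predict(fit, X_tr))
      pred_te <- as.vector(stats::predict(fit, X_te))
      details$fit <- fit
    } else {
      sc <- fit_scaler(X_tr)
      Z_tr <- apply_scaler(X_tr, sc); Z_te <- apply_scaler(X_te, sc)

      if (model_name == "KNN") {
        k <- hp$k %||% 5L
        if (k > n) stop_bad_arg("KNN k exceeds training size")
        fit <- caret::knnreg(Z_tr, y_tr, k = k)
        pred_tr <- as.vector(stats::predict(fit, Z_tr))
        pred_te <- as.vector(stats::predict(fit, Z_te))
        details$fit <- fit
      } else if (model_name == "PLS") {
        max_comp <- min(p, n - 1L)
        ncomp <- hp$ncomp %||% select_pls_ncomp(Z_tr, y_tr, max_comp)
        fit <- mixOmics::pls(Z_tr, y_tr, ncomp = ncomp, mode = "regression",
                             scale = TRUE)
        pr_tr <- predict(fit, newdata = Z_tr)
        pred_tr <- as.vector(pr_tr$predict[, 1, ncomp])
        pred_te <- as.vector(predict(fit, newdata = Z_te)$predict[, 1, ncomp])
        # raw-scale coefficients: undo both the PLS internal scaling and ours
        b_std <- pr_tr$B.hat[, 1, ncomp]
        sz <- apply(Z_tr, 2, stats::sd); sz[sz == 0] <- 1
        b_z <- b_std * stats::sd(y_tr) / sz
        b_raw <- b_z / sc$sd
        details$coefficients <- b_raw
        details$intercept <- mean(y_tr) - sum(b_raw * sc$mu)
        details$ncomp <- ncomp
        details$fit <- fit
      } else { # SVM
        eps <- hp$epsilon %||% 0.01
        if (is.null(hp$cost) || is.null(hp$gamma)) {
          cost_grid <- hp$cost_grid %||% 10^(0:3)
          gamma_grid <- hp$gamma_grid %||% (c(0.25, 1, 4) / p)
          folds <- rep(seq_len(5L), length.out = n)[sample.int(n)]
          best <- c(Inf, cost_grid[1], gamma_grid[1])
          for (co in cost_grid) for (ga in gamma_grid) {
            sse <- 0
            for (f in seq_len(5L)) {
              tr <- folds != f
              m0 <- e1071::svm(Z_tr[tr, , drop = FALSE], y_tr[tr],
                               kernel = "radial", cost = co, gamma = ga,
                               epsilon = eps, scale = FALSE)
              sse <- sse + sum((stats::predict(m0, Z_tr[!tr, , drop = FALSE]) - y_tr[!tr])^2)
            }
            if (sse < best[1]) best <- c(sse, co, ga)
          }
          hp$cost <- best[2]; hp$gamma <- best[3]
        }
        fit <- e1071::svm(Z_tr, y_tr, kernel = "radial", cost = hp$cost,
                          gamma = hp$gamma, epsilon = eps, scale = FALSE)
        pred_tr <- as.vector(stats::predict(fit, Z_tr))
        pred_te <- as.vector(stats::predict(fit, Z_te))
        details$fit <- fit
        details$cost <- hp$cost; details$gamma <- hp$gamma
      }
      details$scaler <- sc
    }
  })
  list(model_name = model_name, pred_train = pred_tr, pred_test = pred_te,
       details = details)
}

#' Regression accuracy: R-squared and RMSE
#'
#' `R2 = 1 - sum((yhat - y)^2) / sum((mean(y) - y)^2)` and
#' `RMSE = sqrt(mean((y - yhat)^2))` (kg). Perfect prediction gives (1, 0);
#' predicting the mean gives R2 = 0.
#'
#' @param y True values (nonzero variance).
#' @param yhat Predictions, same length.
#' @return List: `R2`, `RMSE`, `m`.
#' @export
evaluate_regression <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0L) {
    stop_bad_arg("`y` and `yhat` must be nonempty and of equal length")
  }
  ss_tot <- sum((mean(y) - y)^2)
  if (ss_tot == 0) stop_bad_arg("R2 undefined: zero target variance")
  ss_res <- sum((yhat - y)^2)
  list(R2 = 1 - ss_res / ss_tot, RMSE = sqrt(mean((y - yhat)^2)), m = length(y))
}

#' Fit all requested models over all requested feature sets
#'
#' Runs the full evaluation grid: for each feature set and model family the
#' records are split 7:3 (same seeded split for every cell), the model is
#' fitted on the training part, and R-squared / RMSE are reported for both
#' splits.
#'
#' @param records Plot records data frame.
#' @param feature_sets Character vector of set ids (default A, B, C, G).
#' @param models Character vector of model names (default all four).
#' @param seed Integer seed used for the split and all model fits.
#' @param hyperparams Optional named list of per-model hyperparameter lists.
#' @return Data frame: `feature_set`, `model`, `split`, `R2`, `RMSE`, `m`.
#' @export
yield_model_grid <- function(records, feature_sets = c("A", "B", "C", "G"),
                             models = c("KNN", "PLS", "RF", "SVM"),
                             seed = 1L, hyperparams = list()) {
  parts <- split_records(records, seed = seed)
  rows <- list()
  for (fs in feature_sets) {
    tr <- build_feature_matrix(parts$train, fs)
    te <- build_feature_matrix(parts$test, fs)
    for (mo in models) {
      fp <- fit_and_predict(mo, tr, te, hyperparams[[mo]] %||% list(), seed = seed)
      ev_tr <- evaluate_regression(tr$y, fp$pred_train)
      ev_te <- evaluate_regression(te$y, fp$pred_test)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_set = fs, model = mo,
        split = c("train", "test"),
        R2 = c(ev_tr$R2, ev_te$R2), RMSE = c(ev_tr$RMSE, ev_te$RMSE),
        m = c(ev_tr$m, ev_te$m))
    }
  }
  do.call(rbind, rows)
}
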