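test_that("SPAD aggregation is the nested tree/leaf mean", {
  expect_equal(aggregate_spad(matrix(40, 1, 6)), 40)
  m3 <- rbind(rep(40, 6), rep(42, 6), rep(44, 6))
  expect_equal(aggregate_spad(m3), 42)
  set.seed(2)
  rand <- matrix(runif(18, 30, 50), 3, 6)
  expect_equal(aggregate_spad(rand), mean(rowMeans(rand)), tolerance = 1e-12)
  df <- data.frame(tree = rep(1:2, each = 6), spad = runif(12))
  expect_equal(aggregate_spad(df),
               mean(c(mean(df$spad[1:6]), mean(df$spad[7:12]))), tolerance = 1e-12)
  expect_error(aggregate_spad(matrix(1, 2, 5)), "6")
  expect_error(aggregate_spad(data.frame(tree = 1, spad = 1)), "6")
})

test_that("plot yield is count x weight x trees", {
  expect_equal(compute_plot_yield(80, 0.25, 20), 400)
  expect_equal(compute_plot_yield(0, 0.3), 0)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0, 200); b <- runif(1, 0, 0.5); n <- sample(1:30, 1)
    expect_equal(compute_plot_yield(a, b, n), a * b * n, tolerance = 1e-12)
  }
  expect_error(compute_plot_yield(-1, 0.2), "avg_fruit_count")
})

test_that("Pearson correlation handles the canonical cases", {
  expect_equal(pearson_r(1:3, c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(1:3, c(3, 2, 1)), -1.0)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), manual, tolerance = 1e-15)
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
})

test_that("screening rules pick features by group thresholds", {
  toy <- c(a = 0.9, b = 0.1)
  rules <- list(g1 = list(features = c("a", "b"), rule = "threshold", value = 0.6))
  expect_equal(select_features(toy, rules), "a")
  # a zero threshold is vacuous: everything passes, input order kept
  rules0 <- list(g1 = list(features = c("a", "b"), rule = "threshold", value = 0))
  expect_equal(select_features(toy, rules0), c("a", "b"))
  expect_error(select_features(c(zz = 0.5), rules), "no screening group")
})

test_that("default rules reproduce the ten-feature fused set on the reference table", {
  ref <- c(s1 = 0.702, s2 = 0.689,
           MGRVI = 0.445, RGBVI = 0.186, ExR = 0.245, NDI = 0.353,
           VARI = 0.755, ExG = 0.423, ExGR = 0.024, GLI = 0.437,
           DVI = 0.687, GDVI = 0.642, GEVI = 0.602, NDVI = 0.398,
           GRVI = 0.501, GNDVI = 0.742, EVI = 0.429, RVI = 0.505,
           f1 = 0.792, f2 = 0.750, f3 = 0.740, f4 = 0.800)
  sel <- select_features(ref)
  expect_setequal(sel, c("s1", "s2", "f1", "f2", "f3", "f4",
                         "DVI", "GDVI", "GEVI", "VARI"))
  # GNDVI passes the multispectral threshold but is explicitly excluded
  expect_false("GNDVI" %in% sel)
  expect_true(abs(ref[["GNDVI"]]) > 0.6)
})

test_that("feature sets follow the A-G nesting", {
  expect_equal(feature_set_columns("A"), c("s1", "s2"))
  expect_equal(feature_set_columns("B"), c("f1", "f2", "f3", "f4"))
  expect_equal(feature_set_columns("C"), c("d1", "d2", "d3", "k1"))
  expect_equal(feature_set_columns("G"),
               c("s1", "s2", "f1", "f2", "f3", "f4", "d1", "d2", "d3", "k1"))
  expect_equal(intersect(feature_set_columns("E"), feature_set_columns("F")),
               feature_set_columns("C"))
  expect_error(feature_set_columns("Z"), "unknown feature set")
})

test_that("feature matrices respect set order and flag missing columns", {
  plots <- generate_plot_dataset(80, seed = 3)
  fm <- build_feature_matrix(plots, "G")
  expect_equal(ncol(fm$X), 10L)
  expect_equal(colnames(fm$X), feature_set_columns("G"))
  fmA <- build_feature_matrix(plots, "A")
  expect_equal(dim(fmA$X), c(80L, 2L))
  broken <- plots; broken$d2 <- NULL
  expect_error(build_feature_matrix(broken, "C"), "d2")
})

test_that("the 7:3 split is seeded, disjoint and exhaustive", {
  plots <- generate_plot_dataset(80, seed = 1)
  sp <- split_records(plots, seed = 4)
  expect_equal(nrow(sp$train), 56L)
  expect_equal(nrow(sp$test), 24L)
  expect_identical(split_records(plots, seed = 4)$train$plot_id, sp$train$plot_id)
  for (seed in 1:5) {
    s <- split_records(plots, seed = seed)
    expect_equal(sort(c(s$train$plot_id, s$test$plot_id)), sort(plots$plot_id))
    expect_length(intersect(s$train$plot_id, s$test$plot_id), 0)
  }
  p10 <- generate_plot_dataset(10, seed = 2)
  s10 <- split_records(p10, seed = 1)
  expect_equal(c(nrow(s10$train), nrow(s10$test)), c(7L, 3L))
  expect_error(split_records(p10[1:5, ]), "at least 10")
})

test_that("R2 and RMSE match their defining formulas", {
  y <- c(1, 2, 3); yhat <- c(1, 2, 4)
  ev <- evaluate_regression(y, yhat)
  expect_equal(ev$R2, 0.5)                    # 1 - 1/2
  expect_equal(ev$RMSE, sqrt(1 / 3), tolerance = 1e-15)
  expect_equal(evaluate_regression(y, y), list(R2 = 1, RMSE = 0, m = 3L))
  ev0 <- evaluate_regression(y, rep(mean(y), 3))
  expect_equal(ev0$R2, 0)
  set.seed(8)
  for (i in 1:50) {
    yy <- rnorm(20); pp <- rnorm(20)
    ev <- evaluate_regression(yy, pp)
    expect_equal(ev$R2, 1 - sum((pp - yy)^2) / sum((mean(yy) - yy)^2),
                 tolerance = 1e-12)
    expect_equal(ev$RMSE, sqrt(sum((yy - pp)^2) / 20), tolerance = 1e-12)
  }
  expect_error(evaluate_regression(c(1, 1), c(1, 2)), "zero target variance")
  expect_error(evaluate_regression(1:3, 1:4), "equal length")
})

test_that("noise-free linear data is fit nearly perfectly by PLS and KNN k=1", {
  plots <- generate_plot_dataset(80, noise_sd = 0, seed = 7)
  parts <- split_records(plots, seed = 7)
  tr <- build_feature_matrix(parts$train, "G")
  te <- build_feature_matrix(parts$test, "G")
  fp <- fit_and_predict("PLS", tr, te, seed = 7)
  expect_gte(evaluate_regression(te$y, fp$pred_test)$R2, 0.999)
  # PLS with all components recovers the generative coefficients
  beta <- attr(plots, "beta")
  expect_lt(max(abs(fp$details$coefficients - beta[-1])), 1e-6)
  expect_lt(abs(fp$details$intercept - beta[["intercept"]]), 1e-6)

  k1 <- fit_and_predict("KNN", tr, te, hyperparams = list(k = 1), seed = 1)
  expect_equal(k1$pred_train, tr$y)   # nearest neighbor of a row is itself
})

test_that("SVM agrees with an independent implementation of the same kernel machine", {
  plots <- generate_plot_dataset(80, noise_sd = 5, seed = 7)
  parts <- split_records(plots, seed = 7)
  tr <- build_feature_matrix(parts$train, "G")
  te <- build_feature_matrix(parts$test, "G")
  fp <- fit_and_predict("SVM", tr, te, seed = 7)
  r2 <- evaluate_regression(te$y, fp$pred_test)$R2
  expect_gte(r2, 0.9)

  # refit the identical formulation (RBF eps-SVR) with kernlab
  sc <- fp$details$scaler
  Ztr <- orchardyield:::apply_scaler(tr$X, sc)
  Zte <- orchardyield:::apply_scaler(te$X, sc)
  kfit <- kernlab::ksvm(Ztr, tr$y, type = "eps-svr", kernel = "rbfdot",
                        kpar = list(sigma = fp$details$gamma),
                        C = fp$details$cost, epsilon = 0.01, scaled = FALSE)
  kpred <- as.vector(kernlab::predict(kfit, Zte))
  agree <- evaluate_regression(kpred, fp$pred_test)$R2
  expect_gte(agree, 0.98)
  expect_gte(evaluate_regression(te$y, kpred)$R2, 0.9)
})

test_that("unknown models and oversized k are rejected", {
  plots <- generate_plot_dataset(20, seed = 1)
  parts <- split_records(plots, seed = 1)
  tr <- build_feature_matrix(parts$train, "A")
  te <- build_feature_matrix(parts$test, "A")
  expect_error(fit_and_predict("GBM", tr, te), "unknown model")
  expect_error(fit_and_predict("KNN", tr, te, hyperparams = list(k = 99)),
               "exceeds")
})

test_that("the model grid covers sets x models x splits deterministically", {
  plots <- generate_plot_dataset(30, noise_sd = 5, seed = 5)
  grid <- yield_model_grid(plots, feature_sets = c("A", "B"),
                           models = c("KNN", "PLS"), seed = 5)
  expect_equal(nrow(grid), 2 * 2 * 2)
  expect_setequal(unique(grid$split), c("train", "test"))
  grid2 <- yield_model_grid(plots, feature_sets = c("A", "B"),
                            models = c("KNN", "PLS"), seed = 5)
  expect_identical(grid, grid2)
})
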