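test_that("an organ-free spec yields an all-background scene", {
  sp <- scene_spec(64, 48, "flowering", n_flowers_or_fruits = 0,
                   leaf_coverage = 0, branch_thickness = 0, seed = 5)
  sc <- generate_scene(sp)
  expect_true(all(sc$mask == 0))
  expect_equal(unname(sc$true_counts[["background"]]), 48 * 64)
  expect_equal(sum(sc$true_counts), 48 * 64)
  expect_true(all(sc$image >= 245))
})

test_that("identical spec and seed give bit-identical scenes", {
  sp <- scene_spec(96, 96, "young_fruit", seed = 42)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$true_counts, b$true_counts)
})

test_that("flower pixel count matches a brute-force in-circle rasterization", {
  sp <- scene_spec(80, 80, "flowering", n_flowers_or_fruits = 1,
                   leaf_coverage = 0, branch_thickness = 0,
                   organ_radius = 20, seed = 9)
  sc <- generate_scene(sp)
  org <- sc$organs
  expect_equal(nrow(org), 1L)
  # independent per-pixel in-circle test at the recorded center
  n_inside <- 0L
  for (i in 1:80) for (j in 1:80) {
    if ((i - org$cy)^2 + (j - org$cx)^2 <= org$radius^2) n_inside <- n_inside + 1L
  }
  expect_equal(unname(sc$true_counts[["flower"]]), n_inside)
})

test_that("mask histogram equals true_counts and stages exclude the other organ", {
  for (seed in 1:6) {
    stage <- if (seed %% 2 == 0) "flowering" else "young_fruit"
    sc <- generate_scene(scene_spec(72, 88, stage, seed = seed))
    expect_identical(unname(tabulate(sc$mask + 1L, 5L)), unname(sc$true_counts))
    if (stage == "flowering") {
      expect_equal(unname(sc$true_counts[["fruit"]]), 0)
    } else {
      expect_equal(unname(sc$true_counts[["flower"]]), 0)
    }
  }
})

test_that("invalid scene specs are rejected", {
  expect_error(scene_spec(0, 64), "width")
  expect_error(scene_spec(64, 64, leaf_coverage = 1.2), "leaf_coverage")
})

test_that("noise-free rasters equal the analytic band means everywhere", {
  for (v in c(0, 0.4, 1)) {
    st <- generate_reflectance(v, width = 8, height = 6, seed = 1, noise_sd = 0)
    mu <- reflectance_band_means(v)
    for (band in names(mu)) {
      expect_equal(as.vector(st[[band]]), rep(mu[[band]], 48), tolerance = 1e-14)
    }
  }
})

test_that("NDVI and DVI increase with vigor, matching the band model", {
  vig <- seq(0, 1, length.out = 5)
  dvi <- vapply(vig, function(v) {
    st <- generate_reflectance(v, 10, 10, seed = 3, noise_sd = 0)
    mean(st$NIR - st$R)
  }, 0)
  expect_true(all(diff(dvi) > 0))
  # closed-form check: DVI = (0.30 + 0.45 v) - (0.30 - 0.18 v) = 0.63 v
  expect_equal(dvi, 0.63 * vig, tolerance = 1e-12)
  ndvi_lo <- with(generate_reflectance(0, 6, 6, seed = 1, noise_sd = 0),
                  mean((NIR - R) / (NIR + R)))
  ndvi_hi <- with(generate_reflectance(1, 6, 6, seed = 1, noise_sd = 0),
                  mean((NIR - R) / (NIR + R)))
  expect_gt(ndvi_hi, ndvi_lo)
})

test_that("reflectance values stay in [0, 1] and noise is reproducible", {
  a <- generate_reflectance(0.7, 16, 16, seed = 8, noise_sd = 0.05)
  b <- generate_reflectance(0.7, 16, 16, seed = 8, noise_sd = 0.05)
  expect_identical(a, b)
  for (band in names(a)) {
    expect_true(all(a[[band]] >= 0 & a[[band]] <= 1))
  }
})

test_that("noise-free plot yields equal the generative linear model exactly", {
  plots <- generate_plot_dataset(80, noise_sd = 0, seed = 4)
  beta <- attr(plots, "beta")
  X <- as.matrix(plots[, names(beta)[-1]])
  manual <- beta[["intercept"]] + as.vector(X %*% beta[-1])
  expect_equal(plots$yield_kg, pmax(manual, 0), tolerance = 1e-12)
})

test_that("a single-feature beta gives a perfect feature-yield correlation", {
  plots <- generate_plot_dataset(60, beta = c(intercept = 100, f4 = 80),
                                 noise_sd = 0, seed = 2)
  expect_equal(pearson_r(plots$f4, plots$yield_kg), 1.0, tolerance = 1e-12)
})

test_that("OLS on a large noisy dataset recovers the generative coefficients", {
  plots <- generate_plot_dataset(10000, noise_sd = 5, seed = 11)
  beta <- attr(plots, "beta")
  fit <- stats::lm(yield_kg ~ s1 + s2 + f1 + f2 + f3 + f4 + d1 + d2 + d3 + k1,
                   data = plots)
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  truth <- c(beta[["intercept"]], beta[-1])
  expect_true(all(abs(est - truth) <= 3 * se))
})

test_that("negative noise and too-few plots are rejected", {
  expect_error(generate_plot_dataset(20, noise_sd = -1), "non-negative")
  expect_error(generate_plot_dataset(1), "n_plots")
})

test_that("SPAD readings aggregate back to the plot values", {
  plots <- generate_plot_dataset(30, noise_sd = 0, seed = 6)
  spad <- simulate_spad_readings(plots, seed = 3)
  s1_hat <- vapply(plots$plot_id, function(pid) {
    dd <- spad[spad$plot_id == pid & spad$stage == "flowering", ]
    aggregate_spad(dd[, c("tree", "spad")])
  }, 0)
  expect_gt(stats::cor(s1_hat, plots$s1), 0.98)
  expect_lt(mean(abs(s1_hat - plots$s1)), 1.5)
})
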