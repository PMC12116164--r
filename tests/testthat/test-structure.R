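test_that("tile counts follow ceiling/floor arithmetic per pad policy", {
  img <- array(128, c(1024, 1536, 3))
  expect_equal(length(tile_image(img, tile_size = 512)$tiles), 6L)
  expect_equal(length(tile_image(img, tile_size = 512,
                                 pad_policy = "drop_partial")$tiles), 6L)

  img2 <- array(128, c(1000, 1300, 3))
  g2 <- tile_image(img2, mask = matrix(3L, 1000, 1300), tile_size = 512,
                   pad_policy = "pad_white")
  expect_equal(length(g2$tiles), 6L)
  # padded region is white in the image, background in the mask
  t6 <- g2$tiles[[6]]
  expect_equal(t6$valid_h, 1000 - 512)
  expect_true(all(t6$image[(t6$valid_h + 1):512, , ] == 255))
  expect_true(all(t6$mask[(t6$valid_h + 1):512, ] == 0))
  expect_true(all(t6$mask[seq_len(t6$valid_h), seq_len(t6$valid_w)] == 3L))

  expect_warning(g0 <- tile_image(array(0, c(100, 100, 3)), tile_size = 512,
                                  pad_policy = "drop_partial"),
                 "0 tiles")
  expect_equal(length(g0$tiles), 0L)
  expect_error(tile_image(img, tile_size = 0), "positive")
})

test_that("reflect padding mirrors content and keeps mask padding background", {
  img <- array(seq_len(6 * 5 * 3), c(6, 5, 3))
  msk <- matrix(rep(1:5, each = 6), 6, 5)
  g <- tile_image(img, msk, tile_size = 4, pad_policy = "pad_reflect")
  t4 <- g$tiles[[4]]  # bottom-right: rows 5:6, cols 5 valid
  expect_equal(t4$valid_h, 2L)
  expect_equal(t4$valid_w, 1L)
  # mirrored image content, background mask in the padded area
  expect_equal(t4$image[3, 1, 1], t4$image[2, 1, 1])
  expect_true(all(t4$mask[3:4, ] == 0))
  expect_true(all(t4$mask[, 2:4] == 0))
})

test_that("background-only tiles are filtered, others kept", {
  white <- array(255, c(8, 8, 3))
  half_leaf <- white
  half_leaf[1:4, , ] <- 80
  grid <- structure(list(
    tile_size = 8L, pad_policy = "pad_white", image_dim = c(8, 16),
    tiles = list(list(row = 0L, col = 0L, image = white, mask = NULL,
                      valid_h = 8L, valid_w = 8L),
                 list(row = 0L, col = 1L, image = half_leaf, mask = NULL,
                      valid_h = 8L, valid_w = 8L))), class = "tile_grid")
  kept <- filter_background_tiles(grid)
  expect_equal(length(kept$tiles), 1L)
  expect_equal(kept$tiles[[1]]$row, 0L)
  expect_equal(kept$tiles[[1]]$col, 1L)
  expect_equal(attr(kept, "n_dropped"), 1L)
  # pure white is dropped at any threshold below/at 255
  for (th in c(128, 240, 255)) {
    expect_equal(length(filter_background_tiles(grid, whiteness_threshold = th)$tiles), 1L)
  }
})

test_that("a scene with organs confined to the center tile keeps exactly one tile", {
  sc <- generate_scene(scene_spec(96, 96, "flowering", n_flowers_or_fruits = 1,
                                  leaf_coverage = 0, branch_thickness = 0,
                                  organ_radius = 12, seed = 13))
  # relocate the disc to the grid center by construction: draw directly
  mask <- matrix(0L, 96, 96)
  mask <- orchardyield:::paint_disc(mask, 48, 48, 12, 1L)
  img <- orchardyield:::render_scene_image(mask, 250)
  grid <- tile_image(img, mask, tile_size = 32)
  kept <- filter_background_tiles(grid, whiteness_threshold = 240,
                                  min_foreground_fraction = 0.01)
  # oracle: count non-white pixels tile by tile
  non_white <- vapply(grid$tiles, function(t) {
    sum(!apply(t$image >= 240, c(1, 2), all))
  }, 0)
  expect_equal(sum(non_white / (32 * 32) >= 0.01), 1L)
  expect_equal(length(kept$tiles), 1L)
  expect_equal(c(kept$tiles[[1]]$row, kept$tiles[[1]]$col), c(1L, 1L))
})

test_that("class pixel counting maps labels to the stage triple", {
  m <- matrix(0L, 30, 30)
  m[1:10, 1:10] <- 1L   # 100 flower
  m[11:25, 1:20] <- 3L  # 300 leaf
  m[26:30, 1:20] <- 4L  # 100 branch
  cnt <- count_class_pixels(m, stage = "flowering")
  expect_equal(cnt$FA, 100)
  expect_equal(cnt$IA, 300)
  expect_equal(cnt$GA, 100)
  expect_equal(cnt$background, 900 - 500)

  all_bg <- count_class_pixels(matrix(0L, 5, 5), stage = "young_fruit")
  expect_equal(all_bg$FB + all_bg$IB + all_bg$GB, 0)

  m2 <- m; m2[1, 30] <- 2L  # a fruit pixel in a flowering mask
  expect_warning(cnt2 <- count_class_pixels(m2, stage = "flowering"), "fruit")
  expect_equal(cnt2$FA, 100)
})

test_that("tiled ground-truth counts equal the generator's pixel ledger", {
  for (seed in c(3, 17)) {
    stage <- if (seed == 3) "flowering" else "young_fruit"
    sc <- generate_scene(scene_spec(100, 90, stage, seed = seed))
    grid <- tile_image(sc$image, sc$mask, tile_size = 32, pad_policy = "pad_white")
    cnt <- count_class_pixels(grid, stage = stage)
    organ <- if (stage == "flowering") "flower" else "fruit"
    triple <- if (stage == "flowering") c("FA", "IA", "GA") else c("FB", "IB", "GB")
    expect_equal(cnt[[triple[1]]], unname(sc$true_counts[[organ]]))
    expect_equal(cnt[[triple[2]]], unname(sc$true_counts[["leaf"]]))
    expect_equal(cnt[[triple[3]]], unname(sc$true_counts[["branch"]]))
    expect_equal(cnt$background, unname(sc$true_counts[["background"]]))
  }
})

test_that("structural ratios follow the canopy-share definitions", {
  cnt <- structure(list(stage = "flowering", FA = 100, IA = 300, GA = 100,
                        background = 0), class = "class_pixel_counts")
  r <- structural_ratios(cnt)
  expect_equal(r$total, 500)
  expect_equal(r$f1, 0.2)
  expect_equal(r$f2, 1 / 3)

  cnt2 <- structure(list(stage = "young_fruit", FB = 0, IB = 500, GB = 100,
                         background = 0), class = "class_pixel_counts")
  r2 <- structural_ratios(cnt2)
  expect_equal(r2$total, 600)
  expect_equal(r2$f3, 0)
  expect_equal(r2$f4, 0)

  # degenerate cases
  z <- structure(list(stage = "flowering", FA = 0, IA = 0, GA = 0,
                      background = 10), class = "class_pixel_counts")
  expect_error(structural_ratios(z), "SA = 0")
  bad <- structure(list(stage = "flowering", FA = 5, IA = 0, GA = 1,
                        background = 0), class = "class_pixel_counts")
  expect_error(structural_ratios(bad), "IA = 0")
  noleaf <- structure(list(stage = "flowering", FA = 0, IA = 0, GA = 7,
                           background = 0), class = "class_pixel_counts")
  expect_equal(structural_ratios(noleaf)$f2, 0)
})

test_that("ratios agree with exact-fraction evaluation over random counts", {
  set.seed(12)
  for (i in 1:1000) {
    fa <- sample(1:5000, 1); ia <- sample(1:5000, 1); ga <- sample(0:5000, 1)
    cnt <- structure(list(stage = "flowering", FA = fa, IA = ia, GA = ga,
                          background = 0), class = "class_pixel_counts")
    r <- structural_ratios(cnt)
    # exact-fraction identities evaluated in integer arithmetic
    expect_equal(r$f1 * (fa + ia + ga), fa, tolerance = 1e-15)
    expect_equal(r$f2 * ia, fa, tolerance = 1e-15)
    # class-share identity
    expect_equal(r$f1 + ia / r$total + ga / r$total, 1, tolerance = 1e-12)
  }
})

test_that("ratios are invariant to how the mask was tiled", {
  sc <- generate_scene(scene_spec(112, 80, "young_fruit", seed = 8))
  whole <- structural_ratios(count_class_pixels(sc$mask, "young_fruit"))
  for (ts in c(16, 48, 100)) {
    grid <- tile_image(sc$image, sc$mask, tile_size = ts, pad_policy = "pad_white")
    tiled <- structural_ratios(count_class_pixels(grid, "young_fruit"))
    expect_identical(tiled$f3, whole$f3)
    expect_identical(tiled$f4, whole$f4)
  }
})

test_that("adding flower pixels increases f1 and f2 strictly", {
  base <- structure(list(stage = "flowering", FA = 50, IA = 400, GA = 100,
                         background = 0), class = "class_pixel_counts")
  more <- structure(list(stage = "flowering", FA = 80, IA = 400, GA = 100,
                         background = 0), class = "class_pixel_counts")
  rb <- structural_ratios(base); rm <- structural_ratios(more)
  expect_gt(rm$f1, rb$f1)
  expect_gt(rm$f2, rb$f2)
})

test_that("per-tree ratios aggregate to the plot mean", {
  mk <- function(fa, ia) structural_ratios(structure(
    list(stage = "flowering", FA = fa, IA = ia, GA = 100, background = 0),
    class = "class_pixel_counts"))
  agg <- aggregate_tree_ratios(list(mk(100, 300), mk(200, 200)))
  expect_equal(unname(agg["f1"]), mean(c(100 / 500, 200 / 500)))
  expect_equal(unname(agg["f2"]), mean(c(1 / 3, 1)))
  expect_error(aggregate_tree_ratios(list(mk(1, 1), structural_ratios(
    structure(list(stage = "young_fruit", FB = 1, IB = 1, GB = 1, background = 0),
              class = "class_pixel_counts")))), "mixed")
})
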