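test_that("chromatic normalization sums to one and propagates nodata", {
  st <- band_stack(R = matrix(85, 2, 2), G = matrix(85, 2, 2), B = matrix(85, 2, 2))
  nm <- normalize_rgb(st)
  expect_equal(as.vector(nm$r), rep(1 / 3, 4))
  expect_equal(as.vector(nm$g), rep(1 / 3, 4))

  st2 <- band_stack(R = matrix(50), G = matrix(100), B = matrix(50))
  nm2 <- normalize_rgb(st2)
  expect_equal(c(nm2$r, nm2$g, nm2$b), c(0.25, 0.5, 0.25))

  st0 <- band_stack(R = matrix(c(0, 10), 1), G = matrix(c(0, 10), 1),
                    B = matrix(c(0, 20), 1))
  nm0 <- normalize_rgb(st0)
  expect_true(is.na(nm0$r[1, 1]))
  expect_false(anyNA(nm0$r[1, 2]))
  expect_equal(nm0$r[1, 2] + nm0$g[1, 2] + nm0$b[1, 2], 1, tolerance = 1e-12)
})

test_that("visible indices match hand arithmetic on chromatic coordinates", {
  nm <- structure(list(r = matrix(0.2), g = matrix(0.5), b = matrix(0.3)),
                  class = "normalized_rgb")
  vi <- visible_indices(nm)
  expect_equal(vi$VARI[1, 1], (0.5 - 0.2) / (0.5 + 0.2 - 0.3))  # 0.75
  expect_equal(vi$VARI[1, 1], 0.75)
  expect_equal(vi$ExG[1, 1], 2 * 0.5 - 0.2 - 0.3)               # 0.5
  expect_equal(vi$ExR[1, 1], 1.4 * 0.2 - 0.5)
  expect_equal(vi$GLI[1, 1], (2 * 0.5 - 0.3 - 0.2) / (2 * 0.5 + 0.3 + 0.2))
  expect_equal(vi$NDI[1, 1], (0.5 - 0.2) / (0.5 + 0.2))
  expect_equal(vi$MGRVI[1, 1], (0.25 - 0.04) / (0.25 + 0.04))
})

test_that("r = g implies zero NDI and MGRVI; VARI nodata is per-index", {
  nm <- structure(list(r = matrix(0.4), g = matrix(0.4), b = matrix(0.2)),
                  class = "normalized_rgb")
  vi <- visible_indices(nm)
  expect_equal(vi$NDI[1, 1], 0)
  expect_equal(vi$MGRVI[1, 1], 0)
  # g + r - b = 0 (exactly, in binary) kills VARI but not ExG
  nm2 <- structure(list(r = matrix(0.25), g = matrix(0.5), b = matrix(0.75)),
                   class = "normalized_rgb")
  vi2 <- visible_indices(nm2)
  expect_true(is.na(vi2$VARI[1, 1]))
  expect_false(is.na(vi2$ExG[1, 1]))
})

test_that("multispectral indices match hand arithmetic", {
  st <- band_stack(R = matrix(0.2), G = matrix(0.3), B = matrix(0.1),
                   NIR = matrix(0.6))
  mi <- multispectral_indices(st)
  expect_equal(mi$NDVI[1, 1], 0.5)
  expect_equal(mi$DVI[1, 1], 0.4)
  expect_equal(mi$GDVI[1, 1], 0.3)
  expect_equal(mi$EVI[1, 1], 2.5 * 0.4 / (0.6 + 1.2 - 0.75 + 1))
  expect_equal(mi$EVI[1, 1], 1 / 2.05, tolerance = 1e-12)
  expect_equal(mi$GEVI[1, 1], 2.5 * 0.3 / (0.6 + 1.8 - 0.75 + 1))
  # GNDVI as printed uses the blue band; the green variant is optional
  expect_equal(mi$GNDVI[1, 1], (0.6 - 0.1) / (0.6 + 0.1))
  mig <- multispectral_indices(st, gndvi = "green")
  expect_equal(mig$GNDVI[1, 1], (0.6 - 0.3) / (0.6 + 0.3))
})

test_that("zero cases and missing bands behave per contract", {
  st <- band_stack(R = matrix(c(0.3, 0)), G = matrix(c(0.2, 0)),
                   B = matrix(c(0.1, 0)), NIR = matrix(c(0.3, 0)))
  mi <- multispectral_indices(st)
  expect_equal(mi$DVI[1, 1], 0)     # NIR = R
  expect_equal(mi$NDVI[1, 1], 0)
  expect_true(is.na(mi$NDVI[2, 1])) # NIR + R = 0
  st_no_nir <- band_stack(R = matrix(1), G = matrix(1), B = matrix(1))
  expect_error(multispectral_indices(st_no_nir), "NIR")
})

test_that("chromatic indices are invariant to positive scaling of raw bands", {
  set.seed(5)
  R <- matrix(runif(12, 10, 200), 3, 4)
  G <- matrix(runif(12, 10, 200), 3, 4)
  B <- matrix(runif(12, 10, 200), 3, 4)
  v1 <- visible_indices(normalize_rgb(band_stack(R, G, B)))
  for (k in c(0.2, 7)) {
    v2 <- visible_indices(normalize_rgb(band_stack(k * R, k * G, k * B)))
    for (nm in names(v1)) expect_equal(v2[[nm]], v1[[nm]], tolerance = 1e-12)
  }
})

test_that("normalized-difference indices stay within [-1, 1]", {
  set.seed(9)
  st <- band_stack(R = matrix(runif(100), 10), G = matrix(runif(100), 10),
                   B = matrix(runif(100), 10), NIR = matrix(runif(100), 10))
  vi <- visible_indices(normalize_rgb(st))
  mi <- multispectral_indices(st)
  for (nm in c("NDI", "MGRVI")) {
    v <- vi[[nm]][!is.na(vi[[nm]])]
    expect_true(all(v >= -1 & v <= 1))
  }
  for (nm in c("NDVI", "GNDVI")) {
    v <- mi[[nm]][!is.na(mi[[nm]])]
    expect_true(all(v >= -1 & v <= 1))
  }
})

test_that("index maps computed tile-wise equal the whole-raster maps", {
  set.seed(2)
  st <- band_stack(R = matrix(runif(64), 8), G = matrix(runif(64), 8),
                   B = matrix(runif(64), 8), NIR = matrix(runif(64), 8))
  whole <- multispectral_indices(st)$NDVI
  halves <- lapply(list(1:4, 5:8), function(rows) {
    sub <- band_stack(R = st$R[rows, , drop = FALSE], G = st$G[rows, , drop = FALSE],
                      B = st$B[rows, , drop = FALSE], NIR = st$NIR[rows, , drop = FALSE])
    multispectral_indices(sub)$NDVI
  })
  expect_identical(rbind(halves[[1]], halves[[2]]), whole)
})

test_that("zonal means match a brute-force point-in-polygon tally", {
  # constant map over a polygon
  poly <- cbind(c(1, 5, 5, 1), c(1, 1, 5, 5))
  expect_equal(zonal_index(matrix(0.5, 8, 8), poly)$mean, 0.5)

  # polygon covering exactly 4 known pixels: centers (0.5, 0.5)...(1.5, 1.5)
  m <- matrix(0, 4, 4)
  m[1, 1] <- 0.1; m[2, 1] <- 0.2; m[1, 2] <- 0.3; m[2, 2] <- 0.4
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  z <- zonal_index(m, sq)
  expect_equal(z$n, 4L)
  expect_equal(z$mean, 0.25)

  # random raster + irregular polygon vs the ray-casting oracle
  set.seed(33)
  for (rep in 1:5) {
    img <- matrix(runif(20 * 20), 20, 20)
    ang <- sort(runif(6, 0, 2 * pi))
    rad <- runif(6, 3, 9)
    poly <- cbind(10 + rad * cos(ang), 10 + rad * sin(ang))
    z <- zonal_index(img, poly)
    vals <- c()
    for (i in 1:20) for (j in 1:20) {
      if (ray_cast_inside(j - 0.5, i - 0.5, poly[, 1], poly[, 2])) {
        vals <- c(vals, img[i, j])
      }
    }
    expect_equal(z$n, length(vals))
    expect_equal(z$mean, mean(vals), tolerance = 1e-12)
  }

  expect_error(zonal_index(matrix(NA_real_, 3, 3), sq), "no valid pixels")
})

test_that("raster and polygon files round-trip", {
  tmp <- withr::local_tempdir()
  st <- generate_reflectance(0.6, 10, 12, seed = 2, noise_sd = 0.03)
  p <- file.path(tmp, "r.tif")
  write_raster_tiff(st, p)
  back <- read_raster_tiff(p)
  for (b in names(st)) expect_equal(back[[b]], st[[b]], tolerance = 1e-6)

  poly <- cbind(c(1, 9, 9, 1), c(1, 1, 11, 11))
  gp <- file.path(tmp, "p.geojson")
  write_polygon_geojson(poly, gp, plot_id = "plot_001")
  expect_equal(read_polygon_geojson(gp), poly)
})

test_that("the twelve-index plot vector is complete and finite", {
  st <- generate_reflectance(0.5, 16, 16, seed = 4, noise_sd = 0.02)
  iv <- plot_index_vector(st)
  expect_named(iv, c("VARI", "ExR", "ExG", "GLI", "NDI", "MGRVI",
                     "DVI", "GDVI", "EVI", "GEVI", "NDVI", "GNDVI"))
  expect_true(all(is.finite(iv)))
})
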