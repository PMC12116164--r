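#' Analytic band reflectance means as a function of plot vigor
#'
#' The synthetic reflectance model is affine in a latent plot vigor
#' `v` in `[0, 1]`: healthier plots are greener and brighter in the
#' near-infrared, darker in red. NIR and green increase monotonically with
#' vigor; all means stay within `[0, 1]`.
#'
#' @param vigor Latent vigor value(s) in `[0, 1]`.
#' @return A list with numeric elements `B`, `G`, `R`, `NIR`.
#' @export
reflectance_band_means <- function(vigor) {
  check_scalar_number(vigor[1], "vigor", lower = 0, upper = 1)
  list(
    B   = 0.10 - 0.04 * vigor,
    G   = 0.12 + 0.10 * vigor,
    R   = 0.30 - 0.18 * vigor,
    NIR = 0.30 + 0.45 * vigor
  )
}

#' Generate a synthetic 4-band reflectance raster for a plot
#'
#' Each band is its analytic mean (see [reflectance_band_means()]) plus
#' spatially correlated Gaussian noise (white noise smoothed with a small
#' moving-average kernel), clipped to `[0, 1]`. With `noise_sd = 0` every
#' pixel equals the band mean exactly.
#'
#' @param vigor Latent plot vigor in `[0, 1]` (or a `plot_truth` row/list with
#'   a `latent_vigor` element).
#' @param width,height Raster dimensions in pixels.
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of the per-band noise field.
#' @return A `band_stack`: list of `H x W` matrices named `B`, `G`, `R`, `NIR`.
#' @export
generate_reflectance <- function(vigor, width, height, seed = 1L, noise_sd = 0.02) {
  if (is.list(vigor) || is.data.frame(vigor)) vigor <- vigor$latent_vigor
  check_scalar_number(vigor, "vigor", lower = 0, upper = 1)
  check_scalar_number(width, "width", lower = 1)
  check_scalar_number(height, "height", lower = 1)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  mu <- reflectance_band_means(vigor)
  with_seed(seed, {
    bands <- lapply(mu, function(m) {
      plane <- matrix(m, height, width)
      if (noise_sd > 0) {
        noise <- matrix(rnorm(height * width), height, width)
        noise <- smooth_field(noise)
        plane <- plane + noise_sd * noise / stats::sd(as.vector(noise))
      }
      clip(plane, 0, 1)
    })
    structure(bands, class = "band_stack")
  })
}

# 3x3 moving-average smoothing with edge replication: cheap spatially
# correlated noise.
smooth_field <- function(x) {
  h <- nrow(x); w <- ncol(x)
  ip <- c(1, seq_len(h), h); jp <- c(1, seq_len(w), w)
  xp <- x[ip, jp, drop = FALSE]
  out <- matrix(0, h, w)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + xp[di + seq_len(h), dj + seq_len(w), drop = FALSE]
  }
  out / 9
}
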