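#' Assemble a band stack
#'
#' @param R,G,B Visible band matrices (raw digital numbers or reflectance).
#' @param NIR Optional near-infrared band matrix.
#' @return A `band_stack` list of equally sized matrices.
#' @export
band_stack <- function(R, G, B, NIR = NULL) {
  bands <- list(B = B, G = G, R = R)
  if (!is.null(NIR)) bands$NIR <- NIR
  dims <- lapply(bands, dim)
  if (any(!vapply(dims, identical, TRUE, dims[[1]]))) {
    stop_bad_arg("all bands must share dimensions")
  }
  structure(bands, class = "band_stack")
}

#' Chromatic normalization of the visible bands
#'
#' Converts raw visible digital numbers to chromatic coordinates
#' `r = rt / (rt + gt + bt)` (and analogously `g`, `b`), which mitigates
#' between-image brightness variation. At every valid pixel the coordinates
#' sum to one; pixels where the raw sum is zero become nodata (`NA`).
#'
#' @param stack A `band_stack` with `R`, `G`, `B` bands.
#' @return A `normalized_rgb` list of matrices `r`, `g`, `b` (NA = nodata).
#' @export
normalize_rgb <- function(stack) {
  if (!all(c("R", "G", "B") %in% names(stack))) stop_bad_arg("R, G, B bands required")
  tot <- stack$R + stack$G + stack$B
  tot[tot == 0] <- NA_real_
  structure(list(r = stack$R / tot, g = stack$G / tot, b = stack$B / tot),
            class = "normalized_rgb")
}

# Division that maps a zero denominator to nodata instead of Inf/NaN.
safe_div <- function(num, den) {
  den[den == 0] <- NA_real_
  num / den
}

#' Visible-light vegetation indices from chromatic coordinates
#'
#' Computes per-pixel maps of VARI `(g-r)/(g+r-b)`, ExR `1.4r - g`,
#' ExG `2g - r - b`, GLI `(2g-b-r)/(2g+b+r)`, NDI `(g-r)/(g+r)` and
#' MGRVI `(g^2-r^2)/(g^2+r^2)`. Indices are computed on the normalized
#' chromatic coordinates, not raw digital numbers, so they are invariant to
#' positive rescaling of the raw bands. Zero-denominator pixels become
#' nodata for that index only. With `extended = TRUE`, ExGR `ExG - ExR` and
#' RGBVI `(g^2 - b*r)/(g^2 + b*r)` are added (standard literature forms).
#'
#' @param norm A [normalize_rgb()] result.
#' @param extended Also compute ExGR and RGBVI (default `FALSE`).
#' @return Named list of index matrices.
#' @export
visible_indices <- function(norm, extended = FALSE) {
  stopifnot(inherits(norm, "normalized_rgb"))
  r <- norm$r; g <- norm$g; b <- norm$b
  out <- list(
    VARI  = safe_div(g - r, g + r - b),
    ExR   = 1.4 * r - g,
    ExG   = 2 * g - r - b,
    GLI   = safe_div(2 * g - b - r, 2 * g + b + r),
    NDI   = safe_div(g - r, g + r),
    MGRVI = safe_div(g^2 - r^2, g^2 + r^2)
  )
  if (extended) {
    out$ExGR  <- out$ExG - out$ExR
    out$RGBVI <- safe_div(g^2 - b * r, g^2 + b * r)
  }
  out
}

#' Multispectral vegetation indices
#'
#' Computes DVI `NIR - R`, GDVI `NIR - G`,
#' EVI `2.5 (NIR-R) / (NIR + 6R - 7.5B + 1)`,
#' GEVI `2.5 (NIR-G) / (NIR + 6G - 7.5B + 1)`, NDVI `(NIR-R)/(NIR+R)` and
#' GNDVI. The default GNDVI form is `(NIR-B)/(NIR+B)`; `gndvi = "green"`
#' selects the common literature variant `(NIR-G)/(NIR+G)`. With
#' `extended = TRUE`, GRVI `(NIR-G)/(NIR+G)` and RVI `NIR/R` are added.
#'
#' @param stack A `band_stack` including `NIR`.
#' @param gndvi `"blue"` (default, blue-band form) or `"green"`.
#' @param extended Also compute GRVI and RVI (default `FALSE`).
#' @return Named list of index matrices (NA = nodata).
#' @export
multispectral_indices <- function(stack, gndvi = c("blue", "green"),
                                  extended = FALSE) {
  gndvi <- match.arg(gndvi)
  if (!"NIR" %in% names(stack)) stop_bad_arg("NIR band required")
  nir <- stack$NIR; r <- stack$R; g <- stack$G; b <- stack$B
  out <- list(
    DVI   = nir - r,
    GDVI  = nir - g,
    EVI   = safe_div(2.5 * (nir - r), nir + 6 * r - 7.5 * b + 1),
    GEVI  = safe_div(2.5 * (nir - g), nir + 6 * g - 7.5 * b + 1),
    NDVI  = safe_div(nir - r, nir + r),
    GNDVI = if (gndvi == "blue") safe_div(nir - b, nir + b) else safe_div(nir - g, nir + g)
  )
  if (extended) {
    out$GRVI <- safe_div(nir - g, nir + g)
    out$RVI  <- safe_div(nir, r)
  }
  out
}

#' Zonal mean of an index map over a plot polygon
#'
#' Averages the valid (non-nodata) pixels whose centers fall inside the
#' polygon. Pixel centers are at `(row - 0.5, col - 0.5)` in pixel
#' coordinates (x = column direction, y = row direction).
#'
#' @param index_map Numeric matrix (NA = nodata).
#' @param polygon Two-column matrix of polygon vertices `(x, y)` in pixel
#'   coordinates, or a list with `x` and `y`.
#' @return List: `mean` (the zonal statistic) and `n` (valid pixels used).
#' @export
zonal_index <- function(index_map, polygon) {
  if (is.list(polygon) && !is.matrix(polygon)) {
    polygon <- cbind(polygon$x, polygon$y)
  }
  if (!is.matrix(polygon) || ncol(polygon) != 2) {
    stop_bad_arg("`polygon` must be a 2-column (x, y) matrix")
  }
  h <- nrow(index_map); w <- ncol(index_map)
  cx <- rep(seq_len(w) - 0.5, each = h)
  cy <- rep(seq_len(h) - 0.5, times = w)
  inside <- pracma::inpolygon(cx, cy, polygon[, 1], polygon[, 2], boundary = TRUE)
  vals <- as.vector(index_map)[inside]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop_bad_arg("no valid pixels inside the polygon")
  list(mean = mean(vals), n = length(vals))
}

#' Per-plot vegetation index table from a reflectance raster
#'
#' Convenience wrapper: chromatic normalization + all twelve default indices,
#' aggregated over a polygon with [zonal_index()]. The polygon defaults to
#' the full raster extent.
#'
#' @param stack A `band_stack` with `B`, `G`, `R`, `NIR`.
#' @param polygon Optional polygon as in [zonal_index()].
#' @return Named numeric vector of the twelve per-plot index means.
#' @export
plot_index_vector <- function(stack, polygon = NULL) {
  h <- nrow(stack$B); w <- ncol(stack$B)
  if (is.null(polygon)) {
    polygon <- cbind(c(0, w, w, 0), c(0, 0, h, h))
  }
  maps <- c(visible_indices(normalize_rgb(stack)), multispectral_indices(stack))
  vapply(maps, function(m) zonal_index(m, polygon)$mean, 0)
}
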