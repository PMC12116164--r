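# Readers/writers for the on-disk formats: scenes as paired PNGs (the mask
# as 8-bit grayscale with pixel value = label id), reflectance rasters as
# 4-band 32-bit float TIFF in band order B,G,R,NIR, polygons as GeoJSON in
# pixel coordinates, tables as CSV.

#' Write / read a label mask as PNG
#'
#' @param mask `H x W` integer label matrix (values 0-255).
#' @param path Output path.
#' @return `write_mask_png`: the path, invisibly. `read_mask_png`: the mask.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write / read a scene as an image + mask PNG pair
#'
#' Files are named `scene_XXXX.png` and `scene_XXXX_mask.png`.
#'
#' @param scene A `seg_scene`.
#' @param dir Output directory.
#' @param id Integer scene id.
#' @return `write_scene`: the image path, invisibly. `read_scene`: a list
#'   with `image` and `mask`.
#' @export
write_scene <- function(scene, dir, id) {
  img_path <- file.path(dir, sprintf("scene_%04d.png", id))
  png::writePNG(scene$image / 255, img_path)
  write_mask_png(scene$mask, file.path(dir, sprintf("scene_%04d_mask.png", id)))
  invisible(img_path)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir, id) {
  img <- png::readPNG(file.path(dir, sprintf("scene_%04d.png", id)))
  img <- array(as.integer(round(img * 255)), dim(img))
  mask <- read_mask_png(file.path(dir, sprintf("scene_%04d_mask.png", id)))
  list(image = img, mask = mask)
}

#' Write / read a 4-band reflectance raster as float TIFF
#'
#' Band order on disk is B, G, R, NIR.
#'
#' @param stack A `band_stack` with bands `B`, `G`, `R`, `NIR` in `[0, 1]`.
#' @param path Output path (`.tif`).
#' @return `write_raster_tiff`: the path, invisibly; `read_raster_tiff`:
#'   a `band_stack`.
#' @export
write_raster_tiff <- function(stack, path) {
  a <- array(0, c(dim(stack$B), 4L))
  for (i in seq_along(c("B", "G", "R", "NIR"))) {
    a[, , i] <- stack[[c("B", "G", "R", "NIR")[i]]]
  }
  tiff::writeTIFF(a, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_raster_tiff
#' @export
read_raster_tiff <- function(path) {
  a <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(a)) != 3L || dim(a)[3] != 4L) stop_bad_arg("expected a 4-band raster")
  structure(list(B = a[, , 1], G = a[, , 2], R = a[, , 3], NIR = a[, , 4]),
            class = "band_stack")
}

#' Write / read a plot polygon as GeoJSON
#'
#' Coordinates are in raster pixel units (x = column, y = row direction).
#'
#' @param polygon Two-column `(x, y)` matrix of ring vertices.
#' @param path Output path (`.geojson`).
#' @param plot_id Optional id stored as a feature property.
#' @return `write_polygon_geojson`: the path, invisibly;
#'   `read_polygon_geojson`: the vertex matrix.
#' @export
write_polygon_geojson <- function(polygon, path, plot_id = NULL) {
  ring <- rbind(polygon, polygon[1, ])
  feature <- list(
    type = "Feature",
    properties = if (is.null(plot_id)) stats::setNames(list(), character(0)) else list(plot_id = plot_id),
    geometry = list(type = "Polygon",
                    coordinates = list(lapply(seq_len(nrow(ring)),
                                              function(i) ring[i, ])))
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = list(feature)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygon_geojson
#' @export
read_polygon_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  coords <- gj$features[[1]]$geometry$coordinates[[1]]
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  # drop the closing vertex
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Write / read plot record tables as CSV
#'
#' @param records Data frame of plot records.
#' @param path Output path (`.csv`).
#' @return `write_plot_csv`: the path, invisibly; `read_plot_csv`: a data
#'   frame.
#' @export
write_plot_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plot_csv
#' @export
read_plot_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
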