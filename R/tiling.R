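#' Tile an image (and optional mask) into fixed-size patches
#'
#' Splits an `H x W x 3` image into `tile_size` square tiles, row-major from
#' the top-left, 0-based tile coordinates. Partial edge tiles are handled by
#' the pad policy: `pad_white` fills with the white backdrop value (255) and
#' labels padded mask pixels background, `pad_reflect` mirrors the image
#' content, `drop_partial` keeps only full tiles. Each tile records its valid
#' (un-padded) extent so padded pixels can be excluded from pixel counting.
#'
#' @param image `H x W x 3` numeric array (0-255) or `H x W` matrix.
#' @param mask Optional `H x W` integer label matrix aligned with `image`.
#' @param tile_size Tile side length in pixels (default 512).
#' @param pad_policy One of `"pad_white"`, `"pad_reflect"`, `"drop_partial"`.
#' @return A `tile_grid`: list with `tile_size`, `pad_policy`, `image_dim` and
#'   `tiles`, each tile a list `(row, col, image, mask, valid_h, valid_w)`.
#' @export
tile_image <- function(image, mask = NULL, tile_size = 512,
                       pad_policy = c("pad_white", "pad_reflect", "drop_partial")) {
  pad_policy <- match.arg(pad_policy)
  if (tile_size <= 0) stop_bad_arg("`tile_size` must be positive")
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3L || d[1] == 0 || d[2] == 0) stop_bad_arg("`image` must be a nonempty H x W x C array")
  h <- d[1]; w <- d[2]
  if (!is.null(mask) && !identical(dim(mask), c(h, w))) {
    stop_bad_arg("`mask` dimensions must match `image`")
  }

  if (pad_policy == "drop_partial") {
    nr <- h %/% tile_size; nc <- w %/% tile_size
    if (nr == 0 || nc == 0) {
      warning("image smaller than tile_size: 0 tiles under drop_partial")
    }
  } else {
    nr <- ceiling(h / tile_size); nc <- ceiling(w / tile_size)
  }

  tiles <- list()
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      i0 <- (r - 1L) * tile_size + 1L
      j0 <- (cc - 1L) * tile_size + 1L
      i1 <- min(h, i0 + tile_size - 1L)
      j1 <- min(w, j0 + tile_size - 1L)
      vh <- i1 - i0 + 1L; vw <- j1 - j0 + 1L
      ti <- array(if (pad_policy == "pad_white") 255 else 0,
                  c(tile_size, tile_size, d[3]))
      ti[seq_len(vh), seq_len(vw), ] <- image[i0:i1, j0:j1, , drop = FALSE]
      tm <- NULL
      if (!is.null(mask)) {
        tm <- matrix(ORGAN_LABELS[["background"]], tile_size, tile_size)
        tm[seq_len(vh), seq_len(vw)] <- mask[i0:i1, j0:j1]
      }
      if (pad_policy == "pad_reflect" && (vh < tile_size || vw < tile_size)) {
        ri <- reflect_index(vh, tile_size)
        rj <- reflect_index(vw, tile_size)
        ti <- ti[ri, rj, , drop = FALSE]
        if (!is.null(tm)) {
          tmr <- tm[ri, rj]
          tmr[seq_len(vh), seq_len(vw)] <- tm[seq_len(vh), seq_len(vw)]
          # reflected mask pixels are padding: label them background
          pad_sel <- matrix(TRUE, tile_size, tile_size)
          pad_sel[seq_len(vh), seq_len(vw)] <- FALSE
          tmr[pad_sel] <- ORGAN_LABELS[["background"]]
          tm <- tmr
        }
      }
      tiles[[length(tiles) + 1L]] <- list(row = r - 1L, col = cc - 1L,
                                          image = ti, mask = tm,
                                          valid_h = vh, valid_w = vw)
    }
  }
  structure(list(tile_size = as.integer(tile_size), pad_policy = pad_policy,
                 image_dim = c(h, w), tiles = tiles),
            class = "tile_grid")
}

# Index vector that mirrors positions beyond `n` back into [1, n].
reflect_index <- function(n, len) {
  idx <- seq_len(len)
  over <- idx > n
  if (any(over)) {
    m <- idx[over] - n
    idx[over] <- pmax(1L, n - m + 1L)
  }
  idx
}

#' Drop tiles that contain only white backdrop
#'
#' A pixel is "white" when all its channels are at or above
#' `whiteness_threshold`; a tile is kept when its white fraction is below
#' `1 - min_foreground_fraction`, i.e. at least `min_foreground_fraction` of
#' its pixels show something other than backdrop. Tile order is preserved.
#'
#' @param grid A [tile_image()] result.
#' @param whiteness_threshold 8-bit intensity at or above which a channel
#'   counts as white (default 240).
#' @param min_foreground_fraction Minimum non-white pixel fraction to keep a
#'   tile (default 0.01).
#' @return A `tile_grid` containing the kept tiles; attribute `n_dropped`.
#' @export
filter_background_tiles <- function(grid, whiteness_threshold = 240,
                                    min_foreground_fraction = 0.01) {
  stopifnot(inherits(grid, "tile_grid"))
  if (length(grid$tiles) == 0L) stop_bad_arg("empty tile grid")
  check_scalar_number(whiteness_threshold, "whiteness_threshold", 0, 255)
  check_scalar_number(min_foreground_fraction, "min_foreground_fraction", 0, 1)
  keep <- vapply(grid$tiles, function(t) {
    white <- apply(t$image >= whiteness_threshold, c(1, 2), all)
    mean(white) < 1 - min_foreground_fraction
  }, logical(1))
  out <- grid
  out$tiles <- grid$tiles[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
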