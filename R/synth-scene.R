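#' Specify a synthetic tree scene
#'
#' A scene emulates a ground photograph of a single apple tree taken against a
#' white backdrop: a branching trunk, elliptical leaf blobs, and disc-shaped
#' flowers (flowering stage) or bagged young fruits (young-fruit stage).
#' Organ geometry is procedural, so every generated scene carries exact
#' per-class pixel counts.
#'
#' @param width,height Scene dimensions in pixels.
#' @param stage `"flowering"` or `"young_fruit"`. Flowering scenes contain no
#'   fruit label and young-fruit scenes no flower label.
#' @param n_flowers_or_fruits Number of organ discs to draw.
#' @param leaf_coverage Target fraction of pixels covered by leaves, in
#'   `[0, 1]`. Blobs are added until the target is reached (or an iteration cap).
#' @param branch_thickness Trunk base thickness in pixels; `NULL` defaults to
#'   8% of the smaller image dimension, 0 suppresses branches entirely.
#' @param background_value Mean 8-bit intensity of the white backdrop.
#' @param organ_radius Disc radius in pixels; `NULL` defaults to 9% of the
#'   smaller image dimension with 20% jitter per disc.
#' @param seed Integer seed; identical spec + seed gives bit-identical scenes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width, height, stage = c("flowering", "young_fruit"),
                       n_flowers_or_fruits = 3, leaf_coverage = 0.35,
                       branch_thickness = NULL, background_value = 250,
                       organ_radius = NULL, seed = 1L) {
  stage <- match.arg(stage)
  check_scalar_number(width, "width", lower = 1)
  check_scalar_number(height, "height", lower = 1)
  check_scalar_number(n_flowers_or_fruits, "n_flowers_or_fruits", lower = 0)
  check_scalar_number(leaf_coverage, "leaf_coverage", lower = 0, upper = 1)
  check_scalar_number(background_value, "background_value", lower = 0, upper = 255)
  if (is.null(branch_thickness)) branch_thickness <- round(0.08 * min(width, height))
  check_scalar_number(branch_thickness, "branch_thickness", lower = 0)
  if (!is.null(organ_radius)) check_scalar_number(organ_radius, "organ_radius", lower = 1)
  structure(list(
    width = as.integer(width), height = as.integer(height), stage = stage,
    n_flowers_or_fruits = as.integer(n_flowers_or_fruits),
    leaf_coverage = leaf_coverage, branch_thickness = branch_thickness,
    background_value = background_value, organ_radius = organ_radius,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

# Paint all pixels whose centers lie within `radius` of (cy, cx) on `mask`.
paint_disc <- function(mask, cy, cx, radius, label) {
  h <- nrow(mask); w <- ncol(mask)
  i0 <- max(1L, floor(cy - radius)); i1 <- min(h, ceiling(cy + radius))
  j0 <- max(1L, floor(cx - radius)); j1 <- min(w, ceiling(cx + radius))
  if (i0 > i1 || j0 > j1) return(mask)
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - cy)^2, (jj - cx)^2, `+`)
  sub <- mask[ii, jj, drop = FALSE]
  sub[d2 <= radius^2] <- label
  mask[ii, jj] <- sub
  mask
}

paint_ellipse <- function(mask, cy, cx, a, b, theta, label) {
  h <- nrow(mask); w <- ncol(mask)
  r <- max(a, b)
  i0 <- max(1L, floor(cy - r)); i1 <- min(h, ceiling(cy + r))
  j0 <- max(1L, floor(cx - r)); j1 <- min(w, ceiling(cx + r))
  if (i0 > i1 || j0 > j1) return(mask)
  ii <- i0:i1; jj <- j0:j1
  dy <- matrix(ii - cy, length(ii), length(jj))
  dx <- matrix(jj - cx, length(ii), length(jj), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  sub <- mask[ii, jj, drop = FALSE]
  sub[(u / a)^2 + (v / b)^2 <= 1] <- label
  mask[ii, jj] <- sub
  mask
}

# Thick line segment (capsule) from (y0,x0) to (y1,x1).
paint_segment <- function(mask, y0, x0, y1, x1, thickness, label) {
  h <- nrow(mask); w <- ncol(mask)
  r <- thickness / 2
  i0 <- max(1L, floor(min(y0, y1) - r)); i1 <- min(h, ceiling(max(y0, y1) + r))
  j0 <- max(1L, floor(min(x0, x1) - r)); j1 <- min(w, ceiling(max(x0, x1) + r))
  if (i0 > i1 || j0 > j1) return(mask)
  ii <- i0:i1; jj <- j0:j1
  py <- matrix(ii, length(ii), length(jj))
  px <- matrix(jj, length(ii), length(jj), byrow = TRUE)
  vy <- y1 - y0; vx <- x1 - x0
  len2 <- vy^2 + vx^2
  t <- if (len2 == 0) matrix(0, length(ii), length(jj)) else
    clip(((py - y0) * vy + (px - x0) * vx) / len2, 0, 1)
  d2 <- (py - (y0 + t * vy))^2 + (px - (x0 + t * vx))^2
  sub <- mask[ii, jj, drop = FALSE]
  sub[d2 <= r^2] <- label
  mask[ii, jj] <- sub
  mask
}

# Recursive branch skeleton; returns list of segments (y0,x0,y1,x1,thickness).
branch_segments <- function(h, w, thickness) {
  segs <- list()
  grow <- function(y, x, angle, len, thick, depth) {
    y1 <- y - len * cos(angle)
    x1 <- x + len * sin(angle)
    segs[[length(segs) + 1L]] <<- c(y, x, y1, x1, thick)
    if (depth <= 0 || thick < 1) return(invisible())
    n_child <- sample(2:3, 1)
    for (k in seq_len(n_child)) {
      da <- runif(1, 0.3, 0.9) * sample(c(-1, 1), 1)
      grow(y1, x1, angle + da, len * runif(1, 0.55, 0.75),
           thick * 0.6, depth - 1L)
    }
  }
  grow(h, w / 2 + runif(1, -0.05, 0.05) * w, runif(1, -0.15, 0.15),
       0.42 * h, thickness, 3L)
  segs
}

#' Generate a synthetic tree scene with an exact segmentation mask
#'
#' Draws branch segments, leaf ellipses and organ discs in a fixed z-order
#' (branch < leaf < flower/fruit, nearest to camera wins), then composites an
#' RGB image with per-organ colors and pixel noise over a white backdrop.
#' Because the mask is composited from known shapes, the returned per-class
#' pixel counts are exact.
#'
#' @param spec A [scene_spec()].
#' @return A `seg_scene`: list with `image` (H x W x 3 integer array, 0-255),
#'   `mask` (H x W integer matrix over the unified label space), `true_counts`
#'   (named integer vector summing to H*W), `stage`, `organs` (placement
#'   ledger of the drawn discs: label, center, radius), and the `spec`.
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop_bad_arg("`spec` must be a scene_spec")
  h <- spec$height; w <- spec$width; m <- min(h, w)
  organ_label <- if (spec$stage == "flowering") ORGAN_LABELS[["flower"]] else ORGAN_LABELS[["fruit"]]

  with_seed(spec$seed, {
    mask <- matrix(ORGAN_LABELS[["background"]], h, w)

    segs <- list()
    if (spec$branch_thickness > 0) {
      segs <- branch_segments(h, w, spec$branch_thickness)
      for (s in segs) mask <- paint_segment(mask, s[1], s[2], s[3], s[4], s[5],
                                            ORGAN_LABELS[["branch"]])
    }

    if (spec$leaf_coverage > 0) {
      target <- spec$leaf_coverage * h * w
      for (iter in seq_len(400L)) {
        if (sum(mask == ORGAN_LABELS[["leaf"]]) >= target) break
        if (length(segs) > 0 && runif(1) < 0.7) {
          s <- segs[[sample(length(segs), 1)]]
          t <- runif(1)
          cy <- s[1] + t * (s[3] - s[1]) + rnorm(1, 0, 0.06 * m)
          cx <- s[2] + t * (s[4] - s[2]) + rnorm(1, 0, 0.06 * m)
        } else {
          cy <- runif(1, 0.08 * h, 0.8 * h)
          cx <- runif(1, 0.12 * w, 0.88 * w)
        }
        a <- runif(1, 0.05, 0.11) * m
        mask <- paint_ellipse(mask, cy, cx, a, 0.6 * a, runif(1, 0, pi),
                              ORGAN_LABELS[["leaf"]])
      }
    }

    organs <- NULL
    if (spec$n_flowers_or_fruits > 0) {
      organs <- data.frame(label = integer(0), cy = numeric(0),
                           cx = numeric(0), radius = numeric(0))
      for (k in seq_len(spec$n_flowers_or_fruits)) {
        r <- spec$organ_radius %||% (0.09 * m * runif(1, 0.8, 1.2))
        cy <- runif(1, r + 1, max(r + 1, 0.8 * h - r))
        cx <- runif(1, r + 1, w - r)
        mask <- paint_disc(mask, cy, cx, r, organ_label)
        organs[k, ] <- list(organ_label, cy, cx, r)
      }
    }

    image <- render_scene_image(mask, spec$background_value)
    counts <- tabulate(mask + 1L, nbins = 5L)
    names(counts) <- names(ORGAN_LABELS)
    structure(list(image = image, mask = mask, true_counts = counts,
                   stage = spec$stage, organs = organs, spec = spec),
              class = "seg_scene")
  })
}

# RGB composite: organ base colors with slight brightness jitter + pixel noise.
ORGAN_COLORS <- rbind(
  background = c(250, 250, 250),  # overwritten by backdrop model
  flower     = c(225, 105, 135),
  fruit      = c(235, 205, 130),
  leaf       = c(70, 135, 60),
  branch     = c(105, 70, 40)
)

render_scene_image <- function(mask, background_value) {
  h <- nrow(mask); w <- ncol(mask)
  img <- array(0, c(h, w, 3))
  bg <- mask == ORGAN_LABELS[["background"]]
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    plane[bg] <- clip(rnorm(sum(bg), background_value, 2), 245, 255)
    for (lab in c("flower", "fruit", "leaf", "branch")) {
      sel <- mask == ORGAN_LABELS[[lab]]
      if (any(sel)) {
        base <- ORGAN_COLORS[lab, ch] * runif(1, 0.92, 1.08)
        plane[sel] <- clip(base + rnorm(sum(sel), 0, 6), 0, 255)
      }
    }
    img[, , ch] <- plane
  }
  array(as.integer(round(img)), dim(img))
}

#' @export
print.seg_scene <- function(x, ...) {
  cat(sprintf("<seg_scene> %dx%d, stage=%s\n", nrow(x$mask), ncol(x$mask), x$stage))
  cat("pixel counts:\n")
  print(x$true_counts)
  invisible(x)
}
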