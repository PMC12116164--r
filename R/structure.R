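#' Count organ pixels over mask tiles
#'
#' Sums per-label pixel counts over all (kept) tiles, excluding padded pixels,
#' and maps them to the stage triple: flowering uses flower/leaf/branch counts
#' (`FA`, `IA`, `GA`), young fruit uses fruit/leaf/branch (`FB`, `IB`, `GB`).
#' A label inconsistent with the stage (fruit pixels in a flowering scene or
#' vice versa) triggers a warning and contributes 0 to the triple.
#'
#' @param masks A `tile_grid` with mask patches, a single label matrix, or a
#'   list of label matrices over the unified 5-label space.
#' @param stage `"flowering"` or `"young_fruit"`.
#' @return A `class_pixel_counts` list: `stage`, the stage triple, and
#'   `background` count.
#' @export
count_class_pixels <- function(masks, stage = c("flowering", "young_fruit")) {
  stage <- match.arg(stage)
  if (inherits(masks, "tile_grid")) {
    mats <- lapply(masks$tiles, function(t) {
      if (is.null(t$mask)) stop_bad_arg("tile grid carries no masks")
      t$mask[seq_len(t$valid_h), seq_len(t$valid_w), drop = FALSE]
    })
  } else if (is.matrix(masks)) {
    mats <- list(masks)
  } else {
    mats <- masks
  }
  counts <- numeric(5)
  for (m in mats) {
    if (any(m < 0 | m > 4)) stop_bad_arg("labels outside the unified 5-label space")
    counts <- counts + tabulate(as.integer(m) + 1L, nbins = 5L)
  }
  names(counts) <- names(ORGAN_LABELS)

  off_stage <- if (stage == "flowering") "fruit" else "flower"
  if (counts[[off_stage]] > 0) {
    warning(sprintf("%d %s pixels found in a %s-stage mask; counted as 0 for the stage triple",
                    counts[[off_stage]], off_stage, stage))
  }
  organ <- if (stage == "flowering") "flower" else "fruit"
  triple <- c(counts[[organ]], counts[["leaf"]], counts[["branch"]])
  names(triple) <- if (stage == "flowering") c("FA", "IA", "GA") else c("FB", "IB", "GB")
  structure(c(list(stage = stage), as.list(triple),
              list(background = counts[["background"]])),
            class = "class_pixel_counts")
}

#' Structural feature ratios from organ pixel counts
#'
#' For the flowering stage the canopy total is `SA = FA + IA + GA` and the
#' ratios are the flower area share `f1 = FA / SA` and flower-to-leaf ratio
#' `f2 = FA / IA`; for the young-fruit stage, `SB = FB + IB + GB`,
#' `f3 = FB / SB`, `f4 = FB / IB`. A zero numerator yields 0; a zero canopy
#' total, or a zero leaf count with a positive organ count, is an error.
#'
#' @param counts A [count_class_pixels()] result.
#' @return A `structural_ratios` list: `stage`, `total` (SA or SB), and either
#'   `f1`/`f2` or `f3`/`f4`.
#' @export
structural_ratios <- function(counts) {
  stopifnot(inherits(counts, "class_pixel_counts"))
  if (counts$stage == "flowering") {
    fa <- counts$FA; ia <- counts$IA; ga <- counts$GA
    sa <- fa + ia + ga
    if (sa == 0) stop_bad_arg("SA = 0: no canopy pixels, ratios undefined")
    f1 <- fa / sa
    f2 <- if (fa == 0) 0 else {
      if (ia == 0) stop_bad_arg("IA = 0 with FA > 0: f2 undefined")
      fa / ia
    }
    structure(list(stage = "flowering", total = sa, f1 = f1, f2 = f2),
              class = "structural_ratios")
  } else {
    fb <- counts$FB; ib <- counts$IB; gb <- counts$GB
    sb <- fb + ib + gb
    if (sb == 0) stop_bad_arg("SB = 0: no canopy pixels, ratios undefined")
    f3 <- fb / sb
    f4 <- if (fb == 0) 0 else {
      if (ib == 0) stop_bad_arg("IB = 0 with FB > 0: f4 undefined")
      fb / ib
    }
    structure(list(stage = "young_fruit", total = sb, f3 = f3, f4 = f4),
              class = "structural_ratios")
  }
}

#' Aggregate per-tree structural ratios to plot level
#'
#' Plots are photographed as several trees; the plot-level ratio is the mean
#' of the per-tree ratios.
#'
#' @param ratio_list List of [structural_ratios()] results from one stage.
#' @return Named numeric vector of the stage's mean ratios.
#' @export
aggregate_tree_ratios <- function(ratio_list) {
  stopifnot(length(ratio_list) > 0)
  stages <- vapply(ratio_list, `[[`, "", "stage")
  if (length(unique(stages)) != 1L) stop_bad_arg("mixed stages in ratio list")
  keys <- if (stages[1] == "flowering") c("f1", "f2") else c("f3", "f4")
  vapply(keys, function(k) mean(vapply(ratio_list, `[[`, 0, k)), 0)
}
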