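PLOT_FEATURES <- c("s1", "s2", "f1", "f2", "f3", "f4", "d1", "d2", "d3", "k1")

#' Default generative yield coefficients
#'
#' Named coefficient vector of the synthetic yield model
#' `yield = intercept + beta . features + N(0, noise_sd)`, in kg per feature
#' unit. Magnitudes are chosen so that 20-tree plots span roughly 150-500 kg
#' with a between-plot yield standard deviation of a few tens of kg, in line
#' with small orchard sampling plots.
#'
#' @return Named numeric vector with an `intercept` entry plus one entry per
#'   feature (`s1`, `s2`, `f1`-`f4`, `d1`-`d3`, `k1`).
#' @export
default_yield_beta <- function() {
  c(intercept = 150, s1 = 1.2, s2 = 1.0,
    f1 = 60, f2 = 25, f3 = 50, f4 = 80,
    d1 = 40, d2 = 25, d3 = 20, k1 = 35)
}

# Noiseless feature values implied by a vigor level; shared by the plot
# generator and by tests that need the closed-form feature model.
plot_feature_means <- function(vigor) {
  mu <- reflectance_band_means(vigor)
  tot <- mu$R + mu$G + mu$B
  r <- mu$R / tot; g <- mu$G / tot; b <- mu$B / tot
  lg <- function(lo, span) lo + span * stats::plogis((vigor - 0.5) / 0.18)
  data.frame(
    s1 = 35 + 12 * vigor,
    s2 = 33 + 14 * vigor,
    f1 = lg(0.04, 0.26),
    f2 = lg(0.08, 0.50),
    f3 = lg(0.06, 0.30),
    f4 = lg(0.10, 0.60),
    d1 = mu$NIR - mu$R,
    d2 = mu$NIR - mu$G,
    d3 = 2.5 * (mu$NIR - mu$G) / (mu$NIR + 6 * mu$G - 7.5 * mu$B + 1),
    k1 = (g - r) / (g + r - b)
  )
}

# Per-feature measurement noise (sd) of the generator.
PLOT_FEATURE_NOISE <- c(s1 = 1.0, s2 = 1.0,
                        f1 = 0.012, f2 = 0.02, f3 = 0.012, f4 = 0.02,
                        d1 = 0.015, d2 = 0.015, d3 = 0.015, k1 = 0.02)

#' Generate synthetic plot records with a known yield model
#'
#' Draws a latent vigor per plot from Uniform(0, 1), derives SPAD values,
#' structural ratios and vegetation-index features from vigor (affine for
#' SPAD and band math, logistic for ratios) plus independent Gaussian
#' measurement noise, and sets
#' `yield_kg = intercept + beta . features + N(0, noise_sd)`, truncated at 0.
#' All ground truth (vigor, beta, noise level) travels with the result, so
#' regression models fitted downstream can be checked against the generative
#' coefficients.
#'
#' @param n_plots Number of plots (>= 2).
#' @param beta Named coefficient vector; missing feature names count as 0.
#'   See [default_yield_beta()].
#' @param noise_sd Yield noise standard deviation in kg (>= 0).
#' @param seed Integer seed.
#' @return A `plot_truth` data frame with columns `plot_id`, `latent_vigor`,
#'   the ten features, and `yield_kg`; attributes `beta`, `noise_sd`, `seed`.
#' @export
generate_plot_dataset <- function(n_plots, beta = default_yield_beta(),
                                  noise_sd = 5, seed = 1L) {
  check_scalar_number(n_plots, "n_plots", lower = 2)
  if (noise_sd < 0) stop_bad_arg("`noise_sd` must be non-negative")
  if (is.null(names(beta))) stop_bad_arg("`beta` must be a named vector")
  full <- setNames(numeric(length(PLOT_FEATURES) + 1L), c("intercept", PLOT_FEATURES))
  unknown <- setdiff(names(beta), names(full))
  if (length(unknown) > 0) stop_bad_arg("unknown beta names: ", paste(unknown, collapse = ", "))
  full[names(beta)] <- beta

  with_seed(seed, {
    vigor <- runif(n_plots)
    feat <- do.call(rbind, lapply(vigor, plot_feature_means))
    for (f in PLOT_FEATURES) {
      feat[[f]] <- feat[[f]] + rnorm(n_plots, 0, PLOT_FEATURE_NOISE[[f]])
    }
    # ratios and indices stay physically plausible
    for (f in c("f1", "f2", "f3", "f4")) feat[[f]] <- pmax(feat[[f]], 0)
    yield <- full[["intercept"]] +
      as.matrix(feat[, PLOT_FEATURES]) %*% full[PLOT_FEATURES] +
      rnorm(n_plots, 0, noise_sd)
    out <- data.frame(plot_id = sprintf("plot_%03d", seq_len(n_plots)),
                      latent_vigor = vigor, feat,
                      yield_kg = pmax(as.vector(yield), 0))
    attr(out, "beta") <- full
    attr(out, "noise_sd") <- noise_sd
    attr(out, "seed") <- as.integer(seed)
    class(out) <- c("plot_truth", "data.frame")
    out
  })
}

#' Simulate raw per-leaf SPAD readings for a plot table
#'
#' Emulates the field protocol: three trees per plot, two leaves from each of
#' three canopy layers per tree (six readings per tree), at both stages. Tree
#' and leaf effects are zero-mean, so the nested mean recovers the plot SPAD
#' value up to sampling noise.
#'
#' @param plots A `plot_truth` data frame.
#' @param trees_per_plot Trees sampled per plot (default 3).
#' @param tree_sd,leaf_sd Between-tree and between-leaf noise (SPAD units).
#' @param seed Integer seed.
#' @return Long data frame: `plot_id`, `stage`, `tree`, `leaf`, `spad`.
#' @export
simulate_spad_readings <- function(plots, trees_per_plot = 3, tree_sd = 0.8,
                                   leaf_sd = 1.2, seed = 1L) {
  stopifnot(is.data.frame(plots))
  with_seed(seed, {
    rows <- expand.grid(leaf = 1:6, tree = seq_len(trees_per_plot),
                        stage = c("flowering", "young_fruit"),
                        plot_id = plots$plot_id, stringsAsFactors = FALSE)
    base <- ifelse(rows$stage == "flowering",
                   plots$s1[match(rows$plot_id, plots$plot_id)],
                   plots$s2[match(rows$plot_id, plots$plot_id)])
    tree_key <- interaction(rows$plot_id, rows$stage, rows$tree, drop = TRUE)
    tree_eff <- rnorm(nlevels(tree_key), 0, tree_sd)[as.integer(tree_key)]
    rows$spad <- base + tree_eff + rnorm(nrow(rows), 0, leaf_sd)
    rows[, c("plot_id", "stage", "tree", "leaf", "spad")]
  })
}
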