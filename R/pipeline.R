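#' Configure an end-to-end pipeline run
#'
#' Assembles the configuration for [run_pipeline()]: which stages to run,
#' synthetic-orchard sizes, the segmentation model/training setup, and the
#' fusion-model grid. All randomness derives from `seed`.
#'
#' Stages: `simulate` (scenes, rasters, SPAD readings, plot table),
#' `segtrain` (train the segmentation network on the simulated scenes),
#' `structure` (tile + filter + count + ratios, from predicted masks when a
#' model was trained and `use_true_masks` is `FALSE`, otherwise from ground
#' truth), `indices` (zonal vegetation indices per plot), `fuse` (screen
#' features, fit the model grid), `explain` (exact Shapley attribution of
#' the chosen model).
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer master seed.
#' @param stages Character vector of stage names, in any order.
#' @param n_plots Number of synthetic plots.
#' @param beta,noise_sd Yield model passed to [generate_plot_dataset()].
#' @param scene_size Scene side length in pixels (divisible by 16).
#' @param tile_size Tile size for the structure stage.
#' @param raster_size Reflectance raster side length in pixels.
#' @param use_true_masks Use ground-truth masks in the structure stage even
#'   when a segmentation model is available.
#' @param seg_config,seg_train [model_config()] / [train_config()] for the
#'   optional `segtrain` stage; defaults are desk-scale.
#' @param n_train_scenes Scenes used for `segtrain`.
#' @param feature_sets,models Fusion grid (defaults A, B, C, G x all four).
#' @param shap_model,shap_set,shap_background,shap_explain Shapley stage:
#'   model family, feature set, background rows, rows to explain.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       stages = c("simulate", "structure", "indices", "fuse", "explain"),
                       n_plots = 80L,
                       beta = default_yield_beta(),
                       noise_sd = 5,
                       scene_size = 96L,
                       tile_size = 64L,
                       raster_size = 24L,
                       use_true_masks = TRUE,
                       seg_config = NULL,
                       seg_train = NULL,
                       n_train_scenes = 8L,
                       feature_sets = c("A", "B", "C", "G"),
                       models = c("KNN", "PLS", "RF", "SVM"),
                       shap_model = "SVM", shap_set = "G",
                       shap_background = 20L, shap_explain = 16L) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 n_plots = as.integer(n_plots), beta = beta, noise_sd = noise_sd,
                 scene_size = as.integer(scene_size),
                 tile_size = as.integer(tile_size),
                 raster_size = as.integer(raster_size),
                 use_true_masks = isTRUE(use_true_masks),
                 seg_config = seg_config, seg_train = seg_train,
                 n_train_scenes = as.integer(n_train_scenes),
                 feature_sets = feature_sets, models = models,
                 shap_model = shap_model, shap_set = shap_set,
                 shap_background = as.integer(shap_background),
                 shap_explain = as.integer(shap_explain)),
            class = "run_config")
}

KNOWN_STAGES <- c("simulate", "segtrain", "structure", "indices", "fuse", "explain")

#' Validate a run configuration without side effects
#'
#' @param config A [run_config()].
#' @return Data frame of findings (`level` in error/warning, `message`);
#'   zero rows means the configuration is runnable.
#' @export
validate_config <- function(config) {
  findings <- list()
  add <- function(level, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(level = level, message = msg)
  }
  unknown <- setdiff(config$stages, KNOWN_STAGES)
  if (length(unknown) > 0) add("error", paste("unknown stage(s):", paste(unknown, collapse = ", ")))
  if (is.null(config$out_dir) || !nzchar(config$out_dir)) add("error", "out_dir is not set")
  if (!"simulate" %in% config$stages) {
    for (st in intersect(config$stages, c("structure", "indices", "fuse", "explain"))) {
      add("error", sprintf("stage '%s' requires the simulate stage (no external inputs configured)", st))
    }
  }
  if (config$scene_size %% 16L != 0L) add("error", "scene_size must be divisible by 16")
  if ("fuse" %in% config$stages) {
    for (dep in setdiff(c("structure", "indices"), config$stages)) {
      add("error", sprintf("fuse stage requires the '%s' stage", dep))
    }
  }
  if ("explain" %in% config$stages && !"fuse" %in% config$stages) {
    add("error", "explain stage requires the fuse stage")
  }
  if (config$n_plots < 10L && "fuse" %in% config$stages) {
    add("error", "fuse stage needs at least 10 plots for the 7:3 split")
  }
  if ("segtrain" %in% config$stages) {
    ep <- (config$seg_train %||% list(epochs = 60L))$epochs %||% 60L
    if (ep == 0) add("warning", "segtrain epochs = 0: the model will be untrained")
  }
  if (!config$shap_model %in% config$models && "explain" %in% config$stages) {
    add("warning", sprintf("shap_model %s is not in the evaluated model grid", config$shap_model))
  }
  if (length(findings) == 0L) {
    return(data.frame(level = character(0), message = character(0)))
  }
  do.call(rbind, findings)
}

# Scene spec for one plot/stage, sized so the extracted structural ratios
# track the plot's generative ratios.
scene_spec_for_plot <- function(plot_row, stage, scene_size, seed) {
  if (stage == "flowering") {
    f_area <- plot_row$f1; f_leaf <- plot_row$f2
  } else {
    f_area <- plot_row$f3; f_leaf <- plot_row$f4
  }
  n <- max(1L, round(30 * clip(f_area, 0, 0.45)))
  disc_frac <- n * pi * 0.09^2
  leaf_cov <- clip(disc_frac / max(f_leaf, 0.1), 0.08, 0.6)
  scene_spec(scene_size, scene_size, stage = stage,
             n_flowers_or_fruits = n, leaf_coverage = leaf_cov,
             seed = seed)
}

predictor_from_fit <- function(fp) {
  det <- fp$details
  switch(fp$model_name,
    RF = function(X) as.vector(stats::predict(det$fit, X)),
    KNN = function(X) as.vector(stats::predict(det$fit, apply_scaler(X, det$scaler))),
    SVM = function(X) as.vector(stats::predict(det$fit, apply_scaler(X, det$scaler))),
    PLS = function(X) {
      Z <- apply_scaler(X, det$scaler)
      as.vector(stats::predict(det$fit, newdata = Z)$predict[, 1, det$ncomp])
    })
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' artifacts (PNG scenes and masks, float-TIFF rasters, GeoJSON polygons,
#' CSV tables, the JSON report) under `config$out_dir`. Fully reproducible
#' given the config: the report is byte-identical across runs except for its
#' `timestamp`/`timings` entries.
#'
#' @param config A [run_config()] (or a path to a JSON file of its fields).
#' @return A `run_report` list (also written to `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  findings <- validate_config(config)
  errs <- findings$message[findings$level == "error"]
  if (length(errs) > 0) stop_bad_arg("invalid config: ", paste(errs, collapse = "; "))
  for (w in findings$message[findings$level == "warning"]) warning(w, call. = FALSE)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- intersect(KNOWN_STAGES, config$stages)  # dependency order
  report <- list(package = "orchardyield",
                 version = as.character(utils::packageVersion("orchardyield")),
                 seed = config$seed, stages = stages,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  timings <- list()
  seed <- config$seed
  plots <- NULL; scenes <- NULL; model <- NULL

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- fun()
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    res
  }

  if ("simulate" %in% stages) {
    sim <- run_stage("simulate", function() {
      plots <- generate_plot_dataset(config$n_plots, config$beta,
                                     config$noise_sd, seed = seed)
      write_plot_csv(plots[, c("plot_id", "s1", "s2", "f1", "f2", "f3", "f4",
                               "yield_kg")],
                     file.path(out, "plots.csv"))
      spad <- simulate_spad_readings(plots, seed = seed + 1L)
      write_plot_csv(spad, file.path(out, "spad_readings.csv"))
      scene_dir <- file.path(out, "scenes")
      dir.create(scene_dir, showWarnings = FALSE)
      scenes <- list()
      for (i in seq_len(nrow(plots))) {
        for (stg in c("flowering", "young_fruit")) {
          sp <- scene_spec_for_plot(plots[i, ], stg, config$scene_size,
                                    seed = seed + 10L * i + (stg == "young_fruit"))
          sc <- generate_scene(sp)
          scenes[[paste(plots$plot_id[i], stg, sep = ":")]] <- sc
        }
      }
      # a small sample of scenes goes to disk; all stay in memory
      for (k in seq_len(min(4L, length(scenes)))) write_scene(scenes[[k]], scene_dir, k)
      list(plots = plots, scenes = scenes)
    })
    plots <- sim$plots; scenes <- sim$scenes
    report$simulate <- list(n_plots = nrow(plots), n_scenes = length(scenes),
                            noise_sd = config$noise_sd)
  }

  if ("segtrain" %in% stages) {
    report$segtrain <- run_stage("segtrain", function() {
      cfg <- config$seg_config %||% model_config(input_size = config$scene_size)
      tc <- config$seg_train %||% train_config(epochs = 60L, seed = seed)
      model <<- build_model(cfg, seed = seed)
      train_scenes <- scenes[seq_len(min(config$n_train_scenes, length(scenes)))]
      tr <- train_segmenter(model, train_scenes, tc)
      utils::write.csv(tr$history, file.path(out, "training_history.csv"),
                       row.names = FALSE)
      mets <- evaluate_model(model, train_scenes)
      save_model(model, file.path(out, "segnet.rds"))
      list(n_scenes = length(train_scenes), n_steps = tr$n_steps,
           final_train_loss = tr$history$train_loss[nrow(tr$history)],
           train_miou = mets$miou, train_pa = mets$pixel_accuracy)
    })
  }

  if ("structure" %in% stages) {
    st <- run_stage("structure", function() {
      rows <- list()
      for (i in seq_len(nrow(plots))) {
        vals <- c(f1 = NA_real_, f2 = NA_real_, f3 = NA_real_, f4 = NA_real_)
        for (stg in c("flowering", "young_fruit")) {
          sc <- scenes[[paste(plots$plot_id[i], stg, sep = ":")]]
          msk <- if (!config$use_true_masks && !is.null(model)) {
            predict_mask(model, sc$image)
          } else sc$mask
          grid <- tile_image(sc$image, msk, tile_size = config$tile_size,
                             pad_policy = "pad_white")
          grid <- filter_background_tiles(grid)
          cnt <- suppressWarnings(count_class_pixels(grid, stage = stg))
          rat <- structural_ratios(cnt)
          if (stg == "flowering") {
            vals["f1"] <- rat$f1; vals["f2"] <- rat$f2
          } else {
            vals["f3"] <- rat$f3; vals["f4"] <- rat$f4
          }
        }
        rows[[i]] <- data.frame(plot_id = plots$plot_id[i], t(vals))
      }
      ratios <- do.call(rbind, rows)
      write_plot_csv(ratios, file.path(out, "structural_ratios.csv"))
      ratios
    })
    report$structure <- list(n_plots = nrow(st),
                             mask_source = if (!config$use_true_masks && !is.null(model))
                               "predicted" else "ground_truth")
  }

  if ("indices" %in% stages) {
    idx_tab <- run_stage("indices", function() {
      raster_dir <- file.path(out, "rasters")
      dir.create(raster_dir, showWarnings = FALSE)
      rows <- list()
      for (i in seq_len(nrow(plots))) {
        stack <- generate_reflectance(plots$latent_vigor[i], config$raster_size,
                                      config$raster_size, seed = seed + 1000L + i)
        s <- config$raster_size
        poly <- cbind(c(1, s - 1, s - 1, 1), c(1, 1, s - 1, s - 1))
        iv <- plot_index_vector(stack, poly)
        if (i <= 4L) {
          write_raster_tiff(stack, file.path(raster_dir, sprintf("%s.tif", plots$plot_id[i])))
          write_polygon_geojson(poly, file.path(raster_dir, sprintf("%s.geojson", plots$plot_id[i])),
                                plot_id = plots$plot_id[i])
        }
        rows[[i]] <- data.frame(plot_id = plots$plot_id[i], t(iv))
      }
      tab <- do.call(rbind, rows)
      write_plot_csv(tab, file.path(out, "vegetation_indices.csv"))
      tab
    })
    report$indices <- list(n_plots = nrow(idx_tab),
                           indices = setdiff(names(idx_tab), "plot_id"))
  }

  if ("fuse" %in% stages) {
    fuse <- run_stage("fuse", function() {
      spad <- read_plot_csv(file.path(out, "spad_readings.csv"))
      s_tab <- do.call(rbind, lapply(split(spad, spad$plot_id), function(dd) {
        data.frame(plot_id = dd$plot_id[1],
                   s1 = aggregate_spad(dd[dd$stage == "flowering", c("tree", "spad")]),
                   s2 = aggregate_spad(dd[dd$stage == "young_fruit", c("tree", "spad")]))
      }))
      al <- index_aliases()
      idx_tab <- read_plot_csv(file.path(out, "vegetation_indices.csv"))
      for (a in names(al)) idx_tab[[a]] <- idx_tab[[al[[a]]]]
      ratios <- read_plot_csv(file.path(out, "structural_ratios.csv"))
      records <- Reduce(function(a, b) merge(a, b, by = "plot_id"),
                        list(s_tab, ratios, idx_tab[, c("plot_id", names(al))],
                             plots[, c("plot_id", "yield_kg")]))
      records <- records[match(plots$plot_id, records$plot_id), ]
      write_plot_csv(records, file.path(out, "fused_records.csv"))

      corr <- yield_correlations(records)
      grid <- yield_model_grid(records, config$feature_sets, config$models,
                               seed = seed)
      utils::write.csv(grid, file.path(out, "model_grid.csv"), row.names = FALSE)
      list(records = records, corr = corr, grid = grid)
    })
    report$fuse <- list(
      n_records = nrow(fuse$records),
      correlations = as.list(round(fuse$corr, 6)),
      grid = fuse$grid)
    fused_records <- fuse$records
  }

  if ("explain" %in% stages) {
    report$shapley <- run_stage("explain", function() {
      parts <- split_records(fused_records, seed = seed)
      tr <- build_feature_matrix(parts$train, config$shap_set)
      te <- build_feature_matrix(parts$test, config$shap_set)
      fp <- fit_and_predict(config$shap_model, tr, te, seed = seed)
      bg_idx <- with_seed(seed + 5L,
                          sample.int(nrow(tr$X), min(config$shap_background, nrow(tr$X))))
      expl_idx <- seq_len(min(config$shap_explain, nrow(te$X)))
      rep_sh <- shapley_importance(predictor_from_fit(fp),
                                   te$X[expl_idx, , drop = FALSE],
                                   tr$X[bg_idx, , drop = FALSE])
      phi_long <- data.frame(
        plot_id = rep(parts$test$plot_id[expl_idx], times = ncol(rep_sh$phi)),
        feature = rep(colnames(rep_sh$phi), each = length(expl_idx)),
        phi = as.vector(rep_sh$phi))
      utils::write.csv(phi_long, file.path(out, "shapley_values.csv"),
                       row.names = FALSE)
      list(model = config$shap_model, feature_set = config$shap_set,
           baseline = rep_sh$baseline,
           global_importance = as.list(round(rep_sh$global_importance, 6)))
    })
  }

  report$timings <- timings
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows",
                       pretty = TRUE)
  invisible(report)
}

#' Load a run configuration from JSON
#'
#' @param path JSON file with [run_config()] fields (unknown fields error).
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) stop_bad_arg("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$beta)) vals$beta <- unlist(vals$beta)
  do.call(run_config, vals)
}
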