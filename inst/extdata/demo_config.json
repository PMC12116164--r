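{
  "out_dir": "orchardyield_demo_run",
  "seed": 1,
  "stages": ["simulate", "structure", "indices", "fuse", "explain"],
  "n_plots": 24,
  "noise_sd": 5,
  "scene_size": 48,
  "tile_size": 32,
  "raster_size": 16,
  "use_true_masks": true,
  "feature_sets": ["A", "B", "C", "G"],
  "models": ["KNN", "PLS", "RF", "SVM"],
  "shap_model": "SVM",
  "shap_set": "G",
  "shap_background": 16,
  "shap_explain": 6
}
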