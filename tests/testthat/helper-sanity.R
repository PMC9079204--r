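# Shared learning-sanity runs: one 400-study phantom dataset with balanced,
# cleanly separated grades; three seeded 5-fold cross-validation runs of each
# custom model at 10 epochs. Computed once per session and reused by the
# acceptance and property tests (several tests interrogate the same runs).

.sanity_cache <- new.env(parent = emptyenv())

sanity_train_config <- function(seed) {
  train_config(epochs = 10L, batch_size = 16L, initial_lr = 1e-3,
               clip_norm = 1, lr_factor = 0.5, restore_best = TRUE,
               restarts = 2L, seed = seed)
}

sanity_model_spec <- function(family) {
  model_spec(family, filter_plan = c(8L, 16L, 32L, 64L), stem_filters = 8L)
}

sanity_runs <- function() {
  if (!is.null(.sanity_cache$runs)) return(.sanity_cache$runs)
  studies <- generate_dataset(400, rep(0.25, 4), planar_fraction = 0.05,
                              seed = 424242, metastasis_rate = 0.15)
  pp <- preprocess_studies(studies)
  # one grade-3 whole-body study, with its cardiac mask in crop coordinates,
  # for the activation-map property
  g3 <- which(pp$meta$grade == 3 & pp$meta$protocol == "whole_body")[1]
  mask128 <- crop_mask(region_mask(studies[[g3]], "cardiac"), pp$windows[[g3]])
  rm(studies)
  runs <- list(meta = pp$meta, g3_index = g3,
               g3_image = pp$images[[g3]],
               g3_mask32 = resample_area(mask128 * 1, 32, 32) > 0.25,
               seeds = c(101L, 202L, 303L), cv = list())
  for (seed in runs$seeds) {
    for (fam in c("linear", "residual")) {
      cv <- run_cross_validation(
        pp$images, pp$meta$grade, sanity_model_spec(fam),
        task = "four_class", k = 5L,
        train_cfg = sanity_train_config(seed),
        aug_cfg = augmentation_config(multiplier = 0L),
        seed = seed, input_size = 32L,
        has_metastases = pp$meta$has_metastases,
        keep_models = (fam == "linear"))
      entry <- list(report = cv$report,
                    subgroup = subgroup_report(cv),
                    predictions = cv$predictions)
      if (fam == "linear") {
        # retain the fold model whose test set contains the grade-3 study
        f <- cv$predictions$fold[runs$g3_index] + 1L
        entry$model <- cv$models[[f]]
      }
      runs$cv[[paste(fam, seed, sep = "_")]] <- entry
    }
  }
  .sanity_cache$runs <- runs
  runs
}
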