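# End-to-end orchestration: synthesize a cohort, rasterize training masks,
# train the two segmentation models (and optionally the length regressor)
# on the training folds, run inference on the held-out fold, convert
# per-image estimates to per-participant densities, and write agreement and
# group-comparison reports.

#' Pipeline configuration
#'
#' Defaults are desk scale: a small cohort of 96 x 96 px images (the full
#' 400/384 um pitch, i.e. a cropped field) and tiny networks, so a complete
#' run finishes in a few minutes on one CPU core. Per-image cell counts
#' follow the full-field per-image distribution
#' (`dc_count_area_mm2 = 0.16`), so the cell-counting stage sees the same
#' counts per image as the study's 0.16 mm^2 frames; DC densities are
#' accordingly computed against 0.16 mm^2.
#'
#' @param out_dir run directory (created if needed)
#' @param synth a [synth_params()]; defaults to a 96 px crop at the
#'   default pitch
#' @param group_specs per-group latent distributions
#' @param n_subjects subjects per group
#' @param images_per_eye images per eye per subject
#' @param nerve_net,dc_net [resunet_config()]s for the two models
#' @param regressor `NULL` to skip the regression estimator, otherwise a
#'   [length_regressor_config()]
#' @param k_folds folds for the subject-stratified split; fold 0 is held
#'   out for evaluation and the remaining folds train the models
#' @param dc_count_area_mm2 area converting latent cell densities to
#'   expected per-image counts (see [generate_cohort()]); the default 0.16
#'   keeps the full-field per-image count distribution on the crop
#' @param min_area_px component-size threshold for cell counting
#' @param write_data write images/annotations to disk (slower; off by
#'   default, reports and CSVs are always written)
#' @param seed master seed
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir = tempfile("subbasal_run_"),
                            synth = synth_params(image_shape = c(96L, 96L),
                                                 seed = 1L),
                            group_specs = default_group_specs(),
                            n_subjects = 5, images_per_eye = 2,
                            nerve_net = resunet_config(depth = 3L,
                                                       base_channels = 8L,
                                                       epochs = 30L,
                                                       learning_rate = 2e-3),
                            dc_net = resunet_config(depth = 3L,
                                                    base_channels = 8L,
                                                    head = "softmax3",
                                                    epochs = 45L,
                                                    learning_rate = 2e-3),
                            regressor = length_regressor_config(),
                            k_folds = 5L, dc_count_area_mm2 = 0.16,
                            min_area_px = 10L, write_data = FALSE,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full automated pipeline on a synthetic cohort
#'
#' Stages: synth -> rasterize -> train -> segment -> cnfl/dc -> evaluate ->
#' stats. Deterministic given the config. All tabular outputs and a
#' manifest (seeds, problem sizes, per-stage timings) are written under
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()]
#' @return list of class `pipeline_result` with elements `per_image`
#'   (data frame of truth and estimates on the held-out fold), `per_subject`,
#'   `cnfl_agreement` ([agreement_report()]), `heldout_nerve_dice`,
#'   `heldout_dc_specificity`, `dc_count_mae` (mean absolute error of the
#'   per-image total cell count), `dc_count_mae_class` (same, per class, so
#'   it also absorbs with/without-dendrites confusion), `cnfl_mape`,
#'   `group_stats`, `selection` (estimator choice report) and `out_dir`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name) {
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    t0 <<- Sys.time()
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage: synth ---------------------------------------------------
  cohort <- generate_cohort(config$group_specs, config$n_subjects,
                            config$images_per_eye, seed = config$seed,
                            params = config$synth,
                            dc_count_area_mm2 = config$dc_count_area_mm2)
  if (config$write_data) write_cohort(cohort, file.path(config$out_dir, "data"))
  truth <- cohort$truth
  area <- image_area_mm2(config$synth$image_shape, config$synth$pixel_pitch_um)
  tick("synth")

  # --- stage: rasterize ----------------------------------------------
  nerve_masks <- lapply(cohort$samples, function(s)
    rasterize_nerve_mask(s$tracing))
  dc_masks <- lapply(cohort$samples, function(s)
    rasterize_dc_mask(s$annotation))
  tick("rasterize")

  # --- stage: folds and training -------------------------------------
  folds <- make_folds(truth$subject_id, k = config$k_folds,
                      seed = config$seed)
  test_idx <- which(folds[truth$subject_id] == 0L)
  train_idx <- setdiff(seq_len(nrow(truth)), test_idx)
  images <- lapply(cohort$samples, `[[`, "image")

  nerve_model <- build_resunet(config$nerve_net)
  nerve_model <- train_resunet(nerve_model, images[train_idx],
                               nerve_masks[train_idx])
  dc_model <- build_resunet(config$dc_net)
  dc_model <- train_resunet(dc_model, images[train_idx],
                            dc_masks[train_idx])
  saveRDS(nerve_model, file.path(config$out_dir, "nerve_model.rds"))
  saveRDS(dc_model, file.path(config$out_dir, "dc_model.rds"))
  tick("train")

  # --- stage: segment + per-image estimation -------------------------
  pitch <- config$synth$pixel_pitch_um
  per_image <- truth
  per_image$pred_length_mm <- NA_real_
  per_image$pred_n_with <- NA_integer_
  per_image$pred_n_without <- NA_integer_
  nerve_dice <- numeric(0)
  dc_spec <- numeric(0)
  reg_lengths <- rep(NA_real_, nrow(truth))
  for (i in test_idx) {
    pm <- predict_mask(nerve_model, images[[i]])
    nerve_dice <- c(nerve_dice, dice(pm, nerve_masks[[i]]))
    per_image$pred_length_mm[i] <- cnfl_image(pm, pitch)$length_mm
    dm <- predict_mask(dc_model, images[[i]])
    fg_pred <- (dm$data[, , 2] + dm$data[, , 3]) > 0
    fg_true <- (dc_masks[[i]]$data[, , 2] + dc_masks[[i]]$data[, , 3]) > 0
    dc_spec <- c(dc_spec, specificity(fg_pred + 0, fg_true + 0))
    per_image$pred_n_with[i] <-
      count_components(dm, "with_dendrites", config$min_area_px)
    per_image$pred_n_without[i] <-
      count_components(dm, "without_dendrites", config$min_area_px)
  }

  selection <- NULL
  if (!is.null(config$regressor)) {
    reg <- build_length_regressor(config$regressor)
    reg <- train_length_regressor(reg, images[train_idx],
                                  truth$true_length_mm[train_idx])
    saveRDS(reg, file.path(config$out_dir, "length_regressor.rds"))
    for (i in test_idx)
      reg_lengths[i] <- predict_length(reg, images[[i]])$length_mm
    selection <- select_estimator(per_image$pred_length_mm[test_idx],
                                  reg_lengths[test_idx],
                                  truth$true_length_mm[test_idx])
    per_image$pred_length_reg_mm <- reg_lengths
    if (selection$chosen == "regression")
      per_image$pred_length_mm <- reg_lengths
  }
  tick("segment")

  # --- stage: per-participant densities ------------------------------
  test <- per_image[test_idx, ]
  dc_area <- cohort$dc_count_area_mm2
  per_subject <- do.call(rbind, lapply(split(test, test$subject_id),
                                       function(d) {
    data.frame(
      subject_id = d$subject_id[1], group = d$group[1],
      true_cnfl = mean(d$true_length_mm) / area,
      auto_cnfl = mean(d$pred_length_mm) / area,
      true_dc_with = mean(d$n_with) / dc_area,
      auto_dc_with = mean(d$pred_n_with) / dc_area,
      true_dc_without = mean(d$n_without) / dc_area,
      auto_dc_without = mean(d$pred_n_without) / dc_area)
  }))
  rownames(per_subject) <- NULL
  tick("densities")

  # --- stage: evaluate + stats ---------------------------------------
  cnfl_agreement <- if (nrow(per_subject) >= 3)
    agreement_report(per_subject$auto_cnfl, per_subject$true_cnfl) else NULL
  # total per-image cell count error (the clinically argued quantity) and
  # the harder per-class error, which also absorbs class confusion
  dc_count_mae <- mean(abs((test$pred_n_with + test$pred_n_without) -
                             (test$n_with + test$n_without)))
  dc_count_mae_class <- mean(abs(c(test$pred_n_with - test$n_with,
                                   test$pred_n_without - test$n_without)))
  group_stats <- tryCatch({
    gdf <- data.frame(group = per_subject$group,
                      cnfl = per_subject$auto_cnfl,
                      dc_with = per_subject$auto_dc_with,
                      dc_without = per_subject$auto_dc_without)
    compare_groups(gdf)
  }, error = function(e) NULL)
  tick("evaluate")

  write.csv(per_image, file.path(config$out_dir, "per_image.csv"),
            row.names = FALSE)
  write.csv(per_subject, file.path(config$out_dir, "per_subject.csv"),
            row.names = FALSE)
  if (!is.null(group_stats))
    write.csv(group_stats, file.path(config$out_dir, "group_stats.csv"),
              row.names = FALSE)
  result <- structure(
    list(per_image = per_image, per_subject = per_subject,
         cnfl_agreement = cnfl_agreement,
         heldout_nerve_dice = mean(nerve_dice),
         heldout_dc_specificity = mean(dc_spec),
         dc_count_mae = dc_count_mae,
         dc_count_mae_class = dc_count_mae_class,
         cnfl_mape = mape(per_subject$auto_cnfl, per_subject$true_cnfl),
         group_stats = group_stats, selection = selection,
         folds = folds, out_dir = config$out_dir),
    class = "pipeline_result")
  manifest <- list(seed = config$seed,
                   n_subjects = config$n_subjects,
                   images_per_eye = config$images_per_eye,
                   image_shape = config$synth$image_shape,
                   n_images = nrow(truth),
                   n_test_images = length(test_idx),
                   timings_sec = timings)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(cnfl_agreement))
    jsonlite::write_json(unclass(cnfl_agreement),
                         file.path(config$out_dir, "cnfl_agreement.json"),
                         auto_unbox = TRUE, digits = NA)
  result
}
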