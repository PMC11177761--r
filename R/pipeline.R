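#' Pipeline configuration
#'
#' Bundles the per-stage configurations of the end-to-end run:
#' generate -> split -> (augment) -> train segmenter -> segment/crop ->
#' train classifier -> evaluate. One global seed deterministically derives
#' every stage seed.
#'
#' @param cohort a [synthetic_cohort_config()] (the demo data source).
#' @param augmentation optional [augmentation_config()]; `NULL` skips
#'   offline augmentation.
#' @param train_fraction,val_fraction split fractions (embryo level,
#'   patient-grouped; validation carved out of training).
#' @param unet a [unet_spec()] for the segmentation step.
#' @param seg_train a [seg_train_config()].
#' @param seg_max_frames cap on ground-truth frames used to train the
#'   segmenter.
#' @param backbone a [backbone_spec()] for the classifier branches.
#' @param mode `"fusion"` (three timepoints) or `"si"` (final frame only).
#' @param train a [train_config()].
#' @param crop_margin bounding-box margin fraction for [crop_and_resize()].
#' @param seed global integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = synthetic_cohort_config(
                              n_embryos = 60L, n_negative = 40L,
                              n_positive = 20L, image_size = 64L,
                              effect_size = 2),
                            augmentation = NULL,
                            train_fraction = 2 / 3, val_fraction = 0.15,
                            unet = unet_spec(depth = 3L, base_channels = 8L),
                            seg_train = seg_train_config(epochs = 10L),
                            seg_max_frames = 120L,
                            backbone = backbone_spec("tinycnn"),
                            mode = c("fusion", "si"),
                            train = train_config(max_epochs = 15L),
                            crop_margin = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(cohort = cohort, augmentation = augmentation,
                 train_fraction = train_fraction,
                 val_fraction = val_fraction, unet = unet,
                 seg_train = seg_train,
                 seg_max_frames = as.integer(seg_max_frames),
                 backbone = backbone, mode = mode, train = train,
                 crop_margin = crop_margin, seed = as.integer(seed)),
            class = "pipeline_config")
}

cohort_by_id <- function(cohort, ids) {
  keep <- vapply(cohort$embryos, function(e) e$record$embryo_id %in% ids,
                 logical(1))
  cohort$embryos[keep]
}

# frames for classifier input: segment, postprocess, crop. Falls back to a
# full-frame mask when the segmenter yields nothing above threshold.
crop_with_segmenter <- function(embryos, segmenter, target_side,
                                margin_frac) {
  fallbacks <- 0L
  frames_by_t <- lapply(1:3, function(t) {
    imgs <- lapply(embryos, function(e) e$frames[[t]])
    probs <- segment_images(segmenter, imgs)
    lapply(seq_along(imgs), function(i) {
      mask <- tryCatch(postprocess_mask(probs[[i]]), error = function(err) {
        fallbacks <<- fallbacks + 1L
        matrix(1, nrow(imgs[[i]]), ncol(imgs[[i]]))
      })
      crop_and_resize(imgs[[i]], mask, target_side, margin_frac)
    })
  })
  list(frames_by_t = frames_by_t, fallbacks = fallbacks)
}

classifier_xy <- function(embryos, frames_by_t, backbone, mode) {
  xs <- classifier_inputs(frames_by_t, backbone)
  y <- vapply(embryos, `[[`, numeric(1), "label")
  x <- if (mode == "fusion") xs else xs[[3L]]
  list(x = x, y = y)
}

#' Run the full pipeline
#'
#' Executes every stage in order on a synthetic cohort and writes all
#' intermediate artifacts (manifest, split CSV, segmenter checkpoint,
#' predictions CSV, metrics JSON, summary JSON) under `run_dir`. A rerun
#' with the same config produces an identical summary. Any stage error
#' aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param run_dir output directory (created; default: a `run-<seed>`
#'   subdirectory of `tempdir()`).
#' @return the summary list, invisibly (also written to
#'   `run_dir/summary.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), run_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(run_dir)) {
    run_dir <- file.path(tempdir(), sprintf("run-%d", config$seed))
  }
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cc <- config$cohort
  cc$seed <- derive_seed(config$seed, 1L)
  cohort <- stage("generate",
                  generate_cohort(cc, dir = file.path(run_dir, "data")))

  split <- stage("split", split_grouped_stratified(
    cohort$manifest, config$train_fraction,
    seed = derive_seed(config$seed, 2L),
    val_fraction = config$val_fraction))
  write_split(split, file.path(run_dir, "split.csv"))

  train_embryos <- cohort_by_id(cohort, split$train_ids)
  val_embryos <- cohort_by_id(cohort, split$val_ids)
  test_embryos <- cohort_by_id(cohort, split$test_ids)

  augmented_total <- 0L
  if (!is.null(config$augmentation)) {
    stage("augment", {
      aug_cfg <- config$augmentation
      augmented <- vector("list", length(train_embryos))
      for (i in seq_along(train_embryos)) {
        aug_cfg$seed <- derive_seed(config$seed, 100L + i)
        augs <- augment_embryo(train_embryos[[i]]$frames, aug_cfg)
        augmented[[i]] <- lapply(augs, function(a) {
          e <- train_embryos[[i]]
          e$frames <- a$frames
          e
        })
      }
      train_embryos <- c(train_embryos, unlist(augmented,
                                               recursive = FALSE))
      augmented_total <- length(unlist(augmented, recursive = FALSE))
    })
  }

  seg <- stage("train-seg", {
    all_frames <- unlist(lapply(train_embryos, `[[`, "frames"),
                         recursive = FALSE)
    all_masks <- unlist(lapply(train_embryos, `[[`, "masks"),
                        recursive = FALSE)
    keep <- local_seed(derive_seed(config$seed, 3L),
                       sample(length(all_frames),
                              min(config$seg_max_frames,
                                  length(all_frames))))
    st <- config$seg_train
    st$seed <- derive_seed(config$seed, 4L)
    train_segmenter(all_frames[keep], all_masks[keep], st,
                    spec = config$unet,
                    checkpoint = file.path(run_dir, "segmenter.rds"))
  })

  backbone_obj <- stage("build-model", local_seed(
    derive_seed(config$seed, 6L), build_backbone(config$backbone)))
  side <- backbone_obj$native_side
  cr_train <- stage("segment", crop_with_segmenter(
    train_embryos, seg$model, side, config$crop_margin))
  cr_val <- crop_with_segmenter(val_embryos, seg$model, side,
                                config$crop_margin)
  cr_test <- crop_with_segmenter(test_embryos, seg$model, side,
                                 config$crop_margin)

  model <- local_seed(derive_seed(config$seed, 7L), {
    if (config$mode == "fusion") {
      build_fusion_model(fusion_model_spec(config$backbone))
    } else {
      build_si_model(config$backbone)
    }
  })
  fit <- stage("train", {
    tc <- config$train
    tc$seed <- derive_seed(config$seed, 5L)
    train_classifier(
      model,
      classifier_xy(train_embryos, cr_train$frames_by_t, backbone_obj,
                    config$mode),
      classifier_xy(val_embryos, cr_val$frames_by_t, backbone_obj,
                    config$mode),
      tc)
  })

  summary <- stage("evaluate", {
    test_xy <- classifier_xy(test_embryos, cr_test$frames_by_t,
                             backbone_obj, config$mode)
    probs <- predict_proba(fit$model, test_xy$x)
    preds <- classify(probs)
    report <- compute_metrics(preds, test_xy$y,
                              predictor_name = config$mode)
    write_metrics_json(report, file.path(run_dir, "metrics.json"))
    utils::write.csv(data.frame(
      embryo_id = vapply(test_embryos, function(e) e$record$embryo_id,
                         character(1)),
      probability = probs, label = preds), file.path(run_dir,
                                                     "predictions.csv"),
      row.names = FALSE)
    list(
      counts = list(train = length(split$train_ids),
                    val = length(split$val_ids),
                    test = length(split$test_ids),
                    augmented_train = augmented_total,
                    augmented_train_total = augmented_total +
                      if (augmented_total > 0) length(split$train_ids) else 0L),
      split_table = as.data.frame(split$table),
      segmentation = list(final_train_loss = utils::tail(
        seg$history$train_loss, 1L)),
      crop_fallbacks = cr_train$fallbacks + cr_val$fallbacks +
        cr_test$fallbacks,
      classifier = list(mode = config$mode,
                        backbone = config$backbone$name,
                        epochs_run = nrow(fit$history),
                        stopped_early = fit$stopped_early,
                        not_learned = is_constant_predictor(probs)),
      metrics = list(accuracy = report$accuracy,
                     precision = report$precision,
                     recall = report$recall, f1 = report$f1))
  })
  jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
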