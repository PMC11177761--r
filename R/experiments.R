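# Benchmark experiments on synthetic cohorts. These are the package's
# desk-scale study conditions: they exercise the full training stack at
# 64 px with the tinycnn backbone so they run on one CPU in minutes.

cohort_classifier_xy <- function(embryos, backbone, mode) {
  frames_by_t <- lapply(1:3, function(t) {
    lapply(embryos, function(e) e$frames[[t]])
  })
  xs <- classifier_inputs(frames_by_t, backbone)
  list(x = if (mode == "fusion") xs else xs[[3L]],
       y = vapply(embryos, `[[`, numeric(1), "label"))
}

#' Fusion-versus-single-image comparison on synthetic cohorts
#'
#' The central qualitative claim of the multi-timepoint design, restated
#' testably: when the discriminative morphology signal exists only in the
#' first two timepoints, a classifier fusing all three frames must beat
#' one that sees only the final (68 hpi) frame. For each seed a balanced
#' synthetic cohort is generated with `signal_timepoints = c(1, 2)`, both
#' models are trained identically on raw frames (tinycnn branches), and
#' test accuracies are compared.
#'
#' @param seeds integer vector of replicate seeds.
#' @param n cohort size (split 2/3 train / 1/3 test, patient-grouped;
#'   15\% of train held out for early stopping).
#' @param effect_size morphology signal strength.
#' @param image_size frame side in pixels.
#' @param max_epochs,patience training budget per model.
#' @return list with per-seed `fusion_acc`, `si_acc`, `margin`, and their
#'   medians.
#' @export
fusion_vs_si_experiment <- function(seeds = 1:5, n = 300L, effect_size = 2,
                                    image_size = 64L, max_epochs = 10L,
                                    patience = Inf) {
  res <- lapply(seeds, function(s) {
    n_pos <- n %/% 2L
    cfg <- synthetic_cohort_config(
      n_embryos = n, n_negative = n - n_pos, n_positive = n_pos,
      image_size = image_size, effect_size = effect_size,
      signal_timepoints = c(1L, 2L), seed = derive_seed(s, 11L))
    cohort <- generate_cohort(cfg)
    sp <- split_grouped_stratified(cohort$manifest, 2 / 3,
                                   seed = derive_seed(s, 12L),
                                   val_fraction = 0.15)
    spec <- backbone_spec("tinycnn")
    accs <- vapply(c("fusion", "si"), function(mode) {
      tr <- cohort_classifier_xy(cohort_by_id(cohort, sp$train_ids), spec,
                                 mode)
      va <- cohort_classifier_xy(cohort_by_id(cohort, sp$val_ids), spec,
                                 mode)
      te <- cohort_classifier_xy(cohort_by_id(cohort, sp$test_ids), spec,
                                 mode)
      model <- local_seed(derive_seed(s, if (mode == "fusion") 15L else 16L), {
        if (mode == "fusion") {
          build_fusion_model(fusion_model_spec(spec))
        } else {
          build_si_model(spec)
        }
      })
      fit <- train_classifier(model, tr, va, train_config(
        max_epochs = max_epochs, early_stop_patience = patience,
        seed = derive_seed(s, if (mode == "fusion") 13L else 14L)))
      mean(classify(predict_proba(fit$model, te$x)) == te$y)
    }, numeric(1))
    c(fusion = accs[["fusion"]], si = accs[["si"]])
  })
  fusion_acc <- vapply(res, `[[`, numeric(1), "fusion")
  si_acc <- vapply(res, `[[`, numeric(1), "si")
  list(fusion_acc = fusion_acc, si_acc = si_acc,
       margin = fusion_acc - si_acc,
       median_fusion = stats::median(fusion_acc),
       median_si = stats::median(si_acc),
       median_margin = stats::median(fusion_acc - si_acc))
}

#' Segmenter benchmark on synthetic frames
#'
#' Trains a U-Net on synthetic embryo frames with ground-truth zona masks
#' and reports held-out mean Dice after post-processing. The bright-ring
#' separation task is deliberately learnable; the benchmark checks that
#' the full train/segment/postprocess path delivers high-overlap masks.
#'
#' @param n_images total frames (split `train_fraction` / rest held out).
#' @param image_size frame side in pixels.
#' @param epochs training epochs.
#' @param spec a [unet_spec()] (test-scale default: depth 3, base 4).
#' @param seed integer seed.
#' @param train_fraction fraction used for training.
#' @return list with `train_n`, `test_n`, `heldout_dice` and the fit
#'   history.
#' @export
segmenter_benchmark <- function(n_images = 200L, image_size = 64L,
                                epochs = 20L,
                                spec = unet_spec(depth = 3L,
                                                 base_channels = 4L),
                                seed = 1L, train_fraction = 0.75) {
  n_embryos <- ceiling(n_images / 3)
  n_pos <- max(1L, n_embryos %/% 3L)
  cohort <- generate_cohort(synthetic_cohort_config(
    n_embryos = n_embryos, n_negative = n_embryos - n_pos,
    n_positive = n_pos, image_size = image_size,
    seed = derive_seed(seed, 21L)))
  imgs <- unlist(lapply(cohort$embryos, `[[`, "frames"),
                 recursive = FALSE)[seq_len(n_images)]
  msks <- unlist(lapply(cohort$embryos, `[[`, "masks"),
                 recursive = FALSE)[seq_len(n_images)]
  n_train <- round(train_fraction * n_images)
  ix <- local_seed(derive_seed(seed, 22L), sample(n_images))
  tr <- ix[seq_len(n_train)]
  te <- ix[(n_train + 1L):n_images]
  fit <- train_segmenter(imgs[tr], msks[tr],
                         seg_train_config(epochs = epochs, batch_size = 16L,
                                          seed = derive_seed(seed, 23L)),
                         spec = spec)
  list(train_n = n_train, test_n = length(te),
       heldout_dice = mean_dice(fit$model, imgs[te], msks[te]),
       history = fit$history)
}

#' Generator signal monotonicity check
#'
#' Accuracy of the blastomere-size-CV threshold discriminator
#' ([cv_threshold_discriminator()]) as a function of `effect_size`,
#' averaged over seeds. The class signal injected by the generator must
#' grow (weakly) with the effect size, and vanish at zero.
#'
#' @param effect_sizes effect sizes to sweep.
#' @param seeds replicate seeds.
#' @param n cohort size per replicate.
#' @param image_size frame side in pixels.
#' @return data frame with `effect_size` and mean `accuracy`.
#' @export
signal_monotonicity_experiment <- function(effect_sizes = c(0, 0.5, 1, 2),
                                           seeds = 1:10, n = 60L,
                                           image_size = 64L) {
  acc <- vapply(effect_sizes, function(es) {
    mean(vapply(seeds, function(s) {
      n_pos <- n %/% 2L
      cohort <- generate_cohort(synthetic_cohort_config(
        n_embryos = n, n_negative = n - n_pos, n_positive = n_pos,
        image_size = image_size, effect_size = es,
        seed = derive_seed(s, 31L)))
      sp <- split_grouped_stratified(cohort$manifest, 2 / 3,
                                     seed = derive_seed(s, 32L))
      cv_threshold_discriminator(
        cohort_by_id(cohort, sp$train_ids),
        cohort_by_id(cohort, sp$test_ids))$test_accuracy
    }, numeric(1)))
  }, numeric(1))
  data.frame(effect_size = effect_sizes, accuracy = acc)
}
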