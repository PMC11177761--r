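#' Fusion model specification
#'
#' The three-branch late-fusion classifier: each of the three timepoint
#' frames passes through its own backbone emitting a 10-dimensional feature
#' vector; the three vectors are concatenated (30 features by default) and
#' a single fully connected layer with sigmoidal output produces the
#' pregnancy probability.
#'
#' @param branches either one [backbone_spec()] used for all three
#'   branches, or a list of exactly three specs with equal `feature_dim`.
#' @param share_branch_weights store a single branch and reuse it for all
#'   three timepoints (default FALSE: three independent branches).
#' @return a `fusion_model_spec` list.
#' @export
fusion_model_spec <- function(branches = backbone_spec("tinycnn"),
                              share_branch_weights = FALSE) {
  if (inherits(branches, "backbone_spec")) {
    branches <- list(branches, branches, branches)
  }
  if (length(branches) != 3L) stop("exactly 3 branch specs required")
  fds <- vapply(branches, `[[`, integer(1), "feature_dim")
  if (length(unique(fds)) != 1L) stop("branch feature_dims must match")
  if (share_branch_weights &&
      length(unique(vapply(branches, `[[`, character(1), "name"))) != 1L) {
    stop("shared branches require identical specs")
  }
  structure(list(branches = branches,
                 share_branch_weights = share_branch_weights,
                 feature_dim = fds[1L]),
            class = "fusion_model_spec")
}

#' Build the three-branch fusion classifier
#'
#' @param spec a [fusion_model_spec()].
#' @return an `en_fusion` object; `$forward(xs, training)` takes a list of
#'   three (H, W, N, 3) arrays (one per timepoint, preprocessed with
#'   [prep_backbone_input()]) and returns per-sample logits; `head_in` is
#'   the fused feature length (3 x feature_dim).
#' @export
build_fusion_model <- function(spec = fusion_model_spec()) {
  stopifnot(inherits(spec, "fusion_model_spec"))
  branches <- if (spec$share_branch_weights) {
    bb <- build_backbone(spec$branches[[1L]])
    list(bb, bb, bb)
  } else {
    lapply(spec$branches, build_backbone)
  }
  head_in <- 3L * spec$feature_dim
  head <- nn_dense(head_in, 1L)
  model <- list(spec = spec, branches = branches, head = head,
                head_in = head_in,
                params_branches = if (spec$share_branch_weights) {
                  list(branches[[1L]])
                } else branches)
  model$forward <- function(xs, training = FALSE) {
    stopifnot(is.list(xs), length(xs) == 3L)
    feats <- lapply(1:3, function(t) {
      branches[[t]]$forward(xs[[t]], training)
    })
    head$fwd(ag_cbind(feats), training)
  }
  class(model) <- c("en_fusion", "en_classifier")
  model
}

#' Build the single-image classifier
#'
#' The single-image variant applies one backbone to the final (68 hpi)
#' frame only; its head maps the 10 features straight to the outcome
#' logit.
#'
#' @param spec a [backbone_spec()].
#' @return an `en_si` object; `$forward(x, training)` takes one
#'   (H, W, N, 3) array.
#' @export
build_si_model <- function(spec = backbone_spec("tinycnn")) {
  backbone <- build_backbone(spec)
  head <- nn_dense(spec$feature_dim, 1L)
  model <- list(spec = spec, backbone = backbone, head = head,
                head_in = spec$feature_dim)
  model$forward <- function(x, training = FALSE) {
    if (is.list(x)) x <- x[[length(x)]]
    head$fwd(backbone$forward(x, training), training)
  }
  class(model) <- c("en_si", "en_classifier")
  model
}

#' Classifier training configuration
#'
#' The training regime: learning rate 0.001 reduced by a factor of 0.1
#' every 30 epochs, batch size 32, up to 100 epochs, binary cross-entropy
#' loss, early stopping on validation loss (patience 10 epochs), Adam
#' updates.
#'
#' @param lr initial learning rate.
#' @param lr_step_epochs epochs between learning-rate drops.
#' @param lr_factor multiplicative drop (in (0, 1)).
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (`Inf` disables).
#' @param min_epochs epochs that must complete before early stopping can
#'   trigger (validation loss is noisy while normalization statistics are
#'   still maturing).
#' @param pos_weight positive-class weight in the loss (1 = unweighted;
#'   the 120/48 class imbalance suggests 2.5 when enabled).
#' @param seed integer seed.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, lr_step_epochs = 30L, lr_factor = 0.1,
                         batch_size = 32L, max_epochs = 100L,
                         early_stop_patience = 10L, min_epochs = 10L,
                         pos_weight = 1, seed = NULL) {
  if (lr <= 0 || batch_size < 1L || max_epochs < 1L) {
    stop("lr, batch_size and max_epochs must be positive")
  }
  if (lr_factor <= 0 || lr_factor >= 1) stop("lr_factor must be in (0, 1)")
  structure(list(lr = lr, lr_step_epochs = as.integer(lr_step_epochs),
                 lr_factor = lr_factor, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 min_epochs = as.integer(min_epochs),
                 pos_weight = pos_weight, seed = seed),
            class = "train_config")
}

#' Stepped learning-rate schedule
#'
#' Effective learning rate at epoch `e`:
#' `lr * factor^floor((e - 1) / step)` — with the defaults, 1e-3 for
#' epochs 1-30, 1e-4 for 31-60, 1e-5 for 61-90, 1e-6 from epoch 91.
#'
#' @param epoch epoch number (1-based; vectorized).
#' @param lr,step,factor schedule parameters.
#' @return learning rate(s).
#' @export
lr_schedule <- function(epoch, lr = 1e-3, step = 30L, factor = 0.1) {
  lr * factor^((epoch - 1) %/% step)
}

slice_x <- function(x, ix) {
  if (is.list(x)) lapply(x, function(a) a[, , ix, , drop = FALSE])
  else x[, , ix, , drop = FALSE]
}

x_count <- function(x) {
  if (is.list(x)) dim(x[[1L]])[3L] else dim(x)[3L]
}

classifier_loss_value <- function(model, x, y, pos_weight) {
  z <- model$forward(x, training = FALSE)
  ag_bce_logits(z, y, pos_weight)$value
}

#' Train a classifier
#'
#' Minibatch Adam with the stepped learning-rate schedule, early stopping
#' on validation loss, and retention of the best-validation weights.
#'
#' @param model an `en_fusion` or `en_si` model.
#' @param train,val named lists `list(x, y)`; `x` is a list of three
#'   (H, W, N, 3) arrays for the fusion model or one array for the
#'   single-image model, `y` a 0/1 vector.
#' @param config a [train_config()].
#' @return list with `model` (best-validation weights restored),
#'   `history` (epoch, lr, train_loss, val_loss, val_acc) and
#'   `stopped_early`.
#' @export
train_classifier <- function(model, train, val, config = train_config()) {
  stopifnot(inherits(model, "en_classifier"))
  n <- x_count(train$x)
  if (n == 0L || length(train$y) != n) stop("empty or inconsistent train set")
  nv <- x_count(val$x)
  if (nv == 0L || length(val$y) != nv) stop("empty or inconsistent val set")
  local_seed(config$seed, {
    opt <- optim_adam(trainable_params(model))
    best_val <- Inf
    best_snap <- NULL
    bad <- 0L
    hist <- vector("list", config$max_epochs)
    stopped <- FALSE
    for (e in seq_len(config$max_epochs)) {
      lr_now <- lr_schedule(e, config$lr, config$lr_step_epochs,
                            config$lr_factor)
      ord <- sample(n)
      tot <- 0; nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        ix <- ord[start:min(start + config$batch_size - 1L, n)]
        opt$zero_grad()
        z <- model$forward(slice_x(train$x, ix), training = TRUE)
        loss <- ag_bce_logits(z, train$y[ix], config$pos_weight)
        ag_backward(loss)
        opt$step(lr_now)
        tot <- tot + loss$value; nb <- nb + 1L
      }
      val_p <- predict_proba(model, val$x)
      val_loss <- -mean(ifelse(val$y == 1, log(pmax(val_p, 1e-12)),
                               log(pmax(1 - val_p, 1e-12))))
      val_acc <- mean(classify(val_p) == val$y)
      hist[[e]] <- data.frame(epoch = e, lr = lr_now, train_loss = tot / nb,
                              val_loss = val_loss, val_acc = val_acc)
      # ties resolve to the later (more trained) epoch; patience counts
      # only strict improvements, and never before min_epochs
      if (val_loss <= best_val + 1e-9) {
        if (val_loss < best_val - 1e-9) bad <- 0L else bad <- bad + 1L
        best_val <- min(best_val, val_loss)
        best_snap <- param_snapshot(model)
      } else {
        bad <- bad + 1L
      }
      if (e >= config$min_epochs && bad >= config$early_stop_patience) {
        stopped <- TRUE
        break
      }
    }
    if (!is.null(best_snap)) param_restore(model, best_snap)
    list(model = model, history = do.call(rbind, hist),
         stopped_early = stopped)
  })
}

#' Predict pregnancy probabilities / binarize them
#'
#' `predict_proba` runs the model in evaluation mode and applies the
#' sigmoid; results are invariant to how the input is batched.
#' `classify` thresholds probabilities into 0/1 labels.
#'
#' @param model a trained `en_fusion` or `en_si` model.
#' @param x model input (see [train_classifier()]).
#' @param batch_size forward batch size.
#' @param probs probability vector.
#' @param threshold decision threshold in (0, 1).
#' @return `predict_proba`: probabilities in (0, 1); `classify`: integer
#'   labels (`1` when `p >= threshold`).
#' @export
predict_proba <- function(model, x, batch_size = 64L) {
  stopifnot(inherits(model, "en_classifier"))
  n <- x_count(x)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    z <- model$forward(slice_x(x, ix), training = FALSE)
    out[ix] <- 1 / (1 + exp(-as.numeric(z$value)))
  }
  out
}

#' @rdname predict_proba
#' @export
classify <- function(probs, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  as.integer(probs >= threshold)
}

#' Detect a degenerate constant predictor
#'
#' Training without pretrained weights can fail to move off the majority
#' class; such a run classifies every sample identically. This helper
#' flags that state ("not learned") from the predicted probabilities.
#'
#' @param probs probability vector.
#' @param threshold decision threshold.
#' @return TRUE when all thresholded predictions agree.
#' @export
is_constant_predictor <- function(probs, threshold = 0.5) {
  length(unique(classify(probs, threshold))) == 1L
}

#' Assemble classifier inputs from frames
#'
#' Preprocesses per-timepoint frame lists into the arrays expected by the
#' fusion and single-image models.
#'
#' @param frames_by_timepoint list of three lists of grayscale matrices
#'   (same embryo order in each).
#' @param backbone an `en_backbone` or [backbone_spec()] (controls native
#'   side and normalization).
#' @return list of three (side, side, N, 3) arrays.
#' @export
classifier_inputs <- function(frames_by_timepoint, backbone) {
  stopifnot(length(frames_by_timepoint) == 3L)
  lapply(frames_by_timepoint, prep_backbone_input, backbone = backbone)
}
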