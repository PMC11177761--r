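test_that("every backbone maps a replicated-grayscale batch to length-10 features", {
  set.seed(1)
  # tinycnn checked with a preprocessed grayscale batch end to end
  spec <- backbone_spec("tinycnn")
  bb <- build_backbone(spec)
  frames <- replicate(3, matrix(runif(64 * 64), 64, 64), simplify = FALSE)
  x <- prep_backbone_input(frames, bb)
  expect_equal(dim(x), c(64L, 64L, 3L, 3L))
  f <- bb$forward(x)
  expect_equal(dim(f$value), c(3L, 10L))
  # the standard architectures at their native sides
  for (nm in c("alexnet", "resnet18")) {
    bbz <- build_backbone(backbone_spec(nm))
    side <- bbz$native_side
    fz <- bbz$forward(array(runif(side * side * 2 * 3),
                            c(side, side, 2, 3)))
    expect_equal(dim(fz$value), c(2L, 10L))
    rm(bbz, fz); gc(FALSE)
  }
  for (nm in c("resnet34", "densenet121", "inception_v3")) {
    bbz <- build_backbone(backbone_spec(nm))
    side <- bbz$native_side
    expect_equal(side, if (nm == "inception_v3") 299L else 224L)
    fz <- bbz$forward(array(runif(side * side * 3), c(side, side, 1, 3)))
    expect_equal(dim(fz$value), c(1L, 10L))
    rm(bbz, fz); gc(FALSE)
  }
  expect_error(backbone_spec("vgg16"))
  expect_error(backbone_spec("tinycnn", pretrained = TRUE), "pretrained")
})

test_that("pretrained weights unavailable offline: explicit error with fallback flag", {
  expect_error(build_backbone(backbone_spec("resnet18", pretrained = TRUE)),
               "random_init_fallback")
  expect_warning(
    bb <- build_backbone(backbone_spec("resnet18", pretrained = TRUE,
                                       random_init_fallback = TRUE)),
    "random initialization")
  # pretrained path defaults to training the last layer only
  expect_equal(bb$spec$freeze_mode, "last_layer_only")
  # ImageNet channel statistics only apply to pretrained weights
  expect_equal(ns("backbone_norm_stats")("resnet18", TRUE)$mean[1], 0.485)
  expect_equal(ns("backbone_norm_stats")("tinycnn", FALSE)$sd, rep(0.5, 3))
})

test_that("last-layer-only freezing leaves non-head parameters bit-identical after a step", {
  set.seed(2)
  spec <- backbone_spec("tinycnn", freeze_mode = "last_layer_only")
  model <- build_si_model(spec)
  trunk_before <- lapply(ns("collect_params")(model$backbone$trunk),
                         function(p) p$value)
  head_before <- lapply(ns("trainable_params")(model), function(p) p$value)
  expect_equal(ns("n_params")(model, trainable_only = TRUE),
               32 * 10 + 10 + 10 * 1 + 1)  # backbone fc + model head
  x <- array(runif(64 * 64 * 4 * 3), c(64, 64, 4, 3))
  y <- c(0, 1, 0, 1)
  opt <- ns("optim_adam")(ns("trainable_params")(model))
  opt$zero_grad()
  loss <- ns("ag_bce_logits")(model$forward(x, training = TRUE), y)
  ns("ag_backward")(loss)
  opt$step()
  trunk_after <- lapply(ns("collect_params")(model$backbone$trunk),
                        function(p) p$value)
  expect_identical(trunk_before, trunk_after)
  head_after <- lapply(ns("trainable_params")(model), function(p) p$value)
  expect_false(identical(head_before, head_after))
})

test_that("fusion model concatenates three 10-d branches into a 30-d head", {
  set.seed(3)
  spec <- backbone_spec("tinycnn")
  fm <- build_fusion_model(fusion_model_spec(spec))
  expect_equal(fm$head_in, 30L)
  xs <- replicate(3, array(runif(64 * 64 * 2 * 3), c(64, 64, 2, 3)),
                  simplify = FALSE)
  z <- fm$forward(xs)
  expect_equal(dim(z$value), c(2L, 1L))
  p <- predict_proba(fm, xs)
  expect_true(all(p > 0 & p < 1))
  # weight sharing stores a single branch copy
  shared <- build_fusion_model(fusion_model_spec(spec,
                                                 share_branch_weights = TRUE))
  unshared_n <- ns("n_params")(fm$params_branches)
  shared_n <- ns("n_params")(shared$params_branches)
  expect_equal(unshared_n, 3 * shared_n)
  expect_error(fusion_model_spec(list(spec, spec)), "3 branch")
})

test_that("single-image model uses one branch and is smaller than the fusion model", {
  set.seed(4)
  spec <- backbone_spec("tinycnn")
  si <- build_si_model(spec)
  fm <- build_fusion_model(fusion_model_spec(spec))
  expect_equal(si$head_in, 10L)
  expect_lt(ns("n_params")(si), ns("n_params")(fm))
  x <- array(runif(64 * 64 * 2 * 3), c(64, 64, 2, 3))
  p <- predict_proba(si, x)
  expect_true(all(p > 0 & p < 1))
  # given the full triplet it reads the final (68 hpi) frame
  xs <- list(x * 0, x * 0, x)
  expect_equal(predict_proba(si, xs), p)
})

test_that("learning-rate schedule steps by 0.1 every 30 epochs", {
  lrs <- lr_schedule(1:100)
  expect_equal(unique(lrs[1:30]), 1e-3)
  expect_equal(unique(lrs[31:60]), 1e-4)
  expect_equal(unique(lrs[61:90]), 1e-5)
  expect_equal(unique(lrs[91:100]), 1e-6)
  expect_equal(sort(unique(lrs)), c(1e-6, 1e-5, 1e-4, 1e-3))
  expect_error(train_config(lr_factor = 1.5), "lr_factor")
})

test_that("early stopping halts when validation keeps worsening and restores the best epoch", {
  # a linear model on fixed inputs whose validation labels are flipped:
  # train loss falls monotonically, validation loss rises
  set.seed(5)
  x <- array(runif(4 * 4 * 20 * 3), c(4, 4, 20, 3))
  y <- rbinom(20, 1, 0.5)
  w <- ns("ag_param")(ns("init_dense_w")(48L, 1L))
  b <- ns("ag_param")(0)
  model <- structure(list(w = w, b = b, forward = function(xx, training = FALSE) {
    ns("ag_dense")(ns("ag_flatten4")(ns("ag_tensor")(xx)), w, b)
  }), class = c("en_si", "en_classifier"))
  fit <- train_classifier(model, list(x = x, y = y),
                          list(x = x, y = 1 - y),
                          train_config(max_epochs = 50L,
                                       early_stop_patience = 5L,
                                       min_epochs = 1L, batch_size = 10L,
                                       lr = 0.05, seed = 1L))
  expect_true(fit$stopped_early)
  expect_lte(nrow(fit$history), 10L)
  expect_error(train_classifier(model, list(x = x, y = numeric(0)),
                                list(x = x, y = 1 - y), train_config()),
               "train set")
})

test_that("predictions are invariant to batch partitioning and thresholding is exact", {
  set.seed(6)
  si <- build_si_model(backbone_spec("tinycnn"))
  x <- array(runif(64 * 64 * 9 * 3), c(64, 64, 9, 3))
  p1 <- predict_proba(si, x, batch_size = 64L)
  p2 <- predict_proba(si, x, batch_size = 1L)
  p3 <- predict_proba(si, x, batch_size = 4L)
  expect_equal(p1, p2)
  expect_equal(p1, p3)
  expect_equal(classify(c(0.2, 0.8), 0.5), c(0L, 1L))
  expect_equal(classify(c(0.2, 0.8), 1 - 1e-9), c(0L, 0L))
  expect_error(classify(0.5, 1), "threshold")
  expect_true(is_constant_predictor(c(0.1, 0.2, 0.3)))
  expect_false(is_constant_predictor(c(0.1, 0.9)))
})
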