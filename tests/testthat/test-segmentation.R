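test_that("U-Net channel ladder doubles per level and shapes are preserved", {
  u5 <- build_unet(unet_spec(depth = 5L, base_channels = 64L))
  expect_equal(u5$encoder_channels, c(64L, 128L, 256L, 512L, 1024L))
  rm(u5); gc(FALSE)
  # full-resolution shape contract at the acquisition size (thin ladder
  # keeps the check fast; the channel rule is already asserted above)
  u <- build_unet(unet_spec(depth = 5L, base_channels = 2L))
  x <- array(runif(256 * 256), c(256, 256, 1, 1))
  z <- u$forward(x)
  expect_equal(dim(z$value), c(256L, 256L, 1L, 1L))
  expect_error(u$forward(array(0, c(100, 100, 1, 1))), "divisible")
  # degenerate depth: two convs + 1x1 head, no pooling
  u1 <- build_unet(unet_spec(depth = 1L, base_channels = 4L))
  z1 <- u1$forward(array(runif(33 * 17), c(33, 17, 1, 1)))
  expect_equal(dim(z1$value), c(33L, 17L, 1L, 1L))
  expect_error(unet_spec(depth = 0), "depth")
})

test_that("segmenter training reduces the loss and is seed-reproducible", {
  co <- tiny_cohort()
  imgs <- unlist(lapply(co$embryos[1:8], `[[`, "frames"), recursive = FALSE)
  msks <- unlist(lapply(co$embryos[1:8], `[[`, "masks"), recursive = FALSE)
  cfg <- seg_train_config(epochs = 3L, batch_size = 8L, seed = 5L)
  fit <- train_segmenter(imgs, msks, cfg,
                         spec = unet_spec(depth = 2L, base_channels = 4L))
  expect_lt(utils::tail(fit$history$train_loss, 1),
            fit$history$train_loss[1])
  fit2 <- train_segmenter(imgs, msks, cfg,
                          spec = unet_spec(depth = 2L, base_channels = 4L))
  expect_equal(fit$history$train_loss, fit2$history$train_loss)
  expect_error(train_segmenter(list(), list(), cfg), "no training pairs")
  expect_error(train_segmenter(imgs[1:2], msks[1:3], cfg))
  # checkpoint round-trip
  d <- withr::local_tempdir()
  ck <- file.path(d, "seg.rds")
  fit3 <- train_segmenter(imgs[1:6], msks[1:6],
                          seg_train_config(epochs = 1L, seed = 1L),
                          spec = unet_spec(depth = 2L, base_channels = 4L),
                          checkpoint = ck)
  m2 <- load_segmenter(ck)
  p1 <- segment_images(fit3$model, imgs[1:2])
  p2 <- segment_images(m2, imgs[1:2])
  expect_equal(p1, p2)
})

test_that("postprocessing keeps the largest component and fills holes", {
  pm <- matrix(0, 40, 40)
  pm[5:20, 5:25] <- 0.9      # 336-px blob
  pm[30:33, 30:33] <- 0.9    # small blob
  out <- postprocess_mask(pm, 0.5)
  expect_equal(count_components(out), 1L)
  expect_equal(out[10, 10], 1)
  expect_equal(out[31, 31], 0)
  # interior hole gets filled
  pm2 <- matrix(0, 30, 30)
  pm2[5:25, 5:25] <- 0.8
  pm2[12:15, 12:15] <- 0    # hole
  out2 <- postprocess_mask(pm2)
  expect_equal(out2[13, 13], 1)
  expect_equal(count_components(out2), 1L)
  expect_error(postprocess_mask(matrix(0, 10, 10)), "empty mask")
  expect_error(postprocess_mask(matrix(2, 4, 4)), "\\[0, 1\\]")
})

test_that("crop_and_resize squares, centers and resizes the masked region", {
  img <- matrix(runif(64 * 64), 64, 64)
  full <- matrix(1, 64, 64)
  expect_equal(crop_and_resize(img, full, 64L, margin_frac = 0), img)
  # rectangular masks still produce square output of the target side
  m <- matrix(0, 64, 64)
  m[10:40, 20:35] <- 1
  out <- crop_and_resize(img, m, 32L)
  expect_equal(dim(out), c(32L, 32L))
  # a centered disk stays centered after crop+resize
  co <- seq_len(64) - 0.5
  D <- sqrt(outer((co - 32)^2, (co - 32)^2, "+"))
  disk <- (D <= 20) * 1
  bright <- disk * 0.9 + 0.05
  cr <- crop_and_resize(bright, disk, 48L, margin_frac = 0.05)
  w <- cr - min(cr)
  cm <- c(sum(row(cr) * w), sum(col(cr) * w)) / sum(w)
  expect_lt(max(abs(cm - c(24.5, 24.5))), 2)
  expect_error(crop_and_resize(img, matrix(0, 64, 64), 32L), "empty mask")
})

test_that("dice matches its formula, is symmetric and handles empty masks", {
  a <- matrix(0, 8, 8); a[1:2, 1:2] <- 1          # |A| = 4
  b <- matrix(0, 8, 8); b[2:3, 1:2] <- 1          # |B| = 4, overlap 2
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  disj <- matrix(0, 8, 8); disj[7:8, 7:8] <- 1
  expect_equal(dice(a, disj), 0)
  expect_equal(dice(matrix(0, 4, 4), matrix(0, 4, 4)), 1)  # both empty
  expect_error(dice(a, matrix(0, 4, 4)), "shape")
  set.seed(8)
  for (i in 1:20) {
    x <- matrix(rbinom(64, 1, 0.4), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(dice(x, y), dice(y, x))
    brute <- if (sum(x) + sum(y) == 0) 1 else {
      2 * sum(x == 1 & y == 1) / (sum(x) + sum(y))
    }
    expect_equal(dice(x, y), brute)
  }
})

test_that("a short training run learns the bright-ring separation task", {
  co <- tiny_cohort()
  imgs <- unlist(lapply(co$embryos, `[[`, "frames"), recursive = FALSE)
  msks <- unlist(lapply(co$embryos, `[[`, "masks"), recursive = FALSE)
  fit <- train_segmenter(imgs[1:30], msks[1:30],
                         seg_train_config(epochs = 10L, batch_size = 4L,
                                          seed = 2L),
                         spec = unet_spec(depth = 3L, base_channels = 4L))
  d <- ns("mean_dice")(fit$model, imgs[31:36], msks[31:36])
  expect_gt(d, 0.8)
})
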