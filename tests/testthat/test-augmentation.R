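test_that("rotation is exact at quarter turns and periodic", {
  set.seed(1)
  m <- matrix(runif(65 * 65), 65, 65)
  expect_equal(em_rotate(m, 0), m)
  expect_lt(max(abs(em_rotate(m, 360) - m)), 1e-6)
  # 90 degrees equals the index-permutation quarter turn
  expect_lt(max(abs(em_rotate(m, 90) - t(m)[65:1, ])), 1e-9)
  expect_error(em_rotate(m, Inf), "finite")
})

test_that("zoom and shear preserve shape and compose sensibly", {
  sm <- outer(1:64, 1:64, function(i, j) 0.5 + 0.3 * sin(i / 9) * cos(j / 11))
  expect_equal(em_zoom(sm, 1), sm)
  expect_error(em_zoom(sm, 0), "positive")
  # forward zoom then inverse zoom is near-identity away from the border
  z <- em_zoom(em_zoom(sm, 2), 0.5)
  cc <- 24:40
  expect_lt(max(abs(z[cc, cc] - sm[cc, cc])), 0.01)
  # shear at the interval midpoint (factor 1 -> coefficient 0) is identity;
  # any shear preserves the output shape
  expect_equal(em_shear(sm, 1), sm)
  sh <- em_shear(sm, 1.2)
  expect_equal(dim(sh), dim(sm))
  expect_true(all(sh >= 0 & sh <= 1))
  expect_equal(dim(em_translate(sm, 3, -2)), dim(sm))
  expect_equal(em_flip_h(em_flip_h(sm)), sm)
  expect_equal(em_flip_v(sm), sm[64:1, ])
})

test_that("noise operators match their additive/multiplicative definitions", {
  g <- matrix(0.5, 128, 128)
  set.seed(2)
  expect_equal(add_gaussian_noise(g, 0, 0), g)      # v = 0: unchanged
  expect_equal(add_speckle_noise(matrix(0, 20, 20)), matrix(0, 20, 20))
  expect_error(add_gaussian_noise(g, 0, -1), "variance")
  out <- add_gaussian_noise(g)
  expect_true(all(out >= 0 & out <= 1))
  d <- out - g
  # moments recover (0, 0.003) on a mid-gray image (no clipping active)
  expect_lt(abs(mean(d)), 3 * sqrt(0.003 / length(d)))
  expect_lt(abs(stats::var(as.numeric(d)) - 0.003), 0.003 * 0.1)
})

test_that("augment_embryo yields exactly `factor` aligned, in-range triplets", {
  co <- tiny_cohort()
  e <- co$embryos[[1]]
  cfg <- augmentation_config(factor = 6L, seed = 13L)
  a <- augment_embryo(e$frames, cfg, masks = e$masks)
  expect_length(a, 6L)
  for (rep in a) {
    expect_length(rep$frames, 3L)
    for (f in rep$frames) expect_true(all(f >= 0 & f <= 1))
    for (m in rep$masks) expect_true(all(m %in% c(0, 1)))
  }
  # determinism and distinctness
  a2 <- augment_embryo(e$frames, cfg, masks = e$masks)
  expect_identical(a[[3]]$frames, a2[[3]]$frames)
  expect_false(identical(a[[1]]$frames[[1]], a[[2]]$frames[[1]]))
  # identical geometric transform across the triplet: re-applying the
  # recorded parameters reproduces each frame before noise
  p <- a[[2]]$params
  redo <- ns("apply_augment_geometry")(e$frames[[2]], p, cfg)
  noisy <- a[[2]]$frames[[2]]
  expect_lt(mean(abs(noisy - redo)), 4 * sqrt(max(0.003, 0.006)))
  # mask warped with the frame stays aligned (IoU vs bilinear+threshold)
  soft <- ns("apply_augment_geometry")(e$masks[[1]], p, cfg,
                                       filter = "bilinear", bg = 0) >= 0.5
  hard <- a[[2]]$masks[[1]] > 0
  expect_gt(sum(soft & hard) / sum(soft | hard), 0.98)
  expect_error(augment_embryo(e$frames[1:2], cfg), "3 frames")
})

test_that("degenerate config is the identity and flips/translation stay off by default", {
  co <- tiny_cohort()
  e <- co$embryos[[2]]
  cfg <- augmentation_config(rotation_deg = c(0, 0), zoom = c(1, 1),
                             shear = c(1, 1),
                             gaussian_noise = c(mean = 0, var = 0),
                             speckle_noise = c(mean = 0, var = 0),
                             factor = 1L, seed = 1L)
  a <- augment_embryo(e$frames, cfg)
  expect_equal(a[[1]]$frames[[1]], e$frames[[1]], tolerance = 1e-12)
  expect_false(a[[1]]$params$flip_h)
  expect_equal(a[[1]]$params$di, 0)
  expect_error(augmentation_config(zoom = c(1.2, 0.8)), "lower <= upper")
  expect_error(augmentation_config(factor = 0), "factor")
})

test_that("augment_manifest materializes factor x rows with PNGs and a params log", {
  d <- withr::local_tempdir()
  co <- generate_cohort(synthetic_cohort_config(
    n_embryos = 3L, n_negative = 2L, n_positive = 1L, image_size = 64L,
    seed = 21L), dir = file.path(d, "data"))
  aug <- augment_manifest(co$manifest, file.path(d, "aug"),
                          augmentation_config(factor = 4L, seed = 2L))
  expect_equal(nrow(aug), 12L)
  expect_equal(as.integer(table(aug$label)[as.character(c(0, 1))]),
               c(8L, 4L))
  expect_true(all(file.exists(aug$frame_t2)))
  expect_true(file.exists(file.path(d, "aug", "augment_params.json")))
  re <- read_manifest(file.path(d, "aug", "manifest_augmented.csv"))
  expect_equal(nrow(re), 12L)
})
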