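#' Augmentation configuration
#'
#' Parameter ranges for the training-set augmentation recipe: a random
#' rotation, zoom and shear composed into one affine warp, followed by
#' exactly one of light Gaussian or speckle noise (chosen with probability
#' 1/2). Each input sample is expanded into `factor` augmented samples.
#'
#' The shear interval is interpreted in `"offset"` mode by default: a drawn
#' factor s in `[0.8, 1.2]` becomes the off-diagonal shear coefficient
#' s - 1 in `[-0.2, 0.2]`, since a literal coefficient of 0.8-1.2 would
#' shear the embryo beyond recognition; `shear_mode = "literal"` applies the
#' drawn value directly. Horizontal/vertical flips and translation are
#' implemented but disabled by default.
#'
#' @param rotation_deg rotation interval in degrees.
#' @param zoom zoom-factor interval.
#' @param shear shear-factor interval.
#' @param gaussian_noise c(mean, variance) of additive Gaussian noise.
#' @param speckle_noise c(mean, variance) of multiplicative speckle noise.
#' @param allow_hflip,allow_vflip,allow_translation enable optional flips
#'   (probability 1/2 each) and translation.
#' @param translation_frac maximum |shift| as a fraction of the image side
#'   when translation is enabled.
#' @param shear_mode `"offset"` or `"literal"` (see Details).
#' @param factor number of augmented samples per input sample (default 30).
#' @param seed optional integer seed for reproducible draws.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(rotation_deg = c(0, 360),
                                zoom = c(0.8, 1.2),
                                shear = c(0.8, 1.2),
                                gaussian_noise = c(mean = 0, var = 0.003),
                                speckle_noise = c(mean = 0, var = 0.006),
                                allow_hflip = FALSE, allow_vflip = FALSE,
                                allow_translation = FALSE,
                                translation_frac = 0.05,
                                shear_mode = c("offset", "literal"),
                                factor = 30L, seed = NULL) {
  shear_mode <- match.arg(shear_mode)
  for (iv in list(rotation_deg, zoom, shear)) {
    if (length(iv) != 2L || iv[1] > iv[2]) {
      stop("interval must be c(lower, upper) with lower <= upper")
    }
  }
  if (gaussian_noise[2] < 0 || speckle_noise[2] < 0) {
    stop("noise variance must be >= 0")
  }
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  structure(list(rotation_deg = rotation_deg, zoom = zoom, shear = shear,
                 gaussian_noise = gaussian_noise,
                 speckle_noise = speckle_noise,
                 allow_hflip = allow_hflip, allow_vflip = allow_vflip,
                 allow_translation = allow_translation,
                 translation_frac = translation_frac,
                 shear_mode = shear_mode, factor = factor, seed = seed),
            class = "augmentation_config")
}

# Forward affine warp about the image center. R2 is the 2x2 linear part in
# row-vector convention (coordinates are (row, col), pixel i at i - 0.5),
# t a length-2 translation. Background fills with `bg` (border median when
# NULL); `filter` is "bilinear" for intensities, "none" for masks.
warp_affine <- function(img, R2, t = c(0, 0), bg = NULL,
                        filter = "bilinear") {
  stopifnot_gray(img)
  if (is.null(bg)) bg <- border_median(img)
  ctr <- dim(img) / 2
  b <- ctr - as.numeric(ctr %*% R2) + t
  out <- EBImage::affine(EBImage::Image(img), rbind(R2, b),
                         filter = filter, output.dim = dim(img),
                         bg.col = bg)
  ebi_to_matrix(out)
}

rot_mat <- function(angle_deg) {
  th <- angle_deg * pi / 180
  # +90 degrees maps (di, dj) -> (-dj, di), matching EBImage::rotate
  rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
}

shear_coef <- function(factor, mode) {
  if (mode == "offset") factor - 1 else factor
}

#' Geometric augmentation primitives
#'
#' Rotation, zoom and shear about the image center, and translation; all
#' preserve the image shape, filling uncovered pixels with the image border
#' median (or `bg`). `em_rotate(x, 90)` agrees exactly with a quarter-turn
#' array rotation.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param angle_deg rotation angle in degrees (counter-clockwise in pixel
#'   (row, col) coordinates).
#' @param factor zoom or shear factor.
#' @param mode shear interpretation, `"offset"` or `"literal"`; see
#'   [augmentation_config()].
#' @param di,dj translation in pixels along rows/columns.
#' @param bg background fill value; image border median when `NULL`.
#' @param filter `"bilinear"` or `"none"` (nearest neighbour, for masks).
#' @return transformed matrix of the same shape.
#' @name augment-geometric
NULL

#' @rdname augment-geometric
#' @export
em_rotate <- function(img, angle_deg, bg = NULL, filter = "bilinear") {
  if (!is.finite(angle_deg)) stop("angle must be finite")
  warp_affine(img, rot_mat(angle_deg), bg = bg, filter = filter)
}

#' @rdname augment-geometric
#' @export
em_zoom <- function(img, factor, bg = NULL, filter = "bilinear") {
  if (factor <= 0) stop("zoom factor must be positive")
  warp_affine(img, diag(2) * factor, bg = bg, filter = filter)
}

#' @rdname augment-geometric
#' @export
em_shear <- function(img, factor, mode = c("offset", "literal"), bg = NULL,
                     filter = "bilinear") {
  mode <- match.arg(mode)
  cf <- shear_coef(factor, mode)
  warp_affine(img, rbind(c(1, 0), c(cf, 1)), bg = bg, filter = filter)
}

#' @rdname augment-geometric
#' @export
em_translate <- function(img, di, dj, bg = NULL, filter = "bilinear") {
  warp_affine(img, diag(2), t = c(di, dj), bg = bg, filter = filter)
}

#' @rdname augment-geometric
#' @export
em_flip_h <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

#' @rdname augment-geometric
#' @export
em_flip_v <- function(img) img[rev(seq_len(nrow(img))), , drop = FALSE]

#' Additive Gaussian and multiplicative speckle noise
#'
#' `add_gaussian_noise` returns `clip(img + n)` and `add_speckle_noise`
#' returns `clip(img * (1 + n))` with `n ~ Normal(mean, variance)`, clipped
#' to `[0, 1]`.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param mean,variance noise moments (defaults: Gaussian variance 0.003,
#'   speckle variance 0.006).
#' @return matrix of the same shape in `[0, 1]`.
#' @name augment-noise
NULL

#' @rdname augment-noise
#' @export
add_gaussian_noise <- function(img, mean = 0, variance = 0.003) {
  stopifnot_gray(img)
  if (variance < 0) stop("variance must be >= 0")
  clip01(img + stats::rnorm(length(img), mean, sqrt(variance)))
}

#' @rdname augment-noise
#' @export
add_speckle_noise <- function(img, mean = 0, variance = 0.006) {
  stopifnot_gray(img)
  if (variance < 0) stop("variance must be >= 0")
  clip01(img * (1 + stats::rnorm(length(img), mean, sqrt(variance))))
}

sample_augment_params <- function(config) {
  list(
    angle = stats::runif(1, config$rotation_deg[1], config$rotation_deg[2]),
    zoom = stats::runif(1, config$zoom[1], config$zoom[2]),
    shear = stats::runif(1, config$shear[1], config$shear[2]),
    flip_h = config$allow_hflip && stats::runif(1) < 0.5,
    flip_v = config$allow_vflip && stats::runif(1) < 0.5,
    di = if (config$allow_translation) {
      stats::runif(1, -config$translation_frac, config$translation_frac)
    } else 0,
    dj = if (config$allow_translation) {
      stats::runif(1, -config$translation_frac, config$translation_frac)
    } else 0,
    noise = if (stats::runif(1) < 0.5) "gaussian" else "speckle"
  )
}

# Compose rotation, zoom, shear (and optional flips/translation) into one
# affine so each frame is resampled only once.
augment_transform_matrix <- function(params, config) {
  R2 <- rot_mat(params$angle) %*% (diag(2) * params$zoom) %*%
    rbind(c(1, 0), c(shear_coef(params$shear, config$shear_mode), 1))
  if (params$flip_v) R2 <- rbind(c(-1, 0), c(0, 1)) %*% R2
  if (params$flip_h) R2 <- rbind(c(1, 0), c(0, -1)) %*% R2
  R2
}

apply_augment_geometry <- function(img, params, config, filter = "bilinear",
                                   bg = NULL) {
  R2 <- augment_transform_matrix(params, config)
  t <- c(params$di, params$dj) * dim(img)
  warp_affine(img, R2, t = t, bg = bg, filter = filter)
}

apply_augment_noise <- function(img, params, config) {
  if (params$noise == "gaussian") {
    add_gaussian_noise(img, config$gaussian_noise[1], config$gaussian_noise[2])
  } else {
    add_speckle_noise(img, config$speckle_noise[1], config$speckle_noise[2])
  }
}

#' Augment one embryo's frame triplet
#'
#' Expands a triplet of frames into `config$factor` augmented triplets.
#' Within one augmented triplet the same geometric transform is applied to
#' all three frames (preserving cross-timepoint correspondence); noise is
#' drawn independently per frame. Masks, when supplied, are co-transformed
#' with nearest-neighbour interpolation and stay binary.
#'
#' @param frames list of 3 grayscale matrices of equal shape.
#' @param config an [augmentation_config()].
#' @param masks optional list of 3 binary masks aligned with `frames`.
#' @return list of `factor` elements, each with `frames`, optionally
#'   `masks`, and the drawn transform `params`.
#' @export
augment_embryo <- function(frames, config = augmentation_config(),
                           masks = NULL) {
  stopifnot(inherits(config, "augmentation_config"))
  if (length(frames) != 3L) stop("expected 3 frames")
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("frame shapes differ")
  }
  if (!is.null(masks) && length(masks) != 3L) stop("expected 3 masks")
  local_seed(config$seed, {
    lapply(seq_len(config$factor), function(k) {
      params <- sample_augment_params(config)
      fr <- lapply(frames, function(f) {
        apply_augment_noise(apply_augment_geometry(f, params, config),
                            params, config)
      })
      out <- list(frames = fr, params = params)
      if (!is.null(masks)) {
        out$masks <- lapply(masks, function(m) {
          apply_augment_geometry(m, params, config, filter = "none", bg = 0)
        })
      }
      out
    })
  })
}

#' Materialize an augmented training set
#'
#' Applies [augment_embryo()] to every embryo in a manifest and writes the
#' augmented frames (PNG) plus an augmented manifest CSV. Augmentation is
#' meant for the training partition only, mirroring the offline x30
#' expansion of the study design (168 embryos -> 5,040 samples).
#'
#' @param manifest manifest data frame (see [read_manifest()]) whose
#'   `frame_t1..t3` columns point to readable images.
#' @param out_dir output directory, created if needed.
#' @param config an [augmentation_config()].
#' @return the augmented manifest (invisibly written to
#'   `out_dir/manifest_augmented.csv`), with `source_embryo_id` and
#'   `replicate` columns; transform parameters are logged to
#'   `out_dir/augment_params.json`.
#' @export
augment_manifest <- function(manifest, out_dir,
                             config = augmentation_config()) {
  validate_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", nrow(manifest) * config$factor)
  logs <- vector("list", nrow(manifest))
  at <- 0L
  for (r in seq_len(nrow(manifest))) {
    frames <- lapply(c("frame_t1", "frame_t2", "frame_t3"),
                     function(cl) read_gray(manifest[[cl]][r]))
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, r)
    augs <- augment_embryo(frames, cfg_r)
    eid <- manifest$embryo_id[r]
    logs[[r]] <- lapply(augs, `[[`, "params")
    names(logs)[r] <- eid
    for (k in seq_along(augs)) {
      aid <- sprintf("%s_aug%02d", eid, k)
      paths <- vapply(1:3, function(t) {
        p <- file.path(out_dir, sprintf("%s_t%d.png", aid, t))
        write_gray(augs[[k]]$frames[[t]], p)
        p
      }, character(1))
      at <- at + 1L
      rows[[at]] <- data.frame(
        embryo_id = aid, patient_id = manifest$patient_id[r],
        label = manifest$label[r], frame_t1 = paths[1], frame_t2 = paths[2],
        frame_t3 = paths[3], source_embryo_id = eid, replicate = k,
        stringsAsFactors = FALSE)
    }
  }
  aug <- do.call(rbind, rows)
  utils::write.csv(aug, file.path(out_dir, "manifest_augmented.csv"),
                   row.names = FALSE)
  jsonlite::write_json(logs, file.path(out_dir, "augment_params.json"),
                       auto_unbox = TRUE, digits = NA)
  aug
}
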