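#' U-Net specification
#'
#' An encoder-decoder segmentation network with `depth` resolution levels.
#' The contracting path applies two 3x3 convolutions + ReLU per level and
#' 2x2 max pooling between levels, doubling the channel count at each
#' downsampling step (base 64 gives the ladder 64, 128, 256, 512, 1024 at
#' depth 5); the expansive path upsamples, applies a 2x2 "up-convolution"
#' halving the channels, concatenates the matching encoder features, and
#' applies two further 3x3 convolutions + ReLU. A final 1x1 convolution
#' emits the per-pixel embryo logit. Convolutions use "same" padding so a
#' 256x256 input yields a 256x256 probability map.
#'
#' @param depth number of resolution levels (>= 1; default 5).
#' @param base_channels channels at the top level (default 64; tests use 8).
#' @param in_channels,out_channels input/output channel counts (1 and 1).
#' @return a `unet_spec` list.
#' @export
unet_spec <- function(depth = 5L, base_channels = 64L, in_channels = 1L,
                      out_channels = 1L) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  base_channels <- as.integer(base_channels)
  if (base_channels < 1L) stop("base_channels must be >= 1")
  structure(list(depth = depth, base_channels = base_channels,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "unet_spec")
}

# 2x nearest upsample + 2x2 conv halving channels ("up-convolution"); the
# 2x2 kernel needs one extra row/column of zero padding to preserve size.
nn_upconv <- function(cin, cout) {
  conv <- nn_conv(cin, cout, 2L)
  nn_module(list(conv = conv), function(x, training) {
    conv$fwd(ag_pad_hw(ag_upsample2(x), c(0L, 0L), c(1L, 1L)), training)
  })
}

unet_double_conv <- function(cin, cout) {
  nn_seq(nn_conv(cin, cout, 3L, pad = 1L), nn_relu(),
         nn_conv(cout, cout, 3L, pad = 1L), nn_relu())
}

#' Build a U-Net segmenter
#'
#' @param spec a [unet_spec()].
#' @return an `en_unet` object with `$forward(x, training)` mapping an
#'   (H, W, N, in_channels) array — H and W divisible by `2^(depth-1)` —
#'   to per-pixel logits of the same spatial size, and
#'   `encoder_channels`, the channel ladder.
#' @export
build_unet <- function(spec = unet_spec()) {
  stopifnot(inherits(spec, "unet_spec"))
  d <- spec$depth
  ch <- spec$base_channels * 2L^(seq_len(d) - 1L)
  enc <- vector("list", d)
  cin <- spec$in_channels
  for (k in seq_len(d)) {
    enc[[k]] <- unet_double_conv(cin, ch[k])
    cin <- ch[k]
  }
  ups <- dec <- vector("list", max(0L, d - 1L))
  for (k in seq_len(d - 1L)) {
    ups[[k]] <- nn_upconv(ch[k + 1L], ch[k])
    dec[[k]] <- unet_double_conv(2L * ch[k], ch[k])
  }
  final <- nn_conv(ch[1L], spec$out_channels, 1L)
  net <- list(spec = spec, enc = enc, ups = ups, dec = dec, final = final,
              encoder_channels = ch)
  net$forward <- function(x, training = FALSE) {
    if (is.numeric(x)) x <- ag_tensor(x)
    dm <- dim(x$value)
    div <- 2L^(d - 1L)
    if (dm[1L] %% div != 0L || dm[2L] %% div != 0L) {
      stop(sprintf("input side must be divisible by %d for depth %d",
                   div, d))
    }
    skips <- vector("list", d - 1L)
    for (k in seq_len(d - 1L)) {
      x <- enc[[k]]$fwd(x, training)
      skips[[k]] <- x
      x <- ag_maxpool(x, c(2L, 2L))
    }
    x <- enc[[d]]$fwd(x, training)
    for (k in rev(seq_len(d - 1L))) {
      x <- ups[[k]]$fwd(x, training)
      x <- dec[[k]]$fwd(ag_concat(list(skips[[k]], x)), training)
    }
    final$fwd(x, training)
  }
  class(net) <- "en_unet"
  net
}

#' Segmenter training configuration
#'
#' Defaults follow the classification-step regime (learning rate 0.001
#' stepped by 0.1 every 30 epochs, batch size 32) with a summed soft-Dice +
#' binary cross-entropy loss.
#'
#' @param loss `"dice_bce"`, `"bce"` or `"dice"`.
#' @param lr,lr_step_epochs,lr_factor learning-rate schedule.
#' @param batch_size,epochs minibatch size and epoch count.
#' @param seed integer seed.
#' @return a `seg_train_config` list.
#' @export
seg_train_config <- function(loss = c("dice_bce", "bce", "dice"), lr = 1e-3,
                             lr_step_epochs = 30L, lr_factor = 0.1,
                             batch_size = 32L, epochs = 20L, seed = NULL) {
  loss <- match.arg(loss)
  if (lr <= 0 || batch_size < 1L || epochs < 1L) {
    stop("lr, batch_size and epochs must be positive")
  }
  structure(list(loss = loss, lr = lr, lr_step_epochs = lr_step_epochs,
                 lr_factor = lr_factor, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = seed),
            class = "seg_train_config")
}

stack_images <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L) {
    images <- lapply(seq_len(dim(images)[3L]), function(i) images[, , i])
  }
  d <- dim(images[[1L]])
  out <- array(0, dim = c(d[1L], d[2L], length(images), 1L))
  for (i in seq_along(images)) out[, , i, 1L] <- images[[i]]
  out
}

#' Train a U-Net segmenter
#'
#' Minibatch Adam on a soft-Dice + binary cross-entropy loss. With
#' `checkpoint` given, the trained weights are serialized there.
#'
#' @param images,masks lists of aligned grayscale frames and binary masks
#'   (or (H, W, N) arrays).
#' @param config a [seg_train_config()].
#' @param spec a [unet_spec()] (test-scale default: depth 3, base 8).
#' @param val optional `list(images, masks)` monitored per epoch with mean
#'   Dice.
#' @param checkpoint optional RDS path for the trained weights.
#' @return list with `model`, `history` (per-epoch data frame) and
#'   `config`.
#' @export
train_segmenter <- function(images, masks, config = seg_train_config(),
                            spec = unet_spec(depth = 3L, base_channels = 8L),
                            val = NULL, checkpoint = NULL) {
  if (length(images) == 0L) stop("no training pairs")
  x <- stack_images(images)
  y <- stack_images(masks)
  if (!identical(dim(x), dim(y))) stop("image/mask shape mismatch")
  if (!is_binary(y)) stop("masks must be binary")
  n <- dim(x)[3L]
  if (n == 0L) stop("no training pairs")
  local_seed(config$seed, {
    model <- build_unet(spec)
    opt <- optim_adam(trainable_params(model))
    hist <- vector("list", config$epochs)
    for (e in seq_len(config$epochs)) {
      lr_now <- lr_schedule(e, config$lr, config$lr_step_epochs,
                            config$lr_factor)
      ord <- sample(n)
      tot <- 0
      nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        ix <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- x[, , ix, , drop = FALSE]
        yb <- y[, , ix, , drop = FALSE]
        opt$zero_grad()
        z <- model$forward(xb, training = TRUE)
        loss <- switch(config$loss,
                       bce = ag_bce_logits(z, yb),
                       dice = ag_dice_loss(z, yb),
                       dice_bce = ag_add(ag_bce_logits(z, yb),
                                         ag_dice_loss(z, yb)))
        ag_backward(loss)
        opt$step(lr_now)
        tot <- tot + loss$value
        nb <- nb + 1L
      }
      row <- data.frame(epoch = e, lr = lr_now, train_loss = tot / nb,
                        val_dice = NA_real_)
      if (!is.null(val)) {
        row$val_dice <- mean_dice(model, val$images, val$masks)
      }
      hist[[e]] <- row
    }
    if (!is.null(checkpoint)) {
      saveRDS(list(spec = spec, weights = param_snapshot(model)), checkpoint)
    }
    list(model = model, history = do.call(rbind, hist), config = config)
  })
}

#' Restore a segmenter from a checkpoint
#' @param checkpoint RDS path written by [train_segmenter()].
#' @return an `en_unet` with restored weights.
#' @export
load_segmenter <- function(checkpoint) {
  ck <- readRDS(checkpoint)
  model <- build_unet(ck$spec)
  param_restore(model, ck$weights)
  model
}

#' Segment images with a trained U-Net
#'
#' @param model an `en_unet`.
#' @param images list of grayscale matrices (or (H, W, N) array).
#' @param batch_size forward batch size.
#' @return list of per-pixel embryo probability maps.
#' @export
segment_images <- function(model, images, batch_size = 16L) {
  x <- stack_images(images)
  n <- dim(x)[3L]
  out <- vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    z <- model$forward(x[, , ix, , drop = FALSE], training = FALSE)
    p <- 1 / (1 + exp(-z$value))
    for (k in seq_along(ix)) out[[ix[k]]] <- p[, , k, 1L]
  }
  out
}

mean_dice <- function(model, images, masks) {
  probs <- segment_images(model, images)
  if (is.array(masks) && length(dim(masks)) == 3L) {
    masks <- lapply(seq_len(dim(masks)[3L]), function(i) masks[, , i])
  }
  mean(vapply(seq_along(probs), function(i) {
    pred <- tryCatch(postprocess_mask(probs[[i]]), error = function(e) NULL)
    if (is.null(pred)) return(0)  # nothing above threshold scores 0
    dice(pred, masks[[i]])
  }, numeric(1)))
}

#' Post-process a probability map into a single-component mask
#'
#' Binarizes at `threshold`, keeps only the largest connected component
#' and fills interior holes — there is exactly one embryo per frame, so
#' the output always has one component.
#'
#' @param prob_map matrix of probabilities in `[0, 1]`.
#' @param threshold binarization threshold (default 0.5).
#' @return binary mask matrix.
#' @export
postprocess_mask <- function(prob_map, threshold = 0.5) {
  stopifnot_gray(prob_map)
  if (min(prob_map) < 0 || max(prob_map) > 1) {
    stop("prob_map values must lie in [0, 1]")
  }
  bin <- prob_map >= threshold
  if (!any(bin)) stop("empty mask: no pixel above threshold")
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labm <- ebi_to_matrix(lab)
  sizes <- tabulate(labm[labm > 0])
  keep <- (labm == which.max(sizes)) * 1
  filled <- EBImage::fillHull(EBImage::Image(keep))
  ebi_to_matrix(filled)
}

#' Crop to the mask bounding box and resize
#'
#' Crops `img` to the mask's bounding box expanded by `margin_frac`,
#' squares the crop by symmetric padding (background = image border
#' median), and resizes to `target_side`. With `zero_background = TRUE`,
#' pixels outside the mask are zeroed first.
#'
#' @param img grayscale matrix.
#' @param mask aligned binary mask (non-empty).
#' @param target_side output side in pixels (224 for most backbones, 299
#'   for Inception V3).
#' @param margin_frac bounding-box expansion fraction (default 0.05).
#' @param zero_background zero out non-embryo pixels.
#' @return `target_side` x `target_side` matrix.
#' @export
crop_and_resize <- function(img, mask, target_side = 224L,
                            margin_frac = 0.05, zero_background = FALSE) {
  stopifnot_gray(img)
  if (!any(mask > 0)) stop("empty mask")
  if (!identical(dim(img), dim(mask))) stop("image/mask shape mismatch")
  if (zero_background) img <- img * (mask > 0)
  ij <- which(mask > 0, arr.ind = TRUE)
  r1 <- min(ij[, 1]); r2 <- max(ij[, 1])
  c1 <- min(ij[, 2]); c2 <- max(ij[, 2])
  mh <- round(margin_frac * (r2 - r1 + 1L))
  mw <- round(margin_frac * (c2 - c1 + 1L))
  r1 <- r1 - mh; r2 <- r2 + mh; c1 <- c1 - mw; c2 <- c2 + mw
  h <- r2 - r1 + 1L
  w <- c2 - c1 + 1L
  side <- max(h, w)
  # symmetric padding to square, also covering out-of-frame margins
  pr <- (side - h) %/% 2L
  pc <- (side - w) %/% 2L
  bg <- border_median(img)
  sq <- matrix(bg, side, side)
  for (i in seq_len(side)) {
    src_r <- r1 - pr + i - 1L
    if (src_r < 1L || src_r > nrow(img)) next
    cols <- (c1 - pc):(c1 - pc + side - 1L)
    ok <- cols >= 1L & cols <= ncol(img)
    sq[i, ok] <- img[src_r, cols[ok]]
  }
  if (side == target_side) return(sq)
  ebi_to_matrix(EBImage::resize(EBImage::Image(sq), w = target_side,
                                h = target_side))
}

#' Dice coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; symmetric, 1 for identical non-empty masks,
#' 0 for disjoint ones. Two empty masks are defined to agree perfectly
#' (returns 1).
#'
#' @param pred,truth binary matrices of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (!is_binary(pred) || !is_binary(truth)) stop("masks must be binary")
  sp <- sum(pred)
  st <- sum(truth)
  if (sp + st == 0) return(1)
  2 * sum(pred * truth) / (sp + st)
}
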