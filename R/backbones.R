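#' Backbone specification
#'
#' Describes one convolutional feature extractor used by the classification
#' step. Five standard architectures are supported together with `tinycnn`,
#' a three-block network small enough to train end-to-end on a laptop CPU in
#' minutes; `tinycnn` is this package's own test-scale backbone and has no
#' published pretrained weights.
#'
#' @param name one of `"alexnet"`, `"resnet18"`, `"resnet34"`,
#'   `"inception_v3"`, `"densenet121"`, `"tinycnn"`.
#' @param pretrained logical. This package does not bundle model-zoo weight
#'   files; requesting `pretrained = TRUE` is an error unless
#'   `random_init_fallback = TRUE`, in which case the architecture is built
#'   with random weights and a warning.
#' @param feature_dim length of the per-image feature vector emitted by the
#'   backbone (default 10).
#' @param freeze_mode `"last_layer_only"` trains only the final
#'   feature-producing layer; `"none"` trains everything. Default:
#'   `"last_layer_only"` when `pretrained`, else `"none"`.
#' @param random_init_fallback allow `pretrained = TRUE` to fall back to
#'   random initialization.
#' @return a `backbone_spec` list.
#' @export
backbone_spec <- function(name = c("tinycnn", "alexnet", "resnet18",
                                   "resnet34", "inception_v3", "densenet121"),
                          pretrained = FALSE, feature_dim = 10L,
                          freeze_mode = NULL, random_init_fallback = FALSE) {
  name <- match.arg(name)
  feature_dim <- as.integer(feature_dim)
  if (feature_dim < 1L) stop("feature_dim must be >= 1")
  if (name == "tinycnn" && pretrained) {
    stop("tinycnn has no pretrained weights")
  }
  if (is.null(freeze_mode)) {
    freeze_mode <- if (pretrained) "last_layer_only" else "none"
  }
  freeze_mode <- match.arg(freeze_mode, c("none", "last_layer_only"))
  structure(list(name = name, pretrained = pretrained,
                 feature_dim = feature_dim, freeze_mode = freeze_mode,
                 random_init_fallback = random_init_fallback),
            class = "backbone_spec")
}

backbone_native_side <- function(name) {
  switch(name, tinycnn = 64L, inception_v3 = 299L, 224L)
}

backbone_norm_stats <- function(name, pretrained) {
  if (pretrained && name != "tinycnn") {
    list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
  } else {
    list(mean = rep(0.5, 3), sd = rep(0.5, 3))
  }
}

# ---- architectures ---------------------------------------------------------

arch_tinycnn <- function(fd) {
  trunk <- nn_seq(
    nn_conv_bn_relu(3L, 8L, 3L, pad = 1L), nn_maxpool(2L),
    nn_conv_bn_relu(8L, 16L, 3L, pad = 1L), nn_maxpool(2L),
    nn_conv_bn_relu(16L, 32L, 3L, pad = 1L), nn_maxpool(2L),
    nn_gap())
  head <- nn_dense(32L, fd)
  list(trunk = trunk, head = head)
}

arch_alexnet <- function(fd) {
  trunk <- nn_seq(
    nn_conv(3L, 64L, 11L, stride = 4L, pad = 2L), nn_relu(),
    nn_maxpool(3L, 2L),
    nn_conv(64L, 192L, 5L, pad = 2L), nn_relu(), nn_maxpool(3L, 2L),
    nn_conv(192L, 384L, 3L, pad = 1L), nn_relu(),
    nn_conv(384L, 256L, 3L, pad = 1L), nn_relu(),
    nn_conv(256L, 256L, 3L, pad = 1L), nn_relu(), nn_maxpool(3L, 2L),
    nn_flatten(),
    nn_dropout(0.5), nn_dense(256L * 6L * 6L, 4096L), nn_relu(),
    nn_dropout(0.5), nn_dense(4096L, 4096L), nn_relu())
  head <- nn_dense(4096L, fd)
  list(trunk = trunk, head = head)
}

resnet_basic_block <- function(cin, cout, stride = 1L) {
  conv1 <- nn_conv(cin, cout, 3L, stride = stride, pad = 1L, bias = FALSE)
  bn1 <- nn_bn(cout)
  conv2 <- nn_conv(cout, cout, 3L, pad = 1L, bias = FALSE)
  bn2 <- nn_bn(cout)
  down <- if (stride != 1L || cin != cout) {
    list(conv = nn_conv(cin, cout, 1L, stride = stride, bias = FALSE),
         bn = nn_bn(cout))
  } else NULL
  nn_module(list(conv1 = conv1, bn1 = bn1, conv2 = conv2, bn2 = bn2,
                 down = down), function(x, training) {
    idn <- if (is.null(down)) x else {
      down$bn$fwd(down$conv$fwd(x, training), training)
    }
    out <- ag_relu(bn1$fwd(conv1$fwd(x, training), training))
    out <- bn2$fwd(conv2$fwd(out, training), training)
    ag_relu(ag_add(out, idn))
  })
}

arch_resnet <- function(fd, layers) {
  chans <- c(64L, 128L, 256L, 512L)
  mods <- list(nn_conv(3L, 64L, 7L, stride = 2L, pad = 3L, bias = FALSE),
               nn_bn(64L), nn_relu(), nn_maxpool(3L, 2L, 1L))
  cin <- 64L
  for (s in seq_along(chans)) {
    stride <- if (s == 1L) 1L else 2L
    for (b in seq_len(layers[s])) {
      mods[[length(mods) + 1L]] <-
        resnet_basic_block(cin, chans[s], if (b == 1L) stride else 1L)
      cin <- chans[s]
    }
  }
  mods[[length(mods) + 1L]] <- nn_gap()
  list(trunk = nn_seq(mods), head = nn_dense(512L, fd))
}

densenet_layer <- function(cin, growth = 32L, bn_size = 4L) {
  bn1 <- nn_bn(cin)
  conv1 <- nn_conv(cin, bn_size * growth, 1L, bias = FALSE)
  bn2 <- nn_bn(bn_size * growth)
  conv2 <- nn_conv(bn_size * growth, growth, 3L, pad = 1L, bias = FALSE)
  nn_module(list(bn1 = bn1, conv1 = conv1, bn2 = bn2, conv2 = conv2),
            function(x, training) {
    out <- conv1$fwd(ag_relu(bn1$fwd(x, training)), training)
    out <- conv2$fwd(ag_relu(bn2$fwd(out, training)), training)
    ag_concat(list(x, out))
  })
}

arch_densenet121 <- function(fd) {
  growth <- 32L
  mods <- list(nn_conv(3L, 64L, 7L, stride = 2L, pad = 3L, bias = FALSE),
               nn_bn(64L), nn_relu(), nn_maxpool(3L, 2L, 1L))
  cin <- 64L
  blocks <- c(6L, 12L, 24L, 16L)
  for (bi in seq_along(blocks)) {
    for (l in seq_len(blocks[bi])) {
      mods[[length(mods) + 1L]] <- densenet_layer(cin, growth)
      cin <- cin + growth
    }
    if (bi < length(blocks)) {
      cout <- cin %/% 2L
      mods[[length(mods) + 1L]] <- nn_bn(cin)
      mods[[length(mods) + 1L]] <- nn_relu()
      mods[[length(mods) + 1L]] <- nn_conv(cin, cout, 1L, bias = FALSE)
      mods[[length(mods) + 1L]] <- nn_avgpool(2L)
      cin <- cout
    }
  }
  mods[[length(mods) + 1L]] <- nn_bn(cin)
  mods[[length(mods) + 1L]] <- nn_relu()
  mods[[length(mods) + 1L]] <- nn_gap()
  list(trunk = nn_seq(mods), head = nn_dense(cin, fd))
}

inception_a <- function(cin, pool_features) {
  b1 <- nn_conv_bn_relu(cin, 64L, 1L)
  b2 <- nn_seq(nn_conv_bn_relu(cin, 48L, 1L),
               nn_conv_bn_relu(48L, 64L, 5L, pad = 2L))
  b3 <- nn_seq(nn_conv_bn_relu(cin, 64L, 1L),
               nn_conv_bn_relu(64L, 96L, 3L, pad = 1L),
               nn_conv_bn_relu(96L, 96L, 3L, pad = 1L))
  b4 <- nn_seq(nn_avgpool(3L, 1L, 1L), nn_conv_bn_relu(cin, pool_features, 1L))
  nn_module(list(b1 = b1, b2 = b2, b3 = b3, b4 = b4), function(x, training) {
    ag_concat(list(b1$fwd(x, training), b2$fwd(x, training),
                   b3$fwd(x, training), b4$fwd(x, training)))
  })
}

inception_b <- function(cin) {
  b1 <- nn_conv_bn_relu(cin, 384L, 3L, stride = 2L)
  b2 <- nn_seq(nn_conv_bn_relu(cin, 64L, 1L),
               nn_conv_bn_relu(64L, 96L, 3L, pad = 1L),
               nn_conv_bn_relu(96L, 96L, 3L, stride = 2L))
  b3 <- nn_maxpool(3L, 2L)
  nn_module(list(b1 = b1, b2 = b2, b3 = b3), function(x, training) {
    ag_concat(list(b1$fwd(x, training), b2$fwd(x, training),
                   b3$fwd(x, training)))
  })
}

inception_c <- function(cin, c7) {
  b1 <- nn_conv_bn_relu(cin, 192L, 1L)
  b2 <- nn_seq(nn_conv_bn_relu(cin, c7, 1L),
               nn_conv_bn_relu(c7, c7, c(1L, 7L), pad = c(0L, 3L)),
               nn_conv_bn_relu(c7, 192L, c(7L, 1L), pad = c(3L, 0L)))
  b3 <- nn_seq(nn_conv_bn_relu(cin, c7, 1L),
               nn_conv_bn_relu(c7, c7, c(7L, 1L), pad = c(3L, 0L)),
               nn_conv_bn_relu(c7, c7, c(1L, 7L), pad = c(0L, 3L)),
               nn_conv_bn_relu(c7, c7, c(7L, 1L), pad = c(3L, 0L)),
               nn_conv_bn_relu(c7, 192L, c(1L, 7L), pad = c(0L, 3L)))
  b4 <- nn_seq(nn_avgpool(3L, 1L, 1L), nn_conv_bn_relu(cin, 192L, 1L))
  nn_module(list(b1 = b1, b2 = b2, b3 = b3, b4 = b4), function(x, training) {
    ag_concat(list(b1$fwd(x, training), b2$fwd(x, training),
                   b3$fwd(x, training), b4$fwd(x, training)))
  })
}

inception_d <- function(cin) {
  b1 <- nn_seq(nn_conv_bn_relu(cin, 192L, 1L),
               nn_conv_bn_relu(192L, 320L, 3L, stride = 2L))
  b2 <- nn_seq(nn_conv_bn_relu(cin, 192L, 1L),
               nn_conv_bn_relu(192L, 192L, c(1L, 7L), pad = c(0L, 3L)),
               nn_conv_bn_relu(192L, 192L, c(7L, 1L), pad = c(3L, 0L)),
               nn_conv_bn_relu(192L, 192L, 3L, stride = 2L))
  b3 <- nn_maxpool(3L, 2L)
  nn_module(list(b1 = b1, b2 = b2, b3 = b3), function(x, training) {
    ag_concat(list(b1$fwd(x, training), b2$fwd(x, training),
                   b3$fwd(x, training)))
  })
}

inception_e <- function(cin) {
  b1 <- nn_conv_bn_relu(cin, 320L, 1L)
  b2a <- nn_conv_bn_relu(cin, 384L, 1L)
  b2b1 <- nn_conv_bn_relu(384L, 384L, c(1L, 3L), pad = c(0L, 1L))
  b2b2 <- nn_conv_bn_relu(384L, 384L, c(3L, 1L), pad = c(1L, 0L))
  b3a <- nn_seq(nn_conv_bn_relu(cin, 448L, 1L),
                nn_conv_bn_relu(448L, 384L, 3L, pad = 1L))
  b3b1 <- nn_conv_bn_relu(384L, 384L, c(1L, 3L), pad = c(0L, 1L))
  b3b2 <- nn_conv_bn_relu(384L, 384L, c(3L, 1L), pad = c(1L, 0L))
  b4 <- nn_seq(nn_avgpool(3L, 1L, 1L), nn_conv_bn_relu(cin, 192L, 1L))
  nn_module(list(b1 = b1, b2a = b2a, b2b1 = b2b1, b2b2 = b2b2, b3a = b3a,
                 b3b1 = b3b1, b3b2 = b3b2, b4 = b4), function(x, training) {
    y2 <- b2a$fwd(x, training)
    y3 <- b3a$fwd(x, training)
    ag_concat(list(
      b1$fwd(x, training),
      ag_concat(list(b2b1$fwd(y2, training), b2b2$fwd(y2, training))),
      ag_concat(list(b3b1$fwd(y3, training), b3b2$fwd(y3, training))),
      b4$fwd(x, training)))
  })
}

arch_inception_v3 <- function(fd) {
  mods <- list(
    nn_conv_bn_relu(3L, 32L, 3L, stride = 2L),
    nn_conv_bn_relu(32L, 32L, 3L),
    nn_conv_bn_relu(32L, 64L, 3L, pad = 1L),
    nn_maxpool(3L, 2L),
    nn_conv_bn_relu(64L, 80L, 1L),
    nn_conv_bn_relu(80L, 192L, 3L),
    nn_maxpool(3L, 2L),
    inception_a(192L, 32L),
    inception_a(256L, 64L),
    inception_a(288L, 64L),
    inception_b(288L),
    inception_c(768L, 128L),
    inception_c(768L, 160L),
    inception_c(768L, 160L),
    inception_c(768L, 192L),
    inception_d(768L),
    inception_e(1280L),
    inception_e(2048L),
    nn_gap())
  list(trunk = nn_seq(mods), head = nn_dense(2048L, fd))
}

# ---- public constructor ----------------------------------------------------

#' Build a backbone feature extractor
#'
#' Constructs the requested architecture ending in a fully connected layer
#' that emits a `feature_dim`-long vector per image (the per-branch feature
#' size of the fusion classifier). Grayscale inputs are expected replicated
#' to 3 channels and resized to the backbone's native side (224 px, 299 px
#' for Inception V3, 64 px for `tinycnn`); see [prep_backbone_input()].
#'
#' @param spec a [backbone_spec()].
#' @return an object of class `en_backbone` with elements `spec`, `trunk`,
#'   `head`, `native_side` and `$forward(x, training)` mapping an
#'   (H, W, N, 3) array to an (N, feature_dim) autograd tensor.
#' @export
build_backbone <- function(spec) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (spec$pretrained) {
    if (!spec$random_init_fallback) {
      stop("pretrained weights for '", spec$name, "' are not available ",
           "offline; pass random_init_fallback = TRUE in backbone_spec() ",
           "to build the architecture with random initialization")
    }
    warning("building '", spec$name, "' with random initialization ",
            "(no pretrained weights available)")
  }
  arch <- switch(spec$name,
                 tinycnn = arch_tinycnn(spec$feature_dim),
                 alexnet = arch_alexnet(spec$feature_dim),
                 resnet18 = arch_resnet(spec$feature_dim, c(2L, 2L, 2L, 2L)),
                 resnet34 = arch_resnet(spec$feature_dim, c(3L, 4L, 6L, 3L)),
                 densenet121 = arch_densenet121(spec$feature_dim),
                 inception_v3 = arch_inception_v3(spec$feature_dim))
  if (spec$freeze_mode == "last_layer_only") {
    freeze_params(collect_params(arch$trunk))
  }
  bb <- list(spec = spec, trunk = arch$trunk, head = arch$head,
             native_side = backbone_native_side(spec$name),
             norm = backbone_norm_stats(spec$name, spec$pretrained))
  bb$forward <- function(x, training = FALSE) {
    if (is.numeric(x)) x <- ag_tensor(x)
    arch$head$fwd(arch$trunk$fwd(x, training), training)
  }
  class(bb) <- "en_backbone"
  bb
}

#' Preprocess grayscale frames for a backbone
#'
#' Resizes each frame to the backbone's native side (bilinear), replicates
#' the single channel to 3, and normalizes with the backbone's canonical
#' channel statistics (ImageNet statistics when pretrained, 0.5/0.5
#' otherwise).
#'
#' @param frames a list of 2-D matrices in `[0, 1]`, or an (H, W, N) array.
#' @param backbone an `en_backbone` (or a `backbone_spec`).
#' @return an (side, side, N, 3) numeric array.
#' @export
prep_backbone_input <- function(frames, backbone) {
  spec <- if (inherits(backbone, "en_backbone")) backbone$spec else backbone
  side <- backbone_native_side(spec$name)
  norm <- backbone_norm_stats(spec$name, spec$pretrained)
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3L]), function(i) frames[, , i])
  }
  n <- length(frames)
  out <- array(0, dim = c(side, side, n, 3L))
  for (i in seq_len(n)) {
    f <- frames[[i]]
    if (!all(dim(f) == c(side, side))) {
      f <- ebi_to_matrix(EBImage::resize(EBImage::Image(f), w = side,
                                         h = side))
    }
    for (ch in 1:3) out[, , i, ch] <- (f - norm$mean[ch]) / norm$sd[ch]
  }
  out
}

ebi_to_matrix <- function(img) {
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2L) m <- m[, , 1L]
  m
}
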