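# The autograd engine is validated against finite differences: every
# backward rule used by the U-Net and the classifiers must match the
# numerical gradient of its own forward pass.

test_that("convolution gradients match finite differences", {
  set.seed(1)
  H <- 5L; W <- 6L; N <- 2L; Cin <- 2L; Cout <- 3L
  x <- array(rnorm(H * W * N * Cin), c(H, W, N, Cin))
  w <- array(rnorm(3 * 3 * Cin * Cout) * 0.3, c(3, 3, Cin, Cout))
  b <- rnorm(Cout)
  wv <- NULL
  fwd <- function(xv, wvv, bv) {
    out <- ns("ag_conv2d")(ns("ag_tensor")(xv, TRUE), ns("ag_param")(wvv),
                           ns("ag_param")(bv), c(2L, 1L), c(1L, 1L))
    if (is.null(wv)) wv <<- rnorm(length(out$value))
    sum(out$value * wv)
  }
  xt <- ns("ag_tensor")(x, TRUE)
  wt <- ns("ag_param")(w)
  bt <- ns("ag_param")(b)
  out <- ns("ag_conv2d")(xt, wt, bt, c(2L, 1L), c(1L, 1L))
  wv <- rnorm(length(out$value))
  top <- ns("ag_node")(sum(out$value * wv), list(out), function(g) {
    list(array(g * wv, dim(out$value)))
  })
  ns("ag_backward")(top)
  expect_lt(max(abs(xt$grad - num_grad(function(v) fwd(v, w, b), x))), 1e-4)
  expect_lt(max(abs(wt$grad - num_grad(function(v) fwd(x, v, b), w))), 1e-4)
  expect_lt(max(abs(bt$grad - num_grad(function(v) fwd(x, w, v), b))), 1e-4)
})

test_that("pooling, upsampling, padding and batchnorm gradients are exact", {
  set.seed(2)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  for (kind in c("max", "avg")) {
    pool <- if (kind == "max") ns("ag_maxpool") else ns("ag_avgpool")
    xt <- ns("ag_tensor")(x, TRUE)
    p <- pool(xt, c(3L, 3L), c(2L, 2L), c(1L, 1L))
    wv <- rnorm(length(p$value))
    top <- ns("ag_node")(sum(p$value * wv), list(p), function(g) {
      list(array(g * wv, dim(p$value)))
    })
    ns("ag_backward")(top)
    f <- function(v) {
      sum(pool(ns("ag_tensor")(v), c(3L, 3L), c(2L, 2L), c(1L, 1L))$value *
            wv)
    }
    expect_lt(max(abs(xt$grad - num_grad(f, x))), 1e-4)
  }
  # upsample -> pad -> gap chain
  x2 <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  xt <- ns("ag_tensor")(x2, TRUE)
  g <- ns("ag_gap")(ns("ag_pad_hw")(ns("ag_upsample2")(xt), c(0L, 0L),
                                    c(1L, 1L)))
  top <- ns("ag_node")(sum(g$value^2), list(g),
                       function(gr) list(2 * gr * g$value))
  ns("ag_backward")(top)
  f <- function(v) {
    sum(ns("ag_gap")(ns("ag_pad_hw")(ns("ag_upsample2")(
      ns("ag_tensor")(v)), c(0L, 0L), c(1L, 1L)))$value^2)
  }
  expect_lt(max(abs(xt$grad - num_grad(f, x2))), 1e-4)
  # batchnorm, training mode
  x3 <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  gm <- c(1.2, 0.8); bb <- c(0.1, -0.2)
  xt <- ns("ag_tensor")(x3, TRUE)
  o <- ns("ag_batchnorm")(xt, ns("ag_param")(gm), ns("ag_param")(bb),
                          ns("bn_state")(2L), TRUE)
  wv <- rnorm(length(o$value))
  top <- ns("ag_node")(sum(o$value * wv), list(o), function(g) {
    list(array(g * wv, dim(o$value)))
  })
  ns("ag_backward")(top)
  f <- function(v) {
    sum(ns("ag_batchnorm")(ns("ag_tensor")(v), ns("ag_param")(gm),
                           ns("ag_param")(bb), ns("bn_state")(2L),
                           TRUE)$value * wv)
  }
  expect_lt(max(abs(xt$grad - num_grad(f, x3))), 1e-4)
})

test_that("loss gradients match finite differences", {
  set.seed(3)
  z <- array(rnorm(6 * 6 * 2 * 1), c(6, 6, 2, 1))
  y <- array(rbinom(72, 1, 0.4), c(6, 6, 2, 1))
  zt <- ns("ag_tensor")(z, TRUE)
  ns("ag_backward")(ns("ag_dice_loss")(zt, y))
  f <- function(v) ns("ag_dice_loss")(ns("ag_tensor")(v), y)$value
  expect_lt(max(abs(zt$grad - num_grad(f, z))), 1e-4)

  zl <- rnorm(8)
  yl <- rbinom(8, 1, 0.5)
  zt <- ns("ag_tensor")(zl, TRUE)
  ns("ag_backward")(ns("ag_bce_logits")(zt, yl, weight_pos = 2))
  f <- function(v) ns("ag_bce_logits")(ns("ag_tensor")(v), yl,
                                       weight_pos = 2)$value
  expect_lt(max(abs(zt$grad - num_grad(f, zl))), 1e-6)
})

test_that("Adam training drives a separable problem to near-zero loss", {
  set.seed(4)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- as.numeric(X[, 1] - 0.5 * X[, 2] > 0)
  net <- ns("nn_seq")(ns("nn_dense")(8L, 16L), ns("nn_relu")(),
                      ns("nn_dense")(16L, 1L))
  opt <- ns("optim_adam")(ns("trainable_params")(net), lr = 0.05)
  loss <- NULL
  for (it in 1:150) {
    opt$zero_grad()
    loss <- ns("ag_bce_logits")(net$fwd(ns("ag_tensor")(X), TRUE), y)
    ns("ag_backward")(loss)
    opt$step()
  }
  expect_lt(loss$value, 0.05)
})
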