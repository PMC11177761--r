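#' @useDynLib embryonet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Minimal reverse-mode autograd on dense R arrays, sized for the networks in
# this package. Feature maps are (H, W, N, C) arrays, dense activations are
# (N, F) matrices. Each op returns a node that records its parents and a
# closure computing parent gradients; ag_backward() runs the tape in reverse
# topological order. Gradients are only propagated into subgraphs that
# contain trainable parameters, so a frozen backbone costs no backward time.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L

ag_next_id <- function() {
  .ag$id <- .ag$id + 1L
  sprintf("t%d", .ag$id)
}

#' Create an autograd tensor
#'
#' Wraps a numeric array in a node of the autograd tape. Users of the
#' high-level model constructors never need to call this directly.
#'
#' @param value numeric vector, matrix or array.
#' @param requires logical; propagate gradients into this node?
#' @return an object of class `ag_tensor`.
#' @keywords internal
ag_tensor <- function(value, requires = FALSE) {
  e <- new.env(parent = emptyenv())
  e$id <- ag_next_id()
  e$value <- value
  e$grad <- NULL
  e$requires <- requires
  e$parents <- list()
  e$backward <- NULL
  class(e) <- "ag_tensor"
  e
}

ag_param <- function(value) {
  t <- ag_tensor(value, requires = TRUE)
  t$is_param <- TRUE
  t
}

is_ag <- function(x) inherits(x, "ag_tensor")

ag_node <- function(value, parents, backward) {
  t <- ag_tensor(value, requires = any(vapply(parents, function(p) p$requires,
                                              logical(1))))
  t$parents <- parents
  t$backward <- backward
  t
}

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_tensor", if (is.null(d)) length(x$value) else paste(d, collapse = "x"),
      if (isTRUE(x$requires)) "grad" else "", ">\n")
  invisible(x)
}

# ---- backward pass ---------------------------------------------------------

ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  topo <- vector("list", 64L)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(t = loss, i = 0L))
  # iterative DFS (graphs can be deep: densenet)
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    t <- fr$t
    if (is.null(seen[[t$id]])) seen[[t$id]] <- 0L
    kids <- t$parents
    advanced <- FALSE
    i <- fr$i
    while (i < length(kids)) {
      i <- i + 1L
      p <- kids[[i]]
      if (p$requires && is.null(seen[[p$id]])) {
        stack[[length(stack)]]$i <- i
        stack[[length(stack) + 1L]] <- list(t = p, i = 0L)
        advanced <- TRUE
        break
      }
    }
    if (!advanced) {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- t
      seen[[t$id]] <- 1L
      stack[[length(stack)]] <- NULL
    } else {
      # fix up stored index (lists are copied on modification inside [[<-]])
    }
  }
  topo <- topo[seq_len(ntopo)]
  loss$grad <- 1
  for (k in rev(seq_len(ntopo))) {
    t <- topo[[k]]
    if (is.null(t$backward) || is.null(t$grad)) next
    gs <- t$backward(t$grad)
    for (i in seq_along(t$parents)) {
      p <- t$parents[[i]]
      g <- gs[[i]]
      if (!p$requires || is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

# ---- elementwise and linear ops -------------------------------------------

ag_relu <- function(x) {
  v <- x$value
  ag_node(relu_fwd_cpp(v), list(x), function(g) {
    list(relu_bwd_cpp(g, v))
  })
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_scale <- function(x, k) {
  ag_node(x$value * k, list(x), function(g) list(g * k))
}

# x: (N, F); w: (F, O); b: length O or NULL
ag_dense <- function(x, w, b = NULL) {
  xv <- x$value
  out <- xv %*% w$value
  if (!is.null(b)) out <- add_bias_cols_cpp(out, b$value)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(out, parents, function(g) {
    gx <- if (x$requires) g %*% t(w$value) else NULL
    gw <- if (w$requires) crossprod(xv, g) else NULL
    if (is.null(b)) return(list(gx, gw))
    gb <- if (b$requires) colSums(g) else NULL
    list(gx, gw, gb)
  })
}

ag_dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  keep <- (array(stats::runif(length(x$value)), dim = dim(x$value)) >= rate) /
    (1 - rate)
  ag_node(x$value * keep, list(x), function(g) list(g * keep))
}

# ---- convolution -----------------------------------------------------------

# x: (H, W, N, Cin); w: (kh, kw, Cin, Cout); b: length Cout or NULL.
# stride/pad are length-2 (h, w). Zero padding.
ag_conv2d <- function(x, w, b = NULL, stride = c(1L, 1L), pad = c(0L, 0L)) {
  d <- dim(x$value)
  wd <- dim(w$value)
  stopifnot(length(d) == 4L, length(wd) == 4L, d[4L] == wd[3L])
  H <- d[1L]; W <- d[2L]; N <- d[3L]; Cin <- d[4L]
  kh <- wd[1L]; kw <- wd[2L]; Cout <- wd[4L]
  sh <- as.integer(stride[1L]); sw <- as.integer(stride[2L])
  ph <- as.integer(pad[1L]); pw <- as.integer(pad[2L])
  Ho <- (H + 2L * ph - kh) %/% sh + 1L
  Wo <- (W + 2L * pw - kw) %/% sw + 1L
  M <- im2col_cpp(x$value, H, W, N, Cin, kh, kw, sh, sw, ph, pw)
  Wmat <- matrix(w$value, nrow = kh * kw * Cin, ncol = Cout)
  Y <- M %*% Wmat
  if (!is.null(b)) Y <- add_bias_cols_cpp(Y, b$value)
  dim(Y) <- c(Ho, Wo, N, Cout)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(Y, parents, function(g) {
    gmat <- matrix(g, nrow = Ho * Wo * N, ncol = Cout)
    gx <- if (x$requires) {
      dM <- gmat %*% t(Wmat)
      col2im_cpp(dM, H, W, N, Cin, kh, kw, sh, sw, ph, pw)
    } else NULL
    gw <- if (w$requires) {
      gw0 <- crossprod(M, gmat)
      dim(gw0) <- wd
      gw0
    } else NULL
    if (is.null(b)) return(list(gx, gw))
    gb <- if (b$requires) colSums(gmat) else NULL
    list(gx, gw, gb)
  })
}

ag_maxpool <- function(x, k = c(2L, 2L), stride = k, pad = c(0L, 0L)) {
  d <- dim(x$value)
  r <- pool_fwd_cpp(x$value, d[1L], d[2L], d[3L], d[4L],
                    k[1L], k[2L], stride[1L], stride[2L], pad[1L], pad[2L],
                    TRUE)
  ag_node(r$out, list(x), function(g) {
    list(maxpool_bwd_cpp(g, r$argmax, d[1L], d[2L], d[3L], d[4L]))
  })
}

ag_avgpool <- function(x, k = c(2L, 2L), stride = k, pad = c(0L, 0L)) {
  d <- dim(x$value)
  r <- pool_fwd_cpp(x$value, d[1L], d[2L], d[3L], d[4L],
                    k[1L], k[2L], stride[1L], stride[2L], pad[1L], pad[2L],
                    FALSE)
  ag_node(r$out, list(x), function(g) {
    list(avgpool_bwd_cpp(g, d[1L], d[2L], d[3L], d[4L],
                         k[1L], k[2L], stride[1L], stride[2L],
                         pad[1L], pad[2L]))
  })
}

# nearest-neighbour 2x upsampling
ag_upsample2 <- function(x) {
  d <- dim(x$value)
  ih <- rep(seq_len(d[1L]), each = 2L)
  iw <- rep(seq_len(d[2L]), each = 2L)
  out <- x$value[ih, iw, , , drop = FALSE]
  ag_node(out, list(x), function(g) {
    o1 <- seq(1L, 2L * d[1L], by = 2L)
    o2 <- seq(1L, 2L * d[2L], by = 2L)
    gx <- g[o1, o2, , , drop = FALSE] + g[o1 + 1L, o2, , , drop = FALSE] +
      g[o1, o2 + 1L, , , drop = FALSE] + g[o1 + 1L, o2 + 1L, , , drop = FALSE]
    list(gx)
  })
}

# zero padding of the spatial dims; before/after are (h, w) pixel counts
ag_pad_hw <- function(x, before = c(0L, 0L), after = c(0L, 0L)) {
  d <- dim(x$value)
  out <- array(0, dim = c(d[1L] + before[1L] + after[1L],
                          d[2L] + before[2L] + after[2L], d[3L], d[4L]))
  ih <- before[1L] + seq_len(d[1L])
  iw <- before[2L] + seq_len(d[2L])
  out[ih, iw, , ] <- x$value
  ag_node(out, list(x), function(g) {
    list(g[ih, iw, , , drop = FALSE])
  })
}

# channel concatenation of (H, W, N, C_i) maps
ag_concat <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  cs <- vapply(vals, function(v) dim(v)[4L], integer(1))
  d1 <- dim(vals[[1L]])
  out <- array(0, dim = c(d1[1L], d1[2L], d1[3L], sum(cs)))
  at <- 0L
  for (i in seq_along(vals)) {
    out[, , , at + seq_len(cs[i])] <- vals[[i]]
    at <- at + cs[i]
  }
  ag_node(out, xs, function(g) {
    at <- 0L
    gs <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      if (xs[[i]]$requires) gs[[i]] <- g[, , , at + seq_len(cs[i]), drop = FALSE]
      at <- at + cs[i]
    }
    gs
  })
}

# column-wise concatenation of (N, F_i) matrices
ag_cbind <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  fs <- vapply(vals, ncol, integer(1))
  out <- do.call(cbind, vals)
  ag_node(out, xs, function(g) {
    at <- 0L
    gs <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      if (xs[[i]]$requires) gs[[i]] <- g[, at + seq_len(fs[i]), drop = FALSE]
      at <- at + fs[i]
    }
    gs
  })
}

# global average pooling (H, W, N, C) -> (N, C)
ag_gap <- function(x) {
  d <- dim(x$value)
  v <- x$value
  dim(v) <- c(d[1L] * d[2L], d[3L] * d[4L])
  out <- matrix(colMeans(v), nrow = d[3L], ncol = d[4L])
  ag_node(out, list(x), function(g) {
    gx <- array(rep(as.numeric(g) / (d[1L] * d[2L]),
                    each = d[1L] * d[2L]), dim = d)
    list(gx)
  })
}

# (H, W, N, C) -> (N, H*W*C), per-sample feature order (h, w, c)
ag_flatten4 <- function(x) {
  d <- dim(x$value)
  v <- aperm(x$value, c(1L, 2L, 4L, 3L))
  dim(v) <- c(d[1L] * d[2L] * d[4L], d[3L])
  out <- t(v)
  ag_node(out, list(x), function(g) {
    gv <- t(g)
    dim(gv) <- c(d[1L], d[2L], d[4L], d[3L])
    list(aperm(gv, c(1L, 2L, 4L, 3L)))
  })
}

# ---- batch normalization ---------------------------------------------------

# Per-channel batchnorm over (H, W, N) with running statistics held in an
# environment created by bn_state(). gamma/beta are length-C params.
bn_state <- function(C) {
  e <- new.env(parent = emptyenv())
  e$mean <- numeric(C)
  e$var <- rep(1, C)
  class(e) <- "bn_state"
  e
}

ag_batchnorm <- function(x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  m <- d[1L] * d[2L] * d[3L]
  v <- x$value
  dim(v) <- c(m, d[4L])
  if (training) {
    mu <- colMeans(v)
    cen <- add_bias_cols_cpp(v, -mu)
    va <- colMeans(cen * cen)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va * m / max(1, m - 1)
  } else {
    mu <- state$mean
    va <- state$var
    cen <- add_bias_cols_cpp(v, -mu)
  }
  sd_inv <- 1 / sqrt(va + eps)
  xhat <- scale_cols_cpp(cen, sd_inv)
  out <- add_bias_cols_cpp(scale_cols_cpp(xhat, gamma$value), beta$value)
  dim(out) <- d
  ag_node(out, list(x, gamma, beta), function(g) {
    gm <- g
    dim(gm) <- c(m, d[4L])
    ggamma <- if (gamma$requires) colSums(gm * xhat) else NULL
    gbeta <- if (beta$requires) colSums(gm) else NULL
    gx <- if (x$requires) {
      if (training) {
        mean_g <- colMeans(gm)
        mean_gx <- colMeans(gm * xhat)
        t1 <- add_bias_cols_cpp(gm, -mean_g) - scale_cols_cpp(xhat, mean_gx)
        gxm <- scale_cols_cpp(t1, gamma$value * sd_inv)
      } else {
        gxm <- scale_cols_cpp(gm, gamma$value * sd_inv)
      }
      dim(gxm) <- d
      gxm
    } else NULL
    list(gx, ggamma, gbeta)
  })
}

# ---- losses ----------------------------------------------------------------

# binary cross-entropy on logits; z: (N, 1) or vector, y in {0, 1}
ag_bce_logits <- function(z, y, weight_pos = 1) {
  zv <- as.numeric(z$value)
  y <- as.numeric(y)
  w <- ifelse(y == 1, weight_pos, 1)
  n <- length(zv)
  per <- pmax(zv, 0) - zv * y + log1p(exp(-abs(zv)))
  loss <- sum(w * per) / sum(w)
  ag_node(loss, list(z), function(g) {
    p <- 1 / (1 + exp(-zv))
    gz <- g * w * (p - y) / sum(w)
    dim(gz) <- dim(z$value)
    list(gz)
  })
}

# soft Dice loss on logits; z and y are (H, W, N, 1) (y binary)
ag_dice_loss <- function(z, y, eps = 1) {
  p <- 1 / (1 + exp(-z$value))
  y <- as.numeric(y)
  sp <- sum(p)
  sy <- sum(y)
  spy <- sum(p * y)
  denom <- sp + sy + eps
  loss <- 1 - (2 * spy + eps) / denom
  ag_node(loss, list(z), function(g) {
    # d/dp of -(2*spy + eps)/denom
    dp <- -(2 * y * denom - (2 * spy + eps)) / denom^2
    gz <- g * dp * p * (1 - p)
    dim(gz) <- dim(z$value)
    list(gz)
  })
}

# mean squared error (used by tests / gradient checks)
ag_mse <- function(z, y) {
  d <- z$value - y
  n <- length(d)
  ag_node(sum(d * d) / n, list(z), function(g) list(g * 2 * d / n))
}

# ---- parameter handling and optimizer -------------------------------------

collect_params <- function(module) {
  out <- list()
  walk <- function(x) {
    if (is_ag(x)) {
      if (isTRUE(x$is_param)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(module)
  out
}

collect_bn_states <- function(module) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "bn_state")) {
      out[[length(out) + 1L]] <<- x
    } else if (is.list(x) && !is_ag(x)) {
      for (el in x) walk(el)
    }
  }
  walk(module)
  out
}

trainable_params <- function(module) {
  Filter(function(p) isTRUE(p$requires), collect_params(module))
}

n_params <- function(module, trainable_only = FALSE) {
  ps <- if (trainable_only) trainable_params(module) else collect_params(module)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

freeze_params <- function(params) {
  for (p in params) p$requires <- FALSE
  invisible(params)
}

# snapshot/restore of all learned state: parameter values plus batchnorm
# running statistics
param_snapshot <- function(module) {
  list(params = lapply(collect_params(module), function(p) p$value),
       bn = lapply(collect_bn_states(module),
                   function(s) list(mean = s$mean, var = s$var)))
}

param_restore <- function(module, snapshot) {
  ps <- collect_params(module)
  stopifnot(length(ps) == length(snapshot$params))
  for (i in seq_along(ps)) ps[[i]]$value <- snapshot$params[[i]]
  bs <- collect_bn_states(module)
  stopifnot(length(bs) == length(snapshot$bn))
  for (i in seq_along(bs)) {
    bs[[i]]$mean <- snapshot$bn[[i]]$mean
    bs[[i]]$var <- snapshot$bn[[i]]$var
  }
  invisible(module)
}

#' Adam optimizer over a parameter list
#'
#' @param params list of trainable `ag_tensor` parameters.
#' @param lr learning rate.
#' @param betas first/second moment decay rates.
#' @param eps numerical stabilizer.
#' @return optimizer object with a `$step(lr)` method.
#' @keywords internal
optim_adam <- function(params, lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8) {
  st <- lapply(params, function(p) list(m = 0 * p$value, v = 0 * p$value))
  t <- 0L
  list(
    params = params,
    step = function(lr_now = lr) {
      t <<- t + 1L
      b1 <- betas[1L]; b2 <- betas[2L]
      for (i in seq_along(params)) {
        p <- params[[i]]
        if (is.null(p$grad)) next
        g <- p$grad
        st[[i]]$m <<- b1 * st[[i]]$m + (1 - b1) * g
        st[[i]]$v <<- b2 * st[[i]]$v + (1 - b2) * g * g
        mhat <- st[[i]]$m / (1 - b1^t)
        vhat <- st[[i]]$v / (1 - b2^t)
        p$value <- p$value - lr_now * mhat / (sqrt(vhat) + eps)
      }
    },
    zero_grad = function() {
      for (p in params) p$grad <- NULL
    }
  )
}

# Kaiming-uniform init for conv (kh, kw, cin, cout) and dense (fin, fout)
init_conv_w <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  bound <- sqrt(6 / fan_in)
  array(stats::runif(kh * kw * cin * cout, -bound, bound),
        dim = c(kh, kw, cin, cout))
}

init_dense_w <- function(fin, fout) {
  bound <- sqrt(6 / fin)
  matrix(stats::runif(fin * fout, -bound, bound), nrow = fin, ncol = fout)
}
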