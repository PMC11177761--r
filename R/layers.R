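# Module constructors. A module is a list carrying its ag_tensor parameters
# (so collect_params() finds them) plus a $fwd(x, training) closure. Modules
# compose with nn_seq(). All state lives in environments, so copies of the
# containing lists still reference the same parameters.

nn_module <- function(fields, fwd) {
  m <- fields
  m$fwd <- fwd
  class(m) <- "en_module"
  m
}

mod_fwd <- function(m, x, training = FALSE) m$fwd(x, training)

as_hw2 <- function(k) {
  k <- as.integer(k)
  if (length(k) == 1L) c(k, k) else k[1:2]
}

nn_conv <- function(cin, cout, k, stride = 1L, pad = 0L, bias = TRUE) {
  k <- as_hw2(k); stride <- as_hw2(stride); pad <- as_hw2(pad)
  w <- ag_param(init_conv_w(k[1L], k[2L], cin, cout))
  b <- if (bias) ag_param(numeric(cout)) else NULL
  nn_module(list(w = w, b = b),
            function(x, training) ag_conv2d(x, w, b, stride, pad))
}

nn_bn <- function(C) {
  gamma <- ag_param(rep(1, C))
  beta <- ag_param(numeric(C))
  st <- bn_state(C)
  nn_module(list(gamma = gamma, beta = beta, state = st),
            function(x, training) ag_batchnorm(x, gamma, beta, st, training))
}

nn_relu <- function() nn_module(list(), function(x, training) ag_relu(x))

nn_maxpool <- function(k, stride = k, pad = 0L) {
  k <- as_hw2(k); stride <- as_hw2(stride); pad <- as_hw2(pad)
  nn_module(list(), function(x, training) ag_maxpool(x, k, stride, pad))
}

nn_avgpool <- function(k, stride = k, pad = 0L) {
  k <- as_hw2(k); stride <- as_hw2(stride); pad <- as_hw2(pad)
  nn_module(list(), function(x, training) ag_avgpool(x, k, stride, pad))
}

nn_gap <- function() nn_module(list(), function(x, training) ag_gap(x))

nn_flatten <- function() nn_module(list(), function(x, training) ag_flatten4(x))

nn_dropout <- function(rate = 0.5) {
  nn_module(list(), function(x, training) ag_dropout(x, rate, training))
}

nn_dense <- function(fin, fout, bias = TRUE) {
  w <- ag_param(init_dense_w(fin, fout))
  b <- if (bias) ag_param(numeric(fout)) else NULL
  nn_module(list(w = w, b = b), function(x, training) ag_dense(x, w, b))
}

nn_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1L]]) &&
      !inherits(mods[[1L]], "en_module")) {
    mods <- mods[[1L]]
  }
  nn_module(list(mods = mods), function(x, training) {
    for (m in mods) x <- m$fwd(x, training)
    x
  })
}

# conv + batchnorm + relu, the basic unit of the larger backbones
nn_conv_bn_relu <- function(cin, cout, k, stride = 1L, pad = 0L) {
  conv <- nn_conv(cin, cout, k, stride, pad, bias = FALSE)
  bn <- nn_bn(cout)
  nn_module(list(conv = conv, bn = bn), function(x, training) {
    ag_relu(bn$fwd(conv$fwd(x, training), training))
  })
}
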