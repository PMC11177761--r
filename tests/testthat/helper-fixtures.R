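# Shared fixtures, built in code. The small cohort is generated once per
# test session.

ns <- function(name) get(name, envir = asNamespace("embryonet"))

tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(synthetic_cohort_config(
        n_embryos = 12L, n_negative = 8L, n_positive = 4L,
        image_size = 64L, effect_size = 1, seed = 42L))
    }
    cache
  }
})

# random manifest with grouped patients, for split property tests
random_manifest <- function(n = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- sample(4:30, 1)
  pid <- integer(0)
  p <- 0L
  while (length(pid) < n) {
    p <- p + 1L
    pid <- c(pid, rep(p, sample(1:3, 1)))
  }
  pid <- pid[seq_len(n)]
  data.frame(
    embryo_id = sprintf("E%03d", seq_len(n)),
    patient_id = sprintf("P%03d", pid),
    label = rbinom(n, 1, 0.3),
    frame_t1 = NA_character_, frame_t2 = NA_character_,
    frame_t3 = NA_character_, stringsAsFactors = FALSE)
}

# numerical gradient for engine checks
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

count_components <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  length(setdiff(unique(as.integer(lab)), 0L))
}
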