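# Shared helpers.

clip01 <- function(x) {
  d <- dim(x)
  out <- pmin(1, pmax(0, x))  # pmin/pmax with a scalar first drops dim
  dim(out) <- d
  out
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stage seed from a global one, keeping within 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}

stopifnot_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("expected a numeric matrix (grayscale image)")
  }
  invisible(img)
}

is_binary <- function(x) all(x %in% c(0, 1))

# Median intensity of the one-pixel image border, used as background fill
# for geometric transforms.
border_median <- function(img) {
  stopifnot_gray(img)
  h <- nrow(img); w <- ncol(img)
  stats::median(c(img[1, ], img[h, ], img[, 1], img[, w]))
}

matrix_to_ebi <- function(m) EBImage::Image(m)

read_gray <- function(path) {
  m <- ebi_to_matrix(EBImage::readImage(path))
  clip01(m)
}

write_gray <- function(img, path) {
  EBImage::writeImage(EBImage::Image(clip01(img)), path)
  invisible(path)
}
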