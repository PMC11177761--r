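#' Synthetic cohort configuration
#'
#' Describes a synthetic embryo-image cohort. Defaults mirror the study
#' cohort composition: 252 embryos, 180 with a negative and 72 with a
#' positive pregnancy outcome, one embryo per patient, 256 px frames at
#' three cleavage-stage timepoints (1 cell at ~19 hpi, 2-4 cells at
#' ~44 hpi, 6-8 cells at ~68 hpi).
#'
#' The positive/negative classes differ only through `effect_size`: positive
#' embryos have more size-symmetric blastomeres (lower size CV) and fewer
#' fragments, with both gaps scaled by `effect_size`. `effect_size = 0`
#' makes the label-conditional image distributions identical.
#'
#' @param n_embryos,n_negative,n_positive cohort class counts
#'   (`n_negative + n_positive` must equal `n_embryos`).
#' @param embryos_per_patient either a single integer (consecutive embryos
#'   grouped into patients of that size) or a named numeric vector of
#'   probabilities over group sizes, e.g. `c("1" = 0.7, "2" = 0.3)`, to
#'   exercise grouped splitting.
#' @param image_size frame side in pixels (>= 64; 256 matches the source
#'   acquisition, 64 is the test scale).
#' @param effect_size strength of the label-dependent morphology signal
#'   (>= 0).
#' @param signal_timepoints subset of 1:3; timepoints outside this set are
#'   rendered with zero effect size.
#' @param noise_sd pixel Gaussian noise standard deviation.
#' @param seed integer seed; a fixed seed gives bit-identical cohorts.
#' @return a `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_embryos = 252L, n_negative = 180L,
                                    n_positive = 72L,
                                    embryos_per_patient = 1L,
                                    image_size = 256L, effect_size = 1,
                                    signal_timepoints = 1:3,
                                    noise_sd = 0.02, seed = 1L) {
  n_embryos <- as.integer(n_embryos)
  n_negative <- as.integer(n_negative)
  n_positive <- as.integer(n_positive)
  if (n_embryos <= 0L || n_negative <= 0L || n_positive <= 0L) {
    stop("cohort counts must be positive")
  }
  if (n_negative + n_positive != n_embryos) {
    stop("n_negative + n_positive must equal n_embryos")
  }
  image_size <- as.integer(image_size)
  if (image_size < 64L) stop("image_size must be >= 64")
  if (effect_size < 0) stop("effect_size must be >= 0")
  signal_timepoints <- sort(unique(as.integer(signal_timepoints)))
  if (!all(signal_timepoints %in% 1:3)) {
    stop("signal_timepoints must be a subset of 1:3")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_embryos = n_embryos, n_negative = n_negative,
                 n_positive = n_positive,
                 embryos_per_patient = embryos_per_patient,
                 image_size = image_size, effect_size = effect_size,
                 signal_timepoints = signal_timepoints, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

# anti-aliased blend of a shape given its signed pixel distance (negative
# inside); cov = 1 deep inside, 0 outside, linear across the boundary pixel
aa_blend <- function(img, signed_dist, value) {
  cov <- clip01(0.5 - signed_dist)
  img * (1 - cov) + cov * value
}

#' Render one synthetic embryo frame
#'
#' Draws a bright zona pellucida ring containing stage-dependent
#' blastomeres (1 at stage 1, 2-4 at stage 2, 6-8 at stage 3) as
#' anti-aliased ellipses, plus small bright speckles emulating cytoplasmic
#' fragmentation. For positive labels the blastomeres are more
#' size-symmetric and fragmentation is rarer, with both differences scaled
#' by `effect_size`. Uses the current RNG state.
#'
#' @param stage developmental stage, 1, 2 or 3.
#' @param label binary outcome label (0/1).
#' @param effect_size signal strength (>= 0).
#' @param image_size frame side in pixels.
#' @param noise_sd pixel Gaussian noise sd.
#' @return list with `image` (matrix in `[0, 1]`), `mask` (binary matrix
#'   marking the zona disk, one connected component) and `morphology`
#'   (blastomere count, blastomere-size CV, fragment count).
#' @export
render_embryo_frame <- function(stage, label, effect_size = 1,
                                image_size = 64L, noise_sd = 0.02) {
  if (!stage %in% 1:3) stop("stage must be 1, 2 or 3")
  if (!label %in% c(0, 1)) stop("label must be 0 or 1")
  size <- as.integer(image_size)
  n_cells <- switch(stage, 1L, sample(2:4, 1L), sample(6:8, 1L))

  cx <- size * (0.5 + stats::runif(1, -0.04, 0.04))
  cy <- size * (0.5 + stats::runif(1, -0.04, 0.04))
  r_out <- size * stats::runif(1, 0.30, 0.36)
  thick <- size * 0.05
  r_in <- r_out - thick

  co <- seq_len(size) - 0.5
  X <- matrix(co, size, size)
  Y <- matrix(co, size, size, byrow = TRUE)
  D <- sqrt((X - cx)^2 + (Y - cy)^2)

  img <- matrix(0.15, size, size)
  img <- aa_blend(img, D - r_in, 0.32)                # interior
  img <- aa_blend(img, pmax(r_in - D, D - r_out), 0.85)  # zona ring

  # blastomeres: lognormal radii; the label narrows the spread
  sigma <- 0.25 * exp(-0.7 * effect_size * label)
  r_mean <- 0.58 * r_in / sqrt(n_cells)
  radii <- pmin(r_mean * exp(stats::rnorm(n_cells, 0, sigma)), 0.9 * r_in)
  centers <- matrix(0, n_cells, 2)
  for (k in seq_len(n_cells)) {
    for (try in 1:40) {
      rr <- stats::runif(1, 0, max(r_in - radii[k], 1))
      th <- stats::runif(1, 0, 2 * pi)
      p <- c(cx + rr * cos(th), cy + rr * sin(th))
      if (k == 1L) break
      dmin <- min(sqrt(colSums((t(centers[seq_len(k - 1L), , drop = FALSE]) -
                                  p)^2)) - 0.75 * (radii[seq_len(k - 1L)] +
                                                     radii[k]))
      if (dmin > 0) break
    }
    centers[k, ] <- p
  }
  for (k in seq_len(n_cells)) {
    ecc <- stats::runif(1, 0, 0.15)
    a <- radii[k] * (1 + ecc)
    b <- radii[k] / (1 + ecc)
    phi <- stats::runif(1, 0, pi)
    dx <- X - centers[k, 1]
    dy <- Y - centers[k, 2]
    u <- (dx * cos(phi) + dy * sin(phi)) / a
    v <- (-dx * sin(phi) + dy * cos(phi)) / b
    pix_d <- (sqrt(u^2 + v^2) - 1) * min(a, b)
    img <- aa_blend(img, pix_d, stats::rnorm(1, 0.55, 0.03))
    mem <- clip01(1 - abs(pix_d)) * 0.8                 # membrane highlight
    img <- img * (1 - mem) + mem * 0.72
  }

  # fragmentation speckles: small bright dots, rarer for positive labels
  n_frag <- stats::rpois(1, 6 * exp(-0.7 * effect_size * label))
  for (k in seq_len(n_frag)) {
    rr <- stats::runif(1, 0, 0.85 * r_in)
    th <- stats::runif(1, 0, 2 * pi)
    fr <- size * stats::runif(1, 0.012, 0.025)
    fd <- sqrt((X - cx - rr * cos(th))^2 + (Y - cy - rr * sin(th))^2) - fr
    img <- aa_blend(img, fd, 0.8)
  }

  if (noise_sd > 0) {
    img <- img + stats::rnorm(size * size, 0, noise_sd)
  }
  list(image = clip01(img),
       mask = (D <= r_out) * 1,
       morphology = list(
         n_blastomeres = n_cells,
         size_cv = if (n_cells > 1L) stats::sd(radii) / mean(radii) else 0,
         n_fragments = n_frag))
}

assign_patients <- function(n, embryos_per_patient) {
  if (is.numeric(embryos_per_patient) && length(embryos_per_patient) == 1L &&
      is.null(names(embryos_per_patient))) {
    k <- max(1L, as.integer(embryos_per_patient))
    return(rep(seq_len(ceiling(n / k)), each = k)[seq_len(n)])
  }
  sizes <- as.integer(names(embryos_per_patient))
  probs <- as.numeric(embryos_per_patient)
  out <- integer(0)
  pid <- 0L
  while (length(out) < n) {
    pid <- pid + 1L
    s <- sample(sizes, 1L, prob = probs)
    out <- c(out, rep(pid, s))
  }
  out[seq_len(n)]
}

#' Generate a synthetic embryo cohort
#'
#' Produces `n_embryos` synthetic embryos, each with three frames, three
#' ground-truth zona masks and a binary outcome label, plus a manifest.
#' With `dir` supplied, frames and masks are written as PNG
#' (`<embryo_id>_t{1,2,3}.png`, `..._mask.png`) and the manifest as
#' `manifest.csv`; the manifest's frame columns then reference the written
#' files. The same config and seed reproduce the cohort bit-identically.
#'
#' @param config a [synthetic_cohort_config()].
#' @param dir optional output directory.
#' @return an object of class `synthetic_cohort`: list with `embryos`
#'   (each holding `record`, `frames`, `masks`, `label`, `morphology`),
#'   `manifest` and `config`.
#' @export
generate_cohort <- function(config = synthetic_cohort_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  setup <- local_seed(config$seed, {
    list(labels = sample(c(rep(0L, config$n_negative),
                           rep(1L, config$n_positive))),
         patients = assign_patients(config$n_embryos,
                                    config$embryos_per_patient))
  })
  labels <- setup$labels
  patients <- setup$patients
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  embryos <- vector("list", config$n_embryos)
  paths <- matrix(NA_character_, config$n_embryos, 3)
  for (i in seq_len(config$n_embryos)) {
    eid <- sprintf("E%04d", i)
    frames <- masks <- vector("list", 3L)
    morph <- vector("list", 3L)
    local_seed(derive_seed(config$seed, i), {
      for (t in 1:3) {
        eff <- if (t %in% config$signal_timepoints) config$effect_size else 0
        r <- render_embryo_frame(t, labels[i], eff, config$image_size,
                                 config$noise_sd)
        frames[[t]] <- r$image
        masks[[t]] <- r$mask
        morph[[t]] <- r$morphology
      }
    })
    if (!is.null(dir)) {
      for (t in 1:3) {
        paths[i, t] <- file.path(dir, sprintf("%s_t%d.png", eid, t))
        write_gray(frames[[t]], paths[i, t])
        write_gray(masks[[t]], file.path(dir,
                                         sprintf("%s_t%d_mask.png", eid, t)))
      }
    }
    embryos[[i]] <- list(
      record = list(embryo_id = eid,
                    patient_id = sprintf("P%04d", patients[i]),
                    label = labels[i]),
      frames = frames, masks = masks, label = labels[i],
      morphology = morph)
  }
  manifest <- data.frame(
    embryo_id = vapply(embryos, function(e) e$record$embryo_id, character(1)),
    patient_id = vapply(embryos, function(e) e$record$patient_id,
                        character(1)),
    label = labels, frame_t1 = paths[, 1], frame_t2 = paths[, 2],
    frame_t3 = paths[, 3], stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(embryos = embryos, manifest = manifest, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d embryos (%d negative / %d positive), %dpx\n",
              x$config$n_embryos, x$config$n_negative, x$config$n_positive,
              x$config$image_size))
  invisible(x)
}

#' Blastomere-size CV statistic and threshold discriminator
#'
#' `cv_signal_stat` summarizes one synthetic embryo by its mean
#' blastomere-size coefficient of variation over multi-cell stages.
#' `cv_threshold_discriminator` picks the CV threshold maximizing training
#' accuracy (predicting positive when CV falls below it) and reports test
#' accuracy — a deliberately simple reference discriminator used to check
#' that the generator's class signal grows with `effect_size`.
#'
#' @param embryo one element of a `synthetic_cohort`'s `embryos`.
#' @param train,test lists of synthetic embryos.
#' @return `cv_signal_stat`: a single number. `cv_threshold_discriminator`:
#'   list with `threshold`, `train_accuracy`, `test_accuracy`.
#' @export
cv_signal_stat <- function(embryo) {
  cvs <- vapply(embryo$morphology, function(m) {
    if (m$n_blastomeres > 1L) m$size_cv else NA_real_
  }, numeric(1))
  mean(cvs, na.rm = TRUE)
}

#' @rdname cv_signal_stat
#' @export
cv_threshold_discriminator <- function(train, test) {
  stat_tr <- vapply(train, cv_signal_stat, numeric(1))
  y_tr <- vapply(train, `[[`, numeric(1), "label")
  cand <- sort(unique(stat_tr))
  cand <- c(cand[1] - 1e-6, (cand[-1] + cand[-length(cand)]) / 2,
            cand[length(cand)] + 1e-6)
  acc <- vapply(cand, function(th) mean((stat_tr < th) == y_tr), numeric(1))
  th <- cand[which.max(acc)]
  stat_te <- vapply(test, cv_signal_stat, numeric(1))
  y_te <- vapply(test, `[[`, numeric(1), "label")
  list(threshold = th, train_accuracy = max(acc),
       test_accuracy = mean((stat_te < th) == y_te))
}
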