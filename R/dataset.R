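#' Manifest I/O
#'
#' A manifest is a data frame with one row per embryo and columns
#' `embryo_id` (unique), `patient_id`, `label` (0/1 pregnancy outcome;
#' positive = beta-hCG above threshold) and `frame_t1`..`frame_t3` (paths
#' to the three analysis frames). Save/load round-trips losslessly.
#'
#' @param path CSV file path.
#' @param manifest manifest data frame.
#' @return `read_manifest`: the validated manifest. `write_manifest`: the
#'   path, invisibly.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(embryo_id = "character",
                                      patient_id = "character",
                                      frame_t1 = "character",
                                      frame_t2 = "character",
                                      frame_t3 = "character"))
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  req <- c("embryo_id", "patient_id", "label", "frame_t1", "frame_t2",
           "frame_t3")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(m) == 0L) stop("empty manifest")
  if (anyDuplicated(m$embryo_id)) stop("embryo_id values must be unique")
  if (!all(m$label %in% c(0, 1))) stop("label must be 0 or 1")
  invisible(m)
}

#' Timepoint specification
#'
#' The three analysis timepoints in hours post-insemination and how they
#' map onto a 10-minute-interval time-lapse frame series. Defaults are
#' 19, 44 and 68 hpi with a +/- 1 h tolerance.
#'
#' @param targets_hpi three strictly increasing target times (hours).
#' @param tolerance_hpi acceptance window around each target (hours, > 0).
#' @param frame_interval_min acquisition interval (minutes).
#' @return a `timepoint_spec` list.
#' @export
timepoint_spec <- function(targets_hpi = c(19, 44, 68), tolerance_hpi = 1,
                           frame_interval_min = 10) {
  if (any(diff(targets_hpi) <= 0)) stop("targets_hpi must be increasing")
  if (tolerance_hpi <= 0) stop("tolerance_hpi must be > 0")
  if (frame_interval_min <= 0) stop("frame_interval_min must be > 0")
  structure(list(targets_hpi = targets_hpi, tolerance_hpi = tolerance_hpi,
                 frame_interval_min = frame_interval_min),
            class = "timepoint_spec")
}

#' Map hours post-insemination to a frame index
#'
#' With frames acquired every `frame_interval_min` minutes starting at 0,
#' the frame index for a time `hpi` is the nearest integer to
#' `hpi * 60 / frame_interval_min` (19 hpi at 10-min intervals -> 114).
#'
#' @param hpi hours post-insemination (>= 0, vectorized).
#' @param spec a [timepoint_spec()].
#' @return integer frame indices.
#' @export
frame_index_for_hpi <- function(hpi, spec = timepoint_spec()) {
  if (any(hpi < 0)) stop("hpi must be >= 0")
  as.integer(round(hpi * 60 / spec$frame_interval_min))
}

hpi_for_frame_index <- function(index, spec = timepoint_spec()) {
  index * spec$frame_interval_min / 60
}

#' Extract the three analysis frames from a time-lapse series
#'
#' For each target timepoint, picks the available frame closest to it,
#' provided it lies within `tolerance_hpi`; otherwise fails naming the
#' missing target.
#'
#' @param frame_index sorted integer indices of the available frames.
#' @param spec a [timepoint_spec()].
#' @param frames optional list of images aligned with `frame_index`.
#' @return list with `positions` (into `frame_index`), `indices`, `hpi`,
#'   and `frames` (when supplied).
#' @export
extract_timepoints <- function(frame_index, spec = timepoint_spec(),
                               frames = NULL) {
  if (length(frame_index) == 0L) stop("empty frame series")
  if (is.unsorted(frame_index)) stop("frame_index must be sorted")
  hpi <- hpi_for_frame_index(frame_index, spec)
  pos <- vapply(spec$targets_hpi, function(target) {
    p <- which.min(abs(hpi - target))
    if (abs(hpi[p] - target) > spec$tolerance_hpi) {
      stop(sprintf("no frame within %g +/- %g hpi", target,
                   spec$tolerance_hpi), call. = FALSE)
    }
    p
  }, integer(1))
  out <- list(positions = pos, indices = frame_index[pos], hpi = hpi[pos])
  if (!is.null(frames)) out$frames <- frames[pos]
  out
}

# Greedy assignment of whole patient groups to the test side: a group goes
# to test while it fits under every per-class target; a repair pass then
# moves groups whose transfer strictly reduces the remaining deficit.
greedy_select <- function(counts, targets) {
  sel <- logical(nrow(counts))
  got <- numeric(ncol(counts))
  for (g in seq_len(nrow(counts))) {
    if (all(got + counts[g, ] <= targets)) {
      sel[g] <- TRUE
      got <- got + counts[g, ]
    }
  }
  for (g in which(!sel)) {
    if (sum(abs(targets - got - counts[g, ])) < sum(abs(targets - got))) {
      sel[g] <- TRUE
      got <- got + counts[g, ]
    }
  }
  sel
}

#' Leakage-safe stratified train/test split
#'
#' Splits a manifest at the embryo level into train and test sets such
#' that (i) all embryos of one patient land in the same partition — a
#' patient with an embryo in training has all their embryos in training —
#' and (ii) per-class test counts are as close to
#' `(1 - train_fraction) * class size` as the patient grouping allows.
#' With one embryo per patient and the study cohort (252 embryos,
#' 180/72 by class, fraction 2/3) the split is exactly 168 train
#' (120/48) and 84 test (60/24). Deterministic given `seed`.
#'
#' An optional validation fraction is carved out of the training side
#' under the same grouping rules (for early stopping; the study protocol
#' describes no separate validation set).
#'
#' @param manifest manifest data frame.
#' @param train_fraction fraction of each class assigned to training
#'   (0 < f < 1).
#' @param seed integer seed controlling the group shuffle.
#' @param val_fraction fraction *of the training set* carved out for
#'   validation (0 disables).
#' @return a `split_assignment`: list with `train_ids`, `test_ids`,
#'   `val_ids` and a `table` of per-class counts.
#' @export
split_grouped_stratified <- function(manifest, train_fraction = 2 / 3,
                                     seed = NULL, val_fraction = 0) {
  validate_manifest(manifest)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  classes <- sort(unique(manifest$label))
  for (cl in classes) {
    owners <- unique(manifest$patient_id[manifest$label == cl])
    if (length(owners) == 1L &&
        length(unique(manifest$patient_id)) > 1L) {
      warning(sprintf("all label-%s embryos belong to one patient; ",
                      cl), "stratification degrades for that class")
    }
  }
  groups <- split(seq_len(nrow(manifest)), manifest$patient_id)
  counts <- t(vapply(groups, function(ix) {
    vapply(classes, function(cl) sum(manifest$label[ix] == cl), numeric(1))
  }, numeric(length(classes))))
  if (length(classes) == 1L) counts <- matrix(counts, ncol = 1L)
  ord <- local_seed(seed, sample(length(groups)))
  targets_test <- round((1 - train_fraction) *
                          colSums(counts))
  sel_test <- greedy_select(counts[ord, , drop = FALSE], targets_test)
  test_groups <- names(groups)[ord][sel_test]
  test_ids <- manifest$embryo_id[manifest$patient_id %in% test_groups]
  train_ids <- setdiff(manifest$embryo_id, test_ids)

  val_ids <- character(0)
  if (val_fraction > 0) {
    tr <- manifest[manifest$embryo_id %in% train_ids, , drop = FALSE]
    gr2 <- split(seq_len(nrow(tr)), tr$patient_id)
    cnt2 <- t(vapply(gr2, function(ix) {
      vapply(classes, function(cl) sum(tr$label[ix] == cl), numeric(1))
    }, numeric(length(classes))))
    if (length(classes) == 1L) cnt2 <- matrix(cnt2, ncol = 1L)
    ord2 <- local_seed(derive_seed(if (is.null(seed)) NULL else seed, 99L),
                       sample(length(gr2)))
    sel_val <- greedy_select(cnt2[ord2, , drop = FALSE],
                             round(val_fraction * colSums(cnt2)))
    val_groups <- names(gr2)[ord2][sel_val]
    val_ids <- tr$embryo_id[tr$patient_id %in% val_groups]
    train_ids <- setdiff(train_ids, val_ids)
  }

  tab <- vapply(list(train = train_ids, val = val_ids, test = test_ids),
                function(ids) {
    vapply(classes, function(cl) {
      sum(manifest$label[manifest$embryo_id %in% ids] == cl)
    }, numeric(1))
  }, numeric(length(classes)))
  tab <- matrix(tab, nrow = length(classes),
                dimnames = list(as.character(classes),
                                c("train", "val", "test")))
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 val_ids = val_ids, table = tab),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("grouped stratified split\n")
  if (!is.null(x$table)) print(x$table)
  else cat(sprintf("train %d / val %d / test %d\n", length(x$train_ids),
                   length(x$val_ids), length(x$test_ids)))
  invisible(x)
}

#' Write / read a split assignment
#'
#' @param split a `split_assignment`.
#' @param path CSV path (columns `embryo_id`, `partition`).
#' @return `write_split`: the path, invisibly; `read_split`: a
#'   `split_assignment` without the count table.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    embryo_id = c(split$train_ids, split$val_ids, split$test_ids),
    partition = c(rep("train", length(split$train_ids)),
                  rep("val", length(split$val_ids)),
                  rep("test", length(split$test_ids))),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(train_ids = df$embryo_id[df$partition == "train"],
                 test_ids = df$embryo_id[df$partition == "test"],
                 val_ids = df$embryo_id[df$partition == "val"]),
            class = "split_assignment")
}
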