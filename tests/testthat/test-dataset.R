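test_that("hpi maps to the nearest 10-minute frame index", {
  spec <- timepoint_spec()
  expect_equal(frame_index_for_hpi(19, spec), 114L)
  expect_equal(frame_index_for_hpi(0, spec), 0L)
  expect_equal(frame_index_for_hpi(68, spec), 408L)
  expect_equal(frame_index_for_hpi(44, spec), 264L)
  expect_error(frame_index_for_hpi(-1, spec), ">= 0")
  # monotone in hpi
  h <- sort(runif(50, 0, 80))
  expect_true(all(diff(frame_index_for_hpi(h, spec)) >= 0))
  expect_error(timepoint_spec(targets_hpi = c(19, 18, 68)), "increasing")
})

test_that("extract_timepoints picks in-tolerance frames and names missing targets", {
  spec <- timepoint_spec()
  full <- 0:450
  r <- extract_timepoints(full, spec)
  expect_equal(r$indices, c(114L, 264L, 408L))
  # truncated at 40 hpi: 44 and 68 unavailable
  expect_error(extract_timepoints(0:240, spec), "44")
  # gap: nearest frame at 44.9 hpi for target 44 accepted (within +/- 1)
  idx449 <- round(44.9 * 6)
  series <- c(0:130, idx449, 400:415)
  r2 <- extract_timepoints(series, spec)
  expect_equal(r2$indices[2], idx449)
  # frames carried through
  imgs <- as.list(seq_along(full))
  r3 <- extract_timepoints(full, spec, frames = imgs)
  expect_equal(r3$frames[[3]], which(full == 408L))
  expect_error(extract_timepoints(integer(0), spec), "empty")
})

test_that("study-cohort split is exactly 168/84 with per-class 120/48 and 60/24", {
  m <- generate_cohort(synthetic_cohort_config(seed = 7L,
                                               image_size = 64L))$manifest
  sp <- split_grouped_stratified(m, 2 / 3, seed = 7L)
  expect_length(sp$train_ids, 168L)
  expect_length(sp$test_ids, 84L)
  tab <- sp$table
  expect_equal(unname(tab[, "train"]), c(120, 48))
  expect_equal(unname(tab[, "test"]), c(60, 24))
  # deterministic given the seed
  sp2 <- split_grouped_stratified(m, 2 / 3, seed = 7L)
  expect_identical(sort(sp$test_ids), sort(sp2$test_ids))
})

test_that("patient grouping is never split and degenerate grouping degrades gracefully", {
  m <- random_manifest(12, seed = 1)
  m$patient_id <- "P001"   # one patient owns everything
  sp <- suppressWarnings(split_grouped_stratified(m, 2 / 3, seed = 1L))
  expect_true(length(sp$train_ids) == 12L || length(sp$test_ids) == 12L)

  # three single-embryo patients at fraction 2/3: exactly one valid family
  # of assignments (2 train + 1 test), verified against enumeration
  m3 <- random_manifest(3, seed = 2)
  m3$patient_id <- sprintf("P%03d", 1:3)
  m3$label <- c(0, 0, 1)
  sp3 <- suppressWarnings(split_grouped_stratified(m3, 2 / 3, seed = 5L))
  valid <- list()  # enumerate all patient-respecting 2/1 partitions
  for (test_p in 1:3) {
    valid[[test_p]] <- sort(m3$embryo_id[test_p])
  }
  expect_true(length(sp3$test_ids) %in% c(1L))
  expect_true(list(sort(sp3$test_ids)) %in% valid)
})

test_that("random manifests always satisfy the partition invariants", {
  set.seed(99)
  for (i in 1:200) {
    m <- random_manifest()
    sp <- suppressWarnings(split_grouped_stratified(m, 2 / 3,
                                                    seed = i,
                                                    val_fraction =
                                                      if (i %% 3 == 0) 0.2
                                                      else 0))
    all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
    expect_setequal(all_ids, m$embryo_id)
    expect_equal(anyDuplicated(all_ids), 0L)
    part <- function(ids) unique(m$patient_id[m$embryo_id %in% ids])
    expect_length(intersect(part(sp$train_ids), part(sp$test_ids)), 0L)
    expect_length(intersect(part(sp$val_ids), part(sp$test_ids)), 0L)
    expect_length(intersect(part(sp$train_ids), part(sp$val_ids)), 0L)
  }
})

test_that("manifest and split CSVs round-trip losslessly", {
  d <- withr::local_tempdir()
  m <- random_manifest(10, seed = 3)
  write_manifest(m, file.path(d, "m.csv"))
  expect_equal(read_manifest(file.path(d, "m.csv")), m)
  sp <- split_grouped_stratified(m, 0.5, seed = 1L, val_fraction = 0.2)
  write_split(sp, file.path(d, "s.csv"))
  sp2 <- read_split(file.path(d, "s.csv"))
  expect_setequal(sp2$train_ids, sp$train_ids)
  expect_setequal(sp2$test_ids, sp$test_ids)
  expect_setequal(sp2$val_ids, sp$val_ids)
  expect_error(suppressWarnings(read_manifest(file.path(d, "nope.csv"))))
  m_bad <- m
  m_bad$label[1] <- 2
  expect_error(write_manifest(m_bad, file.path(d, "bad.csv")), "label")
})
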