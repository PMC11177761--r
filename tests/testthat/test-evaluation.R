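test_that("confusion counts tally each quadrant", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cc[c("TP", "FP", "TN", "FN")],
               list(TP = 1L, FP = 1L, TN = 1L, FN = 1L),
               ignore_attr = TRUE)
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FP + perfect$FN, 0L)
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "binary")
  # large random vectors agree with an independent element-wise tally
  set.seed(1)
  p <- rbinom(1000, 1, 0.4)
  t <- rbinom(1000, 1, 0.3)
  cc2 <- confusion_counts(p, t)
  tab <- table(factor(p, 0:1), factor(t, 0:1))
  expect_equal(cc2$TP, unname(tab["1", "1"]))
  expect_equal(cc2$TN, unname(tab["0", "0"]))
  expect_equal(cc2$FP, unname(tab["1", "0"]))
  expect_equal(cc2$FN, unname(tab["0", "1"]))
})

test_that("metrics match direct formula substitution and identities", {
  r <- compute_metrics(structure(list(TP = 3, TN = 2, FP = 1, FN = 2),
                                 class = "confusion_counts"))
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$accuracy, 0.625)
  expect_equal(r$f1, 2 * 0.75 * 0.6 / 1.35)
  perfect <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(c(perfect$precision, perfect$recall, perfect$accuracy,
                 perfect$f1), rep(1, 4))
  # precision == recall implies F1 equals that common value
  pr <- compute_metrics(structure(list(TP = 3, TN = 0, FP = 2, FN = 2),
                                  class = "confusion_counts"))
  expect_equal(pr$precision, pr$recall)
  expect_equal(pr$f1, pr$precision)
  # zero denominators: reported as 0 and flagged
  z <- compute_metrics(c(0, 0, 0), c(1, 0, 1))
  expect_equal(z$precision, 0)
  expect_true("precision" %in% z$undefined)
  expect_error(compute_metrics(structure(list(TP = 0, TN = 0, FP = 0,
                                              FN = 0),
                                         class = "confusion_counts")),
               "samples")
})

test_that("metric identities hold on random confusion counts", {
  set.seed(2)
  for (i in 1:50) {
    p <- rbinom(40, 1, runif(1, 0.2, 0.8))
    t <- rbinom(40, 1, runif(1, 0.2, 0.8))
    r <- compute_metrics(p, t)
    n <- with(r$counts, TP + TN + FP + FN)
    expect_equal(r$accuracy * n, r$counts$TP + r$counts$TN)
    if (!length(r$undefined)) {
      expect_equal(r$f1, 2 / (1 / r$precision + 1 / r$recall))
      # macro recall averages the two per-class recalls
      expect_equal(r$macro_recall,
                   (r$counts$TP / (r$counts$TP + r$counts$FN) +
                      r$counts$TN / (r$counts$TN + r$counts$FP)) / 2)
    }
  }
})

test_that("majority vote equals the brute-force mode and applies its tie policy", {
  expect_equal(majority_vote(matrix(c(1, 1, 0, 0, 1), 1)), 1L)
  expect_equal(majority_vote(matrix(0, 1, 5)), 0L)
  even <- matrix(c(1, 1, 0, 0), 1)
  expect_error(majority_vote(even), "tie")
  expect_equal(majority_vote(even, tie = "negative"), 0L)
  set.seed(3)
  for (i in 1:100) {
    nr <- sample(c(1, 3, 5, 7), 1)
    panel <- matrix(rbinom(nr * 10, 1, 0.5), 10, nr)
    brute <- apply(panel, 1, function(v) {
      tt <- table(v)
      as.integer(names(tt)[which.max(tt)])
    })
    expect_equal(majority_vote(panel), brute)
  }
  expect_error(majority_vote(matrix(numeric(0), 1, 0)), "rater")
})

test_that("comparison report flags best and second-best per metric", {
  r1 <- compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1), predictor_name = "a")
  r2 <- compute_metrics(c(1, 0, 0, 1), c(1, 0, 0, 1), predictor_name = "b")
  cr <- comparison_report(list(r1, r2))
  expect_equal(unname(cr$best), rep("b", 3))
  expect_equal(rownames(cr$table), c("recall", "precision", "accuracy"))
  single <- comparison_report(list(r1))
  expect_true(all(is.na(single$second)))
  # argmax oracle over random report sets
  set.seed(4)
  for (i in 1:50) {
    reports <- lapply(1:3, function(k) {
      compute_metrics(rbinom(30, 1, 0.5), rbinom(30, 1, 0.5),
                      predictor_name = paste0("m", k))
    })
    cr2 <- comparison_report(reports)
    accs <- vapply(reports, `[[`, numeric(1), "accuracy")
    expect_equal(cr2$best[3], paste0("m", which.max(accs)))
  }
})

test_that("metrics reports round-trip through JSON bitwise", {
  d <- withr::local_tempdir()
  set.seed(5)
  r <- compute_metrics(rbinom(37, 1, 0.4), rbinom(37, 1, 0.6),
                       predictor_name = "fusion")
  path <- file.path(d, "r.json")
  write_metrics_json(r, path)
  r2 <- read_metrics_json(path)
  expect_identical(r2$precision, r$precision)
  expect_identical(r2$f1, r$f1)
  expect_identical(r2$counts$TP, as.integer(r$counts$TP))
  expect_identical(r2$predictor_name, "fusion")
})
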