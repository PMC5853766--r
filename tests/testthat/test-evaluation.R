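test_that("normal is negative, everything else positive", {
  expect_identical(binarize_label("NORMAL"), "NEGATIVE")
  expect_identical(binarize_label("SYSTOLIC_MURMUR"), "POSITIVE")
  expect_identical(binarize_label("S4"), "POSITIVE")
  expect_identical(binarize_label("S3"), "POSITIVE")
  expect_identical(binarize_label("DIASTOLIC_MURMUR"), "POSITIVE")
  expect_error(binarize_label("WHEEZE"), class = "pcgdx_config_error")
})

test_that("confusion counts partition the sample", {
  pos <- rep("SYSTOLIC_MURMUR", 10); neg <- rep("NORMAL", 10)
  perfect <- confusion(c(pos, neg), c(pos, neg))
  expect_equal(unlist(perfect[c("tp", "fp", "fn", "tn")]),
               c(tp = 10, fp = 0, fn = 0, tn = 10))

  truths <- c(rep("S3", 16), rep("NORMAL", 14))
  allpos <- confusion(rep("S4", 30), truths)
  expect_equal(unlist(allpos[c("tp", "fp", "fn", "tn")]),
               c(tp = 16, fp = 14, fn = 0, tn = 0))
  swapped <- confusion(rep("NORMAL", 30), truths)
  expect_equal(unlist(swapped[c("tp", "fp", "fn", "tn")]),
               c(tp = 0, fp = 0, fn = 16, tn = 14))
  cc <- confusion(sample(c(pos, neg)), c(pos, neg))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 20)
  expect_error(confusion(pos, neg[1:5]), "length")
})

test_that("diagnostic metrics reproduce the three published device rows", {
  # device-level confusion counts reconstructed from n=30 with 16
  # positives / 14 negatives
  check_row <- function(counts, pct) {
    dm <- diagnostic_metrics(structure(counts, class = "confusion_counts"))
    expect_equal(dm$percent, pct)
  }
  check_row(list(tp = 15, fp = 2, fn = 1, tn = 12), c(90, 94, 86, 88, 92))
  check_row(list(tp = 15, fp = 3, fn = 1, tn = 11), c(87, 94, 79, 83, 92))
  check_row(list(tp = 13, fp = 0, fn = 3, tn = 14), c(90, 81, 100, 100, 82))
})

test_that("perfect counts give 100% everywhere", {
  dm <- diagnostic_metrics(list(tp = 10, fp = 0, fn = 0, tn = 10))
  expect_true(all(dm$percent == 100))
  expect_true(all(dm$estimate == 1))
})

test_that("zero-denominator metrics are undefined, not 0 or 100", {
  dm <- diagnostic_metrics(list(tp = 0, fp = 0, fn = 0, tn = 5))
  sens <- dm[dm$metric == "sensitivity", ]
  ppv <- dm[dm$metric == "ppv", ]
  expect_true(is.na(sens$estimate))
  expect_identical(sens$percent_ci, "—")
  expect_true(is.na(ppv$estimate))
  spec <- dm[dm$metric == "specificity", ]
  expect_equal(spec$estimate, 1)
})

test_that("Clopper-Pearson intervals reproduce the published CIs", {
  pct <- function(k, n) {
    ci <- clopper_pearson(k, n)
    round(100 * c(ci$lower, ci$upper))
  }
  expect_equal(pct(27, 30), c(73, 98))
  expect_equal(pct(26, 30), c(69, 96))
  expect_equal(pct(15, 16), c(70, 100))
  expect_equal(pct(12, 14), c(57, 98))
  expect_equal(pct(11, 14), c(49, 95))
  expect_equal(pct(15, 17), c(64, 99))
  expect_equal(pct(15, 18), c(59, 96))
  expect_equal(pct(12, 13), c(64, 100))
  expect_equal(pct(11, 12), c(62, 100))
  expect_equal(pct(13, 16), c(54, 96))
  expect_equal(pct(14, 17), c(57, 96))
})

test_that("interval boundaries behave exactly at k = 0 and k = n", {
  lo <- clopper_pearson(0, 10)
  expect_identical(lo$lower, 0)
  expect_lt(lo$upper, 1)
  hi <- clopper_pearson(10, 10)
  expect_identical(hi$upper, 1)
  expect_gt(hi$lower, 0)
  expect_error(clopper_pearson(5, 4), class = "pcgdx_config_error")
})

test_that("the Beta-quantile form matches brute-force CDF inversion", {
  for (n in c(1, 5, 16, 30, 50)) {
    for (k in 0:n) {
      ci <- clopper_pearson(k, n)
      ora <- cp_bisect(k, n)
      expect_equal(ci$lower, unname(ora["lower"]), tolerance = 1e-6)
      expect_equal(ci$upper, unname(ora["upper"]), tolerance = 1e-6)
    }
  }
})

test_that("CI width shrinks with n at a fixed proportion", {
  widths <- vapply(c(10, 20, 40, 80, 160), function(n) {
    ci <- clopper_pearson(round(0.8 * n), n)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("evaluate_dataset partitions counts across subgroups", {
  set.seed(4)
  truths <- sample(PCG_CLASSES, 40, replace = TRUE)
  preds <- ifelse(runif(40) < 0.8, truths,
                  sample(PCG_CLASSES, 40, replace = TRUE))
  sex <- rep(c("M", "F"), 20)
  ev <- evaluate_dataset(preds, truths, subgroups = sex)

  tot <- ev$counts$Total
  m <- ev$counts$M; f <- ev$counts$F
  for (fld in c("tp", "fp", "fn", "tn")) {
    expect_equal(m[[fld]] + f[[fld]], tot[[fld]])
  }
  # brute-force recount oracle for accuracy
  acc_hand <- mean(binarize_label(preds) == binarize_label(truths))
  acc_pkg <- ev$metrics[ev$metrics$subgroup == "Total" &
                          ev$metrics$metric == "accuracy", "estimate"]
  expect_equal(acc_pkg, acc_hand)
  expect_equal(sum(ev$confusion_5class), 40)

  single <- evaluate_dataset(preds, truths)
  expect_identical(single$metrics$estimate,
                   ev$metrics[ev$metrics$subgroup == "Total", "estimate"])
  expect_error(evaluate_dataset(preds, truths, subgroups = sex[1:5]),
               class = "pcgdx_config_error")
})
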