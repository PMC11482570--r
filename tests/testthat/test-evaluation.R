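test_that("confusion matrix counts agree with a double-loop oracle", {
  lv <- severity_levels()
  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix(c("normal"), c("normal", "mild")), "length")
  expect_error(confusion_matrix("normal", "huge"), "unknown label")

  act <- rep("mild", 10)
  cm <- confusion_matrix(act, act)
  expect_identical(sum(diag(cm)), 10L)
  expect_identical(sum(cm), 10L)

  set.seed(61)
  a <- sample(lv, 500, replace = TRUE)
  p <- sample(lv, 500, replace = TRUE)
  cm <- confusion_matrix(a, p)
  oracle <- matrix(0L, 4, 4, dimnames = list(lv, lv))
  for (i in seq_along(a)) {
    oracle[a[i], p[i]] <- oracle[a[i], p[i]] + 1L
  }
  expect_identical(unclass(cm), structure(oracle,
                                          dimnames = list(actual = lv,
                                                          predicted = lv)))
})

test_that("binary metrics are the four exact count ratios", {
  m <- binary_metrics(tp = 1, fp = 0, tn = 1, fn = 0)
  expect_identical(unlist(m[c("accuracy", "sensitivity", "specificity",
                              "precision")]), c(accuracy = 1,
                                                sensitivity = 1,
                                                specificity = 1,
                                                precision = 1))
  set.seed(62)
  for (i in 1:200) {
    cnt <- rpois(4, 20)
    if (sum(cnt) == 0) next
    m <- binary_metrics(tp = cnt[1], fp = cnt[2], tn = cnt[3], fn = cnt[4])
    expect_equal(m$accuracy, (cnt[1] + cnt[3]) / sum(cnt))
    if (cnt[1] + cnt[4] > 0) expect_equal(m$sensitivity,
                                          cnt[1] / (cnt[1] + cnt[4]))
    if (cnt[3] + cnt[2] > 0) expect_equal(m$specificity,
                                          cnt[3] / (cnt[3] + cnt[2]))
    if (cnt[1] + cnt[2] > 0) expect_equal(m$precision,
                                          cnt[1] / (cnt[1] + cnt[2]))
  }
})

test_that("zero-denominator metrics are reported as undefined, not zero", {
  m <- binary_metrics(tp = 0, fp = 3, tn = 5, fn = 0)
  expect_true(is.na(m$sensitivity))
  expect_identical(m$undefined, "sensitivity")
  m2 <- binary_metrics(tp = 0, fp = 0, tn = 5, fn = 2)
  expect_true(is.na(m2$precision))
  expect_false(is.na(m2$accuracy))
  expect_error(binary_metrics(0, 0, 0, 0), "positive total")
})

test_that("one-vs-rest metrics reduce the K-class matrix correctly", {
  lv <- severity_levels()
  ident <- confusion_matrix(rep(lv, 5), rep(lv, 5))
  ov <- ovr_metrics(ident)
  expect_true(all(unlist(ov$per_class[-1]) == 1))
  expect_identical(ov$micro_accuracy, 1)
  expect_identical(unname(ov$macro_n_defined), rep(4L, 4))

  cm <- reference_confusion("realtime")
  ov <- ovr_metrics(cm)
  expect_equal(ov$micro_accuracy, 153 / 176)
  # normal-vs-rest reduction of the same matrix
  normal <- ov$per_class[ov$per_class$class == "normal", ]
  expect_equal(normal$accuracy, 166 / 176)
  expect_equal(normal$sensitivity, 47 / 52)
  # against a naive one-vs-rest counting oracle for every class
  total <- sum(cm)
  for (i in 1:4) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp; fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    row <- ov$per_class[i, ]
    expect_equal(row$accuracy, (tp + tn) / total)
    expect_equal(row$precision, tp / (tp + fp))
  }
})

test_that("packaged reference matrices have the recorded totals", {
  rt <- reference_confusion("realtime")
  expect_identical(sum(rt), 176L)
  expect_identical(sum(diag(rt)), 153L)
  cl <- reference_confusion("cloud")
  expect_identical(sum(cl), 174L)
  expect_identical(sum(diag(cl)), 113L)
  expect_equal(ovr_metrics(cl)$micro_accuracy, 113 / 174)
  sp <- reference_confusion("saltpepper")
  expect_identical(rownames(sp), severity_levels())
})

test_that("metrics are invariant under simultaneous class permutation", {
  cm <- reference_confusion("realtime")
  perm <- c(3, 1, 4, 2)
  cm2 <- unclass(cm)[perm, perm]
  ov1 <- ovr_metrics(cm)
  ov2 <- ovr_metrics(cm2)
  expect_identical(ov1$micro_accuracy, ov2$micro_accuracy)
  expect_equal(sort(ov1$per_class$accuracy), sort(ov2$per_class$accuracy))
  expect_equal(ov1$macro$precision, ov2$macro$precision)
})

test_that("confusion CSV round-trips", {
  cm <- reference_confusion("saltpepper")
  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, path)
  back <- read_confusion_csv(path)
  expect_identical(unclass(back), unclass(cm))
})
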