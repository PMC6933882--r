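test_that("confusion counts tally the four cells with SIP as positive", {
  c1 <- confusion_counts(rep(c(1, 0), c(4, 6)), rep(c(1, 0), c(4, 6)))
  expect_equal(unclass(c1)[c("TP", "FP", "TN", "FN")],
               list(TP = 4L, FP = 0L, TN = 6L, FN = 0L))
  c2 <- confusion_counts(rep(c(1, 0), c(4, 6)), rep(0, 10))
  expect_equal(c2$TP, 0L); expect_equal(c2$FP, 0L)
  expect_equal(c2$FN, 4L); expect_equal(c2$TN, 6L)
  truth <- c(1, 1, 1, 0, 0, 0, 0, 1, 0, 1)
  pred  <- c(1, 0, 1, 1, 0, 0, 1, 1, 0, 0)
  c3 <- confusion_counts(truth, pred)
  expect_equal(unclass(c3)[c("TP", "FP", "TN", "FN")],
               list(TP = 3L, FP = 2L, TN = 3L, FN = 2L))
  expect_error(confusion_counts(c(1, 0), c(1)), "length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "binary")
})

test_that("metric formulas reproduce direct arithmetic and flag zero denominators", {
  m <- compute_metrics(list(TP = 3, FP = 1, TN = 5, FN = 1))
  expect_equal(m$acc, 0.8)
  expect_equal(m$sen, 0.75)
  expect_equal(m$sp, 5 / 6)
  expect_equal(m$pe, 0.75)
  expect_equal(m$mcc, 14 / 24)
  expect_length(attr(m, "undefined"), 0)

  perfect <- compute_metrics(list(TP = 7, FP = 0, TN = 9, FN = 0))
  expect_equal(unlist(unclass(perfect)), c(acc = 1, sen = 1, sp = 1, pe = 1, mcc = 1))

  none_pred <- compute_metrics(list(TP = 0, FP = 0, TN = 9, FN = 1))
  expect_true(is.na(none_pred$pe))
  expect_true("pe" %in% attr(none_pred, "undefined"))
  expect_error(compute_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)), "zero")
})

test_that("MCC is symmetric under simultaneous class/prediction swap", {
  set.seed(53)
  for (rep in 1:10) {
    cts <- as.list(sample(0:20, 4, replace = TRUE))
    names(cts) <- c("TP", "FP", "TN", "FN")
    if (sum(unlist(cts)) == 0) next
    swapped <- list(TP = cts$TN, FP = cts$FN, TN = cts$TP, FN = cts$FP)
    expect_equal(compute_metrics(cts)$mcc, compute_metrics(swapped)$mcc)
  }
})

test_that("stratified folds partition the data with balanced class counts", {
  folds <- stratified_kfold(rep(c(1, 0), each = 10), 5, seed = 59)
  expect_equal(sort(unlist(folds)), 1:20)
  for (f in folds) expect_equal(sum(f <= 10), 2)  # 2 positives per fold

  y <- rep(c(1, 0), c(7, 13))
  folds2 <- stratified_kfold(y, 5, seed = 61)
  expect_equal(sort(unlist(folds2)), 1:20)
  pos_counts <- vapply(folds2, function(f) sum(y[f] == 1), integer(1))
  neg_counts <- vapply(folds2, function(f) sum(y[f] == 0), integer(1))
  expect_lte(diff(range(pos_counts)), 1)
  expect_lte(diff(range(neg_counts)), 1)
  expect_error(stratified_kfold(rep(c(1, 0), c(3, 17)), 5), "at least")
})

test_that("ROC curve endpoints, monotonicity and trapezoidal AUC are correct", {
  r <- roc_curve(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(auc(r), 0.75)  # 3 of 4 pairs concordant

  perf <- roc_curve(c(5, 4, 1, 0), c(1, 1, 0, 0))
  expect_equal(auc(perf), 1)
  flat <- roc_curve(rep(0.5, 6), rep(c(1, 0), 3))
  expect_equal(auc(flat), 0.5)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC equals Mann-Whitney concordance on small random instances", {
  set.seed(67)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1] <- 1L - labels[1]
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # force ties
    expect_equal(auc(roc_curve(scores, labels)), mw_auc_oracle(scores, labels))
  }
})

test_that("AUC agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(roc_curve(scores, labels)), ref)
})

test_that("cross-validation report has fold rows plus a mean/sd summary", {
  s <- separable_set(25, dim = 30, gap = 3)
  rep_ <- run_cv(s$X, s$y, folds = 5, n_components = 10,
                 B1 = 3, B2 = 4, q = 3, seed = 73)
  expect_equal(nrow(rep_$folds), 5)
  expect_gte(mean(rep_$folds$acc), 0.95)
  for (col in c("acc", "sen", "sp", "pe", "mcc", "auc")) {
    row <- rep_$summary[rep_$summary$metric == col, ]
    expect_equal(row$mean, mean(rep_$folds[[col]]))
    expect_equal(row$sd, stats::sd(rep_$folds[[col]]))
  }
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_cv_report(rep_, tf)
  tab <- utils::read.table(tf, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 7)
  expect_equal(tab$fold[6:7], c("mean", "sd"))
})

test_that("shuffled labels bring accuracy down to the majority fraction", {
  set.seed(79)
  X <- matrix(rnorm(100 * 12), 100, 12)
  y <- rep(c(1L, 0L), c(20, 80))   # majority fraction 0.8
  rep_ <- run_cv(X, y, folds = 5, n_components = 8, B1 = 4, B2 = 4, q = 3,
                 seed = 79)
  expect_lt(abs(mean(rep_$folds$acc) - 0.8), 0.05)
})

test_that("SVM baseline separates toy data and mirrors the report format", {
  s <- separable_set(25, dim = 30, gap = 3)
  rp_rep <- run_cv(s$X, s$y, folds = 5, n_components = 10,
                   B1 = 3, B2 = 4, q = 3, seed = 83)
  svm_rep <- svm_cv(s$X, s$y, folds = 5, n_components = 10, seed = 83)
  expect_equal(mean(svm_rep$folds$acc), 1)
  expect_identical(names(svm_rep$folds), names(rp_rep$folds))
  expect_identical(svm_rep$summary$metric, rp_rep$summary$metric)
})
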