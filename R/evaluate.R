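#' Confusion-matrix counts
#'
#' Tallies true/false positives and negatives with the self-interacting class
#' (label 1) as positive.
#'
#' @param true_labels,predicted_labels Equal-length binary vectors.
#' @return Object of class `"confusion_counts"`: list with integer `TP`,
#'   `FP`, `TN`, `FN`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion_counts <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  t <- as.integer(true_labels); p <- as.integer(predicted_labels)
  if (anyNA(t) || anyNA(p) || !all(c(t, p) %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  structure(list(TP = sum(t == 1L & p == 1L),
                 FP = sum(t == 0L & p == 1L),
                 TN = sum(t == 0L & p == 0L),
                 FN = sum(t == 1L & p == 0L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(FP+TN)`, precision `TP/(FP+TP)` and the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`. A metric whose
#' denominator is zero is returned as `NA` and listed in the `undefined`
#' attribute rather than silently set to 0 - on strongly imbalanced folds
#' precision can be undefined when no positive is predicted.
#'
#' @param counts A [confusion_counts()] object (or list with TP/FP/TN/FN).
#' @return Object of class `"metric_set"`: named list `acc`, `sen`, `sp`,
#'   `pe`, `mcc` with attribute `undefined` naming any flagged metrics.
#' @export
#' @examples
#' compute_metrics(list(TP = 3, FP = 1, TN = 5, FN = 1))
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total <= 0) stop("confusion counts are all zero")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- list(
    acc = (TP + TN) / total,
    sen = safe_div(TP, TP + FN),
    sp  = safe_div(TN, FP + TN),
    pe  = safe_div(TP, FP + TP),
    mcc = {
      den <- sqrt(as.numeric(TP + FN) * (TN + FP) * (TP + FP) * (TN + FN))
      if (den == 0) NA_real_ else (as.numeric(TP) * TN - as.numeric(FP) * FN) / den
    })
  structure(m, undefined = names(m)[vapply(m, is.na, logical(1))],
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.4f", v)
  cat(sprintf("Acc %s  Sen %s  Sp %s  PE %s  MCC %s\n",
              fmt(x$acc), fmt(x$sen), fmt(x$sp), fmt(x$pe), fmt(x$mcc)))
  invisible(x)
}

#' Stratified k-fold partition
#'
#' Shuffles each class separately (seeded) and deals its members round-robin
#' across folds, so per-fold class counts differ from proportionality by at
#' most one sample. Returns disjoint index sets covering all samples.
#'
#' @param labels Binary vector.
#' @param folds Number of folds; default 5.
#' @param seed Optional integer seed for the shuffle.
#' @return List of `folds` integer index vectors.
#' @export
stratified_kfold <- function(labels, folds = 5L, seed = NULL) {
  labels <- as.integer(labels)
  folds <- as.integer(folds)
  if (sum(labels == 1L) < folds || sum(labels == 0L) < folds)
    stop("every class needs at least as many members as folds")
  .with_seed(seed, {
    assign_class <- function(idx) {
      idx <- sample(idx)
      split(idx, rep_len(seq_len(folds), length(idx)))
    }
    pos <- assign_class(which(labels == 1L))
    neg <- assign_class(which(labels == 0L))
    lapply(seq_len(folds), function(f) sort(c(pos[[f]], neg[[f]])))
  })
}

#' ROC curve from scores
#'
#' Sweeps a decision threshold over the distinct score values (predicting
#' positive when `score >= threshold`) and records the false- and
#' true-positive rates, which are nondecreasing from (0, 0) to (1, 1).
#'
#' @param scores Numeric scores; larger means more positive.
#' @param true_labels Binary labels; both classes must be present.
#' @return Object of class `"roc_curve"`: list with `thresholds`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, true_labels) {
  labels <- as.integer(true_labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1L) / P, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0L) / N, numeric(1))
  structure(list(thresholds = th, fpr = fpr, tpr = tpr), class = "roc_curve")
}

#' Area under the ROC curve
#'
#' Trapezoidal-rule area under a [roc_curve()]; equals the Mann-Whitney
#' concordance probability (ties counted half).
#'
#' @param curve A [roc_curve()] object.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

.fold_stats <- function(true_labels, pred, scores) {
  counts <- confusion_counts(true_labels, pred)
  metrics <- compute_metrics(counts)
  a <- if (length(unique(true_labels)) > 1L) auc(roc_curve(scores, true_labels))
       else NA_real_
  list(counts = counts, metrics = metrics, auc = a)
}

.report_row <- function(fold, n_test, stats) {
  data.frame(fold = fold, n_test = n_test,
             TP = stats$counts$TP, FP = stats$counts$FP,
             TN = stats$counts$TN, FN = stats$counts$FN,
             acc = stats$metrics$acc, sen = stats$metrics$sen,
             sp = stats$metrics$sp, pe = stats$metrics$pe,
             mcc = stats$metrics$mcc, auc = stats$auc)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Runs stratified k-fold cross-validation of the PCA + random-projection
#' ensemble on a feature matrix. In each fold the PCA model and the ensemble
#' are fit on the training folds only and applied to the held-out fold, so no
#' information leaks from the test fold into the reduction or the classifier.
#' Setting `pca_global = TRUE` instead fits one PCA on all samples first.
#'
#' @param features Numeric `N x p` feature matrix (typically 400 columns).
#' @param labels Binary vector of length `N`.
#' @param folds Number of CV folds; default 5.
#' @param n_components PCA target dimension; default 300 (truncated to the
#'   training-fold rank when smaller). `0` skips the reduction.
#' @param pca_global Fit PCA once on all data instead of per training fold.
#' @param B1,B2,q,k_grid,kind Ensemble settings, see [rp_fit()].
#' @param seed Integer seed driving the fold split and every ensemble fit.
#' @return Object of class `"cv_report"`: data frame `folds` (one row per
#'   fold: counts, Acc/Sen/Sp/PE/MCC, AUC), `summary` (mean and sample sd
#'   across folds), `pooled_auc` over the concatenated held-out scores, and
#'   per-fold details (`pca` models, predictions, scores).
#' @export
run_cv <- function(features, labels, folds = 5L, n_components = 300L,
                   pca_global = FALSE, B1 = 10L, B2 = 30L, q = 5L,
                   k_grid = seq(1L, 30L, by = 8L),
                   kind = "gaussian_sphere", seed = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) stop("features and labels misaligned")
  fold_sets <- stratified_kfold(labels, folds,
                                seed = if (is.null(seed)) NULL else seed)
  global_model <- if (pca_global && n_components > 0L)
    fit_pca(features, min(n_components, nrow(features) - 1L, ncol(features)))
  else NULL

  rows <- list(); details <- list()
  all_scores <- numeric(0); all_truth <- integer(0)
  for (f in seq_len(folds)) {
    test_idx <- fold_sets[[f]]
    train_idx <- setdiff(seq_len(nrow(features)), test_idx)
    pca <- if (n_components == 0L) NULL
           else if (pca_global) global_model
           else fit_pca(features[train_idx, , drop = FALSE],
                        min(n_components, length(train_idx) - 1L, ncol(features)))
    tr <- if (is.null(pca)) features[train_idx, , drop = FALSE]
          else apply_pca(pca, features[train_idx, , drop = FALSE])
    te <- if (is.null(pca)) features[test_idx, , drop = FALSE]
          else apply_pca(pca, features[test_idx, , drop = FALSE])
    model <- rp_fit(tr, labels[train_idx], B1 = B1, B2 = B2,
                    q = min(q, ncol(tr) - 1L), k_grid = k_grid, kind = kind,
                    seed = if (is.null(seed)) NULL else seed + f)
    scores <- vote_fraction(model, te)
    pred <- as.integer(scores >= model$vote_threshold)
    stats <- .fold_stats(labels[test_idx], pred, scores)
    rows[[f]] <- .report_row(f, length(test_idx), stats)
    details[[f]] <- list(pca = pca, model_threshold = model$vote_threshold,
                         test_idx = test_idx, pred = pred, scores = scores)
    all_scores <- c(all_scores, scores)
    all_truth <- c(all_truth, labels[test_idx])
  }
  fold_df <- do.call(rbind, rows)
  metric_cols <- c("acc", "sen", "sp", "pe", "mcc", "auc")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(c) mean(fold_df[[c]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_cols, function(c) stats::sd(fold_df[[c]][!is.na(fold_df[[c]])]), numeric(1)),
    row.names = NULL)
  structure(list(folds = fold_df, summary = summary,
                 pooled_auc = if (length(unique(all_truth)) > 1L)
                   auc(roc_curve(all_scores, all_truth)) else NA_real_,
                 details = details),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 4, ...) {
  df <- x$folds
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  s <- x$summary
  cat("Average: ",
      paste(sprintf("%s %.*f +/- %.*f", s$metric, digits, s$mean, digits, s$sd),
            collapse = "  "), "\n", sep = "")
  cat(sprintf("Pooled AUC: %.*f\n", digits, x$pooled_auc))
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' One row per fold plus a `mean` and `sd` row, numeric columns rounded to 4
#' decimals.
#'
#' @param report A [run_cv()] report.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cv_report <- function(report, path) {
  df <- report$folds
  df$fold <- as.character(df$fold)
  metric_cols <- c("acc", "sen", "sp", "pe", "mcc", "auc")
  mk <- function(tag, vals) {
    r <- df[1, ]; r[] <- NA
    r$fold <- tag
    r[metric_cols] <- vals
    r
  }
  out <- rbind(df,
               mk("mean", report$summary$mean),
               mk("sd", report$summary$sd))
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 4)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' RBF-SVM baseline
#'
#' Reference classifier for comparison with the random-projection ensemble: a
#' support-vector machine with radial basis kernel at fixed hyperparameters
#' `cost = 0.6`, `gamma = 0.02` (LIBSVM via e1071). Evaluated with the same
#' stratified folds and report format as [run_cv()]; ROC scores are the SVM
#' decision values.
#'
#' @param features,labels,folds,n_components,pca_global,seed As in [run_cv()].
#' @param cost,gamma RBF-SVM hyperparameters.
#' @return A `"cv_report"` object.
#' @export
svm_cv <- function(features, labels, folds = 5L, n_components = 300L,
                   pca_global = FALSE, cost = 0.6, gamma = 0.02, seed = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  fold_sets <- stratified_kfold(labels, folds,
                                seed = if (is.null(seed)) NULL else seed)
  rows <- list(); details <- list()
  all_scores <- numeric(0); all_truth <- integer(0)
  for (f in seq_len(folds)) {
    test_idx <- fold_sets[[f]]
    train_idx <- setdiff(seq_len(nrow(features)), test_idx)
    pca <- if (n_components == 0L) NULL
           else fit_pca(features[train_idx, , drop = FALSE],
                        min(n_components, length(train_idx) - 1L, ncol(features)))
    tr <- if (is.null(pca)) features[train_idx, , drop = FALSE]
          else apply_pca(pca, features[train_idx, , drop = FALSE])
    te <- if (is.null(pca)) features[test_idx, , drop = FALSE]
          else apply_pca(pca, features[test_idx, , drop = FALSE])
    fit <- e1071::svm(tr, factor(labels[train_idx], levels = c(0, 1)),
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    pr <- stats::predict(fit, te, decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))
    # orient decision values so larger = more positive
    if (colnames(attr(pr, "decision.values"))[1] == "0/1") dv <- -dv
    pred <- as.integer(as.character(pr))
    stats <- .fold_stats(labels[test_idx], pred, dv)
    rows[[f]] <- .report_row(f, length(test_idx), stats)
    details[[f]] <- list(test_idx = test_idx, pred = pred, scores = dv)
    all_scores <- c(all_scores, dv)
    all_truth <- c(all_truth, labels[test_idx])
  }
  fold_df <- do.call(rbind, rows)
  metric_cols <- c("acc", "sen", "sp", "pe", "mcc", "auc")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(c) mean(fold_df[[c]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_cols, function(c) stats::sd(fold_df[[c]][!is.na(fold_df[[c]])]), numeric(1)),
    row.names = NULL)
  structure(list(folds = fold_df, summary = summary,
                 pooled_auc = if (length(unique(all_truth)) > 1L)
                   auc(roc_curve(all_scores, all_truth)) else NA_real_,
                 details = details),
            class = "cv_report")
}
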