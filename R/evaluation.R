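#' 10-fold cross-validation of a logistic submodel
#'
#' Randomly partitions the data into k folds (unstratified, matching the
#' study's random subsetting), refits the model on each training set
#' (90%), predicts the held-out fold (10%), and reports the
#' misclassification rate at a 0.5 probability threshold averaged over
#' folds, plus the AUC of the pooled out-of-fold predictions. With a rare
#' response a training fold can end up single-class; such folds are
#' skipped with a warning and recorded.
#'
#' @param formula logistic model formula.
#' @param data data frame.
#' @param k number of folds (default 10).
#' @param seed RNG seed controlling the partition.
#' @return list of class `cv_result`: `folds` (assignment per row),
#'   `oof_pred` (out-of-fold probabilities, NA for skipped folds),
#'   `error_rate` (mean over evaluated folds), `auc` (pooled), `roc`,
#'   `skipped_folds`.
#' @export
kfold_cv <- function(formula, data, k = 10, seed = NULL) {
  n <- nrow(data)
  stopifnot(n >= k, k >= 2)
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  resp_name <- all.vars(formula)[1]
  y <- data[[resp_name]]
  oof <- rep(NA_real_, n)
  errs <- numeric(0)
  skipped <- integer(0)
  for (f in seq_len(k)) {
    tr <- data[fold != f, , drop = FALSE]
    te <- data[fold == f, , drop = FALSE]
    if (length(unique(tr[[resp_name]])) < 2L) {
      warning("fold ", f, " skipped: single-class training response")
      skipped <- c(skipped, f)
      next
    }
    fit <- tryCatch(fit_logistic(formula, tr), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("fold ", f, " skipped: ", conditionMessage(fit))
      skipped <- c(skipped, f)
      next
    }
    p <- predict_prob(fit, te)
    oof[fold == f] <- p
    errs <- c(errs, mean((p >= 0.5) != (te[[resp_name]] == 1)))
  }
  ok <- !is.na(oof)
  roc <- if (length(unique(y[ok])) == 2L) roc_auc(oof[ok], y[ok]) else NULL
  structure(list(folds = fold, oof_pred = oof, error_rate = mean(errs),
                 auc = if (is.null(roc)) NA_real_ else roc$auc,
                 roc = roc, skipped_folds = skipped),
            class = "cv_result")
}

#' ROC curve and AUC
#'
#' The AUC is the probability that a randomly chosen positive receives a
#' higher score than a randomly chosen negative, with ties counted 1/2
#' (the Mann-Whitney statistic, equivalent to trapezoidal integration of
#' the ROC curve). 0.5 is chance performance; 1.0 is perfect ranking.
#'
#' @param scores numeric predicted scores (any monotone transform of risk).
#' @param labels binary 0/1 outcomes; both classes must be present.
#' @return list of class `roc_curve`: `auc`, `thresholds`, `tpr`, `fpr`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  structure(list(auc = auc,
                 thresholds = c(Inf, thr),
                 tpr = c(0, tpr), fpr = c(0, fpr)),
            class = "roc_curve")
}

#' R-squared of a binned calibration regression
#'
#' Ordinary least-squares coefficient of determination from regressing the
#' observed per-bin high-impact proportion on the mean predicted
#' probability per bin.
#'
#' @param bin_means mean predicted probability per bin.
#' @param bin_observed observed high-impact proportion per bin.
#' @return R-squared in [0, 1].
#' @export
calibration_r2 <- function(bin_means, bin_observed) {
  stopifnot(length(bin_means) == length(bin_observed))
  if (length(bin_means) < 3) stop("need at least 3 bins")
  if (stats::var(bin_means) == 0) {
    stop("zero variance in predicted bin means")
  }
  summary(stats::lm(bin_observed ~ bin_means))$r.squared
}
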