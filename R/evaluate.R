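#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability: the fraction of
#' (positive, negative) pairs in which the positive case scores higher,
#' with ties credited 0.5 (midranks). Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Percentile interval from class-stratified bootstrap resamples, fully
#' reproducible under the seed.
#'
#' @inheritParams roc_auc
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return Numeric `c(lo, hi)`.
#' @export
auc_ci <- function(scores, labels, n_boot = 2000L, seed = 1L, conf = 0.95) {
  labels <- as.integer(labels)
  i1 <- which(labels == 1L); i0 <- which(labels == 0L)
  if (length(i1) == 0L || length(i0) == 0L)
    stop("both classes must be present")
  if (n_boot < 100L) stop("n_boot must be >= 100")
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    s1 <- sample(i1, replace = TRUE); s0 <- sample(i0, replace = TRUE)
    idx <- c(s1, s0)
    roc_auc(scores[idx], labels[idx])
  }, 0)
  a <- (1 - conf) / 2
  stats::quantile(reps, c(a, 1 - a), names = FALSE)
}

#' Operating threshold by the Youden index
#'
#' Evaluates `J = sensitivity + specificity - 1` at every distinct observed
#' score as a candidate threshold (cases with score >= threshold predicted
#' positive) and returns the maximiser; ties are broken by the lowest
#' threshold.
#'
#' @inheritParams roc_auc
#' @return An object of class `cutoff_result`: list with `threshold`,
#'   `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  th <- sort(unique(scores))
  sens <- vapply(th, function(t) sum(scores >= t & labels == 1L) / n1, 0)
  spec <- vapply(th, function(t) sum(scores < t & labels == 0L) / n0, 0)
  j <- sens + spec - 1
  k <- which.max(j)                      # first = lowest threshold on ties
  structure(list(threshold = th[k], sensitivity = sens[k],
                 specificity = spec[k], youden_j = j[k]),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("threshold %.4g: sensitivity %.3f, specificity %.3f, Youden J %.3f\n",
              x$threshold, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' Confusion matrix and derived metrics at a threshold
#'
#' @inheritParams roc_auc
#' @param threshold score threshold; score >= threshold predicts positive.
#' @return list with `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
classification_report <- function(scores, labels, threshold) {
  stopifnot(is.finite(threshold))
  labels <- as.integer(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L); tn <- sum(!pred & labels == 0L)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Calibration curve
#'
#' Equal-width probability bins on `[0, 1]`; per occupied bin, the mean
#' predicted probability against the observed event fraction. Empty bins
#' are omitted.
#'
#' @inheritParams roc_auc
#' @param n_bins number of bins (default 10).
#' @return data.frame with `bin_mid`, `mean_predicted`, `observed`, `n`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10L) {
  labels <- as.integer(labels)
  if (length(scores) < n_bins)
    stop("need at least as many cases as bins")
  b <- pmin(pmax(findInterval(scores, seq(0, 1, length.out = n_bins + 1L),
                              rightmost.closed = TRUE), 1L), n_bins)
  occ <- sort(unique(b))
  data.frame(
    bin_mid = (occ - 0.5) / n_bins,
    mean_predicted = vapply(occ, function(k) mean(scores[b == k]), 0),
    observed = vapply(occ, function(k) mean(labels[b == k]), 0),
    n = vapply(occ, function(k) sum(b == k), 0L))
}

#' Decision curve analysis
#'
#' Net benefit of treating at score >= t:
#' `NB(t) = TP(t)/n - FP(t)/n * t/(1-t)`, with the treat-all reference
#' `prevalence - (1 - prevalence) * t/(1-t)` and treat-none fixed at 0.
#'
#' @inheritParams roc_auc
#' @param thresholds numeric grid strictly inside (0, 1).
#' @return data.frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  labels <- as.integer(labels)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  n <- length(labels)
  prev <- mean(labels == 1L)
  nb <- vapply(thresholds, function(t) {
    pred <- scores >= t
    sum(pred & labels == 1L) / n - sum(pred & labels == 0L) / n * t / (1 - t)
  }, 0)
  data.frame(threshold = thresholds, net_benefit = nb,
             treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
             treat_none = 0)
}

#' Full diagnostic evaluation report
#'
#' Bundles ROC/AUC with a bootstrap confidence interval, the operating
#' cutoff (Youden by default, or a pre-specified threshold, e.g. carried
#' over from a training cohort), the confusion matrix at that cutoff, the
#' calibration curve and the decision curve.
#'
#' @inheritParams roc_auc
#' @param threshold optional fixed threshold; when `NULL` the Youden
#'   cutoff is estimated from these data.
#' @param n_boot,seed bootstrap settings for the AUC interval.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(scores, labels, threshold = NULL,
                        n_boot = 2000L, seed = 1L) {
  labels <- as.integer(labels)
  cut <- if (is.null(threshold)) youden_cutoff(scores, labels)
  else {
    cr <- classification_report(scores, labels, threshold)
    structure(list(threshold = threshold, sensitivity = cr$sensitivity,
                   specificity = cr$specificity,
                   youden_j = cr$sensitivity + cr$specificity - 1),
              class = "cutoff_result")
  }
  rep <- classification_report(scores, labels, cut$threshold)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(scores[labels == 0L] >= t), 0),
    tpr = vapply(th, function(t) mean(scores[labels == 1L] >= t), 0))
  structure(list(
    roc = roc,
    auc = roc_auc(scores, labels),
    auc_ci = auc_ci(scores, labels, n_boot = n_boot, seed = seed),
    cutoff = cut,
    confusion = rep,
    calibration = tryCatch(calibration_curve(scores, labels),
                           error = function(e) NULL),
    decision = decision_curve(scores, labels),
    n = length(labels),
    prevalence = mean(labels == 1L)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Diagnostic evaluation on %d cases (prevalence %.2f)\n",
              x$n, x$prevalence))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  cutoff %.3f: sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
              x$cutoff$threshold, x$confusion$sensitivity,
              x$confusion$specificity, x$confusion$accuracy))
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$confusion$tp, x$confusion$fp, x$confusion$tn,
              x$confusion$fn))
  invisible(x)
}

#' @export
plot.eval_report <- function(x, which = c("roc", "calibration", "decision"),
                             ...) {
  which <- match.arg(which)
  if (which == "calibration" && !is.null(x$calibration)) {
    graphics::plot(x$calibration$mean_predicted, x$calibration$observed,
                   xlim = c(0, 1), ylim = c(0, 1), xlab = "predicted",
                   ylab = "observed", main = "Calibration", pch = 19, ...)
    graphics::abline(0, 1, lty = 2)
  } else if (which == "decision") {
    graphics::plot(x$decision$threshold, x$decision$net_benefit, type = "l",
                   xlab = "threshold probability", ylab = "net benefit",
                   main = "Decision curve",
                   ylim = range(c(x$decision$net_benefit, 0,
                                  pmax(x$decision$treat_all, -0.2))), ...)
    graphics::lines(x$decision$threshold, x$decision$treat_all, col = "grey50")
    graphics::abline(h = 0, lty = 2)
  } else {
    graphics::plot(x$roc$fpr, x$roc$tpr, type = "s",
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = sprintf("ROC (AUC %.3f)", x$auc), ...)
    graphics::abline(0, 1, lty = 3, col = "grey70")
  }
  invisible(x)
}
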