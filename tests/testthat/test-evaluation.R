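toy_scores <- c(0.1, 0.4, 0.35, 0.8)
toy_labels <- c(0, 0, 1, 1)

test_that("AUC equals the Mann-Whitney concordance with midrank ties", {
  expect_equal(roc_auc(toy_scores, toy_labels), 0.75)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  ## invariant under strictly monotone transforms
  set.seed(8)
  s <- rnorm(60); l <- rbinom(60, 1, 0.4)
  expect_equal(roc_auc(s, l), roc_auc(qlogis(plogis(s) * 0.98 + 0.01), l))
  expect_equal(roc_auc(s, l), roc_auc(rank(s), l))
  ## permuted labels: AUC near 1/2 at large n
  set.seed(9)
  sp <- rnorm(4000); lp <- sample(rep(0:1, 2000))
  expect_equal(roc_auc(sp, lp), 0.5, tolerance = 0.05)
})

test_that("Youden cutoff maximizes J with low-threshold tie-breaking", {
  cut <- youden_cutoff(toy_scores, toy_labels)
  expect_equal(cut$threshold, 0.35)
  expect_equal(cut$youden_j, 0.5)
  ## perfect separation: J = 1 at the minimal positive score
  ps <- youden_cutoff(c(0.1, 0.2, 0.7, 0.9), c(0, 0, 1, 1))
  expect_equal(ps$youden_j, 1)
  expect_equal(ps$threshold, 0.7)
  ## all scores equal: J = 0
  expect_equal(youden_cutoff(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))$youden_j, 0)
  ## agreement with an independent ROC-vertex enumeration on random data
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(10:40, 1)
    s <- round(runif(n), 2)          # force ties
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(youden_cutoff(s, l)$threshold, oracle_youden_vertex(s, l))
  }
})

test_that("classification reports reconstruct the confusion matrix", {
  r <- classification_report(toy_scores, toy_labels, 0.35)
  expect_equal(r[c("tp", "fn", "tn", "fp")], list(tp = 2L, fn = 0L,
                                                  tn = 1L, fp = 1L))
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$tp + r$fp + r$tn + r$fn, 4L)
  ## threshold below everything: all positive, specificity 0
  lo <- classification_report(toy_scores, toy_labels, 0)
  expect_equal(lo$specificity, 0)
  expect_equal(lo$sensitivity, 1)
  ## threshold above everything: sensitivity 0
  hi <- classification_report(toy_scores, toy_labels, 2)
  expect_equal(hi$sensitivity, 0)
})

test_that("bootstrap AUC intervals are seeded and cover the binormal truth", {
  set.seed(10)
  s <- c(rnorm(50, 1.2), rnorm(50)); l <- rep(1:0, each = 50)
  ci1 <- auc_ci(s, l, n_boot = 200, seed = 3)
  ci2 <- auc_ci(s, l, n_boot = 200, seed = 3)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] <= roc_auc(s, l) && roc_auc(s, l) <= ci1[2])
  expect_error(auc_ci(s, l, n_boot = 10), ">= 100")
  ## coverage: binormal scores with analytic AUC = Phi(mu / sqrt(2))
  mu <- sqrt(2) * qnorm(0.9)
  hits <- 0L
  for (rep in 1:100) {
    set.seed(1000 + rep)
    sc <- c(rnorm(100, mu), rnorm(100))
    lb <- rep(1:0, each = 100)
    ci <- auc_ci(sc, lb, n_boot = 300, seed = rep)
    if (ci[1] <= 0.9 && 0.9 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("calibration curves recover the diagonal for calibrated scores", {
  set.seed(12)
  n <- 5000
  p <- runif(n)
  y <- rbinom(n, 1, p)
  cc <- calibration_curve(p, y)
  expect_lte(max(abs(cc$observed - cc$mean_predicted)), 0.05)
  ## all scores 0.5 with balanced labels: single point (0.5, 0.5)
  one <- calibration_curve(rep(0.5, 20), rep(0:1, 10))
  expect_identical(nrow(one), 1L)
  expect_equal(one$mean_predicted, 0.5)
  expect_equal(one$observed, 0.5)
  ## labels all zero: observed fraction 0 everywhere occupied
  z <- calibration_curve(runif(50), rep(0, 50))
  expect_true(all(z$observed == 0))
})

test_that("decision curves obey the closed-form references", {
  th <- seq(0.05, 0.95, by = 0.05)
  ## perfect scores: net benefit = prevalence wherever no FP occur
  s <- c(0.99, 0.99, 0.01, 0.01, 0.01); l <- c(1, 1, 0, 0, 0)
  dc <- decision_curve(s, l, th[th < 0.99])
  expect_equal(dc$net_benefit, rep(0.4, nrow(dc)))
  ## treat-all reference
  expect_equal(dc$treat_all, 0.4 - 0.6 * dc$threshold / (1 - dc$threshold))
  expect_true(all(dc$treat_none == 0))
  ## no case predicted positive: net benefit 0
  none <- decision_curve(rep(0.1, 4), c(1, 0, 1, 0), 0.5)
  expect_equal(none$net_benefit, 0)
  expect_error(decision_curve(s, l, c(0, 0.5)), "inside")
})

test_that("evaluation report assembles consistent pieces and cross-checks pROC", {
  skip_if_not_installed("pROC")
  set.seed(13)
  s <- plogis(c(rnorm(80, 1), rnorm(80, -1)))
  l <- rep(1:0, each = 80)
  rep <- eval_report(s, l, n_boot = 200, seed = 1)
  expect_equal(rep$auc,
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))))
  expect_equal(rep$confusion$accuracy,
               (rep$confusion$tp + rep$confusion$tn) / rep$n)
  expect_true(rep$auc_ci[1] <= rep$auc && rep$auc <= rep$auc_ci[2])
  ## pROC's Youden threshold lies between our threshold and the next
  ## lower observed score (pROC reports the midpoint of the step)
  pr <- pROC::coords(pROC::roc(l, s, quiet = TRUE), "best",
                     best.method = "youden")
  ours <- rep$cutoff
  expect_equal(ours$sensitivity, pr$sensitivity, tolerance = 1e-9)
  expect_equal(ours$specificity, pr$specificity, tolerance = 1e-9)
  expect_output(print(rep), "AUC")
  pdf(NULL)
  on.exit(dev.off())
  plot(rep, "roc"); plot(rep, "calibration"); plot(rep, "decision")
})
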