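test_that("stratified folds keep class proportions within one subject", {
  lab <- rep(c("Impaired", "Intact"), c(10, 40))
  plan <- make_stratified_folds(lab, k = 5L, seed = 1L)
  for (i in 1:5) {
    fold_lab <- lab[plan$assignments == i]
    expect_equal(sum(fold_lab == "Impaired"), 2L)
    expect_equal(sum(fold_lab == "Intact"), 8L)
  }
  # the study's class split: 192 impaired of 618 over 5 folds -> 38 or 39
  lab618 <- rep(c("Impaired", "Intact"), c(192, 426))
  plan618 <- make_stratified_folds(lab618, k = 5L, seed = 2L)
  imp_counts <- vapply(1:5, function(i) {
    sum(lab618[plan618$assignments == i] == "Impaired")
  }, 1L)
  expect_true(all(imp_counts %in% c(38L, 39L)))
  expect_equal(sum(imp_counts), 192L)
  expect_error(make_stratified_folds(rep(c("Impaired", "Intact"), c(4, 30)),
                                     k = 5L), "fewer than k")
})

test_that("stratification holds across a seed sweep", {
  lab <- rep(c("Impaired", "Intact"), c(31, 87))
  glob <- 31 / 118
  for (seed in 1:100) {
    plan <- make_stratified_folds(lab, k = 5L, seed = seed)
    sizes <- tabulate(plan$assignments, 5L)
    imp <- vapply(1:5, function(i) {
      sum(lab[plan$assignments == i] == "Impaired")
    }, 1L)
    expect_true(all(abs(imp - sizes * glob) <= 1))
  }
})

test_that("cross-validation validates every subject exactly once", {
  co <- small_cohort(seed = 12L, n = 120L, missing_rate = 0)
  fm <- standardize(co$X_raw)
  y <- binarize_moca(co$moca_followup)
  plan <- make_stratified_folds(y, k = 4L, seed = 3L)
  tc <- fast_tc(seed = 5L)
  cv <- cross_validate(fm$values, y, plan, tc = tc)
  held <- lapply(cv$folds, `[[`, "holdout")
  expect_equal(sort(unlist(held)), seq_len(120L))
  expect_equal(sum(lengths(held)), 120L)
  recalls <- vapply(cv$folds, `[[`, 1.0, "recall_impaired")
  expect_true(all(recalls >= 0 & recalls <= 1))
  # deterministic rerun
  cv2 <- cross_validate(fm$values, y, plan, tc = tc)
  expect_identical(lapply(cv$folds, `[[`, "confusion"),
                   lapply(cv2$folds, `[[`, "confusion"))
})

fold_stub <- function(recall, fp) {
  list(recall_impaired = recall, confusion = list(FP = fp),
       params = paste0("params-r", recall, "-fp", fp))
}

test_that("best-model selection maximizes recall with documented tie-breaks", {
  folds <- Map(fold_stub, c(0.8, 0.9, 0.85, 0.9, 0.7),
               c(10, 12, 9, 8, 20))
  expect_equal(select_best_model(folds)$fold, 4L)
  expect_equal(select_best_model(folds[1])$fold, 1L)
  ties <- Map(fold_stub, rep(0.9, 3), rep(5, 3))
  expect_equal(select_best_model(ties)$fold, 1L)
  # permutation-equivariance under exact ties on recall
  folds_p <- folds[c(2, 4, 1, 3, 5)]
  expect_equal(select_best_model(folds_p)$fold, 2L)  # the old fold 4
})

test_that("confusion counts use Impaired as the positive class", {
  y <- cog_factor(c("Impaired", "Impaired", "Intact", "Intact"))
  cm0 <- confusion_from_predictions(y, y)
  expect_equal(cm0$FP + cm0$FN, 0L)
  cm_all <- confusion_from_predictions(y, rep("Impaired", 4))
  expect_equal(cm_all$TN, 0L)
  expect_equal(cm_all$FP, 2L)
  expect_error(confusion_from_predictions(y, c("Impaired", "x", "Intact",
                                               "Intact")), "unknown")
})

test_that("the published misclassification table implies the published
          confusion matrix and metrics", {
  # per-transition-class totals (371/92/100/55) with misclassified counts
  # (84/3/15/36): impaired-at-follow-up correct = (92-3)+(100-15) = 174,
  # intact correct = (371-84)+(55-36) = 306
  classes <- rep(c("Cognitively Intact", "Stable Impaired",
                   "Conversion to Impaired",
                   "Reversion to Cognitively Intact"),
                 c(371, 92, 100, 55))
  y_true <- cog_factor(ifelse(classes %in% c("Stable Impaired",
                                             "Conversion to Impaired"),
                              "Impaired", "Intact"))
  wrong <- unlist(mapply(function(n, m) c(rep(TRUE, m), rep(FALSE, n - m)),
                         c(371, 92, 100, 55), c(84, 3, 15, 36)))
  y_pred <- cog_factor(ifelse(wrong,
                              ifelse(y_true == "Impaired", "Intact",
                                     "Impaired"),
                              as.character(y_true)))
  cm <- confusion_from_predictions(y_true, y_pred)
  expect_equal(unclass(cm)[c("TP", "FN", "TN", "FP")],
               list(TP = 174L, FN = 18L, TN = 306L, FP = 120L))

  m <- metrics_from_confusion(cm)
  expect_equal(m$impaired$recall, 174 / 192)
  expect_equal(m$impaired$precision, 174 / 294)
  expect_equal(m$impaired$f1, 2 * (174/294) * (174/192) /
                 ((174/294) + (174/192)))
  expect_equal(m$accuracy, 480 / 618)
  expect_equal(m$intact$precision, 306 / 324)
  expect_equal(m$intact$recall, 306 / 426)
  expect_equal(m$macro_recall, mean(c(174 / 192, 306 / 426)))

  tab <- transition_error_table(classes, y_true, y_pred)
  expect_equal(tab$misclassified, c(84L, 3L, 15L, 36L))
  expect_equal(sum(tab$count) - sum(tab$misclassified), 480L)
})

test_that("metric edge cases follow the documented conventions", {
  perfect <- metrics_from_confusion(confusion_counts(TP = 5, FN = 0,
                                                     TN = 7, FP = 0))
  expect_equal(perfect$impaired$recall, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_recall, 1)
  # nothing predicted positive: precision undefined, recall 0
  degen <- metrics_from_confusion(confusion_counts(TP = 0, FN = 3,
                                                   TN = 9, FP = 0))
  expect_true(is.na(degen$impaired$precision))
  expect_equal(degen$impaired$recall, 0)
  expect_true(is.na(degen$impaired$f1))
})

test_that("micro accuracy equals the prevalence-weighted mean of recalls", {
  set.seed(40)
  for (i in 1:20) {
    cm <- confusion_counts(TP = sample(0:50, 1), FN = sample(1:50, 1),
                           TN = sample(0:50, 1), FP = sample(1:50, 1))
    m <- metrics_from_confusion(cm)
    n_imp <- cm$TP + cm$FN
    n_int <- cm$TN + cm$FP
    expect_equal(m$accuracy,
                 (n_imp * m$impaired$recall + n_int * m$intact$recall) /
                   (n_imp + n_int))
  }
})

test_that("ROC/AUC equals the exhaustive pair-count rank statistic", {
  # closed-form cases
  sep <- roc_and_auc(rep(c("Impaired", "Intact"), each = 5),
                     c(runif(5, 0.8, 1), runif(5, 0, 0.2)))
  expect_equal(sep$auc, 1.0)
  const <- roc_and_auc(rep(c("Impaired", "Intact"), each = 5), rep(0.4, 10))
  expect_equal(const$auc, 0.5)
  # worked example: impaired scores (0.9, 0.3) vs intact 0.8 gives one
  # winning and one losing pair -> (1 + 0) / 2 = 0.5
  ex <- roc_and_auc(c("Impaired", "Intact", "Impaired"), c(0.9, 0.8, 0.3))
  expect_equal(ex$auc, auc_pair_count(c("Impaired", "Intact", "Impaired"),
                                      c(0.9, 0.8, 0.3)))
  expect_equal(ex$auc, 0.5)
  # trapezoid = pair counting on random instances, including ties
  set.seed(41)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    lab <- sample(c("Impaired", "Intact"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab <- c("Impaired", "Intact",
                                          lab[-(1:2)])
    p <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_and_auc(lab, p)$auc, auc_pair_count(lab, p),
                 tolerance = 1e-12)
  }
  # curve endpoints and monotonicity
  expect_equal(ex$tpr[1], 0); expect_equal(ex$fpr[1], 0)
  expect_equal(ex$tpr[length(ex$tpr)], 1)
  expect_equal(ex$fpr[length(ex$fpr)], 1)
  expect_true(all(diff(ex$tpr) >= 0) && all(diff(ex$fpr) >= 0))
  expect_error(roc_and_auc(rep("Intact", 4), runif(4)), "both classes")
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  lab <- sample(c("Impaired", "Intact"), 80, replace = TRUE)
  p <- runif(80)
  ours <- roc_and_auc(lab, p)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = p, levels = c("Intact", "Impaired"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("transition error rows reconcile with the confusion totals", {
  co <- small_cohort(seed = 14L, n = 150L, missing_rate = 0)
  y_b <- binarize_moca(co$moca_baseline)
  y_f <- binarize_moca(co$moca_followup)
  trans <- assign_transition_class(y_b, y_f)
  set.seed(43)
  y_pred <- cog_factor(sample(c("Impaired", "Intact"), 150, replace = TRUE))
  tab <- transition_error_table(trans, y_f, y_pred)
  cm <- confusion_from_predictions(y_f, y_pred)
  expect_equal(sum(tab$misclassified), cm$FP + cm$FN)
  expect_equal(sum(tab$count), 150L)
  expect_true(all(tab$misclassified <= tab$count))
  perfect <- transition_error_table(trans, y_f, y_f)
  expect_true(all(perfect$misclassified == 0L))
})
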