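#' Stratified k-fold plan
#'
#' Assigns each subject to one of `k` folds so that per-fold class counts
#' differ from perfect proportionality by at most one subject per class.
#' Deterministic given the seed.
#'
#' @param labels factor (or coercible) of class labels.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return object of class `fold_plan`: `k`, `assignments` (integer fold
#'   index per subject), `seed`.
#' @export
make_stratified_folds <- function(labels, k = 5L, seed = 1L) {
  lab <- cog_factor(labels)
  k <- as.integer(k)
  tab <- table(lab)
  if (any(tab < k)) {
    stop("class(es) with fewer than k members: ",
         paste(names(tab)[tab < k], collapse = ", "))
  }
  set.seed(as.integer(seed))
  assignments <- integer(length(lab))
  for (lv in levels(lab)) {
    members <- which(lab == lv)
    m <- length(members)
    # m %% k folds receive one extra member; which folds get the extras is
    # itself randomized, then members are shuffled onto the fold ids.
    fold_ids <- rep_len(sample(k), m)
    assignments[members] <- sample(fold_ids)
  }
  structure(list(k = k, assignments = assignments, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Cross-validate the classifier
#'
#' Trains one network per fold on the remaining folds and evaluates it on
#' the held-out fold; every subject is validated exactly once.
#'
#' @param X feature matrix.
#' @param labels class labels.
#' @param plan a [make_stratified_folds()] plan.
#' @param hidden_sizes network architecture.
#' @param tc,lc training and loss configs; fold `i` trains with child seed
#'   `derive`d from `tc$seed` and the fold index.
#' @return list of class `cv_result`: `folds` (per fold: `params`,
#'   `history`, `confusion`, `recall_impaired`, `holdout` indices,
#'   `p_impaired` held-out probabilities) and `plan`.
#' @export
cross_validate <- function(X, labels, plan, hidden_sizes = 7L,
                           tc = train_config(), lc = focal_loss_config()) {
  stopifnot(inherits(plan, "fold_plan"))
  lab <- cog_factor(labels)
  stopifnot(nrow(X) == length(lab))
  y <- one_hot(lab)
  folds <- lapply(seq_len(plan$k), function(i) {
    hold <- which(plan$assignments == i)
    tr <- setdiff(seq_len(nrow(X)), hold)
    tci <- tc
    tci$seed <- derive_seed(tc$seed, paste0("fold-", i))
    fit <- train_network(X[tr, , drop = FALSE], y[tr, , drop = FALSE],
                         hidden_sizes = hidden_sizes, tc = tci, lc = lc)
    p <- forward(fit$params, X[hold, , drop = FALSE])
    pred <- cog_factor(ifelse(p[, "Impaired"] >= tc$threshold,
                              "Impaired", "Intact"))
    cm <- confusion_from_predictions(lab[hold], pred)
    list(params = fit$params, history = fit$history, confusion = cm,
         recall_impaired = recall_from_confusion(cm),
         holdout = hold, p_impaired = p[, "Impaired"])
  })
  structure(list(folds = folds, plan = plan), class = "cv_result")
}

recall_from_confusion <- function(cm) {
  if (cm$TP + cm$FN == 0) return(NA_real_)
  cm$TP / (cm$TP + cm$FN)
}

#' Select the best cross-validation fold
#'
#' Picks the fold whose model achieved the highest held-out recall for the
#' Impaired class; ties are broken by fewer Intact-class errors (false
#' positives), then by the lowest fold index.
#'
#' @param cv a `cv_result` (or plain list of fold results).
#' @return list with `fold` (index) and `params`.
#' @export
select_best_model <- function(cv) {
  folds <- if (inherits(cv, "cv_result")) cv$folds else cv
  stopifnot(length(folds) >= 1)
  recalls <- vapply(folds, function(f) f$recall_impaired, 1.0)
  fps <- vapply(folds, function(f) f$confusion$FP, 1.0)
  best <- order(-recalls, fps, seq_along(folds))[1]
  list(fold = best, params = folds[[best]]$params)
}

#' Confusion counts with Impaired as the positive class
#'
#' @param y_true,y_pred label vectors coercible via [cog_factor()].
#' @return object of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_from_predictions <- function(y_true, y_pred) {
  t_ <- cog_factor(y_true)
  p_ <- cog_factor(y_pred)
  stopifnot(length(t_) == length(p_))
  confusion_counts(
    TP = sum(t_ == "Impaired" & p_ == "Impaired"),
    FN = sum(t_ == "Impaired" & p_ == "Intact"),
    TN = sum(t_ == "Intact" & p_ == "Intact"),
    FP = sum(t_ == "Intact" & p_ == "Impaired")
  )
}

#' @rdname confusion_from_predictions
#' @param TP,FP,TN,FN non-negative integer counts.
#' @export
confusion_counts <- function(TP, FN, TN, FP) {
  stopifnot(TP >= 0, FN >= 0, TN >= 0, FP >= 0)
  structure(list(TP = as.integer(TP), FN = as.integer(FN),
                 TN = as.integer(TN), FP = as.integer(FP)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$TN, x$FP, x$FN, x$TP), 2, 2, byrow = TRUE,
              dimnames = list(paste("true", COG_LEVELS),
                              paste("pred", COG_LEVELS)))
  print(m)
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from confusion counts
#'
#' Per-class recall, precision and F1 (the Intact-class metrics are
#' obtained by swapping the positive class), micro accuracy, and macro
#' recall (unweighted mean of the two per-class recalls). Ratios with a
#' zero denominator are reported as `NA`, not zero.
#'
#' @param cm a `confusion_counts`.
#' @return list of class `class_metrics`.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_counts"))
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  stopifnot(total > 0)
  rec_imp <- safe_ratio(cm$TP, cm$TP + cm$FN)
  prec_imp <- safe_ratio(cm$TP, cm$TP + cm$FP)
  rec_int <- safe_ratio(cm$TN, cm$TN + cm$FP)
  prec_int <- safe_ratio(cm$TN, cm$TN + cm$FN)
  f1 <- function(p, r) {
    if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
    2 * p * r / (p + r)
  }
  macro <- if (is.na(rec_imp) || is.na(rec_int)) NA_real_ else
    mean(c(rec_imp, rec_int))
  structure(list(
    impaired = list(recall = rec_imp, precision = prec_imp,
                    f1 = f1(prec_imp, rec_imp)),
    intact = list(recall = rec_int, precision = prec_int,
                  f1 = f1(prec_int, rec_int)),
    accuracy = (cm$TP + cm$TN) / total,
    macro_recall = macro,
    confusion = cm
  ), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, digits = 2, ...) {
  r2 <- function(v) formatC(round(v, digits), format = "f", digits = digits)
  cat("Impaired:  recall", r2(x$impaired$recall),
      " precision", r2(x$impaired$precision),
      " F1", r2(x$impaired$f1), "\n")
  cat("Intact:    recall", r2(x$intact$recall),
      " precision", r2(x$intact$precision),
      " F1", r2(x$intact$f1), "\n")
  cat("Accuracy", r2(x$accuracy), "  macro recall", r2(x$macro_recall), "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the sorted unique predicted
#' probabilities (plus sentinels), records TPR/FPR at each, and integrates
#' by the trapezoidal rule. The resulting AUC equals the rank statistic:
#' the probability that a random Impaired subject receives a higher score
#' than a random Intact subject, ties counted one half.
#'
#' @param y_true labels coercible via [cog_factor()]; both classes must be
#'   present.
#' @param p_impaired predicted probability of the Impaired class.
#' @return object of class `roc_curve`: `thresholds` (descending), `tpr`,
#'   `fpr`, `auc`.
#' @export
roc_and_auc <- function(y_true, p_impaired) {
  lab <- cog_factor(y_true)
  stopifnot(length(lab) == length(p_impaired))
  pos <- lab == "Impaired"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  thr <- c(Inf, sort(unique(p_impaired), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(p_impaired[pos] >= t), 1.0)
  fpr <- vapply(thr, function(t) mean(p_impaired[!pos] >= t), 1.0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve over", length(x$thresholds), "thresholds, AUC =",
      sprintf("%.4f\n", x$auc))
  invisible(x)
}

#' Misclassification by longitudinal transition class
#'
#' Tabulates, for each of the four baseline-to-follow-up trajectory
#' classes, how many subjects there are and how many the model
#' misclassified (predicted follow-up label differs from the true one).
#'
#' @param transition_classes factor from [assign_transition_class()].
#' @param y_true,y_pred follow-up labels.
#' @return data.frame with `class`, `count`, `misclassified`.
#' @export
transition_error_table <- function(transition_classes, y_true, y_pred) {
  tc <- factor(as.character(transition_classes),
               levels = TRANSITION_LEVELS)
  t_ <- cog_factor(y_true)
  p_ <- cog_factor(y_pred)
  stopifnot(length(tc) == length(t_), length(t_) == length(p_))
  wrong <- t_ != p_
  data.frame(
    class = TRANSITION_LEVELS,
    count = as.integer(table(tc)),
    misclassified = vapply(TRANSITION_LEVELS,
                           function(cl) sum(wrong[tc == cl]), 1L,
                           USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
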