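#' Label a cohort at a flow cutoff
#'
#' The positive class is flow dysfunction: access flow at or below the
#' cutoff. The guideline surveillance cutoff is 600 mL/min; 750 mL/min is
#' the first-level screen.
#'
#' @param features Feature table from [feature_table()].
#' @param flows Access flows (mL/min), defaults to `features$flow_mL_min`.
#' @param cutoff Cutoff in mL/min.
#' @return A `labeled_cohort` object: `patient_id`, `x` (matrix of the five
#'   harmonic ratios), `flow_mL_min`, `cutoff_mL_min`, `label` (factor with
#'   levels `normal`, `dysfunction`), and class counts `n_pos`, `n_neg`.
#' @export
label_cohort <- function(features, flows = features$flow_mL_min, cutoff) {
  stopifnot(nrow(features) == length(flows), all(flows > 0), cutoff > 0)
  x <- as.matrix(features[, hr_feature_names()])
  stopifnot(all(is.finite(x)))
  pos <- flows <= cutoff
  if (!any(pos)) stop("no dysfunction cases at cutoff ", cutoff, " mL/min")
  if (all(pos)) stop("no normal cases at cutoff ", cutoff, " mL/min")
  label <- factor(ifelse(pos, "dysfunction", "normal"),
                  levels = c("normal", "dysfunction"))
  structure(list(patient_id = features$patient_id, x = x,
                 flow_mL_min = flows, cutoff_mL_min = cutoff,
                 label = label, n_pos = sum(pos), n_neg = sum(!pos)),
            class = "labeled_cohort")
}

#' SVM configuration
#'
#' @param cost Margin penalty C (default 1).
#' @param gamma RBF kernel width; `NULL` (default) uses the reciprocal of
#'   (feature count x mean feature variance after standardization), i.e.
#'   `1/ncol(x)` on z-scored features.
#' @param scale Standardize each feature (z-score fitted on the training
#'   data only) before the kernel; default `TRUE` — the raw harmonic ratios
#'   span unequal ranges.
#' @return A list of SVM settings.
#' @export
svm_config <- function(cost = 1, gamma = NULL, scale = TRUE) {
  stopifnot(cost > 0, is.null(gamma) || gamma > 0)
  list(cost = cost, gamma = gamma, scale = scale)
}

.fit_svm <- function(x, label, config) {
  zero_var <- which(apply(x, 2, stats::var) == 0)
  if (length(zero_var))
    stop("degenerate features with zero variance: ",
         paste(colnames(x)[zero_var], collapse = ", "))
  gamma <- if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
  e1071::svm(x, label, type = "C-classification", kernel = "radial",
             cost = config$cost, gamma = gamma, scale = config$scale)
}

# Signed decision values oriented so positive = dysfunction side.
.decision_values <- function(fit, x) {
  pr <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  flip <- if (grepl("^dysfunction", colnames(dv)[1])) 1 else -1
  list(pred = pr, dv = flip * as.numeric(dv[, 1]))
}

#' Train the RBF-kernel SVM on a labelled cohort
#'
#' Fits a maximum-margin classifier with a radial-basis-function kernel on
#' the five harmonic ratios and exports each patient's signed distance to
#' the separating hyperplane (positive = dysfunction side), the quantity
#' plotted against measured flow in decision-function diagnostics.
#'
#' @param cohort A `labeled_cohort`.
#' @param config From [svm_config()].
#' @return An `svm_fit` object: `model` (the e1071 fit), `decision_values`,
#'   `train_predictions`, `cohort`.
#' @export
train_svm <- function(cohort, config = svm_config()) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  fit <- .fit_svm(cohort$x, cohort$label, config)
  d <- .decision_values(fit, cohort$x)
  structure(list(model = fit, decision_values = d$dv,
                 train_predictions = d$pred, cohort = cohort,
                 config = config),
            class = "svm_fit")
}

#' Stratified k-fold cross-validation
#'
#' Partitions each class separately into `k` folds (deterministic under
#' `seed`), trains on k-1 folds, predicts the held-out fold, and pools the
#' out-of-fold predictions into a single confusion matrix. When the smaller
#' class has fewer than `k` members the fold count falls back to that class
#' size (each fold then holds one member of the smaller class — leave-pair-
#' out in the balanced limit) with a warning.
#'
#' @param cohort A `labeled_cohort`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param config From [svm_config()].
#' @return A `cv_result` object: `confusion` (a `confusion_matrix`),
#'   `decision_values` (out-of-fold, oriented positive = dysfunction),
#'   `predictions`, `label`, `fold`, `k`, `seed`.
#' @export
cross_validate <- function(cohort, k = 10, seed = 1, config = svm_config()) {
  stopifnot(inherits(cohort, "labeled_cohort"), k >= 2)
  n_min <- min(cohort$n_pos, cohort$n_neg)
  if (n_min < k) {
    warning("smaller class (n = ", n_min, ") has fewer members than k = ",
            k, "; falling back to ", n_min, " folds (leave-pair-out limit)")
    k <- n_min
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(cohort$label)
  fold <- integer(n)
  for (cl in levels(cohort$label)) {
    idx <- which(cohort$label == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  pred <- factor(rep(NA_character_, n), levels = levels(cohort$label))
  dv <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- .fit_svm(cohort$x[!test, , drop = FALSE],
                    droplevels_keep(cohort$label[!test]), config)
    d <- .decision_values(fit, cohort$x[test, , drop = FALSE])
    pred[test] <- d$pred
    dv[test] <- d$dv
  }
  structure(list(confusion = confusion_matrix(cohort$label, pred),
                 decision_values = dv, predictions = pred,
                 label = cohort$label, fold = fold, k = k, seed = seed),
            class = "cv_result")
}

# keep both factor levels even if a training split lost one (then svm errors,
# which is the right failure mode)
droplevels_keep <- function(f) factor(f, levels = levels(f))

#' Confusion matrix for dysfunction detection
#'
#' @param truth Factor of true labels (`normal`/`dysfunction`).
#' @param pred Factor of predicted labels.
#' @return A `confusion_matrix` object with counts `tp`, `fn`, `fp`, `tn`
#'   (positive class = dysfunction).
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == "dysfunction" & pred == "dysfunction")
  fn <- sum(truth == "dysfunction" & pred == "normal")
  fp <- sum(truth == "normal" & pred == "dysfunction")
  tn <- sum(truth == "normal" & pred == "normal")
  confusion_counts(tp, fn, fp, tn)
}

#' Build a confusion matrix from counts
#'
#' @param tp,fn,fp,tn Non-negative counts; positive class = dysfunction
#'   (flow at or below the cutoff).
#' @return A `confusion_matrix` object.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0, tp + fn + fp + tn > 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_matrix")
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/total` and positive predictive value `tp/(tp+fp)`, as
#' percentages rounded to one decimal for report parity. A metric whose
#' denominator is zero is returned as `NA` with its name listed in the
#' `undefined` field.
#'
#' @param cm A `confusion_matrix`.
#' @return A list: `sensitivity_pct`, `specificity_pct`, `accuracy_pct`,
#'   `ppv_pct`, `undefined` (character vector).
#' @export
#' @examples
#' confusion_metrics(confusion_counts(tp = 10, fn = 1, fp = 0, tn = 34))
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pct <- function(num, den) if (den == 0) NA_real_ else
    round(100 * num / den, 1)
  out <- list(sensitivity_pct = pct(cm$tp, cm$tp + cm$fn),
              specificity_pct = pct(cm$tn, cm$tn + cm$fp),
              accuracy_pct = pct(cm$tp + cm$tn, cm$tp + cm$fn + cm$fp + cm$tn),
              ppv_pct = pct(cm$tp, cm$tp + cm$fp))
  out$undefined <- names(out)[vapply(out[1:4], is.na, logical(1))]
  out
}

#' ROC analysis of cross-validated decision values
#'
#' Sweeps a threshold over the signed decision values at a fixed label
#' cutoff and computes the ROC curve and its area (trapezoidal rule; ties
#' handled by midpoint ranks, so the AUC equals the probability that a
#' random dysfunction case outranks a random normal case).
#'
#' @param label Factor of true labels (`normal`/`dysfunction`), e.g.
#'   `cv$label`.
#' @param decision_values Signed scores, larger = more dysfunction-like,
#'   e.g. `cv$decision_values` from [cross_validate()].
#' @return A `roc_result`: `auc`, and `curve` (data.frame of `threshold`,
#'   `fpr`, `tpr`).
#' @export
roc_analysis <- function(label, decision_values) {
  stopifnot(length(label) == length(decision_values))
  if (length(unique(label)) < 2)
    stop("ROC analysis needs both classes present")
  r <- pROC::roc(response = label, predictor = decision_values,
                 levels = c("normal", "dysfunction"), direction = "<",
                 quiet = TRUE)
  curve <- data.frame(threshold = r$thresholds,
                      fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  structure(list(auc = as.numeric(pROC::auc(r)), curve = curve),
            class = "roc_result")
}

#' Cross-validated evaluation across a set of detection cutoffs
#'
#' Relabels the cohort at each cutoff, runs stratified k-fold
#' cross-validation, and reports per-cutoff confusion metrics, AUC and
#' out-of-fold decision values. Also emits the two-level screening
#' recommendation (first-level 750 mL/min, second-level 600 mL/min) used
#' when no single cutoff is optimal.
#'
#' @param features Feature table from [feature_table()].
#' @param flows Access flows (mL/min).
#' @param cutoffs Vector of cutoffs (mL/min), default
#'   `c(500, 600, 650, 750)`.
#' @param k Folds (default 10).
#' @param seed Integer seed.
#' @param config From [svm_config()].
#' @return A `threshold_sweep` object: `reports` (named list per cutoff:
#'   `cutoff`, `confusion`, metrics, `auc`, `decision_values`, `k`, `seed`,
#'   or an `error` message when a cutoff leaves one class empty) and
#'   `recommendation`.
#' @export
threshold_sweep <- function(features, flows = features$flow_mL_min,
                            cutoffs = c(500, 600, 650, 750), k = 10,
                            seed = 1, config = svm_config()) {
  reports <- lapply(cutoffs, function(co) {
    tryCatch({
      cohort <- label_cohort(features, flows, co)
      cv <- suppressWarnings(cross_validate(cohort, k = k, seed = seed,
                                            config = config))
      roc <- roc_analysis(cv$label, cv$decision_values)
      c(list(cutoff = co, confusion = cv$confusion),
        confusion_metrics(cv$confusion),
        list(auc = roc$auc, decision_values = cv$decision_values,
             patient_id = cohort$patient_id, k = cv$k, seed = seed))
    }, error = function(e) list(cutoff = co, error = conditionMessage(e)))
  })
  names(reports) <- as.character(cutoffs)
  structure(list(reports = reports,
                 recommendation = list(first_level_mL_min = 750,
                                       second_level_mL_min = 600)),
            class = "threshold_sweep")
}
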