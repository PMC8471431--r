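test_that("cohort labelling counts dysfunction cases at each cutoff", {
  set.seed(1)
  flows <- c(rep(350, 11), rep(700, 10), rep(1000, 24))
  ft <- features_from_matrix(matrix(runif(45 * 5), 45, 5), flows)
  c600 <- label_cohort(ft, cutoff = 600)
  expect_equal(c(c600$n_pos, c600$n_neg), c(11, 34))
  c750 <- label_cohort(ft, cutoff = 750)
  expect_equal(c(c750$n_pos, c750$n_neg), c(21, 24))
  expect_equal(levels(c600$label), c("normal", "dysfunction"))
  expect_error(label_cohort(ft, cutoff = 100), "no dysfunction")
  expect_error(label_cohort(ft, cutoff = 2000), "no normal")
})

test_that("the RBF-SVM fits separable data and exports decision values", {
  set.seed(42)
  n <- 30
  x <- rbind(matrix(rnorm(n * 5, 0.4, 0.05), n, 5),
             matrix(rnorm(n * 5, 1.6, 0.05), n, 5))
  flows <- c(rep(900, n), rep(300, n))
  ft <- features_from_matrix(x, flows)
  fit <- train_svm(label_cohort(ft, cutoff = 600))
  expect_equal(mean(fit$train_predictions == fit$cohort$label), 1)
  # decision values are oriented: dysfunction side positive
  expect_true(all(fit$decision_values[flows <= 600] > 0))
  expect_true(all(fit$decision_values[flows > 600] < 0))
  # duplicating every row leaves the decision boundary unchanged
  ft2 <- features_from_matrix(rbind(x, x), c(flows, flows))
  fit2 <- train_svm(label_cohort(ft2, cutoff = 600))
  p1 <- predict(fit$model, x)
  p2 <- predict(fit2$model, x)
  expect_equal(as.character(p1), as.character(p2))
  # zero-variance feature is refused by name
  x_bad <- x; x_bad[, 2] <- 1
  expect_error(train_svm(label_cohort(features_from_matrix(x_bad, flows),
                                      cutoff = 600)), "hr32")
})

test_that("stratified cross-validation is deterministic and pools folds", {
  set.seed(3)
  x <- rbind(matrix(rnorm(12 * 5, 0.3, 0.05), 12, 5),
             matrix(rnorm(33 * 5, 1.5, 0.05), 33, 5))
  flows <- c(rep(400, 12), rep(1000, 33))
  cohort <- label_cohort(features_from_matrix(x, flows), cutoff = 600)
  cv1 <- cross_validate(cohort, k = 10, seed = 11)
  cv2 <- cross_validate(cohort, k = 10, seed = 11)
  expect_identical(unlist(cv1$confusion), unlist(cv2$confusion))
  expect_identical(cv1$decision_values, cv2$decision_values)
  # well-separated classes: no out-of-fold errors
  expect_equal(cv1$confusion$fp + cv1$confusion$fn, 0)
  expect_equal(cv1$confusion$tp, 12)
  # every fold contains both classes
  expect_true(all(table(cv1$fold, cohort$label) > 0))
  # fall back when the smaller class is below k
  small <- label_cohort(features_from_matrix(x[c(1:5, 13:45), ],
                                             flows[c(1:5, 13:45)]),
                        cutoff = 600)
  expect_warning(cv3 <- cross_validate(small, k = 10, seed = 2),
                 "fewer members")
  expect_equal(cv3$k, 5)
})

test_that("confusion metrics reproduce the published validation table", {
  m600 <- confusion_metrics(confusion_counts(tp = 10, fn = 1, fp = 0,
                                             tn = 34))
  expect_equal(m600$sensitivity_pct, 90.9)
  expect_equal(m600$specificity_pct, 100.0)
  expect_equal(m600$accuracy_pct, 97.8)
  expect_equal(m600$ppv_pct, 100.0)
  m750 <- confusion_metrics(confusion_counts(tp = 20, fn = 1, fp = 0,
                                             tn = 24))
  expect_equal(m750$sensitivity_pct, 95.2)
  expect_equal(m750$specificity_pct, 100.0)
  expect_equal(m750$accuracy_pct, 97.8)
  perfect <- confusion_metrics(confusion_counts(7, 0, 0, 13))
  expect_equal(unlist(perfect[1:4]), rep(100, 4), ignore_attr = TRUE)
  none_pos <- confusion_metrics(confusion_counts(0, 0, 2, 8))
  expect_true(is.na(none_pos$sensitivity_pct))
  expect_true("sensitivity_pct" %in% none_pos$undefined)
})

test_that("ROC analysis matches the brute-force rank statistic", {
  lab <- factor(c(rep("dysfunction", 4), rep("normal", 6)),
                levels = c("normal", "dysfunction"))
  perfect <- c(4, 3, 5, 6, -1, 0, 1, 2, -2, 1.5)
  expect_equal(roc_analysis(lab, perfect)$auc, 1)
  expect_equal(roc_analysis(lab, rep(0, 10))$auc, 0.5)
  for (seed in 1:25) {
    set.seed(seed)
    n_pos <- sample(2:10, 1); n_neg <- sample(2:10, 1)
    lab <- factor(c(rep("dysfunction", n_pos), rep("normal", n_neg)),
                  levels = c("normal", "dysfunction"))
    dv <- round(rnorm(n_pos + n_neg), 1)  # rounding forces ties
    expect_equal(roc_analysis(lab, dv)$auc,
                 brute_auc(dv[1:n_pos], dv[-(1:n_pos)]),
                 tolerance = 1e-12)
  }
  expect_error(roc_analysis(factor(rep("normal", 4),
                                   levels = c("normal", "dysfunction")),
                            rnorm(4)), "both classes")
})

test_that("the cutoff sweep reports per-cutoff metrics and partial failures", {
  set.seed(9)
  x <- rbind(matrix(rnorm(12 * 5, 0.3, 0.08), 12, 5),
             matrix(rnorm(33 * 5, 1.5, 0.08), 33, 5))
  flows <- c(runif(12, 300, 500), runif(33, 800, 1400))
  ft <- features_from_matrix(x, flows)
  sw <- threshold_sweep(ft, cutoffs = c(250, 600), k = 5, seed = 4)
  expect_match(sw$reports[["250"]]$error, "no dysfunction")
  rep600 <- sw$reports[["600"]]
  expect_equal(rep600$accuracy_pct, 100)
  expect_equal(sw$recommendation$first_level_mL_min, 750)
  expect_equal(sw$recommendation$second_level_mL_min, 600)
  # degenerate sweep of one cutoff equals a single cross-validation run
  cv <- suppressWarnings(cross_validate(label_cohort(ft, cutoff = 600),
                                        k = 5, seed = 4))
  expect_identical(unlist(rep600$confusion), unlist(cv$confusion))
  expect_identical(rep600$decision_values, cv$decision_values)
})
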