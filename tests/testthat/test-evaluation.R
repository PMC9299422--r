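test_that("fold assignment is stratified, exhaustive, disjoint and seeded", {
  man <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    paf_label = rep(c(TRUE, FALSE), each = 5)
  )
  f <- assign_folds(man, k = 5, seed = 3)
  expect_setequal(f$patient_id, man$patient_id)
  per_fold <- table(f$fold, man$paf_label[match(f$patient_id, man$patient_id)])
  expect_true(all(per_fold == 1)) # 1 pAF + 1 control per fold
  expect_identical(f, assign_folds(man, k = 5, seed = 3))
  expect_false(identical(f$fold, assign_folds(man, k = 5, seed = 4)$fold))
  expect_error(assign_folds(man[1:6, ], k = 5), "per class")

  man2 <- tibble::tibble(
    patient_id = sprintf("Q%02d", 1:23),
    paf_label = c(rep(TRUE, 9), rep(FALSE, 14))
  )
  f2 <- assign_folds(man2, k = 5, seed = 1)
  sizes <- table(f2$fold, man2$paf_label[match(f2$patient_id, man2$patient_id)])
  expect_lte(diff(range(sizes[, 1])), 1) # within-class sizes differ by <= 1
  expect_lte(diff(range(sizes[, 2])), 1)
})

test_that("AUROC equals the pairwise comparator, with ties at one half", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(auroc(rep(0.4, 8), rep(c(0, 1), 4)), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), class = "holterpaf_single_class")

  for (trial in 1:30) {
    set.seed(trial)
    n <- sample(4:50, 1)
    scores <- sample(round(runif(n), 2)) # duplicates force tie handling
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    expect_equal(auroc(scores, labels), brute_auroc(scores, labels))
    expect_equal(
      auroc(scores, labels),
      as.numeric(suppressMessages(pROC::auc(labels, scores,
        direction = "<", quiet = TRUE)))
    )
  }
})

test_that("the Youden cutoff maximises sensitivity + specificity exactly", {
  cut <- optimal_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(cut, 0.8) # canonical output of the separable example
  cm <- confusion_metrics(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), cut)
  expect_equal(cm$sensitivity + cm$specificity, 2)
  expect_error(optimal_cutoff(1:4, rep(1, 4)), class = "holterpaf_single_class")

  for (trial in 1:30) {
    set.seed(trial + 100)
    n <- sample(5:50, 1)
    scores <- round(runif(n), 2)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    cut <- optimal_cutoff(scores, labels)
    cm <- confusion_metrics(scores, labels, cut)
    expect_equal(cm$sensitivity + cm$specificity,
      brute_best_youden(scores, labels))
  }
})

test_that("confusion metrics follow the contingency table, NA on empty cells", {
  # TP 3, FP 7, FN 2, TN 88
  scores <- c(rep(0.9, 3), rep(0.9, 7), rep(0.1, 2), rep(0.1, 88))
  labels <- c(rep(1, 3), rep(0, 7), rep(1, 2), rep(0, 88))
  cm <- confusion_metrics(scores, labels, 0.5)
  expect_equal(cm$sensitivity, 0.6)
  expect_equal(cm$specificity, 88 / 95, tolerance = 1e-12)
  expect_equal(round(cm$specificity, 3), 0.926)
  expect_equal(cm$ppv, 0.3)
  expect_equal(round(cm$npv, 3), 0.978)

  all_good <- confusion_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(all_good[c("sensitivity", "specificity", "ppv", "npv")]),
    c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))

  none_pos <- confusion_metrics(c(0.1, 0.2), c(1, 0), 0.5)
  expect_true(is.na(none_pos$ppv)) # no predicted positives: absent, not zero
})

test_that("F-beta follows its closed form, including conventions", {
  fs <- f_scores(1, 1)
  expect_equal(fs$f1, 1)
  expect_equal(fs$f2, 1)
  expect_equal(f_scores(0.5, 1.0)$f2, 5 * 0.5 / 3, tolerance = 1e-12)
  expect_equal(f_scores(0, 0)$f1, 0)
  # recomputation identity holds to machine precision on random panels
  for (trial in 1:20) {
    set.seed(trial)
    p <- runif(1)
    s <- runif(1)
    fs <- f_scores(p, s)
    expect_equal(fs$f1, 2 * p * s / (p + s), tolerance = 1e-12)
    expect_equal(fs$f2, 5 * p * s / (4 * p + s), tolerance = 1e-12)
  }
})

test_that("fold CIs follow the Student-t formula", {
  same <- fold_ci(rep(0.8, 5))
  expect_equal(same$ci_low, 0.8)
  expect_equal(same$ci_high, 0.8)

  two <- fold_ci(c(0.8, 0.9))
  expect_equal(two$estimate, 0.85)
  expect_equal(two$ci_high - two$estimate, two$estimate - two$ci_low)

  vals <- c(0.80, 0.82, 0.84, 0.86, 0.88)
  ci <- fold_ci(vals)
  half <- qt(0.975, 4) * sd(vals) / sqrt(5)
  expect_equal(ci$estimate, 0.84)
  expect_equal(ci$ci_low, 0.84 - half, tolerance = 1e-12)
  expect_equal(ci$ci_high, 0.84 + half, tolerance = 1e-12)
  expect_error(fold_ci(0.8), "at least 2")
})

test_that("bootstrap CIs are seeded, degenerate-safe and roughly calibrated", {
  set.seed(1)
  scores <- c(rnorm(40, 1), rnorm(60, 0))
  labels <- rep(c(1, 0), c(40, 60))
  ci1 <- bootstrap_ci(auroc, scores, labels, n_boot = 300, seed = 5)
  ci2 <- bootstrap_ci(auroc, scores, labels, n_boot = 300, seed = 5)
  expect_identical(ci1, ci2)
  expect_lte(ci1$ci_low, ci1$estimate)
  expect_gte(ci1$ci_high, ci1$estimate)

  flat <- bootstrap_ci(auroc, rep(0.5, 20), rep(c(0, 1), 10), n_boot = 100, seed = 2)
  expect_equal(flat$ci_low, 0.5)
  expect_equal(flat$ci_high, 0.5)

  # coverage of the percentile interval for AUROC at n = 200, 100 replications
  true_auc <- pnorm(1 / sqrt(2)) # two unit-variance Gaussians, delta = 1
  hits <- 0L
  for (r in 1:100) {
    set.seed(1000 + r)
    s <- c(rnorm(60, 1), rnorm(140, 0))
    l <- rep(c(1, 0), c(60, 140))
    ci <- bootstrap_ci(auroc, s, l, n_boot = 300, seed = r)
    hits <- hits + (ci$ci_low <= true_auc && true_auc <= ci$ci_high)
  }
  # binomial 99.9 percent acceptance band around nominal 95 percent coverage
  expect_gte(hits, 86)
})

test_that("elapsed-time detection rates count strata correctly", {
  man <- tibble::tibble(
    patient_id = sprintf("P%d", 1:7),
    paf_label = c(rep(TRUE, 6), FALSE),
    index_date = as.Date("2024-01-01") -
      round(c(1, 2, 5, 8, 14, 40, NA) * 30.44),
    exam_date = as.Date("2024-01-01")
  )
  preds <- tibble::tibble(
    patient_id = man$patient_id,
    score = c(0.9, 0.2, 0.8, 0.9, 0.1, 0.9, 0.5),
    label = man$paf_label
  )
  el <- elapsed_time_sensitivity(preds, man, cutoff = 0.5, t_list = c(3, 6, 12, 36))
  g3 <- el[el$t_months == 3 & el$stratum == "gt", ]
  l3 <- el[el$t_months == 3 & el$stratum == "lt", ]
  expect_equal(g3$n, 4L) # elapsed 5, 8, 14, 40 months
  expect_equal(g3$rate, 3 / 4) # P5 (14 months) missed
  expect_equal(l3$n, 2L)
  expect_equal(l3$rate, 1 / 2)
  # strata partition the pAF patients at every cutoff
  for (tm in c(3, 6, 12, 36)) {
    expect_equal(sum(el$n[el$t_months == tm]), 6L)
  }
  g36 <- el[el$t_months == 36 & el$stratum == "gt", ]
  expect_equal(g36$n, 1L)
  expect_equal(g36$rate, 1)
})

test_that("ROC points step monotonically from (0,0) to (1,1)", {
  set.seed(9)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- c(0, 1)
  roc <- roc_points(scores, labels)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})
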