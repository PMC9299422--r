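#' Stratified patient-level fold assignment
#'
#' Randomly assigns every patient to one of `k` folds, stratified by pAF
#' label so fold sizes within each class differ by at most one. All segments
#' of a patient share its fold: the test fold never contains data from a
#' patient seen in training.
#'
#' @param manifest Cohort manifest (`patient_id`, `paf_label`).
#' @param k Number of folds (default 5).
#' @param seed Seed; the assignment is deterministic given it.
#' @return Tibble `patient_id`, `fold` (integer in `1..k`).
#' @export
assign_folds <- function(manifest, k = 5, seed = 1L) {
  counts <- table(manifest$paf_label)
  if (length(counts) < 2L || any(counts < k)) {
    abort(sprintf("need at least %d patients per class for %d folds", k, k))
  }
  withr::with_seed(seed, {
    fold <- integer(nrow(manifest))
    for (lab in c(TRUE, FALSE)) {
      idx <- which(manifest$paf_label == lab)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  tibble::tibble(patient_id = manifest$patient_id, fold = fold)
}

#' Area under the ROC curve
#'
#' The rank-based Mann-Whitney estimator: the probability that a random
#' positive outranks a random negative, ties counted one half.
#'
#' @param scores Numeric scores (higher = more pAF-like).
#' @param labels Binary labels (logical or 0/1).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be present", class = "holterpaf_single_class")
  }
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-style optimal cutoff
#'
#' Scans the observed scores as candidate thresholds (prediction positive iff
#' `score >= cutoff`) and returns the one maximising sensitivity +
#' specificity. Ties are broken toward higher sensitivity, then toward the
#' lower threshold.
#'
#' @inheritParams auroc
#' @return The selected cutoff.
#' @export
optimal_cutoff <- function(scores, labels) {
  y <- as.logical(labels)
  if (!any(y) || all(y)) {
    abort("both classes must be present", class = "holterpaf_single_class")
  }
  cand <- sort(unique(scores))
  best <- NULL
  for (cut in cand) {
    pred <- scores >= cut
    sens <- sum(pred & y) / sum(y)
    spec <- sum(!pred & !y) / sum(!y)
    j <- sens + spec
    if (is.null(best) || j > best$j + 1e-12 ||
      (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(cut = cut, j = j, sens = sens)
    }
  }
  best$cut
}

#' Confusion-matrix metrics at a cutoff
#'
#' Prediction is positive iff `score >= cutoff`. Ratios with a zero
#' denominator are reported as `NA`, not zero.
#'
#' @inheritParams auroc
#' @param cutoff Decision threshold.
#' @return Named list: `sensitivity`, `specificity`, `ppv`, `npv`, plus the
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_metrics <- function(scores, labels, cutoff) {
  y <- as.logical(labels)
  pred <- scores >= cutoff
  tp <- sum(pred & y)
  fp <- sum(pred & !y)
  fn <- sum(!pred & y)
  tn <- sum(!pred & !y)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  list(
    sensitivity = ratio(tp, tp + fn), specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

#' F1 and F2 scores from precision and sensitivity
#'
#' `F_beta = (1 + beta^2) * ppv * sens / (beta^2 * ppv + sens)`, with the
#' convention that the score is 0 when both inputs are 0.
#'
#' @param ppv Positive predictive value (precision).
#' @param sensitivity Sensitivity (recall).
#' @return Named list `f1`, `f2`.
#' @export
f_scores <- function(ppv, sensitivity) {
  fbeta <- function(beta) {
    den <- beta^2 * ppv + sensitivity
    if (is.na(den)) return(NA_real_)
    if (den == 0) return(0)
    (1 + beta^2) * ppv * sensitivity / den
  }
  list(f1 = fbeta(1), f2 = fbeta(2))
}

#' t-based confidence interval over cross-validation folds
#'
#' Mean of the per-fold metric values with a Student-t 95 percent interval:
#' `mean +/- t(k-1, 0.975) * SD / sqrt(k)`.
#'
#' @param values Per-fold metric values (`k >= 2`).
#' @param level Confidence level.
#' @return List `estimate`, `ci_low`, `ci_high`.
#' @export
fold_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  k <- length(values)
  if (k < 2L) abort("fold_ci needs at least 2 fold values")
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, df = k - 1) * sd(values) / sqrt(k)
  list(estimate = m, ci_low = m - half, ci_high = m + half)
}

#' Percentile bootstrap confidence interval over patients
#'
#' Resamples patients with replacement `n_boot` times, recomputing the metric
#' on each replicate. Replicates missing a class are redrawn (bounded
#' retries); the interval is the 2.5/97.5 percentile range. Deterministic
#' given the seed.
#'
#' @param metric_fn `function(scores, labels)` returning a scalar.
#' @inheritParams auroc
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Seed.
#' @param level Confidence level.
#' @return List `estimate`, `ci_low`, `ci_high`, `n_boot`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, n_boot = 1000, seed = 1L,
                         level = 0.95) {
  y <- as.logical(labels)
  n <- length(scores)
  point <- metric_fn(scores, y)
  withr::with_seed(seed, {
    reps <- numeric(n_boot)
    n_failed <- 0L
    for (b in seq_len(n_boot)) {
      val <- NA_real_
      for (try in 1:20) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) < 2L) next
        val <- tryCatch(metric_fn(scores[idx], y[idx]), error = function(e) NA_real_)
        if (!is.na(val)) break
      }
      if (is.na(val)) n_failed <- n_failed + 1L
      reps[b] <- val
    }
  })
  if (n_failed > n_boot / 2) {
    abort("metric undefined on more than half the bootstrap replicates")
  }
  qs <- quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE,
    names = FALSE)
  list(estimate = point, ci_low = qs[1], ci_high = qs[2], n_boot = n_boot)
}

#' Detection rate by elapsed time from pAF diagnosis
#'
#' Among pAF patients only, splits the cohort at each cutoff `T` (months from
#' the index date — first AF documentation — to the Holter exam; months are
#' 30.44 days) and reports the sensitivity at the chosen score cutoff within
#' the `> T` and `< T` strata. Patients with elapsed time exactly `T` join
#' the `< T` stratum. Empty strata report `NA` with count 0.
#'
#' @param predictions Tibble `patient_id`, `score`, `label`.
#' @param manifest Manifest with `index_date`, `exam_date`.
#' @param cutoff Score cutoff defining detection.
#' @param t_list Elapsed-time cutoffs in months.
#' @param days_per_month Month length convention (default 30.44).
#' @return Tibble `t_months`, `stratum`, `n`, `n_detected`, `rate`.
#' @export
elapsed_time_sensitivity <- function(predictions, manifest, cutoff,
                                     t_list = c(3, 6, 12, 36),
                                     days_per_month = 30.44) {
  df <- dplyr::inner_join(
    predictions[as.logical(predictions$label), ],
    manifest[, c("patient_id", "index_date", "exam_date")],
    by = "patient_id"
  )
  df$elapsed_months <- as.numeric(df$exam_date - df$index_date) / days_per_month
  df$detected <- df$score >= cutoff
  rows <- lapply(t_list, function(tm) {
    above <- df[df$elapsed_months > tm, ]
    below <- df[df$elapsed_months <= tm, ]
    mk <- function(d, tag) {
      tibble::tibble(
        t_months = tm, stratum = tag, n = nrow(d),
        n_detected = sum(d$detected),
        rate = if (nrow(d) == 0L) NA_real_ else mean(d$detected)
      )
    }
    dplyr::bind_rows(mk(above, "gt"), mk(below, "lt"))
  })
  dplyr::bind_rows(rows)
}

metric_panel <- function(scores, labels, cutoff) {
  cm <- confusion_metrics(scores, labels, cutoff)
  fs <- f_scores(cm$ppv, cm$sensitivity)
  c(
    auroc = auroc(scores, labels),
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    ppv = cm$ppv, npv = cm$npv, f1 = fs$f1, f2 = fs$f2
  )
}

subsample_training_segments <- function(meta, per_patient, seed) {
  if (!is.finite(per_patient)) return(seq_len(nrow(meta)))
  withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(meta)), meta$patient_id), function(idx) {
      if (length(idx) <= per_patient) idx else sort(sample(idx, per_patient))
    }), use.names = FALSE)
  })
}

#' Run the full two-stage experiment on a cohort
#'
#' Orchestrates the complete protocol: preprocessing under the chosen
#' setting, patient-level stratified k-fold cross-validation, per-fold
#' segment-encoder training, latent aggregation, patient-level boosting,
#' the SVE-burden baseline on the identical patient folds, the segment-level
#' (encoder-only) ablation, fold-based confidence intervals for the model,
#' bootstrap confidence intervals for the baseline, and the elapsed-time
#' sensitivity table at the Youden-style cutoff.
#'
#' @param manifest Cohort manifest tibble with resolved paths.
#' @param setting 1 (keep SVE segments) or 2 (sinus rhythm only).
#' @param encoder An [encoder_config()].
#' @param gbm A [gbm_config()].
#' @param k Number of folds.
#' @param n_bins Temporal bins for [aggregate_latents()].
#' @param stft_window,stft_hop STFT parameters.
#' @param period `"ALL"`, `"DAY"` or `"NIGHT"`: restrict segments to a
#'   diurnal period before both training stages (folds stay identical to the
#'   all-day run, since they depend only on the manifest and seed).
#' @param train_segments_per_patient Cap on segments per patient used to fit
#'   the encoder (all surviving segments are still scored and aggregated).
#' @param n_boot Bootstrap replicates for the baseline CI.
#' @param seed Master seed; folds, subsampling and both learners derive
#'   their seeds from it.
#' @param baseline Compute the SVE-burden baseline?
#' @return Object of class `paf_experiment`: list with `predictions`
#'   (patient-level tibble `patient_id,score,label,fold,burden`),
#'   `fold_metrics`, `report` (tidy metric panel with CIs), `segment_auroc`
#'   (per-fold encoder-only AUROC), `elapsed` (detection-rate table),
#'   `cutoff`, `roc` and the resolved configuration.
#' @export
run_experiment <- function(manifest, setting = 1,
                           encoder = encoder_config(),
                           gbm = gbm_config(),
                           k = 5, n_bins = 24,
                           stft_window = 50, stft_hop = 25,
                           period = c("ALL", "DAY", "NIGHT"),
                           train_segments_per_patient = Inf,
                           n_boot = 1000,
                           seed = 1L,
                           baseline = TRUE) {
  period <- match.arg(period)
  validate_manifest(manifest)
  folds <- assign_folds(manifest, k = k, seed = seed)

  segs <- preprocess_cohort(manifest, setting = setting)
  spans <- attr(segs, "spans")
  base_segs <- if (setting == 1) segs else preprocess_cohort(manifest, setting = 1)
  if (period != "ALL") {
    segs <- segs[segs$diurnal == period, ]
  }
  if (nrow(segs) == 0L) abort("no segments survive preprocessing")

  seg_fold <- folds$fold[match(segs$patient_id, folds$patient_id)]
  spec <- segment_spectrograms(segs, stft_window, stft_hop)
  x <- spec$x
  meta <- spec$meta
  # raw waveforms are no longer needed once spectrograms exist
  segs$samples <- NULL
  base_segs$samples <- NULL

  preds <- list()
  fold_metrics <- list()
  seg_auroc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- which(seg_fold != f)
    te <- which(seg_fold == f)
    tr_sub <- tr[subsample_training_segments(
      meta[tr, ], train_segments_per_patient, seed + 1000L + f
    )]
    enc_cfg <- encoder
    enc_cfg$seed <- encoder$seed + f
    enc <- train_segment_model(
      build_encoder(enc_cfg, dim(x)[1:3]),
      x[, , , tr_sub, drop = FALSE], meta[tr_sub, ], enc_cfg
    )
    sc_tr <- score_segments(enc, x[, , , tr, drop = FALSE])
    sc_te <- score_segments(enc, x[, , , te, drop = FALSE])
    scored_tr <- dplyr::bind_cols(meta[tr, ], sc_tr)
    scored_te <- dplyr::bind_cols(meta[te, ], sc_te)
    if (length(unique(meta$label[te])) == 2L) {
      seg_auroc[f] <- auroc(sc_te$probability, meta$label[te])
    }

    tr_pat <- folds$patient_id[folds$fold != f]
    te_pat <- folds$patient_id[folds$fold == f]
    ftr <- build_patient_features(scored_tr, tr_pat, spans, n_bins,
      enc$config$latent_dim)
    fte <- build_patient_features(scored_te, te_pat, spans, n_bins,
      enc$config$latent_dim)
    gbm_cfg <- gbm
    gbm_cfg$seed <- gbm$seed + f
    lab_tr <- manifest$paf_label[match(tr_pat, manifest$patient_id)]
    lab_te <- manifest$paf_label[match(te_pat, manifest$patient_id)]
    pm <- train_patient_model(ftr$features, lab_tr, gbm_cfg)
    p_te <- predict_patient(pm, fte$features)
    preds[[f]] <- tibble::tibble(
      patient_id = te_pat, score = p_te, label = lab_te, fold = f
    )
    if (length(unique(lab_te)) == 2L) {
      cut_f <- optimal_cutoff(p_te, lab_te)
      fold_metrics[[f]] <- tibble::as_tibble(
        c(list(fold = f), as.list(metric_panel(p_te, lab_te, cut_f)))
      )
    }
  }
  predictions <- dplyr::arrange(dplyr::bind_rows(preds), .data$patient_id)
  fold_metrics <- dplyr::bind_rows(fold_metrics)

  cutoff <- optimal_cutoff(predictions$score, predictions$label)
  pooled <- metric_panel(predictions$score, predictions$label, cutoff)

  report <- dplyr::bind_rows(lapply(names(pooled), function(mname) {
    vals <- fold_metrics[[mname]]
    vals <- vals[!is.na(vals)]
    ci <- if (length(vals) >= 2L) fold_ci(vals) else
      list(estimate = unname(pooled[[mname]]), ci_low = NA_real_, ci_high = NA_real_)
    tibble::tibble(
      model = "two_stage", subgroup = period, setting = setting,
      metric = mname, estimate = ci$estimate,
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      ci_method = "FOLDS", pooled = unname(pooled[[mname]]),
      n_patients = nrow(predictions)
    )
  }))

  burden <- NULL
  if (baseline) {
    burden_tbl <- sve_burden_cohort(base_segs)
    burden <- dplyr::left_join(predictions[, c("patient_id", "label", "fold")],
      burden_tbl, by = "patient_id")
    burden <- burden[!is.na(burden$burden), ]
    b_cut <- optimal_cutoff(burden$burden, burden$label)
    b_panel <- metric_panel(burden$burden, burden$label, b_cut)
    b_report <- dplyr::bind_rows(lapply(names(b_panel), function(mname) {
      ci <- bootstrap_ci(
        function(s, l) metric_panel(s, l, b_cut)[[mname]],
        burden$burden, burden$label, n_boot = n_boot, seed = seed
      )
      tibble::tibble(
        model = "sve_burden", subgroup = period, setting = setting,
        metric = mname, estimate = ci$estimate,
        ci_low = ci$ci_low, ci_high = ci$ci_high,
        ci_method = "BOOTSTRAP", pooled = unname(b_panel[[mname]]),
        n_patients = nrow(burden)
      )
    }))
    report <- dplyr::bind_rows(report, b_report)
    predictions <- dplyr::left_join(predictions,
      burden_tbl[, c("patient_id", "burden")], by = "patient_id")
  }

  elapsed <- elapsed_time_sensitivity(predictions, manifest, cutoff)

  structure(
    list(
      predictions = predictions,
      fold_metrics = fold_metrics,
      report = report,
      segment_auroc = seg_auroc,
      elapsed = elapsed,
      cutoff = cutoff,
      roc = roc_points(predictions$score, predictions$label),
      folds = folds,
      config = list(
        setting = setting, k = k, n_bins = n_bins, period = period,
        stft_window = stft_window, stft_hop = stft_hop,
        train_segments_per_patient = train_segments_per_patient,
        n_boot = n_boot, seed = seed,
        encoder = unclass(encoder), gbm = unclass(gbm)
      )
    ),
    class = "paf_experiment"
  )
}

#' Diurnal sub-analysis
#'
#' Re-runs the full two-stage experiment restricted to daytime or nighttime
#' segments (night = 22:00-07:00), with the same patient folds as the all-day
#' run.
#'
#' @inheritParams run_experiment
#' @param period `"DAY"` or `"NIGHT"`.
#' @param ... Passed to [run_experiment()].
#' @export
diurnal_experiment <- function(manifest, setting = 1, period, ...) {
  run_experiment(manifest, setting = setting, period = period, ...)
}

#' @export
print.paf_experiment <- function(x, ...) {
  a <- x$report[x$report$metric == "auroc" & x$report$model == "two_stage", ]
  cat(sprintf(
    "<paf_experiment> setting %d, %s, %d patients, %d folds\n",
    x$config$setting, x$config$period, nrow(x$predictions), x$config$k
  ))
  if (nrow(a) == 1L) {
    cat(sprintf(
      "  two-stage AUROC %.3f (%.3f-%.3f, fold CI); cutoff %.3f\n",
      a$estimate, a$ci_low, a$ci_high, x$cutoff
    ))
  }
  b <- x$report[x$report$metric == "auroc" & x$report$model == "sve_burden", ]
  if (nrow(b) == 1L) {
    cat(sprintf(
      "  SVE-burden AUROC %.3f (%.3f-%.3f, bootstrap CI)\n",
      b$estimate, b$ci_low, b$ci_high
    ))
  }
  sa <- mean(x$segment_auroc, na.rm = TRUE)
  if (!is.nan(sa)) cat(sprintf("  segment-level (encoder-only) AUROC %.3f\n", sa))
  invisible(x)
}

#' @method tidy paf_experiment
#' @export
tidy.paf_experiment <- function(x, ...) x$report

#' @method glance paf_experiment
#' @export
glance.paf_experiment <- function(x, ...) {
  g <- function(model) {
    r <- x$report[x$report$metric == "auroc" & x$report$model == model, ]
    if (nrow(r) == 1L) r$estimate else NA_real_
  }
  tibble::tibble(
    setting = x$config$setting, period = x$config$period,
    n_patients = nrow(x$predictions), k = x$config$k,
    auroc = g("two_stage"),
    auroc_pooled = x$report$pooled[
      x$report$metric == "auroc" & x$report$model == "two_stage"][1],
    auroc_baseline = g("sve_burden"),
    auroc_segment = mean(x$segment_auroc, na.rm = TRUE),
    cutoff = x$cutoff
  )
}

#' ROC curve points
#'
#' @inheritParams auroc
#' @return Tibble `fpr`, `tpr`, `threshold`, stepping through the observed
#'   scores from the most permissive to the strictest threshold.
#' @export
roc_points <- function(scores, labels) {
  y <- as.logical(labels)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  pts <- lapply(thr, function(t) {
    pred <- scores >= t
    tibble::tibble(
      fpr = sum(pred & !y) / sum(!y),
      tpr = sum(pred & y) / sum(y),
      threshold = t
    )
  })
  dplyr::arrange(dplyr::bind_rows(pts), .data$fpr, .data$tpr)
}
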