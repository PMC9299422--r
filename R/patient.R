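#' Gradient-boosting configuration for the patient classifier
#'
#' The second learning stage: boosted decision trees over fixed-length
#' per-patient feature vectors built from the temporally ordered segment
#' embeddings. An optional random-search budget tunes the tree parameters on
#' an inner patient-wise validation split.
#'
#' @param n_trees Boosting rounds.
#' @param learning_rate Shrinkage per round.
#' @param max_depth Tree depth.
#' @param min_child_samples Minimum observations per leaf.
#' @param subsample Row subsampling fraction per round.
#' @param colsample Column subsampling fraction per tree.
#' @param n_random Random-search draws (0 = fixed defaults).
#' @param seed Seed for boosting and the random search.
#' @return List of class `gbm_config`.
#' @export
gbm_config <- function(n_trees = 200, learning_rate = 0.05, max_depth = 3,
                       min_child_samples = 5, subsample = 0.8,
                       colsample = 0.8, n_random = 0, seed = 1L) {
  if (n_trees < 1) abort("n_trees must be >= 1")
  structure(
    list(
      n_trees = as.integer(n_trees), learning_rate = learning_rate,
      max_depth = as.integer(max_depth),
      min_child_samples = as.integer(min_child_samples),
      subsample = subsample, colsample = colsample,
      n_random = as.integer(n_random), seed = as.integer(seed)
    ),
    class = "gbm_config"
  )
}

#' Aggregate a patient's segment scores into a fixed-length feature vector
#'
#' Divides the recording span into `n_bins` equal clock-time bins and pools
#' the temporally ordered segment embeddings per bin: mean latent vector,
#' mean segment probability, segment count and an empty-bin flag. A global
#' block appends the overall mean/max/SD of segment probabilities, the
#' fraction of SVE-containing segments and the total segment count. The
#' result has length `n_bins * (latent_dim + 3) + 5` regardless of how many
#' segments survived preprocessing; a patient with zero segments yields the
#' all-empty vector (zeros with every empty flag set). The function depends
#' only on the (timestamp, score) pairs, not on input order.
#'
#' @param scores Tibble with `start_time`, `probability`, matrix column
#'   `latent` and `contains_sve` for one patient's segments.
#' @param span_start,span_end Clock limits of the recording.
#' @param n_bins Number of temporal bins (default 24, one per hour of a 24-h
#'   recording).
#' @param latent_dim Latent dimension (needed when `scores` is empty).
#' @return Named numeric feature vector.
#' @export
aggregate_latents <- function(scores, span_start, span_end, n_bins = 24,
                              latent_dim = NULL) {
  if (n_bins < 1) abort("n_bins must be >= 1")
  n <- nrow(scores)
  if (is.null(latent_dim)) {
    if (n == 0L) abort("latent_dim must be given for empty score sets")
    latent_dim <- ncol(scores$latent)
  }
  per_bin <- latent_dim + 3L
  out <- numeric(n_bins * per_bin + 5L)
  bin_names <- unlist(lapply(seq_len(n_bins), function(b) {
    c(sprintf("bin%02d_lat%02d", b, seq_len(latent_dim)),
      sprintf("bin%02d_%s", b, c("mean_prob", "count", "empty")))
  }))
  names(out) <- c(bin_names,
    c("prob_mean", "prob_max", "prob_sd", "sve_fraction", "n_segments"))
  if (n == 0L) {
    out[sprintf("bin%02d_empty", seq_len(n_bins))] <- 1
    return(out)
  }
  total <- as.numeric(difftime(span_end, span_start, units = "secs"))
  if (total <= 0) abort("span_end must be after span_start")
  rel <- as.numeric(difftime(scores$start_time, span_start, units = "secs"))
  bin <- pmin(pmax(floor(rel / total * n_bins), 0), n_bins - 1L) + 1L
  for (b in seq_len(n_bins)) {
    sel <- which(bin == b)
    base <- (b - 1L) * per_bin
    if (length(sel) == 0L) {
      out[base + latent_dim + 3L] <- 1 # empty flag
    } else {
      out[base + seq_len(latent_dim)] <-
        colMeans(scores$latent[sel, , drop = FALSE])
      out[base + latent_dim + 1L] <- mean(scores$probability[sel])
      out[base + latent_dim + 2L] <- length(sel)
    }
  }
  gp <- scores$probability
  out["prob_mean"] <- mean(gp)
  out["prob_max"] <- max(gp)
  out["prob_sd"] <- if (n > 1L) sd(gp) else 0
  out["sve_fraction"] <- mean(scores$contains_sve)
  out["n_segments"] <- n
  out
}

#' Build per-patient feature rows for a scored cohort
#'
#' @param scored Segment tibble joined with encoder scores (columns
#'   `patient_id`, `start_time`, `probability`, `latent`, `contains_sve`).
#' @param patients Character vector of patient ids to emit rows for (patients
#'   with no surviving segments get the all-empty vector).
#' @param spans Tibble `patient_id`, `span_start`, `span_end`.
#' @param n_bins,latent_dim As in [aggregate_latents()].
#' @return List with `features` (matrix, one row per patient, rownames =
#'   patient ids) and `patient_id`.
#' @export
build_patient_features <- function(scored, patients, spans, n_bins = 24,
                                   latent_dim = NULL) {
  if (is.null(latent_dim)) latent_dim <- ncol(scored$latent)
  rows <- lapply(patients, function(pid) {
    sc <- scored[scored$patient_id == pid, , drop = FALSE]
    sp <- spans[spans$patient_id == pid, ]
    if (nrow(sp) != 1L) abort(paste0("missing span for patient ", pid))
    aggregate_latents(sc, sp$span_start, sp$span_end, n_bins, latent_dim)
  })
  features <- do.call(rbind, rows)
  rownames(features) <- patients
  list(features = features, patient_id = patients)
}

xgb_params <- function(cfg) {
  list(
    objective = "binary:logistic",
    eta = cfg$learning_rate,
    max_depth = cfg$max_depth,
    # xgboost's min_child_weight is a hessian sum; for logistic loss the
    # per-sample hessian is at most 1/4, so convert the sample count
    min_child_weight = cfg$min_child_samples * 0.25,
    subsample = cfg$subsample,
    colsample_bytree = cfg$colsample,
    nthread = 1,
    seed = cfg$seed
  )
}

#' Train the patient-level boosted-tree classifier
#'
#' Fits gradient-boosted trees to the per-patient feature vectors and binary
#' pAF labels. With `n_random > 0`, that many random configurations are
#' scored by AUROC on an inner patient-wise stratified validation split and
#' the best is refitted on all training patients.
#'
#' @param features Numeric matrix, one row per patient.
#' @param labels Logical/0-1 vector.
#' @param config A [gbm_config()].
#' @return Object of class `patient_classifier`.
#' @export
train_patient_model <- function(features, labels, config = gbm_config()) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) {
    abort("patient training data contain a single class",
      class = "holterpaf_single_class")
  }
  if (sum(y == 1) < 2L || sum(y == 0) < 2L) {
    abort("need at least 2 patients per class", class = "holterpaf_single_class")
  }
  cfg <- config
  if (cfg$n_random > 0L) {
    cfg <- withr::with_seed(config$seed, {
      pos <- which(y == 1)
      neg <- which(y == 0)
      val <- c(sample(pos, max(1L, round(0.25 * length(pos)))),
        sample(neg, max(1L, round(0.25 * length(neg)))))
      tr <- setdiff(seq_along(y), val)
      cands <- lapply(seq_len(config$n_random), function(i) {
        gbm_config(
          n_trees = sample(c(50L, 100L, 200L, 400L), 1),
          learning_rate = 10^runif(1, -2, -0.7),
          max_depth = sample(2:5, 1),
          min_child_samples = sample(c(2L, 5L, 10L), 1),
          subsample = runif(1, 0.6, 1),
          colsample = runif(1, 0.5, 1),
          seed = config$seed
        )
      })
      scores <- vapply(cands, function(cc) {
        fit <- xgboost::xgb.train(
          params = xgb_params(cc),
          data = xgboost::xgb.DMatrix(features[tr, , drop = FALSE], label = y[tr]),
          nrounds = cc$n_trees, verbose = 0
        )
        p <- predict(fit, xgboost::xgb.DMatrix(features[val, , drop = FALSE]))
        if (length(unique(y[val])) < 2L) 0.5 else auroc(p, y[val])
      }, numeric(1))
      cands[[which.max(scores)]]
    })
  }
  booster <- xgboost::xgb.train(
    params = xgb_params(cfg),
    data = xgboost::xgb.DMatrix(features, label = y),
    nrounds = cfg$n_trees, verbose = 0
  )
  structure(
    list(
      booster = booster, config = cfg, n_features = ncol(features),
      feature_names = colnames(features), n_patients = nrow(features)
    ),
    class = "patient_classifier"
  )
}

#' Predict patient-level pAF probabilities
#'
#' @param model A [train_patient_model()] fit.
#' @param features Feature matrix with the training feature length.
#' @return Numeric probabilities in `[0, 1]`, one per row.
#' @export
predict_patient <- function(model, features) {
  stopifnot(inherits(model, "patient_classifier"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != model$n_features) {
    abort(sprintf(
      "feature length %d does not match training length %d",
      ncol(features), model$n_features
    ))
  }
  as.numeric(predict(model$booster, xgboost::xgb.DMatrix(features)))
}

#' @export
print.patient_classifier <- function(x, ...) {
  cat(sprintf(
    "<patient_classifier> %d boosted trees (depth %d, eta %g) on %d features, %d patients\n",
    x$config$n_trees, x$config$max_depth, x$config$learning_rate,
    x$n_features, x$n_patients
  ))
  invisible(x)
}

#' @method tidy patient_classifier
#' @export
tidy.patient_classifier <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble::tibble(
    feature = imp$Feature, gain = imp$Gain,
    cover = imp$Cover, frequency = imp$Frequency
  )
}

#' @method glance patient_classifier
#' @export
glance.patient_classifier <- function(x, ...) {
  tibble::tibble(
    n_trees = x$config$n_trees, max_depth = x$config$max_depth,
    learning_rate = x$config$learning_rate,
    n_features = x$n_features, n_patients = x$n_patients
  )
}

#' Save / load a patient classifier
#'
#' @param model A `patient_classifier`.
#' @param path Checkpoint path.
#' @export
save_patient_model <- function(model, path) {
  obj <- model
  obj$booster <- xgboost::xgb.save.raw(model$booster)
  saveRDS(unclass(obj), path)
  invisible(path)
}

#' @rdname save_patient_model
#' @export
load_patient_model <- function(path) {
  obj <- readRDS(path)
  obj$booster <- xgboost::xgb.load.raw(obj$booster)
  structure(obj, class = "patient_classifier")
}
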