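# Shared fixtures, all generated in code.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A clean sinusoid-free recording of pure template beats.
fixture_recording <- function(duration_s = 70, seed = 101, noise_sd = 0.02,
                              sve_rate = 0, ve_rate = 0, start = "10:00:00") {
  cfg <- sim_config(
    duration_s = duration_s, noise_sd = noise_sd,
    sve_rate_control = sve_rate, sve_rate_paf = sve_rate, ve_rate = ve_rate,
    seed = seed
  )
  set.seed(seed)
  generate_patient_recording(
    cfg, "FIX", utc(paste("2024-01-01", start)),
    sve_rate = sve_rate, ve_rate = ve_rate
  )
}

# Small labelled cohort on disk; returns the manifest (with sim_* truth).
fixture_cohort <- function(n = 12, duration_s = 300, seed = 77,
                           paf_fraction = 0.5, ...) {
  cfg <- sim_config(
    n_patients = n, paf_fraction = paf_fraction, duration_s = duration_s,
    seed = seed, ...
  )
  generate_cohort(cfg, withr::local_tempdir(.local_envir = parent.frame()))
}

# Desk-scale encoder / GBM configurations used across training tests.
desk_encoder <- function(seed = 1, max_epochs = 8, patience = 3, ...) {
  encoder_config(
    channels = c(8, 16, 32), latent_dim = 16, batch_size = 128,
    max_epochs = max_epochs, patience = patience, learning_rate = 1e-3,
    seed = seed, ...
  )
}

desk_gbm <- function(seed = 1, n_trees = 300, ...) {
  gbm_config(
    n_trees = n_trees, learning_rate = 0.05, max_depth = 2,
    min_child_samples = 2, colsample = 0.7, seed = seed, ...
  )
}

# Exhaustive pairwise AUROC comparator (independent of the rank-based
# implementation): P(score_pos > score_neg) + 0.5 P(tie).
brute_auroc <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]
  neg <- scores[!y]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Exhaustive Youden sweep over observed thresholds.
brute_best_youden <- function(scores, labels) {
  y <- as.logical(labels)
  best <- -Inf
  for (cut in unique(scores)) {
    pred <- scores >= cut
    j <- sum(pred & y) / sum(y) + sum(!pred & !y) / sum(!y)
    best <- max(best, j)
  }
  best
}

# Brute-force excision + tiling oracle on the boolean sample grid.
brute_segments <- function(n, fs, ve_samples, sve_samples, setting,
                           window_s = 3.5) {
  removed <- rep(FALSE, n)
  w <- round(window_s * fs)
  centers <- c(ve_samples, if (setting == 2) sve_samples)
  for (s in centers) {
    lo <- max(0L, s - w)
    hi <- min(n - 1L, s + w - 1L) # removal interval [s - w, s + w)
    removed[(lo + 1L):(hi + 1L)] <- TRUE
  }
  seg_len <- round(7 * fs)
  starts <- integer(0)
  i <- 0L
  while (i < n) {
    if (removed[i + 1L]) {
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && !removed[j + 1L]) j <- j + 1L # kept interval [i, j)
    k <- (j - i) %/% seg_len
    if (k > 0L) starts <- c(starts, i + seg_len * (seq_len(k) - 1L))
    i <- j
  }
  starts
}
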