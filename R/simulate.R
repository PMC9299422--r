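#' Simulation configuration for a synthetic Holter cohort
#'
#' Defines every knob of the cohort generator. The defaults describe a
#' desk-scale screening cohort in which pAF patients differ from controls
#' through two information channels: a subtle P-wave morphology shift
#' (`p_wave_effect`) and an elevated supraventricular ectopy rate
#' (`sve_rate_paf` vs `sve_rate_control`). Setting `p_wave_effect = 0` and
#' `sve_rate_paf = sve_rate_control` defines the null cohort in which no
#' classifier should beat chance.
#'
#' @param n_patients Number of patients.
#' @param paf_fraction Fraction of patients labelled pAF (rounded).
#' @param duration_s Recording length per patient, seconds. `duration_s * fs`
#'   must be an integer.
#' @param fs Sampling frequency, Hz.
#' @param mean_hr_day,mean_hr_night Daytime / nighttime mean heart rate, bpm;
#'   blended smoothly around the fixed 22:00 and 07:00 boundaries.
#' @param hr_patient_sd Between-patient SD of the heart-rate offset, bpm.
#' @param rr_jitter_sd SD of the multiplicative log-normal RR jitter
#'   (dimensionless, on the log scale).
#' @param p_wave_effect Fractional P-duration prolongation (with a matching
#'   amplitude reduction) applied to pAF patients only; 0 disables it.
#' @param p_duration_sd Between-patient SD of the relative P-duration
#'   multiplier (both classes).
#' @param sve_rate_control,sve_rate_paf Supraventricular ectopic beats per
#'   hour for controls / pAF patients.
#' @param ve_rate Ventricular ectopic beats per hour (both classes).
#' @param noise_sd Additive Gaussian noise SD, millivolts.
#' @param start_clock Recording start clock time, `"HH:MM:SS"`.
#' @param exam_date Holter exam date for every patient (`Date` or string).
#' @param elapsed_months_range For pAF patients, elapsed time from pAF index
#'   date to the Holter exam is drawn from an equal-weight mixture of uniforms
#'   over consecutive strata bounded by these values (months); the default
#'   places patients on both sides of each cutoff in 3, 6, 12, 36.
#' @param template Beat morphology parameters, see [beat_template_params()].
#' @param seed Integer seed; the whole cohort is a pure function of this
#'   configuration including the seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 60,
                       paf_fraction = 0.25,
                       duration_s = 1200,
                       fs = 128,
                       mean_hr_day = 75,
                       mean_hr_night = 58,
                       hr_patient_sd = 3,
                       rr_jitter_sd = 0.05,
                       p_wave_effect = 0.2,
                       p_duration_sd = 0.06,
                       sve_rate_control = 20,
                       sve_rate_paf = 60,
                       ve_rate = 5,
                       noise_sd = 0.04,
                       start_clock = "10:00:00",
                       exam_date = as.Date("2024-03-15"),
                       elapsed_months_range = c(1, 3, 6, 12, 36, 48),
                       template = beat_template_params(),
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), paf_fraction = paf_fraction,
    duration_s = duration_s, fs = fs,
    mean_hr_day = mean_hr_day, mean_hr_night = mean_hr_night,
    hr_patient_sd = hr_patient_sd, rr_jitter_sd = rr_jitter_sd,
    p_wave_effect = p_wave_effect, p_duration_sd = p_duration_sd,
    sve_rate_control = sve_rate_control, sve_rate_paf = sve_rate_paf,
    ve_rate = ve_rate, noise_sd = noise_sd,
    start_clock = start_clock, exam_date = as.Date(exam_date),
    elapsed_months_range = elapsed_months_range,
    template = template, seed = as.integer(seed)
  )
  rates <- c(cfg$sve_rate_control, cfg$sve_rate_paf, cfg$ve_rate)
  if (any(rates < 0)) abort("ectopy rates must be >= 0")
  if (cfg$paf_fraction < 0 || cfg$paf_fraction > 1) {
    abort("paf_fraction must be in [0, 1]")
  }
  if (abs(cfg$duration_s * cfg$fs - round(cfg$duration_s * cfg$fs)) > 1e-9) {
    abort("duration_s * fs must be an integer")
  }
  if (cfg$n_patients < 1L) abort("n_patients must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Beat morphology template parameters
#'
#' Parameterises the P-QRS-T pulse-train model of a single sinus beat. Each
#' component is a smooth Gaussian lobe; `*_weights` project the canonical
#' waveform onto the three Holter channels so channels differ in shape, not
#' just in scale. The P wave precedes the QRS onset by `pr_interval_ms`.
#'
#' @param p_duration_ms P-wave duration (the lobe spans roughly this width).
#' @param p_amplitude_mv P amplitude in the reference channel, mV.
#' @param pr_interval_ms P-onset to QRS-onset interval.
#' @param qrs_duration_ms QRS duration.
#' @param r_amplitude_mv R-wave amplitude, mV.
#' @param t_amplitude_mv T-wave amplitude, mV.
#' @param t_duration_ms T-wave duration.
#' @param p_weights,qrs_weights,t_weights Length-3 per-channel projection
#'   weights.
#' @return A list of class `beat_template_params`.
#' @export
beat_template_params <- function(p_duration_ms = 100,
                                 p_amplitude_mv = 0.15,
                                 pr_interval_ms = 160,
                                 qrs_duration_ms = 90,
                                 r_amplitude_mv = 1.0,
                                 t_amplitude_mv = 0.30,
                                 t_duration_ms = 160,
                                 p_weights = c(1, 0.65, 0.85),
                                 qrs_weights = c(1, -0.35, 0.9),
                                 t_weights = c(1, 0.5, 0.75)) {
  p <- list(
    p_duration_ms = p_duration_ms, p_amplitude_mv = p_amplitude_mv,
    pr_interval_ms = pr_interval_ms, qrs_duration_ms = qrs_duration_ms,
    r_amplitude_mv = r_amplitude_mv, t_amplitude_mv = t_amplitude_mv,
    t_duration_ms = t_duration_ms,
    p_weights = p_weights, qrs_weights = qrs_weights, t_weights = t_weights
  )
  durs <- c(p$p_duration_ms, p$pr_interval_ms, p$qrs_duration_ms, p$t_duration_ms)
  if (any(durs <= 0)) abort("all durations must be > 0")
  structure(p, class = "beat_template_params")
}

gauss_lobe <- function(t, center, sd, amplitude) {
  amplitude * exp(-0.5 * ((t - center) / sd)^2)
}

#' Synthesize a single 3-channel beat waveform
#'
#' Builds the beat as a sum of Gaussian lobes: an optional P wave, a triphasic
#' QRS (small Q, dominant R, small S) and a T wave, each projected onto the
#' three channels with its weight vector. The returned waveform is anchored at
#' the R peak.
#'
#' @param params [beat_template_params()].
#' @param fs Sampling frequency, Hz.
#' @param include_p Include the P wave? Ectopic beats (aberrant atrial or
#'   ventricular) are synthesized without one.
#' @param wide Widen and invert for a ventricular morphology (broad QRS,
#'   discordant T, no P).
#' @return List with `waveform` (3 x L matrix, mV), `r_index` (1-based column
#'   of the R peak) and `fs`.
#' @export
beat_template <- function(params, fs, include_p = TRUE, wide = FALSE) {
  p <- params
  qrs_scale <- if (wide) 2.2 else 1
  sd_p <- p$p_duration_ms / 1000 / 6
  sd_r <- p$qrs_duration_ms * qrs_scale / 1000 / 6
  sd_t <- p$t_duration_ms / 1000 / 6
  # component centers relative to the R peak (seconds)
  c_p <- -(p$pr_interval_ms / 1000) - p$p_duration_ms / 2000 + p$qrs_duration_ms / 2000
  c_q <- -0.35 * p$qrs_duration_ms * qrs_scale / 1000
  c_s <- +0.35 * p$qrs_duration_ms * qrs_scale / 1000
  c_t <- 0.30 + (qrs_scale - 1) * 0.04
  t0 <- min(c_p - 4 * sd_p, c_q - 4 * sd_r)
  t1 <- c_t + 4 * sd_t
  tt <- seq(floor(t0 * fs), ceiling(t1 * fs)) / fs
  t_sign <- if (wide) -1 else 1
  base_p <- if (include_p && !wide) {
    gauss_lobe(tt, c_p, sd_p, p$p_amplitude_mv)
  } else {
    numeric(length(tt))
  }
  amp_r <- p$r_amplitude_mv * (if (wide) 1.3 else 1)
  base_qrs <- gauss_lobe(tt, 0, sd_r, amp_r) +
    gauss_lobe(tt, c_q, sd_r * 0.7, -0.12 * amp_r) +
    gauss_lobe(tt, c_s, sd_r * 0.7, -0.25 * amp_r)
  base_t <- gauss_lobe(tt, c_t, sd_t, t_sign * p$t_amplitude_mv)
  wf <- outer(p$p_weights, base_p) +
    outer(p$qrs_weights, base_qrs) +
    outer(p$t_weights, base_t)
  list(waveform = wf, r_index = which.min(abs(tt)), fs = fs)
}

clock_hours <- function(time) {
  (as.numeric(time) %% 86400) / 3600
}

#' Instantaneous diurnal heart rate
#'
#' Blends a daytime and a nighttime heart-rate plateau with smooth cosine
#' ramps around the fixed nighttime window boundaries (22:00 and 07:00, the
#' same boundaries the diurnal analysis uses). The night plateau runs
#' 23:00-06:00, the day plateau 08:00-21:00, with 2-hour transitions. The
#' function is periodic with period 24 h.
#'
#' @param clock_time `POSIXct` time(s), or numeric hours in \[0, 24).
#' @param mean_hr_day,mean_hr_night Plateau levels, bpm.
#' @return Heart rate(s), bpm.
#' @export
diurnal_rate <- function(clock_time, mean_hr_day, mean_hr_night) {
  h <- if (inherits(clock_time, "POSIXct")) clock_hours(clock_time) else clock_time %% 24
  w <- ifelse(h >= 23 | h < 6, 1,
    ifelse(h >= 8 & h < 21, 0,
      ifelse(h >= 21 & h < 23,
        0.5 * (1 - cos(pi * (h - 21) / 2)), # evening ramp day -> night
        0.5 * (1 + cos(pi * (h - 6) / 2)) # morning ramp night -> day
      )
    )
  )
  mean_hr_day + (mean_hr_night - mean_hr_day) * w
}

#' Generate one synthetic patient recording
#'
#' Places beats sequentially with RR intervals set by the diurnal heart-rate
#' profile times multiplicative log-normal jitter. Ectopic beats arise by
#' Poisson thinning at the configured hourly rates: SVE beats are premature
#' with a diminished P wave; VE beats are wide, P-less and discordant. Every
#' beat is annotated with its true class at its R-peak sample. Beats whose RR
#' to the previous placed beat falls below the template's refractory core are
#' skipped and counted.
#'
#' @param config A [sim_config()].
#' @param patient_id Identifier.
#' @param start_time `POSIXct` start of the recording.
#' @param p_duration_mult Per-patient multiplier on the P duration.
#' @param p_amp_mult Per-patient multiplier on the P amplitude.
#' @param sve_rate,ve_rate Hourly ectopy rates for this patient.
#' @param hr_offset Additive heart-rate offset, bpm.
#' @return List with `recording` ([holter_recording()]), `annotations`
#'   (tibble) and `n_skipped` (beats dropped for overlap).
#' @export
generate_patient_recording <- function(config, patient_id, start_time,
                                       p_duration_mult = 1, p_amp_mult = 1,
                                       sve_rate = config$sve_rate_control,
                                       ve_rate = config$ve_rate,
                                       hr_offset = 0) {
  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))
  tpl_par <- config$template
  tpl_par$p_duration_ms <- tpl_par$p_duration_ms * p_duration_mult
  tpl_par$p_amplitude_mv <- tpl_par$p_amplitude_mv * p_amp_mult
  tpl_n <- beat_template(tpl_par, fs)
  sve_par <- tpl_par
  sve_par$p_amplitude_mv <- sve_par$p_amplitude_mv * 0.25
  sve_par$p_duration_ms <- sve_par$p_duration_ms * 0.7
  tpl_s <- beat_template(sve_par, fs)
  tpl_v <- beat_template(tpl_par, fs, include_p = FALSE, wide = TRUE)
  if (config$duration_s < ncol(tpl_n$waveform) / fs) {
    abort("duration_s too short to hold a single beat")
  }

  # beat times first, then classes, then template placement
  mean_rr_guess <- 60 / (config$mean_hr_day + hr_offset)
  n_guess <- ceiling(config$duration_s / mean_rr_guess * 1.5) + 16L
  beat_t <- numeric(n_guess)
  k <- 0L
  t <- 0.35 # leave room for the first template's pre-R span
  h0 <- clock_hours(start_time)
  sigma <- config$rr_jitter_sd
  while (t < config$duration_s - 0.35) {
    k <- k + 1L
    beat_t[k] <- t
    hr <- diurnal_rate(h0 + t / 3600, config$mean_hr_day, config$mean_hr_night) +
      hr_offset
    jit <- exp(rnorm(1, -sigma^2 / 2, sigma))
    t <- t + 60 / max(hr, 20) * jit
  }
  beat_t <- beat_t[seq_len(k)]
  rr <- diff(c(0, beat_t))
  p_ve <- pmin(1, ve_rate * rr / 3600)
  p_sve <- pmin(1, sve_rate * rr / 3600)
  u <- runif(k)
  cls <- rep("NORMAL", k)
  cls[u < p_ve] <- "VE"
  cls[u >= p_ve & u < p_ve + p_sve] <- "SVE"
  # SVE beats fire early: pull the beat forward by a quarter of its RR
  prem <- cls == "SVE"
  beat_t[prem] <- beat_t[prem] - 0.25 * rr[prem]

  sig <- matrix(0, nrow = 3, ncol = n)
  ann_sample <- integer(k)
  keep <- logical(k)
  n_skipped <- 0L
  min_rr <- 0.30 # refractory core of the template, seconds
  last_t <- -Inf
  for (i in seq_len(k)) {
    if (beat_t[i] - last_t < min_rr) {
      n_skipped <- n_skipped + 1L
      next
    }
    tpl <- switch(cls[i], NORMAL = tpl_n, SVE = tpl_s, VE = tpl_v)
    r_samp <- round(beat_t[i] * fs)
    idx <- seq_len(ncol(tpl$waveform)) + (r_samp - tpl$r_index)
    ok <- idx >= 1L & idx <= n
    if (!any(ok)) next
    sig[, idx[ok]] <- sig[, idx[ok]] + tpl$waveform[, ok, drop = FALSE]
    ann_sample[i] <- r_samp
    keep[i] <- TRUE
    last_t <- beat_t[i]
  }
  if (config$noise_sd > 0) {
    sig <- sig + matrix(rnorm(3 * n, 0, config$noise_sd), nrow = 3)
  }
  list(
    recording = holter_recording(patient_id, sig, fs, start_time = start_time),
    annotations = tibble::tibble(
      sample_index = as.integer(ann_sample[keep]),
      beat_class = beat_class_factor(cls[keep])
    ),
    n_skipped = n_skipped
  )
}

draw_elapsed_months <- function(n, breaks) {
  strata <- sample.int(length(breaks) - 1L, n, replace = TRUE)
  runif(n, breaks[strata], breaks[strata + 1L])
}

#' Generate a labelled synthetic Holter cohort on disk
#'
#' Writes `n_patients` WFDB records + annotation files + a manifest CSV under
#' `dir`. `round(n_patients * paf_fraction)` patients are labelled pAF; their
#' index dates are drawn so elapsed times span the 3/6/12/36-month strata of
#' the elapsed-time analysis. Identical configuration (including seed) yields
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return The cohort manifest tibble, augmented with per-patient ground-truth
#'   columns (`sim_p_duration_mult`, `sim_sve_rate`, `sim_ve_rate`,
#'   `sim_n_skipped`) that are not part of the CSV on disk.
#' @export
generate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- config$n_patients
  n_paf <- as.integer(round(n * config$paf_fraction))
  withr::with_seed(config$seed, {
    labels <- rep(FALSE, n)
    if (n_paf > 0) labels[sample.int(n, n_paf)] <- TRUE
    ids <- sprintf("P%04d", seq_len(n))
    start_time <- as.POSIXct(
      paste(format(config$exam_date), config$start_clock),
      tz = "UTC"
    )
    elapsed <- numeric(n)
    elapsed[labels] <- draw_elapsed_months(n_paf, config$elapsed_months_range)
    p_mult <- rnorm(n, 1 + config$p_wave_effect * labels, config$p_duration_sd)
    p_mult <- pmax(p_mult, 0.5)
    p_amp <- pmax(rnorm(n, 1 - 0.5 * config$p_wave_effect * labels,
      config$p_duration_sd), 0.3)
    sve_rate <- ifelse(labels, config$sve_rate_paf, config$sve_rate_control)
    hr_off <- rnorm(n, 0, config$hr_patient_sd)
    patient_seeds <- sample.int(.Machine$integer.max - 1L, n)
    n_skipped <- integer(n)
    for (i in seq_len(n)) {
      withr::with_seed(patient_seeds[i], {
        pat <- generate_patient_recording(
          config, ids[i], start_time,
          p_duration_mult = p_mult[i], p_amp_mult = p_amp[i],
          sve_rate = sve_rate[i], ve_rate = config$ve_rate,
          hr_offset = hr_off[i]
        )
      })
      write_record(pat$recording, pat$annotations, file.path(dir, ids[i]))
      n_skipped[i] <- pat$n_skipped
    }
    manifest <- tibble::tibble(
      patient_id = ids,
      paf_label = labels,
      index_date = dplyr::if_else(
        labels, config$exam_date - round(elapsed * 30.44), as.Date(NA)
      ),
      exam_date = config$exam_date,
      record_path = paste0(ids, ".hea"),
      annotation_path = paste0(ids, ".atr")
    )
    write_cohort_manifest(manifest, file.path(dir, "manifest.csv"))
    manifest$record_path <- file.path(dir, manifest$record_path)
    manifest$annotation_path <- file.path(dir, manifest$annotation_path)
    manifest$sim_p_duration_mult <- p_mult
    manifest$sim_sve_rate <- sve_rate
    manifest$sim_ve_rate <- config$ve_rate
    manifest$sim_n_skipped <- n_skipped
    manifest
  })
}

#' Measure the P-wave duration from a recording
#'
#' Averages windows around annotated normal beats (aligned at the R peak),
#' locates the P lobe in the PR window of the first channel and returns its
#' full width at half maximum in milliseconds. A simple quality-control
#' readback used to verify that generated cohorts carry the configured
#' morphology shift.
#'
#' @param recording A [holter_recording()].
#' @param annotations Annotation tibble; only `NORMAL` beats are used.
#' @param max_beats Cap on the number of beats averaged.
#' @return P-wave FWHM in ms (`NA` if no P lobe is found).
#' @export
measure_p_duration <- function(recording, annotations, max_beats = 200) {
  fs <- recording$fs
  pre <- round(0.36 * fs)
  post <- round(0.10 * fs)
  r <- annotations$sample_index[annotations$beat_class == "NORMAL"]
  r <- r[r - pre >= 0 & r + post < ncol(recording$signal)]
  if (length(r) == 0L) return(NA_real_)
  if (length(r) > max_beats) r <- r[seq(1L, length(r), length.out = max_beats)]
  win <- vapply(
    r,
    function(s) recording$signal[1, (s - pre):(s + post) + 1L],
    numeric(pre + post + 1L)
  )
  avg <- rowMeans(win)
  tt <- (seq_along(avg) - 1L - pre) / fs # seconds relative to R peak
  search <- which(tt >= -0.30 & tt <= -0.09)
  if (length(search) < 3L) return(NA_real_)
  seg <- avg[search] - stats::median(avg[search])
  pk <- which.max(abs(seg))
  half <- abs(seg[pk]) / 2
  above <- abs(seg) >= half
  lo <- pk
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- pk
  while (hi < length(seg) && above[hi + 1L]) hi <- hi + 1L
  (hi - lo + 1L) / fs * 1000
}
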