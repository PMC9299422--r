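#' Construct a Holter recording object
#'
#' A `holter_recording` bundles a multi-channel sampled ECG with its sampling
#' frequency, channel names and the clock time of its first sample. Sample `k`
#' (0-based) occurs at `start_time + k / fs` seconds.
#'
#' @param patient_id Character scalar identifier.
#' @param signal Numeric matrix, channels in rows, samples in columns,
#'   amplitudes in millivolts.
#' @param fs Sampling frequency in Hz (the pipeline assumes 128 Hz).
#' @param channel_names Character vector, one name per channel. Defaults to
#'   the three leads a typical 3-channel Holter exports: modified V5,
#'   modified V1 and lead III.
#' @param start_time `POSIXct` clock time of the first sample (or `NA` when
#'   the header carries none and the cohort manifest supplies it).
#'
#' @return An object of class `holter_recording`.
#' @export
holter_recording <- function(patient_id, signal, fs,
                             channel_names = NULL, start_time = as.POSIXct(NA)) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    abort("`signal` must be a numeric matrix (channels x samples)")
  }
  if (ncol(signal) < 1L) abort("`signal` must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) abort("`fs` must be > 0")
  if (anyNA(signal)) abort("`signal` must not contain missing values")
  if (is.null(channel_names)) {
    channel_names <- if (nrow(signal) == 3L) {
      c("mod V5", "mod V1", "lead III")
    } else {
      paste0("ch", seq_len(nrow(signal)))
    }
  }
  if (length(channel_names) != nrow(signal)) {
    abort("`channel_names` length must equal the number of channels")
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      signal = signal,
      fs = fs,
      channel_names = as.character(channel_names),
      start_time = start_time
    ),
    class = "holter_recording"
  )
}

#' @export
print.holter_recording <- function(x, ...) {
  cat(sprintf(
    "<holter_recording> %s: %d ch x %d samples @ %g Hz (%.1f min), start %s\n",
    x$patient_id, nrow(x$signal), ncol(x$signal), x$fs,
    ncol(x$signal) / x$fs / 60,
    if (is.na(x$start_time)) "unknown" else format(x$start_time, tz = "UTC")
  ))
  invisible(x)
}

#' @export
#' @rdname holter_recording
n_samples <- function(recording) ncol(recording$signal)

#' Convert between sample index and clock time
#'
#' @param recording A [holter_recording()].
#' @param sample_index 0-based sample indices.
#' @param time `POSIXct` times.
#' @return `sample_time()` returns `POSIXct`; `time_sample()` the 0-based
#'   sample index of each time on the sample grid.
#' @export
sample_time <- function(recording, sample_index) {
  recording$start_time + sample_index / recording$fs
}

#' @rdname sample_time
#' @export
time_sample <- function(recording, time) {
  round(as.numeric(difftime(time, recording$start_time, units = "secs")) * recording$fs)
}

#' Read a WFDB/MIT Holter record
#'
#' Reads a WFDB header + format-16 signal file pair and returns the signal in
#' physical units (millivolts), converting each channel as
#' `(digital - baseline) / gain`. Channel order follows the header. Records
#' with a channel count other than 3 are read but flagged with a conformance
#' warning, since the downstream pipeline expects the 3-channel Holter montage.
#'
#' @param path Path to the record (with or without the `.hea` extension).
#' @param patient_id Identifier to attach; defaults to the record name.
#' @return A [holter_recording()].
#' @export
read_record <- function(path, patient_id = NULL) {
  p <- wfdb_paths(path)
  hdr <- read_wfdb_header(p$hea)
  if (hdr$n_sig != 3L) {
    warn(sprintf(
      "record %s has %d channels; the pipeline expects 3", hdr$record, hdr$n_sig
    ), class = "holterpaf_conformance_warning")
  }
  dig <- read_wfdb_signal(file.path(dirname(p$hea), hdr$signals[[1]]$file),
    hdr$n_sig, hdr$n_samples)
  n_invalid <- sum(dig == WFDB_INVALID_16)
  if (n_invalid > 0L) {
    warn(sprintf("%d invalid samples set to 0 in record %s", n_invalid, hdr$record))
    dig[dig == WFDB_INVALID_16] <- 0L
  }
  gains <- vapply(hdr$signals, `[[`, numeric(1), "gain")
  baselines <- vapply(hdr$signals, `[[`, numeric(1), "baseline")
  phys <- (dig - baselines) / gains
  desc <- vapply(hdr$signals, `[[`, character(1), "description")
  if (!any(nzchar(desc))) desc <- NULL
  holter_recording(
    patient_id = patient_id %||% hdr$record,
    signal = phys, fs = hdr$fs,
    channel_names = desc, start_time = hdr$start_time
  )
}

#' Read beat annotations for a record
#'
#' Reads a WFDB annotation file and maps the standard beat codes onto the
#' pipeline's three-way classification: `N`/`L`/`R` to `NORMAL`, `A`/`a`/`J`/`S`
#' to `SVE`, `V` to `VE`, and every other code to `OTHER`. Annotations beyond
#' the end of the recording are dropped with a warning; output is sorted by
#' sample index.
#'
#' @param path Path to the annotation file (`.atr`).
#' @param n_samples Number of samples in the recording the annotations belong
#'   to; used to drop out-of-range entries. `Inf` disables the check.
#' @return A tibble with columns `sample_index` (0-based integer) and
#'   `beat_class` (factor with levels NORMAL, SVE, VE, OTHER).
#' @export
read_annotations <- function(path, n_samples = Inf) {
  ann <- read_wfdb_annotations(path)
  cls <- WFDB_CODE_MAP[as.character(ann$code)]
  cls[is.na(cls)] <- "OTHER"
  out <- tibble::tibble(
    sample_index = as.integer(ann$sample),
    beat_class = beat_class_factor(cls)
  )
  bad <- out$sample_index >= n_samples | out$sample_index < 0L
  if (any(bad)) {
    warn(sprintf("dropped %d out-of-range annotations from %s", sum(bad), path))
    out <- out[!bad, ]
  }
  dplyr::arrange(out, .data$sample_index)
}

#' Write a Holter record and its annotations in WFDB/MIT format
#'
#' Quantises the physical signal to 16-bit digital values with the given gain
#' and writes `.hea`, `.dat` and (when annotations are given) `.atr` files.
#' Round-tripping through [read_record()] reproduces the signal to within one
#' quantisation step (`1 / gain` mV).
#'
#' @param recording A [holter_recording()].
#' @param annotations Optional annotation tibble as from [read_annotations()].
#' @param path Output record path (extension ignored).
#' @param gain ADC units per millivolt (default 200, the WFDB default).
#' @return Invisibly, the record paths.
#' @export
write_record <- function(recording, annotations = NULL, path, gain = 200) {
  stopifnot(inherits(recording, "holter_recording"))
  dig <- round(recording$signal * gain)
  dig[dig > 32767] <- 32767
  dig[dig < -32767] <- -32767
  storage.mode(dig) <- "integer"
  p <- write_wfdb(
    path, dig, recording$fs,
    gains = rep(gain, nrow(dig)), baselines = rep(0L, nrow(dig)),
    units = "mV", descriptions = recording$channel_names,
    start_time = recording$start_time
  )
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    ann <- dplyr::arrange(annotations, .data$sample_index)
    codes <- WFDB_WRITE_CODE[as.character(ann$beat_class)]
    write_wfdb_annotations(p$atr, ann$sample_index, unname(codes))
  } else {
    write_wfdb_annotations(p$atr, integer(0), integer(0))
  }
  invisible(p)
}

#' Read and validate a cohort manifest
#'
#' The manifest is a CSV with one row per patient and columns `patient_id`,
#' `paf_label`, `index_date`, `exam_date`, `record_path`, `annotation_path`.
#' `index_date` is the date pAF was first documented (blank for controls);
#' `exam_date` is the Holter exam date. Dates are ISO-8601. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A validated tibble (`paf_label` logical, dates as `Date`).
#' @export
read_cohort_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c(
    "patient_id", "paf_label", "index_date", "exam_date",
    "record_path", "annotation_path"
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(paste0("manifest lacks columns: ", paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    patient_id = df$patient_id,
    paf_label = tolower(df$paf_label) %in% c("true", "t", "1", "yes"),
    index_date = as.Date(ifelse(nzchar(df$index_date), df$index_date, NA)),
    exam_date = as.Date(df$exam_date),
    record_path = df$record_path,
    annotation_path = df$annotation_path
  )
  validate_manifest(out)
  root <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", out$record_path)
  out$record_path[rel] <- file.path(root, out$record_path[rel])
  rel <- !grepl("^(/|[A-Za-z]:)", out$annotation_path)
  out$annotation_path[rel] <- file.path(root, out$annotation_path[rel])
  out
}

validate_manifest <- function(manifest) {
  if (anyDuplicated(manifest$patient_id)) {
    abort("duplicate patient_id in manifest", class = "holterpaf_validation_error")
  }
  bad <- manifest$paf_label & is.na(manifest$index_date)
  if (any(bad)) {
    abort(
      paste0(
        "pAF patients without an index_date: ",
        paste(manifest$patient_id[bad], collapse = ", ")
      ),
      class = "holterpaf_validation_error"
    )
  }
  invisible(manifest)
}

#' @rdname read_cohort_manifest
#' @param manifest Manifest tibble.
#' @export
write_cohort_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  df <- manifest[, c(
    "patient_id", "paf_label", "index_date", "exam_date",
    "record_path", "annotation_path"
  )]
  df$paf_label <- ifelse(df$paf_label, "true", "false")
  df$index_date <- ifelse(is.na(df$index_date), "", format(df$index_date))
  df$exam_date <- format(df$exam_date)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
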