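SEGMENT_SECONDS <- 7
# 7 s x 128 Hz = 896 samples per channel, the fixed segment geometry the
# encoder consumes (a 3 x 896 matrix per segment).
segment_samples_for <- function(fs) as.integer(round(SEGMENT_SECONDS * fs))

#' Build the ectopy excision mask for a recording
#'
#' Removes a symmetric window of 3.5 s forward and backward around every
#' annotated ectopic beat, so each excised event spans one 7-s segment length
#' and T-wave turbulence following ventricular ectopy is excluded along with
#' the beat itself. Ventricular ectopy is excised under both analysis
#' settings; supraventricular ectopy is additionally excised under setting 2
#' (`"without_sve"`), which trains on pure sinus rhythm. Overlapping removal
#' windows merge.
#'
#' @param recording A [holter_recording()].
#' @param annotations Annotation tibble (sorted by sample index).
#' @param setting `"with_sve"` (setting 1) or `"without_sve"` (setting 2).
#' @param window_s Half-width of the removal window, seconds.
#' @return An object of class `excision_mask`: list with `kept` (tibble of
#'   half-open sample intervals `start`,`end`), `removal_log` (counts by
#'   reason) and `n_samples`.
#' @export
build_excision_mask <- function(recording, annotations,
                                setting = c("with_sve", "without_sve"),
                                window_s = 3.5) {
  setting <- match.arg(setting)
  n <- n_samples(recording)
  w <- round(window_s * recording$fs)
  excise_ve <- annotations$beat_class == "VE"
  excise_sve <- setting == "without_sve" & annotations$beat_class == "SVE"
  centers <- annotations$sample_index[excise_ve | excise_sve]
  log <- c(
    VE_window = sum(excise_ve),
    SVE_window = sum(excise_sve)
  )
  if (length(centers) == 0L) {
    kept <- tibble::tibble(start = 0L, end = n)
  } else {
    rem_start <- pmax(centers - w, 0L)
    rem_end <- pmin(centers + w, n)
    o <- order(rem_start)
    rem_start <- rem_start[o]
    rem_end <- rem_end[o]
    # merge overlapping / touching removal windows
    ms <- rem_start[1L]
    me <- rem_end[1L]
    starts <- integer(0)
    ends <- integer(0)
    for (i in seq_along(rem_start)[-1L]) {
      if (rem_start[i] <= me) {
        me <- max(me, rem_end[i])
      } else {
        starts <- c(starts, ms)
        ends <- c(ends, me)
        ms <- rem_start[i]
        me <- rem_end[i]
      }
    }
    starts <- c(starts, ms)
    ends <- c(ends, me)
    kept_start <- c(0L, ends)
    kept_end <- c(starts, n)
    ok <- kept_end > kept_start
    kept <- tibble::tibble(
      start = as.integer(kept_start[ok]),
      end = as.integer(kept_end[ok])
    )
  }
  structure(
    list(kept = kept, removal_log = log, n_samples = n),
    class = "excision_mask"
  )
}

#' Tag a clock time as daytime or nighttime
#'
#' Nighttime is the fixed window from 22:00 to 07:00, half-open
#' (`[22:00, 07:00)`, wrapping midnight): 22:00:00 is NIGHT, 07:00:00 is DAY.
#'
#' @param time `POSIXct` time(s) or numeric clock hours.
#' @return Factor with levels `DAY`, `NIGHT`.
#' @export
diurnal_tag <- function(time) {
  h <- if (inherits(time, "POSIXct")) clock_hours(time) else time %% 24
  factor(ifelse(h >= 22 | h < 7, "NIGHT", "DAY"), levels = c("DAY", "NIGHT"))
}

#' Cut the kept intervals of a recording into 7-s segments
#'
#' Tiles each kept interval with consecutive non-overlapping 7-s windows
#' starting at the interval start; a trailing remainder shorter than 7 s is
#' discarded. Each segment carries its start clock time, diurnal tag and a
#' `contains_sve` flag (any SVE annotation inside the window — always FALSE
#' under setting 2, where SVE windows were excised).
#'
#' @param recording A [holter_recording()].
#' @param mask An `excision_mask` from [build_excision_mask()].
#' @param annotations Annotation tibble (for the SVE flags).
#' @param keep_samples Attach the raw 3 x 896 sample matrices as a list
#'   column? Set `FALSE` for metadata-only tiling.
#' @return Tibble with columns `patient_id`, `start_sample`, `start_time`,
#'   `diurnal`, `contains_sve`, `label` (NA until [label_segments()]) and
#'   optionally `samples`.
#' @export
extract_segments <- function(recording, mask, annotations, keep_samples = TRUE) {
  seg_len <- segment_samples_for(recording$fs)
  starts <- unlist(lapply(seq_len(nrow(mask$kept)), function(i) {
    a <- mask$kept$start[i]
    b <- mask$kept$end[i]
    k <- (b - a) %/% seg_len
    if (k <= 0L) integer(0) else a + seg_len * (seq_len(k) - 1L)
  }))
  if (length(starts) == 0L) {
    out <- tibble::tibble(
      patient_id = character(0), start_sample = integer(0),
      start_time = as.POSIXct(character(0), tz = "UTC"),
      diurnal = diurnal_tag(numeric(0)), contains_sve = logical(0),
      label = logical(0)
    )
    if (keep_samples) out$samples <- list()
    return(out)
  }
  sve_samples <- annotations$sample_index[annotations$beat_class == "SVE"]
  contains_sve <- vapply(
    starts,
    function(s) any(sve_samples >= s & sve_samples < s + seg_len),
    logical(1)
  )
  start_time <- sample_time(recording, starts)
  out <- tibble::tibble(
    patient_id = recording$patient_id,
    start_sample = as.integer(starts),
    start_time = start_time,
    diurnal = diurnal_tag(start_time),
    contains_sve = contains_sve,
    label = NA
  )
  if (keep_samples) {
    out$samples <- lapply(starts, function(s) {
      recording$signal[, (s + 1L):(s + seg_len), drop = FALSE]
    })
  }
  out
}

#' Rule-based segment noise gate
#'
#' Drops segments whose raw signal is unusable: any channel that is flatline
#' (variance below `flat_var`), saturated (more than `max_rail_frac` of
#' samples at or beyond `rail_mv` in magnitude), or outside the physiological
#' amplitude range (`amp_range_mv`). A deterministic stand-in for manual /
#' learned noise review, with every threshold exposed.
#'
#' @param samples Raw (un-normalised) channels x samples matrix, mV.
#' @param flat_var Flatline variance threshold, mV^2.
#' @param rail_mv Saturation rail, mV.
#' @param max_rail_frac Tolerated fraction of samples at the rail.
#' @param amp_range_mv Hard amplitude bound, mV.
#' @return `TRUE` to keep the segment, `FALSE` to drop it.
#' @export
noise_gate <- function(samples, flat_var = 1e-6, rail_mv = 5,
                       max_rail_frac = 0.05, amp_range_mv = 8) {
  for (ch in seq_len(nrow(samples))) {
    x <- samples[ch, ]
    if (var(x) < flat_var) return(FALSE)
    if (mean(abs(x) >= rail_mv) > max_rail_frac) return(FALSE)
    if (max(abs(x)) > amp_range_mv) return(FALSE)
  }
  TRUE
}

#' Z-normalise a segment per channel
#'
#' Subtracts the mean and divides by the standard deviation of each channel
#' independently. A zero-variance channel maps to all zeros.
#'
#' @param samples Channels x samples matrix.
#' @return Matrix of the same shape with per-channel mean 0 and SD 1.
#' @export
znormalize <- function(samples) {
  out <- samples
  for (ch in seq_len(nrow(samples))) {
    s <- sd(samples[ch, ])
    out[ch, ] <- if (s > 0) (samples[ch, ] - mean(samples[ch, ])) / s else 0
  }
  out
}

hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Short-time Fourier transform of a segment
#'
#' Computes, per channel, the log-scaled magnitude STFT `log(1 + |X|)` over
#' Hann-windowed frames of `window_size` samples advanced by `hop`, with no
#' padding: `F = floor(window_size / 2) + 1` frequency bins and
#' `T = floor((n - window_size) / hop) + 1` frames.
#'
#' @param samples Channels x samples matrix (normally Z-normalised).
#' @param window_size Frame length in samples (the pipeline default is 50).
#' @param hop Frame advance in samples (default half the window).
#' @return Numeric array of dimension `F x T x channels`, with attributes
#'   `window_size` and `hop`.
#' @export
stft_transform <- function(samples, window_size = 50, hop = window_size / 2) {
  n <- ncol(samples)
  hop <- as.integer(round(hop))
  if (window_size > n) abort("window_size exceeds the segment length")
  n_f <- window_size %/% 2 + 1L
  n_t <- (n - window_size) %/% hop + 1L
  w <- hann_window(window_size)
  starts <- (seq_len(n_t) - 1L) * hop
  idx <- outer(seq_len(window_size), starts, `+`) # window_size x n_t
  n_ch <- nrow(samples)
  frames <- matrix(0, nrow = window_size, ncol = n_t * n_ch)
  for (ch in seq_len(n_ch)) {
    frames[, (ch - 1L) * n_t + seq_len(n_t)] <- samples[ch, ][idx] * w
  }
  spec <- Mod(mvfft(frames))[seq_len(n_f), , drop = FALSE]
  out <- array(log1p(spec), dim = c(n_f, n_t, n_ch))
  attr(out, "window_size") <- window_size
  attr(out, "hop") <- hop
  out
}

#' Propagate patient-level labels to segments
#'
#' Under segment-wise training every segment inherits the pAF label of the
#' patient it came from: all segments of a pAF patient are positive, all
#' segments of a control are negative.
#'
#' @param segments Segment tibble with a `patient_id` column.
#' @param manifest Cohort manifest (`patient_id`, `paf_label`).
#' @return Segment tibble with the `label` column filled.
#' @export
label_segments <- function(segments, manifest) {
  lab <- setNames(manifest$paf_label, manifest$patient_id)
  unknown <- setdiff(unique(segments$patient_id), names(lab))
  if (length(unknown) > 0L) {
    abort(paste0("segments reference patients absent from the manifest: ",
      paste(unknown, collapse = ", ")))
  }
  segments$label <- unname(lab[segments$patient_id])
  segments
}

#' Full preprocessing chain for one patient
#'
#' Excision mask, 7-s tiling, noise gating. Returns raw (un-normalised)
#' segments; Z-normalisation and STFT are applied at encoding time.
#'
#' @param recording A [holter_recording()].
#' @param annotations Annotation tibble.
#' @param setting 1 (keep SVE) or 2 (excise SVE windows).
#' @param gate Apply the [noise_gate()]? Dropped segments are counted in the
#'   `removal_log` attribute.
#' @param ... Passed to [noise_gate()].
#' @return Segment tibble (see [extract_segments()]) with attribute
#'   `removal_log`.
#' @export
preprocess_patient <- function(recording, annotations, setting = 1,
                               gate = TRUE, ...) {
  set_chr <- if (as.character(setting) %in% c("2", "without_sve")) {
    "without_sve"
  } else {
    "with_sve"
  }
  mask <- build_excision_mask(recording, annotations, set_chr)
  segs <- extract_segments(recording, mask, annotations)
  n_noise <- 0L
  if (gate && nrow(segs) > 0L) {
    keep <- vapply(segs$samples, noise_gate, logical(1), ...)
    n_noise <- sum(!keep)
    segs <- segs[keep, ]
  }
  attr(segs, "removal_log") <- c(mask$removal_log, noise = n_noise)
  segs
}

#' Preprocess an entire cohort
#'
#' Runs [preprocess_patient()] over every manifest row and labels the pooled
#' segments.
#'
#' @param manifest Cohort manifest tibble with resolved paths.
#' @param setting 1 or 2.
#' @param ... Passed to [preprocess_patient()].
#' @return Labelled segment tibble for all patients, with an attached
#'   `spans` attribute (tibble `patient_id`, `span_start`, `span_end` — the
#'   clock extent of each recording, used for temporal binning).
#' @export
preprocess_cohort <- function(manifest, setting = 1, ...) {
  spans <- vector("list", nrow(manifest))
  pieces <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_record(manifest$record_path[i], manifest$patient_id[i])
    ann <- read_annotations(manifest$annotation_path[i], n_samples(rec))
    spans[[i]] <<- tibble::tibble(
      patient_id = manifest$patient_id[i],
      span_start = rec$start_time,
      span_end = rec$start_time + n_samples(rec) / rec$fs
    )
    preprocess_patient(rec, ann, setting = setting, ...)
  })
  out <- label_segments(dplyr::bind_rows(pieces), manifest)
  attr(out, "spans") <- dplyr::bind_rows(spans)
  out
}

#' Stack segment spectrograms into one array
#'
#' Z-normalises each segment, applies [stft_transform()] and stacks the
#' results into a single `F x T x channels x n_segments` array — the tensor
#' the segment encoder consumes.
#'
#' @param segments Segment tibble with a `samples` list column.
#' @param window_size,hop STFT parameters.
#' @return List with `x` (the 4-D array) and `meta` (the segment tibble
#'   without the `samples` column).
#' @export
segment_spectrograms <- function(segments, window_size = 50, hop = window_size / 2) {
  if (nrow(segments) == 0L) abort("no segments to transform")
  first <- stft_transform(znormalize(segments$samples[[1]]), window_size, hop)
  d <- dim(first)
  x <- array(0, dim = c(d, nrow(segments)))
  x[, , , 1L] <- first
  if (nrow(segments) > 1L) {
    for (i in 2:nrow(segments)) {
      x[, , , i] <- stft_transform(znormalize(segments$samples[[i]]), window_size, hop)
    }
  }
  meta <- segments[, setdiff(names(segments), "samples")]
  list(x = x, meta = meta)
}
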