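# Minimal MIT/WFDB reader and writer: header (.hea), 16-bit signal (.dat),
# annotation (.atr) files. Only what ambulatory Holter exports need: format 16,
# per-channel gain/baseline, base time/date, beat annotations with the
# standard two-byte annotation words (SKIP/NUM/SUB/CHN/AUX handled on read).

WFDB_INVALID_16 <- -32768L

# Standard WFDB annotation codes used here. The mapping to the pipeline's
# three-way beat classification is fixed: N/L/R -> NORMAL, A/a/J/S -> SVE,
# V -> VE, everything else -> OTHER.
WFDB_CODE_MAP <- c(
  "1" = "NORMAL", "2" = "NORMAL", "3" = "NORMAL", # N, L, R
  "4" = "SVE", "7" = "SVE", "8" = "SVE", "9" = "SVE", # a, J, A, S
  "5" = "VE" # V
)
WFDB_WRITE_CODE <- c(NORMAL = 1L, SVE = 8L, VE = 5L, OTHER = 13L)

wfdb_paths <- function(path) {
  dir <- dirname(path)
  rec <- sub("\\.(hea|dat|atr)$", "", basename(path))
  list(
    record = rec,
    hea = file.path(dir, paste0(rec, ".hea")),
    dat = file.path(dir, paste0(rec, ".dat")),
    atr = file.path(dir, paste0(rec, ".atr"))
  )
}

parse_wfdb_time <- function(base_time, base_date) {
  if (is.na(base_time) || !nzchar(base_time)) return(as.POSIXct(NA))
  date <- if (!is.na(base_date) && nzchar(base_date)) {
    as.Date(base_date, format = "%d/%m/%Y")
  } else {
    as.Date("2000-01-01")
  }
  as.POSIXct(paste(format(date), base_time), tz = "UTC")
}

read_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path)) {
    abort(paste0("WFDB header not found: ", hea_path), class = "holterpaf_format_error")
  }
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L) {
    abort(paste0("Empty WFDB header: ", hea_path), class = "holterpaf_format_error")
  }
  top <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(top) < 4L) {
    abort(paste0("Malformed WFDB header line: ", lines[[1]]),
      class = "holterpaf_format_error"
    )
  }
  n_sig <- suppressWarnings(as.integer(top[[2]]))
  fs <- suppressWarnings(as.numeric(sub("/.*$", "", top[[3]])))
  n_samples <- suppressWarnings(as.integer(top[[4]]))
  if (is.na(n_sig) || is.na(fs) || is.na(n_samples) || fs <= 0) {
    abort(paste0("Malformed WFDB header line: ", lines[[1]]),
      class = "holterpaf_format_error"
    )
  }
  base_time <- if (length(top) >= 5L) top[[5]] else NA_character_
  base_date <- if (length(top) >= 6L) top[[6]] else NA_character_

  if (length(lines) < 1L + n_sig) {
    abort("WFDB header declares more signals than it describes",
      class = "holterpaf_format_error"
    )
  }
  sig <- lapply(lines[1L + seq_len(n_sig)], function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 3L) {
      abort(paste0("Malformed WFDB signal line: ", ln), class = "holterpaf_format_error")
    }
    fmt <- sub("x.*$", "", tok[[2]])
    if (fmt != "16") {
      abort(paste0("Unsupported WFDB signal format: ", tok[[2]], " (only format 16)"),
        class = "holterpaf_format_error"
      )
    }
    # gain spec: gain(baseline)/units, each part optional
    gspec <- tok[[3]]
    units <- if (grepl("/", gspec)) sub("^[^/]*/", "", gspec) else "mV"
    gmain <- sub("/.*$", "", gspec)
    baseline <- if (grepl("\\(", gmain)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gmain))
    } else {
      NA_real_
    }
    gain <- as.numeric(sub("\\(.*$", "", gmain))
    if (is.na(gain) || gain == 0) gain <- 200 # WFDB default ADU/mV
    adc_zero <- if (length(tok) >= 5L) suppressWarnings(as.numeric(tok[[5]])) else 0
    if (is.na(baseline)) baseline <- if (is.na(adc_zero)) 0 else adc_zero
    desc <- if (length(tok) >= 9L) paste(tok[9:length(tok)], collapse = " ") else ""
    list(
      file = tok[[1]], gain = gain, baseline = baseline,
      units = units, description = desc
    )
  })
  list(
    record = top[[1]], n_sig = n_sig, fs = fs, n_samples = n_samples,
    start_time = parse_wfdb_time(base_time, base_date), signals = sig
  )
}

read_wfdb_signal <- function(dat_path, n_sig, n_samples) {
  if (!file.exists(dat_path)) {
    abort(paste0("WFDB signal file not found: ", dat_path),
      class = "holterpaf_format_error"
    )
  }
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n_sig * n_samples, size = 2L,
    signed = TRUE, endian = "little")
  if (length(raw) < n_sig * n_samples) {
    abort("WFDB signal file shorter than header declares",
      class = "holterpaf_format_error"
    )
  }
  matrix(raw, nrow = n_sig, ncol = n_samples) # interleaved frames -> channels in rows
}

write_wfdb <- function(path, digital, fs, gains, baselines, units, descriptions,
                       start_time) {
  p <- wfdb_paths(path)
  n_sig <- nrow(digital)
  n_samples <- ncol(digital)
  fmt_gain <- sprintf("%g(%d)/%s", gains, as.integer(baselines), units)
  init <- digital[, 1L]
  cks <- vapply(seq_len(n_sig), function(i) {
    s <- sum(as.numeric(digital[i, ])) %% 65536
    as.integer(if (s >= 32768) s - 65536 else s)
  }, integer(1))
  head_line <- if (is.na(start_time)) {
    sprintf("%s %d %g %d", p$record, n_sig, fs, n_samples)
  } else {
    sprintf(
      "%s %d %g %d %s %s", p$record, n_sig, fs, n_samples,
      format(start_time, "%H:%M:%S", tz = "UTC"),
      format(start_time, "%d/%m/%Y", tz = "UTC")
    )
  }
  sig_lines <- sprintf(
    "%s.dat 16 %s 16 %d %d %d 0 %s",
    p$record, fmt_gain, as.integer(baselines), init, cks, descriptions
  )
  writeLines(c(head_line, sig_lines), p$hea)
  con <- file(p$dat, "wb")
  on.exit(close(con))
  writeBin(as.integer(digital), con, size = 2L, endian = "little")
  invisible(p)
}

# --- annotation files ---------------------------------------------------------

# Annotation words are 16-bit little-endian: code in the top 6 bits, time
# increment in the low 10. Intervals > 1023 samples use a SKIP (59)
# pseudo-annotation followed by a 32-bit interval stored high word first.
read_wfdb_annotations <- function(atr_path) {
  if (!file.exists(atr_path)) {
    abort(paste0("WFDB annotation file not found: ", atr_path),
      class = "holterpaf_format_error"
    )
  }
  bytes <- readBin(atr_path, "raw", n = file.info(atr_path)$size)
  n <- length(bytes)
  out_sample <- integer(0)
  out_code <- integer(0)
  t <- 0
  i <- 1L
  pending_skip <- 0
  word_at <- function(j) {
    as.integer(bytes[j]) + 256L * as.integer(bytes[j + 1L])
  }
  while (i + 1L <= n) {
    w <- word_at(i)
    i <- i + 2L
    code <- w %/% 1024L
    interval <- w %% 1024L
    if (w == 0L) break # end of file marker
    if (code == 59L) { # SKIP: 4-byte interval, high word first
      if (i + 3L > n) break
      hi <- word_at(i)
      lo <- word_at(i + 2L)
      i <- i + 4L
      v <- hi * 65536 + lo
      if (v >= 2147483648) v <- v - 4294967296
      pending_skip <- pending_skip + v
    } else if (code == 63L) { # AUX: skip string (padded to even length)
      i <- i + interval + (interval %% 2L)
    } else if (code %in% c(60L, 61L, 62L)) { # NUM / SUB / CHN: no time
      next
    } else {
      t <- t + pending_skip + interval
      pending_skip <- 0
      out_sample <- c(out_sample, t)
      out_code <- c(out_code, code)
    }
  }
  list(sample = out_sample, code = out_code)
}

write_wfdb_annotations <- function(atr_path, samples, codes) {
  stopifnot(length(samples) == length(codes))
  words <- integer(0)
  prev <- 0
  for (k in seq_along(samples)) {
    dt <- samples[[k]] - prev
    prev <- samples[[k]]
    if (dt > 1023) {
      hi <- dt %/% 65536
      lo <- dt %% 65536
      words <- c(words, 59L * 1024L, hi, lo, codes[[k]] * 1024L)
    } else {
      words <- c(words, codes[[k]] * 1024L + dt)
    }
  }
  words <- c(words, 0L)
  bytes <- as.raw(rbind(words %% 256L, words %/% 256L))
  writeBin(bytes, atr_path)
  invisible(atr_path)
}
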