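test_that("WFDB write/read round-trips signal, metadata and annotations", {
  set.seed(3)
  sig <- matrix(rnorm(3 * 8960, 0, 0.6), nrow = 3)
  rec <- holter_recording("R01", sig, 128, start_time = utc("2024-02-01 08:30:00"))
  ann <- tibble::tibble(
    sample_index = c(100L, 2000L, 5000L, 8900L),
    beat_class = factor(c("NORMAL", "SVE", "VE", "OTHER"),
      levels = c("NORMAL", "SVE", "VE", "OTHER"))
  )
  dir <- withr::local_tempdir()
  write_record(rec, ann, file.path(dir, "R01"))

  back <- read_record(file.path(dir, "R01"))
  expect_equal(ncol(back$signal), 8960) # 70 s x 128 Hz
  expect_lte(max(abs(back$signal - sig)), 1 / 200 / 2 + 1e-12) # half a quantum
  expect_equal(back$fs, 128)
  expect_equal(back$start_time, rec$start_time)
  expect_equal(back$channel_names, rec$channel_names)

  ann_back <- read_annotations(file.path(dir, "R01.atr"), 8960)
  expect_equal(as.data.frame(ann_back), as.data.frame(ann))
})

test_that("physical values follow (digital - baseline) / gain from the header", {
  dir <- withr::local_tempdir()
  digital <- matrix(rep(0:255, each = 3), nrow = 3) # a known ramp
  digital[2, ] <- digital[2, ] + 50L
  storage.mode(digital) <- "integer"
  holterpaf:::write_wfdb(
    file.path(dir, "ramp"), digital, 128,
    gains = c(200, 100, 200), baselines = c(0L, 50L, -10L),
    units = "mV", descriptions = c("a", "b", "c"),
    start_time = utc("2024-01-01 00:00:00")
  )
  rec <- read_record(file.path(dir, "ramp"))
  expect_equal(rec$signal[1, ], (0:255 - 0) / 200)
  expect_equal(rec$signal[2, ], (0:255 + 50 - 50) / 100)
  expect_equal(rec$signal[3, ], (0:255 + 10) / 200)
})

test_that("annotation beat codes map to the three-way classification", {
  dir <- withr::local_tempdir()
  # N(1), S(9), V(5), N(1), plus a code outside the beat map (12 -> OTHER)
  holterpaf:::write_wfdb_annotations(
    file.path(dir, "m.atr"), c(10L, 50L, 90L, 130L, 170L), c(1L, 9L, 5L, 1L, 12L)
  )
  ann <- read_annotations(file.path(dir, "m.atr"))
  expect_equal(
    as.character(ann$beat_class),
    c("NORMAL", "SVE", "VE", "NORMAL", "OTHER")
  )
  expect_equal(ann$sample_index, c(10L, 50L, 90L, 130L, 170L))
})

test_that("empty annotation files and out-of-range entries are handled", {
  dir <- withr::local_tempdir()
  holterpaf:::write_wfdb_annotations(file.path(dir, "e.atr"), integer(0), integer(0))
  expect_equal(nrow(read_annotations(file.path(dir, "e.atr"))), 0L)

  holterpaf:::write_wfdb_annotations(file.path(dir, "o.atr"), c(10L, 99999L), c(1L, 1L))
  expect_warning(
    ann <- read_annotations(file.path(dir, "o.atr"), n_samples = 1000),
    "out-of-range"
  )
  expect_equal(ann$sample_index, 10L)
})

test_that("long inter-annotation gaps use the SKIP encoding transparently", {
  dir <- withr::local_tempdir()
  samples <- c(5L, 500L, 200000L, 200500L) # 199500-sample gap needs SKIP
  holterpaf:::write_wfdb_annotations(file.path(dir, "s.atr"), samples, rep(1L, 4))
  expect_equal(read_annotations(file.path(dir, "s.atr"))$sample_index, samples)
})

test_that("non-conformant channel counts warn but read", {
  dir <- withr::local_tempdir()
  rec <- holter_recording("X", matrix(rnorm(2 * 256), nrow = 2), 128,
    channel_names = c("a", "b"), start_time = utc("2024-01-01 00:00:00"))
  write_record(rec, NULL, file.path(dir, "X"))
  expect_warning(read_record(file.path(dir, "X")), "expects 3")
})

test_that("recording constructor enforces its invariants", {
  expect_error(holter_recording("X", matrix(numeric(0), 3, 0), 128), "one sample")
  expect_error(holter_recording("X", matrix(0, 3, 4), -1), "fs")
  expect_error(holter_recording("X", matrix(c(1, NA, 1, 1, 1, 1), 3, 2), 128),
    "missing")
  expect_error(read_record(tempfile()), class = "holterpaf_format_error")
})

test_that("sample index and clock time convert bijectively on the grid", {
  rec <- holter_recording("X", matrix(0, 3, 1000), 128,
    start_time = utc("2024-01-01 23:59:59"))
  k <- c(0L, 1L, 127L, 128L, 999L)
  expect_equal(time_sample(rec, sample_time(rec, k)), k)
  expect_equal(sample_time(rec, 128L), utc("2024-01-02 00:00:00"))
})

test_that("cohort manifests validate ids, labels and dates", {
  dir <- withr::local_tempdir()
  man <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    paf_label = c(TRUE, FALSE, FALSE),
    index_date = as.Date(c("2023-06-01", NA, NA)),
    exam_date = as.Date("2024-01-01"),
    record_path = paste0(c("A", "B", "C"), ".hea"),
    annotation_path = paste0(c("A", "B", "C"), ".atr")
  )
  path <- file.path(dir, "manifest.csv")
  write_cohort_manifest(man, path)
  back <- read_cohort_manifest(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$paf_label, man$paf_label)
  expect_equal(back$index_date, man$index_date)
  expect_true(all(startsWith(back$record_path, dir))) # relative paths resolved

  dup <- man
  dup$patient_id <- c("A", "A", "C")
  expect_error(write_cohort_manifest(dup, path), class = "holterpaf_validation_error")

  bad <- man
  bad$index_date[1] <- NA
  expect_error(write_cohort_manifest(bad, path), class = "holterpaf_validation_error")
})
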