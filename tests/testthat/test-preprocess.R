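mk_rec <- function(n, fs = 128, start = "2024-01-01 10:00:00") {
  set.seed(n)
  holter_recording("P", matrix(rnorm(3 * n, 0, 0.3), nrow = 3), fs,
    start_time = utc(start))
}

ann_tbl <- function(samples, classes) {
  tibble::tibble(sample_index = as.integer(samples),
    beat_class = factor(classes, levels = c("NORMAL", "SVE", "VE", "OTHER")))
}

test_that("excision removes 3.5 s around ectopy and merges windows", {
  rec <- mk_rec(8960) # 70 s at 128 Hz
  none <- ann_tbl(integer(0), character(0))
  m0 <- build_excision_mask(rec, none, "with_sve")
  expect_equal(as.data.frame(m0$kept), data.frame(start = 0L, end = 8960L))

  # one VE at t = 35 s: removal [31.5 s, 38.5 s) = samples [4032, 4928)
  ve <- ann_tbl(35 * 128, "VE")
  m1 <- build_excision_mask(rec, ve, "with_sve")
  expect_equal(as.data.frame(m1$kept),
    data.frame(start = c(0L, 4928L), end = c(4032L, 8960L)))

  # one SVE at 35 s: kept whole under setting 1, excised under setting 2
  sve <- ann_tbl(35 * 128, "SVE")
  expect_equal(build_excision_mask(rec, sve, "with_sve")$kept$end, 8960L)
  expect_equal(as.data.frame(build_excision_mask(rec, sve, "without_sve")$kept),
    as.data.frame(m1$kept))

  # two close VEs merge into one removal window
  two <- ann_tbl(c(35, 37) * 128, c("VE", "VE"))
  m2 <- build_excision_mask(rec, two, "with_sve")
  expect_equal(nrow(m2$kept), 2L)
  expect_equal(m2$kept$end[1], (35 * 128 - 448))
  expect_equal(m2$kept$start[2], (37 * 128 + 448))
})

test_that("tiling yields the documented segment counts", {
  rec <- mk_rec(8960)
  none <- ann_tbl(integer(0), character(0))
  segs <- extract_segments(rec, build_excision_mask(rec, none, "with_sve"), none)
  expect_equal(nrow(segs), 10L) # 70 s / 7 s

  ve <- ann_tbl(35 * 128, "VE")
  segs_ve <- extract_segments(rec, build_excision_mask(rec, ve, "with_sve"), ve)
  expect_equal(nrow(segs_ve), 8L) # 4 + 4, two 3.5-s remainders discarded

  short <- mk_rec(883) # 6.9 s: below one window
  segs_s <- extract_segments(short,
    build_excision_mask(short, none, "with_sve"), none)
  expect_equal(nrow(segs_s), 0L)

  expect_true(all(vapply(segs$samples, function(s) all(dim(s) == c(3, 896)),
    logical(1))))
})

test_that("segment tiling matches the brute-force oracle on random ectopy", {
  fs <- 128
  for (trial in 1:25) {
    set.seed(trial + 500)
    n <- sample(3000:20000, 1)
    rec <- holter_recording("P", matrix(0, 3, n), fs,
      start_time = utc("2024-01-01 10:00:00"))
    ve <- sort(sample(0:(n - 1), sample(0:4, 1)))
    sve <- sort(sample(0:(n - 1), sample(0:4, 1)))
    both <- ann_tbl(c(ve, sve), c(rep("VE", length(ve)), rep("SVE", length(sve))))
    both <- dplyr::arrange(both, sample_index)
    for (setting in c(1, 2)) {
      set_chr <- if (setting == 1) "with_sve" else "without_sve"
      mask <- build_excision_mask(rec, both, set_chr)
      segs <- extract_segments(rec, mask, both, keep_samples = FALSE)
      expect_equal(segs$start_sample,
        brute_segments(n, fs, ve, sve, setting),
        label = sprintf("trial %d setting %d", trial, setting))
      # no segment may overlap any excised region
      for (s in segs$start_sample) {
        inside <- any(mask$kept$start <= s & s + 896 <= mask$kept$end)
        expect_true(inside)
      }
      if (setting == 2) expect_false(any(segs$contains_sve))
    }
  }
})

test_that("retained duration never exceeds the recording and tags partition", {
  pat <- fixture_recording(duration_s = 120, sve_rate = 60, ve_rate = 30,
    start = "21:55:00")
  segs <- preprocess_patient(pat$recording, pat$annotations, setting = 1)
  expect_lte(7 * nrow(segs), 120)
  expect_true(all(segs$diurnal %in% c("DAY", "NIGHT")))
  expect_equal(
    sum(segs$diurnal == "DAY") + sum(segs$diurnal == "NIGHT"), nrow(segs)
  )
})

test_that("the noise gate drops flatline, saturated and out-of-range segments", {
  clean <- fixture_recording(duration_s = 14)$recording$signal[, 1:896]
  expect_true(noise_gate(clean))
  expect_false(noise_gate(matrix(0, 3, 896))) # flatline
  clipped <- clean
  clipped[1, 1:90] <- 5 # 10 percent of samples at the 5 mV rail
  expect_false(noise_gate(clipped))
  big <- clean
  big[2, 10] <- 9 # outside the physiological range
  expect_false(noise_gate(big))
})

test_that("Z-normalisation centres, scales, guards and is idempotent", {
  set.seed(8)
  m <- matrix(rnorm(3 * 896, 5, 3), nrow = 3)
  z <- znormalize(m)
  expect_equal(unname(apply(z, 1, mean)), rep(0, 3), tolerance = 1e-6)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 3), tolerance = 1e-6)
  expect_equal(znormalize(z), z, tolerance = 1e-6)
  flat <- m
  flat[2, ] <- 4.2
  expect_equal(znormalize(flat)[2, ], rep(0, 896))
})

test_that("the STFT has the documented geometry and localises pure tones", {
  z <- matrix(0, 3, 896)
  sp0 <- stft_transform(z, 50, 25)
  expect_equal(dim(sp0), c(26, 34, 3)) # F = 50/2 + 1, T = (896-50)/25 + 1
  expect_true(all(sp0 == 0))

  fs <- 128
  bin <- 5 # frequency 5 * fs / 50 = 12.8 Hz, exactly on a bin
  x <- matrix(rep(sin(2 * pi * bin * (0:895) / 50), 3), nrow = 3, byrow = TRUE)
  sp <- stft_transform(x, 50, 25)
  mag2 <- expm1(sp[, , 1])^2
  conc <- sum(mag2[bin:(bin + 2), ]) / sum(mag2) # bin +/- 1 (1-based rows)
  expect_gt(conc, 0.9)
  expect_equal(which.max(rowSums(mag2)), bin + 1L)

  # frame 1 equals a directly computed windowed DFT
  w <- 0.5 * (1 - cos(2 * pi * (0:49) / 49))
  direct <- abs(fft(x[1, 1:50] * w))[1:26]
  expect_equal(expm1(sp[, 1, 1]), direct, tolerance = 1e-10)

  expect_error(stft_transform(z, 1000), "window_size")
})

test_that("the diurnal boundary convention is [22:00, 07:00) for night", {
  expect_equal(as.character(diurnal_tag(utc("2024-01-01 22:00:00"))), "NIGHT")
  expect_equal(as.character(diurnal_tag(utc("2024-01-01 07:00:00"))), "DAY")
  expect_equal(as.character(diurnal_tag(utc("2024-01-01 12:00:00"))), "DAY")
  expect_equal(as.character(diurnal_tag(utc("2024-01-01 03:30:00"))), "NIGHT")
  expect_equal(as.character(diurnal_tag(utc("2024-01-01 21:59:59"))), "DAY")
})

test_that("patient labels propagate to every segment", {
  man <- fixture_cohort(n = 4, duration_s = 120, seed = 13)
  segs <- preprocess_cohort(man, setting = 1)
  counts <- table(segs$patient_id, segs$label)
  for (pid in man$patient_id) {
    lab <- man$paf_label[man$patient_id == pid]
    n_pid <- sum(segs$patient_id == pid)
    expect_equal(sum(segs$label[segs$patient_id == pid] == lab), n_pid)
  }
  expect_equal(sum(segs$label), sum(segs$label[segs$patient_id %in%
    man$patient_id[man$paf_label]]))
})
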