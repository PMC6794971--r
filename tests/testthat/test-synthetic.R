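test_that("generation is deterministic per seed and subjects are distinct", {
  params <- cohort_params(n_subjects = 2, duration_min = 5)
  a <- generate_subject("S1", params, seed = 12)
  b <- generate_subject("S1", params, seed = 12)
  expect_identical(a, b)
  c2 <- generate_subject("S1", params, seed = 13)
  expect_false(identical(a$streams$ecg$values, c2$streams$ecg$values))

  cohort <- generate_cohort(cohort_params(n_subjects = 15, duration_min = 5), seed = 1)
  expect_length(cohort, 15)
  expect_length(unique(vapply(cohort, `[[`, "", "subject_id")), 15)
})

test_that("chest streams are 16-bit ADC integers and rates are native", {
  rec <- generate_subject("S1", cohort_params(n_subjects = 1, duration_min = 5), seed = 2)
  for (nm in c("ecg", "emg", "resp")) {
    v <- rec$streams[[nm]]$values
    expect_true(all(v >= 0 & v < 2^16 & v == floor(v)))
    expect_equal(rec$streams[[nm]]$rate_hz, 700)
  }
  expect_equal(rec$streams$bvp$rate_hz, 64)
  expect_equal(rec$streams$acc_wrist$rate_hz, 32)
  expect_equal(rec$streams$temp_wrist$rate_hz, 4)
  expect_equal(length(rec$labels), 700 * 60 * 5)
})

test_that("equal class durations yield five contiguous 60 s label runs", {
  params <- cohort_params(
    n_subjects = 1, duration_min = 5,
    class_proportions = rep(0.2, 5)
  )
  rec <- generate_subject("S1", params, seed = 5)
  runs <- rle(rec$labels)
  expect_equal(runs$values, 0:4)
  expect_equal(runs$lengths, rep(700 * 60, 5))
})

test_that("pooled 10 Hz label shares track the requested class proportions", {
  params <- cohort_params(n_subjects = 3, duration_min = 50)
  cohort <- generate_cohort(params, seed = 9)
  labels10 <- unlist(lapply(cohort, function(r) downsample_labels(r$labels)))
  shares <- tabulate(labels10 + 1L, 5) / length(labels10)
  target <- wesad_class_counts() / sum(wesad_class_counts())
  expect_true(all(abs(shares - target) <= 0.02))
})

test_that("zero inter-subject jitter makes configured rates identical", {
  params <- cohort_params(n_subjects = 2, duration_min = 5, subject_jitter = 0)
  cohort <- generate_cohort(params, seed = 30)
  rates <- lapply(cohort, function(rec) {
    s <- process_recording(rec)
    pk <- mindcnn:::detect_peaks_by_minute(s$streams$ecg, default_peak_params("ecg"))
    mf <- minute_peak_features(s$streams$ecg, pk, "ecg")
    cls <- s$labels[seq(1, length(s$labels), by = 600)][seq_len(nrow(mf))]
    tapply(mf$peaks, cls, mean)
  })
  # same configured heart rates -> same detected per-class peak rates (+-1 beat)
  expect_true(all(abs(rates[[1]] - rates[[2]]) <= 1.5))
})

test_that("detected ECG peak rate recovers the configured heart rate (slope 1)", {
  params <- cohort_params(n_subjects = 1, duration_min = 15, subject_jitter = 0)
  rec <- generate_subject("S1", params, seed = 21)
  s <- process_recording(rec)
  pk <- mindcnn:::detect_peaks_by_minute(s$streams$ecg, default_peak_params("ecg"))
  mf <- minute_peak_features(s$streams$ecg, pk, "ecg")
  cls <- s$labels[seq(1, length(s$labels), by = 600)][seq_len(nrow(mf))]
  configured <- params$heart_rate_bpm[cls + 1]
  fitline <- lm(mf$peaks ~ configured)
  expect_lt(abs(coef(fitline)[2] - 1), 0.1)
  # each minute's count within 10% of the configured rate
  expect_true(all(abs(mf$peaks - configured) / configured <= 0.1))
})
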