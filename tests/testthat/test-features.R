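test_that("peak detector handles monotone series and the suppression rule", {
  p <- peak_params(threshold_k = 0, min_distance = 3)
  expect_length(detect_peaks(1:100, p), 0)
  # two candidate peaks 2 samples apart: only the amplitude-7 one survives
  x <- c(0, 5, 0, 7, 0)
  expect_equal(detect_peaks(x, p, threshold = 0), 4L)
  # at min_distance 1 both survive
  expect_equal(detect_peaks(x, peak_params(0, 1), threshold = 0), c(2L, 4L))
})

test_that("a 1.2 Hz sinusoid over a minute yields 72 peaks at 10 Hz", {
  t <- (0:599) / 10
  x <- sin(2 * pi * 1.2 * t)
  got <- detect_peaks(x, peak_params(threshold_k = 0, min_distance = 3))
  expect_length(got, 72)
  expect_equal(got, oracle_peaks(x, 3, mean(x)))
})

test_that("peak detector matches the brute-force oracle on random series", {
  set.seed(13)
  for (case in 1:8) {
    n <- sample(c(50, 500, 2000), 1)
    x <- cumsum(rnorm(n)) + rnorm(n, sd = 2)
    params <- peak_params(
      threshold_k = sample(c(0, 0.5, 1), 1),
      min_distance = sample(c(1, 2, 3, 7), 1)
    )
    thr <- mean(x) + params$threshold_k * sd(x)
    expect_equal(detect_peaks(x, params), oracle_peaks(x, params$min_distance, thr))
  }
})

test_that("minute features follow the stated arithmetic and conventions", {
  # one minute with three peaks of amplitude 2, 4, 8
  x <- rep(0, 600)
  pk <- c(100L, 200L, 300L)
  x[pk] <- c(2, 4, 8)
  mf <- minute_peak_features(x, pk, "ecg")
  expect_equal(mf$peaks, 3)
  expect_equal(mf$average_amplitude, mean(c(2, 4, 8)), tolerance = 1e-3)
  expect_equal(mf$differ_mean, 3) # mean(|4-2|, |8-4|)
  # empty minute -> all-zero convention
  mf0 <- minute_peak_features(rep(0, 600), integer(0), "ecg")
  expect_equal(unlist(mf0), c(peaks = 0, average_amplitude = 0, differ_mean = 0, resting = 0))
  # 60 evenly spread peaks -> resting 1 peak/second
  pk60 <- seq(5L, 600L, by = 10L)
  x60 <- rep(0, 600)
  x60[pk60] <- 1
  expect_equal(minute_peak_features(x60, pk60, "ecg")$resting, 1)
  # trailing partial minute dropped
  expect_equal(nrow(minute_peak_features(rep(0, 1400), integer(0), "emg")), 2)
  expect_false("resting" %in% names(minute_peak_features(rep(0, 600), integer(0), "bvp")))
})

test_that("resting equals peaks/60 whenever peaks are evenly spread", {
  set.seed(5)
  for (k in c(12, 30, 60)) {
    pk <- as.integer(round(seq(3, 597, length.out = k)))
    x <- rep(0, 600)
    x[pk] <- 1
    mf <- minute_peak_features(x, pk, "ecg")
    expect_equal(mf$resting, mf$peaks / 60)
  }
})

test_that("accelerometer statistics match their closed forms", {
  set.seed(42)
  n <- 1000
  x <- rnorm(n)
  acc <- cbind(x, x, rnorm(n) + 1) # y duplicates x exactly
  f <- subject_accel_features(acc)
  expect_equal(unname(f["ACC_Corr_XY"]), 1) # N/(N-1) clipped to 1
  expect_equal(unname(f["ACC_Mean_X"]), mean(x))
  expect_equal(unname(f["ACC_Std_X"]), sqrt(mean((x - mean(x))^2)))
  expect_equal(unname(f["ACC_Crest_Z"]), crest_factor(acc[, 3]))
  expect_true(all(abs(f[c("ACC_Corr_XY", "ACC_Corr_XZ", "ACC_Corr_YZ")]) <= 1))
  # pearson option gives the textbook coefficient
  fp <- subject_accel_features(acc, method = "pearson")
  expect_equal(unname(fp["ACC_Corr_XZ"]), cor(x, acc[, 3]))
})

test_that("large-sample Gaussian excess kurtosis is near zero", {
  set.seed(11)
  acc <- matrix(rnorm(3e5), ncol = 3)
  f <- subject_accel_features(acc)
  expect_true(all(abs(f[c("ACC_Kurt_X", "ACC_Kurt_Y", "ACC_Kurt_Z")]) < 0.05))
})

test_that("crest factor of a constant positive signal is sqrt((N-1)/N)", {
  expect_equal(crest_factor(rep(3.7, 1000)), sqrt(999 / 1000))
})

test_that("zero-variance axis raises an error naming the axis", {
  acc <- cbind(rnorm(100), 2, rnorm(100))
  expect_error(subject_accel_features(acc), class = "mindcnn_domain_error", regexp = "Y")
})

test_that("assembled matrix has the block layout and broadcast structure", {
  rec <- generate_subject("S1", cohort_params(n_subjects = 1, duration_min = 10), seed = 3)
  ds <- assemble_feature_matrix(process_recording(rec))
  expect_equal(dim(ds$features), c(6000, 28)) # 10 min x 600 samples
  blocks <- channel_blocks()
  expect_equal(lengths(blocks), c(ECG = 4L, EMG = 3L, RESP = 3L, BVP = 3L, ACCL = 15L))
  # ECG block constant within each minute
  for (m in c(1, 4, 10)) {
    rows <- ((m - 1) * 600 + 1):(m * 600)
    expect_equal(nrow(unique(ds$features[rows, blocks$ECG, drop = FALSE])), 1)
  }
  # ACCL block constant across the whole subject
  expect_equal(nrow(unique(ds$features[, blocks$ACCL, drop = FALSE])), 1)
  expect_true(all(ds$features[, "ECG_Differ_Mean"] >= 0))
})

test_that("recordings shorter than a minute are excluded with a warning", {
  short <- process_recording(tiny_recording(seconds = 30))
  expect_warning(
    expect_error(assemble_feature_matrix(short), class = "mindcnn_domain_error"),
    "shorter than one minute"
  )
})
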