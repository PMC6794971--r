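# Shared fixtures, all generated in code.

# tiny raw recording built by hand (not via the generator) for io tests
tiny_recording <- function(subject_id = "T1", seconds = 2, seed = 99) {
  set.seed(seed)
  n700 <- 700 * seconds
  adc <- function(n) sample.int(2^16, n) - 1L
  raw_recording(
    subject_id,
    streams = list(
      ecg = list(rate_hz = 700, values = adc(n700)),
      emg = list(rate_hz = 700, values = adc(n700)),
      resp = list(rate_hz = 700, values = adc(n700)),
      bvp = list(rate_hz = 64, values = rnorm(64 * seconds)),
      acc_wrist = list(rate_hz = 32, values = matrix(
        round(rnorm(32 * seconds * 3, 0, 20)), 32 * seconds, 3
      )),
      temp_wrist = list(rate_hz = 4, values = rnorm(4 * seconds, 33, 0.1))
    ),
    labels = rep(c(0L, 2L), each = n700 / 2),
    units = "raw"
  )
}

# well-separated study conditions: every pairwise heart-rate and respiration
# ratio exceeds 20%, so classes are resolvable from minute peak rates
separated_params <- function(n_subjects = 3, duration_min = 10) {
  cohort_params(
    n_subjects = n_subjects, duration_min = duration_min,
    heart_rate_bpm = c(60, 80, 143, 45, 107),
    resp_rate_bpm = c(12, 18, 36, 8, 26),
    emg_burst_rate = c(5, 12, 30, 2, 18)
  )
}

# continuous feature dataset with ~3 pooled-SD class separation: unit
# Gaussian noise in 28 dims, class c shifted +3 along coordinate c
blob_dataset <- function(n_per_class = 600, seed = 3, n_subjects = 3) {
  set.seed(seed)
  n <- 5 * n_per_class
  X <- matrix(rnorm(n * 28), n, 28)
  labels <- rep(0:4, each = n_per_class)
  for (c in 0:4) X[labels == c, c + 1] <- X[labels == c, c + 1] + 3
  ord <- sample.int(n)
  feature_dataset(
    X[ord, ], labels[ord],
    rep(paste0("S", seq_len(n_subjects)), length.out = n)
  )
}

# cached pipeline products shared across test files (built once per run)
.fixture_env <- new.env()

e2e_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    cohort <- generate_cohort(separated_params(), seed = 7)
    .fixture_env$cohort <- cohort
    .fixture_env$ds <- assemble_feature_matrix(lapply(cohort, process_recording))
  }
  .fixture_env$ds
}

e2e_cohort <- function() {
  e2e_dataset()
  .fixture_env$cohort
}
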