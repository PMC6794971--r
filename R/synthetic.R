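# synthetic_data: multimodal raw-recording generator with class-dependent
# periodicities, so the full pipeline (ADC conversion -> resampling ->
# features -> training) runs without any external dataset.

#' Published class distribution of the WESAD study conditions
#'
#' Sample counts of the five conditions in the public WESAD wearable
#' stress/affect dataset after aggregation to 10 Hz; their proportions are
#' the default class schedule of the synthetic cohort generator.
#'
#' @return Named integer vector of per-class sample counts.
#' @export
wesad_class_counts <- function() {
  c(
    baseline = 274790L, amusement = 117150L, stress = 65450L,
    meditation = 37090L, recovery = 79000L
  )
}

#' Parameters of a synthetic cohort
#'
#' Class effects enter only through interpretable rate/amplitude parameters:
#' heart rate drives the ECG and BVP pulse trains, respiration rate the
#' breathing sinusoid, EMG burst rate/amplitude the muscle-activity bursts,
#' and an activity standard deviation the wrist accelerometer. Subjects get
#' multiplicative parameter jitter. All five per-class vectors are ordered
#' by class code ([class_levels()]).
#'
#' @param n_subjects Number of subjects; 15.
#' @param duration_min Recording length per subject in minutes; 100. Class
#'   segments are whole minutes (largest-remainder rounding of
#'   `class_proportions`, with at least one minute per class when the
#'   duration allows), because the engineered peak features are
#'   minute-based: sub-minute class segments would be unresolvable.
#' @param class_proportions Share of recording time per class; defaults to
#'   the [wesad_class_counts()] proportions.
#' @param heart_rate_bpm Per-class heart rate (beats/min), in 40–200.
#' @param resp_rate_bpm Per-class respiration rate (breaths/min), in 5–40.
#' @param emg_burst_rate Per-class EMG burst rate (bursts/min).
#' @param emg_burst_amp_uv Per-class EMG burst amplitude (microvolts).
#' @param accel_activity_g Per-class wrist-accelerometer activity sd (g).
#' @param temp_baseline_c Skin temperature baseline (Celsius).
#' @param noise_sd Named list of additive noise sds: `ecg_mv`, `emg_uv`,
#'   `resp_pct`, `bvp`, `acc_g`.
#' @param subject_jitter Relative sd of the per-subject multiplicative
#'   jitter on rate parameters; 0.05.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 15L, duration_min = 100L,
                          class_proportions = wesad_class_counts() / sum(wesad_class_counts()),
                          heart_rate_bpm = c(70, 85, 110, 55, 75),
                          resp_rate_bpm = c(14, 16, 24, 7, 12),
                          emg_burst_rate = c(6, 12, 30, 2, 8),
                          emg_burst_amp_uv = c(0.3, 0.5, 0.9, 0.15, 0.35),
                          accel_activity_g = c(0.05, 0.12, 0.2, 0.02, 0.08),
                          temp_baseline_c = 33,
                          noise_sd = list(
                            ecg_mv = 0.04, emg_uv = 0.04, resp_pct = 1,
                            bvp = 2, acc_g = 0.02
                          ),
                          subject_jitter = 0.05) {
  stopifnot(
    is_count(n_subjects), is_count(duration_min), duration_min >= 1,
    length(class_proportions) == 5L, all(class_proportions > 0),
    all(heart_rate_bpm >= 40), all(heart_rate_bpm <= 200),
    all(resp_rate_bpm >= 5), all(resp_rate_bpm <= 40),
    subject_jitter >= 0
  )
  structure(
    list(
      n_subjects = as.integer(n_subjects), duration_min = as.integer(duration_min),
      class_proportions = class_proportions / sum(class_proportions),
      heart_rate_bpm = heart_rate_bpm, resp_rate_bpm = resp_rate_bpm,
      emg_burst_rate = emg_burst_rate, emg_burst_amp_uv = emg_burst_amp_uv,
      accel_activity_g = accel_activity_g, temp_baseline_c = temp_baseline_c,
      noise_sd = noise_sd, subject_jitter = subject_jitter
    ),
    class = "cohort_params"
  )
}

# whole-minute class schedule via largest remainder; every class gets at
# least one minute when duration_min >= 5
schedule_minutes <- function(proportions, duration_min) {
  exact <- proportions * duration_min
  mins <- floor(exact)
  rem <- exact - mins
  short <- duration_min - sum(mins)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    mins[add] <- mins[add] + 1
  }
  if (duration_min >= 5) {
    while (any(mins == 0)) {
      mins[which.max(mins)] <- max(mins) - 1
      mins[which.min(mins)] <- 1
    }
  }
  as.integer(mins)
}

# unimodal pulse per cycle: Gaussian bump in phase, width `s` radians
pulse_wave <- function(phase, s) exp((cos(phase) - 1) / s^2)

# accumulated phase for a per-sample frequency vector at rate fs
accum_phase <- function(f_hz, fs) 2 * pi * cumsum(f_hz) / fs

si_to_adc <- function(si, span) {
  pmin(pmax(round((si / span + 0.5) * ADC_MAX), 0), ADC_MAX - 1)
}

#' Generate one subject's raw multimodal recording
#'
#' Chest streams are emitted as 16-bit ADC integers at 700 Hz (so the unit
#' conversion path is exercised); wrist streams at their native 64/32/4 Hz
#' rates. ECG and BVP are periodic pulse trains at the class's heart rate
#' plus noise, respiration is sinusoidal at the class's rate, EMG is
#' baseline noise with Poisson-timed bursts, and the label stream follows
#' the whole-minute class schedule at 700 Hz. Deterministic per seed.
#'
#' @param subject_id Subject tag.
#' @param params A [cohort_params()].
#' @param seed Integer RNG seed.
#' @return A [raw_recording()] with `units = "raw"`.
#' @export
generate_subject <- function(subject_id, params = cohort_params(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mins <- schedule_minutes(params$class_proportions, params$duration_min)
  duration_s <- 60 * sum(mins)
  jit <- function() max(0.5, stats::rnorm(1, 1, params$subject_jitter))
  hr <- params$heart_rate_bpm * jit()
  rr <- params$resp_rate_bpm * jit()
  burst_rate <- params$emg_burst_rate * jit()
  burst_amp <- params$emg_burst_amp_uv * jit()
  act <- params$accel_activity_g * jit()
  temp0 <- params$temp_baseline_c + stats::rnorm(1, 0, 0.5)
  ns <- params$noise_sd

  cls_min <- rep(0:4, times = mins) # class per minute
  cls_at <- function(fs) rep(cls_min, each = 60 * fs) # class per sample at rate fs

  # chest unit, 700 Hz
  c700 <- cls_at(700)
  n700 <- length(c700)
  ecg_mv <- 1.2 * pulse_wave(accum_phase(hr[c700 + 1L] / 60, 700), 0.6) +
    stats::rnorm(n700, 0, ns$ecg_mv)
  resp_pct <- 20 * sin(accum_phase(rr[c700 + 1L] / 60, 700)) +
    stats::rnorm(n700, 0, ns$resp_pct)
  emg_uv <- stats::rnorm(n700, 0, ns$emg_uv)
  burst_len <- round(0.3 * 700)
  pos <- 0L
  for (k in seq_along(mins)) {
    seg_n <- mins[k] * 60L * 700L
    n_bursts <- stats::rpois(1, burst_rate[k] * mins[k])
    if (n_bursts > 0 && seg_n > burst_len) {
      starts <- pos + sort(sample.int(seg_n - burst_len, n_bursts, replace = TRUE))
      for (s0 in starts) {
        idx <- s0:(s0 + burst_len - 1L)
        emg_uv[idx] <- emg_uv[idx] + burst_amp[k] * abs(stats::rnorm(burst_len, 0, 1)) *
          sin(pi * seq_len(burst_len) / burst_len)
      }
    }
    pos <- pos + seg_n
  }
  acc_chest <- matrix(
    round(ADC_MAX / 2 + stats::rnorm(3 * n700, 0, 120)), n700, 3L
  )
  eda_chest <- round(20000 + 2000 * (c700 == 2L) + stats::rnorm(n700, 0, 50))
  temp_chest <- round(30000 + stats::rnorm(n700, 0, 20))

  # wrist unit: BVP 64 Hz, accelerometer 32 Hz, EDA/temperature 4 Hz
  c64 <- cls_at(64)
  bvp <- 40 * pulse_wave(accum_phase(hr[c64 + 1L] / 60, 64), 0.9) +
    stats::rnorm(length(c64), 0, ns$bvp)
  c32 <- cls_at(32)
  n32 <- length(c32)
  common <- stats::rnorm(n32)
  acc_sd <- act[c32 + 1L]
  acc_wrist <- cbind(
    round(64 * (0.00 + acc_sd * (0.6 * common + 0.8 * stats::rnorm(n32)) +
      stats::rnorm(n32, 0, ns$acc_g))),
    round(64 * (0.10 + acc_sd * (0.6 * common + 0.8 * stats::rnorm(n32)) +
      stats::rnorm(n32, 0, ns$acc_g))),
    round(64 * (1.00 + acc_sd * stats::rnorm(n32) + stats::rnorm(n32, 0, ns$acc_g)))
  )
  c4 <- cls_at(4)
  eda_wrist <- 0.5 + 0.4 * (c4 == 2L) + stats::rnorm(length(c4), 0, 0.02)
  temp_wrist <- temp0 + 0.2 * sin(2 * pi * seq_along(c4) / (4 * duration_s)) +
    stats::rnorm(length(c4), 0, 0.02)

  streams <- list(
    ecg = list(rate_hz = 700, values = si_to_adc(ecg_mv, 3)),
    emg = list(rate_hz = 700, values = si_to_adc(emg_uv, 3)),
    resp = list(rate_hz = 700, values = si_to_adc(resp_pct, 100)),
    acc_chest = list(rate_hz = 700, values = acc_chest),
    eda_chest = list(rate_hz = 700, values = eda_chest),
    temp_chest = list(rate_hz = 700, values = temp_chest),
    bvp = list(rate_hz = 64, values = bvp),
    acc_wrist = list(rate_hz = 32, values = acc_wrist),
    eda_wrist = list(rate_hz = 4, values = eda_wrist),
    temp_wrist = list(rate_hz = 4, values = temp_wrist)
  )
  raw_recording(subject_id, streams, labels = c700, units = "raw")
}

#' Generate a synthetic cohort
#'
#' Draws one deterministic per-subject seed stream from `seed`, so the whole
#' cohort is reproducible and subjects differ through parameter jitter.
#'
#' @param params A [cohort_params()].
#' @param seed Integer RNG seed.
#' @return List of [raw_recording()]s with subject ids `"S1"`, `"S2"`, ...
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1L) {
  stopifnot(params$n_subjects >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, params$n_subjects)
  lapply(seq_len(params$n_subjects), function(i) {
    generate_subject(paste0("S", i), params, seed = subject_seeds[i])
  })
}
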