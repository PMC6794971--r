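# unit_conversion: raw ADC counts -> SI units

#' Conversion constants for raw sensor streams
#'
#' The chest unit emits 16-bit ADC counts; bipolar signals (ECG, EMG,
#' respiration) sit at midscale `2^15` when the physical signal is zero.
#' The wrist accelerometer reports in units of 1/64 g.
#'
#' @param chan_bit ADC output size (counts per full scale); 2^16.
#' @param vcc_ecg_mv ECG supply voltage in millivolts (full bipolar span).
#' @param vcc_emg_uv EMG supply voltage in microvolts.
#' @param acc_scale Accelerometer scale in m/s^2 per raw unit. The default
#'   `9.81 / 64` follows from the 1/64 g resolution of the wrist unit.
#' @return An object of class `conversion_spec`.
#' @export
conversion_spec <- function(chan_bit = 2^16, vcc_ecg_mv = 3, vcc_emg_uv = 3,
                            acc_scale = 9.81 / 64) {
  stopifnot(chan_bit > 0, vcc_ecg_mv > 0, vcc_emg_uv > 0, acc_scale > 0)
  structure(
    list(
      chan_bit = chan_bit, vcc_ecg_mv = vcc_ecg_mv,
      vcc_emg_uv = vcc_emg_uv, acc_scale = acc_scale
    ),
    class = "conversion_spec"
  )
}

#' Convert one raw stream to SI units
#'
#' Affine maps per signal kind, all monotone increasing in the raw value:
#' \describe{
#'   \item{ecg}{`(raw/chan_bit - 0.5) * vcc_ecg_mv` millivolts.}
#'   \item{emg}{`(raw/chan_bit - 0.5) * vcc_emg_uv` microvolts.}
#'   \item{resp}{`(raw/chan_bit - 0.5) * 100` percent displacement.}
#'   \item{acc}{`raw * acc_scale` m/s^2, applied per axis.}
#'   \item{bvp, temp}{identity pass-through (the devices already report
#'     physical units).}
#' }
#' Midscale ADC input (`2^15`) maps to exactly zero for the bipolar kinds.
#'
#' @param kind One of `"ecg"`, `"emg"`, `"resp"`, `"acc"`, `"bvp"`, `"temp"`.
#' @param raw Numeric vector (or matrix for triaxial `acc`). For
#'   `ecg`/`emg`/`resp` values must lie in `[0, chan_bit)`.
#' @param spec A [conversion_spec()].
#' @return Converted values, same shape and length as `raw`.
#' @examples
#' convert_signal("ecg", 32768) # midscale -> 0 mV
#' convert_signal("resp", 0) # lower rail -> -50 %
#' @export
convert_signal <- function(kind, raw, spec = conversion_spec()) {
  kind <- match.arg(kind, c("ecg", "emg", "resp", "acc", "bvp", "temp"))
  if (kind %in% c("ecg", "emg", "resp")) {
    if (any(raw < 0) || any(raw >= spec$chan_bit)) {
      stop_mindcnn(
        sprintf("raw %s values must lie in [0, %g)", kind, spec$chan_bit),
        "mindcnn_domain_error"
      )
    }
  }
  switch(kind,
    ecg = (raw / spec$chan_bit - 0.5) * spec$vcc_ecg_mv,
    emg = (raw / spec$chan_bit - 0.5) * spec$vcc_emg_uv,
    resp = (raw / spec$chan_bit - 0.5) * 100,
    acc = raw * spec$acc_scale,
    bvp = raw,
    temp = raw
  )
}

# which conversion applies to each named stream; streams with no published
# conversion (chest accelerometer, EDA, both temperatures) pass through
STREAM_KIND <- c(
  ecg = "ecg", emg = "emg", resp = "resp", acc_wrist = "acc",
  bvp = "bvp", temp_wrist = "temp", temp_chest = "temp",
  acc_chest = "temp", eda_chest = "temp", eda_wrist = "temp"
)

#' Convert every stream of a raw recording to SI units
#'
#' Applies [convert_signal()] stream-wise: ECG/EMG/respiration via the ADC
#' formulas, the wrist accelerometer via the 1/64 g scale, everything else
#' unchanged. Labels are untouched.
#'
#' @param rec A [raw_recording()] with `units = "raw"`.
#' @param spec A [conversion_spec()].
#' @return The recording with converted streams and `units = "si"`.
#' @export
convert_recording <- function(rec, spec = conversion_spec()) {
  if (rec$units != "raw") {
    stop_mindcnn("recording is already in SI units", "mindcnn_domain_error")
  }
  streams <- rec$streams
  for (nm in names(streams)) {
    kind <- STREAM_KIND[[nm]] %||% "temp"
    streams[[nm]]$values <- convert_signal(kind, streams[[nm]]$values, spec)
  }
  raw_recording(rec$subject_id, streams, rec$labels, units = "si")
}
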