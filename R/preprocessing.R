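# Band limiting and phase segmentation.
#
# Breath sounds are analyzed in the 100-2000 Hz band: below 100 Hz muscle and
# ambient rumble dominate, above 2 kHz there is little crackle energy. The
# filter is applied forward-backward (zero phase) so that crackle onset times
# -- the basis of the early/mid/late timing classification -- are not shifted
# by group delay.

#' Band-pass filter settings
#'
#' @param low_hz Lower band edge in Hz.
#' @param high_hz Upper band edge in Hz.
#' @param order Butterworth prototype order (applied twice via
#'   forward-backward filtering).
#' @return A `filter_settings` object.
#' @export
filter_settings <- function(low_hz = 100, high_hz = 2000, order = 4L) {
  ct_assert(is_scalar_num(low_hz) && low_hz > 0, "low_hz must be > 0")
  ct_assert(is_scalar_num(high_hz) && high_hz > low_hz,
            "high_hz must exceed low_hz")
  ct_assert(is_scalar_num(order) && order >= 1, "order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 kind = "bandpass"),
            class = "filter_settings")
}

#' Band-limit a recording
#'
#' Zero-phase Butterworth band-pass (forward-backward application of an
#' order-`order` design). Output length equals input length and in-band
#' transients keep their timing.
#'
#' @param recording An `audio_recording`.
#' @param settings A [filter_settings()] object; band edges must be below the
#'   Nyquist frequency.
#' @return The filtered `audio_recording`.
#' @export
bandpass <- function(recording, settings = filter_settings()) {
  ct_assert(inherits(recording, "audio_recording"), "not an audio_recording")
  ct_assert(inherits(settings, "filter_settings"), "not filter_settings")
  nyq <- recording$fs / 2
  ct_assert(settings$high_hz < nyq,
            "validation error: high cutoff must be below the Nyquist frequency")
  bf <- signal::butter(settings$order,
                       c(settings$low_hz, settings$high_hz) / nyq,
                       type = "pass")
  y <- signal::filtfilt(bf, recording$samples)
  out <- recording
  out$samples <- as.numeric(y)
  out
}

#' Extract one breath phase as a sample vector
#'
#' Returns the samples in `[start_s, end_s)` of the given phase; the sample
#' at `end_s` is excluded (half-open convention), so an exact 2 s phase at
#' 44.1 kHz yields exactly 88200 samples.
#'
#' @param recording An `audio_recording`.
#' @param phase One row of a phase table (list or 1-row data frame with
#'   `start_s`, `end_s`).
#' @return Numeric vector of samples.
#' @export
extract_phase <- function(recording, phase) {
  ct_assert(inherits(recording, "audio_recording"), "not an audio_recording")
  start_s <- as.numeric(phase$start_s)
  end_s <- as.numeric(phase$end_s)
  ct_assert(is_scalar_num(start_s) && is_scalar_num(end_s),
            "phase must have scalar start_s and end_s")
  ct_assert(start_s >= 0 && end_s > start_s,
            "validation error: phase must satisfy 0 <= start_s < end_s")
  ct_assert(end_s <= recording$duration_s + 1e-9,
            "validation error: phase extends past the recording")
  fs <- recording$fs
  i0 <- round(start_s * fs)                 # 0-based first sample
  n <- round((end_s - start_s) * fs)
  ct_assert(n >= 1, "validation error: zero-length phase")
  recording$samples[(i0 + 1L):(i0 + n)]
}
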