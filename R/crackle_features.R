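# Crackle detection and time-expanded-waveform metrology.
#
# A crackle in the time-expanded waveform is read as a sequence of
# deflections: the excursions of the signal between consecutive baseline
# (zero) crossings after the onset. The classical parameters are
#   IDW  - initial deflection width, the duration of deflection 1;
#   2CD  - two-cycle duration, onset to the end of deflection 4
#          (two full oscillation cycles);
#   LDW  - largest deflection width among deflections 1-4;
#   A1-A3 - peak magnitudes of deflections 1-3, with damping ratios
#          A2/A1 and A3/A1.
# A fine crackle is defined by 2CD < 10 ms. Zero-crossing times are refined
# to sub-sample precision by linear interpolation.
#
# The detector whitens the segment against its own robust (per-bin median)
# amplitude spectrum, so the stationary breath-sound background -- whose
# energy is concentrated below ~1 kHz, right on top of the crackle band --
# is flattened while the crackle transient keeps its broadband onset. The
# short-window energy of the whitened signal is then thresholded against a
# rolling (blockwise) median + k * MAD baseline, which absorbs the slow
# inspiratory loudness envelope. An instantaneous-energy detector without
# whitening has no margin at low onset SNR, because in-band colored noise
# raises the energy floor by the ratio of the full band to the noise band.
# The detector is deterministic and stands behind the same interface a
# proprietary spectrometer's detector would.

#' Crackle detection settings
#'
#' @param energy_window_ms Smoothing window for the whitened-signal energy
#'   (ms); short, since the whitened crackle is click-like.
#' @param threshold_k Threshold multiplier of the rolling robust spread
#'   (MAD) above the rolling median energy.
#' @param refractory_ms Minimum separation between events; later candidates
#'   within this interval are merged into the earlier onset (it also
#'   suppresses re-triggering on a crackle's decaying tail).
#' @param analysis_window_ms Window after each onset searched for the four
#'   deflections during measurement.
#' @param baseline_window_ms Block length of the rolling median/MAD baseline
#'   that tracks the inspiratory loudness envelope.
#' @param whiten_block Block size (samples) for the robust spectrum estimate
#'   used in whitening.
#' @param whiten_floor Regularization floor for the whitening gain, as a
#'   fraction of the peak of the estimated amplitude spectrum.
#' @param onset_backtrack_ms How far before the energy rise the onset may be
#'   pulled back to the last baseline crossing of the raw signal.
#' @return A `detection_settings` object.
#' @export
detection_settings <- function(energy_window_ms = 0.5, threshold_k = 20,
                               refractory_ms = 10, analysis_window_ms = 25,
                               baseline_window_ms = 100,
                               whiten_block = 1024L, whiten_floor = 0.005,
                               onset_backtrack_ms = 1.2) {
  for (v in c(energy_window_ms, threshold_k, refractory_ms,
              analysis_window_ms, baseline_window_ms, whiten_block,
              whiten_floor, onset_backtrack_ms))
    ct_assert(is_scalar_num(v) && v > 0, "all detection settings must be > 0")
  structure(list(energy_window_ms = energy_window_ms,
                 threshold_k = threshold_k,
                 refractory_ms = refractory_ms,
                 analysis_window_ms = analysis_window_ms,
                 baseline_window_ms = baseline_window_ms,
                 whiten_block = as.integer(whiten_block),
                 whiten_floor = whiten_floor,
                 onset_backtrack_ms = onset_backtrack_ms),
            class = "detection_settings")
}

# Sub-sample zero-crossing time (seconds) given 0-based sample index k where
# sign changes between samples k and k+1. Exact-zero samples count as
# crossings at the sample instant.
interp_crossing <- function(x, k, fs) {
  a <- x[k + 1L]; b <- x[k + 2L]
  if (a == 0) return(k / fs)
  (k + a / (a - b)) / fs
}

# 0-based indices k such that the signal crosses (or leaves) zero between
# samples k and k+1, searching samples with index >= from (0-based). A
# departure from an exact-zero baseline (silence) counts as a crossing at
# the zero sample.
zero_crossings_after <- function(x, from = 0L) {
  n <- length(x)
  if (n < 2L) return(integer(0))
  a <- x[-n]; b <- x[-1L]
  k <- which((a > 0 & b <= 0) | (a < 0 & b >= 0) | (a == 0 & b != 0)) - 1L
  unique(k[k >= from])
}

# Spectrally whiten a segment against its own robust amplitude spectrum.
# The per-bin median over overlapped Hann blocks estimates the stationary
# background spectrum even when transients are present; dividing the
# segment's FFT by it (plus a floor) flattens the background. The gain is
# real, so the operation is zero-phase and transient timing is preserved.
# Degenerate segments (background estimate identically zero, e.g. silence
# with sparse transients) are returned unwhitened.
whiten_segment <- function(x, blk, floor_frac) {
  n <- length(x)
  if (n < 2L * blk) return(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(blk) / (blk + 1))
  starts <- seq(1L, n - blk + 1L, by = blk %/% 2L)
  amp <- vapply(starts, function(s0) Mod(stats::fft(x[s0:(s0 + blk - 1L)] * w)),
                numeric(blk))
  amed <- apply(amp, 1L, stats::median)
  if (max(amed) <= 0) return(x)
  gain <- 1 / (stats::approx((seq_len(blk) - 1L) / blk, amed,
                             xout = (seq_len(n) - 1L) / n, rule = 2)$y +
                 floor_frac * max(amed))
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

# Rolling robust baseline: median and MAD over half-overlapped blocks,
# linearly interpolated back to the sample grid.
rolling_robust <- function(v, block_len) {
  n <- length(v)
  block_len <- min(block_len, n)
  starts <- seq(1L, max(1L, n - block_len + 1L), by = max(1L, block_len %/% 2L))
  med_b <- vapply(starts, function(s0)
    stats::median(v[s0:min(n, s0 + block_len - 1L)]), numeric(1))
  mad_b <- vapply(starts, function(s0)
    stats::mad(v[s0:min(n, s0 + block_len - 1L)]), numeric(1))
  ctr <- starts + block_len / 2
  if (length(starts) == 1L) {
    list(med = rep(med_b, n), mad = rep(mad_b, n))
  } else {
    list(med = stats::approx(ctr, med_b, xout = seq_len(n), rule = 2)$y,
         mad = stats::approx(ctr, mad_b, xout = seq_len(n), rule = 2)$y)
  }
}

#' Detect crackle onsets in a band-limited segment
#'
#' The segment is spectrally whitened against its own robust (per-bin
#' median) background spectrum, its short-window energy is compared with a
#' rolling median + k * MAD baseline, and each suprathreshold run yields one
#' candidate. The onset is the last baseline (zero) crossing of the raw
#' signal within a short backtrack window before the energy rise (falling
#' back to the rise time itself when no crossing is found there -- distant
#' crossings of slow noise components would corrupt the timing). Candidates
#' within the refractory interval of an accepted onset are merged into it,
#' keeping the earlier onset. Deterministic given its inputs.
#'
#' @param segment Numeric vector (one band-limited inspiratory phase).
#' @param fs Sampling rate in Hz.
#' @param settings A [detection_settings()] object.
#' @return Sorted numeric vector of onset times in seconds relative to the
#'   start of the segment.
#' @export
detect_crackles <- function(segment, fs, settings = detection_settings()) {
  ct_assert(is.numeric(segment), "segment must be numeric")
  ct_assert(inherits(settings, "detection_settings"), "not detection_settings")
  n <- length(segment)
  win <- max(1L, round(settings$analysis_window_ms / 1000 * fs))
  ct_assert(n >= win,
            "validation error: segment shorter than the analysis window")
  if (all(segment == 0)) return(numeric(0))

  x <- segment
  xw <- whiten_segment(x, settings$whiten_block, settings$whiten_floor)
  w <- max(3L, round(settings$energy_window_ms / 1000 * fs))
  e <- moving_average(xw^2, w)

  bl <- rolling_robust(e, max(32L, round(settings$baseline_window_ms / 1000 * fs)))
  thr <- bl$med + settings$threshold_k * pmax(bl$mad, .Machine$double.xmin)
  above <- e > thr
  if (!any(above)) return(numeric(0))

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  first_idx <- starts[r$values]
  run_peak <- mapply(function(s0, e0) max(e[s0:e0]),
                     first_idx, ends[r$values])
  # a run 4 orders of magnitude below the strongest is the decaying tail of
  # an earlier event poking through a near-zero baseline, not a crackle
  peak_floor <- 1e-4 * max(run_peak)

  refr <- settings$refractory_ms / 1000
  back <- max(1L, round(settings$onset_backtrack_ms / 1000 * fs))
  onsets <- numeric(0)
  last <- -Inf
  for (q in seq_along(first_idx)) {
    f <- first_idx[q]
    if (run_peak[q] < peak_floor) next
    t_rise <- (f - 1L) / fs
    if (t_rise - last < refr) next  # merged into the previous event
    lo <- max(1L, f - back)
    k <- zero_crossings_after(x[lo:f], from = 0L)
    on <- if (length(k) > 0L) {
      (lo - 1L) / fs + interp_crossing(x[lo:length(x)], max(k), fs)
    } else {
      # no crossing behind the rise (silent baseline): take the first
      # departure from baseline at/after it
      hi <- min(length(x), f + back)
      kf <- zero_crossings_after(x[f:hi], from = 0L)
      if (length(kf) > 0L) {
        (f - 1L) / fs + interp_crossing(x[f:length(x)], min(kf), fs)
      } else t_rise
    }
    onsets <- c(onsets, on)
    last <- max(on, t_rise)
  }
  sort(onsets)
}

#' Measure the time-expanded-waveform parameters of one crackle
#'
#' Locates the first four baseline crossings after the onset (sub-sample, by
#' linear interpolation) and measures the deflections between them: IDW, 2CD,
#' LDW, A1-A3 and the amplitude ratios. Events with fewer than four
#' deflections inside the analysis window are unmeasurable and return `NULL`.
#'
#' @param segment Numeric vector containing the crackle.
#' @param fs Sampling rate in Hz.
#' @param onset_s Onset time in seconds relative to the segment start.
#' @param settings A [detection_settings()] object (the analysis window).
#' @return A one-row data frame with `onset_s`, `tcd_ms`, `idw_ms`, `ldw_ms`,
#'   `a1`, `a2`, `a3`, `a2_a1`, `a3_a1`, `is_fine`, or `NULL` when
#'   unmeasurable.
#' @export
measure_waveform <- function(segment, fs, onset_s,
                             settings = detection_settings()) {
  ct_assert(is.numeric(segment), "segment must be numeric")
  n <- length(segment)
  ct_assert(is_scalar_num(onset_s) && onset_s >= 0 && onset_s < n / fs,
            "validation error: onset outside the segment")
  i_on <- floor(onset_s * fs + 1e-9)   # 0-based sample at/just before onset
  win <- round(settings$analysis_window_ms / 1000 * fs)
  hi <- min(n, i_on + win + 1L)
  x <- segment[(i_on + 1L):hi]
  off <- i_on / fs                     # time of local index 0

  # crossings strictly after the onset instant
  ks <- zero_crossings_after(x, from = 0L)
  times <- vapply(ks, function(k) off + interp_crossing(x, k, fs), numeric(1))
  times <- times[times > onset_s + 0.25 / fs]
  if (length(times) < 4L) return(NULL)
  b <- c(onset_s, times[1:4])

  widths <- diff(b) * 1000
  amps <- vapply(1:4, function(j) {
    lo <- max(1L, floor((b[j] - off) * fs) + 1L)
    hi_j <- min(length(x), ceiling((b[j + 1L] - off) * fs) + 1L)
    max(abs(x[lo:hi_j]))
  }, numeric(1))

  tcd <- (b[5] - b[1]) * 1000
  out <- data.frame(
    onset_s = onset_s,
    tcd_ms = tcd,
    idw_ms = widths[1],
    ldw_ms = max(widths),
    a1 = amps[1], a2 = amps[2], a3 = amps[3],
    a2_a1 = if (amps[1] > 0) amps[2] / amps[1] else NA_real_,
    a3_a1 = if (amps[1] > 0) amps[3] / amps[1] else NA_real_,
    is_fine = tcd < 10,
    stringsAsFactors = FALSE
  )
  out
}

#' Classify a crackle onset into the inspiratory timing tercile
#'
#' The inspiratory phase is split into equal thirds: early (< 1/3),
#' mid (\[1/3, 2/3)), late (>= 2/3).
#'
#' @param relative_onset Fraction of the inspiratory phase in \[0, 1).
#' @return `"early"`, `"mid"` or `"late"` (vectorized).
#' @export
classify_tercile <- function(relative_onset) {
  ct_assert(is.numeric(relative_onset) &&
              all(relative_onset >= 0 & relative_onset < 1),
            "validation error: relative_onset must lie in [0, 1)")
  ifelse(relative_onset < 1 / 3, "early",
         ifelse(relative_onset < 2 / 3, "mid", "late"))
}

#' Aggregate measured crackle events to patient-level features
#'
#' The crackle count is the average number of fine crackles per inspiratory
#' phase (both recording sites pooled). The patient's onset-timing tercile is
#' the tercile of the mean relative onset of the *first* fine crackle of each
#' inspiration. Waveform parameters are summarized as per-patient medians
#' over fine crackles.
#'
#' @param events Data frame of measured events with columns `inspiration_id`
#'   (any identifier unique per inspiration and site), `relative_onset`,
#'   `tcd_ms`, `idw_ms`, `ldw_ms`, `a2_a1`, `a3_a1`, `is_fine`.
#' @param n_inspirations Total number of inspiratory phases analyzed (>= 1).
#' @param count Which events enter the count: `"fine"` (default) or `"all"`.
#' @return One-row data frame: `count_per_insp`, `onset_tercile` (`NA` when
#'   no fine crackles), `mean_first_onset`, and medians of the waveform
#'   parameters.
#' @export
aggregate_patient <- function(events, n_inspirations, count = c("fine", "all")) {
  count <- match.arg(count)
  ct_assert(is_scalar_num(n_inspirations) && n_inspirations >= 1,
            "n_inspirations must be >= 1")
  if (is.null(events) || nrow(events) == 0L) {
    return(data.frame(count_per_insp = 0, onset_tercile = NA_character_,
                      mean_first_onset = NA_real_, tcd_ms = NA_real_,
                      idw_ms = NA_real_, ldw_ms = NA_real_, a2_a1 = NA_real_,
                      a3_a1 = NA_real_, stringsAsFactors = FALSE))
  }
  fine <- events[events$is_fine, , drop = FALSE]
  counted <- if (count == "fine") fine else events
  n_count <- nrow(counted)

  if (nrow(fine) > 0L) {
    firsts <- tapply(fine$relative_onset, fine$inspiration_id, min)
    m <- mean(firsts)
    terc <- classify_tercile(m)
    med <- function(v) stats::median(v, na.rm = TRUE)
    data.frame(
      count_per_insp = n_count / n_inspirations,
      onset_tercile = terc,
      mean_first_onset = m,
      tcd_ms = med(fine$tcd_ms), idw_ms = med(fine$idw_ms),
      ldw_ms = med(fine$ldw_ms), a2_a1 = med(fine$a2_a1),
      a3_a1 = med(fine$a3_a1),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(count_per_insp = n_count / n_inspirations,
               onset_tercile = NA_character_, mean_first_onset = NA_real_,
               tcd_ms = NA_real_, idw_ms = NA_real_, ldw_ms = NA_real_,
               a2_a1 = NA_real_, a3_a1 = NA_real_, stringsAsFactors = FALSE)
  }
}
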