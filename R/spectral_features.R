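# Inspiratory power spectrum and percentile frequencies.
#
# The spectrum is a Welch estimate: the segment is cut into tapered
# (Hann-windowed) blocks with 50% overlap, each block's modified periodogram
# is computed by FFT and scaled as a one-sided power spectral density, and
# the periodograms are averaged, then truncated to the 100-2000 Hz analysis
# band. The percentile frequency Fq is the smallest grid frequency below
# which at least q of the total band power is accumulated (right-continuous
# step rule, no interpolation); F50/F95/F99 are its q = 0.50/0.95/0.99
# values. All of this is invariant to positive rescaling of the waveform.

#' Welch power spectrum of a segment
#'
#' @param segment Numeric sample vector (at least `window_len` samples).
#' @param fs Sampling rate in Hz.
#' @param window_len Block length in samples (default 4096, about 93 ms at
#'   44.1 kHz, resolution about 10.8 Hz).
#' @param overlap Fractional block overlap in \[0, 1) (default 0.5).
#' @param band Analysis band in Hz (default 100-2000).
#' @return A `power_spectrum` object: `freqs_hz`, `power` (one-sided PSD,
#'   power per Hz), `band`, `resolution_hz`.
#' @export
power_spectrum <- function(segment, fs, window_len = 4096L, overlap = 0.5,
                           band = c(100, 2000)) {
  ct_assert(is.numeric(segment), "segment must be numeric")
  window_len <- as.integer(window_len)
  ct_assert(length(segment) >= window_len,
            "validation error: segment shorter than the spectral window")
  ct_assert(overlap >= 0 && overlap < 1, "overlap must lie in [0, 1)")
  ct_assert(length(band) == 2L && band[1] < band[2] && band[2] <= fs / 2,
            "band must be within (0, fs/2]")

  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(window_len) / (window_len + 1))  # Hann
  step <- max(1L, as.integer(round(window_len * (1 - overlap))))
  starts <- seq(1L, length(segment) - window_len + 1L, by = step)
  norm <- fs * sum(w^2)
  nh <- window_len %/% 2L + 1L

  acc <- numeric(nh)
  for (s0 in starts) {
    blk <- segment[s0:(s0 + window_len - 1L)] * w
    X <- stats::fft(blk)
    p <- (Mod(X[seq_len(nh)])^2) / norm
    p[2:(nh - 1L)] <- 2 * p[2:(nh - 1L)]  # one-sided: fold negative freqs
    acc <- acc + p
  }
  psd <- acc / length(starts)
  freqs <- (seq_len(nh) - 1L) * fs / window_len

  keep <- freqs >= band[1] & freqs <= band[2]
  structure(
    list(freqs_hz = freqs[keep], power = psd[keep], band = band,
         resolution_hz = fs / window_len),
    class = "power_spectrum"
  )
}

#' Percentile frequency of a power spectrum
#'
#' The smallest grid frequency f such that the cumulative power up to and
#' including f reaches at least `q` of the total band power. At an exact
#' boundary (e.g. two equal tones and q = 0.5) the lower frequency is
#' returned.
#'
#' @param spectrum A `power_spectrum` (or a list with `freqs_hz`, `power`).
#' @param q Fraction in (0, 1\].
#' @return Frequency in Hz.
#' @export
percentile_frequency <- function(spectrum, q) {
  ct_assert(is_scalar_num(q) && q > 0 && q <= 1, "q must lie in (0, 1]")
  p <- spectrum$power
  f <- spectrum$freqs_hz
  ct_assert(length(p) == length(f) && length(p) >= 1L,
            "spectrum must have matching freqs_hz and power")
  ct_assert(all(p >= 0), "power must be non-negative")
  tot <- sum(p)
  ct_assert(tot > 0, "undefined value: total spectral power is zero")
  cum <- cumsum(p)
  f[which(cum >= q * tot - 1e-12 * tot)[1L]]
}

#' F50/F95/F99 of a spectrum
#'
#' @param spectrum A `power_spectrum`.
#' @return List with `f50_hz`, `f95_hz`, `f99_hz`.
#' @export
percentile_frequencies <- function(spectrum) {
  list(f50_hz = percentile_frequency(spectrum, 0.50),
       f95_hz = percentile_frequency(spectrum, 0.95),
       f99_hz = percentile_frequency(spectrum, 0.99))
}

#' Patient-level percentile frequencies across inspiratory phases
#'
#' Computes one Welch spectrum per inspiratory segment, averages the spectra
#' (equal weight per segment -- "total signal power" at the patient level),
#' and extracts F50/F95/F99. Recordings from both auscultation sites can be
#' passed together as a list.
#'
#' @param recordings An `audio_recording` or list of them.
#' @param phases Phase table, or list of phase tables parallel to
#'   `recordings`.
#' @param ... Passed to [power_spectrum()].
#' @return List with `f50_hz`, `f95_hz`, `f99_hz` and the averaged
#'   `spectrum`.
#' @export
patient_percentiles <- function(recordings, phases, ...) {
  if (inherits(recordings, "audio_recording")) recordings <- list(recordings)
  if (is.data.frame(phases)) phases <- rep(list(phases), length(recordings))
  ct_assert(length(recordings) == length(phases),
            "recordings and phases must be parallel lists")

  acc <- NULL
  n_seg <- 0L
  proto <- NULL
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    ph <- phases[[i]]
    insp <- ph[ph$kind == "inspiration", , drop = FALSE]
    ct_assert(nrow(insp) >= 1L, "at least one inspiratory phase is required")
    for (j in seq_len(nrow(insp))) {
      seg <- extract_phase(rec, insp[j, ])
      sp <- power_spectrum(seg, rec$fs, ...)
      if (is.null(acc)) {
        acc <- sp$power
        proto <- sp
      } else {
        ct_assert(length(sp$power) == length(acc),
                  "all segments must share one spectral grid")
        acc <- acc + sp$power
      }
      n_seg <- n_seg + 1L
    }
  }
  proto$power <- acc / n_seg
  c(percentile_frequencies(proto), list(spectrum = proto))
}
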