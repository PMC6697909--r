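# Synthetic annotated lung-sound audio.
#
# The crackle model is an exponentially damped sinusoid,
#   s(t) = amplitude * polarity * sin(2 pi f0 t) * exp(-t / tau_s),  t >= 0,
# the simplest waveform reproducing the deflection anatomy of a
# time-expanded fine crackle while keeping the metrology targets in closed
# form: zero crossings at k/(2 f0), hence IDW = 1/(2 f0) and 2CD = 2/f0, and
# successive deflection peaks in the exact ratio exp(-1/(2 f0 tau_s)).
# Breath noise is band-limited Gaussian noise with a half-sine amplitude
# envelope per phase (inspiration louder than expiration) -- a fixture, not a
# physiological claim.

#' Specify one synthetic crackle
#'
#' @param onset_s Onset time on the recording clock, seconds.
#' @param f0 Oscillation frequency in Hz, within the 100-2000 Hz analysis
#'   band. A fine crackle (2CD < 10 ms) corresponds to `f0 > 200` Hz.
#' @param tau_s Exponential decay constant in seconds (> 0).
#' @param amplitude Peak scale (> 0, dimensionless). Under finite-SNR
#'   synthesis this acts as a relative multiplier (see [synth_breath()]).
#' @param polarity +1 or -1 (sign of the initial deflection).
#' @return A `crackle_spec` object.
#' @export
crackle_spec <- function(onset_s, f0, tau_s, amplitude = 1, polarity = 1) {
  ct_assert(is_scalar_num(onset_s) && onset_s >= 0, "onset_s must be >= 0")
  ct_assert(is_scalar_num(f0) && f0 >= 100 && f0 <= 2000,
            "f0 must lie in [100, 2000] Hz")
  ct_assert(is_scalar_num(tau_s) && tau_s > 0, "tau_s must be > 0")
  ct_assert(is_scalar_num(amplitude) && amplitude >= 0, "amplitude must be >= 0")
  ct_assert(polarity %in% c(-1, 1), "polarity must be +1 or -1")
  structure(list(onset_s = onset_s, f0 = f0, tau_s = tau_s,
                 amplitude = amplitude, polarity = polarity),
            class = "crackle_spec")
}

#' Sample a damped-sinusoid crackle waveform
#'
#' @param spec A [crackle_spec()]; its `onset_s` is ignored here (the
#'   waveform starts at t = 0).
#' @param fs Sampling rate in Hz; must be at least `4 * f0`.
#' @param duration_s Length of the returned sequence in seconds.
#' @return Numeric vector of `round(duration_s * fs)` samples with attributes
#'   `idw_s` (= 1/(2 f0)), `tcd_s` (= 2/f0) and `f0` as analytic ground
#'   truth.
#' @export
crackle_waveform <- function(spec, fs, duration_s = 0.025) {
  ct_assert(inherits(spec, "crackle_spec"), "not a crackle_spec")
  ct_assert(is_scalar_num(fs) && fs > 0, "fs must be > 0")
  ct_assert(fs >= 4 * spec$f0,
            "aliasing error: fs must be at least 4 * f0")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  s <- spec$amplitude * spec$polarity *
    sin(2 * pi * spec$f0 * t) * exp(-t / spec$tau_s)
  structure(s, idw_s = 1 / (2 * spec$f0), tcd_s = 2 / spec$f0, f0 = spec$f0)
}

#' Synthesize one breath-sound recording with ground-truth crackles
#'
#' Builds band-limited Gaussian breath noise (default 100-1000 Hz) shaped by
#' a half-sine envelope in each phase (inspiration gain 1, expiration gain
#' 0.45, silence between recordings), then inserts the specified crackle
#' waveforms. When `snr_db` is finite, each crackle is rescaled so that its
#' peak power over the local noise power -- measured in a 20 ms window
#' centred at its onset -- equals `snr_db` (the spec amplitude then acts as a
#' further relative multiplier). `snr_db = Inf` disables the noise entirely.
#'
#' @param fs Sampling rate in Hz.
#' @param phases Phase table (see [protocol_phases()]).
#' @param crackles List of [crackle_spec()] objects; every onset must fall
#'   inside an inspiratory phase.
#' @param snr_db Per-crackle onset SNR in dB, or `Inf` for noise-free.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param site_label Site metadata for the returned recording.
#' @return A list with `recording` (an `audio_recording`) and `events`
#'   (ground-truth data frame: `onset_s`, `breath_index`, `relative_onset`,
#'   `tercile`, `f0`, `tau_s`, `amplitude`, `tcd_ms`, `idw_ms`, `is_fine`).
#' @export
synth_breath <- function(fs, phases, crackles = list(), snr_db = 20,
                         seed = 1L, site_label = "other") {
  validate_phases(phases)
  ct_assert(nrow(phases) >= 1L, "at least one phase is required")
  ct_assert(is.list(crackles), "crackles must be a list of crackle_spec")
  dur <- max(phases$end_s)
  n <- round(dur * fs)
  t <- (seq_len(n) - 1L) / fs

  insp <- phases[phases$kind == "inspiration", , drop = FALSE]
  locate <- function(onset) {
    hit <- which(onset >= insp$start_s & onset < insp$end_s)
    ct_assert(length(hit) == 1L,
              sprintf("validation error: crackle onset %.3f s is outside every inspiratory phase",
                      onset))
    hit
  }
  phase_of <- vapply(crackles, function(cs) locate(cs$onset_s), integer(1))

  noise <- numeric(n)
  if (is.finite(snr_db)) {
    raw <- with_seed(seed, stats::rnorm(n))
    bf <- signal::butter(4, c(100, 1000) / (fs / 2), type = "pass")
    raw <- as.numeric(signal::filtfilt(bf, raw))
    env <- numeric(n)
    for (i in seq_len(nrow(phases))) {
      i0 <- round(phases$start_s[i] * fs) + 1L
      i1 <- round(phases$end_s[i] * fs)
      m <- i1 - i0 + 1L
      g <- if (phases$kind[i] == "inspiration") 1 else 0.45
      env[i0:i1] <- g * sin(pi * (seq_len(m) - 0.5) / m)
    }
    noise <- 0.05 * raw * env
  }

  x <- noise
  events <- vector("list", length(crackles))
  half_win <- max(1L, round(0.010 * fs))
  for (k in seq_along(crackles)) {
    cs <- crackles[[k]]
    i0 <- round(cs$onset_s * fs) + 1L
    wav_dur <- min(max(12 * cs$tau_s, 6 / cs$f0), dur - cs$onset_s)
    w <- crackle_waveform(cs, fs, wav_dur)
    amp_eff <- cs$amplitude
    if (is.finite(snr_db)) {
      lo <- max(1L, i0 - half_win)
      hi <- min(n, i0 + half_win)
      p_noise <- mean(noise[lo:hi]^2)
      peak_unit <- max(abs(w)) / max(cs$amplitude, .Machine$double.eps)
      amp_eff <- cs$amplitude * sqrt(p_noise) * 10^(snr_db / 20) / peak_unit
      w <- w * (amp_eff / cs$amplitude)
    }
    i1 <- min(n, i0 + length(w) - 1L)
    x[i0:i1] <- x[i0:i1] + w[seq_len(i1 - i0 + 1L)]

    ph <- insp[phase_of[k], ]
    rel <- (cs$onset_s - ph$start_s) / (ph$end_s - ph$start_s)
    events[[k]] <- data.frame(
      onset_s = cs$onset_s,
      breath_index = ph$breath_index,
      relative_onset = rel,
      tercile = classify_tercile(rel),
      f0 = cs$f0,
      tau_s = cs$tau_s,
      amplitude = amp_eff,
      tcd_ms = 2000 / cs$f0,
      idw_ms = 500 / cs$f0,
      is_fine = (2000 / cs$f0) < 10,
      stringsAsFactors = FALSE
    )
  }
  ev <- if (length(events)) do.call(rbind, events) else data.frame(
    onset_s = numeric(0), breath_index = integer(0),
    relative_onset = numeric(0), tercile = character(0), f0 = numeric(0),
    tau_s = numeric(0), amplitude = numeric(0), tcd_ms = numeric(0),
    idw_ms = numeric(0), is_fine = logical(0), stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  list(recording = audio_recording(x, fs, site_label = site_label),
       events = ev)
}
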