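# Shared fixtures, built in code at test time.

FS <- 44100

# The standard detection fixture: 8 protocol breaths, 20 fine crackles
# spread deterministically over the inspirations, synthesized at the given
# onset SNR. Returns the band-limited recording plus ground truth.
detection_fixture <- function(snr_db = 10, seed = 1L) {
  phases <- protocol_phases(8, 2, 2)
  insp <- phases[phases$kind == "inspiration", ]
  specs <- list()
  for (k in 1:20) {
    j <- ((k - 1L) %% 8L) + 1L
    rel <- 0.1 + 0.8 * ((k * 7) %% 13) / 13
    f0 <- 300 + 40 * (k %% 6)
    specs[[k]] <- crackle_spec(insp$start_s[j] + rel * 2, f0, 0.004)
  }
  sb <- synth_breath(FS, phases, specs, snr_db = snr_db, seed = seed)
  list(recording = bandpass(sb$recording), phases = phases, insp = insp,
       truth = sb$events)
}

detect_all <- function(fix, settings = detection_settings()) {
  det <- numeric(0)
  for (j in seq_len(nrow(fix$insp))) {
    seg <- extract_phase(fix$recording, fix$insp[j, ])
    det <- c(det, detect_crackles(seg, FS, settings) + fix$insp$start_s[j])
  }
  det
}

match_rate <- function(from, to, tol_s = 0.002) {
  if (length(from) == 0L) return(NA_real_)
  mean(vapply(from, function(t) any(abs(to - t) <= tol_s), logical(1)))
}

# Independent brute-force percentile-frequency oracle: explicit running sum.
oracle_percentile <- function(freqs, power, q) {
  tot <- sum(power)
  acc <- 0
  for (i in seq_along(power)) {
    acc <- acc + power[i]
    if (acc >= q * tot - 1e-12 * tot) return(freqs[i])
  }
  freqs[length(freqs)]
}

# Independent AC1 oracle for 2 raters / 2 categories, coded 0/1, written
# directly from the defining quantities (no shared code with gwet_ac1).
oracle_ac1_2rater <- function(r1, r2) {
  n <- length(r1)
  pa <- mean(r1 == r2)
  pi1 <- (mean(r1) + mean(r2)) / 2
  pe <- 2 * pi1 * (1 - pi1)
  (pa - pe) / (1 - pe)
}

# A tiny synthetic cohort with a prescribed group separation on one feature.
two_group_cohort <- function(n_per = 40, delta = 0, seed = 1L) {
  set.seed(seed)
  data.frame(
    group = rep(c("honeycombing", "non_honeycombing"), each = n_per),
    onset_tercile = sample(c("early", "mid", "late"), 2 * n_per, TRUE),
    x = rnorm(2 * n_per) + rep(c(delta, 0), each = n_per),
    stringsAsFactors = FALSE
  )
}
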