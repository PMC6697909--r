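test_that("noise-free crackles are detected within 1 ms and measured exactly", {
  phases <- protocol_phases(8, 2, 2)
  insp <- phases[phases$kind == "inspiration", ]
  specs <- list(crackle_spec(0.5, 400, 0.005), crackle_spec(1.0, 300, 0.004),
                crackle_spec(1.5, 600, 0.003))
  sb <- synth_breath(FS, phases, specs, snr_db = Inf, seed = 1)
  seg <- extract_phase(sb$recording, insp[1, ])
  on <- detect_crackles(seg, FS)
  expect_length(on, 3L)
  expect_lt(max(abs(on - c(0.5, 1.0, 1.5))), 1e-3)

  m <- measure_waveform(seg, FS, on[1])
  expect_equal(m$idw_ms, 1.25, tolerance = 0.04)   # 1/(2*400) s
  expect_equal(m$tcd_ms, 5.0, tolerance = 0.02)    # 2/400 s
  expect_equal(m$ldw_ms, 1.25, tolerance = 0.04)
  expect_true(m$is_fine)
  expect_equal(m$a2_a1, exp(-1.25 / 5), tolerance = 0.02)
})

test_that("degenerate segments are handled", {
  expect_equal(detect_crackles(numeric(FS), FS), numeric(0))
  expect_error(detect_crackles(numeric(10), FS), "shorter than")
})

test_that("detection meets the SNR-10 dB accuracy contract", {
  fix <- detection_fixture(snr_db = 10, seed = 1L)
  det <- detect_all(fix)
  expect_gte(match_rate(fix$truth$onset_s, det), 0.9)   # recall
  expect_gte(match_rate(det, fix$truth$onset_s), 0.9)   # precision
})

test_that("detection is translation-equivariant", {
  spec <- crackle_spec(0.3, 450, 0.004)
  base <- synth_breath(FS, protocol_phases(1, 2, 2), list(spec),
                       snr_db = Inf, seed = 1)$recording$samples[1:88200]
  on0 <- detect_crackles(base, FS)
  for (k in c(441L, 2205L)) {
    shifted <- c(numeric(k), base)[1:88200]
    onk <- detect_crackles(shifted, FS)
    expect_length(onk, length(on0))
    expect_lt(max(abs(onk - (on0 + k / FS))), 1 / FS)
  }
})

test_that("waveform metrology is unbiased over random crackle shapes", {
  set.seed(2024)
  n_bad_idw <- 0L; n_bad_tcd <- 0L
  for (i in 1:200) {
    f0 <- runif(1, 200, 800)
    tau <- runif(1, 0.002, 0.010)
    w <- as.numeric(crackle_waveform(crackle_spec(0, f0, tau), FS, 0.03))
    seg <- c(numeric(100), w)
    m <- measure_waveform(seg, FS, 100 / FS)
    expect_false(is.null(m))
    tol_ms <- 2000 / FS
    if (abs(m$idw_ms - 500 / f0) > tol_ms) n_bad_idw <- n_bad_idw + 1L
    if (abs(m$tcd_ms - 2000 / f0) > tol_ms) n_bad_tcd <- n_bad_tcd + 1L
    # ordering invariant on every measured event
    expect_true(m$idw_ms <= m$ldw_ms + 1e-9 && m$ldw_ms <= m$tcd_ms + 1e-9)
    expect_identical(m$is_fine, m$tcd_ms < 10)
  }
  expect_equal(n_bad_idw, 0L)
  expect_equal(n_bad_tcd, 0L)
})

test_that("slow crackles are measured as coarse", {
  w <- as.numeric(crackle_waveform(crackle_spec(0, 150, 0.008), FS, 0.03))
  m <- measure_waveform(c(numeric(10), w), FS, 10 / FS)
  expect_equal(m$tcd_ms, 2000 / 150, tolerance = 0.02)
  expect_false(m$is_fine)
})

test_that("unmeasurable events (too few deflections) return NULL", {
  w <- as.numeric(crackle_waveform(crackle_spec(0, 400, 0.005), FS, 0.03))
  short <- w[1:round(0.003 * FS)]       # ends before the fourth crossing
  expect_null(measure_waveform(short, FS, 0))
  expect_error(measure_waveform(w, FS, 1), "outside the segment")
})

test_that("onset terciles split the inspiration into equal thirds", {
  expect_equal(classify_tercile(0.15), "early")
  expect_equal(classify_tercile(0.50), "mid")
  expect_equal(classify_tercile(0.95), "late")
  expect_equal(classify_tercile(c(0, 1 / 3, 2 / 3)), c("early", "mid", "late"))
  expect_error(classify_tercile(1), "\\[0, 1\\)")
  expect_error(classify_tercile(-0.1), "\\[0, 1\\)")
})

test_that("patient aggregation counts fine crackles per inspiration", {
  ev <- data.frame(
    inspiration_id = rep(sprintf("L:%d", 1:8), each = 12),
    relative_onset = rep(seq(0.1, 0.65, length.out = 12), 8),
    tcd_ms = 6, idw_ms = 1.2, ldw_ms = 1.4, a2_a1 = 0.75, a3_a1 = 0.3,
    is_fine = TRUE, stringsAsFactors = FALSE
  )
  agg <- aggregate_patient(ev, n_inspirations = 8)
  expect_equal(agg$count_per_insp, 12)
  expect_equal(agg$onset_tercile, "early")     # first onset 0.1 everywhere
  expect_equal(agg$tcd_ms, 6)

  # mean of first-crackle onsets decides the tercile
  ev2 <- data.frame(inspiration_id = c("a", "b", "c"),
                    relative_onset = c(0.1, 0.2, 0.15),
                    tcd_ms = 6, idw_ms = 1, ldw_ms = 1.2, a2_a1 = 0.7,
                    a3_a1 = 0.3, is_fine = TRUE, stringsAsFactors = FALSE)
  expect_equal(aggregate_patient(ev2, 3)$onset_tercile, "early")
  expect_equal(aggregate_patient(ev2, 3)$mean_first_onset, 0.15)

  # only 2CD < 10 ms counts as fine
  ev3 <- data.frame(inspiration_id = "a", relative_onset = c(0.2, 0.3, 0.4),
                    tcd_ms = c(5.5, 12.0, 7.0), idw_ms = 1, ldw_ms = 1.5,
                    a2_a1 = 0.7, a3_a1 = 0.3, stringsAsFactors = FALSE)
  ev3$is_fine <- ev3$tcd_ms < 10
  expect_equal(aggregate_patient(ev3, 1)$count_per_insp, 2)
  expect_equal(aggregate_patient(ev3, 1, count = "all")$count_per_insp, 3)

  # no events at all
  agg0 <- aggregate_patient(NULL, 8)
  expect_equal(agg0$count_per_insp, 0)
  expect_true(is.na(agg0$onset_tercile))
})

test_that("a synthetic patient's count is recovered end to end", {
  # lambda = 12 fine crackles per inspiration, noise-free, one site
  phases <- protocol_phases(8, 2, 2)
  insp <- phases[phases$kind == "inspiration", ]
  specs <- list()
  for (j in seq_len(nrow(insp))) {
    rels <- seq(0.08, 0.92, length.out = 12)
    for (r in rels) {
      specs[[length(specs) + 1L]] <-
        crackle_spec(insp$start_s[j] + r * 2, 420, 0.0045)
    }
  }
  sb <- synth_breath(FS, phases, specs, snr_db = 25, seed = 6)
  rec <- bandpass(sb$recording)
  events <- list()
  for (j in seq_len(nrow(insp))) {
    seg <- extract_phase(rec, insp[j, ])
    for (on in detect_crackles(seg, FS)) {
      m <- measure_waveform(seg, FS, on)
      if (is.null(m)) next
      m$relative_onset <- on / 2
      m$inspiration_id <- sprintf("L:%d", j)
      events[[length(events) + 1L]] <- m
    }
  }
  agg <- aggregate_patient(do.call(rbind, events), nrow(insp))
  expect_lt(abs(agg$count_per_insp - 12) / 12, 0.1)
})
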