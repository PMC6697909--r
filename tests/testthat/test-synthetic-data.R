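test_that("crackle waveform carries exact analytic ground truth", {
  spec <- crackle_spec(0, 400, 0.005)
  w <- crackle_waveform(spec, FS, 0.025)
  expect_length(w, round(0.025 * FS))
  expect_equal(attr(w, "idw_s"), 1.25e-3)
  expect_equal(attr(w, "tcd_s"), 5.0e-3)

  expect_true(all(crackle_waveform(crackle_spec(0, 400, 0.005, amplitude = 0),
                                   FS, 0.01) == 0))
  expect_error(crackle_waveform(crackle_spec(0, 2000, 0.005), 4000, 0.01),
               "aliasing")
})

test_that("waveform zero crossings sit at k/(2 f0) within one sample", {
  set.seed(7)
  for (i in 1:20) {
    f0 <- runif(1, 150, 900)
    w <- as.numeric(crackle_waveform(crackle_spec(0, f0, 0.004), FS, 0.012))
    a <- w[-length(w)]; b <- w[-1]
    k <- which((a > 0 & b <= 0) | (a < 0 & b >= 0))
    tz <- (k - 1 + a[k] / (a[k] - b[k])) / FS
    expected <- seq_along(tz) / (2 * f0)
    expect_lt(max(abs(tz - expected)), 1 / FS)
  }
})

test_that("successive peak ratio matches the dense-grid damping oracle", {
  # oracle: per-half-cycle |s(t)| maxima on a 1 MHz grid
  f0 <- 400; tau <- 0.005
  tg <- seq(0, 3 / f0, by = 1e-6)
  s <- sin(2 * pi * f0 * tg) * exp(-tg / tau)
  half <- floor(tg * 2 * f0)
  peaks <- tapply(abs(s), half, max)
  oracle_ratio <- unname(peaks[2] / peaks[1])
  expect_equal(oracle_ratio, exp(-1 / (2 * f0 * tau)), tolerance = 1e-4)

  w <- crackle_waveform(crackle_spec(0, f0, tau), FS, 0.02)
  m <- measure_waveform(as.numeric(w), FS, 0)
  expect_equal(m$a2_a1, oracle_ratio, tolerance = 0.02)
  expect_equal(oracle_ratio, 0.78, tolerance = 0.01)
})

test_that("quartile matching inverts the printed median [IQR] summaries", {
  # non-honeycombing crackle count 8.0 [3.3-13.7]
  p <- quartiles_to_lognormal(8.0, 3.3, 13.7)
  expect_equal(p$mu, log(8), tolerance = 1e-12)
  expect_equal(p$sigma, 1.055, tolerance = 0.005)
  # numeric inversion oracle: the quantile function returns the median and
  # the quartile ratio exactly (a lognormal can match all three points only
  # when q1 * q3 = median^2, which printed summaries need not satisfy)
  q <- qlnorm(c(0.25, 0.5, 0.75), p$mu, p$sigma)
  expect_equal(q[2], 8.0, tolerance = 1e-12)
  expect_equal(q[3] / q[1], 13.7 / 3.3, tolerance = 1e-9)

  # honeycombing count 21.5 [14.7-30.3]: nearly log-symmetric, so the
  # individual quartiles are also recovered closely
  p2 <- quartiles_to_lognormal(21.5, 14.7, 30.3)
  expect_equal(p2$mu, 3.068, tolerance = 0.001)
  expect_equal(p2$sigma, 0.536, tolerance = 0.005)
  q2 <- qlnorm(c(0.25, 0.5, 0.75), p2$mu, p2$sigma)
  expect_equal(q2[2], 21.5, tolerance = 1e-12)
  expect_equal(q2[3] / q2[1], 30.3 / 14.7, tolerance = 1e-9)
  expect_equal(q2, c(14.7, 21.5, 30.3), tolerance = 0.02)

  expect_error(quartiles_to_lognormal(5, 5, 7), "q1 < median")
  expect_error(quartiles_to_lognormal(5, 6, 7), "q1 < median")
})

test_that("synthetic cohort has exact group sizes and is seed-reproducible", {
  co <- synth_cohort(default_cohort_spec(), seed = 1L)
  expect_equal(nrow(co), 71L)
  expect_equal(sum(co$group == "honeycombing"), 24L)
  expect_equal(sum(co$group == "non_honeycombing"), 47L)
  expect_identical(co, synth_cohort(default_cohort_spec(), seed = 1L))
  expect_false(identical(co, synth_cohort(default_cohort_spec(), seed = 2L)))
  # physical orderings hold row-wise
  expect_true(all(co$f50_hz <= co$f95_hz & co$f95_hz <= co$f99_hz))
  expect_true(all(co$idw_ms <= co$ldw_ms & co$ldw_ms <= co$tcd_ms))
  expect_true(all(co$count_per_insp >= 0))
})

test_that("calibrated count distributions reproduce the printed summaries", {
  spec <- default_cohort_spec()
  set.seed(123)
  # non-honeycombing 8.0 [3.3-13.7]: median and IQR ratio are the
  # calibration targets (the printed triple is not log-symmetric)
  d <- spec$dist$non_honeycombing$count_per_insp
  q <- quantile(rlnorm(1e5, d$mu, d$sigma), c(0.25, 0.5, 0.75), names = FALSE)
  expect_lt(abs(q[2] - 8.0) / 8.0, 0.05)
  expect_lt(abs(q[3] / q[1] - 13.7 / 3.3) / (13.7 / 3.3), 0.05)
  # honeycombing 21.5 [14.7-30.3]: all three quartiles within 5%
  dh <- spec$dist$honeycombing$count_per_insp
  qh <- quantile(rlnorm(1e5, dh$mu, dh$sigma), c(0.25, 0.5, 0.75),
                 names = FALSE)
  expect_lt(abs(qh[2] - 21.5) / 21.5, 0.05)
  expect_lt(abs(qh[1] - 14.7) / 14.7, 0.05)
  expect_lt(abs(qh[3] - 30.3) / 30.3, 0.05)
})

test_that("onset-tercile frequencies converge to the spec probabilities", {
  spec <- default_cohort_spec(n_honeycombing = 2L, n_non_honeycombing = 30000L)
  co <- synth_cohort(spec, seed = 99L)
  tab <- table(factor(co$onset_tercile[co$group == "non_honeycombing"],
                      c("early", "mid", "late")))
  gof <- suppressWarnings(
    chisq.test(tab, p = spec$tercile_probs$non_honeycombing))
  expect_gt(gof$p.value, 0.001)
  # honeycombing group never produces late-onset patients
  co2 <- synth_cohort(default_cohort_spec(), seed = 5L)
  expect_false(any(co2$onset_tercile[co2$group == "honeycombing"] == "late"))
})

test_that("breath synthesis respects its contract", {
  phases <- protocol_phases(2, 2, 2)
  # noise disabled: signal nonzero only on crackle supports
  specs <- list(crackle_spec(0.5, 400, 0.004), crackle_spec(1.0, 500, 0.003),
                crackle_spec(4.5, 300, 0.005))
  sb <- synth_breath(FS, phases, specs, snr_db = Inf, seed = 1)
  x <- sb$recording$samples
  expect_equal(nrow(sb$events), 3L)
  expect_true(all(x[1:round(0.49 * FS)] == 0))
  expect_gt(max(abs(x[round(0.5 * FS):round(0.56 * FS)])), 0)

  # no crackles -> empty ground truth
  sb0 <- synth_breath(FS, phases, list(), snr_db = 20, seed = 1)
  expect_equal(nrow(sb0$events), 0L)

  # determinism under a fixed seed, difference across seeds
  sb1 <- synth_breath(FS, phases, specs, snr_db = 10, seed = 3)
  sb2 <- synth_breath(FS, phases, specs, snr_db = 10, seed = 3)
  expect_identical(sb1$recording$samples, sb2$recording$samples)
  sb3 <- synth_breath(FS, phases, specs, snr_db = 10, seed = 4)
  expect_false(identical(sb1$recording$samples, sb3$recording$samples))

  # onset inside an expiration is rejected
  expect_error(
    synth_breath(FS, phases, list(crackle_spec(2.5, 400, 0.004)), Inf, 1),
    "outside every inspiratory phase")
})

test_that("synthetic ratings have tunable agreement and are seeded", {
  r <- synth_ratings(50, 3, prevalence = 0.3, agreement_level = 1, seed = 1)
  expect_true(all(r[, 1] == r[, 2] & r[, 2] == r[, 3]))
  expect_equal(gwet_ac1(r)$ac1, 1)

  expect_error(synth_ratings(50, 1, 0.3, 0.9), "n_raters >= 2")
  expect_identical(synth_ratings(40, 3, 0.3, 0.8, seed = 2),
                   synth_ratings(40, 3, 0.3, 0.8, seed = 2))
  # lower agreement gives lower AC1
  lo <- gwet_ac1(synth_ratings(400, 3, 0.3, 0.5, seed = 3))$ac1
  hi <- gwet_ac1(synth_ratings(400, 3, 0.3, 0.95, seed = 3))$ac1
  expect_gt(hi, lo)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(777)
  a <- runif(1)
  set.seed(777)
  invisible(synth_cohort(default_cohort_spec(), seed = 12L))
  invisible(synth_ratings(10, 2, 0.5, 0.9, seed = 12L))
  b <- runif(1)
  expect_identical(a, b)
})
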