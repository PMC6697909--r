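test_that("group summaries use interpolated quartiles and half-up percents", {
  s <- summarize_group(1:9)
  expect_equal(s$median, 5)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 7)
  expect_error(summarize_group(numeric(0)), "empty")

  expect_equal(counts_pct(13, 24), "13 (54.2)")
  expect_equal(counts_pct(6, 24), "6 (25.0)")
  expect_equal(counts_pct(8, 47), "8 (17.0)")
})

test_that("Mann-Whitney U matches exact enumeration on small samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)   # 2 / choose(6, 3) of 20 assignments, two-sided

  # identical samples: p = 1 by symmetry
  r2 <- mann_whitney(c(1, 5, 9, 12), c(1, 5, 9, 12))
  expect_equal(r2$p, 1, tolerance = 1e-6)

  # exact and normal-approximate p agree for moderate tie-free samples
  set.seed(8)
  x <- rnorm(15); y <- rnorm(15) + 0.3
  exact_p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  approx_p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(exact_p - approx_p), 0.01)
  expect_equal(mann_whitney(x, y)$p, exact_p)
})

test_that("chi-squared test follows the Pearson form without correction", {
  r <- chi_squared(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1)

  expect_equal(chi_squared(rbind(c(5, 5), c(5, 5)))$statistic, 0)

  # onset-timing contingency of the two HRCT groups
  r3 <- chi_squared(rbind(c(20, 4, 0), c(12, 27, 8)))
  expect_equal(r3$df, 2)
  expect_lt(r3$p, 0.001)

  expect_error(chi_squared(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("Gwet's AC1 reproduces hand-computed and boundary cases", {
  # identical raters
  expect_equal(gwet_ac1(cbind(c(1, 0, 1, 1), c(1, 0, 1, 1)))$ac1, 1)

  # (+,+), (+,+), (-,-), (+,-): p_a 0.75, pi+ 0.625, p_e 0.46875
  r <- gwet_ac1(rbind(c(1, 1), c(1, 1), c(0, 0), c(1, 0)))
  expect_equal(r$p_a, 0.75)
  expect_equal(r$p_e, 0.46875)
  expect_equal(r$ac1, 0.5294118, tolerance = 1e-6)

  # complete disagreement at prevalence 1/2: p_a 0, p_e 0.5, AC1 = -1
  r2 <- gwet_ac1(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)))
  expect_equal(r2$ac1, -1)

  expect_error(gwet_ac1(cbind(c(1, 0, 1))), ">= 2")
  expect_error(gwet_ac1(rbind(c(1, 1))), ">= 2")
})

test_that("AC1 equals the direct-formula oracle on all small 2-rater tables", {
  for (n_items in 2:6) {
    grid <- expand.grid(rep(list(0:3), n_items))
    for (g in seq_len(nrow(grid))) {
      pair <- as.integer(grid[g, ])
      r1 <- pair %/% 2L
      r2 <- pair %% 2L
      if (length(unique(c(r1, r2))) < 2L) next   # single category: undefined
      got <- gwet_ac1(cbind(r1, r2))$ac1
      expect_equal(got, oracle_ac1_2rater(r1, r2), tolerance = 1e-12)
    }
  }
})

test_that("AC1 interval contains the estimate and is capped at 1", {
  r <- gwet_ac1(synth_ratings(71, 3, 24 / 71, 0.9, seed = 1))
  expect_true(r$ci_low <= r$ac1 && r$ac1 <= r$ci_high)
  expect_lte(r$ci_high, 1)
  expect_equal(r$n_items, 71L)
  expect_equal(r$n_raters, 3L)
})

test_that("logistic odds ratios behave under the null and recover signal", {
  # null: outcome independent of predictor
  set.seed(7)
  d <- data.frame(group = ifelse(rbinom(400, 1, 0.5) == 1, "honeycombing",
                                 "non_honeycombing"),
                  x = rnorm(400))
  f <- fit_logistic(d, "group", c(x = 1))
  expect_true(f$converged)
  expect_gt(f$terms$or_value, 0.7)
  expect_lt(f$terms$or_value, 1.4)
  expect_gt(f$terms$p, 0.05)
  expect_equal(f$n_used, 400L)

  # recovery: beta1 = 0.8 within 3 estimated SEs at n = 2000
  set.seed(11)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, plogis(-1 + 0.8 * x))
  d2 <- data.frame(group = ifelse(y == 1, "honeycombing", "non_honeycombing"),
                   x = x)
  f2 <- fit_logistic(d2, "group", c(x = 1))
  expect_lt(abs(f2$terms$beta - 0.8), 3 * f2$terms$se)
})

test_that("odds-ratio unit scaling is an exact algebraic identity", {
  set.seed(5)
  d <- data.frame(group = rep(c("honeycombing", "non_honeycombing"), 60),
                  z = rnorm(120, sd = 3))
  f1 <- fit_logistic(d, "group", c(z = 1))
  f100 <- fit_logistic(d, "group", c(z = 100))
  expect_equal(f100$terms$beta, f1$terms$beta)
  expect_equal(f100$terms$or_value, f1$terms$or_value^100, tolerance = 1e-9)
  expect_equal(log(f100$terms$ci_low), 100 * log(f1$terms$ci_low),
               tolerance = 1e-9)
})

test_that("affine predictor rescaling leaves fitted probabilities unchanged", {
  set.seed(13)
  d <- data.frame(group = rep(c("honeycombing", "non_honeycombing"), 50),
                  v = rnorm(100))
  f_raw <- stats::glm(I(group == "honeycombing") ~ v, data = d,
                      family = binomial())
  d2 <- d; d2$v <- (d$v - 3) / 0.25
  f_scaled <- stats::glm(I(group == "honeycombing") ~ v, data = d2,
                         family = binomial())
  expect_lt(max(abs(fitted(f_raw) - fitted(f_scaled))), 1e-6)
  expect_equal(coef(f_scaled)[["v"]], coef(f_raw)[["v"]] * 0.25,
               tolerance = 1e-6)
})

test_that("perfect separation is flagged, not silently estimated", {
  d <- data.frame(group = rep(c("honeycombing", "non_honeycombing"),
                              each = 20),
                  x = c(rnorm(20, 10), rnorm(20, -10)))
  expect_warning(f <- fit_logistic(d, "group", c(x = 1)), "non-converged")
  expect_false(f$converged)
  expect_true(is.na(f$terms$or_value))
})

test_that("multivariate term selection keeps one member per correlated cluster", {
  # single significant candidate is returned alone
  co <- two_group_cohort(n_per = 60, delta = 1.5, seed = 3)
  sel <- select_multivariate_terms(co, c(x = 1))
  expect_equal(names(sel), "x")

  # f95 and f99 strongly correlated: only the representative f99 survives
  set.seed(21)
  n <- 60
  base <- rnorm(2 * n)
  co2 <- data.frame(
    group = rep(c("honeycombing", "non_honeycombing"), each = n),
    f99_hz = 800 + 60 * base + rep(c(60, 0), each = n),
    f95_hz = 500 + 55 * base + rnorm(2 * n, sd = 5) + rep(c(55, 0), each = n),
    stringsAsFactors = FALSE
  )
  stopifnot(abs(cor(co2$f99_hz, co2$f95_hz, method = "spearman")) > 0.7)
  sel2 <- select_multivariate_terms(co2, c(f99_hz = 100, f95_hz = 100))
  expect_equal(names(sel2), "f99_hz")

  # nothing significant: empty with a warning
  co3 <- two_group_cohort(n_per = 40, delta = 0, seed = 9)
  expect_warning(sel3 <- select_multivariate_terms(co3, c(x = 1)),
                 "no candidate")
  expect_length(sel3, 0L)
})

test_that("null cohorts mostly yield empty selections", {
  n_empty <- 0L
  for (s in 1:50) {
    co <- two_group_cohort(n_per = 35, delta = 0, seed = 1000 + s)
    co$y <- rnorm(nrow(co)); co$z <- rnorm(nrow(co))
    sel <- suppressWarnings(
      select_multivariate_terms(co, c(x = 1, y = 1, z = 1)))
    if (length(sel) == 0L) n_empty <- n_empty + 1L
  }
  expect_gt(n_empty, 25L)
})

test_that("ROC analysis finds the upper-left-corner cutoff", {
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12),
                    c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff, 6.5)
  expect_equal(r$cutoff_sens, 1)
  expect_equal(r$cutoff_spec, 1)

  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both classes")
})

test_that("trapezoidal AUC equals the rank statistic on random data", {
  set.seed(101)
  for (i in 1:500) {
    n1 <- sample(5:25, 1); n0 <- sample(5:25, 1)
    pos <- rnorm(n1, mean = runif(1, 0, 1.5))
    neg <- rnorm(n0)
    r <- roc_analysis(c(pos, neg), c(rep(TRUE, n1), rep(FALSE, n0)))
    U_pos <- mann_whitney(pos, neg)$U    # pairs with pos > neg
    expect_equal(r$auc * n1 * n0, U_pos, tolerance = 1e-8)
  }
})

test_that("ROC of permuted labels is chance-level", {
  set.seed(3)
  sc <- rnorm(2000)
  lb <- sample(rep(c(TRUE, FALSE), 1000))
  r <- roc_analysis(sc, lb)
  expect_gt(r$auc, 0.47)
  expect_lt(r$auc, 0.53)
})

test_that("the reported cutoff equals the brute-force corner minimizer", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    sc <- round(rnorm(n, sd = 2), 1)    # ties on purpose
    lb <- rbinom(n, 1, plogis(sc)) == 1
    if (length(unique(lb)) < 2L) next
    r <- roc_analysis(sc, lb)
    # oracle: scan every threshold midpoint directly
    s <- sort(unique(sc))
    thr <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
    d2 <- vapply(thr, function(t) {
      sens <- sum(sc >= t & lb) / sum(lb)
      spec <- sum(sc < t & !lb) / sum(!lb)
      (1 - sens)^2 + (1 - spec)^2
    }, numeric(1))
    expect_equal((1 - r$cutoff_sens)^2 + (1 - r$cutoff_spec)^2, min(d2),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(77)
  sc <- rnorm(80)
  lb <- rbinom(80, 1, plogis(1.2 * sc)) == 1
  r <- roc_analysis(sc, lb)
  ref <- as.numeric(pROC::auc(pROC::roc(response = lb, predictor = sc,
                                        direction = "<", quiet = TRUE)))
  expect_equal(r$auc, ref, tolerance = 1e-10)
})

test_that("dichotomization uses the >= convention and propagates NA", {
  d <- data.frame(count_per_insp = c(13.2, 13.19, NA))
  d2 <- dichotomize(d, "count_per_insp", 13.2)
  expect_equal(d2$count_per_insp_ge_cutoff, c(1L, 0L, NA_integer_))
})
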