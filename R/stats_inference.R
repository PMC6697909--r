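# Statistical chain: group summaries and tests, Gwet's AC1 agreement,
# unit-scaled logistic odds ratios, and ROC analysis with the
# upper-left-corner optimal cutoff.

# ---- Summaries ------------------------------------------------------------

#' Median and interquartile range of a sample
#'
#' Quartiles by linear interpolation of order statistics
#' (`stats::quantile`, type 7), the convention used for the
#' "median \[25th-75th percentile\]" table cells.
#'
#' @param values Non-empty numeric vector (NAs dropped).
#' @return List with `median`, `q1`, `q3`.
#' @export
summarize_group <- function(values) {
  values <- values[!is.na(values)]
  ct_assert(length(values) >= 1L, "validation error: empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Format a count as "k (pct)"
#'
#' Percentage of `k` out of `n`, rounded half-up to one decimal.
#'
#' @param k Numerator count.
#' @param n Denominator (>= 1).
#' @return Character scalar like `"13 (54.2)"`.
#' @export
counts_pct <- function(k, n) {
  ct_assert(is_scalar_num(n) && n >= 1, "validation error: n must be >= 1")
  ct_assert(is_scalar_num(k) && k >= 0 && k <= n, "k must lie in [0, n]")
  sprintf("%d (%.1f)", as.integer(k), round_half_up(100 * k / n, 1L))
}

# ---- Two-group tests ------------------------------------------------------

#' Mann-Whitney U test
#'
#' U counts the pairs (x_i, y_j) with x_i > y_j (+1/2 per tie). The p-value
#' is from exact enumeration when `n_x * n_y <= 400` and there are no ties,
#' and otherwise from the normal approximation with tie and continuity
#' corrections (delegated to `stats::wilcox.test`).
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  ct_assert(length(x) >= 1L && length(y) >= 1L, "both samples must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !has_ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction by default (switchable), df = (r-1)(c-1).
#'
#' @param table Matrix of non-negative counts with all row/column sums > 0.
#' @param correct Apply the Yates correction (2x2 only).
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_squared <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  ct_assert(all(table >= 0), "counts must be non-negative")
  ct_assert(all(rowSums(table) > 0) && all(colSums(table) > 0),
            "validation error: zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

# ---- Gwet's AC1 -----------------------------------------------------------

#' Gwet's AC1 chance-corrected agreement coefficient
#'
#' AC1 = (p_a - p_e) / (1 - p_e), where p_a is the mean pairwise observed
#' agreement per item and the chance term is
#' p_e = sum_c pi_c (1 - pi_c) / (C - 1) with pi_c the mean proportion of
#' raters using category c. Unlike kappa, the chance term shrinks at extreme
#' prevalence, so AC1 stays informative for rare findings. The variance is
#' Gwet's item-level linearized estimator; the 95% Wald interval is
#' truncated above at 1.
#'
#' @param ratings Items x raters matrix (or data frame) of categorical
#'   ratings; at least 2 items and 2 raters. Missing ratings are allowed
#'   (items need >= 2 non-missing raters to contribute to agreement).
#' @return List with `ac1`, `ci_low`, `ci_high`, `se`, `p_a`, `p_e`,
#'   `n_items`, `n_raters`.
#' @export
gwet_ac1 <- function(ratings) {
  r <- as.matrix(ratings)
  ct_assert(nrow(r) >= 2L && ncol(r) >= 2L,
            "validation error: AC1 needs >= 2 items and >= 2 raters")
  cats <- sort(unique(as.vector(r[!is.na(r)])))
  C <- length(cats)
  ct_assert(C >= 2L, "validation error: ratings use a single category")

  n <- nrow(r)
  # r_ic: raters per item and category
  ric <- vapply(cats, function(cc) rowSums(r == cc, na.rm = TRUE),
                numeric(n))
  ri <- rowSums(ric)
  ct_assert(all(ri >= 2), "every item needs >= 2 non-missing ratings")

  a_i <- rowSums(ric * (ric - 1)) / (ri * (ri - 1))   # pairwise agreement
  p_a <- mean(a_i)
  pi_c <- colMeans(ric / ri)
  p_e <- sum(pi_c * (1 - pi_c)) / (C - 1)
  ac1 <- (p_a - p_e) / (1 - p_e)

  # Gwet's linearized item-level variance
  ac1_i <- (a_i - p_e) / (1 - p_e)
  pe_i <- rowSums(sweep(ric / ri, 2L, (1 - pi_c), `*`)) / (C - 1)
  ac1_star <- ac1_i - 2 * (1 - ac1) * (pe_i - p_e) / (1 - p_e)
  v <- sum((ac1_star - ac1)^2) / (n * (n - 1))
  se <- sqrt(max(v, 0))
  ci <- ac1 + c(-1, 1) * stats::qnorm(0.975) * se
  list(ac1 = ac1, ci_low = ci[1], ci_high = min(ci[2], 1), se = se,
       p_a = p_a, p_e = p_e, n_items = n, n_raters = ncol(r))
}

# ---- Logistic regression with unit-scaled odds ratios ---------------------

#' Fit a logistic model and report unit-scaled odds ratios
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm`) on the
#' complete cases. Each term may carry a `unit_scale` so the odds ratio is
#' reported per that many raw units: OR = exp(beta * unit_scale) with Wald
#' 95% CI exp((beta +/- 1.96 se) * unit_scale). On (quasi-)separation the
#' fit is flagged non-converged and ORs/CIs are returned as `NA` rather than
#' as unstable estimates.
#'
#' @param records Data frame of patient records.
#' @param outcome Name of a binary column (logical, 0/1, or the group label
#'   column `group`, where `"honeycombing"` codes 1).
#' @param terms Named numeric vector of unit scales (names are predictor
#'   columns; use scale 1 for indicators), or character vector of names
#'   (scale 1).
#' @return A `logistic_fit` object: data frame `terms` (name, unit_scale,
#'   beta, se, or_value, ci_low, ci_high, p), plus `n_used`, `converged`,
#'   `log_likelihood`.
#' @export
fit_logistic <- function(records, outcome = "group", terms) {
  if (is.character(terms)) terms <- stats::setNames(rep(1, length(terms)), terms)
  ct_assert(length(terms) >= 1L && !is.null(names(terms)),
            "terms must be a named vector of unit scales")
  ct_assert(all(names(terms) %in% names(records)),
            "all terms must be columns of records")

  y <- records[[outcome]]
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "honeycombing"
  y <- as.integer(y)
  dat <- records[, names(terms), drop = FALSE]
  dat <- data.frame(lapply(dat, function(v) {
    if (is.logical(v)) return(as.numeric(v))
    ct_assert(is.numeric(v),
              "categorical terms must be coded as 0/1 indicators first")
    as.numeric(v)
  }), check.names = FALSE)
  dat$.y <- y
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  n_used <- nrow(dat)
  ct_assert(sum(dat$.y) >= 1 && sum(1 - dat$.y) >= 1,
            "validation error: need both outcome classes among complete cases")

  fml <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", names(terms)), collapse = " + ")))
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_flag <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- summary(fit)$coefficients
  converged <- fit$converged && !sep_flag

  rows <- lapply(names(terms), function(nm) {
    key <- sprintf("`%s`", nm)
    key <- if (key %in% rownames(cf)) key else nm
    beta <- cf[key, "Estimate"]; se <- cf[key, "Std. Error"]
    sc <- terms[[nm]]
    if (converged) {
      data.frame(name = nm, unit_scale = sc, beta = beta, se = se,
                 or_value = exp(beta * sc),
                 ci_low = exp((beta - stats::qnorm(0.975) * se) * sc),
                 ci_high = exp((beta + stats::qnorm(0.975) * se) * sc),
                 p = cf[key, "Pr(>|z|)"], stringsAsFactors = FALSE)
    } else {
      data.frame(name = nm, unit_scale = sc, beta = beta, se = se,
                 or_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p = NA_real_, stringsAsFactors = FALSE)
    }
  })
  out <- list(terms = do.call(rbind, rows), n_used = n_used,
              converged = converged,
              log_likelihood = as.numeric(stats::logLik(fit)))
  if (!converged) {
    warning("logistic fit flagged non-converged (possible separation); ",
            "odds ratios withheld", call. = FALSE)
  }
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, converged = %s, logLik = %.3f\n",
              x$n_used, x$converged, x$log_likelihood))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Select terms for the multivariate model
#'
#' Keeps candidates whose univariate logistic p-value is below `p_enter`,
#' then prunes strongly correlated continuous variables: within each
#' connected cluster of retained terms with |Spearman rho| above
#' `corr_threshold`, only the designated representative survives (the
#' frequency-percentile cluster's representative is F99 by default;
#' otherwise the cluster member with the smallest univariate p).
#'
#' @param records Data frame of patient records.
#' @param candidates Named numeric vector of unit scales (or character
#'   vector) of candidate terms.
#' @param outcome Outcome column (see [fit_logistic()]).
#' @param p_enter Univariate inclusion threshold (default 0.05).
#' @param corr_threshold |Spearman rho| above which two terms are treated as
#'   redundant (default 0.7).
#' @param representatives Character vector of preferred cluster
#'   representatives.
#' @return Named numeric vector of retained terms (empty, with a warning,
#'   when nothing is significant). The univariate fits are attached as
#'   attribute `"univariate"`.
#' @export
select_multivariate_terms <- function(records, candidates, outcome = "group",
                                      p_enter = 0.05, corr_threshold = 0.7,
                                      representatives = "f99_hz") {
  if (is.character(candidates))
    candidates <- stats::setNames(rep(1, length(candidates)), candidates)
  ct_assert(length(candidates) >= 1L, "candidates must be non-empty")

  uni <- lapply(names(candidates), function(nm) {
    f <- fit_logistic(records, outcome, candidates[nm])
    cbind(f$terms, n_used = f$n_used)
  })
  uni <- do.call(rbind, uni)

  keep <- uni$name[!is.na(uni$p) & uni$p < p_enter]
  if (length(keep) == 0L) {
    warning("no candidate reached univariate p < ", p_enter, call. = FALSE)
    out <- stats::setNames(numeric(0), character(0))
    attr(out, "univariate") <- uni
    return(out)
  }

  cont <- keep[vapply(keep, function(nm) {
    v <- records[[nm]]
    is.numeric(v) && length(unique(v[!is.na(v)])) > 2L
  }, logical(1))]

  drop <- character(0)
  if (length(cont) > 1L) {
    cm <- abs(stats::cor(records[, cont, drop = FALSE],
                         method = "spearman", use = "pairwise.complete.obs"))
    adj <- cm > corr_threshold
    diag(adj) <- FALSE
    # connected components by repeated expansion
    unvisited <- cont
    while (length(unvisited) > 0L) {
      comp <- unvisited[1L]
      repeat {
        nb <- cont[apply(adj[comp, , drop = FALSE], 2L, any)]
        grown <- union(comp, nb)
        if (length(grown) == length(comp)) break
        comp <- grown
      }
      if (length(comp) > 1L) {
        rep_nm <- intersect(representatives, comp)
        if (length(rep_nm) == 0L) {
          ps <- uni$p[match(comp, uni$name)]
          rep_nm <- comp[which.min(ps)]
        }
        drop <- c(drop, setdiff(comp, rep_nm[1L]))
      }
      unvisited <- setdiff(unvisited, comp)
    }
  }
  keep <- setdiff(keep, drop)
  out <- candidates[keep]
  attr(out, "univariate") <- uni
  out
}

# ---- ROC ------------------------------------------------------------------

#' ROC analysis with the upper-left-corner optimal cutoff
#'
#' Higher scores are treated as more indicative of the positive class. The
#' curve is traced over all distinct-score thresholds ("positive" when
#' score >= threshold), the AUC is the trapezoidal area, and the optimal
#' cutoff minimizes the Euclidean distance to the upper-left corner
#' (sensitivity 1, specificity 1), ties broken toward higher specificity.
#' The reported cutoff is the midpoint between the adjacent distinct scores
#' realizing the optimum.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1, or `"honeycombing"`-labelled) class
#'   indicator, `TRUE` = positive; both classes must be present.
#' @return A `roc_result`: `thresholds`, `sens`, `spec`, `auc`, `cutoff`,
#'   `cutoff_sens`, `cutoff_spec`.
#' @export
roc_analysis <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "honeycombing"
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  ct_assert(n1 >= 1L && n0 >= 1L,
            "validation error: both classes must be present")

  s <- sort(unique(scores))
  # thresholds: below the minimum, each midpoint, above the maximum
  thr <- c(s[1L] - 1, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2,
           s[length(s)] + 1)
  sens <- vapply(thr, function(t) sum(scores >= t & labels) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & !labels) / n0, numeric(1))

  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1L] + sens[o][-length(o)]) / 2)

  d2 <- (1 - sens)^2 + (1 - spec)^2
  best <- which(d2 <= min(d2) + 1e-12)
  best <- best[which.max(spec[best])]
  structure(
    list(thresholds = thr, sens = sens, spec = spec, auc = auc,
         cutoff = thr[best], cutoff_sens = sens[best],
         cutoff_spec = spec[best]),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f; upper-left cutoff %.4g (sens %.3f, spec %.3f)\n",
    x$auc, x$cutoff, x$cutoff_sens, x$cutoff_spec))
  invisible(x)
}

#' Dichotomize a variable at a cutoff
#'
#' Adds an indicator column `<variable>_ge_cutoff` equal to 1 when the value
#' is greater than or equal to `cutoff` (missing values stay missing).
#'
#' @param records Data frame.
#' @param variable Column name.
#' @param cutoff Finite threshold.
#' @return `records` with the indicator column appended.
#' @export
dichotomize <- function(records, variable, cutoff) {
  ct_assert(variable %in% names(records), "variable not found in records")
  ct_assert(is_scalar_num(cutoff), "cutoff must be finite")
  v <- records[[variable]]
  records[[paste0(variable, "_ge_cutoff")]] <-
    ifelse(is.na(v), NA_integer_, as.integer(v >= cutoff))
  records
}
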