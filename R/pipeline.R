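# Pipeline orchestration: synthesize -> extract -> analyze -> report.
#
# Each stage is an exported function over the module surfaces, usable from R
# or from the thin CLI wrapper in inst/cli/crackletrack.R. A fully specified
# config plus seed determines every output byte (no timestamps are written),
# which the manifest checksums make testable.

#' Build a pipeline configuration
#'
#' @param seed Master seed; all per-recording seeds are derived from it.
#' @param n_honeycombing,n_non_honeycombing Cohort group sizes.
#' @param n_audio_per_group Patients per group for which annotated audio is
#'   synthesized (audio is the per-recording demonstration fixture; the
#'   cohort table is the statistical unit).
#' @param fs Sampling rate in Hz.
#' @param n_breaths,t_insp_s,t_exp_s Breathing protocol per recording.
#' @param snr_db Onset SNR of synthesized crackles.
#' @param filter,detection [filter_settings()] / [detection_settings()].
#' @param spectral List with `window_len`, `overlap`.
#' @param ratings List with `n_raters`, `agreement_level` for the synthetic
#'   HRCT rating fixture.
#' @param model List with named numeric vectors `candidates` (unit scales
#'   for univariate screening) and `forced` (terms always added to the
#'   multivariate model).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_honeycombing = 24L, n_non_honeycombing = 47L,
                            n_audio_per_group = 1L,
                            fs = 44100, n_breaths = 8L,
                            t_insp_s = 2, t_exp_s = 2, snr_db = 20,
                            filter = filter_settings(),
                            detection = detection_settings(),
                            spectral = list(window_len = 4096L, overlap = 0.5),
                            ratings = list(n_raters = 3L, agreement_level = 0.9),
                            model = NULL) {
  if (is.null(model)) {
    model <- list(
      candidates = c(timing_early = 1, count_per_insp = 5, f99_hz = 100,
                     f95_hz = 100, f50_hz = 100, tcd_ms = 1, idw_ms = 1,
                     ldw_ms = 1, a2_a1 = 1, a3_a1 = 1, age_y = 1),
      forced = c(ldw_ms = 1, age_y = 1)
    )
  }
  cfg <- list(seed = as.integer(seed),
              n_honeycombing = as.integer(n_honeycombing),
              n_non_honeycombing = as.integer(n_non_honeycombing),
              n_audio_per_group = as.integer(n_audio_per_group),
              fs = fs, n_breaths = as.integer(n_breaths),
              t_insp_s = t_insp_s, t_exp_s = t_exp_s, snr_db = snr_db,
              filter = filter, detection = detection, spectral = spectral,
              ratings = ratings, model = model)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields in the file override the defaults of [pipeline_config()];
#' nested `filter`, `detection`, `spectral` and `ratings` blocks override
#' per field.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ct_assert(file.exists(path), sprintf("config not found: %s", path))
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("seed", "n_honeycombing", "n_non_honeycombing",
               "n_audio_per_group", "fs", "n_breaths", "t_insp_s",
               "t_exp_s", "snr_db")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$filter))
    args$filter <- do.call(filter_settings, y$filter)
  if (!is.null(y$detection))
    args$detection <- do.call(detection_settings, y$detection)
  cfg <- do.call(pipeline_config, args)
  for (nm in c("spectral", "ratings")) {
    if (!is.null(y[[nm]])) cfg[[nm]] <- utils::modifyList(cfg[[nm]], y[[nm]])
  }
  cfg
}

rec_seed <- function(seed, i) (seed + 7919L * i) %% .Machine$integer.max

# Crackle specs for one recording, derived from a patient's feature row.
patient_crackle_specs <- function(row, phases, seed) {
  insp <- phases[phases$kind == "inspiration", , drop = FALSE]
  f0 <- 2000 / row$tcd_ms
  f0 <- min(max(f0, 150), 1900)
  tau <- if (row$a2_a1 > 0 && row$a2_a1 < 1) {
    -(1 / (2 * f0)) / log(row$a2_a1)
  } else {
    4 / f0
  }
  rel_lo <- switch(row$onset_tercile,
                   early = 0.02, mid = 1 / 3, late = 2 / 3, 0.02)
  with_seed(seed, {
    specs <- list()
    gap <- 0.016                     # min separation (fraction of phase)
    for (j in seq_len(nrow(insp))) {
      n_j <- stats::rpois(1L, row$count_per_insp)
      if (n_j < 1L) next
      first <- stats::runif(1L, rel_lo, rel_lo + 0.08)
      span <- 0.97 - first
      n_j <- min(n_j, floor(span / gap))
      # uniform placement with a minimum gap enforced by construction
      u <- sort(stats::runif(n_j - 1L))
      rel <- c(first,
               first + u * (span - (n_j - 1L) * gap) +
                 seq_len(n_j - 1L) * gap)
      dur <- insp$end_s[j] - insp$start_s[j]
      for (r in rel) {
        specs[[length(specs) + 1L]] <-
          crackle_spec(onset_s = insp$start_s[j] + r * dur, f0 = f0,
                       tau_s = tau)
      }
    }
    specs
  })
}

#' Synthesize the full fixture set
#'
#' Writes the cohort table, the synthetic HRCT rating matrix, annotated
#' audio (WAV + phase/event CSVs) for the first `n_audio_per_group` patients
#' of each group at both auscultation sites, and a checksum manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame (file, md5).
#' @export
cmd_synthesize <- function(config = pipeline_config(), out_dir) {
  ct_assert(inherits(config, "pipeline_config"), "not a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ct_assert(dir.exists(out_dir), sprintf("cannot create %s", out_dir))

  spec <- default_cohort_spec(config$n_honeycombing, config$n_non_honeycombing,
                              seed = config$seed)
  cohort <- synth_cohort(spec)
  cohort_path <- file.path(out_dir, "cohort.csv")
  utils::write.csv(cohort, cohort_path, row.names = FALSE)

  n_all <- nrow(cohort)
  ratings <- synth_ratings(n_all, config$ratings$n_raters,
                           prevalence = config$n_honeycombing / n_all,
                           agreement_level = config$ratings$agreement_level,
                           seed = rec_seed(config$seed, 1L))
  ratings_path <- file.path(out_dir, "ratings.csv")
  utils::write.csv(as.data.frame(ratings), ratings_path, row.names = FALSE)

  audio_dir <- file.path(out_dir, "audio")
  dir.create(audio_dir, showWarnings = FALSE)
  phases <- protocol_phases(config$n_breaths, config$t_insp_s, config$t_exp_s)

  idx_h <- which(cohort$group == "honeycombing")[seq_len(config$n_audio_per_group)]
  idx_n <- which(cohort$group == "non_honeycombing")[seq_len(config$n_audio_per_group)]
  sites <- c(left = "left_posterior_base", right = "right_posterior_base")
  k <- 1L
  for (i in c(idx_h, idx_n)) {
    row <- cohort[i, ]
    for (s in names(sites)) {
      k <- k + 1L
      sd_k <- rec_seed(config$seed, 100L + k)
      specs <- patient_crackle_specs(row, phases, sd_k)
      sb <- synth_breath(config$fs, phases, specs, snr_db = config$snr_db,
                         seed = sd_k + 1L, site_label = sites[[s]])
      peak <- max(abs(sb$recording$samples))
      if (peak > 0.95) sb$recording$samples <- sb$recording$samples * 0.95 / peak
      prefix <- file.path(audio_dir, sprintf("%s_%s", row$patient_id, s))
      write_wav(sb$recording, paste0(prefix, ".wav"))
      ev <- sb$events
      ev$inspiration_id <- paste0(s, ":", ev$breath_index)
      write_annotations(phases, ev, prefix,
                        recording_id = sprintf("%s_%s", row$patient_id, s))
    }
  }

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  md5 <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- data.frame(file = files, md5 = md5, stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Extract patient features from annotated audio
#'
#' For every `<patient>_<site>.wav` with its `_phases.csv` annotation:
#' band-limits the signal, detects crackles in each inspiratory phase,
#' measures their time-expanded waveforms, and writes one measured-event CSV
#' per recording. Events from both sites are pooled per patient into the
#' aggregate features (crackles per inspiration, onset tercile, waveform
#' medians) together with the spectral percentile frequencies. A recording
#' whose annotations are missing or unreadable is logged and skipped; the
#' run continues.
#'
#' @param config A [pipeline_config()].
#' @param audio_dir Directory of WAV + annotation files.
#' @param out_csv Output features CSV path.
#' @return Invisibly, a list with `features` (data frame), `n_failed`, and
#'   `log` (character vector of per-recording notes).
#' @export
cmd_extract <- function(config = pipeline_config(), audio_dir, out_csv) {
  ct_assert(dir.exists(audio_dir),
            sprintf("no such audio directory: %s", audio_dir))
  wavs <- sort(list.files(audio_dir, pattern = "\\.wav$", full.names = TRUE))
  ct_assert(length(wavs) > 0L,
            sprintf("empty audio dir: no .wav files in %s", audio_dir))

  ids <- sub("_(left|right)\\.wav$", "", basename(wavs))
  log <- character(0)
  n_failed <- 0L
  rows <- list()
  for (pid in unique(ids)) {
    p_wavs <- wavs[ids == pid]
    events <- list()
    recs <- list()
    phs <- list()
    n_insp <- 0L
    for (wp in p_wavs) {
      prefix <- sub("\\.wav$", "", wp)
      site <- sub(".*_(left|right)$", "\\1", basename(prefix))
      res <- tryCatch({
        ann <- read_annotations(prefix)
        rec <- read_wav(wp)
        rec <- bandpass(rec, config$filter)
        insp <- ann$phases[ann$phases$kind == "inspiration", , drop = FALSE]
        ev_rec <- list()
        n_unmeasurable <- 0L
        for (j in seq_len(nrow(insp))) {
          seg <- extract_phase(rec, insp[j, ])
          onsets <- detect_crackles(seg, rec$fs, config$detection)
          for (on in onsets) {
            m <- measure_waveform(seg, rec$fs, on, config$detection)
            if (is.null(m)) {
              n_unmeasurable <- n_unmeasurable + 1L
              next
            }
            dur <- insp$end_s[j] - insp$start_s[j]
            m$onset_s <- insp$start_s[j] + on
            m$relative_onset <- min(on / dur, 1 - 1e-9)
            m$tercile <- classify_tercile(m$relative_onset)
            m$breath_index <- insp$breath_index[j]
            m$inspiration_id <- paste0(site, ":", insp$breath_index[j])
            ev_rec[[length(ev_rec) + 1L]] <- m
          }
        }
        ev_df <- if (length(ev_rec)) do.call(rbind, ev_rec) else NULL
        if (!is.null(ev_df)) {
          ev_out <- ev_df
          ev_out$recording_id <- basename(prefix)
          utils::write.csv(ev_out, paste0(prefix, "_measured_events.csv"),
                           row.names = FALSE)
        }
        if (n_unmeasurable > 0L) {
          log <- c(log, sprintf("%s: %d unmeasurable event(s) excluded",
                                basename(prefix), n_unmeasurable))
        }
        list(ev = ev_df, rec = rec, ph = ann$phases, n_insp = nrow(insp))
      }, error = function(e) {
        log <<- c(log, sprintf("%s: FAILED (%s)", basename(prefix),
                               conditionMessage(e)))
        NULL
      })
      if (is.null(res)) {
        n_failed <- n_failed + 1L
        next
      }
      if (!is.null(res$ev)) events[[length(events) + 1L]] <- res$ev
      recs[[length(recs) + 1L]] <- res$rec
      phs[[length(phs) + 1L]] <- res$ph
      n_insp <- n_insp + res$n_insp
    }
    if (length(recs) == 0L) next
    ev_all <- if (length(events)) do.call(rbind, events) else NULL
    agg <- aggregate_patient(ev_all, n_insp)
    pf <- patient_percentiles(recs, phs,
                              window_len = config$spectral$window_len,
                              overlap = config$spectral$overlap,
                              band = c(config$filter$low_hz, config$filter$high_hz))
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(patient_id = pid, stringsAsFactors = FALSE),
      agg,
      data.frame(f50_hz = pf$f50_hz, f95_hz = pf$f95_hz, f99_hz = pf$f99_hz)
    )
  }
  ct_assert(length(rows) > 0L, "no recording could be processed")
  features <- do.call(rbind, rows)
  utils::write.csv(features, out_csv, row.names = FALSE)
  if (length(log)) message(paste(log, collapse = "\n"))
  invisible(list(features = features, n_failed = n_failed, log = log))
}

#' Run the statistical analysis chain on a feature table
#'
#' Produces group summaries (median \[IQR\] with Mann-Whitney p for
#' continuous features; category counts with chi-squared p for onset timing
#' and sex), univariate logistic screening, correlated-variable pruning,
#' the multivariate model (selected + forced terms) with unit-scaled odds
#' ratios, ROC analyses with upper-left-corner cutoffs for the crackle count
#' and F99, a dichotomized re-fit at those cutoffs, and -- when a rating
#' matrix is supplied -- Gwet's AC1 agreement.
#'
#' @param config A [pipeline_config()].
#' @param features Data frame with a `group` column (or path to such a CSV).
#' @param ratings Optional items x raters matrix (or CSV path).
#' @param out_json Optional path for the JSON results bundle.
#' @return The results bundle (list).
#' @export
cmd_analyze <- function(config = pipeline_config(), features, ratings = NULL,
                        out_json = NULL) {
  if (is.character(features)) features <- utils::read.csv(features,
                                                          stringsAsFactors = FALSE)
  ct_assert("group" %in% names(features),
            "features must have a group column")
  grp <- features$group
  ct_assert(all(grp %in% c("honeycombing", "non_honeycombing")),
            "group must be honeycombing / non_honeycombing")
  ct_assert(length(unique(grp)) == 2L,
            "validation error: both outcome groups must be present")
  features$timing_early <-
    ifelse(is.na(features$onset_tercile), NA_real_,
           as.numeric(features$onset_tercile == "early"))

  cont_feats <- intersect(
    c("age_y", "count_per_insp", "f99_hz", "f95_hz", "f50_hz", "tcd_ms",
      "idw_ms", "ldw_ms", "a2_a1", "a3_a1"),
    names(features))
  summaries <- lapply(cont_feats, function(nm) {
    x <- features[[nm]][grp == "honeycombing"]
    y <- features[[nm]][grp == "non_honeycombing"]
    mw <- mann_whitney(x, y)
    sh <- summarize_group(x); sn <- summarize_group(y)
    data.frame(feature = nm,
               hc_median = sh$median, hc_q1 = sh$q1, hc_q3 = sh$q3,
               nh_median = sn$median, nh_q1 = sn$q1, nh_q3 = sn$q3,
               p = mw$p, stringsAsFactors = FALSE)
  })
  summaries <- do.call(rbind, summaries)

  categorical <- list()
  if ("onset_tercile" %in% names(features)) {
    tab <- table(factor(grp, c("honeycombing", "non_honeycombing")),
                 factor(features$onset_tercile, c("early", "mid", "late")))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    ct <- chi_squared(unclass(tab))
    categorical$onset_timing <- list(
      counts = as.data.frame.matrix(tab), statistic = ct$statistic,
      df = ct$df, p = ct$p)
  }
  if ("sex" %in% names(features)) {
    tab <- table(factor(grp, c("honeycombing", "non_honeycombing")),
                 features$sex)
    if (all(colSums(tab) > 0) && ncol(tab) == 2L) {
      ct <- chi_squared(unclass(tab))
      categorical$sex <- list(counts = as.data.frame.matrix(tab),
                              statistic = ct$statistic, df = ct$df, p = ct$p)
    }
  }

  candidates <- config$model$candidates
  candidates <- candidates[names(candidates) %in% names(features)]
  selected <- select_multivariate_terms(features, candidates,
                                        representatives = "f99_hz")
  uni <- attr(selected, "univariate")

  forced <- config$model$forced
  forced <- forced[names(forced) %in% names(features)]
  multi_terms <- c(selected, forced[!(names(forced) %in% names(selected))])
  multivariate <- if (length(multi_terms) >= 1L) {
    fit_logistic(features, "group", multi_terms)
  } else NULL

  roc_count <- roc_analysis(features$count_per_insp, grp)
  roc_f99 <- roc_analysis(features$f99_hz, grp)

  dich <- features
  dich <- dichotomize(dich, "count_per_insp", roc_count$cutoff)
  dich <- dichotomize(dich, "f99_hz", roc_f99$cutoff)
  dich_fit <- fit_logistic(
    dich, "group",
    c(count_per_insp_ge_cutoff = 1, f99_hz_ge_cutoff = 1, timing_early = 1))

  agreement <- NULL
  if (!is.null(ratings)) {
    if (is.character(ratings)) ratings <- as.matrix(utils::read.csv(ratings))
    agreement <- gwet_ac1(ratings)
  }

  bundle <- list(
    n = list(honeycombing = sum(grp == "honeycombing"),
             non_honeycombing = sum(grp == "non_honeycombing")),
    summaries = summaries,
    categorical = categorical,
    univariate = uni,
    selected_terms = as.list(selected),
    multivariate = if (!is.null(multivariate)) {
      list(terms = multivariate$terms, n_used = multivariate$n_used,
           converged = multivariate$converged)
    } else NULL,
    roc = list(
      count_per_insp = roc_count[c("auc", "cutoff", "cutoff_sens",
                                   "cutoff_spec")],
      f99_hz = roc_f99[c("auc", "cutoff", "cutoff_sens", "cutoff_spec")]
    ),
    dichotomized = list(terms = dich_fit$terms, n_used = dich_fit$n_used,
                        converged = dich_fit$converged),
    agreement = agreement
  )
  if (!is.null(out_json)) {
    jsonlite::write_json(bundle, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  }
  bundle
}

fmt_miqr <- function(m, q1, q3, digits = 1) {
  f <- sprintf("%%.%df", digits)
  sprintf(paste0(f, " [", f, "-", f, "]"), m, q1, q3)
}

fmt_or <- function(or, lo, hi, p) {
  if (is.na(or)) return("-- (separation)")
  sprintf("%.3f (%.3f-%.3f) P=%.3f", or, lo, hi, p)
}

#' Render a results bundle as a markdown report
#'
#' Formats the bundle produced by [cmd_analyze()] -- group comparison table,
#' multivariate odds ratios, ROC cutoffs, dichotomized model, agreement --
#' without recomputing anything, so regenerating the report from the same
#' bundle is byte-identical.
#'
#' @param bundle Results bundle (list) or path to the JSON bundle.
#' @param out_md Optional output path.
#' @return The report as a character vector of lines, invisibly when
#'   writing.
#' @export
cmd_report <- function(bundle, out_md = NULL) {
  if (is.character(bundle)) bundle <- jsonlite::read_json(bundle,
                                                          simplifyVector = TRUE)
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))
  add("# Fine-crackle acoustics report")
  add("")
  add("Groups: honeycombing n = %d, non-honeycombing n = %d",
      bundle$n$honeycombing, bundle$n$non_honeycombing)
  add("")
  add("## Acoustic features by group (median [IQR])")
  add("")
  add("| Feature | Honeycombing | Non-honeycombing | P |")
  add("|---|---|---|---|")
  s <- bundle$summaries
  for (i in seq_len(nrow(s))) {
    dg <- if (grepl("_hz$", s$feature[i])) 0 else
      if (s$feature[i] %in% c("a2_a1", "a3_a1")) 2 else 1
    add("| %s | %s | %s | %.3g |", s$feature[i],
        fmt_miqr(s$hc_median[i], s$hc_q1[i], s$hc_q3[i], dg),
        fmt_miqr(s$nh_median[i], s$nh_q1[i], s$nh_q3[i], dg), s$p[i])
  }
  if (!is.null(bundle$categorical$onset_timing)) {
    ot <- bundle$categorical$onset_timing
    add("")
    add("Onset timing early/mid/late: chi-squared %.2f, df %d, P %.3g",
        ot$statistic, as.integer(ot$df), ot$p)
  }
  if (!is.null(bundle$multivariate)) {
    add("")
    add("## Multivariate logistic model (n = %d)",
        as.integer(bundle$multivariate$n_used))
    add("")
    add("| Variable | OR | 95%% CI | P |")
    add("|---|---|---|---|")
    tm <- bundle$multivariate$terms
    # JSON round trips drop all-NA columns (a separated fit's withheld ORs)
    for (col in c("or_value", "ci_low", "ci_high", "p")) {
      if (is.null(tm[[col]])) tm[[col]] <- rep(NA_real_, nrow(tm))
    }
    for (i in seq_len(nrow(tm))) {
      if (is.na(tm$or_value[i])) {
        add("| %s (per %g) | -- | -- | -- |", tm$name[i], tm$unit_scale[i])
      } else {
        add("| %s (per %g) | %.3f | %.3f-%.3f | %.3f |", tm$name[i],
            tm$unit_scale[i], tm$or_value[i], tm$ci_low[i], tm$ci_high[i],
            tm$p[i])
      }
    }
  }
  add("")
  add("## ROC (upper-left-corner cutoffs)")
  add("")
  rc <- bundle$roc$count_per_insp; rf <- bundle$roc$f99_hz
  add("- Crackles/inspiration: AUC %.3f, cutoff %.2f (sens %.1f%%, spec %.1f%%)",
      rc$auc, rc$cutoff, 100 * rc$cutoff_sens, 100 * rc$cutoff_spec)
  add("- F99: AUC %.3f, cutoff %.0f Hz (sens %.1f%%, spec %.1f%%)",
      rf$auc, rf$cutoff, 100 * rf$cutoff_sens, 100 * rf$cutoff_spec)
  if (!is.null(bundle$dichotomized)) {
    add("")
    add("## Dichotomized multivariate model")
    add("")
    add("| Variable | OR | 95%% CI | P |")
    add("|---|---|---|---|")
    tm <- bundle$dichotomized$terms
    for (col in c("or_value", "ci_low", "ci_high", "p")) {
      if (is.null(tm[[col]])) tm[[col]] <- rep(NA_real_, nrow(tm))
    }
    for (i in seq_len(nrow(tm))) {
      if (is.na(tm$or_value[i])) {
        add("| %s | -- | -- | -- |", tm$name[i])
      } else {
        add("| %s | %.3f | %.3f-%.3f | %.3f |", tm$name[i], tm$or_value[i],
            tm$ci_low[i], tm$ci_high[i], tm$p[i])
      }
    }
  }
  if (!is.null(bundle$agreement)) {
    add("")
    add("Interobserver agreement (Gwet's AC1): %.2f (95%% CI %.2f-%.2f)",
        bundle$agreement$ac1, bundle$agreement$ci_low,
        bundle$agreement$ci_high)
  }
  add("")
  if (!is.null(out_md)) {
    writeLines(L, out_md)
    return(invisible(L))
  }
  L
}
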