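subject_seed <- function(master_seed, subject, salt = 0L) {
  # keep derived seeds well inside 32-bit integer range
  as.integer((as.numeric(master_seed) * 2654435 + subject * 97 + salt) %%
               2147483647)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Generates (or takes) a behavioral table, synthesizes each subject's EEG,
#' filters it, rejects artifacts, excludes trials, epochs response-locked
#' with a stimulus-locked baseline, and computes: per-subject RP waveforms
#' and last-500-ms Cz amplitudes per condition, cluster-based permutation
#' tests of each condition's waveforms against zero, t-tests of the RP
#' amplitudes against zero, per-subject single-trial robust trend slopes by
#' decision type, and the behavioral consistency grade per condition.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @param seed master integer seed; all per-subject and permutation seeds
#'   derive from it.
#' @param behavior optional pre-generated behavioral table (defaults to
#'   \code{generate_behavior(cfg, ...)} under the master seed).
#' @param highpass_hz,notch_band filter settings (defaults 0.1 Hz and
#'   59--61 Hz).
#' @param average_reference re-reference to the scalp-channel average
#'   before analysis (default \code{FALSE}: the synthetic montage has too
#'   few channels for an average reference to act as a neutral reference).
#' @param n_permutations permutations for the cluster tests (default 1000).
#' @param stat_window RP statistics window (default last 500 ms).
#' @param verbose print per-subject progress (default \code{FALSE}).
#' @return list with \code{rp_summary} (subject x condition mean
#'   amplitudes), \code{waveforms} (per condition: subjects x time matrix
#'   of Cz averages), \code{time}, \code{cluster_tests} (per condition),
#'   \code{amplitude_tests} (per condition t-test of mean amplitudes
#'   against 0), \code{slope_tests} (per subject x decision type),
#'   \code{consistency} (per condition behavioral grade), and
#'   \code{n_trials} bookkeeping.
#' @export
analyze_dataset <- function(cfg = generator_config(), seed = 1,
                            behavior = NULL,
                            highpass_hz = 0.1, notch_band = c(59, 61),
                            average_reference = FALSE,
                            n_permutations = 1000,
                            stat_window = c(-0.5, 0),
                            verbose = FALSE) {
  if (is.null(behavior)) {
    set.seed(seed)
    behavior <- generate_behavior(cfg)
  }
  subjects <- sort(unique(behavior$subject))
  conds <- condition_names()
  waveforms <- NULL
  rp_rows <- list()
  slope_rows <- list()
  n_time <- NULL
  for (s in subjects) {
    bs <- behavior[behavior$subject == s, , drop = FALSE]
    rec <- generate_eeg(bs, cfg, seed = subject_seed(seed, s))
    if (average_reference) rec <- rereference(rec)
    rec <- apply_filters(rec, highpass_hz, notch_band)
    bad <- reject_artifacts(rec)
    ev <- events_to_trials(rec$events)
    ev$hand <- NULL  # the behavior table already carries the hand
    trials <- merge(ev, bs, by = "trial", sort = TRUE)
    trials <- exclude_trials(trials)
    ep <- epoch_recording(rec, trials, lock = "response",
                          bad_mask = bad)
    if (is.null(n_time)) {
      n_time <- length(ep$time)
      time <- ep$time
      waveforms <- lapply(setNames(conds, conds), function(cn)
        matrix(NA_real_, length(subjects), n_time))
    }
    rp <- compute_rp(ep, channel = "Cz", stat_window = stat_window)
    rp$summary$subject <- s
    rp_rows[[length(rp_rows) + 1L]] <- rp$summary
    si <- match(s, subjects)
    for (cn in intersect(conds, names(rp$waveforms)))
      waveforms[[cn]][si, ] <- rp$waveforms[[cn]][1L, ]
    # single-trial robust slopes, pooled across difficulty per decision type
    kept <- ep$meta[ep$meta$kept, , drop = FALSE]
    cz <- match("Cz", ep$labels)
    for (dtype in c("deliberate", "arbitrary")) {
      i <- which(kept$decision_type == dtype)
      if (length(i) < 10L) next
      x <- ep$data[i, cz, , drop = FALSE]
      dim(x) <- dim(x)[c(1L, 3L)]
      slopes <- suppressWarnings(
        trend_slope_trials(x, time, rec$rate))
      tst <- subject_slope_test(slopes, n_comparisons = length(subjects))
      slope_rows[[length(slope_rows) + 1L]] <- data.frame(
        subject = s, decision_type = dtype,
        mean_slope = tst$mean_slope, p_corrected = tst$p_corrected,
        significant_downward = tst$significant_downward,
        n_trials = length(i), stringsAsFactors = FALSE)
    }
    if (verbose)
      message("subject ", s, ": ", sum(ep$meta$kept), "/",
              nrow(ep$meta), " trials kept")
  }
  rp_summary <- do.call(rbind, rp_rows)
  cluster_tests <- lapply(setNames(conds, conds), function(cn) {
    w <- waveforms[[cn]]
    w <- w[stats::complete.cases(w), , drop = FALSE]
    cluster_permutation_vs_zero(w, time,
                                n_permutations = n_permutations,
                                seed = subject_seed(seed, 0L,
                                                    match(cn, conds)))
  })
  amplitude_tests <- lapply(setNames(conds, conds), function(cn) {
    a <- rp_summary$mean_amplitude[rp_summary$condition == cn]
    tt <- t.test(a)
    list(mean = unname(tt$estimate), p = tt$p.value,
         t = unname(tt$statistic), n = length(a))
  })
  consistency <- vapply(setNames(conds, conds), function(cn) {
    b <- behavior[behavior$condition == cn, ]
    consistency_grade(b$rating_chosen, b$rating_unchosen)
  }, numeric(1L))
  list(rp_summary = rp_summary, waveforms = waveforms, time = time,
       cluster_tests = cluster_tests, amplitude_tests = amplitude_tests,
       slope_tests = do.call(rbind, slope_rows),
       consistency = consistency,
       n_trials = nrow(behavior))
}

#' Run a reproducible end-to-end workflow into a directory
#'
#' Ties the stages together under one master seed and writes their results
#' as plain files: the behavioral table (CSV), the model's behavioral
#' summary at the default parameter table (CSV), the predicted
#' movement-locked ERP per condition (CSV), the EEG analysis summary
#' (JSON), and optionally a model fit per condition (JSON). Rerunning with
#' the same seed and configuration reproduces every file bit for bit.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master integer seed.
#' @param cfg a \code{\link{generator_config}}.
#' @param stages subset of \code{c("synth", "model", "predict-rp",
#'   "analyze", "fit")}; default all but \code{"fit"} (the grid search is
#'   by far the most expensive stage).
#' @param n_model_runs simulated trials per condition for the model stages
#'   (default 1000).
#' @param fit_max_levels zoom levels for the optional fit stage (default
#'   2).
#' @param verbose print progress.
#' @return (invisibly) named list of written file paths.
#' @export
run_workflow <- function(out_dir, seed = 1, cfg = generator_config(),
                         stages = c("synth", "model", "predict-rp",
                                    "analyze"),
                         n_model_runs = 1000, fit_max_levels = 2,
                         verbose = FALSE) {
  stages <- match.arg(stages, c("synth", "model", "predict-rp", "analyze",
                                "fit"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$config <- file.path(out_dir, "config.json")
  jsonlite::write_json(c(list(seed = seed), unclass(cfg)),
                       paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  behavior <- NULL
  if ("synth" %in% stages || "analyze" %in% stages || "fit" %in% stages) {
    set.seed(seed)
    behavior <- generate_behavior(cfg)
    paths$behavior <- file.path(out_dir, "behavior.csv")
    write.csv(behavior, paths$behavior, row.names = FALSE)
  }
  tab <- default_parameter_table()
  if ("model" %in% stages) {
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      cond <- condition_from_table(tab, tab$decision_type[i],
                                   tab$difficulty[i])
      sim <- simulate_condition(cond, n_model_runs,
                                seed = subject_seed(seed, i, 100L))
      data.frame(decision_type = tab$decision_type[i],
                 difficulty = tab$difficulty[i],
                 consistency = sim$consistency,
                 mean_rt = mean(sim$rt, na.rm = TRUE),
                 n_undecided = sim$n_undecided)
    })
    paths$model <- file.path(out_dir, "model_behavior.csv")
    write.csv(do.call(rbind, rows), paths$model, row.names = FALSE)
  }
  if ("predict-rp" %in% stages) {
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      cond <- condition_from_table(tab, tab$decision_type[i],
                                   tab$difficulty[i])
      rp <- predict_rp(cond, n_model_runs,
                       seed = subject_seed(seed, i, 200L))
      cbind(decision_type = tab$decision_type[i],
            difficulty = tab$difficulty[i], rp)
    })
    paths$rp_model <- file.path(out_dir, "rp_model.csv")
    write.csv(do.call(rbind, rows), paths$rp_model, row.names = FALSE)
  }
  if ("analyze" %in% stages) {
    res <- analyze_dataset(cfg, seed, behavior = behavior,
                           verbose = verbose)
    summary <- list(
      rp_summary = res$rp_summary,
      amplitude_tests = res$amplitude_tests,
      clusters = lapply(res$cluster_tests, `[[`, "clusters"),
      slope_tests = res$slope_tests,
      consistency = as.list(res$consistency))
    paths$analysis <- file.path(out_dir, "analysis.json")
    jsonlite::write_json(summary, paths$analysis, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
  }
  if ("fit" %in% stages) {
    fits <- list()
    for (cn in condition_names()) {
      b <- behavior[behavior$condition == cn, ]
      tgt <- fit_gamma_cdf(b$rt[b$rt > 0 & b$rt < 20])
      cons <- consistency_grade(b$rating_chosen, b$rating_unchosen)
      fit <- grid_search_fit(tgt, cons, seed = subject_seed(seed, 1L, 300L),
                             max_levels = fit_max_levels)
      fits[[cn]] <- list(best = as.list(fit$best),
                         rt_error = fit$rt_error,
                         consistency_error = fit$consistency_error,
                         overall_error = fit$overall_error)
    }
    paths$fit <- file.path(out_dir, "fits.json")
    jsonlite::write_json(fits, paths$fit, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(paths)
}
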