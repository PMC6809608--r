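decimate_window <- function(x, time, rate, window, lowpass_hz, decim) {
  if (!is.null(lowpass_hz)) x <- filtfilt_fir(x, fir_lowpass(rate, lowpass_hz))
  sel <- which(time >= window[1] & time < window[2])
  sel <- sel[seq(1L, length(sel), by = decim)]
  list(x = x[sel], t = time[sel])
}

#' Linear trend of an averaged waveform before the response
#'
#' Ordinary least-squares regression of voltage against time over the last
#' second before response onset, computed --- like the single-trial variant
#' --- on decimated samples: a 25 Hz low-pass is applied for anti-aliasing
#' and every \code{decim}-th sample is kept. Decimation also brings the
#' autocorrelated EEG samples closer to the independence assumption of the
#' regression.
#'
#' @param x voltage time course in microvolts (one subject's average at one
#'   channel, response-locked).
#' @param time time axis in seconds relative to the response.
#' @param rate sampling rate in Hz.
#' @param window regression window in seconds, default \code{c(-1, 0)}.
#' @param lowpass_hz anti-aliasing corner (default 25 Hz; \code{NULL} to
#'   skip, e.g. when the input is already filtered).
#' @param decim keep every \code{decim}-th sample (default 10).
#' @return list with \code{slope} (microvolts per second), \code{p}
#'   (two-sided p-value of the slope) and \code{n} (samples used).
#' @export
trend_slope_average <- function(x, time, rate, window = c(-1, 0),
                                lowpass_hz = 25, decim = 10L) {
  d <- decimate_window(x, time, rate, window, lowpass_hz, decim)
  if (length(d$x) < 20L)
    stop("regression window holds fewer than 20 decimated samples")
  fit <- lm(d$x ~ d$t)
  s <- summary(fit)$coefficients
  list(slope = unname(s[2L, 1L]), p = unname(s[2L, 4L]), n = length(d$x))
}

#' Robust single-trial trend slopes
#'
#' Fits a robust first-order regression (iteratively reweighted least
#' squares with bisquare weights) of voltage against time to every trial,
#' on the same low-passed, decimated samples as
#' \code{\link{trend_slope_average}}. Trials where the reweighting does not
#' converge fall back to ordinary least squares with a warning.
#'
#' @param trials_x matrix, trials x time, in microvolts (single channel,
#'   response-locked).
#' @param time,rate,window,lowpass_hz,decim see
#'   \code{\link{trend_slope_average}}.
#' @param maxit maximum IRLS iterations (default 50).
#' @return numeric vector of per-trial slopes (microvolts per second) with
#'   attribute \code{n_fallback} (trials that fell back to OLS).
#' @export
trend_slope_trials <- function(trials_x, time, rate, window = c(-1, 0),
                               lowpass_hz = 25, decim = 10L, maxit = 50L) {
  stopifnot(is.matrix(trials_x), nrow(trials_x) >= 10L)
  slopes <- numeric(nrow(trials_x))
  n_fallback <- 0L
  for (i in seq_len(nrow(trials_x))) {
    d <- decimate_window(trials_x[i, ], time, rate, window, lowpass_hz,
                         decim)
    fit <- suppressWarnings(
      MASS::rlm(d$x ~ d$t, psi = MASS::psi.bisquare, maxit = maxit))
    if (!fit$converged) {
      n_fallback <- n_fallback + 1L
      slopes[i] <- unname(coef(lm(d$x ~ d$t))[2L])
    } else {
      slopes[i] <- unname(coef(fit)[2L])
    }
  }
  if (n_fallback > 0L)
    warning(n_fallback, " trial(s) fell back to OLS (IRLS non-convergence)")
  attr(slopes, "n_fallback") <- n_fallback
  slopes
}

#' Test a subject's single-trial slopes for a reliable downward trend
#'
#' One-sample t-test of the per-trial slopes against zero with a Bonferroni
#' correction for the number of subjects tested; a subject counts as having
#' a significant downward trend when the corrected two-sided p-value is
#' below \code{alpha} and the mean slope is negative.
#'
#' @param slopes per-trial slopes from \code{\link{trend_slope_trials}}.
#' @param n_comparisons number of subjects in the family (Bonferroni
#'   factor), default 1.
#' @param alpha significance level (default 0.05).
#' @return list with \code{mean_slope}, \code{p} (uncorrected),
#'   \code{p_corrected} and \code{significant_downward}.
#' @export
subject_slope_test <- function(slopes, n_comparisons = 1L, alpha = 0.05) {
  tt <- t.test(slopes)
  p_corr <- min(1, tt$p.value * n_comparisons)
  list(mean_slope = unname(tt$estimate), p = tt$p.value,
       p_corrected = p_corr,
       significant_downward = p_corr < alpha && unname(tt$estimate) < 0)
}

max_cluster_mass <- function(tvec, thr) {
  m <- 0
  for (sgn in c(1, -1)) {
    supra <- sgn * tvec > thr
    if (!any(supra)) next
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      mass <- abs(sum(tvec[starts[j]:ends[j]]))
      if (mass > m) m <- mass
    }
  }
  m
}

find_clusters <- function(tvec, thr) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- sgn * tvec > thr
    if (!any(supra)) next
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values))
      out[[length(out) + 1L]] <- list(start = starts[j], end = ends[j],
                                      mass = sum(tvec[starts[j]:ends[j]]))
  }
  out[order(vapply(out, `[[`, integer(1L), "start"))]
}

#' Cluster-based permutation test of waveforms against zero
#'
#' One-sample cluster-based nonparametric permutation test: a t statistic
#' is computed across subjects at every time point; contiguous runs of
#' samples with |t| above \code{threshold_t} form clusters whose mass is
#' the sum of t values; the null distribution of the maximum absolute
#' cluster mass is built by randomly flipping the sign of each subject's
#' waveform (the exchangeability move for a one-sample design), and each
#' observed cluster is assigned the fraction of permutations whose maximum
#' mass reaches its own. Positive and negative clusters are pooled against
#' the same max-|mass| null (a two-tailed test).
#'
#' @param waves matrix, subjects x time, in microvolts.
#' @param time time axis in seconds.
#' @param threshold_t cluster-forming threshold on |t| (default 2).
#' @param alpha significance level for flagging clusters (default 0.05).
#' @param n_permutations number of sign-flip permutations (default 1000,
#'   minimum 100).
#' @param seed optional integer seed for the permutation draws.
#' @return object of class \code{cluster_result}: list with
#'   \code{clusters} (data.frame: start_s, end_s, mass, p, significant),
#'   \code{t} (observed t series), \code{threshold_t},
#'   \code{n_permutations}, \code{alpha}, \code{time}.
#' @export
cluster_permutation_vs_zero <- function(waves, time, threshold_t = 2,
                                        alpha = 0.05,
                                        n_permutations = 1000,
                                        seed = NULL) {
  stopifnot(is.matrix(waves), ncol(waves) == length(time))
  n <- nrow(waves)
  if (n < 6L) stop("need at least 6 subjects")
  if (n_permutations < 100L) stop("need at least 100 permutations")
  if (!is.null(seed)) set.seed(seed)
  ss <- colSums(waves^2)
  t_of_means <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n)
  }
  t_obs <- t_of_means(colMeans(waves))
  clusters <- find_clusters(t_obs, threshold_t)
  signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  n_permutations, n)
  perm_means <- (signs %*% waves) / n
  null_max <- apply(perm_means, 1L, function(m)
    max_cluster_mass(t_of_means(m), threshold_t))
  cl_df <- if (length(clusters)) {
    data.frame(
      start_s = time[vapply(clusters, `[[`, integer(1L), "start")],
      end_s = time[vapply(clusters, `[[`, integer(1L), "end")],
      mass = vapply(clusters, `[[`, numeric(1L), "mass"),
      p = vapply(clusters, function(cl)
        (1 + sum(null_max >= abs(cl$mass))) / (n_permutations + 1),
        numeric(1L)))
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0),
               mass = numeric(0), p = numeric(0))
  }
  cl_df$significant <- cl_df$p < alpha
  structure(list(clusters = cl_df, t = t_obs, threshold_t = threshold_t,
                 n_permutations = n_permutations, alpha = alpha,
                 time = time),
            class = "cluster_result")
}

#' Saccade-detection configuration
#'
#' @param band band-pass interval in Hz for the radial EOG signal (default
#'   30--100 Hz).
#' @param z_thresh robust-z threshold in standardized IQR units (default
#'   2.5). One standardized IQR is \code{IQR * 0.7413}, the normal-
#'   consistent robust standard deviation.
#' @param min_duration minimum excursion duration in seconds that counts as
#'   a saccade (default 0.002; the excursion must last longer than this).
#' @param refractory detections closer than this (onset-to-onset gap below
#'   it) merge into one saccade, in seconds (default 0.05).
#' @param count_window window before each response over which saccades are
#'   counted, in seconds (default 0.5).
#' @return list of class \code{saccade_config}.
#' @export
saccade_config <- function(band = c(30, 100), z_thresh = 2.5,
                           min_duration = 0.002, refractory = 0.05,
                           count_window = 0.5) {
  stopifnot(length(band) == 2L, all(band > 0), diff(band) > 0,
            z_thresh > 0, min_duration > 0, refractory > 0,
            count_window > 0)
  structure(list(band = band, z_thresh = z_thresh,
                 min_duration = min_duration, refractory = refractory,
                 count_window = count_window),
            class = "saccade_config")
}

#' Detect saccades in the radial EOG signal
#'
#' The radial eye signal is the average of the four EOG channels,
#' band-passed to \code{cfg$band}. A saccade is a maximal run of samples
#' whose absolute deviation from the signal median exceeds
#' \code{cfg$z_thresh} standardized IQRs for longer than
#' \code{cfg$min_duration}; detections closer than \code{cfg$refractory}
#' merge into one.
#'
#' @param eog matrix, 4 x samples, the EOG channels in microvolts.
#' @param rate sampling rate in Hz.
#' @param cfg a \code{\link{saccade_config}}.
#' @return integer vector of saccade onset samples.
#' @export
detect_saccades <- function(eog, rate, cfg = saccade_config()) {
  if (!is.matrix(eog) || nrow(eog) != 4L)
    stop("eog must be a 4 x samples matrix (four EOG channels)")
  check_corner(cfg$band, rate)
  radial <- colMeans(eog)
  # a wide transition keeps the kernel short, so impulse-like bursts do
  # not ring into spurious distant detections
  radial <- filtfilt_fir(radial, fir_bandpass(rate, cfg$band,
                                              trans_hz = 15))
  dev <- abs(radial - median(radial))
  sig <- IQR(radial) * 0.7413
  supra <- dev > cfg$z_thresh * sig
  if (!any(supra)) return(integer(0))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths > cfg$min_duration * rate)
  onsets <- starts[keep]
  offsets <- ends[keep]
  if (!length(onsets)) return(integer(0))
  # chained merge: an excursion starting closer than the refractory gap to
  # the end of the previous one belongs to the same saccade
  gap <- cfg$refractory * rate
  merged <- onsets[1L]
  last_end <- offsets[1L]
  for (j in seq_along(onsets)[-1L]) {
    if (onsets[j] - last_end >= gap) merged <- c(merged, onsets[j])
    last_end <- offsets[j]
  }
  as.integer(merged)
}

#' Count pre-response saccades per trial
#'
#' Counts detected saccades inside the \code{cfg$count_window} seconds
#' before each response event (half-open window ending at the response).
#'
#' @param rec an \code{\link{eeg_recording}} containing four channels whose
#'   labels start with \code{"EOG"}.
#' @param cfg a \code{\link{saccade_config}}.
#' @return data.frame with \code{trial}, \code{response_sample} and
#'   \code{saccades}.
#' @export
saccade_count <- function(rec, cfg = saccade_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  eog_idx <- grep("^EOG", rec$labels)
  if (length(eog_idx) != 4L)
    stop("recording must contain exactly 4 EOG channels (labels 'EOG*')")
  onsets <- detect_saccades(rec$data[eog_idx, , drop = FALSE], rec$rate,
                            cfg)
  resp <- rec$events[rec$events$kind %in%
                       c("response-left", "response-right"), , drop = FALSE]
  w <- round(cfg$count_window * rec$rate)
  counts <- vapply(resp$sample, function(s)
    sum(onsets >= s - w & onsets < s), integer(1L))
  data.frame(trial = if ("trial" %in% names(resp)) resp$trial else
               seq_len(nrow(resp)),
             response_sample = resp$sample, saccades = counts)
}

#' Behavioral consistency grade
#'
#' Fraction of trials on which the chosen alternative was the one rated
#' higher in the rating session. Trials with tied ratings cannot be graded
#' and are excluded with a warning.
#'
#' @param rating_chosen,rating_unchosen numeric vectors of the ratings of
#'   the chosen and unchosen alternatives, one element per trial.
#' @return consistency grade in [0, 1].
#' @export
consistency_grade <- function(rating_chosen, rating_unchosen) {
  stopifnot(length(rating_chosen) == length(rating_unchosen))
  tied <- rating_chosen == rating_unchosen
  if (any(tied)) {
    warning(sum(tied), " tied-rating trial(s) excluded from the grade")
    rating_chosen <- rating_chosen[!tied]
    rating_unchosen <- rating_unchosen[!tied]
  }
  if (!length(rating_chosen)) stop("no gradable trials")
  mean(rating_chosen > rating_unchosen)
}
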