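#' Multichannel EEG recording container
#'
#' Lightweight container for a continuous recording: a channels-by-samples
#' matrix in microvolts, the sampling rate, channel labels, and an event
#' table. Events carry a sample index, a kind (\code{"stimulus"},
#' \code{"response-left"}, \code{"response-right"} or \code{"other"}) and a
#' trial index used to join behavioral metadata.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz.
#' @param labels character vector of channel labels (one per row).
#' @param events data.frame with at least columns \code{sample} (integer,
#'   1-based) and \code{kind}; a \code{trial} column links stimulus and
#'   response events of the same trial.
#' @return object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(data, rate, labels, events) {
  stopifnot(is.matrix(data), is.numeric(data), rate > 0,
            length(labels) == nrow(data))
  stopifnot(is.data.frame(events), all(c("sample", "kind") %in% names(events)))
  if (nrow(events) &&
      (any(events$sample < 1L) || any(events$sample > ncol(data))))
    stop("event sample indices must lie within the recording")
  rownames(data) <- labels
  structure(list(data = data, rate = rate, labels = labels,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$rate, nrow(x$events)))
  invisible(x)
}

#' Re-reference a recording to the average of scalp channels
#'
#' Subtracts the mean of the scalp channels (all channels except those in
#' \code{exclude}) from every channel. Averaging over a diffuse montage is
#' known to shrink spatially broad components such as the RP.
#'
#' @param rec an \code{\link{eeg_recording}}.
#' @param exclude labels of external channels (EOG etc.) excluded from the
#'   reference; they are still re-referenced.
#' @return the re-referenced recording.
#' @export
rereference <- function(rec, exclude = grep("^EOG", rec$labels,
                                            value = TRUE)) {
  stopifnot(inherits(rec, "eeg_recording"))
  scalp <- setdiff(rec$labels, exclude)
  if (!length(scalp)) stop("no scalp channels left to average")
  ref <- colMeans(rec$data[scalp, , drop = FALSE])
  rec$data <- sweep(rec$data, 2L, ref)
  rec
}

#' Filter a recording: high-pass, notch, optional low-pass
#'
#' Zero-phase FIR filtering of every channel. The high-pass (default
#' 0.1 Hz, transition width 0.1 Hz) removes slow drifts and DC offset; the
#' notch (default 59--61 Hz band-stop, 1 Hz transitions) removes line noise;
#' an optional low-pass (e.g. 25 Hz before decimation for trend regression)
#' can be added. The kernels are combined by convolution and applied in a
#' single forward-backward pass per channel.
#'
#' @param rec an \code{\link{eeg_recording}}.
#' @param highpass_hz high-pass corner in Hz, or \code{NULL} to skip.
#' @param notch_band two-element band-stop interval in Hz, or \code{NULL}.
#' @param lowpass_hz optional low-pass corner in Hz.
#' @return the filtered recording.
#' @export
apply_filters <- function(rec, highpass_hz = 0.1, notch_band = c(59, 61),
                          lowpass_hz = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  kernels <- list()
  if (!is.null(highpass_hz))
    kernels <- c(kernels, list(fir_highpass(rec$rate, highpass_hz)))
  if (!is.null(notch_band))
    kernels <- c(kernels, list(fir_bandstop(rec$rate, notch_band)))
  if (!is.null(lowpass_hz))
    kernels <- c(kernels, list(fir_lowpass(rec$rate, lowpass_hz)))
  if (!length(kernels)) return(rec)
  b <- Reduce(function(u, v) convolve(u, rev(v), type = "open"), kernels)
  rec$data <- filtfilt_rows(rec$data, b)
  rec
}

#' Mark artifact-contaminated intervals of a recording
#'
#' Applies three per-channel rules: absolute amplitude beyond
#' \code{amp_limit}; peak-to-peak difference beyond \code{diff_limit} within
#' any \code{diff_window}-second interval; and peak-to-peak activity below
#' \code{flat_limit} sustained for more than \code{flat_window} seconds
#' (a flatline). Any violation on any channel marks the offending interval,
#' expanded by \code{pad} seconds on both sides, as bad for all channels.
#'
#' @param rec an \code{\link{eeg_recording}} (already filtered).
#' @param amp_limit absolute amplitude limit in microvolts (default 100).
#' @param diff_limit peak-to-peak limit in microvolts (default 100).
#' @param diff_window window for the difference rule in seconds (default
#'   0.2).
#' @param flat_limit peak-to-peak floor in microvolts (default 0.5).
#' @param flat_window minimum flatline duration in seconds (default 0.1).
#' @param pad expansion of each bad interval in seconds (default 0.15).
#' @return logical vector, one element per sample; \code{TRUE} = bad.
#' @export
reject_artifacts <- function(rec, amp_limit = 100, diff_limit = 100,
                             diff_window = 0.2, flat_limit = 0.5,
                             flat_window = 0.1, pad = 0.15) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  w_diff <- max(2L, round(diff_window * rec$rate))
  w_flat <- max(2L, round(flat_window * rec$rate)) + 1L
  bad <- logical(n)
  for (ch in seq_len(nrow(rec$data))) {
    x <- rec$data[ch, ]
    v <- abs(x) > amp_limit
    rng <- cpp_trailing_range(x, w_diff)
    v <- v | cpp_dilate(rng > diff_limit, w_diff - 1L, 0L)
    flat <- cpp_trailing_range(x, w_flat) < flat_limit
    flat[seq_len(min(w_flat - 1L, n))] <- FALSE  # partial windows
    v <- v | cpp_dilate(flat, w_flat - 1L, 0L)
    bad <- bad | v
  }
  w_pad <- round(pad * rec$rate)
  as.logical(cpp_dilate(bad, w_pad, w_pad))
}

#' Flag trials for exclusion based on behavior
#'
#' Applies the behavioral exclusion rules: a wrong response key, reaction
#' time below \code{min_rt} or above \code{max_rt}, and reaction time more
#' than \code{sd_mult} standard deviations from that subject's mean in that
#' condition. The standard-deviation rule is computed once, per subject and
#' condition, on the trials surviving the absolute rules.
#'
#' @param trials data.frame with columns \code{subject}, \code{condition}
#'   (any label identifying the subject x condition cell), \code{rt}
#'   (seconds), and optionally \code{valid_key} (logical).
#' @param min_rt,max_rt absolute RT bounds in seconds (defaults 0.2 and 10).
#' @param sd_mult outlier multiplier (default 3).
#' @return the input with columns \code{kept} (logical) and \code{reason}
#'   (\code{NA} for kept trials).
#' @export
exclude_trials <- function(trials, min_rt = 0.2, max_rt = 10, sd_mult = 3) {
  stopifnot(all(c("subject", "condition", "rt") %in% names(trials)))
  reason <- rep(NA_character_, nrow(trials))
  if ("valid_key" %in% names(trials))
    reason[!trials$valid_key] <- "wrong_key"
  reason[is.na(reason) & trials$rt < min_rt] <- "rt_too_fast"
  reason[is.na(reason) & trials$rt > max_rt] <- "rt_too_slow"
  ok <- is.na(reason)
  cell <- interaction(trials$subject, trials$condition, drop = TRUE)
  for (g in levels(cell)) {
    i <- which(cell == g & ok)
    if (length(i) < 2L) next
    m <- mean(trials$rt[i]); s <- sd(trials$rt[i])
    out <- abs(trials$rt[i] - m) > sd_mult * s
    reason[i[out]] <- "rt_outlier"
  }
  trials$kept <- is.na(reason)
  trials$reason <- reason
  trials
}

#' Turn an event table into a per-trial table
#'
#' Pairs each trial's stimulus and response events and extracts the
#' response hand from the response event kind.
#'
#' @param events event data.frame with columns \code{sample}, \code{kind},
#'   \code{trial}.
#' @return data.frame with \code{trial}, \code{stimulus_sample},
#'   \code{response_sample}, \code{hand}.
#' @export
events_to_trials <- function(events) {
  stopifnot("trial" %in% names(events))
  stim <- events[events$kind == "stimulus", c("trial", "sample")]
  names(stim)[2L] <- "stimulus_sample"
  resp <- events[events$kind %in% c("response-left", "response-right"),
                 c("trial", "sample", "kind")]
  names(resp)[2L] <- "response_sample"
  resp$hand <- ifelse(resp$kind == "response-left", "left", "right")
  resp$kind <- NULL
  merge(stim, resp, by = "trial", sort = TRUE)
}

window_samples <- function(window, rate) {
  # half-open convention: [start, end) in seconds -> sample offsets
  seq.int(round(window[1] * rate), round(window[2] * rate) - 1L)
}

#' Segment a recording into baseline-corrected epochs
#'
#' Cuts one epoch per trial, locked to the stimulus or the response, over
#' \code{window} seconds relative to the lock (half-open convention:
#' \code{[start, end)} in samples, so a [-2, 0.2) s window at 512 Hz yields
#' 1126 samples). The per-channel mean over the baseline window (itself
#' locked to \code{baseline_lock}) is subtracted from each trial. Trials
#' whose epoch or baseline extends beyond the recording, or overlaps the
#' bad-interval mask, are dropped with a reason; trials already flagged in
#' \code{trials$kept} are dropped with their recorded reason.
#'
#' @param rec an \code{\link{eeg_recording}}.
#' @param trials per-trial table as from \code{\link{events_to_trials}},
#'   optionally merged with behavioral columns (\code{condition},
#'   \code{rt}, \code{kept}, \code{reason}, ...).
#' @param lock \code{"response"} or \code{"stimulus"}.
#' @param window epoch window in seconds relative to the lock, default
#'   \code{c(-2, 0.2)}.
#' @param baseline_window baseline window in seconds, default
#'   \code{c(-1, -0.5)}.
#' @param baseline_lock lock of the baseline window, \code{"stimulus"}
#'   (default) or \code{"response"}.
#' @param bad_mask optional logical per-sample artifact mask from
#'   \code{\link{reject_artifacts}}.
#' @return object of class \code{eeg_epochs}: list with \code{data} (kept
#'   trials x channels x time array), \code{time} (seconds relative to
#'   lock), \code{rate}, \code{labels}, \code{lock}, \code{baseline}
#'   (window + lock), and \code{meta} (all trials, with \code{kept} and
#'   \code{reason}; \code{data} rows correspond to \code{which(meta$kept)}).
#' @export
epoch_recording <- function(rec, trials, lock = c("response", "stimulus"),
                            window = c(-2, 0.2),
                            baseline_window = c(-1, -0.5),
                            baseline_lock = c("stimulus", "response"),
                            bad_mask = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  lock <- match.arg(lock)
  baseline_lock <- match.arg(baseline_lock)
  offs <- window_samples(window, rec$rate)
  boffs <- window_samples(baseline_window, rec$rate)
  n <- ncol(rec$data)
  meta <- trials
  if (!"kept" %in% names(meta)) meta$kept <- TRUE
  if (!"reason" %in% names(meta)) meta$reason <- NA_character_
  lock_col <- if (lock == "response") "response_sample" else "stimulus_sample"
  bl_col <- if (baseline_lock == "response") "response_sample" else
    "stimulus_sample"
  keep_rows <- list()
  for (i in seq_len(nrow(meta))) {
    if (!meta$kept[i]) next
    idx <- meta[[lock_col]][i] + offs
    bidx <- meta[[bl_col]][i] + boffs
    if (min(idx, bidx) < 1L || max(idx, bidx) > n) {
      meta$kept[i] <- FALSE; meta$reason[i] <- "out_of_bounds"; next
    }
    if (!is.null(bad_mask) && any(bad_mask[idx])) {
      meta$kept[i] <- FALSE; meta$reason[i] <- "artifact"; next
    }
    seg <- rec$data[, idx, drop = FALSE]
    seg <- seg - rowMeans(rec$data[, bidx, drop = FALSE])
    keep_rows[[length(keep_rows) + 1L]] <- seg
  }
  dat <- array(NA_real_,
               dim = c(length(keep_rows), nrow(rec$data), length(offs)),
               dimnames = list(NULL, rec$labels, NULL))
  for (j in seq_along(keep_rows)) dat[j, , ] <- keep_rows[[j]]
  structure(list(data = dat, time = offs / rec$rate, rate = rec$rate,
                 labels = rec$labels, lock = lock,
                 baseline = list(window = baseline_window,
                                 lock = baseline_lock),
                 meta = meta),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d kept / %d trials, %d channels, %d samples (%s-locked)\n",
    dim(x$data)[1L], nrow(x$meta), dim(x$data)[2L], dim(x$data)[3L], x$lock))
  invisible(x)
}

stat_window_index <- function(time, window) {
  time >= window[1] & time < window[2]
}

#' Readiness-potential amplitude and grand-average waveform
#'
#' Averages response-locked epochs at one channel per subject and
#' condition, then takes the mean amplitude over the statistics window
#' (default the last 500 ms before the response). Subjects with fewer than
#' \code{min_trials} kept trials in a condition are flagged.
#'
#' @param epochs an \code{\link{epoch_recording}} result whose \code{meta}
#'   contains \code{subject} and \code{condition} columns.
#' @param channel channel label, default \code{"Cz"}.
#' @param stat_window window in seconds for the summary statistic, default
#'   \code{c(-0.5, 0)}.
#' @param min_trials inclusion criterion per subject x condition (default
#'   30).
#' @return list with \code{summary} (data.frame: subject, condition,
#'   mean_amplitude in microvolts, n_trials, flagged), \code{waveforms}
#'   (per subject x condition mean time courses; data.frame with subject,
#'   condition and a row per epoch sample is impractical, so a named list
#'   of matrices subjects x time, one per condition), \code{grand}
#'   (condition x time matrix: mean over subjects) and \code{time}.
#' @export
compute_rp <- function(epochs, channel = "Cz", stat_window = c(-0.5, 0),
                       min_trials = 30) {
  stopifnot(inherits(epochs, "eeg_epochs"),
            channel %in% epochs$labels,
            all(c("subject", "condition") %in% names(epochs$meta)))
  kept <- epochs$meta[epochs$meta$kept, , drop = FALSE]
  ch <- match(channel, epochs$labels)
  x <- epochs$data[, ch, , drop = FALSE]
  dim(x) <- dim(x)[c(1L, 3L)]  # trials x time
  sel <- stat_window_index(epochs$time, stat_window)
  subjects <- sort(unique(kept$subject))
  conditions <- sort(unique(kept$condition))
  waveforms <- list()
  rows <- list()
  for (cond in conditions) {
    wf <- matrix(NA_real_, length(subjects), length(epochs$time),
                 dimnames = list(subjects, NULL))
    for (s in seq_along(subjects)) {
      i <- which(kept$subject == subjects[s] & kept$condition == cond)
      if (!length(i)) next
      avg <- colMeans(x[i, , drop = FALSE])
      wf[s, ] <- avg
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects[s], condition = cond,
        mean_amplitude = mean(avg[sel]), n_trials = length(i),
        flagged = length(i) < min_trials, stringsAsFactors = FALSE)
    }
    waveforms[[cond]] <- wf
  }
  grand <- t(vapply(waveforms, function(w) colMeans(w, na.rm = TRUE),
                    numeric(length(epochs$time))))
  list(summary = do.call(rbind, rows), waveforms = waveforms,
       grand = grand, time = epochs$time)
}

#' Lateralized readiness potential from C3/C4 by response hand
#'
#' Per subject, the LRP time course is the mean C3 - C4 difference in
#' left-hand response trials minus the same difference in right-hand
#' trials; the summary statistic is its mean over \code{stat_window}.
#'
#' @param epochs response-locked \code{eeg_epochs} whose \code{meta} has
#'   \code{subject} and \code{hand} columns.
#' @param channels the two motor channel labels, default
#'   \code{c("C3", "C4")}.
#' @param stat_window summary window in seconds, default \code{c(-0.5, 0)}.
#' @return list with \code{waveforms} (subjects x time matrix),
#'   \code{grand} (mean over subjects), \code{summary} (data.frame:
#'   subject, lrp mean over the window) and \code{time}.
#' @export
compute_lrp <- function(epochs, channels = c("C3", "C4"),
                        stat_window = c(-0.5, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"),
            all(channels %in% epochs$labels),
            all(c("subject", "hand") %in% names(epochs$meta)))
  kept <- epochs$meta[epochs$meta$kept, , drop = FALSE]
  i3 <- match(channels[1L], epochs$labels)
  i4 <- match(channels[2L], epochs$labels)
  d <- epochs$data[, i3, ] - epochs$data[, i4, ]  # trials x time
  subjects <- sort(unique(kept$subject))
  wf <- matrix(NA_real_, length(subjects), length(epochs$time),
               dimnames = list(subjects, NULL))
  for (s in seq_along(subjects)) {
    il <- which(kept$subject == subjects[s] & kept$hand == "left")
    ir <- which(kept$subject == subjects[s] & kept$hand == "right")
    if (!length(il) || !length(ir))
      stop("subject ", subjects[s], " lacks trials for one response hand")
    wf[s, ] <- colMeans(d[il, , drop = FALSE]) -
      colMeans(d[ir, , drop = FALSE])
  }
  sel <- stat_window_index(epochs$time, stat_window)
  list(waveforms = wf, grand = colMeans(wf),
       summary = data.frame(subject = subjects,
                            lrp = rowMeans(wf[, sel, drop = FALSE]),
                            stringsAsFactors = FALSE),
       time = epochs$time)
}
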