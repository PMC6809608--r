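#' Epoch a simulated trial relative to its decision crossing
#'
#' Averages the two SMA (noise-component) traces pointwise --- an electrode
#' over the region would pick up both accumulators --- and extracts the last
#' \code{epoch_len} samples ending at the decision crossing. Trials whose
#' crossing came earlier than \code{epoch_len} samples are padded at the
#' head with \code{NA} markers, which later drop out of averages.
#'
#' @param trial a decided trial from \code{\link{run_trial}}.
#' @param epoch_len epoch length in samples (default 2000, i.e. 2 s at the
#'   default 1 ms step).
#' @return list with \code{samples} (length \code{epoch_len}, \code{NA}-
#'   padded head) and \code{n_missing} (number of leading \code{NA}s).
#' @export
epoch_model_trial <- function(trial, epoch_len = 2000L) {
  if (is.na(trial$crossing_index) || identical(trial$winner, "none"))
    stop("cannot epoch an undecided trial")
  avg <- (trial$sma_traces$congruent + trial$sma_traces$incongruent) / 2
  n <- length(avg)
  keep <- tail(avg, epoch_len)
  n_missing <- epoch_len - length(keep)
  list(samples = c(rep(NA_real_, n_missing), keep), n_missing = n_missing)
}

#' Average model epochs into a predicted movement-locked ERP
#'
#' Per-sample mean over the non-missing entries of the epochs, multiplied by
#' -1 (model activation ramps up toward the threshold; scalp RP negativity
#' ramps down, so the model prediction is flipped vertically). A sample with
#' no contributing trials is returned as \code{NA}.
#'
#' @param epochs list of epochs from \code{\link{epoch_model_trial}}.
#' @return list with \code{mean} (sign-flipped average, activation units)
#'   and \code{count} (contributing trials per sample).
#' @export
average_model_rp <- function(epochs) {
  stopifnot(length(epochs) >= 1L)
  m <- vapply(epochs, `[[`, numeric(length(epochs[[1L]]$samples)), "samples")
  count <- rowSums(!is.na(m))
  avg <- -rowMeans(m, na.rm = TRUE)
  avg[count == 0L] <- NA_real_
  list(mean = avg, count = count)
}

#' Predict the movement-locked ERP of the model's noise component
#'
#' Simulates \code{n_runs} trials of a condition, epochs each decided trial
#' over the last \code{epoch_len} samples before its decision crossing,
#' and averages (see \code{\link{average_model_rp}}). For arbitrary
#' conditions the noise pair both decides and is recorded, yielding an
#' RP-like negative ramp; for deliberate conditions the recorded unbounded
#' noise pair is interrupted at a random level by the value-component
#' crossing, yielding only a weak trend.
#'
#' @param cond a \code{\link{condition_params}} object.
#' @param n_runs number of simulated trials (default 1000).
#' @param seed optional integer seed.
#' @param epoch_len epoch length in samples.
#' @return data.frame with \code{time} (seconds relative to the crossing,
#'   ending at 0), \code{mean} (sign-flipped average activation) and
#'   \code{count} (contributing trials), plus attributes
#'   \code{n_undecided} and \code{condition}.
#' @export
predict_rp <- function(cond, n_runs = 1000, seed = NULL,
                       epoch_len = 2000L) {
  stopifnot(inherits(cond, "condition_params"), n_runs >= 1)
  if (!is.null(seed)) set.seed(seed)
  epochs <- vector("list", n_runs)
  n_undecided <- 0L
  for (i in seq_len(n_runs)) {
    tr <- run_trial(cond)
    if (!tr$decided) { n_undecided <- n_undecided + 1L; next }
    epochs[[i]] <- epoch_model_trial(tr, epoch_len)
  }
  epochs <- epochs[!vapply(epochs, is.null, logical(1L))]
  if (!length(epochs)) stop("no decided trials to average")
  avg <- average_model_rp(epochs)
  dt <- cond$congruent$dt
  out <- data.frame(time = (seq_len(epoch_len) - epoch_len) * dt,
                    mean = avg$mean, count = avg$count)
  attr(out, "n_undecided") <- n_undecided
  attr(out, "condition") <- paste(cond$decision_type, cond$difficulty,
                                  sep = "-")
  out
}

#' Least-squares slope of a predicted ERP over a final time window
#'
#' Convenience summary used to compare the steepness of predicted ERPs:
#' ordinary least-squares slope of \code{mean} against \code{time} over
#' \code{window} (seconds relative to the crossing).
#'
#' @param rp data.frame from \code{\link{predict_rp}}.
#' @param window two-element numeric window, default \code{c(-0.5, 0)}.
#' @return slope in activation units per second.
#' @export
model_rp_slope <- function(rp, window = c(-0.5, 0)) {
  sel <- rp$time >= window[1] & rp$time <= window[2] & !is.na(rp$mean)
  unname(coef(lm(mean ~ time, data = rp[sel, ]))[2L])
}
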