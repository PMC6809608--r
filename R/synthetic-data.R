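#' Configuration of the synthetic behavior + EEG generator
#'
#' Defaults emulate the study conditions the analysis pipeline assumes:
#' four conditions (deliberate/arbitrary x easy/hard) with gamma reaction
#' times centered on 2.13, 2.52, 0.98 and 1.00 s, congruent-choice
#' probabilities 0.99, 0.83, 0.54 and 0.49, 512 Hz EEG with 1/f
#' (autocorrelated) noise, a negative pre-movement ramp reaching -2.5
#' microvolts at Cz injected in arbitrary trials only, a lateralized
#' C3/C4 component in the final 0.3 s, and band-limited EOG saccade bursts.
#'
#' @param n_subjects number of synthetic subjects (default 18).
#' @param trials_per_condition trials per condition per subject (default
#'   90).
#' @param rt_mean named means of the gamma RT distributions in seconds.
#' @param rt_shape gamma shape shared by conditions (default 6; RT
#'   coefficient of variation about 0.41, typical of response-time data).
#' @param p_congruent named congruent-choice probabilities.
#' @param rate EEG sampling rate in Hz (default 512).
#' @param channels channel labels; must include Cz, C3, C4 and four EOG
#'   channels.
#' @param noise_exponent spectral exponent of the 1/f noise (default 1).
#' @param noise_amplitude noise RMS in microvolts (default 10).
#' @param rp_onset RP ramp onset relative to the response, in seconds
#'   (default -1.2).
#' @param rp_peak RP amplitude at the response in microvolts (default
#'   -2.5); injected at Cz in arbitrary conditions only.
#' @param rp_falloff fraction of the Cz ramp reaching neighboring scalp
#'   channels (default 0.5).
#' @param rp_shape \code{"linear"} ramp (default) or \code{"quadratic"}.
#' @param lrp_amp amplitude of the lateralized component injected at the
#'   hemisphere contralateral to the response hand over the final
#'   \code{lrp_window} seconds (microvolts, default 1.5).
#' @param lrp_window duration of the lateralized component in seconds
#'   (default 0.3).
#' @param saccade_rate EOG saccade rate per second (default 3.3, which
#'   yields about 1.65 saccades per 500 ms window).
#' @param saccade_amp saccade burst amplitude in microvolts (default 30).
#' @param blink_rate eye-blink rate per second on the vertical EOG
#'   channels (default 1/60).
#' @param artifact_rate rate of large-amplitude artifacts per second
#'   (default 1/120).
#' @param fixation_range inter-trial fixation duration range in seconds,
#'   drawn uniformly (default c(1, 1.5)).
#' @param highlight_s duration the chosen cause stays highlighted after
#'   the response before the next trial (default 1 s).
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(
    n_subjects = 18L,
    trials_per_condition = 90L,
    rt_mean = c("deliberate-easy" = 2.13, "deliberate-hard" = 2.52,
                "arbitrary-easy" = 0.98, "arbitrary-hard" = 1.00),
    rt_shape = 6,
    p_congruent = c("deliberate-easy" = 0.99, "deliberate-hard" = 0.83,
                    "arbitrary-easy" = 0.54, "arbitrary-hard" = 0.49),
    rate = 512,
    channels = c("Cz", "C3", "C4", "F1", "F2",
                 "EOG1", "EOG2", "EOG3", "EOG4"),
    noise_exponent = 1,
    noise_amplitude = 10,
    rp_onset = -1.2,
    rp_peak = -2.5,
    rp_falloff = 0.5,
    rp_shape = c("linear", "quadratic"),
    lrp_amp = 1.5,
    lrp_window = 0.3,
    saccade_rate = 3.3,
    saccade_amp = 30,
    blink_rate = 1 / 60,
    artifact_rate = 1 / 120,
    fixation_range = c(1, 1.5),
    highlight_s = 1) {
  rp_shape <- match.arg(rp_shape)
  stopifnot(n_subjects >= 1, trials_per_condition >= 2,
            all(rt_mean > 0), rt_shape > 0,
            all(p_congruent >= 0 & p_congruent <= 1),
            rate > 0, noise_amplitude >= 0, saccade_rate >= 0,
            length(fixation_range) == 2L, all(fixation_range > 0))
  stopifnot(all(c("Cz", "C3", "C4") %in% channels),
            sum(grepl("^EOG", channels)) == 4L)
  structure(as.list(environment()), class = "generator_config")
}

condition_names <- function() {
  c("deliberate-easy", "deliberate-hard", "arbitrary-easy",
    "arbitrary-hard")
}

#' Generate item ratings and difficulty-matched pairs
#'
#' Rates \code{n_items} items on a 1--7 scale and builds pairs of items for
#' the two difficulty levels: hard pairs differ by exactly 1 rating point,
#' easy pairs by at least 4. If a sampled rating set cannot supply both
#' kinds of pairs it is resampled with a widened spread (up to
#' \code{max_tries} attempts).
#'
#' @param seed optional integer seed.
#' @param n_items number of items (default 50).
#' @param n_pairs pairs per difficulty level (default 45).
#' @param max_tries resampling attempts (default 20).
#' @param ratings optional fixed integer ratings (length \code{n_items});
#'   when supplied, no resampling happens and an infeasible rating set is
#'   an error.
#' @return list with \code{ratings} (data.frame: item, rating) and
#'   \code{pairs} (data.frame: pair, item_high, item_low, rating_high,
#'   rating_low, difficulty).
#' @export
generate_ratings_and_pairs <- function(seed = NULL, n_items = 50L,
                                       n_pairs = 45L, max_tries = 20L,
                                       ratings = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fixed <- !is.null(ratings)
  if (fixed) {
    stopifnot(length(ratings) == n_items)
    max_tries <- 1L
  }
  for (try in seq_len(max_tries)) {
    if (!fixed) ratings <- sample(1:7, n_items, replace = TRUE)
    combos <- utils::combn(n_items, 2L)
    d <- abs(ratings[combos[1L, ]] - ratings[combos[2L, ]])
    hard_i <- which(d == 1L)
    easy_i <- which(d >= 4L)
    if (length(hard_i) >= 1L && length(easy_i) >= 1L) {
      pick <- function(idx, difficulty) {
        sel <- idx[sample.int(length(idx), n_pairs, replace = TRUE)]
        a <- combos[1L, sel]; b <- combos[2L, sel]
        hi <- ifelse(ratings[a] >= ratings[b], a, b)
        lo <- ifelse(ratings[a] >= ratings[b], b, a)
        data.frame(item_high = hi, item_low = lo,
                   rating_high = ratings[hi], rating_low = ratings[lo],
                   difficulty = difficulty, stringsAsFactors = FALSE)
      }
      pairs <- rbind(pick(easy_i, "easy"), pick(hard_i, "hard"))
      pairs <- cbind(pair = seq_len(nrow(pairs)), pairs)
      return(list(ratings = data.frame(item = seq_len(n_items),
                                       rating = ratings),
                  pairs = pairs))
    }
  }
  stop("could not form the required rating pairs after ", max_tries,
       " attempts; rating spread too narrow")
}

#' Generate a synthetic behavioral trial table
#'
#' Draws, per subject and condition, gamma reaction times and choices that
#' pick the higher-rated alternative with the condition's congruent-choice
#' probability; item side assignment (and hence response hand) is
#' randomized, so hands come out balanced.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @param seed optional integer seed.
#' @return data.frame with one row per trial: subject, decision_type,
#'   difficulty, condition (\code{"<type>-<difficulty>"}), trial (running
#'   index within subject), rating_high, rating_low, rating_chosen,
#'   rating_unchosen, choice (congruent/incongruent), hand (left/right),
#'   rt (s), valid_key.
#' @export
generate_behavior <- function(cfg = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (s in seq_len(cfg$n_subjects)) {
    rp <- generate_ratings_and_pairs(n_pairs =
                                       ceiling(cfg$trials_per_condition / 2))
    for (cond in condition_names()) {
      parts <- strsplit(cond, "-", fixed = TRUE)[[1L]]
      n <- cfg$trials_per_condition
      # each condition cell draws from its own difficulty's pair list
      cand <- which(rp$pairs$difficulty == parts[2L])
      rows <- cand[sample.int(length(cand), n, replace = TRUE)]
      p <- rp$pairs[rows, ]
      rt <- rgamma(n, shape = cfg$rt_shape,
                   scale = cfg$rt_mean[[cond]] / cfg$rt_shape)
      congruent <- runif(n) < cfg$p_congruent[[cond]]
      high_side <- sample(c("left", "right"), n, replace = TRUE)
      hand <- ifelse(congruent, high_side,
                     ifelse(high_side == "left", "right", "left"))
      out[[length(out) + 1L]] <- data.frame(
        subject = s, decision_type = parts[1L], difficulty = parts[2L],
        condition = cond, trial = seq_len(n),
        rating_high = p$rating_high, rating_low = p$rating_low,
        rating_chosen = ifelse(congruent, p$rating_high, p$rating_low),
        rating_unchosen = ifelse(congruent, p$rating_low, p$rating_high),
        choice = ifelse(congruent, "congruent", "incongruent"),
        hand = hand, rt = rt, valid_key = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out$trial <- stats::ave(seq_len(nrow(out)), out$subject,
                          FUN = seq_along)
  rownames(out) <- NULL
  out
}

# 1/f-shaped noise via spectral shaping of white noise, scaled to a target
# RMS amplitude.
one_over_f_noise <- function(n, exponent, amplitude) {
  nfft <- stats::nextn(n, 2L)
  w <- stats::fft(rnorm(nfft))
  f <- c(1, seq_len(nfft - 1L))
  f <- pmin(f, nfft - f + 1)        # mirror for negative frequencies
  w <- w / f^(exponent / 2)
  x <- Re(stats::fft(w, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  x * amplitude / sd(x)
}

ramp_template <- function(n, peak, shape) {
  u <- seq_len(n) / n
  if (shape == "quadratic") peak * u^2 else peak * u
}

saccade_burst <- function(rate, dur = 0.01, freq = 65, amp = 30) {
  n <- max(4L, round(dur * rate))
  t <- seq_len(n) / rate
  amp * sin(2 * pi * freq * t) * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / n))
}

#' Generate a synthetic EEG recording for one subject
#'
#' Lays the subject's trials out in time (uniform 1--1.5 s fixation, then
#' the stimulus, the response after the trial's RT, and a 1 s highlight
#' before the next trial), then synthesizes channels x samples of 1/f
#' noise and injects: a negative pre-movement ramp at Cz (and neighbors,
#' scaled by \code{rp_falloff}) ending at each \emph{arbitrary}-trial
#' response; a lateralized ramp at the electrode contralateral to the
#' response hand (C4 for left-hand, C3 for right-hand responses) in the
#' final \code{lrp_window} seconds of every trial; Poisson saccade bursts
#' and slow blink transients on the EOG channels; and occasional
#' large-amplitude artifacts.
#'
#' @param behavior_subject one subject's rows of
#'   \code{\link{generate_behavior}}.
#' @param cfg a \code{\link{generator_config}}.
#' @param seed optional integer seed.
#' @return an \code{\link{eeg_recording}}; its \code{events} carry a
#'   \code{trial} column matching \code{behavior_subject$trial} ordering
#'   (a global trial counter across the four conditions).
#' @export
generate_eeg <- function(behavior_subject, cfg = generator_config(),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- behavior_subject
  n_trials <- nrow(b)
  fix <- runif(n_trials, cfg$fixation_range[1L], cfg$fixation_range[2L])
  # epoching needs 2 s + baseline before the first stimulus and 0.2 s after
  # the last response
  t_stim <- numeric(n_trials)
  cursor <- 5
  for (i in seq_len(n_trials)) {
    cursor <- cursor + fix[i]
    t_stim[i] <- cursor
    cursor <- cursor + b$rt[i] + cfg$highlight_s
  }
  t_resp <- t_stim + b$rt
  n <- ceiling((cursor + 3) * cfg$rate)
  chans <- cfg$channels
  data <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
  for (ch in seq_along(chans))
    data[ch, ] <- one_over_f_noise(n, cfg$noise_exponent,
                                   cfg$noise_amplitude)
  s_resp <- round(t_resp * cfg$rate)
  s_stim <- round(t_stim * cfg$rate)
  rp_len <- round(-cfg$rp_onset * cfg$rate)
  rp <- ramp_template(rp_len, cfg$rp_peak, cfg$rp_shape)
  neighbors <- intersect(c("C3", "C4", "F1", "F2"), chans)
  lrp_len <- round(cfg$lrp_window * cfg$rate)
  lrp <- ramp_template(lrp_len, -cfg$lrp_amp, "linear")
  for (i in seq_len(n_trials)) {
    if (b$decision_type[i] == "arbitrary") {
      idx <- (s_resp[i] - rp_len + 1L):s_resp[i]
      data["Cz", idx] <- data["Cz", idx] + rp
      for (nb in neighbors)
        data[nb, idx] <- data[nb, idx] + cfg$rp_falloff * rp
    }
    contra <- if (b$hand[i] == "left") "C4" else "C3"
    lidx <- (s_resp[i] - lrp_len + 1L):s_resp[i]
    data[contra, lidx] <- data[contra, lidx] + lrp
  }
  eog_idx <- grep("^EOG", chans)
  burst <- saccade_burst(cfg$rate, amp = cfg$saccade_amp)
  n_sacc <- rpois(1L, cfg$saccade_rate * n / cfg$rate)
  if (n_sacc > 0) {
    at <- sort(sample.int(n - length(burst), n_sacc))
    for (a in at) {
      idx <- a:(a + length(burst) - 1L)
      for (e in eog_idx) data[e, idx] <- data[e, idx] + burst
    }
  }
  n_blink <- rpois(1L, cfg$blink_rate * n / cfg$rate)
  if (n_blink > 0) {
    blen <- round(0.4 * cfg$rate)
    btpl <- 120 * sin(pi * seq_len(blen) / blen)^2
    at <- sample.int(n - blen, n_blink)
    for (a in at) {
      idx <- a:(a + blen - 1L)
      data[eog_idx[3L], idx] <- data[eog_idx[3L], idx] + btpl
      data[eog_idx[4L], idx] <- data[eog_idx[4L], idx] - btpl
    }
  }
  n_art <- rpois(1L, cfg$artifact_rate * n / cfg$rate)
  if (n_art > 0) {
    alen <- round(0.05 * cfg$rate)
    at <- sample.int(n - alen, n_art)
    for (a in at) {
      ch <- sample(seq_along(chans), 1L)
      idx <- a:(a + alen - 1L)
      data[ch, idx] <- data[ch, idx] +
        sample(c(-1, 1), 1L) * 150 * sin(pi * seq_len(alen) / alen)
    }
  }
  events <- rbind(
    data.frame(sample = s_stim, kind = "stimulus",
               trial = seq_len(n_trials)),
    data.frame(sample = s_resp,
               kind = ifelse(b$hand == "left", "response-left",
                             "response-right"),
               trial = seq_len(n_trials)))
  events <- events[order(events$sample), ]
  eeg_recording(data, cfg$rate, chans, events)
}
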