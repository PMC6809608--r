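# Shared builders for tests. Everything is generated in code; no stored
# fixtures.

# best-fit parameter sets, one list entry per condition
fit_conditions <- function(dt = 0.001, t_max = 20) {
  tab <- default_parameter_table()
  out <- lapply(seq_len(nrow(tab)), function(i)
    condition_from_table(tab, tab$decision_type[i], tab$difficulty[i],
                         dt = dt, t_max = t_max))
  names(out) <- paste(tab$decision_type, tab$difficulty, sep = "-")
  out
}

# a plain recording with given channel data (matrix or vector)
make_recording <- function(data, rate = 512,
                           labels = NULL, events = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (is.null(labels))
    labels <- c("Cz", "C3", "C4", "F1", "F2",
                "EOG1", "EOG2", "EOG3", "EOG4")[seq_len(nrow(data))]
  if (is.null(events))
    events <- data.frame(sample = 1L, kind = "other", trial = NA_integer_)
  eeg_recording(data, rate, labels, events)
}

# recording with regularly spaced stimulus/response event pairs
make_event_recording <- function(data, rate = 512, rts = NULL,
                                 first_stim_s = 4, spacing_s = 5,
                                 hands = NULL, labels = NULL) {
  n_trials <- length(rts)
  stim <- round((first_stim_s + (seq_len(n_trials) - 1L) * spacing_s) * rate)
  resp <- stim + round(rts * rate)
  if (is.null(hands)) hands <- rep(c("left", "right"),
                                   length.out = n_trials)
  events <- rbind(
    data.frame(sample = stim, kind = "stimulus", trial = seq_len(n_trials)),
    data.frame(sample = resp,
               kind = paste0("response-", hands),
               trial = seq_len(n_trials)))
  make_recording(data, rate, labels = labels, events = events)
}

# small, fully specified generator for pipeline tests
tiny_generator <- function(trials_per_condition = 10L, ...) {
  generator_config(n_subjects = 1L,
                   trials_per_condition = trials_per_condition,
                   saccade_rate = 0, blink_rate = 0, artifact_rate = 0,
                   ...)
}
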