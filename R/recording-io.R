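#' Write / read a recording as a plain-text directory container
#'
#' Serializes an \code{\link{eeg_recording}} into a directory holding
#' \code{data.csv} (channels x samples, one row per channel, microvolts),
#' \code{events.csv}, and \code{meta.json} (rate and channel labels).
#' Plain text travels and diffs well; for long recordings prefer
#' regenerating from seeds over shipping the samples.
#'
#' @param rec an \code{\link{eeg_recording}}.
#' @param dir directory to create/fill.
#' @return \code{write_recording} returns \code{dir} invisibly;
#'   \code{read_recording} returns the reconstructed recording.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "eeg_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(rec$data, file.path(dir, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  write.csv(rec$events, file.path(dir, "events.csv"), row.names = FALSE)
  jsonlite::write_json(list(rate = rec$rate, labels = rec$labels),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stop("not a recording container (missing meta.json): ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  data <- as.matrix(read.csv(file.path(dir, "data.csv"), header = FALSE))
  dimnames(data) <- NULL
  events <- read.csv(file.path(dir, "events.csv"),
                     stringsAsFactors = FALSE)
  eeg_recording(data, as.numeric(meta$rate), meta$labels, events)
}
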