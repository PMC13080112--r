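#' EEG recording container
#'
#' A minimal in-memory container for a multichannel EEG signal: a
#' channels x samples numeric matrix in microvolts plus acquisition and
#' cohort metadata.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one name per channel.
#' @param subject_id,group,paradigm metadata strings (`group` is `"HC"` or
#'   `"MCI"`, `paradigm` is `"rest"` or `"task"`).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = rownames(data),
                          subject_id = NA_character_,
                          group = NA_character_,
                          paradigm = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_invalid("`data` must be a numeric matrix")
  if (is.null(channel_names))
    channel_names <- sprintf("E%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop_invalid("one channel name per row is required")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_invalid("`fs` must be a positive scalar")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 subject_id = subject_id, group = group,
                 paradigm = paradigm),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s/%s/%s: %d ch x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$group, x$paradigm, nrow(x$data), ncol(x$data), x$fs,
    ncol(x$data) / x$fs))
  invisible(x)
}

#' Epoch set container
#'
#' Epoched EEG data as a channels x samples x epochs array with shared
#' metadata. Epochs keep their original order and identifiers so that
#' every augmented segment remains traceable to its source subject.
#'
#' @param data 3-d numeric array, channels x samples x epochs.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of channel names.
#' @param epoch_ids identifiers of the epochs (defaults to 1..n).
#' @inheritParams eeg_recording
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, channel_names = NULL, epoch_ids = NULL,
                      subject_id = NA_character_, group = NA_character_,
                      paradigm = NA_character_) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (is.null(channel_names))
    channel_names <- sprintf("E%02d", seq_len(dim(data)[1]))
  if (is.null(epoch_ids)) epoch_ids <- seq_len(dim(data)[3])
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 epoch_ids = epoch_ids, subject_id = subject_id,
                 group = group, paradigm = paradigm),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s/%s/%s: %d epochs of %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$group, x$paradigm, d[3], d[1], d[2], x$fs))
  invisible(x)
}

n_epochs <- function(x) dim(x$data)[3]

epoch_matrix <- function(x, i) x$data[, , i, drop = TRUE]

#' Write a recording to disk
#'
#' The on-disk format is a raw little-endian double matrix (channels x
#' samples, column-major) in `<prefix>.dat` plus a JSON sidecar
#' `<prefix>.json` carrying the sampling rate, channel names and cohort
#' metadata. The round trip through [read_recording()] is bit-exact.
#'
#' @param rec an [eeg_recording()].
#' @param prefix path prefix (without extension).
#' @return the prefix, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8L, endian = "little")
  meta <- list(fs = rec$fs, n_channels = nrow(rec$data),
               n_samples = ncol(rec$data),
               channel_names = rec$channel_names,
               subject_id = rec$subject_id, group = rec$group,
               paradigm = rec$paradigm)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix path prefix used when writing.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "double", n = n, size = 8L, endian = "little")
  eeg_recording(matrix(x, meta$n_channels, meta$n_samples),
                fs = as.numeric(meta$fs),
                channel_names = meta$channel_names,
                subject_id = meta$subject_id, group = meta$group,
                paradigm = meta$paradigm)
}

#' Read or write a task event table
#'
#' Events are stored as CSV with columns `onset_s` (stimulus onset in
#' seconds from recording start), `condition` (`"congruent"` or
#' `"incongruent"`) and `correct` (0/1).
#'
#' @param events data frame of events.
#' @param path CSV path.
#' @return `write_events` returns `path` invisibly; `read_events` returns
#'   the event data frame.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("onset_s", "condition", "correct") %in% names(events)))
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset_s", "condition", "correct") %in% names(ev)))
  ev
}
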