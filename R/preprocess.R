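#' Preprocessing configuration
#'
#' Defaults follow the analysis conventions used throughout the package:
#' 2-20 Hz zero-phase Butterworth band-pass, resampling to 250 Hz, common
#' average reference, +/-100 microvolt epoch rejection, ten non-overlapping
#' 20-s resting epochs, a 0-1000 ms task window baseline-corrected against
#' -200-0 ms, and ten random trial blocks for task averaging.
#'
#' @param band_low_hz,band_high_hz band-pass edges in Hz.
#' @param target_fs_hz resampling target in Hz.
#' @param reject_uV absolute amplitude rejection threshold in microvolts.
#' @param rest_epoch_s,rest_n_epochs resting augmentation: epoch length in
#'   seconds and number of epochs.
#' @param task_window_ms analysis window relative to stimulus onset (ms).
#' @param baseline_ms baseline window relative to onset (ms).
#' @param task_n_blocks number of random trial blocks for task averaging.
#' @param filter_order overall order of the Butterworth band-pass.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low_hz = 2, band_high_hz = 20,
                              target_fs_hz = 250, reject_uV = 100,
                              rest_epoch_s = 20, rest_n_epochs = 10L,
                              task_window_ms = c(0, 1000),
                              baseline_ms = c(-200, 0),
                              task_n_blocks = 10L, filter_order = 4L) {
  if (!(0 < band_low_hz && band_low_hz < band_high_hz &&
        band_high_hz < target_fs_hz / 2))
    stop_invalid("need 0 < band_low < band_high < target_fs/2")
  if (reject_uV <= 0) stop_invalid("`reject_uV` must be > 0")
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 target_fs_hz = target_fs_hz, reject_uV = reject_uV,
                 rest_epoch_s = rest_epoch_s,
                 rest_n_epochs = as.integer(rest_n_epochs),
                 task_window_ms = task_window_ms, baseline_ms = baseline_ms,
                 task_n_blocks = as.integer(task_n_blocks),
                 filter_order = as.integer(filter_order)),
            class = "preprocess_config")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass of total
#' order `cfg$filter_order` channel by channel. Phase neutrality matters
#' here because topography timing must not shift relative to the
#' microstate labels.
#'
#' @param rec an [eeg_recording()].
#' @param cfg a [preprocess_config()].
#' @return the filtered recording.
#' @export
bandpass <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * cfg$band_high_hz)
    stop_invalid("sampling rate too low for the requested band")
  ba <- signal::butter(max(1L, cfg$filter_order %/% 2L),
                       c(cfg$band_low_hz, cfg$band_high_hz) / (rec$fs / 2),
                       type = "pass")
  out <- filtfilt_mat_cpp(ba$b, ba$a, rec$data)
  rownames(out) <- rec$channel_names
  rec$data <- out
  rec
}

#' Resample a recording to a lower sampling rate
#'
#' Polyphase resampling by the rational factor `target_fs / fs`
#' (integer-Hz rates assumed). Upsampling is refused.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target sampling rate in Hz.
#' @return the resampled recording with updated `fs`.
#' @export
resample_eeg <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs)
    stop_invalid("upsampling is not supported (target_fs > fs)")
  if (target_fs == rec$fs) return(rec)
  g <- gcd_int(round(rec$fs), round(target_fs))
  p <- round(target_fs) / g
  q <- round(rec$fs) / g
  n_out <- round(ncol(rec$data) * target_fs / rec$fs)
  out <- matrix(0, nrow(rec$data), n_out)
  for (ch in seq_len(nrow(rec$data))) {
    y <- signal::resample(rec$data[ch, ], p = p, q = q)
    out[ch, ] <- y[seq_len(n_out)]
  }
  rownames(out) <- rec$channel_names
  rec$data <- out
  rec$fs <- target_fs
  rec
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels at every sample, so
#' the channel mean is zero everywhere. Idempotent.
#'
#' @param rec an [eeg_recording()].
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L)
    stop_invalid("CAR needs at least 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

#' Reject epochs by absolute amplitude
#'
#' Drops every epoch whose absolute maximum over all channels and samples
#' strictly exceeds `reject_uV` (an epoch peaking exactly at the threshold
#' is retained). Surviving epochs keep their order and identifiers. If all
#' epochs are rejected an empty epoch set is returned with a warning.
#'
#' @param epochs an [epoch_set()] in microvolts.
#' @param reject_uV rejection threshold in microvolts.
#' @return the filtered epoch set.
#' @export
reject_by_amplitude <- function(epochs, reject_uV = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  peak <- apply(abs(epochs$data), 3L, max)
  keep <- peak <= reject_uV
  if (!any(keep))
    warning("all epochs exceeded the amplitude threshold; empty result",
            call. = FALSE)
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$epoch_ids <- epochs$epoch_ids[keep]
  epochs
}

#' Segment a continuous resting recording into fixed-length epochs
#'
#' Takes exactly `n_epochs` contiguous, non-overlapping, gap-free epochs
#' of `epoch_s` seconds from the start of the recording.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_s epoch length in seconds.
#' @param n_epochs number of epochs.
#' @return an [epoch_set()].
#' @export
segment_resting <- function(rec, epoch_s = 20, n_epochs = 10L) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(epoch_s * rec$fs)
  need <- len * n_epochs
  if (ncol(rec$data) < need)
    stop_invalid(sprintf(
      "recording too short: %d samples available, %d (= %d x %gs @ %g Hz) required",
      ncol(rec$data), need, n_epochs, epoch_s, rec$fs))
  arr <- array(rec$data[, seq_len(need)],
               dim = c(nrow(rec$data), len, n_epochs))
  epoch_set(arr, fs = rec$fs, channel_names = rec$channel_names,
            subject_id = rec$subject_id, group = rec$group,
            paradigm = rec$paradigm)
}

#' Extract baseline-corrected task epochs
#'
#' Keeps only correct responses to incongruent stimuli. Each epoch spans
#' the configured post-onset analysis window; the channelwise mean of the
#' pre-stimulus baseline window is subtracted. Trials whose windows fall
#' outside the recording are refused.
#'
#' @param rec an [eeg_recording()].
#' @param events event table with columns `onset_s`, `condition`
#'   (`"congruent"`/`"incongruent"`) and `correct` (0/1).
#' @param cfg a [preprocess_config()].
#' @return an [epoch_set()]; empty (with a warning) if no trial qualifies.
#' @export
extract_task_epochs <- function(rec, events, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"),
            all(c("onset_s", "condition", "correct") %in% names(events)))
  sel <- which(events$condition == "incongruent" & events$correct == 1)
  fs <- rec$fs
  n_win <- round(diff(cfg$task_window_ms) / 1000 * fs)
  w0 <- round(cfg$task_window_ms[1] / 1000 * fs)
  b0 <- round(cfg$baseline_ms[1] / 1000 * fs)
  b1 <- round(cfg$baseline_ms[2] / 1000 * fs)
  if (length(sel) == 0L) {
    warning("no correct incongruent trials; empty result", call. = FALSE)
    return(epoch_set(array(0, c(nrow(rec$data), n_win, 0L)), fs = fs,
                     channel_names = rec$channel_names,
                     epoch_ids = integer(0), subject_id = rec$subject_id,
                     group = rec$group, paradigm = rec$paradigm))
  }
  onset <- round(events$onset_s[sel] * fs) + 1L
  lo <- onset + b0
  hi <- onset + w0 + n_win - 1L
  if (any(lo < 1L) || any(hi > ncol(rec$data)))
    stop_invalid("some trial windows fall outside the recording")
  arr <- array(0, c(nrow(rec$data), n_win, length(sel)))
  for (i in seq_along(sel)) {
    base <- rowMeans(rec$data[, (onset[i] + b0):(onset[i] + b1 - 1L),
                              drop = FALSE])
    arr[, , i] <- rec$data[, (onset[i] + w0):(onset[i] + w0 + n_win - 1L),
                           drop = FALSE] - base
  }
  epoch_set(arr, fs = fs, channel_names = rec$channel_names,
            epoch_ids = sel, subject_id = rec$subject_id,
            group = rec$group, paradigm = rec$paradigm)
}

#' Average trials within random balanced blocks
#'
#' Randomly partitions the epochs into `n_blocks` groups of near-equal
#' size (differing by at most one trial) and averages channelwise within
#' each block, yielding `n_blocks` stable representative segments.
#'
#' @param epochs an [epoch_set()].
#' @param n_blocks number of blocks.
#' @param seed optional RNG seed.
#' @return an [epoch_set()] of `n_blocks` averaged epochs.
#' @export
block_average <- function(epochs, n_blocks = 10L, seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- n_epochs(epochs)
  if (n < n_blocks)
    stop_invalid(sprintf("%d trials cannot fill %d blocks", n, n_blocks))
  with_seed(seed)
  assign_blk <- rep(seq_len(n_blocks), length.out = n)[sample.int(n)]
  d <- dim(epochs$data)
  out <- array(0, c(d[1], d[2], n_blocks))
  for (b in seq_len(n_blocks)) {
    idx <- which(assign_blk == b)
    out[, , b] <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2L)
  }
  epoch_set(out, fs = epochs$fs, channel_names = epochs$channel_names,
            epoch_ids = seq_len(n_blocks), subject_id = epochs$subject_id,
            group = epochs$group, paradigm = epochs$paradigm)
}
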