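#' Group specification for the synthetic cohort generator
#'
#' Describes one diagnostic group's microstate dynamics for one paradigm:
#' a row-stochastic distinct-state transition matrix (zero diagonal),
#' per-state mean run durations, the gamma shape of the run-length
#' distribution, the rendering signal-to-noise ratio, and the group's
#' MoCA distribution.
#'
#' @param group_label `"HC"` or `"MCI"`.
#' @param n_subjects number of subjects in the group.
#' @param transition_matrix k x k row-stochastic matrix over distinct-state
#'   transitions; the diagonal must be zero.
#' @param mean_durations_ms per-state mean run duration in milliseconds.
#' @param duration_shape gamma shape of the run-length distribution
#'   (scale is `mean/shape`).
#' @param snr template-signal RMS over noise RMS used when rendering.
#' @param moca_mean,moca_sd group MoCA distribution (points, 0-30 scale).
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(group_label, n_subjects, transition_matrix,
                       mean_durations_ms, duration_shape = 2,
                       snr = 5, moca_mean = NA_real_, moca_sd = NA_real_) {
  group_label <- match.arg(group_label, c("HC", "MCI"))
  tm <- as.matrix(transition_matrix)
  k <- nrow(tm)
  if (ncol(tm) != k) stop_invalid("`transition_matrix` must be square")
  if (any(abs(diag(tm)) > 1e-12))
    stop_invalid("`transition_matrix` must have a zero diagonal")
  if (any(tm < 0)) stop_invalid("transition probabilities must be >= 0")
  if (any(abs(rowSums(tm) - 1) > 1e-9))
    stop_invalid("rows of `transition_matrix` must sum to 1")
  if (length(mean_durations_ms) != k || any(mean_durations_ms <= 0))
    stop_invalid("`mean_durations_ms` must be positive, one per state")
  if (n_subjects < 1) stop_invalid("`n_subjects` must be >= 1")
  if (duration_shape <= 0) stop_invalid("`duration_shape` must be > 0")
  if (snr <= 0) stop_invalid("`snr` must be > 0")
  structure(list(group_label = group_label,
                 n_subjects = as.integer(n_subjects),
                 transition_matrix = unname(tm),
                 mean_durations_ms = unname(mean_durations_ms),
                 duration_shape = duration_shape, snr = snr,
                 moca_mean = moca_mean, moca_sd = moca_sd),
            class = "group_spec")
}

# distinct-state transition matrix with P(i -> j) proportional to a
# preference weight w_j; a convenient low-dimensional parametrization of
# stationary occupancy contrasts
transition_from_weights <- function(w) {
  k <- length(w)
  tm <- matrix(0, k, k)
  for (i in seq_len(k)) {
    row <- w
    row[i] <- 0
    tm[i, ] <- row / sum(row)
  }
  tm
}

#' Default synthetic cohort conditions
#'
#' Returns the per-group, per-paradigm generator settings used throughout
#' the package's validation: 31 HC and 32 MCI subjects; resting and task
#' dynamics whose mean durations and stationary occupancies reproduce the
#' qualitative group contrasts reported for MCI (longer resting A runs,
#' reduced resting D coverage/occurrence; in the task, longer and more
#' prevalent A, shorter and less prevalent C); MoCA 25.48 +/- 1.48 (HC)
#' versus 19.16 +/- 1.48 (MCI); rendering SNR 5.
#'
#' @return a list `list(hc = list(rest=, task=), mci = list(rest=, task=))`
#'   of [group_spec()] objects.
#' @export
default_group_specs <- function() {
  list(
    hc = list(
      rest = group_spec("HC", 31,
                        transition_from_weights(c(.25, .25, .25, .25)),
                        mean_durations_ms = c(57.6, 64.0, 68.0, 76.4),
                        moca_mean = 25.48, moca_sd = 1.48),
      task = group_spec("HC", 31,
                        transition_from_weights(c(.194, .269, .269, .268)),
                        mean_durations_ms = c(42.8, 56.0, 85.8, 60.0),
                        moca_mean = 25.48, moca_sd = 1.48)
    ),
    mci = list(
      rest = group_spec("MCI", 32,
                        transition_from_weights(c(.265, .265, .264, .206)),
                        mean_durations_ms = c(69.2, 64.0, 68.0, 65.6),
                        moca_mean = 19.16, moca_sd = 1.48),
      task = group_spec("MCI", 32,
                        transition_from_weights(c(.252, .269, .187, .292)),
                        mean_durations_ms = c(55.6, 40.0, 60.0, 40.0),
                        moca_mean = 19.16, moca_sd = 1.48)
    )
  )
}

#' Stationary distribution of the embedded (distinct-state) chain
#' @noRd
embedded_stationary <- function(tm) {
  e <- eigen(t(tm))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Build k microstate template maps
#'
#' Templates are the canonical A-D prototype fields of
#' [canonical_templates()] plus a seed-dependent smooth perturbation
#' (a Gaussian-kernel-smoothed random field, 15% relative amplitude), then
#' average-referenced and unit-normalized. For `k > 4` additional smooth
#' dipolar maps with random orientations are appended.
#'
#' @param montage a [make_montage()] object.
#' @param k number of templates (at most the channel count).
#' @param seed optional RNG seed.
#' @return k x n_channels matrix of unit-norm, zero-mean maps.
#' @export
make_templates <- function(montage, k = 4L, seed = NULL) {
  pos <- montage$positions
  n <- nrow(pos)
  if (k > n) stop_invalid("`k` must not exceed the channel count")
  with_seed(seed)
  proto <- canonical_templates(montage)
  base <- proto[seq_len(min(k, 4L)), , drop = FALSE]
  if (k > 4L) {
    for (m in seq_len(k - 4L)) {
      d <- rnorm(3)
      d <- d / sqrt(sum(d^2))
      extra <- pos %*% d
      base <- rbind(base, t(extra))
    }
    rownames(base) <- LETTERS[seq_len(k)]
  }
  # smooth random perturbation: chordal-distance Gaussian kernel x noise
  d2 <- as.matrix(dist(pos))^2
  kern <- exp(-d2 / (2 * 0.5^2))
  out <- base
  for (m in seq_len(k)) {
    pert <- as.vector(kern %*% rnorm(n))
    pert <- pert / sqrt(sum(pert^2))
    v <- base[m, ] / sqrt(sum(base[m, ]^2)) + 0.15 * pert
    v <- v - mean(v)
    out[m, ] <- v / sqrt(sum(v^2))
  }
  out
}

#' Simulate a microstate label sequence
#'
#' Semi-Markov generator: alternating runs of states; run lengths are
#' gamma(shape, scale = mean/shape) in samples, rounded and floored at one
#' sample; successors follow the distinct-state transition matrix. The
#' initial state is drawn from the embedded chain's stationary
#' distribution, so empirical coverage converges to the stationary
#' occupancy implied by `(transition_matrix, mean_durations_ms)`.
#'
#' @param spec a [group_spec()].
#' @param duration_s sequence duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed optional RNG seed.
#' @return a `label_sequence`: integer vector of states (1..k) with
#'   attributes `fs` and `k`.
#' @export
simulate_label_sequence <- function(spec, duration_s, fs, seed = NULL) {
  stopifnot(inherits(spec, "group_spec"))
  if (duration_s <= 0) stop_invalid("`duration_s` must be > 0")
  if (fs <= 0) stop_invalid("`fs` must be > 0")
  tm <- spec$transition_matrix
  if (any(rowSums(tm) == 0))
    stop_invalid("degenerate transition row: no successor state")
  with_seed(seed)
  k <- nrow(tm)
  n_samples <- round(duration_s * fs)
  mean_len <- spec$mean_durations_ms * fs / 1000  # samples
  cum <- t(apply(tm, 1L, cumsum))
  pi0 <- embedded_stationary(tm)
  states <- integer(0)
  lengths <- integer(0)
  total <- 0L
  last <- 0L
  while (total < n_samples) {
    n_more <- max(16L, ceiling((n_samples - total) / min(mean_len) * 1.2))
    if (last == 0L) {
      init <- sample.int(k, 1L, prob = pi0)
      chunk <- sample_chain_cpp(n_more, cum, init)
    } else {
      chunk <- sample_chain_cpp(n_more + 1L, cum, last)[-1L]
    }
    len <- pmax(1L, as.integer(round(rgamma(length(chunk),
                                            shape = spec$duration_shape,
                                            scale = mean_len[chunk] /
                                              spec$duration_shape))))
    states <- c(states, chunk)
    lengths <- c(lengths, len)
    total <- total + sum(len)
    last <- chunk[length(chunk)]
  }
  keep <- which(cumsum(lengths) >= n_samples)[1L]
  states <- states[seq_len(keep)]
  lengths <- lengths[seq_len(keep)]
  lengths[keep] <- lengths[keep] - (sum(lengths) - n_samples)
  labels <- rep(states, lengths)
  new_label_sequence(labels, fs = fs, k = k)
}

new_label_sequence <- function(labels, fs, k,
                               source = NA_character_) {
  structure(as.integer(labels), fs = fs, k = as.integer(k),
            source = source, class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d samples @ %g Hz, %d states\n",
              length(x), attr(x, "fs"), attr(x, "k")))
  invisible(x)
}

#' States of a label sequence as letters
#' @param labels a `label_sequence` (or integer vector of states).
#' @return character vector of `A`..`Z` letters.
#' @export
label_letters <- function(labels) LETTERS[as.integer(labels)]

#' Render a label sequence into multichannel EEG
#'
#' The signal at each sample is the active state's template map scaled by
#' a 10 Hz sinusoidal carrier: its rectified magnitude is the positive
#' amplitude envelope of the topography, and the carrier's polarity
#' alternation is invisible to the polarity-invariant analysis
#' downstream. A signed in-band carrier (rather than a strictly positive
#' envelope) keeps the topographic signal inside the 2-20 Hz analysis
#' band, as for real band-limited EEG; a positive envelope would put most
#' topographic power at DC, which the high-pass edge of the band filter
#' smears across neighbouring states. Spatially and temporally white
#' Gaussian noise is added at the requested SNR (template-signal RMS over
#' noise RMS; `snr = Inf` renders noiselessly), and the summed data are
#' re-referenced to the common average so the output satisfies CAR.
#'
#' @param labels a `label_sequence`.
#' @param templates k x n unit-norm template matrix.
#' @param snr signal-to-noise ratio (> 0, possibly `Inf`).
#' @param fs sampling rate in Hz (defaults to the label sequence's).
#' @param seed optional RNG seed.
#' @param amplitude peak envelope amplitude in microvolts.
#' @param subject_id,group,paradigm metadata for the output recording.
#' @return an [eeg_recording()].
#' @export
render_eeg <- function(labels, templates, snr, fs = attr(labels, "fs"),
                       seed = NULL, amplitude = 30,
                       subject_id = NA_character_, group = NA_character_,
                       paradigm = NA_character_) {
  if (snr <= 0) stop_invalid("`snr` must be > 0")
  with_seed(seed)
  n_ch <- ncol(templates)
  carrier <- carrier_wave(length(labels), fs, amplitude)
  sig <- t(templates)[, as.integer(labels), drop = FALSE] *
    rep(carrier, each = n_ch)
  dimnames(sig) <- NULL
  if (is.finite(snr)) {
    sig_rms <- sqrt(mean(carrier^2) / n_ch)
    noise <- matrix(rnorm(length(sig), sd = sig_rms / snr),
                    n_ch, length(labels))
    sig <- sig + noise
  }
  sig <- sweep(sig, 2L, colMeans(sig))
  eeg_recording(sig, fs = fs,
                channel_names = colnames(templates) %||%
                  sprintf("E%02d", seq_len(n_ch)),
                subject_id = subject_id, group = group, paradigm = paradigm)
}

# 10 Hz carrier; the phase offset keeps every sample's amplitude nonzero
# so that noiseless backfitting is exact at all samples
carrier_wave <- function(n, fs, amplitude) {
  t_s <- (seq_len(n) - 1) / fs
  amplitude * sin(2 * pi * 10 * t_s + 0.3)
}

# one subject's recordings (consumes the current RNG stream) ------------
synth_subject <- function(subject_id, spec_pair, templates, fs,
                          paradigms, rest_duration_s, n_task_trials,
                          task_window_s = 1.0, task_baseline_s = 0.2,
                          amplitude = 30) {
  group <- spec_pair[[1L]]$group_label
  out <- list(subject_id = subject_id, group = group)
  moca_spec <- spec_pair[[1L]]
  out$moca <- min(30, max(0, round(rnorm(1, moca_spec$moca_mean,
                                         moca_spec$moca_sd))))
  if ("rest" %in% paradigms) {
    labels <- simulate_label_sequence(spec_pair$rest, rest_duration_s, fs)
    attr(labels, "source") <- "rest"
    out$rest <- render_eeg(labels, templates, snr = spec_pair$rest$snr,
                           fs = fs, amplitude = amplitude,
                           subject_id = subject_id, group = group,
                           paradigm = "rest")
    out$truth_rest <- labels
  }
  if ("task" %in% paradigms) {
    spec <- spec_pair$task
    evoked <- simulate_label_sequence(spec, task_window_s, fs)
    attr(evoked, "source") <- "task"
    n_ch <- ncol(templates)
    n_base <- round(task_baseline_s * fs)
    n_resp <- length(evoked)
    trial_len <- n_base + n_resp
    carrier <- carrier_wave(n_resp, fs, amplitude)
    evoked_sig <- t(templates)[, as.integer(evoked), drop = FALSE] *
      rep(carrier, each = n_ch)
    dimnames(evoked_sig) <- NULL
    trial <- cbind(matrix(0, n_ch, n_base), evoked_sig)
    sig <- trial[, rep(seq_len(trial_len), n_task_trials), drop = FALSE]
    if (is.finite(spec$snr)) {
      sig_rms <- sqrt(mean(carrier^2) / n_ch) *
        sqrt(n_resp / trial_len)  # signal RMS over the whole trial
      sig <- sig + matrix(rnorm(length(sig), sd = sig_rms / spec$snr),
                          n_ch, ncol(sig))
    }
    sig <- sweep(sig, 2L, colMeans(sig))
    out$task <- eeg_recording(sig, fs = fs,
                              channel_names = colnames(templates) %||%
                                sprintf("E%02d", seq_len(n_ch)),
                              subject_id = subject_id, group = group,
                              paradigm = "task")
    out$events <- data.frame(
      onset_s = (seq_len(n_task_trials) - 1) * trial_len / fs +
        n_base / fs,
      condition = "incongruent", correct = 1L)
    out$truth_task <- evoked
  }
  out
}

#' Generate a complete synthetic two-paradigm cohort
#'
#' Renders one resting recording (default 200 s) and one continuous task
#' recording (default 150 correct-incongruent trials of 1.2 s including a
#' 200 ms baseline, with an event table) per subject, samples per-group
#' MoCA scores, and returns the generating ground truth (templates and
#' per-subject label sequences).
#'
#' @param hc,mci group specifications: either a single [group_spec()]
#'   (used for both paradigms) or a list `list(rest=, task=)`. Defaults to
#'   [default_group_specs()].
#' @param montage a [make_montage()] object.
#' @param paradigms subset of `c("rest", "task")`.
#' @param seed optional RNG seed for the whole cohort.
#' @param rest_duration_s retained resting duration per subject (seconds).
#' @param n_task_trials number of correct-incongruent task trials.
#' @param fs sampling rate of the rendered recordings (Hz).
#' @param amplitude envelope amplitude in microvolts.
#' @return an object of class `eeg_cohort`: a list with `subjects` (data
#'   frame of subject_id, group, moca), `rest` and `task` recording lists,
#'   `events` per subject, `montage` and `ground_truth`.
#' @export
make_cohort <- function(hc = default_group_specs()$hc,
                        mci = default_group_specs()$mci,
                        montage = make_montage(),
                        paradigms = c("rest", "task"),
                        seed = NULL, rest_duration_s = 200,
                        n_task_trials = 150L, fs = 250,
                        amplitude = 30) {
  paradigms <- match.arg(paradigms, c("rest", "task"), several.ok = TRUE)
  hc <- normalize_spec_pair(hc)
  mci <- normalize_spec_pair(mci)
  with_seed(seed)
  templates <- make_templates(montage, k = 4L)
  colnames(templates) <- montage$channel_names
  ids <- c(sprintf("HC%02d", seq_len(hc[[1L]]$n_subjects)),
           sprintf("MCI%02d", seq_len(mci[[1L]]$n_subjects)))
  specs <- c(rep(list(hc), hc[[1L]]$n_subjects),
             rep(list(mci), mci[[1L]]$n_subjects))
  subjects <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    subjects[[i]] <- synth_subject(ids[i], specs[[i]], templates, fs,
                                   paradigms, rest_duration_s,
                                   n_task_trials, amplitude = amplitude)
  }
  structure(list(
    subjects = data.frame(
      subject_id = ids,
      group = vapply(subjects, `[[`, "", "group"),
      moca = vapply(subjects, `[[`, 0, "moca")),
    rest = if ("rest" %in% paradigms)
      setNames(lapply(subjects, `[[`, "rest"), ids),
    task = if ("task" %in% paradigms)
      setNames(lapply(subjects, `[[`, "task"), ids),
    events = if ("task" %in% paradigms)
      setNames(lapply(subjects, `[[`, "events"), ids),
    montage = montage,
    ground_truth = list(
      templates = templates,
      rest_labels = if ("rest" %in% paradigms)
        setNames(lapply(subjects, `[[`, "truth_rest"), ids),
      task_labels = if ("task" %in% paradigms)
        setNames(lapply(subjects, `[[`, "truth_task"), ids),
      specs = list(hc = hc, mci = mci), seed = seed)),
    class = "eeg_cohort")
}

normalize_spec_pair <- function(x) {
  if (inherits(x, "group_spec")) return(list(rest = x, task = x))
  stopifnot(is.list(x), all(c("rest", "task") %in% names(x)),
            inherits(x$rest, "group_spec"), inherits(x$task, "group_spec"))
  x
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d subjects (%s)\n", nrow(x$subjects),
              paste(names(table(x$subjects$group)),
                    table(x$subjects$group), collapse = ", ", sep = ": ")))
  invisible(x)
}
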