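#' Merge consecutive identical labels into runs
#'
#' Collapses maximal runs of the same state ("AAAAABBBAAB" becomes
#' "ABAB") while retaining the run lengths needed for the duration
#' features.
#'
#' @param labels a `label_sequence` (or integer vector of states).
#' @return an object of class `merged_sequence`: `symbols` (integer
#'   states, no two adjacent equal), `lengths` (samples per run), `k`,
#'   `fs` and `total_samples`.
#' @export
merge_runs <- function(labels) {
  if (length(labels) == 0L) stop_invalid("empty label sequence")
  r <- rle(as.integer(labels))
  structure(list(symbols = r$values, lengths = r$lengths,
                 k = attr(labels, "k") %||% max(r$values),
                 fs = attr(labels, "fs"),
                 total_samples = length(labels)),
            class = "merged_sequence")
}

#' @export
print.merged_sequence <- function(x, ...) {
  cat(sprintf("<merged_sequence> %d runs over %d samples (%d states)\n",
              length(x$symbols), x$total_samples, x$k))
  invisible(x)
}

as_merged <- function(x) {
  if (inherits(x, "merged_sequence")) x else merge_runs(x)
}

#' Mean duration per microstate class
#'
#' The average uninterrupted dwell time of each class in milliseconds.
#' Classes that never occur are reported as `NA` (missing), not zero.
#'
#' @param merged a [merge_runs()] result (or a label sequence).
#' @param fs sampling rate in Hz.
#' @return named numeric vector (ms), one entry per class `A`..`?`.
#' @export
mean_duration <- function(merged, fs = NULL) {
  m <- as_merged(merged)
  fs <- fs %||% m$fs
  if (is.null(fs) || is.na(fs) || fs <= 0)
    stop_invalid("a positive sampling rate is required")
  out <- vapply(seq_len(m$k), function(s) {
    d <- m$lengths[m$symbols == s]
    if (length(d) == 0L) NA_real_ else mean(d) / fs * 1000
  }, 0)
  names(out) <- LETTERS[seq_len(m$k)]
  out
}

#' Fractional coverage per microstate class
#'
#' The fraction of total recording time occupied by each class; the
#' coverages sum to one because every sample is labelled.
#'
#' @inheritParams mean_duration
#' @return named numeric vector of fractions.
#' @export
coverage <- function(merged) {
  m <- as_merged(merged)
  out <- vapply(seq_len(m$k), function(s)
    sum(m$lengths[m$symbols == s]) / m$total_samples, 0)
  names(out) <- LETTERS[seq_len(m$k)]
  out
}

#' Occurrence rate per microstate class
#'
#' Number of appearances (runs) of each class per second of recording.
#'
#' @inheritParams mean_duration
#' @return named numeric vector (1/s).
#' @export
occurrence <- function(merged, fs = NULL) {
  m <- as_merged(merged)
  fs <- fs %||% m$fs
  if (is.null(fs) || is.na(fs) || fs <= 0)
    stop_invalid("a positive sampling rate is required")
  total_s <- m$total_samples / fs
  out <- vapply(seq_len(m$k), function(s)
    sum(m$symbols == s) / total_s, 0)
  names(out) <- LETTERS[seq_len(m$k)]
  out
}

#' Distinct-state transition probabilities
#'
#' `TP[i, j]` is the probability that class `i` is succeeded by class `j`
#' among the transitions leaving `i` in the merged sequence. Rows of
#' states with no outgoing transition (a state that only ends the
#' sequence, or never occurs) are reported as missing. The diagonal is
#' structurally zero and returned as `NA`.
#'
#' @inheritParams mean_duration
#' @return k x k matrix with `NA` diagonal; off-diagonal rows over
#'   observed successors sum to 1.
#' @export
transition_probabilities <- function(merged) {
  m <- as_merged(merged)
  k <- m$k
  tp <- matrix(NA_real_, k, k,
               dimnames = list(LETTERS[seq_len(k)], LETTERS[seq_len(k)]))
  if (length(m$symbols) >= 2L) {
    from <- m$symbols[-length(m$symbols)]
    to <- m$symbols[-1L]
    counts <- table(factor(from, levels = seq_len(k)),
                    factor(to, levels = seq_len(k)))
    n_out <- rowSums(counts)
    for (i in seq_len(k)) {
      if (n_out[i] > 0) {
        tp[i, ] <- counts[i, ] / n_out[i]
        tp[i, i] <- NA_real_
      }
    }
  }
  tp
}

#' Lempel-Ziv complexity of a merged microstate sequence
#'
#' Exhaustive-history parsing: scanning left to right, the complexity
#' counter increases each time the current word extended by the next
#' symbol does not occur in the previously seen part of the sequence. The
#' raw component count is returned; `normalized = TRUE` divides by the
#' asymptotic factor `n / log_k(n)`.
#'
#' @param x a [merge_runs()] result, a label sequence (merged first), or
#'   a raw symbol vector (parsed as given).
#' @param normalized return the normalized variant (default raw count).
#' @return complexity count (or normalized value).
#' @export
lzc <- function(x, normalized = FALSE) {
  s <- if (inherits(x, "merged_sequence")) x$symbols
  else if (inherits(x, "label_sequence")) merge_runs(x)$symbols
  else if (is.character(x)) match(x, LETTERS)
  else as.integer(x)
  if (length(s) == 0L) stop_invalid("empty symbol sequence")
  cn <- lzc_cpp(as.integer(s))
  if (!normalized) return(cn)
  k <- max(length(unique(s)), 2L)
  n <- length(s)
  cn * logb(n, base = k) / n
}

#' Canonical names of the 26 per-paradigm microstate features
#'
#' Naming convention: single-state metrics are
#' `"<prefix><state>-<metric>"` (e.g. `rA-MD`), transitions are
#' `"<prefix><from>→<to>"` (e.g. `tC→D`), plus `<prefix>-GEV`
#' and `<prefix>-LZC`.
#'
#' @param prefix `"r"` (resting) or `"t"` (task).
#' @param k number of classes (4).
#' @param ascii use the ASCII transition dialect `"A.B"` instead of the
#'   arrow.
#' @return character vector of 26 names.
#' @export
feature_names <- function(prefix = c("r", "t"), k = 4L, ascii = FALSE) {
  prefix <- match.arg(prefix)
  st <- LETTERS[seq_len(k)]
  arrow <- if (ascii) "." else "→"
  pairs <- expand.grid(from = st, to = st, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[order(pairs$from, pairs$to), ]
  c(paste0(prefix, st, "-MD"),
    paste0(prefix, st, "-COV"),
    paste0(prefix, st, "-OC"),
    paste0(prefix, pairs$from, arrow, pairs$to),
    paste0(prefix, "-GEV"),
    paste0(prefix, "-LZC"))
}

#' Convert canonical feature names to the ASCII dialect (and back)
#' @param x character vector of feature names.
#' @return renamed vector.
#' @export
ascii_feature_names <- function(x) gsub("→", ".", x, fixed = TRUE)

#' Extract the 26 microstate features of one segment
#'
#' Computes mean duration, coverage and occurrence per class (4 each),
#' the 12 ordered distinct-pair transition probabilities, the segment's
#' GEV and the Lempel-Ziv complexity of the merged sequence, named by the
#' paradigm prefix convention. States that never occur (or have no
#' outgoing transitions) propagate missing values.
#'
#' @param labels a `label_sequence` for the segment.
#' @param gev the segment-level GEV (see [segment_gev()]).
#' @param prefix `"r"` or `"t"`.
#' @param fs sampling rate in Hz (defaults to the sequence's).
#' @return named numeric vector of exactly 26 features.
#' @export
extract_features <- function(labels, gev = NA_real_,
                             prefix = c("r", "t"), fs = NULL) {
  prefix <- match.arg(prefix)
  if (length(labels) == 0L) stop_invalid("empty label sequence")
  m <- as_merged(labels)
  fs <- fs %||% m$fs
  md <- mean_duration(m, fs)
  cov <- coverage(m)
  oc <- occurrence(m, fs)
  tp <- transition_probabilities(m)
  st <- LETTERS[seq_len(m$k)]
  pairs <- expand.grid(from = st, to = st, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[order(pairs$from, pairs$to), ]
  tpv <- tp[cbind(pairs$from, pairs$to)]
  out <- c(md, cov, oc, tpv, gev, lzc(m))
  names(out) <- feature_names(prefix, k = m$k)
  out
}

#' Write a feature table as tidy CSV
#'
#' One row per (subject, segment); metadata columns followed by the
#' feature columns. Transition names use the UTF-8 arrow by default; set
#' `ascii = TRUE` for the `"A.B"` dialect accepted by tools that reject
#' non-ASCII headers.
#'
#' @param tab feature table data frame.
#' @param path output CSV path.
#' @param ascii write ASCII transition names.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tab, path, ascii = FALSE) {
  if (ascii) names(tab) <- ascii_feature_names(names(tab))
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
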