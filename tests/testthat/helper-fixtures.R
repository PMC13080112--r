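# Shared fixtures, built lazily and cached for the whole test session.
# The default-conditions pipeline run backs the acceptance tests (template
# recovery, OFS cap, configuration ordering); everything else uses small
# cohorts built on the fly.

.fixtures <- new.env(parent = emptyenv())

# full default-conditions pipeline run (63 subjects, both paradigms,
# four configurations); built once
default_run <- function() {
  if (is.null(.fixtures$default_run)) {
    cfg <- run_config(seed = 20260901L,
                      configurations = c("rest", "task", "fused",
                                         "fused_moca"))
    .fixtures$default_run <- run_pipeline(cfg)
  }
  .fixtures$default_run
}

# small two-group cohort specs with strong contrasts, for cheap tests
small_specs <- function(n_hc = 5L, n_mci = 5L) {
  gs <- default_group_specs()
  for (p in c("rest", "task")) {
    gs$hc[[p]]$n_subjects <- n_hc
    gs$mci[[p]]$n_subjects <- n_mci
  }
  gs
}

# feature table drawn at the label-sequence level (no rendering):
# features extracted from simulated sequences, one 20-s segment x n_seg
# per subject; fast enough for screening/classification tests
label_level_table <- function(hc_spec, mci_spec, n_seg = 10L,
                              segment_s = 20, fs = 250, prefix = "r") {
  n_hc <- hc_spec$n_subjects
  n_mci <- mci_spec$n_subjects
  ids <- c(sprintf("HC%02d", seq_len(n_hc)),
           sprintf("MCI%02d", seq_len(n_mci)))
  specs <- c(rep(list(hc_spec), n_hc), rep(list(mci_spec), n_mci))
  rows <- lapply(seq_along(ids), function(i) {
    segs <- lapply(seq_len(n_seg), function(s) {
      lab <- simulate_label_sequence(specs[[i]], segment_s, fs)
      fv <- extract_features(lab, gev = NA_real_, prefix = prefix)
      df <- data.frame(subject_id = ids[i], segment_id = s,
                       group = specs[[i]]$group_label,
                       stringsAsFactors = FALSE)
      df[names(fv)] <- as.list(fv)
      df
    })
    do.call(rbind, segs)
  })
  out <- do.call(rbind, rows)
  # GEV is undefined at the label level; drop it rather than fabricate
  out[[paste0(prefix, "-GEV")]] <- NULL
  out
}
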