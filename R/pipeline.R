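#' Pipeline run configuration
#'
#' Collects every stage's settings and the run-level seed. The defaults
#' are the package's reference study conditions: a 63-subject synthetic
#' cohort (31 HC / 32 MCI), 200 s of resting EEG and 150 correct
#' incongruent task trials per subject at 250 Hz, SNR 5, four microstate
#' classes fit with 20 restarts, FDR screening at 0.05, and SGKF 5-fold
#' x 5-repeat evaluation with an OFS capped at five features.
#'
#' @param seed master seed for the run; all stage seeds derive from it.
#' @param hc,mci group specifications (see [make_cohort()]).
#' @param montage electrode montage.
#' @param paradigms paradigms to simulate and analyse.
#' @param fs rendering sampling rate (Hz).
#' @param rest_duration_s resting duration per subject (s).
#' @param n_task_trials task trials per subject.
#' @param preprocess a [preprocess_config()].
#' @param k number of microstate classes.
#' @param n_restarts clustering restarts.
#' @param max_peaks_per_subject cap on pooled GFP-peak maps per subject.
#' @param alpha FDR screening threshold.
#' @param f_max,f_curve_max OFS cap and curve extent.
#' @param n_folds,n_repeats cross-validation layout.
#' @param inner_folds folds of the nested hyperparameter search.
#' @param grid SVM hyperparameter grid.
#' @param configurations model configurations to evaluate; any of
#'   `"rest"`, `"task"`, `"fused"`, `"fused_moca"`, `"moca_only"`.
#' @param paper_mode screen on the full data set instead of within folds.
#' @param out_dir optional directory for stage artifacts.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       hc = default_group_specs()$hc,
                       mci = default_group_specs()$mci,
                       montage = make_montage(),
                       paradigms = c("rest", "task"),
                       fs = 250, rest_duration_s = 200,
                       n_task_trials = 150L,
                       preprocess = preprocess_config(),
                       k = 4L, n_restarts = 20L,
                       max_peaks_per_subject = 1000L,
                       alpha = 0.05, f_max = 5L, f_curve_max = 10L,
                       n_folds = 5L, n_repeats = 5L, inner_folds = 5L,
                       grid = default_svm_grid(),
                       configurations = c("rest", "task", "fused",
                                          "fused_moca"),
                       paper_mode = FALSE, out_dir = NULL) {
  structure(list(seed = seed, hc = normalize_spec_pair(hc),
                 mci = normalize_spec_pair(mci), montage = montage,
                 paradigms = paradigms, fs = fs,
                 rest_duration_s = rest_duration_s,
                 n_task_trials = n_task_trials, preprocess = preprocess,
                 k = k, n_restarts = n_restarts,
                 max_peaks_per_subject = max_peaks_per_subject,
                 alpha = alpha, f_max = f_max,
                 f_curve_max = f_curve_max, n_folds = n_folds,
                 n_repeats = n_repeats, inner_folds = inner_folds,
                 grid = grid,
                 configurations = configurations,
                 paper_mode = paper_mode, out_dir = out_dir),
            class = "run_config")
}

# preprocess one subject's recordings into augmented analysis segments
preprocess_subject <- function(subj, cfg) {
  out <- list()
  if (!is.null(subj$rest)) {
    rec <- bandpass(subj$rest, cfg$preprocess)
    rec <- resample_eeg(rec, min(cfg$preprocess$target_fs_hz, rec$fs))
    rec <- common_average_reference(rec)
    ep <- segment_resting(rec, cfg$preprocess$rest_epoch_s,
                          cfg$preprocess$rest_n_epochs)
    out$rest <- reject_by_amplitude(ep, cfg$preprocess$reject_uV)
  }
  if (!is.null(subj$task)) {
    rec <- bandpass(subj$task, cfg$preprocess)
    rec <- resample_eeg(rec, min(cfg$preprocess$target_fs_hz, rec$fs))
    rec <- common_average_reference(rec)
    ep <- extract_task_epochs(rec, subj$events, cfg$preprocess)
    ep <- reject_by_amplitude(ep, cfg$preprocess$reject_uV)
    out$task <- block_average(ep, cfg$preprocess$task_n_blocks)
  }
  out
}

# GFP-peak maps of every epoch in an epoch set, pooled (rows = maps)
epoch_peak_maps <- function(ep) {
  maps <- lapply(seq_len(n_epochs(ep)), function(i) {
    x <- epoch_matrix(ep, i)
    pk <- find_gfp_peaks(gfp(x)$values)
    if (length(pk) == 0L) return(NULL)
    t(x[, pk, drop = FALSE])
  })
  do.call(rbind, maps)
}

# per-segment feature rows for one subject's epoch set
segment_feature_rows <- function(ep, model, prefix) {
  rows <- lapply(seq_len(n_epochs(ep)), function(i) {
    x <- epoch_matrix(ep, i)
    labels <- backfit(x, model, fs = ep$fs)
    fv <- extract_features(labels, gev = segment_gev(x, model),
                           prefix = prefix, fs = ep$fs)
    df <- data.frame(subject_id = ep$subject_id,
                     segment_id = ep$epoch_ids[i], group = ep$group,
                     stringsAsFactors = FALSE)
    df[names(fv)] <- as.list(fv)
    df
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes synthesis, preprocessing and augmentation, pooled
#' polarity-invariant clustering, backfitting and feature extraction,
#' full-data screening tables, and the wrapper OFS evaluation for each
#' requested configuration. Every stochastic stage consumes a named seed
#' derived from the master seed, recorded in the returned report; reruns
#' with the same configuration are identical.
#'
#' @param config a [run_config()].
#' @param progress print stage progress.
#' @return an object of class `run_report`; see [summarize()].
#' @export
run_pipeline <- function(config = run_config(), progress = FALSE) {
  t_start <- proc.time()[["elapsed"]]
  say <- function(...) if (progress) message(sprintf(...))
  set.seed(config$seed)
  stage_names <- c("synth", "cluster_rest", "cluster_task",
                   "cv_rest", "cv_task", "cv_fused", "cv_fused_moca",
                   "cv_moca_only")
  seeds <- setNames(as.list(sample.int(.Machine$integer.max,
                                       length(stage_names))), stage_names)
  cfg <- config
  paradigms <- cfg$paradigms
  # --- synthesis + preprocessing (streaming, one subject at a time) ----
  say("synth + preprocess")
  set.seed(seeds$synth)
  templates <- make_templates(cfg$montage, k = cfg$k)
  colnames(templates) <- cfg$montage$channel_names
  ids <- c(sprintf("HC%02d", seq_len(cfg$hc[[1L]]$n_subjects)),
           sprintf("MCI%02d", seq_len(cfg$mci[[1L]]$n_subjects)))
  specs <- c(rep(list(cfg$hc), cfg$hc[[1L]]$n_subjects),
             rep(list(cfg$mci), cfg$mci[[1L]]$n_subjects))
  epochs <- list(rest = list(), task = list())
  peaks <- list(rest = list(), task = list())
  truth <- list(rest = list(), task = list())
  subjects <- data.frame(subject_id = ids,
                         group = vapply(specs, function(s)
                           s[[1L]]$group_label, ""),
                         moca = NA_real_)
  for (i in seq_along(ids)) {
    subj <- synth_subject(ids[i], specs[[i]], templates, cfg$fs,
                          paradigms, cfg$rest_duration_s,
                          cfg$n_task_trials)
    subjects$moca[i] <- subj$moca
    pp <- preprocess_subject(subj, cfg)
    for (p in paradigms) {
      epochs[[p]][[ids[i]]] <- pp[[p]]
      pm <- epoch_peak_maps(pp[[p]])
      if (nrow(pm) > cfg$max_peaks_per_subject)
        pm <- pm[sample.int(nrow(pm), cfg$max_peaks_per_subject), ,
                 drop = FALSE]
      peaks[[p]][[ids[i]]] <- pm
      truth[[p]][[ids[i]]] <- subj[[paste0("truth_", p)]]
    }
  }
  # --- pooled clustering per paradigm ----------------------------------
  models <- list()
  feature_tables <- list()
  screens <- list()
  for (p in paradigms) {
    say("cluster + features: %s", p)
    pooled <- do.call(rbind, peaks[[p]])
    models[[p]] <- modified_kmeans(pooled, k = cfg$k,
                                   n_restarts = cfg$n_restarts,
                                   seed = seeds[[paste0("cluster_", p)]],
                                   montage = cfg$montage)
    prefix <- if (p == "rest") "r" else "t"
    tabs <- lapply(epochs[[p]], segment_feature_rows,
                   model = models[[p]], prefix = prefix)
    tab <- do.call(rbind, tabs)
    rownames(tab) <- NULL
    tab$paradigm <- p
    feature_tables[[p]] <- tab
    screens[[p]] <- suppressMessages(
      screen_features(tab[setdiff(names(tab), "paradigm")],
                      alpha = cfg$alpha))
  }
  # --- template recovery diagnostics -----------------------------------
  recovery <- lapply(models, function(m) {
    fitted <- normalize_maps(m$templates)
    truthn <- normalize_maps(templates)
    abs(diag(truthn %*% t(fitted)))
  })
  # --- configuration evaluation ----------------------------------------
  moca_tab <- subjects[c("subject_id", "moca")]
  names(moca_tab)[2L] <- "MoCA"
  reports <- list()
  for (conf in cfg$configurations) {
    say("cross-validated evaluation: %s", conf)
    tab <- switch(conf,
      rest = feature_tables$rest,
      task = feature_tables$task,
      fused = fuse_tables(feature_tables[paradigms]),
      fused_moca = fuse_tables(feature_tables[paradigms],
                               covariate = moca_tab),
      moca_only = {
        base <- feature_tables[[paradigms[1L]]][
          c("subject_id", "segment_id", "group")]
        fuse_tables(list(base), covariate = moca_tab)
      },
      stop_invalid("unknown configuration: ", conf))
    reports[[conf]] <- wrapper_ofs(
      tab, f_max = cfg$f_max, f_curve_max = cfg$f_curve_max,
      alpha = cfg$alpha, n_folds = cfg$n_folds,
      n_repeats = cfg$n_repeats, inner_folds = cfg$inner_folds,
      grid = cfg$grid,
      paper_mode = cfg$paper_mode,
      seed = seeds[[paste0("cv_", conf)]])
  }
  report <- structure(list(
    subjects = subjects, models = models,
    feature_tables = feature_tables, screens = screens,
    reports = reports, template_recovery = recovery,
    ground_truth = list(templates = templates, labels = truth),
    seeds = seeds, config = cfg,
    elapsed_s = proc.time()[["elapsed"]] - t_start),
    class = "run_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write pipeline artifacts and a hashed manifest
#'
#' Feature tables, screening tables, microstate models, the
#' per-configuration reports and a manifest (every artifact with its MD5
#' content hash, plus the seed registry) are written under `dir`.
#'
#' @param report a [run_pipeline()] report.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (p in names(report$feature_tables)) {
    f <- file.path(dir, sprintf("features_%s.csv", p))
    write_feature_table(report$feature_tables[[p]], f, ascii = TRUE)
    paths <- c(paths, f)
  }
  for (p in names(report$screens)) {
    f <- file.path(dir, sprintf("screen_%s.csv", p))
    write_screen_table(report$screens[[p]], f)
    paths <- c(paths, f)
  }
  for (p in names(report$models)) {
    f <- file.path(dir, sprintf("model_%s.json", p))
    write_model(report$models[[p]], f)
    paths <- c(paths, f)
  }
  summ <- summarize(report)
  f <- file.path(dir, "summary.csv")
  write.csv(summ$summary, f, row.names = FALSE)
  paths <- c(paths, f)
  f <- file.path(dir, "curve.csv")
  write.csv(summ$curve, f, row.names = FALSE)
  paths <- c(paths, f)
  manifest <- list(
    seeds = report$seeds,
    elapsed_s = report$elapsed_s,
    artifacts = data.frame(path = basename(paths),
                           md5 = unname(tools::md5sum(paths))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Summarize a pipeline report
#'
#' @param report a [run_pipeline()] report.
#' @return a list with `summary` (one row per configuration: OFS,
#'   accuracy/sensitivity/specificity mean and SD in percent) and
#'   `curve` (per configuration and feature count F).
#' @export
summarize <- function(report) {
  stopifnot(inherits(report, "run_report"))
  rows <- lapply(names(report$reports), function(conf) {
    r <- report$reports[[conf]]
    m <- r$metrics
    data.frame(configuration = conf, F = r$f_best,
               ofs = paste(ascii_feature_names(r$ofs), collapse = " "),
               accuracy_mean = m$accuracy_mean,
               accuracy_sd = m$accuracy_sd,
               sensitivity_mean = m$sensitivity_mean,
               sensitivity_sd = m$sensitivity_sd,
               specificity_mean = m$specificity_mean,
               specificity_sd = m$specificity_sd,
               stringsAsFactors = FALSE)
  })
  curve <- do.call(rbind, lapply(names(report$reports), function(conf) {
    pf <- report$reports[[conf]]$per_f
    cbind(data.frame(configuration = conf), pf)
  }))
  list(summary = do.call(rbind, rows), curve = curve)
}

#' @export
print.run_report <- function(x, ...) {
  s <- summarize(x)$summary
  cat(sprintf("<run_report> %d subjects, %s paradigms, %.0f s\n",
              nrow(x$subjects),
              paste(names(x$feature_tables), collapse = "+"),
              x$elapsed_s))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s F=%d  acc %.1f+/-%.1f%%  sens %.1f%%  spec %.1f%%\n",
                s$configuration[i], s$F[i], s$accuracy_mean[i],
                s$accuracy_sd[i], s$sensitivity_mean[i],
                s$specificity_mean[i]))
  invisible(x)
}
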