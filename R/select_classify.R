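#' Discretize feature columns into three z-score bins
#'
#' Each column is z-scored with training statistics and cut at -0.5 and
#' +0.5 SD, the discretization used for mutual-information estimation in
#' mRMR ranking. Bin parameters are learned on training data only and can
#' be re-applied to held-out rows. Zero-variance columns collapse to a
#' single bin and are flagged.
#'
#' @param x numeric matrix or data frame of feature columns.
#' @param train_stats optional statistics from a previous call (its
#'   `"train_stats"` attribute); when `NULL` they are estimated from `x`.
#' @return integer matrix of bins (1-3) with attribute `train_stats`
#'   (list of `center`, `scale`, `constant`).
#' @export
discretize <- function(x, train_stats = NULL) {
  x <- as.matrix(x)
  if (is.null(train_stats)) {
    center <- colMeans(x, na.rm = TRUE)
    scale <- apply(x, 2L, sd, na.rm = TRUE)
    train_stats <- list(center = center,
                        scale = ifelse(is.na(scale) | scale == 0, 1, scale),
                        constant = is.na(scale) | scale == 0)
  }
  z <- sweep(sweep(x, 2L, train_stats$center), 2L, train_stats$scale, "/")
  b <- matrix(2L, nrow(x), ncol(x), dimnames = dimnames(x))
  b[z <= -0.5] <- 1L
  b[z > 0.5] <- 3L
  b[, train_stats$constant] <- 2L
  attr(b, "train_stats") <- train_stats
  b
}

#' Plug-in mutual information between two discrete variables
#'
#' Estimated in bits from the joint contingency table. Zero iff the
#' empirical joint distribution factorizes.
#'
#' @param x,y discrete vectors of equal length.
#' @return mutual information in bits (>= 0).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop_invalid("`x` and `y` must have equal length")
  j <- table(x, y) / length(x)
  px <- rowSums(j)
  py <- colSums(j)
  e <- outer(px, py)
  nz <- j > 0
  sum(j[nz] * log2(j[nz] / e[nz]))
}

#' Greedy mRMR feature ranking
#'
#' Minimum-redundancy-maximum-relevance in the difference form: the first
#' feature maximizes the relevance `I(x; C)` with the class label; each
#' subsequent feature maximizes relevance minus the mean mutual
#' information with the already selected set. Ties are broken by feature
#' name order.
#'
#' @param x discrete feature matrix (see [discretize()]), columns named.
#' @param labels class labels (two classes).
#' @param top_m number of features to rank (default all).
#' @return a data frame (class `mrmr_ranking`) in greedy order with
#'   columns `feature`, `relevance`, `redundancy`, `score`.
#' @export
mrmr_rank <- function(x, labels, top_m = ncol(x)) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 1L) stop_invalid("at least one feature is required")
  top_m <- min(top_m, p)
  feats <- colnames(x) %||% paste0("V", seq_len(p))
  rel <- vapply(seq_len(p), function(j) mutual_information(x[, j], labels), 0)
  mi_cache <- matrix(NA_real_, p, p)
  selected <- integer(0)
  rows <- vector("list", top_m)
  name_rank <- rank(feats, ties.method = "first")
  for (step in seq_len(top_m)) {
    cand <- setdiff(seq_len(p), selected)
    red <- vapply(cand, function(j) {
      if (length(selected) == 0L) return(0)
      mean(vapply(selected, function(s) {
        if (is.na(mi_cache[j, s])) {
          mi <- mutual_information(x[, j], x[, s])
          mi_cache[j, s] <<- mi
          mi_cache[s, j] <<- mi
        }
        mi_cache[j, s]
      }, 0))
    }, 0)
    score <- rel[cand] - red
    best <- cand[order(-score, name_rank[cand])][1L]
    rows[[step]] <- data.frame(feature = feats[best],
                               relevance = rel[best],
                               redundancy = red[match(best, cand)],
                               score = score[match(best, cand)],
                               stringsAsFactors = FALSE)
    selected <- c(selected, best)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mrmr_ranking", class(out))
  out
}

#' Fuse per-paradigm feature tables (and an optional covariate)
#'
#' Concatenates the feature columns of several tables by
#' `(subject_id, segment_id)`. All tables must cover the same subjects
#' with the same segment counts; offenders are listed otherwise. A
#' per-subject covariate table (e.g. MoCA scores) may be appended; its
#' value is replicated across a subject's segments.
#'
#' @param tables named list of feature tables (each with `subject_id`,
#'   `segment_id`, `group` and feature columns).
#' @param covariate optional data frame `subject_id`, plus one or more
#'   scalar covariate columns (e.g. `MoCA`).
#' @return the fused feature table.
#' @export
fuse_tables <- function(tables, covariate = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  meta <- c("subject_id", "segment_id", "group", "paradigm")
  base <- tables[[1L]]
  key <- function(t) paste(t$subject_id, t$segment_id, sep = "#")
  out <- base[setdiff(names(base), "paradigm")]
  if (length(tables) > 1L) {
    for (i in 2L:length(tables)) {
      t2 <- tables[[i]]
      missing_in_2 <- setdiff(unique(base$subject_id),
                              unique(t2$subject_id))
      extra_in_2 <- setdiff(unique(t2$subject_id),
                            unique(base$subject_id))
      if (length(missing_in_2) || length(extra_in_2))
        stop_invalid("subject mismatch between tables: ",
                     paste(c(missing_in_2, extra_in_2), collapse = ", "))
      if (!identical(sort(key(base)), sort(key(t2))))
        stop_invalid("segment mismatch between tables")
      idx <- match(key(base), key(t2))
      feats <- setdiff(names(t2), meta)
      out[feats] <- t2[idx, feats, drop = FALSE]
    }
  }
  if (!is.null(covariate)) {
    stopifnot("subject_id" %in% names(covariate))
    miss <- setdiff(unique(out$subject_id), covariate$subject_id)
    if (length(miss))
      stop_invalid("covariate missing for subjects: ",
                   paste(miss, collapse = ", "))
    idx <- match(out$subject_id, covariate$subject_id)
    for (cv in setdiff(names(covariate), "subject_id"))
      out[[cv]] <- covariate[[cv]][idx]
  }
  out
}

#' Stratified group k-fold partitions
#'
#' Folds partition the subjects (all segments of a subject share a fold)
#' while keeping both the class counts per fold and the fold sizes
#' balanced within one subject. Independent repeats draw different
#' random partitions.
#'
#' @param subject_ids subject identifier per subject (unique).
#' @param groups class label per subject.
#' @param n_folds number of folds.
#' @param n_repeats number of repeated partitions.
#' @param seed optional RNG seed.
#' @return list of `n_repeats` lists of `n_folds` character vectors of
#'   test-fold subject ids.
#' @export
sgkf_split <- function(subject_ids, groups, n_folds = 5L,
                       n_repeats = 5L, seed = NULL) {
  stopifnot(length(subject_ids) == length(groups),
            !anyDuplicated(subject_ids))
  with_seed(seed)
  classes <- unique(groups)
  counts <- table(groups)
  if (any(counts < n_folds))
    stop_invalid("every class needs at least n_folds subjects")
  lapply(seq_len(n_repeats), function(r) {
    fold_of <- setNames(integer(length(subject_ids)), subject_ids)
    offset <- 0L   # rotate the deal across classes so totals stay even
    for (cl in classes) {
      ids <- subject_ids[groups == cl]
      ids <- ids[sample.int(length(ids))]
      fold_of[ids] <- (offset + seq_along(ids) - 1L) %% n_folds + 1L
      offset <- (offset + length(ids)) %% n_folds
    }
    lapply(seq_len(n_folds), function(f)
      unname(names(fold_of)[fold_of == f]))
  })
}

#' Default SVM hyperparameter grid
#'
#' Decade grids: `C` in 0.01-100 for both kernels and `gamma` in
#' 0.001-10 for the RBF kernel. The linear kernel is listed first so
#' grid ties resolve toward the simpler model.
#'
#' @return data frame with columns `kernel`, `cost`, `gamma`.
#' @export
default_svm_grid <- function() {
  costs <- c(0.01, 0.1, 1, 10, 100)
  gammas <- c(0.001, 0.01, 0.1, 1, 10)
  rbind(data.frame(kernel = "linear", cost = costs, gamma = 1),
        expand.grid(kernel = "radial", cost = costs, gamma = gammas,
                    stringsAsFactors = FALSE))
}

# decision-value prediction straight from the svm object's support
# vectors; avoids the data-frame overhead of predict.svm in the inner
# grid search (two-class, unscaled models only; equality with predict()
# is asserted in the test suite)
fast_svm_predict <- function(fit, x) {
  k <- if (fit$kernel == 0L) {          # linear
    x %*% t(fit$SV)
  } else {                              # radial
    d2 <- outer(rowSums(x^2), rowSums(fit$SV^2), "+") -
      2 * tcrossprod(x, fit$SV)
    exp(-fit$gamma * d2)
  }
  dec <- as.vector(k %*% fit$coefs) - fit$rho
  factor(fit$levels[ifelse(dec > 0, fit$labels[1L], fit$labels[2L])],
         levels = fit$levels)
}

impute_median <- function(x, med = NULL) {
  if (is.null(med)) med <- apply(x, 2L, median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  attr(x, "medians") <- med
  x
}

standardize <- function(x, stats = NULL) {
  if (is.null(stats)) {
    stats <- list(center = colMeans(x),
                  scale = pmax(apply(x, 2L, sd), 1e-12))
  }
  out <- sweep(sweep(x, 2L, stats$center), 2L, stats$scale, "/")
  attr(out, "stats") <- stats
  out
}

#' Nested grid-searched SVM fit and prediction
#'
#' Within the training fold, hyperparameters (kernel, C, gamma) are
#' chosen by subject-grouped stratified inner 5-fold cross-validation
#' over the grid; the winning configuration (first in grid order on
#' ties) is refit on the full training fold and applied to the test
#' fold. Missing values are imputed with training-fold medians and
#' features standardized with training-fold statistics; both transforms
#' are re-applied unchanged to the test fold.
#'
#' @param x_train,y_train,subjects_train training segments: feature
#'   matrix, class factor, subject id per row.
#' @param x_test test-fold feature matrix.
#' @param grid hyperparameter grid (see [default_svm_grid()]).
#' @param inner_folds number of inner folds.
#' @param seed optional RNG seed for the inner partition.
#' @return list with `pred` (factor of test predictions), `best` (chosen
#'   grid row), `inner_accuracy` (per-combination mean inner accuracy).
#' @export
nested_fit_predict <- function(x_train, y_train, subjects_train, x_test,
                               grid = default_svm_grid(),
                               inner_folds = 5L, seed = NULL) {
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  y_train <- factor(y_train)
  if (nlevels(droplevels(y_train)) < 2L)
    stop_invalid("training fold contains a single class")
  with_seed(seed)
  x_train <- impute_median(x_train)
  x_test <- impute_median(x_test, attr(x_train, "medians"))
  gs <- svm_grid_search(x_train, y_train, subjects_train, grid,
                        inner_folds)
  out <- svm_fit_predict(x_train, y_train, x_test, gs$best)
  list(pred = out, best = gs$best, inner_accuracy = gs$inner_accuracy)
}

# inner subject-grouped stratified CV over the hyperparameter grid;
# consumes the current RNG stream for the inner partition
svm_grid_search <- function(x_train, y_train, subjects_train, grid,
                            inner_folds = 5L) {
  subj <- unique(data.frame(subject_id = subjects_train,
                            group = as.character(y_train),
                            stringsAsFactors = FALSE))
  inner <- sgkf_split(subj$subject_id, subj$group,
                      n_folds = inner_folds, n_repeats = 1L)[[1L]]
  inner_idx <- lapply(inner, function(ids) which(subjects_train %in% ids))
  n_grid <- nrow(grid)
  correct <- matrix(0, n_grid, length(inner_idx))
  total <- integer(length(inner_idx))
  for (f in seq_along(inner_idx)) {
    idx <- inner_idx[[f]]
    xi <- standardize(x_train[-idx, , drop = FALSE])
    xv <- standardize(x_train[idx, , drop = FALSE], attr(xi, "stats"))
    yi <- y_train[-idx]
    yv <- y_train[idx]
    total[f] <- length(idx)
    for (g in seq_len(n_grid)) {
      fit <- e1071::svm(xi, yi, kernel = grid$kernel[g],
                        cost = grid$cost[g], gamma = grid$gamma[g],
                        scale = FALSE, tolerance = 0.01)
      correct[g, f] <- sum(fast_svm_predict(fit, xv) == yv)
    }
  }
  acc <- rowSums(correct) / sum(total)
  best <- which.max(acc)
  list(best = grid[best, , drop = FALSE], inner_accuracy = acc)
}

# refit on the full training fold with chosen hyperparameters, predict
# the test fold (training-fold standardization)
svm_fit_predict <- function(x_train, y_train, x_test, best) {
  xs <- standardize(x_train)
  xt <- standardize(x_test, attr(xs, "stats"))
  fit <- e1071::svm(xs, y_train, kernel = best$kernel,
                    cost = best$cost, gamma = best$gamma,
                    scale = FALSE, tolerance = 0.01)
  fast_svm_predict(fit, xt)
}

classification_metrics <- function(pred, truth, positive = "MCI") {
  truth <- as.character(truth)
  pred <- as.character(pred)
  neg <- setdiff(unique(truth), positive)
  c(accuracy = 100 * mean(pred == truth),
    sensitivity = 100 * mean(pred[truth == positive] == positive),
    specificity = 100 * mean(pred[truth %in% neg] %in% neg))
}

#' Wrapper construction of the optimal feature subset (OFS)
#'
#' For every feature count `F = 1..f_curve_max`, the top-F mRMR prefix is
#' evaluated with the full protocol: subject-grouped stratified 5-fold
#' cross-validation repeated `n_repeats` times, with statistical
#' screening, mRMR ranking, imputation, standardization and nested
#' hyperparameter search all performed inside each training fold.
#' Hyperparameters are optimized once per training fold (inner
#' subject-grouped 5-fold grid search on the OFS-cardinality prefix) and
#' the winning configuration is reused along the fold's F curve. The
#' OFS is the best-accuracy prefix with `F <= f_max` (ties to the
#' smaller F). Sensitivity is the recall of the positive (MCI) class,
#' specificity the recall of the controls; metrics are segment-level,
#' with subject-level majority-vote accuracy reported alongside.
#'
#' The OFS membership named in the report is obtained by applying the
#' same screening + ranking to the full data set after performance
#' estimation (presentation only; the quoted metrics always come from
#' the cross-validated runs).
#'
#' @param tab feature table (single paradigm, fused, or fused +
#'   covariate): `subject_id`, `segment_id`, `group`, feature columns.
#' @param f_max maximum OFS cardinality.
#' @param f_curve_max largest feature count on the accuracy curve.
#' @param alpha FDR screening threshold.
#' @param n_folds,n_repeats cross-validation layout.
#' @param inner_folds folds of the nested hyperparameter search.
#' @param grid hyperparameter grid.
#' @param paper_mode screen once on the full data set instead of within
#'   training folds (reproduces a full-data screening protocol, at the
#'   cost of a slight optimistic bias).
#' @param screen_unit statistical unit for screening (see
#'   [screen_features()]).
#' @param exempt feature columns exempt from screening (covariates such
#'   as `"MoCA"`); they always enter the candidate set.
#' @param positive the positive class label.
#' @param seed RNG seed for partitions and inner searches.
#' @return an object of class `cv_report`: `per_f` (per-F metric table,
#'   mean and SD over folds x repeats), `ofs`, `f_best`, `metrics`
#'   (metrics at `f_best`), `hyperparameters` (chosen per fold at
#'   `f_best`), `candidates_per_fold`, and the configuration.
#' @export
wrapper_ofs <- function(tab, f_max = 5L, f_curve_max = 10L, alpha = 0.05,
                        n_folds = 5L, n_repeats = 5L, inner_folds = 5L,
                        grid = default_svm_grid(), paper_mode = FALSE,
                        screen_unit = "subject",
                        exempt = "MoCA", positive = "MCI", seed = NULL) {
  stopifnot(all(c("subject_id", "segment_id", "group") %in% names(tab)))
  with_seed(seed)
  meta <- c("subject_id", "segment_id", "group", "paradigm")
  feats <- setdiff(names(tab), meta)
  exempt <- intersect(exempt, feats)
  y_all <- factor(tab$group)
  subjects <- unique(tab[c("subject_id", "group")])
  splits <- sgkf_split(subjects$subject_id, subjects$group,
                       n_folds = n_folds, n_repeats = n_repeats)
  x_all <- as.matrix(tab[setdiff(feats, character(0))])
  screen_cols <- setdiff(feats, exempt)
  full_screen <- if (length(screen_cols))
    screen_columns(tab, screen_cols, alpha, screen_unit) else character(0)
  fold_results <- list()
  fold_id <- 0L
  for (r in seq_along(splits)) {
    for (f in seq_along(splits[[r]])) {
      fold_id <- fold_id + 1L
      test_subjects <- splits[[r]][[f]]
      is_test <- tab$subject_id %in% test_subjects
      train_tab <- tab[!is_test, , drop = FALSE]
      retained <- if (paper_mode) full_screen
      else if (length(screen_cols))
        screen_columns(train_tab, screen_cols, alpha, screen_unit)
      else character(0)
      candidates <- c(retained, exempt)
      res <- list(repeat_i = r, fold = f,
                  n_candidates = length(candidates))
      if (length(candidates) == 0L) {
        res$per_f <- NULL
        fold_results[[fold_id]] <- res
        next
      }
      x_tr <- impute_median(x_all[!is_test, candidates, drop = FALSE])
      ranking <- mrmr_rank(discretize(x_tr), y_all[!is_test])
      order_feats <- ranking$feature
      f_top <- min(f_curve_max, length(candidates))
      # hyperparameters are optimized once per training fold, by nested
      # grid search on the OFS-cardinality mRMR prefix, then reused
      # along the F curve
      sel_gs <- order_feats[seq_len(min(f_max, f_top))]
      x_gs <- impute_median(x_all[!is_test, sel_gs, drop = FALSE])
      gs <- svm_grid_search(x_gs, y_all[!is_test],
                            tab$subject_id[!is_test], grid, inner_folds)
      per_f <- vector("list", f_top)
      for (ff in seq_len(f_top)) {
        sel <- order_feats[seq_len(ff)]
        x_trf <- impute_median(x_all[!is_test, sel, drop = FALSE])
        x_tef <- impute_median(x_all[is_test, sel, drop = FALSE],
                               attr(x_trf, "medians"))
        pred <- svm_fit_predict(x_trf, y_all[!is_test], x_tef, gs$best)
        m <- classification_metrics(pred, y_all[is_test], positive)
        vote <- subject_vote(pred, tab$subject_id[is_test],
                             y_all[is_test], positive)
        per_f[[ff]] <- data.frame(
          F = ff, accuracy = m["accuracy"], sensitivity = m["sensitivity"],
          specificity = m["specificity"], subject_accuracy = vote,
          kernel = gs$best$kernel, cost = gs$best$cost,
          gamma = gs$best$gamma, row.names = NULL)
      }
      res$per_f <- do.call(rbind, per_f)
      res$features <- order_feats[seq_len(f_top)]
      fold_results[[fold_id]] <- res
    }
  }
  all_f <- do.call(rbind, lapply(seq_along(fold_results), function(i) {
    pf <- fold_results[[i]]$per_f
    if (is.null(pf)) return(NULL)
    pf$fold_id <- i
    pf
  }))
  if (is.null(all_f))
    stop_invalid("screening retained no candidate feature in any fold")
  agg <- function(v, f) c(mean = mean(v[all_f$F == f]),
                          sd = sd(v[all_f$F == f]))
  fs <- sort(unique(all_f$F))
  per_f <- do.call(rbind, lapply(fs, function(f) {
    sub <- all_f[all_f$F == f, ]
    data.frame(F = f, n_folds = nrow(sub),
               accuracy_mean = mean(sub$accuracy),
               accuracy_sd = sd(sub$accuracy),
               sensitivity_mean = mean(sub$sensitivity),
               sensitivity_sd = sd(sub$sensitivity),
               specificity_mean = mean(sub$specificity),
               specificity_sd = sd(sub$specificity),
               subject_accuracy_mean = mean(sub$subject_accuracy))
  }))
  truncated <- any(vapply(fold_results, function(x)
    is.null(x$per_f) || max(x$per_f$F) < f_curve_max, TRUE))
  eligible <- per_f[per_f$F <= f_max &
                      per_f$n_folds == max(per_f$n_folds), ]
  f_best <- eligible$F[which.max(eligible$accuracy_mean)]
  # presentation OFS from full-data selection
  cand_full <- c(full_screen, exempt)
  ofs <- character(0)
  if (length(cand_full)) {
    rk <- mrmr_rank(discretize(impute_median(
      x_all[, cand_full, drop = FALSE])), y_all)
    ofs <- rk$feature[seq_len(min(f_best, nrow(rk)))]
  }
  hyper <- all_f[all_f$F == f_best, c("fold_id", "kernel", "cost", "gamma")]
  structure(list(per_f = per_f, f_best = f_best, ofs = ofs,
                 metrics = per_f[per_f$F == f_best, ],
                 hyperparameters = hyper,
                 candidates_per_fold = vapply(fold_results, `[[`, 0L,
                                              "n_candidates"),
                 truncated = truncated, full_screen = full_screen,
                 config = list(f_max = f_max, f_curve_max = f_curve_max,
                               alpha = alpha, n_folds = n_folds,
                               n_repeats = n_repeats,
                               paper_mode = paper_mode, seed = seed,
                               positive = positive)),
            class = "cv_report")
}

# screening split into per-paradigm families by feature-name prefix
screen_columns <- function(tab, cols, alpha, unit) {
  prefixes <- substr(cols, 1L, 1L)
  retained <- character(0)
  for (p in unique(prefixes)) {
    fam <- cols[prefixes == p]
    sc <- suppressMessages(
      screen_features(tab[c("subject_id", "group", fam)],
                      alpha = alpha, unit = unit))
    retained <- c(retained, sc$retained)
  }
  retained
}

subject_vote <- function(pred, subject_ids, truth, positive) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  subs <- unique(subject_ids)
  votes <- vapply(subs, function(s) {
    i <- subject_ids == s
    p <- names(sort(table(pred[i]), decreasing = TRUE))[1L]
    p == truth[i][1L]
  }, TRUE)
  100 * mean(votes)
}

#' @export
print.cv_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<cv_report> OFS (F=%d): %s\n  accuracy %.1f +/- %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    x$f_best, paste(x$ofs, collapse = ", "),
    m$accuracy_mean, m$accuracy_sd, m$sensitivity_mean,
    m$specificity_mean))
  invisible(x)
}
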