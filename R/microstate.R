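#' Global field power
#'
#' GFP(t) is the population standard deviation of the scalp potential
#' across electrodes at sample t:
#' `sqrt(mean((u_j(t) - mean_j u(t))^2))`. Peaks of GFP mark the moments
#' of maximal topographic stability used for clustering.
#'
#' @param rec an [eeg_recording()] or a channels x samples matrix.
#' @return an object of class `gfp_series`: list with `values` (one per
#'   sample, microvolts) and `fs`.
#' @export
gfp <- function(rec) {
  x <- if (inherits(rec, "eeg_recording")) rec$data else as.matrix(rec)
  fs <- if (inherits(rec, "eeg_recording")) rec$fs else NA_real_
  if (nrow(x) < 2L) stop_invalid("GFP needs at least 2 channels")
  mu <- colMeans(x)
  v <- sqrt(colMeans(x^2) - mu^2)
  v[v < 0] <- 0
  structure(list(values = v, fs = fs), class = "gfp_series")
}

#' Locate strict local maxima of a GFP series
#'
#' A sample is a peak when it strictly exceeds both neighbours; endpoints
#' are never peaks and plateaus yield none. A constant series produces an
#' empty peak set with a warning.
#'
#' @param series a `gfp_series` from [gfp()], or a numeric vector.
#' @return integer vector of peak sample indices (strictly increasing).
#' @export
find_gfp_peaks <- function(series) {
  v <- if (inherits(series, "gfp_series")) series$values else series
  if (length(v) < 3L) stop_invalid("need at least 3 samples")
  if (max(v) - min(v) == 0) {
    warning("constant series: no GFP peaks", call. = FALSE)
    return(integer(0))
  }
  i <- 2:(length(v) - 1L)
  i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
}

# rows centered and scaled to unit norm; zero rows left at zero
normalize_maps <- function(m) {
  m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Polarity-invariant modified k-means microstate clustering
#'
#' Iterates (a) assignment of each map to the template of highest absolute
#' spatial correlation (polarity ignored) and (b) template update as the
#' dominant eigenvector of the assigned maps' outer-product sum,
#' unit-normalized. Convergence is declared when assignments are stable or
#' the global explained variance (GEV) changes by less than `tol`. The
#' best of `n_restarts` random restarts by GEV is retained (ties by lowest
#' restart index). Emptied clusters are re-seeded from the worst-fit map.
#'
#' When a `montage` is supplied (and `k == 4`) the fitted templates are
#' canonically labelled `A`-`D` by globally optimal bijective matching
#' against [canonical_templates()] on absolute correlation; otherwise the
#' clusters keep an arbitrary but deterministic order.
#'
#' @param peak_maps N_p x n matrix of average-referenced GFP-peak
#'   topographies (rows are maps).
#' @param k number of microstate classes.
#' @param n_restarts number of random restarts.
#' @param seed optional RNG seed.
#' @param montage optional [make_montage()] for canonical A-D labelling.
#' @param max_iter iteration cap per restart.
#' @param tol GEV convergence tolerance.
#' @return an object of class `microstate_model`: `templates` (k x n,
#'   unit-norm, rownames the class labels), `gev`, `assignments`,
#'   `n_restarts`, `seed` and restart diagnostics.
#' @export
modified_kmeans <- function(peak_maps, k = 4L, n_restarts = 20L,
                            seed = NULL, montage = NULL,
                            max_iter = 100L, tol = 1e-6) {
  peak_maps <- as.matrix(peak_maps)
  n_p <- nrow(peak_maps)
  if (n_p < k) stop_invalid("need at least k peak maps")
  with_seed(seed)
  gfp_p <- apply(peak_maps, 1L, function(u) sqrt(mean((u - mean(u))^2)))
  u_raw <- peak_maps - rowMeans(peak_maps)  # centered, amplitude kept
  u <- normalize_maps(peak_maps)
  w <- gfp_p^2 / sum(gfp_p^2)   # GEV weights
  best <- NULL
  restart_gev <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    ctr <- u[sample.int(n_p, k), , drop = FALSE]
    assign_prev <- integer(n_p)
    gev_prev <- -Inf
    for (it in seq_len(max_iter)) {
      a <- abs(u %*% t(ctr))            # |spatial correlation|
      cl <- max.col(a, ties.method = "first")
      r_abs <- a[cbind(seq_len(n_p), cl)]
      for (j in seq_len(k)) {            # re-seed empty clusters
        if (!any(cl == j)) {
          worst <- which.min(r_abs)
          cl[worst] <- j
          r_abs[worst] <- 1
        }
      }
      gev_now <- sum(w * a[cbind(seq_len(n_p), cl)]^2)
      for (j in seq_len(k)) {
        # dominant eigenvector of the raw outer-product sum: maps enter
        # the update with their amplitude, i.e. GFP^2-weighted
        uj <- u_raw[cl == j, , drop = FALSE]
        s <- crossprod(uj)
        e <- eigen(s, symmetric = TRUE)
        v <- e$vectors[, 1L]
        v <- v - mean(v)                # maps are average-referenced
        ctr[j, ] <- v / sqrt(sum(v^2))
      }
      if (identical(cl, assign_prev) || abs(gev_now - gev_prev) < tol)
        break
      assign_prev <- cl
      gev_prev <- gev_now
    }
    a <- abs(u %*% t(ctr))
    cl <- max.col(a, ties.method = "first")
    gev_r <- sum(w * a[cbind(seq_len(n_p), cl)]^2)
    restart_gev[r] <- gev_r
    if (is.null(best) || gev_r > best$gev + 1e-12)
      best <- list(ctr = ctr, cl = cl, gev = gev_r, restart = r,
                   n_iter = it)
  }
  ctr <- fix_template_signs(best$ctr)
  labels <- LETTERS[seq_len(k)]
  cl <- best$cl
  if (!is.null(montage) && k == 4L) {
    perm <- match_canonical(ctr, canonical_templates(montage))
    ctr <- ctr[perm, , drop = FALSE]
    cl <- match(cl, perm)
  }
  rownames(ctr) <- labels
  colnames(ctr) <- colnames(peak_maps)
  structure(list(templates = ctr, class_labels = labels, gev = best$gev,
                 assignments = cl, n_restarts = n_restarts, seed = seed,
                 best_restart = best$restart, restart_gev = restart_gev),
            class = "microstate_model")
}

# deterministic sign: the largest-magnitude element of each map positive
fix_template_signs <- function(ctr) {
  for (j in seq_len(nrow(ctr))) {
    i <- which.max(abs(ctr[j, ]))
    if (ctr[j, i] < 0) ctr[j, ] <- -ctr[j, ]
  }
  ctr
}

# globally optimal bijective matching (k = 4: enumerate permutations),
# maximizing total |correlation|; ties broken by class order A -> D
match_canonical <- function(templates, prototypes) {
  k <- nrow(templates)
  cmat <- abs(normalize_maps(prototypes) %*% t(normalize_maps(templates)))
  perms <- perm_enum(k)
  score <- apply(perms, 1L, function(p) sum(cmat[cbind(seq_len(k), p)]))
  perms[which.max(score), ]
}

perm_enum <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- perm_enum(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  unname(out)
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k=%d, GEV=%.3f (%d restarts, best #%d)\n",
              nrow(x$templates), x$gev, x$n_restarts, x$best_restart))
  invisible(x)
}

#' Backfit microstate templates to continuous data
#'
#' Labels every sample with the template of highest absolute spatial
#' correlation. No temporal constraint or minimum-duration smoothing is
#' applied, so short pathological states are preserved. Zero-variance
#' samples inherit the previous sample's label (class A at the start) and
#' are flagged in the `degenerate` attribute.
#'
#' @param rec an [eeg_recording()], [epoch_set()] epoch matrix, or
#'   channels x samples matrix.
#' @param model a [modified_kmeans()] model.
#' @param fs sampling rate (taken from `rec` when available).
#' @return a `label_sequence` (states indexed in template row order).
#' @export
backfit <- function(rec, model, fs = NULL) {
  x <- if (inherits(rec, "eeg_recording")) rec$data else as.matrix(rec)
  fs <- fs %||% (if (inherits(rec, "eeg_recording")) rec$fs else NA_real_)
  if (nrow(x) != ncol(model$templates))
    stop_invalid("channel count does not match the model")
  u <- t(x) - colMeans(x)                   # center across channels
  a <- abs(u %*% t(model$templates))
  lab <- max.col(a, ties.method = "first")
  degen <- rowSums(u^2) == 0
  if (any(degen)) {
    for (i in which(degen)) lab[i] <- if (i == 1L) 1L else lab[i - 1L]
  }
  out <- new_label_sequence(lab, fs = fs, k = nrow(model$templates))
  attr(out, "degenerate") <- which(degen)
  out
}

#' Global explained variance of a microstate model
#'
#' GEV is the GFP^2-weighted mean squared spatial correlation between each
#' peak topography and its assigned template:
#' `sum_p GFP_p^2 r_p^2 / sum_p GFP_p^2`. By default maps are assigned to
#' the template of highest absolute correlation (the model's own
#' assignment rule).
#'
#' @param peak_maps N_p x n matrix of peak topographies.
#' @param model a [modified_kmeans()] model.
#' @param assignments optional integer template assignment per map.
#' @return GEV fraction in `[0, 1]`.
#' @export
model_gev <- function(peak_maps, model, assignments = NULL) {
  peak_maps <- as.matrix(peak_maps)
  if (nrow(peak_maps) == 0L)
    stop_invalid("GEV is undefined without peak maps")
  gfp_p <- apply(peak_maps, 1L, function(u) sqrt(mean((u - mean(u))^2)))
  u <- normalize_maps(peak_maps)
  a <- u %*% t(model$templates)
  r <- if (is.null(assignments)) {
    aa <- abs(a)
    aa[cbind(seq_len(nrow(u)), max.col(aa, ties.method = "first"))]
  } else {
    a[cbind(seq_len(nrow(u)), assignments)]
  }
  sum(gfp_p^2 * r^2) / sum(gfp_p^2)
}

#' Segment-level GEV against a fitted model
#'
#' Convenience wrapper: finds the segment's own GFP peaks and evaluates
#' [model_gev()] on those peak maps.
#'
#' @param x channels x samples matrix (one segment).
#' @param model a [modified_kmeans()] model.
#' @return GEV fraction, or `NA` if the segment has no GFP peaks.
#' @export
segment_gev <- function(x, model) {
  g <- gfp(x)
  pk <- find_gfp_peaks(g)
  if (length(pk) == 0L) return(NA_real_)
  model_gev(t(x[, pk, drop = FALSE]), model)
}

#' Write a label sequence as run-length-encoded CSV
#'
#' One row per run: `state` (class letter), `start_sample` (1-based),
#' `length` (samples). The sampling rate is kept in a `# fs=` comment
#' header so the file round-trips through [read_label_sequence()].
#'
#' @param labels a `label_sequence`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_sequence <- function(labels, path) {
  m <- merge_runs(labels)
  df <- data.frame(state = LETTERS[m$symbols],
                   start_sample = cumsum(c(1L, m$lengths))[seq_along(m$lengths)],
                   length = m$lengths)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g k=%d", attr(labels, "fs"), m$k), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a label sequence written by [write_label_sequence()]
#' @param path CSV path.
#' @return a `label_sequence`.
#' @export
read_label_sequence <- function(path) {
  header <- readLines(path, n = 1L)
  fs <- as.numeric(sub("^# fs=([0-9.eE+-]+) .*$", "\\1", header))
  k <- as.integer(sub("^.* k=([0-9]+)$", "\\1", header))
  df <- read.csv(path, comment.char = "#")
  new_label_sequence(rep(match(df$state, LETTERS), df$length),
                     fs = fs, k = k)
}

#' Serialize a microstate model to JSON
#'
#' @param model a [modified_kmeans()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(class_labels = rownames(model$templates),
              channel_names = colnames(model$templates),
              templates = unname(apply(model$templates, 1L, identity,
                                       simplify = FALSE)),
              gev = model$gev, n_restarts = model$n_restarts,
              seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a microstate model serialized by [write_model()]
#' @param path JSON path.
#' @return a `microstate_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tpl <- do.call(rbind, if (is.list(obj$templates)) obj$templates
                 else list(obj$templates))
  if (is.null(dim(tpl))) tpl <- matrix(tpl, nrow = 1L)
  rownames(tpl) <- obj$class_labels
  colnames(tpl) <- obj$channel_names
  structure(list(templates = tpl, class_labels = obj$class_labels,
                 gev = obj$gev, n_restarts = obj$n_restarts,
                 seed = obj$seed),
            class = "microstate_model")
}
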