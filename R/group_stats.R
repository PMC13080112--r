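#' Assumption-dispatched two-sample test
#'
#' Normality of each group is checked with the Shapiro-Wilk test and
#' homogeneity of variance with Levene's test (mean-centred). When both
#' groups pass normality and the variances are homogeneous (all p >
#' `alpha`), an independent two-sample t-test (pooled variance) is used;
#' when either assumption is violated the Mann-Whitney U test is used
#' instead. Two-sided throughout. A feature constant in both groups has
#' no defined test and is reported with `p = 1` and a flag.
#'
#' @param x,y numeric samples of the two groups (at least 3 each;
#'   missing values are dropped).
#' @param alpha significance level for the assumption checks.
#' @return a one-row data frame: `test_used`, `statistic`, `p_raw`,
#'   `mean_x`, `sd_x`, `mean_y`, `sd_y`, `degenerate`.
#' @export
dispatch_test <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  base <- data.frame(test_used = NA_character_, statistic = NA_real_,
                     p_raw = NA_real_, mean_x = mean(x), sd_x = sd(x),
                     mean_y = mean(y), sd_y = sd(y), degenerate = FALSE,
                     stringsAsFactors = FALSE)
  if (length(x) < 3L || length(y) < 3L)
    stop_invalid("each group needs at least 3 observations")
  if (var(x) == 0 && var(y) == 0) {
    base$test_used <- "none"
    base$p_raw <- 1
    base$degenerate <- TRUE
    return(base)
  }
  sw_ok <- function(v) {
    if (var(v) == 0) return(FALSE)  # degenerate in one group: not normal
    shapiro.test(v)$p.value > alpha
  }
  lev_p <- tryCatch({
    dat <- data.frame(v = c(x, y),
                      g = factor(rep(c("x", "y"), c(length(x), length(y)))))
    car::leveneTest(v ~ g, data = dat, center = mean)[1L, "Pr(>F)"]
  }, error = function(e) 0)
  parametric <- sw_ok(x) && sw_ok(y) && lev_p > alpha
  if (parametric) {
    tt <- t.test(x, y, var.equal = TRUE)
    base$test_used <- "t"
    base$statistic <- unname(tt$statistic)
    base$p_raw <- tt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    base$test_used <- "mann-whitney"
    base$statistic <- unname(wt$statistic)
    base$p_raw <- wt$p.value
  }
  base
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: p-values are ranked ascending, scaled by `m/rank`,
#' monotonicity is enforced from the largest rank down, values are capped
#' at 1 and returned in the original order.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_invalid("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Screen features by FDR-corrected group difference
#'
#' Runs [dispatch_test()] on every feature column of a feature table and
#' retains those with `p_fdr < alpha`. By default the statistical unit is
#' the subject: the augmented segments of each subject are averaged
#' before testing, because within-subject segments are not independent.
#' The correction family is the set of features in `tab` (call once per
#' paradigm for per-condition families).
#'
#' @param tab feature table: columns `subject_id`, `group`, optionally
#'   `segment_id`/`paradigm`, plus numeric feature columns.
#' @param alpha FDR threshold.
#' @param unit `"subject"` (default; test subject means) or `"segment"`.
#' @return a list with `retained` (character vector of feature names,
#'   possibly empty) and `results` (per-feature data frame with
#'   `test_used`, group means/SDs, `p_raw`, `p_fdr`).
#' @export
screen_features <- function(tab, alpha = 0.05,
                            unit = c("subject", "segment")) {
  unit <- match.arg(unit)
  stopifnot(all(c("subject_id", "group") %in% names(tab)))
  groups <- unique(tab$group)
  if (length(groups) != 2L)
    stop_invalid("exactly two groups are required")
  meta <- c("subject_id", "segment_id", "group", "paradigm")
  feats <- setdiff(names(tab), meta)
  if (unit == "subject") {
    agg <- aggregate(tab[feats], by = tab[c("subject_id", "group")],
                     FUN = function(v) mean(v, na.rm = TRUE))
  } else {
    agg <- tab[c("subject_id", "group", feats)]
  }
  g1 <- agg$group == groups[1L]
  rows <- lapply(feats, function(f) {
    x <- agg[[f]][g1]
    y <- agg[[f]][!g1]
    x[is.nan(x)] <- NA
    y[is.nan(y)] <- NA
    res <- dispatch_test(x, y, alpha = alpha)
    cbind(data.frame(feature = f, stringsAsFactors = FALSE), res)
  })
  results <- do.call(rbind, rows)
  results$p_fdr <- bh_fdr(results$p_raw)
  retained <- results$feature[!is.na(results$p_fdr) &
                                results$p_fdr < alpha]
  if (length(retained) == 0L)
    message("no feature survived FDR screening at alpha = ", alpha)
  list(retained = retained, results = results,
       groups = groups, alpha = alpha, unit = unit)
}

#' Write a screening results table mirroring a group-comparison layout
#'
#' @param screen a [screen_features()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(screen, path) {
  r <- screen$results
  out <- data.frame(
    feature = ascii_feature_names(r$feature),
    group1 = sprintf("%.3f ± %.3f", r$mean_x, r$sd_x),
    group2 = sprintf("%.3f ± %.3f", r$mean_y, r$sd_y),
    test = r$test_used, p_fdr = signif(r$p_fdr, 4),
    stringsAsFactors = FALSE)
  names(out)[2:3] <- screen$groups
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
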