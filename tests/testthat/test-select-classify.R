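test_that("discretization uses the learned z-score bins", {
  set.seed(1)
  x <- cbind(g = rnorm(20000), const = rep(2, 20000))
  d <- discretize(x)
  mass <- table(d[, "g"]) / nrow(x)
  expect_equal(unname(as.vector(mass)),
               c(pnorm(-0.5), pnorm(0.5) - pnorm(-0.5), pnorm(-0.5)),
               tolerance = 0.02)
  expect_true(all(d[, "const"] == 2L))
  expect_true(attr(d, "train_stats")$constant[["const"]])
  # shifting a column leaves its bins unchanged after z-scoring
  d2 <- discretize(cbind(g = x[, "g"] + 100, const = x[, "const"]))
  expect_identical(unname(d2[, "g"]), unname(d[, "g"]))
  # held-out rows are binned with training statistics
  tr <- discretize(x[1:100, , drop = FALSE])
  te <- discretize(x[101:200, , drop = FALSE],
                   train_stats = attr(tr, "train_stats"))
  expect_identical(attr(te, "train_stats"), attr(tr, "train_stats"))
})

test_that("mutual information is symmetric, nonnegative and calibrated", {
  x <- rep(0:1, 100)
  expect_equal(mutual_information(x, x), 1)      # balanced binary identity
  set.seed(2)
  a <- sample(1:3, 500, TRUE)
  b <- sample(1:3, 500, TRUE)
  expect_equal(mutual_information(a, b), mutual_information(b, a))
  expect_lt(mutual_information(a, b), 0.02)      # independent: near zero
  expect_gte(mutual_information(a, sample(a)), 0)
  expect_equal(mutual_information(a, a), mi_oracle(a, a))
  expect_error(mutual_information(1:5, 1:6), "equal length")
})

test_that("greedy mRMR matches the exhaustive sequential oracle", {
  set.seed(3)
  for (i in 1:5) {
    n <- 150
    y <- factor(rep(c("HC", "MCI"), each = n / 2))
    x <- matrix(rnorm(n * 6), n, 6)
    x[, 1] <- x[, 1] + (as.integer(y) - 1.5)
    x[, 2] <- x[, 1] + rnorm(n, sd = 0.3)
    colnames(x) <- sprintf("f%d", 1:6)
    d <- discretize(x)
    expect_identical(mrmr_rank(d, y)$feature, mrmr_oracle(d, y))
  }
})

test_that("mRMR demotes a redundant duplicate below a weaker feature", {
  set.seed(4)
  n <- 400
  y <- factor(rep(c("HC", "MCI"), each = n / 2))
  strong <- rnorm(n) + (as.integer(y) - 1.5) * 2
  x <- cbind(strong = strong, clone = strong + rnorm(n, sd = 0.05),
             weaker = rnorm(n) + (as.integer(y) - 1.5) * 0.9)
  r <- mrmr_rank(discretize(x), y)
  expect_identical(r$feature[1], "strong")
  expect_lt(match("weaker", r$feature), match("clone", r$feature))
  single <- mrmr_rank(discretize(x[, 1, drop = FALSE]), y)
  expect_identical(single$feature, "strong")
})

test_that("fusion concatenates screened tables by subject and segment", {
  mk <- function(prefix, p) {
    tab <- expand.grid(segment_id = 1:3,
                       subject_id = sprintf("S%d", 1:4),
                       stringsAsFactors = FALSE)
    tab$group <- ifelse(tab$subject_id %in% c("S1", "S2"), "HC", "MCI")
    tab$paradigm <- p
    for (f in paste0(prefix, seq_len(if (prefix == "r") 10 else 13)))
      tab[[f]] <- rnorm(nrow(tab))
    tab
  }
  rest <- mk("r", "rest")
  task <- mk("t", "task")
  fused <- fuse_tables(list(rest = rest, task = task))
  meta <- c("subject_id", "segment_id", "group", "paradigm")
  expect_equal(length(setdiff(names(fused), meta)), 23L)
  expect_identical(fuse_tables(list(rest)),
                   rest[setdiff(names(rest), "paradigm")])
  moca <- data.frame(subject_id = sprintf("S%d", 1:4), MoCA = c(26, 27, 19, 20))
  fm <- fuse_tables(list(rest = rest, task = task), covariate = moca)
  expect_equal(length(setdiff(names(fm), meta)), 24L)
  expect_true(all(tapply(fm$MoCA, fm$subject_id, function(v)
    length(unique(v))) == 1))
  bad <- task[task$subject_id != "S4", ]
  expect_error(fuse_tables(list(rest, bad)), "S4")
})

test_that("stratified group folds partition subjects with balanced classes", {
  ids <- sprintf("S%02d", 1:63)
  grp <- c(rep("HC", 31), rep("MCI", 32))
  sp <- sgkf_split(ids, grp, n_folds = 5, n_repeats = 5, seed = 1)
  expect_length(sp, 5L)
  for (r in sp) {
    expect_length(r, 5L)
    all_ids <- unlist(r)
    expect_setequal(all_ids, ids)          # a partition
    expect_equal(anyDuplicated(all_ids), 0L)
    sizes <- lengths(r)
    expect_true(all(sizes >= 12 & sizes <= 13))
    for (f in r) {
      counts <- table(factor(grp[match(f, ids)], c("HC", "MCI")))
      expect_true(all(counts >= 6 & counts <= 7))
    }
  }
  expect_identical(sgkf_split(ids, grp, seed = 7), sgkf_split(ids, grp, seed = 7))
  expect_error(sgkf_split(ids[1:6], grp[c(1:3, 32:34)], n_folds = 5),
               "at least n_folds")
})

test_that("nested SVM classifies separable data and validates inputs", {
  set.seed(5)
  n_sub <- 20
  subj <- rep(sprintf("S%02d", 1:n_sub), each = 5)
  y <- factor(rep(rep(c("HC", "MCI"), each = n_sub / 2), each = 5))
  x <- matrix(rnorm(length(y) * 3, sd = 0.3), ncol = 3) +
    outer(as.integer(y) - 1.5, rep(2, 3))
  test_idx <- subj %in% c("S01", "S02", "S11", "S12")
  fit <- nested_fit_predict(x[!test_idx, ], y[!test_idx], subj[!test_idx],
                            x[test_idx, ], seed = 6)
  expect_equal(as.character(fit$pred), as.character(y[test_idx]))
  expect_true(fit$best$kernel %in% c("linear", "radial"))
  expect_error(nested_fit_predict(x[y == "HC", ], y[y == "HC"],
                                  subj[y == "HC"], x[test_idx, ]),
               "single class")
})

test_that("feature selection and model fitting never see test-fold labels", {
  set.seed(7)
  tab <- label_level_table(small_specs(10, 10)$hc$rest,
                           small_specs(10, 10)$mci$rest, n_seg = 3L,
                           segment_s = 10)
  test_subjects <- c("HC01", "HC02", "MCI01", "MCI02")
  is_test <- tab$subject_id %in% test_subjects
  train <- tab[!is_test, ]
  # corrupt every test-fold label; the training-side selection pipeline
  # must be bit-identical
  corrupted <- tab
  corrupted$group[is_test] <- sample(corrupted$group[is_test])
  feats <- setdiff(names(tab), c("subject_id", "segment_id", "group"))
  sc1 <- suppressMessages(screen_features(tab[!is_test, ]))
  sc2 <- suppressMessages(screen_features(corrupted[!is_test, ]))
  expect_identical(sc1$retained, sc2$retained)
  x1 <- as.matrix(train[feats])
  r1 <- mrmr_rank(discretize(mstatefusion:::impute_median(x1)),
                  factor(train$group))
  x2 <- as.matrix(corrupted[!is_test, feats])
  r2 <- mrmr_rank(discretize(mstatefusion:::impute_median(x2)),
                  factor(corrupted$group[!is_test]))
  expect_identical(r1, r2)
})

test_that("wrapper evaluation caps the OFS and reports the metric curve", {
  set.seed(8)
  tab <- label_level_table(small_specs(10, 10)$hc$rest,
                           small_specs(10, 10)$mci$rest, n_seg = 4L,
                           segment_s = 15)
  rep <- wrapper_ofs(tab, f_max = 3, f_curve_max = 4, n_folds = 3,
                     n_repeats = 2, inner_folds = 2, alpha = 0.2, seed = 9)
  expect_s3_class(rep, "cv_report")
  expect_lte(rep$f_best, 3L)
  expect_lte(length(rep$ofs), 3L)
  expect_true(all(rep$per_f$accuracy_mean >= 0 &
                    rep$per_f$accuracy_mean <= 100))
  expect_true(all(c("accuracy_mean", "sensitivity_mean",
                    "specificity_mean") %in% names(rep$per_f)))
  expect_equal(nrow(rep$hyperparameters),
               sum(rep$candidates_per_fold > 0))
})

test_that("label-permuted classification accuracy centres on chance", {
  set.seed(10)
  n_sub <- 24
  ids <- sprintf("S%02d", seq_len(n_sub))
  subj <- rep(ids, each = 5)
  x <- matrix(rnorm(length(subj) * 4), ncol = 4)
  accs <- vapply(1:30, function(i) {
    grp_subj <- sample(rep(c("HC", "MCI"), each = n_sub / 2))
    y <- factor(grp_subj[match(subj, ids)])
    folds <- sgkf_split(ids, grp_subj, n_folds = 4, n_repeats = 1)[[1]]
    correct <- 0L
    for (f in folds) {
      te <- subj %in% f
      fit <- e1071::svm(x[!te, ], y[!te], kernel = "radial", cost = 1,
                        gamma = 0.25, scale = FALSE)
      correct <- correct + sum(predict(fit, x[te, ]) == y[te])
    }
    100 * correct / length(subj)
  }, 0)
  expect_gt(mean(accs), 40)
  expect_lt(mean(accs), 60)
})
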