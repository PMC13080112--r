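test_that("GFP equals the cross-channel population SD", {
  one <- matrix(c(1, -1), 2, 1)
  expect_equal(gfp(one)$values, 1)
  expect_equal(gfp(matrix(5, 4, 3))$values, rep(0, 3))
  x <- matrix(rnorm(6 * 50), 6)
  expect_equal(gfp(3.2 * x)$values, 3.2 * gfp(x)$values)  # homogeneity
  expect_equal(gfp(x)$values,
               apply(x, 2, function(u) sqrt(mean((u - mean(u))^2))))
  expect_error(gfp(matrix(1, 1, 10)), "2 channels")
})

test_that("GFP peaks are strict interior local maxima", {
  expect_equal(find_gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_equal(find_gfp_peaks(1:10), integer(0))        # monotone
  expect_equal(find_gfp_peaks(c(0, 1, 1, 0)), integer(0))  # plateau
  expect_warning(out <- find_gfp_peaks(rep(2, 10)), "constant")
  expect_equal(out, integer(0))
  expect_error(find_gfp_peaks(c(1, 2)), "3 samples")
})

test_that("modified k-means recovers planted templates despite polarity", {
  m <- make_montage(16)
  # four orthogonalized zero-mean templates
  set.seed(1)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(16 * 4), 16))))[, 2:5]
  tpl <- t(q)
  maps <- tpl[rep(1:4, each = 30), ]
  signs <- sample(c(-1, 1), nrow(maps), replace = TRUE)
  maps <- maps * signs
  mod <- modified_kmeans(maps, k = 4, n_restarts = 20, seed = 2)
  cc <- abs(tpl %*% t(mod$templates))
  matched <- apply(cc, 1, max)
  expect_true(all(matched > 1 - 1e-9))
  expect_equal(sort(apply(cc, 1, which.max)), 1:4)   # bijective matching
  expect_equal(mod$gev, 1, tolerance = 1e-9)
})

test_that("modified k-means is deterministic and polarity-invariant", {
  set.seed(3)
  maps <- matrix(rnorm(60 * 10), 60)
  a <- modified_kmeans(maps, k = 3, n_restarts = 5, seed = 4)
  b <- modified_kmeans(maps, k = 3, n_restarts = 5, seed = 4)
  expect_identical(a$templates, b$templates)
  expect_identical(a$assignments, b$assignments)
  flip <- maps
  flip[seq(1, 60, 2), ] <- -flip[seq(1, 60, 2), ]
  c_ <- modified_kmeans(flip, k = 3, n_restarts = 5, seed = 4)
  expect_equal(c_$gev, a$gev, tolerance = 1e-9)
  expect_identical(c_$assignments, a$assignments)
  expect_error(modified_kmeans(maps[1:2, ], k = 3), "at least k")
})

test_that("GEV is non-decreasing in k on a fixed data set", {
  set.seed(5)
  m <- make_montage(12)
  tpl <- make_templates(m, k = 4, seed = 5)
  lab <- simulate_label_sequence(default_group_specs()$hc$rest, 8, 250,
                                 seed = 6)
  rec <- render_eeg(lab, tpl, snr = 3, seed = 7)
  pk <- find_gfp_peaks(gfp(rec))
  maps <- t(rec$data[, pk])
  gevs <- vapply(1:6, function(k)
    modified_kmeans(maps, k = k, n_restarts = 8, seed = 8)$gev, 0)
  expect_true(all(diff(gevs) > -1e-6))
  expect_true(all(gevs >= 0 & gevs <= 1))
})

test_that("clustering attains the exhaustive-search GEV on tiny instances", {
  for (s in 1:3) {
    set.seed(s)
    maps <- matrix(rnorm(10 * 6), 10)
    mod <- modified_kmeans(maps, k = 2, n_restarts = 20, seed = s + 10)
    oracle <- kmeans_oracle_gev(maps)
    expect_gte(mod$gev, oracle - 1e-6)
    expect_lte(mod$gev, oracle + 1e-6)
  }
})

test_that("canonical labelling matches templates to prototype classes", {
  m <- make_montage()
  tpl <- make_templates(m, k = 4, seed = 9)
  lab <- simulate_label_sequence(default_group_specs()$hc$rest, 30, 250,
                                 seed = 10)
  rec <- render_eeg(lab, tpl, snr = 8, seed = 11)
  pk <- find_gfp_peaks(gfp(rec))
  mod <- modified_kmeans(t(rec$data[, pk]), k = 4, n_restarts = 10,
                         seed = 12, montage = m)
  expect_identical(rownames(mod$templates), c("A", "B", "C", "D"))
  # generated class m should map to fitted class m after labelling
  cc <- abs(tpl %*% t(mod$templates))
  expect_true(all(diag(cc) > 0.95))
})

test_that("backfitting labels every sample by absolute correlation", {
  m <- make_montage(8)
  tpl <- make_templates(m, k = 4, seed = 13)
  model <- structure(list(templates = tpl), class = "microstate_model")
  # constant single-template recording
  rec <- eeg_recording(matrix(tpl[3, ], 8, 40) * 5, 250)
  expect_true(all(as.integer(backfit(rec, model)) == 3L))
  # zero-variance samples inherit the previous label and are flagged
  x <- matrix(tpl[2, ], 8, 5) * 2
  x[, 3] <- 0
  lab <- backfit(x, model, fs = 250)
  expect_equal(as.integer(lab), rep(2L, 5))
  expect_equal(attr(lab, "degenerate"), 3L)
  expect_error(backfit(matrix(0, 5, 4), model, fs = 250), "channel count")
})

test_that("GEV formula behaves at its extremes and under scaling", {
  m <- make_montage(10)
  tpl <- make_templates(m, k = 4, seed = 14)
  model <- structure(list(templates = tpl), class = "microstate_model")
  maps <- tpl[c(1, 2, 3, 4, 1), ] * c(1, 2, 3, 4, 5)
  expect_equal(model_gev(maps, model), 1, tolerance = 1e-9)
  expect_equal(model_gev(100 * maps, model), model_gev(maps, model),
               tolerance = 1e-12)
  # maps orthogonal to every template: GEV ~ 0
  set.seed(15)
  q <- qr.Q(qr(cbind(1, t(tpl), rnorm(10))))[, 6, drop = FALSE]
  expect_lt(model_gev(t(q), model), 1e-9)
  expect_error(model_gev(maps[0, , drop = FALSE], model), "undefined")
})

test_that("label sequences round-trip through run-length CSV", {
  lab <- simulate_label_sequence(default_group_specs()$hc$rest, 4, 250,
                                 seed = 21)
  path <- file.path(withr::local_tempdir(), "labels.csv")
  write_label_sequence(lab, path)
  back <- read_label_sequence(path)
  expect_identical(as.integer(back), as.integer(lab))
  expect_identical(attr(back, "fs"), attr(lab, "fs"))
  expect_identical(attr(back, "k"), attr(lab, "k"))
})

test_that("models round-trip through JSON serialization", {
  m <- make_montage(12)
  set.seed(16)
  maps <- matrix(rnorm(40 * 12), 40)
  mod <- modified_kmeans(maps, k = 4, n_restarts = 3, seed = 17)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_model(mod, path)
  back <- read_model(path)
  expect_equal(back$templates, mod$templates, tolerance = 1e-12)
  expect_equal(back$gev, mod$gev, tolerance = 1e-12)
})
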