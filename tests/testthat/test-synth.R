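test_that("montage electrodes lie on the unit sphere with unique names", {
  m <- make_montage()
  expect_equal(nrow(m$positions), 62L)
  expect_true(all(abs(sqrt(rowSums(m$positions^2)) - 1) < 1e-9))
  expect_false(anyDuplicated(m$channel_names) > 0)
  expect_error(make_montage(3), "at least 4")
})

test_that("templates are average-referenced, unit-norm and separated", {
  m <- make_montage()
  tpl <- make_templates(m, k = 4, seed = 1)
  expect_equal(dim(tpl), c(4L, 62L))
  expect_true(all(abs(rowMeans(tpl)) < 1e-9))          # CAR by construction
  expect_true(all(abs(sqrt(rowSums(tpl^2)) - 1) < 1e-9))
  cc <- tpl %*% t(tpl)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.8)
  expect_error(make_templates(make_montage(6), k = 7), "exceed")
})

test_that("template generation is seed-deterministic but seed-sensitive", {
  m <- make_montage()
  expect_identical(make_templates(m, seed = 1), make_templates(m, seed = 1))
  t1 <- make_templates(m, seed = 1)
  t2 <- make_templates(m, seed = 2)
  per_class <- abs(rowSums(t1 * t2))   # |corr| per class across seeds
  expect_true(all(per_class < 1 - 1e-6))
})

test_that("label generator honours the transition support", {
  tm <- matrix(0, 4, 4)
  tm[1, 2] <- 1
  tm[2, 1] <- 1
  tm[3, c(1, 2, 4)] <- 1 / 3
  tm[4, c(1, 2, 3)] <- 1 / 3
  spec <- group_spec("HC", 1, tm, mean_durations_ms = rep(20, 4))
  lab <- simulate_label_sequence(spec, 10, 250, seed = 1)
  expect_true(all(as.integer(lab) %in% 1:2))
  expect_identical(simulate_label_sequence(spec, 10, 250, seed = 5),
                   simulate_label_sequence(spec, 10, 250, seed = 5))
  bad <- spec
  bad$transition_matrix[1, ] <- 0
  expect_error(simulate_label_sequence(bad, 1, 250), "degenerate")
})

test_that("empirical run lengths match the gamma run-length model", {
  spec <- group_spec("HC", 1, transition_from_weights(rep(.25, 4)),
                     mean_durations_ms = rep(20, 4))
  lab <- simulate_label_sequence(spec, 600, 250, seed = 2)
  r <- rle(as.integer(lab))
  md_a <- mean(r$lengths[r$values == 1]) / 250 * 1000
  expect_lt(abs(md_a - 20), 2)
})

test_that("long-run transition frequencies and coverage converge", {
  gs <- default_group_specs()
  spec <- gs$mci$rest
  lab <- simulate_label_sequence(spec, 3600, 250, seed = 3)
  tp <- transition_probabilities(merge_runs(lab))
  off <- !diag(4)
  expect_true(all(abs(tp[off] - spec$transition_matrix[off]) < 0.03))
  pi0 <- mstatefusion:::embedded_stationary(spec$transition_matrix)
  occ <- pi0 * spec$mean_durations_ms
  occ <- occ / sum(occ)
  expect_true(all(abs(coverage(merge_runs(lab)) - occ) < 0.03))
})

test_that("rendering is CAR, SNR-scaled and noiseless-invertible", {
  m <- make_montage()
  tpl <- make_templates(m, seed = 4)
  spec <- default_group_specs()$hc$rest
  lab <- simulate_label_sequence(spec, 5, 250, seed = 5)
  clean <- render_eeg(lab, tpl, snr = Inf)
  expect_lt(max(abs(colMeans(clean$data))), 1e-9)
  model <- structure(list(templates = tpl), class = "microstate_model")
  expect_identical(as.integer(backfit(clean, model)), as.integer(lab))
  noisy1 <- render_eeg(lab, tpl, snr = 5, seed = 6)
  noisy2 <- render_eeg(lab, tpl, snr = 5, seed = 6)
  expect_identical(noisy1$data, noisy2$data)
  # measured SNR close to nominal: residual RMS vs clean-signal RMS
  resid <- noisy1$data - sweep(clean$data, 2, colMeans(clean$data))
  snr_hat <- sqrt(mean(clean$data^2)) / sqrt(mean(resid^2))
  expect_lt(abs(snr_hat - 5) / 5, 0.1)
})

test_that("polarity flips of the recording leave backfit labels unchanged", {
  m <- make_montage()
  tpl <- make_templates(m, seed = 7)
  lab <- simulate_label_sequence(default_group_specs()$hc$rest, 4, 250,
                                 seed = 8)
  rec <- render_eeg(lab, tpl, snr = 10, seed = 9)
  model <- structure(list(templates = tpl), class = "microstate_model")
  flipped <- rec
  flipped$data <- -flipped$data
  expect_identical(as.integer(backfit(rec, model)),
                   as.integer(backfit(flipped, model)))
})

test_that("cohort generation has the expected layout and MoCA contrast", {
  gs <- default_group_specs()
  # default group sizes are the study's 31 HC / 32 MCI
  expect_equal(gs$hc$rest$n_subjects, 31L)
  expect_equal(gs$mci$rest$n_subjects, 32L)
  co <- make_cohort(hc = small_specs(2, 2)$hc, mci = small_specs(2, 2)$mci,
                    seed = 1, rest_duration_s = 2, n_task_trials = 3)
  expect_equal(nrow(co$subjects), 4L)
  expect_named(co$rest, co$subjects$subject_id)
  expect_named(co$task, co$subjects$subject_id)
  expect_s3_class(co$rest[[1]], "eeg_recording")
  expect_equal(nrow(co$events[[1]]), 3L)
  # single subject per group
  co1 <- make_cohort(hc = small_specs(1, 1)$hc, mci = small_specs(1, 1)$mci,
                     seed = 2, rest_duration_s = 1, n_task_trials = 2)
  expect_equal(nrow(co1$subjects), 2L)
  # MoCA group means approach the specification (CLT check)
  big <- small_specs(300, 300)
  cob <- make_cohort(hc = big$hc, mci = big$mci, seed = 3,
                     rest_duration_s = 0.2, n_task_trials = 1,
                     paradigms = "rest")
  mh <- mean(cob$subjects$moca[cob$subjects$group == "HC"])
  mm <- mean(cob$subjects$moca[cob$subjects$group == "MCI"])
  expect_lt(abs(mh - 25.48), 0.4)
  expect_lt(abs(mm - 19.16), 0.4)
})

test_that("cohort generation is reproducible from its seed", {
  sp <- small_specs(2, 2)
  a <- make_cohort(hc = sp$hc, mci = sp$mci, seed = 11,
                   rest_duration_s = 1, n_task_trials = 2)
  b <- make_cohort(hc = sp$hc, mci = sp$mci, seed = 11,
                   rest_duration_s = 1, n_task_trials = 2)
  expect_identical(a$rest[[3]]$data, b$rest[[3]]$data)
  expect_identical(a$ground_truth$rest_labels, b$ground_truth$rest_labels)
})

test_that("recordings round-trip bit-exactly through the on-disk format", {
  m <- make_montage()
  tpl <- make_templates(m, seed = 12)
  lab <- simulate_label_sequence(default_group_specs()$hc$rest, 1, 250,
                                 seed = 13)
  rec <- render_eeg(lab, tpl, snr = 5, seed = 14, subject_id = "S01",
                    group = "HC", paradigm = "rest")
  prefix <- file.path(withr::local_tempdir(), "rec")
  write_recording(rec, prefix)
  back <- read_recording(prefix)
  expect_identical(back$data, rec$data)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$subject_id, "S01")
  ev <- data.frame(onset_s = c(0.2, 1.4), condition = "incongruent",
                   correct = 1L)
  path <- file.path(withr::local_tempdir(), "events.csv")
  write_events(ev, path)
  expect_equal(read_events(path)$onset_s, ev$onset_s)
})

test_that("group specifications validate their invariants", {
  tm <- transition_from_weights(rep(.25, 4))
  expect_s3_class(group_spec("HC", 5, tm, rep(50, 4)), "group_spec")
  bad <- tm
  diag(bad) <- 0.1
  expect_error(group_spec("HC", 5, bad, rep(50, 4)), "diagonal")
  expect_error(group_spec("HC", 5, tm * 2, rep(50, 4)), "sum to 1")
  expect_error(group_spec("HC", 5, tm, c(-1, 1, 1, 1)), "positive")
  expect_error(group_spec("HC", 0, tm, rep(50, 4)), ">= 1")
})
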