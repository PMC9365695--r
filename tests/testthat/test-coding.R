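test_that("fit_cd equals an explicit dense linear solve and honors the ridge limit", {
  set.seed(60)
  # brute-force oracle: explicit matrix inverse times the mean difference
  for (i in 1:50) {
    p <- sample(2:10, 1)
    n <- sample((p + 4):40, 1)
    X <- matrix(rnorm(n * p), n)
    lab <- sample(c("a", "b"), n, replace = TRUE)
    if (min(table(lab)) < 2) next
    gamma <- 10^runif(1, -5, -1)
    cd <- fit_cd(X, lab, gamma, positive_class = "b")
    mu_d <- colMeans(X[lab == "b", , drop = FALSE]) -
      colMeans(X[lab == "a", , drop = FALSE])
    w_oracle <- solve(stats::cov(X) + diag(gamma, p)) %*% mu_d
    expect_lt(max(abs(cd$weights - w_oracle)), 1e-8)
  }
  # gamma -> large: the direction converges to the raw mean difference
  X <- matrix(rnorm(200 * 6), 200)
  lab <- rep(c("a", "b"), 100)
  X[lab == "b", ] <- X[lab == "b", ] + rnorm(6)
  cd_big <- fit_cd(X, lab, gamma = 1e6, positive_class = "b")
  mu_d <- colMeans(X[lab == "b", ]) - colMeans(X[lab == "a", ])
  dir1 <- cd_big$weights / sqrt(sum(cd_big$weights^2))
  dir2 <- mu_d / sqrt(sum(mu_d^2))
  expect_lt(max(abs(dir1 - dir2)), 1e-3)
  # a whitened two-cell problem with mean difference along cell 1 points
  # along cell 1
  Z <- matrix(rnorm(2000 * 2), 2000)
  labz <- rep(c("a", "b"), 1000)
  Z[labz == "b", 1] <- Z[labz == "b", 1] + 0.1
  cdz <- fit_cd(Z, labz, 1e-4, positive_class = "b")
  expect_gt(abs(cdz$weights[1]) / sqrt(sum(cdz$weights^2)), 0.95)
  # error paths
  expect_error(fit_cd(Z, rep("a", 2000)), "two classes")
  expect_error(fit_cd(Z, labz, gamma = 0), "gamma")
})

test_that("the downdate LOO path is algebraically identical to per-fold refits", {
  set.seed(61)
  for (i in 1:5) {
    n <- sample(30:60, 1)
    p <- sample(3:12, 1)
    X <- matrix(rnorm(n * p), n)
    lab <- sample(c("A", "B"), n, replace = TRUE)
    if (min(table(lab)) < 3) next
    Xe <- matrix(rnorm(n * p), n)
    d1 <- loo_decode(X, lab, method = "downdate", extra = list(e = Xe))
    d2 <- loo_decode(X, lab, method = "refit", extra = list(e = Xe))
    expect_equal(d1$per_trial$score, d2$per_trial$score, tolerance = 1e-9)
    expect_equal(d1$per_trial$zscore, d2$per_trial$zscore, tolerance = 1e-9)
    expect_identical(d1$per_trial$predicted, d2$per_trial$predicted)
    expect_equal(d1$extra_scores$e, d2$extra_scores$e, tolerance = 1e-9)
  }
})

test_that("leave-one-out decoding behaves at the extremes", {
  # perfectly separated noise-free classes decode perfectly
  X <- rbind(matrix(-1, 20, 4), matrix(1, 20, 4)) +
    matrix(rnorm(160, 0, 1e-6), 40)
  lab <- rep(c("a", "b"), each = 20)
  expect_equal(loo_decode(X, lab)$accuracy, 1)
  # single-class folds are skipped with a log, not an error
  lab2 <- c(rep("a", 2), rep("b", 38))
  d <- loo_decode(X, lab2)
  expect_identical(d$n_skipped, 2L)
  expect_true(all(!d$per_trial$used[1:2]))
})

test_that("delay_feature samples without replacement and is unbiased", {
  set.seed(62)
  s <- generate_trials(30, task_params(opto_fraction = 0),
                       task_schedule = "WM")
  store <- simulate_population(s, neural_params(n_cells = 4,
                                                n_noise_factors = 0))
  tens <- align_trials(s, store, "delay_onset", c(0, 3200))
  # a trial with >= 5 frames: the resampled mean converges to the full mean
  idx <- which(vapply(tens$windows, ncol, integer(1)) >= 5)[1]
  full_mean <- rowMeans(tens$windows[[idx]])
  reps <- replicate(4000, delay_feature(tens, k = 5)$X[idx, ])
  expect_lt(max(abs(rowMeans(reps) - full_mean)), 0.01)
  # constant traces give the constant
  stc <- activity_store(matrix(2.5, 1, ncol(store$activity)),
                        store$frame_times_ms)
  tc <- align_trials(s, stc, "delay_onset", c(0, 3200))
  ft <- delay_feature(tc, k = 5)
  expect_true(all(ft$X[ft$usable, 1] == 2.5))
  # trials with fewer than k frames are excluded, not padded
  short <- which(vapply(tens$windows, ncol, integer(1)) < 5)
  ft2 <- delay_feature(tens, k = 5)
  expect_true(all(!ft2$usable[short]))
  expect_true(all(is.na(ft2$X[short, ])))
})

test_that("cell sweeps equal full decoding at n = n_cells and chance at n = 1 on null data", {
  set.seed(63)
  X <- matrix(rnorm(120 * 12), 120)
  lab <- rep(c("a", "b"), 60)
  X[lab == "b", 1:6] <- X[lab == "b", 1:6] + 0.8
  full <- loo_decode(X, lab)$accuracy
  sw <- sweep_cells(X, lab, ns = c(1, 12), repeats = 8)
  expect_equal(sw$accuracy[sw$n_cells == 12], full, tolerance = 1e-12)
  expect_equal(sw$variance_fraction[sw$n_cells == 12], 1, tolerance = 1e-12)
  null <- matrix(rnorm(200 * 10), 200)
  sw0 <- sweep_cells(null, rep(c("a", "b"), 100), ns = 1, repeats = 20)
  expect_equal(sw0$accuracy, 0.5, tolerance = 0.12)
})

test_that("PC sweeps at k = 0 and k = rank reproduce full decoding", {
  set.seed(64)
  n <- 80; p <- 10
  frames <- matrix(rnorm(400 * p), 400)
  X <- matrix(rnorm(n * p), n)
  lab <- rep(c("a", "b"), n / 2)
  X[lab == "b", 1:3] <- X[lab == "b", 1:3] + 1
  pcs <- fit_single_trial_pcs(frames)
  full_in_basis <- loo_decode(
    sweep(X, 2, pcs$center) %*% pcs$rotation, lab)$accuracy
  top_all <- sweep_pcs(X, lab, pcs, ks = p, mode = "top")
  ex_none <- sweep_pcs(X, lab, pcs, ks = 0, mode = "exclude")
  expect_equal(top_all$accuracy, full_in_basis, tolerance = 1e-12)
  expect_equal(ex_none$accuracy, full_in_basis, tolerance = 1e-12)
  expect_equal(top_all$variance_fraction, 1, tolerance = 1e-12)
  # excluding the full rank leaves nothing: chance with a warning
  expect_warning(out <- sweep_pcs(X, lab, pcs, ks = p, mode = "exclude"),
                 "rank")
  expect_equal(out$accuracy, 0.5)
})

test_that("stimulus-period cue dimensions generalize across tasks; delay cue dimensions do not", {
  set.seed(65)
  ex <- sim_experiment(1000)
  tr <- ex$filtered$trials
  Xs <- epoch_means(ex$filtered, ex$store, "stim")
  ok <- rowSums(is.na(Xs)) == 0 & tr$stim_class %in% c("A", "B")
  wm <- ok & tr$task == "WM"
  disc <- ok & tr$task == "DISC"
  res <- stimulus_period_cd(Xs[wm, ], tr$stim_class[wm],
                            Xs[disc, ], tr$stim_class[disc])
  expect_gte(res$within_accuracy, 0.85)
  expect_gte(res$cross_accuracy, res$within_accuracy - 0.1)

  # the delay cue dimension, applied to Discrimination-task delays (only
  # present after the rare mirrored stimuli), is near chance: the memory
  # code is engaged by the WM task only
  f <- delay_features(ex)
  dec <- loo_decode(f$X[f$wm_cue, ], tr$prev_stim_class[f$wm_cue],
                    positive_class = "B")
  disc_lab <- f$ok & tr$task == "DISC" & tr$prev_stim_class %in% c("A", "B")
  if (sum(disc_lab) >= 10) {
    pred <- predict_cd(dec$cd_full, f$X[disc_lab, ])
    expect_lt(mean(pred$predicted == tr$prev_stim_class[disc_lab]), 0.75)
  }
  # mismatched stimulus classes across tasks are an error
  expect_error(stimulus_period_cd(Xs[wm, ], tr$stim_class[wm],
                                  Xs[disc, ][1:5, ], rep("P", 5)),
               "match")
})

test_that("persistence statistics behave for perfect, null and planted-rho scores", {
  set.seed(66)
  cfg <- analysis_config()
  delays <- runif(600, 2000, 3200)
  g <- rnorm(600)
  ps1 <- suppressWarnings(persistence_stats(g, g, delays, cfg))
  expect_equal(ps1$slope, 1, tolerance = 1e-12)
  expect_equal(ps1$r_squared, 1, tolerance = 1e-12)
  ps0 <- persistence_stats(rnorm(600), rnorm(600), delays, cfg)
  expect_lt(abs(ps0$slope), 0.1)
  expect_lt(ps0$r_squared, 0.05)
  # planted AR(1) across halves recovers rho
  rho <- 0.6
  e <- rnorm(5000)
  l <- rho * e + sqrt(1 - rho^2) * rnorm(5000)
  ps <- persistence_stats(e, l, runif(5000, 2000, 3200), cfg)
  expect_equal(ps$slope, rho, tolerance = 0.05 / rho)
  # short-delay trials are excluded; too few qualifying trials error out
  expect_error(persistence_stats(e[1:20], l[1:20], rep(1000, 20), cfg),
               "insufficient")
})

test_that("code collapse predicts subsequent false alarms through the 5-frame feature", {
  set.seed(67)
  cfg <- analysis_config()
  s <- generate_trials(3500, task_params(opto_fraction = 0),
                       task_schedule = "WM")
  # a weak, highly variable code, so that decoding errors concentrate on
  # low-gain trials, which the behavioral coupling turns into false alarms
  np <- neural_params(n_cells = 120, n_noise_factors = 20,
                      code_amplitude = 0.1, code_trial_cv = 0.6)
  store <- simulate_population(s, np, cfg)
  gt <- attr(store, "ground_truth")
  gains <- gt$gains
  gain <- (gains$g_cue_early + gains$g_cue_late) / 2
  s <- simulate_responses(s, behavior_params(fa_base = 0.03,
                                             fa_slope_per_s = 0,
                                             code_coupling = 1),
                          cue_code_gain = gain)
  sf <- filter_trials(s, cfg, imaging = TRUE)
  tr <- sf$trials
  tens <- align_trials(sf, store, "delay_onset",
                       c(0, cfg$analysis_delay_cap_ms))
  ft <- delay_feature(tens, k = 5)
  lab_ok <- tr$prev_stim_class %in% c("A", "B") & ft$usable
  correct_trials <- lab_ok & tr$outcome == "CR"
  dec <- loo_decode(ft$X[correct_trials, ],
                    tr$prev_stim_class[correct_trials],
                    positive_class = "B")
  # incorrect (FA) trials are scored by the model trained on correct trials
  fa_trials <- lab_ok & tr$outcome == "FA"
  pred_fa <- predict_cd(dec$cd_full, ft$X[fa_trials, ])
  correct_flag <- c(dec$per_trial$correct,
                    pred_fa$predicted == tr$prev_stim_class[fa_trials])
  outcomes <- c(tr$outcome[correct_trials], tr$outcome[fa_trials])
  res <- outcome_split_accuracy(correct_flag, outcomes)
  expect_true(res$testable)
  expect_lt(res$accuracy_pre_fa, res$accuracy_pre_cr)
  expect_lt(res$fisher_p, 0.05)
  # all-CR input is not testable
  res0 <- outcome_split_accuracy(correct_flag, rep("CR",
                                                   length(correct_flag)))
  expect_false(res0$testable)
})

test_that("task and cue decodability are coupled through the shared gain", {
  set.seed(68)
  # shared gain: correlated correctness indicators, averaged across
  # experiments as in the per-experiment correlation analysis
  rs <- vapply(1:8, function(e) {
    ex <- sim_experiment(700, neural_params(gain_shared = 0.9,
                                            code_amplitude = 0.2,
                                            noise_sigma = 0.2,
                                            code_trial_cv = 0.8))
    f <- delay_features(ex)
    tr <- f$trials
    # task correctness from decoding over both tasks, restricted afterwards
    # to the WM trials on which the cue decoder also runs
    dec_task <- loo_decode(f$X[f$ok, ], tr$task[f$ok],
                           positive_class = "WM")
    task_correct <- rep(NA, nrow(tr))
    task_correct[f$ok] <- dec_task$per_trial$correct
    dec_cue <- loo_decode(f$X[f$wm_cue, ], tr$prev_stim_class[f$wm_cue],
                          positive_class = "B")
    conditional_cue_accuracy(task_correct[f$wm_cue],
                             dec_cue$per_trial$correct)$pearson_r
  }, numeric(1))
  expect_gt(mean(rs), 0)
  # identical correctness vectors: r = 1
  v <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(conditional_cue_accuracy(v, v)$pearson_r, 1)
  # degenerate all-correct task decoder: split not testable
  cc0 <- conditional_cue_accuracy(rep(TRUE, 5), v)
  expect_false(cc0$testable)
})
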