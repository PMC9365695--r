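test_that("pooled trial averages have the right shape and arithmetic", {
  set.seed(50)
  cfg <- analysis_config()
  exs <- lapply(1:2, function(i) {
    s <- two_task_session(120)
    store <- simulate_population(s, neural_params(n_cells = 5,
                                                  n_noise_factors = 0), cfg)
    experiment_trial_averages(filter_trials(s, cfg, imaging = TRUE), store,
                              cfg)
  })
  pooled <- pool_trial_averages(exs)
  expect_identical(nrow(pooled$matrix), 10L)
  expect_identical(ncol(pooled$matrix),
                   pooled$n_delay_frames + pooled$n_stim_frames)

  # hand-computed oracle on a 3-trial toy: the column means of aligned
  # windows must match direct arithmetic
  tr <- data.frame(
    trial_index = 1:3, task = "WM", rotation = "NONE", trial_type = "cue",
    cue_identity = "A", stimulus_orientation = -45,
    delay_ms = 1000, stimulus_ms = 1000, lick_latency_ms = NA_real_,
    outcome = NA_character_, opto_epoch = "none", opto_area = NA_character_,
    halted = FALSE, early_lick = FALSE)
  s <- session_table(tr, frame_rate_hz = 2)
  act <- matrix(seq_len(2 * 12), nrow = 2)  # 2 cells, 12 frames at 500 ms
  store <- activity_store(act, seq(0, by = 500, length.out = 12),
                          frame_rate_hz = 2)
  av <- experiment_trial_averages(s, store, analysis_config(),
                                  stim_window_ms = 1000)
  # delay windows start at frames 1, 5, 9 (trials are 2 s apart); first
  # delay frame position averages activity columns 1, 5, 9
  expect_equal(av$delay[, 1], rowMeans(act[, c(1, 5, 9)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(av$delay[, 2], rowMeans(act[, c(2, 6, 10)]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # a constant-activity cell stays a constant row
  act2 <- act; act2[1, ] <- 7
  st2 <- activity_store(act2, seq(0, by = 500, length.out = 12),
                        frame_rate_hz = 2)
  av2 <- experiment_trial_averages(s, st2, analysis_config())
  expect_true(all(av2$delay[1, ] == 7))
})

test_that("fit_pcs handles planted rank, isotropy and is idempotent", {
  set.seed(51)
  # planted rank-3 structure plus small noise
  L <- matrix(rnorm(60 * 3), 60)
  tc <- matrix(rnorm(3 * 40), 3)
  m <- L %*% tc + matrix(rnorm(60 * 40, 0, 0.1), 60)
  pcs <- fit_pcs(m)
  expect_gte(sum(pcs$var_explained[1:3]), 0.75)
  expect_true(all(diff(pcs$var_explained) <= 1e-12))
  # isotropic noise: variance fractions are all close to 1/min(dim)
  iso <- fit_pcs(matrix(rnorm(30 * 2000), 30))
  expect_true(all(abs(iso$var_explained - 1 / 30) < 0.01))
  # PCA of PCA projections is the identity rotation up to sign
  Xc <- scale(t(m), center = TRUE, scale = FALSE)
  proj <- Xc %*% pcs$rotation[, 1:5]
  pcs2 <- fit_pcs(t(proj))
  expect_equal(abs(pcs2$rotation), diag(5), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("trajectories are identical for identical activity and separate under a planted offset", {
  set.seed(52)
  cfg <- analysis_config()
  s <- two_task_session(400)
  # no task/cue codes: the two tasks share the same generative process
  np0 <- neural_params(n_cells = 40, code_amplitude = 0,
                       n_noise_factors = 0, noise_sigma = 0)
  store0 <- simulate_population(s, np0, cfg)
  sf <- filter_trials(s, cfg, imaging = TRUE)
  av <- experiment_trial_averages(sf, store0, cfg)
  pcs <- fit_pcs(pool_trial_averages(list(av))$matrix)
  tj <- project_trajectories(sf, store0, pcs, cfg,
                             delay_groups = list(c(800, 1600)))
  expect_lt(max(abs(tj$WM[["800-1600"]]$raw$delay[1:3, ] -
                      tj$DISC[["800-1600"]]$raw$delay[1:3, ])), 0.1)

  # a planted task offset ALONG A DOMINANT MODE separates the trajectories
  # by about its norm (an offset outside the top PCs would be invisible
  # here, which is the point of the coding-dimension analyses)
  gt0 <- attr(store0, "ground_truth")
  u <- gt0$bump_loadings[, 1]
  u <- u / sqrt(sum(u^2))
  store1 <- store0
  amp <- 1
  mid <- store1$frame_times_ms + 500 / store1$frame_rate_hz
  for (i in which(sf$trials$task == "WM")) {
    cols <- which(mid >= sf$trials$delay_onset_ms[i] &
                    mid < sf$trials$stim_onset_ms[i])
    store1$activity[, cols] <- store1$activity[, cols] + amp * u
  }
  pcs1 <- fit_pcs(pool_trial_averages(list(
    experiment_trial_averages(sf, store1, cfg)))$matrix)
  pr <- single_trial_projections(sf, store1, pcs1, cfg)
  d <- delaycode:::.task_distance(pr$proj, pr$task)
  d_delay <- mean(d[seq_len(pr$n_delay_frames)], na.rm = TRUE)
  expect_gt(d_delay, 0.5 * amp)
  expect_lt(d_delay, 1.5 * amp)
})

test_that("display smoothing is causal and never touches the statistics path", {
  # impulse response of the half-normal filter has no mass before the impulse
  x <- matrix(0, 20, 1)
  x[10, 1] <- 1
  sm <- delaycode:::.half_normal_smooth(x, sigma_ms = 100, frame_ms = 50)
  expect_true(all(sm[1:9, 1] == 0))
  expect_gt(sm[10, 1], sm[11, 1])
  expect_true(all(sm[10:13, 1] > 0))

  set.seed(53)
  cfg <- analysis_config()
  s <- two_task_session(260)
  store <- simulate_population(s, neural_params(n_cells = 30,
                                                n_noise_factors = 0), cfg)
  sf <- filter_trials(s, cfg, imaging = TRUE)
  pcs <- fit_pcs(pool_trial_averages(list(
    experiment_trial_averages(sf, store, cfg)))$matrix)
  raws <- lapply(c(50, 100, 200), function(sg)
    project_trajectories(sf, store, pcs, cfg,
                         delay_groups = list(c(800, 1600)),
                         smooth_sigma_ms = sg)$WM[["800-1600"]]$raw$delay)
  expect_identical(raws[[1]], raws[[2]])
  expect_identical(raws[[2]], raws[[3]])
})

test_that("task-trajectory distance is invariant to rotations of the PC basis", {
  set.seed(54)
  arr <- array(rnorm(40 * 12 * 3), c(40, 12, 3))
  task <- rep(c("WM", "DISC"), 20)
  d0 <- delaycode:::.task_distance(arr, task)
  qr_rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  arr_rot <- array(NA_real_, dim(arr))
  for (t in 1:12) arr_rot[, t, ] <- arr[, t, ] %*% qr_rot
  expect_equal(delaycode:::.task_distance(arr_rot, task), d0,
               tolerance = 1e-10)
})

test_that("trajectory distances sit inside the shuffle null without a code and outside with one", {
  set.seed(55)
  # comparisons are restricted to matched-input trials (identical displayed
  # stimuli in both tasks), so a generator without codes is a true null
  mk_proj <- function(amp) {
    do.call(c, lapply(1:2, function(i)
      matched_projections(400, offset_amp = amp)))
  }
  null_res <- trajectory_distance_with_null(mk_proj(0), n_shuffles = 300)
  # single-draw sanity check; the calibrated coverage over repeated
  # simulations is asserted in the acceptance suite
  inside <- null_res$distance >= null_res$null_ci[1, ] &
    null_res$distance <= null_res$null_ci[2, ]
  expect_gte(mean(inside, na.rm = TRUE), 0.7)
  expect_lte(sum(null_res$significant, na.rm = TRUE), 1)
  # Bonferroni divisor reflects the realized timepoint count
  expect_equal(null_res$alpha_corrected,
               0.05 / length(null_res$distance))

  # planted strong separation: most delay timepoints significant
  sep <- trajectory_distance_with_null(mk_proj(3), n_shuffles = 300)
  kd <- 10
  expect_gte(mean(sep$significant[1:kd], na.rm = TRUE), 0.8)
})

test_that("eigenspectra differ only when one task has planted extra variance", {
  set.seed(56)
  X <- matrix(rnorm(300 * 40), 300)
  task <- rep(c("WM", "DISC"), each = 150)
  same <- eigenspectrum_compare(X, task, n_shuffles = 200)
  expect_lte(sum(same$significant), 1)
  # identical datasets give identical spectra
  dup <- eigenspectrum_compare(rbind(X, X), rep(c("WM", "DISC"),
                                                each = 300),
                               n_shuffles = 50)
  expect_equal(dup$spectra[[1]], dup$spectra[[2]], tolerance = 1e-8)
  # rank-1 planted difference is detected
  X2 <- X
  u <- rnorm(40); u <- u / sqrt(sum(u^2))
  X2[task == "WM", ] <- X2[task == "WM", ] +
    outer(rnorm(150, 0, 2), u)
  diff <- eigenspectrum_compare(X2, task, n_shuffles = 200)
  expect_true(diff$significant[1])
})
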