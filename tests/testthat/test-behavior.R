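test_that("outcomes follow the 1 s response-window rule", {
  tr <- data.frame(
    trial_index = 1:5,
    task = "WM", rotation = "NONE",
    trial_type = c("target", "cue", "probe", "target", "cue"),
    cue_identity = NA_character_, stimulus_orientation = 45,
    delay_ms = 1500, stimulus_ms = 2000,
    lick_latency_ms = c(400, 1200, NA, NA, 350),
    outcome = NA_character_, opto_epoch = "none",
    opto_area = NA_character_, halted = FALSE, early_lick = FALSE)
  s <- classify_outcomes(session_table(tr))
  expect_identical(s$trials$outcome, c("hit", "CR", "CR", "miss", "FA"))
  tr$lick_latency_ms[1] <- -5
  expect_error(classify_outcomes(session_table(tr)), "negative")
})

test_that("d-prime matches the inverse-normal definition and its symmetries", {
  expect_equal(dprime(0.841345, 0.158655), 2, tolerance = 1e-4)
  expect_equal(dprime(0.5, 0.5), 0)
  expect_identical(dprime(1, 0.2), Inf)
  expect_error(dprime(1.2, 0.5), "\\[0, 1\\]")
  for (x in c(0.1, 0.35, 0.8)) {
    for (y in c(0.2, 0.6)) {
      expect_equal(dprime(x, y), -dprime(y, x))
    }
    expect_equal(dprime(x, x), 0)
  }
})

test_that("d-prime decreases across delay quartiles only under a delay-dependent FA model", {
  set.seed(30)
  mk <- function(slope, n_mice = 8, n_tr = 8000) {
    trials <- do.call(rbind, lapply(seq_len(n_mice), function(m) {
      s <- generate_trials(n_tr, task_params(opto_fraction = 0),
                           task_schedule = "WM")
      s <- simulate_responses(s, behavior_params(fa_slope_per_s = slope))
      tr <- filter_trials(s)$trials
      tr$mouse_id <- paste0("m", m)
      tr
    }))
    trials
  }
  wm <- dprime_by_delay_quartile(mk(0.119))
  d <- wm$pooled$dprime
  expect_true(all(diff(d) < 0))
  # the adjacent-quartile step is shallow, but across mice the first-to-last
  # quartile drop is reliable
  expect_lt(stats::wilcox.test(wm$per_mouse[, 1], wm$per_mouse[, 4],
                               paired = TRUE, exact = FALSE,
                               alternative = "greater")$p.value, 0.05)
  expect_length(wm$adjacent_tests, 3)
  # null slope: adjacent quartiles indistinguishable (allow one chance hit)
  null <- dprime_by_delay_quartile(mk(0, n_tr = 4000))
  expect_lte(sum(null$adjacent_tests < 0.05), 1)
  # quartiles without misses are reported missing, not infinite
  few <- mk(0)[1:400, ]
  few$outcome[few$trial_type == "target"] <- "hit"
  q <- dprime_by_delay_quartile(few)
  expect_true(all(is.na(q$pooled$dprime)))
  expect_true(all(q$pooled$infinite))
})

test_that("response curves recover constant and sloped generators", {
  set.seed(31)
  s <- generate_trials(4e4, task_params(opto_fraction = 0),
                       task_schedule = "WM")
  s <- simulate_responses(s, behavior_params(fa_base = 0.2,
                                             fa_slope_per_s = 0))
  tr <- filter_trials(s)$trials
  rc <- response_curve(tr, "cue")
  expect_lt(abs(rc$slope_pct_per_s), 0.6)
  expect_true(all(rc$curve$ci_lo <= rc$curve$rate &
                    rc$curve$rate <= rc$curve$ci_hi))
  # single-bin input: slope undefined, reported missing
  one <- tr[tr$trial_type == "cue", ][1:50, ]
  one$delay_ms <- 1000
  expect_true(is.na(response_curve(one, "cue")$slope_pct_per_s))
})

test_that("reaction-time peaks recover the planted WM lags within one bin", {
  set.seed(32)
  # latency mean at a bin center and a tight spread keep the histogram mode
  # identifiable to one bin
  bp <- behavior_params(rt_mean_ms = 458, rt_sd_ms = 30,
                        rt_shift_wm_ms = 163, rt_shift_wm_target_ms = 70)
  s <- two_task_session(4e4)
  s <- simulate_responses(s, bp)
  tr <- filter_trials(s, drop_opto = TRUE)$trials
  cue_lag <- rt_peak_lag(tr, "cue")
  expect_equal(cue_lag$lag_ms, 163, tolerance = 17 / 163)
  tgt_lag <- rt_peak_lag(tr, "target")
  expect_equal(tgt_lag$lag_ms, 70, tolerance = 17 / 70)
  # no shift: lag within one bin of zero
  set.seed(33)
  s0 <- two_task_session(2e4)
  s0 <- simulate_responses(s0, behavior_params(rt_mean_ms = 458,
                                               rt_sd_ms = 30,
                                               rt_shift_wm_ms = 0,
                                               rt_shift_wm_target_ms = 0))
  tr0 <- filter_trials(s0, drop_opto = TRUE)$trials
  expect_lte(abs(rt_peak_lag(tr0, "cue")$lag_ms), 1000 / 60 + 1e-9)
  expect_error(rt_peak_lag(tr0[1:80, ], "cue"), "insufficient")
})

test_that("Fisher p-values equal exhaustive hypergeometric enumeration", {
  # the printed example: 10/10 vs 0/10 responders
  expect_equal(stats::fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               fisher_oracle_p(10, 10, 0, 10), tolerance = 1e-9)
  expect_equal(fisher_oracle_p(10, 10, 0, 10), 1.082509e-05,
               tolerance = 1e-4)
  # random tables with margins up to 40
  set.seed(34)
  for (i in 1:300) {
    n_s <- sample(2:40, 1); n_c <- sample(2:40, 1)
    k_s <- sample(0:n_s, 1); k_c <- sample(0:n_c, 1)
    expect_equal(
      stats::fisher.test(matrix(c(k_s, n_s - k_s, k_c, n_c - k_c), 2))$p.value,
      fisher_oracle_p(k_s, n_s, k_c, n_c), tolerance = 1e-7)
  }
})

test_that("silencing effect table reports stratum differences, CIs and adjusted p", {
  set.seed(35)
  s <- two_task_session(5e4, opto_fraction = 0.08)
  s <- simulate_responses(s, behavior_params(opto_fa_boost = 0.3,
                                             opto_recovery_ms = Inf))
  tr <- filter_trials(s)$trials
  tab <- opto_effect_table(tr)
  eff <- tab$effects
  expect_true(all(eff$fisher_p[eff$testable] > 0))
  expect_true(all(eff$fisher_p_adj[eff$testable] >=
                    eff$fisher_p[eff$testable] - 1e-12))
  # the planted effect: WM cue FAs increase under delay-onset silencing
  row <- eff[eff$task == "WM" & eff$trial_type == "cue" &
               eff$epoch == "delay_onset", ]
  expect_gt(row$rate_diff_pp, 15)
  expect_lt(row$fisher_p_adj, 0.001)
  # probes and the Discrimination task are untouched
  null_rows <- eff[eff$testable &
                     !(eff$task == "WM" & eff$trial_type == "cue" &
                         eff$epoch == "delay_onset"), ]
  expect_true(all(abs(null_rows$rate_diff_pp) < 12))
  # performance map = 100 - FA% - miss%: silencing lowers WM performance
  perf <- tab$performance
  expect_lt(perf$perf_diff_pp[perf$task == "WM" &
                                perf$epoch == "delay_onset"], -10)
})

test_that("identical response rates in both arms give zero difference and p near 1", {
  set.seed(36)
  s <- two_task_session(5e4, opto_fraction = 0.08)
  s <- simulate_responses(s, behavior_params(opto_fa_boost = 0))
  tr <- filter_trials(s)$trials
  eff <- opto_effect_table(tr)$effects
  testable <- eff[eff$testable, ]
  expect_true(all(abs(testable$rate_diff_pp) < 12))
  expect_gt(min(testable$fisher_p), 0.001)
})
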