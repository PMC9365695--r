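# Shared fixture builders. Everything is generated in code; no stored data.

# Two-task imaging-style session with blocks short enough that every schedule
# appears even in small sessions.
two_task_session <- function(n, block = 100, opto_fraction = 0, ...) {
  generate_trials(
    n, task_params(opto_fraction = opto_fraction, ...),
    task_schedule = rep(rep(c("DISC", "WM"), each = block),
                        length.out = n),
    rotation_schedule = rep(rep(c("CW", "CCW"), each = 3 * block / 2),
                            length.out = n))
}

# Session + population + filtered view, the common entry point for decoding
# tests.
sim_experiment <- function(n = 600, np = neural_params(),
                           cfg = analysis_config(), opto_fraction = 0,
                           bp = behavior_params()) {
  s <- two_task_session(n, opto_fraction = opto_fraction)
  s <- simulate_responses(s, bp)
  store <- simulate_population(s, np, cfg)
  sf <- filter_trials(s, cfg, imaging = TRUE)
  list(session = s, filtered = sf, store = store,
       gt = attr(store, "ground_truth"), cfg = cfg)
}

# delay-averaged features and labels for one simulated experiment
delay_features <- function(ex) {
  X <- epoch_means(ex$filtered, ex$store, "delay")
  tr <- ex$filtered$trials
  list(X = X, trials = tr,
       ok = rowSums(is.na(X)) == 0,
       wm_cue = rowSums(is.na(X)) == 0 & tr$task == "WM" &
         tr$prev_stim_class %in% c("A", "B"))
}

# One axonal-imaging experiment: WM-only session with delay-onset silencing,
# axon traces carrying bouton-average-level noise (sigma/sqrt(8), the noise of
# an eight-bouton average).
axon_experiment <- function(recovery_ms, n_trials = 110, n_axons = 24,
                            fa_boost = 0.4, cfg = analysis_config()) {
  s <- generate_trials(n_trials,
                       task_params(opto_fraction = 0.15,
                                   opto_epochs = "delay_onset",
                                   opto_areas = "AM"),
                       task_schedule = "WM", frame_rate_hz = 22.78)
  s <- simulate_responses(s, behavior_params(opto_fa_boost = fa_boost,
                                             opto_recovery_ms = recovery_ms))
  sim <- simulate_boutons(
    s,
    axon_params(n_axons = n_axons, boutons_per_axon_mean = 1,
                bouton_noise_sigma = 0.3 / sqrt(8),
                silencing_recovery_ms = recovery_ms),
    np = neural_params(frame_rate_hz = 22.78, n_noise_factors = 10,
                       noise_sigma = 0),
    cfg)
  list(session = s,
       store = activity_store(sim$boutons$activity,
                              sim$boutons$frame_times_ms,
                              signal_kind = "axon", frame_rate_hz = 22.78))
}

# Behavior-only silencing experiment (pooled for the robustness analyses).
behavior_experiment <- function(recovery_ms, n_trials = 160,
                                fa_boost = 0.4) {
  s <- generate_trials(n_trials,
                       task_params(opto_fraction = 0.15,
                                   opto_epochs = "delay_onset",
                                   opto_areas = "AM"),
                       task_schedule = "WM")
  simulate_responses(s, behavior_params(opto_fa_boost = fa_boost,
                                        opto_recovery_ms = recovery_ms))
}

# one full silencing simulation: axonal CD effects + pooled behavior
silencing_simulation <- function(recovery_ms, n_ax = 12, n_beh = 40,
                                 cfg = analysis_config()) {
  exps <- lapply(seq_len(n_ax), function(i) axon_experiment(recovery_ms))
  fb <- feedback_cd_timecourse(exps, cfg)
  trials <- do.call(rbind, lapply(seq_len(n_beh), function(i) {
    tr <- filter_trials(behavior_experiment(recovery_ms), cfg)$trials
    tr$experiment <- i
    tr
  }))
  bb <- behavioral_robustness(trials)
  list(fb = fb, bb = bb)
}

# Projections for the task-trajectory distance analyses: experiments with
# matched cue orientations, restricted to trials following identical sensory
# input. `offset_amp` plants a task offset along a dominant (bump) mode of
# WM-trial delay activity.
matched_projections <- function(n_trials = 400,
                                np = neural_params(n_cells = 25,
                                                   code_amplitude = 0,
                                                   n_noise_factors = 0,
                                                   noise_sigma = 0.2),
                                cfg = analysis_config(), offset_amp = 0) {
  s <- two_task_session(n_trials)
  store <- simulate_population(s, np, cfg)
  if (offset_amp > 0) {
    u <- attr(store, "ground_truth")$bump_loadings[, 1]
    u <- u / sqrt(sum(u^2))
    mid <- store$frame_times_ms + 500 / store$frame_rate_hz
    for (k in which(s$trials$task == "WM")) {
      cols <- which(mid >= s$trials$delay_onset_ms[k] &
                      mid < s$trials$stim_onset_ms[k])
      store$activity[, cols] <- store$activity[, cols] + offset_amp * u
    }
  }
  sf <- filter_trials(s, cfg, imaging = TRUE)
  out <- lapply(define_experiments(sf), function(e) {
    se <- subset_experiment(sf, e)
    keep <- matched_input_trials(se, e$orientation)
    if (length(unique(se$trials$task[keep])) < 2L || sum(keep) < 10L) {
      return(NULL)
    }
    se$trials <- se$trials[keep, , drop = FALSE]
    pcs <- fit_pcs(pool_trial_averages(list(
      experiment_trial_averages(se, store, cfg)))$matrix)
    single_trial_projections(se, store, pcs, cfg)
  })
  Filter(Negate(is.null), out)
}

# independent hypergeometric oracle for the two-sided Fisher exact p-value:
# sum of the probabilities of all tables (at fixed margins) no more probable
# than the observed one
fisher_oracle_p <- function(k_s, n_s, k_c, n_c) {
  m <- k_s + k_c
  lo <- max(0L, m - n_c)
  hi <- min(n_s, m)
  probs <- stats::dhyper(lo:hi, n_s, n_c, m)
  obs <- stats::dhyper(k_s, n_s, n_c, m)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# numerical-integration oracle for the delay distribution: offset+Exp(mean),
# values beyond the cap resampled uniformly on [lo, hi]
delay_moment_oracle <- function(moment = 1, offset = 800, mean_ms = 800,
                                cap = 4000, lo = 3600, hi = 4000) {
  p_resample <- exp(-(cap - offset) / mean_ms)
  trunc_part <- stats::integrate(function(x)
    x^moment * stats::dexp(x - offset, 1 / mean_ms),
    lower = offset, upper = cap, rel.tol = 1e-10)$value
  unif_part <- p_resample * stats::integrate(function(x)
    x^moment / (hi - lo), lower = lo, upper = hi, rel.tol = 1e-10)$value
  trunc_part + unif_part
}
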