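# Task-sequence generator: Markov trial types (cue 80% / probe 10% / target
# 10%, with a mandatory cue after every probe or target), exponential-plus-
# offset delay durations capped by uniform resampling, and optogenetic
# silencing flags.

#' Task-structure parameters
#'
#' Defaults reproduce the task design emulated here: trial types drawn cue/probe/target with
#' probabilities 0.8/0.1/0.1 except that a cue is mandatory after a probe or a
#' target; delays are 800 ms plus an Exponential(mean 800 ms) draw, capped at
#' 4000 ms by resampling from Uniform(3600, 4000) ms; silencing occurs on a
#' fixed fraction of trials (8% in behavioral sessions over the two analyzed
#' onsets, 15% at delay onset in axonal-imaging sessions) at one of the listed
#' onsets.
#'
#' @param p_cue,p_probe,p_target Trial-type probabilities after a cue; must sum
#'   to 1.
#' @param delay_mean_ms Mean of the exponential delay component, ms.
#' @param delay_offset_ms Minimum delay duration, ms.
#' @param delay_cap_ms Delay cap, ms.
#' @param resample_lo_ms,resample_hi_ms Uniform resampling interval applied
#'   when the cap is exceeded, ms.
#' @param opto_fraction Fraction of trials with optogenetic silencing.
#' @param opto_epochs Character vector of silencing onsets, drawn uniformly on
#'   silenced trials.
#' @param opto_areas Areas targeted, drawn uniformly on silenced trials.
#' @param stimulus_median_ms Median stimulus duration, ms. Stimulus duration is
#'   running-speed-dependent in the experiment (a distance to traverse) and is
#'   emulated as lognormal around this median.
#' @param stimulus_sigma_log Log-scale SD of the stimulus duration.
#' @param halt_prob,early_lick_prob Per-trial probabilities of halting or
#'   licking during the delay (such trials are excluded from analyses).
#' @return An object of class `task_params`.
#' @export
task_params <- function(p_cue = 0.8, p_probe = 0.1, p_target = 0.1,
                        delay_mean_ms = 800, delay_offset_ms = 800,
                        delay_cap_ms = 4000,
                        resample_lo_ms = 3600, resample_hi_ms = 4000,
                        opto_fraction = 0.08,
                        opto_epochs = c("delay_onset", "stim_onset"),
                        opto_areas = "AM",
                        stimulus_median_ms = 1967,
                        stimulus_sigma_log = 0.2,
                        halt_prob = 0.02, early_lick_prob = 0.012) {
  stopifnot(abs(p_cue + p_probe + p_target - 1) < 1e-12,
            resample_lo_ms < resample_hi_ms,
            resample_hi_ms <= delay_cap_ms,
            opto_fraction >= 0, opto_fraction <= 1)
  structure(as.list(environment()), class = "task_params")
}

#' Sample inter-stimulus delay durations
#'
#' Delays are `offset + Exponential(mean)`; draws beyond the cap are replaced
#' by a uniform draw on the resampling interval, which keeps the average delay
#' close to the nominal 1600 ms.
#'
#' @param n Number of delays.
#' @param params A [task_params()].
#' @return Numeric vector of delays in `[offset, cap]`, ms.
#' @export
sample_delay <- function(n, params = task_params()) {
  d <- params$delay_offset_ms + stats::rexp(n, rate = 1 / params$delay_mean_ms)
  over <- d > params$delay_cap_ms
  n_over <- sum(over)
  if (n_over > 0L) {
    d[over] <- stats::runif(n_over, params$resample_lo_ms,
                            params$resample_hi_ms)
  }
  d
}

#' Generate a synthetic session of task trials
#'
#' Draws trial types from the Markov rule (cue/probe/target with the stated
#' probabilities after a cue; a cue with probability 1 after a probe or a
#' target), assigns stimulus orientations by task and rotation block, tracks
#' the WM cue/target contingency (the cue orientation mirrors the current
#' target and switches only after a target), samples delays and stimulus
#' durations, and flags silenced/halted/early-lick trials. Outcomes are left
#' unassigned; see [simulate_responses()].
#'
#' @param n Number of trials.
#' @param params A [task_params()].
#' @param task_schedule Character vector (recycled to length `n`) of task
#'   labels per trial, or a single task. Default alternates `DISC`/`WM` in
#'   blocks of 415 trials.
#' @param rotation_schedule Rotation block label per trial (recycled), one of
#'   `CW`, `CCW`, `NONE`. Default alternates CW/CCW in blocks out of phase with
#'   the task blocks (block length 250), as in imaging sessions.
#' @param base_cue_orientation Absolute value of the base (unrotated) WM
#'   cue/target orientation, degrees (30 in imaging sessions, 45 otherwise).
#' @param mouse_id,area,frame_rate_hz Session metadata.
#' @return A [session_table()].
#' @export
generate_trials <- function(n, params = task_params(),
                            task_schedule = NULL, rotation_schedule = NULL,
                            base_cue_orientation = 30,
                            mouse_id = "sim", area = "AM",
                            frame_rate_hz = 4.68) {
  stopifnot(n >= 1)
  if (is.null(task_schedule)) {
    task_schedule <- rep(c("DISC", "WM"), each = 415, length.out = n)
  }
  task <- rep(as.character(task_schedule), length.out = n)
  if (is.null(rotation_schedule)) {
    rotation_schedule <- rep(rep(c("CW", "CCW"), each = 250), length.out = n)
  }
  rotation <- rep(as.character(rotation_schedule), length.out = n)

  # Markov trial types: state = previous type
  u <- stats::runif(n)
  type <- character(n)
  prev <- "cue"
  for (i in seq_len(n)) {
    if (prev %in% c("probe", "target")) {
      type[i] <- "cue"
    } else {
      type[i] <- if (u[i] < params$p_cue) "cue" else
        if (u[i] < params$p_cue + params$p_probe) "probe" else "target"
    }
    prev <- type[i]
  }

  # WM contingency: current target identity flips after each target; the cue
  # mirrors the current target. Identity A = negative base orientation.
  target_id <- character(n)
  cur <- sample(c("A", "B"), 1L)
  for (i in seq_len(n)) {
    target_id[i] <- cur
    if (type[i] == "target") cur <- if (cur == "A") "B" else "A"
  }
  mirror <- ifelse(target_id == "A", "B", "A")

  rot <- ifelse(rotation == "CW", -15, ifelse(rotation == "CCW", 15, 0))
  id_sign <- function(id) ifelse(id == "A", -1, 1)
  orientation <- numeric(n)
  cue_identity <- rep(NA_character_, n)
  is_cue <- type == "cue"
  is_probe <- type == "probe"
  is_target <- type == "target"
  # probes: horizontal, never rotated
  orientation[is_probe] <- 90
  # targets: the task's go orientation (WM: current target identity; DISC:
  # either mirrored orientation at random)
  disc_target_id <- sample(c("A", "B"), n, replace = TRUE)
  tid <- ifelse(task == "WM", target_id, disc_target_id)
  orientation[is_target] <-
    (id_sign(tid) * base_cue_orientation + rot)[is_target]
  # cues: DISC vertical (0 deg base); WM mirrored relative to current target
  wm_cue <- task == "WM" & is_cue
  disc_cue <- task == "DISC" & is_cue
  orientation[disc_cue] <- rot[disc_cue]
  orientation[wm_cue] <- (id_sign(mirror) * base_cue_orientation + rot)[wm_cue]
  cue_identity[wm_cue] <- mirror[wm_cue]

  opto <- stats::runif(n) < params$opto_fraction
  opto_epoch <- rep("none", n)
  opto_epoch[opto] <- sample(params$opto_epochs, sum(opto), replace = TRUE)
  opto_area <- rep(NA_character_, n)
  opto_area[opto] <- sample(params$opto_areas, sum(opto), replace = TRUE)

  trials <- data.frame(
    trial_index = seq_len(n),
    task = task, rotation = rotation, trial_type = type,
    cue_identity = cue_identity,
    stimulus_orientation = orientation,
    delay_ms = sample_delay(n, params),
    stimulus_ms = stats::rlnorm(n, log(params$stimulus_median_ms),
                                params$stimulus_sigma_log),
    lick_latency_ms = NA_real_,
    outcome = NA_character_,
    opto_epoch = opto_epoch, opto_area = opto_area,
    halted = stats::runif(n) < params$halt_prob,
    early_lick = stats::runif(n) < params$early_lick_prob,
    stringsAsFactors = FALSE)
  session_table(trials, mouse_id = mouse_id, area = area,
                frame_rate_hz = frame_rate_hz)
}

#' Behavioral-response parameters
#'
#' The false-alarm model is linear in the preceding delay duration for WM-task
#' cues (the signature of decaying working memory) and delay-independent for
#' Discrimination-task cues and for probes in both tasks; probabilities are
#' clipped to \[0, 1\].
#'
#' @param fa_base Baseline false-alarm probability (at zero delay).
#' @param fa_slope_per_s Increase in WM cue false-alarm probability per second
#'   of delay (default 0.119/s).
#' @param probe_fa Delay-independent probe false-alarm probability.
#' @param hit_rate Probability of licking to a target (before lapses).
#' @param lapse Lapse probability on go trials.
#' @param rt_mean_ms Mean lick latency, ms.
#' @param rt_sd_ms Lick latency SD, ms.
#' @param rt_shift_wm_ms Additional WM-task latency to cues, ms (default 163).
#' @param rt_shift_wm_target_ms Additional WM-task latency to targets, ms
#'   (default 70).
#' @param opto_fa_boost Added WM cue false-alarm probability when the memory
#'   was erased by delay-onset silencing and has not recovered by stimulus
#'   onset.
#' @param opto_recovery_ms Time after delay onset at which the silenced memory
#'   recovers (`Inf` for no recovery).
#' @param code_coupling Strength of the coupling between the neural cue-code
#'   gain and behavior: on WM cue trials the false-alarm probability increases
#'   by `code_coupling * max(0, 1 - gain)` when a per-trial gain is supplied to
#'   [simulate_responses()].
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(fa_base = 0.08, fa_slope_per_s = 0.119,
                            probe_fa = 0.15, hit_rate = 0.95, lapse = 0.02,
                            rt_mean_ms = 450, rt_sd_ms = 60,
                            rt_shift_wm_ms = 163,
                            rt_shift_wm_target_ms = 70,
                            opto_fa_boost = 0, opto_recovery_ms = Inf,
                            code_coupling = 0) {
  stopifnot(fa_base >= 0, fa_base <= 1, probe_fa >= 0, probe_fa <= 1,
            hit_rate >= 0, hit_rate <= 1, lapse >= 0, lapse <= 1)
  structure(as.list(environment()), class = "behavior_params")
}

#' Simulate behavioral responses and outcomes
#'
#' Assigns lick latencies and outcomes to every trial: targets become hits or
#' misses (hit probability `hit_rate * (1 - lapse)`), cues and probes become
#' false alarms or correct rejections. WM cue false alarms increase linearly
#' with the preceding delay duration; Discrimination cues and probes are
#' delay-independent. Delay-onset silencing raises WM cue false alarms by
#' `opto_fa_boost` unless the delay outlasts `opto_recovery_ms`.
#'
#' @param session A [session_table()] from [generate_trials()].
#' @param bp A [behavior_params()].
#' @param cue_code_gain Optional per-trial neural cue-code gain (same length as
#'   trials) coupling code collapse to errors via `bp$code_coupling`.
#' @return The session with `outcome` and `lick_latency_ms` populated.
#' @export
simulate_responses <- function(session, bp = behavior_params(),
                               cue_code_gain = NULL) {
  stopifnot(inherits(session, "session_table"))
  tr <- session$trials
  n <- nrow(tr)
  delay_s <- tr$delay_ms / 1000
  p_lick <- numeric(n)
  is_cue <- tr$trial_type == "cue"
  is_probe <- tr$trial_type == "probe"
  is_target <- tr$trial_type == "target"
  wm <- tr$task == "WM"
  p_lick[is_cue & !wm] <- bp$fa_base
  p_lick[is_cue & wm] <- bp$fa_base + bp$fa_slope_per_s * delay_s[is_cue & wm]
  p_lick[is_probe] <- bp$probe_fa
  p_lick[is_target] <- bp$hit_rate * (1 - bp$lapse)
  silenced <- tr$opto_epoch == "delay_onset" & wm & is_cue &
    tr$delay_ms < bp$opto_recovery_ms
  p_lick[silenced] <- p_lick[silenced] + bp$opto_fa_boost
  if (!is.null(cue_code_gain) && bp$code_coupling > 0) {
    stopifnot(length(cue_code_gain) == n)
    collapse <- pmax(0, 1 - cue_code_gain)
    p_lick[is_cue & wm] <- p_lick[is_cue & wm] +
      bp$code_coupling * collapse[is_cue & wm]
  }
  p_lick <- pmin(pmax(p_lick, 0), 1)
  lick <- stats::runif(n) < p_lick
  shift <- ifelse(wm & is_cue, bp$rt_shift_wm_ms,
                  ifelse(wm & is_target, bp$rt_shift_wm_target_ms, 0))
  lat <- stats::rnorm(n, bp$rt_mean_ms + shift, bp$rt_sd_ms)
  lat <- pmin(pmax(lat, 1), 999)  # licks land inside the 1 s response window
  tr$lick_latency_ms <- ifelse(lick, lat, NA_real_)
  session$trials <- tr
  classify_outcomes(session)
}
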