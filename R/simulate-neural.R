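# Neural-population generator. The planted structure mirrors what the analyses
# assume about the data:
#   (i)  low-dimensional sequential dynamics -- Gaussian bumps tiling the
#        delay, identical in expectation across tasks;
#   (ii) high-dimensional task and cue codes -- fixed sparse directions
#        orthogonalized against the bump subspace, switched on during WM-task
#        delays, with lognormal trial-to-trial gain and AR(1) persistence
#        between delay halves;
#   (iii) a low-dimensional stimulus-evoked response plus a dense stimulus-
#        identity code confined to the stimulus epoch;
#   (iv) i.i.d. Gaussian noise, with the summed activity rectified at zero.

#' Neural-population parameters
#'
#' @param n_cells Number of cells.
#' @param frame_rate_hz Imaging rate (4.68 Hz for somatic populations,
#'   22.78 Hz for axonal recordings).
#' @param n_seq_bumps Number of sequential delay bumps (the planted rank of the
#'   shared delay dynamics).
#' @param bump_width_ms Gaussian bump SD, ms.
#' @param bump_amplitude Bump loading scale, activity units.
#' @param baseline Constant baseline activity, activity units.
#' @param code_amplitude Amplitude of the task/cue codes along their (unit
#'   norm) directions, activity units.
#' @param code_participation Fraction of cells in each code's support.
#' @param code_trial_cv Coefficient of variation of the lognormal per-trial
#'   code gain.
#' @param gain_shared Fraction of gain variance shared between the task and
#'   cue codes (couples their trial-to-trial fluctuations).
#' @param persistence_rho AR(1) correlation of the code gain between the early
#'   and late halves of the delay.
#' @param noise_sigma I.i.d. noise SD per cell and frame, activity units.
#' @param n_noise_factors Number of shared (correlated) noise modes: latent
#'   frame-by-frame fluctuations along random orthonormal directions,
#'   emulating the large shared variability of cortical populations (in the
#'   emulated regime the top ~100 components carry most of the population
#'   variance). Capped internally at `n_cells - n_seq_bumps - 2`.
#' @param shared_noise_sigma Per-factor SD of the shared noise, activity
#'   units.
#' @param stim_gain Amplitude of the dense stimulus-evoked transient.
#' @param stim_code_amplitude Amplitude of the dense low-dimensional
#'   stimulus-identity code (present during the stimulus epoch only).
#' @return An object of class `neural_params`.
#' @export
neural_params <- function(n_cells = 300, frame_rate_hz = 4.68,
                          n_seq_bumps = 3, bump_width_ms = 500,
                          bump_amplitude = 1, baseline = 1.2,
                          code_amplitude = 0.35, code_participation = 0.5,
                          code_trial_cv = 0.25, gain_shared = 0.5,
                          persistence_rho = 0.7, noise_sigma = 0.15,
                          n_noise_factors = 110, shared_noise_sigma = 1,
                          stim_gain = 1, stim_code_amplitude = 1.5) {
  stopifnot(code_participation >= 0, code_participation <= 1,
            noise_sigma >= 0, persistence_rho >= 0, persistence_rho <= 1,
            gain_shared >= 0, gain_shared <= 1, n_noise_factors >= 0)
  structure(as.list(environment()), class = "neural_params")
}

# sparse random direction orthogonalized against the columns of B, unit norm;
# redraws when the support lies entirely inside span(B) (possible in very
# small populations), and keeps the raw sparse direction if span(B) leaves no
# usable complement
.code_direction <- function(n_cells, participation, B) {
  Q <- if (!is.null(B) && ncol(B) > 0L) qr.Q(qr(B)) else NULL
  for (try in 1:20) {
    support <- sample(n_cells, max(2L, round(participation * n_cells)))
    w <- numeric(n_cells)
    w[support] <- stats::rnorm(length(support))
    if (!is.null(Q)) w <- w - Q %*% crossprod(Q, w)
    nrm <- sqrt(sum(w^2))
    if (nrm > 1e-8) return(as.numeric(w / nrm))
  }
  w <- numeric(n_cells)
  support <- sample(n_cells, max(2L, round(participation * n_cells)))
  w[support] <- stats::rnorm(length(support))
  as.numeric(w / sqrt(sum(w^2)))
}

# lognormal AR(1) gains: per-trial early/late gains with corr(rho) between
# halves and a latent shared across codes
.code_gains <- function(n, cv, rho, shared, n_codes = 2L) {
  sigma <- sqrt(log(1 + cv^2))
  z0e <- stats::rnorm(n)
  z0l <- rho * z0e + sqrt(1 - rho^2) * stats::rnorm(n)
  out <- vector("list", n_codes)
  for (k in seq_len(n_codes)) {
    zke <- stats::rnorm(n)
    zkl <- rho * zke + sqrt(1 - rho^2) * stats::rnorm(n)
    ze <- sqrt(shared) * z0e + sqrt(1 - shared) * zke
    zl <- sqrt(shared) * z0l + sqrt(1 - shared) * zkl
    out[[k]] <- list(early = exp(sigma * ze - sigma^2 / 2),
                     late = exp(sigma * zl - sigma^2 / 2))
  }
  out
}

#' Simulate a somatic population recording for a session
#'
#' @param session A [session_table()] (outcomes need not be assigned).
#' @param np A [neural_params()].
#' @param cfg An [analysis_config()] (supplies the early/late split used by the
#'   AR(1) gain process).
#' @return An [activity_store()] (`signal_kind = "soma"`). The planted ground
#'   truth is attached as `attr(store, "ground_truth")`: code directions
#'   `w_task`, `w_cue`, `w_stim`, bump loadings, per-trial gains (data frame
#'   with `g_task_early/late`, `g_cue_early/late`) and the per-trial cue sign
#'   (`+1` for preceding stimulus class B, `-1` for A, `0` when no mirrored
#'   stimulus preceded the delay).
#' @export
simulate_population <- function(session, np = neural_params(),
                                cfg = analysis_config()) {
  stopifnot(inherits(session, "session_table"), inherits(np, "neural_params"))
  tr <- session$trials
  n_tr <- nrow(tr)
  nc <- np$n_cells
  frame_ms <- 1000 / np$frame_rate_hz
  total_ms <- tr$stim_onset_ms[n_tr] + tr$stimulus_ms[n_tr]
  frame_times <- seq(0, total_ms, by = frame_ms)
  mid <- frame_times + frame_ms / 2
  nf <- length(frame_times)

  # planted structure
  L <- matrix(0, nc, np$n_seq_bumps)
  bump_of <- rep(seq_len(np$n_seq_bumps), length.out = nc)
  L[cbind(seq_len(nc), bump_of)] <-
    np$bump_amplitude * stats::rlnorm(nc, 0, 0.3)
  centers <- (seq_len(np$n_seq_bumps) - 0.5) / np$n_seq_bumps *
    cfg$analysis_delay_cap_ms
  k_shared <- min(np$n_noise_factors, max(0L, nc - np$n_seq_bumps - 2L))
  Fload <- if (k_shared > 0L) {
    qr.Q(qr(matrix(stats::rnorm(nc * k_shared), nc, k_shared)))
  } else NULL
  span <- cbind(L, Fload)
  # WM codes live in the modes uncorrelated with the bumps and the shared
  # noise (high-dimensional embedding); the stimulus-identity code rides a
  # dominant shared mode (low-dimensional embedding)
  w_task <- .code_direction(nc, np$code_participation, span)
  w_cue <- .code_direction(nc, np$code_participation, span)
  w_stim <- if (!is.null(Fload)) Fload[, 1] else
    .code_direction(nc, 1, NULL)
  v_stim <- stats::rlnorm(nc, 0, 0.3)

  gains <- .code_gains(n_tr, np$code_trial_cv, np$persistence_rho,
                       np$gain_shared)
  g_task <- gains[[1]]
  g_cue <- gains[[2]]
  cue_sign <- ifelse(is.na(tr$prev_stim_class), 0,
                     ifelse(tr$prev_stim_class == "B", 1,
                            ifelse(tr$prev_stim_class == "A", -1, 0)))
  # stimulus-evoked identity code follows the DISPLAYED orientation (the
  # sensory input), so stimuli matched in orientation across tasks evoke
  # identical responses; probes (horizontal) carry no identity code
  stim_sign <- ifelse(tr$trial_type == "probe", 0,
                      sign(tr$stimulus_orientation))
  is_wm <- as.numeric(tr$task == "WM")

  # frame-level bookkeeping (vectorized over all frames of the session)
  j <- findInterval(mid, tr$delay_onset_ms)        # trial of each frame
  j[j < 1L] <- 1L
  in_delay <- mid < tr$stim_onset_ms[j]
  in_stim <- !in_delay & mid < tr$stim_onset_ms[j] + tr$stimulus_ms[j]
  rel_delay <- (mid - tr$delay_onset_ms[j]) * in_delay
  late <- in_delay & rel_delay >= cfg$half_split_ms
  g_t <- ifelse(late, g_task$late[j], g_task$early[j])
  g_c <- ifelse(late, g_cue$late[j], g_cue$early[j])
  task_coef <- np$code_amplitude * is_wm[j] * g_t * in_delay
  cue_coef <- np$code_amplitude * is_wm[j] * cue_sign[j] * g_c * in_delay
  bumps <- vapply(centers, function(ctr)
    in_delay * exp(-(rel_delay - ctr)^2 / (2 * np$bump_width_ms^2)),
    numeric(nf))
  rel_stim <- (mid - tr$stim_onset_ms[j]) * in_stim
  kern <- in_stim * exp(-rel_stim / 800)
  stim_coef <- np$stim_code_amplitude * stim_sign[j] * in_stim
  # transient dense stimulus response plus a sustained low-dimensional
  # identity code (stimulus information is carried in high-variance modes)
  act <- np$baseline + L %*% t(bumps) +
    outer(w_task, task_coef) + outer(w_cue, cue_coef) +
    outer(v_stim, np$stim_gain * kern) + outer(w_stim, stim_coef)
  if (!is.null(Fload) && np$shared_noise_sigma > 0) {
    act <- act + Fload %*%
      matrix(stats::rnorm(k_shared * nf, 0, np$shared_noise_sigma),
             k_shared, nf)
  }
  if (np$noise_sigma > 0) {
    act <- act + matrix(stats::rnorm(nc * nf, 0, np$noise_sigma), nc, nf)
  }
  act <- pmax(act, 0)
  store <- activity_store(act, frame_times, signal_kind = "soma",
                          frame_rate_hz = np$frame_rate_hz)
  attr(store, "ground_truth") <- list(
    w_task = w_task, w_cue = w_cue, w_stim = w_stim,
    bump_loadings = L, centers = centers,
    gains = data.frame(trial_index = tr$trial_index,
                       g_task_early = g_task$early, g_task_late = g_task$late,
                       g_cue_early = g_cue$early, g_cue_late = g_cue$late),
    cue_sign = cue_sign)
  store
}

#' Axon/bouton parameters
#'
#' @param n_axons Number of axons.
#' @param boutons_per_axon_mean Mean boutons per axon (putative axons
#'   average about eight boutons). Counts are `1 + Poisson(mean - 1)`.
#' @param bouton_noise_sigma Independent noise SD added to each bouton on top
#'   of its axon's latent trace.
#' @param private_rate_hz Rate of axon-specific deconvolved events (each
#'   axon's own spiking makes its temporal signature distinguishable from
#'   axons sharing the same population dynamics).
#' @param private_amplitude Mean amplitude of the private events
#'   (exponentially distributed).
#' @param silencing_cue_attenuation Fractional attenuation of the cue code on
#'   delay-onset silencing trials (1 removes the code).
#' @param silencing_recovery_ms Time after delay onset at which the cue code
#'   recovers on silenced trials (`Inf` for no recovery).
#' @return An object of class `axon_params`.
#' @export
axon_params <- function(n_axons = 60, boutons_per_axon_mean = 8,
                        bouton_noise_sigma = 0.3,
                        private_rate_hz = 0.4, private_amplitude = 1.5,
                        silencing_cue_attenuation = 0.8,
                        silencing_recovery_ms = Inf) {
  stopifnot(boutons_per_axon_mean >= 1, private_rate_hz >= 0,
            silencing_cue_attenuation >= 0, silencing_cue_attenuation <= 1)
  structure(as.list(environment()), class = "axon_params")
}

#' Simulate axonal bouton recordings with delay-onset silencing
#'
#' Each axon carries a latent trace (sequential bumps plus a cue code over
#' axons); on delay-onset silencing trials the cue-code amplitude is multiplied
#' by `1 - silencing_cue_attenuation` from delay onset until
#' `silencing_recovery_ms` (modulatory silencing: the bump/mean activity is
#' untouched, only the cue code is attenuated). Each bouton is its axon's
#' latent trace plus i.i.d. noise.
#'
#' @param session A [session_table()] (typically generated with
#'   `opto_epochs = "delay_onset"` and `opto_fraction = 0.15`).
#' @param ap An [axon_params()].
#' @param np A [neural_params()] describing the axon-level signal
#'   (`n_cells` is overridden by `ap$n_axons`; use
#'   `frame_rate_hz = 22.78` for axonal imaging).
#' @param cfg An [analysis_config()].
#' @return A list: `boutons` (an [activity_store()], `signal_kind = "bouton"`),
#'   `axons` (latent axon traces, `signal_kind = "axon"`), `axon_of_bouton`
#'   (integer ground-truth assignment) and `ground_truth` (as in
#'   [simulate_population()]).
#' @export
simulate_boutons <- function(session, ap = axon_params(),
                             np = neural_params(frame_rate_hz = 22.78),
                             cfg = analysis_config()) {
  stopifnot(inherits(ap, "axon_params"))
  tr <- session$trials
  np$n_cells <- ap$n_axons
  # latent axon signal: reuse the population generator without private noise,
  # then apply silencing to the cue-code component
  np_lat <- np
  np_lat$noise_sigma <- 0
  lat <- simulate_population(session, np_lat, cfg)
  gt <- attr(lat, "ground_truth")

  if (ap$private_rate_hz > 0) {
    nf <- ncol(lat$activity)
    p_event <- min(1, ap$private_rate_hz / np$frame_rate_hz)
    events <- matrix(stats::rbinom(ap$n_axons * nf, 1L, p_event) *
                       stats::rexp(ap$n_axons * nf, 1 / ap$private_amplitude),
                     ap$n_axons, nf)
    lat$activity <- lat$activity + events
  }

  # subtract the attenuated part of the cue code on silenced trials
  silenced <- tr$opto_epoch == "delay_onset"
  if (any(silenced) && ap$silencing_cue_attenuation > 0) {
    mid <- .frame_midpoints(lat)
    is_wm <- as.numeric(tr$task == "WM")
    for (i in which(silenced)) {
      stop_ms <- min(tr$delay_onset_ms[i] + ap$silencing_recovery_ms,
                     tr$stim_onset_ms[i])
      dcols <- .frames_in(mid, tr$delay_onset_ms[i], stop_ms)
      if (length(dcols) == 0L) next
      t_rel <- mid[dcols] - tr$delay_onset_ms[i]
      late <- t_rel >= cfg$half_split_ms
      g_c <- ifelse(late, gt$gains$g_cue_late[i], gt$gains$g_cue_early[i])
      code <- np$code_amplitude * is_wm[i] * gt$cue_sign[i] *
        outer(gt$w_cue, g_c)
      lat$activity[, dcols] <- pmax(
        lat$activity[, dcols] - ap$silencing_cue_attenuation * code, 0)
    }
  }

  n_b <- 1L + stats::rpois(ap$n_axons, ap$boutons_per_axon_mean - 1)
  axon_of_bouton <- rep(seq_len(ap$n_axons), times = n_b)
  boutons <- lat$activity[axon_of_bouton, , drop = FALSE]
  if (ap$bouton_noise_sigma > 0) {
    boutons <- boutons +
      matrix(stats::rnorm(length(boutons), 0, ap$bouton_noise_sigma),
             nrow(boutons), ncol(boutons))
  }
  bout_store <- activity_store(
    boutons, lat$frame_times_ms,
    unit_ids = paste0("b", seq_len(nrow(boutons))),
    signal_kind = "bouton", frame_rate_hz = np$frame_rate_hz)
  axon_store <- activity_store(
    lat$activity, lat$frame_times_ms,
    unit_ids = paste0("a", seq_len(ap$n_axons)),
    signal_kind = "axon", frame_rate_hz = np$frame_rate_hz)
  list(boutons = bout_store, axons = axon_store,
       axon_of_bouton = axon_of_bouton, ground_truth = gt)
}
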