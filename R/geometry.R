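# Pooled pseudo-population PCA, task-split trajectory projections, Euclidean
# distances with a trial-shuffled null, and eigenspectrum comparison.

#' Trial-averaged delay and stimulus responses of one experiment
#'
#' Averages each cell's delay-aligned activity over trials at each frame
#' position (trials contribute as long as their delay lasts, up to the
#' analysis cap), and likewise for stimulus-aligned activity.
#'
#' @param session A filtered [session_table()] (one experiment).
#' @param store The matching [activity_store()].
#' @param cfg An [analysis_config()].
#' @param stim_window_ms Length of the stimulus-aligned window, ms.
#' @param trials Optional logical/integer subset of trials to average.
#' @return A list with `delay` and `stim` (cells x frame-position matrices) and
#'   the per-position trial counts.
#' @export
experiment_trial_averages <- function(session, store, cfg = analysis_config(),
                                      stim_window_ms = 2000, trials = NULL) {
  avg_one <- function(tens) {
    keep <- if (is.null(trials)) seq_along(tens$windows) else trials
    wins <- tens$windows[keep]
    n_frames <- vapply(wins, ncol, integer(1))
    K <- max(n_frames)
    if (K == 0L) stop("no frames in any trial window", call. = FALSE)
    nc <- nrow(wins[[1]])
    sums <- matrix(0, nc, K)
    counts <- integer(K)
    for (w in wins) {
      k <- ncol(w)
      if (k == 0L) next
      sums[, 1:k] <- sums[, 1:k] + w
      counts[1:k] <- counts[1:k] + 1L
    }
    used <- counts > 0L
    list(avg = sweep(sums[, used, drop = FALSE], 2L, counts[used], "/"),
         n = counts[used])
  }
  d <- avg_one(align_trials(session, store, "delay_onset",
                            c(0, cfg$analysis_delay_cap_ms)))
  s <- avg_one(align_trials(session, store, "stim_onset",
                            c(0, stim_window_ms)))
  list(delay = d$avg, stim = s$avg, n_delay = d$n, n_stim = s$n)
}

#' Pool trial-averaged responses across experiments
#'
#' Concatenates each cell's trial-averaged delay response and stimulus
#' response along time, then stacks cells across experiments into one
#' pseudo-population matrix. Frame positions are truncated to the counts
#' common to all experiments. Cells with any unobserved frame position are
#' dropped with a message.
#'
#' @param experiments List of [experiment_trial_averages()] results.
#' @return A list with `matrix` (cells x timepoints), `cell_refs` (data frame:
#'   experiment, unit row) and `n_delay_frames` / `n_stim_frames`.
#' @export
pool_trial_averages <- function(experiments) {
  stopifnot(length(experiments) >= 1L)
  kd <- min(vapply(experiments, function(e) ncol(e$delay), integer(1)))
  ks <- min(vapply(experiments, function(e) ncol(e$stim), integer(1)))
  mats <- lapply(experiments, function(e)
    cbind(e$delay[, 1:kd, drop = FALSE], e$stim[, 1:ks, drop = FALSE]))
  mat <- do.call(rbind, mats)
  refs <- do.call(rbind, lapply(seq_along(mats), function(i)
    data.frame(experiment = i, unit = seq_len(nrow(mats[[i]])))))
  bad <- !stats::complete.cases(mat)
  if (any(bad)) {
    message(sum(bad), " cell(s) dropped from pooled matrix (no usable trials)")
    mat <- mat[!bad, , drop = FALSE]
    refs <- refs[!bad, , drop = FALSE]
  }
  list(matrix = mat, cell_refs = refs, n_delay_frames = kd,
       n_stim_frames = ks)
}

#' Principal components of pooled trial-averaged responses
#'
#' Mean-centered PCA with timepoints as observations and cells as variables,
#' so each component is a direction in cell space.
#'
#' @param mat Cells x timepoints matrix (e.g. `pool_trial_averages()$matrix`).
#' @return A list with `rotation` (cells x components, orthonormal),
#'   `var_explained` (fractions, non-increasing) and `center` (per-cell mean).
#' @export
fit_pcs <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) > 1L)
  p <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  list(rotation = p$rotation,
       var_explained = p$sdev^2 / sum(p$sdev^2),
       center = p$center)
}

# causal half-normal smoothing along columns of a (time x k) matrix
.half_normal_smooth <- function(x, sigma_ms, frame_ms) {
  if (sigma_ms <= 0) return(x)
  lags <- 0:ceiling(3 * sigma_ms / frame_ms)
  w <- exp(-(lags * frame_ms)^2 / (2 * sigma_ms^2))
  n <- nrow(x)
  out <- x
  for (t in seq_len(n)) {
    l <- lags[lags < t]
    ww <- w[seq_along(l)] / sum(w[seq_along(l)])
    out[t, ] <- crossprod(ww, x[t - l, , drop = FALSE])
  }
  out
}

#' Project task-split trial-averaged trajectories onto the top PCs
#'
#' Trials are split by task and into delay-duration groups; each group only
#' includes trials whose delay is at least the group's minimum stimulus-onset
#' time, so trajectories are averages of complete segments. Causal half-normal
#' smoothing (sigma = 100 ms) is applied for display only; the statistics path
#' uses raw projections.
#'
#' @param session,store Filtered experiment and activity.
#' @param pcs A [fit_pcs()] result (components fitted on pooled averages).
#' @param cfg An [analysis_config()].
#' @param delay_groups List of `(lo, hi)` delay ranges, ms.
#' @param smooth_sigma_ms Display smoothing SD, ms (0 disables).
#' @param n_pcs Number of components to project onto.
#' @return Nested list `projections[[task]][[group]]`: a list with `delay` and
#'   `stim` (time x n_pcs matrices, display-smoothed) plus `raw` (unsmoothed).
#'   Groups with no trial are omitted with a warning.
#' @export
project_trajectories <- function(session, store, pcs, cfg = analysis_config(),
                                 delay_groups = list(c(800, 1600),
                                                     c(1600, 2400),
                                                     c(2400, 3200)),
                                 smooth_sigma_ms = 100, n_pcs = 3) {
  rot <- pcs$rotation[, seq_len(n_pcs), drop = FALSE]
  frame_ms <- 1000 / store$frame_rate_hz
  proj <- function(avg_mat) t(avg_mat - pcs$center) %*% rot
  out <- list()
  for (task in unique(session$trials$task)) {
    out[[task]] <- list()
    for (g in delay_groups) {
      sel <- which(session$trials$task == task &
                     session$trials$delay_ms >= g[1] &
                     session$trials$delay_ms < g[2])
      gname <- sprintf("%g-%g", g[1], g[2])
      if (length(sel) == 0L) {
        warning("no trials in delay group ", gname, " for task ", task)
        next
      }
      av <- experiment_trial_averages(session, store, cfg, trials = sel)
      raw <- list(delay = proj(av$delay), stim = proj(av$stim))
      out[[task]][[gname]] <- list(
        delay = .half_normal_smooth(raw$delay, smooth_sigma_ms, frame_ms),
        stim = .half_normal_smooth(raw$stim, smooth_sigma_ms, frame_ms),
        raw = raw)
    }
  }
  out
}

#' Single-trial projections onto the top PCs
#'
#' Projects each trial's delay-aligned (up to the analysis cap) and
#' stimulus-aligned frames onto the leading components; no smoothing or
#' interpolation (this is the statistics path). Frame positions missing
#' because a delay ended are `NA`.
#'
#' @param session,store Filtered experiment and activity.
#' @param pcs A [fit_pcs()] result.
#' @param cfg An [analysis_config()].
#' @param stim_window_ms Stimulus window, ms.
#' @param n_pcs Number of components.
#' @return A list with `proj` (trials x timepoints x n_pcs array; delay frames
#'   then stimulus frames), `task` (per-trial label) and `n_delay_frames`.
#' @export
single_trial_projections <- function(session, store, pcs,
                                     cfg = analysis_config(),
                                     stim_window_ms = 2000, n_pcs = 3) {
  rot <- pcs$rotation[, seq_len(n_pcs), drop = FALSE]
  dt <- align_trials(session, store, "delay_onset",
                     c(0, cfg$analysis_delay_cap_ms))
  st <- align_trials(session, store, "stim_onset", c(0, stim_window_ms))
  kd <- max(vapply(dt$windows, ncol, integer(1)))
  ks <- max(vapply(st$windows, ncol, integer(1)))
  n <- length(dt$windows)
  arr <- array(NA_real_, c(n, kd + ks, n_pcs))
  for (i in seq_len(n)) {
    pd <- t(dt$windows[[i]] - pcs$center) %*% rot
    if (nrow(pd) > 0L) arr[i, seq_len(nrow(pd)), ] <- pd
    ps <- t(st$windows[[i]] - pcs$center) %*% rot
    if (nrow(ps) > 0L) arr[i, kd + seq_len(nrow(ps)), ] <- ps
  }
  list(proj = arr, task = session$trials$task, n_delay_frames = kd)
}

.task_distance <- function(arr, task) {
  # Euclidean distance between task-conditioned means at each timepoint
  m_wm <- colMeans(arr[task == "WM", , , drop = FALSE], na.rm = TRUE,
                   dims = 1)
  m_di <- colMeans(arr[task == "DISC", , , drop = FALSE], na.rm = TRUE,
                   dims = 1)
  sqrt(rowSums((m_wm - m_di)^2))
}

#' Task-trajectory distance with a trial-shuffled null
#'
#' Computes, per experiment, the Euclidean distance in the top-PC space
#' between the WM and Discrimination trial-averaged trajectories at each
#' timepoint, averages distances across experiments, and compares against a
#' null distribution obtained by shuffling task labels across trials within
#' each experiment. Timepoints are tested with a two-sided one-sample t-test
#' of the per-experiment distances against the null mean, at a Bonferroni-
#' corrected alpha derived from the realized timepoint count.
#'
#' @param projections List over experiments of [single_trial_projections()]
#'   results.
#' @param n_shuffles Number of label shuffles (a warning is issued below 100).
#' @param alpha Family-wise error level before Bonferroni correction.
#' @return A list with `distance` (observed mean across experiments, per
#'   timepoint), `per_experiment` (experiments x timepoints), `null_ci`
#'   (2.5/97.5 percentiles of the null), `null_mean`, `p` (per-timepoint),
#'   `alpha_corrected` and `significant`.
#' @export
trajectory_distance_with_null <- function(projections, n_shuffles = 1000,
                                          alpha = 0.05) {
  if (n_shuffles < 100) {
    warning("n_shuffles < 100: null confidence interval will be unstable")
  }
  for (p in projections) {
    if (length(unique(p$task)) < 2L) {
      stop("both task labels must be present in every experiment",
           call. = FALSE)
    }
  }
  # truncate to the timepoints common to all experiments
  nt <- min(vapply(projections, function(p) dim(p$proj)[2], integer(1)))
  projections <- lapply(projections, function(p) {
    p$proj <- p$proj[, seq_len(nt), , drop = FALSE]
    p
  })
  obs <- t(vapply(projections, function(p) .task_distance(p$proj, p$task),
                  numeric(nt)))
  null <- matrix(NA_real_, n_shuffles, nt)
  for (s in seq_len(n_shuffles)) {
    null[s, ] <- colMeans(t(vapply(projections, function(p)
      .task_distance(p$proj, sample(p$task)), numeric(nt))), na.rm = TRUE)
  }
  null_mean <- colMeans(null)
  alpha_c <- alpha / nt
  pvals <- vapply(seq_len(nt), function(t) {
    x <- obs[, t]
    x <- x[is.finite(x)]
    if (length(x) < 2L || stats::sd(x) == 0 || !is.finite(null_mean[t])) {
      return(NA_real_)
    }
    stats::t.test(x, mu = null_mean[t])$p.value
  }, numeric(1))
  list(distance = colMeans(obs, na.rm = TRUE),
       per_experiment = obs,
       null_ci = apply(null, 2L, stats::quantile,
                       probs = c(0.025, 0.975), na.rm = TRUE),
       null_mean = null_mean,
       p = pvals, alpha_corrected = alpha_c,
       significant = !is.na(pvals) & pvals < alpha_c)
}

#' Compare population covariance eigenspectra between tasks
#'
#' Eigenvalues of the single-trial delay-activity covariance per task
#' (trial counts equalized by subsampling the larger task), compared rank by
#' rank against a null built by shuffling task labels.
#'
#' @param X Trials x cells matrix of delay-averaged single-trial activity.
#' @param task Per-trial task labels.
#' @param n_shuffles Label shuffles for the null.
#' @param n_ranks Number of leading eigenvalues to compare.
#' @return A list with `spectra` (per task), `diff` (task A - task B),
#'   `null_ci` per rank, and `significant` per rank.
#' @export
eigenspectrum_compare <- function(X, task, n_shuffles = 500, n_ranks = 10) {
  tasks <- sort(unique(task))
  stopifnot(length(tasks) == 2L)
  n_min <- min(table(task))
  regularized <- n_min <= ncol(X)
  if (regularized) {
    message("fewer trials than cells; covariance eigenvalues of rank > ",
            n_min - 1L, " are zero")
  }
  n_ranks <- min(n_ranks, n_min - 1L, ncol(X))
  spec <- function(rows) {
    ev <- eigen(stats::cov(X[rows, , drop = FALSE]),
                symmetric = TRUE, only.values = TRUE)$values
    ev[seq_len(n_ranks)]
  }
  sub <- function(lab) {
    rows <- which(task == lab)
    if (length(rows) > n_min) rows <- sample(rows, n_min)
    rows
  }
  s1 <- spec(sub(tasks[1])); s2 <- spec(sub(tasks[2]))
  obs_diff <- s1 - s2
  null <- matrix(NA_real_, n_shuffles, n_ranks)
  for (s in seq_len(n_shuffles)) {
    perm <- sample(task)
    r1 <- which(perm == tasks[1]); r2 <- which(perm == tasks[2])
    null[s, ] <- spec(sample(r1, n_min)) - spec(sample(r2, n_min))
  }
  ci <- apply(null, 2L, stats::quantile, probs = c(0.025, 0.975))
  list(spectra = stats::setNames(list(s1, s2), tasks), diff = obs_diff,
       null_ci = ci,
       significant = obs_diff < ci[1, ] | obs_diff > ci[2, ],
       regularized = regularized)
}
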