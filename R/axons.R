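# Bouton-to-axon clustering and the feedback-disruption analyses: effects of
# silencing one cortical area on the working-memory code carried by the
# feedback axons it receives from the other.

#' Cluster boutons into putative axons
#'
#' Gaussian-mixture clustering of the ICA feature vectors. The number of
#' clusters minimizes a small-sample-corrected Akaike information criterion
#' (AICc) over `k_range` (falling back to plain AIC where the correction term
#' is undefined, i.e. when the parameter count approaches the bouton count;
#' BIC is available as an alternative). Boutons whose Mahalanobis distance to
#' their allocated component exceeds the `outlier_quantile` chi-square
#' quantile are left unassigned; the remaining members of each cluster are
#' averaged into one putative-axon trace.
#'
#' @param features Boutons x d feature matrix (see [ica_features()]).
#' @param k_range Candidate cluster counts.
#' @param outlier_quantile Chi-square quantile beyond which a bouton is marked
#'   `OUTLIER` (default 0.99).
#' @param traces Optional boutons x frames matrix; if given, cluster members
#'   are averaged into `axon_traces`.
#' @param criterion `"aicc"` (default), `"aic"` or `"bic"`.
#' @param model_names Mclust covariance structures to consider (diagonal /
#'   spherical families; full covariances are overparameterized at typical
#'   bouton counts).
#' @return An object of class `axon_cluster`: `assignment` (integer cluster id
#'   per bouton, `NA` for outliers), `n_clusters`, `criterion_curve` (per-k
#'   values), `outlier` (logical), `axon_traces` (or `NULL`), `model`.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_boutons <- function(features, k_range = 2:30,
                            outlier_quantile = 0.99, traces = NULL,
                            criterion = c("aicc", "aic", "bic"),
                            model_names = c("EII", "VII", "EEI", "VVI")) {
  criterion <- match.arg(criterion)
  features <- as.matrix(features)
  n <- nrow(features)
  d <- ncol(features)
  stopifnot(all(k_range >= 1L), all(k_range <= n))
  crit_value <- function(fit) {
    ll <- fit$loglik
    df <- fit$df
    switch(criterion,
           bic = -2 * ll + df * log(n),
           aic = -2 * ll + 2 * df,
           aicc = {
             v <- -2 * ll + 2 * df
             if (n > df + 1) v + 2 * df * (df + 1) / (n - df - 1) else v
           })
  }
  fits <- list()
  curve <- data.frame(k = k_range, value = NA_real_, model = NA_character_)
  for (i in seq_along(k_range)) {
    fit <- suppressWarnings(
      Mclust(features, G = k_range[i], modelNames = model_names,
             verbose = FALSE))
    if (is.null(fit)) next
    fits[[i]] <- fit
    curve$value[i] <- crit_value(fit)
    curve$model[i] <- fit$modelName
  }
  if (all(is.na(curve$value))) {
    stop("no mixture model could be fitted on the feature matrix",
         call. = FALSE)
  }
  best_i <- which.min(curve$value)
  best <- fits[[best_i]]
  G <- as.integer(best$G)
  assignment <- best$classification
  # Mahalanobis distance of each bouton to its component
  sigma <- best$parameters$variance$sigma  # d x d x G
  mu <- best$parameters$mean               # d x G
  cut <- stats::qchisq(outlier_quantile, df = d)
  md <- numeric(n)
  for (g in seq_len(G)) {
    rows <- which(assignment == g)
    if (length(rows) == 0L) next
    S <- sigma[, , g]
    qrS <- qr(S)
    if (qrS$rank < d) S <- S + diag(1e-8 * mean(diag(S)) + 1e-12, d)
    diffs <- sweep(features[rows, , drop = FALSE], 2L, mu[, g])
    md[rows] <- rowSums((diffs %*% solve(S)) * diffs)
  }
  outlier <- md > cut
  assignment[outlier] <- NA_integer_
  axon_traces <- NULL
  if (!is.null(traces)) {
    axon_traces <- t(vapply(seq_len(G), function(g) {
      rows <- which(!is.na(assignment) & assignment == g)
      if (length(rows) == 0L) return(rep(NA_real_, ncol(traces)))
      colMeans(traces[rows, , drop = FALSE])
    }, numeric(ncol(traces))))
  }
  structure(
    list(assignment = assignment, n_clusters = G,
         criterion_curve = curve, outlier = outlier,
         axon_traces = axon_traces, model = best$modelName,
         criterion = criterion),
    class = "axon_cluster")
}

#' Silencing effect on one unit's delay activity
#'
#' Statistic: difference of delay-averaged activity, silenced minus control.
#' The null distribution resamples control trials into two pseudo-arms of the
#' observed sizes; the two-sided p-value is the (add-one corrected) percentile
#' of the observed statistic in the null, and a t-type p (observed statistic
#' against the null distribution's mean and SD) is reported alongside.
#'
#' @param control,silenced Per-trial delay-averaged activity of the unit on
#'   control and silenced trials (each >= 10 trials).
#' @param n_boot Null resamples.
#' @param alpha Significance level.
#' @param unit_id Label.
#' @return A one-row data frame: `unit_id`, `delta` (silenced - control),
#'   `p_value` (percentile), `p_t` (t-type), `significant` (`p_value < alpha`)
#'   and arm sizes.
#' @export
silencing_effect_per_unit <- function(control, silenced, n_boot = 1000,
                                      alpha = 0.05, unit_id = "u1") {
  n_c <- length(control); n_s <- length(silenced)
  if (n_c < 10L || n_s < 10L) {
    stop("insufficient data: need >= 10 trials per arm", call. = FALSE)
  }
  obs <- mean(silenced) - mean(control)
  null <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n_c, n_s)
    mean(control[idx]) - mean(control[-idx])
  }, numeric(1))
  p_lo <- (sum(null <= obs) + 1) / (n_boot + 1)
  p_hi <- (sum(null >= obs) + 1) / (n_boot + 1)
  p <- min(1, 2 * min(p_lo, p_hi))
  z <- (obs - mean(null)) / stats::sd(null)
  data.frame(unit_id = unit_id, delta = obs, p_value = p,
             p_t = 2 * stats::pnorm(-abs(z)),
             significant = p < alpha, n_control = n_c, n_silenced = n_s)
}

# per-trial projections of epoch-mean activity onto a set of directions
.epoch_proj_mat <- function(em, W) {
  out <- em %*% W
  out[!is.finite(out)] <- NA_real_
  out
}

#' Silencing effects on feedback cue-code activity, by delay epoch
#'
#' For each axonal-imaging experiment: fits the cue coding dimension on
#' control WM trials (correct, non-silenced), projects every trial's delay
#' activity onto it (responses following cue A are sign-inverted so that
#' "more cue code" is always positive), and computes the control-minus-
#' silenced difference of the projection separately for the early
#' (`[0, half)`) and late (`[half, delay_end)`) delay epochs. Effects are
#' tested across experiments with two-sided signed-rank tests. A net-effect
#' control repeats the computation on the population-mean activity and on PC1
#' (under modulatory silencing of the cue code both should be null).
#'
#' @param experiments List of experiments, each a list with `session` (a
#'   [session_table()], outcomes assigned) and `store` (an
#'   [activity_store()] of axon traces).
#' @param cfg An [analysis_config()].
#' @param gamma Ridge regularizer for the coding dimension.
#' @return A list with `effects` (per experiment: `cd_early`, `cd_late`,
#'   `mean_early`, `mean_late`, `pc1_early`, `pc1_late`), `p_early`, `p_late`
#'   (signed-rank on the CD effects), `p_mean_early`, `p_mean_late`, and
#'   `recovery_index` per experiment.
#' @export
feedback_cd_timecourse <- function(experiments, cfg = analysis_config(),
                                   gamma = 1e-4) {
  rows <- lapply(experiments, function(ex) {
    session <- filter_trials(ex$session, cfg, imaging = TRUE)
    store <- ex$store
    tr <- session$trials
    labeled <- tr$task == "WM" & tr$prev_stim_class %in% c("A", "B")
    control <- labeled & tr$opto_epoch == "none"
    silenced <- labeled & tr$opto_epoch == "delay_onset"
    if (!any(silenced)) return(NULL)
    train <- control & (is.na(tr$outcome) | tr$outcome != "FA")
    if (length(unique(tr$prev_stim_class[train])) < 2L ||
        any(table(tr$prev_stim_class[train]) < 2L)) {
      return(NULL)  # cue dimension not fittable in this experiment
    }
    X <- epoch_means(session, store, "delay")
    cd <- fit_cd(X[train, , drop = FALSE], tr$prev_stim_class[train],
                 gamma = gamma, positive_class = "B")
    flip <- ifelse(tr$prev_stim_class == "A", -1, 1)
    w_unit <- cd$weights / sqrt(sum(cd$weights^2))
    lab_a <- tr$prev_stim_class == "A"
    nu <- nrow(store$activity)
    pc1 <- stats::prcomp(X, center = TRUE)$rotation[, 1]
    W <- cbind(cd = w_unit, mean = rep(1 / nu, nu), pc1 = pc1)
    em_early <- .epoch_proj_mat(
      epoch_means(session, store, "delay", c(0, cfg$half_split_ms)), W)
    em_late <- .epoch_proj_mat(
      epoch_means(session, store, "delay",
                  c(cfg$half_split_ms, cfg$analysis_delay_cap_ms)), W)
    has_late <- tr$delay_ms > cfg$half_split_ms
    eff <- function(col, use_flip) {
      early <- em_early[, col]
      late <- em_late[, col]
      if (use_flip) {
        # center at the control class-mean midpoint so a common projection
        # offset does not leak into the sign-inverted averages
        ctr <- function(p) {
          p - (mean(p[control & lab_a], na.rm = TRUE) +
                 mean(p[control & !lab_a], na.rm = TRUE)) / 2
        }
        early <- ctr(early) * flip
        late <- ctr(late) * flip
      }
      c(early = mean(early[control], na.rm = TRUE) -
          mean(early[silenced], na.rm = TRUE),
        late = mean(late[control & has_late], na.rm = TRUE) -
          mean(late[silenced & has_late], na.rm = TRUE))
    }
    cd_eff <- eff("cd", TRUE)
    mean_eff <- eff("mean", FALSE)
    pc1_eff <- eff("pc1", FALSE)
    data.frame(cd_early = cd_eff["early"], cd_late = cd_eff["late"],
               mean_early = mean_eff["early"], mean_late = mean_eff["late"],
               pc1_early = pc1_eff["early"], pc1_late = pc1_eff["late"])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no experiment has silenced trials; effects not testable",
         call. = FALSE)
  }
  effects <- do.call(rbind, rows)
  rownames(effects) <- NULL
  sr <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::wilcox.test(x, exact = FALSE)$p.value
  }
  list(effects = effects,
       p_early = sr(effects$cd_early), p_late = sr(effects$cd_late),
       p_mean_early = sr(effects$mean_early),
       p_mean_late = sr(effects$mean_late),
       recovery_index = recovery_index(effects$cd_early, effects$cd_late))
}

#' Recovery index of a silencing effect
#'
#' The difference of the silencing effect size between the early and the late
#' delay; positive values indicate recovery (a transient perturbation),
#' zero indicates a sustained disruption. Applies identically to cue-code
#' effects and to behavioral effect sizes.
#'
#' @param early,late Effect sizes per experiment.
#' @return `early - late`, vectorized.
#' @export
recovery_index <- function(early, late) early - late

#' Behavioral robustness to delay-onset silencing, by delay length
#'
#' Per experiment, the proportion of correct responses to the stimulus
#' following the (possibly silenced) delay, for control versus delay-onset
#' silencing trials, split into short (`< split_ms`) and long (`>= split_ms`)
#' delays; control and silenced proportions are compared per stratum with a
#' two-sided paired t-test across experiments.
#'
#' @param trials Data frame of trials with outcomes and an `experiment`
#'   column.
#' @param split_ms Short/long boundary, ms.
#' @return A list with `per_experiment` (proportions per stratum), `p_short`,
#'   `p_long`, and mean control-minus-silenced `deficit_short` /
#'   `deficit_long`.
#' @export
behavioral_robustness <- function(trials, split_ms = 1600) {
  stopifnot("experiment" %in% names(trials))
  correct <- trials$outcome %in% c("hit", "CR")
  arm <- ifelse(trials$opto_epoch == "none", "control",
                ifelse(trials$opto_epoch == "delay_onset", "silenced", NA))
  len <- ifelse(trials$delay_ms < split_ms, "short", "long")
  per <- do.call(rbind, lapply(split(seq_len(nrow(trials)),
                                     trials$experiment), function(idx) {
    p <- function(a, l) {
      sel <- idx[!is.na(arm[idx]) & arm[idx] == a & len[idx] == l]
      if (length(sel) == 0L) NA_real_ else mean(correct[sel])
    }
    data.frame(control_short = p("control", "short"),
               silenced_short = p("silenced", "short"),
               control_long = p("control", "long"),
               silenced_long = p("silenced", "long"))
  }))
  paired_p <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 2L || stats::sd(a[ok] - b[ok]) == 0) return(NA_real_)
    stats::t.test(a[ok], b[ok], paired = TRUE)$p.value
  }
  list(per_experiment = per,
       p_short = paired_p(per$control_short, per$silenced_short),
       p_long = paired_p(per$control_long, per$silenced_long),
       deficit_short = mean(per$control_short - per$silenced_short,
                            na.rm = TRUE),
       deficit_long = mean(per$control_long - per$silenced_long,
                           na.rm = TRUE))
}
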