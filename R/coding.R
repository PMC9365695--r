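# Coding dimensions: regularized linear discriminant directions in cell space,
# leave-one-out decoding, embedding-dimensionality sweeps, single-trial
# persistence and behavioral-outcome prediction.
#
# The discrimination vector solves (Sigma + gamma I) w = mu_a - mu_b, where
# Sigma is the cells' covariance across trials of delay-averaged activity and
# gamma is a small ridge stabilizing the inversion. The decision rule on the
# 1-D projection is the midpoint of the projected training-class means
# (equivalently, nearest projected class mean).

#' Fit a coding dimension (regularized LDA)
#'
#' @param X Trials x cells matrix of epoch-averaged activity (training set:
#'   incorrect and silenced trials are excluded by the caller).
#' @param labels Per-trial binary labels (factor/character).
#' @param gamma Ridge regularizer added to the diagonal of the covariance
#'   (must be positive).
#' @param positive_class Label projected to positive scores (canonical
#'   orientation: the WM task for the task dimension, cue B for the cue
#'   dimension). Defaults to the last sorted label.
#' @return An object of class `coding_dimension`: `weights`, `gamma`,
#'   `class_means_projected` (named pair), `threshold` (their midpoint),
#'   `covariance_rank`, `positive_class`, `classes`, `proj_sd` (pooled SD of
#'   projected training scores, used to z-score held-out projections) and
#'   `n_train`.
#' @export
fit_cd <- function(X, labels, gamma = 1e-4, positive_class = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("need exactly two classes with >= 2 trials each", call. = FALSE)
  }
  if (any(table(labels) < 2L)) {
    stop("need >= 2 trials per class", call. = FALSE)
  }
  if (is.null(positive_class)) positive_class <- classes[2]
  stopifnot(positive_class %in% classes)
  a <- positive_class
  b <- setdiff(classes, a)
  mu_a <- colMeans(X[labels == a, , drop = FALSE])
  mu_b <- colMeans(X[labels == b, , drop = FALSE])
  Sigma <- stats::cov(X)
  w <- solve(Sigma + diag(gamma, ncol(X)), mu_a - mu_b)
  scores <- as.numeric(X %*% w)
  m_a <- mean(scores[labels == a])
  m_b <- mean(scores[labels == b])
  pooled_sd <- stats::sd(scores - ifelse(labels == a, m_a, m_b))
  structure(
    list(weights = as.numeric(w), gamma = gamma,
         class_means_projected = stats::setNames(c(m_a, m_b), c(a, b)),
         threshold = (m_a + m_b) / 2,
         covariance_rank = qr(Sigma)$rank,
         positive_class = a, classes = c(a, b),
         proj_sd = pooled_sd, n_train = nrow(X)),
    class = "coding_dimension")
}

#' Project activity onto a coding dimension and predict labels
#'
#' @param cd A [fit_cd()] result.
#' @param X Trials x cells matrix.
#' @return A data frame with `score` (raw projection), `zscore` (centered at
#'   the training threshold, scaled by the training pooled SD) and `predicted`
#'   (nearest projected training-class mean).
#' @export
predict_cd <- function(cd, X) {
  X <- as.matrix(X)
  score <- as.numeric(X %*% cd$weights)
  predicted <- ifelse(score > cd$threshold, cd$positive_class,
                      setdiff(cd$classes, cd$positive_class))
  data.frame(score = score,
             zscore = (score - cd$threshold) / cd$proj_sd,
             predicted = predicted)
}

#' Leave-one-out cross-validated decoding
#'
#' For each trial, a coding dimension is fitted on the remaining trials and
#' the held-out trial is predicted from its projection; the reported accuracy
#' is the average of these held-out predictions. The training-set accuracy
#' (each trial predicted by the model fitted on all trials) is also returned.
#' Extra trials excluded from training (e.g. incorrect or silenced trials) can
#' be scored with the same per-fold conventions via [predict_cd()] on the
#' full-data fit.
#'
#' @param X Trials x cells matrix.
#' @param labels Binary per-trial labels.
#' @param gamma Ridge regularizer.
#' @param positive_class See [fit_cd()].
#' @param method `"downdate"` (default) removes each held-out trial from the
#'   precomputed covariance by a rank-one Sherman-Morrison downdate --
#'   algebraically identical to refitting without the trial; `"refit"` refits
#'   from scratch per fold (reference path).
#' @param extra Optional named list of trials x cells matrices (e.g. early-
#'   and late-delay means); each fold projects its trial's row onto the fold's
#'   coding dimension and centers it at the midpoint of the projected
#'   training-class means of that matrix (so that a common projection offset
#'   cannot masquerade as class signal), giving leakage-free per-trial
#'   projections of auxiliary features (returned in `extra_scores`).
#' @return A list with `per_trial` (data frame: score, zscore, predicted,
#'   truth, correct, used), `accuracy` (held-out), `train_accuracy`,
#'   `n_skipped` (folds whose training set lost a class) and `extra_scores`.
#' @export
loo_decode <- function(X, labels, gamma = 1e-4, positive_class = NULL,
                       method = c("downdate", "refit"), extra = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- nrow(X)
  score <- zscore <- rep(NA_real_, n)
  predicted <- rep(NA_character_, n)
  extra_scores <- if (is.null(extra)) NULL else
    lapply(extra, function(m) rep(NA_real_, n))
  skipped <- 0L
  classes <- sort(unique(labels))
  if (is.null(positive_class)) positive_class <- classes[2]
  a <- positive_class
  b <- setdiff(classes, a)

  if (method == "refit") {
    for (i in seq_len(n)) {
      lab_tr <- labels[-i]
      if (length(unique(lab_tr)) < 2L || any(table(lab_tr) < 2L)) {
        skipped <- skipped + 1L
        next
      }
      cd <- fit_cd(X[-i, , drop = FALSE], lab_tr, gamma, positive_class)
      pr <- predict_cd(cd, X[i, , drop = FALSE])
      score[i] <- pr$score; zscore[i] <- pr$zscore
      predicted[i] <- pr$predicted
      for (nm in names(extra)) {
        pe <- as.numeric(extra[[nm]] %*% cd$weights)
        mids <- (mean(pe[-i][labels[-i] == a]) +
                   mean(pe[-i][labels[-i] == b])) / 2
        extra_scores[[nm]][i] <- pe[i] - mids
      }
    }
  } else {
    mu <- colMeans(X)
    n_a <- sum(labels == a); n_b <- sum(labels == b)
    mu_a <- colMeans(X[labels == a, , drop = FALSE])
    mu_b <- colMeans(X[labels == b, , drop = FALSE])
    # S + (n-2) gamma I, where S is the total scatter of all n trials; the
    # fold covariance is (S - c_i u_i u_i^T)/(n-2), u_i = x_i - mu
    S <- stats::cov(X) * (n - 1)
    A_inv <- chol2inv(chol(S + diag((n - 2) * gamma, ncol(X))))
    cc <- n / (n - 1)
    for (i in seq_len(n)) {
      in_a <- labels[i] == a
      if ((in_a && n_a < 3L) || (!in_a && n_b < 3L)) {
        skipped <- skipped + 1L
        next
      }
      u <- X[i, ] - mu
      Au <- A_inv %*% u
      denom <- 1 - cc * sum(u * Au)
      mu_a_i <- if (in_a) (n_a * mu_a - X[i, ]) / (n_a - 1) else mu_a
      mu_b_i <- if (!in_a) (n_b * mu_b - X[i, ]) / (n_b - 1) else mu_b
      ud <- mu_a_i - mu_b_i
      w <- (n - 2) * (A_inv %*% ud + cc * Au * sum(Au * ud) / denom)
      proj <- as.numeric(X %*% w)
      m_a <- mean(proj[labels == a][if (in_a) -match(i, which(labels == a))
                                    else TRUE])
      m_b <- mean(proj[labels == b][if (!in_a) -match(i, which(labels == b))
                                    else TRUE])
      thr <- (m_a + m_b) / 2
      train <- setdiff(seq_len(n), i)
      resid <- proj[train] - ifelse(labels[train] == a, m_a, m_b)
      sd_tr <- stats::sd(resid)
      score[i] <- proj[i]
      zscore[i] <- (proj[i] - thr) / sd_tr
      predicted[i] <- if (proj[i] > thr) a else b
      for (nm in names(extra)) {
        pe <- as.numeric(extra[[nm]] %*% w)
        mids <- (mean(pe[-i][labels[-i] == a]) +
                   mean(pe[-i][labels[-i] == b])) / 2
        extra_scores[[nm]][i] <- pe[i] - mids
      }
    }
  }
  used <- !is.na(predicted)
  cd_full <- fit_cd(X, labels, gamma, positive_class)
  train_pred <- predict_cd(cd_full, X)$predicted
  list(per_trial = data.frame(score = score, zscore = zscore,
                              predicted = predicted, truth = labels,
                              correct = predicted == labels, used = used),
       accuracy = mean(predicted[used] == labels[used]),
       train_accuracy = mean(train_pred == labels),
       n_skipped = skipped, cd_full = cd_full,
       extra_scores = extra_scores)
}

#' Delay feature from a fixed number of randomly sampled frames
#'
#' Averages `k` randomly sampled delay frames per trial (without replacement),
#' so every trial contributes the same amount of data regardless of its delay
#' duration (five frames at 4.68 Hz correspond to 1068 ms of data). Used for
#' outcome-split decoding, where delay length correlates with both
#' signal-to-noise and false-alarm probability.
#'
#' @param tensor A delay-aligned [align_trials()] tensor.
#' @param k Number of frames to sample per trial.
#' @return A list with `X` (trials x cells; `NA` rows for trials with fewer
#'   than `k` delay frames) and `usable` (logical).
#' @export
delay_feature <- function(tensor, k = 5) {
  n <- length(tensor$windows)
  nc <- nrow(tensor$windows[[1]])
  X <- matrix(NA_real_, n, nc)
  usable <- logical(n)
  for (i in seq_len(n)) {
    w <- tensor$windows[[i]]
    if (ncol(w) < k) next
    cols <- sample.int(ncol(w), k)
    X[i, ] <- rowMeans(w[, cols, drop = FALSE])
    usable[i] <- TRUE
  }
  colnames(X) <- tensor$unit_ids
  list(X = X, usable = usable)
}

#' Decoding accuracy versus number of randomly sampled cells
#'
#' @param X Trials x cells matrix.
#' @param labels Binary labels.
#' @param ns Cell counts to evaluate.
#' @param repeats Random subsamples per count.
#' @param gamma Ridge regularizer.
#' @return A data frame with `n_cells`, `accuracy` (mean over repeats),
#'   `accuracy_sd` and `variance_fraction` (variance of the sampled submatrix
#'   over the total).
#' @export
sweep_cells <- function(X, labels, ns, repeats = 50, gamma = 1e-4) {
  X <- as.matrix(X)
  stopifnot(max(ns) <= ncol(X))
  total_var <- sum(apply(X, 2L, stats::var))
  do.call(rbind, lapply(ns, function(n) {
    res <- vapply(seq_len(repeats), function(r) {
      cols <- sample.int(ncol(X), n)
      acc <- loo_decode(X[, cols, drop = FALSE], labels, gamma)$accuracy
      c(acc, sum(apply(X[, cols, drop = FALSE], 2L, stats::var)) / total_var)
    }, numeric(2))
    data.frame(n_cells = n, accuracy = mean(res[1, ]),
               accuracy_sd = stats::sd(res[1, ]),
               variance_fraction = mean(res[2, ]))
  }))
}

#' Principal components of single-trial frames concatenated in time
#'
#' @param frames Frames x cells matrix (all analyzed trials' frames
#'   concatenated along time).
#' @return As [fit_pcs()].
#' @export
fit_single_trial_pcs <- function(frames) {
  p <- stats::prcomp(frames, center = TRUE, scale. = FALSE)
  list(rotation = p$rotation, var_explained = p$sdev^2 / sum(p$sdev^2),
       center = p$center)
}

#' Decoding accuracy when restricting to, or excluding, the top PCs
#'
#' Components are computed per experiment from single-trial frames
#' concatenated in time; trial features are projected onto the leading `k`
#' components (`mode = "top"`) or onto everything but the leading `k`
#' (`mode = "exclude"`) before decoding.
#'
#' @param X Trials x cells matrix of epoch-averaged features.
#' @param labels Binary labels.
#' @param pcs A [fit_single_trial_pcs()] result.
#' @param ks Component counts to evaluate.
#' @param mode `"top"` or `"exclude"`.
#' @param gamma Ridge regularizer.
#' @return A data frame with `k`, `accuracy`, `variance_fraction` (cumulative
#'   variance retained) and `chance` (flag: exclusion removed the full rank).
#' @export
sweep_pcs <- function(X, labels, pcs, ks, mode = c("top", "exclude"),
                      gamma = 1e-4) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  rank <- ncol(pcs$rotation)
  Xc <- sweep(X, 2L, pcs$center)
  full_proj <- Xc %*% pcs$rotation
  do.call(rbind, lapply(ks, function(k) {
    if (k == 0L) {
      cols <- seq_len(rank)
      vf <- if (mode == "top") 0 else 1
    } else if (mode == "top") {
      cols <- seq_len(min(k, rank))
      vf <- sum(pcs$var_explained[cols])
    } else {
      cols <- setdiff(seq_len(rank), seq_len(min(k, rank)))
      vf <- sum(pcs$var_explained[cols])
    }
    if (mode == "top" && k == 0L) cols <- seq_len(rank)
    if (length(cols) == 0L) {
      warning("k >= rank: nothing left to decode from; returning chance")
      return(data.frame(k = k, accuracy = 0.5, variance_fraction = 0,
                        chance = TRUE))
    }
    acc <- loo_decode(full_proj[, cols, drop = FALSE], labels,
                      gamma)$accuracy
    data.frame(k = k, accuracy = acc, variance_fraction = vf, chance = FALSE)
  }))
}

#' Stimulus-period cue dimension and its cross-task application
#'
#' Fits a coding dimension on WM-task stimulus-evoked responses (cue A versus
#' cue B) and applies the same weights, unchanged, to the other task's
#' stimulus-evoked responses of the same orientations.
#'
#' @param X_wm Trials x cells WM-task stimulus-epoch averages.
#' @param labels_wm WM-task stimulus classes (`A`/`B`).
#' @param X_other,labels_other The same for the Discrimination task (matched
#'   orientations).
#' @param gamma Ridge regularizer.
#' @return A list with `cd`, `within_accuracy` (leave-one-out, WM task) and
#'   `cross_accuracy` (WM-fit model on the other task's trials).
#' @export
stimulus_period_cd <- function(X_wm, labels_wm, X_other, labels_other,
                               gamma = 1e-4) {
  if (!setequal(unique(labels_other), unique(labels_wm))) {
    stop("stimulus classes do not match across tasks (experiment pairing ",
         "violated)", call. = FALSE)
  }
  dec <- loo_decode(X_wm, labels_wm, gamma, positive_class = "B")
  pred <- predict_cd(dec$cd_full, X_other)
  list(cd = dec$cd_full, within_accuracy = dec$accuracy,
       cross_accuracy = mean(pred$predicted == labels_other))
}

#' Single-trial persistence of coding-dimension activity
#'
#' For trials with sufficiently long delays, compares the coding-dimension
#' projection averaged over the first half of the delay against the second
#' half: both are z-scored across the included trials and related by least
#' squares. The slope measures persistence of the representation and the R^2
#' its robustness. Sign conventions (inverting Discrimination-task or cue-A
#' projections so that "more code" is positive in every trial) are applied by
#' the caller via `sign_flip`.
#'
#' @param early,late Per-trial projections averaged over `[0, half)` and
#'   `[half, delay_end)` ms of the delay.
#' @param delays Per-trial delay durations, ms.
#' @param cfg An [analysis_config()] (supplies
#'   `min_persistence_delay_ms`).
#' @param sign_flip Optional per-trial sign (+1/-1) applied to both halves
#'   before z-scoring.
#' @return A list with `slope`, `r_squared`, `n_trials`, and the z-scored
#'   `early_z` / `late_z` values.
#' @export
persistence_stats <- function(early, late, delays, cfg = analysis_config(),
                              sign_flip = NULL) {
  stopifnot(length(early) == length(late), length(delays) == length(early))
  if (!is.null(sign_flip)) {
    early <- early * sign_flip
    late <- late * sign_flip
  }
  keep <- delays >= cfg$min_persistence_delay_ms & is.finite(early) &
    is.finite(late)
  if (sum(keep) < 10L) {
    stop("insufficient data: fewer than 10 trials with delay >= ",
         cfg$min_persistence_delay_ms, " ms", call. = FALSE)
  }
  ez <- as.numeric(scale(early[keep]))
  lz <- as.numeric(scale(late[keep]))
  fit <- stats::lm(lz ~ ez)
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       n_trials = sum(keep), early_z = ez, late_z = lz,
       sign_convention_applied = !is.null(sign_flip))
}

#' Decoding accuracy split by the subsequent behavioral response
#'
#' Among no-go trials, splits the classification correctness of the delay
#' activity by whether the trial ended in a correct rejection or a false
#' alarm, and tests the association with a two-sided Fisher exact test.
#'
#' @param correct Logical per-trial classification correctness (decoding with
#'   the fixed-frame-count delay feature; incorrect trials scored by models
#'   trained on correct trials only).
#' @param outcomes Per-trial outcomes (`"CR"`/`"FA"`).
#' @return A list with `accuracy_pre_cr`, `accuracy_pre_fa`, `fisher_p`,
#'   `table` and `testable`.
#' @export
outcome_split_accuracy <- function(correct, outcomes) {
  keep <- outcomes %in% c("CR", "FA") & !is.na(correct)
  correct <- correct[keep]; outcomes <- outcomes[keep]
  n_fa <- sum(outcomes == "FA")
  n_cr <- sum(outcomes == "CR")
  if (n_fa == 0L || n_cr == 0L) {
    return(list(accuracy_pre_cr = if (n_cr) mean(correct[outcomes == "CR"])
                else NA_real_,
                accuracy_pre_fa = if (n_fa) mean(correct[outcomes == "FA"])
                else NA_real_,
                fisher_p = NA_real_, table = NULL, testable = FALSE))
  }
  tab <- table(factor(correct, c(TRUE, FALSE)),
               factor(outcomes, c("CR", "FA")))
  list(accuracy_pre_cr = mean(correct[outcomes == "CR"]),
       accuracy_pre_fa = mean(correct[outcomes == "FA"]),
       fisher_p = stats::fisher.test(tab)$p.value,
       table = tab, testable = TRUE)
}

#' Cue-decoding accuracy conditioned on task-decoding correctness
#'
#' @param task_correct,cue_correct Logical per-trial correctness of the task
#'   and cue decoders on the same trials.
#' @return A list with `cue_acc_task_correct`, `cue_acc_task_wrong`,
#'   `pearson_r` (correlation of the two correctness indicators) and
#'   `testable` (FALSE when the task decoder made no errors; `pearson_r` is
#'   still computed when defined).
#' @export
conditional_cue_accuracy <- function(task_correct, cue_correct) {
  keep <- !is.na(task_correct) & !is.na(cue_correct)
  task_correct <- task_correct[keep]; cue_correct <- cue_correct[keep]
  r <- if (stats::sd(task_correct) == 0 || stats::sd(cue_correct) == 0)
    NA_real_ else stats::cor(task_correct, cue_correct)
  testable <- any(task_correct) && any(!task_correct)
  list(cue_acc_task_correct = if (any(task_correct))
    mean(cue_correct[task_correct]) else NA_real_,
    cue_acc_task_wrong = if (any(!task_correct))
      mean(cue_correct[!task_correct]) else NA_real_,
    pearson_r = r, testable = testable)
}
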