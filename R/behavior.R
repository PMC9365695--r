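# Psychometrics: outcome classification, d-prime, delay-resolved response
# curves, reaction-time peaks, and Fisher tests of silencing effects.

#' Classify trial outcomes from lick latencies
#'
#' A lick within the 1 s response window after stimulus onset counts as a
#' response: targets become hits (lick) or misses (no lick); cues and probes
#' (no-go stimuli) become false alarms or correct rejections.
#'
#' @param session A [session_table()] with `lick_latency_ms` populated (or
#'   `NA` for no lick).
#' @param response_window_ms Response window after stimulus onset, ms.
#' @return The session with `outcome` assigned.
#' @export
classify_outcomes <- function(session, response_window_ms = 1000) {
  stopifnot(inherits(session, "session_table"))
  tr <- session$trials
  if (any(!is.na(tr$lick_latency_ms) & tr$lick_latency_ms < 0)) {
    stop("negative lick latency", call. = FALSE)
  }
  lick <- !is.na(tr$lick_latency_ms) &
    tr$lick_latency_ms <= response_window_ms
  go <- tr$trial_type == "target"
  tr$outcome <- ifelse(go, ifelse(lick, "hit", "miss"),
                       ifelse(lick, "FA", "CR"))
  session$trials <- tr
  session
}

#' Signal-detection sensitivity d'
#'
#' `d' = qnorm(hit_rate) - qnorm(fa_rate)`. A hit rate of 1 or a false-alarm
#' rate of 0 yields `+Inf`; callers treat such values as non-existent data
#' points.
#'
#' @param hit_rate,fa_rate Rates in \[0, 1\].
#' @return d' (possibly infinite).
#' @export
dprime <- function(hit_rate, fa_rate) {
  if (any(hit_rate < 0 | hit_rate > 1 | fa_rate < 0 | fa_rate > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

.dprime_of_trials <- function(tr) {
  hits <- tr$trial_type == "target"
  cues <- tr$trial_type == "cue"
  if (!any(hits) || !any(cues)) return(NA_real_)
  dprime(mean(tr$outcome[hits] == "hit"), mean(tr$outcome[cues] == "FA"))
}

#' d' split by delay-duration quartile
#'
#' Quartile edges come from the empirical delay distribution of the included
#' trials. Infinite d' values (quartiles without misses or without false
#' alarms) are reported as missing. When several mice contribute, adjacent
#' quartiles are compared by a two-sided signed-rank test across mice.
#'
#' @param trials Data frame of trials (e.g. rows pooled from filtered
#'   sessions), optionally with a `mouse_id` column.
#' @return A list with `pooled` (data frame: quartile, delay range, d',
#'   n_target, n_cue), `per_mouse` (matrix mice x quartiles, or `NULL`) and
#'   `adjacent_tests` (signed-rank p-values between quartiles 1-2, 2-3, 3-4,
#'   or `NULL` with fewer than two mice).
#' @export
dprime_by_delay_quartile <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  edges <- stats::quantile(trials$delay_ms, probs = seq(0, 1, 0.25))
  q <- cut(trials$delay_ms, breaks = edges, include.lowest = TRUE,
           labels = FALSE)
  pooled <- do.call(rbind, lapply(1:4, function(k) {
    sub <- trials[q == k, , drop = FALSE]
    d <- .dprime_of_trials(sub)
    data.frame(quartile = k, delay_lo_ms = edges[k], delay_hi_ms = edges[k + 1],
               dprime = ifelse(is.finite(d), d, NA_real_),
               infinite = is.infinite(d),
               n_target = sum(sub$trial_type == "target"),
               n_cue = sum(sub$trial_type == "cue"))
  }))
  per_mouse <- NULL
  adjacent <- NULL
  mice <- unique(trials$mouse_id %||% "m0")
  if (length(mice) >= 2L) {
    per_mouse <- t(vapply(mice, function(m) {
      vapply(1:4, function(k) {
        d <- .dprime_of_trials(trials[q == k & trials$mouse_id == m, ,
                                      drop = FALSE])
        ifelse(is.finite(d), d, NA_real_)
      }, numeric(1))
    }, numeric(4)))
    adjacent <- vapply(1:3, function(k) {
      a <- per_mouse[, k]; b <- per_mouse[, k + 1]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 2L) return(NA_real_)
      stats::wilcox.test(a[ok], b[ok], paired = TRUE, exact = FALSE)$p.value
    }, numeric(1))
  }
  list(pooled = pooled, per_mouse = per_mouse, adjacent_tests = adjacent)
}

#' Response probability as a function of the preceding delay
#'
#' Bins trials of one type by the preceding delay duration, reports the
#' per-bin response probability with Clopper-Pearson 95% intervals, and fits a
#' weighted least-squares line through the binned rates (weights = bin trial
#' counts), returning its slope in percent per second.
#'
#' @param trials Data frame of trials of a single task.
#' @param trial_type `"cue"` or `"probe"`.
#' @param bin_ms Delay bin width, ms.
#' @param min_bin_n Bins with fewer trials are dropped.
#' @return A list with `curve` (data frame: bin center, rate, ci_lo, ci_hi, n),
#'   `slope_pct_per_s`, `slope_se` and `n_trials`; the slope is `NA` with
#'   fewer than two bins.
#' @export
response_curve <- function(trials, trial_type = "cue", bin_ms = 100,
                           min_bin_n = 10) {
  sub <- trials[trials$trial_type == trial_type, , drop = FALSE]
  stopifnot(nrow(sub) > 0)
  responded <- sub$outcome %in% c("FA", "hit")
  bin <- floor(sub$delay_ms / bin_ms)
  tab <- stats::aggregate(responded, by = list(bin = bin),
                          FUN = function(z) c(k = sum(z), n = length(z)))
  k <- tab$x[, "k"]; n <- tab$x[, "n"]
  keep <- n >= min_bin_n
  k <- k[keep]; n <- n[keep]
  centers <- (tab$bin[keep] + 0.5) * bin_ms
  ci <- t(mapply(function(k, n) stats::binom.test(k, n)$conf.int, k, n))
  curve <- data.frame(delay_ms = centers, rate = k / n,
                      ci_lo = ci[, 1], ci_hi = ci[, 2], n = n)
  if (nrow(curve) < 2L) {
    slope <- NA_real_; se <- NA_real_
  } else {
    fit <- stats::lm(rate ~ I(delay_ms / 1000), data = curve, weights = n)
    slope <- 100 * stats::coef(fit)[[2]]
    se <- 100 * summary(fit)$coefficients[2, 2]
  }
  list(curve = curve, slope_pct_per_s = slope, slope_se = se,
       n_trials = nrow(sub))
}

#' Reaction-time histogram peaks and the WM-Discrimination lag
#'
#' Normalized per-task lick-latency histograms; the peak is the center of the
#' mode bin and the lag is the WM peak minus the Discrimination peak.
#'
#' @param trials Data frame of trials from both tasks.
#' @param stimulus `"cue"` (false-alarm latencies) or `"target"` (hit
#'   latencies).
#' @param bin_ms Histogram bin width, ms (one 60 Hz display frame).
#' @param min_licks Minimum licks required per task.
#' @return A list with `peak_ms` (named per task), `lag_ms` (WM - DISC) and the
#'   per-task histograms.
#' @export
rt_peak_lag <- function(trials, stimulus = c("cue", "target"),
                        bin_ms = 1000 / 60, min_licks = 50) {
  stimulus <- match.arg(stimulus)
  sub <- trials[trials$trial_type == stimulus &
                  !is.na(trials$lick_latency_ms), , drop = FALSE]
  hists <- list()
  peaks <- c(DISC = NA_real_, WM = NA_real_)
  for (task in c("DISC", "WM")) {
    lat <- sub$lick_latency_ms[sub$task == task]
    if (length(lat) < min_licks) {
      stop("insufficient licks for task ", task, " (", length(lat), " < ",
           min_licks, ")", call. = FALSE)
    }
    bin <- floor(lat / bin_ms)
    tab <- table(bin)
    mode_bin <- as.integer(names(tab)[which.max(tab)])
    peaks[task] <- (mode_bin + 0.5) * bin_ms
    hists[[task]] <- data.frame(
      latency_ms = (as.integer(names(tab)) + 0.5) * bin_ms,
      density = as.integer(tab) / length(lat))
  }
  list(peak_ms = peaks, lag_ms = unname(peaks["WM"] - peaks["DISC"]),
       histograms = hists)
}

#' Optogenetic silencing effect table
#'
#' For every (area, silencing onset, task, trial type) stratum, compares the
#' response rate (false alarms for cues/probes, misses for targets) between
#' silenced and control trials: rate difference in percentage points, binomial
#' (Clopper-Pearson) 95% CI of the silenced rate, and a two-sided Fisher exact
#' test on the 2x2 response table, with Bonferroni adjustment across the three
#' trial types within each (area, onset, task). Also returns the performance
#' map, performance = 100 - FA rate (%) - miss rate (%).
#'
#' @param trials Data frame of trials (control trials have
#'   `opto_epoch == "none"`).
#' @return A list with `effects` (one row per stratum) and `performance`
#'   (per area/onset/task, control vs silenced).
#' @export
opto_effect_table <- function(trials) {
  epochs <- setdiff(unique(trials$opto_epoch), c("none", "delay_end"))
  areas <- unique(stats::na.omit(trials$opto_area))
  rows <- list()
  for (area in areas) for (epoch in epochs) for (task in unique(trials$task)) {
    for (tt in intersect(.trial_type_levels, unique(trials$trial_type))) {
      ctrl <- trials$opto_epoch == "none" & trials$task == task &
        trials$trial_type == tt
      sil <- trials$opto_epoch == epoch & trials$task == task &
        trials$trial_type == tt &
        !is.na(trials$opto_area) & trials$opto_area == area
      bad_resp <- if (tt == "target") "miss" else "FA"
      n_c <- sum(ctrl); n_s <- sum(sil)
      if (n_c == 0L || n_s == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          area = area, epoch = epoch, task = task, trial_type = tt,
          rate_diff_pp = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          fisher_p = NA_real_, fisher_p_adj = NA_real_,
          n_control = n_c, n_silenced = n_s, testable = FALSE)
        next
      }
      k_c <- sum(trials$outcome[ctrl] == bad_resp)
      k_s <- sum(trials$outcome[sil] == bad_resp)
      bt <- stats::binom.test(k_s, n_s)
      fp <- stats::fisher.test(
        matrix(c(k_s, n_s - k_s, k_c, n_c - k_c), 2))$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        area = area, epoch = epoch, task = task, trial_type = tt,
        rate_diff_pp = 100 * (k_s / n_s - k_c / n_c),
        ci_lo = 100 * bt$conf.int[1], ci_hi = 100 * bt$conf.int[2],
        fisher_p = fp, fisher_p_adj = NA_real_,
        n_control = n_c, n_silenced = n_s, testable = TRUE)
    }
  }
  effects <- do.call(rbind, rows)
  # Bonferroni across trial types within (area, epoch, task)
  grp <- interaction(effects$area, effects$epoch, effects$task, drop = TRUE)
  for (g in levels(grp)) {
    sel <- grp == g & effects$testable
    m <- sum(sel)
    effects$fisher_p_adj[sel] <- pmin(1, effects$fisher_p[sel] * m)
  }
  perf <- do.call(rbind, lapply(split(
    effects[effects$testable, , drop = FALSE],
    interaction(effects$area[effects$testable],
                effects$epoch[effects$testable],
                effects$task[effects$testable], drop = TRUE)),
    function(d) {
      data.frame(area = d$area[1], epoch = d$epoch[1], task = d$task[1],
                 perf_diff_pp = -sum(d$rate_diff_pp[
                   d$trial_type %in% c("cue", "target")], na.rm = TRUE))
    }))
  rownames(perf) <- NULL
  list(effects = effects, performance = perf)
}
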