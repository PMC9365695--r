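# Responsiveness criteria and latency estimation deciding which units enter
# population analyses.

#' Conjunctive responsiveness test for somatic units
#'
#' A unit is delay- (or stimulus-) responsive if its mean activity after onset
#' exceeds the mean before onset by more than an effect-size threshold
#' (0.2 deconvolved dF/F0) AND the post-pre difference is significant by a
#' two-sided paired t-test across trials (alpha = 0.01). Both conditions must
#' hold.
#'
#' @param pre,post Per-trial mean activity in the pre- and post-onset windows
#'   (same length; default window length 800 ms each, set by the caller when
#'   computing the means).
#' @param unit_id Label carried into the result.
#' @param kind `"delay"` or `"stimulus"`.
#' @param threshold Effect-size threshold, activity units.
#' @param alpha Significance level.
#' @return A one-row data frame: `unit_id`, `kind`, `effect_size`, `p_value`,
#'   `responsive`.
#' @export
is_responsive <- function(pre, post, unit_id = "u1",
                          kind = c("delay", "stimulus"),
                          threshold = 0.2, alpha = 0.01) {
  kind <- match.arg(kind)
  stopifnot(length(pre) == length(post))
  ok <- is.finite(pre) & is.finite(post)
  if (sum(ok) < 10L) {
    stop("insufficient data: need >= 10 trials with both windows complete",
         call. = FALSE)
  }
  effect <- mean(post[ok]) - mean(pre[ok])
  p <- stats::t.test(post[ok], pre[ok], paired = TRUE)$p.value
  data.frame(unit_id = unit_id, kind = kind, effect_size = effect,
             p_value = p,
             responsive = (effect > threshold) && (p < alpha))
}

#' Delay responsiveness of an axon
#'
#' An axon is delay-responsive if its z-scored activity in any sliding 1 s
#' window of the delay exceeds the last second of the preceding stimulus by
#' more than 0.2 z with a significant paired t-test (alpha = 0.01, Bonferroni-
#' corrected over windows).
#'
#' @param delay_mat Trials x frames matrix of z-scored delay activity, aligned
#'   to delay onset (columns = common frames across trials).
#' @param baseline Per-trial mean z-scored activity over the last 1 s of the
#'   preceding stimulus.
#' @param frame_rate_hz Acquisition rate.
#' @param unit_id Label.
#' @param threshold Effect threshold, z units.
#' @param alpha Significance level (applied after Bonferroni over windows).
#' @return A one-row data frame as in [is_responsive()], plus `n_windows` and
#'   `best_window_p` (minimum raw per-window p).
#' @export
is_axon_delay_responsive <- function(delay_mat, baseline, frame_rate_hz,
                                     unit_id = "a1", threshold = 0.2,
                                     alpha = 0.01) {
  stopifnot(nrow(delay_mat) == length(baseline))
  win <- max(1L, floor(frame_rate_hz))  # frames per second
  nf <- ncol(delay_mat)
  if (nf < win) stop("insufficient data: delay < 1 s", call. = FALSE)
  starts <- seq_len(nf - win + 1L)
  effects <- numeric(length(starts))
  ps <- numeric(length(starts))
  for (s in starts) {
    m <- rowMeans(delay_mat[, s:(s + win - 1L), drop = FALSE])
    effects[s] <- mean(m - baseline)
    ps[s] <- stats::t.test(m, baseline, paired = TRUE)$p.value
  }
  p_adj <- pmin(1, ps * length(starts))
  hit <- (effects > threshold) & (p_adj < alpha)
  data.frame(unit_id = unit_id, kind = "delay",
             effect_size = max(effects),
             p_value = min(p_adj), responsive = any(hit),
             n_windows = length(starts), best_window_p = min(ps))
}

#' Response latency of a unit from a Gaussian fit
#'
#' Odd-numbered trials estimate the latency (the mean of a Gaussian fit to the
#' trial-averaged response); even-numbered trials are reserved for display
#' averages so that sorting by latency is cross-validated.
#'
#' @param windows Trials x frames matrix of one unit's delay-aligned activity.
#' @param times_ms Frame times relative to delay onset (common across trials).
#' @param unit_id Label.
#' @return A list with `unit_id`, `latency_ms`, `fit_ok`, `fit_params`
#'   (amplitude, mean, width, offset), `wide` (width spans more than half the
#'   window, e.g. bimodal responses) and `even_average` (frame-wise mean over
#'   even trials).
#' @export
unit_latency <- function(windows, times_ms, unit_id = "u1") {
  stopifnot(nrow(windows) >= 20L)
  odd <- seq(1L, nrow(windows), by = 2L)
  even <- seq(2L, nrow(windows), by = 2L)
  avg <- colMeans(windows[odd, , drop = FALSE])
  even_avg <- colMeans(windows[even, , drop = FALSE])
  span <- diff(range(times_ms))
  frame_ms <- span / max(1L, length(times_ms) - 1L)
  # center-of-mass start: coincides with the peak for unimodal responses and
  # lands between the modes of bimodal ones (making those fits reproducibly
  # wide rather than dependent on which mode the optimizer falls into)
  wts <- pmax(avg - min(avg), 0)
  m0 <- if (sum(wts) > 0) sum(times_ms * wts) / sum(wts) else mean(times_ms)
  start <- list(a = max(avg) - min(avg), m = m0, s = span / 4, c = min(avg))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(t - m)^2 / (2 * s^2)) + c,
      data = data.frame(y = avg, t = times_ms), start = start,
      lower = c(a = 0, m = min(times_ms) - span, s = frame_ms / 2,
                c = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- FALSE; lat <- NA_real_; pars <- NULL; wide <- FALSE
  if (!is.null(fit)) {
    pars <- stats::coef(fit)
    lat <- pars[["m"]]
    resid_sd <- stats::sd(stats::residuals(fit))
    ok <- lat >= min(times_ms) && lat <= max(times_ms) &&
      pars[["s"]] >= frame_ms / 2 && pars[["s"]] <= span &&
      pars[["a"]] > 3 * resid_sd   # a flat trace has no latency
    wide <- isTRUE(pars[["s"]] > span / 2)
    if (!ok) lat <- NA_real_
  }
  list(unit_id = unit_id, latency_ms = lat, fit_ok = ok,
       fit_params = pars, wide = wide, even_average = even_avg)
}

#' Order units by latency for display
#'
#' Rows (units) are min-max normalized even-trial averages, ordered by the
#' cross-validated latency estimate; ties break by unit id so the order is
#' stable. The same ordering is used for both task panels.
#'
#' @param latencies Data frame with `unit_id` and `latency_ms`.
#' @param even_averages Units x frames matrix of even-trial averages (rows
#'   named by unit id), or a named list of such matrices (one per task).
#' @return A list with `order` (unit ids in display order) and `panels`
#'   (normalized, reordered matrices).
#' @export
sort_for_display <- function(latencies, even_averages) {
  ord <- order(latencies$latency_ms, latencies$unit_id)
  ids <- latencies$unit_id[ord]
  if (is.matrix(even_averages)) even_averages <- list(all = even_averages)
  panels <- lapply(even_averages, function(m) {
    m <- m[ids, , drop = FALSE]
    t(apply(m, 1L, function(r) {
      rng <- range(r)
      if (diff(rng) == 0) rep(0, length(r)) else (r - rng[1]) / diff(rng)
    }))
  })
  list(order = ids, panels = panels)
}
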