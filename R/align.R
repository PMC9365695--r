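# Trial-frame alignment. Convention: time is in milliseconds, 0-based, windows
# are half-open [start, end); an imaging frame belongs to an epoch iff its
# timestamp midpoint lies inside the epoch.

.frame_midpoints <- function(store) {
  store$frame_times_ms + 500 / store$frame_rate_hz
}

# Column indices of frames whose midpoints lie in [from, to); mid is sorted,
# so binary search suffices.
.frames_in <- function(mid, from, to) {
  lo <- findInterval(from, mid, left.open = TRUE) + 1L
  hi <- findInterval(to, mid, left.open = TRUE)
  if (hi < lo) integer(0) else lo:hi
}

#' Cut per-trial windows of activity aligned to delay or stimulus onset
#'
#' @param session A [session_table()] whose trials carry `delay_onset_ms` /
#'   `stim_onset_ms` (added automatically at construction).
#' @param store An [activity_store()] covering the session.
#' @param alignment `"delay_onset"` or `"stim_onset"`.
#' @param window_ms Length-2 numeric, window relative to the alignment point,
#'   half-open `[start, end)`.
#' @return An object of class `trial_tensor`: a list with `windows` (per-trial
#'   units x frames matrices), `times` (per-trial frame midpoints relative to
#'   the alignment point), `trial_index`, `incomplete` (flag: the requested
#'   window extends past the trial's epoch or the recording end), `alignment`
#'   and `window_ms`. Frames are never shared across the delay/stimulus
#'   boundary of a trial: delay-aligned windows stop at stimulus onset, and
#'   stimulus-aligned windows stop at the trial end.
#' @export
align_trials <- function(session, store,
                         alignment = c("delay_onset", "stim_onset"),
                         window_ms = c(0, 1600)) {
  alignment <- match.arg(alignment)
  stopifnot(inherits(session, "session_table"),
            inherits(store, "activity_store"),
            length(window_ms) == 2L, window_ms[2] >= window_ms[1])
  tr <- session$trials
  mid <- .frame_midpoints(store)
  rec_end <- max(store$frame_times_ms) + 1000 / store$frame_rate_hz
  n <- nrow(tr)
  windows <- vector("list", n)
  times <- vector("list", n)
  incomplete <- logical(n)
  for (i in seq_len(n)) {
    origin <- if (alignment == "delay_onset") tr$delay_onset_ms[i] else
      tr$stim_onset_ms[i]
    epoch_end <- if (alignment == "delay_onset") tr$stim_onset_ms[i] else
      tr$stim_onset_ms[i] + tr$stimulus_ms[i]
    from <- origin + window_ms[1]
    to <- min(origin + window_ms[2], epoch_end)
    cols <- .frames_in(mid, from, to)
    windows[[i]] <- store$activity[, cols, drop = FALSE]
    times[[i]] <- mid[cols] - origin
    incomplete[i] <- (origin + window_ms[2] > epoch_end) ||
      (origin + window_ms[2] > rec_end)
  }
  structure(
    list(windows = windows, times = times, trial_index = tr$trial_index,
         incomplete = incomplete, alignment = alignment,
         window_ms = window_ms, unit_ids = store$unit_ids),
    class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat(sprintf("<trial_tensor> %d trials, %s-aligned, window [%g, %g) ms\n",
              length(x$windows), x$alignment, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Per-trial epoch-averaged activity
#'
#' Averages each unit's activity over the frames of a trial epoch, the basic
#' feature used by the coding-dimension analyses (a trials x cells matrix of
#' delay- or stimulus-averaged activity).
#'
#' @param session A [session_table()].
#' @param store An [activity_store()].
#' @param epoch `"delay"` or `"stim"`.
#' @param window_ms Optional window (relative ms) within the epoch; defaults to
#'   the full epoch.
#' @return Numeric matrix, trials x units; rows of all-`NaN` indicate trials
#'   with no frame in the window.
#' @export
epoch_means <- function(session, store, epoch = c("delay", "stim"),
                        window_ms = c(0, Inf)) {
  epoch <- match.arg(epoch)
  tens <- align_trials(
    session, store,
    alignment = if (epoch == "delay") "delay_onset" else "stim_onset",
    window_ms = c(window_ms[1], min(window_ms[2], 1e9)))
  out <- t(vapply(tens$windows, rowMeans,
                  numeric(length(store$unit_ids))))
  dimnames(out) <- list(NULL, store$unit_ids)
  out
}
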