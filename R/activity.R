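# Deconvolved-activity container: units x frames matrix with frame timestamps.

#' Construct an activity store
#'
#' Holds a units-by-frames matrix of deconvolved activity (dF/F0 for somata,
#' baseline-subtracted dF for boutons) together with frame timestamps.
#'
#' @param activity Numeric matrix, units x frames.
#' @param frame_times_ms Strictly increasing frame timestamps (frame start
#'   times), milliseconds.
#' @param unit_ids Character vector of unit labels (default `u1..un`).
#' @param signal_kind One of `"soma"`, `"bouton"`, `"axon"`.
#' @param frame_rate_hz Acquisition rate, Hz.
#' @return An object of class `activity_store`.
#' @export
activity_store <- function(activity, frame_times_ms,
                           unit_ids = NULL,
                           signal_kind = c("soma", "bouton", "axon"),
                           frame_rate_hz = 4.68) {
  signal_kind <- match.arg(signal_kind)
  activity <- as.matrix(activity)
  if (ncol(activity) != length(frame_times_ms)) {
    stop("columns of activity must correspond to frame_times_ms",
         call. = FALSE)
  }
  if (length(frame_times_ms) > 1L && any(diff(frame_times_ms) <= 0)) {
    stop("frame_times_ms must be strictly increasing", call. = FALSE)
  }
  if (is.null(unit_ids)) unit_ids <- paste0("u", seq_len(nrow(activity)))
  stopifnot(length(unit_ids) == nrow(activity))
  rownames(activity) <- unit_ids
  structure(
    list(activity = activity, frame_times_ms = as.numeric(frame_times_ms),
         unit_ids = as.character(unit_ids), signal_kind = signal_kind,
         frame_rate_hz = frame_rate_hz),
    class = "activity_store")
}

#' @export
print.activity_store <- function(x, ...) {
  cat(sprintf("<activity_store> %d %s units x %d frames @ %.2f Hz\n",
              nrow(x$activity), x$signal_kind, ncol(x$activity),
              x$frame_rate_hz))
  invisible(x)
}

#' Write an activity store to a plain-text directory container
#'
#' The container is a directory holding `meta.yaml` (signal kind, frame rate,
#' unit ids), `frame_times_ms.tsv` and `activity.tsv` (units x frames).
#'
#' @param store An [activity_store()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_activity <- function(store, path) {
  stopifnot(inherits(store, "activity_store"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(
    list(signal_kind = store$signal_kind,
         frame_rate_hz = store$frame_rate_hz,
         unit_ids = store$unit_ids),
    file.path(path, "meta.yaml"))
  utils::write.table(
    data.frame(frame_times_ms = store$frame_times_ms),
    file.path(path, "frame_times_ms.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(store$activity, file.path(path, "activity.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an activity store written by [write_activity()]
#'
#' @param path Container directory.
#' @return An [activity_store()].
#' @export
read_activity <- function(path) {
  meta_path <- file.path(path, "meta.yaml")
  if (!file.exists(meta_path)) {
    stop("not an activity container (missing meta.yaml): ", path,
         call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  times <- utils::read.delim(file.path(path, "frame_times_ms.tsv"))$frame_times_ms
  act <- as.matrix(utils::read.delim(file.path(path, "activity.tsv"),
                                     header = FALSE))
  dimnames(act) <- NULL
  activity_store(act, times, unit_ids = meta$unit_ids,
                 signal_kind = meta$signal_kind,
                 frame_rate_hz = meta$frame_rate_hz)
}
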