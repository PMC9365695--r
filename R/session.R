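# Trial-log data model: one row per trial (a delay followed by a stimulus).
# Trials are continuous (no inter-trial interval), so each trial's stimulus is
# the cue to the next trial, and a trial's delay carries the memory of the
# previous trial's stimulus.

.task_levels <- c("DISC", "WM")
.rotation_levels <- c("CW", "CCW", "NONE")
.trial_type_levels <- c("cue", "probe", "target")
.cue_levels <- c("A", "B")
.outcome_levels <- c("hit", "miss", "FA", "CR")
.opto_epoch_levels <- c("none", "delay_onset", "delay_end", "stim_onset")

.trial_columns <- c(
  "trial_index", "task", "rotation", "trial_type", "cue_identity",
  "stimulus_orientation", "delay_ms", "stimulus_ms", "lick_latency_ms",
  "outcome", "opto_epoch", "opto_area", "halted", "early_lick")

#' Construct a session table
#'
#' A session table is the trial log of one behavioral/imaging session: an
#' ordered data frame of trials plus session-level metadata. Columns follow the
#' trial-record schema (`trial_index`, `task`, `rotation`, `trial_type`,
#' `cue_identity`, `stimulus_orientation`, `delay_ms`, `stimulus_ms`,
#' `lick_latency_ms`, `outcome`, `opto_epoch`, `opto_area`, `halted`,
#' `early_lick`); derived columns (`prev_trial_type`, `prev_cue_identity`,
#' `stim_class`, `delay_onset_ms`, `stim_onset_ms`) are added when absent.
#'
#' @param trials Data frame of trials.
#' @param mouse_id,area Labels.
#' @param frame_rate_hz Imaging frame rate of the accompanying recording, Hz.
#' @return An object of class `session_table`.
#' @export
session_table <- function(trials, mouse_id = "m0", area = "AM",
                          frame_rate_hz = 4.68) {
  stopifnot(is.data.frame(trials), frame_rate_hz > 0)
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols) > 0L) {
    stop("session table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials <- .with_derived_columns(trials)
  .validate_trials(trials)
  structure(
    list(trials = trials, mouse_id = mouse_id, area = area,
         frame_rate_hz = frame_rate_hz),
    class = "session_table")
}

.with_derived_columns <- function(trials) {
  n <- nrow(trials)
  if (is.null(trials$prev_trial_type)) {
    prev <- c(NA_character_, as.character(trials$trial_type[-n]))
    # a predecessor only counts if it is the immediately preceding trial index
    contiguous <- c(FALSE, diff(trials$trial_index) == 1L)
    prev[!contiguous] <- NA_character_
    trials$prev_trial_type <- prev
  }
  if (is.null(trials$prev_cue_identity)) {
    prev_id <- c(NA_character_, as.character(trials$cue_identity[-n]))
    prev_is_cue <- !is.na(trials$prev_trial_type) &
      trials$prev_trial_type == "cue"
    prev_id[!prev_is_cue] <- NA_character_
    trials$prev_cue_identity <- prev_id
  }
  if (is.null(trials$stim_class)) {
    trials$stim_class <- .stim_class(trials)
  }
  if (is.null(trials$prev_stim_class)) {
    prev_cls <- c(NA_character_, as.character(trials$stim_class[-n]))
    prev_cls[c(TRUE, diff(trials$trial_index) != 1L)] <- NA_character_
    trials$prev_stim_class <- prev_cls
  }
  if (is.null(trials$prev_stim_orientation)) {
    prev_or <- c(NA_real_, trials$stimulus_orientation[-n])
    prev_or[c(TRUE, diff(trials$trial_index) != 1L)] <- NA_real_
    trials$prev_stim_orientation <- prev_or
  }
  if (is.null(trials$delay_onset_ms) || is.null(trials$stim_onset_ms)) {
    # continuous sessions: trial t starts where trial t-1 ended
    dur <- trials$delay_ms + trials$stimulus_ms
    trials$delay_onset_ms <- cumsum(c(0, dur[-n]))
    trials$stim_onset_ms <- trials$delay_onset_ms + trials$delay_ms
  }
  trials
}

# Orientation class of the presented stimulus: A/B for the two mirrored
# (go-relevant) orientations, C for the vertical Discrimination cue, P for the
# horizontal probe. Classes are rotation-invariant.
.stim_class <- function(trials) {
  cls <- rep(NA_character_, nrow(trials))
  probe <- trials$trial_type == "probe"
  cls[probe] <- "P"
  rot <- ifelse(trials$rotation == "CW", -15,
                ifelse(trials$rotation == "CCW", 15, 0))
  base <- trials$stimulus_orientation - rot
  cls[!probe & abs(base) < 1e-6] <- "C"
  cls[!probe & base < -1e-6] <- "A"
  cls[!probe & base > 1e-6] <- "B"
  cls
}

.validate_trials <- function(trials) {
  check_enum <- function(col, levels, allow_na = FALSE) {
    v <- as.character(trials[[col]])
    bad <- !(v %in% levels) & !(allow_na & is.na(v))
    if (any(bad)) {
      stop(sprintf("unparseable %s at trial_index %s: %s", col,
                   paste(trials$trial_index[bad][1], collapse = ","),
                   v[which(bad)[1]]), call. = FALSE)
    }
  }
  check_enum("task", .task_levels)
  check_enum("rotation", .rotation_levels)
  check_enum("trial_type", .trial_type_levels)
  check_enum("cue_identity", .cue_levels, allow_na = TRUE)
  check_enum("outcome", .outcome_levels, allow_na = TRUE)
  check_enum("opto_epoch", .opto_epoch_levels)
  if (any(diff(trials$trial_index) <= 0L)) {
    stop("trial_index must be strictly increasing", call. = FALSE)
  }
  if (any(trials$delay_ms < 0)) stop("negative delay_ms", call. = FALSE)
  lat <- trials$lick_latency_ms
  if (any(!is.na(lat) & lat < 0)) {
    stop("negative lick_latency_ms", call. = FALSE)
  }
  invisible(trials)
}

#' @export
print.session_table <- function(x, ...) {
  cat(sprintf("<session_table> mouse %s, area %s, %.2f Hz, %d trials\n",
              x$mouse_id, x$area, x$frame_rate_hz, nrow(x$trials)))
  invisible(x)
}

#' Read a session table from a delimited text file
#'
#' Files are tab-separated with a fixed header; session metadata is stored in
#' leading comment lines of the form `# key=value`. Enum fields are validated
#' row by row.
#'
#' @param path Path to a TSV written by [write_session_table()] (or any
#'   delimited file with the mandatory columns).
#' @return A [session_table()].
#' @export
read_session_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  meta <- list(mouse_id = "m0", area = "AM", frame_rate_hz = 4.68)
  for (h in header) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[kv[1]]] <- kv[2]
  }
  trials <- utils::read.delim(path, comment.char = "#",
                              stringsAsFactors = FALSE, na.strings = "NA")
  session_table(trials, mouse_id = meta$mouse_id, area = meta$area,
                frame_rate_hz = as.numeric(meta$frame_rate_hz))
}

#' Write a session table to a TSV file
#'
#' @param session A [session_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_table <- function(session, path) {
  stopifnot(inherits(session, "session_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s",
                     c("mouse_id", "area", "frame_rate_hz"),
                     c(session$mouse_id, session$area,
                       format(session$frame_rate_hz))), con)
  utils::write.table(session$trials, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Exclude trials that do not enter analyses
#'
#' Removes trials where the animal halted or licked during the delay, trials
#' immediately following a probe or a target (their type is fully predictable),
#' and trials silenced at the end of the delay (the animal can exploit the
#' light to anticipate the stimulus). For imaging analyses, trials with delays
#' beyond the analysis cap are removed as well. Original trial indices are
#' preserved on survivors, so the filter is idempotent.
#'
#' @param session A [session_table()].
#' @param cfg An [analysis_config()].
#' @param imaging If `TRUE`, additionally drop trials with
#'   `delay_ms > cfg$analysis_delay_cap_ms`.
#' @param drop_opto If `TRUE`, drop all optogenetic silencing trials (used for
#'   behavioral characterization, where silenced trials are analyzed
#'   separately).
#' @return A filtered [session_table()].
#' @export
filter_trials <- function(session, cfg = analysis_config(), imaging = FALSE,
                          drop_opto = FALSE) {
  stopifnot(inherits(session, "session_table"))
  tr <- session$trials
  keep <- !tr$halted & !tr$early_lick &
    !(tr$prev_trial_type %in% c("probe", "target")) &
    tr$opto_epoch != "delay_end"
  if (imaging) keep <- keep & tr$delay_ms <= cfg$analysis_delay_cap_ms
  if (drop_opto) keep <- keep & tr$opto_epoch == "none"
  if (!any(keep)) stop("no trials survive filters", call. = FALSE)
  out <- session
  out$trials <- tr[keep, , drop = FALSE]
  rownames(out$trials) <- NULL
  out
}

#' Partition a session into experiments
#'
#' Neural activity is only compared across tasks after identical sensory input.
#' An experiment pairs Discrimination-task trials and WM-task trials whose cue
#' stimuli share an orientation, which happens across opposite rotation blocks
#' (the vertical Discrimination cue rotated -15 deg matches the WM cue whose
#' rotated orientation is also -15 deg, and likewise at +15 deg) -- hence up to
#' two experiments per session. If only one cue orientation is shared, the
#' experiment is the whole session.
#'
#' @param session A [session_table()].
#' @return A list of experiments, each a list with elements `orientation`
#'   (matched cue orientation, degrees) and `trial_index` (original indices of
#'   member trials). Empty (with a warning) if the tasks share no cue
#'   orientation.
#' @export
define_experiments <- function(session) {
  stopifnot(inherits(session, "session_table"))
  tr <- session$trials
  if (length(unique(tr$task)) < 2L) return(list())
  cues <- tr[tr$trial_type == "cue", , drop = FALSE]
  ors <- function(task) unique(cues$stimulus_orientation[cues$task == task])
  shared <- intersect(ors("DISC"), ors("WM"))
  if (length(shared) <= 1L) {
    # without two matched cue orientations (e.g. a single rotation block),
    # fall back to any task stimulus shared between the tasks: the
    # experiment is then the whole session
    stim <- tr[tr$trial_type %in% c("cue", "target"), , drop = FALSE]
    all_shared <- intersect(
      unique(stim$stimulus_orientation[stim$task == "DISC"]),
      unique(stim$stimulus_orientation[stim$task == "WM"]))
    if (length(shared) == 0L && length(all_shared) == 0L) {
      warning("no stimulus orientation shared between tasks; ",
              "no experiments defined")
      return(list())
    }
    o <- if (length(shared) == 1L) shared else all_shared[1]
    return(list(list(orientation = o, trial_index = tr$trial_index)))
  }
  lapply(sort(shared), function(o) {
    # blocks in which orientation o occurs as a cue, per task
    pick <- function(task) {
      rots <- unique(cues$rotation[cues$task == task &
                                     cues$stimulus_orientation == o])
      tr$trial_index[tr$task == task & tr$rotation %in% rots]
    }
    idx <- sort(c(pick("DISC"), pick("WM")))
    list(orientation = o, trial_index = idx)
  })
}

#' Subset a session to an experiment
#'
#' @param session A [session_table()].
#' @param experiment One element of [define_experiments()].
#' @return A [session_table()] restricted to the experiment's trials.
#' @export
subset_experiment <- function(session, experiment) {
  out <- session
  out$trials <- session$trials[
    session$trials$trial_index %in% experiment$trial_index, , drop = FALSE]
  rownames(out$trials) <- NULL
  out
}

#' Trials following identical sensory input
#'
#' Cross-task comparisons of neural activity are restricted to trials whose
#' sensory input is matched: cue trials displaying the experiment's matched
#' orientation whose preceding stimulus was a cue of that same orientation
#' (so both the delay being analyzed and the stimulus that follows it arise
#' from identical displayed input in both tasks).
#'
#' @param session A [session_table()] (typically already subset to one
#'   experiment).
#' @param orientation Matched cue orientation, degrees.
#' @return Logical vector over the session's trials.
#' @export
matched_input_trials <- function(session, orientation) {
  tr <- session$trials
  tr$trial_type == "cue" &
    abs(tr$stimulus_orientation - orientation) < 1e-6 &
    !is.na(tr$prev_stim_orientation) &
    abs(tr$prev_stim_orientation - orientation) < 1e-6 &
    !is.na(tr$prev_trial_type) & tr$prev_trial_type == "cue"
}
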