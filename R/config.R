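#' Analysis configuration
#'
#' Bundles the handful of thresholds shared by every analysis stage: the delay
#' cap applied to imaging analyses, the early/late split of the delay, the
#' minimum delay a trial needs to enter persistence analyses, and the ridge
#' regularizer used when fitting coding dimensions.
#'
#' @param analysis_delay_cap_ms Imaging analyses only use trials whose delay is
#'   at most this long (default 3200 ms; longer delays are too rare per session
#'   to average).
#' @param half_split_ms Boundary between the "early" and "late" halves of the
#'   delay (default 1600 ms, the mean delay duration).
#' @param min_persistence_delay_ms Minimum delay duration for a trial to enter
#'   single-trial persistence analyses (default 2000 ms).
#' @param gamma Ridge regularizer added to the cell covariance before inversion
#'   when fitting coding dimensions (default 1e-4).
#' @param seed Integer seed recorded alongside results.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(analysis_delay_cap_ms = 3200,
                            half_split_ms = 1600,
                            min_persistence_delay_ms = 2000,
                            gamma = 1e-4,
                            seed = 1L) {
  stopifnot(half_split_ms < analysis_delay_cap_ms, gamma > 0,
            analysis_delay_cap_ms > 0)
  structure(
    list(analysis_delay_cap_ms = analysis_delay_cap_ms,
         half_split_ms = half_split_ms,
         min_persistence_delay_ms = min_persistence_delay_ms,
         gamma = gamma,
         seed = as.integer(seed)),
    class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys are arguments of
#'   [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
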