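# Deflation fixed-point ICA (logcosh/tanh contrast) used to build the
# temporal feature space for bouton clustering.

#' Temporal ICA features for boutons
#'
#' Extracts `d` temporal independent components from the full bouton x frames
#' time series (PCA whitening followed by deflation fixed-point iteration
#' with the tanh nonlinearity) and represents each bouton by its loadings on
#' the components. Boutons of one axon share latent temporal signals and
#' therefore land close together in this feature space.
#'
#' Components whose fixed-point update falls below the sampling-noise floor
#' carry no detectable non-Gaussian structure (pure-noise dimensions have no
#' preferred rotation); they are completed with an arbitrary orthonormal
#' direction rather than iterated indefinitely. Downstream clustering uses
#' distances in the feature space, which such completions do not affect.
#'
#' @param traces Boutons x frames matrix.
#' @param d Feature dimensionality (default 40).
#' @param maxit Maximum fixed-point iterations per component.
#' @param tol Convergence tolerance on the direction update.
#' @param retries Restarts with a fresh random direction if a structured
#'   component does not converge.
#' @return A list with `features` (boutons x d loadings), `sources` (d x
#'   frames temporal components, unit variance), `structured` (logical per
#'   component: carried a detectable non-Gaussian signal) and `converged`.
#' @export
ica_features <- function(traces, d = 40, maxit = 200, tol = 1e-4,
                         retries = 3) {
  traces <- as.matrix(traces)
  if (nrow(traces) < d) {
    stop("need at least d boutons (", d, "), got ", nrow(traces),
         call. = FALSE)
  }
  nf <- ncol(traces)
  X <- sweep(traces, 1L, rowMeans(traces))      # center each bouton trace
  sv <- svd(t(X), nu = d, nv = 0)               # frames x boutons
  # whitened temporal data: d x frames, unit variance, uncorrelated
  Z <- t(sv$u[, seq_len(d), drop = FALSE]) * sqrt(nf)

  # null fluctuation level of the update norm for a direction without
  # non-Gaussian structure (sd of tanh(N(0,1)) is about 0.63)
  null_floor <- 3 * 0.63 * sqrt(d / nf)

  W <- matrix(0, d, d)
  structured <- logical(d)
  orth <- function(w, k) {
    if (k > 1L) {
      prev <- W[seq_len(k - 1L), , drop = FALSE]
      w <- w - as.numeric(t(prev) %*% (prev %*% w))
    }
    w
  }
  for (k in seq_len(d)) {
    done <- FALSE
    for (attempt in seq_len(retries)) {
      w <- orth(stats::rnorm(d), k)
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(maxit)) {
        wz <- as.numeric(crossprod(w, Z))
        g <- tanh(wz)
        w_new <- as.numeric(Z %*% g) / nf - mean(1 - g^2) * w
        w_new <- orth(w_new, k)
        nrm <- sqrt(sum(w_new^2))
        if (nrm < null_floor) {
          # Gaussian residual: keep the current orthonormal direction
          structured[k] <- FALSE
          done <- TRUE
          break
        }
        w_new <- w_new / nrm
        delta <- abs(1 - abs(sum(w_new * w)))
        w <- sign(sum(w_new * w) + 1e-300) * w_new
        if (delta < tol) {
          structured[k] <- TRUE
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    if (!done) {
      stop("ICA component ", k, " did not converge after ", retries,
           " restarts", call. = FALSE)
    }
    W[k, ] <- w
  }
  S <- W %*% Z                                    # d x frames sources
  features <- X %*% t(S) / nf                     # boutons x d loadings
  rownames(features) <- rownames(traces)
  list(features = features, sources = S, structured = structured,
       converged = TRUE)
}
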