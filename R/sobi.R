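# Second-order blind identification: joint approximate diagonalization of
# time-lagged covariance matrices, component bookkeeping, and automated
# artifact-component rejection.

#' Time-lagged covariance matrices
#'
#' For each lag tau, the symmetrized sample covariance between `x(t)` and
#' `x(t + tau)` of the row-wise mean-removed signal. With `boundaries`
#' given (list of `c(first, last)` column index pairs, e.g. per-subject
#' segments of a pooled signal) lagged products never straddle a segment
#' boundary.
#'
#' @param x Dims-by-samples signal matrix.
#' @param lags Integer vector of non-negative lags (samples).
#' @param boundaries Optional list of segment index pairs.
#' @return List of symmetric matrices, one per lag.
#' @export
lagged_covariances <- function(x, lags, boundaries = NULL) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (any(lags >= n)) {
    stop("lags must be smaller than the number of samples", call. = FALSE)
  }
  if (is.null(boundaries)) boundaries <- list(c(1L, n))
  x <- x - rowMeans(x)
  bounds <- do.call(rbind, lapply(boundaries, as.integer))
  cube <- lagged_cov_cpp(x, as.integer(lags), bounds)
  p <- nrow(x)
  lapply(seq_along(lags), function(k) matrix(cube[, , k], p, p))
}

#' Joint approximate diagonalization by Givens rotations
#'
#' Finds an orthogonal matrix `V` maximizing the sum of squared diagonal
#' entries of `t(V) \%*\% M \%*\% V` over the matrix set, by cyclic Jacobi
#' sweeps of Givens rotations (the Cardoso-Souloumiac angle for symmetric
#' matrices). Iterates until every rotation angle in a sweep is below
#' `tol` or `max_sweeps` is reached; the off-diagonal criterion is
#' non-increasing across sweeps.
#'
#' @param matrices List of symmetric matrices of common dimension.
#' @param tol Convergence tolerance on the rotation angle.
#' @param max_sweeps Maximum number of sweeps; hitting it triggers a
#'   warning (with the final criterion), not an error.
#' @return Orthogonal matrix `V` with attributes `sweeps` (used),
#'   `converged` and `off_criterion` (per-sweep sum of squared
#'   off-diagonals).
#' @export
joint_diagonalize <- function(matrices, tol = 1e-8, max_sweeps = 200) {
  p <- nrow(matrices[[1]])
  K <- length(matrices)
  for (m in matrices) {
    if (!all(dim(m) == c(p, p))) {
      stop("all matrices must have the same dimension", call. = FALSE)
    }
  }
  M <- array(unlist(matrices), dim = c(p, p, K))
  V <- diag(p)
  off_crit <- function() {
    s <- 0
    for (k in seq_len(K)) {
      mk <- M[, , k]
      s <- s + sum(mk^2) - sum(diag(mk)^2)
    }
    s
  }
  crit_hist <- numeric(0)
  sweeps <- 0L
  converged <- FALSE
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    max_theta <- 0
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        # Cardoso-Souloumiac closed-form angle for symmetric matrices
        h_on <- M[i, i, ] - M[j, j, ]
        h_off <- 2 * M[i, j, ]
        ton <- sum(h_on^2) - sum(h_off^2)
        toff <- 2 * sum(h_on * h_off)
        theta <- 0.5 * atan2(toff, ton + sqrt(ton^2 + toff^2))
        max_theta <- max(max_theta, abs(theta))
        if (abs(theta) > tol) {
          cs <- cos(theta)
          sn <- sin(theta)
          # rotate rows i, j of every matrix
          Mi <- M[i, , ]
          Mj <- M[j, , ]
          M[i, , ] <- cs * Mi + sn * Mj
          M[j, , ] <- -sn * Mi + cs * Mj
          # rotate columns i, j
          Mi <- M[, i, ]
          Mj <- M[, j, ]
          M[, i, ] <- cs * Mi + sn * Mj
          M[, j, ] <- -sn * Mi + cs * Mj
          vi <- V[, i]
          V[, i] <- cs * vi + sn * V[, j]
          V[, j] <- -sn * vi + cs * V[, j]
        }
      }
    }
    crit_hist <- c(crit_hist, off_crit())
    if (max_theta <= tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "joint diagonalization did not converge in %d sweeps (criterion %.3g)",
      max_sweeps, crit_hist[length(crit_hist)]))
  }
  attr(V, "sweeps") <- sweeps
  attr(V, "converged") <- converged
  attr(V, "off_criterion") <- crit_hist
  V
}

#' Second-order blind identification (SOBI)
#'
#' Estimates an unmixing matrix for a whitened signal by jointly
#' diagonalizing its time-lagged covariance matrices. Components are
#' ordered by decreasing total lagged-autocovariance energy and each
#' component's sign is fixed so its largest-magnitude topography weight is
#' positive; both conventions exist only to make results reproducible
#' (blind separation is inherently ambiguous up to permutation and sign).
#'
#' @param x Whitened dims-by-samples signal (lag-0 covariance close to the
#'   identity; a warning is emitted otherwise).
#' @param lags Lag set in samples (default 1:50; 4-200 ms at 250 Hz).
#' @param tol,max_sweeps Passed to [joint_diagonalize()].
#' @param reduction Optional `pca_reduction` used to back-project
#'   topographies to the original channel space; without it topographies
#'   live in the input space.
#' @param boundaries Optional segment boundaries for
#'   [lagged_covariances()].
#' @return List with `model` (a `sobi_model`: `unmixing`, `mixing`,
#'   `topographies`, `lags`, `kept`, `energy`, `converged`) and
#'   `activations` (components x samples).
#' @export
sobi <- function(x, lags = 1:50, tol = 1e-8, max_sweeps = 200,
                 reduction = NULL, boundaries = NULL) {
  x <- as.matrix(x)
  p <- nrow(x)
  c0 <- tcrossprod(x - rowMeans(x)) / (ncol(x) - 1)
  if (max(abs(c0 - diag(p))) > 0.1) {
    warning("input does not look whitened (lag-0 covariance far from identity)")
  }
  covs <- lagged_covariances(x, lags, boundaries = boundaries)
  V <- joint_diagonalize(covs, tol = tol, max_sweeps = max_sweeps)
  W <- t(V)                                  # components x dims
  # order components by total lagged-autocovariance energy
  energy <- rowSums(vapply(covs, function(cc) diag(W %*% cc %*% t(W)),
                           numeric(p))^2)
  ord <- order(energy, decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  energy <- energy[ord]
  # topographies: back-project through the PCA reduction when available
  topo_of <- function(w) {
    if (is.null(reduction)) {
      t(w)
    } else {
      scl <- if (reduction$whiten) reduction$sdev else rep(1, p)
      t(reduction$rotation) %*% (t(w) * scl)
    }
  }
  topo <- topo_of(W)
  for (k in seq_len(p)) {
    imax <- which.max(abs(topo[, k]))
    if (topo[imax, k] < 0) {
      W[k, ] <- -W[k, ]
      topo[, k] <- -topo[, k]
    }
  }
  model <- structure(
    list(unmixing = W, mixing = t(W), topographies = topo, lags = lags,
         kept = seq_len(p), energy = energy,
         converged = attr(V, "converged"),
         rejection = NULL),
    class = "sobi_model"
  )
  list(model = model, activations = W %*% x)
}

#' @export
print.sobi_model <- function(x, ...) {
  cat(sprintf("<sobi_model> %d components (%d kept), %d lags, converged: %s\n",
              nrow(x$unmixing), length(x$kept), length(x$lags),
              x$converged))
  invisible(x)
}

#' Averaged-periodogram power spectral density (Welch)
#' @noRd
welch_psd <- function(x, fs, seg_s = 2, max_windows = 256) {
  nseg <- max(32, round(seg_s * fs))
  nwin <- floor(length(x) / nseg)
  if (nwin < 1) {
    nseg <- length(x)
    nwin <- 1
  }
  use <- if (nwin > max_windows) {
    unique(round(seq(1, nwin, length.out = max_windows)))
  } else {
    seq_len(nwin)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  acc <- numeric(nseg)
  for (i in use) {
    seg <- x[((i - 1) * nseg + 1):(i * nseg)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  nwin <- length(use)
  half <- seq_len(floor(nseg / 2))
  f <- (half - 1) * fs / nseg
  list(freq = f[-1], psd = (acc[half] / (nwin * sum(w^2) * fs))[-1])
}

#' Automated artifact-component rejection
#'
#' Automated stand-in for visual component screening. A component is
#' rejected when any of: (a) the 1/f slope of its log power spectrum over
#' 3-40 Hz falls outside `slope_range` (non-EEG-like spectrum); (b) more
#' than `hf_power_max` of its total power lies above 40 Hz (broadband/
#' muscle-like activity); (c) its topography is dominated by one channel
#' (`max(weight^2) > dominance_max * sum(weight^2)`, electrode artifact).
#'
#' @param model A `sobi_model`.
#' @param activations Components-by-samples activation matrix.
#' @param fs Sampling rate (Hz).
#' @param slope_range Admissible range for the spectral slope
#'   (log-power per log-Hz over 3-40 Hz).
#' @param hf_power_max Maximum tolerated high-frequency power fraction.
#' @param dominance_max Maximum tolerated single-channel topography share.
#' @return The model with `kept` reduced to surviving components and a
#'   `rejection` data frame (component, kept, reason, slope, hf_fraction,
#'   dominance).
#' @export
reject_artifact_ics <- function(model, activations, fs,
                                slope_range = c(-10, -0.2),
                                hf_power_max = 0.5,
                                dominance_max = 0.8) {
  p <- nrow(model$unmixing)
  slope <- hf <- dom <- numeric(p)
  reason <- character(p)
  for (k in seq_len(p)) {
    ps <- welch_psd(activations[k, ], fs)
    fit_band <- ps$freq >= 3 & ps$freq <= 40
    slope[k] <- stats::coef(stats::lm(log(ps$psd[fit_band]) ~
                                        log(ps$freq[fit_band])))[2]
    hf[k] <- sum(ps$psd[ps$freq > 40]) / sum(ps$psd)
    w2 <- model$topographies[, k]^2
    dom[k] <- max(w2) / sum(w2)
    reasons <- c(
      if (slope[k] < slope_range[1] || slope[k] > slope_range[2]) "slope",
      if (hf[k] > hf_power_max) "hf_power",
      if (dom[k] > dominance_max) "dominance")
    reason[k] <- paste(reasons, collapse = "+")
  }
  kept <- which(reason == "")
  if (length(kept) == 0) {
    stop("all components were rejected as artifacts; cannot proceed",
         call. = FALSE)
  }
  model$kept <- kept
  model$rejection <- data.frame(component = seq_len(p),
                                kept = reason == "", reason = reason,
                                slope = slope, hf_fraction = hf,
                                dominance = dom)
  model
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance between an estimated
#' unmixing and the true mixing: 0 means perfect recovery, values near 1
#' mean no separation. Computed on `P = unmixing \%*\% true_mixing`.
#'
#' @param P Square performance matrix.
#' @return Scalar in `[0, 1]`.
#' @export
amari_index <- function(P) {
  P <- abs(as.matrix(P))
  p <- nrow(P)
  stopifnot(ncol(P) == p)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (r + c) / (2 * p * (p - 1))
}

#' Match recovered components to true sources by topography
#'
#' Greedy assignment on absolute cosine similarity between estimated
#' component topographies and true mixing columns.
#'
#' @param topographies Channels-by-components matrix.
#' @param true_mixing Channels-by-sources matrix.
#' @return Data frame with `source`, `component` and `cosine` (absolute
#'   similarity of the matched pair).
#' @export
match_sources <- function(topographies, true_mixing) {
  tn <- sweep(as.matrix(true_mixing), 2,
              sqrt(colSums(true_mixing^2)), "/")
  en <- sweep(as.matrix(topographies), 2,
              sqrt(colSums(topographies^2)), "/")
  sim <- abs(crossprod(tn, en))      # sources x components
  out <- data.frame(source = integer(0), component = integer(0),
                    cosine = numeric(0))
  while (any(is.finite(sim))) {
    ij <- arrayInd(which.max(sim), dim(sim))
    out <- rbind(out, data.frame(source = ij[1], component = ij[2],
                                 cosine = sim[ij[1], ij[2]]))
    sim[ij[1], ] <- -Inf
    sim[, ij[2]] <- -Inf
    if (nrow(out) == min(dim(sim))) break
  }
  out[order(out$source), , drop = FALSE]
}
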