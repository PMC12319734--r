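# Hilbert-envelope spectral dynamics: time-frequency spectra of relative
# amplitude change, trial-averaged band envelopes, evoked power timecourses.

# Analytic signal via the frequency domain (full-length transform).
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert envelope
#'
#' Absolute value of the analytic signal; non-negative and positively
#' homogeneous (envelope(c x) = c envelope(x) for c > 0).
#'
#' @param x numeric vector, or matrix whose rows are signals.
#' @return envelope with the same shape as \code{x}.
#' @examples
#' t <- seq(0, 2, by = 1/250)
#' e <- hilbertEnvelope(3 * sin(2 * pi * 20 * t))  # ~3 away from edges
#' @export
hilbertEnvelope <- function(x) {
  if (is.null(dim(x))) return(Mod(analyticSignal(x)))
  t(apply(x, 1, function(r) Mod(analyticSignal(r))))
}

# Band-limited analytic signal of a long timecourse: reflection padding,
# one FFT, raised-cosine band edges on the positive frequencies only.
bandAnalytic <- function(x, rate, lo, hi, padSeconds = 0.5, edge = 0.25) {
  n <- length(x)
  P <- min(n - 1, round(padSeconds * rate))
  xp <- c(x[P + 1 - seq_len(P)], x, x[n - seq_len(P)])
  np <- length(xp)
  f <- (seq_len(np) - 1) / np * rate
  pos <- f <= rate / 2
  H <- numeric(np)
  H[pos] <- 2 * smoothBox(f[pos], lo, hi, edge)
  H[1] <- 0
  y <- stats::fft(stats::fft(xp) * H, inverse = TRUE) / np
  y[P + seq_len(n)]
}

#' Time-frequency spectrum of relative amplitude change
#'
#' The broadband virtual-electrode timecourse is filtered into overlapping
#' narrow bands (default 1 Hz bandwidth, centres every 0.5 Hz from 1.5 to
#' 99.5 Hz); per band the Hilbert envelope is computed, epoched into full
#' trials, and averaged over trials to A(t, f). The baseline amplitude
#' B(f) is the mean of A over the baseline window (default 12-13.5 s into
#' the trial, i.e. the rest period), and R(t, f) = (A - B) / B.
#'
#' The 1 Hz analysis bandwidth implies ~1 s temporal smoothing of envelope
#' features per band (bandwidth-time tradeoff).
#'
#' @param ve broadband virtual-electrode timecourse (continuous run).
#' @param rate sampling rate, Hz.
#' @param trialStarts 0-based sample indices of trial starts (cue ends).
#' @param trialSamples samples per trial epoch.
#' @param freqs band centre frequencies, Hz.
#' @param bandwidth band width, Hz.
#' @param baselineWindow seconds relative to trial start.
#' @param voxel voxel index bookkeeping.
#' @param padSeconds reflection padding before filtering, seconds.
#' @return a \linkS4class{TFS}.
#' @export
computeTFS <- function(ve, rate, trialStarts, trialSamples,
                       freqs = seq(1.5, 99.5, by = 0.5), bandwidth = 1,
                       baselineWindow = c(12, 13.5), voxel = NA_integer_,
                       padSeconds = 0.5) {
  stopIfNot(length(trialStarts) >= 1, "need at least one trial")
  idx <- outer(trialStarts + 1, seq_len(trialSamples) - 1L, "+")
  stopIfNot(max(idx) <= length(ve), "trial epochs exceed the record")
  times <- (seq_len(trialSamples) - 1) / rate
  bsel <- times >= baselineWindow[1] & times <= baselineWindow[2]
  stopIfNot(any(bsel), "epoch does not cover the baseline window")
  # one forward FFT of the padded signal, shared across all bands
  n <- length(ve)
  P <- min(n - 1, round(padSeconds * rate))
  xp <- c(ve[P + 1 - seq_len(P)], ve, ve[n - seq_len(P)])
  np <- length(xp)
  X <- stats::fft(xp)
  f <- (seq_len(np) - 1) / np * rate
  pos <- f <= rate / 2
  fpos <- f[pos]
  R <- matrix(0, trialSamples, length(freqs))
  for (k in seq_along(freqs)) {
    H <- numeric(np)
    H[pos] <- 2 * smoothBox(fpos, freqs[k] - bandwidth / 2,
                            freqs[k] + bandwidth / 2, 0.25)
    H[1] <- 0
    env <- Mod(stats::fft(X * H, inverse = TRUE) / np)[P + seq_len(n)]
    A <- colMeans(matrix(env[idx], nrow(idx)))
    B <- mean(A[bsel])
    if (B <= 0) stop("zero baseline amplitude in band ", freqs[k], call. = FALSE)
    R[, k] <- (A - B) / B
  }
  new("TFS", values = R, times = times, freqs = freqs,
      baselineWindow = baselineWindow, voxel = as.integer(voxel))
}

#' Trial-averaged beta envelope, optionally split by condition
#'
#' The Hilbert envelope of a beta-band virtual electrode is computed on the
#' continuous timecourse, epoched around trial starts, and averaged across
#' trials: overall and (when \code{conditions} is given) per condition.
#'
#' @param ve beta-band virtual-electrode timecourse.
#' @param rate sampling rate, Hz.
#' @param trialStarts 0-based sample indices of trial starts.
#' @param window numeric (t_start, t_end) seconds relative to trial start;
#'   trials whose window leaves the record are dropped.
#' @param conditions optional character vector (one per trial), e.g. the
#'   cue side; each present condition must retain at least one trial.
#' @param band,voxel bookkeeping labels.
#' @return an \linkS4class{EnvelopeTimecourse} with rows \code{"all"} plus
#'   one per condition level.
#' @export
betaEnvelope <- function(ve, rate, trialStarts, window,
                         conditions = NULL, band = "beta 13-30 Hz",
                         voxel = NA_integer_) {
  env <- Mod(bandAnalytic(ve, rate, 0, rate / 2, edge = 1e-6))  # |analytic|
  o1 <- round(window[1] * rate)
  o2 <- round(window[2] * rate)
  ns <- o2 - o1 + 1
  starts <- trialStarts + 1 + o1
  ok <- starts >= 1 & starts + ns - 1 <= length(ve)
  stopIfNot(any(ok), "no trial fits the requested window")
  starts <- starts[ok]
  if (!is.null(conditions)) conditions <- conditions[ok]
  E <- matrix(env[outer(starts, seq_len(ns) - 1L, "+")], length(starts))
  rows <- list(all = colMeans(E))
  if (!is.null(conditions)) {
    for (lv in unique(conditions)) {
      sel <- conditions == lv
      if (!any(sel)) stop("empty condition: ", lv, call. = FALSE)
      rows[[lv]] <- colMeans(E[sel, , drop = FALSE])
    }
  }
  new("EnvelopeTimecourse",
      amplitude = do.call(rbind, rows),
      times = window[1] + (seq_len(ns) - 1) / rate,
      conditions = names(rows), band = band, voxel = as.integer(voxel))
}

#' Evoked power timecourse at the peak voxel
#'
#' From a minimum-norm reconstruction, the three orientation timecourses of
#' one voxel are summed in quadrature, giving a single non-negative
#' evoked-power timecourse over the stimulus window. Invariant under
#' rotation of the per-voxel orientation basis.
#'
#' @param mne output of \code{\link{mneEvoked}}.
#' @param voxel voxel index; defaults to the reconstruction's peak voxel.
#' @return list with \code{times} (s), \code{power}, and \code{voxel}.
#' @export
evokedPowerTimecourse <- function(mne, voxel = NULL) {
  if (is.null(voxel)) voxel <- mne$peakVoxel
  list(times = mne$times, power = mne$power[voxel, ], voxel = voxel)
}

#' Linear resampling onto a shared time axis
#'
#' Cross-platform comparisons (375 vs 600 Hz) are made after resampling
#' both timecourses (or TFS time axes) onto a common grid, by default
#' 1 ms resolution over the overlap of the two axes.
#'
#' @param x numeric vector (timecourse) or matrix [time, frequency].
#' @param times time axis of \code{x}, seconds.
#' @param newTimes target time axis.
#' @return resampled vector/matrix on \code{newTimes}.
#' @export
resampleTimecourse <- function(x, times, newTimes) {
  if (is.null(dim(x)))
    return(stats::approx(times, x, xout = newTimes, rule = 2)$y)
  apply(x, 2, function(cl) stats::approx(times, cl, xout = newTimes, rule = 2)$y)
}
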