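# Preprocessing: Welch channel screening, homogeneous field correction,
# reference gradiometry, zero-phase FIR filtering, epoching and trial
# rejection. Processing order in the pipeline is fixed:
# screen -> HFC / gradiometry -> filter -> epoch -> reject.

subsetArray <- function(array, idx) {
  new("SensorArray", platform = array@platform,
      channelName = array@channelName[idx],
      position = array@position[idx, , drop = FALSE],
      orientation = array@orientation[idx, , drop = FALSE],
      kind = array@kind[idx], samplingRate = array@samplingRate,
      noiseFloor = array@noiseFloor[idx], baseline = array@baseline)
}

#' Subset a recording or lead field to a set of channels
#'
#' @param x a \linkS4class{Recording} or \linkS4class{LeadField}.
#' @param channels integer indices or channel names to keep.
#' @return object of the same class restricted to those channels.
#' @export
subsetChannels <- function(x, channels) {
  if (is(x, "Recording")) {
    idx <- if (is.character(channels))
      match(channels, x@array@channelName) else channels
    new("Recording", platform = x@platform, subject = x@subject, run = x@run,
        data = x@data[idx, , drop = FALSE], samplingRate = x@samplingRate,
        events = x@events, array = subsetArray(x@array, idx))
  } else if (is(x, "LeadField")) {
    idx <- if (is.character(channels))
      match(channels, x@channelName) else channels
    new("LeadField", gains = x@gains[, , idx, drop = FALSE], space = x@space,
        channelName = x@channelName[idx])
  } else stop("unsupported class", call. = FALSE)
}

#' Welch amplitude spectral density
#'
#' Hann-windowed segments (default 2 s, 50\% overlap), one-sided PSD,
#' returned as amplitude spectral density in the data units per sqrt(Hz).
#'
#' @param x numeric matrix (nChannel x nSample) or vector.
#' @param rate sampling rate, Hz.
#' @param segSeconds segment length, seconds.
#' @param overlap fractional overlap between segments.
#' @return list with \code{freq} (Hz) and \code{asd} (nChannel x nFreq).
#' @export
welchASD <- function(x, rate, segSeconds = 2, overlap = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  n <- ncol(x)
  ns <- round(segSeconds * rate)
  stopIfNot(n >= ns, "record shorter than one Welch segment")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, ns - 1) / (ns - 1))
  hop <- max(1, floor(ns * (1 - overlap)))
  starts <- seq(1, n - ns + 1, by = hop)
  acc <- matrix(0, nrow(x), floor(ns / 2) + 1)
  keep <- seq_len(floor(ns / 2) + 1)
  for (s in starts) {
    seg <- x[, s:(s + ns - 1), drop = FALSE] *
      matrix(w, nrow(x), ns, byrow = TRUE)
    X <- stats::mvfft(t(seg))
    acc <- acc + t(Mod(X[keep, , drop = FALSE])^2)
  }
  psd <- 2 * acc / (length(starts) * rate * sum(w^2))
  list(freq = (keep - 1) * rate / ns, asd = sqrt(psd))
}

#' Screen channels by 60-80 Hz noise floor
#'
#' Removes channels whose mean Welch amplitude spectral density in the
#' 60-80 Hz band is below \code{lowCut} (non-operational sensors) or above
#' \code{highCut} (high noise). By default the rule is applied to the OPM
#' platform only; the same automated rule can be applied to SQUID data via
#' \code{force}.
#'
#' @param recording a \linkS4class{Recording} of at least 10 s.
#' @param lowCut,highCut band-mean ASD bounds, fT/sqrt(Hz).
#' @param band frequency band (Hz) over which the floor is averaged.
#' @param force apply to non-OPM platforms too.
#' @return list with \code{recording} (channels removed), \code{kept} and
#'   \code{removed} channel names, \code{noiseFloor} (per original channel,
#'   fT/sqrt(Hz)), and a \code{report} data.frame.
#' @export
screenChannels <- function(recording, lowCut = 5, highCut = 20,
                           band = c(60, 80), force = FALSE) {
  stopIfNot(ncol(recording@data) / recording@samplingRate >= 10,
            "need >= 10 s of data for a stable Welch estimate")
  w <- welchASD(recording@data, recording@samplingRate)
  sel <- w$freq >= band[1] & w$freq <= band[2]
  floor_ <- rowMeans(w$asd[, sel, drop = FALSE])
  names(floor_) <- recording@array@channelName
  if (recording@platform != "opm" && !force) {
    return(list(recording = recording, kept = recording@array@channelName,
                removed = character(0), noiseFloor = floor_,
                report = data.frame(channel = names(floor_),
                                    noise_floor = unname(floor_),
                                    decision = "keep")))
  }
  bad <- floor_ < lowCut | floor_ > highCut
  if (all(bad)) stop("channel screening removed every channel", call. = FALSE)
  dec <- ifelse(!bad, "keep", ifelse(floor_ < lowCut, "remove_low", "remove_high"))
  list(recording = subsetChannels(recording, which(!bad)),
       kept = names(floor_)[!bad], removed = names(floor_)[bad],
       noiseFloor = floor_,
       report = data.frame(channel = names(floor_),
                           noise_floor = unname(floor_), decision = dec))
}

#' Homogeneous field correction (HFC)
#'
#' Projects out, at every time sample, the field component that is
#' spatially uniform across the array: with B the nChannel x 3 matrix of
#' channel orientations, data are replaced by
#' (I - B (B'B)^-1 B') data. The operation is an orthogonal projector
#' (idempotent) and removes any interference that couples into the array as
#' a uniform field, at the cost of three spatial degrees of freedom.
#'
#' @param recording an OPM \linkS4class{Recording} (orientations available
#'   for all kept channels).
#' @return the corrected \linkS4class{Recording}.
#' @export
applyHFC <- function(recording) {
  B <- recording@array@orientation
  if (nrow(B) < 3) stop("HFC needs at least 3 channels", call. = FALSE)
  proj <- B %*% solve(crossprod(B), t(B))
  out <- recording
  out@data <- recording@data - proj %*% recording@data
  out
}

#' Reference-array gradiometry
#'
#' Regresses each scalp channel on the reference channels over the full
#' record and subtracts the least-squares fit, suppressing
#' reference-correlated interference (a zeroth-order stand-in for synthetic
#' higher-order gradiometry). Reference channels are dropped from the
#' output.
#'
#' @param recording a SQUID \linkS4class{Recording} containing reference
#'   channels.
#' @return the corrected \linkS4class{Recording} (scalp channels only).
#' @export
referenceGradiometry <- function(recording) {
  isRef <- recording@array@kind == "reference"
  if (!any(isRef)) stop("no reference channels in recording", call. = FALSE)
  R <- recording@data[isRef, , drop = FALSE]
  S <- recording@data[!isRef, , drop = FALSE]
  Rc <- R - rowMeans(R)
  Sc <- S - rowMeans(S)
  G <- tcrossprod(Rc)                      # nRef x nRef
  if (max(abs(G)) < 1e-20) {
    out <- subsetChannels(recording, which(!isRef))
    return(out)
  }
  # pseudo-inverse handles collinear / constant reference channels while
  # keeping the residuals exactly orthogonal to the reference span
  eg <- eigen(G, symmetric = TRUE)
  keep <- eg$values > 1e-12 * eg$values[1]
  Ginv <- eg$vectors[, keep, drop = FALSE] %*%
    (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
  beta <- Sc %*% t(Rc) %*% Ginv
  out <- subsetChannels(recording, which(!isRef))
  out@data <- S - beta %*% Rc
  out
}

# FIR band-pass design following the MNE-python default convention:
# transition bandwidths min(max(edge/4, 2 Hz), edge); -6 dB cutoffs shifted
# half a transition band outside the passband; length = 6.6 / shortest
# transition band (in samples), forced odd; hamming window.
firBandpass <- function(low, high, rate) {
  stopIfNot(low > 0 && high > low, "need 0 < low < high")
  stopIfNot(high < rate / 2, "high edge must be below Nyquist")
  transL <- min(max(low / 4, 2), low)
  transH <- min(max(high / 4, 2), high)
  L <- ceiling(6.6 * rate / min(transL, transH))
  if (L %% 2 == 0) L <- L + 1
  lo <- max(low - transL / 2, 1e-3)
  hi <- min(high + transH / 2, rate / 2 * 0.999)
  signal::fir1(L - 1, c(lo, hi) / (rate / 2), type = "pass")
}

# Zero-phase FFT application of symmetric odd-length FIR filters.
#
# The symmetric (linear-phase) kernel is circularly shifted by its group
# delay before the DFT, which makes its frequency response real, so
# filtering is a real multiplication in the frequency domain with no delay
# to compensate. Channels are packed in pairs into complex signals (one
# FFT per two channels); with a real response the real/imaginary parts
# remain the two filtered channels. One forward transform is shared across
# all requested filters.
#
# x: channels x samples; hs: list of FIR kernels. Returns a list of
# filtered matrices, one per kernel.
firApplyMulti <- function(x, hs) {
  n <- ncol(x)
  nch <- nrow(x)
  Lmax <- max(vapply(hs, length, integer(1)))
  # padding of one group delay is enough: circular wrap-around then only
  # ever touches the padding, never the signal samples
  P <- min(n - 1, (Lmax - 1) / 2 + 1)
  np <- n + 2 * P
  nfft <- stats::nextn(np, c(2, 3, 5))
  npair <- ceiling(nch / 2)
  pad <- cbind(x[, P + 1 - seq_len(P), drop = FALSE], x,
               x[, n - seq_len(P), drop = FALSE])
  if (nch %% 2 == 1) pad <- rbind(pad, 0)
  odd <- seq(1, 2 * npair, by = 2)
  M <- matrix(0+0i, nfft, npair)
  M[seq_len(np), ] <- t(pad[odd, , drop = FALSE]) +
    1i * t(pad[odd + 1, , drop = FALSE])
  rm(pad)
  F <- stats::mvfft(M)
  rm(M)
  lapply(hs, function(h) {
    L <- length(h)
    d <- (L - 1) / 2
    hs_ <- numeric(nfft)
    hs_[seq_len(d + 1)] <- h[(d + 1):L]          # circular shift by -d
    hs_[nfft - d + seq_len(d)] <- h[seq_len(d)]
    H <- Re(stats::fft(hs_))
    Y <- stats::mvfft(F * H, inverse = TRUE)[P + seq_len(n), , drop = FALSE] / nfft
    out <- matrix(0, 2 * npair, n)
    out[odd, ] <- t(Re(Y))
    out[odd + 1, ] <- t(Im(Y))
    out[seq_len(nch), , drop = FALSE]
  })
}

firApply <- function(x, h) {
  if (is.null(dim(x))) return(drop(firApply(matrix(x, 1), h)))
  firApplyMulti(x, list(h))[[1]]
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR whose order follows the 6.6-cycles rule (length =
#' 6.6 times the reciprocal of the shortest transition band, minus 1);
#' transition bandwidths are min(max(edge/4, 2 Hz), edge) on each side.
#' Applied by FFT convolution with reflection padding and group-delay
#' compensation, so the output is zero-phase.
#'
#' @param x a \linkS4class{Recording}, \linkS4class{Epochs}, numeric matrix
#'   (channels x samples) or vector.
#' @param low,high band edges, Hz (high below Nyquist).
#' @param rate sampling rate (taken from the object when omitted).
#' @return the filtered object (same class as the input); Recording/Epochs
#'   get their band label updated.
#' @export
bandpassFilter <- function(x, low, high, rate = NULL) {
  if (is(x, "Recording")) {
    h <- firBandpass(low, high, x@samplingRate)
    out <- x
    out@data <- firApply(x@data, h)
    return(out)
  }
  if (is(x, "Epochs")) {
    h <- firBandpass(low, high, x@samplingRate)
    out <- x
    for (i in seq_len(dim(x@data)[1]))
      out@data[i, , ] <- firApply(x@data[i, , , drop = TRUE], h)
    out@band <- sprintf("%g-%g Hz", low, high)
    return(out)
  }
  stopIfNot(!is.null(rate), "rate must be given for matrix input")
  firApply(x, firBandpass(low, high, rate))
}

#' Filter a recording into several bands at once
#'
#' Shares one forward FFT across all bands, so filtering k bands costs
#' little more than one. Equivalent to k calls to
#' \code{\link{bandpassFilter}}.
#'
#' @param recording a \linkS4class{Recording}.
#' @param bands named list of numeric length-2 band edges (Hz).
#' @return named list of filtered \linkS4class{Recording}s.
#' @export
bandpassBands <- function(recording, bands) {
  hs <- lapply(bands, function(b)
    firBandpass(b[1], b[2], recording@samplingRate))
  ys <- firApplyMulti(recording@data, hs)
  out <- lapply(seq_along(bands), function(i) {
    r <- recording
    r@data <- ys[[i]]
    r
  })
  names(out) <- names(bands)
  out
}

#' Segment a recording into epochs around events
#'
#' @param recording a \linkS4class{Recording} (or any object with data and
#'   events).
#' @param window numeric (t_start, t_end) seconds relative to each event.
#' @param eventTypes regular expression selecting event \code{trial_type}s
#'   (e.g. \code{"^stim_"} or \code{"^cue_"}).
#' @param band band label to attach.
#' @return an \linkS4class{Epochs}; events whose window falls outside the
#'   record are dropped.
#' @export
epochData <- function(recording, window, eventTypes = "^stim_",
                      band = "broadband") {
  ev <- recording@events
  sel <- grepl(eventTypes, ev$trial_type)
  ev <- ev[sel, , drop = FALSE]
  fs <- recording@samplingRate
  o1 <- round(window[1] * fs)
  o2 <- round(window[2] * fs)
  nsamp <- o2 - o1 + 1
  n <- ncol(recording@data)
  starts <- ev$sample + 1 + o1            # event samples are 0-based
  ok <- starts >= 1 & (starts + nsamp - 1) <= n
  ev <- ev[ok, , drop = FALSE]
  starts <- starts[ok]
  dat <- array(0, c(length(starts), nrow(recording@data), nsamp))
  for (i in seq_along(starts))
    dat[i, , ] <- recording@data[, starts[i] + seq_len(nsamp) - 1]
  info <- data.frame(trial_type = ev$trial_type,
                     trial = if ("trial" %in% names(ev)) ev$trial else NA_integer_,
                     onset = ev$onset)
  new("Epochs", data = dat, window = window, samplingRate = fs,
      channelName = recording@array@channelName,
      trialIndex = seq_along(starts), trialInfo = info, band = band)
}

#' Reject epochs on a peak-to-peak amplitude rule
#'
#' Removes any epoch in which any channel's max - min exceeds the limit
#' (default 4 pT = 4000 fT).
#'
#' @param epochs an \linkS4class{Epochs}.
#' @param p2pLimit peak-to-peak limit in the data units (fT).
#' @return list with \code{epochs} (retained trials), \code{removed}
#'   (indices of rejected trials) and a \code{report} data.frame (trial,
#'   max peak-to-peak, decision).
#' @export
rejectEpochs <- function(epochs, p2pLimit = 4000) {
  nt <- dim(epochs@data)[1]
  p2p <- vapply(seq_len(nt), function(i) {
    d <- epochs@data[i, , , drop = TRUE]
    if (is.null(dim(d))) d <- matrix(d, 1)
    max(apply(d, 1, function(ch) max(ch) - min(ch)))
  }, numeric(1))
  bad <- p2p > p2pLimit
  if (all(bad)) stop("all epochs rejected", call. = FALSE)
  out <- epochs
  out@data <- epochs@data[!bad, , , drop = FALSE]
  out@trialIndex <- epochs@trialIndex[!bad]
  out@trialInfo <- epochs@trialInfo[!bad, , drop = FALSE]
  list(epochs = out, removed = which(bad),
       report = data.frame(trial = seq_len(nt), peak_to_peak = p2p,
                           threshold = p2pLimit,
                           decision = ifelse(bad, "remove", "keep")))
}

#' Epoch a recording and reject bad trials in one step
#'
#' @inheritParams epochData
#' @inheritParams rejectEpochs
#' @return as \code{\link{rejectEpochs}}.
#' @export
epochAndReject <- function(recording, window, eventTypes = "^stim_",
                           p2pLimit = 4000, band = "broadband") {
  rejectEpochs(epochData(recording, window, eventTypes, band), p2pLimit)
}
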