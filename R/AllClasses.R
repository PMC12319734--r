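#' @import methods
NULL

#' Trial schedule for the braille attention-switching paradigm
#'
#' One experimental trial starts (t = 0 s) at the end of an auditory cue
#' telling the participant to attend left or right. Five braille patterns are
#' then presented to both index fingers, the first at 1.17 s and subsequent
#' ones at 1.37 s intervals; each lasts 0.37 s and the trial ends with a 7 s
#' rest. A fixed fraction (0.2) of all stimulus slots across the experiment
#' carry the target pattern.
#'
#' @slot nTrials number of trials.
#' @slot cueSide character vector, one of \code{"left"}/\code{"right"} per trial.
#' @slot onsets numeric matrix (nTrials x 5) of stimulus onset times in
#'   seconds relative to cue end (trial start).
#' @slot pattern character matrix (nTrials x 5), \code{"target"} or
#'   \code{"non_target"}.
#' @slot timing named numeric vector: \code{first_onset_s},
#'   \code{inter_stimulus_interval_s}, \code{stimulus_duration_s},
#'   \code{rest_s}, \code{cue_s}.
#' @slot pTarget target probability (fraction of slots that are targets).
#' @exportClass TrialSchedule
setClass("TrialSchedule",
  representation(
    nTrials = "integer",
    cueSide = "character",
    onsets = "matrix",
    pattern = "matrix",
    timing = "numeric",
    pTarget = "numeric"
  )
)

setValidity("TrialSchedule", function(object) {
  n <- object@nTrials
  msg <- character(0)
  if (length(object@cueSide) != n) msg <- c(msg, "cueSide length != nTrials")
  if (n > 0) {
    if (!all(dim(object@onsets) == c(n, 5L)))
      msg <- c(msg, "onsets must be nTrials x 5")
    if (!all(dim(object@pattern) == c(n, 5L)))
      msg <- c(msg, "pattern must be nTrials x 5")
    if (!all(object@pattern %in% c("target", "non_target")))
      msg <- c(msg, "pattern entries must be 'target' or 'non_target'")
    if (!all(object@cueSide %in% c("left", "right")))
      msg <- c(msg, "cueSide entries must be 'left' or 'right'")
    expected <- object@timing[["first_onset_s"]] +
      (0:4) * object@timing[["inter_stimulus_interval_s"]]
    if (max(abs(sweep(object@onsets, 2, expected))) > 1e-9)
      msg <- c(msg, "stimulus onsets must be first_onset + k*ISI, k = 0..4")
  }
  need <- c("first_onset_s", "inter_stimulus_interval_s",
            "stimulus_duration_s", "rest_s", "cue_s")
  if (!all(need %in% names(object@timing)))
    msg <- c(msg, "timing must name first_onset_s, inter_stimulus_interval_s, stimulus_duration_s, rest_s, cue_s")
  if (length(msg)) msg else TRUE
})

#' Sensor array geometry for one MEG platform
#'
#' \code{"opm"}: 64 triaxial magnetometer sites (192 channels) at 375 Hz.
#' \code{"squid"}: 275 radial axial gradiometers (5 cm baseline) plus 29
#' distal reference channels at 600 Hz.
#'
#' @slot platform \code{"opm"} or \code{"squid"}.
#' @slot channelName character vector of channel names.
#' @slot position numeric matrix (nChannel x 3), coil position in metres
#'   (inner coil for gradiometers).
#' @slot orientation numeric matrix (nChannel x 3), unit sensitive axis.
#' @slot kind \code{"magnetometer"}, \code{"axial_gradiometer"} or
#'   \code{"reference"} per channel.
#' @slot samplingRate sampling frequency in Hz.
#' @slot noiseFloor per-channel white-noise amplitude spectral density,
#'   fT/sqrt(Hz).
#' @slot baseline gradiometer baseline in metres (0 for magnetometers).
#' @exportClass SensorArray
setClass("SensorArray",
  representation(
    platform = "character",
    channelName = "character",
    position = "matrix",
    orientation = "matrix",
    kind = "character",
    samplingRate = "numeric",
    noiseFloor = "numeric",
    baseline = "numeric"
  )
)

setValidity("SensorArray", function(object) {
  n <- length(object@channelName)
  msg <- character(0)
  if (!object@platform %in% c("opm", "squid"))
    msg <- c(msg, "platform must be 'opm' or 'squid'")
  if (nrow(object@position) != n || nrow(object@orientation) != n ||
      length(object@kind) != n || length(object@noiseFloor) != n)
    msg <- c(msg, "channel slots must agree in length")
  nrm <- sqrt(rowSums(object@orientation^2))
  if (n > 0 && max(abs(nrm - 1)) > 1e-9)
    msg <- c(msg, "orientation vectors must have unit norm (tol 1e-9)")
  if (!all(object@kind %in% c("magnetometer", "axial_gradiometer", "reference")))
    msg <- c(msg, "unknown channel kind")
  if (length(msg)) msg else TRUE
})

#' Volumetric source space on a cubic grid inside a sphere
#'
#' @slot positions numeric matrix (nVoxel x 3), metres.
#' @slot centre conductor sphere centre (3-vector, metres).
#' @slot radius source sphere radius (m); all voxels strictly inside.
#' @slot spacing grid spacing (m).
#' @exportClass SourceSpace
setClass("SourceSpace",
  representation(
    positions = "matrix",
    centre = "numeric",
    radius = "numeric",
    spacing = "numeric"
  )
)

setValidity("SourceSpace", function(object) {
  d <- sqrt(rowSums(sweep(object@positions, 2, object@centre)^2))
  if (any(d >= object@radius)) return("all voxels must lie strictly inside the source sphere")
  TRUE
})

#' Lead field: dipole-to-channel gain matrix
#'
#' Gains in fT per nAm (for gradiometers: fT field difference between coils
#' per nAm), stored as an array [voxel, orientation(3), channel] on the
#' cardinal dipole orientations.
#'
#' @slot gains numeric array [nVoxel, 3, nChannel].
#' @slot space the \linkS4class{SourceSpace} used.
#' @slot channelName channel names (matching a \linkS4class{SensorArray}).
#' @exportClass LeadField
setClass("LeadField",
  representation(
    gains = "array",
    space = "SourceSpace",
    channelName = "character"
  )
)

setValidity("LeadField", function(object) {
  d <- dim(object@gains)
  msg <- character(0)
  if (length(d) != 3 || d[2] != 3) msg <- c(msg, "gains must be [voxel, 3, channel]")
  if (d[1] != nrow(object@space@positions)) msg <- c(msg, "voxel count mismatch")
  if (d[3] != length(object@channelName)) msg <- c(msg, "channel count mismatch")
  if (!all(is.finite(object@gains))) msg <- c(msg, "gains must be finite")
  if (length(msg)) msg else TRUE
})

#' Continuous multichannel MEG recording
#'
#' @slot platform \code{"opm"} or \code{"squid"}.
#' @slot subject subject identifier.
#' @slot run run identifier (1 or 2).
#' @slot data numeric matrix (nChannel x nSample), fT (magnetometers) or
#'   fT gradient difference (gradiometers).
#' @slot samplingRate Hz.
#' @slot events data.frame with columns onset, duration, trial_type, sample.
#' @slot array the \linkS4class{SensorArray} that recorded the data.
#' @exportClass Recording
setClass("Recording",
  representation(
    platform = "character",
    subject = "character",
    run = "integer",
    data = "matrix",
    samplingRate = "numeric",
    events = "data.frame",
    array = "SensorArray"
  )
)

setValidity("Recording", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (nrow(object@events) > 0 &&
      any(object@events$sample > ncol(object@data) | object@events$sample < 0))
    msg <- c(msg, "event samples must lie within the record")
  if (length(msg)) msg else TRUE
})

#' Trial-segmented data
#'
#' @slot data numeric array [trial, channel, sample].
#' @slot window numeric length-2, (t_start, t_end) seconds relative to event.
#' @slot samplingRate Hz.
#' @slot channelName channel names.
#' @slot trialIndex integer indices of the retained trials (into the original
#'   event list).
#' @slot trialInfo data.frame of per-trial metadata (e.g. cue side), one row
#'   per retained trial.
#' @slot band free-text band label (e.g. "beta 13-30 Hz").
#' @exportClass Epochs
setClass("Epochs",
  representation(
    data = "array",
    window = "numeric",
    samplingRate = "numeric",
    channelName = "character",
    trialIndex = "integer",
    trialInfo = "data.frame",
    band = "character"
  )
)

setValidity("Epochs", function(object) {
  d <- dim(object@data)
  msg <- character(0)
  if (length(d) != 3) msg <- c(msg, "data must be [trial, channel, sample]")
  if (d[1] != length(object@trialIndex)) msg <- c(msg, "trialIndex length mismatch")
  if (d[2] != length(object@channelName)) msg <- c(msg, "channelName length mismatch")
  if (length(msg)) msg else TRUE
})

#' LCMV beamformer weights
#'
#' @slot weights numeric matrix (nVoxel x nChannel); unit gain at own voxel.
#' @slot orientation numeric matrix (nVoxel x 3), chosen source orientation
#'   (maximum projected power).
#' @slot info list describing covariance windows and regularisation.
#' @exportClass BeamformerWeights
setClass("BeamformerWeights",
  representation(
    weights = "matrix",
    orientation = "matrix",
    info = "list"
  )
)

#' Pseudo-T image of beta modulation
#'
#' Voxel-wise normalised contrast of beamformer-projected power between a
#' late (rebound) and an early (desynchronisation) window:
#' (P_late - P_early) / (P_late + P_early), bounded in [-1, 1].
#'
#' @slot values numeric vector, one per voxel.
#' @slot space the \linkS4class{SourceSpace}.
#' @slot windows list with elements \code{early} and \code{late} (seconds).
#' @exportClass PseudoTImage
setClass("PseudoTImage",
  representation(
    values = "numeric",
    space = "SourceSpace",
    windows = "list"
  )
)

setValidity("PseudoTImage", function(object) {
  if (length(object@values) != nrow(object@space@positions))
    return("values length must equal voxel count")
  if (any(object@values < -1 - 1e-9 | object@values > 1 + 1e-9))
    return("pseudo-T values must lie in [-1, 1]")
  TRUE
})

#' Time-frequency spectrum of relative amplitude change
#'
#' R(t, f) = (A(t, f) - B(f)) / B(f) where A is the trial-averaged Hilbert
#' envelope and B its mean over the baseline window.
#'
#' @slot values numeric matrix [time, frequency].
#' @slot times seconds relative to trial start (cue end).
#' @slot freqs band centre frequencies, Hz.
#' @slot baselineWindow numeric length-2, seconds.
#' @slot voxel index of the source-space voxel probed.
#' @exportClass TFS
setClass("TFS",
  representation(
    values = "matrix",
    times = "numeric",
    freqs = "numeric",
    baselineWindow = "numeric",
    voxel = "integer"
  )
)

setValidity("TFS", function(object) {
  msg <- character(0)
  if (nrow(object@values) != length(object@times)) msg <- c(msg, "time axis mismatch")
  if (ncol(object@values) != length(object@freqs)) msg <- c(msg, "frequency axis mismatch")
  if (any(object@values < -1 - 1e-9)) msg <- c(msg, "R must be >= -1 (envelopes are non-negative)")
  if (length(msg)) msg else TRUE
})

#' Trial-averaged band-limited envelope timecourse(s)
#'
#' @slot amplitude numeric matrix [condition, time], non-negative.
#' @slot times seconds relative to trial start (cue end).
#' @slot conditions condition labels (e.g. all / attend_left / attend_right).
#' @slot band band label.
#' @slot voxel source-space voxel index.
#' @exportClass EnvelopeTimecourse
setClass("EnvelopeTimecourse",
  representation(
    amplitude = "matrix",
    times = "numeric",
    conditions = "character",
    band = "character",
    voxel = "integer"
  )
)

setValidity("EnvelopeTimecourse", function(object) {
  msg <- character(0)
  if (ncol(object@amplitude) != length(object@times)) msg <- c(msg, "time axis mismatch")
  if (nrow(object@amplitude) != length(object@conditions)) msg <- c(msg, "condition mismatch")
  if (any(object@amplitude < 0)) msg <- c(msg, "envelopes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Fingerprinting (identifiability) matrix
#'
#' Element [i, j] is the averaged feature correlation between subject i's
#' first dataset and subject j's second dataset (within-platform schemes), or
#' the mean of the four possible cross-platform comparisons.
#'
#' @slot values numeric N x N matrix of averaged correlations in [-1, 1].
#' @slot scheme \code{"within_opm"}, \code{"within_squid"} or
#'   \code{"cross_platform"}.
#' @slot featureSet \code{"beta"} (pseudo-T image + TFS) or \code{"evoked"}
#'   (evoked image + evoked timecourse).
#' @slot subjects subject identifiers (row/column order).
#' @exportClass FingerprintMatrix
setClass("FingerprintMatrix",
  representation(
    values = "matrix",
    scheme = "character",
    featureSet = "character",
    subjects = "character"
  )
)

setValidity("FingerprintMatrix", function(object) {
  msg <- character(0)
  if (nrow(object@values) != ncol(object@values)) msg <- c(msg, "matrix must be square")
  if (nrow(object@values) != length(object@subjects)) msg <- c(msg, "subject labels mismatch")
  if (!object@scheme %in% c("within_opm", "within_squid", "cross_platform"))
    msg <- c(msg, "unknown scheme")
  if (any(object@values < -1 - 1e-9 | object@values > 1 + 1e-9))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Permutation null distribution
#'
#' @slot observed observed statistic.
#' @slot samples permutation samples of the statistic.
#' @slot nPerm number of permutations.
#' @slot p empirical p-value (with +1 correction; in [1/(nPerm+1), 1]).
#' @slot tail \code{"greater"}, \code{"less"} or \code{"two_sided"}.
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(
    observed = "numeric",
    samples = "numeric",
    nPerm = "integer",
    p = "numeric",
    tail = "character"
  )
)

setValidity("NullDistribution", function(object) {
  msg <- character(0)
  if (length(object@samples) != object@nPerm) msg <- c(msg, "samples count must equal nPerm")
  if (object@p < 1 / (object@nPerm + 1) - 1e-12 || object@p > 1 + 1e-12)
    msg <- c(msg, "p must lie in [1/(nPerm+1), 1]")
  if (length(msg)) msg else TRUE
})
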