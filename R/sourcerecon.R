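# Source reconstruction: LCMV beamformer (pseudo-T beta images, virtual
# electrodes) and minimum-norm evoked imaging.

# Channel covariance from an Epochs object, optionally restricted to a time
# window (seconds relative to the event); per-trial, per-channel demeaning.
epochsCovariance <- function(epochs, window = NULL) {
  fs <- epochs@samplingRate
  t <- epochs@window[1] + (seq_len(dim(epochs@data)[3]) - 1) / fs
  sel <- if (is.null(window)) seq_along(t) else
    which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  nch <- dim(epochs@data)[2]
  C <- matrix(0, nch, nch)
  ns <- 0
  for (i in seq_len(dim(epochs@data)[1])) {
    X <- epochs@data[i, , sel, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nch)
    X <- X - rowMeans(X)
    C <- C + tcrossprod(X)
    ns <- ns + ncol(X)
  }
  C / max(ns - 1, 1)
}

# Lead field as an nChannel x (3 nVoxel) matrix, columns grouped per voxel.
leadfieldMatrix <- function(leadfield) {
  d <- dim(leadfield@gains)
  matrix(aperm(leadfield@gains, c(3, 2, 1)), d[3], 3 * d[1])
}

regularise <- function(C, regFraction) {
  sMax <- max(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  C + diag(regFraction * sMax, nrow(C))
}

# Core LCMV solve given a (regularised) covariance.
lcmvFromCovariance <- function(C, leadfield, info) {
  Ci <- tryCatch(solve(C), error = function(e)
    stop("covariance is singular after regularisation", call. = FALSE))
  Lm <- leadfieldMatrix(leadfield)
  CiL <- Ci %*% Lm
  nvox <- dim(leadfield@gains)[1]
  W <- matrix(0, nvox, nrow(C))
  ori <- matrix(0, nvox, 3)
  for (v in seq_len(nvox)) {
    idx <- (v - 1) * 3 + 1:3
    A <- crossprod(Lm[, idx], CiL[, idx])       # l' C^-1 l over orientations
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    # smallest non-degenerate eigenvalue maximises projected power; the
    # near-null (radial, magnetically silent) direction is excluded
    ok <- e$values > 1e-6 * e$values[1]
    u <- e$vectors[, max(which(ok))]
    if (u[which.max(abs(u))] < 0) u <- -u
    l <- drop(Lm[, idx] %*% u)
    Cil <- drop(CiL[, idx] %*% u)
    W[v, ] <- Cil / sum(l * Cil)
    ori[v, ] <- u
  }
  new("BeamformerWeights", weights = W, orientation = ori, info = info)
}

#' LCMV beamformer weights from task epochs
#'
#' The data covariance is the average of covariances computed in an "early"
#' (desynchronisation) and a "late" (rebound) window, regularised by adding
#' \code{regFraction} times its maximum singular value to the diagonal. Per
#' voxel, the source orientation is the one maximising beamformer-projected
#' power (the minimiser of l' C^-1 l over the three cardinal gains), and
#' the weights satisfy the unit-gain constraint w'l = 1.
#'
#' @param epochs beta-band \linkS4class{Epochs} (0-1.2 s stimulus windows).
#' @param leadfield a \linkS4class{LeadField} restricted to the epochs'
#'   channels.
#' @param early,late covariance windows, seconds relative to stimulus onset.
#' @param regFraction diagonal loading as a fraction of the maximum singular
#'   value (default 0.05).
#' @return a \linkS4class{BeamformerWeights}.
#' @export
lcmvWeights <- function(epochs, leadfield, early = c(0.2, 0.5),
                        late = c(0.75, 1.05), regFraction = 0.05) {
  stopIfNot(dim(epochs@data)[2] == length(leadfield@channelName),
            "epochs and leadfield channel counts differ")
  Ce <- epochsCovariance(epochs, early)
  Cl <- epochsCovariance(epochs, late)
  C <- regularise((Ce + Cl) / 2, regFraction)
  lcmvFromCovariance(C, leadfield,
                     info = list(early = early, late = late,
                                 regFraction = regFraction,
                                 covariance = C, Cearly = Ce, Clate = Cl))
}

#' LCMV weights from a continuous recording (broadband covariance)
#'
#' Used for virtual electrodes: covariance over all available samples of
#' the (band-filtered) recording, regularised as in \code{\link{lcmvWeights}}.
#'
#' @param recording a filtered \linkS4class{Recording}.
#' @param leadfield matching \linkS4class{LeadField}.
#' @param regFraction diagonal loading fraction.
#' @return a \linkS4class{BeamformerWeights}.
#' @export
continuousLcmvWeights <- function(recording, leadfield, regFraction = 0.05) {
  X <- recording@data - rowMeans(recording@data)
  C <- regularise(tcrossprod(X) / (ncol(X) - 1), regFraction)
  lcmvFromCovariance(C, leadfield,
                     info = list(early = NULL, late = NULL,
                                 regFraction = regFraction, covariance = C))
}

#' Pseudo-T image of beta modulation
#'
#' Per voxel, the beamformer-projected power P = w' C w is computed in the
#' early and late covariance windows and contrasted as
#' (P_late - P_early) / (P_late + P_early), a symmetric normalised contrast
#' bounded in [-1, 1] (0 where both powers vanish). Sensory sources, whose
#' rebound-window power exceeds their desynchronisation-window power, map
#' to positive values.
#'
#' @param weights \linkS4class{BeamformerWeights} from
#'   \code{\link{lcmvWeights}}.
#' @param epochs the same beta-band epochs (used when the weights carry no
#'   cached window covariances).
#' @param early,late windows, seconds.
#' @param space the \linkS4class{SourceSpace} (for the image container).
#' @return a \linkS4class{PseudoTImage}.
#' @export
pseudoTImage <- function(weights, epochs, space,
                         early = c(0.2, 0.5), late = c(0.75, 1.05)) {
  Ce <- if (!is.null(weights@info$Cearly) &&
            isTRUE(all.equal(weights@info$early, early)))
    weights@info$Cearly else epochsCovariance(epochs, early)
  Cl <- if (!is.null(weights@info$Clate) &&
            isTRUE(all.equal(weights@info$late, late)))
    weights@info$Clate else epochsCovariance(epochs, late)
  W <- weights@weights
  Pe <- rowSums((W %*% Ce) * W)
  Pl <- rowSums((W %*% Cl) * W)
  denom <- Pl + Pe
  val <- ifelse(denom > 0, (Pl - Pe) / denom, 0)
  new("PseudoTImage", values = val, space = space,
      windows = list(early = early, late = late))
}

#' Minimum norm estimate of the evoked response
#'
#' The trial-averaged sensor data m(t) are inverted with
#' J = L' (L L' + lambda2 tr(L L')/N I)^-1 m, i.e. an identity noise
#' covariance scaled to the lead field (lambda2 = 1/9 corresponds to the
#' conventional SNR = 3). Per voxel the three orientation timecourses are
#' summed in quadrature to a power timecourse; the image is taken at the
#' dataset's own evoked-peak time (the time of the maximum voxel power).
#'
#' @param epochs evoked-band (5-40 Hz) \linkS4class{Epochs}.
#' @param leadfield matching \linkS4class{LeadField}.
#' @param lambda2 regularisation parameter.
#' @return list with \code{power} (nVoxel x nSample), \code{times}
#'   (seconds), \code{image} (power at peak time), \code{peakVoxel},
#'   \code{peakTime}, and \code{J} (3 nVoxel x nSample orientation
#'   timecourses).
#' @export
mneEvoked <- function(epochs, leadfield, lambda2 = 1 / 9) {
  stopIfNot(dim(epochs@data)[2] == length(leadfield@channelName),
            "epochs and leadfield channel counts differ")
  m <- apply(epochs@data, c(2, 3), mean)
  Lm <- leadfieldMatrix(leadfield)
  G <- tcrossprod(Lm)
  G <- G + diag(lambda2 * sum(diag(G)) / nrow(G), nrow(G))
  J <- crossprod(Lm, tryCatch(solve(G, m), error = function(e)
    stop("Gram matrix is rank deficient", call. = FALSE)))
  nvox <- dim(leadfield@gains)[1]
  dim(J) <- c(3, nvox, ncol(m))
  power <- apply(J^2, c(2, 3), sum)
  times <- epochs@window[1] + (seq_len(ncol(m)) - 1) / epochs@samplingRate
  pk <- which(power == max(power), arr.ind = TRUE)[1, ]
  dim(J) <- c(3 * nvox, ncol(m))
  list(power = power, times = times, image = power[, pk[2]],
       peakVoxel = unname(pk[1]), peakTime = times[pk[2]], J = J)
}

#' Beamformer virtual electrode
#'
#' Projects channel data through one voxel's beamformer weights to give a
#' source-level timecourse. Linear in the data.
#'
#' @param weights a \linkS4class{BeamformerWeights}.
#' @param data a \linkS4class{Recording}, \linkS4class{Epochs} or numeric
#'   matrix (channels x samples).
#' @param voxel source-space voxel index.
#' @return numeric timecourse (for Epochs: a trials x samples matrix).
#' @export
virtualElectrode <- function(weights, data, voxel) {
  w <- weights@weights[voxel, ]
  if (is(data, "Recording")) return(drop(w %*% data@data))
  if (is(data, "Epochs")) {
    nt <- dim(data@data)[1]
    out <- matrix(0, nt, dim(data@data)[3])
    for (i in seq_len(nt))
      out[i, ] <- w %*% data@data[i, , , drop = TRUE]
    return(out)
  }
  drop(w %*% data)
}

#' Per-hemisphere peak voxels of a pseudo-T image
#'
#' Hemispheres are defined by the sign of the x coordinate of the shared
#' source grid; the peak is the within-hemisphere maximum of the image.
#' Voxels within \code{midlineExclusion} of the interhemispheric plane are
#' excluded: beamformer leakage between bilateral sources concentrates
#' there and can produce spurious deep maxima.
#'
#' @param image a \linkS4class{PseudoTImage} (or any per-voxel values with a
#'   \code{space}).
#' @param space optional \linkS4class{SourceSpace} when \code{image} is a
#'   bare numeric vector.
#' @param midlineExclusion half-width (m) of the excluded midline strip.
#' @return named integer vector with elements \code{left} (x < 0) and
#'   \code{right} (x > 0).
#' @export
hemispherePeaks <- function(image, space = NULL, midlineExclusion = 0.015) {
  if (is(image, "PseudoTImage")) {
    space <- image@space
    v <- image@values
  } else v <- image
  x <- space@positions[, 1]
  leftIdx <- which(x <= -midlineExclusion)
  rightIdx <- which(x >= midlineExclusion)
  if (!length(leftIdx) || !length(rightIdx))
    stop("midline exclusion removed an entire hemisphere", call. = FALSE)
  c(left = leftIdx[which.max(v[leftIdx])],
    right = rightIdx[which.max(v[rightIdx])])
}

#' Write a per-voxel image as TSV (x, y, z, value) with JSON peak metadata
#'
#' @param image a \linkS4class{PseudoTImage} or numeric vector.
#' @param space the \linkS4class{SourceSpace} (taken from the image if S4).
#' @param path TSV path; peak metadata goes to the matching .json.
#' @return \code{path}, invisibly.
#' @export
writeImageTsv <- function(image, path, space = NULL) {
  if (is(image, "PseudoTImage")) {
    space <- image@space
    v <- image@values
  } else v <- image
  df <- data.frame(x = space@positions[, 1], y = space@positions[, 2],
                   z = space@positions[, 3], value = v)
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pk <- hemispherePeaks(v, space)
  jsonlite::write_json(list(peak_left_voxel = pk[["left"]],
                            peak_right_voxel = pk[["right"]],
                            peak_value = max(v)),
                       sub("\\.tsv$", ".json", path),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}
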