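# Synthetic cohort: subject-stable neural "fingerprint" parameters and
# dual-platform sensor-level recordings.
#
# Each subject carries left/right primary-sensory beta sources whose
# narrowband oscillation desynchronises during each braille stimulus and
# rebounds above baseline afterwards, a bilateral evoked transient per
# stimulus, and a tonic attentional suppression of beta amplitude in the
# hemisphere contralateral to the cued hand. Between-subject variation in
# these parameters is what downstream fingerprinting must recover;
# within-subject run-to-run jitter is what it must be robust to.

#' Subject-specific fingerprint parameters
#'
#' @slot positionLeft,positionRight beta/evoked source centres (m).
#' @slot sigmaS spatial extent (Gaussian sigma, m) of the beta patch.
#' @slot betaPeak subject beta peak frequency, Hz (13-30).
#' @slot betaBandwidth carrier bandwidth, Hz.
#' @slot erdDepth fractional beta amplitude drop during stimulation (0, 1].
#' @slot rebound fractional rebound amplitudes for stimuli 1..5 (>= 0).
#' @slot betaAmp baseline beta source amplitude, nAm RMS.
#' @slot evokedAmp,evokedLatency,evokedWidth evoked transient amplitude
#'   (nAm), latency (s) and Gaussian width (s).
#' @slot attentionDepth fractional contralateral beta drop after the cue.
#' @slot momentAngle tangential moment orientation angle, radians.
#' @slot runJitter run-level multiplicative jitter scale (s.d.).
#' @exportClass SubjectParams
setClass("SubjectParams",
  representation(
    positionLeft = "numeric", positionRight = "numeric",
    sigmaS = "numeric", betaPeak = "numeric", betaBandwidth = "numeric",
    erdDepth = "numeric", rebound = "numeric", betaAmp = "numeric",
    evokedAmp = "numeric", evokedLatency = "numeric", evokedWidth = "numeric",
    attentionDepth = "numeric", momentAngle = "numeric", runJitter = "numeric"
  )
)

setValidity("SubjectParams", function(object) {
  msg <- character(0)
  if (object@erdDepth <= 0 || object@erdDepth > 1)
    msg <- c(msg, "erdDepth must lie in (0, 1]")
  if (any(object@rebound < 0)) msg <- c(msg, "rebound amplitudes must be >= 0")
  if (object@betaPeak < 13 || object@betaPeak > 30)
    msg <- c(msg, "betaPeak must lie in [13, 30] Hz")
  if (length(object@rebound) != 5) msg <- c(msg, "rebound must have 5 entries")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SubjectParams", function(object) {
  cat("SubjectParams: beta", round(object@betaPeak, 1), "Hz, ERD depth",
      round(object@erdDepth, 2), ", rebound",
      paste(round(object@rebound, 2), collapse = "/"),
      ", attention", round(object@attentionDepth, 2), "\n")
})

#' Sample fingerprint parameters for a cohort
#'
#' Parameters are drawn once per subject and are identical across that
#' subject's four sessions (two runs on each platform) up to the run-level
#' jitter applied at simulation time. \code{betweenScale} scales every
#' between-subject spread: 1 gives the default cohort, 0 makes all subjects
#' identical (the information-free regime in which identification should
#' fall to chance).
#'
#' @param nSubjects number of subjects (>= 1).
#' @param seed integer seed.
#' @param betweenScale multiplier on between-subject parameter spreads.
#' @param runJitter run-level multiplicative jitter s.d. (applied to
#'   amplitude-like parameters per run).
#' @return list of \linkS4class{SubjectParams}, length \code{nSubjects}.
#' @export
sampleCohortParams <- function(nSubjects = 15, seed = 1, betweenScale = 1,
                               runJitter = 0.05) {
  stopIfNot(nSubjects >= 1, "nSubjects must be >= 1")
  bs <- betweenScale
  withSeed(seed, {
    lapply(seq_len(nSubjects), function(i) {
      posL <- c(-0.035, 0.01, 0.06) + stats::rnorm(3, 0, 0.009) * bs
      posR <- c(0.035, 0.01, 0.06) + stats::rnorm(3, 0, 0.009) * bs
      # hand-area sources stay properly lateral (the hemisphere split is at
      # x = 0) and the whole patch strictly inside the 0.08 m source sphere
      clip <- function(p) {
        p[1] <- sign(p[1]) * min(max(abs(p[1]), 0.02), 0.05)
        if (sqrt(sum(p^2)) > 0.07) p * 0.07 / sqrt(sum(p^2)) else p
      }
      r0 <- 0.5 + 0.25 * stats::runif(1, -1, 1) * bs
      trend <- stats::runif(1, -0.15, 0.3) * bs
      new("SubjectParams",
          positionLeft = clip(posL), positionRight = clip(posR),
          sigmaS = 0.01 + 0.004 * stats::runif(1, -1, 1) * bs,
          betaPeak = min(30, max(13, 22 + 6 * stats::runif(1, -1, 1) * bs)),
          betaBandwidth = 4 + 1.5 * stats::runif(1, -1, 1) * bs,
          erdDepth = min(1, max(0.05, 0.5 + 0.15 * stats::runif(1, -1, 1) * bs)),
          rebound = pmax(0, r0 * (1 + trend * (0:4))),
          betaAmp = 8 + 3 * stats::runif(1, -1, 1) * bs,
          evokedAmp = 25 + 10 * stats::runif(1, -1, 1) * bs,
          evokedLatency = 0.05 + 0.015 * stats::runif(1, -1, 1) * bs,
          evokedWidth = 0.02 + 0.005 * stats::runif(1, -1, 1) * bs,
          attentionDepth = min(0.95, max(0, 0.2 + 0.05 * stats::runif(1, -1, 1) * bs)),
          momentAngle = pi / 4 + pi * stats::runif(1, -1, 1) * bs,
          runJitter = runJitter)
    })
  })
}

# Smooth boxcar over [a, b] with 20 ms logistic edges.
smoothBox <- function(t, a, b, edge = 0.02) {
  stats::plogis((t - a) / edge) * stats::plogis((b - t) / edge)
}

#' Deterministic beta-envelope profile for one hemisphere
#'
#' Ground-truth multiplicative envelope (baseline 1) used by the source
#' simulator: a drop of \code{erdDepth} during each stimulus (0.05-0.55 s
#' post-onset), a Gaussian rebound (centre 0.85 s post-onset, sigma 0.12 s)
#' scaled by the per-stimulus rebound amplitude, and - on trials where the
#' cue directs attention to the hand contralateral to \code{hemisphere} - a
#' tonic suppression of \code{attentionDepth} in the -0.8..1 s window around
#' cue end.
#'
#' @param params a \linkS4class{SubjectParams}.
#' @param schedule a \linkS4class{TrialSchedule}.
#' @param rate sampling rate, Hz.
#' @param hemisphere \code{"left"} or \code{"right"}.
#' @return numeric envelope, one value per sample of the concatenated run.
#' @export
betaEnvelopeProfile <- function(params, schedule, rate,
                                hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  dur <- trialDuration(schedule)
  n <- round(schedule@nTrials * dur * rate)
  t <- (seq_len(n) - 1) / rate
  env <- rep(1, n)
  attendedContra <- if (hemisphere == "left") "right" else "left"
  for (k in seq_len(schedule@nTrials)) {
    t0 <- (k - 1) * dur
    on <- t0 + schedule@onsets[k, ]
    for (j in 1:5) {
      env <- env - params@erdDepth * smoothBox(t, on[j] + 0.05, on[j] + 0.55)
      env <- env + params@rebound[j] * 0.5 *
        exp(-((t - on[j] - 0.85)^2) / (2 * 0.12^2))
    }
    if (schedule@cueSide[k] == attendedContra)
      env <- env - params@attentionDepth * smoothBox(t, t0 - 0.8, t0 + 1.0, 0.05)
  }
  pmax(env, 0.02)
}

# Narrowband Gaussian carrier, unit RMS: white noise FFT-filtered to
# peak +/- bandwidth/2 with raised-cosine edges.
betaCarrier <- function(n, rate, peak, bandwidth) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)                   # two-sided frequency axis
  lo <- peak - bandwidth / 2
  hi <- peak + bandwidth / 2
  H <- smoothBox(f, lo, hi, edge = 0.5)
  y <- Re(stats::fft(X * H, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# Biphasic evoked transient: difference of Gaussians, peak amplitude ~1.
evokedPulse <- function(u, width) {
  exp(-u^2 / (2 * width^2)) - 0.6 * exp(-(u - 1.5 * width)^2 / (2 * (1.5 * width)^2))
}

# Apply run-level multiplicative jitter to amplitude-like parameters.
jitterParams <- function(params, runSeed) {
  if (params@runJitter <= 0 || is.null(runSeed)) return(params)
  withSeed(runSeed, {
    j <- function(x) x * (1 + stats::rnorm(length(x), 0, params@runJitter))
    params@erdDepth <- min(1, max(0.02, j(params@erdDepth)))
    params@rebound <- pmax(0, j(params@rebound))
    params@betaAmp <- max(0.1, j(params@betaAmp))
    params@evokedAmp <- max(0.1, j(params@evokedAmp))
    params@attentionDepth <- min(0.95, max(0, j(params@attentionDepth)))
    params
  })
}

#' Simulate source-level dipole moment timecourses for one run
#'
#' Each hemisphere's source carries (a) a narrowband oscillation at the
#' subject's beta peak whose envelope follows
#' \code{\link{betaEnvelopeProfile}}, and (b) an evoked transient
#' (difference-of-Gaussians, with a smaller response at stimulus offset) at
#' each stimulus. The evoked waveform is deterministic and shared across
#' hemispheres (bilateral simultaneous stimulation drives correlated evoked
#' responses); the beta carriers are independent between hemispheres.
#'
#' @param params a \linkS4class{SubjectParams} (run jitter already applied
#'   if desired; see \code{runSeed}).
#' @param schedule a \linkS4class{TrialSchedule}.
#' @param rate sampling rate, Hz (>= 150).
#' @param seed seed for the stochastic beta carriers.
#' @param runSeed optional seed for run-level parameter jitter.
#' @return list with elements \code{left} and \code{right}; each is a list
#'   with \code{position}, \code{patchPositions} (7 x 3), \code{patchWeights},
#'   \code{momentDir} (unit tangential 3-vector), \code{timecourse} (nAm),
#'   \code{envelope} (ground-truth beta envelope), \code{rate}.
#' @export
simulateSources <- function(params, schedule, rate, seed = 1, runSeed = NULL) {
  stopIfNot(rate >= 150, "rate must be >= 150 Hz")
  params <- jitterParams(params, runSeed)
  dur <- trialDuration(schedule)
  n <- round(schedule@nTrials * dur * rate)
  t <- (seq_len(n) - 1) / rate

  evoked <- numeric(n)
  for (k in seq_len(schedule@nTrials)) {
    on <- (k - 1) * dur + schedule@onsets[k, ] + params@evokedLatency
    for (j in 1:5) {
      evoked <- evoked + evokedPulse(t - on[j], params@evokedWidth) +
        0.6 * evokedPulse(t - on[j] - schedule@timing[["stimulus_duration_s"]],
                          params@evokedWidth)
    }
  }
  evoked <- params@evokedAmp * evoked

  mkSource <- function(hemi, pos, carrierSeed) {
    env <- betaEnvelopeProfile(params, schedule, rate, hemi)
    carrier <- if (n > 0)
      withSeed(carrierSeed, betaCarrier(n, rate, params@betaPeak,
                                        params@betaBandwidth))
    else numeric(0)
    rad <- normalize(pos)
    ref <- if (abs(rad[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
    t1 <- normalize(c(ref[2] * rad[3] - ref[3] * rad[2],
                      ref[3] * rad[1] - ref[1] * rad[3],
                      ref[1] * rad[2] - ref[2] * rad[1]))
    t2 <- c(rad[2] * t1[3] - rad[3] * t1[2],
            rad[3] * t1[1] - rad[1] * t1[3],
            rad[1] * t1[2] - rad[2] * t1[1])
    dir <- cos(params@momentAngle) * t1 + sin(params@momentAngle) * t2
    offs <- rbind(c(0, 0, 0), diag(3), -diag(3))
    patch <- sweep(params@sigmaS * offs, 2, pos, "+")
    w <- c(1, rep(exp(-0.5), 6))
    list(position = pos, patchPositions = patch, patchWeights = w / sum(w),
         momentDir = dir,
         timecourse = params@betaAmp * env * carrier + evoked,
         envelope = env, rate = rate)
  }

  list(left = mkSource("left", params@positionLeft, childSeed(seed, "L")),
       right = mkSource("right", params@positionRight, childSeed(seed, "R")))
}

# Per-channel gain vector (fT/nAm) of one patch source, including axial
# gradiometer differencing.
sourceGain <- function(array, source, centre = c(0, 0, 0)) {
  nchan <- length(array@channelName)
  isGrad <- array@kind == "axial_gradiometer"
  pts <- array@position
  if (any(isGrad))
    pts <- rbind(pts, array@position[isGrad, , drop = FALSE] +
                   array@baseline * array@orientation[isGrad, , drop = FALSE])
  g <- numeric(nchan)
  for (p in seq_len(nrow(source$patchPositions))) {
    B <- sarvasFieldMany(source$patchPositions[p, ], source$momentDir, pts, centre)
    proj <- rowSums(B[seq_len(nchan), , drop = FALSE] * array@orientation)
    if (any(isGrad)) {
      outer_ <- rowSums(B[-seq_len(nchan), , drop = FALSE] *
                          array@orientation[isGrad, , drop = FALSE])
      proj[isGrad] <- proj[isGrad] - outer_
    }
    g <- g + source$patchWeights[p] * proj
  }
  g
}

#' Project sources to sensors and add platform noise
#'
#' Channel data are the gain-weighted sum of the source moment timecourses
#' plus white sensor noise at the platform noise floor (variance
#' floor^2 * rate / 2, i.e. a flat spectrum up to Nyquist). Optionally adds
#' a spatially uniform interference field (for testing homogeneous field
#' correction; axial gradiometers reject it by construction) and/or a
#' low-frequency drift seen by both scalp and reference channels (for
#' testing reference gradiometry).
#'
#' @param sources output of \code{\link{simulateSources}} (its \code{rate}
#'   must match the array's).
#' @param array a \linkS4class{SensorArray}.
#' @param seed noise seed.
#' @param events event table for the run (see \code{\link{scheduleToEvents}}).
#' @param subject,run metadata for the \linkS4class{Recording}.
#' @param noise logical; add white sensor noise?
#' @param interferenceAmp amplitude (fT) of a spatially uniform interference
#'   field with a random slowly varying direction; 0 disables.
#' @param driftAmp amplitude (fT) of a reference-correlated low-frequency
#'   drift; 0 disables.
#' @param centre conductor sphere centre.
#' @return a \linkS4class{Recording}.
#' @export
projectAndNoise <- function(sources, array, seed = 1,
                            events = data.frame(), subject = "01", run = 1L,
                            noise = TRUE, interferenceAmp = 0, driftAmp = 0,
                            centre = c(0, 0, 0)) {
  rate <- array@samplingRate
  for (s in sources)
    if (length(s$timecourse) && !isTRUE(all.equal(s$rate, rate)))
      stop("rate mismatch between sources and array", call. = FALSE)
  n <- if (length(sources)) length(sources[[1]]$timecourse) else 0L
  nchan <- length(array@channelName)
  dat <- matrix(0, nchan, n)
  for (s in sources) {
    if (!length(s$timecourse)) next
    g <- sourceGain(array, s, centre)
    dat <- dat + tcrossprod(g, s$timecourse)
  }
  withSeed(seed, {
    if (noise && n > 0) {
      sd_ <- array@noiseFloor * sqrt(rate / 2)
      dat <- dat + matrix(stats::rnorm(nchan * n), nchan, n) * sd_
    }
    if (interferenceAmp > 0 && n > 0) {
      # uniform field: direction wanders slowly, same vector at every sensor
      tt <- (seq_len(n) - 1) / rate
      u <- rbind(sin(2 * pi * 0.7 * tt), sin(2 * pi * 1.1 * tt + 1),
                 sin(2 * pi * 0.4 * tt + 2)) * interferenceAmp
      isGrad <- array@kind == "axial_gradiometer"
      contrib <- array@orientation %*% u
      contrib[isGrad, ] <- 0          # gradiometers reject uniform fields
      dat <- dat + contrib
    }
    if (driftAmp > 0 && n > 0) {
      drift <- cumsum(stats::rnorm(n)) / sqrt(n)
      drift <- driftAmp * drift / max(abs(drift), 1e-12)
      isRef <- array@kind == "reference"
      coef <- ifelse(isRef, 1, 0.8 + 0.4 * stats::runif(nchan))
      dat <- dat + tcrossprod(coef, drift)
    }
  })
  new("Recording", platform = array@platform, subject = subject,
      run = as.integer(run), data = dat, samplingRate = rate,
      events = if (nrow(events)) events else
        data.frame(onset = numeric(0), duration = numeric(0),
                   trial_type = character(0), sample = integer(0)),
      array = array)
}

#' Generate a full synthetic cohort on disk (BIDS-like layout)
#'
#' Writes, for each subject, four sessions (opm run 1/2, squid run 1/2)
#' under \code{sub-XX/ses-<platform><run>/meg/} with the channel data as a
#' TSV array container, a \code{*_events.tsv} table, a \code{*_channels.tsv}
#' geometry table with JSON sidecar, and the subject's ground-truth
#' parameters as JSON (so source-reconstruction accuracy can be checked
#' against truth).
#'
#' @param path output directory (created if needed).
#' @param nSubjects number of subjects.
#' @param runsPerPlatform runs per platform per subject.
#' @param nTrials trials per run.
#' @param seed master seed; all per-run seeds derive from it.
#' @param betweenScale,runJitter forwarded to
#'   \code{\link{sampleCohortParams}}.
#' @param opmArray,squidArray sensor arrays (defaults built on the fly).
#' @return invisibly, a manifest data.frame (subject, platform, run, paths).
#' @export
generateCohort <- function(path, nSubjects = 15, runsPerPlatform = 2,
                           nTrials = 80, seed = 1, betweenScale = 1,
                           runJitter = 0.05,
                           opmArray = buildSensorArray("opm"),
                           squidArray = buildSensorArray("squid")) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output path: ", path, call. = FALSE)
  cohort <- sampleCohortParams(nSubjects, seed, betweenScale, runJitter)
  arrays <- list(opm = opmArray, squid = squidArray)
  rows <- list()
  for (i in seq_len(nSubjects)) {
    sub <- sprintf("sub-%02d", i)
    jsonlite::write_json(paramsToList(cohort[[i]]),
                         file.path(path, paste0(sub, "_params.json")),
                         digits = NA, auto_unbox = TRUE)
    for (plat in c("opm", "squid")) {
      for (r in seq_len(runsPerPlatform)) {
        arr <- arrays[[plat]]
        ses <- file.path(path, sub, sprintf("ses-%s%d", plat, r), "meg")
        dir.create(ses, recursive = TRUE, showWarnings = FALSE)
        sched <- generateSchedule(nTrials, seed = childSeed(seed, i, plat, r, "sched"))
        ev <- scheduleToEvents(sched, arr@samplingRate)
        src <- simulateSources(cohort[[i]], sched, arr@samplingRate,
                               seed = childSeed(seed, i, plat, r, "carrier"),
                               runSeed = childSeed(seed, i, plat, r, "jitter"))
        rec <- projectAndNoise(src, arr, seed = childSeed(seed, i, plat, r, "noise"),
                               events = ev, subject = sprintf("%02d", i),
                               run = r)
        stem <- file.path(ses, sprintf("%s_ses-%s%d_task-braille", sub, plat, r))
        writeEventsTsv(ev, paste0(stem, "_events.tsv"))
        writeArrayTsv(arr, paste0(stem, "_channels.tsv"))
        utils::write.table(format(t(rec@data), digits = 8, trim = TRUE),
                           paste0(stem, "_meg.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE,
                           col.names = arr@channelName)
        jsonlite::write_json(list(subject = sprintf("%02d", i), platform = plat,
                                  run = r, sampling_rate_hz = arr@samplingRate,
                                  n_samples = ncol(rec@data)),
                             paste0(stem, "_meg.json"),
                             digits = NA, auto_unbox = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          subject = sub, platform = plat, run = r,
          data = paste0(stem, "_meg.tsv"), events = paste0(stem, "_events.tsv"))
      }
    }
  }
  invisible(do.call(rbind, rows))
}

paramsToList <- function(p) {
  list(position_left = p@positionLeft, position_right = p@positionRight,
       sigma_s = p@sigmaS, beta_peak_hz = p@betaPeak,
       beta_bandwidth_hz = p@betaBandwidth, erd_depth = p@erdDepth,
       rebound = p@rebound, beta_amp_nAm = p@betaAmp,
       evoked_amp_nAm = p@evokedAmp, evoked_latency_s = p@evokedLatency,
       evoked_width_s = p@evokedWidth, attention_depth = p@attentionDepth,
       moment_angle_rad = p@momentAngle, run_jitter = p@runJitter)
}
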