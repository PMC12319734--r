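# End-to-end orchestration: simulate -> preprocess -> localise -> features
# -> fingerprint -> report, as a configured, seeded, reproducible run.

#' Build a pipeline run configuration
#'
#' Every threshold carries the analysis default: 5/20 fT/sqrt(Hz) channel
#' screening bounds in the 60-80 Hz band, 4 pT trial rejection, 5%
#' covariance regularisation, 1-100 / 13-30 / 5-40 Hz bands, 0-1.2 s
#' stimulus epochs with 0.2-0.5 s and 0.75-1.05 s covariance windows,
#' 12-13.5 s TFS baseline, -0.8..1 s attention window, and 100,000 /
#' 10,000 permutations for the diagonal and group nulls. Configurations
#' round-trip losslessly through \code{\link{writeRunConfig}}.
#'
#' @param nSubjects,runsPerPlatform,nTrials cohort size.
#' @param seed master seed; all stage seeds derive from it.
#' @param betweenScale,runJitter cohort parameter spreads (see
#'   \code{\link{sampleCohortParams}}).
#' @param gridSpacing source grid spacing, metres.
#' @param tfsFreqs,tfsBandwidth TFS band centres and width, Hz.
#' @param nPermDiagonal,nPermGroup permutation counts.
#' @param squidAutoReject apply the automated 4 pT rule to SQUID data too.
#' @param ... overrides for the remaining defaults listed above.
#' @return a named list of class \code{RunConfig}.
#' @export
runConfig <- function(nSubjects = 15, runsPerPlatform = 2, nTrials = 80,
                      seed = 1, betweenScale = 1, runJitter = 0.05,
                      gridSpacing = 0.005,
                      tfsFreqs = seq(1.5, 99.5, by = 0.5), tfsBandwidth = 1,
                      nPermDiagonal = 100000, nPermGroup = 10000,
                      squidAutoReject = FALSE, ...) {
  cfg <- list(
    nSubjects = nSubjects, runsPerPlatform = runsPerPlatform,
    nTrials = nTrials, seed = seed, betweenScale = betweenScale,
    runJitter = runJitter,
    headRadius = 0.09, sourceRadius = 0.08, gridSpacing = gridSpacing,
    screenLow = 5, screenHigh = 20, screenBand = c(60, 80),
    p2pLimit = 4000, regFraction = 0.05, mneLambda2 = 1 / 9,
    broadband = c(1, 100), betaBand = c(13, 30), evokedBand = c(5, 40),
    epochWindow = c(0, 1.2), early = c(0.2, 0.5), late = c(0.75, 1.05),
    tfsFreqs = tfsFreqs, tfsBandwidth = tfsBandwidth,
    baselineWindow = c(12, 13.5), attentionWindow = c(-0.8, 1),
    attentionEpoch = c(-1, 1.2),
    nPermDiagonal = nPermDiagonal, nPermGroup = nPermGroup,
    comparisonResolution = 0.001, squidAutoReject = squidAutoReject,
    featureSets = c("beta", "evoked"))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config key: ", nm, call. = FALSE)
    cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "RunConfig"
  cfg
}

#' Serialise / restore a run configuration (lossless)
#'
#' @param config a \code{RunConfig}.
#' @param path JSON path.
#' @return \code{writeRunConfig}: \code{path}, invisibly;
#'   \code{readRunConfig}: the \code{RunConfig}.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$squidAutoReject <- isTRUE(cfg$squidAutoReject)
  class(cfg) <- "RunConfig"
  cfg
}

# Simulate and fully process one dataset (subject x platform x run),
# returning its fingerprint features and a processing log entry.
processDataset <- function(params, array, leadfield, config,
                           subjectId, plat, run) {
  seed <- config$seed
  rate <- array@samplingRate
  sched <- generateSchedule(config$nTrials,
                            seed = childSeed(seed, subjectId, plat, run, "sched"))
  ev <- scheduleToEvents(sched, rate)
  src <- simulateSources(params, sched, rate,
                         seed = childSeed(seed, subjectId, plat, run, "carrier"),
                         runSeed = childSeed(seed, subjectId, plat, run, "jitter"))
  rec <- projectAndNoise(src, array,
                         seed = childSeed(seed, subjectId, plat, run, "noise"),
                         events = ev, subject = subjectId, run = run)

  removedChannels <- character(0)
  if (plat == "opm") {
    scr <- screenChannels(rec, config$screenLow, config$screenHigh,
                          config$screenBand)
    removedChannels <- scr$removed
    rec <- scr$recording
    rec <- applyHFC(rec)
  } else {
    removedChannels <- rec@array@channelName[rec@array@kind == "reference"]
    rec <- referenceGradiometry(rec)
  }
  lf <- subsetChannels(leadfield, rec@array@channelName)

  doEvoked <- "evoked" %in% config$featureSets
  bands <- list(beta = config$betaBand, broad = config$broadband)
  if (doEvoked) bands$evoked <- config$evokedBand
  filt <- bandpassBands(rec, bands)
  recBeta <- filt$beta
  recBroad <- filt$broad

  doReject <- plat == "opm" || config$squidAutoReject
  epBeta <- epochData(recBeta, config$epochWindow, "^stim_", "beta")
  removedTrials <- integer(0)
  if (doReject) {
    rej <- rejectEpochs(epBeta, config$p2pLimit)
    epBeta <- rej$epochs
    removedTrials <- rej$removed
  }

  bw <- lcmvWeights(epBeta, lf, config$early, config$late, config$regFraction)
  pti <- pseudoTImage(bw, epBeta, lf@space, config$early, config$late)
  peaks <- hemispherePeaks(pti)

  dur <- trialDuration(sched)
  cueEv <- ev[grepl("^cue_", ev$trial_type), ]
  starts <- cueEv$sample
  trialSamples <- floor(dur * rate)
  over <- max(starts) + trialSamples - ncol(rec@data)
  if (over > 0) trialSamples <- trialSamples - over

  # TFS at the beta-modulation peak of each hemisphere; the stacked
  # left/right spectra form the spectral fingerprint feature
  wBroad <- continuousLcmvWeights(recBroad, lf, config$regFraction)
  tfsBoth <- lapply(c(left = "left", right = "right"), function(hemi) {
    ve <- virtualElectrode(wBroad, recBroad, peaks[[hemi]])
    computeTFS(ve, rate, starts, trialSamples,
               freqs = config$tfsFreqs, bandwidth = config$tfsBandwidth,
               baselineWindow = config$baselineWindow,
               voxel = peaks[[hemi]])
  })
  tfs <- tfsBoth$left

  wBeta <- continuousLcmvWeights(recBeta, lf, config$regFraction)
  cueSide <- sub("^cue_", "", cueEv$trial_type)
  envFull <- list()
  envCond <- list()
  for (hemi in c("left", "right")) {
    veB <- virtualElectrode(wBeta, recBeta, peaks[[hemi]])
    envFull[[hemi]] <- betaEnvelope(veB, rate, starts,
                                    window = c(0, (trialSamples - 1) / rate),
                                    voxel = peaks[[hemi]])
    envCond[[hemi]] <- betaEnvelope(veB, rate, starts,
                                    window = config$attentionEpoch,
                                    conditions = cueSide,
                                    voxel = peaks[[hemi]])
  }

  evokedFeat <- NULL
  evTc <- NULL
  mne <- NULL
  if (doEvoked) {
    epEvoked <- epochData(filt$evoked, config$epochWindow, "^stim_", "evoked")
    if (doReject) epEvoked <- rejectEpochs(epEvoked, config$p2pLimit)$epochs
    mne <- mneEvoked(epEvoked, lf, config$mneLambda2)
    evTc <- evokedPowerTimecourse(mne)
    evokedFeat <- list(image = mne$image, profile = evTc$power,
                       times = mne$times)
  }

  list(
    beta = list(image = pti@values,
                profile = cbind(tfsBoth$left@values, tfsBoth$right@values),
                times = tfs@times),
    evoked = evokedFeat,
    envelopeAll = envFull$left@amplitude["all", ],
    envelopeTimes = envFull$left@times,
    envelopeEvoked = if (doEvoked) evTc$power else NULL,
    evokedTimes = if (doEvoked) mne$times else NULL,
    envCond = envCond,
    peaks = peaks,
    log = list(subject = subjectId, platform = plat, run = run,
               n_channels_removed = length(removedChannels),
               channels_removed = removedChannels,
               n_trials_removed = length(removedTrials),
               n_trials_retained = nTrials(epBeta))
  )
}

#' Run the full cross-platform fingerprinting pipeline
#'
#' Simulates the configured synthetic cohort (both platforms, all runs),
#' preprocesses each recording (channel screening + homogeneous field
#' correction for OPM; reference gradiometry for SQUID; zero-phase FIR
#' band-pass filters; epoching with peak-to-peak trial rejection),
#' reconstructs sources (LCMV pseudo-T beta images, minimum-norm evoked
#' images), derives the fingerprint features (TFS at the left-hemisphere
#' beta peak; evoked power timecourse at the evoked peak), and computes the
#' fingerprinting matrices, identification counts, diagonal permutation
#' nulls, the sham-mixing group-timecourse nulls, and the attentional
#' contrast per platform.
#'
#' @param config a \code{RunConfig} from \code{\link{runConfig}}.
#' @param outputDir optional directory: matrices (TSV), null summaries and
#'   the per-stage log (JSON) are written there.
#' @param verbose print per-dataset progress.
#' @return a results list: \code{matrices} (beta and evoked feature sets,
#'   three schemes each), \code{identification}, \code{permTests},
#'   \code{groupNull}, \code{attention}, \code{features}, \code{log},
#'   \code{config}.
#' @export
runPipeline <- function(config = runConfig(), outputDir = NULL,
                        verbose = FALSE) {
  arrays <- list(opm = buildSensorArray("opm", config$headRadius),
                 squid = buildSensorArray("squid", config$headRadius))
  space <- buildSourceSpace(config$gridSpacing, config$sourceRadius)
  leadfields <- list(opm = computeLeadfield(space, arrays$opm),
                     squid = computeLeadfield(space, arrays$squid))
  cohort <- sampleCohortParams(config$nSubjects, config$seed,
                               config$betweenScale, config$runJitter)

  features <- list()
  peaks <- list()
  logs <- list()
  envAll <- list(opm = list(), squid = list())
  envEvoked <- list(opm = list(), squid = list())
  envCond <- list(opm = list(), squid = list())
  for (i in seq_len(config$nSubjects)) {
    sid <- sprintf("%02d", i)
    features[[sid]] <- list()
    for (plat in c("opm", "squid")) {
      for (r in seq_len(config$runsPerPlatform)) {
        if (verbose)
          message("subject ", sid, " ", plat, " run ", r)
        ds <- processDataset(cohort[[i]], arrays[[plat]], leadfields[[plat]],
                             config, sid, plat, r)
        key <- paste0(plat, r)
        features[[sid]][[key]] <- ds$beta
        if (!is.null(ds$evoked))
          features[[sid]][[paste0(key, "_evoked")]] <- ds$evoked
        envAll[[plat]][[sid]][[r]] <-
          list(amp = ds$envelopeAll, times = ds$envelopeTimes)
        if (!is.null(ds$envelopeEvoked))
          envEvoked[[plat]][[sid]][[r]] <-
            list(amp = ds$envelopeEvoked, times = ds$evokedTimes)
        envCond[[plat]][[sid]][[r]] <- ds$envCond
        peaks[[sid]][[key]] <- ds$peaks
        logs[[length(logs) + 1]] <- ds$log
      }
    }
  }

  doEvoked <- "evoked" %in% config$featureSets
  betaFeat <- lapply(features, function(f)
    f[c("opm1", "opm2", "squid1", "squid2")])
  schemes <- c("within_opm", "within_squid", "cross_platform")
  matrices <- list(beta = list())
  for (sc in schemes)
    matrices$beta[[sc]] <- buildFingerprintMatrix(
      betaFeat, sc, "beta", config$comparisonResolution)
  if (doEvoked) {
    evokedFeat <- lapply(features, function(f) {
      out <- f[paste0(c("opm1", "opm2", "squid1", "squid2"), "_evoked")]
      names(out) <- c("opm1", "opm2", "squid1", "squid2")
      out
    })
    matrices$evoked <- list()
    for (sc in schemes)
      matrices$evoked[[sc]] <- buildFingerprintMatrix(
        evokedFeat, sc, "evoked", config$comparisonResolution)
  }
  identification <- lapply(matrices, function(ms)
    vapply(ms, function(m) identifySubjects(m)$nIdentified, numeric(1)))
  permTests <- if (config$nSubjects >= 3) lapply(matrices, function(ms) {
    out <- list()
    for (sc in schemes)
      out[[sc]] <- diagonalPermutationTest(ms[[sc]], config$nPermDiagonal,
                                           seed = childSeed(config$seed, "perm", sc))
    out
  }) else NULL

  # subject-average timecourses per platform on a shared grid
  groupNull <- list()
  for (feat in names(matrices)) {
    src <- if (feat == "beta") envAll else envEvoked
    tOpm <- src$opm[[1]][[1]]$times
    tSquid <- src$squid[[1]][[1]]$times
    grid <- seq(max(min(tOpm), min(tSquid)), min(max(tOpm), max(tSquid)),
                by = config$comparisonResolution)
    avg <- function(plat) t(vapply(src[[plat]], function(runs) {
      tc <- rowMeans(vapply(runs, function(r) r$amp, numeric(length(runs[[1]]$amp))))
      resampleTimecourse(tc, runs[[1]]$times, grid)
    }, numeric(length(grid))))
    groupNull[[feat]] <- groupTimecourseNull(avg("opm"), avg("squid"),
                                             config$nPermGroup,
                                             seed = childSeed(config$seed, "group", feat))
  }

  # attentional contrast per platform (runs averaged per subject)
  attention <- list()
  for (plat in c("opm", "squid")) {
    envs <- lapply(envCond[[plat]], function(runs) {
      combine <- function(hemi) {
        e1 <- runs[[1]][[hemi]]
        amp <- e1@amplitude
        if (length(runs) > 1)
          for (r in 2:length(runs)) {
            e2 <- runs[[r]][[hemi]]
            amp <- amp + e2@amplitude[match(e1@conditions, e2@conditions), ,
                                      drop = FALSE]
          }
        e1@amplitude <- amp / length(runs)
        e1
      }
      list(left = combine("left"), right = combine("right"))
    })
    attention[[plat]] <- attentionalContrast(envs, config$attentionWindow)
  }

  results <- list(config = config, matrices = matrices,
                  identification = identification, permTests = permTests,
                  groupNull = groupNull, attention = attention,
                  features = features, peaks = peaks, log = logs)
  if (!is.null(outputDir)) writeResults(results, outputDir)
  results
}

# Write the result bundle: matrices as TSV, summaries and logs as JSON.
writeResults <- function(results, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  for (feat in names(results$matrices))
    for (sc in names(results$matrices[[feat]]))
      writeFingerprintTsv(results$matrices[[feat]][[sc]],
                          file.path(outputDir,
                                    sprintf("fingerprint_%s_%s.tsv", feat, sc)))
  summary_ <- list(
    identification = lapply(results$identification, as.list),
    permutation_p = lapply(results$permTests, function(ms)
      lapply(ms, function(nd) nd@p)),
    group_correlation = lapply(results$groupNull, function(nd)
      list(observed = nd@observed, p = nd@p)),
    attention_p = lapply(results$attention, function(a) a$p))
  jsonlite::write_json(summary_, file.path(outputDir, "summary.json"),
                       digits = NA, auto_unbox = TRUE)
  writeLines(vapply(results$log, function(l)
    jsonlite::toJSON(l, auto_unbox = TRUE), character(1)),
    file.path(outputDir, "stages.jsonl"))
  writeRunConfig(results$config, file.path(outputDir, "config.json"))
  invisible(outputDir)
}
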