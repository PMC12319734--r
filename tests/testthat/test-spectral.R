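test_that("the Hilbert envelope of a sinusoid equals its amplitude", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  x <- 3.2 * sin(2 * pi * 17 * t)
  env <- hilbertEnvelope(x)
  central <- seq(fs, 9 * fs)
  expect_lt(max(abs(env[central] - 3.2)) / 3.2, 0.01)
  expect_equal(hilbertEnvelope(rep(0, 100)), rep(0, 100))
  expect_equal(hilbertEnvelope(2.5 * x), 2.5 * env, tolerance = 1e-12)
})

test_that("a stationary signal yields a flat TFS", {
  fs <- 250
  n <- 30 * fs
  t <- (seq_len(n) - 1) / fs
  freqs <- seq(5, 95, 10)
  # constant-envelope multi-tone: every analysis band sees a stationary
  # amplitude, so R should vanish everywhere
  x <- rowSums(sapply(seq_along(freqs), function(k)
    sin(2 * pi * freqs[k] * t + k)))
  # trials placed away from the record edges (reflection padding distorts
  # the envelope within ~1/bandwidth of the record boundaries)
  tfs <- computeTFS(x, fs, trialStarts = c(1 * fs, 15 * fs),
                    trialSamples = 14 * fs, freqs = freqs, bandwidth = 1)
  expect_lt(max(abs(tfs@values)), 0.05)
  # baseline-window mean is ~0 by construction
  bsel <- tfs@times >= 12 & tfs@times <= 13.5
  expect_lt(max(abs(colMeans(tfs@values[bsel, ]))), 1e-10)
})

test_that("an envelope step from b to 2b maps to an R step from 0 to 1", {
  fs <- 250
  t <- (0:(28 * fs - 1)) / fs
  env <- ifelse(t %% 14 < 7, 1, 2)         # first half baseline-level b
  x <- env * sin(2 * pi * 21 * t)
  tfs <- computeTFS(x, fs, trialStarts = c(0, 14 * fs),
                    trialSamples = 14 * fs, freqs = 21, bandwidth = 1,
                    baselineWindow = c(2, 5))
  expect_lt(max(abs(tfs@values[tfs@times > 2 & tfs@times < 5, 1])), 0.05)
  expect_equal(mean(tfs@values[tfs@times > 9 & tfs@times < 12, 1]), 1,
               tolerance = 0.05)
})

test_that("a planted sustained desynchronisation is recovered at depth", {
  fs <- 250
  t <- (0:(28 * fs - 1)) / fs
  env <- 1 - 0.4 * megfingerprint:::smoothBox(t %% 14, 6, 10)
  x <- env * sin(2 * pi * 21 * t)
  tfs <- computeTFS(x, fs, trialStarts = c(0, 14 * fs),
                    trialSamples = 14 * fs, freqs = c(20.5, 21, 21.5),
                    bandwidth = 1, baselineWindow = c(1, 5))
  dip <- min(tfs@values[tfs@times > 6 & tfs@times < 10, 2])
  expect_equal(dip, -0.4, tolerance = 0.05)
})

test_that("a zero baseline raises a division-guard error", {
  fs <- 250
  expect_error(computeTFS(numeric(14 * fs), fs, 0, 14 * fs, freqs = 85,
                          bandwidth = 1), "baseline")
})

test_that("trial-averaged envelopes reduce to the single-trial envelope", {
  fs <- 250
  oneTrial <- sin(2 * pi * 19 * (0:(2 * fs - 1)) / fs) *
    (1 + 0.5 * sin(2 * pi * 0.7 * (0:(2 * fs - 1)) / fs))
  x <- rep(oneTrial, 4)
  env <- betaEnvelope(x, fs, trialStarts = (0:3) * 2 * fs,
                      window = c(0, 2 - 1 / fs))
  single <- hilbertEnvelope(x)[1:(2 * fs)]
  mid <- seq(0.2 * fs, 1.8 * fs)
  expect_equal(env@amplitude["all", mid], single[mid], tolerance = 0.05)
})

test_that("beta envelopes dip at each of the five stimulus onsets", {
  params <- referenceParams(erdDepth = 0.6, rebound = rep(0.3, 5))
  sched <- generateSchedule(6, seed = 12)
  fs <- 250
  src <- simulateSources(params, sched, fs, seed = 5)
  ve <- bandpassFilter(src$left$timecourse, 13, 30, rate = fs)
  dur <- trialDuration(sched)
  starts <- round((seq_len(6) - 1) * dur * fs)
  env <- betaEnvelope(ve, fs, starts, c(0, 13))
  base <- mean(env@amplitude["all", env@times > 12])
  for (j in 1:5) {
    on <- sched@onsets[1, j]
    sel <- env@times >= on & env@times <= on + 0.8
    tDip <- env@times[sel][which.min(env@amplitude["all", sel])]
    expect_lt(min(env@amplitude["all", sel]), 0.75 * base)
    expect_gt(tDip, on)          # dip follows the onset
  }
})

test_that("condition splitting is unbiased when attention has no effect", {
  params <- referenceParams(attentionDepth = 0)
  sched <- generateSchedule(10, seed = 13)
  fs <- 250
  src <- simulateSources(params, sched, fs, seed = 6)
  ve <- bandpassFilter(src$left$timecourse, 13, 30, rate = fs)
  dur <- trialDuration(sched)
  starts <- round((seq_len(10) - 1) * dur * fs)
  env <- betaEnvelope(ve, fs, starts, c(0, 13), conditions = sched@cueSide)
  mL <- mean(env@amplitude["left", ])
  mR <- mean(env@amplitude["right", ])
  # 5 trials/condition leave ~4.5% sampling noise on the difference of
  # condition means; 15% is ~3 sigma and well below the planted effects
  expect_lt(abs(mL - mR) / ((mL + mR) / 2), 0.15)
  expect_error(betaEnvelope(ve, fs, starts, c(0, 13),
                            conditions = rep("left", 10)), NA)
})

test_that("the evoked power timecourse peaks at the planted latency", {
  arr <- opmArray()
  space <- buildSourceSpace(0.01, 0.05)
  lf <- computeLeadfield(space, arr)
  params <- referenceParams()
  params@positionLeft <- c(-0.028, 0.008, 0.032)
  sim <- singleSourceRecording(arr, params, nTrials = 2, noise = FALSE)
  ep <- epochData(bandpassFilter(sim$recording, 5, 40), c(0, 1.2),
                  "^stim_", "evoked")
  mne <- mneEvoked(ep, lf)
  tc <- evokedPowerTimecourse(mne)
  expect_lt(abs(tc$times[which.max(tc$power)] - params@evokedLatency),
            0.0105)
  expect_true(all(tc$power >= 0))
})

test_that("both platforms recover the same TFS from noise-free data", {
  params <- referenceParams()
  space <- buildSourceSpace(0.02, 0.08)
  tfsFor <- function(platform) {
    arr <- buildSensorArray(platform)
    lf <- computeLeadfield(space, arr)
    sched <- generateSchedule(3, seed = 4)
    ev <- scheduleToEvents(sched, arr@samplingRate)
    src <- simulateSources(params, sched, arr@samplingRate, seed = 9)
    rec <- projectAndNoise(src, arr, seed = 2, events = ev, noise = FALSE)
    rec <- if (platform == "opm") applyHFC(rec) else referenceGradiometry(rec)
    lf2 <- subsetChannels(lf, rec@array@channelName)
    filt <- bandpassBands(rec, list(beta = c(13, 30), broad = c(1, 100)))
    ep <- epochData(filt$beta, c(0, 1.2), "^stim_", "beta")
    w <- lcmvWeights(ep, lf2)
    pk <- hemispherePeaks(pseudoTImage(w, ep, space))
    wB <- continuousLcmvWeights(filt$broad, lf2)
    ve <- virtualElectrode(wB, filt$broad, pk[["left"]])
    dur <- trialDuration(sched)
    starts <- round((seq_len(3) - 1) * dur * arr@samplingRate)
    computeTFS(ve, arr@samplingRate, starts,
               floor(dur * arr@samplingRate) - 1,
               freqs = seq(4, 44, 4), bandwidth = 2)
  }
  a <- tfsFor("opm")
  b <- tfsFor("squid")
  grid <- seq(0, 14, by = 0.005)
  pa <- resampleTimecourse(a@values, a@times, grid)
  pb <- resampleTimecourse(b@values, b@times, grid)
  expect_gt(cor(as.vector(pa), as.vector(pb)), 0.95)
})

test_that("resampling onto a shared grid preserves slow structure", {
  t1 <- seq(0, 10, by = 1 / 375)
  t2 <- seq(0, 10, by = 1 / 600)
  f <- function(t) sin(2 * pi * 0.8 * t) + 0.3 * cos(2 * pi * 2.1 * t)
  grid <- seq(0, 10, by = 0.001)
  a <- resampleTimecourse(f(t1), t1, grid)
  b <- resampleTimecourse(f(t2), t2, grid)
  expect_gt(cor(a, b), 0.9999)
})
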