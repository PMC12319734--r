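# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

opmArray <- function() fixture("opm", function() buildSensorArray("opm"))
squidArray <- function() fixture("squid", function() buildSensorArray("squid"))

# A miniature OPM-like array (4 triaxial sites) for cheap IO/screening tests.
miniOpm <- function() fixture("miniOpm", function()
  megfingerprint:::subsetArray(opmArray(), 1:12))

# A miniature SQUID-like array: 10 gradiometers + 5 references.
miniSquid <- function() fixture("miniSquid", function()
  megfingerprint:::subsetArray(squidArray(), c(1:10, 276:280)))

coarseSpace <- function() fixture("coarseSpace", function()
  buildSourceSpace(0.02, 0.08))

coarseOpmLeadfield <- function() fixture("coarseOpmLf", function()
  computeLeadfield(coarseSpace(), opmArray()))

# Deterministic subject parameters with a fixed, easily-reasoned profile.
referenceParams <- function(erdDepth = 0.5, rebound = rep(0.5, 5),
                            attentionDepth = 0.2, betaPeak = 21) {
  new("SubjectParams",
      positionLeft = c(-0.035, 0.01, 0.055),
      positionRight = c(0.035, 0.01, 0.055),
      sigmaS = 0.01, betaPeak = betaPeak, betaBandwidth = 4,
      erdDepth = erdDepth, rebound = rebound, betaAmp = 8,
      evokedAmp = 40, evokedLatency = 0.05, evokedWidth = 0.02,
      attentionDepth = attentionDepth, momentAngle = pi / 4,
      runJitter = 0)
}

# Shared reconstruction scene: one planted left-hemisphere dipole, OPM
# array, 5 mm grid restricted to a 5 cm source sphere.
reconScene <- function() fixture("reconScene", function() {
  space <- buildSourceSpace(0.005, 0.05)
  arr <- opmArray()
  lf <- computeLeadfield(space, arr)
  params <- referenceParams()
  params@positionLeft <- c(-0.028, 0.008, 0.032)
  params@sigmaS <- 1e-6                       # effectively a point source
  sim <- singleSourceRecording(arr, params, nTrials = 3, noise = TRUE)
  beta <- bandpassFilter(sim$recording, 13, 30)
  ep <- epochData(beta, c(0, 1.2), "^stim_", "beta")
  w <- lcmvWeights(ep, lf)
  list(space = space, arr = arr, lf = lf, params = params, sim = sim,
       beta = beta, epochs = ep, weights = w)
})

# Noise-free single-dipole recording helper (left source only).
singleSourceRecording <- function(array, params = referenceParams(),
                                  nTrials = 2, seed = 7, noise = FALSE,
                                  scheduleSeed = 3) {
  sched <- generateSchedule(nTrials, seed = scheduleSeed)
  ev <- scheduleToEvents(sched, array@samplingRate)
  src <- simulateSources(params, sched, array@samplingRate, seed = seed)
  src$right$timecourse[] <- 0          # silence the right hemisphere
  rec <- projectAndNoise(src, array, seed = seed + 1, events = ev,
                         noise = noise)
  list(recording = rec, schedule = sched, events = ev, sources = src,
       params = params)
}
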