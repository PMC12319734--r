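test_that("cohort parameters are reproducible under a seed and vary across seeds", {
  a <- sampleCohortParams(15, seed = 2)
  b <- sampleCohortParams(15, seed = 2)
  c_ <- sampleCohortParams(15, seed = 3)
  expect_length(a, 15)
  expect_equal(a[[7]]@rebound, b[[7]]@rebound)
  expect_equal(a[[7]]@positionLeft, b[[7]]@positionLeft)
  expect_false(isTRUE(all.equal(a[[1]]@betaPeak, c_[[1]]@betaPeak)))
})

test_that("sampled parameters respect their physiological bounds", {
  pars <- sampleCohortParams(100, seed = 11)
  for (p in pars) {
    expect_true(p@erdDepth > 0 && p@erdDepth <= 1)
    expect_true(all(p@rebound >= 0))
    expect_true(p@betaPeak >= 13 && p@betaPeak <= 30)
    expect_lt(sqrt(sum(p@positionLeft^2)), 0.08)
  }
})

test_that("betweenScale = 0 collapses the cohort to identical subjects", {
  pars <- sampleCohortParams(5, seed = 4, betweenScale = 0)
  for (i in 2:5) {
    expect_equal(pars[[i]]@rebound, pars[[1]]@rebound)
    expect_equal(pars[[i]]@betaPeak, pars[[1]]@betaPeak)
    expect_equal(pars[[i]]@positionLeft, pars[[1]]@positionLeft)
  }
})

test_that("between-subject spread of rebound profiles exceeds run jitter", {
  pars <- sampleCohortParams(100, seed = 5, runJitter = 0.05)
  between <- sd(vapply(pars, function(p) p@rebound[1], numeric(1)))
  p1 <- pars[[1]]
  jittered <- vapply(1:100, function(k)
    megfingerprint:::jitterParams(p1, k)@rebound[1], numeric(1))
  within <- sd(jittered)
  expect_gt(between / within, 2)
})

test_that("ERD depth sets the envelope drop during stimulation", {
  p <- referenceParams(erdDepth = 0.5, rebound = rep(0, 5))
  sched <- generateSchedule(4, seed = 2)
  env <- betaEnvelopeProfile(p, sched, 250, "left")
  t <- (seq_along(env) - 1) / 250
  dur <- trialDuration(sched)
  inStim <- rep(FALSE, length(t))
  base <- rep(TRUE, length(t))
  for (k in seq_len(4)) {
    on <- (k - 1) * dur + sched@onsets[k, ]
    for (j in 1:5) {
      inStim <- inStim | (t >= on[j] + 0.2 & t <= on[j] + 0.5)
      base <- base & !(t >= on[j] - 0.3 & t <= on[j] + 1.3)
    }
    base <- base & !(t >= (k - 1) * dur - 0.9 & t <= (k - 1) * dur + 1.1)
  }
  expect_equal(mean(env[inStim]) / mean(env[base]), 0.5, tolerance = 0.03)
  # and the trial-averaged Hilbert envelope of the noise-free beta source
  # (evoked transients silenced so the envelope reflects the beta carrier)
  p@evokedAmp <- 0
  src <- simulateSources(p, sched, 250, seed = 6)
  he <- hilbertEnvelope(src$left$timecourse - mean(src$left$timecourse))
  expect_equal(mean(he[inStim]) / mean(he[base]), 0.5, tolerance = 0.12)
})

test_that("the per-stimulus rebound profile shapes successive rebounds", {
  p <- referenceParams(erdDepth = 0.3, rebound = c(1, 1, 1, 1, 2))
  sched <- generateSchedule(1, seed = 2)
  env <- betaEnvelopeProfile(p, sched, 250, "left")
  t <- (seq_along(env) - 1) / 250
  peak <- function(j) max(env[t >= sched@onsets[1, j] + 0.6 &
                               t <= sched@onsets[1, j] + 1.1]) - 1
  expect_equal(peak(5) / peak(1), 2, tolerance = 0.05)
})

test_that("zero attentional depth makes cue sides indistinguishable", {
  p <- referenceParams(attentionDepth = 0)
  schedL <- generateSchedule(2, seed = 3)
  schedL@cueSide <- c("left", "left")
  schedR <- schedL
  schedR@cueSide <- c("right", "right")
  expect_equal(betaEnvelopeProfile(p, schedL, 250, "left"),
               betaEnvelopeProfile(p, schedR, 250, "left"))
})

test_that("attentional modulation suppresses the contralateral hemisphere", {
  p <- referenceParams(attentionDepth = 0.3)
  sched <- generateSchedule(2, seed = 3)
  sched@cueSide <- c("right", "right")
  envL <- betaEnvelopeProfile(p, sched, 250, "left")
  envR <- betaEnvelopeProfile(p, sched, 250, "right")
  t <- (seq_along(envL) - 1) / 250
  dur <- trialDuration(sched)
  win <- (t > dur - 0.7 & t < dur + 0.9)   # around trial 2's cue end
  expect_lt(mean(envL[win]), mean(envR[win]))
})

test_that("projection produces zero data for silent sources and no noise", {
  src <- simulateSources(referenceParams(), generateSchedule(1, 1), 375,
                         seed = 1)
  src$left$timecourse[] <- 0
  src$right$timecourse[] <- 0
  rec <- projectAndNoise(src, miniOpm(), seed = 2, noise = FALSE)
  expect_equal(max(abs(rec@data)), 0)
})

test_that("sensor noise matches the configured spectral floor", {
  src <- simulateSources(referenceParams(), generateSchedule(2, 1), 375,
                         seed = 1)
  src$left$timecourse[] <- 0
  src$right$timecourse[] <- 0
  rec <- projectAndNoise(src, miniOpm(), seed = 5, noise = TRUE)
  w <- welchASD(rec@data, 375)
  sel <- w$freq >= 60 & w$freq <= 80
  floors <- rowMeans(w$asd[, sel])
  expect_true(all(abs(floors - 15) / 15 < 0.1))
})

test_that("rate mismatch between sources and array is rejected", {
  src <- simulateSources(referenceParams(), generateSchedule(1, 1), 600,
                         seed = 1)
  expect_error(projectAndNoise(src, miniOpm(), seed = 1), "rate mismatch")
})

test_that("a one-subject cohort writes 4 sessions with reproducible events", {
  d1 <- file.path(tempdir(), "cohortA")
  d2 <- file.path(tempdir(), "cohortB")
  man1 <- generateCohort(d1, nSubjects = 1, nTrials = 1, seed = 42,
                         opmArray = miniOpm(), squidArray = miniSquid())
  man2 <- generateCohort(d2, nSubjects = 1, nTrials = 1, seed = 42,
                         opmArray = miniOpm(), squidArray = miniSquid())
  expect_equal(nrow(man1), 4)
  expect_true(all(file.exists(man1$data)))
  expect_true(all(file.exists(man1$events)))
  for (k in seq_len(4))
    expect_identical(readLines(man1$events[k]), readLines(man2$events[k]))
  expect_true(file.exists(file.path(d1, "sub-01_params.json")))
})
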