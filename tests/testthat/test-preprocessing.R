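makeRecording <- function(data, array, rate = array@samplingRate,
                          events = data.frame(onset = numeric(0),
                                              duration = numeric(0),
                                              trial_type = character(0),
                                              sample = integer(0))) {
  new("Recording", platform = array@platform, subject = "t", run = 1L,
      data = data, samplingRate = rate, events = events, array = array)
}

test_that("channel screening removes dead and high-noise channels", {
  arr <- miniOpm()
  n <- 375 * 20
  set.seed(1)
  dat <- matrix(0, 12, n)
  for (i in 2:12) dat[i, ] <- rnorm(n, 0, 15 * sqrt(375 / 2))
  dat[5, ] <- rnorm(n, 0, 40 * sqrt(375 / 2))    # high noise
  # row 1 stays all-zero: non-operational
  rec <- makeRecording(dat, arr)
  scr <- screenChannels(rec)
  expect_true(arr@channelName[1] %in% scr$removed)
  expect_true(arr@channelName[5] %in% scr$removed)
  expect_equal(sort(scr$kept), sort(arr@channelName[-c(1, 5)]))
  expect_lt(abs(scr$noiseFloor[7] - 15) / 15, 0.1)
  expect_lt(scr$noiseFloor[1], 5)
  expect_gt(scr$noiseFloor[5], 20)
})

test_that("screening needs 10 s of data and cannot drop every channel", {
  arr <- miniOpm()
  expect_error(screenChannels(makeRecording(matrix(0, 12, 375), arr)),
               "10 s")
  expect_error(screenChannels(makeRecording(matrix(0, 12, 375 * 12), arr)),
               "every channel")
})

test_that("HFC annihilates uniform-field interference and is idempotent", {
  arr <- opmArray()
  n <- 500
  u <- rbind(sin(2 * pi * 3 * (1:n) / 375), cos(2 * pi * 5 * (1:n) / 375),
             sin(2 * pi * 1 * (1:n) / 375 + 0.3)) * 80
  rec <- makeRecording(arr@orientation %*% u, arr)
  out <- applyHFC(rec)
  expect_lt(max(abs(out@data)) / max(abs(rec@data)), 1e-8)
  # idempotence on arbitrary data
  set.seed(2)
  rec2 <- makeRecording(matrix(rnorm(192 * 200), 192, 200), arr)
  once <- applyHFC(rec2)
  twice <- applyHFC(once)
  expect_equal(twice@data, once@data, tolerance = 1e-12)
})

test_that("HFC retains most variance of a dipolar brain signal", {
  arr <- opmArray()
  g <- megfingerprint:::sourceGain(arr, list(
    position = c(-0.03, 0.01, 0.06),
    patchPositions = matrix(c(-0.03, 0.01, 0.06), 1), patchWeights = 1,
    momentDir = c(0, 1, 0)))
  tc <- sin(2 * pi * 20 * (0:499) / 375)
  rec <- makeRecording(tcrossprod(g, tc), arr)
  out <- applyHFC(rec)
  expect_gt(sum(out@data^2) / sum(rec@data^2), 0.9)
})

test_that("HFC requires at least 3 channels", {
  arr <- megfingerprint:::subsetArray(opmArray(), 1:2)
  expect_error(applyHFC(makeRecording(matrix(0, 2, 10), arr)), "3 channels")
})

test_that("reference gradiometry removes drift and keeps the signal", {
  arr <- miniSquid()
  n <- 4000
  set.seed(3)
  drift <- cumsum(rnorm(n)); drift <- 50 * drift / max(abs(drift))
  signal_ <- matrix(0, 15, n)
  signal_[1:10, ] <- rnorm(10 * n, 0, 0.3)  # own sensor noise on scalp rows
  signal_[3, ] <- signal_[3, ] + sin(2 * pi * 20 * (1:n) / 600) * 30
  dat <- signal_ + tcrossprod(c(rep(1, 10), rep(1, 5)), drift)
  rec <- makeRecording(dat, arr)
  out <- referenceGradiometry(rec)
  expect_equal(nrow(out@data), 10)                       # references dropped
  expect_lt(sd(out@data[1, ]), 0.05 * sd(drift))         # drift removed
  resid <- out@data[3, ] - signal_[3, ]
  expect_lt(sd(resid), 0.05 * sd(signal_[3, ]))          # signal preserved
  # residuals orthogonal to references
  refs <- dat[11:15, ]
  for (i in 1:10)
    expect_lt(abs(cor(out@data[i, ], refs[1, ])), 1e-8)
})

test_that("gradiometry with constant references is a no-op; none is an error", {
  arr <- miniSquid()
  dat <- matrix(rnorm(15 * 100), 15, 100)
  dat[11:15, ] <- 7
  out <- referenceGradiometry(makeRecording(dat, arr))
  expect_equal(out@data, dat[1:10, ], tolerance = 1e-10)
  opm <- miniOpm()
  expect_error(referenceGradiometry(
    makeRecording(matrix(0, 12, 10), opm)), "no reference")
})

test_that("the FIR band-pass passes the band and rejects outside it", {
  fs <- 375
  t <- (0:(20 * fs - 1)) / fs
  mid <- seq(2 * fs, 18 * fs)
  y20 <- bandpassFilter(sin(2 * pi * 20 * t), 13, 30, rate = fs)
  expect_equal(sd(y20[mid]) * sqrt(2), 1, tolerance = 0.01)
  y50 <- bandpassFilter(sin(2 * pi * 50 * t), 13, 30, rate = fs)
  expect_gt(20 * log10(sd(sin(2 * pi * 50 * t)[mid]) / sd(y50[mid])), 20)
  ydc <- bandpassFilter(rep(1, 5000), 1, 100, rate = fs)
  expect_lt(max(abs(ydc[1000:4000])), 0.01)
  expect_error(bandpassFilter(t, 13, 200, rate = fs), "Nyquist")
})

test_that("filtering is zero-phase and linear", {
  fs <- 375
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 20 * t)
  y <- bandpassFilter(x, 13, 30, rate = fs)
  mid <- seq(2 * fs, 8 * fs)
  lag <- which.max(ccf(y[mid], x[mid], lag.max = 20, plot = FALSE)$acf) - 21
  expect_equal(lag, 0)
  set.seed(4)
  a <- rnorm(2000); b <- rnorm(2000)
  expect_equal(bandpassFilter(a + b, 13, 30, rate = fs),
               bandpassFilter(a, 13, 30, rate = fs) +
                 bandpassFilter(b, 13, 30, rate = fs), tolerance = 1e-10)
})

test_that("multi-band filtering matches per-band filtering", {
  arr <- miniOpm()
  set.seed(5)
  rec <- makeRecording(matrix(rnorm(12 * 3000), 12, 3000), arr)
  both <- bandpassBands(rec, list(beta = c(13, 30), broad = c(1, 100)))
  expect_equal(both$beta@data, bandpassFilter(rec, 13, 30)@data,
               tolerance = 1e-10)
  expect_equal(both$broad@data, bandpassFilter(rec, 1, 100)@data,
               tolerance = 1e-10)
})

test_that("peak-to-peak rejection removes exactly the constructed violations", {
  arr <- miniOpm()
  fs <- 375
  n <- fs * 20
  set.seed(6)
  dat <- matrix(rnorm(12 * n, 0, 100), 12, n)
  ev <- data.frame(onset = seq(0.5, by = 1.5, length.out = 10),
                   duration = 0.37,
                   trial_type = "stim_nontarget")
  ev$sample <- as.integer(round(ev$onset * fs))
  bad <- c(2, 5, 9)
  for (k in bad) dat[4, ev$sample[k] + 50] <- 10000   # 10 pT spike
  rec <- makeRecording(dat, arr, events = ev)
  res <- epochAndReject(rec, c(0, 1.2), "^stim_")
  expect_equal(res$removed, bad)
  expect_equal(nTrials(res$epochs), 7)
  # all-quiet data: everything retained
  rec2 <- makeRecording(matrix(rnorm(12 * n, 0, 100), 12, n), arr,
                        events = ev)
  expect_equal(nTrials(epochAndReject(rec2, c(0, 1.2))$epochs), 10)
  # all-bad data: error
  dat3 <- dat
  for (k in 1:10) dat3[1, ev$sample[k] + 10] <- 1e5
  expect_error(epochAndReject(makeRecording(dat3, arr, events = ev),
                              c(0, 1.2)), "all epochs")
})
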