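# Construct a feature list with exactly known correlations to a reference.
corFeature <- function(ref, rho, seed) {
  set.seed(seed)
  raw <- rnorm(length(ref))
  v <- ref - mean(ref)
  w <- raw - mean(raw)
  w <- w - v * sum(v * w) / sum(v * v)       # exactly orthogonal to ref
  v <- v / sd(v); w <- w / sd(w)
  rho * v + sqrt(1 - rho^2) * w
}

test_that("dataset similarity is the mean of the two feature correlations", {
  set.seed(20)
  a <- list(image = rnorm(100), profile = matrix(rnorm(200), 50, 4),
            times = seq(0, 0.49, by = 0.01))
  expect_equal(datasetSimilarity(a, a), 1)
  b <- list(image = corFeature(a$image, 0.8, 1),
            profile = matrix(corFeature(as.vector(a$profile), 0.4, 2), 50, 4),
            times = a$times)
  expect_equal(datasetSimilarity(a, b), 0.6, tolerance = 1e-10)
  neg <- list(image = -a$image, profile = -a$profile, times = a$times)
  expect_equal(datasetSimilarity(a, neg), -1)
  bad <- list(image = rnorm(50), profile = a$profile, times = a$times)
  expect_error(datasetSimilarity(a, bad), "shapes differ")
})

test_that("similarity across sampling rates uses the shared grid", {
  t1 <- seq(0, 2, by = 1 / 375)
  t2 <- seq(0, 2, by = 1 / 600)
  f <- function(t) cbind(sin(2 * pi * 1.1 * t), cos(2 * pi * 0.6 * t))
  a <- list(image = 1:10, profile = f(t1), times = t1)
  b <- list(image = 1:10, profile = f(t2), times = t2)
  expect_equal(datasetSimilarity(a, b), 1, tolerance = 1e-4)
})

# Small synthetic cohort of features: orthogonal subject signatures,
# identical across a subject's four datasets.
orthFeatures <- function(N = 4, n = 64) {
  base <- qr.Q(qr(matrix(rnorm(n * N), n, N)))   # orthonormal columns
  feats <- list()
  for (i in seq_len(N)) {
    f <- list(image = base[, i], profile = base[, i],
              times = seq_len(n) / 100)
    feats[[sprintf("%02d", i)]] <-
      list(opm1 = f, opm2 = f, squid1 = f, squid2 = f)
  }
  feats
}

test_that("fingerprint matrices follow the scheme comparison rules", {
  set.seed(30)
  feats <- orthFeatures(2)
  # perturb one dataset so the four cross comparisons differ
  feats[["01"]]$squid2$image <- corFeature(feats[["01"]]$opm1$image, 0.5, 3)
  feats[["01"]]$squid2$profile <- feats[["01"]]$squid2$image
  mW <- buildFingerprintMatrix(feats, "within_opm")
  expect_equal(values(mW)[1, 2],
               datasetSimilarity(feats[["01"]]$opm1, feats[["02"]]$opm2))
  mX <- buildFingerprintMatrix(feats, "cross_platform")
  expect_equal(values(mX)[2, 1], mean(c(
    datasetSimilarity(feats[["02"]]$opm1, feats[["01"]]$squid1),
    datasetSimilarity(feats[["02"]]$opm1, feats[["01"]]$squid2),
    datasetSimilarity(feats[["02"]]$opm2, feats[["01"]]$squid1),
    datasetSimilarity(feats[["02"]]$opm2, feats[["01"]]$squid2))))
  feats2 <- feats
  feats2[["02"]]$squid2 <- NULL
  expect_error(buildFingerprintMatrix(feats2, "within_squid"),
               "missing dataset squid2 for subject 02")
})

test_that("identical-within, orthogonal-between features give the identity", {
  set.seed(31)
  m <- buildFingerprintMatrix(orthFeatures(4), "cross_platform")
  expect_equal(diag(values(m)), rep(1, 4))
  expect_lt(max(abs(values(m)[row(values(m)) != col(values(m))])), 0.3)
  expect_equal(identifySubjects(m)$nIdentified, 4)
})

test_that("permuting subject order permutes rows and columns consistently", {
  set.seed(32)
  feats <- orthFeatures(4)
  for (i in 1:4) {   # make subjects distinguishable but imperfect
    feats[[i]]$opm2$image <- corFeature(feats[[i]]$opm1$image, 0.9, i)
    feats[[i]]$opm2$profile <- feats[[i]]$opm2$image
  }
  m1 <- buildFingerprintMatrix(feats, "within_opm")
  perm <- c(3, 1, 4, 2)
  m2 <- buildFingerprintMatrix(feats[perm], "within_opm")
  expect_equal(values(m2), values(m1)[perm, perm])
  expect_equal(identifySubjects(m2)$nIdentified,
               identifySubjects(m1)$nIdentified)
})

test_that("identification counts diagonal row maxima, ties are misses", {
  M <- diag(0.9, 4) + 0.2
  expect_equal(identifySubjects(M)$nIdentified, 4)
  swapped <- M[c(2, 1, 3, 4), ]
  expect_equal(identifySubjects(swapped)$nIdentified, 2)
  tie <- M
  tie[1, 2] <- tie[1, 1]
  expect_equal(identifySubjects(tie)$nIdentified, 3)
  expect_false(identifySubjects(tie)$hits[1])
  expect_equal(identifySubjects(matrix(0.4, 1, 1))$nIdentified, 1)
})

test_that("the diagonal permutation statistic and p behave at the extremes", {
  flat <- matrix(0.5, 6, 6)
  ndFlat <- diagonalPermutationTest(flat, nPerm = 500, seed = 1)
  expect_equal(ndFlat@observed, 0)
  expect_gt(ndFlat@p, 0.99)
  strong <- diag(1, 8) + matrix(0.01, 8, 8)
  ndStrong <- diagonalPermutationTest(strong, nPerm = 999, seed = 2)
  expect_equal(ndStrong@p, 1 / 1000)
  expect_error(diagonalPermutationTest(matrix(1, 2, 2)), "3 subjects")
})

test_that("the permutation test is invariant under joint relabelling", {
  set.seed(33)
  M <- matrix(rnorm(64), 8, 8) + diag(2, 8)
  perm <- sample(8)
  nd1 <- diagonalPermutationTest(M, nPerm = 2000, seed = 5)
  nd2 <- diagonalPermutationTest(M[perm, perm], nPerm = 2000, seed = 5)
  expect_equal(nd1@observed, nd2@observed, tolerance = 1e-12)
  expect_lt(abs(nd1@p - nd2@p), 0.03)
})

test_that("chance identifiability matches the binomial closed form", {
  res <- chanceIdentifiability(15, nSim = 20000, seed = 3)
  expect_equal(sum(res$pmf), 1)
  expect_lt(max(abs(res$pmf - res$binomial)), 0.015)
  res1 <- chanceIdentifiability(1, nSim = 500, seed = 1)
  expect_equal(res1$pmf[2], 1)   # P(1 of 1 identified) = 1
})

test_that("the sham-mixing null degenerates correctly and detects flips", {
  set.seed(34)
  base <- matrix(rnorm(5 * 200), 5, 200)
  same <- groupTimecourseNull(base, base, nPerm = 200, seed = 1)
  expect_equal(same@observed, 1)
  # sham splits that pair each trace with its duplicate reproduce r = 1;
  # splits with unbalanced duplicates fall below, never above
  expect_lte(max(same@samples), 1)
  expect_true(any(abs(same@samples - 1) < 1e-12))
  t <- seq(0, 5, length.out = 300)
  shape <- sin(2 * pi * 0.5 * t)
  # subject-level variability dominates the shared shape, so sham-mixed
  # group means decorrelate while the true group means stay anti-correlated
  A <- t(replicate(8, shape + rnorm(300, 0, 1)))
  B <- t(replicate(8, -shape + rnorm(300, 0, 1)))
  flipped <- groupTimecourseNull(A, B, nPerm = 1000, seed = 2)
  expect_lt(flipped@observed, quantile(flipped@samples, 0.05))
  expect_lt(flipped@p, 0.05)
  expect_error(groupTimecourseNull(A, A[, 1:100], nPerm = 10), "shape")
})

test_that("attentional deltas are antisymmetric under label swapping", {
  mkEnv <- function(ampL, ampR) {
    times <- seq(-1, 1.2, by = 0.01)
    new("EnvelopeTimecourse",
        amplitude = rbind(all = (ampL + ampR) / 2, left = ampL + 0 * times,
                          right = ampR + 0 * times),
        times = times, conditions = c("all", "left", "right"),
        band = "beta", voxel = 1L)
  }
  subj <- function(dL, dR)
    list(left = mkEnv(1 + dL / 2, 1 - dL / 2),
         right = mkEnv(1 + dR / 2, 1 - dR / 2))
  envs <- lapply(1:8, function(i) subj(0.2 + 0.01 * i, -0.15 - 0.01 * i))
  res <- attentionalContrast(envs)
  expect_true(all(res$deltaLeft > 0))
  expect_true(all(res$deltaRight < 0))
  expect_lt(res$p, 0.05)
  swapped <- lapply(envs, function(s) lapply(s, function(e) {
    e@conditions <- c("all", "right", "left")
    e
  }))
  res2 <- attentionalContrast(swapped)
  expect_equal(res2$deltaLeft, -res$deltaLeft)
  expect_equal(res2$deltaRight, -res$deltaRight)
  noCond <- lapply(envs, function(s) lapply(s, function(e) {
    e@amplitude <- e@amplitude[1, , drop = FALSE]
    e@conditions <- "all"
    e
  }))
  expect_error(attentionalContrast(noCond), "conditions")
})
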