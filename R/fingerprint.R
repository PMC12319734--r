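# Neural fingerprinting statistics: dataset similarity, identifiability
# matrices, identification, permutation nulls, the sham-mixing group null,
# the attentional contrast, and the chance-identifiability model.

#' Similarity between two datasets' fingerprint features
#'
#' A dataset's features are a functional image (per-voxel vector on the
#' shared source grid) and a profile: the time-frequency spectrum (beta
#' feature set) or the evoked power timecourse (evoked feature set),
#' carried with its time axis. Similarity is the mean of the two Pearson
#' correlations; profiles recorded at different sampling rates are first
#' resampled onto a shared grid (default 1 ms).
#'
#' @param a,b feature lists with elements \code{image} (numeric vector),
#'   \code{profile} (matrix [time, frequency] or vector) and \code{times}.
#' @param resolution shared time grid step, seconds.
#' @return scalar similarity in [-1, 1].
#' @export
datasetSimilarity <- function(a, b, resolution = 0.001) {
  if (length(a$image) != length(b$image))
    stop("image feature shapes differ", call. = FALSE)
  pa <- a$profile
  pb <- b$profile
  if (!is.null(dim(pa)) != !is.null(dim(pb)) ||
      (!is.null(dim(pa)) && ncol(pa) != ncol(pb)))
    stop("profile feature shapes differ", call. = FALSE)
  if (!isTRUE(all.equal(a$times, b$times))) {
    grid <- seq(max(min(a$times), min(b$times)),
                min(max(a$times), max(b$times)), by = resolution)
    pa <- resampleTimecourse(pa, a$times, grid)
    pb <- resampleTimecourse(pb, b$times, grid)
  }
  mean(c(stats::cor(a$image, b$image),
         stats::cor(as.vector(pa), as.vector(pb))))
}

#' Build a fingerprinting matrix for one comparison scheme
#'
#' Within-platform schemes compare only run 1 of subject i with run 2 of
#' subject j (one independent comparison per cell, asymmetric by
#' construction). The cross-platform scheme averages the four possible
#' OPM-run x SQUID-run comparisons per cell.
#'
#' @param features nested list: \code{features[[subject]]} holds feature
#'   lists (see \code{\link{datasetSimilarity}}) named \code{opm1},
#'   \code{opm2}, \code{squid1}, \code{squid2}.
#' @param scheme \code{"within_opm"}, \code{"within_squid"} or
#'   \code{"cross_platform"}.
#' @param featureSet label stored on the result (\code{"beta"} or
#'   \code{"evoked"}).
#' @param resolution forwarded to \code{\link{datasetSimilarity}}.
#' @return a \linkS4class{FingerprintMatrix}.
#' @export
buildFingerprintMatrix <- function(features,
                                   scheme = c("within_opm", "within_squid",
                                              "cross_platform"),
                                   featureSet = "beta", resolution = 0.001) {
  scheme <- match.arg(scheme)
  N <- length(features)
  subjects <- names(features)
  if (is.null(subjects)) subjects <- sprintf("%02d", seq_len(N))
  need <- switch(scheme,
                 within_opm = c("opm1", "opm2"),
                 within_squid = c("squid1", "squid2"),
                 cross_platform = c("opm1", "opm2", "squid1", "squid2"))
  for (i in seq_len(N))
    for (ds in need)
      if (is.null(features[[i]][[ds]]))
        stop("missing dataset ", ds, " for subject ", subjects[i], call. = FALSE)
  M <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      M[i, j] <- switch(scheme,
        within_opm = datasetSimilarity(features[[i]]$opm1,
                                       features[[j]]$opm2, resolution),
        within_squid = datasetSimilarity(features[[i]]$squid1,
                                         features[[j]]$squid2, resolution),
        cross_platform = mean(c(
          datasetSimilarity(features[[i]]$opm1, features[[j]]$squid1, resolution),
          datasetSimilarity(features[[i]]$opm1, features[[j]]$squid2, resolution),
          datasetSimilarity(features[[i]]$opm2, features[[j]]$squid1, resolution),
          datasetSimilarity(features[[i]]$opm2, features[[j]]$squid2, resolution))))
    }
  }
  new("FingerprintMatrix", values = M, scheme = scheme,
      featureSet = featureSet, subjects = subjects)
}

#' Identify subjects from a fingerprinting matrix
#'
#' Row i is a hit when its largest value lies on the diagonal (column i);
#' ties count as misses.
#'
#' @param m a \linkS4class{FingerprintMatrix} or square numeric matrix.
#' @return list with \code{hits} (logical per row) and \code{nIdentified}.
#' @export
identifySubjects <- function(m) {
  M <- if (is(m, "FingerprintMatrix")) m@values else m
  N <- nrow(M)
  hits <- vapply(seq_len(N), function(i) {
    mx <- max(M[i, ])
    M[i, i] == mx && sum(M[i, ] == mx) == 1L
  }, logical(1))
  list(hits = hits, nIdentified = sum(hits))
}

#' Permutation test on the diagonal of a fingerprinting matrix
#'
#' Statistic: mean(diagonal) - mean(off-diagonal). The null randomises the
#' subject labels of the second dataset axis (column relabelling) and
#' recomputes the statistic; the empirical p-value is one-tailed with the
#' +1 correction, p = (1 + #(null >= observed)) / (nPerm + 1).
#'
#' @param m a \linkS4class{FingerprintMatrix} or square matrix (N >= 3).
#' @param nPerm number of permutations (default 1e5).
#' @param seed RNG seed.
#' @return a \linkS4class{NullDistribution}.
#' @export
diagonalPermutationTest <- function(m, nPerm = 100000, seed = 1) {
  M <- if (is(m, "FingerprintMatrix")) m@values else m
  N <- nrow(M)
  stopIfNot(N >= 3, "need at least 3 subjects")
  S <- sum(M)
  stat <- function(d) d / N - (S - d) / (N * (N - 1))
  obs <- stat(sum(diag(M)))
  rows <- seq_len(N)
  samples <- withSeed(seed, vapply(seq_len(nPerm), function(k)
    stat(sum(M[cbind(rows, sample.int(N))])), numeric(1)))
  p <- (1 + sum(samples >= obs)) / (nPerm + 1)
  new("NullDistribution", observed = obs, samples = samples,
      nPerm = as.integer(nPerm), p = p, tail = "greater")
}

#' Chance identifiability of an information-free cohort
#'
#' Simulates N x N similarity matrices with i.i.d. standard-normal entries
#' and counts, per matrix, the rows whose maximum falls on the diagonal.
#' Row maxima are independent with hit probability 1/N, so the count is
#' Binomial(N, 1/N); the closed form is returned alongside the empirical
#' probability mass function.
#'
#' @param nSubjects matrix size N (default 15).
#' @param nSim number of simulated matrices (default 1e5).
#' @param seed RNG seed.
#' @return list with \code{k} (0..N), \code{pmf} (empirical),
#'   \code{binomial} (Binomial(N, 1/N) reference) and \code{counts}.
#' @export
chanceIdentifiability <- function(nSubjects = 15, nSim = 100000, seed = 1) {
  stopIfNot(nSubjects >= 1, "nSubjects must be >= 1")
  N <- nSubjects
  counts <- integer(nSim)
  withSeed(seed, {
    chunk <- max(1, floor(2e6 / (N * N)))
    done <- 0
    while (done < nSim) {
      m <- min(chunk, nSim - done)
      X <- matrix(stats::rnorm(m * N * N), m * N, N)
      hit <- max.col(X, ties.method = "first") == rep_len(seq_len(N), m * N)
      counts[done + seq_len(m)] <-
        as.integer(rowsum(as.integer(hit), rep(seq_len(m), each = N)))
      done <- done + m
    }
  })
  tab <- tabulate(counts + 1L, nbins = N + 1L)
  list(k = 0:N, pmf = tab / nSim,
       binomial = stats::dbinom(0:N, N, 1 / N), counts = counts)
}

#' Sham-mixing null for group-average timecourse similarity
#'
#' Observed statistic: Pearson correlation between the two platforms'
#' group-mean timecourses. Null: the 2N subject-average timecourses are
#' pooled, randomly split into two sham groups of N (a subject's two
#' platform traces may land in the same group), and the correlation between
#' sham group means is recomputed. The p-value is two-tailed: twice the
#' smaller tail probability (with the +1 correction), capped at 1.
#'
#' @param opm,squid numeric matrices (subjects x time) on a shared time
#'   axis.
#' @param nPerm number of sham splits (default 1e4).
#' @param seed RNG seed.
#' @return a \linkS4class{NullDistribution}.
#' @export
groupTimecourseNull <- function(opm, squid, nPerm = 10000, seed = 1) {
  if (!all(dim(opm) == dim(squid)))
    stop("platform timecourse matrices must have identical shape", call. = FALSE)
  N <- nrow(opm)
  # a sham group whose mean is constant (e.g. exactly cancelling traces)
  # carries no linear association; its correlation is taken as 0
  safeCor <- function(a, b)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  obs <- safeCor(colMeans(opm), colMeans(squid))
  pool <- rbind(opm, squid)
  samples <- withSeed(seed, vapply(seq_len(nPerm), function(k) {
    idx <- sample.int(2 * N, N)
    safeCor(colMeans(pool[idx, , drop = FALSE]),
            colMeans(pool[-idx, , drop = FALSE]))
  }, numeric(1)))
  pLow <- (1 + sum(samples <= obs)) / (nPerm + 1)
  pHigh <- (1 + sum(samples >= obs)) / (nPerm + 1)
  new("NullDistribution", observed = obs, samples = samples,
      nPerm = as.integer(nPerm), p = min(1, 2 * min(pLow, pHigh)),
      tail = "two_sided")
}

#' Attentional modulation contrast between hemispheres
#'
#' Per subject and hemisphere, the difference in mean beta envelope between
#' attend-left and attend-right trials over a window around the cue end
#' (default -0.8 to 1 s). Attending right suppresses beta in the left
#' hemisphere (positive difference there) and vice versa; the left- and
#' right-hemisphere differences are compared across subjects with a paired
#' two-sided Wilcoxon signed-rank test.
#'
#' @param envelopes list, one element per subject, each a list with
#'   \code{left} and \code{right}: \linkS4class{EnvelopeTimecourse}s whose
#'   conditions include \code{"left"} and \code{"right"} (cue side).
#' @param window seconds relative to cue end.
#' @return list with \code{delta} (data.frame subject, hemisphere,
#'   difference), \code{test} (the \code{htest}) and \code{p}.
#' @export
attentionalContrast <- function(envelopes, window = c(-0.8, 1)) {
  getDelta <- function(env) {
    need <- c("left", "right")
    if (!all(need %in% env@conditions))
      stop("envelope must carry attend-left and attend-right conditions",
           call. = FALSE)
    sel <- env@times >= window[1] & env@times <= window[2]
    stopIfNot(any(sel), "window outside the envelope time axis")
    mean(env@amplitude[match("left", env@conditions), sel]) -
      mean(env@amplitude[match("right", env@conditions), sel])
  }
  dL <- vapply(envelopes, function(s) getDelta(s$left), numeric(1))
  dR <- vapply(envelopes, function(s) getDelta(s$right), numeric(1))
  test <- stats::wilcox.test(dL, dR, paired = TRUE, exact = TRUE)
  list(delta = data.frame(subject = rep(seq_along(envelopes), 2),
                          hemisphere = rep(c("left", "right"),
                                           each = length(envelopes)),
                          difference = c(dL, dR)),
       deltaLeft = dL, deltaRight = dR, test = test, p = test$p.value)
}

#' Write a fingerprinting matrix as TSV
#'
#' @param m a \linkS4class{FingerprintMatrix}.
#' @param path TSV path; scheme metadata goes to a matching .json sidecar.
#' @return \code{path}, invisibly.
#' @export
writeFingerprintTsv <- function(m, path) {
  df <- as.data.frame(m@values)
  names(df) <- m@subjects
  df <- cbind(subject = m@subjects, df)
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  id <- identifySubjects(m)
  jsonlite::write_json(list(scheme = m@scheme, feature_set = m@featureSet,
                            n_identified = id$nIdentified,
                            n_subjects = length(m@subjects)),
                       sub("\\.tsv$", ".json", path),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Plot a fingerprinting matrix with row-maximum markers
#'
#' @param m a \linkS4class{FingerprintMatrix}.
#' @param ... passed to \code{image}.
#' @return invisibly, the row-maximum column indices.
#' @export
plotFingerprintMatrix <- function(m, ...) {
  M <- m@values
  N <- nrow(M)
  graphics::image(seq_len(N), seq_len(N), t(M[N:1, , drop = FALSE]),
                  xlab = "dataset 2 subject", ylab = "dataset 1 subject",
                  main = paste(m@scheme, "-", m@featureSet), axes = FALSE, ...)
  graphics::axis(1, seq_len(N), m@subjects, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(N), rev(m@subjects), las = 2, cex.axis = 0.7)
  rm_ <- apply(M, 1, which.max)
  graphics::points(rm_, N + 1 - seq_len(N), pch = 4, col = "red", lwd = 2)
  invisible(rm_)
}

#' Plot a permutation null with the observed statistic marked
#'
#' @param nd a \linkS4class{NullDistribution}.
#' @param ... passed to \code{hist}.
#' @return invisibly, \code{nd}.
#' @export
plotNullDistribution <- function(nd, ...) {
  graphics::hist(nd@samples, breaks = 50, main = sprintf("p = %.4g", nd@p),
                 xlab = "null statistic",
                 xlim = range(c(nd@samples, nd@observed)), ...)
  graphics::abline(v = nd@observed, col = "red", lwd = 2)
  invisible(nd)
}
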