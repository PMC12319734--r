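# Sensor arrays, spherical-conductor forward model and lead fields.
#
# The conductor is a homogeneous sphere, for which the external magnetic
# field of a current dipole has the Sarvas closed form. Purely radial
# dipole moments are magnetically silent outside the sphere, the key
# property shared with the single-shell models used for real anatomy.

# Quasi-uniform points on a spherical cap (Fibonacci lattice), cap opening
# angle thetaMax from the +z pole.
fibonacciCap <- function(n, radius, thetaMax = 2 * pi / 3, centre = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - cos(thetaMax)) * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  pts <- radius * cbind(s * cos(phi), s * sin(phi), z)
  sweep(pts, 2, centre, "+")
}

#' Construct a sensor array
#'
#' Sensor sites are placed quasi-uniformly (Fibonacci lattice) on a helmet
#' sphere covering the upper two thirds of the head. For the OPM platform,
#' each of the 64 sites carries a right-handed orthonormal triad of
#' measurement axes (one radial, two tangential), giving 192 magnetometer
#' channels at 375 Hz with a 15 fT/sqrt(Hz) noise floor. For the SQUID
#' platform, 275 axial gradiometers (5 cm baseline, radial axes) sit on the
#' helmet with 29 reference magnetometers on a distal shell, all sampled at
#' 600 Hz with a 5 fT/sqrt(Hz) noise floor.
#'
#' @param platform \code{"opm"} or \code{"squid"}.
#' @param headRadius head (conductor) sphere radius, metres.
#' @param helmetOffset sensor stand-off from the scalp, metres; defaults to
#'   0.0065 (OPM) or 0.02 (SQUID inner coil).
#' @param centre conductor sphere centre.
#' @param samplingRate override the platform default sampling rate (Hz).
#' @param noiseFloor override the platform default noise floor (fT/sqrt(Hz)).
#' @return a \linkS4class{SensorArray}.
#' @examples
#' opm <- buildSensorArray("opm")
#' length(channelNames(opm))  # 192
#' @export
buildSensorArray <- function(platform = c("opm", "squid"),
                             headRadius = 0.09, helmetOffset = NULL,
                             centre = c(0, 0, 0),
                             samplingRate = NULL, noiseFloor = NULL) {
  if (!is.character(platform) || !platform[1] %in% c("opm", "squid"))
    stop("unknown platform: must be 'opm' or 'squid'", call. = FALSE)
  platform <- platform[1]
  if (headRadius <= 0 || (!is.null(helmetOffset) && helmetOffset <= 0))
    stop("headRadius and helmetOffset must be > 0", call. = FALSE)

  if (platform == "opm") {
    off <- if (is.null(helmetOffset)) 0.0065 else helmetOffset
    rate <- if (is.null(samplingRate)) 375 else samplingRate
    floor_ <- if (is.null(noiseFloor)) 15 else noiseFloor
    sites <- fibonacciCap(64L, headRadius + off, centre = centre)
    pos <- ori <- matrix(0, 192, 3)
    nm <- character(192)
    for (s in seq_len(64)) {
      rad <- normalize(sites[s, ] - centre)
      ref <- if (abs(rad[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
      t1 <- normalize(c(ref[2] * rad[3] - ref[3] * rad[2],
                        ref[3] * rad[1] - ref[1] * rad[3],
                        ref[1] * rad[2] - ref[2] * rad[1]))
      t2 <- c(rad[2] * t1[3] - rad[3] * t1[2],
              rad[3] * t1[1] - rad[1] * t1[3],
              rad[1] * t1[2] - rad[2] * t1[1])
      idx <- (s - 1) * 3 + 1:3
      pos[idx, ] <- matrix(sites[s, ], 3, 3, byrow = TRUE)
      ori[idx, ] <- rbind(t1, t2, rad)
      nm[idx] <- sprintf("opm%02d_%s", s, c("tan1", "tan2", "rad"))
    }
    new("SensorArray", platform = "opm", channelName = nm, position = pos,
        orientation = ori, kind = rep("magnetometer", 192),
        samplingRate = rate, noiseFloor = rep(floor_, 192), baseline = 0)
  } else {
    off <- if (is.null(helmetOffset)) 0.02 else helmetOffset
    rate <- if (is.null(samplingRate)) 600 else samplingRate
    floor_ <- if (is.null(noiseFloor)) 5 else noiseFloor
    scalp <- fibonacciCap(275L, headRadius + off, centre = centre)
    refShell <- fibonacciCap(29L, 0.12, thetaMax = pi / 2,
                             centre = centre + c(0, 0, headRadius + off + 0.4))
    pos <- rbind(scalp, refShell)
    ori <- rbind(normalizeRows(sweep(scalp, 2, centre)),
                 normalizeRows(sweep(refShell, 2, centre)))
    nm <- c(sprintf("sq%03d", seq_len(275)), sprintf("ref%02d", seq_len(29)))
    kind <- c(rep("axial_gradiometer", 275), rep("reference", 29))
    new("SensorArray", platform = "squid", channelName = nm, position = pos,
        orientation = ori, kind = kind, samplingRate = rate,
        noiseFloor = rep(floor_, 304), baseline = 0.05)
  }
}

#' Build a cubic-grid source space inside a sphere
#'
#' The grid is offset by half the spacing so no voxel falls on the exact
#' sphere centre (where the forward model is degenerate).
#'
#' @param spacing grid spacing, metres (default 0.005 = 5 mm).
#' @param radius source sphere radius, metres; voxels lie strictly inside.
#' @param centre sphere centre.
#' @return a \linkS4class{SourceSpace}.
#' @export
buildSourceSpace <- function(spacing = 0.005, radius = 0.08,
                             centre = c(0, 0, 0)) {
  ax <- seq(-radius + spacing / 2, radius, by = spacing)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g <- g[sqrt(rowSums(g^2)) < radius - 1e-12, , drop = FALSE]
  g <- sweep(g, 2, centre, "+")
  dimnames(g) <- NULL
  new("SourceSpace", positions = g, centre = centre, radius = radius,
      spacing = spacing)
}

# Sarvas closed form, vectorised over sensor positions.
# dipolePos: 3-vector (m); moment: 3-vector (nAm); sensors: n x 3 (m).
# Returns n x 3 field in fT.
sarvasFieldMany <- function(dipolePos, moment, sensors, centre = c(0, 0, 0)) {
  r0 <- dipolePos - centre
  r <- sweep(sensors, 2, centre)
  if (sqrt(sum(r0^2)) < 1e-12)
    stop("degenerate geometry: dipole at sphere centre", call. = FALSE)
  if (any(sqrt(rowSums(r^2)) <= sqrt(sum(r0^2)) + 1e-12))
    stop("degenerate geometry: sensor not outside the dipole radius", call. = FALSE)
  a <- sweep(r, 2, r0)                      # r - r0
  amag <- sqrt(rowSums(a^2))
  rmag <- sqrt(rowSums(r^2))
  adotr <- rowSums(a * r)
  r0dotr <- drop(r %*% r0)
  F <- amag * (rmag * amag + rmag^2 - r0dotr)
  gF1 <- amag^2 / rmag + adotr / amag + 2 * amag + 2 * rmag
  gF2 <- amag + 2 * rmag + adotr / amag
  gradF <- r * gF1 - matrix(r0, nrow(r), 3, byrow = TRUE) * gF2
  q <- c(moment[2] * r0[3] - moment[3] * r0[2],   # Q x r0
         moment[3] * r0[1] - moment[1] * r0[3],
         moment[1] * r0[2] - moment[2] * r0[1])
  qdotr <- drop(r %*% q)
  # mu0/4pi = 1e-7; moment nAm -> 1e-9 A m; T -> fT 1e15 => overall 0.1
  0.1 * (matrix(q, nrow(r), 3, byrow = TRUE) * F - gradF * qdotr) / F^2
}

#' External field of a current dipole in a spherical conductor
#'
#' Sarvas closed form for the magnetic field outside a homogeneous
#' conducting sphere. Radial dipole moments produce zero external field;
#' the field is linear in the moment.
#'
#' @param dipolePos dipole position (3-vector, metres).
#' @param moment dipole moment (3-vector, nAm).
#' @param sensorPos sensor position (3-vector, metres) or an n x 3 matrix.
#' @param centre conductor sphere centre.
#' @return magnetic field vector(s) in fT (3-vector, or n x 3 matrix when
#'   \code{sensorPos} is a matrix).
#' @examples
#' b <- sarvasField(c(0, 0, 0.07), c(10, 0, 0), c(0, 0, 0.12))
#' @export
sarvasField <- function(dipolePos, moment, sensorPos, centre = c(0, 0, 0)) {
  single <- is.null(dim(sensorPos))
  sensors <- if (single) matrix(sensorPos, 1, 3) else sensorPos
  B <- sarvasFieldMany(dipolePos, moment, sensors, centre)
  if (single) drop(B) else B
}

#' Compute the lead field of an array over a source space
#'
#' For each voxel and each cardinal dipole orientation (1 nAm along x, y,
#' z), the per-channel gain is the Sarvas field projected onto the channel's
#' sensitive axis; axial gradiometer gains are the difference between the
#' inner-coil and outer-coil (baseline further out along the axis)
#' projections.
#'
#' @param space a \linkS4class{SourceSpace}.
#' @param array a \linkS4class{SensorArray} sharing the same sphere centre.
#' @param centre conductor sphere centre.
#' @return a \linkS4class{LeadField} with gains in fT/nAm.
#' @export
computeLeadfield <- function(space, array, centre = space@centre) {
  nvox <- nrow(space@positions)
  nchan <- length(array@channelName)
  isGrad <- array@kind == "axial_gradiometer"
  pts <- array@position
  if (any(isGrad))
    pts <- rbind(pts, array@position[isGrad, , drop = FALSE] +
                   array@baseline * array@orientation[isGrad, , drop = FALSE])
  gains <- array(0, dim = c(nvox, 3L, nchan))
  eye <- diag(3)
  for (v in seq_len(nvox)) {
    for (j in 1:3) {
      B <- sarvasFieldMany(space@positions[v, ], eye[j, ], pts, centre)
      proj <- rowSums(B[seq_len(nchan), , drop = FALSE] * array@orientation)
      if (any(isGrad)) {
        outer_ <- rowSums(B[-seq_len(nchan), , drop = FALSE] *
                            array@orientation[isGrad, , drop = FALSE])
        proj[isGrad] <- proj[isGrad] - outer_
      }
      gains[v, j, ] <- proj
    }
  }
  new("LeadField", gains = gains, space = space,
      channelName = array@channelName)
}

#' Serialise array geometry as TSV + JSON sidecar
#'
#' The TSV holds one row per channel (name, x, y, z, ox, oy, oz, kind); the
#' sidecar records platform, sampling rate, noise floors and gradiometer
#' baseline.
#'
#' @param array a \linkS4class{SensorArray}.
#' @param path path of the channels TSV; the sidecar replaces the extension
#'   with .json.
#' @return \code{writeArrayTsv}: \code{path}, invisibly;
#'   \code{readArrayTsv}: the \linkS4class{SensorArray}.
#' @export
writeArrayTsv <- function(array, path) {
  df <- data.frame(name = array@channelName,
                   x = array@position[, 1], y = array@position[, 2],
                   z = array@position[, 3],
                   ox = array@orientation[, 1], oy = array@orientation[, 2],
                   oz = array@orientation[, 3],
                   kind = array@kind,
                   noise_floor_fT_sqrtHz = array@noiseFloor)
  for (cl in names(df))
    if (is.double(df[[cl]])) df[[cl]] <- format(df[[cl]], digits = 17, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(platform = array@platform,
                            sampling_rate_hz = array@samplingRate,
                            gradiometer_baseline_m = array@baseline),
                       side, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeArrayTsv
#' @export
readArrayTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  new("SensorArray", platform = side$platform, channelName = df$name,
      position = as.matrix(df[, c("x", "y", "z")]),
      orientation = as.matrix(df[, c("ox", "oy", "oz")]),
      kind = df$kind, samplingRate = side$sampling_rate_hz,
      noiseFloor = df$noise_floor_fT_sqrtHz,
      baseline = side$gradiometer_baseline_m)
}
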