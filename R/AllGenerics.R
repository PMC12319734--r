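# Accessor generics and show methods for the core containers.

#' Number of trials
#' @param x a TrialSchedule or Epochs object
#' @return integer count
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname nTrials
#' @export
setMethod("nTrials", "TrialSchedule", function(x) x@nTrials)

#' @rdname nTrials
#' @export
setMethod("nTrials", "Epochs", function(x) dim(x@data)[1])

#' Platform label ("opm" or "squid")
#' @param x a SensorArray or Recording
#' @return character scalar
#' @export
setGeneric("platform", function(x) standardGeneric("platform"))

#' @rdname platform
#' @export
setMethod("platform", "SensorArray", function(x) x@platform)

#' @rdname platform
#' @export
setMethod("platform", "Recording", function(x) x@platform)

#' Sampling rate in Hz
#' @param x a SensorArray, Recording or Epochs object
#' @return numeric scalar, Hz
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "SensorArray", function(x) x@samplingRate)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "Recording", function(x) x@samplingRate)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "Epochs", function(x) x@samplingRate)

#' Channel names
#' @param x a SensorArray, Recording, Epochs or LeadField object
#' @return character vector
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "SensorArray", function(x) x@channelName)

#' @rdname channelNames
#' @export
setMethod("channelNames", "Recording", function(x) x@array@channelName)

#' @rdname channelNames
#' @export
setMethod("channelNames", "Epochs", function(x) x@channelName)

#' @rdname channelNames
#' @export
setMethod("channelNames", "LeadField", function(x) x@channelName)

#' Raw numeric contents of a container
#' @param x a Recording, Epochs, PseudoTImage, TFS or FingerprintMatrix
#' @return the underlying numeric matrix/array/vector
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "Recording", function(x) x@data)

#' @rdname values
#' @export
setMethod("values", "Epochs", function(x) x@data)

#' @rdname values
#' @export
setMethod("values", "PseudoTImage", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "TFS", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "FingerprintMatrix", function(x) x@values)

#' Event table of a recording
#' @param x a Recording
#' @return data.frame with columns onset, duration, trial_type, sample
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname events
#' @export
setMethod("events", "Recording", function(x) x@events)

setMethod("show", "TrialSchedule", function(object) {
  n <- object@nTrials
  cat("TrialSchedule:", n, "trials,", 5L * n, "stimulus slots\n")
  if (n > 0) {
    cat("  targets:", sum(object@pattern == "target"),
        " non-targets:", sum(object@pattern == "non_target"), "\n")
    cat("  cue sides: left", sum(object@cueSide == "left"),
        "/ right", sum(object@cueSide == "right"), "\n")
  }
  cat("  trial duration:", format(trialDuration(object)), "s\n")
})

setMethod("show", "SensorArray", function(object) {
  cat("SensorArray [", object@platform, "]: ",
      length(object@channelName), " channels (",
      paste(names(table(object@kind)), table(object@kind),
            sep = ": ", collapse = ", "),
      "), ", object@samplingRate, " Hz\n", sep = "")
})

setMethod("show", "SourceSpace", function(object) {
  cat("SourceSpace:", nrow(object@positions), "voxels,",
      object@spacing * 1000, "mm grid, radius", object@radius, "m\n")
})

setMethod("show", "LeadField", function(object) {
  d <- dim(object@gains)
  cat("LeadField:", d[1], "voxels x 3 orientations x", d[3], "channels (fT/nAm)\n")
})

setMethod("show", "Recording", function(object) {
  cat("Recording [", object@platform, "] subject ", object@subject,
      " run ", object@run, ": ", nrow(object@data), " channels x ",
      ncol(object@data), " samples @ ", object@samplingRate, " Hz (",
      round(ncol(object@data) / object@samplingRate, 1), " s), ",
      nrow(object@events), " events\n", sep = "")
})

setMethod("show", "Epochs", function(object) {
  d <- dim(object@data)
  cat("Epochs [", object@band, "]: ", d[1], " trials x ", d[2],
      " channels x ", d[3], " samples, window [",
      object@window[1], ", ", object@window[2], "] s\n", sep = "")
})

setMethod("show", "PseudoTImage", function(object) {
  cat("PseudoTImage:", length(object@values), "voxels, range [",
      round(min(object@values), 3), ",", round(max(object@values), 3), "]\n")
})

setMethod("show", "TFS", function(object) {
  cat("TFS:", nrow(object@values), "time points x", ncol(object@values),
      "bands (", min(object@freqs), "-", max(object@freqs), "Hz ), baseline [",
      object@baselineWindow[1], ",", object@baselineWindow[2], "] s\n")
})

setMethod("show", "FingerprintMatrix", function(object) {
  n <- nrow(object@values)
  id <- identifySubjects(object)
  cat("FingerprintMatrix [", object@scheme, ", ", object@featureSet,
      " features]: ", n, " x ", n, ", ", id$nIdentified, "/", n,
      " identified\n", sep = "")
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution: observed =", signif(object@observed, 4),
      ", nPerm =", object@nPerm, ", p =", signif(object@p, 4),
      " (", object@tail, ")\n")
})
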