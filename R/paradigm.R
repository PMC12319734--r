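#' Generate a braille attention-switching trial schedule
#'
#' Each trial begins (t = 0 s) at the end of an auditory cue ("attend left" /
#' "attend right"). Five braille patterns are presented bilaterally, the
#' first at 1.17 s and the rest at 1.37 s intervals; each lasts 0.37 s and
#' the trial ends with a 7 s rest. Targets occupy exactly
#' \code{ceiling(pTarget * nSlots)} stimulus slots, placed by sampling
#' without replacement, so the default 80-trial schedule carries exactly
#' 80 targets and 320 non-targets. Cue sides are balanced (40/40 by default)
#' in a seeded random order.
#'
#' @param nTrials number of trials (>= 0); default 80.
#' @param seed integer seed for target placement and cue-side order.
#' @param pTarget fraction of stimulus slots carrying the target pattern.
#' @param timing named numeric vector of paradigm constants (seconds);
#'   see \linkS4class{TrialSchedule}.
#' @return a \linkS4class{TrialSchedule}.
#' @examples
#' sched <- generateSchedule(80, seed = 1)
#' table(sched@pattern)
#' @export
generateSchedule <- function(nTrials = 80, seed = 1, pTarget = 0.2,
                             timing = c(first_onset_s = 1.17,
                                        inter_stimulus_interval_s = 1.37,
                                        stimulus_duration_s = 0.37,
                                        rest_s = 7.0,
                                        cue_s = 2.0)) {
  if (length(nTrials) != 1 || is.na(nTrials) || nTrials < 0)
    stop("nTrials must be a non-negative count", call. = FALSE)
  nTrials <- as.integer(nTrials)
  nSlots <- 5L * nTrials
  onsets <- matrix(timing[["first_onset_s"]] +
                     rep(0:4, each = max(nTrials, 1)) *
                     timing[["inter_stimulus_interval_s"]],
                   nrow = max(nTrials, 1), ncol = 5L)
  if (nTrials == 0L) {
    return(new("TrialSchedule", nTrials = 0L, cueSide = character(0),
               onsets = matrix(numeric(0), 0, 5), pattern = matrix(character(0), 0, 5),
               timing = timing, pTarget = pTarget))
  }
  withSeed(seed, {
    nTarget <- ceiling(pTarget * nSlots)
    slots <- sample.int(nSlots, nTarget)
    pattern <- matrix("non_target", nTrials, 5L)
    pattern[slots] <- "target"
    nLeft <- floor(nTrials / 2)
    sides <- c(rep("left", nLeft), rep("right", nTrials - nLeft))
    cueSide <- sample(sides)
    new("TrialSchedule", nTrials = nTrials, cueSide = cueSide,
        onsets = onsets, pattern = pattern, timing = timing,
        pTarget = pTarget)
  })
}

#' Trial duration in seconds
#'
#' Defined as the offset of the last stimulus plus the rest period; the
#' auditory cue occupies the tail of the preceding trial's rest, so trial
#' time t = 0 (cue end) coincides with trial start and trials concatenate
#' end to end.
#'
#' @param schedule a \linkS4class{TrialSchedule}.
#' @return duration of one trial, seconds.
#' @export
trialDuration <- function(schedule) {
  tm <- schedule@timing
  tm[["first_onset_s"]] + 4 * tm[["inter_stimulus_interval_s"]] +
    tm[["stimulus_duration_s"]] + tm[["rest_s"]]
}

#' Convert a schedule to a sampled event table
#'
#' Trials are concatenated end to end; trial k starts at
#' k * \code{trialDuration(schedule)} seconds. Emits one cue event
#' (\code{cue_left} / \code{cue_right}) at each trial start, five stimulus
#' events (\code{stim_target} / \code{stim_nontarget}) and a
#' \code{trial_end} event. Sample indices are \code{round(onset * rate)}
#' (0-based, BIDS convention).
#'
#' @param schedule a \linkS4class{TrialSchedule}.
#' @param samplingRate sampling rate, Hz (> 0).
#' @return data.frame with columns onset, duration, trial_type, sample,
#'   trial (1-based trial number); onsets monotone non-decreasing.
#' @export
scheduleToEvents <- function(schedule, samplingRate) {
  if (samplingRate <= 0) stop("samplingRate must be > 0", call. = FALSE)
  n <- schedule@nTrials
  if (n == 0L)
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      trial_type = character(0), sample = integer(0),
                      trial = integer(0)))
  dur <- trialDuration(schedule)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    t0 <- (k - 1) * dur
    type <- ifelse(schedule@pattern[k, ] == "target",
                   "stim_target", "stim_nontarget")
    rows[[k]] <- data.frame(
      onset = c(t0, t0 + schedule@onsets[k, ], k * dur),
      duration = c(0, rep(schedule@timing[["stimulus_duration_s"]], 5), 0),
      trial_type = c(paste0("cue_", schedule@cueSide[k]), type, "trial_end"),
      trial = k
    )
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$onset, method = "radix"), ]
  ev$sample <- as.integer(round(ev$onset * samplingRate))
  rownames(ev) <- NULL
  ev[, c("onset", "duration", "trial_type", "sample", "trial")]
}

#' Write / read a BIDS-style events table
#'
#' Tab-separated with columns onset, duration, trial_type, sample (plus any
#' extra columns); numeric values are written with 17 significant digits so
#' tables round-trip bit-exactly.
#'
#' @param events event data.frame.
#' @param path file path for the *_events.tsv.
#' @return \code{writeEventsTsv} returns \code{path} invisibly;
#'   \code{readEventsTsv} returns the event data.frame.
#' @export
writeEventsTsv <- function(events, path) {
  out <- events
  for (cl in names(out))
    if (is.double(out[[cl]])) out[[cl]] <- format(out[[cl]], digits = 17, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsTsv
#' @export
readEventsTsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if ("sample" %in% names(ev)) ev$sample <- as.integer(ev$sample)
  if ("trial" %in% names(ev)) ev$trial <- as.integer(ev$trial)
  ev
}

#' Serialise a schedule to JSON (and back)
#'
#' @param schedule a \linkS4class{TrialSchedule}.
#' @param path JSON file path.
#' @return \code{writeScheduleJson} returns \code{path} invisibly;
#'   \code{readScheduleJson} returns the \linkS4class{TrialSchedule}.
#' @export
writeScheduleJson <- function(schedule, path) {
  obj <- list(
    n_trials = schedule@nTrials,
    cue_side = schedule@cueSide,
    onsets_s = schedule@onsets,
    pattern = schedule@pattern,
    timing = as.list(schedule@timing),
    p_target = schedule@pTarget
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeScheduleJson
#' @export
readScheduleJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(obj$n_trials)
  new("TrialSchedule",
      nTrials = n,
      cueSide = as.character(obj$cue_side),
      onsets = matrix(as.numeric(obj$onsets_s), nrow = max(n, 0)),
      pattern = matrix(as.character(obj$pattern), nrow = max(n, 0)),
      timing = unlist(obj$timing),
      pTarget = obj$p_target)
}
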