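#' Estimate the burst-suppression timeline
#'
#' A sample is suppressed when the smoothed amplitude envelope (RMS in a
#' sliding window, averaged over channels) stays below \code{threshold} for
#' at least \code{minSupprDur} seconds. The hard 0/1 suppression indicator
#' is then smoothed by the same envelope window, giving a per-sample
#' suppression probability in [0,1]; values above 0.5 count as suppressed.
#' Because the input is z-scored, the threshold is expressed in z-units.
#' The envelope is computed on a band-limited (default 3-30 Hz) copy of the
#' segments: the 0.3 Hz high-pass edge of the preprocessing band-pass rings
#' for up to a second across suppression boundaries, whereas the 3 Hz-and-up
#' content localizes the edges to tens of milliseconds. Suppression runs
#' never bridge segment gaps: unobserved (artifact) time is not claimed
#' suppressed.
#'
#' @param series z-scored \code{SegmentSeries}.
#' @param threshold envelope threshold in z-units.
#' @param minSupprDur minimum suppression duration in seconds.
#' @param envelopeWin RMS window length in seconds.
#' @param envBand frequency band (Hz) the envelope is computed from.
#' @return a \code{BurstSuppressionProfile}.
#' @export
suppressionTimeline <- function(series, threshold = 0.2, minSupprDur = 0.5,
                                envelopeWin = 0.25, envBand = c(3, 30)) {
  fs <- series@samplingRate
  if (minSupprDur < 1 / fs)
    stop("configuration error: minSupprDur must be at least one sample",
         call. = FALSE)
  win <- max(1L, as.integer(round(envelopeWin * fs)))
  minN <- as.integer(round(minSupprDur * fs))
  timeline <- lapply(series@blocks, function(b) {
    bb <- fftBandpass(b, fs, envBand[1], envBand[2])
    env <- sqrt(runningMean(colMeans(bb^2), win))
    sub <- env < threshold
    hard <- rep(0, length(sub))
    runs <- trueRuns(sub)
    if (nrow(runs)) for (j in seq_len(nrow(runs)))
      if (runs[j, "length"] >= minN)
        hard[runs[j, "start"]:runs[j, "end"]] <- 1
    runningMean(hard, win)
  })
  profileFromTimeline(timeline, fs, cleanDuration(series))
}

profileFromTimeline <- function(timeline, fs, analyzedDuration) {
  nSamp <- sum(lengths(timeline))
  suppr <- vapply(timeline, function(t) sum(t > 0.5), numeric(1))
  longest <- 0
  for (t in timeline) {
    runs <- trueRuns(t > 0.5)
    if (nrow(runs)) longest <- max(longest, max(runs[, "length"]))
  }
  new("BurstSuppressionProfile", timeline = timeline,
      bsr = if (nSamp > 0) sum(suppr) / nSamp else 0,
      lsp = longest / fs, analyzedDuration = analyzedDuration,
      samplingRate = fs)
}

#' Burst suppression ratio
#'
#' Suppressed time divided by the total clean (artifact-reduced) analyzed
#' time; a fraction in [0,1].
#'
#' @param profile a \code{BurstSuppressionProfile}.
#' @export
burstSuppressionRatio <- function(profile) {
  nSamp <- sum(lengths(profile@timeline))
  if (nSamp == 0 || profile@analyzedDuration <= 0)
    stop("undefined input: empty burst-suppression profile", call. = FALSE)
  sum(vapply(profile@timeline, function(t) sum(t > 0.5), numeric(1))) / nSamp
}

#' Longest suppression phase
#'
#' Duration in seconds of the longest maximal contiguous suppressed run;
#' runs are truncated at segment boundaries (they never span artifact gaps)
#' and 0 is returned when nothing is suppressed.
#'
#' @param profile a \code{BurstSuppressionProfile}.
#' @export
longestSuppressionPhase <- function(profile) {
  longest <- 0L
  for (t in profile@timeline) {
    runs <- trueRuns(t > 0.5)
    if (nrow(runs)) longest <- max(longest, max(runs[, "length"]))
  }
  longest / profile@samplingRate
}
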