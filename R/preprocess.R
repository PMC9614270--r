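#' Amplitude artifact mask
#'
#' Flags samples whose absolute amplitude on any channel exceeds the
#' patient-level empirical quantile of the pooled absolute amplitudes across
#' all channels. Because amplitudes scale differently between subjects and
#' recording setups, the threshold is per patient rather than fixed.
#'
#' @param rec an \code{EEGRecording} (raw, before re-referencing/filtering).
#' @param quantile pooled amplitude quantile in (0,1); default 0.99.
#' @return logical vector, one entry per sample, TRUE = artifact.
#' @export
amplitudeArtifactMask <- function(rec, quantile = 0.99) {
  if (quantile <= 0 || quantile >= 1)
    stop("configuration error: quantile must lie strictly in (0,1)",
         call. = FALSE)
  stopIfNot(ncol(rec@signal) > 0, "empty recording")
  thr <- stats::quantile(abs(rec@signal), quantile, names = FALSE)
  colSums(abs(rec@signal) > thr) > 0
}

#' Common average reference
#'
#' Subtracts the across-channel mean from every sample, leaving the
#' per-sample channel mean at zero.
#'
#' @param rec an \code{EEGRecording} with at least two channels.
#' @return re-referenced \code{EEGRecording}.
#' @export
commonAverageReference <- function(rec) {
  stopIfNot(nrow(rec@signal) >= 2,
            "common average reference requires at least 2 channels")
  rec@signal <- sweep(rec@signal, 2, colMeans(rec@signal))
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the squared Butterworth magnitude response (the response of a
#' forward-backward, i.e. zero-phase, Butterworth pass) in the frequency
#' domain. The default 0.3-50 Hz band removes drift and high-frequency
#' artifacts; the default order gives more than 20 dB power attenuation at
#' 0.05 Hz and 60 Hz.
#'
#' @param rec an \code{EEGRecording}.
#' @param low,high band edges in Hz; \code{high} must be below Nyquist.
#' @param order Butterworth order (per pass; the zero-phase application
#'   squares the magnitude response).
#' @return filtered \code{EEGRecording}, length preserved.
#' @export
bandpassFilter <- function(rec, low = 0.3, high = 50, order = 5) {
  fs <- rec@samplingRate
  if (high >= fs / 2)
    stop("configuration error: high edge ", high,
         " Hz must be below Nyquist (", fs / 2, " Hz)", call. = FALSE)
  n <- ncol(rec@signal)
  m <- fastLength(n)
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)
  # |H|^2 of a digital (bilinear-transformed, hence prewarped) Butterworth
  # band-pass: low-edge high-pass x high-edge low-pass, squared once more
  # for the forward-backward (zero-phase) pass
  warp <- function(x) tan(pmin(pi * x / fs, pi / 2 - 1e-12))
  fw <- warp(f); loW <- warp(low); hiW <- warp(high)
  H2 <- 1 / (1 + (fw / hiW)^(2 * order)) *
    (fw / loW)^(2 * order) / (1 + (fw / loW)^(2 * order))
  for (ch in seq_len(nrow(rec@signal))) {
    X <- stats::fft(c(rec@signal[ch, ], rep(0, m - n)))
    rec@signal[ch, ] <- Re(stats::fft(X * H2, inverse = TRUE))[seq_len(n)] / m
  }
  rec
}

#' Cut a recording into artifact-free segments
#'
#' Takes the maximal artifact-free runs of the recording, after dilating
#' each flagged sample to its enclosing 0.1 s neighborhood (spike ringing),
#' shrinks every run by \code{edgePad} seconds at each boundary (each
#' boundary abuts either an artifact or a recording edge, both of which
#' carry filter edge effects), and drops runs shorter than
#' \code{minSegmentLen}. Intervals are half-open \code{[start, end)} seconds
#' with 0-based time from recording start.
#'
#' @param rec the (re-referenced, band-passed) \code{EEGRecording}.
#' @param artifactMask per-sample logical mask from
#'   \code{\link{amplitudeArtifactMask}}.
#' @param minSegmentLen minimum kept segment length in seconds.
#' @param edgePad seconds removed at every segment boundary.
#' @param dilate full width in seconds of the neighborhood an artifact
#'   sample contaminates.
#' @return a \code{SegmentSeries} (possibly empty).
#' @export
segmentRecording <- function(rec, artifactMask, minSegmentLen = 1,
                             edgePad = 1, dilate = 0.1) {
  fs <- rec@samplingRate
  n <- ncol(rec@signal)
  stopIfNot(length(artifactMask) == n, "mask not aligned to samples")
  half <- as.integer(round(dilate * fs / 2))
  if (any(artifactMask) && half > 0) {
    idx <- which(artifactMask)
    lo <- pmax(idx - half, 1L)
    hi <- pmin(idx + half, n)
    grow <- rep(FALSE, n)
    for (j in seq_along(idx)) grow[lo[j]:hi[j]] <- TRUE
    artifactMask <- grow
  }
  runs <- trueRuns(!artifactMask)
  padN <- as.integer(round(edgePad * fs))
  minN <- as.integer(round(minSegmentLen * fs))
  starts <- numeric(0); ends <- numeric(0); blocks <- list()
  if (nrow(runs)) for (j in seq_len(nrow(runs))) {
    s <- runs[j, "start"] + padN
    e <- runs[j, "end"] - padN
    if (e - s + 1L < minN) next
    starts <- c(starts, unname((s - 1) / fs))
    ends <- c(ends, unname(e / fs))
    blocks <- c(blocks, list(rec@signal[, s:e, drop = FALSE]))
  }
  new("SegmentSeries", starts = starts, ends = ends, blocks = blocks,
      samplingRate = fs, channelLabels = rec@channelLabels,
      sourceId = rec@patientId)
}

#' Z-score a segment series per channel
#'
#' Standardizes each channel to mean 0 and standard deviation 1 over the
#' concatenation of all clean segments of the patient (one pooled constant
#' pair per channel, applied to every segment).
#'
#' @param series a nonempty \code{SegmentSeries}.
#' @return standardized \code{SegmentSeries}.
#' @export
zscoreSegments <- function(series) {
  stopIfNot(nSegments(series) > 0, "empty segment series")
  pooled <- do.call(cbind, series@blocks)
  mu <- rowMeans(pooled)
  sdv <- apply(pooled, 1, stats::sd)
  if (any(sdv < 1e-12))
    stop("degenerate input: zero-variance channel ",
         series@channelLabels[which(sdv < 1e-12)[1]], call. = FALSE)
  series@blocks <- lapply(series@blocks, function(b) (b - mu) / sdv)
  series
}

#' Patient-level inclusion rule
#'
#' A patient enters the analysis iff at least \code{minTotal} minutes of
#' clean EEG remain after preprocessing (the boundary counts as included).
#'
#' @param series a \code{SegmentSeries}.
#' @param minTotal minimum total clean duration in minutes.
#' @export
passesInclusion <- function(series, minTotal = 20) {
  cleanDuration(series) >= minTotal * 60
}

#' Full preprocessing pipeline
#'
#' Fixed order: amplitude artifact mask on the raw signal, common average
#' reference, 0.3-50 Hz zero-phase band-pass, segmentation into
#' artifact-free runs, per-channel z-scoring over the clean concatenation.
#'
#' @param rec raw \code{EEGRecording} (4 frontal channels).
#' @param quantile amplitude quantile for the artifact mask.
#' @param low,high band-pass edges in Hz.
#' @param minSegmentLen,edgePad,dilate segmentation parameters in seconds.
#' @return list with \code{series} (z-scored \code{SegmentSeries}),
#'   \code{mask} (the amplitude artifact mask) and \code{included}
#'   (the 20-minute inclusion flag).
#' @export
preprocessRecording <- function(rec, quantile = 0.99, low = 0.3, high = 50,
                                minSegmentLen = 1, edgePad = 1,
                                dilate = 0.1) {
  mask <- amplitudeArtifactMask(rec, quantile)
  rec <- commonAverageReference(rec)
  rec <- bandpassFilter(rec, low, high)
  series <- segmentRecording(rec, mask, minSegmentLen, edgePad, dilate)
  if (nSegments(series) > 0) series <- zscoreSegments(series)
  list(series = series, mask = mask,
       included = passesInclusion(series))
}
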