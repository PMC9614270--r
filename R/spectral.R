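#' Welch power spectral density
#'
#' Hann-windowed, overlapping-segment averaged periodogram. For a matrix
#' input (channels x samples) the per-channel densities are averaged. A
#' segment shorter than one window falls back to a single window spanning
#' the whole segment. Normalization is such that the one-sided density
#' integrates to the signal variance (Parseval).
#'
#' @param x numeric vector or channels x samples matrix.
#' @param fs sampling rate in Hz.
#' @param windowSec window length in seconds.
#' @param overlap fractional overlap between consecutive windows.
#' @return list with \code{freq} (one-sided grid in Hz, 0..Nyquist) and
#'   \code{psd} (nonnegative density, power per Hz).
#' @export
welchPsd <- function(x, fs, windowSec = 2, overlap = 0.5) {
  if (is.matrix(x)) {
    per <- lapply(seq_len(nrow(x)), function(ch)
      welchPsd(x[ch, ], fs, windowSec, overlap))
    return(list(freq = per[[1]]$freq,
                psd = Reduce(`+`, lapply(per, `[[`, "psd")) / length(per)))
  }
  n <- length(x)
  win <- min(n, as.integer(round(windowSec * fs)))
  stopIfNot(win >= 2, "segment too short for spectral estimation")
  hop <- max(1L, as.integer(round(win * (1 - overlap))))
  starts <- seq(1L, n - win + 1L, by = hop)
  w <- hannWindow(win)
  U <- sum(w^2)
  frames <- matrix(x[outer(0:(win - 1L), starts, `+`)], nrow = win) * w
  spec <- abs(stats::mvfft(frames))^2 / (fs * U)
  half <- floor(win / 2)
  psd <- rowMeans(spec)[1:(half + 1)]
  scale <- rep(2, half + 1)
  scale[1] <- 1
  if (win %% 2 == 0) scale[half + 1] <- 1
  list(freq = (0:half) * fs / win, psd = psd * scale)
}

#' Average per-segment feature vectors into fixed-length time frames
#'
#' Groups per-segment vectors by frames of \code{frameLen} seconds of
#' concatenated clean time and returns the unweighted mean vector per
#' frame. A segment belongs to the frame containing its clean-time
#' midpoint; frames containing no segment are omitted.
#'
#' @param values segments x features numeric matrix.
#' @param midpoints clean-time midpoints of the segments in seconds.
#' @param frameLen frame length in seconds (2 minutes by default).
#' @return list with \code{frameStarts} and \code{means} (frames x features).
#' @export
frameAverage <- function(values, midpoints, frameLen = 120) {
  stopIfNot(nrow(values) == length(midpoints),
            "one midpoint per segment required")
  frameIdx <- floor(midpoints / frameLen)
  keep <- sort(unique(frameIdx))
  means <- do.call(rbind, lapply(keep, function(k)
    colMeans(values[frameIdx == k, , drop = FALSE])))
  list(frameStarts = keep * frameLen, means = means)
}

# Clean-time segment midpoints: time measured over the concatenation of the
# clean segments, not wall time, so every frame holds comparable data.
cleanMidpoints <- function(series) {
  dur <- series@ends - series@starts
  cumsum(dur) - dur / 2
}

#' Spectral feature frames for one patient
#'
#' Welch spectrum per clean segment, interpolated onto a fixed frequency
#' grid, then averaged into 2-minute frames of clean time: the "spectrum"
#' feature stream.
#'
#' @param series z-scored \code{SegmentSeries}.
#' @param windowSec,overlap Welch parameters.
#' @param frameLen frame length in seconds.
#' @param freqGrid fixed frequency grid in Hz.
#' @return a \code{SpectralFrameSeries}.
#' @export
spectralFrames <- function(series, windowSec = 2, overlap = 0.5,
                           frameLen = 120,
                           freqGrid = seq(0.5, 50, by = 0.5)) {
  stopIfNot(nSegments(series) > 0, "empty segment series")
  perSeg <- do.call(rbind, lapply(series@blocks, function(b) {
    w <- welchPsd(b, series@samplingRate, windowSec, overlap)
    stats::approx(w$freq, w$psd, xout = freqGrid, rule = 2)$y
  }))
  fa <- frameAverage(perSeg, cleanMidpoints(series), frameLen)
  new("SpectralFrameSeries", frameStarts = fa$frameStarts,
      psd = pmax(fa$means, 0), freqGrid = freqGrid,
      patientId = series@sourceId)
}
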