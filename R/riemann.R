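#' Default frequency bands of the multi-band stack
#'
#' delta, theta, lower alpha, higher alpha, lower beta, higher beta.
#' @export
defaultBands <- function() list(
  delta = c(0.3, 4), theta = c(4, 8), alpha_lo = c(8, 12),
  alpha_hi = c(12, 15), beta_lo = c(15, 20), beta_hi = c(20, 30))

# Zero-phase band filtering by spectral masking: exact half-open [lo, hi)
# passbands so that adjacent bands partition the spectrum and their sum
# reconstructs the 0.3-30 Hz filtered signal exactly. bands is a list of
# (lo, hi) pairs; the forward transform is computed once per channel and
# reused across bands. Returns a list of filtered matrices, one per band.
fftFilterBank <- function(x, fs, bands) {
  n <- ncol(x)
  m <- fastLength(n)
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)
  fwd <- lapply(seq_len(nrow(x)), function(ch)
    stats::fft(c(x[ch, ], rep(0, m - n))))
  lapply(bands, function(be) {
    mask <- (f >= be[1]) & (f < be[2])
    out <- x
    for (ch in seq_len(nrow(x)))
      out[ch, ] <- Re(stats::fft(fwd[[ch]] * mask,
                                 inverse = TRUE))[seq_len(n)] / m
    out
  })
}

fftBandpass <- function(x, fs, lo, hi) {
  fftFilterBank(x, fs, list(c(lo, hi)))[[1]]
}

#' Multi-band stacked signal per segment
#'
#' Filters each segment's 4 channels into the six canonical frequency bands
#' (zero-phase) and stacks the filtered copies with the burst-suppression
#' timeline as a final row, artificially creating a higher-dimensional
#' signal (4 channels x 6 bands + 1 = 25 rows by default). Row order is
#' channel-major within band, bands low to high, timeline last; this
#' convention is serialized with any trained model.
#'
#' @param series z-scored \code{SegmentSeries}.
#' @param profile \code{BurstSuppressionProfile} aligned to the series.
#' @param bands named list of (lo, hi) band edges in Hz.
#' @return list of stacked matrices, one per segment.
#' @export
multibandStack <- function(series, profile, bands = defaultBands()) {
  stopIfNot(length(profile@timeline) == nSegments(series),
            "timeline not aligned to segment series")
  fs <- series@samplingRate
  lapply(seq_len(nSegments(series)), function(i) {
    b <- series@blocks[[i]]
    tl <- profile@timeline[[i]]
    stopIfNot(length(tl) == ncol(b), "timeline not aligned to segment series")
    rows <- fftFilterBank(b, fs, bands)
    rbind(do.call(rbind, rows), suppression = tl)
  })
}

#' Oracle Approximating Shrinkage covariance
#'
#' Shrinks the sample covariance S toward the scaled identity
#' \eqn{(tr(S)/p) I} with the OAS shrinkage intensity
#' \deqn{\rho = \min\!\left(1, \frac{(1 - 2/p)\,tr(S^2) + tr(S)^2}
#'  {(n + 1 - 2/p)\,(tr(S^2) - tr(S)^2/p)}\right),}
#' guaranteeing a symmetric positive definite estimate even when rows are
#' constant or n < p.
#'
#' @param x p x n data block (rows = stacked channels, columns = samples).
#' @return p x p SPD matrix.
#' @export
oasCovariance <- function(x) {
  n <- ncol(x)
  p <- nrow(x)
  stopIfNot(n >= 2, "OAS covariance needs at least 2 samples")
  xc <- x - rowMeans(x)
  S <- tcrossprod(xc) / n
  trS <- sum(diag(S))
  trS2 <- sum(S * S)
  denom <- (n + 1 - 2 / p) * (trS2 - trS^2 / p)
  rho <- if (denom <= 0) 1 else
    min(1, ((1 - 2 / p) * trS2 + trS^2) / denom)
  mu <- trS / p
  symmetrize((1 - rho) * S + rho * mu * diag(p))
}

#' Covariance feature frames for one patient
#'
#' OAS covariance of the multi-band stacked signal per clean segment, then
#' the (Euclidean, elementwise) mean of the per-segment covariances within
#' each 2-minute frame of clean time. The arithmetic mean of SPD matrices
#' is SPD, so every frame lies on the manifold.
#'
#' @param series z-scored \code{SegmentSeries}.
#' @param profile aligned \code{BurstSuppressionProfile}.
#' @param frameLen frame length in seconds.
#' @param bands band edges for the multi-band stack.
#' @return a \code{CovarianceFrameSeries}.
#' @export
covarianceFrames <- function(series, profile, frameLen = 120,
                             bands = defaultBands()) {
  stacks <- multibandStack(series, profile, bands)
  covs <- lapply(stacks, oasCovariance)
  p <- nrow(covs[[1]])
  flat <- do.call(rbind, lapply(covs, as.vector))
  fa <- frameAverage(flat, cleanMidpoints(series), frameLen)
  arr <- array(t(fa$means), dim = c(p, p, nrow(fa$means)))
  new("CovarianceFrameSeries", frameStarts = fa$frameStarts,
      matrices = arr, patientId = series@sourceId)
}

#' Riemannian potato outlier rejection
#'
#' Adaptive outlier detector on the SPD manifold: each frame's
#' affine-invariant distance to a running geometric mean is z-scored
#' against the running distance statistics; frames with z above
#' \code{zThreshold} are flagged. The running mean moves by a geodesic step
#' of size \code{adaptRate} toward each inlier frame only, and the first
#' \code{burnIn} frames are never flagged (they establish the statistics).
#' Because the metric is affine-invariant, the output is unchanged by a
#' common rescaling of all frames.
#'
#' @param frames \code{CovarianceFrameSeries}, list of SPD matrices or
#'   3-d array.
#' @param zThreshold flagging threshold on the distance z-score.
#' @param adaptRate geodesic step size of the running-mean update.
#' @param burnIn number of initial frames exempt from flagging.
#' @return logical inlier mask (TRUE = kept).
#' @export
riemannianPotato <- function(frames, zThreshold = 2.5, adaptRate = 0.1,
                             burnIn = 10) {
  mats <- framesAsList(frames)
  stopIfNot(length(mats) >= 2, "potato needs at least 2 frames")
  M <- mats[[1]]
  cnt <- 0; mu <- 0; m2 <- 0          # Welford stats of inlier distances
  inlier <- rep(TRUE, length(mats))
  for (i in seq_along(mats)) {
    d <- airmDistance(M, mats[[i]])
    sdv <- if (cnt > 1) sqrt(m2 / (cnt - 1)) else 0
    if (i > burnIn) {
      z <- if (d == 0) 0 else (d - mu) / max(sdv, 1e-8)
      if (z > zThreshold) {
        inlier[i] <- FALSE
        next
      }
    }
    cnt <- cnt + 1
    delta <- d - mu
    mu <- mu + delta / cnt
    m2 <- m2 + delta * (d - mu)
    M <- spdGeodesic(M, mats[[i]], adaptRate)
  }
  if (!any(inlier))
    stop("degenerate input: all frames flagged by the potato", call. = FALSE)
  inlier
}

#' Balanced Riemannian reference point
#'
#' Riemannian mean of the per-class Riemannian means: the mean is first
#' taken over the frames of each class and then the geometric mean of the
#' two class means is taken with equal weight, making the reference
#' invariant to class-size imbalance.
#'
#' @param frames list of SPD matrices or 3-d array.
#' @param labels binary class label per frame (both classes present).
#' @param ... forwarded to \code{\link{riemannianMean}}.
#' @return SPD reference matrix.
#' @export
balancedReference <- function(frames, labels, ...) {
  mats <- framesAsList(frames)
  stopIfNot(length(mats) == length(labels),
            "one label per frame required")
  cls <- sort(unique(labels))
  stopIfNot(length(cls) == 2, "both classes must be present")
  m0 <- riemannianMean(mats[labels == cls[1]], ...)
  m1 <- riemannianMean(mats[labels == cls[2]], ...)
  riemannianMean(list(m0, m1), ...)
}
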