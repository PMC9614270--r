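# Artifact masking, re-referencing, filtering, segmentation, z-scoring.

test_that("amplitude mask flags the top amplitudes only", {
  rec <- sineRecording(freq = 1, fs = 128, seconds = 50)
  mask <- amplitudeArtifactMask(rec, 0.99)
  # flags concentrate near the sinusoid peaks
  expect_true(all(abs(rec@signal[1, mask]) >
                    quantile(abs(rec@signal[1, ]), 0.985)))
  expect_lte(mean(mask), 0.04)             # pooled bound: (1-q) x channels
  # quantile -> 1 limit: empty mask
  expect_equal(sum(amplitudeArtifactMask(rec, 0.999999)), 0)
  expect_error(amplitudeArtifactMask(rec, 1.2), "configuration error")
})

test_that("planted 10x spikes are caught by the quantile mask", {
  spec <- cohortSpec(nPatients = 2, seed = 5, artifactRate = 1)
  sim <- simulateEEG(0, "Propofol", spec, 21, seed = 77)
  expect_gt(length(sim$groundTruth$artifactIdx), 0)
  mask <- amplitudeArtifactMask(sim$recording)
  flagged <- mean(sim$groundTruth$artifactIdx %in% which(mask))
  expect_gte(flagged, 0.95)
})

test_that("common average reference zeroes the channel mean", {
  set.seed(1)
  sig <- matrix(rnorm(4 * 1000), 4) + 7    # constant offset on all channels
  rec <- new("EEGRecording", signal = sig, samplingRate = 100,
             channelLabels = paste0("c", 1:4), patientId = "x")
  out <- commonAverageReference(rec)
  expect_lt(max(abs(colMeans(out@signal))), 1e-12)
  # two channels (x, -x) unchanged
  rec2 <- new("EEGRecording", signal = rbind(sig[1, ], -sig[1, ]),
              samplingRate = 100, channelLabels = c("a", "b"),
              patientId = "x")
  expect_equal(commonAverageReference(rec2)@signal, rec2@signal)
  rec1 <- new("EEGRecording", signal = sig[1, , drop = FALSE],
              samplingRate = 100, channelLabels = "a", patientId = "x")
  expect_error(commonAverageReference(rec1), "at least 2")
})

test_that("band-pass keeps the passband and rejects DC and 60 Hz", {
  rec10 <- sineRecording(freq = 10, fs = 256, seconds = 20)
  out10 <- bandpassFilter(rec10)
  mid <- 2000:3000
  expect_equal(sd(out10@signal[1, mid]), sd(rec10@signal[1, mid]),
               tolerance = 0.05)
  rec60 <- sineRecording(freq = 60, fs = 256, seconds = 20)
  out60 <- bandpassFilter(rec60)
  expect_lt(sd(out60@signal[1, mid]), 0.1 * sd(rec60@signal[1, mid]))
  expect_true(all(is.finite(out60@signal)))
  recDC <- sineRecording(freq = 10, fs = 256, seconds = 20)
  recDC@signal <- recDC@signal + 100
  outDC <- bandpassFilter(recDC)
  expect_lt(abs(mean(outDC@signal[1, mid])), 0.5)
  expect_error(bandpassFilter(rec10, high = 200), "Nyquist")
})

test_that("segmentation keeps padded maximal clean runs of minimum length", {
  fs <- 100
  rec <- new("EEGRecording", signal = matrix(rnorm(2 * 100 * fs), 2),
             samplingRate = fs, channelLabels = c("a", "b"), patientId = "x")
  # clean 100 s recording, edge pad 1 -> one segment [1, 99)
  s <- segmentRecording(rec, rep(FALSE, 100 * fs))
  expect_equal(nSegments(s), 1)
  expect_equal(s@starts, 1)
  expect_equal(s@ends, 99)
  # an artifact splitting the signal into 0.5 s and 30 s runs (after pad):
  # only the long run survives the 1 s minimum
  mask <- rep(FALSE, 100 * fs)
  mask[round(2.5 * fs)] <- TRUE           # 2.5 s in
  mask[round(35 * fs):(100 * fs)] <- TRUE # everything after 35 s
  s2 <- segmentRecording(rec, mask, dilate = 0)
  expect_equal(nSegments(s2), 1)
  expect_gt(s2@ends[1] - s2@starts[1], 29)
  # alternating 2 s clean / 1-sample artifact with 0.6 s pad: all runs < 1 s
  mask3 <- rep(FALSE, 20 * fs)
  mask3[seq(2 * fs, 20 * fs, by = 2 * fs)] <- TRUE
  s3 <- segmentRecording(rec, c(mask3, rep(TRUE, 80 * fs)),
                         edgePad = 0.6, dilate = 0)
  expect_equal(nSegments(s3), 0)
})

test_that("no flagged sample survives into a segment and clean time is bounded", {
  set.seed(8)
  fs <- 128
  rec <- new("EEGRecording", signal = matrix(rnorm(4 * 120 * fs), 4),
             samplingRate = fs, channelLabels = paste0("c", 1:4),
             patientId = "x")
  mask <- runif(120 * fs) < 0.0005
  s <- segmentRecording(rec, mask)
  flagged <- which(mask)
  for (i in seq_len(nSegments(s))) {
    a <- round(s@starts[i] * fs) + 1
    b <- round(s@ends[i] * fs)
    expect_length(intersect(flagged, a:b), 0)
  }
  expect_lte(cleanDuration(s), 120)
})

test_that("z-scoring standardizes pooled channels and is idempotent", {
  set.seed(2)
  blocks <- list(matrix(rnorm(3 * 400, 5, 3), 3),
                 matrix(rnorm(3 * 600, 5, 3), 3))
  series <- makeSeries(blocks, fs = 100)
  z <- zscoreSegments(series)
  pooled <- do.call(cbind, z@blocks)
  expect_equal(rowMeans(pooled), rep(0, 3), tolerance = 1e-9)
  expect_equal(apply(pooled, 1, sd), rep(1, 3), tolerance = 1e-9)
  # idempotence and scale invariance
  expect_equal(zscoreSegments(z)@blocks, z@blocks, tolerance = 1e-9)
  scaled <- series
  scaled@blocks <- lapply(series@blocks, function(b) b * 5)
  expect_equal(zscoreSegments(scaled)@blocks, z@blocks, tolerance = 1e-9)
  flat <- makeSeries(list(matrix(1, 2, 100)), fs = 100)
  expect_error(zscoreSegments(flat), "degenerate")
})

test_that("inclusion rule uses a 20-minute inclusive boundary", {
  mk <- function(sec) makeSeries(list(matrix(rnorm(2 * sec * 10), 2)),
                                 fs = 10)
  expect_false(passesInclusion(mk(19.9 * 60)))
  expect_true(passesInclusion(mk(20 * 60)))
  empty <- new("SegmentSeries", starts = numeric(0), ends = numeric(0),
               blocks = list(), samplingRate = 10, channelLabels = "a",
               sourceId = "e")
  expect_false(passesInclusion(empty))
})
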