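# Shared fixtures: all built in code at test time.

clip01 <- function(x) pmin(1, pmax(0, x))

# Random SPD matrix with eigenvalues bounded away from zero.
makeSpd <- function(p, scale = 1) {
  A <- matrix(rnorm(p * p), p)
  scale * (crossprod(A) / p + diag(p))
}

# A plain sinusoidal test recording.
sineRecording <- function(freq = 10, fs = 128, seconds = 10, channels = 4,
                          amp = 1) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  sig <- matrix(rep(amp * sin(2 * pi * freq * t), channels),
                nrow = channels, byrow = TRUE)
  new("EEGRecording", signal = sig, samplingRate = fs,
      channelLabels = paste0("ch", seq_len(channels)), patientId = "sine")
}

# Manually built segment series (already "clean"); blocks is a list of
# channels x samples matrices.
makeSeries <- function(blocks, fs = 128, starts = NULL) {
  lens <- vapply(blocks, ncol, numeric(1)) / fs
  if (is.null(starts)) starts <- cumsum(c(0, lens[-length(lens)] + 1))
  new("SegmentSeries", starts = starts, ends = starts + lens,
      blocks = blocks, samplingRate = fs,
      channelLabels = paste0("ch", seq_len(nrow(blocks[[1]]))),
      sourceId = "fixture")
}

# Fabricated cohort feature object with the same shape as
# extractCohortFeatures() output, but with cheap synthetic frame features:
# class-separated Gaussian "spectra" and class-scaled SPD "covariances".
# eegEffect / clinEffect scale the planted class contrasts.
fabricateFeatures <- function(n = 40, prevalence = 0.3, eegEffect = 1,
                              clinEffect = 1, seed = 1, p = 4,
                              nFreq = 20, agentMix = NULL) {
  withr::local_seed(seed)
  pod <- rbinom(n, 1, prevalence)
  pod[1:2] <- c(0, 1)                      # both classes guaranteed
  ids <- sprintf("F%03d", seq_len(n))
  agents <- if (is.null(agentMix)) {
    sample(c("Propofol", "Desflurane", "Sevoflurane"), n, replace = TRUE)
  } else sample(names(agentMix), n, replace = TRUE, prob = agentMix)
  clinical <- data.frame(
    patient_id = ids,
    age = 69 + 3 * clinEffect * pod + rnorm(n, 0, 5),
    asa = pmin(4, pmax(1, round(2.4 + 0.3 * clinEffect * pod + rnorm(n, 0, 0.6)))),
    op_length = pmax(0.5, 2.6 + 1.2 * clinEffect * pod + rnorm(n, 0, 1.4)),
    benzodiazepine = rbinom(n, 1, 0.06),
    induction_agent = sample(c("Propofol", "Thiopental"), n, replace = TRUE),
    maintenance_agent = agents,
    pod = pod,
    bsr = pmax(0.01, 0.18 + 0.10 * eegEffect * pod + rnorm(n, 0, 0.04)),
    lsp = pmax(1, 50 + 30 * eegEffect * pod + rnorm(n, 0, 15)),
    stringsAsFactors = FALSE)
  specF <- list(); covF <- list()
  shape <- sin(seq(0, pi, length.out = nFreq))      # common spectral shape
  for (i in seq_len(n)) {
    nf <- sample(6:12, 1)
    mu <- shape + 0.6 * eegEffect * pod[i] * (seq_len(nFreq) > nFreq / 2)
    specF[[ids[i]]] <- t(vapply(seq_len(nf), function(j)
      mu + rnorm(nFreq, 0, 0.4), numeric(nFreq)))
    u <- 0.5 * eegEffect * pod[i] + rnorm(1, 0, 0.15)
    covF[[ids[i]]] <- vapply(seq_len(nf), function(j) {
      W <- matrix(rnorm(p * p, 0, 0.1), p)
      exp(u) * diag(p) + crossprod(W)
    }, matrix(0, p, p))
  }
  list(clinical = clinical, spec = specF, cov = covF,
       excluded = character(0))
}

# Fast training configuration for fabricated-feature tests.
fastConfig <- function(...) {
  podConfig(R = 4, nTrees = 120, nMajor = 6, nMinor = 10,
            initialAucThreshold = 0.6, ...)
}
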