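#' Construct a synthetic cohort specification
#'
#' Builds a validated \code{\linkS4class{CohortSpec}}. Defaults emulate the
#' structure of a large single-center intraoperative cohort: ~19% POD
#' prevalence, maintenance-agent mix dominated by Propofol / Desflurane /
#' Sevoflurane with a small "Other" remainder, clinical covariates whose POD
#' class offsets match those reported for large anesthesia cohorts (age +2.7 y, ASA +0.24,
#' operation length +1.27 h), reduced alpha-band power and a small upward
#' shift of the expected suppression fraction in POD patients, sporadic
#' high-amplitude artifacts, and recording lengths varying between 20 and
#' 30 minutes (a desk-scale stand-in for full intraoperative recordings).
#'
#' @param nPatients cohort size.
#' @param podPrevalence POD fraction in (0,1).
#' @param agentMix named proportions over Propofol, Desflurane, Sevoflurane,
#'   Other (must sum to 1).
#' @param samplingRate Hz (128 is typical for frontal anesthesia monitors).
#' @param durationRange recording length range in minutes; minimum 20 so no
#'   patient falls below the 20-minute inclusion rule by construction.
#' @param alphaPowerRatioPod multiplicative factor on alpha-band power for
#'   POD patients (1 = no EEG alpha effect).
#' @param bsrShiftPod additive shift of the expected suppression fraction
#'   for POD patients (0 = no suppression effect).
#' @param clinicalShifts named additive POD offsets for age, asa, op_length.
#' @param artifactRate artifact events per minute.
#' @param seed master seed; identical spec + seed reproduces the cohort
#'   bit-exactly.
#' @return a \code{CohortSpec}.
#' @export
cohortSpec <- function(nPatients = 240,
                       podPrevalence = 0.19,
                       agentMix = c(Propofol = 0.277, Desflurane = 0.372,
                                    Sevoflurane = 0.344, Other = 0.007),
                       samplingRate = 128,
                       durationRange = c(20, 30),
                       alphaPowerRatioPod = 0.8,
                       bsrShiftPod = 0.01,
                       clinicalShifts = c(age = 2.7, asa = 0.24,
                                          op_length = 1.27),
                       artifactRate = 0.5,
                       seed = 1L) {
  if (is.null(names(agentMix)) ||
      !setequal(names(agentMix),
                c("Propofol", "Desflurane", "Sevoflurane", "Other")))
    stop("configuration error: agentMix must be named over Propofol, ",
         "Desflurane, Sevoflurane, Other", call. = FALSE)
  if (abs(sum(agentMix) - 1) > 1e-9)
    stop("configuration error: agentMix proportions must sum to 1",
         call. = FALSE)
  if (samplingRate <= 0)
    stop("configuration error: samplingRate must be positive", call. = FALSE)
  new("CohortSpec", nPatients = nPatients, podPrevalence = podPrevalence,
      agentMix = agentMix[c("Propofol", "Desflurane", "Sevoflurane", "Other")],
      samplingRate = samplingRate, durationRange = durationRange,
      alphaPowerRatioPod = alphaPowerRatioPod, bsrShiftPod = bsrShiftPod,
      clinicalShifts = clinicalShifts, artifactRate = artifactRate,
      seed = seed)
}

# Generator constants not exposed as cohort-level knobs: per-agent alpha
# oscillation amplitude relative to the pink background (Propofol anesthesia
# shows the strongest frontal alpha), per-agent mean suppression fraction
# (matching per-agent BSR levels reported for intraoperative cohorts), and
# clinical covariate baselines (non-POD class moments of a large reference cohort).
generatorConstants <- function() {
  list(
    agentAlpha = c(Propofol = 0.9, Desflurane = 0.6, Sevoflurane = 0.7,
                   Other = 0.4),
    agentSupprBase = c(Propofol = 0.24, Desflurane = 0.182,
                       Sevoflurane = 0.161, Other = 0.15),
    supprSd = 0.06,
    alphaLogSd = 0.35,          # per-patient lognormal alpha amplitude spread
    backgroundRms = 10,         # microvolts
    envLogSd = 0.25,            # slow amplitude-envelope spread (log scale)
    envTauSec = 60,             # envelope correlation time
    burstRateRatio = 1.0,       # noise bursts per minute per unit spike rate
    burstDur = c(2, 8),         # burst duration range (s)
    burstAmp = c(5, 9),         # burst amplitude factor range
    ageBase = c(mean = 69.2, sd = 6.0),
    asaBase = c(mean = 2.41, sd = 0.59),
    opLenBase = c(mean = 2.61, sd = 1.53),
    benzoProb = c(noPod = 0.058, pod = 0.069),
    inductionMix = c(Propofol = 0.80, Thiopental = 0.15, Etomidate = 0.05)
  )
}

#' Cohort-level assignments
#'
#' Labels, maintenance/induction agents, recording durations, clinical
#' covariates and per-patient EEG seeds, drawn once from the master seed —
#' so patients can be generated independently, in any order, or streamed
#' one at a time, and still reproduce \code{\link{simulateCohort}}
#' bit-exactly.
#'
#' @param spec a \code{CohortSpec}.
#' @return data.frame with one row per patient.
#' @export
cohortAssignments <- function(spec) {
  k <- generatorConstants()
  withSeed(deriveSeed(spec@seed, "cohort-assignments"), {
    n <- as.integer(spec@nPatients)
    pod <- stats::rbinom(n, 1, spec@podPrevalence)
    agent <- sample(names(spec@agentMix), n, replace = TRUE,
                    prob = spec@agentMix)
    durMin <- stats::runif(n, spec@durationRange[1], spec@durationRange[2])
    sh <- spec@clinicalShifts
    age <- pmin(95, pmax(60, stats::rnorm(
      n, k$ageBase["mean"] + sh["age"] * pod, k$ageBase["sd"])))
    asa <- pmin(4, pmax(1, round(stats::rnorm(
      n, k$asaBase["mean"] + sh["asa"] * pod, k$asaBase["sd"]))))
    opLen <- pmax(0.4, stats::rnorm(
      n, k$opLenBase["mean"] + sh["op_length"] * pod, k$opLenBase["sd"]))
    benzo <- stats::rbinom(n, 1, ifelse(pod == 1, k$benzoProb["pod"],
                                        k$benzoProb["noPod"]))
    induction <- sample(names(k$inductionMix), n, replace = TRUE,
                        prob = k$inductionMix)
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      pod = pod, maintenance_agent = agent, induction_agent = induction,
      age = age, asa = asa, op_length = opLen, benzodiazepine = benzo,
      duration_min = durMin,
      eeg_seed = vapply(seq_len(n), function(i)
        deriveSeed(spec@seed, paste0("eeg-", i)), integer(1)),
      stringsAsFactors = FALSE
    )
  })
}

# Spectrally shaped Gaussian noise: white noise whose spectrum is
# multiplied by `shape` (an amplitude shape over the two-sided frequency
# axis), normalized to unit variance.
shapedNoise <- function(n, shape) {
  m <- length(shape)
  x <- Re(stats::fft(stats::fft(stats::rnorm(m)) * shape, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

twoSidedFreq <- function(m, fs) {
  f <- c(0, seq_len(m - 1)) * fs / m
  pmin(f, fs - f)
}

# Pink (1/f-power) noise; spectrum flattened below floorHz to keep finite
# power at DC.
pinkNoise <- function(n, fs, floorHz = 0.5) {
  m <- fastLength(n)
  shapedNoise(n, 1 / sqrt(pmax(twoSidedFreq(m, fs), floorHz)))
}

# Slowly varying lognormal amplitude envelope (Ornstein-Uhlenbeck on the
# log scale, simulated on a 1 Hz grid and interpolated). Real intraoperative
# EEG is amplitude-nonstationary; this makes the extreme-amplitude samples
# cluster into short stretches, as they do in recordings with artifacts,
# instead of being scattered uniformly.
slowEnvelope <- function(n, fs, logSd, tauSec) {
  nCoarse <- max(2L, ceiling(n / fs) + 1L)
  a <- exp(-1 / tauSec)
  g <- numeric(nCoarse)
  g[1] <- stats::rnorm(1, 0, logSd)
  innov <- stats::rnorm(nCoarse - 1, 0, logSd * sqrt(1 - a^2))
  for (i in 2:nCoarse) g[i] <- a * g[i - 1] + innov[i - 1]
  exp(stats::approx(seq(0, by = fs, length.out = nCoarse), g,
                    xout = seq_len(n) - 1, rule = 2)$y)
}

# Narrow-band stochastic oscillator: Gaussian spectral bump at peakHz.
narrowbandNoise <- function(n, fs, peakHz, bwHz = 1) {
  m <- fastLength(n)
  f <- twoSidedFreq(m, fs)
  shapedNoise(n, exp(-(f - peakHz)^2 / (2 * bwHz^2)))
}

# 1/f background plus alpha oscillation in one draw: the sum of two
# independent Gaussian processes is a Gaussian process whose power
# spectrum is the sum, so a single spectral shaping per channel suffices.
# The pink component is normalized to unit variance, the alpha bump to
# alphaAmp^2; the result therefore has variance 1 + alphaAmp^2.
backgroundPlusAlpha <- function(n, fs, alphaAmp, peakHz, bwHz = 1,
                                floorHz = 0.5) {
  m <- fastLength(n)
  f <- twoSidedFreq(m, fs)
  p2 <- 1 / pmax(f, floorHz)
  a2 <- exp(-(f - peakHz)^2 / bwHz^2)
  shape <- sqrt(p2 / mean(p2) + alphaAmp^2 * a2 / mean(a2))
  x <- Re(stats::fft(stats::fft(stats::rnorm(m)) * shape,
                     inverse = TRUE)) / m
  x[seq_len(n)]
}

# Construct a suppression mask of exactly round(targetFrac * n) samples from
# an alternating-renewal layout; optionally plant one run of exactly
# longestRun seconds (all other episodes kept strictly shorter).
makeSuppressionMask <- function(n, fs, targetFrac, longestRun = NULL,
                                minEp = 2, meanEp = 8, capEp = 25) {
  mask <- rep(FALSE, n)
  target <- round(targetFrac * n)
  if (target < 1) return(mask)
  eps <- integer(0)
  if (!is.null(longestRun)) {
    eps <- as.integer(round(longestRun * fs))
    capEp <- min(capEp, longestRun - 1.5)
  }
  while (sum(eps) < target) {
    L <- min(capEp, minEp + stats::rexp(1, 1 / max(meanEp - minEp, 0.5)))
    L <- as.integer(round(L * fs))
    L <- min(L, target - sum(eps))
    if (L < 1) break
    eps <- c(eps, L)
  }
  K <- length(eps)
  if (K == 0) return(mask)
  eps <- sample(eps)                       # planted run at a random position
  free <- n - sum(eps)
  minGap <- as.integer(fs)                 # >= 1 s isolation between episodes
  if (free < (K + 1) * minGap)
    stop("suppression target too high for the recording length", call. = FALSE)
  w <- stats::rexp(K + 1)
  gaps <- minGap + floor(w / sum(w) * (free - (K + 1) * minGap))
  pos <- 1L
  for (i in seq_len(K)) {
    pos <- pos + gaps[i]
    mask[pos:(pos + eps[i] - 1L)] <- TRUE
    pos <- pos + eps[i]
  }
  mask
}

#' Simulate one intraoperative EEG recording with planted ground truth
#'
#' Signal model: independent 1/f ("pink") background per channel, a shared
#' narrow-band alpha oscillation (per-patient random peak frequency in
#' 8.5-11.5 Hz, independent realization per channel so common-average
#' re-referencing does not cancel it) whose power is scaled by the agent and
#' by \code{alphaPowerRatioPod} for POD patients, alternating-renewal
#' suppression episodes attenuating the whole signal by a factor 0.05, and
#' isolated rectangular artifact pulses of 10x the patient's 99% amplitude
#' quantile lasting 0.1-0.5 s (placed outside suppression episodes). The
#' planted suppression mask, its exact fraction and longest run, and the
#' artifact sample indices are returned as ground truth.
#'
#' @param pod POD label (0/1) controlling the planted class effects.
#' @param agent maintenance agent name.
#' @param spec a \code{CohortSpec} supplying rates and class effects.
#' @param durationMin recording length in minutes.
#' @param seed integer seed for this recording.
#' @param patientIdent identifier stored in the recording.
#' @param supprTarget optional exact target suppression fraction (otherwise
#'   drawn from the agent-specific distribution plus the POD shift).
#' @param longestRun optional exact longest suppression run in seconds.
#' @return list with elements \code{recording} (\code{EEGRecording}) and
#'   \code{groundTruth} (suppression mask/fraction/longest run, artifact
#'   sample indices).
#' @export
simulateEEG <- function(pod, agent, spec, durationMin, seed,
                        patientIdent = "synthetic", supprTarget = NULL,
                        longestRun = NULL) {
  stopIfNot(agent %in% names(spec@agentMix),
            paste("unsupported maintenance agent:", agent))
  stopIfNot(durationMin > 0, "duration must be positive")
  k <- generatorConstants()
  fs <- spec@samplingRate
  n <- as.integer(round(durationMin * 60 * fs))
  withSeed(seed, {
    peakHz <- stats::runif(1, 8.5, 11.5)
    alphaAmp <- k$agentAlpha[[agent]] * exp(stats::rnorm(1, 0, k$alphaLogSd))
    if (pod == 1) alphaAmp <- alphaAmp * sqrt(spec@alphaPowerRatioPod)
    env <- slowEnvelope(n, fs, k$envLogSd, k$envTauSec)
    sig <- matrix(0, 4L, n)
    for (ch in 1:4)
      sig[ch, ] <- k$backgroundRms * env *
        backgroundPlusAlpha(n, fs, alphaAmp, peakHz)
    if (is.null(supprTarget)) {
      supprTarget <- stats::rnorm(1, k$agentSupprBase[[agent]] +
                                    spec@bsrShiftPod * pod, k$supprSd)
      supprTarget <- min(0.6, max(0.02, supprTarget))
    }
    mask <- makeSuppressionMask(n, fs, supprTarget, longestRun)
    if (any(mask)) sig[, mask] <- sig[, mask] * 0.05
    runs <- trueRuns(mask)
    gtLongest <- if (nrow(runs)) max(runs[, "length"]) / fs else 0
    # Movement/EMG-like noise bursts: multi-second stretches of broadband
    # noise at 3-6x the patient's overall RMS on all channels. They
    # dominate the amplitude tail, so the per-patient 99% quantile
    # threshold lands above the normal signal -- the situation the
    # amplitude filter is designed for.
    burstIdx <- integer(0)
    marg <- as.integer(2 * fs)     # artifacts keep clear of suppression
                                   # episodes so segment edge padding cannot
                                   # eat into a planted suppression run
    nBursts <- stats::rpois(1, k$burstRateRatio * spec@artifactRate *
                              durationMin)
    if (nBursts > 0) {
      sigRms <- sqrt(mean(sig^2))
      for (ev in seq_len(nBursts)) {
        L <- as.integer(round(stats::runif(1, k$burstDur[1], k$burstDur[2]) * fs))
        for (try in 1:20) {
          start <- sample.int(max(n - L, 1L), 1)
          idx <- start:(min(start + L - 1L, n))
          if (!any(mask[max(1L, start - marg):min(n, start + L - 1L + marg)]))
            break
          idx <- NULL
        }
        if (is.null(idx)) next
        amp <- stats::runif(1, k$burstAmp[1], k$burstAmp[2])
        sig[, idx] <- amp * sigRms *
          matrix(stats::rnorm(4 * length(idx)), 4L)
        burstIdx <- c(burstIdx, idx)
      }
      burstIdx <- sort(unique(burstIdx))
    }
    artifactIdx <- integer(0)
    nEvents <- stats::rpois(1, spec@artifactRate * durationMin)
    if (nEvents > 0) {
      q99 <- stats::quantile(abs(sig), 0.99, names = FALSE)
      for (ev in seq_len(nEvents)) {
        durS <- stats::runif(1, 0.1, 0.5)
        L <- max(1L, as.integer(round(durS * fs)))
        for (try in 1:20) {
          start <- sample.int(n - L, 1)
          idx <- start:(start + L - 1L)
          if (!any(mask[max(1L, start - marg):min(n, start + L - 1L + marg)]))
            break
          idx <- NULL
        }
        if (is.null(idx)) next
        ch <- sample.int(4L, 1)
        sig[ch, idx] <- 10 * q99 * sample(c(-1, 1), 1) *
          stats::runif(L, 0.9, 1.1)
        artifactIdx <- c(artifactIdx, idx)
      }
      artifactIdx <- sort(unique(artifactIdx))
    }
    # Ground-truth suppression fraction relative to artifact-reduced time:
    # artifacts are placed outside suppression episodes and are removed
    # from the denominator of the BSR by definition.
    nArtifact <- length(unique(c(burstIdx, artifactIdx)))
    gtFraction <- if (n > nArtifact) sum(mask) / (n - nArtifact) else 0
    list(
      recording = new("EEGRecording", signal = sig, samplingRate = fs,
                      channelLabels = c("Fp1", "Fp2", "F7", "F8"),
                      patientId = patientIdent),
      groundTruth = list(supprMask = mask, supprFraction = gtFraction,
                         longestRun = gtLongest, artifactIdx = artifactIdx,
                         burstIdx = burstIdx, alphaPeakHz = peakHz)
    )
  })
}

#' Simulate a single cohort member
#'
#' Generates patient \code{i} of the cohort defined by \code{spec}. All
#' cohort-level draws are made once from the master seed, so patients can be
#' generated in any order (or streamed one at a time) and still reproduce
#' \code{\link{simulateCohort}} bit-exactly.
#'
#' @param spec a \code{CohortSpec}.
#' @param i patient index in 1..nPatients.
#' @param assignments optional precomputed cohort assignment table.
#' @return list with \code{patientId}, \code{recording}, \code{clinical}
#'   (one-row data.frame) and \code{groundTruth}.
#' @export
simulatePatient <- function(spec, i, assignments = NULL) {
  if (is.null(assignments)) assignments <- cohortAssignments(spec)
  a <- assignments[i, ]
  sim <- simulateEEG(a$pod, a$maintenance_agent, spec, a$duration_min,
                     seed = a$eeg_seed, patientIdent = a$patient_id)
  list(
    patientId = a$patient_id,
    recording = sim$recording,
    clinical = a[, c("patient_id", "age", "asa", "op_length",
                     "benzodiazepine", "induction_agent",
                     "maintenance_agent", "pod")],
    groundTruth = sim$groundTruth
  )
}

#' Simulate a full synthetic cohort
#'
#' Returns all patients in memory; for large cohorts prefer streaming via
#' \code{\link{cohortAssignments}} + \code{\link{simulatePatient}} (as
#' \code{\link{extractCohortFeatures}} does) since each recording holds
#' several megabytes of signal.
#'
#' @param spec a \code{CohortSpec}.
#' @return list of patients as returned by \code{\link{simulatePatient}}.
#' @export
simulateCohort <- function(spec) {
  assignments <- cohortAssignments(spec)
  lapply(seq_len(as.integer(spec@nPatients)), simulatePatient, spec = spec,
         assignments = assignments)
}

#' Write a simulated cohort to disk
#'
#' One EEG file per patient (plain-text matrix or EDF), a cohort-level
#' clinical table and a ground-truth table.
#'
#' @param patients list from \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @param format "csv" or "edf".
#' @export
writeCohort <- function(patients, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  clin <- do.call(rbind, lapply(patients, `[[`, "clinical"))
  gt <- do.call(rbind, lapply(patients, function(p) data.frame(
    patient_id = p$patientId,
    suppr_fraction = p$groundTruth$supprFraction,
    longest_run_s = p$groundTruth$longestRun,
    n_artifact_samples = length(p$groundTruth$artifactIdx))))
  writeClinicalTable(clin, file.path(dir, "clinical.tsv"))
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (p in patients) {
    f <- file.path(dir, paste0(p$patientId, ".", format))
    if (format == "edf") writeEDF(p$recording, f)
    else writeEEGcsv(p$recording, f)
  }
  invisible(dir)
}
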