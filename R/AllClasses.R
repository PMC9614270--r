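#' @import methods
NULL

#' Multichannel EEG recording
#'
#' Container for a raw or preprocessed multichannel EEG signal. The pipeline
#' expects the four frontal channels used by depth-of-anesthesia monitors
#' (Fp1, Fp2, F7, F8), but the container itself holds any channel count so
#' that intermediate operations (e.g. re-referencing) can state their own
#' requirements.
#'
#' @slot signal numeric matrix, channels x samples, in microvolts (raw) or
#'   z-units (after standardization).
#' @slot samplingRate sampling frequency in Hz.
#' @slot channelLabels character vector, one label per row of \code{signal}.
#' @slot patientId identifier carried through the pipeline.
#' @export
setClass("EEGRecording",
  representation(
    signal = "matrix",
    samplingRate = "numeric",
    channelLabels = "character",
    patientId = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
      msg <- c(msg, "samplingRate must be a single positive number")
    if (nrow(object@signal) < 1L)
      msg <- c(msg, "signal must have at least one channel (row)")
    if (length(object@channelLabels) != nrow(object@signal))
      msg <- c(msg, "channelLabels length must equal number of signal rows")
    if (length(msg)) msg else TRUE
  }
)

#' Artifact-free segment series
#'
#' Ordered series of artifact-free time segments cut from one recording.
#' Intervals are half-open \code{[start, end)} in seconds from recording
#' start, non-overlapping and strictly increasing.
#'
#' @slot starts,ends segment boundaries in seconds (half-open intervals).
#' @slot blocks list of channels x samples matrices, one per segment.
#' @slot samplingRate Hz.
#' @slot channelLabels channel labels shared by all blocks.
#' @slot sourceId patient/recording identifier.
#' @export
setClass("SegmentSeries",
  representation(
    starts = "numeric",
    ends = "numeric",
    blocks = "list",
    samplingRate = "numeric",
    channelLabels = "character",
    sourceId = "character"
  ),
  validity = function(object) {
    msg <- character()
    n <- length(object@starts)
    if (length(object@ends) != n || length(object@blocks) != n)
      msg <- c(msg, "starts, ends and blocks must have equal length")
    if (n > 0) {
      if (any(object@ends <= object@starts))
        msg <- c(msg, "every segment must have end > start")
      if (n > 1 && any(object@starts[-1] < object@ends[-n]))
        msg <- c(msg, "segments must be non-overlapping and increasing")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Burst-suppression profile
#'
#' Per-sample suppression timeline over the clean (artifact-reduced) part of
#' a recording, plus the two scalar signatures: the burst suppression ratio
#' (BSR, suppressed time divided by analyzed clean time) and the longest
#' suppression phase (LSP, seconds).
#'
#' @slot timeline list of numeric vectors in [0,1], one per clean segment,
#'   aligned sample-for-sample with the segment blocks.
#' @slot bsr fraction in [0,1].
#' @slot lsp seconds.
#' @slot analyzedDuration total clean duration in seconds.
#' @slot samplingRate Hz of the underlying timeline.
#' @export
setClass("BurstSuppressionProfile",
  representation(
    timeline = "list",
    bsr = "numeric",
    lsp = "numeric",
    analyzedDuration = "numeric",
    samplingRate = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@bsr < 0 || object@bsr > 1) msg <- c(msg, "bsr must lie in [0,1]")
    if (object@lsp < 0) msg <- c(msg, "lsp must be nonnegative")
    if (object@lsp > object@analyzedDuration + 1e-9)
      msg <- c(msg, "lsp cannot exceed analyzedDuration")
    if (length(msg)) msg else TRUE
  }
)

#' Spectral frame series
#'
#' Welch power spectra of clean segments averaged into 2-minute frames of
#' concatenated clean time; the "spectrum" feature stream.
#'
#' @slot frameStarts frame start times in clean-time seconds (multiples of
#'   the frame length).
#' @slot psd frames x frequencies matrix of channel-averaged power densities.
#' @slot freqGrid frequency grid in Hz.
#' @slot patientId identifier.
#' @export
setClass("SpectralFrameSeries",
  representation(
    frameStarts = "numeric",
    psd = "matrix",
    freqGrid = "numeric",
    patientId = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (nrow(object@psd) != length(object@frameStarts))
      msg <- c(msg, "psd must have one row per frame")
    if (ncol(object@psd) != length(object@freqGrid))
      msg <- c(msg, "psd must have one column per grid frequency")
    if (length(object@psd) && any(object@psd < 0))
      msg <- c(msg, "psd values must be nonnegative")
    if (length(msg)) msg else TRUE
  }
)

#' Covariance frame series
#'
#' Per-frame SPD covariance matrices of the multi-band stacked signal
#' (4 channels x 6 frequency bands plus the burst-suppression timeline row,
#' 25 rows in the default configuration).
#'
#' @slot frameStarts frame start times in clean-time seconds.
#' @slot matrices p x p x nFrames array of SPD matrices.
#' @slot patientId identifier.
#' @export
setClass("CovarianceFrameSeries",
  representation(
    frameStarts = "numeric",
    matrices = "array",
    patientId = "character"
  ),
  validity = function(object) {
    msg <- character()
    d <- dim(object@matrices)
    if (length(d) != 3L) msg <- c(msg, "matrices must be a 3-d array")
    else {
      if (d[1] != d[2]) msg <- c(msg, "matrices must be square")
      if (d[3] != length(object@frameStarts))
        msg <- c(msg, "one matrix per frame required")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Tangent-space vectors
#'
#' Frame covariances projected to the Euclidean tangent space at a reference
#' point. Row i is the vectorized (upper triangle, off-diagonals scaled by
#' sqrt(2)) matrix logarithm of R^{-1/2} C_i R^{-1/2}; its Euclidean norm
#' equals the affine-invariant Riemannian distance from the reference to C_i.
#'
#' @slot reference SPD reference matrix.
#' @slot vectors frames x p(p+1)/2 matrix.
#' @export
setClass("TangentVectors",
  representation(reference = "matrix", vectors = "matrix"),
  validity = function(object) {
    p <- nrow(object@reference)
    if (ncol(object@vectors) != p * (p + 1) / 2)
      "vectors must have p(p+1)/2 columns" else TRUE
  }
)

#' Bagged SVM ensemble for time-dependent features
#'
#' Result of the two-level undersampled bagging loop: R weighted-SVM base
#' learners fitted on sampled frames, the acceptance-threshold history, and
#' (for covariance features) the balanced Riemannian reference point used
#' for tangent projection of training and test frames alike.
#'
#' @slot estimators list of fitted base learners.
#' @slot kind "spec" or "cov".
#' @slot reference SPD reference matrix (covariance kind) or NULL.
#' @slot thresholdHistory the acceptance threshold at every loop iteration.
#' @slot config the sampling/training configuration used.
#' @export
setClass("BaggedEnsemble",
  representation(
    estimators = "list",
    kind = "character",
    reference = "ANY",
    thresholdHistory = "numeric",
    config = "list"
  ),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("spec", "cov"))
      msg <- c(msg, "kind must be 'spec' or 'cov'")
    if (object@kind == "cov" && is.null(object@reference))
      msg <- c(msg, "covariance ensembles must carry a reference point")
    if (length(msg)) msg else TRUE
  }
)

#' Balanced random forest on per-patient features
#'
#' @slot forest fitted randomForest object (each tree grown on a balanced
#'   class sample).
#' @slot featureSet "patient" or "patient+burstsupp".
#' @slot encoding factor-level metadata used to encode new rows.
#' @export
setClass("PatientModel",
  representation(forest = "ANY", featureSet = "character", encoding = "list"))

#' Frozen probability-fusion state
#'
#' The g-mean-optimal thresholds per classifier, the shift subset selected
#' on the training set, the resulting shifts (0.5 - threshold on subset
#' members, 0 elsewhere), training AUCs and the AUC floor for the
#' low-probability override.
#'
#' @slot thresholds,shifts,trainingAucs named numeric vectors over
#'   c("patient_burst", "spec", "cov").
#' @slot subset which classifiers were shifted.
#' @slot aucFloor minimum training AUC for a classifier to enter the
#'   low-probability mean.
#' @export
setClass("FusionState",
  representation(
    thresholds = "numeric",
    shifts = "numeric",
    subset = "character",
    trainingAucs = "numeric",
    aucFloor = "numeric"
  )
)

#' Synthetic cohort specification
#'
#' All knobs of the synthetic intraoperative EEG cohort generator. Defaults
#' reproduce the statistical structure the classifiers assume: roughly 20%
#' POD prevalence, maintenance-agent mix and clinical covariate class
#' offsets matching a large single-center anesthesia cohort, reduced
#' alpha-band power and elevated burst suppression in POD patients,
#' high-amplitude artifact events and variable recording lengths.
#'
#' @slot nPatients cohort size.
#' @slot podPrevalence POD fraction in (0,1).
#' @slot agentMix proportions over Propofol/Desflurane/Sevoflurane/Other.
#' @slot samplingRate Hz.
#' @slot durationRange recording length range in minutes (min >= 20 so no
#'   patient is excluded by the 20-minute inclusion rule unless planted).
#' @slot alphaPowerRatioPod multiplicative factor on alpha-band power for
#'   the POD class (< 1 means reduced alpha power).
#' @slot bsrShiftPod additive shift on the expected suppression fraction
#'   for the POD class.
#' @slot clinicalShifts named additive class offsets for age (years),
#'   asa (score units) and op_length (hours).
#' @slot artifactRate artifact events per minute.
#' @slot seed integer seed; identical spec + seed reproduces the cohort
#'   bit-exactly.
#' @export
setClass("CohortSpec",
  representation(
    nPatients = "numeric",
    podPrevalence = "numeric",
    agentMix = "numeric",
    samplingRate = "numeric",
    durationRange = "numeric",
    alphaPowerRatioPod = "numeric",
    bsrShiftPod = "numeric",
    clinicalShifts = "numeric",
    artifactRate = "numeric",
    seed = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@nPatients < 1) msg <- c(msg, "nPatients must be >= 1")
    if (object@podPrevalence <= 0 || object@podPrevalence >= 1)
      msg <- c(msg, "podPrevalence must lie strictly in (0,1)")
    if (abs(sum(object@agentMix) - 1) > 1e-9)
      msg <- c(msg, "agentMix proportions must sum to 1")
    if (any(object@agentMix < 0)) msg <- c(msg, "agentMix must be nonnegative")
    if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
    if (length(object@durationRange) != 2L ||
        object@durationRange[1] > object@durationRange[2])
      msg <- c(msg, "durationRange must be (min, max) with min <= max")
    if (object@durationRange[1] < 20)
      msg <- c(msg, "durationRange minimum must be >= 20 minutes")
    if (object@artifactRate < 0) msg <- c(msg, "artifactRate must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' One medication group's complete model stack
#'
#' @slot patientModel balanced RF on clinical features alone.
#' @slot patientBurstModel balanced RF on clinical + BSR/LSP features.
#' @slot specEnsemble,covEnsemble bagged SVM ensembles.
#' @slot fusion frozen FusionState.
#' @slot config training configuration echo.
#' @export
setClass("PodModelStack",
  representation(
    patientModel = "ANY",
    patientBurstModel = "ANY",
    specEnsemble = "ANY",
    covEnsemble = "ANY",
    fusion = "ANY",
    config = "list"
  )
)

#' Medication-group model set with all-medications fallback
#'
#' One PodModelStack per maintenance-agent group large enough to train on,
#' plus an all-medications stack to which patients on other or mixed agents
#' (or members of undersized groups) are routed.
#'
#' @slot stacks named list of PodModelStack ("all" always present).
#' @slot groups agent names with dedicated stacks.
#' @slot minGroupSize groups smaller than this fold into "all".
#' @export
setClass("GroupedModelSet",
  representation(stacks = "list", groups = "character", minGroupSize = "numeric"),
  validity = function(object) {
    if (!"all" %in% names(object@stacks))
      "an 'all' (all-medications) stack is required" else TRUE
  }
)
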