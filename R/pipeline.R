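#' Pipeline configuration
#'
#' All tunables of the preprocessing, feature-extraction, training and
#' fusion stages, with their defaults. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults.
#' @return configuration list.
#' @export
podConfig <- function(...) {
  defaults <- list(
    amplitudeQuantile = 0.99,
    bandLow = 0.3, bandHigh = 50,
    minSegmentLen = 1, edgePad = 1, artifactDilate = 0.1,
    minTotalMinutes = 20,
    supprThreshold = 0.2, minSupprDur = 0.5, envelopeWin = 0.25,
    envBand = c(3, 30),
    welchWindowSec = 2, welchOverlap = 0.5,
    frameLen = 120,
    freqGrid = seq(0.5, 50, by = 0.5),
    bands = defaultBands(),
    potatoZ = 2.5, potatoAdapt = 0.1, potatoBurnIn = 10,
    R = 25, initialAucThreshold = 0.70, iterPerLevel = 5, decay = 0.025,
    nMajor = 10, nMinor = 20, svmCost = 1,
    nTrees = 500,
    aucFloor = 0.55,
    minGroupSize = 20,
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  utils::modifyList(defaults, overrides)
}

#' Extract all classifier features from one recording
#'
#' Runs the fixed preprocessing order (artifact mask, common average
#' reference, band-pass, segmentation, z-scoring), estimates the
#' burst-suppression profile, builds the spectral and covariance frame
#' series, and removes frames flagged by the Riemannian potato from both
#' feature streams.
#'
#' @param rec raw \code{EEGRecording}.
#' @param config list from \code{\link{podConfig}}.
#' @return list with \code{included}, \code{bsr}, \code{lsp},
#'   \code{specFrames} (log10 power matrix, frames x frequencies),
#'   \code{covFrames} (p x p x frames array), \code{nFramesFlagged}.
#' @export
extractPatientFeatures <- function(rec, config = podConfig()) {
  pp <- preprocessRecording(rec, config$amplitudeQuantile, config$bandLow,
                            config$bandHigh, config$minSegmentLen,
                            config$edgePad, config$artifactDilate)
  if (!passesInclusion(pp$series, config$minTotalMinutes))
    return(list(included = FALSE))
  profile <- suppressionTimeline(pp$series, config$supprThreshold,
                                 config$minSupprDur, config$envelopeWin,
                                 config$envBand)
  spec <- spectralFrames(pp$series, config$welchWindowSec,
                         config$welchOverlap, config$frameLen,
                         config$freqGrid)
  cov <- covarianceFrames(pp$series, profile, config$frameLen, config$bands)
  inlier <- rep(TRUE, nFrames(cov))
  if (nFrames(cov) > 2)
    inlier <- riemannianPotato(cov, config$potatoZ, config$potatoAdapt,
                               config$potatoBurnIn)
  keepStarts <- cov@frameStarts[inlier]
  specKeep <- spec@frameStarts %in% keepStarts
  list(
    included = TRUE,
    bsr = bsr(profile),
    lsp = lsp(profile),
    specFrames = log10(spec@psd[specKeep, , drop = FALSE] + 1e-12),
    covFrames = cov@matrices[, , inlier, drop = FALSE],
    nFramesFlagged = sum(!inlier)
  )
}

#' Extract features for a whole cohort
#'
#' Streams the cohort patient by patient (recordings are generated or read,
#' reduced to features, and discarded) and applies the exclusion rules:
#' patients with less than the minimum clean EEG duration are dropped, as
#' in the study protocol.
#'
#' @param spec a \code{CohortSpec} (synthetic cohort), or a list of
#'   patients as returned by \code{\link{simulateCohort}}.
#' @param config pipeline configuration.
#' @param verbose print one line per patient.
#' @return cohort feature object: list with \code{clinical} (data.frame
#'   incl. pod, bsr, lsp), \code{spec} and \code{cov} (named per-patient
#'   frame features), \code{excluded} (patient ids dropped).
#' @export
extractCohortFeatures <- function(spec, config = podConfig(),
                                  verbose = FALSE) {
  if (is(spec, "CohortSpec")) {
    assignments <- cohortAssignments(spec)
    n <- as.integer(spec@nPatients)
    getPatient <- function(i) simulatePatient(spec, i, assignments)
  } else {
    n <- length(spec)
    getPatient <- function(i) spec[[i]]
  }
  clinical <- list(); specF <- list(); covF <- list()
  excluded <- character(); gt <- list()
  for (i in seq_len(n)) {
    p <- getPatient(i)
    f <- extractPatientFeatures(p$recording, config)
    if (!isTRUE(f$included) || nrow(f$specFrames) == 0) {
      excluded <- c(excluded, p$patientId)
      next
    }
    row <- p$clinical
    row$bsr <- f$bsr
    row$lsp <- f$lsp
    clinical[[p$patientId]] <- row
    specF[[p$patientId]] <- f$specFrames
    covF[[p$patientId]] <- f$covFrames
    if (!is.null(p$groundTruth))
      gt[[p$patientId]] <- data.frame(
        patient_id = p$patientId,
        suppr_fraction = p$groundTruth$supprFraction,
        longest_run = p$groundTruth$longestRun)
    if (verbose)
      message(sprintf("%s: %d spec frames, %d cov frames, bsr %.3f",
                      p$patientId, nrow(f$specFrames),
                      dim(f$covFrames)[3], f$bsr))
  }
  list(clinical = do.call(rbind, clinical), spec = specF, cov = covF,
       excluded = excluded,
       groundTruth = if (length(gt)) do.call(rbind, gt) else NULL)
}

#' Subset a cohort feature object by patient id
#'
#' @param features cohort feature object.
#' @param ids patient ids to keep.
#' @export
subsetFeatures <- function(features, ids) {
  keep <- features$clinical$patient_id %in% ids
  list(clinical = features$clinical[keep, , drop = FALSE],
       spec = features$spec[features$clinical$patient_id[keep]],
       cov = features$cov[features$clinical$patient_id[keep]],
       excluded = features$excluded)
}

#' Train one complete model stack
#'
#' Fits the four classifiers on a (training) cohort feature object —
#' balanced random forests on clinical and clinical+burst-suppression
#' features, bagged SVM ensembles on the spectral and covariance frames —
#' then freezes the g-mean shift selection on the training probabilities
#' (out-of-bag for the forest, ensemble frame ratios for the SVMs).
#'
#' @param features training cohort feature object (labels in
#'   \code{features$clinical$pod}).
#' @param config pipeline configuration.
#' @return a \code{PodModelStack}.
#' @export
trainModelStack <- function(features, config = podConfig()) {
  clin <- features$clinical
  labels <- clin$pod
  stopIfNot(length(unique(labels)) == 2,
            "training cohort must contain both classes")
  ids <- clin$patient_id
  patientModel <- trainBalancedRF(clin, labels, "patient",
                                  config$nTrees, config$seed)
  patientBurstModel <- trainBalancedRF(clin, labels, "patient+burstsupp",
                                       config$nTrees, config$seed)
  labNamed <- stats::setNames(labels, ids)
  specEnsemble <- trainBagging(
    frameDataset(features$spec, labNamed, "spec"),
    R = config$R, initialAucThreshold = config$initialAucThreshold,
    iterPerLevel = config$iterPerLevel, decay = config$decay,
    nMajor = config$nMajor, nMinor = config$nMinor, cost = config$svmCost,
    seed = config$seed)
  covEnsemble <- trainBagging(
    frameDataset(features$cov, labNamed, "cov"),
    R = config$R, initialAucThreshold = config$initialAucThreshold,
    iterPerLevel = config$iterPerLevel, decay = config$decay,
    nMajor = config$nMajor, nMinor = config$nMinor, cost = config$svmCost,
    seed = config$seed)
  trainProbs <- list(
    patient_burst = unname(predictRF(patientBurstModel, oob = TRUE)),
    spec = vapply(ids, function(id)
      predictPatient(specEnsemble, features$spec[[id]]), numeric(1)),
    cov = vapply(ids, function(id)
      predictPatient(covEnsemble, features$cov[[id]]), numeric(1)))
  fusion <- selectShifts(trainProbs, labels, config$aucFloor)
  new("PodModelStack", patientModel = patientModel,
      patientBurstModel = patientBurstModel, specEnsemble = specEnsemble,
      covEnsemble = covEnsemble, fusion = fusion,
      config = config)
}

#' Predict POD risk for a cohort with a frozen model stack
#'
#' No component is refit: covariance frames are projected to the saved
#' reference point, forests and SVMs are applied as trained, and the saved
#' shifts and fusion rule produce the combined risk.
#'
#' @param stack a trained \code{PodModelStack}.
#' @param features cohort feature object of the patients to predict.
#' @return risk report data.frame (one row per patient): all classifier
#'   probabilities, shifted variants, p_m, p_comb, binary call.
#' @export
predictModelStack <- function(stack, features) {
  clin <- features$clinical
  ids <- clin$patient_id
  probs <- list(
    patient_burst = predictRF(stack@patientBurstModel, clin),
    spec = vapply(ids, function(id)
      predictPatient(stack@specEnsemble, features$spec[[id]]), numeric(1)),
    cov = vapply(ids, function(id)
      predictPatient(stack@covEnsemble, features$cov[[id]]), numeric(1)))
  report <- applyFusion(stack@fusion, probs)
  cbind(data.frame(patient_id = ids,
                   p_patient = unname(predictRF(stack@patientModel, clin))),
        report, row.names = NULL)
}
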