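#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney U) AUC with ties counted one half. Returns NA
#' (missing) when only one class is present.
#'
#' @param scores predicted scores or probabilities.
#' @param labels binary labels.
#' @return AUC in [0,1], or NA.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: patients shuffled within class and dealt
# round-robin, so fold class counts differ by at most one per class.
stratifiedFolds <- function(labels, nFolds) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  folds
}

cvClassifiers <- c("patient", "patient_burst", "spec", "cov", "combined")

#' Repeated stratified cross-validation of the full pipeline
#'
#' Patient-grouped, label-stratified k-fold CV repeated \code{nRepeats}
#' times. Within each fold, every trainable quantity — forests, SVM
#' ensembles, the covariance reference point, g-mean thresholds and shifts
#' — is fit on the training folds only and applied frozen to the test
#' fold. A fold whose training or test part misses a class is skipped with
#' a warning.
#'
#' @param features cohort feature object (labels in
#'   \code{features$clinical$pod}).
#' @param nRepeats,nFolds CV layout (the study protocol uses 10 x 10).
#' @param config pipeline configuration.
#' @param seed fold-assignment seed; a fixed seed reproduces all folds.
#' @return list with \code{auc} (data.frame: repeat, fold, classifier,
#'   auc), \code{predictions} (pooled test predictions with repeat/fold),
#'   and \code{audit} (per-fold train/test patient ids and a fingerprint
#'   of the training inputs of every fitted component).
#' @export
runCV <- function(features, nRepeats = 10, nFolds = 10,
                  config = podConfig(), seed = config$seed) {
  clin <- features$clinical
  ids <- clin$patient_id
  labels <- clin$pod
  aucRows <- list(); predRows <- list(); audit <- list()
  for (rep in seq_len(nRepeats)) {
    folds <- withSeed(deriveSeed(seed, paste0("cv-folds-", rep)),
                      stratifiedFolds(labels, nFolds))
    for (k in seq_len(nFolds)) {
      testIds <- ids[folds == k]
      trainIds <- ids[folds != k]
      if (length(unique(labels[folds != k])) < 2 ||
          length(unique(labels[folds == k])) < 2) {
        warning("repeat ", rep, " fold ", k,
                " misses a class; fold skipped")
        next
      }
      foldConfig <- config
      foldConfig$seed <- deriveSeed(seed, paste0("cv-", rep, "-", k))
      stack <- trainModelStack(subsetFeatures(features, trainIds),
                               foldConfig)
      report <- predictModelStack(stack, subsetFeatures(features, testIds))
      yTest <- labels[match(report$patient_id, ids)]
      scores <- list(patient = report$p_patient,
                     patient_burst = report$p_patient_burst,
                     spec = report$p_spec, cov = report$p_cov,
                     combined = report$p_comb)
      for (cl in cvClassifiers)
        aucRows[[length(aucRows) + 1L]] <- data.frame(
          rep = rep, fold = k, classifier = cl,
          auc = rocAuc(scores[[cl]], yTest))
      report$rep <- rep; report$fold <- k; report$pod <- yTest
      predRows[[length(predRows) + 1L]] <- report
      audit[[sprintf("r%df%d", rep, k)]] <- list(
        trainIds = sort(trainIds), testIds = sort(testIds),
        componentTrainIds = list(
          reference = sort(trainIds), forests = sort(trainIds),
          thresholds = sort(trainIds), shifts = sort(trainIds)),
        trainFingerprint = fingerprintIds(trainIds))
    }
  }
  list(auc = do.call(rbind, aucRows), predictions = do.call(rbind, predRows),
       audit = audit)
}

# Stable fingerprint of a patient-id set (md5 of the sorted serialized ids),
# used by the leakage audit.
fingerprintIds <- function(ids) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(sort(ids), f)
  unname(tools::md5sum(f))
}

#' Train medication-group models with an all-medications fallback
#'
#' One full model stack per maintenance-agent group (Propofol, Desflurane,
#' Sevoflurane) that has at least \code{minGroupSize} patients and both
#' classes, plus an all-medications stack trained on every patient.
#' Undersized or single-class groups fold into the all-medications stack
#' with a warning; patients on other or mixed agents are always routed to
#' the all-medications stack.
#'
#' @param features cohort feature object with labels.
#' @param config pipeline configuration (\code{minGroupSize} lives there).
#' @return a \code{GroupedModelSet}.
#' @export
routeAndTrainGroups <- function(features, config = podConfig()) {
  clin <- features$clinical
  stacks <- list(all = trainModelStack(features, config))
  trained <- character(0)
  for (g in c("Propofol", "Desflurane", "Sevoflurane")) {
    gids <- clin$patient_id[clin$maintenance_agent == g]
    gl <- clin$pod[clin$maintenance_agent == g]
    if (length(gids) < config$minGroupSize || length(unique(gl)) < 2) {
      warning("group ", g, " too small or single-class (",
              length(gids), " patients); folded into all-medications")
      next
    }
    gConfig <- config
    gConfig$seed <- deriveSeed(config$seed, paste0("group-", g))
    stacks[[g]] <- trainModelStack(subsetFeatures(features, gids), gConfig)
    trained <- c(trained, g)
  }
  new("GroupedModelSet", stacks = stacks, groups = trained,
      minGroupSize = config$minGroupSize)
}

#' Route patients to their medication-group stack
#'
#' @param models a \code{GroupedModelSet}.
#' @param agents maintenance agent per patient.
#' @return stack name per patient ("all" for agents without a dedicated
#'   stack).
#' @export
routePatients <- function(models, agents) {
  ifelse(agents %in% models@groups, agents, "all")
}

#' Evaluate a frozen model set on a new cohort
#'
#' Applies a trained \code{GroupedModelSet} (or single stack) to a new
#' cohort without refitting anything: covariances are projected to the
#' saved reference points and the saved shifts are applied. Metrics are
#' reported overall and per routing group when labels are available.
#'
#' @param models \code{GroupedModelSet} or \code{PodModelStack}.
#' @param features cohort feature object of the new cohort.
#' @return list with \code{report} (risk report incl. routing group) and
#'   \code{metrics} (per-classifier AUC and NPV, overall and per group).
#' @export
transferEvaluate <- function(models, features) {
  clin <- features$clinical
  if (is(models, "PodModelStack")) {
    report <- predictModelStack(models, features)
    report$group <- "all"
  } else {
    groupOf <- routePatients(models, clin$maintenance_agent)
    parts <- lapply(unique(groupOf), function(g) {
      gids <- clin$patient_id[groupOf == g]
      r <- predictModelStack(models@stacks[[g]],
                             subsetFeatures(features, gids))
      r$group <- g
      r
    })
    report <- do.call(rbind, parts)
    report <- report[match(clin$patient_id, report$patient_id), ]
  }
  metrics <- NULL
  if ("pod" %in% names(clin)) {
    y <- clin$pod[match(report$patient_id, clin$patient_id)]
    oneSet <- function(rows, label) {
      data.frame(
        scope = label,
        classifier = cvClassifiers,
        auc = c(rocAuc(report$p_patient[rows], y[rows]),
                rocAuc(report$p_patient_burst[rows], y[rows]),
                rocAuc(report$p_spec[rows], y[rows]),
                rocAuc(report$p_cov[rows], y[rows]),
                rocAuc(report$p_comb[rows], y[rows])),
        npv = c(rep(NA_real_, 4), npv(report$call[rows], y[rows])))
    }
    metrics <- rbind(
      oneSet(seq_len(nrow(report)), "all_patients"),
      do.call(rbind, lapply(unique(report$group), function(g)
        oneSet(which(report$group == g), g))))
  }
  list(report = report, metrics = metrics)
}
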