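#' Assemble a frame-level dataset
#'
#' Bundles per-patient frame features with patient labels for the bagging
#' classifier. For \code{kind = "spec"} each patient's features are a
#' frames x frequencies matrix (log10 power); for \code{kind = "cov"} a
#' p x p x frames array of SPD matrices.
#'
#' @param features named list, one entry per patient.
#' @param labels named binary vector (0/1), same names as \code{features}.
#' @param kind "spec" or "cov".
#' @return a frame dataset (plain list, class "FrameDataset").
#' @export
frameDataset <- function(features, labels, kind = c("spec", "cov")) {
  kind <- match.arg(kind)
  stopIfNot(!is.null(names(features)) && !is.null(names(labels)),
            "features and labels must be named by patient")
  stopIfNot(setequal(names(features), names(labels)),
            "features and labels must cover the same patients")
  labels <- labels[names(features)]
  structure(list(features = features, labels = labels, kind = kind),
            class = "FrameDataset")
}

datasetFrameCount <- function(dataset, id) {
  f <- dataset$features[[id]]
  if (is.matrix(f)) nrow(f) else dim(f)[3]
}

#' Patient-level undersampling of the majority class
#'
#' Keeps every minority-class patient and a random subset of the majority
#' class of size max(minority count, ceiling(majority count / 3)) — the
#' majority class is never reduced below one third of its size.
#'
#' @param labels named binary patient labels (both classes present).
#' @return character vector of kept patient ids.
#' @export
samplePatients <- function(labels) {
  tab <- table(labels)
  stopIfNot(length(tab) == 2, "both classes must be present")
  minorityClass <- names(tab)[which.min(tab)]
  minority <- names(labels)[labels == minorityClass]
  majority <- names(labels)[labels != minorityClass]
  keepMaj <- max(length(minority), ceiling(length(majority) / 3))
  keepMaj <- min(keepMaj, length(majority))
  c(minority, sample(majority, keepMaj))
}

#' Frame-level undersampling
#'
#' Samples a fixed number of frames per patient (patients with fewer frames
#' contribute all of them), so longer surgeries do not dominate training.
#' For covariance features more frames are drawn from the minority class to
#' balance the frame table and diversify the minority covariance pool; for
#' spectral features both caps are equal.
#'
#' @param dataset a frame dataset.
#' @param patientIds patients to draw from (after patient-level sampling).
#' @param nMajor frames per majority-class patient.
#' @param nMinor frames per minority-class patient (must be >= nMajor for
#'   covariance features; forced equal to nMajor for spectral features).
#' @return list with \code{frames} (row indices per patient),
#'   \code{X} (frame feature rows; matrix for spec, list of SPD matrices
#'   for cov), \code{y} (frame labels), \code{pid} (per-frame patient id).
#' @export
sampleFrames <- function(dataset, patientIds, nMajor = 10, nMinor = 20) {
  labels <- dataset$labels[patientIds]
  tab <- table(dataset$labels)
  minorityClass <- names(tab)[which.min(tab)]
  if (dataset$kind == "spec") nMinor <- nMajor
  stopIfNot(nMinor >= nMajor, "nMinor must be at least nMajor")
  X <- list(); y <- numeric(0); pid <- character(0)
  for (id in patientIds) {
    total <- datasetFrameCount(dataset, id)
    cap <- if (as.character(labels[[id]]) == minorityClass) nMinor else nMajor
    idx <- if (total <= cap) seq_len(total) else sort(sample.int(total, cap))
    f <- dataset$features[[id]]
    rows <- if (is.matrix(f)) lapply(idx, function(i) f[i, ])
            else lapply(idx, function(i) f[, , i])
    X <- c(X, rows)
    y <- c(y, rep(labels[[id]], length(idx)))
    pid <- c(pid, rep(id, length(idx)))
  }
  if (dataset$kind == "spec") X <- do.call(rbind, X)
  list(X = X, y = y, pid = pid)
}

# Decision score oriented so that positive favors class "1" (POD). For
# linear e1071 models the decision values are computed directly from the
# primal weight vector (w = SV' alpha), which is much faster than the
# generic kernel path when scoring many frames.
svmScore <- function(model, X) {
  if (inherits(model, "svm") && model$kernel == 0 && !model$scaled[1]) {
    w <- crossprod(model$SV, model$coefs)
    dv <- as.numeric(X %*% w) - model$rho
    lab <- model$levels[model$labels[1]]
    return(if (identical(lab, "1")) dv else -dv)
  }
  dv <- attr(stats::predict(model, X, decision.values = TRUE),
             "decision.values")
  if (startsWith(colnames(dv)[1], "1")) as.numeric(dv) else -as.numeric(dv)
}

# Flatten every frame of every patient into one table (tangent vectors for
# cov after projection, log-power rows for spec), with frame labels.
allFramesTable <- function(dataset, reference = NULL) {
  rows <- list(); y <- numeric(0); pid <- character(0)
  for (id in names(dataset$features)) {
    f <- dataset$features[[id]]
    M <- if (dataset$kind == "cov") tangentProject(f, reference)@vectors
         else f
    rows <- c(rows, list(M))
    y <- c(y, rep(dataset$labels[[id]], nrow(M)))
    pid <- c(pid, rep(id, nrow(M)))
  }
  list(X = do.call(rbind, rows), y = y, pid = pid)
}

#' Train the two-level undersampled bagging ensemble
#'
#' The bagging loop for time-dependent features: repeatedly (i) undersample
#' the majority class on the patient level, (ii) sample a fixed number of
#' frames per patient, (iii) fit a class-weighted linear SVM on the sampled
#' frames (each frame labeled by its patient), (iv) score the SVM by
#' AUC-ROC over all frames of the full training set, and (v) save it iff
#' the AUC reaches the current acceptance threshold. After every
#' \code{iterPerLevel} consecutive failures the threshold is multiplied by
#' (1 - \code{decay}); the loop ends when \code{R} estimators are saved.
#'
#' For covariance features, a balanced Riemannian reference point is first
#' computed from one patient+frame sampling draw of the training set, and
#' all training (and later test) frames are projected to its tangent space;
#' the reference is stored with the ensemble so new data needs no refit.
#'
#' @param dataset a frame dataset (training patients only).
#' @param R number of estimators to save.
#' @param initialAucThreshold starting acceptance threshold.
#' @param iterPerLevel consecutive failures tolerated before decaying.
#' @param decay multiplicative threshold reduction (0.025 = 2.5%).
#' @param nMajor,nMinor frame sampling caps per patient.
#' @param cost soft-margin cost of the linear SVM.
#' @param seed integer seed; fixed seed reproduces the ensemble and the
#'   threshold history bitwise.
#' @return a \code{BaggedEnsemble}.
#' @export
trainBagging <- function(dataset, R = 25, initialAucThreshold = 0.70,
                         iterPerLevel = 5, decay = 0.025, nMajor = 10,
                         nMinor = 20, cost = 1, seed = 1) {
  stopIfNot(R >= 1, "R must be at least 1")
  stopIfNot(length(unique(dataset$labels)) == 2,
            "training set must contain both classes")
  withSeed(deriveSeed(seed, paste0("bagging-", dataset$kind)), {
    reference <- NULL
    if (dataset$kind == "cov") {
      draw <- sampleFrames(dataset, samplePatients(dataset$labels),
                           nMajor, nMinor)
      reference <- balancedReference(draw$X, draw$y)
    }
    full <- allFramesTable(dataset, reference)
    estimators <- list()
    history <- numeric(0)
    threshold <- initialAucThreshold
    failures <- 0L
    while (length(estimators) < R) {
      draw <- sampleFrames(dataset, samplePatients(dataset$labels),
                           nMajor, nMinor)
      X <- if (dataset$kind == "cov")
        tangentProject(draw$X, reference)@vectors else draw$X
      yf <- factor(draw$y, levels = c(0, 1))
      w <- as.vector(length(yf) / (2 * table(yf)))
      names(w) <- c("0", "1")
      fit <- e1071::svm(X, yf, kernel = "linear", cost = cost,
                        class.weights = w, scale = FALSE)
      history <- c(history, threshold)
      auc <- rocAuc(svmScore(fit, full$X), full$y)
      if (!is.na(auc) && auc >= threshold) {
        estimators <- c(estimators, list(fit))
        failures <- 0L
      } else {
        failures <- failures + 1L
        if (failures >= iterPerLevel) {
          threshold <- threshold * (1 - decay)
          failures <- 0L
        }
      }
    }
    new("BaggedEnsemble", estimators = estimators, kind = dataset$kind,
        reference = reference, thresholdHistory = history,
        config = list(R = R, initialAucThreshold = initialAucThreshold,
                      iterPerLevel = iterPerLevel, decay = decay,
                      nMajor = nMajor, nMinor = nMinor, cost = cost,
                      seed = seed))
  })
}

#' Per-patient POD probability from a bagged ensemble
#'
#' The mean ratio of time frames classified as POD over estimators and
#' frames: \deqn{p = \frac{1}{R\,T} \sum_{r=1}^{R} \sum_{t=1}^{T} c_{r,t}}
#' with binary frame classifications \eqn{c_{r,t}} (an SVM decision value
#' of exactly 0 counts as non-POD). Requires no label and no refitting;
#' covariance frames are projected to the ensemble's saved reference point.
#'
#' @param ensemble a trained \code{BaggedEnsemble}.
#' @param frames the patient's frames: log-power matrix (spec) or SPD
#'   frames (cov; \code{CovarianceFrameSeries}, list or array).
#' @return probability in [0,1].
#' @export
predictPatient <- function(ensemble, frames) {
  X <- if (ensemble@kind == "cov")
    tangentProject(frames, ensemble@reference)@vectors
  else frames
  stopIfNot(nrow(X) >= 1, "undefined input: patient has zero frames")
  hits <- vapply(ensemble@estimators,
                 function(est) sum(svmScore(est, X) > 0), numeric(1))
  sum(hits) / (length(ensemble@estimators) * nrow(X))
}
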