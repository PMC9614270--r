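#' g-mean optimal classification threshold
#'
#' Threshold maximizing the geometric mean of sensitivity and specificity,
#' \eqn{g = \sqrt{TPR \cdot (1 - FPR)}}, over the candidate set of
#' midpoints between consecutive distinct sorted probabilities (a
#' probability at or above the threshold is called positive). Ties are
#' broken toward the smallest threshold; if all probabilities are equal
#' there is no informative threshold and 0.5 is returned.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels (both classes present).
#' @return the optimal threshold.
#' @export
gmeanThreshold <- function(probs, labels) {
  labels <- as.integer(labels > 0)
  stopIfNot(length(unique(labels)) == 2, "both classes must be present")
  s <- sort(unique(probs))
  if (length(s) < 2) return(0.5)
  cand <- (s[-1] + s[-length(s)]) / 2
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  g <- vapply(cand, function(th) {
    calls <- probs >= th
    tpr <- sum(calls & labels == 1) / nPos
    fpr <- sum(calls & labels == 0) / nNeg
    sqrt(tpr * (1 - fpr))
  }, numeric(1))
  cand[which.max(g)]          # which.max takes the first (smallest) maximum
}

fusionClassifiers <- c("patient_burst", "spec", "cov")

shiftSubsets <- function() list(
  all = fusionClassifiers,
  pat_spec = c("patient_burst", "spec"),
  pat_cov = c("patient_burst", "cov"),
  spec_cov = c("spec", "cov"))

applyShifts <- function(probs, shifts) {
  shifted <- probs
  for (cl in fusionClassifiers)
    shifted[[cl]] <- clip01(probs[[cl]] + shifts[[cl]])
  shifted
}

#' Combine the three classifier probabilities into the final risk
#'
#' The false-negative-averse fusion rule
#' \deqn{p_{comb} = \max(p_{patient+burst}, \min(p_{spec}, p_{cov}))}
#' with a low-probability override: \eqn{p_m}, the plain mean of the
#' probabilities of all classifiers whose training AUC reaches
#' \code{aucFloor}, replaces the result whenever \eqn{p_m < 0.25}, to
#' retain a better prediction for small values. Inputs are the (shifted,
#' clipped) probabilities.
#'
#' @param pPat,pSpec,pCov probability vectors in [0,1] (shifted variants).
#' @param trainingAucs named training AUCs over
#'   c("patient_burst","spec","cov").
#' @param aucFloor minimum training AUC for a classifier to enter p_m.
#' @return list with \code{pComb} and \code{pM}.
#' @export
combineRisk <- function(pPat, pSpec, pCov, trainingAucs, aucFloor = 0.55) {
  base <- pmax(pPat, pmin(pSpec, pCov))
  ok <- !is.na(trainingAucs[fusionClassifiers]) &
    trainingAucs[fusionClassifiers] >= aucFloor
  if (!any(ok)) {
    warning("no classifier reaches the training-AUC floor (", aucFloor,
            "); falling back to the max/min rule alone")
    return(list(pComb = base, pM = rep(NA_real_, length(base))))
  }
  members <- rbind(patient_burst = pPat, spec = pSpec, cov = pCov)[ok, ,
                                                                   drop = FALSE]
  pM <- colMeans(members)
  list(pComb = ifelse(pM < 0.25, pM, base), pM = pM)
}

#' Select the probability shifts on the training set
#'
#' Computes each classifier's g-mean-optimal threshold on the training
#' probabilities, then evaluates the four candidate shift subsets (shift
#' all three classifiers to an optimal threshold of 0.5, or each pair with
#' the third shift set to 0) and freezes the subset whose shifted
#' probabilities give the highest training AUC of the combined risk.
#' Exact ties keep the earlier subset in the fixed preference order
#' all > (patient+burst, spec) > (patient+burst, cov) > (spec, cov).
#'
#' @param probs named list of training probability vectors
#'   (\code{patient_burst}, \code{spec}, \code{cov}) on the same patients.
#' @param labels binary POD labels.
#' @param aucFloor training-AUC floor for the low-probability override.
#' @return a \code{FusionState}, frozen for test use.
#' @export
selectShifts <- function(probs, labels, aucFloor = 0.55) {
  stopIfNot(all(fusionClassifiers %in% names(probs)),
            "probs must contain patient_burst, spec and cov")
  thresholds <- vapply(fusionClassifiers, function(cl)
    gmeanThreshold(probs[[cl]], labels), numeric(1))
  trainingAucs <- vapply(fusionClassifiers, function(cl)
    rocAuc(probs[[cl]], labels), numeric(1))
  best <- NULL; bestAuc <- -Inf
  for (subsetName in names(shiftSubsets())) {
    members <- shiftSubsets()[[subsetName]]
    shifts <- stats::setNames(rep(0, 3), fusionClassifiers)
    shifts[members] <- 0.5 - thresholds[members]
    shifted <- applyShifts(probs, shifts)
    comb <- combineRisk(shifted$patient_burst, shifted$spec, shifted$cov,
                        trainingAucs, aucFloor)
    auc <- rocAuc(comb$pComb, labels)
    if (!is.na(auc) && auc > bestAuc + 1e-12) {
      bestAuc <- auc
      best <- list(subset = members, shifts = shifts)
    }
  }
  new("FusionState", thresholds = thresholds, shifts = best$shifts,
      subset = best$subset, trainingAucs = trainingAucs,
      aucFloor = aucFloor)
}

#' Apply a frozen fusion state to new probabilities
#'
#' Shifts the three classifier probabilities by the saved shifts, clips to
#' [0,1], and combines them into the final risk with the binary call at
#' the fixed 0.5 threshold.
#'
#' @param state a \code{FusionState}.
#' @param probs named list of probability vectors
#'   (\code{patient_burst}, \code{spec}, \code{cov}).
#' @return data.frame risk report: raw and shifted probabilities, p_m,
#'   p_comb and the binary call.
#' @export
applyFusion <- function(state, probs) {
  shifted <- applyShifts(probs, state@shifts)
  comb <- combineRisk(shifted$patient_burst, shifted$spec, shifted$cov,
                      state@trainingAucs, state@aucFloor)
  data.frame(
    p_patient_burst = probs$patient_burst, p_spec = probs$spec,
    p_cov = probs$cov,
    p_patient_burst_shifted = shifted$patient_burst,
    p_spec_shifted = shifted$spec, p_cov_shifted = shifted$cov,
    p_m = comb$pM, p_comb = comb$pComb, call = comb$pComb >= 0.5)
}

#' Negative predictive value
#'
#' TN / (TN + FN) at the fixed 0.5 decision threshold. Returns NA (missing,
#' not zero) when there are no negative calls.
#'
#' @param calls binary calls (TRUE/1 = POD predicted).
#' @param labels binary true labels.
#' @export
npv <- function(calls, labels) {
  calls <- as.logical(calls)
  labels <- as.integer(labels > 0)
  neg <- !calls
  if (!any(neg)) return(NA_real_)
  sum(neg & labels == 0) / sum(neg)
}
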