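inductionLevels <- c("Propofol", "Thiopental", "Etomidate", "Other")
maintenanceLevels <- c("Propofol", "Desflurane", "Sevoflurane", "Isoflurane",
                       "Other")

# Encode a clinical table (plus optional burst-suppression columns) for the
# forest: numeric covariates passed through, categorical agents as factors
# with fixed vocabularies; unseen levels map to "Other" so frozen models
# transfer to new cohorts without crashing.
encodeClinical <- function(clinical, featureSet) {
  toFactor <- function(x, levels) {
    x <- as.character(x)
    x[!x %in% levels] <- "Other"
    factor(x, levels = levels)
  }
  out <- data.frame(
    age = as.numeric(clinical$age),
    asa = as.numeric(clinical$asa),
    op_length = as.numeric(clinical$op_length),
    benzodiazepine = factor(as.integer(clinical$benzodiazepine > 0),
                            levels = c(0, 1)),
    induction_agent = toFactor(clinical$induction_agent, inductionLevels),
    maintenance_agent = toFactor(clinical$maintenance_agent,
                                 maintenanceLevels)
  )
  if (featureSet == "patient+burstsupp") {
    stopIfNot(all(c("bsr", "lsp") %in% names(clinical)),
              "patient+burstsupp features require bsr and lsp columns")
    out$bsr <- as.numeric(clinical$bsr)
    out$lsp <- as.numeric(clinical$lsp)
  }
  stopIfNot(all(out$age > 0), "age must be positive")
  stopIfNot(all(out$op_length > 0), "op_length must be positive")
  out
}

#' Train a balanced random forest on per-patient features
#'
#' Each tree is grown on a bootstrap of the minority class plus an
#' equal-size random draw from the majority class (stratified sampling with
#' per-class sample size equal to the minority count), so the expected
#' per-tree class ratio is 1:1 regardless of cohort imbalance. Feature set
#' "patient" uses the clinical covariates alone; "patient+burstsupp" adds
#' the burst suppression ratio and longest suppression phase extracted from
#' the intraoperative EEG.
#'
#' @param clinical clinical data.frame (columns age, asa, op_length,
#'   benzodiazepine, induction_agent, maintenance_agent, plus bsr/lsp for
#'   the burst-suppression feature set).
#' @param labels binary POD labels (both classes present).
#' @param featureSet "patient" or "patient+burstsupp".
#' @param nTrees forest size.
#' @param seed integer seed; fixed seed gives identical forests.
#' @return a \code{PatientModel}.
#' @export
trainBalancedRF <- function(clinical, labels,
                            featureSet = c("patient", "patient+burstsupp"),
                            nTrees = 500, seed = 1) {
  featureSet <- match.arg(featureSet)
  y <- factor(labels, levels = c(0, 1))
  stopIfNot(nlevels(droplevels(y)) == 2,
            "training labels must contain both classes")
  X <- encodeClinical(clinical, featureSet)
  nMin <- min(table(y))
  forest <- withSeed(deriveSeed(seed, paste0("brf-", featureSet)),
    randomForest::randomForest(
      x = X, y = y, ntree = nTrees, strata = y,
      sampsize = c(nMin, nMin), replace = TRUE))
  new("PatientModel", forest = forest, featureSet = featureSet,
      encoding = list(columns = names(X)))
}

#' POD probability from a balanced random forest
#'
#' Mean of the per-tree probabilities (the fraction of trees voting POD),
#' in [0,1] and invariant to tree order. With \code{oob = TRUE} the
#' out-of-bag probabilities of the training rows are returned instead
#' (used for fitting thresholds without in-sample optimism).
#'
#' @param model a \code{PatientModel}.
#' @param clinical rows to predict (same columns as in training; unseen
#'   categorical levels map to "Other").
#' @param oob return out-of-bag training probabilities.
#' @return numeric probability vector.
#' @export
predictRF <- function(model, clinical = NULL, oob = FALSE) {
  if (oob) return(stats::predict(model@forest, type = "prob")[, "1"])
  X <- encodeClinical(clinical, model@featureSet)
  stats::predict(model@forest, newdata = X, type = "prob")[, "1"]
}
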