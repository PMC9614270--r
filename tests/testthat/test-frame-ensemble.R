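# Two-level sampling, bagging loop contract, frame-ratio prediction.

test_that("patient-level undersampling keeps at least a third of the majority", {
  withr::local_seed(1)
  lab <- setNames(c(rep(0, 90), rep(1, 30)), sprintf("p%03d", 1:120))
  kept <- samplePatients(lab)
  expect_equal(sum(lab[kept] == 1), 30)       # minority untouched
  expect_equal(sum(lab[kept] == 0), 30)       # max(30, ceil(90/3)) = 30
  lab2 <- setNames(c(rep(0, 300), rep(1, 40)), sprintf("q%03d", 1:340))
  kept2 <- samplePatients(lab2)
  expect_equal(sum(lab2[kept2] == 0), 100)    # ceil(300/3) > 40
  lab3 <- setNames(rep(c(0, 1), each = 30), sprintf("r%03d", 1:60))
  expect_setequal(samplePatients(lab3), names(lab3))
  expect_error(samplePatients(setNames(rep(1, 5), letters[1:5])),
               "both classes")
})

test_that("frame-level sampling respects per-patient caps", {
  withr::local_seed(2)
  feats <- list()
  labs <- c()
  for (i in 1:20) {
    id <- sprintf("s%02d", i)
    nf <- if (i == 1) 3 else 30
    feats[[id]] <- matrix(rnorm(nf * 5), nf)
    labs[id] <- as.integer(i <= 6)
  }
  ds <- frameDataset(feats, labs, "spec")
  draw <- sampleFrames(ds, names(feats), nMajor = 10, nMinor = 20)
  expect_equal(sum(draw$pid == "s01"), 3)      # cap not binding
  expect_lte(nrow(draw$X), 200)                # spec: equal caps
  expect_equal(sum(draw$pid == "s02"), 10)
  # covariance features oversample the minority class
  featsC <- lapply(feats, function(f)
    vapply(seq_len(nrow(f)), function(j) diag(4) + 0, matrix(0, 4, 4)))
  dsC <- frameDataset(featsC, labs, "cov")
  drawC <- sampleFrames(dsC, names(featsC), nMajor = 10, nMinor = 20)
  perPatient <- table(drawC$pid)
  expect_equal(unname(perPatient["s02"]), 20)  # minority (pod) cap
  expect_equal(unname(perPatient["s10"]), 10)  # majority cap
})

test_that("bagging loop saves R estimators and reproduces bitwise", {
  withr::local_seed(3)
  feats <- list(); labs <- c()
  for (i in 1:16) {
    id <- sprintf("t%02d", i)
    y <- as.integer(i <= 5)
    feats[[id]] <- cbind(rnorm(8, mean = 3 * y), matrix(rnorm(8 * 3), 8))
    labs[id] <- y
  }
  ds <- frameDataset(feats, labs, "spec")
  ens <- trainBagging(ds, R = 3, seed = 9)
  expect_s4_class(ens, "BaggedEnsemble")
  expect_length(ens@estimators, 3)
  # perfectly separable: no threshold decay
  expect_true(all(ens@thresholdHistory == 0.70))
  ens2 <- trainBagging(ds, R = 3, seed = 9)
  expect_identical(ens@thresholdHistory, ens2@thresholdHistory)
  expect_equal(predictPatient(ens, feats[["t01"]]),
               predictPatient(ens2, feats[["t01"]]))
})

test_that("the acceptance threshold decays in exact 2.5% steps", {
  withr::local_seed(4)
  feats <- list(); labs <- c()
  for (i in 1:12) {
    id <- sprintf("u%02d", i)
    feats[[id]] <- matrix(rnorm(6 * 4), 6)     # pure noise frames
    labs[id] <- as.integer(i <= 4)
  }
  ds <- frameDataset(feats, labs, "spec")
  ens <- trainBagging(ds, R = 2, initialAucThreshold = 0.9, seed = 5)
  h <- ens@thresholdHistory
  decays <- which(diff(h) != 0)
  expect_gt(length(decays), 0)
  # every change is exactly multiplicative by (1 - 0.025)
  expect_equal(h[decays + 1] / h[decays], rep(0.975, length(decays)),
               tolerance = 1e-12)
  # at most one decay per 5 iterations
  expect_true(all(diff(decays) >= 5))
  expect_gte(min(diff(c(0, decays))), 5)
})

test_that("patient probability is the exact mean frame-classification ratio", {
  # mock base learners with prescribed binary frame classifications
  mockSvm <- function(calls) structure(list(calls = calls),
                                       class = "mockSvm")
  registerS3method("predict", "mockSvm", function(object, newdata, ...) {
    dv <- matrix(ifelse(object$calls, 1, -1), ncol = 1,
                 dimnames = list(NULL, "1/0"))
    structure(factor(as.integer(object$calls)), decision.values = dv)
  }, envir = asNamespace("stats"))
  ens <- new("BaggedEnsemble",
             estimators = list(mockSvm(c(TRUE, FALSE, TRUE)),
                               mockSvm(c(TRUE, TRUE, FALSE))),
             kind = "spec", reference = NULL,
             thresholdHistory = 0.7, config = list())
  frames <- matrix(0, 3, 2)
  expect_equal(predictPatient(ens, frames), 4 / 6)
  # all-POD classifications give probability 1
  ensAll <- new("BaggedEnsemble",
                estimators = list(mockSvm(rep(TRUE, 3))), kind = "spec",
                reference = NULL, thresholdHistory = 0.7, config = list())
  expect_equal(predictPatient(ensAll, frames), 1)
  # invariant to duplicating the estimator list
  ensDup <- ens
  ensDup@estimators <- c(ens@estimators, ens@estimators)
  expect_equal(predictPatient(ensDup, frames), 4 / 6)
})

test_that("an ensemble transfers unchanged to new patients", {
  withr::local_seed(6)
  feats <- list(); labs <- c()
  for (i in 1:14) {
    id <- sprintf("v%02d", i)
    y <- as.integer(i <= 5)
    feats[[id]] <- cbind(rnorm(10, 2 * y), matrix(rnorm(10 * 2), 10))
    labs[id] <- y
  }
  ens <- trainBagging(frameDataset(feats, labs, "spec"), R = 3, seed = 2)
  newFrames <- cbind(rnorm(7, 2), matrix(rnorm(7 * 2), 7))
  p1 <- predictPatient(ens, newFrames)
  # frame order does not matter
  p2 <- predictPatient(ens, newFrames[sample(7), ])
  expect_equal(p1, p2)
  expect_gte(p1, 0)
  expect_lte(p1, 1)
})

test_that("covariance ensembles carry and reuse their reference point", {
  withr::local_seed(7)
  feats <- list(); labs <- c()
  for (i in 1:12) {
    id <- sprintf("w%02d", i)
    y <- as.integer(i <= 4)
    feats[[id]] <- vapply(1:8, function(j) makeSpd(3, scale = 1 + y),
                          matrix(0, 3, 3))
    labs[id] <- y
  }
  ens <- trainBagging(frameDataset(feats, labs, "cov"), R = 2, seed = 3,
                      nMajor = 5, nMinor = 8)
  expect_false(is.null(ens@reference))
  expect_gt(min(eigen(ens@reference, only.values = TRUE)$values), 0)
  p <- predictPatient(ens, feats[["w01"]])
  expect_gte(p, 0); expect_lte(p, 1)
})
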