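# ROC/AUC, cross-validation protocol, group routing, frozen-model transfer.

test_that("AUC equals the normalized Mann-Whitney statistic", {
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(rocAuc(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_true(is.na(rocAuc(runif(5), rep(1, 5))))
  # brute-force all-pairs oracle, ties counted one half
  withr::local_seed(41)
  for (i in 1:25) {
    n <- sample(8:50, 1)
    y <- rbinom(n, 1, 0.4); y[1:2] <- c(0, 1)
    s <- round(runif(n), 1)                 # coarse grid forces ties
    pos <- s[y == 1]; neg <- s[y == 0]
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(rocAuc(s, y), brute, tolerance = 1e-12)
  }
  # random ranking at large n sits near one half
  withr::local_seed(42)
  y <- rbinom(4000, 1, 0.3)
  expect_equal(rocAuc(runif(4000), y), 0.5, tolerance = 0.03)
})

test_that("cross-validation partitions patients and reproduces with a seed", {
  feat <- fabricateFeatures(n = 36, seed = 51)
  cfg <- fastConfig(seed = 3)
  cv <- runCV(feat, nRepeats = 1, nFolds = 4, cfg)
  # each patient appears exactly once per repeat
  expect_setequal(cv$predictions$patient_id, feat$clinical$patient_id)
  expect_equal(nrow(cv$predictions), nrow(feat$clinical))
  expect_equal(nrow(cv$auc), 4 * 5)
  cv2 <- runCV(feat, nRepeats = 1, nFolds = 4, cfg)
  expect_identical(cv$auc, cv2$auc)
  expect_identical(cv$predictions$p_comb, cv2$predictions$p_comb)
})

test_that("no test-fold patient enters any training-fold component", {
  feat <- fabricateFeatures(n = 30, seed = 52)
  cv <- runCV(feat, nRepeats = 1, nFolds = 3, fastConfig(seed = 4))
  for (fold in cv$audit) {
    expect_length(intersect(fold$testIds, fold$trainIds), 0)
    for (comp in fold$componentTrainIds)
      expect_length(intersect(fold$testIds, comp), 0)
    expect_identical(fold$trainFingerprint,
                     podeeg:::fingerprintIds(fold$trainIds))
  }
})

test_that("label permutation collapses CV performance to chance", {
  feat <- fabricateFeatures(n = 44, seed = 53)
  withr::local_seed(54)
  feat$clinical$pod <- sample(feat$clinical$pod)
  cv <- runCV(feat, nRepeats = 1, nFolds = 4, fastConfig(seed = 5))
  pooled <- rocAuc(cv$predictions$p_comb, cv$predictions$pod)
  expect_gt(pooled, 0.3)
  expect_lt(pooled, 0.7)
})

test_that("group routing covers every patient exactly once", {
  feat <- fabricateFeatures(n = 60, seed = 55,
                            agentMix = c(Propofol = 0.45, Sevoflurane = 0.45,
                                         Isoflurane = 0.1))
  models <- suppressWarnings(
    routeAndTrainGroups(feat, fastConfig(seed = 6, minGroupSize = 10)))
  expect_s4_class(models, "GroupedModelSet")
  groupOf <- routePatients(models, feat$clinical$maintenance_agent)
  expect_length(groupOf, nrow(feat$clinical))
  # patients on agents without a dedicated stack go to all-medications
  expect_true(all(groupOf[feat$clinical$maintenance_agent == "Isoflurane"]
                  == "all"))
  expect_true(all(groupOf %in% names(models@stacks)))
})

test_that("undersized groups fold into the all-medications stack", {
  feat <- fabricateFeatures(n = 30, seed = 56,
                            agentMix = c(Propofol = 0.9, Desflurane = 0.1))
  w <- capture_warnings(
    models <- routeAndTrainGroups(feat, fastConfig(seed = 7,
                                                   minGroupSize = 12)))
  expect_true(any(grepl("Desflurane.*folded into all-medications", w)))
  expect_false("Desflurane" %in% models@groups)
})

test_that("transfer onto the training cohort matches in-sample prediction", {
  feat <- fabricateFeatures(n = 30, seed = 57)
  stack <- trainModelStack(feat, fastConfig(seed = 8))
  direct <- predictModelStack(stack, feat)
  tr <- transferEvaluate(stack, feat)
  expect_equal(tr$report$p_comb, direct$p_comb)
  expect_equal(tr$report$patient_id, direct$patient_id)
  expect_true(all(c("auc", "npv") %in% names(tr$metrics)))
})

test_that("a frozen grouped model set predicts a new cohort without refit", {
  feat <- fabricateFeatures(n = 50, seed = 58)
  models <- suppressWarnings(
    routeAndTrainGroups(feat, fastConfig(seed = 9, minGroupSize = 8)))
  feat2 <- fabricateFeatures(n = 40, seed = 59)
  tr <- transferEvaluate(models, feat2)
  expect_equal(nrow(tr$report), 40)
  expect_true(all(tr$report$p_comb >= 0 & tr$report$p_comb <= 1))
  # deterministic: repeating the transfer gives identical output
  tr2 <- transferEvaluate(models, feat2)
  expect_identical(tr$report, tr2$report)
})
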