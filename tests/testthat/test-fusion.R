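# g-mean thresholds, shift selection, max/min fusion, NPV.

test_that("g-mean threshold separates a clean gap at its midpoint", {
  th <- gmeanThreshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(th, 0.5)
  # anti-separated labels cannot reach g = 1
  gOf <- function(probs, labels, th) {
    tpr <- mean(probs[labels == 1] >= th)
    fpr <- mean(probs[labels == 0] >= th)
    sqrt(tpr * (1 - fpr))
  }
  probs <- c(0.1, 0.2, 0.8, 0.9); labs <- c(1, 1, 0, 0)
  thAnti <- gmeanThreshold(probs, labs)
  expect_lt(gOf(probs, labs, thAnti), 1)
  # all probabilities equal: no informative threshold
  expect_equal(gmeanThreshold(rep(0.4, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_error(gmeanThreshold(runif(5), rep(1, 5)), "both classes")
})

test_that("g-mean threshold matches a brute-force scan on random problems", {
  bruteForce <- function(probs, labels) {
    s <- sort(unique(probs))
    cand <- (s[-1] + s[-length(s)]) / 2
    g <- sapply(cand, function(th) {
      tpr <- sum(probs >= th & labels == 1) / sum(labels == 1)
      fpr <- sum(probs >= th & labels == 0) / sum(labels == 0)
      sqrt(tpr * (1 - fpr))
    })
    cand[which.max(g)]
  }
  withr::local_seed(31)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    labels <- rbinom(n, 1, 0.4)
    labels[1:2] <- c(0, 1)
    probs <- round(runif(n), 2)
    expect_equal(gmeanThreshold(probs, labels), bruteForce(probs, labels))
  }
})

test_that("the fusion rule reproduces the worked cases", {
  aucs <- c(patient_burst = 0.8, spec = 0.8, cov = 0.8)
  # max(0.6, min(0.3, 0.4)) = 0.6; p_m = 0.433 above the override cut
  expect_equal(combineRisk(0.6, 0.3, 0.4, aucs)$pComb, 0.6)
  # low-probability override: p_m = 0.1 < 0.25
  expect_equal(combineRisk(0.1, 0.1, 0.1, aucs)$pComb, 0.1)
  # max(0.2, min(0.9, 0.1)) = 0.2; p_m = 0.4
  expect_equal(combineRisk(0.2, 0.9, 0.1, aucs)$pComb, 0.2)
  # no classifier above the floor: warn and fall back to the max/min rule
  expect_warning(out <- combineRisk(0.6, 0.3, 0.4,
                                    c(patient_burst = 0.5, spec = 0.5,
                                      cov = 0.5)),
                 "floor")
  expect_equal(out$pComb, 0.6)
})

test_that("fusion is false-negative averse", {
  withr::local_seed(32)
  aucs <- c(patient_burst = 0.9, spec = 0.9, cov = 0.9)
  for (i in 1:200) {
    p <- runif(3)
    out <- combineRisk(p[1], p[2], p[3], aucs)$pComb
    expect_gte(out, min(p[2], p[3]) - 1e-12)
    if (is.na(out) || out >= 0.25) expect_gte(out, p[1] - 1e-12)
  }
})

test_that("shift selection freezes g-mean-optimal shifts chosen by training AUC", {
  withr::local_seed(33)
  n <- 80
  y <- rbinom(n, 1, 0.3); y[1:2] <- c(0, 1)
  probs <- list(
    patient_burst = clip01(0.3 * y + runif(n, 0, 0.55)),
    spec = clip01(0.25 * y + runif(n, 0, 0.6)),
    cov = clip01(0.2 * y + runif(n, 0, 0.6)))
  st <- selectShifts(probs, y)
  expect_s4_class(st, "FusionState")
  # exhaustive oracle over the four candidate subsets
  subsets <- list(c("patient_burst", "spec", "cov"),
                  c("patient_burst", "spec"),
                  c("patient_burst", "cov"), c("spec", "cov"))
  best <- -Inf; bestSubset <- NULL
  for (ss in subsets) {
    sh <- setNames(rep(0, 3), c("patient_burst", "spec", "cov"))
    for (cl in ss) sh[cl] <- 0.5 - gmeanThreshold(probs[[cl]], y)
    pc <- combineRisk(clip01(probs$patient_burst + sh["patient_burst"]),
                      clip01(probs$spec + sh["spec"]),
                      clip01(probs$cov + sh["cov"]),
                      st@trainingAucs)$pComb
    a <- rocAuc(pc, y)
    if (a > best + 1e-12) { best <- a; bestSubset <- ss }
  }
  expect_setequal(st@subset, bestSubset)
  # shifted members now have a g-mean-optimal threshold at 0.5
  for (cl in st@subset) {
    shifted <- clip01(probs[[cl]] + st@shifts[cl])
    expect_equal(gmeanThreshold(shifted, y), 0.5, tolerance = 0.02)
  }
})

test_that("already-centered classifiers need no shift", {
  y <- rep(c(0, 1), each = 20)
  p <- c(runif(20, 0.05, 0.45), runif(20, 0.55, 0.95))
  probs <- list(patient_burst = p, spec = p, cov = p)
  st <- selectShifts(probs, y)
  # shifts vanish up to the candidate-grid resolution of the threshold
  expect_lt(max(abs(st@shifts)), 0.05)
  expect_setequal(st@subset, c("patient_burst", "spec", "cov"))
})

test_that("NPV follows its definition and degenerates to missing", {
  expect_equal(npv(c(FALSE, FALSE, TRUE, TRUE), c(0, 0, 1, 1)), 1)
  calls <- c(rep(FALSE, 10), TRUE)
  labels <- c(rep(0, 9), 1, 1)
  expect_equal(npv(calls, labels), 0.9)
  expect_true(is.na(npv(rep(TRUE, 4), c(0, 1, 0, 1))))
})

test_that("applied fusion clips shifted probabilities into [0,1]", {
  st <- new("FusionState",
            thresholds = c(patient_burst = 0.9, spec = 0.1, cov = 0.5),
            shifts = c(patient_burst = -0.4, spec = 0.4, cov = 0),
            subset = c("patient_burst", "spec"),
            trainingAucs = c(patient_burst = 0.8, spec = 0.8, cov = 0.8),
            aucFloor = 0.55)
  rep <- applyFusion(st, list(patient_burst = c(0.1, 0.95),
                              spec = c(0.9, 0.8), cov = c(0.5, 0.5)))
  expect_true(all(rep$p_patient_burst_shifted >= 0 &
                    rep$p_patient_burst_shifted <= 1))
  expect_true(all(rep$p_spec_shifted >= 0 & rep$p_spec_shifted <= 1))
  expect_true(all(rep$p_comb >= 0 & rep$p_comb <= 1))
  expect_equal(rep$call, rep$p_comb >= 0.5)
})
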