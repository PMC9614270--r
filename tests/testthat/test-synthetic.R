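# Synthetic cohort generator: determinism, planted structure, class effects.

test_that("identical spec and seed reproduce the cohort bit-exactly", {
  spec <- cohortSpec(nPatients = 3, seed = 42, durationRange = c(20, 21))
  a <- cohortAssignments(spec)
  b <- cohortAssignments(spec)
  expect_identical(a, b)
  p1 <- simulatePatient(spec, 2)
  p2 <- simulatePatient(spec, 2)
  expect_identical(p1$recording@signal, p2$recording@signal)
  expect_identical(p1$clinical, p2$clinical)
  expect_identical(p1$groundTruth, p2$groundTruth)
  # a different seed changes the signal
  spec2 <- cohortSpec(nPatients = 3, seed = 43, durationRange = c(20, 21))
  expect_false(identical(simulatePatient(spec2, 2)$recording@signal,
                         p1$recording@signal))
})

test_that("labels follow the requested prevalence", {
  spec <- cohortSpec(nPatients = 240, podPrevalence = 0.19, seed = 1)
  a <- cohortAssignments(spec)
  k <- sum(a$pod)
  # binomial 95% interval for n = 240, p = 0.19
  expect_gte(k, qbinom(0.025, 240, 0.19))
  expect_lte(k, qbinom(0.975, 240, 0.19))
  expect_equal(nrow(a), 240)
})

test_that("clinical covariates carry the configured class offsets", {
  spec <- cohortSpec(nPatients = 4000, seed = 3)
  a <- cohortAssignments(spec)
  gapAge <- mean(a$age[a$pod == 1]) - mean(a$age[a$pod == 0])
  gapOp <- mean(a$op_length[a$pod == 1]) - mean(a$op_length[a$pod == 0])
  expect_equal(gapAge, 2.7, tolerance = 0.35)
  expect_equal(gapOp, 1.27, tolerance = 0.2)
  expect_true(all(a$asa %in% 1:4))
  expect_true(all(a$maintenance_agent %in%
                    c("Propofol", "Desflurane", "Sevoflurane", "Other")))
})

test_that("zero rates produce zero planted events", {
  spec <- cohortSpec(nPatients = 2, seed = 4, artifactRate = 0)
  sim <- simulateEEG(0, "Other", spec, 20, seed = 10, supprTarget = 0)
  expect_length(sim$groundTruth$artifactIdx, 0)
  expect_length(sim$groundTruth$burstIdx, 0)
  expect_equal(sim$groundTruth$supprFraction, 0)
  expect_equal(sim$groundTruth$longestRun, 0)
})

test_that("planted suppression hits its target fraction", {
  spec <- cohortSpec(nPatients = 2, seed = 4, artifactRate = 0)
  sim <- simulateEEG(0, "Propofol", spec, 25, seed = 12, supprTarget = 0.3)
  expect_equal(sim$groundTruth$supprFraction, 0.3, tolerance = 0.002)
  sim2 <- simulateEEG(0, "Propofol", spec, 25, seed = 13,
                      supprTarget = 0.3, longestRun = 42)
  expect_equal(sim2$groundTruth$longestRun, 42, tolerance = 0.02)
})

test_that("alpha-band power scales by the configured POD ratio", {
  # paired design: same seed, label flipped, no suppression effect -- the
  # only difference is the alpha amplitude scaling
  spec <- cohortSpec(nPatients = 2, seed = 4, alphaPowerRatioPod = 0.6,
                     bsrShiftPod = 0, artifactRate = 0)
  ratios <- vapply(1:6, function(s) {
    r0 <- simulateEEG(0, "Propofol", spec, 20, seed = 700 + s,
                      supprTarget = 0)$recording
    r1 <- simulateEEG(1, "Propofol", spec, 20, seed = 700 + s,
                      supprTarget = 0)$recording
    alphaPower <- function(r) {
      w <- welchPsd(r@signal, r@samplingRate)
      sum(w$psd[w$freq >= 8 & w$freq <= 12])
    }
    alphaPower(r1) / alphaPower(r0)
  }, numeric(1))
  # measured in-band ratio sits slightly above the pure oscillation ratio
  # because the 1/f background contributes equally to both classes
  expect_equal(mean(ratios), 0.6, tolerance = 0.1)
})

test_that("agent mix and invalid specs are validated", {
  expect_error(cohortSpec(agentMix = c(Propofol = 1)), "configuration error")
  expect_error(cohortSpec(podPrevalence = 0), "odPrevalence")
  expect_error(cohortSpec(durationRange = c(10, 30)), "20 minutes")
  expect_error(simulateEEG(0, "Xenon", cohortSpec(nPatients = 2), 20, 1),
               "unsupported")
})

test_that("written cohorts round-trip through the plain-text format", {
  spec <- cohortSpec(nPatients = 2, seed = 15, durationRange = c(20, 20.2))
  patients <- simulateCohort(spec)
  dir <- withr::local_tempdir()
  writeCohort(patients, dir)
  expect_true(file.exists(file.path(dir, "clinical.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
  rec <- readEEG(file.path(dir, "P0001.csv"))
  expect_equal(rec@signal, patients[[1]]$recording@signal,
               tolerance = 1e-6)
  clin <- readClinicalTable(file.path(dir, "clinical.tsv"))
  expect_equal(nrow(clin), 2)
})
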