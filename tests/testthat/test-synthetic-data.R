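small_coop_cfg <- function(seed = 1, ...) {
  cohortConfig("coop", 2, coop_tv(),
               sessionsToCriterionMean = 12, sessionsToCriterionSD = 2,
               stableSessions = 10, seed = seed, ...)
}

test_that("a subject's history has the configured phase structure", {
  cfg <- small_coop_cfg(seed = 5, nReversalSubjects = 1)
  logs <- generateSubject(cfg, 1)
  phases <- vapply(logs, sessionPhase, character(1))
  r <- rle(phases)
  expect_equal(r$values,
               c("acquisition", "stable", "reversal", "reversal_stable"))
  expect_equal(r$lengths[2], 10)
  expect_equal(r$lengths[4], 10)
  expect_gte(r$lengths[1], 5)   # truncated horizon draw
  expect_equal(vapply(logs, function(s) s@sessionIndex, integer(1)),
               seq_along(logs))
  expect_true(all(vapply(logs, nTrials, integer(1)) == 30))
  # subject 2 has no reversal arm
  expect_false("reversal" %in%
                 vapply(generateSubject(cfg, 2), sessionPhase, character(1)))
})

test_that("generation is deterministic per (seed, subject)", {
  cfg <- small_coop_cfg(seed = 9)
  a <- generateSubject(cfg, 1)
  b <- generateSubject(cfg, 1)
  expect_identical(lapply(a, trials), lapply(b, trials))
  c2 <- generateSubject(small_coop_cfg(seed = 10), 1)
  expect_false(identical(lapply(a, trials), lapply(c2, trials)))
})

test_that("cooperative targets reach stable cooperation near the chain prediction", {
  pred <- predictedCooperation(coop_tv())
  nSeeds <- 30L
  ok <- 0L
  reachedCriterion <- 0L
  for (seed in seq_len(nSeeds)) {
    cfg <- small_coop_cfg(seed = 1000 + seed)
    logs <- generateSubject(cfg, 1)
    stable <- logs[vapply(logs, sessionPhase, character(1)) == "stable"]
    rate <- summarizeSessions(stable)@cooperationRate  # 300 stable trials
    if (abs(rate - pred) < 0.05) ok <- ok + 1L
    rates <- vapply(logs, cooperationRate, numeric(1))
    if (classifyCooperator(rates)$cooperator)
      reachedCriterion <- reachedCriterion + 1L
  }
  expect_gte(ok / nSeeds, 0.9)
  expect_gte(reachedCriterion / nSeeds, 0.9)
})

test_that("chance-level and non-cooperative targets fail the criterion", {
  chance <- transitionVector()  # all 0.5
  failures <- 0L
  nSeeds <- 20L
  for (seed in seq_len(nSeeds)) {
    cfg <- cohortConfig("chance", 1, chance, startTV = chance,
                        sessionsToCriterionMean = 20,
                        sessionsToCriterionSD = 3, stableSessions = 15,
                        seed = 2000 + seed)
    logs <- generateSubject(cfg, 1)
    rates <- vapply(logs, cooperationRate, numeric(1))
    if (!classifyCooperator(rates)$cooperator) failures <- failures + 1L
  }
  expect_gte(failures / nSeeds, 0.9)

  # the non-cooperative vector is stationary from the start and stays
  # well under the criterion (predicted cooperation ~ 0.36)
  cfg <- cohortConfig("no_coop", 1, noncoop_tv(), startTV = noncoop_tv(),
                      sessionsToCriterionMean = 20, sessionsToCriterionSD = 3,
                      stableSessions = 15, seed = 31)
  rates <- vapply(generateSubject(cfg, 1), cooperationRate, numeric(1))
  expect_false(classifyCooperator(rates)$cooperator)
})

test_that("start == target yields a stationary history", {
  cfg <- cohortConfig("flat", 1, coop_tv(), startTV = coop_tv(),
                      sessionsToCriterionMean = 10, sessionsToCriterionSD = 0,
                      stableSessions = 10, seed = 4)
  logs <- generateSubject(cfg, 1)
  # acquisition and stable sessions are draws from the same policy: pooled
  # rates of the two phases agree within sampling error
  phases <- vapply(logs, sessionPhase, character(1))
  rAcq <- summarizeSessions(logs[phases == "acquisition"])@cooperationRate
  rSta <- summarizeSessions(logs[phases == "stable"])@cooperationRate
  expect_lt(abs(rAcq - rSta), 0.1)
})

test_that("the default study plan assembles the two-experiment layout", {
  plan <- defaultStudyPlan(seed = 3, stableSessions = 5)
  expect_named(plan, c("treat1_coop", "treat1_no_coop", "treat2_A",
                       "treat2_B"))
  expect_equal(plan$treat1_coop$nSubjects, 8)
  expect_equal(plan$treat1_coop$nReversalSubjects, 4)
  expect_equal(plan$treat1_no_coop$nSubjects, 4)
  expect_equal(plan$treat2_A$nSubjects, 3)
  expect_equal(plan$treat2_A$switchMatrix@pT, 5)   # temptation raised
  expect_equal(plan$treat2_B$switchMatrix@pR, 2)   # cooperation reward raised

  bundle <- generateExperiment(plan)
  subj <- unique(vapply(bundle$sessions, subjectId, character(1)))
  expect_length(subj, 12 + 6)
  expect_length(bundle$manifest$subjects, 18)
  # switch arms carry the post-switch matrix label
  labs <- vapply(bundle$sessions, function(s) s@matrixLabel, character(1))
  phs <- vapply(bundle$sessions, sessionPhase, character(1))
  grp <- vapply(bundle$sessions, function(s) s@group, character(1))
  expect_true(all(labs[grp == "2A" & phs == "switch_stable"] ==
                    plan$treat2_A$switchMatrix@label))
})

test_that("experiment bundles replay byte-identically and round-trip to disk", {
  plan <- defaultStudyPlan(seed = 11, stableSessions = 5)
  plan <- plan["treat2_B"]  # small arm keeps the test quick
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeExperimentBundle(generateExperiment(plan), d1)
  writeExperimentBundle(generateExperiment(plan), d2)
  expect_identical(readLines(file.path(d1, "sessions.csv")),
                   readLines(file.path(d2, "sessions.csv")))
  back <- readSessionLogs(file.path(d1, "sessions.csv"))
  expect_gt(length(back), 0)
  expect_s4_class(back[[1]], "SessionLog")
})
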