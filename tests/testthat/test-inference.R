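test_that("summaries count rates, occupancy and conditional transitions", {
  m1 <- payoffMatrix()
  # 30 trials, 18 C -> rate 0.6
  acts <- c(rep("C", 18), rep("D", 12))
  s <- playSession(fixedSequenceAgent(acts), m1, nTrials = 30)
  expect_equal(summarizeSessions(s)@cooperationRate, 0.6)

  # ALLC vs TFT: all R, p(c|R) = 1, other components undefined
  allc <- playSession(allcAgent(), m1, nTrials = 30)
  sm <- summarizeSessions(allc)
  expect_equal(unname(sm@occupancy["R"]), 1)
  expect_equal(unname(sm@tvEstimate["R"]), 1)
  expect_true(all(is.na(sm@tvEstimate[c("T", "S", "P")])))
  expect_equal(unname(sm@counts["R", "n_given"]), 29)
  expect_error(estimatedTV(sm), "undefined")

  # no pairing across session boundaries: two 1-trial sessions give no pairs
  one <- playSession(allcAgent(), m1, nTrials = 1)
  sm2 <- summarizeSessions(list(one, one))
  expect_true(all(sm2@counts[, "n_given"] == 0))
})

test_that("long memory-one logs recover the generating vector", {
  tv <- transitionVector(0.76, 0.85, 0.93, 0.87)
  s <- playSession(memoryOneAgent(tv), payoffMatrix(), nTrials = 10000,
                   seed = 314)
  est <- summarizeSessions(s)@tvEstimate
  expect_lt(max(abs(est - tvComponents(tv))), 0.05)
})

test_that("round trip: estimates recover random memory-one vectors", {
  set.seed(88)
  for (rep in 1:10) {
    comps <- runif(4, 0.25, 0.75)
    tv <- transitionVector(comps[1], comps[2], comps[3], comps[4])
    seed <- sample.int(10000, 1)
    s <- playSession(memoryOneAgent(tv), payoffMatrix(), nTrials = 20000,
                     seed = seed)
    est <- summarizeSessions(s)@tvEstimate
    expect_lt(max(abs(est - tvComponents(tv))), 0.05)
    set.seed(88 + rep)  # playSession reseeded the stream; restore variety
  }
})

test_that("chain construction matches the TFT coupling and frozen solves", {
  ch <- buildChain(coop_tv())
  M <- ch@transitionMatrix
  expect_equal(unname(M["R", c("R", "T")]), c(0.85, 0.15))
  expect_equal(unname(M["S", c("R", "T")]), c(0.93, 0.07))
  expect_equal(unname(M["T", c("S", "P")]), c(0.76, 0.24))
  expect_equal(unname(M["P", c("S", "P")]), c(0.87, 0.13))
  expect_equal(sum(M[c("R", "S"), c("S", "P")]), 0)  # structural zeros

  # frozen closed-form stationary (flow-balance algebra, independent route)
  pi <- stationaryDistribution(ch)
  expect_equal(unname(pi),
               c(0.7314890155, 0.1179820993, 0.1179820993, 0.0325467860),
               tolerance = 1e-9)
  # exact inflow/outflow symmetry of the TFT-coupled chain
  expect_lt(abs(pi[["T"]] - pi[["S"]]), 1e-12)
})

test_that("stationary linear solve agrees with the power-iteration oracle", {
  set.seed(5)
  for (i in 1:25) {
    comps <- runif(4, 0.05, 0.95)
    tv <- transitionVector(comps[1], comps[2], comps[3], comps[4])
    pi <- stationaryDistribution(buildChain(tv))
    expect_equal(pi, power_stationary(tv), tolerance = 1e-9)
    expect_lt(abs(pi[["T"]] - pi[["S"]]), 1e-12)
  }
})

test_that("predicted cooperation matches reported group means", {
  ref <- referenceStrategies()
  # the five homogeneous groups agree within 0.05; the two B arms are small
  # (n = 3) and heterogeneous (sem up to 0.13), so only a 2-sem agreement is
  # claimed for them
  for (g in ref$group) {
    r <- ref[ref$group == g, ]
    pred <- predictedCooperation(
      transitionVector(r$pc_T, r$pc_R, r$pc_S, r$pc_P))
    tol <- if (g %in% c("2B", "3B")) 2 * r$cooperation_sem else 0.05
    expect_lt(abs(pred - r$cooperation), tol, label = g)
  }
  # and pi_R of the cooperative chain vs its reported occupancy
  piR <- stationaryDistribution(buildChain(coop_tv()))[["R"]]
  expect_lt(abs(piR - 0.76), 0.05)
})

test_that("predicted cooperation is monotone in every component", {
  grid <- seq(0.1, 0.9, by = 0.2)
  base <- c(0.5, 0.5, 0.5, 0.5)
  for (j in 1:4) {
    vals <- vapply(grid, function(v) {
      comps <- base
      comps[j] <- v
      predictedCooperation(
        transitionVector(comps[1], comps[2], comps[3], comps[4]))
    }, numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("degenerate vectors give reducible chains with a flagged closed class", {
  expect_warning(ch1 <- buildChain(transitionVector(1, 1, 1, 1)),
                 "reducible")
  expect_true(ch1@reducible)
  expect_equal(ch1@closedStates, "R")
  expect_equal(unname(ch1@stationary), c(1, 0, 0, 0))

  expect_warning(ch0 <- buildChain(transitionVector(0, 0, 0, 0)),
                 "reducible")
  expect_equal(ch0@closedStates, "P")
  expect_equal(suppressWarnings(
    predictedCooperation(transitionVector(0, 0, 0, 0))), 0)
  # irreducible chains are not flagged
  expect_silent(ch <- buildChain(coop_tv()))
  expect_false(ch@reducible)
})

test_that("cooperation criterion is >60% for >=5 consecutive sessions", {
  res <- classifyCooperator(c(0.5, 0.7, 0.7, 0.7, 0.7, 0.7))
  expect_true(res$cooperator)
  expect_equal(res$criterionSession, 2L)  # 1-based: the second session
  # strict inequality at the threshold
  expect_false(classifyCooperator(rep(0.6, 10))$cooperator)
  # run too short
  expect_false(classifyCooperator(rep(0.9, 4))$cooperator)
  # run at the exact required length qualifies
  expect_true(classifyCooperator(c(0.2, rep(0.61, 5)))$cooperator)
  # custom criterion
  expect_true(classifyCooperator(rep(0.75, 3), threshold = 0.7,
                                 consecutiveSessions = 3)$cooperator)
})
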