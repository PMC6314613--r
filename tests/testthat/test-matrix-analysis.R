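test_that("contrast index evaluates the exact fraction and is scale-invariant", {
  expect_equal(contrastIndex(payoffMatrix(1, 2, 4, 8)), 1 / 3)
  expect_equal(contrastIndex(payoffMatrix(1, 3, 4, 8)), 1 / 2)
  expect_equal(contrastIndex(payoffMatrix(1, 5, 4, 8)), 2 / 3)
  expect_equal(contrastIndex(payoffMatrix(2, 3, 4, 8)), 1 / 5)
  for (k in c(2, 3, 10))
    expect_equal(contrastIndex(payoffMatrix(2 * k, 3 * k, 4, 8)),
                 contrastIndex(payoffMatrix(2, 3, 4, 8)))
})

test_that("cooperation-favoring condition 2pR > pT + pS", {
  expect_false(favorsCooperation(payoffMatrix(1, 2, 4, 8)))  # boundary 2 = 2
  expect_true(favorsCooperation(payoffMatrix(1, 2, 4, 8),
                                suckerPelletEquivalent = -0.5))
  expect_true(favorsCooperation(payoffMatrix(2, 3, 4, 8)))   # 4 > 3
  expect_false(favorsCooperation(payoffMatrix(1, 5, 4, 8)))  # 2 > 5 fails
  expect_error(favorsCooperation(payoffMatrix(), suckerPelletEquivalent = 1),
               "non-positive")
  # all-pellet matrices use their own sucker payoff: 8 > 6 + 0
  expect_true(favorsCooperation(payoffMatrix(4, 6, 1, 0, allPellet = TRUE)))
})

test_that("strategy evaluation matches the published economics", {
  tm <- timingModel()
  ev1 <- evaluateStrategies(payoffMatrix(1, 2, 4, 8), tm, 1000)
  allc <- ev1[ev1$strategy_id == "ALLC", ]
  alt <- ev1[ev1$strategy_id == "alternator", ]
  expect_equal(allc$cycle_pellets_per_trial, 1)
  expect_equal(allc$cycle_timeout_s_per_trial, 0)
  expect_equal(alt$cycle_pellets_per_trial, 1)
  expect_equal(alt$cycle_timeout_s_per_trial, 4)
  # equal asymptotic pellet rates, but ALLC earns more food per unit time
  expect_gt(allc$pellets_per_second, alt$pellets_per_second)
  # on cycle economics ALLC dominates the alternator outright
  expect_true(allc$is_pareto_cycle)
  expect_false(alt$is_pareto_cycle)
  # and (1, 0) is the unique maximal cycle profile
  best <- ev1[ev1$is_pareto_cycle, ]
  expect_true(all(best$cycle_pellets_per_trial == 1 &
                    best$cycle_timeout_s_per_trial == 0))

  # greater-temptation matrices make alternation out-earn ALLC in pellets
  ev3 <- evaluateStrategies(payoffMatrix(1, 3, 4, 8), tm, 1000)
  expect_equal(ev3$cycle_pellets_per_trial[ev3$strategy_id == "alternator"],
               1.5)
  ev5 <- evaluateStrategies(payoffMatrix(1, 5, 4, 8), tm, 1000)
  expect_equal(ev5$cycle_pellets_per_trial[ev5$strategy_id == "alternator"],
               2.5)
})

test_that("alternator-vs-ALLC pellet ordering flips exactly at pT = 2 pR", {
  tm <- timingModel()
  cases <- list(c(1, 2, "eq"), c(1, 3, "alt"), c(1, 5, "alt"), c(2, 3, "allc"),
                c(3, 7, "alt"), c(4, 7, "allc"), c(2, 4, "eq"))
  for (cs in cases) {
    m <- payoffMatrix(as.numeric(cs[1]), as.numeric(cs[2]), 4, 8)
    ev <- evaluateStrategies(m, tm, 100)
    altRate <- ev$cycle_pellets_per_trial[ev$strategy_id == "alternator"]
    allcRate <- ev$cycle_pellets_per_trial[ev$strategy_id == "ALLC"]
    expected <- switch(cs[3], eq = 0, alt = 1, allc = -1)
    expect_equal(sign(altRate - allcRate), expected,
                 label = sprintf("matrix (%s, %s)", cs[1], cs[2]))
  }
})

test_that("cycle-detection totals equal brute-force simulation exactly", {
  tm <- timingModel()
  m <- payoffMatrix(1, 3, 4, 8)
  ev <- evaluateStrategies(m, tm, 1000)
  for (f in c("C", "D")) {
    for (i in c(0, 5, 9, 15)) {
      bits <- as.integer(intToBits(i))[1:4]
      rule <- stats::setNames(ifelse(bits == 1L, "C", "D"),
                              c("R", "T", "S", "P"))
      id <- sprintf("M1-%s-%s", f, paste(rule, collapse = ""))
      bf <- brute_deterministic(f, rule, m, tm, 1000)
      row <- ev[ev$strategy_id == id, ]
      expect_equal(row$pellets, bf$pellets, label = id)
      expect_equal(row$timeout_s, bf$timeout, label = id)
      expect_equal(row$pellets_per_second, bf$pellets / bf$duration,
                   label = id)
    }
  }
})

test_that("adding timeout lowers pellets per second for a fixed pellet stream", {
  tm <- timingModel()
  for (pS in c(8, 12, 20)) {
    ev <- evaluateStrategies(payoffMatrix(1, 3, 4, pS), tm, 200)
    alt <- ev[ev$strategy_id == "alternator", ]
    if (pS == 8) base <- alt$pellets_per_second
    expect_lte(alt$pellets_per_second, base)
  }
})

test_that("normalized reward is the quotient against the best strategy", {
  m1 <- payoffMatrix()
  tm <- timingModel()
  # all-R session under a matrix that strictly favors cooperation
  mC <- payoffMatrix(2, 3, 4, 8)
  sC <- playSession(allcAgent(), mC, tm, nTrials = 30)
  expect_equal(normalizedReward(sC, mC, tm)$value, 1)

  # ALLD vs TFT under matrix1: one T then all P -> 2 pellets; the best
  # strategy over 30 trials is the start-C alternator with 31 pellets
  sD <- playSession(alldAgent(), m1, tm, nTrials = 30)
  nr <- normalizedReward(sD, m1, tm)
  expect_equal(totalReward(sD), 2)
  expect_equal(nr$best_session_reward, 31)
  expect_equal(nr$value, 2 / 31)

  # normalization bound over assorted sessions
  for (seed in 1:5) {
    s <- playSession(bernoulliAgent(0.5), m1, tm, nTrials = 30, seed = seed)
    v <- normalizedReward(s, m1, tm)$value
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})
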