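#' Simulate a fixed-cooperation-level population
#'
#' The reward/timeout baseline: many simulated individuals, each a different
#' random arrangement of a session's C and D choices at a fixed cooperation
#' level, played against Tit-for-Tat under a payoff matrix. With
#' `mode = "exact"` (the default) every individual makes exactly
#' `round(cooperationLevel * nTrials)` cooperative choices in uniformly
#' random order; `mode = "bernoulli"` instead draws each choice i.i.d. with
#' that probability. Sequences are sampled with replacement — with 1e5
#' draws from the ~8.6e7 arrangements of 18 C's in 30 trials, occasional
#' duplicates are possible and harmless.
#'
#' @param nIndividuals number of simulated individuals (default 100000).
#' @param cooperationLevel fraction of cooperative choices (default 0.60).
#' @param nTrials session length (default 30).
#' @param matrix a [PayoffMatrix-class].
#' @param seed integer seed.
#' @param mode `"exact"` composition or `"bernoulli"` per-trial draws.
#' @return A data.frame with columns `individual_id`, `total_reward`
#'   (pellets), `total_timeout` (seconds).
#' @examples
#' pop <- simulatePopulation(500, 0.6, 30, payoffMatrix(), seed = 1)
#' colMeans(pop[, -1])
#' @export
simulatePopulation <- function(nIndividuals = 100000, cooperationLevel = 0.60,
                               nTrials = 30, matrix = payoffMatrix(),
                               seed = NULL, mode = c("exact", "bernoulli")) {
  mode <- match.arg(mode)
  stopifnot(is(matrix, "PayoffMatrix"), nIndividuals >= 2, nTrials >= 1,
            cooperationLevel >= 0, cooperationLevel <= 1)
  k <- round(cooperationLevel * nTrials)
  if (k < 0 || k > nTrials) stop("cooperation count out of range")
  if (!is.null(seed)) set.seed(as.integer(seed))

  ## action matrix: individuals x trials, TRUE = cooperate
  if (mode == "exact") {
    ## uniformly random permutation per row of exactly k C's
    acts <- vapply(seq_len(nIndividuals), function(i) {
      v <- logical(nTrials)
      v[sample.int(nTrials, k)] <- TRUE
      v
    }, logical(nTrials))
    acts <- t(acts)
  } else {
    acts <- matrix(stats::runif(nIndividuals * nTrials) < cooperationLevel,
                   nIndividuals, nTrials)
  }

  ## Tit-for-Tat opponent: cooperates on trial 1, then copies the subject
  opp <- cbind(TRUE, acts[, -nTrials, drop = FALSE])
  nR <- rowSums(acts & opp)
  nT <- rowSums(!acts & opp)
  nS <- rowSums(acts & !opp)
  nP <- rowSums(!acts & !opp)
  pay <- payoffFor(.STATES, matrix)
  rownames(pay) <- .STATES
  data.frame(
    individual_id = seq_len(nIndividuals),
    total_reward = nR * pay["R", "pellets"] + nT * pay["T", "pellets"] +
      nS * pay["S", "pellets"] + nP * pay["P", "pellets"],
    total_timeout = nS * pay["S", "timeout_s"] + nP * pay["P", "timeout_s"] +
      nR * pay["R", "timeout_s"] + nT * pay["T", "timeout_s"])
}

#' Fit the reward-versus-timeout separation line
#'
#' Ordinary least-squares fit of total session reward on total timeout over
#' a simulated population. Subjects whose sessions sit above this line earn
#' more reward for their timeout burden than the fixed-level population —
#' the separation used to tell cooperators from non-cooperators.
#'
#' @param points a data.frame with columns `total_reward` and
#'   `total_timeout` (as from [simulatePopulation()]).
#' @return A list with `slope` (pellets per second), `intercept` (pellets)
#'   and `fit_n`.
#' @examples
#' fitSeparationLine(data.frame(total_timeout = c(0, 2),
#'                              total_reward = c(10, 14)))  # slope 2
#' @export
fitSeparationLine <- function(points) {
  stopifnot(all(c("total_reward", "total_timeout") %in% names(points)),
            nrow(points) >= 2)
  if (length(unique(points$total_timeout)) < 2L)
    stop("degenerate fit: all timeout values are equal")
  fit <- stats::lm.fit(cbind(1, points$total_timeout),
                       points$total_reward)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       fit_n = nrow(points))
}

#' Classify a session relative to the separation line
#'
#' @param totalReward,totalTimeout a session's totals (pellets, seconds).
#' @param line a fit from [fitSeparationLine()].
#' @param tol tolerance for "on" (default 1e-9).
#' @return `"above"`, `"on"` or `"below"`.
#' @export
classifyRelativeToLine <- function(totalReward, totalTimeout, line,
                                   tol = 1e-9) {
  resid <- totalReward - (line$slope * totalTimeout + line$intercept)
  if (abs(resid) <= tol) "on" else if (resid > 0) "above" else "below"
}
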