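#' Contrast index of a payoff matrix
#'
#' The relative difference between the temptation and mutual-cooperation
#' rewards, `CI = (pT - pR) / (pT + pR)`. It lies in (0, 1) whenever
#' `pT > pR >= 0`, and measures how strongly a single defection out-pays a
#' cooperative trial: 1/3 for the (1, 2)-pellet matrix, 1/2 for (1, 3),
#' 2/3 for (1, 5), 1/5 for (2, 3).
#'
#' @param matrix a [PayoffMatrix-class].
#' @return The contrast index (dimensionless).
#' @examples
#' contrastIndex(payoffMatrix(pR = 1, pT = 2))  # 1/3
#' @export
contrastIndex <- function(matrix) {
  stopifnot(is(matrix, "PayoffMatrix"))
  if (matrix@pT + matrix@pR <= 0) stop("pT + pR must be positive")
  (matrix@pT - matrix@pR) / (matrix@pT + matrix@pR)
}

#' Does a payoff matrix favor cooperation?
#'
#' The cooperation-favoring condition of the iterated PD, `2 pR > pT + pS`,
#' evaluated with the sucker payoff expressed in pellet-equivalent units.
#' In mixed-reinforcement matrices the sucker outcome is a timeout, not a
#' pellet count; it enters as `suckerPelletEquivalent`, a non-positive
#' pellet value the analyst assigns to that timeout (default 0, which
#' places the standard (1, 2, 4 s, 8 s) matrix exactly on the
#' `2 pR = pT + pS` boundary; any strictly negative valuation tips it to
#' favoring cooperation). All-pellet matrices use their own `pS` directly.
#'
#' @param matrix a [PayoffMatrix-class].
#' @param suckerPelletEquivalent pellet value (<= 0) assigned to the sucker
#'   timeout; ignored for all-pellet matrices.
#' @return Logical.
#' @examples
#' favorsCooperation(payoffMatrix(2, 3, 4, 8))   # TRUE: 4 > 3
#' favorsCooperation(payoffMatrix(1, 2, 4, 8))   # FALSE: boundary 2 = 2
#' favorsCooperation(payoffMatrix(1, 2, 4, 8), suckerPelletEquivalent = -1)
#' @export
favorsCooperation <- function(matrix, suckerPelletEquivalent = 0) {
  stopifnot(is(matrix, "PayoffMatrix"))
  if (matrix@allPellet) {
    sVal <- matrix@pS
  } else {
    if (suckerPelletEquivalent > 0)
      stop("suckerPelletEquivalent must be non-positive (the sucker timeout is aversive)")
    sVal <- suckerPelletEquivalent
  }
  2 * matrix@pR > matrix@pT + sVal
}

## ---- deterministic memory-one strategy evaluation -----------------------

## A deterministic memory-one strategy is a first move plus an action for
## each previous outcome state.  Facing Tit-for-Tat the outcome state is a
## deterministic function of the previous one (the subject's last action is
## encoded in the state), so the orbit is eventually periodic with period
## <= 4 and can be evaluated exactly for any session length.

.next_state_map <- function(rule) {
  ## rule: named actions over c(R, T, S, P)
  prevOwn <- c(R = "C", T = "D", S = "C", P = "D")
  vapply(.STATES, function(s)
    classifyState(rule[[s]], tftNext(prevOwn[[s]])), character(1))
}

## Exact state-visit counts over nTrials via cycle detection on the orbit.
.orbit_counts <- function(firstMove, rule, nTrials) {
  g <- .next_state_map(rule)
  s <- classifyState(firstMove, "C")
  seen <- stats::setNames(rep(NA_integer_, 4), .STATES)
  orbit <- character(0)
  t <- 0L
  while (is.na(seen[[s]])) {
    seen[[s]] <- t
    orbit <- c(orbit, s)
    s <- g[[s]]
    t <- t + 1L
  }
  cycleStart <- seen[[s]]
  transient <- orbit[seq_len(cycleStart)]
  cycle <- orbit[(cycleStart + 1L):length(orbit)]
  counts <- stats::setNames(numeric(4), .STATES)
  nT <- min(length(transient), nTrials)
  for (st in transient[seq_len(nT)]) counts[st] <- counts[st] + 1
  rem <- nTrials - length(transient)
  if (rem > 0) {
    full <- rem %/% length(cycle)
    for (st in cycle) counts[st] <- counts[st] + full
    extra <- rem %% length(cycle)
    for (st in cycle[seq_len(extra)]) counts[st] <- counts[st] + 1
  }
  list(counts = counts, cycle = cycle, transient = transient)
}

.state_economics <- function(matrix, timing) {
  pay <- payoffFor(.STATES, matrix)
  dur <- .trial_duration(pay$pellets, pay$timeout_s, timing)
  data.frame(state = .STATES, pellets = pay$pellets,
             timeout_s = pay$timeout_s, duration_s = dur)
}

#' Evaluate the canonical strategy set against Tit-for-Tat
#'
#' Exact (cycle-detection) evaluation of the closed strategy set used for
#' best-strategy economics: ALLC, ALLD, the strict alternator, and all 32
#' deterministic memory-one strategies (an action for each previous outcome
#' state times the first move). For each strategy the session totals over
#' `nTrials` trials are reported together with per-trial and per-second
#' rates and the asymptotic (limit-cycle) rates; the Pareto set under
#' (maximize pellets/trial, minimize timeout/trial) is flagged.
#'
#' @param matrix a [PayoffMatrix-class].
#' @param timing a [TimingModel-class].
#' @param nTrials session length to evaluate (>= 2).
#' @return A data.frame with one row per strategy: `strategy_id`, `pellets`,
#'   `timeout_s`, `pellets_per_trial`, `timeout_s_per_trial`,
#'   `pellets_per_second`, `cycle_pellets_per_trial`,
#'   `cycle_timeout_s_per_trial`, `is_pareto_optimal` (finite-session
#'   rates), `is_pareto_cycle` (asymptotic rates).
#' @examples
#' ev <- evaluateStrategies(payoffMatrix(), timingModel(), 30)
#' ev[ev$strategy_id %in% c("ALLC", "ALLD", "alternator"), ]
#' @export
evaluateStrategies <- function(matrix, timing = timingModel(), nTrials = 30) {
  stopifnot(is(matrix, "PayoffMatrix"), is(timing, "TimingModel"),
            nTrials >= 2)
  eco <- .state_economics(matrix, timing)
  rownames(eco) <- eco$state

  evalOne <- function(id, firstMove, rule) {
    oc <- .orbit_counts(firstMove, rule, nTrials)
    cnt <- oc$counts
    pellets <- sum(cnt * eco$pellets)
    timeout <- sum(cnt * eco$timeout_s)
    duration <- sum(cnt * eco$duration_s)
    cyc <- oc$cycle
    cycPellets <- sum(eco[cyc, "pellets"]) / length(cyc)
    cycTimeout <- sum(eco[cyc, "timeout_s"]) / length(cyc)
    data.frame(strategy_id = id, pellets = pellets, timeout_s = timeout,
               pellets_per_trial = pellets / nTrials,
               timeout_s_per_trial = timeout / nTrials,
               pellets_per_second = pellets / duration,
               cycle_pellets_per_trial = cycPellets,
               cycle_timeout_s_per_trial = cycTimeout,
               stringsAsFactors = FALSE)
  }

  rows <- list(
    evalOne("ALLC", "C", c(R = "C", T = "C", S = "C", P = "C")),
    evalOne("ALLD", "D", c(R = "D", T = "D", S = "D", P = "D")),
    ## own-action alternation: defect after own C (states R, S), cooperate
    ## after own D (states T, P)
    evalOne("alternator", "C", c(R = "D", T = "C", S = "D", P = "C")))
  for (f in .ACTIONS) {
    for (i in 0:15) {
      bits <- as.integer(intToBits(i))[1:4]
      rule <- stats::setNames(ifelse(bits == 1L, "C", "D"), .STATES)
      id <- sprintf("M1-%s-%s", f, paste(rule, collapse = ""))
      rows[[length(rows) + 1L]] <- evalOne(id, f, rule)
    }
  }
  out <- do.call(rbind, rows)

  ## Pareto set under (pellets/trial up, timeout/trial down); the session
  ## flag uses finite-session rates, the cycle flag the asymptotic rates
  ## (limit-cycle economics, transient-free)
  pareto <- function(pel, tmo) vapply(seq_along(pel), function(i) {
    dom <- pel >= pel[i] & tmo <= tmo[i] & (pel > pel[i] | tmo < tmo[i])
    !any(dom)
  }, logical(1))
  out$is_pareto_optimal <- pareto(out$pellets_per_trial,
                                  out$timeout_s_per_trial)
  out$is_pareto_cycle <- pareto(out$cycle_pellets_per_trial,
                                out$cycle_timeout_s_per_trial)
  out
}

#' Normalized session reward
#'
#' The quotient between the pellets obtained in a session and the maximum
#' pellets achievable over the same number of trials by the best strategy in
#' the evaluated set (see [evaluateStrategies()]); the best strategy is
#' chosen by the per-session pellet objective. Under a cooperation-favoring
#' matrix the best strategy is ALLC; with a large enough temptation payoff
#' it is alternation.
#'
#' @param session a [SessionLog-class].
#' @param matrix the [PayoffMatrix-class] the session was played under.
#' @param timing a [TimingModel-class].
#' @return A list with `value` (in \[0, 1\]), `best_strategy_id` and
#'   `best_session_reward`.
#' @export
normalizedReward <- function(session, matrix, timing = timingModel()) {
  stopifnot(is(session, "SessionLog"))
  ev <- evaluateStrategies(matrix, timing, nTrials(session))
  best <- which.max(ev$pellets)
  if (ev$pellets[best] <= 0) stop("no strategy earns pellets under this matrix")
  list(value = totalReward(session) / ev$pellets[best],
       best_strategy_id = ev$strategy_id[best],
       best_session_reward = ev$pellets[best])
}
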