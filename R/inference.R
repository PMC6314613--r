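#' Summarize strategy statistics over a pool of sessions
#'
#' Pools the trials of one or more sessions (typically the last five stable
#' sessions of a subject, or a whole group) and computes the cooperation
#' rate, the outcome-state occupancy, and the memory-one transition-vector
#' estimate with its conditional counts. Transition estimation uses only
#' within-session (previous state, current action) pairs — trial one of each
#' session has no previous state and contributes no pair — and components
#' whose conditioning state was never visited are `NA`.
#'
#' @param sessions a [SessionLog-class] or a list of them.
#' @return A [StrategySummary-class].
#' @examples
#' s <- playSession(allcAgent(), payoffMatrix(), nTrials = 30)
#' summarizeSessions(s)  # all-R occupancy, p(c|R) = 1, others NA
#' @export
summarizeSessions <- function(sessions) {
  if (is(sessions, "SessionLog")) sessions <- list(sessions)
  if (!length(sessions) || !all(vapply(sessions, is, logical(1), "SessionLog")))
    stop("sessions must be one or more SessionLog objects")
  trs <- lapply(sessions, trials)
  n <- sum(vapply(trs, nrow, integer(1)))
  if (n == 0L) stop("no trials to summarize")

  allActions <- unlist(lapply(trs, `[[`, "subject_action"))
  allStates <- unlist(lapply(trs, `[[`, "state"))
  occ <- vapply(.STATES, function(s) sum(allStates == s), numeric(1)) / n

  ## conditional counts: previous state -> cooperate now, within session only
  estOrder <- c("T", "R", "S", "P")
  nGiven <- stats::setNames(numeric(4), estOrder)
  nCoop <- stats::setNames(numeric(4), estOrder)
  for (tr in trs) {
    if (nrow(tr) < 2L) next
    prev <- tr$state[-nrow(tr)]
    act <- tr$subject_action[-1L]
    for (s in estOrder) {
      sel <- prev == s
      nGiven[s] <- nGiven[s] + sum(sel)
      nCoop[s] <- nCoop[s] + sum(act[sel] == "C")
    }
  }
  est <- ifelse(nGiven > 0, nCoop / nGiven, NA_real_)
  counts <- cbind(n_given = nGiven, n_coop_after = nCoop)

  new("StrategySummary",
      cooperationRate = mean(allActions == "C"),
      occupancy = occ, nTrials = as.integer(n),
      tvEstimate = stats::setNames(est, estOrder), counts = counts,
      sessionsUsed = length(sessions))
}

#' Estimated transition vector of a summary
#'
#' @param summary a [StrategySummary-class] with all four components defined.
#' @param firstMovePC first-move probability to attach (default 0.5; the
#'   estimate itself carries no first-move information).
#' @return A [TransitionVector-class].
#' @export
estimatedTV <- function(summary, firstMovePC = 0.5) {
  stopifnot(is(summary, "StrategySummary"))
  est <- summary@tvEstimate
  if (anyNA(est))
    stop("undefined components (states never visited): ",
         paste(names(est)[is.na(est)], collapse = ", "))
  transitionVector(est[["T"]], est[["R"]], est[["S"]], est[["P"]],
                   firstMovePC = firstMovePC)
}

## Row-stochastic transition matrix over (R, T, S, P) induced by a
## memory-one strategy facing Tit-for-Tat.  After R or S the subject's last
## action was C, so the opponent cooperates next: the next state is R (if
## the subject cooperates) or T.  After T or P the opponent defects next:
## the next state is S or P.
.chain_matrix <- function(tv) {
  a <- tv@pcT; b <- tv@pcR; c_ <- tv@pcS; d <- tv@pcP
  M <- rbind(R = c(b, 1 - b, 0, 0),
             T = c(0, 0, a, 1 - a),
             S = c(c_, 1 - c_, 0, 0),
             P = c(0, 0, d, 1 - d))
  colnames(M) <- .STATES
  M
}

## Communicating-class decomposition of a small chain; returns the recurrent
## closed class reachable from `from` (unique for this chain topology).
.closed_class_from <- function(M, from = "R") {
  A <- (M > 0) | diag(4) > 0
  reach <- A
  for (i in 1:3) reach <- (reach %*% A) > 0 | reach
  comm <- reach & t(reach)
  isClosed <- vapply(seq_len(4), function(i) {
    cls <- which(comm[i, ])
    sum(M[cls, setdiff(seq_len(4), cls), drop = FALSE]) == 0
  }, logical(1))
  reachable <- which(reach[match(from, .STATES), ])
  candidates <- intersect(reachable, which(isClosed))
  if (!length(candidates))
    stop("no closed class reachable from ", from)  # cannot happen: finite chain
  cls <- which(comm[candidates[1L], ])
  .STATES[sort(cls)]
}

## Stationary distribution restricted to a closed class: replace one balance
## equation with the normalization constraint and solve the linear system.
.stationary_on <- function(M, states) {
  idx <- match(states, .STATES)
  Q <- M[idx, idx, drop = FALSE]
  k <- length(idx)
  A <- t(Q) - diag(k)
  A[k, ] <- 1
  b <- c(rep(0, k - 1L), 1)
  piSub <- solve(A, b)
  pi <- stats::setNames(numeric(4), .STATES)
  pi[idx] <- piSub
  pi
}

#' Build the Tit-for-Tat-coupled Markov chain of a memory-one strategy
#'
#' A memory-one strategy facing Tit-for-Tat induces a Markov chain on the
#' four outcome states, in the canonical order (R, T, S, P): from R the
#' chain moves to R with probability p(c|R), else to T; from S to R with
#' p(c|S), else T; from T to S with p(c|T), else P; from P to S with
#' p(c|P), else P. The stationary distribution is obtained by solving the
#' balance equations with the normalization constraint.
#'
#' Degenerate vectors (components 0 or 1) can make the chain reducible; the
#' stationary distribution then refers to the closed class reachable from R
#' — the experiment always starts with a cooperating opponent — and the
#' model is flagged `reducible` with a warning.
#'
#' @param tv a [TransitionVector-class]; all four components must be defined.
#' @return A [ChainModel-class].
#' @examples
#' ch <- buildChain(transitionVector(0.76, 0.85, 0.93, 0.87))
#' stationaryDistribution(ch)  # pi_R approx 0.73
#' @export
buildChain <- function(tv) {
  stopifnot(is(tv, "TransitionVector"))
  if (anyNA(tvComponents(tv)))
    stop("all transition-vector components must be defined")
  M <- .chain_matrix(tv)
  closed <- .closed_class_from(M, "R")
  reducible <- length(closed) < 4L
  if (reducible)
    warning("reducible chain; stationary distribution refers to the closed class {",
            paste(closed, collapse = ", "), "} reachable from R",
            call. = FALSE)
  pi <- .stationary_on(M, closed)
  new("ChainModel", tv = tv, transitionMatrix = M, stationary = pi,
      reducible = reducible, closedStates = closed)
}

#' Stationary distribution of a chain model
#' @param chain a [ChainModel-class].
#' @return Named numeric over (R, T, S, P).
#' @export
stationaryDistribution <- function(chain) {
  stopifnot(is(chain, "ChainModel"))
  chain@stationary
}

#' Long-run cooperation probability of a memory-one strategy
#'
#' The stationary probability that the subject's action is C when facing
#' Tit-for-Tat: the subject cooperated on the current trial exactly in
#' states R and S, so this is `pi_R + pi_S` of the induced chain. This is
#' the model-implied counterpart of the empirical cooperation rate, and the
#' quantity that links a group's transition vector to its reported
#' cooperation mean.
#'
#' @param tv a [TransitionVector-class] or a prebuilt [ChainModel-class].
#' @return A probability.
#' @examples
#' predictedCooperation(transitionVector(0.76, 0.85, 0.93, 0.87))  # ~0.849
#' @export
predictedCooperation <- function(tv) {
  chain <- if (is(tv, "ChainModel")) tv else buildChain(tv)
  unname(chain@stationary[["R"]] + chain@stationary[["S"]])
}

#' Simulate long-run state occupancy of memory-one chains
#'
#' Monte-Carlo counterpart of the analytic stationary distribution: runs the
#' Tit-for-Tat-coupled chain forward and tallies state visits. Several
#' chains (one per transition vector) are advanced in lock-step, so the
#' per-step work is vectorized across vectors. Used as an independent check
#' on the linear-solve stationary distribution.
#'
#' @param tvs a [TransitionVector-class] or a list of them.
#' @param nSteps steps per chain (default 1e6).
#' @param seed integer seed.
#' @param burnIn initial steps discarded from the tally (default 1000).
#' @return A matrix with one row per vector and columns (R, T, S, P) of
#'   visit frequencies.
#' @export
simulateChainOccupancy <- function(tvs, nSteps = 1e6, seed = NULL,
                                   burnIn = 1000) {
  if (is(tvs, "TransitionVector")) tvs <- list(tvs)
  stopifnot(all(vapply(tvs, is, logical(1), "TransitionVector")),
            nSteps > burnIn)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nC <- length(tvs)
  ## cooperation probability by current state (R, T, S, P), one row per chain
  pc <- do.call(rbind, lapply(tvs, function(tv)
    c(tv@pcR, tv@pcT, tv@pcS, tv@pcP)))
  pcVec <- as.vector(pc)  # column-major: (state-1)*nC + chain
  chainIdx <- seq_len(nC)
  state <- rep(1L, nC)  # start in R: the opponent opens cooperating
  counts <- matrix(0, nC, 4L)
  for (step in seq_len(nSteps)) {
    p <- pcVec[(state - 1L) * nC + chainIdx]
    coop <- stats::runif(nC) < p
    ## from R/S (states 1, 3) the opponent cooperates next: R or T;
    ## from T/P (states 2, 4): S or P
    fromC <- state == 1L | state == 3L
    state <- ifelse(fromC, ifelse(coop, 1L, 2L), ifelse(coop, 3L, 4L))
    if (step > burnIn)
      counts[(state - 1L) * nC + chainIdx] <-
        counts[(state - 1L) * nC + chainIdx] + 1
  }
  occ <- counts / (nSteps - burnIn)
  colnames(occ) <- .STATES
  occ
}

#' Cooperation criterion over a sequence of sessions
#'
#' The learning criterion of the protocol: cooperation in more than
#' `threshold` (strictly) of the trials for at least `consecutiveSessions`
#' consecutive sessions. Defaults encode ">60% for >= 5 consecutive
#' sessions".
#'
#' @param perSessionRates numeric vector of per-session cooperation rates,
#'   in session order.
#' @param threshold strict lower bound on the rate (default 0.6).
#' @param consecutiveSessions required run length (default 5).
#' @return A list with `cooperator` (logical) and `criterionSession`, the
#'   1-based index of the first session of the first qualifying run (`NA`
#'   when the criterion is never met).
#' @examples
#' classifyCooperator(c(0.5, 0.7, 0.7, 0.7, 0.7, 0.7))  # TRUE, session 2
#' @export
classifyCooperator <- function(perSessionRates, threshold = 0.6,
                               consecutiveSessions = 5) {
  stopifnot(length(perSessionRates) >= 1L, threshold > 0, threshold < 1,
            consecutiveSessions >= 1)
  above <- perSessionRates > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= consecutiveSessions)
  if (length(hit))
    list(cooperator = TRUE, criterionSession = starts[hit[1L]])
  else
    list(cooperator = FALSE, criterionSession = NA_integer_)
}

#' Reference cohort summaries
#'
#' The group-level summaries this package uses as generator targets and
#' chain-consistency anchors: for each treatment group, the payoff matrix it
#' was trained on, the group-mean cooperation rate (with its s.e.m.), the
#' empirical outcome-state occupancy, and the group transition vector.
#' Treatment 1 is the standard mixed-reinforcement matrix (1, 2 pellets;
#' 4 s, 8 s) with cooperative, non-cooperative and reversal groups;
#' treatments 2 and 3 are the matrix-manipulation arms (temptation raised to
#' 3 then 5 pellets for arm A; mutual-cooperation reward raised to 2 pellets
#' for arm B).
#'
#' @return A data.frame with columns `treat`, `group`, `pR`, `pT`, `pP`,
#'   `pS`, `cooperation`, `cooperation_sem`, `occ_T`, `occ_R`, `occ_S`,
#'   `occ_P`, `pc_T`, `pc_R`, `pc_S`, `pc_P`.
#' @examples
#' ref <- referenceStrategies()
#' tv <- with(ref[ref$group == "coop", ],
#'            transitionVector(pc_T, pc_R, pc_S, pc_P))
#' predictedCooperation(tv)
#' @export
referenceStrategies <- function() {
  data.frame(
    treat = c("1", "1", "1", "2", "2", "3", "3"),
    group = c("coop", "no_coop", "reversal", "2A", "2B", "3A", "3B"),
    pR = c(1, 1, 1, 1, 1, 1, 2),
    pT = c(2, 2, 2, 3, 3, 5, 3),
    pP = c(4, 4, 4, 4, 4, 4, 4),
    pS = c(8, 8, 8, 8, 8, 8, 8),
    cooperation = c(0.86, 0.36, 0.87, 0.87, 0.64, 0.61, 0.71),
    cooperation_sem = c(0.05, 0.03, 0.04, 0.04, 0.13, 0.10, 0.04),
    occ_T = c(0.10, 0.25, 0.11, 0.09, 0.23, 0.18, 0.20),
    occ_R = c(0.76, 0.19, 0.77, 0.80, 0.34, 0.44, 0.51),
    occ_S = c(0.10, 0.23, 0.02, 0.03, 0.21, 0.21, 0.09),
    occ_P = c(0.04, 0.33, 0.10, 0.08, 0.22, 0.17, 0.20),
    pc_T = c(0.76, 0.44, 0.86, 0.65, 0.47, 0.45, 0.62),
    pc_R = c(0.85, 0.38, 0.89, 0.90, 0.55, 0.64, 0.66),
    pc_S = c(0.93, 0.32, 1.00, 0.87, 0.56, 0.62, 0.67),
    pc_P = c(0.87, 0.32, 0.82, 0.94, 0.65, 0.78, 0.66),
    stringsAsFactors = FALSE)
}
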