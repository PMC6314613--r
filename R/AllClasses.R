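#' @import methods
NULL

## Canonical outcome-state order used everywhere internally.  The four states
## of a Prisoner's Dilemma trial against an opponent: R = mutual cooperation,
## T = temptation (subject defects, opponent cooperates), S = sucker (subject
## cooperates, opponent defects), P = mutual defection.
.STATES <- c("R", "T", "S", "P")
.ACTIONS <- c("C", "D")

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && abs(x - round(x)) < 1e-9
.is_prob <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x <= 1
.is_nonneg <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0

#' PayoffMatrix: reinforcement magnitudes of the iterated PD
#'
#' Holds the four reinforcement magnitudes of the game. In the standard
#' (mixed-reinforcement) mode, mutual cooperation (R) and temptation (T) pay
#' pellets while mutual defection (P) and sucker (S) impose timeout seconds.
#' In all-pellet mode (`allPellet = TRUE`) all four entries are pellet counts
#' and no timeout is ever imposed; this is the textbook additive matrix
#' (e.g. T=6, R=4, P=1, S=0 pellets) used for reward-discrimination
#' arguments.
#'
#' @slot pR pellets for mutual cooperation (or pellets for state R in
#'   all-pellet mode).
#' @slot pT pellets for unilateral defection.
#' @slot pP timeout seconds for mutual defection (pellets in all-pellet mode).
#' @slot pS timeout seconds for unilateral cooperation (pellets in all-pellet
#'   mode).
#' @slot allPellet logical; if `TRUE` all four payoffs are pellets.
#' @slot label free-text label used in session logs.
#' @exportClass PayoffMatrix
setClass("PayoffMatrix",
  representation(pR = "numeric", pT = "numeric", pP = "numeric",
                 pS = "numeric", allPellet = "logical", label = "character"),
  validity = function(object) {
    msg <- character()
    if (!.is_count(object@pR) || !.is_count(object@pT))
      msg <- c(msg, "pR and pT must be non-negative integer pellet counts")
    if (!.is_nonneg(object@pP) || !.is_nonneg(object@pS))
      msg <- c(msg, "pP and pS must be non-negative")
    if (length(object@pT) == 1L && length(object@pR) == 1L &&
        !(object@pT > object@pR))
      msg <- c(msg, "temptation must exceed the mutual-cooperation reward (pT > pR)")
    if (isTRUE(object@allPellet)) {
      if (!.is_count(object@pP) || !.is_count(object@pS))
        msg <- c(msg, "in all-pellet mode pP and pS must be integer pellet counts")
    } else {
      if (length(object@pS) == 1L && length(object@pP) == 1L &&
          object@pS < object@pP)
        msg <- c(msg, "sucker timeout must be at least the mutual-defection timeout (pS >= pP)")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a payoff matrix
#'
#' Defaults are the first-experiment matrix: 1 pellet for mutual cooperation,
#' 2 pellets for unilateral defection, 4 s timeout for mutual defection, 8 s
#' timeout for unilateral cooperation.
#'
#' @param pR,pT pellet counts for the R and T states (`pT > pR` required).
#' @param pP,pS timeout seconds for the P and S states (`pS >= pP` required),
#'   or pellet counts when `allPellet = TRUE`.
#' @param allPellet if `TRUE`, all four payoffs are pellets and no timeout is
#'   imposed.
#' @param label free-text label recorded in session logs.
#' @return A [PayoffMatrix-class] object.
#' @examples
#' payoffMatrix()                      # 1, 2 pellets; 4 s, 8 s timeout
#' payoffMatrix(4, 6, 1, 0, allPellet = TRUE)  # textbook additive matrix
#' @export
payoffMatrix <- function(pR = 1, pT = 2, pP = 4, pS = 8,
                         allPellet = FALSE, label = NULL) {
  if (is.null(label)) {
    unit <- if (allPellet) "p" else "s"
    label <- sprintf("R%g-T%g-P%g%s-S%g%s", pR, pT, pP, unit, pS, unit)
  }
  new("PayoffMatrix", pR = as.numeric(pR), pT = as.numeric(pT),
      pP = as.numeric(pP), pS = as.numeric(pS),
      allPellet = isTRUE(allPellet), label = as.character(label))
}

#' TimingModel: trial event durations
#'
#' Durations of the within-trial events used to convert a session into time:
#' inter-trial interval, maximum conditioned-stimulus (response window)
#' duration, eating time, feeder-light lead time, response latency, and the
#' opponent's fixed-ratio requirement. The trial-duration bookkeeping is
#' `iti + latency + (eating + feeder light)` on rewarded trials and
#' `iti + latency + timeout` on punished ones.
#'
#' @slot itiS inter-trial interval, seconds.
#' @slot csMaxS response-window ceiling, seconds (never elapses here: agents
#'   always respond).
#' @slot eatingS eating time after pellet delivery, seconds.
#' @slot feederLightS feeder-light lead before delivery, seconds.
#' @slot responseLatencyS modeled response latency, seconds.
#' @slot opponentFixedRatio lever presses the opponent needs per pellet.
#' @exportClass TimingModel
setClass("TimingModel",
  representation(itiS = "numeric", csMaxS = "numeric", eatingS = "numeric",
                 feederLightS = "numeric", responseLatencyS = "numeric",
                 opponentFixedRatio = "numeric"),
  validity = function(object) {
    vals <- c(object@itiS, object@csMaxS, object@eatingS,
              object@feederLightS, object@responseLatencyS,
              object@opponentFixedRatio)
    if (any(!is.finite(vals)) || any(vals < 0))
      return("all timing components must be finite and non-negative")
    if (object@csMaxS <= 0) return("csMaxS must be positive")
    TRUE
  })

#' Construct a timing model
#'
#' @param itiS,csMaxS,eatingS,feederLightS,responseLatencyS durations in
#'   seconds; defaults follow the experimental protocol (5 s ITI, 45 s
#'   response window, 5 s eating, 1 s feeder light, zero latency).
#' @param opponentFixedRatio opponent lever presses per pellet (FR schedule).
#' @return A [TimingModel-class] object.
#' @export
timingModel <- function(itiS = 5, csMaxS = 45, eatingS = 5, feederLightS = 1,
                        responseLatencyS = 0, opponentFixedRatio = 3) {
  new("TimingModel", itiS = itiS, csMaxS = csMaxS, eatingS = eatingS,
      feederLightS = feederLightS, responseLatencyS = responseLatencyS,
      opponentFixedRatio = opponentFixedRatio)
}

#' TransitionVector: memory-one cooperation probabilities
#'
#' The four conditional probabilities of cooperating given the previous
#' trial's outcome state — p(c|T), p(c|R), p(c|S), p(c|P) — plus the
#' first-move cooperation probability (there is no previous state on trial
#' one). All components 0.5 is the "random mode" decision rule.
#'
#' @slot pcT,pcR,pcS,pcP probability of cooperating after a T / R / S / P
#'   outcome.
#' @slot firstMovePC probability of cooperating on the first trial.
#' @exportClass TransitionVector
setClass("TransitionVector",
  representation(pcT = "numeric", pcR = "numeric", pcS = "numeric",
                 pcP = "numeric", firstMovePC = "numeric"),
  validity = function(object) {
    comps <- c(object@pcT, object@pcR, object@pcS, object@pcP,
               object@firstMovePC)
    if (length(comps) != 5L || any(!vapply(comps, .is_prob, logical(1))))
      return("all components must be probabilities in [0, 1]")
    TRUE
  })

#' Construct a transition vector
#'
#' Components are given in the conventional reporting order p(c|T), p(c|R),
#' p(c|S), p(c|P).
#'
#' @param pcT,pcR,pcS,pcP cooperation probability after a T / R / S / P
#'   outcome, each in \[0, 1\].
#' @param firstMovePC cooperation probability on trial one (default 0.5).
#' @return A [TransitionVector-class] object.
#' @examples
#' transitionVector(0.76, 0.85, 0.93, 0.87)  # cooperative-group vector
#' @export
transitionVector <- function(pcT = 0.5, pcR = 0.5, pcS = 0.5, pcP = 0.5,
                             firstMovePC = 0.5) {
  new("TransitionVector", pcT = pcT, pcR = pcR, pcS = pcS, pcP = pcP,
      firstMovePC = firstMovePC)
}

#' Components of a transition vector as a named numeric
#'
#' @param tv a [TransitionVector-class].
#' @return Named numeric `c(T=, R=, S=, P=)` — cooperation probability after
#'   each outcome state.
#' @export
tvComponents <- function(tv) {
  stopifnot(is(tv, "TransitionVector"))
  c(T = tv@pcT, R = tv@pcR, S = tv@pcS, P = tv@pcP)
}

#' AgentPolicy: a subject-side decision policy
#'
#' One of the policies used in the analyses: a memory-one stochastic agent
#' (parameterized by a [TransitionVector-class]), the unconditional ALLC and
#' ALLD strategies, the strict alternator, an i.i.d. Bernoulli cooperator, or
#' a fixed action sequence. Use the constructor helpers
#' ([memoryOneAgent()], [allcAgent()], [alldAgent()], [alternatorAgent()],
#' [bernoulliAgent()], [fixedSequenceAgent()]).
#'
#' @slot kind one of `"memory_one"`, `"allc"`, `"alld"`, `"alternator"`,
#'   `"bernoulli"`, `"fixed_sequence"`.
#' @slot tv the [TransitionVector-class] for `memory_one` agents.
#' @slot p cooperation probability for `bernoulli` agents.
#' @slot sequence character vector over C/D for `fixed_sequence` agents.
#' @exportClass AgentPolicy
setClass("AgentPolicy",
  representation(kind = "character", tv = "ANY", p = "numeric",
                 sequence = "character"),
  validity = function(object) {
    kinds <- c("memory_one", "allc", "alld", "alternator", "bernoulli",
               "fixed_sequence")
    if (length(object@kind) != 1L || !(object@kind %in% kinds))
      return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
    if (object@kind == "memory_one" && !is(object@tv, "TransitionVector"))
      return("memory_one agents need a TransitionVector")
    if (object@kind == "bernoulli" && !.is_prob(object@p))
      return("bernoulli agents need p in [0, 1]")
    if (object@kind == "fixed_sequence" &&
        (length(object@sequence) < 1L ||
         !all(object@sequence %in% .ACTIONS)))
      return("fixed_sequence agents need a non-empty sequence over {C, D}")
    TRUE
  })

#' SessionLog: one session of iterated-PD trials
#'
#' An ordered block of trials for one subject in one session, together with
#' its metadata. The trial table has one row per trial with columns
#' `trial_index` (0-based, contiguous), `subject_action`, `opponent_action`,
#' `state`, `pellets`, `timeout_s`, `trial_duration_s`. Every trial is
#' exactly one of rewarded (`pellets > 0`, states R/T) or timed out
#' (`timeout_s > 0`, states S/P) — except in all-pellet matrices, where
#' `timeout_s` is always 0.
#'
#' @slot subjectId,group,phase,matrixLabel session metadata.
#' @slot sessionIndex session number within the subject's training history.
#' @slot trials the trial data.frame described above.
#' @exportClass SessionLog
setClass("SessionLog",
  representation(subjectId = "character", group = "character",
                 phase = "character", sessionIndex = "integer",
                 matrixLabel = "character", trials = "data.frame"),
  validity = function(object) {
    tr <- object@trials
    need <- c("trial_index", "subject_action", "opponent_action", "state",
              "pellets", "timeout_s", "trial_duration_s")
    if (!all(need %in% names(tr)))
      return(paste("trials must have columns:", paste(need, collapse = ", ")))
    if (nrow(tr) == 0L) return("a session must contain at least one trial")
    if (!identical(as.integer(tr$trial_index), seq_len(nrow(tr)) - 1L))
      return("trial_index must be contiguous from 0")
    if (!all(tr$subject_action %in% .ACTIONS) ||
        !all(tr$opponent_action %in% .ACTIONS))
      return("actions must be C or D")
    if (!all(tr$state == classifyState(tr$subject_action, tr$opponent_action)))
      return("state inconsistent with the action pair")
    if (any(tr$pellets < 0) || any(tr$timeout_s < 0))
      return("pellets and timeout_s must be non-negative")
    if (any(tr$pellets > 0 & tr$timeout_s > 0))
      return("a trial cannot be both rewarded and timed out")
    TRUE
  })

#' ChainModel: the four-state Markov chain induced by a memory-one strategy
#'
#' Against a Tit-for-Tat opponent, a memory-one strategy induces a Markov
#' chain on the outcome states (order R, T, S, P). The opponent's copying
#' creates the structural zeros: from R or S (subject just cooperated, so the
#' opponent will cooperate) only R or T are reachable; from T or P only S or
#' P. Built by [buildChain()].
#'
#' @slot tv the generating [TransitionVector-class].
#' @slot transitionMatrix 4x4 row-stochastic matrix, states ordered R,T,S,P.
#' @slot stationary named stationary probabilities (zero outside the closed
#'   class when the chain is reducible).
#' @slot reducible `TRUE` when the chain is not irreducible; the stationary
#'   distribution then refers to the closed class reachable from R (the game
#'   starts with a cooperating opponent).
#' @slot closedStates states of the closed class the stationary refers to.
#' @exportClass ChainModel
setClass("ChainModel",
  representation(tv = "TransitionVector", transitionMatrix = "matrix",
                 stationary = "numeric", reducible = "logical",
                 closedStates = "character"),
  validity = function(object) {
    M <- object@transitionMatrix
    if (!all(dim(M) == c(4L, 4L)) ||
        !identical(rownames(M), .STATES) || !identical(colnames(M), .STATES))
      return("transitionMatrix must be 4x4 with states R, T, S, P")
    if (any(abs(rowSums(M) - 1) > 1e-9))
      return("transitionMatrix rows must sum to 1")
    if (any(M[c("R", "S"), c("S", "P")] != 0) ||
        any(M[c("T", "P"), c("R", "T")] != 0))
      return("structural zeros of the Tit-for-Tat coupling violated")
    pi <- object@stationary
    if (length(pi) != 4L || !identical(names(pi), .STATES))
      return("stationary must be a named length-4 vector over R, T, S, P")
    if (abs(sum(pi) - 1) > 1e-9 || any(pi < -1e-12))
      return("stationary must be a probability distribution")
    if (max(abs(drop(pi %*% M) - pi)) > 1e-8)
      return("stationary does not satisfy pi %*% M = pi")
    TRUE
  })

#' StrategySummary: per-subject or per-group strategy estimates
#'
#' The empirical summary of behavior over a pool of sessions: cooperation
#' rate, outcome-state occupancy, and the estimated transition vector with
#' its conditional counts. Components never observed (a state the subject
#' never visited) are `NA`, not 0/0. Built by [summarizeSessions()].
#'
#' @slot cooperationRate fraction of trials with a C choice.
#' @slot occupancy named state frequencies (R, T, S, P), summing to 1.
#' @slot nTrials pooled trial count.
#' @slot tvEstimate named estimated cooperation probabilities after each
#'   state (T, R, S, P order), `NA` where unobserved.
#' @slot counts 4x2 matrix of (`n_given`, `n_coop_after`) per previous state.
#' @slot sessionsUsed number of sessions pooled.
#' @exportClass StrategySummary
setClass("StrategySummary",
  representation(cooperationRate = "numeric", occupancy = "numeric",
                 nTrials = "integer", tvEstimate = "numeric",
                 counts = "matrix", sessionsUsed = "integer"),
  validity = function(object) {
    if (!.is_prob(object@cooperationRate))
      return("cooperationRate must be a probability")
    occ <- object@occupancy
    if (length(occ) != 4L || !identical(names(occ), .STATES) ||
        abs(sum(occ) - 1) > 1e-9 || any(occ < 0))
      return("occupancy must be a distribution over R, T, S, P")
    est <- object@tvEstimate
    if (length(est) != 4L || !identical(names(est), c("T", "R", "S", "P")))
      return("tvEstimate must be named over T, R, S, P")
    if (any(!is.na(est) & (est < 0 | est > 1)))
      return("defined tvEstimate components must be probabilities")
    TRUE
  })

## ---- show methods -------------------------------------------------------

setMethod("show", "PayoffMatrix", function(object) {
  unit <- if (object@allPellet) "pellets" else "s timeout"
  cat("PayoffMatrix <", object@label, ">\n", sep = "")
  cat(sprintf("  R: %g pellets   T: %g pellets\n", object@pR, object@pT))
  cat(sprintf("  P: %g %s   S: %g %s\n", object@pP, unit, object@pS, unit))
})

setMethod("show", "TransitionVector", function(object) {
  cat("TransitionVector  p(c|T)=", object@pcT, "  p(c|R)=", object@pcR,
      "  p(c|S)=", object@pcS, "  p(c|P)=", object@pcP,
      "  first-move p(C)=", object@firstMovePC, "\n", sep = "")
})

setMethod("show", "AgentPolicy", function(object) {
  cat("AgentPolicy kind=", object@kind, "\n", sep = "")
  if (object@kind == "memory_one") show(object@tv)
  if (object@kind == "bernoulli") cat("  p(C) =", object@p, "\n")
  if (object@kind == "fixed_sequence")
    cat("  sequence:", paste(utils::head(object@sequence, 10), collapse = ""),
        if (length(object@sequence) > 10) "...", "\n")
})

setMethod("show", "SessionLog", function(object) {
  cat("SessionLog ", object@subjectId, " [", object@group, "/", object@phase,
      "] session ", object@sessionIndex, ", matrix ", object@matrixLabel,
      ": ", nrow(object@trials), " trials, ",
      sum(object@trials$pellets), " pellets, ",
      sum(object@trials$timeout_s), " s timeout\n", sep = "")
})

setMethod("show", "ChainModel", function(object) {
  cat("ChainModel over states (R, T, S, P)",
      if (object@reducible)
        paste0(" [reducible; closed class {",
               paste(object@closedStates, collapse = ", "), "}]"),
      "\n", sep = "")
  print(round(object@transitionMatrix, 4))
  cat("stationary: ", paste(sprintf("%s=%.4f", .STATES,
                                    object@stationary), collapse = "  "),
      "\n", sep = "")
})

setMethod("show", "StrategySummary", function(object) {
  cat("StrategySummary over ", object@sessionsUsed, " sessions (",
      object@nTrials, " trials)\n", sep = "")
  cat(sprintf("  cooperation rate: %.3f\n", object@cooperationRate))
  cat("  occupancy: ", paste(sprintf("%s=%.3f", .STATES, object@occupancy),
                             collapse = "  "), "\n", sep = "")
  est <- object@tvEstimate
  cat("  transition vector: ",
      paste(sprintf("p(c|%s)=%s", names(est),
                    ifelse(is.na(est), "NA", sprintf("%.3f", est))),
            collapse = "  "), "\n", sep = "")
})

## ---- simple accessors ---------------------------------------------------

#' Trial table of a session
#' @param x a [SessionLog-class].
#' @return The trial `data.frame` (one row per trial).
#' @export
trials <- function(x) {
  stopifnot(is(x, "SessionLog"))
  x@trials
}

#' Number of trials in a session
#' @param x a [SessionLog-class].
#' @return Integer trial count.
#' @export
nTrials <- function(x) nrow(trials(x))

#' Session metadata accessors
#' @param x a [SessionLog-class].
#' @return The corresponding metadata field.
#' @export
subjectId <- function(x) {
  stopifnot(is(x, "SessionLog"))
  x@subjectId
}

#' @rdname subjectId
#' @export
sessionPhase <- function(x) {
  stopifnot(is(x, "SessionLog"))
  x@phase
}
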