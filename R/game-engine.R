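#' Classify an action pair into its outcome state
#'
#' The bijection between (subject, opponent) action pairs and the four
#' outcome states: (C,C) -> R, (D,C) -> T, (C,D) -> S, (D,D) -> P.
#' Vectorized over both arguments.
#'
#' @param subject,opponent character vectors over `"C"` / `"D"`.
#' @return Character vector of states over `"R"`, `"T"`, `"S"`, `"P"`.
#' @examples
#' classifyState("C", "C")  # "R"
#' classifyState(c("D", "C"), c("C", "D"))  # "T" "S"
#' @export
classifyState <- function(subject, opponent) {
  stopifnot(all(subject %in% .ACTIONS), all(opponent %in% .ACTIONS),
            length(subject) == length(opponent))
  ifelse(subject == "C",
         ifelse(opponent == "C", "R", "S"),
         ifelse(opponent == "C", "T", "P"))
}

#' Reinforcement for an outcome state
#'
#' Maps a state to its (pellets, timeout seconds) reinforcement under a
#' payoff matrix. R and T pay pellets; P and S impose timeout. In all-pellet
#' matrices every state pays pellets and timeout is always 0.
#'
#' @param state character vector of outcome states.
#' @param matrix a [PayoffMatrix-class].
#' @return A data.frame with columns `pellets` and `timeout_s` (one row per
#'   state).
#' @examples
#' payoffFor("S", payoffMatrix())  # 0 pellets, 8 s timeout
#' @export
payoffFor <- function(state, matrix) {
  stopifnot(is(matrix, "PayoffMatrix"), all(state %in% .STATES))
  pel <- c(R = matrix@pR, T = matrix@pT,
           S = if (matrix@allPellet) matrix@pS else 0,
           P = if (matrix@allPellet) matrix@pP else 0)
  tmo <- c(R = 0, T = 0,
           S = if (matrix@allPellet) 0 else matrix@pS,
           P = if (matrix@allPellet) 0 else matrix@pP)
  data.frame(pellets = unname(pel[state]), timeout_s = unname(tmo[state]))
}

#' Tit-for-Tat opponent move
#'
#' Cooperate on the first trial; afterwards copy the subject's previous
#' action.
#'
#' @param previousSubjectAction `"C"`, `"D"`, or `NULL` on the first trial.
#' @return `"C"` or `"D"`.
#' @export
tftNext <- function(previousSubjectAction = NULL) {
  if (is.null(previousSubjectAction)) return("C")
  stopifnot(previousSubjectAction %in% .ACTIONS)
  previousSubjectAction
}

## Trial duration bookkeeping: ITI + latency + (feeder light + eating) on
## rewarded trials, ITI + latency + timeout on punished ones.  A modeling
## construction for reward-rate analyses, not a protocol quantity.
.trial_duration <- function(pellets, timeout_s, timing) {
  timing@itiS + timing@responseLatencyS +
    ifelse(pellets > 0, timing@eatingS + timing@feederLightS, timeout_s)
}

.make_session <- function(subject, opponent, matrix, timing,
                          subjectId = "sim", group = "sim",
                          phase = "simulation", sessionIndex = 1L,
                          matrixLabel = matrix@label) {
  state <- classifyState(subject, opponent)
  pay <- payoffFor(state, matrix)
  trialsDf <- data.frame(
    trial_index = seq_along(subject) - 1L,
    subject_action = subject,
    opponent_action = opponent,
    state = state,
    pellets = pay$pellets,
    timeout_s = pay$timeout_s,
    trial_duration_s = .trial_duration(pay$pellets, pay$timeout_s, timing),
    stringsAsFactors = FALSE)
  new("SessionLog", subjectId = subjectId, group = group, phase = phase,
      sessionIndex = as.integer(sessionIndex), matrixLabel = matrixLabel,
      trials = trialsDf)
}

#' Play one iterated-PD session against Tit-for-Tat
#'
#' Simulates a session trial by trial: the opponent plays Tit-for-Tat (C on
#' trial one, then a copy of the subject's previous action), the subject
#' follows the supplied [AgentPolicy-class], and each trial's reinforcement
#' and duration are recorded. Identical `(agent, matrix, timing, seed)`
#' always reproduce the identical session.
#'
#' @param agent an [AgentPolicy-class].
#' @param matrix a [PayoffMatrix-class].
#' @param timing a [TimingModel-class].
#' @param nTrials number of trials (default 30, the session length of the
#'   protocol).
#' @param seed integer seed for stochastic policies.
#' @param subjectId,group,phase,sessionIndex metadata stored in the log.
#' @return A [SessionLog-class].
#' @examples
#' s <- playSession(allcAgent(), payoffMatrix(), timingModel(), 4)
#' totalReward(s)   # 4 pellets
#' totalTimeout(s)  # 0 s
#' @export
playSession <- function(agent, matrix, timing = timingModel(), nTrials = 30,
                        seed = NULL, subjectId = "sim", group = "sim",
                        phase = "simulation", sessionIndex = 1L) {
  stopifnot(is(agent, "AgentPolicy"), is(matrix, "PayoffMatrix"),
            is(timing, "TimingModel"))
  if (!.is_count(nTrials) || nTrials < 1)
    stop("nTrials must be a positive integer")
  nTrials <- as.integer(nTrials)
  if (agent@kind == "fixed_sequence" && length(agent@sequence) < nTrials)
    stop("fixed_sequence shorter than the session")
  if (!is.null(seed)) set.seed(as.integer(seed))

  subject <- character(nTrials)
  opponent <- character(nTrials)
  prevState <- NULL
  prevOwn <- NULL
  for (t in seq_len(nTrials)) {
    opponent[t] <- tftNext(prevOwn)
    subject[t] <- nextAction(agent, prevState = prevState,
                             prevOwnAction = prevOwn, trialIndex = t - 1L)
    prevState <- classifyState(subject[t], opponent[t])
    prevOwn <- subject[t]
  }
  .make_session(subject, opponent, matrix, timing, subjectId = subjectId,
                group = group, phase = phase, sessionIndex = sessionIndex)
}

#' Session payoff totals
#'
#' Total pellets earned and total timeout seconds incurred by the subject
#' over one session.
#'
#' @param session a [SessionLog-class].
#' @return A single number.
#' @export
totalReward <- function(session) {
  stopifnot(is(session, "SessionLog"))
  if (nrow(session@trials) == 0L) stop("empty session")
  sum(session@trials$pellets)
}

#' @rdname totalReward
#' @export
totalTimeout <- function(session) {
  stopifnot(is(session, "SessionLog"))
  if (nrow(session@trials) == 0L) stop("empty session")
  sum(session@trials$timeout_s)
}

#' Total session duration in seconds
#' @param session a [SessionLog-class].
#' @return Sum of per-trial durations, seconds.
#' @export
sessionDuration <- function(session) {
  stopifnot(is(session, "SessionLog"))
  sum(session@trials$trial_duration_s)
}

#' Cooperation rate of a session
#' @param session a [SessionLog-class].
#' @return Fraction of trials on which the subject chose C.
#' @export
cooperationRate <- function(session) {
  stopifnot(is(session, "SessionLog"))
  mean(session@trials$subject_action == "C")
}
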