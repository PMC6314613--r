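#' Agent policy constructors
#'
#' Helpers building the [AgentPolicy-class] objects used throughout:
#' `memoryOneAgent(tv)` cooperates with the transition-vector component
#' matching the previous outcome state (and with `firstMovePC` on trial
#' one); `allcAgent()` / `alldAgent()` always cooperate / defect;
#' `alternatorAgent()` strictly alternates starting with C;
#' `bernoulliAgent(p)` cooperates i.i.d. with probability `p`;
#' `fixedSequenceAgent(actions)` replays an explicit action sequence.
#'
#' @param tv a [TransitionVector-class].
#' @param p cooperation probability in \[0, 1\].
#' @param actions character vector over `"C"`/`"D"`, or a single string such
#'   as `"CDDD"`.
#' @return An [AgentPolicy-class].
#' @examples
#' memoryOneAgent(transitionVector(0.76, 0.85, 0.93, 0.87))
#' fixedSequenceAgent("CDDD")
#' @export
memoryOneAgent <- function(tv) {
  new("AgentPolicy", kind = "memory_one", tv = tv, p = NA_real_,
      sequence = character())
}

#' @rdname memoryOneAgent
#' @export
allcAgent <- function() {
  new("AgentPolicy", kind = "allc", tv = NULL, p = NA_real_,
      sequence = character())
}

#' @rdname memoryOneAgent
#' @export
alldAgent <- function() {
  new("AgentPolicy", kind = "alld", tv = NULL, p = NA_real_,
      sequence = character())
}

#' @rdname memoryOneAgent
#' @export
alternatorAgent <- function() {
  new("AgentPolicy", kind = "alternator", tv = NULL, p = NA_real_,
      sequence = character())
}

#' @rdname memoryOneAgent
#' @export
bernoulliAgent <- function(p) {
  new("AgentPolicy", kind = "bernoulli", tv = NULL, p = p,
      sequence = character())
}

#' @rdname memoryOneAgent
#' @export
fixedSequenceAgent <- function(actions) {
  if (length(actions) == 1L && nchar(actions) > 1L)
    actions <- strsplit(actions, "")[[1]]
  new("AgentPolicy", kind = "fixed_sequence", tv = NULL, p = NA_real_,
      sequence = as.character(actions))
}

#' Next action of a policy
#'
#' Draws (or looks up) the subject's action for the current trial. Stochastic
#' policies consume R's global random number stream, so a session played
#' under a fixed seed is exactly reproducible.
#'
#' @param policy an [AgentPolicy-class].
#' @param prevState previous trial's outcome state, or `NULL` on trial one.
#' @param prevOwnAction the policy's own previous action (used by the
#'   alternator), or `NULL` on trial one.
#' @param trialIndex 0-based trial index (used by fixed sequences).
#' @return `"C"` or `"D"`.
#' @export
nextAction <- function(policy, prevState = NULL, prevOwnAction = NULL,
                       trialIndex = 0L) {
  stopifnot(is(policy, "AgentPolicy"))
  switch(policy@kind,
    allc = "C",
    alld = "D",
    alternator = {
      if (is.null(prevOwnAction)) "C"
      else if (prevOwnAction == "C") "D" else "C"
    },
    bernoulli = if (stats::runif(1) < policy@p) "C" else "D",
    fixed_sequence = {
      if (trialIndex + 1L > length(policy@sequence))
        stop("fixed sequence exhausted at trial ", trialIndex)
      policy@sequence[trialIndex + 1L]
    },
    memory_one = {
      pc <- if (is.null(prevState)) policy@tv@firstMovePC
            else tvComponents(policy@tv)[[prevState]]
      if (stats::runif(1) < pc) "C" else "D"
    })
}

#' Outcome-state orbit of the alternator against Tit-for-Tat
#'
#' A strict alternator starting with C, facing Tit-for-Tat, visits R once
#' (the opening mutual cooperation) and then cycles through (T, S) forever:
#' every defection is rewarded with the temptation payoff, every return to
#' cooperation is punished with the sucker timeout. The cycle economics —
#' `pT` pellets and `pS` timeout seconds per two trials — are what make
#' alternation competitive with ALLC exactly when `pT >= 2 pR`.
#'
#' @param matrix a [PayoffMatrix-class].
#' @return A list with `transient` (states before the cycle), `cycle` (the
#'   repeating states), `cyclePellets` and `cycleTimeoutS` (reinforcement per
#'   cycle period).
#' @examples
#' alternationCycleStates(payoffMatrix())  # transient R, cycle (T, S)
#' @export
alternationCycleStates <- function(matrix) {
  stopifnot(is(matrix, "PayoffMatrix"))
  cyc <- c("T", "S")
  pay <- payoffFor(cyc, matrix)
  list(transient = "R", cycle = cyc,
       cyclePellets = sum(pay$pellets),
       cycleTimeoutS = sum(pay$timeout_s))
}
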