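#' Cohort configuration for the synthetic-experiment generator
#'
#' Describes one group of simulated subjects. Each subject behaves as a
#' memory-one agent whose transition vector drifts componentwise linearly
#' from `startTV` (chance, all 0.5, by default) to `targetTV` over a
#' per-subject acquisition horizon drawn from a normal distribution
#' (truncated at 5 sessions) — a phenomenological stand-in for learning; no
#' learning rule is fitted or claimed. After reaching target the vector is
#' held fixed for `stableSessions` sessions. Optional extensions re-run the
#' drift after a lever-meaning reversal (for the first
#' `nReversalSubjects` subjects) or after a payoff-matrix switch toward a
#' new target vector.
#'
#' @param groupName group label written into session logs.
#' @param nSubjects number of subjects.
#' @param targetTV the asymptotic [TransitionVector-class].
#' @param startTV starting vector (default chance, all components 0.5).
#' @param sessionsToCriterionMean,sessionsToCriterionSD normal draw for the
#'   per-subject acquisition horizon (defaults 30 and 4 sessions; truncated
#'   at 5).
#' @param nTrialsPerSession trials per session (default 30).
#' @param sessionsPerDay sessions per day (default 2; bookkeeping only).
#' @param acquisitionMatrix the [PayoffMatrix-class] in force from the
#'   start.
#' @param stableSessions sessions held at target after acquisition
#'   (default 10).
#' @param nReversalSubjects how many subjects (taken from the start of the
#'   roster) undergo a reversal phase after stability (default 0).
#' @param reversalHorizonFactor relearning horizon as a fraction of the
#'   subject's acquisition horizon (default 0.5, floor 5 sessions).
#' @param switchMatrix,switchTargetTV when non-`NULL`, after stability the
#'   matrix changes to `switchMatrix` and the vector drifts to
#'   `switchTargetTV` over half the acquisition horizon, followed by
#'   another stable block.
#' @param seed integer seed; subject `i` derives its stream from
#'   `seed + 1009 * i`.
#' @return A validated configuration list of class `"CohortConfig"`.
#' @export
cohortConfig <- function(groupName, nSubjects, targetTV,
                         startTV = transitionVector(),
                         sessionsToCriterionMean = 30,
                         sessionsToCriterionSD = 4,
                         nTrialsPerSession = 30, sessionsPerDay = 2,
                         acquisitionMatrix = payoffMatrix(),
                         stableSessions = 10, nReversalSubjects = 0,
                         reversalHorizonFactor = 0.5,
                         switchMatrix = NULL, switchTargetTV = NULL,
                         seed = 1) {
  stopifnot(is(targetTV, "TransitionVector"), is(startTV, "TransitionVector"),
            is(acquisitionMatrix, "PayoffMatrix"),
            nSubjects >= 1, nTrialsPerSession >= 1, stableSessions >= 1,
            sessionsToCriterionMean >= 5, sessionsToCriterionSD >= 0,
            nReversalSubjects >= 0, nReversalSubjects <= nSubjects)
  if (!is.null(switchMatrix) || !is.null(switchTargetTV))
    stopifnot(is(switchMatrix, "PayoffMatrix"),
              is(switchTargetTV, "TransitionVector"))
  structure(list(
    groupName = as.character(groupName), nSubjects = as.integer(nSubjects),
    targetTV = targetTV, startTV = startTV,
    sessionsToCriterionMean = sessionsToCriterionMean,
    sessionsToCriterionSD = sessionsToCriterionSD,
    nTrialsPerSession = as.integer(nTrialsPerSession),
    sessionsPerDay = as.integer(sessionsPerDay),
    acquisitionMatrix = acquisitionMatrix,
    stableSessions = as.integer(stableSessions),
    nReversalSubjects = as.integer(nReversalSubjects),
    reversalHorizonFactor = reversalHorizonFactor,
    switchMatrix = switchMatrix, switchTargetTV = switchTargetTV,
    seed = as.integer(seed)), class = "CohortConfig")
}

## componentwise linear interpolation between two transition vectors
.interp_tv <- function(from, to, frac) {
  transitionVector(
    pcT = from@pcT + frac * (to@pcT - from@pcT),
    pcR = from@pcR + frac * (to@pcR - from@pcR),
    pcS = from@pcS + frac * (to@pcS - from@pcS),
    pcP = from@pcP + frac * (to@pcP - from@pcP),
    firstMovePC = from@firstMovePC + frac * (to@firstMovePC - from@firstMovePC))
}

## Lever-meaning reversal: a subject that keeps its motor policy presses
## the lever that now means the opposite action, and both players' state
## labels swap (R <-> P, T <-> S).  p'(c|X) = 1 - p(c|swap(X)).
.reversed_tv <- function(tv) {
  transitionVector(pcT = 1 - tv@pcS, pcR = 1 - tv@pcP,
                   pcS = 1 - tv@pcT, pcP = 1 - tv@pcR,
                   firstMovePC = 1 - tv@firstMovePC)
}

.draw_horizon <- function(mean, sd) {
  for (i in 1:100) {
    h <- round(stats::rnorm(1, mean, sd))
    if (h >= 5) return(as.integer(h))
  }
  5L  # bounded retries exhausted: clamp at the truncation floor
}

#' Generate one subject's full training history
#'
#' Produces the ordered sequence of [SessionLog-class] objects for subject
#' `subjectIndex` of a cohort: acquisition (linear transition-vector drift
#' over a drawn horizon), a stable block at the target vector, and — when
#' configured — a reversal phase (drift back from the lever-swapped policy)
#' or a matrix-switch phase (drift to the post-switch target under the new
#' matrix), each followed by its own stable block. Deterministic given
#' `(config$seed, subjectIndex)`.
#'
#' @param config a [cohortConfig()] object.
#' @param subjectIndex 1-based subject index within the cohort.
#' @param timing a [TimingModel-class].
#' @return A list of [SessionLog-class] in session order.
#' @export
generateSubject <- function(config, subjectIndex, timing = timingModel()) {
  stopifnot(inherits(config, "CohortConfig"),
            subjectIndex >= 1, subjectIndex <= config$nSubjects)
  set.seed(config$seed + 1009L * as.integer(subjectIndex))
  subjId <- sprintf("%s-%02d", config$groupName, subjectIndex)
  horizon <- .draw_horizon(config$sessionsToCriterionMean,
                           config$sessionsToCriterionSD)

  sessions <- list()
  sessionIdx <- 0L
  playPhase <- function(phase, matrix, tvs) {
    for (tv in tvs) {
      sessionIdx <<- sessionIdx + 1L
      sessions[[length(sessions) + 1L]] <<- playSession(
        memoryOneAgent(tv), matrix, timing,
        nTrials = config$nTrialsPerSession, seed = NULL,
        subjectId = subjId, group = config$groupName, phase = phase,
        sessionIndex = sessionIdx)
    }
  }
  drift <- function(from, to, h) lapply(seq_len(h), function(s)
    .interp_tv(from, to, s / h))

  playPhase("acquisition", config$acquisitionMatrix,
            drift(config$startTV, config$targetTV, horizon))
  playPhase("stable", config$acquisitionMatrix,
            rep(list(config$targetTV), config$stableSessions))

  if (subjectIndex <= config$nReversalSubjects) {
    hRev <- max(5L, as.integer(round(horizon * config$reversalHorizonFactor)))
    playPhase("reversal", config$acquisitionMatrix,
              drift(.reversed_tv(config$targetTV), config$targetTV, hRev))
    playPhase("reversal_stable", config$acquisitionMatrix,
              rep(list(config$targetTV), config$stableSessions))
  }
  if (!is.null(config$switchMatrix)) {
    hSw <- max(5L, as.integer(round(horizon / 2)))
    playPhase("switch", config$switchMatrix,
              drift(config$targetTV, config$switchTargetTV, hSw))
    playPhase("switch_stable", config$switchMatrix,
              rep(list(config$switchTargetTV), config$stableSessions))
  }
  sessions
}

#' Default study plan
#'
#' The cohort layout of the emulated two-experiment study, with targets
#' taken from [referenceStrategies()]: treatment 1 on the (1, 2, 4 s, 8 s)
#' matrix with 8 cooperative subjects (the first 4 of which undergo
#' reversal) and 4 non-cooperative subjects held at the non-cooperative
#' vector throughout; treatment 2/3 on the (1, 3, 4 s, 8 s) matrix with a
#' 3-subject arm switched to (1, 5, 4 s, 8 s) (temptation raised) and a
#' 3-subject arm switched to (2, 3, 4 s, 8 s) (cooperation reward raised).
#'
#' @param seed integer master seed; each cohort derives its own.
#' @param stableSessions stable-block length passed to every cohort.
#' @return A named list of [cohortConfig()] objects.
#' @export
defaultStudyPlan <- function(seed = 1, stableSessions = 10) {
  ref <- referenceStrategies()
  tvOf <- function(g) {
    r <- ref[ref$group == g, ]
    transitionVector(r$pc_T, r$pc_R, r$pc_S, r$pc_P)
  }
  matOf <- function(g) {
    r <- ref[ref$group == g, ]
    payoffMatrix(r$pR, r$pT, r$pP, r$pS)
  }
  list(
    treat1_coop = cohortConfig(
      "coop", 8, tvOf("coop"), acquisitionMatrix = matOf("coop"),
      nReversalSubjects = 4, stableSessions = stableSessions,
      seed = seed + 101L),
    treat1_no_coop = cohortConfig(
      "no_coop", 4, tvOf("no_coop"), startTV = tvOf("no_coop"),
      acquisitionMatrix = matOf("no_coop"), stableSessions = stableSessions,
      seed = seed + 202L),
    treat2_A = cohortConfig(
      "2A", 3, tvOf("2A"), acquisitionMatrix = matOf("2A"),
      switchMatrix = matOf("3A"), switchTargetTV = tvOf("3A"),
      stableSessions = stableSessions, seed = seed + 303L),
    treat2_B = cohortConfig(
      "2B", 3, tvOf("2B"), acquisitionMatrix = matOf("2B"),
      switchMatrix = matOf("3B"), switchTargetTV = tvOf("3B"),
      stableSessions = stableSessions, seed = seed + 404L))
}

#' Generate a full synthetic experiment
#'
#' Runs [generateSubject()] for every subject of every cohort in a study
#' plan and returns the flat session list together with a manifest (seeds,
#' per-subject phase boundaries) from which the bundle is exactly
#' replayable.
#'
#' @param plan a named list of [cohortConfig()] objects (default
#'   [defaultStudyPlan()]).
#' @param timing a [TimingModel-class].
#' @return A list with `sessions` (list of [SessionLog-class]) and
#'   `manifest`.
#' @examples
#' \donttest{
#' bundle <- generateExperiment(defaultStudyPlan(seed = 7))
#' length(bundle$sessions)
#' }
#' @export
generateExperiment <- function(plan = defaultStudyPlan(),
                               timing = timingModel()) {
  stopifnot(is.list(plan), length(plan) >= 1,
            all(vapply(plan, inherits, logical(1), "CohortConfig")))
  sessions <- list()
  subjects <- list()
  for (cname in names(plan)) {
    cfg <- plan[[cname]]
    for (i in seq_len(cfg$nSubjects)) {
      logs <- generateSubject(cfg, i, timing)
      sessions <- c(sessions, logs)
      phases <- vapply(logs, sessionPhase, character(1))
      r <- rle(phases)
      subjects[[length(subjects) + 1L]] <- list(
        cohort = cname, subject_id = subjectId(logs[[1]]),
        seed = cfg$seed + 1009L * i,
        n_sessions = length(logs),
        phases = data.frame(phase = r$values, n_sessions = r$lengths,
                            stringsAsFactors = FALSE))
    }
  }
  manifest <- list(
    cohorts = lapply(plan, function(cfg) {
      list(group = cfg$groupName, n_subjects = cfg$nSubjects,
           seed = cfg$seed,
           target_tv = unname(tvComponents(cfg$targetTV)),
           matrix_label = cfg$acquisitionMatrix@label,
           stable_sessions = cfg$stableSessions,
           n_reversal_subjects = cfg$nReversalSubjects,
           switch_matrix_label = if (is.null(cfg$switchMatrix)) NULL
                                 else cfg$switchMatrix@label)
    }),
    subjects = subjects)
  list(sessions = sessions, manifest = manifest)
}

#' Write an experiment bundle to disk
#'
#' @param bundle result of [generateExperiment()].
#' @param dir output directory (created if needed); writes `sessions.csv`
#'   in the session-log CSV dialect and `manifest.json`.
#' @return `dir`, invisibly.
#' @export
writeExperimentBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeSessionLogs(bundle$sessions, file.path(dir, "sessions.csv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
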