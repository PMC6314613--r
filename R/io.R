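#' Read and write session logs as CSV
#'
#' The on-disk dialect is one trial per row with columns `subject_id`,
#' `group`, `phase`, `session_index`, `matrix_label`, `trial_index`,
#' `subject_action`, `opponent_action`, `state`, `pellets`, `timeout_s`,
#' `trial_duration_s` (header required, UTF-8). `writeSessionLogs()`
#' flattens a list of sessions into this table; `readSessionLogs()` splits
#' it back into validated [SessionLog-class] objects, ordered by subject and
#' session index.
#'
#' @param sessions a [SessionLog-class] or list of them.
#' @param file path to a CSV file.
#' @return `readSessionLogs()`: a list of [SessionLog-class];
#'   `writeSessionLogs()`: the file path, invisibly.
#' @export
writeSessionLogs <- function(sessions, file) {
  if (is(sessions, "SessionLog")) sessions <- list(sessions)
  stopifnot(all(vapply(sessions, is, logical(1), "SessionLog")))
  tab <- do.call(rbind, lapply(sessions, function(s) {
    cbind(data.frame(subject_id = s@subjectId, group = s@group,
                     phase = s@phase, session_index = s@sessionIndex,
                     matrix_label = s@matrixLabel,
                     stringsAsFactors = FALSE),
          s@trials)
  }))
  utils::write.csv(tab, file, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname writeSessionLogs
#' @export
readSessionLogs <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("subject_id", "group", "phase", "session_index", "matrix_label",
            "trial_index", "subject_action", "opponent_action", "state",
            "pellets", "timeout_s", "trial_duration_s")
  if (!all(need %in% names(tab)))
    stop("missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  key <- interaction(tab$subject_id, tab$session_index, tab$phase,
                     drop = TRUE)
  logs <- lapply(split(tab, key), function(d) {
    d <- d[order(d$trial_index), ]
    new("SessionLog", subjectId = d$subject_id[1], group = d$group[1],
        phase = d$phase[1], sessionIndex = as.integer(d$session_index[1]),
        matrixLabel = d$matrix_label[1],
        trials = data.frame(
          trial_index = as.integer(d$trial_index),
          subject_action = d$subject_action,
          opponent_action = d$opponent_action,
          state = d$state, pellets = d$pellets, timeout_s = d$timeout_s,
          trial_duration_s = d$trial_duration_s,
          stringsAsFactors = FALSE))
  })
  ord <- order(vapply(logs, subjectId, character(1)),
               vapply(logs, function(s) s@sessionIndex, integer(1)))
  unname(logs[ord])
}

#' Game configuration as JSON
#'
#' Serializes / parses the payoff matrix and timing model as a flat JSON
#' object with keys `p_r`, `p_t`, `p_p`, `p_s`, `all_pellet_mode`, `label`,
#' `iti_s`, `cs_max_s`, `eating_s`, `feeder_light_s`, `response_latency_s`,
#' `opponent_fixed_ratio`.
#'
#' @param matrix a [PayoffMatrix-class].
#' @param timing a [TimingModel-class].
#' @param file path to a JSON file.
#' @return `readGameConfig()`: a list with elements `matrix` and `timing`;
#'   `writeGameConfig()`: the file path, invisibly.
#' @export
writeGameConfig <- function(matrix, timing, file) {
  stopifnot(is(matrix, "PayoffMatrix"), is(timing, "TimingModel"))
  cfg <- list(p_r = matrix@pR, p_t = matrix@pT, p_p = matrix@pP,
              p_s = matrix@pS, all_pellet_mode = matrix@allPellet,
              label = matrix@label,
              iti_s = timing@itiS, cs_max_s = timing@csMaxS,
              eating_s = timing@eatingS, feeder_light_s = timing@feederLightS,
              response_latency_s = timing@responseLatencyS,
              opponent_fixed_ratio = timing@opponentFixedRatio)
  jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeGameConfig
#' @export
readGameConfig <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  need <- c("p_r", "p_t", "p_p", "p_s", "all_pellet_mode", "iti_s",
            "cs_max_s", "eating_s", "feeder_light_s", "response_latency_s",
            "opponent_fixed_ratio")
  if (!all(need %in% names(cfg)))
    stop("missing keys: ", paste(setdiff(need, names(cfg)), collapse = ", "))
  list(
    matrix = payoffMatrix(cfg$p_r, cfg$p_t, cfg$p_p, cfg$p_s,
                          allPellet = isTRUE(cfg$all_pellet_mode),
                          label = if (!is.null(cfg$label)) cfg$label else NULL),
    timing = timingModel(cfg$iti_s, cfg$cs_max_s, cfg$eating_s,
                         cfg$feeder_light_s, cfg$response_latency_s,
                         cfg$opponent_fixed_ratio))
}

#' Agent policy from a JSON description
#'
#' Parses `{"kind": ..., "parameters": ...}`: memory-one agents carry the
#' transition-vector components (`pc_t`, `pc_r`, `pc_s`, `pc_p`, optional
#' `first_move_p_c`), Bernoulli agents a probability `p`, fixed sequences a
#' string over C/D.
#'
#' @param x a path to a JSON file, or an already-parsed list.
#' @return An [AgentPolicy-class].
#' @export
agentPolicyFromJSON <- function(x) {
  spec <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE)
          else x
  kind <- spec$kind
  par <- spec$parameters
  switch(kind,
    allc = allcAgent(),
    alld = alldAgent(),
    alternator = alternatorAgent(),
    bernoulli = bernoulliAgent(par$p),
    fixed_sequence = fixedSequenceAgent(par$sequence),
    memory_one = {
      fm <- if (!is.null(par$first_move_p_c)) par$first_move_p_c else 0.5
      memoryOneAgent(transitionVector(par$pc_t, par$pc_r, par$pc_s, par$pc_p,
                                      firstMovePC = fm))
    },
    stop("unknown agent kind: ", kind))
}
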