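#' Two-sided Wilcoxon rank-sum test
#'
#' Thin contract over the standard rank-sum comparison of two independent
#' samples (e.g. per-subject cooperation means before and after a matrix
#' change). The exact null distribution is used for small samples (both
#' n <= 10, no ties); otherwise the normal approximation with continuity
#' correction.
#'
#' @param a,b numeric samples.
#' @return A list with `statistic` (the rank-sum W of `a`), `p_value`, and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' rankSumTest(c(1, 2, 3), c(11, 12, 13))$p_value  # 0.1, minimal for n = 3, 3
#' @export
rankSumTest <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 10 && length(b) <= 10 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Chi-square goodness-of-fit test against chance cooperation
#'
#' Tests whether the number of cooperative choices among `nTotal` deviates
#' from chance (probability `chanceP`, default 0.5), as used to ask whether
#' each transition-vector component differs from random mode. The verdict
#' applies a Bonferroni-corrected threshold `alpha / nComparisons`
#' (0.05 / 4 = 0.0125 for the four outcome states).
#'
#' @param nCooperate cooperative-choice count.
#' @param nTotal total choices (>= 1).
#' @param chanceP null cooperation probability (default 0.5).
#' @param alpha family significance level (default 0.05).
#' @param nComparisons Bonferroni divisor (default 4, one test per state).
#' @return A list with `statistic`, `p_value`, `threshold`, `significant`.
#' @examples
#' chiSquareVsChance(30, 30)$statistic  # 30: total separation from chance
#' chiSquareVsChance(15, 30)$p_value    # 1: exactly chance
#' @export
chiSquareVsChance <- function(nCooperate, nTotal, chanceP = 0.5,
                              alpha = 0.05, nComparisons = 4) {
  if (!.is_count(nCooperate) || !.is_count(nTotal) || nTotal < 1)
    stop("counts must be non-negative integers with nTotal >= 1")
  if (nCooperate > nTotal) stop("nCooperate cannot exceed nTotal")
  res <- suppressWarnings(
    stats::chisq.test(c(nCooperate, nTotal - nCooperate),
                      p = c(chanceP, 1 - chanceP)))
  thr <- alpha / nComparisons
  list(statistic = unname(res$statistic), p_value = res$p.value,
       threshold = thr, significant = res$p.value < thr)
}

#' One-way ANOVA with Bonferroni post-hoc comparisons
#'
#' Omnibus one-way ANOVA across groups (e.g. occupancy of the four outcome
#' states across subjects), followed — only when the omnibus test is
#' significant at `alpha` — by pairwise t-tests judged against the
#' Bonferroni-corrected per-comparison threshold.
#'
#' @param groups a named list of numeric samples (each length >= 2).
#' @param alpha omnibus significance level (default 0.05).
#' @param posthocAlpha per-comparison threshold; default `alpha` divided by
#'   the number of pairwise comparisons.
#' @return A list with `F`, `p_value`, `df`, `significant`, and `pairwise`
#'   (a data.frame of pairwise comparisons, or `NULL` when the omnibus test
#'   is not significant). Degenerate input (zero variance everywhere)
#'   yields `F = NA` with `degenerate = TRUE`.
#' @export
anovaOneWay <- function(groups, alpha = 0.05, posthocAlpha = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  nPairs <- choose(length(groups), 2)
  if (is.null(posthocAlpha)) posthocAlpha <- alpha / nPairs
  if (stats::var(y) == 0)
    return(list(F = NA_real_, p_value = NA_real_, df = c(NA, NA),
                significant = FALSE, degenerate = TRUE, pairwise = NULL))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  sig <- fit$p.value < alpha
  pairwise <- NULL
  if (isTRUE(sig)) {
    combs <- utils::combn(names(groups), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      gi <- combs[1, i]; gj <- combs[2, i]
      tt <- stats::t.test(groups[[gi]], groups[[gj]], var.equal = TRUE)
      data.frame(group_a = gi, group_b = gj,
                 p_value = tt$p.value, threshold = posthocAlpha,
                 significant = tt$p.value < posthocAlpha,
                 stringsAsFactors = FALSE)
    }))
  }
  list(F = unname(fit$statistic), p_value = fit$p.value,
       df = unname(fit$parameter), significant = sig, degenerate = FALSE,
       pairwise = pairwise)
}

#' Group summary table in the standard reporting layout
#'
#' Builds the per-group reporting table — cooperation mean ± sem across
#' subjects, mean state occupancy, and the pooled transition-vector
#' estimate — from a list of sessions, grouping by the sessions' `group`
#' metadata. Cooperation mean and sem are computed across subjects (each
#' subject's rate pooled over its sessions); occupancy and transition
#' estimates pool all trials of the group.
#'
#' @param sessions a list of [SessionLog-class] objects.
#' @param file optional path; when given, the table is also written as CSV.
#' @return A data.frame with columns `group`, `n_subjects`, `cooperation`,
#'   `cooperation_sem`, `occ_T`, `occ_R`, `occ_S`, `occ_P`, `pc_T`, `pc_R`,
#'   `pc_S`, `pc_P`.
#' @export
groupSummaryTable <- function(sessions, file = NULL) {
  stopifnot(length(sessions) >= 1,
            all(vapply(sessions, is, logical(1), "SessionLog")))
  grp <- vapply(sessions, function(s) s@group, character(1))
  subj <- vapply(sessions, subjectId, character(1))
  rows <- lapply(unique(grp), function(g) {
    sel <- sessions[grp == g]
    selSubj <- subj[grp == g]
    perSubject <- vapply(unique(selSubj), function(id)
      summarizeSessions(sel[selSubj == id])@cooperationRate, numeric(1))
    pooled <- summarizeSessions(sel)
    sem <- if (length(perSubject) > 1)
      stats::sd(perSubject) / sqrt(length(perSubject)) else NA_real_
    data.frame(group = g, n_subjects = length(perSubject),
               cooperation = mean(perSubject), cooperation_sem = sem,
               occ_T = pooled@occupancy[["T"]],
               occ_R = pooled@occupancy[["R"]],
               occ_S = pooled@occupancy[["S"]],
               occ_P = pooled@occupancy[["P"]],
               pc_T = pooled@tvEstimate[["T"]],
               pc_R = pooled@tvEstimate[["R"]],
               pc_S = pooled@tvEstimate[["S"]],
               pc_P = pooled@tvEstimate[["P"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file))
    utils::write.csv(out, file, row.names = FALSE)
  out
}
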