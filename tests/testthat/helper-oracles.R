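# Independent oracles used across tests.  These re-derive quantities by a
# different route than the package (power iteration instead of a linear
# solve; step-by-step brute-force play instead of cycle detection) so that
# agreement is evidence, not tautology.

STATES <- c("R", "T", "S", "P")

# stationary distribution by damped power iteration ((M + I)/2 kills
# periodicity without moving the fixed point)
power_stationary <- function(tv, tol = 1e-12, maxit = 1e6) {
  a <- tv@pcT; b <- tv@pcR; cc <- tv@pcS; d <- tv@pcP
  M <- rbind(c(b, 1 - b, 0, 0),
             c(0, 0, a, 1 - a),
             c(cc, 1 - cc, 0, 0),
             c(0, 0, d, 1 - d))
  Mhat <- (M + diag(4)) / 2
  p <- rep(0.25, 4)
  for (i in seq_len(maxit)) {
    nxt <- drop(p %*% Mhat)
    if (max(abs(nxt - p)) < tol) break
    p <- nxt
  }
  stats::setNames(nxt / sum(nxt), STATES)
}

# brute-force play of a deterministic memory-one strategy against TFT
brute_deterministic <- function(firstMove, rule, matrix, timing, nTrials) {
  subj <- character(nTrials)
  opp <- character(nTrials)
  for (t in seq_len(nTrials)) {
    opp[t] <- if (t == 1) "C" else subj[t - 1]
    subj[t] <- if (t == 1) firstMove
               else rule[[classifyState(subj[t - 1], opp[t - 1])]]
  }
  st <- classifyState(subj, opp)
  pay <- payoffFor(st, matrix)
  dur <- timing@itiS + timing@responseLatencyS +
    ifelse(pay$pellets > 0, timing@eatingS + timing@feederLightS,
           pay$timeout_s)
  list(states = st, pellets = sum(pay$pellets),
       timeout = sum(pay$timeout_s), duration = sum(dur))
}

coop_tv <- function() transitionVector(0.76, 0.85, 0.93, 0.87)
noncoop_tv <- function() transitionVector(0.44, 0.38, 0.32, 0.32)
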