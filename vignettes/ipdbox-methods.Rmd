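---
title: "Methods: games, chains and synthetic cohorts in ipdbox"
author: "ipdbox authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: games, chains and synthetic cohorts in ipdbox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdbox)
```

## The experimental game

`ipdbox` models operant experiments in which a food-restricted rat plays the
iterated Prisoner's Dilemma (iPD) against an opponent whose choices are
driven to implement Tit-for-Tat (TFT): cooperate on the first trial, then
copy the subject's previous choice. Each trial ends in one of four outcome
states determined by the two choices,

| state | subject | opponent | meaning             |
|-------|---------|----------|---------------------|
| R     | C       | C        | mutual cooperation  |
| T     | D       | C        | temptation          |
| S     | C       | D        | sucker              |
| P     | D       | D        | mutual defection    |

and the reinforcement is read off a payoff matrix. The distinctive feature
of the design this package emulates is a *mixed-reinforcement* matrix:
R and T pay pellets (`pR = 1`, `pT = 2` by default), while P and S impose
timeout seconds (`pP = 4`, `pS = 8`) — positive and negative reinforcement
in different physical units. An `allPellet` mode covers the textbook
additive matrix (T = 6, R = 4, P = 1, S = 0 pellets) used in
reward-discrimination arguments; in that mode no timeout ever occurs, and
the validity constraint `pS >= pP` (which is about timeouts) is not
enforced.

Sessions are 30 trials, two per day. Trial durations are a modeling
construction for reward-rate analyses — ITI + response latency + (feeder
light + eating time) on rewarded trials, ITI + latency + timeout on punished
ones — the protocol specifies the component times but no aggregate formula.
Omitted responses (the 45 s response window elapsing) are not modeled: the
experiments report none. The opponent's own earnings (one pellet per FR = 3
completion) are not part of any analysis and are not recorded.

## Memory-one strategies and the induced Markov chain

A subject is summarized as a *memory-one* agent: its probability of
cooperating depends only on the previous trial's outcome state, giving the
transition vector

$$\big(p(c\mid T),\; p(c\mid R),\; p(c\mid S),\; p(c\mid P)\big),$$

plus a first-move cooperation probability (default 0.5; the subjects' first
moves are unreported, so this is configurable and never asserted). All
components 0.5 is "random mode".

Against TFT the outcome states form a Markov chain, because the opponent's
next move is the subject's current one. In the canonical order (R, T, S, P):

* from R or S the opponent will cooperate, so the chain moves to R (subject
  cooperates) or T;
* from T or P the opponent will defect, so the chain moves to S or P.

These structural zeros are validated on every `ChainModel`. The stationary
distribution solves $\pi M = \pi$; `buildChain()` replaces one balance
equation by the normalization row and solves the linear system exactly. Two
independent oracles check this route in the tests: a damped power iteration
(on $(M + I)/2$, which removes periodicity without moving the fixed point)
and a long forward simulation (`simulateChainOccupancy()`).

Two consequences of the TFT coupling are used as internal consistency
checks. First, $\pi_T = \pi_S$ exactly: T states are entered by defecting
against a cooperator and left by the mirror move, so their stationary flows
balance. Second, the long-run probability that the subject's *action* is C
is $\pi_R + \pi_S$ (the states where the subject just cooperated);
`predictedCooperation()` returns this and is the bridge between a group's
transition vector and its reported cooperation mean. For the cooperative
group's vector (0.76, 0.85, 0.93, 0.87) the chain gives $\pi_R = 0.731$ and
cooperation 0.849, against reported values of 0.76 and 0.86 — the package
asserts agreement within 0.05, reflecting that the reported occupancies are
empirical pools, not exact stationary solutions. The two small
matrix-switch "B" arms (three subjects each, s.e.m. up to 0.13) sit farther
from stationarity (0.553 vs 0.64, 0.653 vs 0.71); the tests claim only
2-s.e.m. agreement there and no acceptance-level claim is made.

**Reducible chains.** Degenerate vectors (components exactly 0 or 1) can
disconnect the chain. Because every game starts with a cooperating
opponent, `buildChain()` then reports the stationary distribution of the
closed class reachable from R (provably unique for this topology), sets
`reducible = TRUE` and warns. So ALLC-like vectors give $\pi = (1,0,0,0)$
and ALLD-like vectors $\pi = (0,0,0,1)$, with predicted cooperation 1 and 0.

**Estimation.** `summarizeSessions()` pools trials, counts occupancy, and
estimates each transition component as (cooperations after state X) /
(visits to X), pairing only within a session — trial one has no previous
state and is skipped rather than imputed. Never-visited states yield `NA`
components, never 0/0.

## Payoff-matrix analysis

The contrast index $CI = (p_T - p_R)/(p_T + p_R)$ measures how strongly a
single defection out-pays a cooperative trial: 1/3 for the (1, 2) matrix,
1/2 for (1, 3), 2/3 for (1, 5), 1/5 for (2, 3). It is scale-invariant in
the pellet amounts.

The cooperation-favoring condition is $2 p_R > p_T + p_S$ with the sucker
payoff in pellet-equivalent units. In mixed matrices the S outcome is a
timeout, so its pellet value enters as a user-supplied non-positive
parameter `suckerPelletEquivalent` (default 0). The default deliberately
places the (1, 2, 4 s, 8 s) matrix *exactly on the boundary*
($2 = 2 + 0$): the claim that it favors cooperation implicitly requires a
strictly negative valuation of the timeout, and the package exposes that
assumption as a parameter instead of hard-coding it.

`evaluateStrategies()` evaluates a closed strategy set against TFT — ALLC,
ALLD, the strict alternator (starting with C, matching the worked [C D ...]
sequences), and all 32 deterministic memory-one strategies (an action per
previous state × first move). Deterministic play against TFT is eventually
periodic with period ≤ 4, so totals are computed exactly by cycle detection;
a brute-force trial-by-trial simulation is the test oracle. Both a
per-trial pellet objective and a per-second objective are reported: under
the (1, 2) matrix ALLC and alternation tie at 1 pellet/trial asymptotically
(the boundary $p_T = 2 p_R$), and only the time objective — timeouts make
alternation slow — singles out ALLC as the unique Pareto optimum. The
Pareto flag is therefore computed twice: on finite-session rates and on
limit-cycle rates.

`normalizedReward()` divides a session's pellets by the maximum pellet
total achievable over the same number of trials within the evaluated set.
One subtlety: over a finite 30-trial session under the (1, 2) matrix the
start-with-C alternator earns 31 pellets (a transient R plus 15 T's),
one more than ALLC's 30, so the denominator is 31 and an ALLD session
(2 pellets) scores 2/31 ≈ 0.065. The asymptotic tie is unaffected; the
package follows the exact finite-session rule.

## The simulated-population baseline

`simulatePopulation()` rebuilds the reward/timeout baseline: 100,000
individuals, each a uniformly random arrangement of exactly
`round(0.60 × 30) = 18` cooperative choices (the description "a combination
of thirty C and D choices" reads as fixed composition; an i.i.d. Bernoulli
mode is available behind a flag), played against TFT. Sequences are sampled
with replacement — collisions among the ~8.6 × 10⁷ arrangements are
possible and harmless. `fitSeparationLine()` is the ordinary least-squares
fit of total reward on total timeout over that population, and
`classifyRelativeToLine()` places a subject's session above/on/below it
(tolerance 1e-9 for "on"). In 1000 seeded replicates, sessions generated
from the cooperative group's vector fall above the 60% line ≥ 95% of the
time and ALLD sessions (deterministically 2 pellets, 116 s) fall below.

## Statistical contracts

`rankSumTest()`, `chiSquareVsChance()` and `anovaOneWay()` are thin,
explicitly parameterized wrappers over R's standard engines (exact rank-sum
for both n ≤ 10 without ties, otherwise the normal approximation with
continuity correction; 1-df goodness-of-fit against 0.5; one-way ANOVA with
pairwise t-tests gated on the omnibus test). The ANOVA is one-way across
the four states with Bonferroni-corrected post-hoc comparisons (default
threshold 0.0125 = 0.05/4), following the most specific description of the
analysis; the tests' golden values were computed once with an independent
implementation (SciPy) and frozen. These functions consume per-session or
per-subject summaries passed explicitly — they never reach into raw logs —
and `groupSummaryTable()` produces the standard group-report layout
(cooperation mean ± s.e.m. across subjects, pooled occupancy and transition
estimates). The statistical unit for the occupancy comparison defaults to
per-subject summaries; sessions can be passed directly if per-session units
are wanted.

## The synthetic-cohort generator

No machine-readable behavioral data accompany the study this package
emulates, so the generator *is* the data source, and its defaults encode
the stated world: 30-trial sessions, two per day, acquisition horizons
drawn per subject from Normal(30, 4) truncated at 5 sessions (the reported
30 ± 4 is a mean ± s.e.m.; the spread is exposed as a free parameter), a
cooperation criterion of > 60% for ≥ 5 consecutive sessions, and target
transition vectors taken from `referenceStrategies()`.

Acquisition is emulated *phenomenologically*: the subject's transition
vector interpolates componentwise linearly from chance (all 0.5) to the
group target over the drawn horizon, then is held fixed for a stable block.
No learning rule is fitted or claimed — the drift is an isolated stand-in
that alternative acquisition curves could replace. Non-cooperative subjects
are held at their (near-chance) vector throughout, the simplest reading of
a group that never left random mode.

Reversal (lever meanings swapped to rule out place preference) is modeled
as a policy relabeling: a subject that keeps its motor habit now cooperates
where it used to defect, and both players' state labels swap (R ↔ P,
T ↔ S), so the post-reversal starting vector is
$p'(c\mid X) = 1 - p(c\mid \mathrm{swap}(X))$, followed by a fresh drift
back to target over half the acquisition horizon (configurable).
Matrix-switch arms drift from the pre-switch target to the post-switch
target under the new matrix. `generateExperiment()` assembles the full
two-experiment layout — 8 cooperative (4 with reversal) + 4 non-cooperative
subjects on (1, 2, 4 s, 8 s); 3 + 3 subjects on (1, 3, 4 s, 8 s) switching
to (1, 5, 4 s, 8 s) and (2, 3, 4 s, 8 s) — and every bundle is exactly
replayable from its manifest.

**What a green test establishes.** The generator produces ideal memory-one
behavior with a smooth acquisition path. Passing recovery tests establish
that the pipeline — play, log, pool, estimate, solve — is self-consistent
and unbiased at realistic sample sizes. They do not establish that real
rats are memory-one agents, that acquisition is linear, or that the
reported group vectors generated the reported occupancies exactly (they
demonstrably did not, at the 0.03–0.05 level).

## Numerical and test-design choices

* **Stable-block length vs recovery tolerance.** The rarest state under the
  cooperative vector is P (occupancy ≈ 0.033). Recovering $p(c\mid P)$
  within 0.05 needs its binomial standard error
  $\sqrt{0.87 \times 0.13 / n_P}$ comfortably under that tolerance, i.e.
  $n_P \gtrsim 200$. The recovery acceptance test therefore holds the
  stable phase for 30 sessions (8 subjects × 900 trials → $n_P \approx
  240$, s.e. ≈ 0.022); the generator default (10) reflects a realistic
  5-day stability block instead. Similarly, the per-subject generator
  self-test evaluates the last 10 stable sessions (300 trials,
  s.e. ≈ 0.021) rather than 5, where "within 0.05 in ≥ 90% of seeds" would
  be a coin flip by construction. These sizes were fixed by this power
  analysis before the tests were first run.
* **Random-vector domains.** The oracle-equivalence test draws components
  from U(0.05, 0.95): components arbitrarily close to 0/1 give
  near-reducible chains whose mixing times exceed what a 10⁶-step
  simulation can resolve to 0.01. The inference round-trip draws from
  U(0.25, 0.75) with 20,000 trials so every component's recovery tolerance
  is ≈ 3σ.
* **Worked-sequence timeout.** For [C, D, D, D] against TFT under the
  (1, 2, 4 s, 8 s) matrix the states are R, T, P, P: 3 pellets and 8 s of
  timeout by the rules of the game. A 16 s figure circulating for this
  example is inconsistent with those rules; the package reports the
  rule-derived 8 s.
* **Timeout-rate units.** The reported timeout rate (0.23 ± 0.08) has
  unstated normalization; the package exposes both the timeout-trial
  fraction (via occupancy of S and P) and seconds per trial (via
  `totalTimeout`/`nTrials`) and asserts neither against that number.
* **Indexing.** `classifyCooperator()` returns the 1-based index of the
  first session of the first qualifying run, following R convention.
* **Reducibility tie-break.** When the chain is reducible, the closed class
  reachable from R is reported (unique for this topology) rather than a
  component-wise enumeration.

## Limitations

The package does not model chamber hardware, pretraining shaping, omitted
responses, satiety, or any mechanistic learning process; opponents other
than Tit-for-Tat and memory beyond one trial are out of scope. The
best-strategy search is over the closed deterministic memory-one set (plus
the named strategies), which provably contains the pellet-maximizing
sequence structure against TFT, but not arbitrary history-dependent
policies.
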