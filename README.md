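# ipdbox

Simulation and strategy inference for iterated Prisoner's Dilemma (iPD)
operant experiments.

## What this is for

In a line of animal-cognition experiments, a food-restricted rat plays the
iPD against an opponent implementing **Tit-for-Tat** (cooperate first, then
copy the subject's last choice), with *mixed reinforcement*: pellets for the
rewarded outcomes and timeout for the punished ones. Each trial ends in one
of four states — R (mutual cooperation), T (temptation), S (sucker),
P (mutual defection) — and the payoff matrix (default: 1 pellet for R,
2 for T, 4 s timeout for P, 8 s for S) determines the reinforcement.

`ipdbox` gives researchers analyzing such experiments (or planning them) a
tested toolchain for every computational step:

* **Game engine** — trial-level session simulation against Tit-for-Tat with
  configurable payoff matrices (including the all-pellet additive mode) and
  timing, plus CSV/JSON interchange for session logs and configurations.
* **Agents** — memory-one stochastic policies and the named deterministic
  strategies (ALLC, ALLD, alternator, fixed sequences).
* **Inference** — cooperation rate, state occupancy, and transition-vector
  estimation from logs; the induced 4-state Markov chain and its stationary
  distribution; the >60%-for-5-sessions cooperation criterion.
* **Matrix analysis** — contrast index CI = (p_T − p_R)/(p_T + p_R), the
  cooperation-favoring condition 2p_R > p_T + p_S, exact best-strategy
  economics over the deterministic memory-one set, normalized reward.
* **Population baseline** — the 100,000-individual fixed-cooperation-level
  simulation and its OLS reward-vs-timeout separation line.
* **Statistics** — thin contracts over the rank-sum, chi-square-vs-chance
  and one-way-ANOVA+Bonferroni analyses, and the standard group table.
* **Synthetic cohorts** — a generator for whole experiments (acquisition
  drift, stability, reversal, matrix switches) so every pipeline stage is
  testable without animal data.

## The model in brief

A subject is summarized by its **transition vector**
(p(c|T), p(c|R), p(c|S), p(c|P)): the probability of cooperating given the
previous trial's outcome. Against Tit-for-Tat this induces a Markov chain
on (R, T, S, P) — from R/S the chain can only go to R/T, from T/P only to
S/P — whose stationary distribution π gives the model-implied occupancy,
and π_R + π_S the long-run cooperation probability. See the methods
vignette (`vignettes/ipdbox-methods.Rmd`) for the full account.

## Worked example

```r
library(ipdbox)

tv <- transitionVector(0.76, 0.85, 0.93, 0.87)  # cooperative-group vector
buildChain(tv)
#> ChainModel over states (R, T, S, P)
#>      R    T    S    P
#> R 0.85 0.15 0.00 0.00
#> T 0.00 0.00 0.76 0.24
#> S 0.93 0.07 0.00 0.00
#> P 0.00 0.00 0.87 0.13
#> stationary: R=0.7315  T=0.1180  S=0.1180  P=0.0325

predictedCooperation(tv)
#> [1] 0.849
```

A subject with that vector spends ~73% of trials in mutual cooperation and
cooperates ~85% of the time. Playing one 30-trial session and estimating
back:

```r
session <- playSession(memoryOneAgent(tv), payoffMatrix(), nTrials = 30,
                       seed = 11)
session
#> SessionLog sim [sim/simulation] session 1, matrix R1-T2-P4s-S8s: 30 trials, 29 pellets, 28 s timeout

summarizeSessions(session)
#> StrategySummary over 1 sessions (30 trials)
#>   cooperation rate: 0.867
#>   occupancy: R=0.767  T=0.100  S=0.100  P=0.033
#>   transition vector: p(c|T)=0.667  p(c|R)=0.864  p(c|S)=1.000  p(c|P)=1.000
```

One session estimates the vector coarsely (30 trials); pooling a cohort's
stable sessions recovers it within 0.05 per component (that is one of the
acceptance tests). Strategy economics under the default matrix:

```r
contrastIndex(payoffMatrix(1, 2, 4, 8))
#> [1] 0.3333333

ev <- evaluateStrategies(payoffMatrix(), timingModel(), 30)
ev[ev$strategy_id %in% c("ALLC", "ALLD", "alternator"),
   c("strategy_id", "pellets", "timeout_s", "pellets_per_second",
     "is_pareto_cycle")]
#>   strategy_id pellets timeout_s pellets_per_second is_pareto_cycle
#> 1        ALLC      30         0        0.090909091            TRUE
#> 2        ALLD       2       116        0.007352941           FALSE
#> 3  alternator      31       112        0.086592179           FALSE
```

Alternation matches ALLC's asymptotic pellet rate on this matrix (it even
collects one extra pellet in a finite session via its opening R trial), but
its timeouts make it slower per unit time: on limit-cycle economics ALLC is
the unique Pareto optimum, which is exactly why the mixed-reinforcement
matrix favors sustained cooperation.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the session payoff
totals for the worked choice sequences ([C,C,C,C] and [C,D,D,D] under the
additive and the experimental matrices) and the stationary statistics
implied by the reference group transition vectors (π_R of the cooperative
chain; π_R + π_S for the cooperative, non-cooperative, 2A, 3A and reversal
groups), and writes them as JSON keyed by target id.
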