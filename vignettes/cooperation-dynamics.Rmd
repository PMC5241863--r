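---
title: "Cooperation dynamics in finitely repeated Prisoner's Dilemmas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperation dynamics in finitely repeated Prisoner's Dilemmas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcoop)
```

pdcoop studies what happens to cooperation when the same population plays
many finitely repeated Prisoner's Dilemmas against randomly drawn partners.
Backward induction says a ten-round game with a commonly known horizon
should yield defection everywhere; real populations instead start out
highly cooperative, drift toward earlier first defections for a while
("unravelling"), and then — if enough players keep conditionally
cooperating no matter what — settle into a stable, partially unravelled
state. The package provides the four pieces needed to study this
quantitatively with no external data: a deterministic game engine over
threshold strategies, a smoothed fictitious play population model, a
strategy-inference procedure for behavioural logs, and a synthetic
experiment generator with known ground truth.

## The game and the strategy set

One game is `H = 10` rounds of a simultaneous Prisoner's Dilemma with
per-round payoffs `T = 7` (defect on a cooperator), `R = 5` (mutual
cooperation), `P = 3` (mutual defection), `S = 1` (cooperate on a
defector), satisfying `T > R > P > S` and `2R > T + S`. Two derived
normalisations summarise the incentives: `g = (T - R)/(R - P)`, the gain
from defecting one round early, and `l = (P - S)/(R - P)`, the loss from
being defected on. The default matrix gives `g = l = 1`: defecting exactly
one round before a conditional cooperator is payoff-neutral over the whole
game, which places the experiment in a regime where unravelling is neither
free nor prohibitively costly.

Players are modelled as using one of eleven pure strategies: threshold
strategies `T1 ... T10`, where `Tx` cooperates conditionally up to round
`x - 1` and defects unilaterally from round `x` (`T1` is always-defect),
and full conditional cooperation `CC` (grim trigger). All strategies
retaliate in *grim* fashion — one observed defection by the partner
triggers permanent defection. We adopt grim rather than tit-for-tat
retaliation because `CC` is defined as grim trigger and the threshold
strategies are its truncations; the rare forgiving variant observed in
real play is handled at the inference stage, not in the engine. Round
indices are 1-based throughout, and games with no defection are encoded as
`H + 1 = 11` wherever a number is required (`rd_none()`); this "C bin" is
part of every first-defection distribution the package produces.

`strategy_payoff_table()` gives the total game payoff for all 121 ordered
strategy pairs in closed form. With `a` the smaller and `b` the larger of
the two effective thresholds: both earn `R * H` if `a = b = H + 1`; each
earns `(a-1)R + (H-a+1)P` if `a = b <= H`; otherwise the earlier defector
earns `(a-1)R + T + (H-a)P` and the later `(a-1)R + S + (H-a)P`. The test
suite checks this closed form against the round-by-round playout engine on
every pair for horizons 2 through 12; the two are exactly equal, which is
the package's core internal consistency guarantee.

## The learning model

The population model is smoothed fictitious play over the eleven
strategies. Each of `N` agents is either *resilient* — plays `CC` in every
game, never updates — or *rational*. Rational agent `i` keeps a vector of
counts `pi_i` of the strategies its past opponents played (plus a prior),
and before each game computes expected utilities
`u_i(s) = sum_t pihat_i(t) U[s, t]` against the normalised counts, then
samples its strategy from

```
P(s) ∝ exp( (u_i(s) / u_scale) / beta )
```

computed stably by shifting by the maximum. Agents are then paired
uniformly at random (`N/2` disjoint pairs), every pairing is played out
deterministically, and each agent increments the count of its opponent's
strategy by one.

Parameter choices that matter:

* `beta = 0.005` (dimension: points of game payoff) — the published
  choice. With raw point utilities this puts the model deep in the
  sharp-choice regime: a two-point utility gap (one round of `g = 1`
  mis-timing) maps to an odds ratio of `exp(400)`. The reported dynamics
  are insensitive to `beta` anywhere in `[0.001, 0.1]`, which is only
  possible in this regime.
* `u_scale = 1` — utilities enter the softmax in raw points per game.
  This is the standard logit-choice form with `beta` as a temperature in
  payoff units. We also implemented the alternative of normalising
  utilities by the maximum game payoff (`u_scale = T*H = 70`); at
  `beta = 0.005` that variant leaves unravelling visibly incomplete after
  2,000 games without resilient cooperators (mean first defection ≈ 1.4
  rather than 1) and is sensitive to `beta` across `[0.001, 0.1]`, so raw
  points are the default. `u_scale` remains configurable.
* `prior` — one pseudo-count on `CC`, zero elsewhere: agents start out
  believing others conditionally cooperate, which matches the observed
  highly cooperative first games. A uniform prior is available; because
  counts accumulate one observation per game, the prior's influence decays
  hyperbolically and the asymptotic results do not depend on it.
* `belief_update = "true"` (default) credits the opponent's actually
  sampled strategy label. The `"censored"` option splits the increment
  equally over all strategies consistent with the opponent's *observed*
  actions (observationally equivalent thresholds are indistinguishable
  when the opponent never defected first). Both are faithful readings of
  belief updating from play; the true-label variant is the default because
  simulated agents' strategy labels exist and the censored variant's
  equal-split rule is an extra modelling assumption. The choice matters
  quantitatively: censoring weakens the perceived fraction of conditional
  cooperators and lowers the stabilisation point by roughly one round.

### Asymptotics and the critical mass

`estimate_r_inf()` estimates the asymptotic round of first defection as
the mean per-pairing first-defection round (C games count as 11) over the
final 25% of games, restricted to pairings containing at least one
rational agent, and requires at least 50 games in the window. With
`N = 100` and 2,000 games per run:

* `alpha = 0`: cooperation unravels completely, `r_inf = 1.0`, modal
  strategy `T1`.
* `alpha = 0.4`: unravelling stabilises with `T9` modal and substantial
  `T10`/`T8` shares; `r_inf` ≈ 8.7. The underlying mixed equilibrium
  against a 40% grim population puts weights near (1/3, 1/2, 1/6) on
  (`T8`, `T9`, `T10`), whose pairing arithmetic yields ≈ 8.7; the
  experimental stable-phase value this emulates is about 8.2, so the
  model reproduces the location of the stabilised state to within half a
  round.
* `alpha = 0.99`: the lone rational agent learns end-game defection only,
  `r_inf = 10.0`.

`sweep_alpha()` traces `r_inf(alpha)` and reports the critical mass
`alpha_star` as the largest grid value whose mean `r_inf` stays at the
complete-unravelling floor, operationalised as `mean <= 1 + 0.5`. The 0.5
margin separates the exact floor (where seeds agree to three decimals)
from the first departures (≈ 1.8 at the next grid point); the estimate is
insensitive to this choice anywhere in roughly `(0.1, 0.7)`. On the grid
`{0, 0.025, ..., 0.3}` with 10 runs per value the transition sits at
`alpha_star = 0.05`–`0.075`: below it the floor, above it a sharp,
epidemic-threshold-like rise — the qualitative shape and location (≈ 0.1)
of the published curve. In the transition region the curve is noisy and
not monotone run-to-run (nearby `alpha` values can stabilise at different
partial plateaus), so the monotonicity property is checked as a rank
correlation over the whole grid rather than pointwise.

## Inferring strategies from play

Strategy inference works from observed actions only. For each player-game,
`consistent_strategies()` marks every strategy whose deterministic replay
against the opponent's *observed* actions reproduces the player's actions
exactly. Multiple strategies are typically consistent — if the opponent
defected first at round 5, every threshold above 5 and `CC` prescribe
identical retaliation — so a single game cannot identify a strategy;
identity is resolved over time by an exponentially weighted moving
average: `w(j) = indicator(j) + gamma * w(j-1)`, with `gamma = 0.818`
(a ten-game period, half an experimental day). Play consistent with no
strategy raises an `OTHER` flag that enters the same recursion.
`assign_strategy()` takes the argmax with ties broken: known strategies
beat `OTHER`; thresholds beat `CC`; among tied thresholds the largest
(most cooperative) wins, which keeps assignments stable as opponents'
defection rounds vary. Games a player missed are skipped without decay by
default (`missing = "decay"` discounts across the gap instead).

A forgiving variant of `Tx` — defect at `x`, then resume cooperating for
a round or two when the partner cooperated at `x` — is coded as `Tx`, with
a tolerance window of two resumed rounds starting immediately after `x`.
Two rounds is the tolerance because longer resumed cooperation is no
longer a threshold strategy in any useful sense; the window requires the
partner to have cooperated at the threshold round, so exploiting
retaliation is never excused.

`classify_resilient()` flags a player as a resilient cooperator when at
least 80% of their non-missing stable-phase games (days 7–20 by default)
are assigned `CC`. On the default synthetic experiment (2% action noise)
the classification recovers the planted types with accuracy 1.0; with
noiseless play the `OTHER` fraction is exactly zero and grows
monotonically with the noise rate.

## Steady-state detection

`steady_state_onset()` pools each day's per-game first-defection rounds
(sessions pooled, games treated as independent, C games included as 11 —
they are part of the distribution; a flag excludes them) and applies a
two-sample Kolmogorov–Smirnov test to each adjacent pair of days. The
asymptotic p-value is used even though the support is discrete, matching
common practice; a permutation p-value is available, and a Mann–Whitney
variant serves as a robustness check. The onset of the steady state is
reported as the earlier day of the first non-significant adjacent pair:
behaviour changed detectably into every earlier day and stopped changing
from the onset day on. We considered requiring *every* later adjacent pair
to be non-significant, but with ~13 stable-phase boundaries tested at
level 0.05 that rule is broken by a single false positive about 40% of
the time, pushing the detected onset arbitrarily late; it remains
available as `rule = "all"`. Under the default rule the planted day-7
change point of the synthetic experiment is recovered exactly in 50 of 50
seeds.

## The synthetic experiment generator

`generate_experiment()` emits experiment-shaped logs: two sessions of 48
and 46 players by default, 20 days of 20 ten-round games, uniform random
within-session pairing, a planted 40% of resilient cooperators, and
rational players whose scripted threshold drifts linearly from `CC` down
to a plateau of `T9` reached on day 7. Two realism devices shape the
drift: fractional day-targets are realised by stochastic rounding, so the
first-defection distribution shifts detectably on *every* pre-plateau day
(a step schedule would make adjacent early days statistically identical
and the change point unrecoverable), and realised thresholds get a ±1
jitter with probability 0.2, giving the first-defection histogram a
realistic spread. Each intended action flips independently with
probability `noise` (default 2% in the default configuration). Dropouts
remove a player from pairing after a uniformly drawn exit day; an odd
head-count is handled by sitting one random player out per game. A
`rational_mode = "learning"` variant drives rational players with the
fictitious play model instead of the script, for end-to-end realism;
scripted mode exists so inference tests do not depend on the learning
model's behaviour.

What the generator does *not* emulate: the game and session restart
effects of real play (thresholds are constant within a day), payment
incentives, reaction times, and any strategy outside the eleven-strategy
set plus noise. Passing recovery tests on synthetic data therefore shows
that the inference and change-point machinery is correct under the stated
generative assumptions, not that real populations satisfy them. Under the
planted stable phase the no-defection share is ≈ `alpha^2` (both partners
resilient), so `implied_cc_fraction()` recovers the planted fraction —
0.16 of fully cooperative games implying 40% conditional cooperators.

## Numerical and degenerate-input choices

* Softmax probabilities are computed with a max-shift; utilities of any
  magnitude are safe.
* All-zero belief vectors are rejected (a prior misconfiguration), as are
  odd population sizes, `gamma` outside `[0, 1]`, and payoff matrices
  violating the PD inequalities.
* All-zero EWMA weights (no games observed) assign `OTHER`.
* `estimate_r_inf()` is undefined at `alpha = 1` (no rational players) and
  errors rather than returning a number; `alpha_star` is `NA` when no
  grid point sits on the unravelling floor.
* A single-day log yields an empty session-restart result with a warning;
  a single-game day makes the game-restart effect an error.
* Ties in the strategy argmax are exact (weights are sums of powers of
  `gamma`), so the tie-break order is deterministic and documented.

## Problem sizes

The test suite and the acceptance script use the study-scale conditions
throughout: `N = 100`, 2,000-game runs (4,000 for the long-run
permanence check), 10 seeds per reported mean, a 13-point `alpha` grid
with 10 runs per point, and 50 generator seeds for change-point recovery.
A full run of the simulation suite takes a few minutes on one core; the
deterministic engine and inference tests run in seconds.

## Known limitations

* The learning model stabilises ≈ 0.5 rounds above the experimental
  stable-phase first-defection round at `alpha = 0.4`; the location of the
  critical mass and both boundary limits are reproduced. The model makes
  no attempt to fit `beta`, the prior, or the belief-update rule to data.
* The inference procedure assigns within the eleven-strategy set plus
  `OTHER`; mixtures, probabilistic strategies and histories outside grim
  retaliation are out of scope by design.
* The KS test's asymptotic p-value is conservative on heavily tied
  discrete data; onset days from small logs should be read with the
  permutation option.
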