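---
title: "Models and methods behind wtrackrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wtrackrl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task

`wtrackrl` models continual learning of spatial alternation on a six-arm
track. Animals (or simulated agents) first explore the track for roughly two
weeks of daily sessions, rewarded at any arm that is not an immediate repeat
of the previous one. They then face a series of *alternation contingencies*:
triples of arms (outer, center, outer) such as 2–3–4, presented without any
external cue, under the rule

* a **center-arm** visit is rewarded iff the immediately preceding visit was
  not the center arm;
* an **outer-arm** visit is rewarded iff the immediately preceding visit was
  the center arm *and* the most recently visited outer arm was not this arm
  (waived for the first outer visit of a session if no outer arm has been
  visited yet);
* the three remaining arms are never rewarded, but their visits still count
  as "the immediately preceding arm".

Trials starting at the center arm are *outbound* (correct choice: the outer
arm not visited most recently); all other trials, including the first trial
of a session, are *inbound* (correct choice: the center arm). The default
schedule (`default_schedule()`) runs the canonical contingency order 234,
123, 345, 246, 234, 456, three sessions per day, with session lengths
ramping from 10 center visits (first alternation day) through 20 to 40.
Sessions end at the first visit after the center-visit limit; the 30-minute
wall-clock limit of the physical rig is not modeled (sessions end by visit
count only), and "missed pokes" — approaches that fail to break the
reward-well beam — are not simulated, as they are artifacts of the physical
apparatus.

# The agents

All model variants are working-memory actor–critic agents trained by the
REINFORCE policy gradient. The state is the pair
$s_t = \{a_{t-1}, a_t\}$ of the previous and current location; with six arms
plus the rest box this gives 43 states (36 arm pairs, of which the 6
same-arm pairs are representable but unreachable since revisits are
disallowed; 6 rest-box-to-arm states; 1 rest-box start state). The memory
slot always receives $a_{t-1}$ — the gating is fixed open.

Action preferences are *propensities* $m(a, s_t)$, summed from up to four
components:

$$m_3(a, s_t) = b(a \mid a_t, a_{t-1}) + b^i(a)
  + b^{n1}\,\chi(a = a_t \pm 1) + b^{n2}\,\chi(a = a_t \pm 2)$$

* **M1** uses only the state-transition table $b(a, s)$ (pure working
  memory);
* **M2** adds the dynamic independent arm preference $b^i(a)$;
* **M3** adds the scalar neighbor preferences $b^{n1}$ (one arm away) and
  $b^{n2}$ (two arms away), applied in both directions where the track
  permits — at the edge arms only the in-range side receives the bias;
* **M3noArm** keeps the neighbor terms but drops $b^i$.

Propensities pass through a softmax over the five arms other than the
current one (all six from the rest box); the probability of revisiting the
current arm is exactly zero. The softmax subtracts the maximum propensity
first, so it is invariant to common shifts and cannot overflow.

Learning uses the TD prediction error
$\delta_t = r_t + \gamma V(s_{t+1}) - V(s_t)$ with a 43-entry critic table
$V$. Each trial every component first decays by $(1-\omega)$ — the
forgetting that encodes the task's nonstationarity and pulls all
preferences towards indifference — and then the visited state's transition
column, the arm-preference vector, the neighbor scalars and $V(s_t)$
receive REINFORCE/TD increments scaled by $\alpha\delta_t$. The neighbor
increment for distance $i$ uses the summed probability mass on the one or
two in-range arms at $\pm i$. A single $(\alpha, \omega)$ pair governs
every rule; no variant has more than the three shared parameters
$\alpha \in [0,1]$, $\gamma \in [0,1)$, $\omega \in [0.001, 0.015]$ (the
constructor additionally admits $\omega = 0$ as the no-forgetting limit for
analysis).

**Initialization and session boundaries.** All propensities and values
start at zero — the symmetric, preference-free prior that forgetting decays
towards; an animal's exploratory period then shapes them via
`force_trajectory()`, which overrides the agent's choices with the observed
visit sequence while rewards, prediction errors and all updates proceed
normally. The return to the rest box is not modeled: each session restarts
the agent at the rest-box state, and no TD update bridges the gap (the last
within-session update uses the last on-track successor state). The
transition-table decay applies uniformly to all 43 columns each trial,
including rest-box states, following the unconditional $(1-\omega)$ factor
of the update rules.

The per-trial loop is implemented in C++ (`src/sim.cpp`) and mirrors, to
machine precision, the exported single-step R functions
(`total_propensity()`, `action_probabilities()`, `prediction_error()`,
`apply_updates()`); a test replays a compiled simulation through the R
reference and asserts bit-level agreement. Repeat $k$ of a simulation uses
seed $\texttt{seed} + k$, so averages over repeats are reproducible and any
prefix of the repeat set is stable. As a numerical guard, a free-play
session is truncated at 5000 visits; with any reachable propensity values
the center-visit limit terminates sessions far earlier.

# Behavioral metrics

* `preference_stats()` — arm-visit probabilities (and their maximum), the
  6×6 transition matrix, neighbor-transition frequency, directional inertia
  (the fraction of consecutive transition pairs continuing in the same
  direction), and the two-away frequency conditioned on non-neighbor moves.
  Transitions never bridge session boundaries: the first visit of a session
  has no predecessor.
* `large_sweep_rate()` — sweeps are maximal monotone runs of visits; a
  run's span is the number of arms it covers ($|$last − first$|$ + 1); at a
  direction change the pivot visit belongs to the run it terminates.
  Visits in runs spanning more than three arms (default) are counted
  against the total.
* `direction_alternation_rate()` — each trial is labelled continue/reverse
  relative to the previous move's direction; a direction alternation is a
  flip of that label between consecutive trials. All contingencies demand
  perfect direction alternation, which makes the metric a probe for
  generalization of higher-order task structure.
* `performance_curves()` — per-visit reward probability smoothed with a
  Gaussian kernel (SD 10 arm visits), inbound/outbound error likelihoods
  smoothed in trial-type index (SD 10 for display, 2.25 when fitting) and
  linearly interpolated back to visit index, and the trials-to-criterion
  statistic (first visit at which the smoothed reward probability exceeds
  0.75; `NA` if never). Kernels are truncated at ±4 SD and renormalized at
  series edges, so smoothing is a convex combination — rates stay in
  [0, 1] — and never crosses contingency boundaries.

# Fitting

Parameters are fit per animal by approximate Bayesian computation: the
objective (`abc_objective()`) forces the model through the animal's own
exploration, lets it play the schedule freely up to the last fitted
contingency, and sums — with equal weight — the RMS differences between
animal and model-average smoothed inbound and outbound error curves over
the fitted contingencies (defaults: contingencies 2 and 3, the most
representative ones: they follow other simple contingencies and precede
the arm-skipping one). Model repeats are truncated or padded (repeating
the final value) to the animal's per-type trial counts before averaging.
The comparison is made in trial-type index space; since the schedule
budgets match the animal's, interpolating both sides to visit index would
change little while coupling the two error types. Every evaluation reuses
the same simulation seed (common random numbers), making the objective
deterministic given parameters and seed.

Minimization uses simulated annealing — geometric cooling from $T_0 = 1$ by
0.95 per step, Gaussian proposals with per-parameter SD equal to 10% of the
bound range, reflected at the bounds — restarted at least four times from
random initial conditions; the restart with minimal error wins, and the
full restart record is kept in the result. `fit_animal_batch()` repeats the
whole fit (default 20 times) and reports per-parameter medians and IQRs.
`reward_maximizing_params()` finds the parameters maximizing mean
alternation reward by a seeded grid search (default 5×5×5) with one local
refinement pass; ties break to the lowest grid index.

Problem sizes for the shipped experiments were chosen to keep a full
parameter-recovery run on a single core to a few minutes: 50 simulation
repeats per objective evaluation, 100 annealing steps, and four restarts.
At these settings the median absolute error on the learning rate over a
10-rat synthetic cohort is well inside the 0.15 tolerance the recovery
property demands; 200 repeats and 400 steps (the defaults of
`fit_animal()`) tighten the objective further at proportional cost.

# Inference

* `mc_null_p()` — Monte-Carlo p-values against simulated nulls, floored at
  1/draws (with the conventional 10,000 draws the smallest attainable p is
  $10^{-4}$). The three preference tests condition progressively: uniform
  choice for the maximum arm probability; the animal's own arm-visit
  probabilities for neighbor frequency; its full transition matrix for
  directional inertia. Generated null sequences reproduce the animal's
  session structure.
* `population_randomness_test()` — a random-effects test of H$_0$: the
  population probability of a subject being random is 0.5, against the
  one-sided alternative. Each Monte-Carlo sample classifies animal $i$ as
  random with probability $\Phi_i$ (independent Bernoulli across animals —
  the natural reading of the mixture), counts the random subjects $m$, and
  averages the fair-binomial lower tail $\sum_{k \le m} \binom{N}{k}/2^N$.
  Summing over the random count $m$ (rather than the non-random count)
  is what reproduces the expected magnitudes — e.g. $2^{-N}$ when no
  animal is random; an exact Poisson-binomial enumeration backs the sampled
  version in tests. The three preference tests are Bonferroni-corrected at
  $0.05/3 \approx 0.0167$; no other corrections are applied.
* `paired_permutation_test()` — sign-flip permutations of paired
  differences, mean difference as statistic, add-one-smoothed p-values.
* `crossing_permutation_test()` — for two groups of model repeats and an
  animal reference, the statistic is the difference of mean 75%-crossing
  delays (model group mean curve crossing minus the animal's crossing,
  averaged over contingencies); group labels are permuted over the pooled
  repeats, each repeat keeping its curves across contingencies. Curves
  that never cross are censored at the final trial + 1. The reported p is
  the upper-tail quantile of the observed difference among permuted ones.
* `rank_order_r2()` — squared correlation of rank orderings (average ranks
  on ties); `median_split_compare()` — median split on a score with a
  rank-sum comparison of outcomes (the exact distribution where ties
  permit; fully tied outcomes give p = 1). For comparisons described
  ambiguously as "paired rank sum", both the paired sign-flip permutation
  and the signed-rank convention are available via `paired_permutation_test`
  and `stats::wilcox.test(paired = TRUE)` respectively.

# The synthetic cohort

`gen_exploration()` samples session-structured visit sequences from a
softmax kernel combining log arm-preference weights, a neighbor bias added
to arms one step away, and a directional-inertia bias added to arms
continuing the previous move's direction (dropped at the track edges,
where no continuing arm exists); immediate revisits are excluded, so every
visit is rewarded under the exploration rule. Defaults emulate the
observed scale: 15 sessions × 26 rewards = 390 exploration trials, inside
the 362–425 range of the real cohorts. `gen_cohort()` then drives an M3
agent per rat — forced through that rat's own exploration, then free play
— with known ground-truth $(\alpha, \gamma, \omega)$, enabling end-to-end
parameter-recovery experiments. `default_cohort_configs()` draws
heterogeneous per-rat settings: gamma-distributed arm weights, neighbor
bias in [0.4, 2], inertia bias in [0.2, 1.4], $\alpha \in [0.1, 0.9]$,
$\gamma \in [0.2, 0.8]$, $\omega \in [0.002, 0.012]$ — ranges wide enough
for the rank-order analyses to have signal while keeping every agent's
behavior numerically tame.

**What the generator does and does not emulate.** It reproduces the
session structure, the scale and the three exploratory preference families
of real cohorts, and alternation behavior that is *exactly* M3 — which is
what makes recovery experiments interpretable. It therefore cannot exhibit
the behaviors M3 lacks: persistent large sweeps into the first
contingency, or the growth of direction alternation in later contingencies
(generalization). One real-data pattern deliberately not asserted about
synthetic cohorts: in rats, exploratory neighbor preference correlates
with overall alternation reward. In the generator this correlation is
absent by measurement — forcing a neighbor-richer exploration does raise
the learned $b^{n1}$ at the start of alternation, but under forgetting
that initial advantage decays within the first contingency, and
per-contingency gains (1, 5, 6) and losses (3, 4) cancel across the
schedule when learning parameters are held fixed. Tests accordingly assert
the mechanistic chain (generator bias → exploration statistics → learned
propensity) rather than the cohort-level correlation; with real animals
the correlation plausibly reflects covariation between preferences and
learning ability that the generator's independent parameter draws do not
encode.

# Degenerate inputs and tie-breaks

Invalid arms, repeated arms in forced trajectories, empty trajectories,
all-equal median-split scores, and out-of-bounds parameters raise
immediate errors. Trials-to-criterion on a never-crossing curve is `NA`
for descriptive use and censored at length + 1 inside the crossing
permutation test. Grid-search ties break to the lowest index. Contingency
labels can repeat within a schedule (234 appears twice), so all analyses
key on the contingency *index*, reconstructed per rat from consecutive
label blocks when a table is read from file.
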