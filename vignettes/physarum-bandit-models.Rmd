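---
title: "Decision models for Physarum on the two-armed bandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision models for Physarum on the two-armed bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physbandit)
```

## The experimental system being modelled

A *Physarum polycephalum* plasmodium placed on a start block between two
linear arms of 31 one-millimetre agar sites faces a two-armed bandit: each
site is either blank agar or oat-agar (a reward), and the distribution of
rewards differs between the arms. The cell extends a leading edge along each
arm one site at a time; the arm on which it first reaches the final site is
the arm it "chose". The first site of each arm always carries food, forcing
at least one sample of both options. `physbandit` reconstructs this system
in silico: arenas, candidate decision rules, a forward simulator, and
Bayesian model selection over the rules.

## Belief state

All decision rules condition on the same six quantities: the previous move
direction, whether it was rewarded, and per-arm success/failure counts
$A_R, A_L, B_R, B_L$. Each count starts at 1 — a pseudo-observation that
encodes a uniform (Beta(1,1)) prior on the arm's food density — so the
posterior density on arm $a$ after exploration is Beta$(A_a, B_a)$, with
posterior mean $A_a/(A_a+B_a)$, and $A_a + B_a - 2$ always equals the
number of sites discovered on that arm. Consuming the forced first sites
(`initialize_on_arena()`) sets $A_R = A_L = 2$.

## The ten candidate policies

Each policy returns $P(\text{move right})$; the left probability is the
complement, and tied comparisons return $1/2$.

| id | rule |
|---|---|
| `autocorrelation` | repeat the previous direction |
| `anti_autocorrelation` | reverse the previous direction |
| `most_successes` | indicator of $A_R > A_L$ |
| `highest_mean` | indicator of $A_R/(A_R{+}B_R) > A_L/(A_L{+}B_L)$ |
| `relative_successes` | $A_R/(A_R{+}A_L)$ |
| `relative_means` | $m_R/(m_R{+}m_L)$ with $m_a = A_a/(A_a{+}B_a)$ |
| `most_likely` | indicator of $P(X_R > X_L) > 1/2$ |
| `probability_matching` | $P(X_R > X_L)$ |
| `chemotaxis` | follow food at the next site (1 / 0 / 1/2) |
| `gittins` | indicator of the higher Gittins index |

Here $X_a \sim$ Beta$(A_a, B_a)$ are the posterior food densities.
$P(X_R > X_L)$ is computed by an exact finite-sum identity for integer
counts (`beta_superiority()`), with adaptive quadrature (absolute tolerance
$10^{-8}$) as the fallback for non-integer counts; the identity was
validated against the closed form $P = 5/6$ for counts $(2,1)$ vs $(1,2)$
and against Monte-Carlo sampling.

Every policy is corrupted by a behavioural noise parameter $\theta \in
[0,1]$, the fraction of moves on which the cell ignores its rule: the move
probability becomes $(1-\theta)p + \theta/2$. This mixture (a fair coin
with probability $\theta$) is the simplest symmetric corruption and keeps
every trajectory likelihood strictly positive for $\theta > 0$, which the
marginal-likelihood machinery requires. The persistence rules have no
defined direction before the first move and fall back to $1/2$ there. The
chemotaxis rule is deliberately parameter-free so that model comparison is
not biased by extra fitted parameters; it is isolated behind the policy
interface and easy to replace with a graded-attraction variant.

### Ties and numerical comparisons

Count comparisons are exact integer arithmetic (the mean comparison uses
cross-products, so no floating-point ratios are compared). Comparisons of
computed quantities — posterior superiority and Gittins indices — use a
$10^{-9}$ tolerance around equality; exactly symmetric states short-circuit
to $1/2$ before any computation.

## Arenas and treatments

`treatment_registry()` builds the twelve study layouts on 31-site arms with
5% w/v oat-agar rewards. Evenly spaced layouts place reward $k$ of $n$ at
site $1 + \mathrm{round}(k(L-1)/(n-1))$, which forces site 1, reaches site
$L$, and makes consecutive gaps differ by at most one; random layouts draw
the non-initial reward positions uniformly without replacement. For the
non-binary bandit both arms carry eight graded rewards drawn uniformly on
[1%, 8%] and rescaled so that the high-quality (HQ) arm's total
concentration is exactly twice the low-quality (LQ) arm's. The default
totals are $8 \times 5\% = 40\%$ (HQ) and $20\%$ (LQ), i.e. mean site
concentrations of 5% and 2.5% — the same reward concentration as the
binary treatments. A literal reading of the totals as 5% and 2.5% *sums*
is infeasible (eight sites of at least 1% each sum to at least 8%), so the
exact 2:1 ratio is the enforced constraint; rescaled magnitudes are clipped
back into [1%, 8%] and renormalised (at most 100 rounds, tolerance
$10^{-9}$), with the ratio always taking precedence over the per-site
range. Which physical side carries the HQ arm is a per-replicate fair coin,
as in the experiments.

## Forward simulation and summary statistics

`simulate_trajectory()` draws one move per time step on exactly one arm
(observed simultaneous extension on both arms is rare in the experiments
and outside the models' one-move grammar) and stops the moment either arm's
last site is reached, so trajectories hold between $L-1$ and $2(L-1)-1$
moves. Everything is reproducible from an integer seed, and seeded helpers
restore the caller's RNG state.

Two statistics summarise choice behaviour:

* **Discovery-difference curve** (`first_discovery_difference()`): rank $i$
  is *site index* $i$ — the moment the larger of the two leading edges
  first reaches site $i$ — and the recorded value is (HQ sites) − (LQ
  sites) discovered at that moment, averaged over replicates with a 1.96
  standard-error band (zero-width when fewer than two replicates
  contribute). A replicate exploring only the HQ arm scores $i-1$ at rank
  $i$. Replicates whose trajectory ends before rank $i$ (possible only for
  externally truncated data, since a complete trajectory attains every
  rank) carry their final difference forward by default; a flag drops them
  instead, because the aggregation rule used for the original figures is
  not stated.
* **HQ-choice proportion** (`proportion_hq_first()`): the fraction of
  replicates finishing on the HQ arm, with a two-sided exact binomial test
  against 0.5 (`stats::binom.test`, conventional point-mass handling). It
  refuses equal-quality treatments, where no HQ arm exists.

## Gittins indices by calibration

The Gittins index of a Beta$(A,B)$ Bernoulli arm is the retirement rate
$\lambda^*$ at which playing the arm (with the option to retire later) and
retiring immediately have equal value. `gittins_index()` bisects on
$\lambda$ (default tolerance $10^{-4}$); each candidate is evaluated by
backward induction over the posterior lattice, truncated at the first
horizon $T$ with $\gamma^T < 10^{-8}$ (hard cap 2000), so truncation error
is negligible against the bisection tolerance. At $\gamma = 0$ the index
reduces exactly to the myopic mean $A/(A+B)$, and the policy to the
highest-mean rule. The study does not report its discount parameter;
$\gamma = 0.9$ is the package default, exposed everywhere as an argument
and recorded in outputs. Indices are memoised per discount; when a long
simulation needs the whole lattice, it is filled by depth so each bisection
is bracketed by the already-computed neighbours (the index is increasing in
$A$ and decreasing in $B$), roughly halving the bisection work. When the
Gittins policy enters model selection its discount stays fixed — it is a
benchmark, not a fitted competitor.

## Marginal likelihood and model selection

For a trajectory replayed under model $m$ with noise $\theta$, each
realised move contributes $\log[(1-\theta)p_0 + \theta/2]$, where $p_0$ is
the model's noise-free probability of that move; moves forced by an
exhausted opposite arm contribute $\log 1$. The evidence integrates the
summed log-likelihood over $\theta$ with a uniform prior on $[0,1]$ by the
trapezoid rule on an evenly spaced grid (default 101 points), stabilised
with log-sum-exp; a $-\infty$ grid point (a deterministic policy
contradicted at $\theta = 0$) simply drops out of the sum. The trapezoid
error is second order in the grid spacing and is typically around
$10^{-3}$–$10^{-4}$ in log evidence at the default grid — far below the
between-model evidence gaps that drive selection (tens of log units).
`select_model()` applies a uniform model prior, one shared $\theta$ per
model across treatments, and lexicographic tie-breaking.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure of the experiment:
named treatments, tens of replicates per treatment (default 30, matching
the scale of the study's batches), per-replicate randomisation of the HQ
side, fresh random layouts per replicate for random/non-binary treatments,
and an exclusion flag emulating discarded replicates (cells that left the
arm; the real exclusion frequency is unreported, so the default rate is 0).
Excluded replicates stay in the files so that exclusion handling is
testable; analysis functions skip them by default. Steps are ordinal — the
10-minute photographic interval of the experiments is not modelled, because
every decision rule is defined per move, not per minute.

The generator reproduces move sequences under a *known* policy; it does not
emulate biomass, tubule morphology, simultaneous two-arm extension, arena
departure, or any within-step timing. Tests passing on synthetic data
therefore validate the estimation machinery (likelihoods, evidence, summary
statistics) and the internal consistency of the models — not the biological
claim that real cells follow any particular rule.

### Binary versus graded success counting

By default any positive reward magnitude counts as one success, which is
exact for the binary treatments. On the non-binary bandit both arms carry
*equally many* rewards, so binary counting makes every count-based rule
blind to the quality difference by construction; the `graded` switch
instead accumulates `reward / 0.05` per rewarded site (one unit per
5%-equivalent), letting success counts carry magnitude information. The
package's qualitative reproduction of HQ preference on the non-binary
treatment uses the graded switch; all binary treatments use the default.

## Problem sizes and runtime choices

The shipped checks use sample sizes chosen to make binomial and Monte-Carlo
error small relative to the effects tested: 2000 replicates per treatment
for choice proportions and neutrality checks, 100 pooled replicates (over
`4e_vs_8e`, `4r_vs_8r`, `1_vs_8e`) for model recovery, five repetitions per
generating model for the confusion diagonal, $10^6$ draws per Monte-Carlo
comparison of the posterior-superiority identity, and 2000 simulations of
100 pulls for the stationary-bandit benchmark.

## Known limitations

* The chemotaxis rule and the noise construction follow the package's
  stated forms; the original supplementary formulations were not available
  and alternatives can be slotted in behind the policy interface.
* Random layouts are regenerated from the stated placement rules, not
  copied from the original site maps.
* `most_likely` and `highest_mean` threshold almost the same posterior
  comparison on reachable states and are not mutually distinguishable in
  recovery experiments; the confusion-matrix check therefore uses the eight
  mutually distinguishable non-Gittins models.
* Simultaneous extension of both arms within one time step is not modelled.
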