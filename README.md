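# physbandit

Decision-making models for *Physarum polycephalum* on the two-armed bandit.

The slime mould plasmodium, a single giant cell with no nervous system,
can choose the better of two foraging environments. In the experimental
paradigm this package models, the cell sits between two 31-site arms whose
sites are blank agar or oat-agar rewards; it extends a leading edge along
each arm one site per step, and the arm whose last site it reaches first is
the arm it "chose". `physbandit` provides the computational side of that
paradigm:

* **Arenas** — constructors for the twelve treatment layouts (even, random
  and graded non-binary reward distributions) with JSON serialisation.
* **Decision models** — ten candidate rules for the next move, from simple
  persistence to Bayes-optimal, expressed as stochastic policies
  `P(move right | state)` over a shared belief state (per-arm success and
  failure counts with Beta(1,1) pseudo-observations), each mixed with a
  behavioural noise parameter θ: `p ↦ (1−θ)p + θ/2`. The winning heuristic
  is **Relative Successes**, `P(m_t = R) = A_R / (A_R + A_L)` — explore
  each arm in proportion to the rewards found there.
* **Gittins indices** — the optimal discounted-bandit benchmark for
  Beta-Bernoulli arms, computed by the calibration method (bisection on the
  retirement rate over a truncated dynamic-programming lattice).
* **Simulator** — forward simulation of policies on arenas, the
  site-discovery difference curve with 1.96 s.e. bands, the HQ-choice
  proportion with an exact binomial test, and stationary-bandit performance
  benchmarking.
* **Inference** — Bayesian model selection: per-model marginal likelihood
  with θ integrated out over a uniform prior (101-point trapezoid,
  log-sum-exp stabilised) and posterior model probabilities.
* **Synthetic data** — a seeded generator of experiment-shaped datasets
  (replicates, side randomisation, exclusions) plus CSV/YAML/JSON I/O.

See the vignette `vignettes/physarum-bandit-models.Rmd` for the full model
description, numerical choices, and limitations.

## Worked example

```r
library(physbandit)

# a 1:2 treatment with four vs eight evenly spaced rewards
tr <- make_treatment("4e_vs_8e")

# simulate 50 replicates of the Relative Successes heuristic, 10% noise
spec  <- policy_spec("relative_successes", theta = 0.1)
trajs <- simulate_replicates(spec, tr, n = 50, seed = 2)

proportion_hq_first(trajs)
#> $proportion
#> [1] 0.9
#> $p_value
#> [1] 4.209852e-09
#> $n_hq_first
#> [1] 45
#> $n
#> [1] 50
```

Ninety percent of simulated replicates finish on the high-quality arm; the
exact binomial test rejects indifference (p ≈ 4 × 10⁻⁹). Model selection
recovers the generating rule from the trajectories alone:

```r
sel <- select_model(trajs, models = c("relative_successes",
                                      "chemotaxis",
                                      "anti_autocorrelation"))
sel
#> <model_selection> models ranked by log marginal likelihood:
#>   relative_successes     log evidence  -1613.438  posterior 1.0000  theta_hat 0.230
#>   chemotaxis             log evidence  -1679.166  posterior 0.0000  theta_hat 0.910
#>   anti_autocorrelation   log evidence  -1684.476  posterior 0.0000  theta_hat 1.000
```

And the optimal benchmark for a single unexplored arm:

```r
gittins_index(1, 1, discount = 0.9)
#> [1] 0.7029114
```

The index exceeds the posterior mean 0.5 — the exploration bonus of an
uncertain option.

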