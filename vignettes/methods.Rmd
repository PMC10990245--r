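---
title: "Models and methods: environment-specific learning rates in a two-casino bandit task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task

`volbandit` simulates and analyses a meta-learning experiment in which a
participant alternates, trial by trial and in uniformly random balanced
order, between two casinos. Each casino hosts an independent two-armed
bandit with anticorrelated binary rewards: on every trial exactly one of
the two slot machines wins, and the currently "correct" machine wins with
probability $p$. The *stable* casino keeps the same correct machine for a
whole block ($p = 0.75$ or $0.8$ depending on the experiment); the
*volatile* casino reverses it every 16–24 within-casino trials
($p = 0.9$); the *test* casinos of the third experiment reverse exactly
twice per block every 29–37 within-casino trials ($p = 0.85$). Because the
per-block casino counts are exact (120 + 120 or 100 + 100), the casino
order within a block is a balanced random permutation rather than
independent coin flips; pooled over blocks the run-length distribution of
consecutive same-casino trials then approaches $2^{-k}$ (50% of runs have
length 1, 25% length 2), which `run_length_distribution()` verifies.

Reversal gaps, including the gap before the first reversal, are drawn iid
uniformly from the configured interval; their distribution beyond the
interval itself is a design choice, as only the interval is specified by
the task. For the test phase the gaps are redrawn until exactly two
reversals fall inside the block: with unconstrained uniform gaps a third
reversal would fit inside the 100 within-casino trials more than half of
the time, contradicting the designed "switches twice" schedule.

Each block introduces a fresh machine pair per casino; the initially
correct machine is a fair coin flip. The generator never produces missing
responses; the data readers and all analyses tolerate and skip them
(in the real task a 5-second deadline produced under 1% missing trials for
nearly all participants).

## The six Rescorla–Wagner variants

All models learn machine values by the delta rule and choose by softmax:

$$Q^{a}_{t+1} = Q^{a}_{t} + \alpha\,(r_t - Q^{a}_t), \qquad
  p^{a}_t = \frac{e^{\beta Q^a_t}}{e^{\beta Q^a_t} + e^{\beta Q^b_t}}$$

with learning rate $\alpha \in [0,1]$, inverse temperature
$\beta \in [0,10]$, rewards $r_t \in \{0,1\}$ and $Q$ initialised at 0.
Q-values are kept per machine, persist across interleaved trials of the
other casino, and reset at block boundaries (fresh machines). The *dual*
variant splits the learning rate by outcome, using $\alpha^{+}$ after
rewarded and $\alpha^{-}$ after unrewarded trials. The *variable* variant
lets the effective rate track recent absolute prediction errors at a
higher-order rate $\eta \in [0,1]$:

$$\alpha_{t+1} = \eta\,|r_t - Q^a_t| + (1-\eta)\,\alpha_t ,$$

applied only after trials on which that rate was used. Each of the three
kinds comes in an environment-specific version (every free parameter has
one copy per casino) and a shared version (one copy for both casinos),
giving six models. Design choices worth stating explicitly:

* In the variable models the free parameter $\alpha$ is the rate at
  $t = 0$ and is then updated by the rule above; in the
  environment-specific variable model each casino's rate is updated only
  after trials in that casino.
* The effective rate of the variable models resets to $\alpha$ at block
  boundaries, symmetric with the Q reset — each block is a fresh learning
  episode.
* Only the chosen machine's value is updated. The anticorrelated reward
  structure would license counterfactual updating of the unchosen machine,
  but the model equations reference only the chosen action's value, so no
  counterfactual update is performed.
* With equal rates the dual model reduces to the single model exactly, and
  with $\eta = 0$ so does the variable model; the implementation preserves
  these reductions bit-for-bit, which the test suite asserts.

## Hierarchical Bayesian estimation

For each combination of phase and environment, each individual-level
parameter is drawn from a group-level normal distribution specific to that
cell. Estimation works on an unbounded scale and maps to the bounded scale
through the probit transform
$\theta = L + (U - L)\,\Phi(\mu_{\text{raw}} + \sigma z)$ with a
non-centred parameterisation ($z \sim \mathcal N(0,1)$ per individual).
Priors: uniform on the bounded group mean — equivalently
$\mu_{\text{raw}} \sim \mathcal N(0,1)$ through the probit change of
variables — and half-Cauchy(0, 5) on the group SD (positive half). Phases
are fitted separately; `by_block = TRUE` replicates the cell structure per
block for the block-evolution analyses. Group-mean contrasts
(`posterior_prob_greater()`) are computed on the bounded scale, where the
reported group means (e.g. learning rates of 0.4 and 0.6) live. Ties count
against the contrast, which is strict; they have measure zero.

### Sampling

Since no Hamiltonian Monte Carlo backend is part of this package's
dependency set, the posterior is explored with an adaptive
Metropolis-within-Gibbs sampler written in C++: scalar random-walk updates
of every raw group mean and log group SD (proposed jointly per cell) and
every individual deviate, with proposal scales adapted toward standard
acceptance targets (0.44 for scalars, 0.30 for the 2-d group proposal)
in batches of 50 during burn-in only, so the post-burn-in chain is a fixed
Markov kernel. Two ancillarity–sufficiency interweaving moves are applied
each sweep: a translation ($\mu \to \mu + \delta$,
$z_i \to z_i - \delta/\sigma$) and a scaling ($\sigma \to c\sigma$,
$z_i \to z_i / c$), both of which leave every bounded individual parameter
— and hence the likelihood — unchanged and are accepted on the prior ratio
alone. These moves decorrelate the group and individual levels and were
the difference between Gelman–Rubin statistics of ~1.3 and ~1.05 at equal
chain lengths in our calibration runs.

The default schedule is four chains of 4000 iterations with the first 1000
discarded, i.e. 12,000 retained draws. Convergence is monitored with the
split-chain Gelman–Rubin statistic on every scalar (threshold 1.1); a
violating fit is flagged, never silently accepted, and `as_mcmc_list()`
exposes the chains to coda for independent diagnostics. Determinism: each
chain's seed is derived from the master seed via the package's seed
ladder, so a fit is reproducible draw-for-draw.

The sampler's correctness is tested three ways: the joint log-density
agrees term-by-term with a hand-composed oracle; with all choices missing
the likelihood is flat and the sampler must reproduce the prior
(closed-form moments); and closed-loop simulation-and-refitting recovers
generative group means.

## Model comparison

Out-of-sample fit is estimated by leave-one-out cross-validation with
Pareto-smoothed importance sampling over the posterior draws, at one-trial
observation granularity (the pointwise likelihood is per trial). The
generalised Pareto tail fit uses the Zhang–Stephens profile posterior mean
with the usual mild regularisation of the shape toward 0.5; tails smaller
than five draws are left unsmoothed (where the estimate coincides with raw
importance sampling, which the tests exploit as an oracle). Totals are
reported as "LOOIC" on the elpd scale — negative, higher is better —
matching the familiar comparison-table layout, with
$\mathrm{SE} = \sqrt{n\,\mathrm{Var}(\widehat{\mathrm{elpd}}_i)}$ and the
difference SE computed from paired per-observation contributions against
the top-ranked model. A deficit beyond twice its SE flags a decisively
worse model. Observations with Pareto shape above 0.7 are counted and
reported, never repaired.

## Simulation studies

**Reward-rate grids** simulate a single casino in isolation (two blocks of
120 within-casino trials) for every cell of a parameter grid — learning
rates 0.01–0.99 by 0.01 against inverse temperatures 0.1–9.9 by 0.1 for
the single model, or $\alpha^+ \times \alpha^-$ with $\beta$ fixed at 4
(the average observed inverse temperature) for the dual model. The number
of replicate runs per cell is exposed as a parameter; the package default is 100. One pool of
schedule realizations is shared across cells (common random numbers), so
between-cell orderings are estimated with less noise than independent
simulation; a 3×3 moving-average smoothed copy is stored for display only
and never used in assertions. The grids establish the design's premise:
the reward-maximising learning rate is higher in the volatile (90/10,
reversals every 16–24 trials) than in the stable (80/20) casino, at nearly
equal peak reward rates.

**Model recovery** simulates datasets from each of the six models under
the reference generative settings — environment-specific learning-rate
means 0.4 (stable) and 0.6 (volatile), inverse temperatures 3.5 and 4.5,
higher-order rates 0; shared means 0.5 and 4; SDs 0.2, 2 and 0.1 — fits
all six to each dataset, and tabulates which model wins the LOOIC ranking.
Individual parameters are drawn from normals on the bounded scale
truncated to the bounds: means at a bound (the variable models' $\eta$
mean of 0) make untruncated sampling impossible, and truncation is the
cleaner density compared with clipping.

**Parameter recovery** simulates, per environment, cohorts from the dual
model at each combination of group-mean learning rates
$\{0.2, 0.4, 0.6, 0.8\}$ and inverse temperatures $\{2, 4, 6, 8\}$
(SDs 0.2 and 2), refits, and correlates all true individual parameters
with individual-level posterior means.

**Posterior predictive checks** simulate, for every retained joint
posterior draw, each participant's full choice sequence conditional on the
trial sequence they saw, average the simulated reward rate over draws, and
correlate it with the observed reward rate across participants per
environment; the fraction of participants whose observed rate lies inside
their central 95% simulated band is reported as a calibration summary.

Every study derives one child seed per dataset and per fit from its master
seed, so partial reruns are reproducible.

## Behavioral statistics

Participants are retained only if their learning-phase reward rate beats
chance in both environments: a 1-df chi-square of the win count against
half the trials at $\alpha = 0.05$ — two-sided statistic with the
directional requirement that the rate exceed 0.5, the natural reading of
"significantly higher than chance". Lose-switch rates condition on
unrewarded within-casino trials and score whether the next within-casino
choice differs; pairs spanning block boundaries are excluded because each
block introduces new machines. The post-reversal analysis tracks the
proportion of participants choosing the correct machine on the first 10
within-casino trials after each test-phase reversal, with per-position
2×2 chi-squares (no continuity correction, deliberately uncorrected for
multiple comparisons, mirroring the exploratory analysis it reproduces).
Block-wise reward-rate contrasts and the lose-switch environment contrast
are paired one-tailed t-tests in the direction the full-scale studies
establish; zero-variance differences are flagged as degenerate rather
than reported as infinite statistics.

## Problem sizes used by the test suite

The full study sizes (e.g. 10 datasets per generating model × 36
participants × 360 model fits for model recovery) are available through
the functions' defaults but take hours of CPU. The shipped test suite runs
the same code at reduced, fixed-seed sizes chosen to keep the whole suite
in the tens of minutes on one core while preserving each study's
qualitative claim:

* model recovery: 3 datasets per generating model at the full cohort size
  of 36 participants (cohort size stays at full scale because it is what
  separates the single model from its variable-rate neighbour — at 16
  participants the two are not reliably distinguishable), 2 chains ×
  (250 burn-in + 450 retained), LOOIC from every third retained draw;
  asserted: diagonal dominance of the recovery matrix;
* parameter recovery: 4 corner/diagonal combinations per environment, 12
  participants; asserted: all true-vs-estimated correlations above 0.6;
* contrast recovery: 10 repetitions at the first experiment's full size
  (36 participants, 2 × 240 trials), 2 chains × (400 + 1000); asserted:
  volatile-over-stable posterior probabilities above 0.95 for both dual
  rates in at least 8 of 10 repetitions;
* reward-rate grids: 0.05-step learning-rate axis, 0.5-step inverse
  temperature axis, 200 replicates per cell.

## What the synthetic data do and do not show

The generator reproduces the trial-level structure of the task: balanced
casino alternation, anticorrelated probabilistic rewards, block-wise fresh
machines and the three volatility regimes. Simulated agents are exactly
the fitted models; real participants are not. Passing recovery tests
therefore establishes that the estimation and selection machinery is
sound — that the design identifies these models and parameters — not that
human behaviour follows any of them, and no claim about real data
(response times, fatigue, attention lapses, sequential dependencies beyond
the models) is supported by these simulations.

## Known limitations

* The sampler is random-walk based; it needs more iterations than a
  well-tuned Hamiltonian sampler would for the same effective sample size,
  and very large cohorts make the per-sweep cost (linear in participants ×
  trials × parameter cells) noticeable.
* LOOIC at one-trial granularity treats trials as conditionally
  exchangeable given the state; leaving out a trial does not remove its
  influence on the state trajectory of later trials (the standard caveat
  of pointwise LOO on sequential models, shared with the analyses it
  reproduces).
* Blockwise fits default to one joint model with block-specific group
  cells; refitting each block separately is equally possible by
  subsetting the data, and the two differ only through shared
  convergence behaviour.
* The half-Cauchy group-SD prior is taken on the positive half.
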