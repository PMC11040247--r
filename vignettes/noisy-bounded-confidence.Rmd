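---
title: "Noise in bounded-confidence opinion dynamics: model, conventions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise in bounded-confidence opinion dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`noisybc` simulates a population of $n$ agents whose opinions are scalars
$x_i \in [0,1]$ — for instance, concern about climate change from extremely
dismissive (0) to extremely alarmed (1). The baseline dynamic is the
Deffuant bounded-confidence (BC) rule with pairwise interactions and
asynchronous updating: in each time step two distinct agents are drawn
uniformly at random, and each one moves toward the message it receives from
the other if and only if that message lies within its confidence bound,

$$
x_i \mapsto
\begin{cases}
x_i + \mu\,(m_j - x_i) & \text{if } |m_j - x_i| \le \epsilon\\
x_i & \text{otherwise,}
\end{cases}
$$

where $\mu \in (0, 0.5]$ is the convergence speed and $\epsilon$ the
confidence bound. A small $\epsilon$ operationalizes a strong confirmation
bias. Without noise the message is the sender's true opinion,
$m_j = x_j$. Comparisons at the bound are non-strict ($\le$) everywhere.

Both members of a dyad update simultaneously from each other's *pre-step*
opinions. This symmetric convention preserves the classic Deffuant baseline
exactly in the zero-noise limit (each accepted exchange conserves the pair
sum, so the population mean is invariant and dispersion can only shrink);
with noise active, each direction of the exchange draws its own independent
deviations.

## The four noise types

Noise can enter the social-influence process at four distinct stages. The
package implements each as a separate operator, one active per run, all
parameterized by a single level $\nu \ge 0$ (the *standard deviation* of the
zero-mean Gaussian deviations; a bounded-uniform family
$\xi \sim U[-\nu, \nu]$ is available as a robustness variant):

* **Ambiguity** (`draw_ambiguous_message`) perturbs the *message*:
  $m_j = x_j + \xi$, resampled until $m_j \in [0,1]$. The receiver applies
  the BC rule to the noisy message, which affects both whether the
  interaction succeeds and where the receiver ends up. Because of the
  truncation, a sender pinned at a boundary emits half-normal messages:
  at $x_j = 1$ the mean message is $1 - \nu\sqrt{2/\pi}$, which makes
  extremists systematically more acceptable to moderate receivers — the
  mechanism behind the drift of converged societies toward the edges.
* **Selectivity** (`accept_selectivity`) perturbs the *bound*: the partner
  is accepted iff $|x_j - x_i| \le \epsilon + \xi$, with a fresh untruncated
  deviation per receiver per interaction. A draw making the effective bound
  negative rejects even an identical partner.
* **Adaptation** (`adaptation_shift`) perturbs the *receiver after an
  accepted interaction*: the deterministic BC result is shifted by $\xi$,
  resampled so the posterior opinion stays in $[0,1]$.
* **Exogenous** (`apply_exogenous_jumps`) perturbs *independently of
  interaction*: once per time step each agent jumps with probability
  $\omega = \nu$ by a truncated deviation of scale $\nu$ (frequency and
  amplitude deliberately coupled through the single level parameter, which
  must therefore not exceed 1).

$\nu = 0$ is behaviourally identical to no noise for every type, and the
implementation consumes no random numbers in that case, so zero-noise runs
reproduce the noiseless trajectory draw-for-draw under a shared seed — a
property the test suite asserts exactly.

### Numerical conventions

*Truncation is always by resampling, never clipping.* Clipping would pile
probability mass onto the boundary values; rejection sampling realizes the
truncated distribution the model intends. The resampling loop carries a
defensive attempt cap (10^6); for anchors inside $[0,1]$ the acceptance
probability per attempt is at least ~1/2, so the cap is unreachable in
practice.

*Exogenous scheduling.* The number of jumpers per step is drawn as one
Binomial($n$, $\nu$) variate, jumpers are selected by a partial
Fisher–Yates pass, and each jumper draws its truncated deviation. This is
statistically identical to $n$ independent Bernoulli trials but much
cheaper at small $\nu$, and it fixes a deterministic draw order.

*One engine, two implementations.* The stepping kernel is compiled (Rcpp)
because the ensemble experiments need tens of millions of steps per
second; a pure-R `simulation_step()` implements the identical update rules
and consumes R's RNG stream in exactly the same order. The test suite
iterates both from the same seed across every noise type, distribution
family, communication regime and topology and requires bit-identical
trajectories. All randomness flows through R's global RNG, so one
`set.seed()` fully determines a run.

## Initial conditions

Two generators define the study conditions:

* `init_uniform(n)` — i.i.d. Uniform$[0,1]$ opinions; population
  dispersion concentrates around $1/\sqrt{12} \approx 0.289$.
* `init_six_americas(n, profile)` — survey-calibrated: each agent draws
  one of six attitude categories (dismissive, doubtful, disengaged,
  cautious, concerned, alarmed) i.i.d. with the profile's probabilities
  (defaults 7/11/12/19/33/18 %), then an opinion uniformly within that
  category's sixth of $[0,1]$, i.e. category $k$ occupies
  $((k-1)/6,\,k/6]$.

The sixth-interval-uniform mapping was adopted because it reproduces both
reported moments of the calibrated distribution from the printed category
proportions alone: the implied density has mean
$\sum_k p_k (2k-1)/12 \approx 0.6067$ and standard deviation
$\approx 0.2531$, matching the initial mean $0.60\,(\pm 0.03)$ and
dispersion $0.25\,(\pm 0.01)$ at $n = 100$. Categories are sampled i.i.d.
(multinomial counts) rather than as fixed per-category counts; at
$n = 100$ this choice only affects the across-replicate spread of the
initial moments, which the tests check against the binomial prediction.
`category_of_opinion()` inverts the mapping with the boundary convention
that intervals are half-open on the left and $x = 0$ is dismissive, so an
agent is "concerned" only when $x > 4/6$.

## Metrics

* `dispersion()` — the *population* standard deviation (divide by $n$).
  The sample/population distinction is below the reported precision at
  $n = 100$; fixing one convention keeps every threshold deterministic.
* `excess_kurtosis()` — Fisher-normalized (normal $\to 0$, uniform
  $\to -1.2$); undefined at zero dispersion and flagged as such
  (`opinion_summary()` records `NA` there).
* `count_clusters()` — sort the opinions, split where a consecutive gap
  exceeds 0.05, count groups with at least 2 members. The gap default is
  half the smallest inter-cluster spacing ($2\epsilon$) that the noiseless
  model produces at the strongest bias studied, and the minimum size
  discards lone stragglers that are not meaningful opinion clusters.
  Noiseless runs from uniform initial conditions end with about
  $1/(2\epsilon)$ clusters.
* `is_pea()` — the pro-environmental-agreement predicate: mean opinion
  $\ge 4/6$ (at least "concerned" on average) *and* dispersion $\le 0.1$
  (the society largely agrees), both non-strict, evaluated on the final
  snapshot. The non-strict reading of the dispersion bound was chosen for
  consistency with the non-strict BC comparisons; the predicate is
  evaluated on exact floating-point values, so the choice is untestable at
  ensemble scale but should still be fixed.

## Communication regimes and topology

Beyond the default dyadic exchange, two broadcast-style regimes are
available. Their precise update rules are package conventions (documented
here, deliberately excluded from the headline reproductions):

* **many-to-one** — one receiver hears `regime_k` distinct senders, each
  message independently noisy per the active type, and updates once toward
  the *mean of the accepted messages*; senders do not move.
* **one-to-many** — one sender broadcasts to `regime_k` distinct
  receivers. Under ambiguity the broadcast is a *single* noisy signal
  shared by all receivers (one draw per step — a public post is one
  signal); selectivity and adaptation deviations remain per-receiver.

The interaction graph is complete by default. A Watts–Strogatz small-world
alternative (degree 10, rewiring 0.1 — conventional values, as none are
prescribed for the main protocol) draws dyads uniformly over edges; it is
defined for the dyadic regime only.

## Ensembles, sweeps and the transition estimator

`run_ensemble()` runs seeded replicates whose seeds come from the
counter-based `derive_seed()` (an injective affine map modulo
$2^{31}-1$), so ensembles are reproducible and order-independent;
`sweep_grid()` assigns per-cell seeds from the canonical sorted cell order
for the same reason. `pea_frequency()` reports the fraction of replicates
whose final state satisfies `is_pea()`.

`estimate_critical_noise()` locates where agreement breaks as the noise
level rises: the first upward crossing of ensemble-mean final dispersion
through 0.1, linearly interpolated between bracketing grid points. One
subtlety: the agreement window is *interior* in $\nu$. At very low noise
the fragmented clusters of the noiseless model survive the full run, so
mean dispersion starts above 0.1, dips into agreement, and rises again at
the breaking transition. The estimator therefore skips the low-noise
plateau and interpolates the crossing *after* the dispersion has entered
the agreement region; a grid with no such crossing is an error, never an
extrapolation. For adaptation noise at $\epsilon = 0.2$ this yields
$\nu^*/\epsilon \approx 0.21$–$0.23$, consistent with the theoretical
transition at $0.25\,\epsilon$ (the dispersion threshold trips slightly
before the theoretical line).

## Problem sizes

The default protocol is $n = 100$, $\mu = 0.5$, $t = 10^5$ steps (2000
interactions per agent on average). Published phase diagrams average 1000
replicates per cell; the package's acceptance checks use 100–200
replicates per cell, which puts ~3 percentage points of binomial standard
error on a frequency near 0.75 and proportionally less near the
extremes — ample for the tolerances asserted. Larger ensembles are a
matter of passing a bigger `replicates`.

Worth knowing when interpreting results at these sizes: the drift of
converged societies toward the opinion-space edges is a finite-size effect
that weakens with larger $n$, and the width of the bias range in which
noise induces agreement grows with both $n$ and $t$ — so the diffuse-state
dispersion at strong bias ($\epsilon = 0.05$, ambiguity $\nu = 0.08$)
measures ~0.25 at this protocol, a little below the rounded 0.3 one might
quote for a state that "stays diffuse" at its initial dispersion of 0.29.

## What the generators do and do not emulate

The synthetic initial conditions reproduce the *distributional* facts the
study conditions specify: the uniform hypothetical society, and the
six-category survey calibration with uniform placement inside each
category. They do not model covariates, household or network correlation
in survey responses, opinion-dependent sociability, media agents, or
heterogeneous/adaptive $\epsilon$ and $\nu$ — all outside the scope of
this package. Passing tests therefore certify the simulator and its
ensemble statistics under these idealized conditions, not predictions
about any empirical population.

## A worked run

```{r example}
library(noisybc)

cfg <- model_config(epsilon = 0.175,
                    noise = noise_spec("ambiguity", 0.13),
                    init = "six_americas", seed = 7)
res <- run_simulation(cfg)
tail(res$summary, 3)
is_pea(res$final)

ens <- run_ensemble(cfg, 200, seed = 20260929)
ens$summary$pea_frequency

g <- grid_spec(epsilon = c(0.05, 0.175, 0.3),
               nu = c(1e-10, 0.08, 0.18),
               noise_types = "ambiguity", replicates = 100,
               base = model_config(init = "six_americas", seed = 1))
sw <- pea_frequency(g)
sw$cells
```

## Known limitations

* One noise type per run; interacting noise types are out of scope.
* The broadcast-regime update rules and the small-world parameters are
  package conventions; quantities measured under them should be compared
  across configurations of this package, not against external references.
* The transition estimator assumes the dispersion profile crosses its
  threshold once after entering the agreement region; exotic profiles with
  multiple re-entries report the first crossing.
* At $\epsilon$ near the noiseless consensus threshold (~0.3) individual
  runs occasionally end polarized (two clusters separated by more than
  $\epsilon$); ensemble means at moderate replicate counts inherit a few
  percentage points of variability from such outcomes.
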