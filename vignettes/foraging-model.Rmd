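---
title: "Optimal resource allocation of parasitoids in fragmented habitats: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal resource allocation of parasitoids in fragmented habitats: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(fragforage)
```

## The question

Habitat fragmentation confronts a foraging parasitoid female with smaller
host patches, longer travel between them, and less certainty of emerging
near hosts at all.  Because longevity and egg load draw on the same limited
resource pool, fragmentation should reshape how females split that pool —
and how much costly phenotypic plasticity and learning ability they should
maintain to adjust the split during life.  `fragforage` simulates individual
females through their lives in parameterized habitats and uses a genetic
algorithm to find, for each habitat, the reproductive strategy that
maximizes mean progeny per generation.

## The model

### Trade-off, plasticity and its cost

A female's resource budget lies on a linear trade-off between lifespan
(0–1000 time steps) and egg load (0–1000 eggs); the endpoints are arbitrary
scale choices and only set units.  A strategy is the heritable triplet:

* **G1** — the initial position on the trade-off, expressed in longevity
  units (0–1000).  `g1 = 0` is all eggs, `g1 = 1000` all lifespan.
* **G2** — the phenotypic plasticity range, in units along the trade-off
  (0–1000).  `g2 ≈ 0` describes a proovigenic wasp (eggs fixed at
  emergence); large `g2` a synovigenic one that can re-allocate throughout
  life.
* **G3** — the memory factor of the learning rule, in [0, 1].

Plasticity carries a linearly proportional cost `c`, acting symmetrically:
both axes of the trade-off are rescaled by `1 − c · g2/1000`.  Maximal
plasticity at `c = 0.5` thus halves both the maximal lifetime and egg load.
The reachable interval of positions has width `g2` (after cost scaling) and
is centred on the scaled `g1`.  The source description shows G2 as a range
around G1 without pinning the convention, so centring is a design choice
here — symmetric reachability matches the model's bidirectional trading of
longevity and eggs — and the one-sided alternative is available via
`habitat(..., bounds = "upper")`.  At the frontier edges the interval is
shifted inward rather than truncated, preserving its width.

### Patches, gain and leaving

Each habitat patch initially holds `n0` hosts.  Cumulative progeny gained
after `t` steps on a patch follows the saturating exponential

$$N(t) = N_0\,(1 - e^{-\alpha t}),$$

the standard depletable-patch gain curve; `alpha` defaults to 0.01 per time
step, which makes patch residence times commensurate with travel times of
100–500 steps.  Both the curve object and `alpha` are replaceable
(`gain_curve()`), since the shape is a modelling convention rather than a
measurement.

Females leave a patch in marginal-value-theorem fashion: when the local
gain rate falls to the environment-wide average rate.  The model
implements the environment-wide rate as the female's own *learned
estimate* `μ` (default, `leave_rule = "learned"`): she leaves once the
per-step gain drops to `μ`.  Because `μ` is diluted by the zeros observed
while travelling, residence times lengthen with travel time — the classic
MVT response — and because `μ` is capped by `1/t1`, residence also
lengthens on richer patches, whose early gain rates far exceed any
attainable estimate.  An analytic variant (`leave_rule = "mvt"`) leaves
at the first integer step where `N'(t) ≤ N(t)/(t + T)`; for this gain
family that crossing is *independent of patch quality* (both sides scale
with `n0`), so residence cannot respond to `n0` under it — the reason the
learned threshold is the default: quality-dependent patch exploitation is
what couples the memory factor to habitat quality.  Either way one
dynamic modifier applies: a female leaves only if her remaining lifespan
covers the travel to the next patch, re-evaluated every step — otherwise
she stays on the depleted patch.

### Learning

Females estimate their overall host encounter rate by a linear operator,

$$\mu_i = G_3\,\mu_{i-1} + (1 - G_3)\,\lambda_i,$$

updated every step of life.  The instantaneous rate `λ` is 0 while
travelling and the per-step gain increment on a patch, capped at `1/t1`
(`t1` = time to the first host on a fresh patch); the prior `μ0` is the
midpoint of those two extremes.  The estimate maps linearly onto the
plasticity interval: `μ = 0` targets its longevity end, `μ ≥ 1/t1` its egg
end.  The linearity of the map is the simplest monotone choice consistent
with the stated direction (more encounters → more eggs, less longevity).

### Budget accounting

The budget is tracked as a dimensionless fraction of the cost-scaled
frontier: living one step consumes `1/eff_longevity`, committing one egg
consumes `1/eff_eggload`.  Re-allocation re-aims only the *unspent*
fraction — time already lived and eggs already laid are irrevocable — which
makes conversion exact and gives the audit identity

> time spent + eggs committed + unspent remainder = 1

to floating tolerance (~1e−14 observed over 10⁴ random lives).  Eggs are
laid as whole integers through a fractional accumulator (gain is
continuous, progeny discrete); while a female is egg-limited, surplus whole
hosts encountered are lost rather than banked.  The step order is frozen as:
clock/budget, foraging and laying, learning update, re-allocation,
patch-leaving — the order is not dictated by the model description but
affects edge cases, so it is fixed and tested.  Re-allocation happens every
step by default (`reallocate = "patch"` restricts it to patch transitions).

A generation ends when the female runs out of time; a female out of eggs
with lifespan left keeps living (and learning), and plasticity may convert
remaining longevity back into eggs.  There is no travel mortality.  Fitness
is the arithmetic mean progeny over 20 independent generations (the only
between-generation stochasticity is the Bernoulli(p) natal-patch start).

With an optimized plastic strategy in a deterministic habitat (`p = 1`)
and exactly optimal patch leaving (`leave_rule = "mvt"`), time and eggs
run out nearly together: the optimum converts surplus egg budget into
extra lifespan (more patches) until both are exhausted.  Exact
coincidence is impossible in discrete time — life ends within a partial
step and up to one whole egg can remain unlayable — so the unspent
remainder at death can legitimately reach about two step-equivalents; the
test suite asserts it stays under three.  Under the learned leaving
threshold this exhaustion is *not* guaranteed: females there are
encounter-rate-limited rather than egg-limited, converting surplus egg
budget into end-of-life steps is worth almost nothing, and the optimizer
wanders a near-neutral ridge on which some strategies strand unlaid eggs
at negligible fitness cost.

## The optimizer

A steady-state genetic algorithm in the GENITOR style: 100 real-coded
chromosomes (genes in [0,1]³ decoded to the strategy ranges), 500 cycles,
each cycle producing one offspring from two rank-selected parents (linear
ranking, bias 1.5) by per-gene blend crossover with probability 0.60 —
otherwise cloning the fitter parent — with per-gene mutation probability
0.025 (uniform redraw), replacing the current worst chromosome.  Each
chromosome is evaluated once, at creation, over 20 generations; lucky
evaluations are not re-checked, which the 10-restart best-of rule
mitigates.  Each habitat is optimized 10 times from independent populations
and the best solution kept.  The operators (blend crossover, uniform
mutation) are standard real-coded choices; the rates are the model's, the
operators are this package's.

Worst-replacement makes the best-so-far fitness non-decreasing;
`evolve()` accepts any injected fitness function, so the optimizer is
testable against analytic surfaces independently of the simulator.

Where the simulation is deterministic (`p = 1`) and patch leaving is
analytically optimal, independent optimizations agree closely on fitness
and on G1/G2, but G3 is close to selectively neutral there — with a
certain natal patch the learned trajectory barely matters — so its
optimized value wanders; under the learned leaving threshold G2 sits on a
similar near-neutral ridge (see above).  These neutralities are
themselves model predictions worth remembering when reading optimized
values cell by cell.

## The factorial experiment

`design_grid()` holds the study grid — `n0 ∈ {25, 50, 100, 250, 500, 750,
1000}`, `T ∈ {100, …, 500}`, `p ∈ {0, 0.25, 0.5, 0.75, 1}`, `c ∈ {0.1, …,
0.5}`, 875 situations — and `run_design()` optimizes every cell with
per-cell seeds derived from one master seed (a fixed linear congruential
map, `cell_seed()`), so batch runs are reproducible and resumable.  The
optimized parameters are analysed with a fixed-effects 4-way ANOVA with all
six two-way interactions, factors categorical, one best-of-restarts
observation per cell: on the full grid the main-effect dfs are (6, 4, 4, 4)
and the residual df 736.  The design is balanced with one observation per
cell, so sequential sums of squares coincide with Type II/III.
`trend_summary()` gives the per-level mean ± SE tables behind the usual
trend figures.

## Scales used in the shipped analyses

The package's own checks run at reduced scale so they stay quick and
deterministic, chosen as follows:

* Budget conservation: 10⁴ random strategy × habitat lives.
* GA recovery: injected surface `−(g1 − 500)²`, population 50, 200 cycles,
  3 restarts, 10 seeded runs (tolerance ±25 on g1, i.e. 2.5% of range).
* Directional trends: a reduced 24-cell design (`n0 ∈ {25, 1000}`,
  `T ∈ {100, 500}`, `p ∈ {0, 0.5, 1}`, `c ∈ {0.1, 0.5}`) at population
  50, 200 cycles, 3 restarts, replicated over several master seeds.  The
  natal probability keeps its uncertain middle level deliberately:
  plasticity is selected for under environmental *uncertainty*, and with
  `p` restricted to {0, 1} the G2 trends flatten into noise.  At this
  scale all six expected signs (G1 up with travel time, up with poorer
  patches, down with a safer natal start; G2 down with cost, up with
  travel time; G3 down with patch quality) hold in ≥ 92% of single master
  seeds.  The acceptance script replicates the design over 20 master
  seeds before taking the signs.

What passing these checks shows — and does not.  The simulator is an
idealized model: solitary thelytokous females, no host feeding, no egg
maturation delay, no superparasitism, no travel mortality, identical
patches within an environment.  Reproducing the directional results says
the implementation embodies the same mechanism, not that real wasps behave
this way quantitatively.

## A worked example

```{r}
env <- habitat(n0 = 100, travel_time = 300, p_natal = 0.5, cost = 0.2)
fit <- optimal_strategy(env, ga_control(pop_size = 50, cycles = 200,
                                        restarts = 3), seed = 1)
summary(fit)
```

```{r}
set.seed(2)
mean(simulate(fit, nsim = 50))   # realized progeny per generation
```

```{r, fig.width = 5, fig.height = 4}
plot(fit)
```

## Numerical notes

* All randomness flows through R's RNG (`set.seed()` controls the C++
  engine too); identical seeds give bit-identical trajectories, and the
  pure-R reference implementation of the female's life
  (`init_female()`/`step_female()`) agrees exactly with the compiled
  engine.
* Integer leaving times: `mvt_leaving_time()` returns the first step at
  which the rate condition holds, which matches the exhaustive argmax of
  `N(t)/(t+T)` to within one step across the study grid.
* Degenerate inputs: `g2 = 0` collapses the plasticity interval to a
  point; `g1` incompatible with survival (e.g. shorter than the natal
  travel) simply yields zero progeny; a plasticity cost consuming the
  whole budget is rejected at initialization.
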