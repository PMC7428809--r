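---
title: "A multiscale model of stem-cell and crypt metapopulation dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale model of stem-cell and crypt metapopulation dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Epithelial tissues such as the intestinal lining renew from small pools of
stem cells organized into proliferative units -- crypts. `cryptsim`
simulates such a tissue at two coupled scales. Within a crypt, stem cells
follow a stochastic birth-death process: each cell divides symmetrically
(two stem daughters, net +1), divides asymmetrically (one stem daughter and
one differentiated cell, net 0, but still a mutation opportunity), or is
lost to death or differentiation. Between crypts, a metapopulation dynamic
operates on a flat hexagonal lattice: a crypt whose last stem cell dies is
extinct, and neighboring crypts -- released from its homeostatic inhibition
-- expand and bifurcate into the vacant slot, each daughter crypt receiving
half of the parent's stem cells with their full mutation histories.

Every run measures the time to tumor initiation, defined as the
inactivation of both alleles of a tumor suppressor gene (TSG) in at least
one stem cell. The first allele hit is neutral; the second ends the run.
Runs can also end in whole-tissue extinction or be censored at the time
horizon (80 years by default).

### Rates and homeostatic feedback

An unmutated stem cell divides symmetrically at `base_division_rate`
(0.05/day) and asymmetrically at `asym_to_sym_ratio` (20) times that, and
is lost at `base_loss_rate` (0.04878/day). `base_division_rate` is read as
the *symmetric* division rate: with that reading the birth flux (0.05)
balances the loss rate (0.04878) and an isolated crypt holds a stable
census, while asymmetric divisions act purely as mutation opportunities.

Crypts defend a target census `crypt_size` through exponential feedback.
With `n` living stem cells:

* below target, every cell's division rate is multiplied by
  `division_effect_base^((crypt_size - n)/crypt_deviation)`;
* above target, every cell's loss rate is multiplied by
  `loss_effect_base^((n - crypt_size)/crypt_deviation)`.

Both bases default to 2 and `crypt_deviation` to 2.0 cells, so each
two-cell deviation doubles the corrective rate. (A ten-fold sharper
feedback scale of 0.2 is sometimes quoted for models of this kind; the
parameter is configurable, and all defaults here use 2.0.) At the target
census both multipliers are exactly 1: the loss-feedback clock is a single
multiplied clock, not an extra competing clock, so the balanced baseline is
not silently perturbed.

While a crypt has dead neighbor slots, two things change: its loss
feedback is suppressed entirely (the extinct neighbor no longer
contributes inhibitory signal), and its division rate gains a factor
`dead_neighbor_division_multiplier` (2) per dead neighbor. This is what
lets a crypt overshoot to `bifurcation_factor * crypt_size` (twice target)
and split into the vacancy.

### Mutations

At each division opportunity (both daughters of a symmetric division; the
retained stem cell of an asymmetric one) a cell draws two independent
coins. With probability `mutation_rate` (5e-4) it acquires one non-neutral
mutation: deleterious with probability `deleterious_fraction`, otherwise
beneficial-category. Deleterious mutations split 50/50 between reducing
division and survival; beneficial ones split 40/40/20 between raising
division, raising survival, and the mutator phenotype. Each fitness
mutation multiplies the affected rate by `fitness_factor` (1.01) or its
reciprocal (0.990099, always computed as `1/fitness_factor`, never stored);
effects compound multiplicatively without bound. The mutator phenotype is
single-hit: it multiplies both mutation probabilities by `mutator_factor`
(100), capped at `mutation_rate_max` (5e-2) and `tsg_mutation_rate_max`
(5e-5); further mutator mutations change nothing. Independently, with
probability `tsg_mutation_rate` (5e-7) the cell takes a TSG hit.

Note the structural relation in the defaults: the TSG cap equals the base
TSG rate times the mutator factor, so the cap binds exactly for a
factor-100 mutator and never truncates it below its nominal rate. Scaled
study designs that raise the base TSG rate should scale the cap with it,
or different mutator strengths collapse onto the same capped rate and
become indistinguishable by construction.

### Event scheduling

The engine is a discrete-event simulation over competing exponential
clocks. Each cell carries a pooled division clock with rate
`(1 + asym_to_sym_ratio) * r_sym` -- the division kind is drawn
1 : `asym_to_sym_ratio` when it fires, which is distributionally identical
to separate clocks -- and a loss clock. Sampled waiting times are floored
at `division_min_time` (0.05 d) and `loss_min_time` (0 d). Flooring the
pooled clock equals flooring each component, because
`min_i max(E_i, m) = max(min_i E_i, m)`.

Clocks are drawn when a cell appears and redrawn whenever that cell's
rates change: a census or dead-neighbor change in its crypt, or a fitness
mutation of its own. For pure exponentials this redraw-on-change policy is
statistically exact (memorylessness); the floors deform the exponential
slightly, once per scheduled event. The floors are *not* re-applied on
every event in the tissue -- re-drawing all clocks after each of the
twenty-fold more frequent asymmetric divisions would re-impose the
division floor on the pooled waiting time and depress realized division
rates by roughly 10% at baseline, visibly breaking the balanced-rate
design. With the calendar policy the residual bias is a fraction of a
percent, below Monte-Carlo resolution in the oracle comparison below.

Ties in the clock scan are broken deterministically (lowest slot index,
division before loss); exact floating-point ties are measure-zero. The
engine uses its own seeded xoshiro256** generator, so a `(params, seed)`
pair reproduces a run bit-identically on any platform and R's RNG state is
untouched.

### Endpoints and bookkeeping

Initiation is recorded the instant any cell reaches
`tsg_hits_for_initiation` (2) hits, along with whether that cell was a
mutator. Tissue death is the loss of the last stem cell anywhere.
`uncontrolled_threshold` (4x target census) is implemented as an optional
endpoint but disabled by default, since only TSG-inactivation endpoints
are analyzed; enable it with `enable_uncontrolled = TRUE`. The
transient-amplifying compartment (`ta_cells_per_stem`, 2048) is
reporting-only and never enters the dynamics.

## Outcome statistics

* `km_cumulative_hazard()` -- product-limit survival of time to initiation
  over replicates, with cumulative hazard `-log(S)` (Nelson-Aalen as an
  option). Delegated to `survival::survfit()`; an independent brute-force
  product-limit oracle in the test suite checks it on randomized tied
  inputs. When the survival estimate hits zero the hazard is reported as
  `Inf` rather than a finite cap.
* `mutator_fixed_fraction()` -- fraction of living crypts whose every stem
  cell is a mutator (fixation; a 9-of-10 crypt does not count).
* `mutator_agreement_by_distance()` -- among unordered pairs of living
  crypts at each exact hexagonal lattice distance, the fraction sharing
  fixed-mutator status. Exact hex distance is used for the classes, not
  Euclidean bands.
* `crypt_fitness()` / `tissue_crypt_fitness()` -- mean genotype-intrinsic
  division-minus-loss rate over a crypt's cells, feedback excluded, so the
  quantity is comparable across architectures whose feedback states differ
  transiently. Snapshot statistics are taken at the endpoint, whatever the
  endpoint was.
* `turnover_and_burden_metrics()` -- crypt births/deaths, mean crypt
  lifespan, mutations and divisions per day, and the time-weighted mean
  census per living crypt.

## The lattice

Slots live on an axial-coordinate parallelogram (`grid_rows` x
`grid_cols`, default 5 x 5) with hard edges: the tissue is flat, there is
no wrap-around, and edge crypts simply have fewer neighbors (interior 6,
acute corners 2, the other corners 3). Fission targets among several dead
neighbor slots are chosen uniformly at random; the moved half
(`floor(n/2)`) of the cells is sampled without replacement. A crypt
bordering several dead slots can fission repeatedly, but each fission
drops it below threshold, so repeats require regrowth first.

## Sweeps and study designs

`run_sweep()` varies one parameter at a time against a shared baseline.
Two constraint modes reflect two views of tissue organization:
`fixed_crypt_count` keeps the lattice fixed, while
`fixed_total_stem_cells` resizes the lattice on `crypt_size` conditions so
the tissue-wide stem-cell total stays constant. The lattice is resized to
the most-square factorization (`grid_for_total()`); crypt counts that do
not divide the total exactly are an error rather than an approximation.
The virtual key `turnover_multiplier` scales division and loss rates
jointly, emulating faster or slower tissue renewal. Replicate seeds are
`base_seed + 0, 1, 2, ...`, shared across conditions (common random
numbers); manifests record parameters, seeds and package version, which
suffice to regenerate every output byte-identically.

## What the built-in checks do and do not show

The package's tests run the model at reduced scale: a 3 x 3 lattice with
the TSG hit rate raised tenfold (5e-6), 50 replicates per condition, so
that initiation occurs within a small replicate budget. At that scale the
qualitative results reproduce: initiation incidence falls strictly as the
deleterious proportion rises from 0.5 through 0.75 to 0.95; a ten-fold
lower mutation rate and a ten-fold weaker mutator each delay initiation
(the mutator comparison run with the TSG cap scaled to 5e-4 for the
structural reason above, and measured by restricted mean time to
initiation, since 80-year incidence saturates at 1 under the raised TSG
rate); the large majority of initiations occur in mutator cells; and with
100 stem cells split into two-cell crypts there is constant crypt
turnover while fifty-cell crypts never die within 2,000 days.

Engine correctness is checked against independent oracles: hand-evaluated
rate-law values to 1e-12; a brute-force product-limit estimator on 1,000
randomized censored samples; and a naive fixed-step (0.001 d) Bernoulli
birth-death simulator, whose census mean and variance at day 50 the engine
matches within Monte-Carlo error over 10,000 replicates per arm. An
isolated crypt with mutations disabled holds a time-averaged census within
[8, 12] of its target 10 over days 100-1000 for each of 100 seeds.

These are scaled-down, qualitative reproductions. Full-scale curves (5 x 5
lattice, baseline TSG rate 5e-7, 50+ replicates over 80 years) are left to
the user via `run_sweep()`. The model itself abstracts aggressively: no
within-crypt spatial structure, an implicit transient-amplifying
compartment, a single constant fitness-effect size with no distribution,
no back mutation, and mutation rates chosen high to compensate for the
small simulated tissue patch. Conclusions transfer to real tissue only at
the level of trends and mechanisms, not absolute times or incidences. One
boundary behavior worth noting: tissues of single-cell crypts are fragile
(whole-tissue extinctions occur and surviving tissues are degraded), but
under these dynamics the dead-neighbor division boost makes recolonization
fast enough that extinction is not the majority outcome -- more smaller
crypt-level homeostasis assumptions would change that balance.

## Numerical choices

* Feedback exponents use `max(0, .)`: feedback never reverses sign.
* The loss feedback is one multiplied clock. Treating background and
  feedback loss as *additive* competing clocks at equilibrium would double
  the baseline loss rate to 0.09756 and collapse the balanced design; the
  multiplied form keeps the at-target multiplier at exactly 1.
* Fitness multipliers are cached per cell and updated multiplicatively on
  each mutation; exponent arithmetic stays well inside double range even
  at `crypt_size` 180 under a 4x overshoot.
* `run_replicates()` derives seeds additively; keep `base_seed` within R's
  integer range.
* Event logs are optional (`record_events = TRUE`) because long runs
  generate millions of events; aggregate counters, turnover logs and final
  snapshots are always kept.

## Problem sizes used by the test suite

Rate-law and estimator checks are instantaneous. The stochastic checks
use: 100 seeds x 1,000 days (homeostasis); 10,000 replicates per arm to
day 50 (engine-vs-oracle); 50 replicates x 6 conditions on a 3 x 3
lattice to 80 years (initiation trends); 20 seeds x 2,000 days x 2
architectures (turnover). These sizes were chosen as the smallest at which
the trends of interest are decisively resolved.
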