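---
title: "The sticky-cell surface-colonization model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sticky-cell surface-colonization model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stickysim)
```

## The model

`stickysim` is an individual-based model of bacterial surface colonization
built around one trade-off: an adhesive ("sticky") phenotype — a proxy for
extracellular-matrix production — is required for attachment to a surface
but carries a division-rate cost. Cells live in one of two niches:

* a **well-mixed liquid** with carrying capacity $K$ (default 5,000), and
* a **surface lattice** of `height x width` sites (default $100 \times 100$,
  hexagonal), each holding at most one cell.

Sticky cells divide at a relative rate $R \in [0, 1]$ of the non-sticky
rate and can attach to any vacant surface site. Non-sticky cells divide at
full rate but can occupy the surface only while immediately adjacent to a
sticky cell — they hitchhike on their neighbours' adhesive matrix.

Each time step, every cell alive at the start of the step is processed
once, in a freshly shuffled order, and draws **one of five events**
uniformly at random (probability 1/5 each):

1. **Migration to the surface** (liquid cells): with probability $P_m$ the
   cell picks a uniformly random site — over *all* sites, not only vacant
   ones — and attaches only if the site is vacant and the cell is sticky
   or the site neighbours a sticky cell. Otherwise it returns to the
   liquid unchanged.
2. **Migration to the liquid** (surface cells): a non-sticky cell with no
   sticky neighbour is dislodged to the liquid.
3. **Differentiation**: the cell re-decides its phenotype (see strategies
   below).
4. **Death**: the cell dies with probability $P_d$ (default 0.1).
5. **Division**: sticky parents first pass a Bernoulli($R$) gate. A liquid
   daughter needs the liquid below $K$. A surface parent's daughter is
   placed uniformly over the *eligible* vacant neighbouring sites (those
   where it could be retained: the daughter is sticky, or the site
   neighbours a sticky cell) plus one liquid slot if the liquid is below
   $K$ — with all $v$ vacant sites eligible and the liquid open, each slot
   has probability $1/(v+1)$. With no eligible slot the division fails.
   The daughter inherits the parent's phenotype and a possibly mutated
   genotype.

At the end of each step the liquid is **diluted**: uniformly random liquid
cells are removed until the population is back at $K$. Cells born during a
step take part in dilution but draw their first event in the next step.

### Differentiation strategies

Three heritable strategy kinds decide the phenotype at a differentiation
event:

* **pure** — a fixed binary allele; the event is a no-op and switching
  happens only by mutation at division (a mutated pure daughter expresses
  its own allele, since for this strategy genotype and phenotype are the
  same thing);
* **probabilistic** — sticky with probability $P$, non-sticky with
  $1 - P$, regardless of the current state;
* **decision-making** — a threshold gene-regulatory rule on two sensed
  cues, the niche $N$ (0 liquid, 1 surface) and the sticky fraction $S$:
  the cell becomes sticky iff
  $$W_1 N + W_2 S > \theta .$$
  On the surface $S$ is the fraction of neighbouring sites occupied by
  sticky cells; in the liquid it is the population sticky fraction.

The inequality is strict, so the all-zero founding genotype
($W_1 = W_2 = \theta = 0$, $P = 0$, allele 0) never differentiates and
evolution starts from fully non-sticky populations, as intended.

Two readings of "population" are defensible for the liquid cue; the
package defaults to the **global** sticky fraction (liquid plus surface)
and exposes `liquid_S_scope = "liquid_only"` as the alternative. The
global reading creates an interesting feedback: threshold rules in the
liquid pin the global sticky fraction near $\theta / W_2$, which is
visible in evolved runs as a plateaued liquid sticky fraction.

### Mutation

At division each evolvable variable of the daughter genotype mutates
independently with probability `mu_r`; continuous variables receive an
additive Gaussian step with s.d. `mu_s` ($P$ is re-clamped to $[0,1]$;
clamping avoids reflection artefacts at the boundaries), and the pure
allele flips. The defaults `mu_r = 0.01`, `mu_s = 0.1` are package
choices — small enough that strategies evolve gradually through many
intermediate genotypes, large enough that the decision weights reach
order-one magnitudes within $10^5$ steps — and both are config-exposed.

## Geometry

The surface lattice supports four neighbourhoods: `hex6` (default),
`square4`, `moore8` and `tri3`. Hexagonal sites use **axial (rhombic)
addressing** on the rectangular array: neighbours at offsets
$(0,\pm 1), (\pm 1, 0), (-1,+1), (+1,-1)$. We chose axial over the
common "odd-row shifted" offset scheme because the axial offset set is
closed under negation, which makes the neighbour relation symmetric on a
torus of *any* size; parity-based offset schemes lose symmetry on
odd-height tori. `tri3` (honeycomb) alternates its vertical neighbour by
site parity and therefore requires an even height under periodic
boundaries; `lattice_spec()` enforces this.

The boundary condition defaults to **periodic**, avoiding edge artefacts
in the spatial pattern statistics; `bounded` is available, in which case
edge sites simply have fewer neighbours and the sensed $S$ uses the actual
neighbour count.

`hex6` and `moore8` are *continuous* neighbourhoods (a site's neighbours
include mutually adjacent pairs); `square4` and `tri3` are
*discontinuous*. The distinction matters for colony persistence: in a
discontinuous geometry the death of a sticky cell leaves no adjacent pair
of supported neighbours that could reconnect the colony, which is why
surface colonization is fragile there at high stickiness costs.

## Event scheduling

The reference description of the update ("one out of five events can
occur; the event is selected randomly") is compatible with more than one
scheduler. The package default draws exactly one event per cell per step,
uniformly, and then applies the event-specific gate ($P_m$, $P_d$, $R$,
eligibility). This reproduces the stated per-event probabilities as
conditional probabilities and preserves all between-event rate ratios. A
`sequential` mode that attempts all five events in fixed order each step
is provided purely as a sensitivity check: it is a harsher regime (per
step, death is five times more likely, and a cell whose support died is
dislodged before its differentiation chance arrives), under which
climax-style colonies do not persist. All analyses use the default mode.

Within a step, updates are sequential in shuffled order and state changes
are visible immediately — a cell processed later in the step sees the
deaths, differentiations and births that already happened. This is what
makes the colony-fission rescue work: after a sticky cell dies, a
neighbour can differentiate in the very same step.

## Fixture genotypes

The competition assays use hand-specified decision genotypes realizing the
strategies that evolution discovers, making the assays deterministic in
strategy space (`classify_strategy()` verifies each):

| fixture | $W_1$ | $W_2$ | $\theta$ | surface rule | liquid rule |
|---|---|---|---|---|---|
| `climax_genotype()` | 1 | -6 | 0.5 | `threshold_1` (isolated islands) | never |
| `colonizer_genotype()` | 2 | -6 | 0.5 | `threshold_2` (filaments) | never |
| `life_cycle_genotypes()$lc1` | -5 | -6 | -6.5 | `threshold_2` | always |
| `life_cycle_genotypes()$lc2` | -6 | -6 | -6.5 | `threshold_1` | always |
| `life_cycle_genotypes()$lc4` | -10 | 0 | -0.5 | never | always |

`threshold_k` reads "differentiate iff fewer than $k$ sticky neighbours"
(surface) or "iff the population sticky fraction is below $k/6$"
(liquid). The four `lc*` fixtures map onto the four life cycles the model
can evolve: filamentous colonies with sticky propagules, sticky islands
with sticky propagules, sticky islands with non-sticky "parasitic"
propagules (the climax genotype), and a unicellular cycle whose cells are
sticky only in transit.

## Analysis choices

**Surface summary censoring.** The sticky fraction on the surface is
reported only when *more than* 100 cells are attached (strictly greater);
below that the statistic is noise.

**Spatial patterns.** Sticky cells are grouped into connected components
under the lattice adjacency. The verbal pattern classes are
operationalized with config-exposed thresholds: `islands` when at least
90% of components are singletons; `filaments` when the modal component
size is 2–8; `clumps` when a component exceeds 8; `uniform_sticky` when
sticky cells cover more than 95% of the lattice; `none` without sticky
cells. The class precedence follows that order of checks.

**Strategy census.** Genotypes are grouped by exact parameter tuple
(lineage identity maintained by the engine), sorted by abundance with ties
broken by genotype id (oldest first, so the ordering is stable), and the
25 most abundant are classified deterministically on the
$S \in \{0, 1/6, \dots, 1\}$ grid in both niches. Genotypes whose
decisions are not monotone in $S$ (possible when $W_2 > 0$) are flagged
`inverted` rather than forced into a threshold class.

**Life cycles.** Classification uses the end-state census plus pattern
report (not trajectory videos): the dominant strategy pair determines the
cycle, and combinations outside the four known rows return
`unclassified` instead of being silently binned.

**Inflection detection.** Competitions are split into a colonization
phase A and a climax phase B at the maximum of a centered moving average
of the first differences of total population size; the window defaults to
about a tenth of the recorded points (forced odd). On a clean logistic
curve this recovers the midpoint exactly, which is the unit test for it.

## Study profiles and problem sizes

Two configuration profiles bundle the study conditions:

* `full_profile()` — $100 \times 100$ surface, $K = 5000$,
  $4 \times 10^5$ steps: the reference scale.
* `scaled_profile()` — $50 \times 50$ surface, $K = 1250$,
  $10^5$ steps: a quarter-scale profile the package uses for replicated
  experiments (its tests run five to ten replicates per condition).

The replicated sticky-fraction plateaus are computed at the scaled
profile; the climax colonization assay and the two competition assays run
at the full grid, where their reference setups are defined (100 founder
cells per genotype, saturated liquid, $P_m = 0.01$ for the competitions).
Evolutionary plateau *fractions* transfer well between scales because
they are set by the local lattice geometry of the evolved patterns;
absolute population *counts* scale with the lattice area and are only
compared at the full profile.

## What the simulations do and do not show

The model emulates: niche-dependent phenotype regulation, hitchhiking of
matrix-deficient cells on matrix producers, the colonization–dispersal
trade-off, colony fission through the death–differentiation–division
relay, and the resulting life cycles. It deliberately omits: nutrient
fields and growth-rate feedbacks, explicit adhesive-molecule diffusion,
cell motility on the surface, continuous time (events are per-step), and
any third spatial dimension. Passing tests therefore support claims about
the model's internal logic and its emergent regimes — not quantitative
predictions for any particular organism.

Within the model itself, one known sensitivity is worth stating: evolved
surface *occupancy* (and hence absolute sticky-cell counts at a given
sticky fraction) depends on how often vacant regions are re-seeded, which
in turn depends on run length, lattice size and the mix of liquid
strategies present; the sticky *fraction* plateaus are much more robust.
The package therefore treats fractions as the primary cross-scale
quantities.

## Reproducibility

Each run uses a single engine RNG stream (xoshiro256++) seeded from
`sim_config(seed = )`; the draw order is documented in the engine source,
and re-running any configuration reproduces trajectories, grids and
genotype tables byte for byte. R-level helpers that need randomness
(`random_site()`, `decide_phenotype()` for probabilistic genotypes,
`mutate_genotype()`) use R's own RNG so they compose with `set.seed()`.

## A worked example

```{r example, eval = FALSE}
cfg <- scaled_profile(R = 0.4, strategy = "decision", seed = 1)
sim <- run_simulation(cfg)
summary(sim)
plot(sim)

# strategy census and life cycle of the evolved population
cen <- strategy_census(sim$genotypes, cfg$lattice)
pat <- sticky_components(sim$grid, cfg$lattice)
classify_life_cycle(cen, pat)
```
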