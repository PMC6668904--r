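---
title: "Simulating whole-genome duplication with digital organisms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating whole-genome duplication with digital organisms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdsim)
```

wgdsim is an agent-based evolution simulator built to study how whole-genome
duplication (WGD) affects the fate of lineages under stable versus
challenging environments. Digital organisms carry digit-string genomes that
encode gene regulatory networks (GRNs); they forage on a toroidal grid of
growing food sources, replicate under substitution mutation and a
conditional WGD operator, and die when their energy runs out. This vignette
documents the model in full: the genome grammar, the GRN dynamics, the
world, the organism life cycle, the lineage and expression metrics, and the
design decisions taken where the underlying framework is open to
interpretation.

## The genome and its grammar

A genome is a string over the four digits `{0,1,2,3}`, one digit per
nucleotide; founders start from uniformly random strings (100 kb at full
scale). Genes are not pre-specified: they are *discovered* by scanning the
random sequence with a promoter grammar. A gene consists of, with no
interspersed digits:

1. the TATA word `1010`;
2. a promoter block of 5--50 four-digit *cis-elements*;
3. a reserved four-digit *kind word* naming the gene kind;
4. a kind-specific coding payload.

The scan is left-to-right and non-overlapping: at each occurrence of `1010`
a parse is attempted; on success the gene is emitted and scanning resumes
after its end, on failure at the next TATA occurrence. The cis block ends at
the first word (4-aligned relative to the block) that is a reserved kind
word; a block that terminates too early (<5 cis words), too late (>50), runs
off the genome, or contains the TATA word itself fails to parse.

Eight kind words are reserved (`wgd_kind_words()`): five structural
actuator kinds (replication, movement, attack, defense, search), regulatory,
polymerase, and signaling. Attack, defense and search genes are parsed but
behaviourally inert in this package, which focuses on the replication and
movement actuators.

**Identities.** Each gene product has an identity in 0--999, of which at
most 1000 can therefore exist per simulation. Over a four-letter alphabet
only 256 four-digit words exist, so a single word cannot address 1000
identities; the identity is instead derived from the first five payload
digits read base-4 (0--1023) and reduced modulo 1000. Two genes with the
same payload prefix share a product; when that happens (rarely, by hash
collision; systematically, after WGD) the first gene in genome order defines
the product's kind, sign and binding word, and all copies translate into the
same product.

**Signs.** Structural and regulatory genes are promoting or repressing
(activator or repressor) according to the parity of the fifth payload digit
(even = promoting/activating). On random sequence this yields the expected
50/50 split of activators and repressors.

**Signaling payloads.** A signaling gene encodes a linear equation over
sensor inputs: a 2-digit length field (base-4 value 0--15, mapped affinely
to 3--18 elements within the allowed 3--20), then one 8-digit slot per
element -- four digits of sensor address (base-4, reduced modulo the number
of sensor slots) and four digits of weight (base-4 value 0--255, shifted by
-128 to a signed weight in -128..127, so equations can inhibit as well as
promote). Elements may address the same sensor repeatedly.

The scanner finds on the order of 180--190 genes in a random 100 kb genome
under this grammar, consistent with the densities the framework is designed
around (roughly 150--200 genes per 100 kb).

## GRN dynamics

The state of an organism's GRN is its concentration table: one non-negative
concentration per encoded product identity, capped at `grn_cap` (default
100 units). Each time step applies four stages, each stage synchronous:

1. **Decay** -- every concentration is multiplied by `1 - d`, where `d` is
   the product's decay rate. Decay rates are drawn once per simulation, one
   per identity, uniformly in `decay_range` (default 0.05--0.25 per step).
   The multiplicative form guarantees non-negativity without clamping; the
   underlying framework states only that products decay gradually.
2. **Signaling** -- every signaling equation is evaluated on the current
   sensor vector (own energy, nearby food count, nearby organism count,
   five reserved zero slots); the result is floored and reduced modulo
   1000, and every *encoded* identity so named gains one unit.
3. **Expression** -- each gene's expression level is the signed sum, over
   its promoter cis words (with multiplicity), of the concentrations of the
   transcription factors bound to each word: activators add, repressors
   subtract. Expression requires the polymerase: while no polymerase
   product has positive concentration, all levels are zero. The framework
   does not state an explicit expression formula; this signed sum is the
   minimal reading of combination-of-bound-TFs, and it is isolated in
   `expression_level()` so it can be substituted.
4. **Translation** -- every gene whose level reaches `grn_threshold`
   (default 1 unit) adds its level to its product's concentration (the
   dosage equals the expression level), clipped at the cap.

Whether signaling precedes or follows decay is not specified by the
framework; the order above (decay first) was fixed once and is asserted by
the regression tests. A useful closed-form consequence: a gene held at
constant level $L$ drives its product to the fixed point $L/d$.

**Bootstrap.** A new organism starts with everything at zero except the
products of the first 12 regulatory genes in genome order, set to 10 units.
Notably, the polymerase starts at zero, so the expression stage is gated
off until a signaling equation happens to name a polymerase identity; GRNs
therefore ignite stochastically through the sensor pathway. This follows
directly from the stated initialization (12 TFs) combined with the
polymerase rule.

## The world

The world is a toroidal grid (1000 x 1000 cells at full scale) holding at
most one food source per cell. Every source gains 300 energy units per step
up to a storage maximum of 20,000; a full source divides into two sources
of 10,000 each, the child placed on a uniformly chosen food-free Moore
neighbour (division is deferred while all eight neighbours hold food). The
10,000/10,000 split conserves energy at the division and matches the
stated 10,000--20,000 storage range. Initial food is `n_food_init` sources
(default 100) on random cells with uniform energies in the storage range.

Environmental challenge is introduced by removing food:

* **dynamic** -- once the total population first reaches `pop_trigger`
  (default 1000) the schedule arms permanently; thereafter, at every
  multiple of `period` (default 60) steps, `floor(f * N)` of the `N`
  current sources are deleted, chosen uniformly without replacement;
* **fixed** -- a single such removal at `fixed_step` (default 300).

The floor-of-fraction rule makes the removal exact rather than binomially
distributed, which keeps replicate outcomes interpretable.

## The organism

Each organism carries its genome, compiled GRN, concentration state, an
energy store, a grid position and lineage links. Per step, in a freshly
shuffled order, every living organism: senses its Moore neighbourhood
(radius `sensing_radius`, default 5 cells), advances its GRN one step, eats
(a food source on its own cell is assimilated in full and removed --
exclusively, first-come in the shuffled order), moves, and possibly
replicates.

**Movement** occurs iff the summed concentration of movement-promoting
products exceeds that of movement-repressing products, with a fair coin on
an exact tie. The destination is the neighbour cell nearest (toroidal
shortest path) to the highest-energy food within sensing range, or a
uniformly random neighbour when no food is sensed. A move costs 70 units;
staying put is free.

**Replication** requires 20,000 units of energy (the adaptation threshold);
above it the decision follows the replication-promoting versus -repressing
product concentrations, with probability 1/2 on an exact tie. The offspring
inherits the genome through two operators: while the WGD operator is
active, a Bernoulli draw at `wgd_rate` (default 0.40) duplicates the whole
genome (string concatenation, ploidy doubles; lineages can accumulate
several WGDs across generations while the operator is active); then every
digit independently mutates with probability `substitution_rate` (default
1e-4) to a uniformly chosen *different* digit. The parent's energy is split
evenly with the offspring: the framework's phrasing (offspring inheriting
the parent's energy level) would create energy from nothing, so the
conserving split is the default, with `offspring_energy = "copy"` available
as a switch. The offspring lands on a random neighbour cell with a freshly
bootstrapped GRN.

The WGD operator is removed, permanently, the first time the polyploid
subpopulation (ploidy >= 2) is at least as large as the non-polyploid one.
Organisms die immediately and permanently when their energy drops below
zero.

## Metrics

* **STGD** (short-term genetic distance): substitutions per 10 kb between
  an organism and its direct parent -- the Hamming distance scaled by
  `1e4 / length`. At a WGD generation each child half is compared against
  the whole parent (the halves are positionally homologous by
  construction) and the sum is scaled by the child length.
* **LTGD** (long-term genetic distance): the same quantity against the
  simulation's time-0 founder, partitioning a `2^k`-fold duplicated genome
  into founder-length blocks.
* **ED** (expression distance): the relative change of the mean product
  concentration between consecutive steps, with the mean taken over *all*
  encoded identities, zeros included. An organism with ED above 0.30
  (strictly) is called expression-unstable; "stable" means `W` consecutive
  steps at or below 0.30 (default `W = 10`). A zero previous mean with a
  positive current one yields an infinite ED sentinel rather than an error.
* **Outcome summaries**: each replicate simulation ends in one of total
  extinction, polyploid-larger, non-polyploid-larger, or tie; fractions per
  food-reduction level are exact rational counts. Class comparisons of
  per-genome metric values use Welch's two-sample t-test, with optional
  binning into 100-step windows.

## Orchestration, seeding and stopping

`run_simulation()` executes the loop food growth -> scheduled removal ->
shuffled agent updates -> WGD-operator check -> logging, until a stopping
rule fires: all steps done; total extinction; one ploidy class extinct
(armed only after the WGD operator has been removed -- before equalization
the polyploid class is empty by construction); or the population cap
(default 20,000), the concrete form of "too large to remain computationally
tractable".

All randomness derives from one master seed, fanned out into named
sub-streams (genome, world, agents, scheduler, experiment) so that, for
example, extra world-level randomness cannot perturb agent trajectories.
Two runs with the same configuration and seed produce byte-identical logs.

`run_experiment()` runs a replicate grid over food-reduction levels and
tabulates end states into the outcome-fraction layout described above.

## Scaled-down desk profile

Full-scale runs (1000 x 1000 grid, up to 20,000 organisms, 100 kb genomes,
2000 steps) are expensive; `desk_profile()` provides the scaled-down
conditions used for routine work: a 500 x 500 grid, 20 kb genomes, a
2000-organism cap and up to 1000 steps, everything else unchanged.

Two regime criteria fixed the grid size, and they matter more than any
single dimension:

* *The stable scenario must stay stable.* With 200 founders and a
  1000-organism removal trigger kept at their full-scale values, a grid
  much smaller than 500 x 500 lets the population's sensing neighbourhoods
  cover the entire grid, and consumption then drives food extinct even
  with no removal scheduled -- turning the nominally stable environment
  into a famine, which is precisely the environmental challenge it must
  not contain. At 500 x 500 the sensing coverage of a trigger-sized
  population is about half the grid, and food keeps outgrowing
  consumption until a run ends.
* *The challenge scenario must actually challenge.* The dynamic schedule
  only arms once the population reaches 1000, and repeated removals plus
  starvation need several hundred further steps; 1000 steps (half the
  full-scale dynamic horizon) leaves room for both.

The 12-regulatory-gene founder requirement is scaled with genome length
(12 at 100 kb, capped at 12, floor 1): a 20 kb random genome carries only
4--5 regulatory genes on average, so a fixed requirement of 12 would be
unsatisfiable at desk scale; the TF bootstrap already activates all
regulatory products when fewer than 12 exist.

For equalization-time measurements the package uses an *abundant food*
variant of the desk profile: 1% of cells initially hold food (2500 sources
at desk scale), which makes the expected number of sources inside one
sensing neighbourhood about 1.2 -- food is typically within view from the
start, so early adaptation is not limited by search time.

## What the generator emulates, and what it does not

Random founder genomes plus the grammar above reproduce the structural
statistics the framework is built on: gene density, the 5--50 cis-element
range, the activator/repressor balance, signaling equations of 3--20
elements, and up to 1000 products. They do not emulate real genomes in any
further sense: there is no codon structure, no linkage or recombination, no
gene loss or sub-/neofunctionalization, no insertions or deletions
(substitutions never change genome length, so ploidy and length remain
exactly coupled), and expression is a deterministic signed sum rather than
a kinetic model. Conclusions from these simulations are about the model
dynamics -- the interplay of genome doubling, mutation pressure,
GRN-mediated behaviour and resource scarcity -- not about any particular
organism.

The package also provides a *neutral-drift mode* (`selection_free = TRUE`):
no world, no GRN, no energy bookkeeping; every organism replicates with
probability 1/2 per step (the tie rule) up to the cap, still passing its
genome through the WGD and substitution operators. Because the
substitution rate is per digit, mutation accumulation per 10 kb is
identical for the two ploidy classes by construction; this mode isolates
that null from all selective machinery and backs the class-neutrality
checks in the test suite.

## Numerical and degenerate-input choices

* Coordinates are 1-based `(x, y)` cells internally; genome spans are
  0-based half-open.
* Ties in the highest-energy-food movement target resolve to the first
  cell in neighbourhood scan order (deterministic).
* Division order of simultaneously full food sources is increasing cell
  index; the child cell is drawn uniformly among food-free neighbours.
* `floor` rules: removal counts, signaling outputs.
* Negative signaling outputs wrap modulo 1000 into 0--999.
* The concentration cap (100) prevents divergence of the
  translation-dosage feedback; concentrations are additionally floored at
  zero after translation in case of negative thresholds.
* Empty genomes parse to empty gene tables; organisms without movement (or
  replication) genes have both opposing sums at zero and fall to the fair
  coin.
* An ED after a zero-mean step is the `Inf` sentinel, never a division
  error.

## Known limitations

* The expression-level formula, the decay model, the update order, and the
  identity derivation are all choices within the latitude the framework
  leaves open; each is isolated behind one function and documented above.
* At desk scale, outcome fractions rest on 4--10 replicates; they are
  directional summaries, not precise probabilities.
* Population-level energetics are sensitive to the interaction of grid
  size, food growth and the movement cost; the desk profile's regime
  criteria above are the package's considered resolution, but other
  scalings are legitimate and can be configured.
* Only the replication and movement actuators act; attack/defense/search
  are grammar-level stubs, and their sensor slots read zero.
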