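# wgdsim

An agent-based evolution simulator for studying the consequences of
whole-genome duplication (WGD) under environmental challenge.

## The scientific problem

Polyploidy — the duplication of an entire genome — is widespread in
eukaryote evolution, yet its value is contested: established ancient WGDs
are rare relative to recent ones, suggesting most polyploid lineages are
evolutionary dead ends, while clusters of surviving WGDs near periods of
ecological upheaval suggest duplication pays off precisely when
environments turn hostile. Disentangling this empirically is hard, because
it requires complete evolutionary trajectories — every mutation, every
expression state, every extinction — under controlled environmental
scenarios.

wgdsim makes those trajectories observable by simulation. A population of
*digital organisms* (DOs) forages on a toroidal grid of growing, dividing
food sources. Each organism carries a digit-string genome over `{0,1,2,3}`
in which genes are *discovered* by a promoter grammar — a TATA word
(`1010`), 5–50 four-digit cis-elements, a reserved kind word, and a coding
payload — and together encode a gene regulatory network (GRN):

- **regulatory genes** encode transcription factors (TFs) that bind
  specific cis words and activate or repress target genes;
- a **polymerase** product gates all expression;
- **signaling genes** encode linear equations over environmental sensors
  (own energy, nearby food, nearby organisms); each equation's output,
  modulo 1000, names a gene-product identity whose concentration is
  incremented — the organism's sensory input to its GRN;
- **structural genes** promote or repress the organism-level actuators:
  movement (cost 70 energy units per move) and replication (allowed above
  20,000 energy units).

At replication the offspring genome passes through a substitution operator
(rate 10⁻⁴ per digit) and — while the WGD operator is active — a 40% chance
of whole-genome duplication. The operator is removed permanently once
polyploids (ploidy ≥ 2) have caught up with non-polyploids. Environmental
challenge is introduced by removing a fraction *f* of all food sources,
either repeatedly (every 60 steps after the population first reaches 1000)
or once at a fixed step.

Per organism and step the package records the study's three metrics:

- **STGD** — substitutions per 10 kb versus the direct parent,
- **LTGD** — substitutions per 10 kb versus the time-0 founder,
- **ED** — relative change of mean gene-product concentration between
  consecutive steps (ED > 30% flags an unstable expression state),

plus ploidy-stratified outcome summaries over replicate simulations:
fraction of runs ending in total extinction, with polyploids larger, or
with non-polyploids larger.

The package is aimed at researchers in molecular evolution and artificial
life who want a fully inspectable, deterministic, seedable testbed for
WGD–environment interaction hypotheses.

## Worked example

A scaled-down stable-environment run (500 × 500 grid, 20 kb genomes, no
food removal; see the methods vignette for the profile rationale):

```r
library(wgdsim)

cfg <- desk_profile(master_seed = 21,
                    scenario = list(mode = "fixed", fraction = 0))
res <- run_simulation(cfg)
res
#> <wgd_run> 276 steps (population_explosion); 722 polyploid / 1278 non-polyploid organisms alive; ploidy classes equalized at step 201
```

The run starts from 200 clonal non-polyploid founders; polyploids appear
through the 40% WGD operator and draw level at step 201, at which point the
operator is removed and the two classes compete. With food left unremoved
the population grows until the 2000-organism cap ends the run at step 276,
with the non-polyploid subpopulation ahead (1278 vs 722) — the stable
environment favours undoubled genomes. Per-step class counts are in
`res$counts`, and `res$records` holds one row per organism per step with
its energy, STGD, LTGD, ED and adapted/stable flags:

```r
head(res$records[res$records$step == 276, c("do_id", "ploidy_class", "energy", "stgd", "ltgd", "ed")], 3)
#>        do_id  ploidy_class energy stgd ltgd        ed
#> 141858     1 non_polyploid    900    0    0 0.2114638
#> 141859     3 non_polyploid    480    0    0 0.2114638
#> 141860     4 non_polyploid    270    0    0 0.2114638
```

(These three surviving founders, with zero genetic distance to themselves
as founders, are close to starving; the growing population is dominated by
their descendants.)

A replicate experiment over removal levels mirrors the study's summary
tables:

```r
ex <- run_experiment(cfg, reduction_levels = c(0, 0.85), n_replicates = 5)
ex$summary
```

which reports, per reduction level, the exact fractions of runs ending in
extinction / polyploid-larger / non-polyploid-larger / tie.

Configurations serialize to YAML (`write_config()` / `read_config()`; a
ready-made desk-scale dynamic-85% example ships in
`inst/extdata/desk-dynamic-85.yaml`). A thin command-line interface wraps
the same functions:

```sh
inst/cli/wgdsim run --profile desk --scenario fixed --food-reduction 0 --seed 21 --out out/
inst/cli/wgdsim experiment --profile desk --scenario dynamic --food-reduction 0.5,0.85 --replicates 10 --seed 1 --out out/
```

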