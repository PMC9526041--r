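---
title: "Simulating breeding programs with meiosim: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating breeding programs with meiosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`meiosim` simulates diploid breeding programs as a sequence of scripted
operations on a population of phased genotypes. This vignette is the
package's own account of the science inside it: the meiosis and
quantitative-genetic models and their assumptions, the parameters that
matter and their defaults, what the synthetic-data generator does and does
not emulate, the numerical conventions, and the design decisions taken
where more than one reasonable convention exists.

## The genome model

A simulation runs on a genetic map: named markers at centimorgan positions
on chromosomes. Genetic rather than physical coordinates are required
because the meiosis model sizes recombination by map length — a Morgan is,
by definition, one expected crossover per meiosis. Positions within a
chromosome are sorted at construction; co-located markers (ties, common in
real maps) are kept in input order and behave as a single point: no
crossover can ever separate them.

Each genotype is stored as two phased haplotypes — one allele character per
mapped marker per homolog. Alleles are arbitrary nonspace characters, not
restricted to A/C/G/T, so the same machinery serves SNP panels and known
Mendelian genes. The character `-` is reserved as a *missing* allele: loci
absent from a loaded genotype file are filled with it, it is transmitted
through meiosis like any allele, and it carries effect 0 in breeding-value
sums.

## Meiosis: the count-location model

Gametes are generated per chromosome by three random draws:

1. **Count.** The number of crossovers is Poisson with mean equal to the
   chromosome's *tracked span* in Morgans — the distance between its first
   and last mapped marker. A single-marker (or fully co-located) chromosome
   has span zero and never recombines.
2. **Location.** Crossover positions are i.i.d. uniform over that same
   tracked span. Two conventions exist here — drawing over the tracked
   span versus over some nominal full chromosome length. We use the
   tracked span for both the Poisson mean and the uniform range, which
   keeps the two distributions consistent with each other; markers outside
   the tracked span do not exist in the model, so a crossover beyond it
   would be unobservable anyway.
3. **Start.** A fair Bernoulli draw picks the starting homolog; the gamete
   reads along it and switches homologs at each crossover position.

The model has no crossover interference (counts in disjoint subintervals
are independent), no obligate chiasma, no mutation, and no sex-specific
maps. Its key testable consequence is that crossovers form a homogeneous
Poisson process along the map, so the recombination fraction between two
markers $d$ Morgans apart is Haldane's map function

$$ r(d) = \tfrac{1}{2}\left(1 - e^{-2d}\right), $$

which the test suite checks by simulating $10^5$ testcross gametes at
several distances. One numerical tie rule is fixed for determinism: a
crossover falling exactly on a marker position (possible only in degenerate
configurations) toggles the active homolog *before* that marker is read.

## Crossing operations

All offspring-producing operations draw independent gametes through the
same engine. `cross()` and `cross_combinations()` perform listed crosses;
`cross_randomly()` samples parent pairs uniformly with replacement between
crosses, redrawing any pair that sampled the same individual twice —
crossing and selfing are deliberately distinct operations, so random
crossing never selfs. `cross_all_pairs()` uses unordered pairs without
self-pairs, because parent order has no modeled consequence (no male/female
distinction; the stored parent order is simply the call order).

`self_n_times()` advances each group member by $n$ sequential selfing
generations. Intermediate generations are transient: only the final
generation is registered, and the `offspring` multiplier applies at the
*final* step only — i.e. single-seed descent until the last generation,
then `offspring` seeds per line. Because the intermediates are discarded,
the recorded parents of each output line are the input member it descends
from; family bookkeeping therefore follows *lines*, which is the notion of
family that matters when inbreeding nested or biparental populations.
`make_doubled_haploids()` duplicates one gamete per member into both
homologs, giving exactly zero heterozygosity.

## Groups

Every genotype belongs to exactly one group, and groups partition the live
population at all times. Handles are plain integers. Two semantics were
deliberately fixed:

* **Empty groups do not exist.** A handle is valid only while at least one
  live record carries it; moving or deleting the last member extinguishes
  the group. Scripts should treat handles as ephemeral values returned by
  operations, not as stable names.
* **Deletion is the only destructor.** Groups and genotypes persist until
  `delete_groups()`, so mixed-generation pools are possible and memory is
  under the script's control. Record ids are never reused, and the
  pedigree rows (id, name, parents) of deleted records are retained so
  surviving descendants can still resolve their ancestry.

Member order within a group is creation order. This makes
`see_group_data()` output reproducible and gives truncation selection a
deterministic tie rule (below). The half-sib split takes a `which_parent`
argument because the model itself has no male/female distinction — which
slot defines "the shared parent" is genuinely the caller's choice.

## Breeding values, phenotypes, selection

The genotypic value is purely additive:
$\mathrm{BV} = \sum_\text{markers} \left[e(m, a_1) + e(m, a_2)\right]$,
with effects looked up in the loaded table and absent pairs contributing 0.
Sparse effect tables are therefore legal and cheap, and swapping tables
(`load_different_effects()`) re-scores the same genotypes for a different
trait or year. Dominance and epistasis are out of scope.

Phenotypes follow $P = G + E$, $E \sim N(0, V_e)$, with the environmental
variance sized from the target broad-sense heritability by rearranging
$H^2 = V_g / (V_g + V_e)$ into $V_e = V_g / H^2 - V_g$. Conventions:

* $V_g$ is the **unbiased** ($n-1$) sample variance of the group's
  breeding values, computed per call on the group being phenotyped.
* $H^2 = 1$ gives $V_e = 0$ exactly: the phenotype is the breeding value.
* $V_g = 0$ (no genetic variance, including single-member groups) gives
  $V_e = 0$ rather than 0/0: a trait with no genetic variance has no
  meaningful heritability, and noise-free is the only consistent limit.
* Phenotypes are ephemeral — recomputed on every call, never stored — so
  repeated phenotyping models independent trials.

Truncation selection (`select_by_gebv()`, `select_by_phenotype()`) moves
the top (or bottom) members into a new group. Fractional sizes select
$\lfloor n \cdot \text{portion} \rfloor$ members with a minimum of one;
floor is used because it is the reproducible reading of "the top $p$ of the
group", and the minimum prevents small families from silently going
extinct mid-script. Ties are broken in favour of the earlier-created
member, making selection deterministic given a seed.

## File dialects

The map file is `marker / chr / pos` (cM), tab-separated, one header line.
The effects file is `marker / allele / effect`, multiple rows per marker
allowed. The genotype matrix has **genotypes in columns and markers in
rows**: a header line of genotype names, then one row per marker whose
cells are exactly two nonspace characters. This orientation is a
documented package convention, not a community standard — check it first
when preparing data.

Phase on output is always encoded (first character = haplotype 1) and
flagged with a `#phased` comment line, so save/reload round-trips are
exact. Files *without* the flag are treated as unphased and the phase of
each heterozygous locus is randomized at load, independently per locus per
genotype with probability 1/2 — after which phase is tracked exactly.
Markers present in a genotype file but absent from the map are dropped with
a warning; mapped markers absent from a file are filled with `-`. All
writers emit byte-stable output for a fixed session state, which the
deterministic-output tests rely on.

## Population-genetic summaries

`rogers_distance()` implements the individual-level variant of Rogers'
(1972) distance: per locus, each individual is summarized by its
within-individual allele frequencies (0, ½, 1), the per-locus distance is
$\sqrt{\tfrac12 \sum_a (p_a - q_a)^2}$, and the individual distance is the
mean over loci. Implementations of "Rogers' distance" differ; anyone
comparing against other software should check the variant before comparing
numbers.

`ld_r2()` and `ld_decay_profile()` compute $D = p_{AB} - p_A p_B$ and
$r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$ from the **tracked true haplotypes**
(two per individual). The simulator knows phase exactly, so no
genotype-correlation approximation is used — expect small systematic
differences from estimators applied to real unphased data. The decay
profile uses within-chromosome pairs only, bins by left-closed right-open
cM intervals (bin edges are a parameter, since no single binning is
canonical), skips monomorphic markers (undefined denominator) silently and
markers with more than two observed alleles with a logged count.

## Synthetic data

`synth_map()`, `synth_founders()`, and `synth_effects()` generate complete
input sets so every test, example, and scenario runs without external
data; fixtures are always written through the package's file writers so
the dialects themselves are exercised. Synthetic loci are biallelic with a
fixed A/B coding (effects attach to the A allele), minor-allele frequencies
drawn uniformly from a range, and founders that are either fully inbred or
in Hardy-Weinberg proportions.

What the generator deliberately does **not** emulate: linkage
disequilibrium among founders (loci are independent draws), allele-sharing
structure between related founders, multi-allelic markers, and genotyping
error. Structured LD and relatedness *arise* downstream from simulated
crossing — which is exactly what the NAM scenario demonstrates — but tests
passing on these founders say nothing about behaviour on data with strong
founder LD or pedigree structure; for that, load real files.

## Packaged scenarios and problem sizes

`run_cyclic_program()` scripts a recurrent program with nonoverlapping
cycles: random crosses (default 25 crosses × 20 offspring) → self → select
top 20% on phenotypes at $H^2 = 0.1$ (unreplicated early material) → self
→ select top 50% at $H^2 = 0.4$ (early yield trials) → self → next cycle's
founders. The two packaged selection conditions differ in the truncation
universe: across the whole generation, or within each full-sib family
(same portions per family, survivors pooled). Its default synthetic input
is 50 inbred founders on a 5,000-marker map (20 chromosomes × 250 markers
over 150 cM) — a wheat-scale panel; the test suite exercises 5 cycles and
3 replicates of this configuration, sizes chosen to make the qualitative
contrasts (gain accumulates; across-selection gains faster; within-family
selection retains more variance) detectable in seconds-to-minutes runs.

`run_nam_scenario()` builds a nested association mapping population:
each of 10 donors crossed to one shared elite parent, F1s advanced four
selfing generations by single-seed descent, and the fifth selfing expanded
to 100 seeds per line — 10 full-sib families of 100 F6 lines. Reported
outputs are the Rogers matrix (block structure: within-family mean distance
well below between-family), and the LD decay profile. The default
synthetic map is durum-scale (14 chromosomes × 25 markers), kept moderate
because the distance matrix is quadratic in population size.

## Reproducibility

All randomness flows through R's global RNG: `set.seed()` before a run (or
the `seed` arguments of the scenarios and the `--seed` flag of the CLI)
makes every gamete, file, and statistic identical across reruns — the test
suite asserts byte-identical scenario outputs. This uses R's native RNG
idiom rather than passing an explicit generator object through every call,
matching how the language's simulation packages are actually scripted.

## Known limitations

No crossover interference or user-specified crossover distributions; no
mutation; no dominance or epistatic genetic values; no sex chromosomes,
polyploidy, or sex-specific maps; no VCF/PLINK import (the three
tab-separated dialects above are the interface); selection intensity via
independent truncation only (optimal-contribution and index selection can
be scripted by the user through `see_group_data()` + `make_group()`).
Breeding values are recomputed from scratch on every call, which is exact
but can dominate run time for very large effect tables — precomputation is
a possible future optimization, not a current feature.
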