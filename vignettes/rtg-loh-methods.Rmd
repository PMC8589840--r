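---
title: "Models and methods behind rtgloh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rtgloh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtgloh)
```

# The biological model

A diploid hybrid carries two diverged parental subgenomes distinguished by
a dense map of biallelic markers, each heterozygous in the ancestral cell.
When such a cell initiates meiosis, its chromosomes replicate (four
chromatids per homolog pair, two per parent) and Spo11 introduces
double-strand breaks (DSBs) genome-wide, preferentially at recombination
hotspots and rarely near centromeres. If the cell is returned to rich
medium before committing to the meiotic divisions, it repairs the breaks,
buds, and segregates its chromatids mitotically: each of the two resulting
cells receives one centromere of each homolog, with no intervening
replication. Repaired breaks resolve either as a **crossover** (CO;
reciprocal exchange of everything distal to the break between one
chromatid of each parent) or as a **non-crossover** gene conversion (NCO;
a one-way tract copied from the template chromatid onto the broken one).
At the marker level a CO produces *terminal* loss of heterozygosity (LOH)
— in the two segregants that combine a recombinant chromatid with a
parental one of matching distal content — and an NCO produces a short
*interstitial* LOH tract in whichever cell inherits the converted
chromatid. Crossovers conserve the 2:2 parental allele dosage across the
mother/daughter pair at every marker; conversions shift it to 3:1, the
"non-reciprocal" footprint.

Sequence divergence itself suppresses this recombination: the
mismatch-repair machinery (Msh2) recognises heteroduplex mismatches formed
during repair between diverged sequences and aborts the event
(*anti-recombination*). The more markers a repair tract spans, the less
likely the event survives — which is why highly heterozygous interspecies
hybrids show little RTG-induced LOH, and why deleting *MSH2* releases it.

# The simulator

`simulate_rtg_pair()` implements exactly this mechanism. Its parameters
(`sim_config()`), all configurable, with defaults chosen once at
literature scale:

| parameter | default | units | meaning |
|---|---|---|---|
| `lambda` | 20 | DSBs/cell | Poisson mean DSB count per aborted meiosis. Full meiosis makes ~150–200 DSBs; an early-abort timepoint sees a modest fraction of that programme, and 20 breaks over a multi-megabase genome reproduces the "a handful of LOH events per clone" regime. |
| `hotspot_weight` | 0.8 | probability | chance a DSB lands inside a hotspot interval (chosen ∝ its hit count `H`), the rest falling uniformly outside centromeric zones. The observed hotspot coincidence of breakpoints motivates a high weight; the exact value is not a measured quantity and is exposed as configuration. |
| `cen_radius` | 20000 | bp | pericentromeric suppression radius: no DSB within this distance of a centromere, and conversion tracts never extend into the zone (tracts run distally from the break). This makes "centromeres always heterozygous" a structural property of the simulator rather than a statistical tendency — see *Numerical choices*. |
| `p_co` | 0.3 | probability | chance a surviving DSB resolves as CO rather than NCO, within the range commonly reported for mitotically repaired breaks. |
| `tract_mean` | 2000 | bp | mean of the geometric conversion/repair tract length. |
| `rho` | 0.1 | probability | per-mismatch rejection: an event whose repair tract spans `m` markers survives with `(1 − rho)^m`. One marker = one heteroduplex mismatch. |
| `msh2_null` | `FALSE` | flag | forces `rho = 0`, modelling *msh2Δ*. |

Segregation draws, for every chromosome independently, one of the four
valid mitotic-like splits (one centromere of each homolog per cell) with
equal probability. Chromatid identity follows the centromere; crossovers
only exchange arm material, so identity is stable. Enumerating those
splits shows that a lone crossover yields reciprocal terminal LOH in half
of the segregation outcomes (recombinant + matching parental chromatid in
each cell) and no LOH in the other half — both outcomes are biology, not
artefacts.

The returned ground truth contains every DSB (placed, aborted, or
resolved), the expected LOH segments of both cells (maximal homozygous
runs over non-masked markers), and the set of markers whose pair-wise
dosage deviates from 2:2. Because genotypes are a deterministic function
of the chromatid state, the LOH caller should recover the truth segments
*exactly*; the acceptance suite verifies this at population scale.

`simulate_marker_map()` draws marker positions as a per-bp Bernoulli
process with density `theta`, spanning the intraspecies
(`theta ≈ 0.001`) to interspecies (`theta ≈ 0.05`) heterozygosity regimes.
`simulate_mitotic_track()` provides the T0 control: Poisson-many
background LOH events placed uniformly with the same tract distribution.
`simulate_phenotypes()` plants additive QTL effects (a clone gains
`effect` for each QTL marker at which it is homozygous for the stated
parent) plus Gaussian noise.

**What the generator does not emulate.** No sequence-level reads, no
tetrads, no aneuploidy/CNV or structural rearrangement, no chromatid
interference, no cell-to-cell variation in DSB timing, and marker spacing
is homogeneous rather than clustered. Passing tests therefore demonstrate
the internal consistency of caller, statistics and simulator under the
stated mechanism — not that real sequencing data are free of the artefacts
(mapping error, CNV-masked LOH) that a read-level pipeline handles
upstream.

# LOH calling

`call_loh()` groups stretches of consecutive markers with the same
homozygous genotype into segments, with no minimum-marker filter
(single-marker events are genuine conversions). Two coordinate systems
are reported: `first`/`last` (outer segment markers) and `start`/`end`
(midpoints between the outer marker and the nearest informative marker
outside the segment, clamped at arm ends). A segment reaching the last
non-masked marker of a chromosome arm is *terminal*; flanked by
heterozygous markers on both sides, *interstitial*; covering every
informative marker of a chromosome, it is flagged *whole_chromosome*
rather than silently split, because a heterozygous centromere is the RTG
expectation and such events deserve scrutiny.

Decisions where the upstream convention is silent:

* `MISSING` genotypes are transparent: they neither break nor support a
  run. A run bridged across missing data can be broken by setting
  `max_gap` (bp between consecutive informative markers); the default is
  unlimited.
* Subtelomeric masks default to 20 kb per chromosome end, configurable per
  end in the layout; masked markers are invisible to calling and never
  define the terminal extent.
* A `HOM_P1` run abutting a `HOM_P2` run splits into two segments sharing
  the midpoint breakpoint.

`summarize_loh()` reports event counts by class and the fraction of
markers (and of genome, via start/end extents) in LOH split by parent —
the two parental fractions add exactly to the total.
`breakpoint_regions()` extracts, per breakpoint, the interval from the
first homozygous marker to the closest flanking marker outside the
segment, plus the `k = 5` nearest homozygous and heterozygous markers for
the local-heterozygosity distance comparison
(`inter_marker_distances()`). `reciprocity()` counts dosage-violating
markers between a mother and daughter. `compare_clone_sets()` wraps the
one- or two-tailed Wilcoxon rank-sum test (normal approximation with
continuity correction) and the two-sided Fligner–Killeen variance test
for comparing clone-set summaries; all-tied input returns `p = 1` with a
warning rather than an error.

# Breakpoint–hotspot association

`permutation_overlap_test()` uses the statistic "number of breakpoint
regions intersecting at least one hotspot" (closed intervals, ≥ 1 bp). The
null re-places each region uniformly on its own chromosome, preserving its
length and never crossing chromosome ends; randomised regions may overlap
each other. This is the simplest member of the genomic-permutation family
and is stated explicitly so results are reproducible. The empirical
p-value carries the +1 correction and can never drop below
`1/(ntimes + 1)`; the default `ntimes = 10000` and one-sided (enrichment)
alternative match standard practice. A zero-variance null (e.g. a fully
covered chromosome) yields `Z = NA`, a `degenerate` flag and `p = 1`.

`local_z_profile()` re-runs the test with the hotspot track shifted by
`0, ±T, ±2T, …, ±W/2` where `S_m` is the mean hotspot length,
`W = 10·S_m` and `T = S_m/2` — a genuinely local association peaks at
shift 0 and decays. Shifted intervals are truncated at chromosome ends by
default; `circular = TRUE` wraps instead.

`relative_intensity_compare()` computes `RI = H/max(H)` over all hotspots
and compares overlapping vs non-overlapping hotspots at paddings 0, 500,
1000, 2000 and 5000 bp. The comparison test is not fixed by convention;
this package uses the one-sided Wilcoxon rank-sum test and records that
choice in its output.

# URA3-loss rate metrics

`loh_rate()` is the plain frequency `100·CFU_5-FOA/CFU_YPD` (% of plated
cells), invariant under dilution. `loh_metrics()` forms the LOH ratio and
difference on replicate means (so `ln(ratio)` equals
`ln(mean R_T6) − ln(mean R_T0)` exactly), flags negative differences, and
tests the T6-over-T0 increase one-sided with a Welch t-test on
log-transformed rates — the log stabilises the multiplicative replicate CV
— falling back to the rank-sum test when zero rates (or zero variance)
make the log test undefined. Paired and unpaired replicate modes are both
provided because the pairing convention is not fixed; the test used is
always recorded in the output. `progression_correlation()` excludes
negative-difference strains before correlating (two-sided Pearson), using
log10 of the difference (which also drops exact zeros) and the natural-log
ratio as is.

# QTL mapping

Genotypes are coded additively (`HET = 0`, `HOM_P1 = +1`, `HOM_P2 = −1`);
a 2-df genotype-factor model is available since the appropriate cross
model for a diploid LOH panel is not standard — the model used is stored
in the result. `filter_markers()` removes markers with no genotype in any
clone and markers homozygous in fewer than two clones (one homozygote
carries no mappable signal), logging every removal.

`lod_scan()` computes `LOD = (n/2)·log10(RSS0/RSS1)` per marker from the
closed-form simple-regression decomposition, over per-marker complete
cases; zero-variance markers score 0, as does a constant phenotype. The
genome-wide threshold is the 95th-percentile *order statistic* (type-1
quantile) of the maximum LOD over 1000 phenotype permutations — with 1000
permutations the 950th sorted maximum — so the threshold is a realised
null value, not an interpolation. `qtl_interval()` returns the LOD-drop
support interval (default drop 1.5, the common convention where no value
is dictated): the widest contiguous run around the peak within `drop` LOD
units, expanded to the flanking markers just outside, one-sided and
flagged at scan edges. No correction is applied across environments; each
environment gets its own genome-wide permutation threshold (a
Bonferroni-style option can be layered on by the user via the returned
per-environment results). Growth phenotypes are normalised as
`D_r = log2(D) − log2(D_control,local)` and classified with inner
boundaries (±0.25) joining the inferior/superior classes and outer
boundaries (±1) the highly- classes; heterosis calls use one-sided Welch
tests against each parent at α = 0.05, returning `not_evaluable` when a
parent lacks data.

# Numerical choices and degenerate inputs

* **Coordinates** are 1-based inclusive everywhere internally; BED input
  is converted at the boundary (a disk record `chr 0 100` becomes
  `[1, 100]`), preserving interval length. Strand is ignored.
* **Conversion tracts run distally** (away from the centromere) from the
  break and are therefore structurally unable to enter the pericentromeric
  suppression zone; combined with DSB exclusion from the zone, every
  marker within `cen_radius` of a centromere stays heterozygous in every
  simulated clone. The alternative — random tract direction with clamping —
  would give the same marginal behaviour away from centromeres but only a
  probabilistic version of the centromere invariant.
* **Determinism**: every stochastic routine takes a seed; population
  simulation derives one sub-seed per pair so any pair can be regenerated
  without replaying the rest.
* **Degenerate inputs** are contracts, not crashes: empty marker maps warn
  and return empty; all-tied comparisons return `p = 1` with a warning;
  zero-variance permutation nulls flag `Z = NA`; an all-zero T0 gives
  `ratio = NA` while the difference is still reported; markers that lose
  all genotypes or all variance score `LOD = 0`.

# Problem sizes

The shipped tests exercise the pipeline at sizes chosen to be
statistically meaningful yet quick on a laptop: the round-trip/reciprocity
/centromere properties use 200 simulated pairs on a 6-Mb, ~5,000-marker
genome; permutation-test calibration uses 200 null datasets at
`ntimes = 1000`; the anti-recombination contrast uses 500 clones per
divergence regime; QTL recovery uses 125 clones and 100 replicates, and
the family-wise error check 200 runs of 1000 permutations each.
`scripts/acceptance.R` re-runs slightly smaller versions of the same
computations and writes every quantity to JSON.

# Known limitations

* The simulator's DSB counts and tract lengths are literature-scale
  defaults, not fitted to any particular dataset; magnitudes of simulated
  LOH fractions should not be read as predictions for a specific hybrid.
* The permutation null is placement-uniform: it does not model
  GC-content, replication timing or other covariates of real breakpoint
  placement.
* LOD mapping is single-marker regression; there is no hidden-genotype
  interval mapping between markers and no epistasis scan.
* LOH calls are genotype-only: discriminating LOH from hemizygous deletion
  requires read-depth/CNV evidence outside this package's scope.
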