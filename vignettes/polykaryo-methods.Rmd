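---
title: "Models and design choices in polykaryo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in polykaryo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polykaryo)
```

`polykaryo` analyses F1 pseudo-testcross populations in polysomic polyploids
— the mating design in which a heterozygous parent is crossed to a parent
null for the scored alleles, so that every segregating allele behaves like a
testcross locus. The motivating system is a hexaploid apomictic forage grass
(2n = 6x = 36, base number x = 6) in which a sexual mother is crossed to an
apomictic father carrying a single dominant apospory locus (ASGR), and the
offspring are genotyped by sequencing (GBS). This vignette explains the
models, the tunable parameters, what the built-in simulator does and does
not emulate, and the design decisions taken where the problem was genuinely
open.

## The meiosis model

The simulator implements *bivalent-only polysomic meiosis*:

1. **Pairing.** The k homologs of each chromosome are partitioned into
   bivalents (`pair_homologs()`). Preferential pairs resolve first, in
   listed order: each forms with probability `affinity`; the remaining
   homologs are matched uniformly at random over all perfect matchings
   (1/15 each for six free homologs). Odd copy numbers leave one univalent,
   transmitted whole with probability `univalent_p` (default 1/2, an
   unbiased default).
2. **Transmission.** Each bivalent transmits one chromosome that starts from
   either member with probability 1/2 and switches member between adjacent
   markers with the Haldane recombination fraction
   `r = (1 - exp(-2d/100))/2` of the inter-marker distance `d` (cM). No
   chiasma interference, no double reduction, no multivalents: this is the
   simplest model that reproduces every single- and two-locus expectation
   the analyses rely on — simplex transmission 1/2; duplex
   presence:absence 4:1 under random 6-homolog assortment and 5:1 when the
   duplex is confined to a 4-homolog always-co-pairing subgenome; and the
   coupling class frequencies below. Multivalents and double reduction are
   explicitly out of scope.
3. **Population.** A hybrid receives one maternal and one paternal gamete; a
   selfed contaminant receives two maternal gametes and therefore carries no
   paternal-unique alleles. The reproductive mode is apomictic exactly when
   the paternal gamete carries the ASGR haplotype (fully penetrant dominant
   monogenic control — misclassification robustness is explored only in the
   tests); an independent Bernoulli relabels a fraction `undetermined`,
   emulating plants whose pistils cannot be scored.

Defaults mirror the study design this machinery comes from: 102 hybrids, 12
accidental selfs, undetermined rate 25/102 (which leaves ~77 phenotyped
plants), six chromosomes of six copies, and GBS-like depths with mean
lambda = 60 (Poisson by default, negative binomial optional). These are the
*conditions*, not tuning knobs; the tests run at these values.

The simulator emulates the statistical structure the analyses assume —
dosage-driven segregation ratios, pairing-driven repulsion, read-depth
noise, missingness via depth, contaminant selfs. It does **not** emulate
real-data features such as paralogous tag collapse, allele-specific
amplification bias, genotyping batch effects, segregation-distorting
selection, or recombination-rate heterogeneity (a recombination-suppressed
region is modelled simply by placing markers at the same cM position). A
green test suite therefore certifies the statistics, not robustness to
those artefacts.

## Genotype calling and filtering

Calls are threshold-based on biallelic read counts: a heterozygote needs at
least 2 reads of each allele *and* a minor-read fraction strictly above
0.10; otherwise a homozygote for the majority allele needs at least
`t_hom = 11` reads (17 in strict mode); anything else is missing. Markers
with more than 20% missing calls are dropped (exactly 20% is kept — the rule
is strict). A parent that was not sequenced is imputed from the selfs:
homozygous when all non-missing selfs agree on one homozygous state,
heterozygous when they are all heterozygous or segregate, missing otherwise.
Progeny are screened for heterozygote excess with a two-sided exact binomial
test of the het count across SDA markers against 1/2; exclusion requires
p < 1e-10 *and* excess in the heterozygote direction (the signature of
sample mixing), with fewer than 30 informative markers flagged untestable.
The binomial construction is this package's own: the source analyses state
only the threshold and the direction, not the statistic.

One consequence of the thresholds is worth knowing: a hexaploid dosage-1
heterozygote has an expected alt-read fraction of 1/6 ≈ 0.17, close to the
0.10 minor-fraction gate. At depth 60 the exact miscall (het -> hom)
probability is 0.082 — not negligible. It biases each marker's het fraction
to ~0.46, which the 1:1 chi-square at n = 102 still accepts for the large
majority of markers (rejection power ~0.13); the unit tests assert both the
exact-model miscall rate and that surviving property.

## Dosage classification

Per marker, het:hom counts among hybrids are classified: SDA when the ratio
is strictly inside (1/2, 2) — the band is symmetric because homozygote
excess violates 1:1 just as heterozygote excess does; otherwise
DDA when a df-1 Pearson chi-square (no continuity correction; immaterial at
n ~ 102 and alpha 0.05) accepts 5:1 (tetrasomic) or 4:1 (hexasomic),
preferring the larger p-value and flagging markers that fit both. A marker
that fits neither stays unclassified. Exact-ratio counts like (85, 17) and
(80, 20) give vanishing chi-squares, and (70, 30) fails both the band and
the ratio tests — worked values frozen in the tests.

## The coupling model and its oracle

For an SDA `A` and a DDA `B` in coupling on one parental chromosome at
recombination fraction `r`, the progeny class probabilities are

* tetrasomic: `(1/2 - r/6, r/6, 1/3 + r/6, 1/6 - r/6)`
* hexasomic: `(1/2 - r/5, r/5, 3/10 + r/5, 1/5 - r/5)`

(`expected_class_freqs()`). `enumerate_class_freqs()` derives the same
quantities with no shared code by enumerating every bivalent matching and
every transmission outcome; the suite checks agreement to 1e-12 on a
51-point grid in both models. The marginals are conserved
(`P_AB + P_A = 1/2` always; `P_AB + P_B` = 5/6 or 4/5) and at `r = 0.5`
every class factorises into its marginals. `independence_test()` is the
df-3 Pearson test of the four observed classes against the `r = 0.5`
expectations — df 3 and no correction are this package's reading, since the
source specifies the expected frequencies but not the df — and declares
coupling linkage only when the AB class is in excess (the model covers
coupling phase only; repulsion-phase SDA-DDA linkage is out of scope).
`estimate_r_ml()` maximises the multinomial likelihood over
`r` in `[1e-6, 0.5]` with `stats::optimize()`, explicitly checking the
interval ends so boundary optima (e.g. degenerate counts) are not missed; a
1e-4-step grid search is the test oracle, and recovery at n = 102 is
unbiased to within 0.02 for r up to 0.2.

## Karyotyping

All SDA pairs are cross-tabulated pairwise-complete and tested with the
two-sided Fisher exact test (an internal vectorised `dhyper` implementation,
asserted equal to `stats::fisher.test` in a property test). Direction comes
from the Haldane-Anscombe-corrected odds ratio so zero cells still orient a
pair. Pairs with fewer than 10 complete cases are skipped. Grouping uses
two-point LOD `(n11+n00) log10(2(1-r)) + (n10+n01) log10(2r)` with
`r = (n10+n01)/n` clipped to `[1e-6, 0.5]`, single linkage over
coupling-phase edges at LOD >= 7 — repulsion-phase linkage is never used for
grouping because its expectation depends on the inheritance model.

`aggregate_karyotype()` tiers each marker pair at p < 0.05 / 0.001 / 1e-5
per direction (the darkest-tier bound is taken as 1e-5; the source figure
legend states it inconsistently) and calls a group pair coupled/repulsed
when more than half its marker pairs are significant at the outer tier in
that direction.

Two calibration decisions depart from a naive reading and are worth
recording:

* **Chromosome clustering** (`cluster_homologs()`) takes its repulsion edges
  at the *middle* tier (majority at p < 0.001, configurable `edge_tier`),
  not the outer reporting tier. With G groups there are ~G^2/2 candidate
  pairs and the marker pairs within a group pair are nearly perfectly
  correlated, so a 5% per-pair false repulsion rate merges unrelated
  chromosomes in a large fraction of analyses; the middle tier keeps the
  family-wise merge rate negligible while true within-chromosome repulsion
  plus shared-DDA bridges (>= 2 shared assignments, configurable) carry the
  connectivity. Component size is then the homolog count: a 5-group and a
  7-group component recover a compensated-aneuploid pair of chromosomes.
* **Preferential pairing** (`classify_pairing()`) calls a pair preferential
  when it is repulsed at the middle tier in more than `strong_majority`
  (default 0.75) of its marker pairs while neither member shows such
  repulsion with any other component member. The stricter majority is a
  measured calibration: under fully random hexasomic pairing the group-level
  repulsion already has noncentrality ~ n/25, and a bare 50% majority flags
  a chance pair in well over 10% of analyses, whereas a truly preferential
  (affinity ~ 1) pair pushes essentially every marker pair past the tier.
  Pairs whose groups hold fewer than 2 markers are untestable.

## DDA assignment and the subgenome uniformity test

A duplex allele sits on two homologs and should couple with exactly two
homolog groups. `assign_dda()` scores each group by the median signed
Pearson chi-square of the 2x2 presence table of the DDA against the group's
SDA markers, *conditioning on the observed marginals* (df 1). The
margin-conditional form matters: scoring against theoretical class
frequencies lets any group whose sampled presence fraction drifts a couple
of standard errors high pass the gate against every DDA at once, which in
simulation collapsed most assignments to ambiguity. A DDA is assigned only
when exactly two groups pass (median chi-square positive and p < 0.05);
anything else is flagged. Assignment power depends on linkage tightness —
reliable recovery needs the carrier group's median SDA within roughly 5 cM
(r ~ 0.05) of the DDA at n = 102 — which is why the simulation studies in
the tests use compact, evenly spaced maps (20-40 cM, 8-12 markers per
homolog); the vignette-level point is that sparse 100 cM maps leave the
median test underpowered, not broken.

Under undifferentiated polysomy a DDA is equally likely on any of the
`choose(k, 2)` homolog pairs, so `subgenome_uniformity_test()` applies a
df `k-1` chi-square of the per-pair assignment tally against uniformity
(with a simulated multinomial p-value offered when the total is small).
An allopolyploid-like parent — duplex alleles shared within, never across,
subgenomes — concentrates the tally and drives the p-value to zero, while
its always-co-pairing homolog pair contributes *no* segregating duplexes at
all (a duplex on both members of a disomic pair is transmitted to every
gamete and is invisible to the F1 analysis). The pairing regime
discrimination test runs both regimes at n = 102, 200 replicates each.

## The pipeline and its interfaces

`run_pipeline(seed, config)` chains simulate -> read simulation -> calling
-> filtering -> imputation -> outlier screen -> dosage classification ->
karyotyping -> DDA assignment and uniformity -> pairing classification ->
ASGR cosegregation scan, from a single mandatory seed (set once; all stages
consume the one stream, so a run is bit-reproducible). Configuration is an R
list or a YAML file (`read_run_config()`, unknown keys rejected). All
interchange formats are plain delimited text with `#` comment headers
(genotype matrices, read counts) plus JSON for reports; a biallelic VCF with
AD fields can be imported as read counts. Figures (`autoplot()` heat matrix,
scan plots) always have their numeric tables alongside in the returned
objects — no result exists only as an image. There is no shell entry point:
the package's users drive it from R, and the exported functions plus
`run_pipeline()` are the interface.

The cosegregation scan counts, per paternal SDA, the mismatches between
allele presence and the apomictic state over phenotyped individuals
(undetermined plants excluded); markers with zero recombinants in at least
`min_informative = 50` individuals form the perfect-linkage set, and with a
map the nearest flanking markers on either side are reported. On simulated
populations the zero-recombinant block always contains the true ASGR
position, because the carrier-homolog markers at the ASGR position are in
complete coupling with it.

## Problem sizes used in the checks

The simulation studies in the test suite run at the design's population
size (102 hybrids, 12 selfs where relevant) with desk-scale genomes chosen
for the power each check needs: one 6-copy chromosome (10 SDA markers per
homolog, 40 cM, 5 or 2 DDAs per eligible pair) for the pairing-regime
discrimination at 200 replicates per regime; one 5-copy plus one 7-copy
chromosome (10 SDA markers per homolog, 4 DDAs per pair, 25 cM) for
aneuploidy detection at 100 replicates; a five-marker zero-recombination
block plus flanking markers at r >= 0.1 for the ASGR scan at 200
replicates; and 1000-replicate multinomial draws for recombination-fraction
recovery. Monte Carlo tolerances are three standard errors unless a check
is exact.

## Known limitations

* Bivalent-only meiosis: no multivalents, no double reduction, no
  interference; quantities sensitive to those phenomena (e.g. double
  reduction coefficients) cannot be studied with this simulator.
* Presence/absence genotypes only: no 0-6 dosage calling, no
  genotype-likelihood models, biallelic markers only.
* Grouping is two-point and coupling-phase; multipoint ordering and map
  distance estimation are out of scope, as is synteny assignment to a
  reference genome.
* The DDA assignment rule is median-based and needs tight SDA-DDA linkage;
  with sparse maps it abstains (ambiguous) rather than guesses.
* The pairing-affinity of a differentiated subgenome is a free simulator
  parameter; no field estimate is bundled.
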