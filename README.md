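# polykaryo

Molecular karyotyping and apomixis mapping for polysomic polyploids.

`polykaryo` re-creates, as tested R code, the statistical machinery used to
dissect a hexaploid (2n = 6x = 36) F1 pseudo-testcross between a sexual
mother and an apomictic father: inferring marker dosage from segregation
ratios, karyotyping homologous linkage groups with all-pairs Fisher exact
tests, detecting preferential chromosome pairing (subgenome differentiation)
and compensated aneuploidy, modelling simplex-duplex coupling linkage, and
mapping the dominant apospory locus (ASGR) by perfect cosegregation. Because
real populations of this design are rarely at hand, the package ships a
forward simulator of bivalent polysomic meiosis that generates populations
with exactly the statistical structure the analyses assume — every stage is
testable end to end without any external data.

## The models in brief

* **Dosage segregation.** In a pseudo-testcross a single-dose allele (SDA,
  `A00000 x 000000`) segregates 1:1 heterozygote:homozygote. A double-dose
  allele (DDA, duplex) segregates presence:absence
  5:1 under tetrasomic (2-of-4 homolog) and
  4:1 under hexasomic (3-of-6) assortment — both ratios are exact
  enumerations over gamete homolog subsets (`gamete_presence_ratio()`).
  Markers are classified SDA when het:hom is strictly inside (1/2, 2), else
  tested against 5:1 / 4:1 by chi-square (df 1).

* **SDA-DDA coupling model.** For an SDA `A` and DDA `B` linked in coupling
  at recombination fraction `r`, the progeny class probabilities
  (AB, A, B, 0) are

  | model | AB | A | B | 0 |
  |---|---|---|---|---|
  | tetrasomic | 1/2 − r/6 | r/6 | 1/3 + r/6 | 1/6 − r/6 |
  | hexasomic  | 1/2 − r/5 | r/5 | 3/10 + r/5 | 1/5 − r/5 |

  (`expected_class_freqs()`), verified against a brute-force enumeration of
  all bivalent matchings and transmissions (`enumerate_class_freqs()`), with
  a chi-square independence test and maximum-likelihood `r` estimation.

* **Molecular karyotyping.** All SDA marker pairs are tested with Fisher's
  exact test on 2x2 presence/absence tables; coupling (same homolog) and
  repulsion (different homologs of one chromosome) are tiered at
  p < 0.05, 0.001, 1e-5. Two-point LOD >= 7 coupling linkage groups the
  markers into homologs; repulsion plus shared-DDA bridges cluster homolog
  groups into chromosomes, whose component size exposes compensated
  aneuploidy (5- or 7-copy chromosomes); a homolog pair repulsed far more
  strongly than its peers is flagged as preferentially pairing, and a
  chi-square uniformity test on the distribution of DDA linkages over
  homolog pairs detects subgenome differentiation.

* **ASGR mapping.** Reproductive mode is classified from embryo-sac counts
  (any aposporous pistil makes a plant apomictic; fewer than 10 normal
  pistils makes it undetermined), tested for monogenic 1:1 segregation, and
  scanned for markers in perfect cosegregation with the apomictic state.

## Worked example

```r
library(polykaryo)

run <- run_pipeline(seed = 42, config = list(
  n_chrom = 2, n_sda_per_homolog = 8, n_dda_per_pair = 3,
  length_cM = 40, spacing = "even"))
run
#> <polyk_run> seed 42: 372 markers called, 194 SDA / 138 DDA; 13 linkage
#> groups in 3 chromosome components; 0 markers in perfect ASGR linkage

run$uniformity
#> # A tibble: 2 × 6
#>   chromosome chisq    df p_value n_pairs total
#>   <chr>      <dbl> <int>   <dbl>   <int> <int>
#> 1 chr01      10.9     14   0.692      15    26
#> 2 chr02       4.86    14   0.988      15    35
```

The two simulated hexasomic chromosomes are recovered as two six-group
components (a thirteenth, fragmented group stays a flagged singleton), and
the DDA linkages spread uniformly over the 15 homolog pairs of each
chromosome — the autopolyploid signature: high uniformity p-values. A
parent simulated with an always-co-pairing homolog pair instead concentrates
its DDA linkages on the pairs within the remaining four homologs and drives
this p-value toward zero, while `classify_pairing()` flags the pair itself.

Reproductive mode in the same run segregates like a single dominant factor:

```r
ph <- subset(run$cross$individuals, origin == "hybrid")
test_monogenic_segregation(sum(ph$phenotype == "sexual"),
                           sum(ph$phenotype == "apomictic"))
#> # A tibble: 1 × 4
#>   chisq    df p_value     n
#>   <dbl> <int>   <dbl> <int>
#> 1 0.486     1   0.485    74
```

Perfect ASGR cosegregation needs markers inside a recombination-suppressed
block (the generator places markers at distinct positions by default);
constructing a parent with five markers at the ASGR position recovers the
whole block with zero recombinants — see the methods vignette
(`vignettes/polykaryo-methods.Rmd`) and the ASGR tests.

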