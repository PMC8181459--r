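---
title: "Methods: Y-STR forensic statistics and population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-STR forensic statistics and population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrpopgen)
```

## Scope and data model

`ystrpopgen` analyzes tables of Y-chromosomal STR haplotypes — the joint
allele profile of a set of loci on the male-specific Y, inherited as a
single block. The default panel is PowerPlex Y23: 22 table columns covering
23 Y-STRs, with DYS385a/b held as one combined multi-copy column
(`DYS385ab`) whose two values form an unordered pair. Three conventions are
load-bearing:

* **Allele designations are exact strings.** A microvariant such as `19.1`
  (19 repeats plus one extra base) is stored and printed exactly; numeric
  conversion happens only inside distance kernels. The accepted fractional
  parts are `.1`, `.2`, `.3`; `0` and the empty field denote missing calls.
* **DYS385ab is an unordered multiset**, sorted ascending on parse, so
  `17-13` and `13,17` are the same call. It contributes a single locus to
  per-locus statistics (one gene-diversity value), and is excluded from
  repeat-count distances by default because its two values lack copy
  orthology.
* **DYS389II is used exactly as reported** by the kit; no subtraction of
  DYS389I. Any recoding would silently change haplotype identity.

Haplotype identity (`haplotype_key()`) is equality of allele multisets at
every panel locus. Haplotypes with missing calls are excluded from
haplotype-level statistics (identity is undefined for partial profiles) but
still contribute to per-locus statistics at the loci where they have calls.

## Forensic parameters

All haplotype-level statistics factor through the *occurrence spectrum*:
the map from multiplicity $m$ to the number of distinct haplotypes observed
$m$ times, with $n = \sum_m m\,c_m$ and $k = \sum_m c_m$. For haplotype
frequencies $p_i$:

* match probability $\mathrm{MP} = \sum_i p_i^2$,
* haplotype diversity $\mathrm{HD} = \frac{n}{n-1}\,(1 - \mathrm{MP})$,
* discrimination capacity $\mathrm{DC} = k/n$,
* fraction of unique haplotypes $\mathrm{FUH} = c_1/k$,

and per locus, gene diversity $\mathrm{GD} = \frac{n}{n-1}(1 - \sum_i
P_i^2)$ over allele frequencies $P_i$ with $n$ the number of calls. The
identities $\mathrm{HD} = \frac{n}{n-1}(1-\mathrm{MP})$,
$\mathrm{DC}\cdot n = k$ and $\mathrm{FUH}\cdot k = c_1$ hold exactly and
are asserted by the test suite on random spectra.

A worked example with published numbers: the reported occurrence spectra of
two Guangdong population samples — Hakka, $n=260$: $\{1{:}208,\,2{:}18,\,
3{:}4,\,4{:}1\}$; She, $n=215$: $\{1{:}65,\,2{:}43,\,3{:}6,\,4{:}5,\,
5{:}1,\,6{:}1,\,15{:}1\}$ — give $\mathrm{DC} = 0.8885$ and $0.5674$,
$\mathrm{MP} = 4.91\times10^{-3}$ and $1.42\times10^{-2}$, and
$\mathrm{FUH} = 90.04\%$ and $53.28\%$, reproduced exactly by
`generate_spectrum_table()` plus `forensic_report()`.

One deliberate non-reproduction: the same published table prints HD values
of 0.9994 and 0.9939 for these spectra, but the stated formula evaluated on
those spectra yields $\approx 0.99893$ and $\approx 0.99039$. The printed
values are not reachable from the printed spectra by the printed formula
(the same table's third column carries a similar internal inconsistency for
MP). This package follows the formula; the tests assert the
formula-consistent values and treat the printed ones as a documented
discrepancy in the source table, not as a target.

Frequencies and diversities are kept at full double precision internally
and rounded (4 decimals; MP to 3 significant figures) only in print
methods and reports.

## R_ST by AMOVA

Population differentiation uses $R_{ST}$, the $\Phi$-statistic of a
one-level analysis of molecular variance whose inter-individual distance is
the summed squared repeat-count difference over the panel's distance loci —
the appropriate statistic for stepwise-mutating microsatellites. With $N$
individuals in $G$ groups of sizes $n_g$:

$$SS_\mathrm{total} = \tfrac{1}{N}\sum_{i<j} d^2_{ij}, \qquad
  SS_\mathrm{within} = \sum_g \tfrac{1}{n_g}\sum_{i<j\in g} d^2_{ij},$$

$SS_\mathrm{among} = SS_\mathrm{total} - SS_\mathrm{within}$, with
$df_\mathrm{among} = G-1$, $df_\mathrm{within} = N-G$,
$\sigma^2_w = MS_\mathrm{within}$, $\sigma^2_a = (MS_\mathrm{among} -
MS_\mathrm{within})/n_0$ where $n_0 = (N - \sum_g n_g^2/N)/(G-1)$, and
$R_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)$.

Choices a user should know about:

* **Distance kernel.** Sum of squared numeric differences over single-copy
  loci; microvariants enter at face value ($19.1 - 19 = 0.1$), with a
  `truncate_microvariants` flag to floor them instead. DYS385ab is excluded
  by default (a panel whose `distance_loci` include a multi-copy locus gets
  sorted-copy pseudo-columns instead).
* **Missing calls** are handled by pairwise locus deletion without
  rescaling; the number of deleted (pair, locus) combinations is attached
  to the distance matrix.
* **Permutation p-values** shuffle individuals between the two populations
  of a pair and use the add-one estimator $p = (1 + \#\{R_{ST}^{perm} \ge
  R_{ST}^{obs}\})/(1 + B)$, $B = 9999$ by default; the seed is mandatory.
  Under a true null the estimator is (slightly super-) uniform, which the
  suite checks by randomly splitting a single simulated population.
* **Negative estimates.** $\sigma^2_a$ can be negative on undifferentiated
  data; `pairwise_rst()` reports the raw value in `rst_raw` and floors the
  distance-matrix copy at 0, since MDS and neighbor joining require
  non-negative dissimilarities.

The implementation is validated against an independent brute-force
variance-component oracle (explicit pair loops) to $10^{-12}$ on a battery
of 200 random small tables.

## Ordination

`build_frequency_matrix()` assembles the population × (locus, allele)
frequency matrix over the union of observed alleles, zero-filled, columns
ordered by panel locus then allele value. PCA is computed on
column-centered, *unscaled* frequencies (they already share a scale) via
singular value decomposition; explained fractions are squared singular
values over total variance. MDS is classical/metric (Torgerson double
centering, eigendecomposition) under Euclidean or Manhattan row distances —
deterministic, no random starts, unlike SMACOF-style stress optimization.
Manhattan distances are generally non-Euclidean, so negative eigenvalues
can arise; their total magnitude is reported in
`negative_eigenvalue_mass`, never silently dropped. Axis signs follow the
convention that each axis's largest-magnitude loading (PCA) or coordinate
(MDS) is positive, making outputs stable across platforms. On Euclidean
distances, classical MDS coordinates coincide with PCA coordinates up to
per-axis sign, which the suite asserts numerically. Populations, not
individuals, are the ordination unit.

## Neighbor joining

`neighbor_joining()` implements canonical NJ: join the pair minimizing
$Q(i,j) = (r-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$, assign branch
lengths by the rate-corrected split formula, reduce the matrix, and resolve
the final three clusters in closed form. Two determinism rules: $Q$-ties
break to the lowest index pair (so trees are bit-stable), and negative
branch lengths — possible on non-additive inputs like $R_{ST}$ matrices —
are clamped to 0 with the total deficit recorded as the tree's
`clamp_deficit` attribute (exactly 0 on additive inputs). Trees are
returned unrooted as ape `phylo` objects; Newick serialization delegates to
ape. Consistency is tested by generating random trees, taking their
cophenetic (additive) distances, and requiring exact recovery of topology
and branch lengths to $10^{-9}$.

## Haplogroup prediction

Published Y-STR studies often predict Y-SNP haplogroups by lookup in large
proprietary Y-SNP/STR databases. That procedure is not auditable, so the
package implements the simplest faithful, explicit stand-in: k-nearest
neighbors (default $k=5$) on the squared repeat-count distance against a
user-supplied labeled reference panel. The k neighbors vote; the majority
label is reported with its vote fraction as confidence, and queries below
`min_confidence` (default 0.6) are `"unassigned"`. All tie rules are
order-free — neighbor ties resolve by sample id, label ties by smaller mean
distance then lexicographic label — so permuting the reference rows can
never change a prediction. Defaults were chosen once for the synthetic
regime the generator produces (well-separated founders, modest within-group
noise); k small and odd-ish to limit label ties, 0.6 so that an assignment
requires a clear majority. Haplogroup names are opaque strings; no ISOGG
tree logic is applied, and published percentage compositions that depend on
private databases are out of scope.

## The synthetic-data generator

The generator defines the study conditions for every stochastic test; it is
not a tuning knob.

* **Mutation model.** Single-step SMM: per generation and locus a mutation
  occurs with probability $\mu$ and moves the allele by $\pm 1$ repeat with
  equal probability, reflecting at allele 1 (a proposed step to 0 is
  mirrored to 2; from the default ancestral allele of 14 repeats the
  boundary is effectively never visited). Mutation counts over $t$
  generations are drawn $\mathrm{Binomial}(t, \mu)$ and their signs
  resolved in one shot whenever the walk cannot reach the boundary, which
  is exact and fast; the suite checks the resulting displacement
  distribution against an explicit per-generation walk oracle.
* **Demography.** A star phylogeny: one ancestral haplotype, one founder
  per population evolved for `divergence_generations`, then each individual
  evolved independently from its founder for `within_generations`. This is
  deliberately not a coalescent — it gives known divergence with known
  expectations (between-population squared allele difference $2 t \mu$ at
  within-depth 0, checked to 3 Monte-Carlo standard errors at $t \in \{100,
  1000, 5000\}$, $\mu = 0.002$, 250 replicate loci) at a fraction of the
  machinery. Consequences: no within-population genealogy, no drift in
  allele frequencies beyond founder + noise, independence across loci.
  Passing tests therefore demonstrate correctness of the statistics, not
  realism of human Y-chromosome demography.
* **Defaults.** $\mu = 0.002$ per locus per generation, the order of
  typical Y-STR locus mutation rates; ancestral allele 14, mid-range for
  common Y-STR ladders; 22 single-copy loci plus one simulated multi-copy
  locus (two independently evolving copies reported unordered).
* **Spectrum realization.** `generate_spectrum_table()` builds a table
  whose occurrence spectrum equals a requested spectrum *exactly*:
  haplotype $j$ encodes $j$ in base-10 digits across the single-copy loci
  on top of seed-drawn base alleles, guaranteeing distinctness, then rows
  are replicated to their multiplicities and shuffled. This is the bridge
  that makes published spectrum-derived numbers testable without any data
  download.
* **Reference panels.** `generate_reference_panel()` places one founder per
  haplogroup, each shifting its own block of loci by +2 so that pairwise
  squared separations meet `founders_min_separation` by construction
  (infeasible combinations raise a constructive-failure error), and
  perturbs members with $\mathrm{Poisson}(\mu t)$ mutations per locus.

All randomness flows from one explicit, mandatory seed through
`withr::with_seed()`; no function touches the global RNG state.

## Pipeline and problem sizes

`run_pipeline()` chains forensic report → pairwise $R_{ST}$ (+ p-values) →
PCA and MDS → NJ tree (when ≥ 3 populations) → optional haplogroup
prediction, writing delimited outputs plus a YAML manifest with all
parameters, the seed and md5 checksums; reruns with the same configuration
are checksum-identical. Stages abort with the stage name on error.

Test problem sizes were chosen to make the checks sharp while keeping the
default suite quick: the AMOVA oracle battery uses 200 random tables of
$N \le 12$; the permutation-null uniformity check uses 2,000 random splits
of a 16-individual population at 99 permutations each; NJ consistency uses
100 random additive matrices of 4–10 taxa; SMM calibration uses 250
replicate loci per divergence level and 20 replicate $R_{ST}$ estimates per
level; haplogroup recovery uses 500 reference and 200 query haplotypes in 6
haplogroups.

## Known limitations

* Only one-level AMOVA: no regional groupings, no allele-identity
  $F_{ST}$, no exact tests of differentiation.
* The $R_{ST}$ kernel choices of online databases are not printed with
  their results, so values computed here need not match a specific
  database's output on the same data.
* No bootstrap support on NJ trees; no ME/ML tree search.
* The k-NN haplogroup predictor is only as good as its reference panel;
  it knows nothing about haplogroup nomenclature or phylogeny.
* Missing-data handling (pairwise deletion, exclusion from haplotype-level
  statistics) assumes missingness is rare and uninformative.
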