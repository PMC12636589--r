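---
title: "Curating and analysing TE presence/absence polymorphisms with tepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and analysing TE presence/absence polymorphisms with tepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Short-read detectors of transposable-element (TE) insertions produce two
kinds of calls against a reference assembly: *reference-TE absence calls*
(a TE annotated in the assembly looks absent in a resequenced individual)
and *non-reference insertion calls* (discordant read pairs support an
insertion the assembly lacks). Both call sets are noisy in a highly
repetitive genome such as *Aedes aegypti*'s (~65% repeats), and raw calls
are not loci: the same insertion is reported at slightly different
breakpoints in different genomes, some calls are ambiguously assigned to
two families, and many apparent polymorphisms are artifacts (fixed
insertions miscalled as absent in one genome, singleton false positives,
short elements spanned by chance by a large insert).

`tepop` turns such call sets into a curated table of polymorphic TE loci, a
binary presence/absence genotype matrix, and the population-genetic
summaries used to interpret them: site frequency spectra (SFS), joint SFS,
pairwise FST, PCA, cross-population differentiation scans, gene/exon
overlap statistics, and linkage disequilibrium between TE insertions and
candidate insecticide-resistance (IR) SNPs.

Because TE genotyping from short reads cannot reliably distinguish
heterozygous from homozygous carriers, every statistic in the package is
defined on **binary genotypes**: `1` means the insertion is present (het or
hom), `0` means homozygous absent. Frequencies are therefore *proportions
of diploid individuals carrying the insertion*, not allele frequencies, and
the package deliberately avoids allele-frequency estimators (e.g.
Weir–Cockerham FST) whose assumptions binary carrier data do not meet.

## Curation model

### Merging calls into loci

Two calls represent the same insertion when they are of the same family and
category and their intervals lie within `max_gap = 1000` bp of each other
(overlap counts as distance 0; the distance is the minimum gap between the
intervals, which is robust to unequal element lengths). Merging is repeated
to a fixpoint; a left-to-right sweep over start-sorted intervals with a
running cluster end realises exactly the transitive closure of this pairwise
relation, so results do not depend on input order. The merged extent runs
from the leftmost start to the rightmost end.

The two categories differ in *where* merging happens:

* **Reference TEs** are merged *within* each genome. A genome's present set
  is the reference annotation minus its absence calls; that set is merged
  per genome, and two genomes share a locus only if their merged loci have
  identical `(chrom, family, start, end)`. A genome carrying three of
  another genome's four merged TEs therefore carries a *different* locus.
  This identity rule is the strictest reading consistent with per-genome
  merging, and it is what makes the genotype of a sample at a reference
  locus equal 0 exactly when an absence call removed one of the locus's
  constituents.
* **Non-reference TEs** are single-linkage clustered *across* genomes
  (pairs of calls in different genomes merge), and a sample carries the
  locus if it contributes at least one call to the cluster.

### Hybrid-family calls

A detector call assigned to two families (`FamA&FamB`) is resolved by
counting the TE-supporting reads mapped within a 2 kb window around the
call: the family with more reads wins; ties (including no reads at all)
keep the first family of the label, matching the upstream detector's own
convention. Reads naming a family outside the pair are ignored.

### The filter cascade

After loci are formed, four filters run in a fixed order, and each removed
locus is attributed to the *first* stage that rejects it, so the
`filter_report` reconciles exactly (`input = survivors + sum(removed)`):

1. **Non-TE exclusion** — families whose class is Satellite, Simple_repeat
   or buffer are dropped. (The narrative order of the original procedure
   excludes these before merging; exclusion by family class commutes with
   per-family merging, so `tepop` applies it at the locus level where the
   bookkeeping is well defined.)
2. **Family activity** — a family is retained only if it has at least two
   distinct non-reference loci *and* at least one non-reference locus
   carried by two or more samples, evaluated on the pooled dataset. All
   loci of failing families (both categories) are removed. This is the
   conjunctive reading of the two published sentences about family
   activity; a disjunctive reading is possible but weaker, and the
   conjunctive one subsumes it.
3. **Global frequency filters** — a reference locus must be absent in at
   least 2 individuals (removing fixed TEs and those present in all but
   one genome, the latter being likely single-genome genotyping errors);
   a non-reference locus must be carried by at least 2 individuals
   (removing singletons). Applied to the pooled global sample, not per
   country.
4. **Length filter** — reference loci shorter than 600 bp are removed
   (read inclusively: 600 bp survives). Short reference TEs can be spanned
   by a single large insert and miscalled absent, inflating high-frequency
   artifacts. The size-stratified SFS diagnostic (`size_stratified_sfs`,
   strata `[1,200)`, `[200,600]`, `(600,∞)`; the middle stratum is closed
   on both sides because the published "between 200–600 bp" is ambiguous
   and a deterministic convention is needed) is computed immediately
   *before* this filter, since it is the evidence that motivates the
   cutoff.

## Population-genetic summaries

* **SFS** — histogram of per-locus carrier counts `k = 1..n`; the fixed
  absent class (`k = 0`) is tallied separately and not binned with the
  segregating classes.
* **Joint SFS** — `(nA+1) × (nB+1)` count matrix; its marginals equal the
  single-population SFS including the zero class, an identity asserted on
  every input in the tests.
* **FST** — per locus, `FST = (HT − HS)/HT` with `HT = 2p(1−p)` at the
  pooled-individual carrier proportion and `HS` the *unweighted* average of
  the two within-country `2p(1−p)` values. `HT = 0` leaves FST undefined
  (excluded from summaries). The constant 2 cancels in the ratio. With
  equal sample sizes the pooled proportion is the unweighted mean of the
  country proportions and concavity of `p(1−p)` bounds FST in `[0,1]`; with
  unequal sizes values can fall slightly outside and are reported as
  computed, counted in a QC field, and left out of the banded histogram.
  The mean over loci is the arithmetic mean of per-locus ratios
  (average-of-ratios); the source analysis does not state its averaging
  scheme, so this choice is explicit and fixed.
* **PCA** — locus columns are mean-centered without variance scaling
  (matching the default of the common PCA implementations applied to
  genotype matrices) and decomposed by SVD. Signs are fixed so the
  largest-magnitude loading of each component is positive, making output
  byte-reproducible. Variance fractions sum to 1 within 1e-8.

## Scans

* **Differentiation scan** — per country pair, loci ranked by `|pA − pB|`
  descending, ties broken by `(chrom, start)` ascending; the top 10 per
  pair are reported with the per-pair mean `|Δp|`, the grand mean across
  pairs, and a deduplicated cross-pair union (a locus highly differentiated
  in several pairs counts once).
* **Gene proximity** — a gene hits a locus if its span padded by 10 kb on
  both sides intersects the locus interval. The signed distance is 0 on
  overlap, positive downstream of the gene end, negative upstream of the
  gene start (the magnitude is what matters for reporting).
* **Exon overlap** — a locus is exonic if its interval intersects any exon
  (a 1 bp overlap counts); non-exonic loci overlapping annotated repeats
  are flagged so the repeat-free non-exonic class can serve as the fair
  frequency comparator. A `point_breakpoint` switch restricts the test to
  the interval midpoint for sensitivity analysis.
* **High-frequency IR scan** — reports loci lying *entirely within* a
  listed IR gene span whose presence proportion reaches 50% (inclusive) in
  at least one country. Containment, not the padded 10 kb rule, is used
  here because the question is insertions *within* the genes; the
  "at least one country" reading is forced by the per-country frequencies
  the scan reports.

## TE–SNP linkage disequilibrium

SNP genotypes are binarized two ways to be comparable with binary TE
presence: `any_alt` (het or hom-alt = present) and `hom_alt` (only hom-alt
= present). For each TE within 10 kb of a focal gene and each focal SNP,
`r` is the Pearson correlation of the two binary vectors (equal to the
classical `D/sqrt(pq(1−p)(1−q))` on the 2×2 table), `r²` is computed under
both encodings, and the larger `r²` is the reported estimate; pairs above
`r² > 0.2` are returned. Negative association (the TE riding the
non-alternate haplotype) is flagged from the sign of the winning encoding.
Missing SNP genotypes are removed pairwise per (TE, SNP) pair — maximal
data use without imputation. One focal SNP may tag a multi-SNP resistance
haplotype, so the scan does not require all haplotype members. Distances
are reported from the SNP position to the nearest locus edge (0 inside).

## The synthetic-data generator

`make_fixture()` emulates the study conditions end to end, so every stage
is testable without sequence data. Population structure follows the
Balding–Nichols model: each locus draws an ancestral presence frequency
from a Beta distribution and each country draws its own frequency from a
Beta with mean `p_anc` and variance `F·p_anc(1−p_anc)`. A frequency model
(rather than an explicit coalescent) is the right level of abstraction
because the pipeline consumes presence frequencies, and `F` is a direct
differentiation dial for monotonicity checks.

Default ("paper-mini") conditions, chosen once as the study conditions:

* six countries at the real per-country sample sizes (Brazil 18, Colombia
  24, USA 28, Senegal 20, Gabon 13, Kenya 19; 122 genomes), ~2,000 loci;
* `F = 0.05`, in the range of the country-pair differentiation the method
  is meant to resolve;
* reference-locus ancestral frequencies `Beta(2,2)` (reference TEs sit at
  intermediate frequencies by ascertainment), non-reference `Beta(0.5,2.5)`
  (mostly rare);
* breakpoint jitter uniform in ±400 bp — below the 1 kb merge distance so
  each planted cluster must resolve to exactly one locus (a supra-gap
  jitter configuration is used when testing split behaviour instead);
* 5% hybrid-family calls with read-support sidecars constructed to resolve
  back to the true family (strict majority or first-name tie);
* planted pathologies, each with a recorded expected fate: fixed reference
  loci, all-but-one reference loci, singleton non-reference loci,
  sub-600 bp reference loci, satellite/simple-repeat families, and
  co-occurring reference merge pairs 300 bp apart;
* an IR scenario in Colombia: a resistance haplotype at frequency
  `h = 0.5` (an intermediate-frequency haplotype) carrying four linked
  SNPs, one unlinked SNP at frequency 0.3, and a TE riding the wild-type
  haplotype, with per-site discordance `d = 0.02` (a typical short-read
  genotyping error rate). The expected dual-encoding `r²` is computed by
  exact enumeration of the haplotype-pair joint distribution
  (`ir_expected_r2`), not by simulation.

The ground-truth sidecars (`truth/`) contain the realized genotype matrix,
per-locus expected filter fate, per-country frequencies and the analytic LD
expectations; "expected" fates are computed from the *realized* Bernoulli
draws, so a nominally normal locus that happens to be drawn as a singleton
is correctly expected to be filtered.

What the generator does **not** emulate: read-level error models, detector
sensitivity differences between families, reference-annotation errors,
cross-mapping between paralogous TE copies, and missing genotypes for TEs
(the matrix is complete by construction, as in the real pipeline). Passing
tests on the fixture therefore demonstrate the correctness of the curation
and statistics, not the accuracy of upstream TE detection on real reads.

## Numerical and testing choices

* All internal coordinates are 0-based half-open (BED convention); GFF and
  VCF are converted at the boundary. Round-trips are exact.
* Everything is deterministic given a seed; regenerated fixtures are
  byte-identical, and PCA output is byte-stable thanks to the sign rule.
* Merging/clustering is cross-checked in the tests against an independent
  all-pairs transitive-closure oracle (100 random instances of up to 30
  calls); `r²` against the 2×2-table formula (1,000 random pairs, 1e-10);
  top-N differentiation against an exhaustive sort.
* Statistical recovery tests use 2,000 loci × 50 samples/country for the
  FST monotonicity check (paired seeds at `F = 0.05` vs `0.2`) and 500
  loci × 20+20 samples at `F = 0.3` for PCA separation; these sizes give
  the checks comfortable power while keeping the default suite fast.
* The recovery check of the IR scenario runs at `n = 200`; at the default
  discordance the sampling standard deviation of the max-encoding `r²` at
  that size is ≈0.04, so the check is run at a fixed seed rather than
  asserting a band that random draws would regularly leave.

## Known limitations

* The per-genome merging identity rule makes reference loci sensitive to
  single absence calls inside merged clusters: a genotyping error on one
  constituent creates a distinct (usually singleton-pattern) locus rather
  than a missing genotype. This mirrors the published procedure; the
  frequency filters are what keep such artifacts out of the final set.
* FST on carrier proportions is not comparable in absolute value to
  allele-frequency FST; use it for ranking and cross-population contrasts.
* The exon-overlap comparison uses whole locus intervals by default; for
  non-reference loci these are narrow breakpoint clusters, but merged
  reference loci can be long, which inflates overlap odds relative to a
  breakpoint-based rule (`point_breakpoint = TRUE` is the conservative
  alternative).
* `high_frequency_gene_scan` and the LD scan take the gene lists at face
  value; gene ids absent from the annotation are skipped with a warning.
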