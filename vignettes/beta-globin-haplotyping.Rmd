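---
title: "Beta-globin cluster haplotyping and malaria-variant population genetics with sickleHaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-globin cluster haplotyping and malaria-variant population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sickleHaps)
```

## The problem

The sickle-cell mutation (HbS, rs334, an A→T substitution at HBB codon
6) is maintained at high frequency in malaria-endemic regions because
heterozygous carriers are partially protected against severe
*Plasmodium falciparum* malaria. Two classes of markers summarize this
history at the molecular level:

* **β-globin cluster haplotypes.** Five diagnostic restriction-site
  polymorphisms across the β-globin gene cluster — XmnI (5'Gγ),
  HindIII (Gγ), HindIII (Aγ), HincII (3'ψβ) and HinfI (5'β) — define
  the classical haplotype backgrounds (Benin, Bantu/CAR, Senegal,
  Cameroon, Arab-Indian) on which HbS arose; any other combination of
  the five sites is an *atypical* (recombinant) haplotype.
* **Malaria-associated SNPs.** Unlinked variants identified by severe-
  malaria GWAS (the roles played here by an ABO proxy, an HBB proxy
  and a MARVELD3 proxy) whose minor allele frequencies (MAF) are
  expected to decline with distance from the equatorial malaria belt
  if they are under malaria-driven selection.

sickleHaps implements the complete analysis chain for both: in-silico
RFLP haplotyping and HbS genotyping from sequence, haplotype frequency
and combination tables, allele-frequency / Hardy–Weinberg /
F-statistic comparisons across populations, two-locus LD with
Gabriel-style haplotype blocks, and haplotype bifurcation (EHH) trees
around a core variant. A synthetic-data generator produces cohorts,
sequences and phased panels with exactly the statistical structure the
analysis assumes, so every stage is testable without external data.

## In-silico RFLP and HbS genotyping

Restriction enzymes are modelled by IUPAC recognition patterns and a
cut offset (`RestrictionEnzyme`). Scanning (`findSites`) is
single-strand, with each pattern supplied in the orientation of the
template's reference strand: the five diagnostic sites are defined on
the cluster's reference orientation, and double-strand scanning would
count palindromic sites (HindIII `AAGCTT`) twice. All overlapping
matches are reported; only presence within a locus window matters
downstream. A sequence `N` matches only a pattern `N`; a pattern `N`
matches any base.

```{r rflp}
ddei <- defaultEnzymes()$DdeI
findSites("CCTGAGGAG", ddei)   # HbA codon-6 context: site present
findSites("CCTGTGGAG", ddei)   # HbS context: site lost
genotypeHbs("+", "-")
```

A locus is called `+` iff at least one match *starts* inside its
window (1-based inclusive; matches may run past the window end). The
rs334 orientation is A = HbA (DdeI site present), T = HbS (site lost).

Coordinates are 1-based inclusive everywhere (the R/Bioconductor and
VCF convention); region strings follow samtools (`chrom:start-end`).

## Haplotype classification

Classification is exact table lookup: a complete five-site profile
that equals a classical pattern gets that label, a profile equal to a
named atypical subtype gets the subtype, anything else is
`atypical-other`, and profiles with missing states are `unresolved`
(excluded from frequency denominators, reported separately). The
patterns ship as a *versioned JSON configuration*
(`table-ref16-default`) rather than constants, because the primary
sources defer the site tables to supplementary material; all analyses
bind the generator and the classifier to one and the same table, which
makes results table-consistent by construction. Frequencies are
reported per chromosome; combinations (the unordered pair of
haplotypes in an individual) collapse atypical subtypes by default,
matching the granularity at which such tables are conventionally
printed. Percentages are rounded to one decimal place.

An open interpretive point is whether printed per-subtype percentages
in cohort reports use all chromosomes or only atypical chromosomes as
denominator; `haplotypeFrequencies` exposes both via `grouping =
"fine"` (all resolved chromosomes) and subsetting, and the package
asserts nothing that depends on the choice.

```{r classify}
tab <- defaultHaplotypeTable()
co <- makeCohort("demo", c("Benin", "Benin", "atypical-I", "Cameroon"),
                 c("A", "A", "A", "T"), table = tab)
dg <- digestCohort(emitSequences(co))
classifyProfiles(dg, tab)
haplotypeFrequencies(classifyProfiles(dg, tab), "classical-vs-atypical")$table
```

## The synthetic-data generator

`simulateCohort` draws, per chromosome: a haplotype label from the
spec's mixture, an HbS allele binomially at the HbS allele frequency,
and one allele per marker SNP binomially at its MAF. Allele-level
draws mean marker genotypes are in *exact* Hardy–Weinberg proportions
(no inbreeding parameter in this version), and haplotype background
and HbS allele are drawn independently — appropriate for cohorts that
are overwhelmingly HbAA. `emitSequences` realizes each chromosome as
an amplicon-style sequence in which every locus window carries the cut
or uncut local variant (single-base substitutions, so cut and uncut
windows have equal length and fixed coordinates), separated by inert
C-run spacers that cannot complete any recognition site; digesting the
emitted sequences reproduces the profiles and HbS alleles exactly
(`digest ∘ emit = identity`, a tested invariant).

`simulateRegionPanel` uses a block-copy model: markers split into
blocks at explicit breakpoints, a small set of founder haplotypes per
block (pairwise distinct, every marker polymorphic across founders),
and each chromosome picking one founder per block independently. This
deliberately trades coalescent realism for exact control: within-block
LD is complete with two founders, between-block LD decays to sampling
noise, and block boundaries are known, so block detection and
bifurcation structure can be scored against truth. What it does *not*
emulate: mutation/recombination gradients within blocks, allele-
frequency spectra of real panels, or background relatedness — passing
tests demonstrate correctness of the algorithms under the stated
model, not fidelity to any particular human population.

Generator defaults are fixed once and documented here: the default
cline (`defaultClineSpec`) orders six populations from equatorial to
southern with ABO- and HBB-proxy MAFs decreasing 0.30 → 0.05 in 0.05
steps and a flat MARVELD3-proxy MAF of 0.25 — the gradient /
no-gradient contrast reported for these marker roles; HbS allele
frequencies decrease 0.10 → 0. True per-population MAFs for the three
marker SNPs are not legible in the available sources, so these
defaults are illustrative study conditions, not calibrated estimates.
Seeds are explicit everywhere; a master seed derives per-stage seeds
by stable hashing of stage names (`deriveSeed`), and identical spec +
seed gives byte-identical output.

## Population-genetic statistics

* **Allele frequencies.** `estimateFreq` computes
  `p = (2 nAA + nAa) / 2n` and `MAF = min(p, 1 − p)`.
* **Hardy–Weinberg.** `hweExact` is the exact conditional test:
  conditioning on allele counts, it enumerates all heterozygote counts
  of matching parity and sums the probabilities of configurations no
  more probable than the observed one. The exact test is the default
  because cohort sizes of ~50 individuals are too small for the
  chi-square approximation (offered as `method = "chisq"`).
* **F-statistics.** `pairwiseFst` is Wright's frequency-only variance
  ratio `Var(p) / (p̄(1 − p̄))` with no sample-size correction — the
  appropriate form when only per-population frequencies (not genotype
  tables) are available for comparison populations, which is the
  setting of cross-panel MAF comparisons. `weirCockerhamFst` provides
  the sample-size-corrected variant for users with full genotype data.
  `fstMatrix` builds per-SNP matrices and their unweighted mean,
  dropping missing cells from the aggregate.
* **Cline trend.** `clineTrend` is the Spearman rank correlation
  (midranks for ties) between geographic position index and MAF, with
  a two-sided permutation p-value: full enumeration of all orderings
  up to 8 populations (720 permutations at 6) for exact
  reproducibility, seeded Monte-Carlo beyond. Constant MAFs are a
  flagged degenerate case (statistic 0, p 1).

## Linkage disequilibrium and haplotype blocks

Two-locus haplotype frequencies come from direct counting on phased
data and from an EM on unphased 3×3 genotype tables (only double
heterozygotes are ambiguous; the EM preserves observed allele-count
margins, never decreases the log-likelihood, and stops when the
largest frequency change is below 1e-8 or after 1000 iterations). A
table consisting solely of double heterozygotes has a flat likelihood
ridge and is returned at the uninformative 0.25 initialization,
flagged `unidentifiable`. `ldPair` computes D, D′ and r² with the
standard normalizations; monomorphic markers are flagged undefined.

Confidence bounds on |D′| (`dprimeCI`) use the conventional
likelihood-grid construction: allele frequencies fixed at their sample
estimates, likelihood evaluated on a 101-point |D′| grid (resolution
configurable), normalized; the lower bound is the smallest grid value
reaching 5% cumulative likelihood, the upper bound the largest with at
least 5% in the upper tail. `gabrielBlocks` then labels pairs strong
LD (CI lower ≥ 0.70 and upper ≥ 0.98) or strong evidence of
recombination (upper < 0.90), and a candidate span is a block iff at
least 95% of its informative pairs (pairs with both markers
polymorphic) are strong-LD; maximal non-overlapping spans are chosen
greedily, longest first, ties by leftmost start. The four thresholds
are the Haploview defaults — the tools conventionally used for this
analysis do not document alternative parameters — and all are exposed
as arguments. Multi-marker per-block haplotype frequencies
(`blockHaplotypeFreqs`) require phased input in this version; the
two-locus EM is not generalized to longer haplotypes.

## Bifurcation trees and EHH

`buildBifurcation` roots a tree at the chromosomes carrying a chosen
core allele and extends marker by marker (strictly by physical
position) proximally or distally; a node splits when both alleles
occur among its haplotypes, and branch counts drive line thickness in
`plotBifurcation`. Missing alleles drop a chromosome at the depth
where the gap occurs — transparency was preferred over imputation, and
per-depth drop counts are retained in the tree. EHH at depth d is
`Σ_h C(n_h, 2) / C(n_core, 2)` over distinct d-length extensions; it
equals the tree-derived value when nothing was dropped (a tested
invariant). Subsampling to a fixed number of haplotypes per population
(20 is the conventional choice for bifurcation diagrams) is an
explicit seeded operation, `subsampleChromosomes`, never implicit; how
such subsets were drawn historically is typically unstated, so the
package makes the choice visible and reproducible. At the rs334 core
the A (HbA) allele is treated as ancestral and T (HbS) as derived, per
the standard orientation; this is an argument, not a constant.

## Numerical and design notes

* Exact-count worked examples: cohort percentages reported to one
  decimal place reconstruct exactly from integer counts (e.g. 53 of 78
  chromosomes → 67.9%), so the acceptance checks build cohorts with
  those counts via `makeCohort` and push them through the full
  emit → digest → classify → tabulate chain rather than asserting
  arithmetic.
* One reported combination percentage (41.2% over 35 individuals) does
  not reconstruct as an integer count and is therefore not used as a
  check.
* The exact F-statistic estimator behind published frequency-
  differentiation figures is typically unstated; the frequency-only
  Wright form is this package's documented choice.
* Problem sizes used in the test suite and acceptance checks — 600
  chromosomes × 12 markers over 10 seeds for block recovery, 200
  replicates of six 500-individual cohorts for cline-trend power,
  2000-individual cohorts for parameter recovery — were chosen as the
  smallest sizes at which the binomial sampling error is comfortably
  below the effects being scored.
* `runPipeline` writes every stage artifact (TSV/JSON/FASTA/VCF) plus
  a manifest under one output directory; a rerun with the same
  configuration reproduces all numeric outputs byte-identically.

## Known limitations

* The block-copy simulator is not a coalescent: no recombination-rate
  or mutation-model realism, no demographic inference.
* No statistical phasing: chromosome-level five-site profiles are
  taken as given, as in the underlying assay design.
* No methylation sensitivity, partial digestion or gel-mobility
  modelling in the digest; no multi-allelic variant support (such
  records are dropped with a logged count on VCF import).
* The classical/atypical pattern table is configuration; analyses of
  real data should substitute a table from the user's protocol and
  pass it to both generator and classifier.
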