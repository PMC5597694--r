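---
title: "Methods: MHC class I diversity analysis in Pan"
author: "panmhc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MHC class I diversity analysis in Pan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmhc)
```

# Scope and model

`panmhc` analyses full-length MHC class I alleles — sequences spanning
all exons and introns of one gene — typed in diploid individuals of two
closely related species. Four loci are handled: the classical *A*, *B*
and *C* genes and the nonpolymorphic *A-like* locus, which is present on
some chimpanzee haplotypes and has never been observed in bonobos, so it
is modelled as a per-individual presence/absence trait with three states
(positive, explicitly negative, untested).

The analysis chain is: (1) parse and collapse allele names; (2) count
distinct alleles per locus, taxon scope and resolution level; (3)
partition aligned alleles into exons and introns under a gene model and
estimate nucleotide diversity per region; (4) test between-taxon
diversity differences by an individual-resampling permutation test with
Bonferroni correction; (5) reconcile duplicate replicate call sets and
flag spurious deletion alleles. A synthetic-data generator exercises all
five stages with known truth.

# Nomenclature semantics

Allele names follow the colon-delimited convention
`<locus>*f1:f2:f3:f4`. Truncating to 3, 2 or 1 fields collapses alleles
into coding-sequence, protein (allotype) and allele-group classes.
Collapsing is idempotent and monotone, so class counts can only shrink
from full-length to protein level; this monotonicity is asserted
throughout (on the packaged chimpanzee data, the *C* locus collapses
29 → 26 → 25 and *A* collapses 30 → 25 → 25).

Design choices made here, where conventions differ between databases:

* fields compare as zero-padded strings (never as integers), avoiding
  `01` vs `1` drift; locus comparison is case-insensitive;
* species prefixes (`Patr-`, `Papa-`) are significant, so name sets of
  different species are disjoint and combined counts equal per-species
  sums — this additivity is asserted at run time rather than assumed;
* a single-allele genotype row is treated as homozygous (the allele
  counted twice), matching the convention that n individuals contribute
  2n sequences; callers can instead drop single calls as potential
  allele dropout (`genotype_calls(homozygous_single = FALSE)`).

# Packaged study data and the count grid

The package ships a transcription of the genotype tables of a published
survey of 30 chimpanzees (6 *P.t.s.*, 4 *P.t.v.*, 20 *P.t.t.*) and 21
bonobos, plus that study's summary grid of distinct-allele counts.
`reproduce_tables()` recomputes the grid from the genotype listings and
compares cell by cell. Counting is by collapsed name; when aligned
sequences are attached the name classes are cross-validated against
sequence identity.

The comparison deliberately reports disagreements instead of resolving
them: the central-subspecies (*P.t.t.*) column of the published grid
contains cells (the *C* locus 20/17/16, the *A* locus coding/protein 18)
that an independent tally of the genotype listings cannot reproduce
(18/16/15 and 17 respectively). All whole-species and combined-species
cells agree exactly. Since the genotype listings are the primary record,
the package surfaces both numbers and lets the analyst decide.

# Gene models and coding sequences

A gene model is an ordered alternation of exon and intron segments
(starting and ending with an exon) with lengths given on the per-locus
alignment, so gap columns count toward segment length and one model
slices every allele of the locus. Coordinates are 1-based and closed,
following the R/Bioconductor convention used by IRanges; codon indices
for premature stops are 1-based as well.

The packaged gene models are *schematic*: only the anchor lengths
(A: I3 = 583 bp, E8 = 5 bp; B: I3 = 574 bp, E7 = 44 bp; C: I3 = 588 bp,
E8 = 5 bp) are published values; the remaining segment lengths are
HLA-like placeholders chosen so each locus' exon total is a multiple of
three (1098 bp CDS for A/C-like, 1089 bp for B-like). They are suitable
for simulation and for exercising the region logic, and must not be read
as the true *Patr*/*Papa* gene structures.

CDS extraction concatenates exon slices and strips alignment gaps. A
sequence is *functional* iff its length is a multiple of three and no
stop codon ({TAA, TAG, TGA}) occurs before the final codon. Premature
stops are scanned codon-by-codon even when the frame is broken, because
the diagnostic signature of a frameshifting deletion is precisely a stop
arriving in the shifted frame. Codons containing IUPAC ambiguity codes
translate to `X` and never count as stops.

# Nucleotide diversity

For a region selection the sample matrix holds 2n rows (two per
individual, homozygotes duplicated). Diversity is the average over all
C(2n, 2) unordered row pairs of per-pair per-site differences:

$$\pi = \binom{m}{2}^{-1} \sum_{i<j} d_{ij} / L_{ij}, \qquad m = 2n$$

with pairwise deletion: \(L_{ij}\) counts only columns where both rows
carry an unambiguous A/C/G/T. Pairwise deletion was chosen over
complete deletion because full-length alleles differ by indels, and
complete deletion would discard every column with any gap; on gapless
data the two coincide. A row is never compared with itself, and
identical rows (homozygote duplication) contribute d = 0 pairs to the
average — the implemented convention is asserted by a duplication test
against the brute-force oracle.

The default standard error is the Nei-style sampling variance

$$V(\hat\pi) = \frac{n+1}{3(n-1)L}\,\pi + \frac{2(n^2+n+3)}{9n(n-1)}\,\pi^2$$

with n = number of sequences and L the mean per-pair compared sites. A
bootstrap over individuals (both alleles resampled together; default
1000 resamples, seeded) is provided as an alternative, since "standard
error of the mean" is ambiguous between the two in common usage. Both
options are exposed and reported; they are similar in magnitude on the
simulated data.

Implementation note: per-pair mismatch counts are computed for all pairs
at once via four base-indicator cross-products
(\(D = L - \sum_b B_b B_b^\top\)), so a permutation test can reuse one
pooled pairwise matrix and evaluate any group assignment by submatrix
averaging. This makes the resampling loop O(m²) per permutation
independent of sequence length.

# Permutation test

The test statistic is \(|\pi_1 - \pi_2|\). The exchangeable unit is the
individual: both alleles of an individual move together, accounting for
the non-independence of alleles within a genotype. Resampling is a
random partition of the pooled individuals into groups of the original
sizes — label permutation without replacement, not a bootstrap — which
preserves group sizes exactly and matches the stated null of
exchangeable individuals. The observed arrangement counts as one of the
N permutations and the p value uses a greater-or-equal comparison, so
p ∈ [1/N, 1]. With N = 10 000 the smallest attainable p is 0.0001.

For small samples `exhaustive_test()` enumerates all C(n1+n2, n1)
assignments (bounded at 10⁵) and returns the exact p; the Monte-Carlo
test converges to it, which is verified on 20 random instances at
n1 = n2 = 3 within three Monte-Carlo standard deviations.

Multiple testing uses Bonferroni with an *inclusive* threshold:
significant iff p ≤ alpha/n_tests. The number of tests is a run
parameter computed from the comparison manifest, never hard-coded; with
alpha = 0.05 and 25 tests the threshold is 0.002 and p = 0.002 is
significant. (A family of 24 tests would give 0.00208; because the
family size is a modelling decision, it is exposed in the config and
reported alongside the results.)

Seeding: every test derives an independent stream via a deterministic
hash of (base seed, test id), so adding a comparison to a scan never
changes earlier p-values, and results are bit-reproducible for a fixed
seed and input order.

# Replicate reconciliation

Duplicate PCR replicates per individual and locus usually yield
identical allele sets. The characteristic artifact of long-amplicon
consensus calling is the collapse of two very similar true alleles into
one spurious sequence. A solitary allele opposing a two-allele replicate
is discarded only when all three criteria hold:

1. it carries a deletion within an exon relative to both pair members;
2. at least one such deletion column coincides with a column where the
   two pair members differ (the unphased site);
3. its CDS shows a premature stop codon.

Any other disagreement is reported `discordant_unresolved` with both
call sets preserved — the rules never auto-drop data. Read support,
when provided, is logged as soft evidence only (artifact calls tend to
have fewer reads) and is not required for resolution.

# Synthetic data generator

The generator defines the conditions under which the pipeline is
validated:

* **Pools.** K = 12 alleles per locus per taxon (comparable to the
  per-locus allele counts observed in samples of 20–30 individuals),
  derived from one ancestral sequence by Poisson(rate × length)
  substitutions per segment. Alleles are gap-free, pairwise distinct and
  functional by construction (re-drawn otherwise); indels enter only via
  artifact injection, so pi semantics are exercised free of alignment
  ambiguity.
* **Region rates.** Background 0.005 substitutions/site with hotspots
  at 0.04: exons 2/3 for A/B-like loci and exon 5 for C-like, matching
  the qualitative diversity profiles of the three class I genes (peptide
  binding domains for A/B; the distinctive exon-5 peak of C). Between
  two random alleles the expected per-site difference is roughly twice
  the rate, so hotspot pi is of order 0.08 — the magnitude seen at the
  most diverse class I exons.
* **Frequencies.** Symmetric Dirichlet; concentration 1 for the
  high-diversity taxon and 0.4 for the low-diversity taxon, whose
  dominant-allele skew mimics the strongly uneven bonobo *B* frequency
  distribution.
* **Taxa.** The packaged `two_taxon_scenario()` uses two taxa of 20
  individuals (the study's matched per-taxon sample size) and a
  diversity-scale ratio of 0.3 for the low-diversity taxon.
* **Artifacts.** With probability `artifact_rate` a heterozygous call's
  replicate is replaced by a solitary chimera: a copy of one true allele
  with a 1-bp deletion at a column distinguishing the two true alleles,
  the column chosen so the shifted frame hits a premature stop. The
  truth record marks every injected artifact, so QC sensitivity and
  false-positive rates are scored exactly. Because the injector
  guarantees the stop, sensitivity tests assert the rule encoding, not
  real-data performance.

`expected_pi()` provides the closed-form expectation of the sample pi
under the generator (the Dirichlet-frequency quadratic form over the
pool's pairwise differences), which parameter-recovery tests compare
against the mean estimate over replicate datasets.

What the generator does *not* emulate: coalescent genealogies,
recombination, selection on amino acids, alignment uncertainty, and
sequencing error beyond the one artifact class. Passing tests therefore
validate the statistical machinery and rule encodings, not the
biological realism of any particular dataset.

# Validation problem sizes

The test suite validates the permutation test's type-I error on 2000
null datasets (two groups of 10 individuals from one pool, 999
permutations each, binomial 99% CI around 0.05), its power ordering on
200 datasets per diversity ratio, Monte-Carlo/exhaustive agreement on 20
instances at 10⁵ permutations, the pi estimator against a brute-force
oracle on 50 random matrices (tolerance 1e-12), and parameter recovery
on 100 datasets per diversity scale. These sizes give stable Monte-Carlo
verdicts while keeping a full run on one CPU in the minutes range.

# Known limitations

* Novelty classification is name-based against a user-supplied
  catalogue; no sequence search against IPD-MHC is attempted, and
  published novel-allele counts (which depend on a database snapshot)
  are not reproduction targets.
* The packaged gene models are schematic outside their anchor lengths.
* The permutation test implements only the absolute-difference-in-pi
  statistic; the diversity machinery is pluggable but no other statistic
  is exercised.
* Published per-locus pi values read off figures are not reproduction
  targets; the pipeline reproduces the qualitative patterns (hotspot
  ranking, reduced low-diversity-taxon pi, zero-diversity segments) on
  generator output.
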