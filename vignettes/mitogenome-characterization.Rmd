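---
title: "Methods: mitogenome characterization and K2P/NJ phylogenetics"
author: "mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome characterization and K2P/NJ phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

## Scope and data model

`mitochar` analyzes one kind of object: an annotated circular
mitochondrial genome. The annotation is a `GeneTable` — an ordered list
of features (protein-coding genes, tRNAs, rRNAs, one control region)
with 1-based, fully inclusive coordinates on the deposited heavy (H)
strand, matching the GenBank convention and the way mitogenome papers
print their gene-organization tables. A feature with `start > stop`
wraps across the circular origin; its length is
`(L - start + 1) + stop`. Coupling a table with its sequence gives a
`MitoRecord`, the unit all sequence-level analyses consume.

A deliberate design rule runs through the whole package: **declared
annotation columns (size, intergenic spacer, start/stop codon labels,
anticodons) are stored verbatim and never recomputed in place.**
Printed gene tables are not always internally consistent, and an
analysis toolkit should surface such conflicts, not silently repair
them. All recomputation lives in `validateTable()`, which compares the
declared values against coordinate-derived lengths and gaps and, when a
sequence is available, against sequence-derived codons, and returns
findings without mutating anything. On the packaged reference table
this yields exactly one finding: the declared 4 bp spacer before
tRNA-Ile, where the coordinates give 5 bp.

## Gene-map analytics

Junctions pair *consecutive rows in ascending-start order regardless of
strand*, because that is how the intergenic column of a printed gene
table is laid out. For each pair the signed gap is
`start(downstream) - stop(upstream) - 1`: negative gaps are overlaps of
`|gap|` bp, positive gaps are spacers, zero gaps contiguous junctions
counted as neither. The junction between the last feature and the first
(across the origin) is excluded by default — printed tables do not
report it — and can be included with `includeOriginJunction = TRUE`.
Overlap and spacer totals are invariant under any rotation of the
circular origin that splits no feature; the test suite checks this
property on the reference table.

## Composition and skews

AT-skew = (A − T)/(A + T) and GC-skew = (G − C)/(G + C). A zero
denominator yields `NA` rather than an error, and the ratios are
scale-invariant, so they can be computed from counts or percentages
interchangeably. `N` counts toward a partition's length but is excluded
from both numerator and denominator of the percentages.

`partitionComposition()` reports the standard partitions: whole genome,
concatenated PCGs, the three codon positions of that concatenation,
rRNAs, tRNAs, and the control region. Two orientation rules matter:

* gene-functional partitions (PCG, tRNA, rRNA) are **strand-corrected**
  — L-strand members are reverse-complemented to coding sense before
  counting — while the genome row uses the deposited H strand, since it
  describes the reference molecule rather than gene function;
* codon positions are assigned 1, 2, 3 cyclically *restarting at each
  gene's annotated start*, so a gene ending in an incomplete stop codon
  contributes its trailing 1–2 nucleotides to positions 1 (and 2) only.
  On the reference layout this yields position lengths 3807/3802/3800
  from the 11,409 bp PCG concatenation — five genes carry a 1-nt tail
  and two a 2-nt tail — which is exactly the small asymmetry visible in
  published composition tables.

Reporting precision is 1 decimal for percentages and 3 for skews; tests
compare at those precisions.

## Codon usage under the vertebrate mitochondrial code

The genetic code is NCBI translation table 2 (via Biostrings): TGA is
Trp, ATA is Met, AGA/AGG are stops. `extractCodons()` obtains each
CDS in coding sense (L-strand genes reverse-complemented, circular wrap
resolved) and reads triplets in frame from position 1. A CDS whose
length is not a multiple of 3 ends in an incomplete stop codon,
labelled by tail length: `T-` for one trailing nucleotide, `TA-` for
two. The package uses these ASCII labels throughout. Internal stop
codons are findings, not errors, so misannotated inputs remain
analyzable; a CDS shorter than 6 nt is an error.

RSCU(c) = count(c) / mean count over c's synonymous family, with stop
codons and incomplete tails excluded; for every family with nonzero
usage the family mean is exactly 1. CDpT(family) =
1000 · family count / total codons, and family values sum to 1000 up to
rounding. Families are keyed by amino acid with serine split into its
two unrelated codon boxes, Ser (TCN) and Ser2 (AGY), the convention of
mitogenome codon-usage plots; under table 2, Ser2 is AGT/AGC only.

Two codon totals are reported, because both conventions appear in the
literature: `totalCodons` = ⌊Σ PCG lengths / 3⌋ computed on the
concatenation (11,409/3 → 3,803 on the reference layout), and
`completeCodons` = Σ per-gene complete triplets (3,800), which excludes
the seven incomplete tails. The initiator triplet is counted literally
(a GTG start counts under Val) because literal counting is reproducible
without translation heuristics; `initiatorAsMet = TRUE` switches to the
recoding convention.

## The reference fixture and its two inconsistencies

`table1Fixture()` is a verbatim transcription of the published gene
table of the *Onychostoma lepturum* mitogenome (MT258556): 38 features
on 16,598 bp. Verbatim storage matters because the printed table
carries two internal conflicts that the package must surface rather
than resolve silently:

1. the declared intergenic value before tRNA-Ile (4) differs from the
   coordinate-derived gap (5) — found by `validateTable()`;
2. COIII's declared stop is the complete codon TAA, but its 785 bp
   length is ≡ 2 (mod 3), which forces a 2-nt incomplete stop; the
   cross-species codon matrix in the same publication prints `TA-` for
   COIII, and only the `TA-` reading reproduces the published
   codon-position lengths 3807/3802/3800.

The generator spec derived from the fixture, `table1GenomeSpec()`,
therefore uses `TA-` for COIII and coordinate-derived intergenic
values, so that generated genomes validate with zero findings, while
the fixture itself keeps the printed values.

## Synthetic genomes and simulated alignments

`generateGenome()` plants the specified features on a random sequence
in three phases: first all *fixed* positions (start triplets, complete
stops, literal T/TA tails) for every PCG, with conflict checking so
overlapping genes constrain each other; then the remaining codon
positions gene by gene, rejection-sampling each codon until it is not a
stop (or, for an unconstrained terminal codon, until it is one); then
every unconstrained position from the base-composition target. The
default target (A 31.3%, C 28.6%, T 24.0%, G 16.2%) is the published
whole-genome composition of the reference mitogenome, so synthetic
genomes sit at a realistic ~55% A+T. Feasibility (stop label vs length
mod 3) is checked before any generation. Generation is deterministic
given the spec's seed, and the ambient RNG state is restored on exit.

What the generator does *not* emulate: real codon-usage bias (interior
codons are i.i.d. draws), tRNA secondary structure, control-region
tandem repeats, and the origin-proximal skew gradients of real mtDNA.
Tests that pass on generated genomes therefore validate the
*arithmetic* of the analyses (lengths, frames, labels, conservation
identities), not biological signal detection.

`simulateAlignment()` evolves a uniform-random root sequence down a
tree under the two-rate (transition/transversion) continuous-time
model — the generating model of the K2P distance. Branch lengths are
expected substitutions per site; the default rate ratio alpha/beta = 4
is a typical mitochondrial transition bias. The per-branch substitution
probabilities are the closed-form K80 transition probabilities, applied
site-wise.

## Distances, neighbor-joining, bootstrap

`pqProportions()` classifies aligned site pairs as transitions
(A↔G, C↔T) or transversions under **pairwise deletion** (sites with N
or a gap in either row are dropped for that pair only). Pairwise
deletion is the MEGA default for K2P distances and so the setting most
comparative mitogenome studies effectively used; complete deletion is
deliberately not offered, since with mitogenome-scale alignments the
two differ negligibly and a single documented policy keeps results
comparable. `k2pDistance()` applies
d = −½ ln((1 − 2P − Q)√(1 − 2Q)) and raises a saturation error naming
the pair when the logarithm's argument is non-positive.

`njTree()` is the Saitou–Nei agglomeration with the rate-corrected
criterion Q(i,j) = (n−2)d(i,j) − r(i) − r(j). Numerical choices:

* **tie-break**: among minimal-Q pairs (within 1e−12), the pair whose
  cluster labels (a cluster is labelled by its alphabetically first
  member) sort lexicographically smallest is merged, so the algorithm
  is deterministic for any input;
* **negative branches**: a negative branch-length estimate is clamped
  to 0 with the deficit shifted to its sister branch — the
  MEGA-compatible behavior, which preserves the pair's summed length —
  unless `allowNegative = TRUE`; at the final 3-cluster join the
  three-point estimates are clamped at 0 without shifting;
* the tree is left **unrooted** (basal trifurcation); rooting on an
  outgroup is a display operation (`rootAtOutgroup()`) that preserves
  all path lengths.

NJ is exact on additive matrices; the suite verifies topology *and*
branch-length recovery on random 4–8-taxon trees (200 in the acceptance
run), using an independent path-summation oracle (`treeDistances()`)
to build the input distances.

`bootstrapSupport()` resamples alignment columns with replacement,
rebuilds the K2P/NJ tree per replicate, and reports for each internal
bipartition of the original tree the percentage of completed replicates
containing it. A replicate whose distance matrix is incomputable
(saturation) is skipped with a warning and the denominator adjusted.
Bipartitions are canonicalized as the tip set on the side away from the
alphabetically smallest taxon, so comparison is representation-free.

## Problem sizes and test design

The simulation-backed checks run at sizes chosen to make the assertions
sharp while keeping the default test run quick: alignments of 4–5 kb
(about a third of a mitogenome, ample for K2P at the divergences used),
40 independent seeds for the 4-taxon topology-recovery check with
internal branches at 0.05 substitutions/site (the shortest internal
branch the recovery claim covers), 100–1000 bootstrap replicates, and
200 random additive matrices. Format round-trips are required to be
byte-stable on the second write, a stronger and easier-to-test
condition than field-level equality.

## Known limitations

* The GenBank reader targets the minimal single-record dialect used by
  mitogenome submissions (LOCUS/ACCESSION/FEATURES/ORIGIN; feature keys
  gene, CDS, tRNA, rRNA, D_loop, misc_feature). It is not a general
  GenBank parser; EMBL/GFF3 are out of scope.
* Ambiguity codes beyond N are mapped to N with a warning.
* No maximum-likelihood or Bayesian tree inference, no model selection,
  and no alignment: alignments are inputs.
* The most-frequent-codon percentages and partition compositions of the
  *deposited* reference sequence cannot be reproduced from the printed
  table alone; the package covers those analyses with generator-backed
  identities (codon conservation, RSCU/CDpT normalization) instead.
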