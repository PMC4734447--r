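---
title: "Genomic taxonomy and phylogenomics: models, parameters, and design"
author: "GenomicTaxonomy package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic taxonomy and phylogenomics: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

GenomicTaxonomy implements a whole-genome taxonomy stack for prokaryote
genome sets — the six comparisons commonly used to delineate species
boundaries from complete genomes — plus ortholog clustering and
concatenated-gene phylogenomic reconstruction, and a seeded genome
evolution simulator that provides genome sets with *known* divergence
for validating every metric. This vignette explains the models, the
tunable parameters and their defaults, the numerical choices, and what
the simulation-based validation does and does not demonstrate.

# The metrics

## Fragment-based average nucleotide identity (ANI)

The query genome is cut into consecutive, non-overlapping fragments of
`fragLen` = 1,020 bp. Each fragment is aligned to the subject genome by
seed-and-extend local alignment (below), and is *retained* when its
best alignment reaches at least 30% identity over at least 70% of the
fragment length. The one-way ANI is the mean identity over retained
fragments; the two-way ANI is the arithmetic mean of the two one-way
values, which makes it symmetric by construction (a pooled fragment
mean can be obtained from the per-fragment tables in the result). The
1,020 bp / 30% / 70% convention follows the established fragment-based
ANI lineage; all three are arguments. ANI at or above 95% is the
conventional conspecificity boundary.

Two details matter for reproducibility:

* The terminal fragment of a contig is kept when it is at least half a
  window (>= 510 bp) and dropped otherwise. Tiny terminal fragments
  carry noisy identity estimates that would bias the mean.
* Alignment columns containing N or any other ambiguity code always
  count as mismatches, in scoring and in identity.

When no fragment is retained, the result is an explicit no-signal
state, never 0: a mean over nothing is undefined, and 0 would be
indistinguishable from a genuine (impossible) measurement.

## Reciprocal-best-hit average amino acid identity (AAI)

All protein pairs of the two proteomes are aligned by exhaustive
Smith-Waterman (no heuristic — proteome sizes make full dynamic
programming affordable). For each gene the best hit in the other
proteome is the highest bit score passing an e-value cutoff of 1e-5,
with ties broken by higher identity and then by the lexicographically
smaller subject id. A pair is a reciprocal best hit (RBH) when each
member is the other's best hit; pairs below 30% identity or 70%
coverage of the shorter protein are discarded, and AAI is the mean
identity of the survivors. Coverage is measured as alignment columns
capped at the shorter protein's length — a slight over-estimate when
the alignment is gappy, which only makes the 70% filter marginally more
permissive; the identity filter dominates in practice.

## Dinucleotide relative-abundance signature and the delta distance

For each genome the 16 odds ratios rho\*~XY~ = f\*~XY~ / (f\*~X~
f\*~Y~) are computed, with all frequencies counted per contig on the
contig concatenated with its reverse complement. This symmetrized form
makes the profile strand-invariant by construction (rho\*~XY~ equals
rho\* of the reverse-complement pair); dinucleotides are never counted
across contig junctions or the concatenation seam, and pairs containing
ambiguity codes are skipped. The distance between genomes is
delta(a, b) = (1/16) sum |rho\*~XY~(a) − rho\*~XY~(b)| — a scaled L1
metric (symmetric, zero on self, triangle inequality). It is reported
on the raw scale, where 0.01 is the conventional cutoff; a x1000
display scale is available as a flag.

## In-silico DNA-DNA hybridization (DDH)

The genome-wide distance d pools identical and total alignment columns
over all retained ANI fragments from both directions:
d = 1 − (identical columns)/(all columns) — the identities-over-
alignment-length formula family of genome-to-genome distance methods.
The predicted DDH is a logistic mapping

DDH(d) = 100 / (1 + exp(alpha + beta d)),  beta > 0.

No published coefficient set is bundled; instead the default
(alpha = −6, beta = (log(3/7) + 6)/0.05 ≈ 103.05) is **calibrated on
simulated genome pairs** so that d = 0.05 maps to the classical 70%
species boundary and d = 0 maps to ≈99.8%. This aligns the DDH verdict
with the ANI >= 95% verdict on the simulator (a pair at 3% divergence
passes both, a pair at 12% fails both), and is documented as this
package's calibration, not a reproduction of any published regression.
Both coefficients are arguments for users with their own calibration.

## Marker genes and MLSA

Marker discovery is homology-to-reference: the reference marker
sequence (e.g. a 16S rRNA gene) is locally aligned to every contig on
both strands and the best subject span is extracted
(reverse-complemented to reference orientation for minus-strand hits);
a hit must cover at least 50% of the reference. An HMM scan would be
more sensitive across deep divergence, but references are explicit
inputs here and keep the procedure transparent. MLSA aligns each marker
across its carriers, pads genomes lacking a marker with gap columns
(so the concatenated matrix stays complete), concatenates in the fixed
order rrsA, gyrB, pyrH, recA, rpoB, and reports p-distances with
pairwise deletion. A floor of 3 carried markers per genome guards
against padding dominating a genome's distances.

## Ortholog clustering (MCL) and the pan-genome partition

The similarity graph holds one vertex per genome-prefixed gene and an
undirected edge for every protein pair with Smith-Waterman e-value
<= 1e-5 against the pooled residue database; edge weight is
−log10(e-value) capped at 200. Within-genome edges are kept so paralogs
are detectable. Clustering is plain Markov clustering on this weighted
graph: self-loops set to each node's maximum incident weight, column
normalization, then alternating expansion (matrix squaring) and
inflation (entrywise power 1.25 with renormalization), pruning entries
below 1e-5, until the matrix changes by less than 1e-6 (cap 100
iterations; non-convergence warns and interprets the current matrix).
Clusters are the connected components of the converged non-zero
structure; genes are sorted lexicographically beforehand so group ids
are stable and input-order-independent. The OrthoMCL variant
additionally normalizes inter-genome weights by the genome-pair mean
weight; this is available behind `orthoNormalize` (off by default) and
its state would matter when genome pairs differ strongly in their
typical similarity level. With the defaults, inflation 1.25 and e-value
1e-5 are the parameters that matter, and both are exposed.

The partition summary defines: *core* groups occur in every genome;
*single-copy core* groups occur exactly once per genome (the input for
concatenated phylogenomics); *exclusive* genes belong to groups
confined to one genome, splitting into *orphans* (single-member groups)
and exclusive genes *with a paralog* (multi-member single-genome
groups). Orphans plus exclusive-with-paralog always equals the
exclusive gene count.

## Phylogenomic reconstruction

Each single-copy core group is aligned as proteins by progressive
alignment: a neighbor-joining guide tree on k-mer cosine distances
(k = 3 for proteins, 6 for nucleotides), then leaf-to-root
profile-profile global alignment with affine gaps and mean-column
substitution scores. Sequences are processed in lexicographic label
order, so the alignment does not depend on input order; iterative
refinement (as in the mature aligners) is not performed, which is the
main accuracy gap versus those tools on hard alignments. Protein
alignments are back-translated to codon alignments (each residue
column becomes its source codon, gaps become `---`; a trailing stop
codon on the CDS is trimmed; translation consistency is verified and
violations are reported with label and offset) and concatenated with a
per-gene column map.

Distances on the concatenated nucleotide alignment use the Tajima-Nei
equal-input correction: with p the mismatch proportion, g the
pair-pooled base frequencies, x the mismatch-pair frequencies,
h = sum~i<j~ x~ij~^2^/(2 g~i~ g~j~) and
b = (1 − sum g~i~^2^ + p^2^/h)/2, the distance is
d = −b log(1 − p/b). Pairs with p >= b are saturated and reported as
missing with a warning. Columns holding a gap or ambiguity in either
sequence of a pair are removed pairwise (complete deletion across the
whole alignment is available; pairwise deletion maximizes usable
signal per pair and is the default).

Trees come from the standard neighbor-joining agglomeration on the
Q-criterion. Ties are broken by the lexicographically smallest pair of
cluster labels; negative branch lengths are clamped to zero with the
deficit shifted to the sister branch, preserving path lengths.
Additive matrices are recovered exactly (topology and branch lengths)
— a property the test suite exercises on random trees. Bootstrap
supports resample alignment columns (or whole genes via the
concatenation map — both readings of "resample the concatenated
alignment" are defensible when hundreds of genes are concatenated)
with replacement, rebuild the tree per replicate, and report for every
internal split of the point tree the percentage of successful
replicates containing it. Replicates with a saturated pair are dropped
and counted; more than 20% dropped triggers a warning, and supports
are percentages of the successful replicates.

## Classification

The cutoff rules are: ANI >= 95, AAI >= 95, DDH >= 70 mean
same-species; delta <= 0.01 means same-species; boundary values fall
on the same-species side because failures are phrased as lying below
(or above, for delta) the cutoffs. The *consensus* — same-species iff
every available verdict among ANI/AAI/DDH is same-species and the
delta verdict is not different-species — is this package's own
combination rule for convenience; the per-metric verdicts are always
reported side by side and stand on their own.

# Alignment kernels

All alignments use affine gap costs where a gap of length L costs
`gapOpen + L * gapExtend` (defaults 11 and 1), matching the convention
of the reference dynamic-programming implementations used as oracles
in the tests. Nucleotide scoring is +1/−2 with every ambiguity code a
mismatch; protein scoring uses BLOSUM62. Raw scores convert to bit
scores via the Karlin-Altschul parameters (nucleotide lambda = 1.28,
K = 0.46; BLOSUM62 gapped lambda = 0.267, K = 0.041 — the standard
published gapped constants, configurable on the scoring scheme), and
e-values are m·n·2^−bitscore^ with m the query length and n the
database size. Raw (not composition-adjusted) lengths are used for m
and n; at the e-value cutoffs used here the difference is immaterial.

The nucleotide search is seed-and-extend: exact 11-mers of the query
are looked up in a hash index of the subject, seed diagonals within a
32-diagonal band are grouped, and each candidate group is resolved by
full Smith-Waterman on a subject window spanning the group plus
margins. Numerical/efficiency policies, all fixed constants:

* Small subjects (<= max(2 kb, 4x query)) are aligned in full, so the
  result provably equals exhaustive Smith-Waterman there.
* When any diagonal group holds >= 2 seeds, groups with fewer than
  max(2, best/8) seeds are dropped — sparsely seeded groups are chance
  matches (including the codon-usage-driven k-mer matches that arise
  between unrelated coding regions).
* The minus strand is searched with the reverse-complemented query.
  When the plus strand already holds a hit scoring >= 25% of the
  query's maximum attainable score, the minus-strand search only
  evaluates groups with at least max(3, plus-seed-count/8) seeds, and
  a perfect plus-strand hit skips the minus strand entirely (ties
  prefer "+"). An isolated chance seed cannot beat a strong hit; a
  genuine inverted copy seeds densely.
* Within a strand, score ties resolve to the smaller subject start.

The DP kernels use single-precision scores; with unit-scale match
scores and the problem sizes involved, scores stay far below the
precision limit, and traceback decisions recompute the identical
floating-point expressions, so they are exact.

# The simulator

`makeAncestor()` builds a replicon of configurable length (default
200 kb — large enough for stable fragment statistics, small enough for
desk-scale runs) carrying non-overlapping protein-coding genes (ATG
start, sense codons, one stop) on alternating strands at uniform
spacing, plus optional planted marker sequences. Two deliberate
compositional features emulate real genomes:

* The intergenic background is a strand-symmetric first-order Markov
  chain with GC-dependent CpG depletion and a fixed TpA depletion,
  its stationary composition solved numerically to hit the GC target.
  An i.i.d. background would have rho\* ≈ 1 for every dinucleotide
  regardless of GC, leaving the signature module nothing to
  distinguish; real genomes differ in their dinucleotide signatures,
  and the depletion factors give simulated genomes of different GC
  measurably different signatures (delta > 0.01), which is the premise
  the signature metric rests on.
* Genes sample codons with a GC-biased weight (b^GC-count^, b solved
  so the expected codon GC matches the target), mirroring how genomic
  GC expresses itself in codon usage.

`evolveGenomes()` diverges the ancestor in one of two modes:

* **Tree mode**: branch lengths are expected substitutions/site under
  Jukes-Cantor; each site's final base is drawn from the JC transition
  probability (P(same) = 1/4 + 3/4 e^−4t/3^), which is
  distributionally identical to simulating per-site Poisson event
  counts but cheaper. Realized per-branch substitution counts go into
  the truth log.
* **Flat mode** (`p`): the second genome substitutes each site with
  probability exactly p (single hit), so the realized difference
  proportion is ≈ p. This mode exists because divergence-recovery
  checks are phrased against the *realized* difference (ANI ≈
  100(1 − p)); tree mode answers questions about evolutionary
  distances, flat mode about measurement accuracy.

Indels (off by default) follow a geometric length distribution (mean
3) and are excluded from a 30 bp protected window around every
gene/marker boundary, so gene coordinates and the ortholog truth
pairing remain well defined; genes may still acquire internal indels
or premature stops (there is no purifying selection) — such genes are
kept and flagged, as a real annotation pipeline would face them. The
truth log records realized pairwise identity over the site-homology
map, which is what metric-recovery tests compare against.

The named fixtures freeze the study conditions: `two_species` (one
conspecific pair at ~1% pairwise nucleotide divergence — a typical
within-species distance safely inside all four cutoffs — plus one
genome at ~20%), `two_clades` (8 genomes, two clades of four with deep
stems, emulating a marine/freshwater-style split), `ortholog_families`
(3 genomes x 50 single-copy families), and `marker_set` (4 genomes
carrying 5 planted markers with realistic 16S/housekeeping-gene
lengths). Same seed, byte-identical files.

# What the validation shows — and does not

The test suite and the acceptance script validate the stack on
simulated genomes: metric identities on self-comparison, recovery of
known divergence (ANI within +-1 point of 100(1 − p) and d within
+-0.01 of p for p up to 0.20 on 200 kb genomes), kernel equivalence
against independently coded oracles (exhaustive DP, dense MCL,
brute-force dinucleotide counts, closed-form Tajima-Nei), perfect
clustering of planted ortholog families, exact NJ recovery of additive
matrices, and recovery of a planted two-clade topology with >= 95%
bootstrap support (100 replicates at desk scale; the conventional
1,000 is the production default).

Simulated genomes are clean: no rearrangements, no horizontal
transfer, no repeat families beyond what the background chain
produces, uniform substitution rates, annotation-free gene truth.
Passing these tests therefore demonstrates correctness of the
*computations*, not robustness to every property of real genome
assemblies (fragmented contigs are supported but simulated sparingly;
mobile elements and rRNA repeat copies can make marker extraction and
orphan counts assembly-dependent in real data). Counts obtained on
real public genome sets additionally depend on the exact sequence and
annotation versions used, so published group counts are not
reproduction targets.

# Problem sizes

Defaults used by the validation runs, chosen for a single-CPU desk
run: 200 kb genomes for divergence recovery, 120 kb / 50 families for
clustering, 50 kb / 8 genomes / 20 genes for the phylogenomic
pipeline with 100 bootstrap replicates, 30 kb genomes for the
self-identity checks. All scale linearly upward; the same code paths
run unchanged on multi-Mb genomes.
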