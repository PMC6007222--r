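---
title: "Methods: homolog clustering, synteny chaining and SNP marker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homolog clustering, synteny chaining and SNP marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthomark)
```

## The problem

Closely related crop genomes — the Solanaceae (tomato, pepper, potato) are
the motivating family — share most of their gene content and much of their
gene order. A breeder who knows a trait gene in one species can exploit that
conservation to find the candidate ortholog in a less-studied relative, and
then wants a molecular marker for it: a SNP segregating in a breeding panel,
with enough flanking sequence to design primers. `orthomark` implements that
chain of reasoning as a set of deterministic, testable steps:

1. **Homolog grouping.** Gene sequences from two or more genomes are
   clustered by greedy incremental clustering at a sequence-identity cutoff.
2. **Synteny.** Cross-genome ortholog pairs become positional *anchors*;
   collinear runs of anchors are chained into *synteny blocks*.
3. **Classification.** Every gene of the query genome is labeled
   `same_chromosome`, `different_chromosome` or `no_homology` relative to a
   derived chromosome pairing.
4. **Markers.** Genotype matrices are filtered on minor allele frequency
   (MAF), SNPs are linked to genes, and flanking sequences are emitted in
   bracket notation for primer design.

A synthetic-data module plants all the structure the pipeline is supposed to
find, so every step is validated against known truth without any external
download.

## Homolog clustering

Sequences are sorted by length (descending; ties by identifier so results
are reproducible) and scanned once. Each sequence joins the first existing
cluster whose *representative* it matches at identity at or above the
cutoff, otherwise it founds a new cluster. This is the classic greedy
incremental scheme of tools like CD-HIT, and inherits their property that
members of one cluster are each close to the representative but not
necessarily to each other.

Identity is defined by a global (Needleman–Wunsch/Gotoh) alignment with
match +1, mismatch −1, and affine gaps costing 2 + L for a gap of length L.
The number of matching columns is divided, by default, by the length of the
shorter sequence — the convention of the greedy clustering tools this module
emulates; `alignment_length` is available as an alternative denominator.
Because optimal alignments can tie, the traceback uses a fixed state
preference, and `pairwise_identity()` canonicalises its argument order so
the function is exactly symmetric.

The default cutoff is **0.95** ("at least 95 %" identity, read as an
inclusive bound). A k-mer prefilter (default word size 8) skips alignments
that provably cannot reach the cutoff: a pair at identity *p* whose shorter
sequence has length *L* must share at least `L − k(1−p)L − k + 1` words
(floored at zero). The bound is admissible — the prefilter can only save
time, never change the clustering — and the test suite asserts exactly that
by re-clustering with the filter disabled.

## Anchors and synteny blocks

Each homolog group spanning both genomes contributes one anchor per
(A-member, B-member) pair; a one-to-many group fans out into several
anchors and the chaining step resolves which copy is syntenic. Anchors are
positioned by 0-based *gene ordinal* along their chromosome rather than by
base pairs, which makes the chain geometry insensitive to gene-density
variation; base-pair spans are still reported on the resulting blocks.

Within each chromosome pair the longest strictly monotone chain of anchors
is extracted by longest-increasing-subsequence dynamic programming, run in
both orientations (forward: both ordinals increasing; inverted: the partner
ordinal decreasing). Consecutive anchors of a chain may skip at most
`max_gap_genes` gene ordinals on either genome — the gap is counted as the
number of intervening genes, so immediately adjacent anchors have gap 0.
The best chain becomes a block, its anchors are removed, and the process
repeats until no chain reaches `min_block_anchors`. Ties between
equal-length chains break toward the smaller starting ordinal, then forward
orientation before inverted, so repeated runs are byte-identical.

Defaults: `min_block_anchors = 3`, `max_gap_genes = 10`. These are
conservative values in the range used by collinearity tools of the
DAGchainer/MCScanX family; both are exposed on the command line. Optional
anchor quality filters (`e_value_max`, `identity_min`, `coverage_min`)
run before chaining; an anchor *missing* an attribute fails any filter that
is set, which keeps imported hit tables honest.

One consequence of exact chain maximisation is worth knowing: a planted
inversion of *n* genes usually yields an inverted block of *n − 1* anchors,
because the globally longest forward chain can absorb exactly one anchor
from the inverted window (the monotonicity constraint forbids a second).
The recovery tests therefore require an inverted block covering at least
*n − 1* of the planted genes, all inside the window.

## Chromosome pairing and gene classification

Tomato/pepper-style chromosome numbering does not guarantee correspondence,
so "same chromosome" is judged against a *derived* pairing: each
A-chromosome maps to the B-chromosome sharing the most chained anchors with
it (ties broken lexicographically); the pairing can be overridden. A gene
with any partner on the paired chromosome is `same_chromosome` (pink in the
exported views), a gene whose partners all lie elsewhere is
`different_chromosome` (navy), and a gene whose group contains no B-member
is `no_homology` (mint). The three categories partition the gene set by
construction.

## MAF filtering and markers

MAF is computed per site over non-missing alleles only (each diploid call
contributes two); missing calls are excluded from numerator and
denominator, the standard complete-case convention of population genetics.
For multiallelic sites the MAF is the largest non-major allele frequency;
biallelic sites are bounded by 0.5 by construction. The marker-pool filter
keeps sites with MAF **strictly** greater than the threshold (default 0.2),
so a site at exactly 0.2 is dropped. Gene–SNP association uses closed
1-based bounds with a default flank of 0 bp (strictly within the gene).

Flanking-sequence reports take up to 1000 bp (1 kbp) of reference sequence
either side of the variant, truncated at chromosome edges, and print
`LEFT[REF/ALT]RIGHT` — the bracket notation accepted by common
primer-design tools. The reference base is validated against the chromosome
sequence before anything is emitted. Indel records are carried through the
genotype matrix but excluded from SNP marker reports by default.

## The synthetic-data generator

`generate_genome_pair()` builds genome A from seeded random sequence with
evenly spaced single-exon gene models, then derives genome B by per-base
substitution at the divergence rate followed by the requested inversions
(gene order reversed, strands flipped), whole-segment translocations to
another chromosome, gene losses and tandem duplications. Every event is
recorded in a truth object consistent with the emitted FASTA/GFF3.

The default parameters are the study conditions the package is validated
under: 2 chromosomes × 200 genes of 1000 bp (500 bp intergenic), divergence
0.02, two 8-gene inversions, one 5-gene translocation, no loss or
duplication. At 2 % divergence a 1 kbp ortholog pair falls below the 95 %
identity cutoff only in the far binomial tail, so planted orthologs are
recoverable with probability effectively 1 — the regime the Solanaceae
comparison operates in. Genes are single-exon because clustering and
chaining act on whole gene sequences; substitutions are uniform (no
transition/transversion bias), which is adequate for identity-threshold
behaviour.

`generate_genotypes()` draws diploid calls by Hardy–Weinberg sampling at
planted allele frequencies, with an `inbred` flag that draws one allele per
sample (all calls homozygous) to emulate recombinant-inbred-line panels;
real cultivar panels deviate from HWE, but HWE gives a controlled null with
known expectations. Missingness is masked uniformly per call.

What the simulator does **not** emulate: multi-exon gene structure, repeat
content, segmental duplication families, population structure and linkage
disequilibrium. Passing the planted-truth suites therefore demonstrates the
algorithms' correctness on clean collinear signal, not robustness to every
artefact of real annotations.

## Problem sizes and numerical choices

The validation suites use: the 2 × 200-gene pair above for end-to-end
recovery; 200 random ≤ 10-anchor instances checked against an exhaustive
subset oracle for the chaining DP; 50 random pairs against an independently
coded quadratic alignment oracle; and 10 000 simulated sites × 60 samples
for the MAF properties. All randomness flows from explicit integer seeds;
the same seed reproduces every output file byte for byte, which the suite
asserts on FASTA, GFF3, VCF, TSV and SVG outputs.

Degenerate inputs are hard errors rather than silent repairs: empty
sequences, duplicate FASTA identifiers, GFF3 features with `end < start`,
VCF records with REF equal to an ALT, all-missing genotype sites, and
reference-base mismatches at marker extraction all stop with a message
naming the offending record. The one deliberate soft path is GFF3 features
lacking an `ID`, which are skipped with a counted warning, since this is
common in real annotation dumps.

## Design decisions that were genuinely open

* **Sequence type for clustering.** The upstream literature does not state
  whether CDS, transcript or genomic sequences were clustered. The pipeline
  is agnostic: whatever FASTA is supplied defines the clustering alphabet,
  and the identity machinery assumes nucleotides.
* **Identity denominator.** Divides by the shorter sequence by default
  (the named tools' convention), configurable to alignment length.
* **Gap units.** Measured in gene ordinals, not base pairs; robust to gene
  density and makes the exhaustive oracle exact.
* **"Same chromosome" frame.** Majority-anchor pairing rather than name
  matching, because chromosome numbering between species is arbitrary.
* **Strict MAF inequality.** "> 0.2" is implemented strictly; equality is
  dropped, and the tests pin that boundary.
* **Static SVG views.** The three viewer levels are exported as
  deterministic SVG plus backing tables, so every glyph count can be
  asserted against the table it mirrors.

## Limitations

Pairwise genomes only (no multi-way blocks); no phylogenetic orthology
inference — classification is positional and similarity-based; no read
alignment or variant calling (the package consumes VCF); no primer design
(flanking text is formatted for external tools such as Primer3); and the
greedy cluster scan is quadratic in the number of sequences in the worst
case, which is fine at annotation scale for a pair of plant genomes but is
not a metagenome clusterer.
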