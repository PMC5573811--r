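---
title: "Genome-wide terpene synthase family characterization with tpscan"
author: "tpscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide terpene synthase family characterization with tpscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant terpene synthases (TPS) form one of the largest mid-size gene
families in angiosperm genomes. A genome-wide characterization of the
family proceeds through a fixed sequence of steps: candidate loci are
gathered by homology to known TPS proteins; spliced coding sequences are
assembled from the gene models and translated; products shorter than 400
residues are set aside as pseudogene or partial-gene products; the
surviving genes are described by their exon/intron architecture (intron
count, exon sizes in amino acids, intron phases, splice-boundary context),
their conserved protein motifs, their physicochemical properties
(molecular weight, isoelectric point, presence of an N-terminal plastid
transit peptide), their genomic organization (tandem clusters), their
phylogenetic placement into the canonical subfamilies TPS-a, TPS-b, TPS-c,
TPS-e/f and TPS-g, and their expression across tissues. `tpscan`
implements this procedure as a reusable, tested pipeline, together with a
synthetic-genome simulator that plants every structure the pipeline is
supposed to recover, so the whole chain can be validated end to end
against a known truth.

## The model and its conventions

**Gene models and coordinates.** Gene models are CDS-part lists per
transcript held in a `GeneModelSet` (a thin S4 wrapper around a
`GRangesList`). All coordinates are 1-based inclusive, the native
convention of both GFF3 and the IRanges stack. We deliberately do not
introduce a 0-based half-open internal layer: with IRanges as the single
container there is exactly one coordinate convention in play, which
removes the class of off-by-one bugs such a conversion layer is meant to
manage.

**Translation.** The standard genetic code; codons containing N translate
to X; residues are reported up to (not including) the first stop. A
transcript is *complete* when it starts with ATG, ends with exactly one
stop and has no internal stop. ORF lengths count the stop codon, so a
1,680-nt complete ORF encodes 559 residues; this convention is asserted
property-style over thousands of random ORFs.

**Architecture.** The phase of intron *i* is the cumulative coding length
upstream of it modulo 3. Exon lengths in amino acids are reported as
floor(coding nt / 3) with the fractional codon carried into the next exon
-- the published plots report amino-acid exon sizes without stating the
attribution rule, so we freeze this one. Class assignment is on intron
count: 11--14 introns are class I (the canonical statement is 12--14, but
published class-I sets include 12- and 15-exon genes, i.e. 11 and 14
introns), 9 class II, 6 class III, anything else unclassified.

**Splice consensus.** Position frequency matrices are accumulated over a
window of 10 exonic and 10 intronic nucleotides around each donor and
acceptor, in transcript orientation. Information content per column is `2
- (H + e_n)` bits with the standard small-sample correction `e_n = 3 /
(2 ln 2 n)`, floored at zero. The correction term is the conventional
choice for sequence logos; no particular correction is mandated by the
procedure being reproduced, so we document ours.

**Protein properties.** Molecular weight is the sum of average residue
masses plus one water. The isoelectric point is found by bisection of the
Henderson--Hasselbalch net charge on [0, 14] to a 0.005 pH tolerance,
with the Bjellqvist pKa set (the set behind the familiar "theoretical pI"
web values, including the residue-specific terminal pKas). Both agree
with an independent implementation (Biopython's ProtParam) to well below
reporting precision; the only divergence is for extreme compositions
whose pI lies outside [4.05, 12], where that implementation clamps its
search interval and we do not. Transit peptides are *not* predicted by a
reimplementation of the dedicated machine-learning tools; a crude,
clearly-labelled composition heuristic (S+T fraction > 20% and net
positive charge in the N-terminal 60 residues) stands in, and
user-supplied calls take precedence.

**Motifs.** The degenerate consensus notation (`RRX8W`, `R(D/N)R`,
`DDXXD`, `(D/N)D(V/M/L/I)X(S/T)XXXE`, subfamily variants) is compiled
into per-position residue sets; `X` in a pattern is a 20-residue
wildcard, `X` in a protein matches nothing. `RRX8W` is read as exactly
eight wildcards. Scanning reports all, possibly overlapping, matches;
completeness uses first occurrences and does not enforce N-to-C order
(the order is reported separately), since the tabulation being reproduced
does not state an order requirement.

**Homology.** Strict global (Needleman--Wunsch) alignment with BLOSUM62,
gap open 10, gap extension 0.5 backs `globalAlign` and all identity
figures; identity is matches over aligned columns with terminal gaps
excluded, rounded half-up to two decimals. The candidate gate
(`referenceSearch`) instead uses an ends-free (overlap) alignment:
truncated pseudogene products must align cleanly against full-length
references, exactly as a BLASTp-style screen would see them, and a strict
global alignment can turn the long terminal gap into an internal one and
dilute the identity. The gate keeps a gene when some reference aligns at
>= 40% identity over >= 50% query coverage (exposed in the
configuration).

**Phylogeny.** Distances are p-distances with pairwise deletion (a
Poisson correction is available behind a flag); the tree is built by our
own neighbor-joining implementation with deterministic lowest-index
tie-breaking and clamp-and-transfer handling of negative branch lengths.
NJ consistency (exact recovery of additive matrices) is tested over 100
random trees and against a brute-force least-squares topology search at
n = 6; on noisy matrices the topology agrees with the independent
implementation in `ape`. Bootstrap supports resample columns with
replacement, rebuild the NJ tree per replicate, and count bipartitions;
the procedure is bit-reproducible under a fixed seed. Subfamily labels
propagate from reference leaves: each query receives the subfamily of the
smallest edge-induced bipartition side containing it together with
references of exactly one subfamily. The progressive aligner (guide tree
from fractional common k-mer distances, profile--profile merging with
mean-BLOSUM column scores and the same affine gap costs, implemented in
C++) is a deterministic stand-in for an external multiple aligner; with
two sequences it reduces exactly to `globalAlign`.

**Clusters.** Tandem clusters are single-linkage chains of genes on one
chromosome whose inter-gene gap (next start minus current end minus 1) is
strictly below 67 kb. The threshold anchors on gene boundaries -- the
conservative reading of a "distance between genes" rule -- and is
configurable. Singletons are not clusters; strand is ignored; genes on
unplaced scaffolds are excluded from clustering but counted. The
percentage of clustered genes is reported against both the placed-gene
and the all-gene denominators, since published percentages of this kind
are ambiguous about which is meant.

**Expression.** RPKM values fall into four bands: < 0.1 not detected,
0.1--0.5 low (both ends closed), (0.5, 60) moderate, >= 60 high. The two
interior boundaries are the published anchor values; the band between
them is our interpolation, and the closure conventions at 0.1 and 60 are
frozen here. A gene is tissue-specific when it exceeds the 0.5 RPKM
detection threshold in exactly one tissue. Heatmap matrices are
log2(x+1)-transformed and row-ordered by average-linkage clustering on
correlation distance, with rows pre-sorted by identifier so the ordering
is deterministic; these are reproducibility-first stand-ins for an
interactive web tool whose internal settings are not published.

## The synthetic-data generator

`familySpec()` describes a family blueprint and `assembleGenome()` emits
genome FASTA, GFF3 gene models, a reference protein set and a complete
ground-truth table, all reproducible to the byte from the mandatory seed.
The defaults are the study conditions the pipeline is validated under: 28
TPS-a, 18 TPS-b, 2 TPS-c, 2 TPS-e/f and 5 TPS-g functional genes plus 40
pseudogenes (95 TPS loci), 61 of the placed genes arranged in 19 tandem
clusters of 2--6 members, 24 loci on unplaced scaffolds, 4 paralog pairs
planted at 96% protein identity inside shared clusters, and 3 non-TPS
decoy genes that must fail the homology gate. Class III subfamilies get 6
introns and class I subfamilies 12, with fixed per-class intron-phase
vectors and template exon sizes whose amino-acid lengths sit in the
44--125 band; intron lengths are log-normal (meanlog log 160, sdlog
0.45), truncated to [62, 2335] nt, so the bulk falls in the 81--400 nt
band. Every intron has a GT...AG core, a pyrimidine immediately before
the terminal AG, and a purine as the last exon base before the donor --
planted through synonymous codon choice (and, where the reading frame
pins the boundary base, through template residues drawn from pools that
allow a purine), which is what makes the donor consensus read R/GT
without distorting the protein. The unplaced set deserves a note: in real
assemblies, unplaced scaffolds can carry functional genes, but here all
24 unplaced loci are pseudogenes so that the four pipeline dispositions
(functional / pseudogene / non-TPS / unplaced) stay a strict partition
while all headline counts (95 loci, 55 functional, 19 clusters over 61
genes, 24 unplaced) are preserved.

Member sequences diverge from their subfamily template by random
amino-acid substitutions to a target identity in 72--90%, with motif
positions, the start codon and exon-boundary codons protected;
`mutateToIdentity()` additionally plants synonymous substitutions at 1.5
times the nonsynonymous rate, so nucleotide divergence exceeds protein
divergence as it does in real paralogs. Pseudogenes are functional
members with a premature stop planted at codon 100--350, leaving products
far below the 400-residue filter. Transit peptides are planted in 12
TPS-b and 3 TPS-g members (15 proteins) as S/T-rich, positively charged
N-terminal blocks that the packaged heuristic recognizes.

What the generator does *not* emulate -- and hence what a green test
suite does and does not say about real data: intergenic sequence is
uniform random (no repeats, no transposable elements, no GC structure);
codon usage is uniform within each amino acid; subfamily templates are
unrelated random proteins, so between-subfamily identity is far lower
than in a real TPS family; there is no alternative splicing (one
transcript per locus) and no partially assembled gene models. Passing
tests therefore demonstrate that the pipeline's logic is correct under
its stated assumptions, not that a real genome's annotation noise is
handled.

## Numerical choices and degenerate inputs

Percentages and identities are rounded half-up (never banker's rounding)
at two decimals, one decimal where a published figure is printed that
way. The NJ tie-break and the traceback preference of the profile aligner
are fixed so that every run of the pipeline under one seed is
byte-identical. Bootstrap replicates whose resampled columns leave some
pair with no comparable sites are skipped (they cannot define distances);
constant expression rows get correlation distance 1 with a warning;
splice-consensus sites whose intron or exon is shorter than the flank are
skipped with a warning; an empty gene set short-circuits the downstream
stages. Alignment of proteins containing X scores X against everything at
-1 in the MSA profile scorer, and X never satisfies a motif element.

## Problem sizes used in validation

The packaged validation runs the full default blueprint (98 gene
models on 6 chromosomes plus 24 unplaced scaffolds, about 4 Mb of
sequence) once through the full pipeline with 100 bootstrap replicates in
the test suite, and with the standard 1,000 replicates in
`scripts/acceptance.R`; unit and property tests use a reduced blueprint
(14 functional genes, 3 clusters) and direct in-code constructions.
Recovery on the default blueprint is exact: subfamily counts 28/18/2/2/5,
19 clusters, and zero pseudogene-filter errors.

## Known limitations

Locus-level merging of multiple transcripts is by shared gene identifier
only; the pipeline treats transcripts as the analysis unit. The transit
peptide call is a labelled heuristic, not a trained predictor. The
candidate gate is a full pairwise-alignment screen, adequate for
gene-family scale but not a seeded heuristic search for genome-scale
protein databases. The progressive aligner targets low-divergence
families; deep alignments (between-subfamily, here essentially random)
are used only for clade separation, where p-distances saturate but the
within/between contrast remains unambiguous.
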