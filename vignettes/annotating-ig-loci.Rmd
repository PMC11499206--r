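---
title: "Annotating germline immunoglobulin loci across genome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating germline immunoglobulin loci across genome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igloci)
```

## The problem

Germline immunoglobulin loci (IGH on one chromosome, the light-chain
loci IGK and IGL on two others) hold the V, D, J and C genes that
somatic recombination assembles into antibody chains. Annotating them
in a genome assembly means answering four questions: where does the
locus start and end; which candidate stretches are genes and where are
their exons and recombination signals; is each gene usable
(functional), intact-but-defective (ORF) or broken (pseudogene); and
what should each gene be called so that assemblies and individuals can
be compared gene by gene. When several haplotype-resolved assemblies
of one species exist, a fifth question follows: which genes are shared,
which alleles vary, and which presence/absence differences are real
copy number variation rather than assembly artefacts.

`igloci` implements this whole procedure against a reference gene set
(a "human-like" comparator: named, typed alleles with labelled
regions), plus a synthetic-assembly generator that provides ground
truth for every stage.

## Locus localization and delimitation

Localization scans every assembly sequence, on both strands, with
exact 14-mer seeds drawn from every reference region (step 12; short D
regions use a full-pattern scan at a 25% mismatch ceiling). Seed
support is clustered (gap threshold 500 kb) and the densest cluster
becomes the locus envelope; orientation is the seed-weighted majority
strand. Isolated clusters below five seeds are ignored — random
sequence essentially never produces an exact 14-mer match, so a locus
that is present yields hundreds of seeds. Two clusters within 10% of
each other's weight raise an ambiguity error rather than a silent
choice. We deliberately defer alignment-level identity gating to the
detection scan: it is applied to every candidate gene anyway, and a
seed-only localization halves the end-to-end cost.

Delimitation follows the flank rules used in IG locus curation: IGH
runs from 10,000 bp 5' of the first gene to 11,000 bp 3' of the last;
IGK and IGL consult their conserved flanking non-IG genes (locus
bornes — PAX8/RPIA for IGK, TOP3B/RSPH14 for IGL) on each side
independently: if the borne lies within 10,000 bp of the terminal
gene, the boundary is placed on the first base proximal to the borne
(the borne itself stays outside the locus — the curation convention
names the borne *edge* as the boundary without saying which side of
it; we keep the borne out); otherwise the fixed 10,000 bp flank
applies. Boundaries clamp to the sequence ends rather than erroring,
since contigs may truncate a flank. All flank sizes are configuration
values (`igloci_config()`) with these defaults.

Coordinates are 1-based inclusive everywhere, including GFF3 output
(which needs no shift), so a locus length is always `end − start + 1`
— the convention under which the published gorilla locus tables
reproduce exactly (`gorilla_locus_coordinates()`). Reverse-strand loci
are stored chromosome-forward with orientation `REV`, mirroring the
"complement" notation of public locus tables.

## Gene detection

Detection re-runs the seeded scan inside the extracted,
locus-oriented sequence, then projects each reference region into its
candidate window by pairwise alignment. The projection aligns the
reference region globally and the window locally ("global-local"), so
exon boundaries stay exact when the target carries terminal
substitutions or internal indels — a plain local alignment clips
mismatching ends and slides boundaries into introns. Gap costs are
low (open 10, extend 0.5 per base) so that a genuine insertion or
deletion is represented as a gap instead of a misaligned boundary;
identity is measured over aligned columns only (so an indel does not
dilute it) and coverage as the fraction of reference bases with an
aligned target base. A region projection is accepted at identity
≥ 70%, coverage ≥ 50% and positive alignment score; a candidate gene
needs overall identity ≥ 70% and coverage ≥ 60%. These thresholds are
deliberately permissive — they must admit cross-species divergence and
decayed pseudogenes while rejecting random sequence — and are exposed
in `igloci_config()`. When several references compete for one genomic
location, only the best-supported few are aligned (seed support tracks
identity) and overlap resolution keeps the highest
identity × coverage, ties broken by longer span then 5'-most start.

Per gene type, delimitation checks the expected anatomy: V genes need
a projectable leader and V exon with `GT..AG` intron dinucleotides and
a 3' RSS (12-spacer class for IGK V genes, 23 otherwise); D genes
need a 12-class RSS on both sides (a candidate with neither is a
dropped decoy); J genes need a 5' 23-class RSS, a terminal `GT` donor
and the FR4 `W/F-G-X-G` motif in some reading frame; C genes are
delimited exon by exon with acceptor/donor checks, hinge exons
labelled `H1..Hn` in order, out-of-order projections flagged
`REARRANGED` and unprojectable reference exons `MISSING_EXON`.
Assembly gaps are maximal N runs of at least 100 bp (shorter runs are
taken as ambiguity codes, not gaps); genes overlapping a gap are
marked, and the mark matters later for CNV calling.

## The RSS model

The recombination signal is modelled as consensus heptamer `CACAGTG`,
spacer of nominally 12 or 23 bp, and nonamer `ACAAAAACC`. The score is

```
score = 1 − (hept_mm + nona_mm) / 2 − 0.1 · |spacer − nominal|
```

where `hept_mm` is the weighted mismatch fraction of the heptamer
(positional weights 2,2,2,1,1,1,1 — the first three bases are the
`CAC` critical for recombination) and `nona_mm` the uniform mismatch
fraction of the nonamer. The score is 1 exactly at the canonical
motif with nominal spacer, and a motif is accepted at ≥ 0.7. The
search tries heptamer anchors within ±10 bp of the expected position
and spacers within one base of nominal. Motifs on the 5' side of a
gene (D 5' RSS, J RSS) lie on the opposite strand of the reading
direction, so their genomic window is reverse-complemented before
scoring — one consensus serves both sides.

## Functionality

Functionality is a total function of a set of reason codes. Codes
that destroy the product — `STOP_CODON`, `FRAMESHIFT` (net indel not a
multiple of 3 against the best reference), `TRUNCATED`,
`REPEAT_INSERTION` (an insertion of ≥ 100 bp inside the gene body; we
use the length proxy rather than a repeat library, keeping the
package self-contained), `REARRANGED`, `MISSING_EXON`,
`NO_INIT_CODON` — make a pseudogene. An intact frame with only
regulatory defects (`DEFECTIVE_SPLICE`, `DEFECTIVE_RSS`,
`NO_CANONICAL_MOTIF`) is an ORF; no codes means functional. A D gene
with one ablated RSS therefore classifies as ORF, which follows this
algebra (and IMGT practice) consistently.

Allele identity is decided over core regions only — the V exon, the
D/J region, the concatenated C exons — excluding introns and flanks;
this mirrors allele tables keyed on expressed-region differences, and
is the one place where a curator might reasonably choose otherwise
(full-gene identity would split alleles on intron variants). An exact
core match to a known allele returns its number; anything else is a
new allele, numbered after the maximum existing number, reported with
its substitution/indel list against the nearest known allele. Star
confidence counts the distinct genomic sequences carrying an allele,
capped at three. IMGT-style unique numbering is projected from a
numbered reference through a global amino-acid alignment rather than
re-derived from first principles; projection is refused below 40%
identity, and the conserved anchors (23 C, 41 W, 104 C) are checked
where the reference map covers them.

Subgroup assignment takes the subgroup of the highest-identity V
reference at ≥ 75% nucleotide identity, falls back to the best
clan-level representative between 50% and 75%, and reports
`unclassified` below 50%. The thresholds reproduce the
subgroup-versus-clan split on synthetic data and are configuration
values; ties break lexicographically for determinism.

## Nomenclature

Ortholog names must respect locus order, not just best-hit identity:
the accepted assignments are the longest chain of best hits consistent
with the reference gene order, computed as a longest increasing
subsequence over reference ranks (an `O(n²)` dynamic programme;
among equal-length chains the highest summed identity wins, then the
5'-most genes — so a high-identity true ortholog beats its duplicate).

Off-chain genes are then examined for bloc duplication: a maximal run
of unnamed genes whose mean per-gene core identity to an equal-length,
type-matched run of named genes reaches 99.5% takes the initial names
plus `D`. Single-gene duplications qualify (curated loci contain
cases like a gene and its `D` copy); a run matching two initial blocs
at threshold is an ambiguity error. Identity is measured on gene core
sequences — the published threshold is stated without defining the
measured span, so we use the reproducible core-sequence mean and
expose the threshold in the configuration.

Everything still unnamed is an inserted gene: V genes take the 3'
neighbour's name with `-k` sub-positions counted 3'→5'; D genes the
5' neighbour's name counted 5'→3'; J and C genes letter suffixes
(`A`, `B`, …, then `AA`) on the nearest named same-type 5' neighbour;
genes 5' of every named gene get new top-level position numbers
incrementing the locus-extreme position. Sub-position numbering
continues past any sub-position already present, preserving
uniqueness. (Curated D insertions sometimes recode the subgroup digit
gene by gene — `IGHD6-5-1`, `IGHD1-5-2` — which is locus-specific
curation; the package applies the plain 5'-anchor rule.)

## Cross-assembly comparison

Genes are matched across assemblies by assigned name; the union gene
order is a topological merge of the per-assembly orders (each is a
projection of one underlying locus order), so deletions in one
assembly cannot scramble the union. Shared-gene percentage is genes
present in all assemblies over the union — the only total consistent
with a Venn diagram — rounded to an integer. Polymorphism is the
fraction of union genes with at least two distinct core-sequence
alleles across the assemblies carrying them; a gene seen once is
monomorphic.

A candidate CNV region is a maximal run of union genes each absent
somewhere and present somewhere. Absence behind an assembly gap is
missing evidence: a gene is gap-masked when the interval between its
nearest present neighbours overlaps an N-run gap, and any gap-masked
absence disqualifies the run — a 20 kb gap over a D cluster or a 47 kb
gap over six V genes is not a CNV. Regions lying between the limit
genes of a known CNV definition take the known name; the rest are
`CNVp1`, `CNVp2`, … 5'→3'. Within a CNV, each assembly's exact gene
content is its form: known contents keep their letters, novel
contents get the next letters after the maximum known one, in order of
first occurrence, so re-running or appending an assembly with a seen
form never relabels anything.

## The synthetic generator, and what passing tests show

`generate_reference_set()` builds a toy reference with valid gene
anatomy: leaders starting `ATG`, stop-free codon streams, conserved
C23/W41/C104 anchors, canonical RSS context, FR4-bearing J regions,
C genes with designed hinge counts (the defaults exercise the
0/5/2/4/1 designs of an IgG-bearing constant cluster), V subgroups
and clans built from diverged subgroup bases, and optional second
alleles. `generate_assembly_set()` plants these genes in order into
i.i.d. random background with per-junction spacers, then applies the
designed structures: defect edits (each reason code has a literal
edit, plus the 15-bp in-frame and 2-bp frameshift hinge deletions),
a duplicated bloc copied at a target identity, inserted genes derived
from a reference at a chosen divergence, per-assembly gene deletions,
N-run gaps, antisense genes, borne probes at chosen distances,
reverse-complemented assemblies, designed polymorphic variants, and
per-assembly allelic substitution noise that is "safe" by
construction — it never creates a stop codon or touches motifs, so a
planted functional gene stays functional at any tested rate.

The generator emulates structure, not realism: background is uniform
random (no repeat families, so specificity against shuffled decoys is
honest but says nothing about Alu-dense real flanks), introns are
random with fixed splice dinucleotides, substitution noise is uniform
within cores, and repeat insertions are literal random segments.
Passing the recovery suite therefore demonstrates that the algorithms
implement their rules exactly — it does not demonstrate performance on
real primate sequence, where segmental duplications and repeats are
the dominant difficulty.

The packaged studies (`simulate_detection_study()`,
`simulate_nomenclature_study()`, `simulate_cnv_study()`) fix the
conditions used by the validation suite: four assemblies of a ~53-gene
IGH-like locus (32 V, 8 D, 5 J, 8 C) at 1% substitution with the full
defect mix; a noiseless nomenclature locus with a three-gene bloc at
99.8% identity (and a 98% variant that must *not* be called a
duplication) plus inserted V/D genes and an extra J-C tandem in one
assembly; and a three-assembly CNV locus with a known six-gene CNV, a
planted deletion and a gap-masked absence. These sizes keep the whole
suite at desk scale while covering every structure the pipeline
handles.

## Numerical choices and degenerate inputs

* Alignment scoring: match 2 / mismatch −3 throughout; gap open 10,
  extend 0.5 for boundary projection (long indels must beat chance
  matching of random inserts), open 5, extend 2 for the global
  coding-sequence comparisons.
* Ties are always broken deterministically: lexicographic reference
  names for subgroups, lower allele numbers for nearest alleles,
  5'-most starts in overlap resolution, first occurrence for CNV form
  letters.
* Empty inputs are legal where a curator would expect them: an empty
  reference set reads as an empty table; a locus with no hits raises a
  typed "not found" condition that the assembly-level driver reports
  and skips; an anchorless locus refuses inserted-gene naming with a
  diagnostic rather than inventing names.
* Determinism: every stochastic step lives in the generator behind a
  single seed; annotation itself is deterministic, and the same seed
  reproduces byte-identical assemblies and truth tables.

## Limitations

Loci split across unplaced contigs are reported "not found" per
contig rather than stitched. Profile-based detection of genes with no
reference homolog is out of scope — a gene family absent from the
reference set is invisible. The comparison module's statistics are
only as good as the naming: a systematic naming error would propagate
into presence and CNV calls (on synthetic truth the naming is exact;
on real data it should be reviewed). EMBL/GenBank flat-file emission
and database submission tooling are not provided.
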