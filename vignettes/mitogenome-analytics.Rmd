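---
title: "Analysing circular mitochondrial genomes with mitoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing circular mitochondrial genomes with mitoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscan)
```

## Scope and data model

Insect mitochondrial genomes are compact circular molecules of 15--20 kb
carrying a near-invariant complement of 37 genes — 13 protein-coding genes
(PCGs), 22 tRNAs, 2 rRNAs — plus one non-coding A+T-rich (control) region.
mitoscan implements the standard descriptive analyses performed on a newly
sequenced mitogenome: annotation-table arithmetic on circular coordinates,
nucleotide composition and strand-skew statistics, codon usage and RSCU
under the invertebrate mitochondrial genetic code, structural scanning of
the control region, and a concatenated-protein neighbor-joining phylogeny
with bootstrap supports. A seeded simulator produces annotated genomes and
tree-evolved alignments with recorded ground truth so that the entire
pipeline is testable without downloads.

Coordinates are 1-based and inclusive throughout, the convention of printed
annotation tables; converters to other conventions belong at I/O boundaries
only. Strands are written J (majority) and N (minority); a feature with
`end < start` wraps across the linearisation origin and is only legal on a
circular genome.

The package ships the published annotation, codon-count and composition
tables of the stonefly *Kamimuria wangi* mitogenome (16,179 nt, GenBank
KC894944) as fixtures (`kwangi_annotation()`, `kwangi_codon_counts()`,
`kwangi_composition()`), both as worked examples and as reference values
for the test suite.

## Annotation arithmetic

For consecutive features in table order the intergenic nucleotide count is
`IGN = start_next - end_prev - 1`; negative values denote overlap. On a
circular genome the first feature also has a wrap boundary against the
last. Two invariants follow and are asserted throughout: the telescoping
identity (sum of feature lengths plus sum of all boundary IGNs, wrap
included, equals the genome length), and the +k shift law (moving a start
by +k moves its boundary IGN by exactly +k).

`validate_annotation()` reports findings rather than raising errors, so a
published table with internal inconsistencies can be loaded verbatim. The
shipped stonefly table carries one such inconsistency: the COII row prints
length 686 and IGN 56, while its own coordinates (3010--3705, preceded by
a feature ending at 3004) give 696 and 5. All other printed cells agree
with the coordinate arithmetic. The package always reports
coordinate-derived values and flags the discrepancy; it never silently
"fixes" printed numbers. The same policy applies to the genome's prose
totals (tRNA and rRNA nucleotide sums), which also disagree slightly with
the summed coordinate lengths.

## Composition and strand skews

`base_composition()` counts A, T, G, C exactly; IUPAC ambiguity codes are
excluded from every denominator and reported separately. Strand asymmetry
uses the standard skew statistics

$$\mathrm{AT\text{-}skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{G - C}{G + C},$$

computed from raw counts and stored unrounded; a zero denominator yields a
missing value, never 0. Printed-precision output (1 decimal for
percentages, 2 for skews) uses half-up rounding (`round_half_up()`),
matching how published tables round — R's default round-half-even would
disagree on boundary cases such as 2.305.

`region_composition_report()` emits one profile per conventional table
row: whole genome, pooled PCGs, the three codon positions, pooled tRNAs,
each rRNA, and the A+T-rich region. Two conventions are deliberate choices
because published tables do not state them:

* PCGs are pooled in coding (mRNA-sense) orientation, minority-strand
  genes reverse-complemented first. The codon-position rows require a
  reading frame, which only exists in coding orientation, so the same
  convention is used for the pooled PCG row; it is recorded in the
  report's `policy` field.
* Start and stop codons are included in codon-position pooling (no
  trimming), again recorded in the output.

## Codon usage and RSCU

Relative synonymous codon usage for codon $c$ in synonymous family $F$ is

$$\mathrm{RSCU}_c = \frac{n_c\,|F|}{\sum_{c' \in F} n_{c'}},$$

the observed count over the family mean; 1 means no bias. Families derive
from the genetic code in force. The default is NCBI translation table 5
(invertebrate mitochondrial): AUA = Met, UGA = Trp, AGA/AGG = Ser, so
serine has an eight-codon family and the termination codons {UAA, UAG}
form their own two-codon family with RSCU of their own. These assignments
are exactly what the packaged codon-count table validates: the printed
values UCA 2.02 (requires the 8-codon Ser family), AUA 1.56 (2-codon Met
family) and UAA 1.56 (= 2 × 98/126) are reproduced only under table 5.
Initiator codons are counted as ordinary codons, as published totals
include them. Biostrings supplies the code table itself; its initiator
list for table 5 omits ATA, which NCBI includes and which three of the
stonefly's PCGs use, so the package adds it back.

`amino_acid_usage()` reports percentages derived from the counts. The
published per-amino-acid percentages accompanying the stonefly table (Ile
8.12%, Leu 11.61%, Ser 11.99%, Thr 7.03%) are not reproducible from the
printed counts under any natural denominator (e.g. Ser is 305 of 3,615
non-stop codons ≈ 8.4%); the package therefore reports count-derived
percentages and no test asserts those printed values.

## Control-region scanning

The A+T-rich region of insect mitogenomes carries replication-initiation
signals: a poly-T tract, hairpin-forming inverted repeats downstream of
it, and short motifs such as (TA)n runs and GAAT in the flanking
sequence. `scan_control_region()` locates the annotated control region and
reports all three element classes with region-relative and
genome-absolute coordinates.

Stem-loop semantics had to be pinned down precisely to be testable. A
candidate hairpin is identified by its loop interval; the stem grows
outward pair by pair, and the reported stem is the longest growth whose
mismatch count stays within `max_mismatch` and whose innermost and
outermost pairs are Watson–Crick (mismatches are interior). All paired
positions of a candidate lie on one antidiagonal (constant position sum),
so a candidate whose pairs are a subset of another's is redundant; such
dominated candidates are dropped, deduplicating overlapping candidates to
maximal-stem representatives. G·T wobble pairs are not counted by default
(the scan is at the DNA level) but can be enabled. The scanner is verified
against an independent brute-force enumeration of all (start, stem, loop)
triples on a thousand random short sequences.

Published descriptions give no detection parameters, so the defaults —
poly-T tracts of ≥ 10 nt (the observed tract length in the motivating
genome), stems ≥ 6 pairs, loops 3--20 nt, ≤ 1 mismatch — are exposed in
`cr_scan_config()` and recorded in every report. "Downstream of the
poly-T stretch" is interpreted as higher reference-strand coordinate
within the region. Note that in ~78% AT sequence, chance inverted repeats
passing these thresholds are abundant (hundreds per kilobase); a
structural scan at these settings is a candidate generator, not a
specificity filter, which is why the published hairpins are described as
"potential" structures. Thermodynamic folding is out of scope.

## Phylogeny

The tree pipeline mirrors the standard mitogenomic workflow: translate
each PCG under table 5 (terminal stops removed; internal stops reported,
not dropped), concatenate the 13 per-gene protein alignments in canonical
genome order into a partitioned supermatrix, compute uncorrected
p-distances over gap-free column pairs, and build the tree by
neighbor joining:

* Q-matrix selection $Q_{ij} = (n-2)d_{ij} - r_i - r_j$, ties broken by
  the lowest (row, column) pair so the algorithm is fully deterministic;
* branch lengths $v_i = d_{ij}/2 + (r_i - r_j)/(2(n-2))$, negative
  estimates clamped to zero with the deficit moved to the sister edge
  (standard practice; occurrences are counted in the tree's
  `clamped_edges` attribute);
* distance update $d_{uk} = (d_{ik} + d_{jk} - d_{ij})/2$.

On additive matrices this reproduces the generating tree exactly, which
the tests assert over random 4--10-taxon trees, alongside agreement with
an independent NJ implementation (ape's).

`bootstrap_support()` resamples alignment columns with replacement over
the whole concatenated matrix — column-level rather than per-partition
resampling, a deliberate choice since gene-wise resampling changes the
variance structure and the conventional workflow resamples columns — and
reports each internal bipartition's replicate frequency on the full-data
tree, plus a 50% majority-rule consensus. Taxa are sorted internally so
supports do not depend on input order; all resampling is governed by one
seed. Model-based inference (maximum likelihood, Bayesian MCMC, model
selection) is out of scope; `export_supermatrix()` writes
FASTA/PHYLIP/partition files for running those externally.

## The synthetic-data generator

`generate_mitogenome()` emulates the study system: its default gene plan
is the 37-gene + control-region arrangement of the stonefly table with
its real coordinate-derived lengths and IGN profile (including the twelve
negative, overlapping boundaries), per-class AT targets from the
published composition (PCGs 68%, tRNAs 72%, rRNAs 71%, control region
78%, spacers 70%), the published start/stop codon assignments, and a
control region containing a 10 nt poly-T tract, two downstream
stem-loops, a (TA)₅ run and two GAAT motifs.

Construction guarantees, in order of application: coordinates telescope
exactly from the length/IGN plan (infeasible plans — an overlap swallowing
a gene, a PCG length not divisible by 3 — are rejected up front);
structural RNA payloads are exact-composition shuffles so class AT
targets are realised to within a base; PCG payloads are sampled
codon-wise with stop codons rejected, at a base-level AT adjusted so the
post-rejection expectation equals the target; planned initiator/terminator
codons are stamped last and are authoritative; a deterministic repair
pass removes any internal stop codons that overlap interactions created
(the stamped codon positions themselves are never touched). Every
generated genome passes `validate_annotation()` cleanly — asserted, not
assumed.

Planted control-region truth has two strengths. Poly-T tracts and motifs
are **exact**: a scrub pass removes chance tracts and motifs from the
background with AT-preserving single-base edits, so the detected sets
equal the planted sets. Hairpins on a realistic AT-rich background are
**subset-exact**: each planted hairpin is detected at its planted
coordinates with its planted stem (flanking blocker bases prevent chance
outward extension, and loop ends are chosen non-complementary so no
smaller-loop candidate can dominate it), but chance hairpins also appear,
as they do in real AT-rich sequence. For tests needing full equality,
`plant_control_region(background = "ac")` builds the region on a
scaffold over {A, C}, an alphabet with no Watson–Crick self-pairing, where
the detected element sets provably equal the planted truth.

`evolve_alignment()` evolves per-gene root proteins down a guide tree
under an equal-rates replacement process: along a branch of length $b$
each site is replaced with probability $1 - (1-\mu)^b$ (so probabilities
compose along paths; $\mu$ = 0.5 per unit branch length by default), the
replacement drawn uniformly from the other 19 residues. This is
deliberately not a biological substitution model — no JTT/WAG
exchangeabilities, no rate heterogeneity, no indels — but it gives the
data a known true topology, which is what NJ correctness and bootstrap
tests need. The default guide tree has the 13 taxa of the comparative
study design with the two stoneflies and the mayfly forming an embedded
clade among ten outgroups; default gene lengths match the real proteins
(3,766 aligned residues in total).

What passing on synthetic data does *not* show: robustness to alignment
error, compositional heterogeneity across lineages, rate variation, gene
rearrangement, or indels — none of which the generator emulates.

## Problem sizes and reproducibility

The test suite runs the full pipeline at the study's own scale: the
16.2 kb default genome, the 13-taxon × 3,766-residue supermatrix, 500
bootstrap replicates for the clade-support check, 100 random additive
matrices for NJ exactness, and 1,000 random sequences (≤ 40 nt) for the
stem-loop brute-force equivalence. A single integer seed governs each
stochastic component; generator outputs embed the seed and a hash of the
generating spec.

## Known limitations

* The GenBank reader is a minimal flat-file parser (single-interval
  locations, optionally complemented); join() locations and multi-record
  files are not supported.
* Wrap-around features are supported in the coordinate arithmetic and
  sequence extraction, but the generator's default plan contains none
  (matching the reference table).
* The control-region scan reports candidate structure; it performs no
  thermodynamic evaluation.
* NJ on p-distances is the in-package tree method; saturated or
  compositionally biased data deserve model-based methods, for which the
  supermatrix export exists.
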