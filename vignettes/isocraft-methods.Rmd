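---
title: "Methods: full-length transcriptome characterization with isocraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: full-length transcriptome characterization with isocraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`isocraft` characterizes a full-length transcriptome from spliced long-read
(FLNC) genome alignments: isoform collapse, locus assignment, novelty
classification, alternative splicing (AS), alternative polyadenylation
(APA), chimeric fusion transcripts, long non-coding RNA (lncRNA)
candidates, and an A/B/R (sterile / maintainer / restorer line) expression
screen. This vignette explains the procedure, the assumptions behind each
rule, the tunable parameters, what the bundled simulator does and does not
emulate, and the design choices made where the method was genuinely open.

## Coordinates and inputs

All internal coordinates are 0-based, half-open intervals on the forward
genomic strand; strand is metadata. Conversion to and from GFF3's 1-based
closed convention happens only at the I/O boundary. The pipeline consumes a
genome FASTA, a GFF3 annotation, and spliced alignments (SAM/BAM with `N`
CIGAR operations for introns); it does not align reads itself. Alignment
identity is defined as matches over aligned columns, with insertions and
deletions counted as mismatches, computed from the `NM` tag.

## Isoform collapse

A read's *splice chain* is the ordered list of its junctions (the gaps
between aligned blocks). Multi-exon reads with identical chains collapse
into one isoform; `junction_tolerance` (default 0 nt) optionally relaxes
equality to positional agreement within a window for noisy aligners, using
greedy positional pairing. Because single-exon reads have no junctions to
compare, they collapse by reciprocal span overlap of at least 50%
(`single_exon_overlap_frac`) on the same strand — a rule the junction-based
definition cannot provide but that real single-exon isoforms require.

The isoform's TSS is the 5'-most supporting end (truncation only shortens
reads), while its TES is the modal supporting 3' end with ties resolved
downstream, reflecting that 3' ends cluster at genuine cleavage sites.

**5'-degradation pruning.** Full-length cDNA libraries still contain
5'-truncated molecules. An isoform X is removed when its entire chain is a
suffix, in transcript orientation, of a longer isoform Y's chain on the same
chromosome and strand, and X's 5' end lies inside Y's span; Y inherits X's
supporting reads. The rule deliberately applies only to spliced fragments:
an empty chain is a suffix of everything, so including single-exon isoforms
would delete every one of them.

**Support filter.** An isoform is retained when any of three independent
evidence clauses holds: at least `min_support_reads` (2) FLNC reads; a
single read with identity strictly above `min_single_read_identity` (0.99);
or every junction present in the short-read junction set (at least
`min_sj_cov` = 1 spanning reads) or the annotation. The junction clause
requires at least one junction — junction evidence cannot vouch for a
single-exon singleton, and a vacuous reading would retain every one.

**Loci.** Two same-strand isoforms whose spans overlap by at least
`min_locus_overlap_frac` (20%, inclusive) of the *shorter* span are
connected; loci are the connected components, so membership is transitive
and order-free. The shorter-span denominator is the symmetric, permissive
reading of "overlap by 20% of their length", matching the merging intent.

## Novelty classification and full-length status

A locus is a **novel gene** when no annotated gene overlaps at least 20% of
the locus span on the same strand — either the best overlap falls short or
it is antisense. Exactly 20% counts as known (the complement of the
"below 20%" criterion). Ties between annotated genes resolve by shared
splice sites, then lexicographic gene id, for determinism.

An isoform of a known gene is a **novel isoform** when it is multi-exon and
carries at least one splice site absent from the gene's annotated site set.
This is deliberately a *site-level* rule: a multi-exon isoform that
recombines exclusively annotated sites (for example, a skipping variant
whose flanking sites both exist) is classified known. Single-exon isoforms
of known genes, which the site rule cannot address, are known when at least
half their span lies in annotated exonic sequence of the gene, else novel.
All isoforms of novel genes are novel.

A multi-exon, gene-matched isoform (or read) is **full length** when its
5'-most splice donor equals the 5'-most donor of some annotated transcript
of its gene — 5' degradation destroys precisely this feature, and later
junctions are allowed to differ. Single-exon subjects are inapplicable and
excluded from full-length denominators.

## AS events

Within each multi-isoform locus every isoform pair is compared and each
distinct `(type, coordinates)` signature is counted once per locus — the
counting convention behind whole-dataset event totals. Patterns, in order
of precedence: **ES** (an internal exon absent from the partner, which
carries a junction spanning it with both flanking sites shared; one event
per skipped exon), **IR** (an exon fully containing the partner's intron
with both its splice sites), **AA/AD** (junction pairs sharing a donor or
an acceptor respectively, in transcript orientation, so the labels swap
with strand), and **other** for every remaining junction difference
(alternative first/last exons, mutually exclusive exons, complex nests).
Pure TSS/TES differences generate no event because collapse already merged
identical chains.

## APA

Read 3' ends are pooled per gene (per locus for novel genes), sorted along
the strand, and clustered by single linkage with a gap of
`polya_cluster_window` = 24 nt — the conventional width of cleavage
heterogeneity. A site's position is the modal end, ties downstream;
clusters with fewer than `polya_min_site_support` = 2 ends are dropped to
suppress degradation artifacts. Both values are exposed; the method names
no canonical setting. A gene with ≥2 sites shows APA. The nucleotide
profile takes ±`polya_flank` (30) nt of genomic sequence around each site
in transcript orientation (reverse-complemented on `-`), averages base
fractions per position, reports T as U, and excludes chromosome-edge
padding from the affected denominators.

## Fusion transcripts

Chimeric cDNAs appear as split (supplementary-linked) alignments. A read is
a fusion candidate when (1) its segments hit ≥2 annotated genes at least
`fusion_min_gene_distance` = 10 kb apart (closest boundaries; different
chromosomes qualify trivially), (2) every segment covers strictly more than
10% of the read length, (3) all segments together cover strictly more than
99%, and (4) at least `fusion_min_pe_support` = 2 short-read pairs span the
junction. Coverages are fractions of read length, not genomic length,
because the criteria describe read (FLNC) coverage. The strict inequalities
are intentional and tested at the boundary. Split reads are excluded from
isoform collapse entirely: their primary segment alone would otherwise
fabricate a truncated isoform of one partner gene, so chimeras never
surface in the isoform catalogue.

## lncRNA candidates

Novel isoforms at least `min_lncrna_len` = 200 nt long, with no
protein-homology flag (homology search happens outside the package and
enters as a per-isoform boolean), no ORF of `min_orf_aa` = 100 amino acids
or more, and a coding-potential verdict other than coding are lncRNA
candidates. ORFs are sought in the three forward frames of the oriented
transcript (six-frame mode exists for strand-unknown single-exon isoforms):
maximal ATG-to-stop spans, plus flagged 5'/3'-partial spans. Coding
potential is a transparent two-voter rule: the Fickett TESTCODE statistic
(published position-asymmetry and composition tables; coding above 1.10,
noncoding below 0.95) and a hexamer log-likelihood ratio trained on the
annotation's ORF regions versus deterministic intergenic tiles, voting by
sign. The verdict is coding or noncoding only when both voters agree;
ambiguity is treated as noncoding for candidacy and logged. This keeps the
stage self-contained, inspectable and trainable on any genome, at the cost
of the discriminative power a large externally trained model would add.

## Expression screen

FPKM is `count × 10⁹ / (length × library size)` with per-sample library
sizes taken from the count matrix itself. Fold changes use a pseudocount of
1 on mean FPKM. The two-group test runs on log2(FPKM + 1): by default a
moderated t (empirical-Bayes variance shrinkage with a mean-variance
trend). With three replicates a per-feature variance estimate has ~4
degrees of freedom; measured at the package's own operating point (2,000
features, 100 true 8-fold effects, negative-binomial dispersion 0.1,
n = 3), an unmoderated Welch t delivers under 10% power at a 5%
Benjamini–Hochberg FDR, while the moderated test reaches full power at the
same empirical type-I error (~0.05) — so moderation is the default and
`test = "welch"` remains available. A feature is differentially expressed
at `q < 0.05` and `|log2FC| > 1`. Identical replicate groups with zero
variance (possible with deterministic counts) receive p = 1 when means are
equal and p = 0 otherwise.

The restorer-specific rule flags a feature when *either* the fold-change
clause (log2FC > 3 against both A and B) *or* the expression-pattern clause
(FPKM > 1 in every R replicate and < 1 in every A and B replicate) holds;
the grammar admits a conjunctive reading, so `rule = "both"` is exposed.
The pattern clause is enforced in every replicate, the strictest reading,
to make the flag deterministic. `ddct()` implements the 2^-ΔΔCt
relative-expression calculation against an internal control gene and a
calibrator sample.

The mapping summary classifies every read as unmapped, multiple-best (two
or more primary/secondary alignments tying the best identity), low-pid
(best identity below `pid_floor` = 0.90, an exposed choice since the class
has no canonical cutoff), or high-quality.

## The simulator and what passing tests mean

`simulate_truth_set()` generates a toy genome whose genes carry biased-codon
CDS (so coding sequence has the positional asymmetry and hexamer structure
the lncRNA stage needs to detect), implants unannotated splice variants
drawn from an ES/AA/AD/IR mix, novel genes (half noncoding by default),
multiple cleavage sites per gene with a U-rich upstream window and
downstream adenosines, chimeric reads emitted as supplementary-linked split
SAM records, 5'-truncated reads (13% by default, the complement of typical
corrected full-length rates), identity noise near 0.99, occasional
multi-mapping, unmapped and intergenic noise reads, and an A/B/R count
matrix with negative-binomial noise (dispersion 0.1) around a design that
includes 8-fold DEGs and restorer-specific novel isoforms. Every read,
site, fusion and design flag is recorded, and `truth_metrics()` computes
per-stage precision/recall against those labels. By construction,
skipping/retention variants reuse annotated splice sites, so their expected
novelty call is "known" under the site-level rule — the truth labels encode
the rule's semantics, not merely absence from the annotation file.

The generator works at the alignment level: it does not emulate
base-calling error profiles, homopolymer indels, reverse-transcription
template switching, internal poly(A) priming, or genome repetitiveness and
multi-mapping ambiguity beyond injected ties. Passing tests therefore
demonstrate the correctness of the characterization logic under controlled
violations (truncation, end jitter, count noise), not robustness to every
artifact of real libraries.

Problem sizes used by the test suite and the acceptance script — chosen as
comfortable desk-scale versions of the method's regime — are a noiseless
~45-gene simulation shared across files, a ~200-gene / ~2,000-read
simulation for exact-recovery and headline metrics, 1,000-read and
1,000-sequence brute-force oracle comparisons, and 20 replicate
2,000-feature count simulations for the screen's operating
characteristics. Same seed, same bytes: simulation outputs and pipeline
reports are deterministic, and collapse/locus assignment are invariant to
input order.

## Known limitations

* Junction tolerance defaults to exact matching; noisy aligners need the
  tolerance raised, which coarsens AA/AD detection below that scale.
* The locus graph can chain distinct genes through a bridging isoform
  (transitive merging is deliberate but greedy).
* The coding-potential voter is weaker than a trained logistic model on
  real genomes; homology evidence enters only as a precomputed flag.
* The expression screen models log-scale counts, not counts; with more
  replicates or strong heteroskedasticity a count-model GLM is preferable.
* Fusion calling trusts the aligner's split alignments and refines no
  breakpoints.
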