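---
title: "Classifying a reannotated plant transcriptome with lncraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying a reannotated plant transcriptome with lncraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncraft)
library(dplyr)
```

## The problem

Total RNA-Seq of a plant leaf captures far more than the annotated
protein-coding transcriptome: novel splice isoforms, intergenic
transcription, antisense transcripts, small-RNA precursors and
transposable-element (TE) transcripts. After a reference-guided assembly
(Cufflinks-style RABT) of such data — here modelled on the maize B73 /
*rmr6* leaf transcriptome under osmotic stress — the assembled annotation
needs curation, and every transcript needs a verdict: is it coding, a
potential long non-coding RNA (lncRNA), a small-RNA precursor, a
TE-derived transcript, a natural antisense transcript (lncNAT) or a long
intergenic non-coding RNA (lincRNA)? `lncraft` implements that decision
tree as a reusable, fully tested pipeline, together with a synthetic-data
generator that plants known labels so the whole cascade can be verified
without any external download.

## The classification model

**Curation** (in fixed order, idempotent on its own output):

1. *Duplicate merge* — transcripts with identical chromosome, strand and
   exon chain (the classic case of one miRNA locus annotated under two
   gene ids) collapse to one record; the lexicographically smallest id
   survives, the others become aliases.
2. *Minimum length* — novel transcripts (classes J/O/X/U) shorter than
   57 nt are discarded. The value corresponds to the shortest reference
   transcript of the annotation being curated: no novel model should be
   shorter than anything already accepted. The bound is strict
   (56 nt goes, 57 stays); reference and EST models are exempt.
3. *Renaming* — novel isoforms become `<hostTx>_j_k`, exonic-overlap and
   antisense transcripts `_O_k` / `_X_k`, intergenic ones
   `TCONS_########`, numbered in genomic order. Ids already in the scheme
   are kept and numbering continues after them, which is what makes the
   step idempotent.
4. *Monoexonic clustering* — single-exon intergenic (class U) fragments
   separated by strictly less than 500 nt are chained by single linkage
   and fused into one `Cluster_t_k` model. The gap is measured between
   half-open interval end and next start, so two fragments exactly 500 nt
   apart are *not* fused. An optional verification requires the fused
   genomic sequence to contain every member exactly; the published
   procedure mentions an alignment check at this point without describing
   it, so the hook is configurable and off by default.
5. *EST integration* — external non-redundant transcripts are appended
   unless an identical exon chain already exists.

**Coding potential.** A transcript is a *potential lncRNA* when it is at
least 200 nt long, carries no ORF of 120 or more amino acids, and the
peptide of its longest ORF (when one exists) matches no protein in the
supplied library. The decision order is: long ORF → coding; length
below 200 nt → coding bucket (keeping the output a two-way partition of
the transcriptome, which is how the published class-by-category tables
add up); protein match → coding; otherwise potential lncRNA. An ORF runs
ATG to the next in-frame stop; `aa_length` excludes the stop, and an ATG
with no downstream stop counts as a 3'-partial ORF. By default only the
three sense frames are scanned, because strand-specific assembly fixes
transcript orientation; six-frame scanning is available for
unknown-strand input. Only the longest ORF's peptide is searched — the
definition speaks of *the* predicted protein, and scanning every minor
ORF would make the criterion a different (stricter) filter.

**Subclassification.** Potential lncRNAs are searched against a
small-RNA-precursor library first, then a TE library, in exact-match mode
(word size 16, 100 % identity, E < 0.01). The small-RNA-first precedence
keeps the three subcategories disjoint; the published counts imply
disjoint categories but not an order, so the order is configurable.
Remaining transcripts are *truly lncRNAs* and split into lncNATs —
at least one contiguous exon-to-exon overlap of 10 nt or more with a
transcript of *another* gene on the opposite strand — and lincRNAs.
Overlap is measured on exons rather than transcript spans because a
10-nt "overlapping sequence" is a statement about the mature transcripts,
not about introns; and it is a single contiguous run, not a cumulative
sum. lincRNAs are then searched against the coding sequences for
candidate targets: *perfect* means a 100 %-identity alignment of at least
100 nt (detected as a maximal exact run, so a flanking chance match
cannot demote it), *near-exact* means identity above 95 % over at least
100 nt.

**TE classification.** Every transcript is searched against the TE
library and its best hit (highest bit score; ties broken by alignment
length, then subject id) is thresholded: high-confidence (HC) at bit
score > 500 **and** coverage > 50 %, putative/relic (PR) at bit
score > 250 **or** coverage > 30 % when not HC. All bounds are strict.
"Coverage" is query coverage — the fraction of the transcript aligned —
because the question is how much of a transcript is TE-derived; the
original criteria do not say which side the percentage refers to, so this
choice is stated here explicitly.

**Differential expression.** Tables in the Cuffdiff dialect are filtered
with inclusive bounds: status `OK`, |log2FC| ≥ 1, q ≤ 0.05; `NOTEST` and
`LOWDATA` rows count as not expressed, and an optional genomic window
(for example 30 Mb around an introgressed mutant locus, where apparent
differential expression can reflect mapping artefacts) can be excluded.
`compute_log2fc()` is plain `log2(b/a)` and deliberately errors on zero
input rather than reproducing any quantifier's pseudocount convention;
published cells with a zero baseline are therefore not reproducible by
ratio arithmetic and are not used as worked examples.

## The homology engine

All homology steps run on a self-contained seed-and-extend search, so no
external aligner is invoked anywhere. Exact words (default 11 nt; 16 nt
in the exact-match mode; 4 residues for peptides) are hashed over the
library; each seeded diagonal is scored position-wise (+1/−2 for
nucleotides, BLOSUM62 for peptides) and the maximal-scoring contiguous
segment is reported — an ungapped extension computed exactly by a
prefix-minimum scan. Raw scores are normalised with Karlin–Altschul
statistics, `bit = (λ·S − ln K)/ln 2` with λ = 1.28, K = 0.46 for the
nucleotide scoring (λ = 0.318, K = 0.13 for BLOSUM62), and
`E = m·n·2^(−bit)` where `m` is the query length and `n` the summed
library length. E-value cutoffs are strict.

The engine is ungapped by design. The classification contract here is
thresholding behaviour — does a transcript share enough sequence with a
library — not score parity with any particular aligner, and at the
study's thresholds an indel splits one long segment into two high-scoring
ones that pass or fail together. In 100 %-identity mode the engine
returns exactly the maximal common substrings of word length or more,
which the tests verify against an exhaustive substring-enumeration
oracle. The translated mode's E-value cutoff (1e−3) is a pinned default:
the original protein-match step names no tool or threshold.

## The synthetic-data generator

`simulate_transcriptome()` builds the study's input shapes with planted
truth: a genome (default two 1-Mb chromosomes), an annotation of roughly
300 transcripts, protein / small-RNA / TE / CDS libraries and a DE table.
Transcripts are constructed sequence-first and validated before placement
so every label is guaranteed by construction, not merely likely:

* coding genes embed a random-codon ORF of 120–400 aa whose translation
  enters the protein library;
* planted non-coding sequences are redrawn until they contain no ORF of
  120 aa or more (including 3'-partials), no protein match of their
  longest ORF, and no chance 16-mer shared with the small-RNA or TE
  libraries — at desk scale such collisions would otherwise occur about
  once per run;
* small-RNA precursors embed an exact 24–80 nt library copy; TE
  transcripts embed library fragments sized to land clearly in the HC or
  PR regime (500 nt fragment in a 900 nt transcript, versus 200 nt);
* antisense lncRNAs overlap a host gene's terminal exon by 10–60 nt
  (with deliberate near-misses of 1–9 nt that must classify as
  lincRNAs), and the fragment chains for the clustering step straddle
  the 500-nt gap threshold from both sides;
* lncRNA lengths follow a shifted exponential truncated to
  [201, 4179] nt with means near 465 nt (lincRNA) and 535 nt (lncNAT) —
  the right-skewed shape and summary statistics reported for plant
  lncRNA populations; a uniform draw over the full range would triple
  the observed means.

The generator also emits curation work: duplicated reference records,
sub-57-nt fragments, fragment chains and a partially redundant EST set,
together with the exact post-curation identifiers the curation step will
assign (cluster numbering in genomic order), so truth remains keyed after
renaming and fusion. One master seed drives per-component derived seeds;
identical seeds give byte-identical output files.

What the generator does *not* emulate: read-level noise, expression
estimation, splice-graph ambiguity, assembly artefacts, genomic repeat
structure, or indel divergence of TE copies (substitutions only, rate 0
by default). Passing the planted-recovery tests therefore demonstrates
that the decision tree and its thresholds are implemented exactly — not
that the thresholds are optimal for real maize data.

## Numerical and design choices

* Internal coordinates are 0-based half-open; GTF I/O converts at the
  boundary, so all interval arithmetic is offset-free.
* Unknown-strand transcripts are excluded from antisense logic with a
  warning.
* Reported percentages round half away from zero (two decimals for
  class-share tables, one for TE shares), matching the printed precision
  of the tables the package reproduces. One published TE-share cell
  (117/622) prints as 18.2 % where the quotient is 18.8 %; the package
  reports the arithmetically consistent value and keeps the printed
  number only in the verbatim fixture file.
* Deterministic tie-breaks everywhere a choice exists: best hits by
  (bit score, alignment length, subject id); cluster and rename
  numbering by genomic order.
* A lincRNA with several targets is counted once per match class, and a
  lincRNA with any perfect target counts as perfect only.
* NAT pairs whose partner is neither coding, lncNAT nor small-RNA
  precursor (for example TE-derived) are detected but not typed, since
  the published typology has exactly three kinds.

## Problem sizes used by the test-suite

End-to-end recovery runs at the default scale (two 1-Mb chromosomes,
~300 transcripts, ~240 surviving post-curation models). The
oracle-equivalence suites use 500 random sequences (ORF finder), 1,000
random placements (antisense classifier), ≤ 5 kb instances (exact-match
homology) and 30 random fragment layouts (clustering). The
partition-invariant sweep runs 100 seeds at a reduced scale (~45
transcripts on two 120-kb chromosomes) — large enough that every
category is populated, small enough to keep the sweep fast.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_transcriptome(sim_config(seed = 1))
res <- run_reannotation_pipeline(sim$annotation, sim$genome,
                                 sim$libraries, est_set = sim$est_set)
glance(res$classification)
tidy(res$classification) |> count(category_final)
autoplot(res$classification)
```

## Known limitations

* The engine does not model gapped alignment; heavily indel-diverged TE
  relics would score as several shorter segments and may fall from HC to
  PR relative to a gapped aligner.
* Antisense detection requires known strands; assemblies with many
  unknown-strand models will under-call lncNATs.
* `compute_log2fc()` refuses zero baselines by design; upstream
  quantifier conventions for zero counts must be handled before import.
* The coding filter is purely threshold-and-homology; it does not use
  codon-usage or machine-learned coding-potential scores, so its verdicts
  are only as good as the supplied protein library.
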