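---
title: "Detecting and characterising plastid RNA editing with plastedit"
author: "plastedit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising plastid RNA editing with plastedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastedit)
```

## The problem and the data model

Plastid transcripts are post-transcriptionally edited: individual
cytidines are converted to uridines (and occasionally the reverse), so
the mRNA sequence differs from the plastome that encodes it. Comparing
RNA-read alignments against the genomic reference reveals these sites
as positions where a consistent fraction of reads carries a
non-reference base. `plastedit` implements that comparison end to end,
together with the summaries such a study reports: codon-level effects,
gene-group tallies, expression ranking, intergenic-spacer divergence
and rRNA structure change.

The central object is the `Plastome` class: the plus-strand sequence,
the quadripartite region layout (large single copy, small single copy,
two inverted repeats) when known, and gene models as a `GRanges` with
name, kind (protein / rRNA / tRNA), functional group and pseudogene
flag. All coordinates are 1-based inclusive, the GenBank/GFF3
convention, and all per-gene coordinates refer to the spliced coding
sequence on the gene strand. Introns are out of scope: the genes this
analysis annotates are treated on their spliced CDS, and the synthetic
generator emits intronless genes only.

## The calling statistic

At each reference position the pileup counts the aligned A/C/G/T bases
of every retained read (deletions and Ns excluded, so coverage always
equals the sum of the four counts). The conversion frequency of an
alternative base is simply

> f = edited-base reads / total coverage at the position,

and a site is called when `f > threshold` — **strictly** greater, with
the threshold defaulting to 0.05, i.e. "over 5%". A frequency of
exactly 5% is not a call. One detail matters when recomputing published
per-site tables: printed coverages sometimes exceed the sum of the two
printed base counts (the remaining reads carried other bases), so
`conversionFrequency()` accepts an explicit coverage.

Choices a user can change:

* `threshold` (default 0.05): the published calling rule. Must lie
  strictly inside (0, 1).
* `minCoverage` (default 10): the source analyses state no explicit
  coverage floor (their tabulated minimum is 78x), but at very low
  coverage a single error read can exceed 5%; ten reads is the smallest
  coverage at which one read cannot. Fixture evaluations use
  `minCoverage = 1` so no printed row is dropped.
* `allowedConversions` (default `C-to-U`, `U-to-C`, `A-to-G`): plastid
  editing is overwhelmingly C-to-U with rare U-to-C; the transcribed
  per-site table also contains one A-to-G row, so the default admits
  it. `"all"` enables the remaining conversions.

Conversion content is always reported on the **gene strand**: a
plus-strand G-to-A signal inside a minus-strand gene is a C-to-U edit.
Positions covered by no gene are labelled `IGS` and reported in
plus-strand content. When two alternative bases both clear the
threshold the higher-frequency one is reported and the site is flagged
`multiAllelic`; this does not occur in real plastid data at the default
conversions but is defined for completeness.

The read filter mirrors the original mapping protocol: unmapped,
secondary and supplementary SAM records are skipped, and any read with
more than `maxMismatches = 2` mismatches against the reference is
discarded entirely. Base-quality filtering defaults to off (reads are
assumed quality-trimmed upstream); duplicates are not removed, and
reads mapping into the inverted repeats are counted at their reported
position only — no multi-mapping reallocation is attempted, since no
published rule exists for it.

## Codon annotation

Coding sites are annotated under the plastid genetic code, NCBI
translation table 11. The source tables never name a code, but table 11
is standard for land-plant plastids and consistent with every printed
translation. The affected codon is extracted on the gene strand,
transcribed (T to U), the edited base substituted, and both codons
translated. Classification rules:

* `start_gain` requires codon 1 and an AUG result (the genomic ACG
  start some plastid genes carry); an ACG-to-AUG edit elsewhere is
  ordinary nonsynonymous T-to-M.
* `stop_gain` whenever the post-edit codon is a stop; `stop_loss` when
  only the pre-edit codon is. Stop-containing changes never count as
  synonymous, even if both sides are stops.
* `synonymous` iff both amino acids are equal and neither is a stop.

Display strings follow the field's convention: the edited letter upper
case, flanking letters lower case, e.g. `S(uCa) -> L(uUa)`.

## Fixture mode and its inconsistencies

The package ships transcriptions of a published per-site editing table
(91 rows) and per-gene expression table (80 genes) so that the
study-level summaries are desk-reproducible. The transcription policy
is: printed values are preserved verbatim, even where internally
inconsistent, and a recomputed frequency column
(`count_alt / coverage`) is added. `classifyFixtureRow()` classifies a
row from its printed codons and flags rows whose codons differ at more
or fewer than exactly one position (transcribed typos such as a printed
`uCa -> uUu`).

Two inconsistencies deserve note, because the package computes them
rather than hiding them:

* The printed table has 91 rows while its accompanying text counts 90
  sites. Two rows of one gene (ndhK) print byte-identical coverage and
  read counts to two rows of another (ndhC) — the likely duplication —
  but which row is redundant cannot be decided from the printed data,
  so the fixture keeps all 91 rows and summaries are defined over the
  fixture.
* Classifying the printed codons yields 13 synonymous rows (the 11
  asterisked ones plus a Y-to-Y and a V-to-V row printed without the
  asterisk), whereas the accompanying text counts 12 of 90. Dropping
  one duplicated synonymous row would reconcile both counts; the
  package reports the honest classification of the full table (13) and
  documents the difference instead of adjusting it.

Amino-acid-transition summaries over the fixture use the printed
amino-acid letters (not re-translation of printed codons), because a
handful of rows print codons and letters that disagree; this choice
reproduces the published transition counts (25 S-to-L).

## Expression

Reads are assigned to genes by the **midpoint rule**: a read belongs to
the gene whose span contains its alignment midpoint, giving every read
at most one gene without a transcript model. Expression is RPKM,
`reads x 10^9 / (length_bp x total_assigned)`, exactly the measure the
transcribed expression table prints. The printed RPKM magnitudes cannot
be recomputed without the underlying read counts, so only ranking
statements (most- and least-expressed genes) are checked against the
fixture.

## Intergenic-spacer identity

Spacers are the gaps between adjacent annotated genes along the plus
strand (tRNA and rRNA genes count as delimiters; abutting or
overlapping genes yield no spacer). Two plastomes are compared spacer
by spacer with end-to-end Needleman-Wunsch alignment under match +1,
mismatch -1, linear gap -2, and

> identity = identical columns / all alignment columns,

with gap columns in the denominator, so identity is sensitive to
indels — the point of a divergence-hotspot screen. Spacers strictly
below 95% identity are flagged.

Because many alignments can share the optimal score, the identity of
"the" optimal alignment is not well defined; `alignGlobal()` therefore
reports the maximum number of identical columns across **all**
optimal-score alignments. Under linear gap scoring the score pins down
a linear relation between match and mismatch counts
(`score = 5*matches + 3*mismatches - 2*(n+m)` at the default scores),
so this choice also determines the mismatch and column counts, making
the reported identity canonical — in particular invariant under
reversing or complementing both sequences. The published hotspot
identities were produced by a different (whole-genome) aligner with
unspecified scoring, so reproducing their exact values is out of
scope; this module defines its own convention and states it.

## rRNA structure change

Folding is Nussinov base-pair maximisation: the nested structure with
the greatest number of Watson-Crick (plus, optionally, G·U wobble)
pairs, subject to a minimum hairpin loop of 3 unpaired bases. The
traceback is deterministic — the pairing branch is preferred and,
among equally good partners, the smallest index — so identical inputs
always give identical structures. The effect of an edit is quantified
as the symmetric difference between the pair sets folded before and
after the substitution.

This is a combinatorial stand-in for thermodynamic folding, chosen
because it is deterministic, dependency-free and sufficient to
demonstrate that an edit rewires pairing; it does not predict the
minimum-free-energy structure, pair probabilities or pseudoknots, and
no attempt is made to reproduce any published structure drawing. One
subtlety the test suite documents: with wobble pairs enabled the
maximal pair count is *not* invariant under reverse complement (a G·U
pair maps onto C·A, which cannot pair), so that symmetry is only
asserted for pure Watson-Crick folding.

## The synthetic-data generator

`makePlastome()` emulates the features of a real plastome that the
pipeline depends on: a quadripartite layout with IRB the exact reverse
complement of IRA; intronless protein genes (ATG start, stop-free
body, terminal stop) placed without overlap on both strands of the
single-copy regions; and editing sites planted by forcing the pre-edit
base into the coding sequence. `simulateReads()` draws 76 bp reads
from the spliced gene sequences in proportion to per-gene expression
weights, uniform within each gene; a read covering an injected site
carries the edited base independently with the site's target fraction
(the Bernoulli model underlying the frequency statistic), then each
base is substituted with the per-base error rate. Reads from
minus-strand genes are reverse-complemented into plus-strand alignment
records. Everything is deterministic under the configuration seed
(genome construction and read simulation use distinct streams derived
from it), and complete truth tables accompany every output.

Deliberate simplifications, and what they mean for interpreting green
tests: no indels or quality scores (the caller is substitution-only by
design); no fragment-size model; no transcription of intergenic
regions (expression truth stays clean, at the cost of not exercising
IGS labelling from simulated data); no reads from the inverted
repeats, so IR multi-mapping ambiguity is never simulated. Recovery of
injected sites on this simulator therefore demonstrates the
correctness of the counting, calling, strand handling and annotation
logic — not robustness to alignment artefacts, splicing or
library-preparation biases in real data.

Default study conditions: read length 76 bp (the transcriptome
platform the analysis emulates; the genomic arithmetic helper uses
301 bp reads), error rate 0.001 per base (post-trimming short-read
error scale), gene lengths 300-600 bp and uniform expression weights
unless specified. The end-to-end recovery experiment used by the tests
and the acceptance script runs 20 genes of 600 bp, one injected
C-to-U site per gene at fractions 0.15-0.90, 50,000 reads (interior
site coverage well above 200x) and 0.1% error — sizes chosen so the
binomial sampling error at every site is far from the 5% threshold
while the whole experiment folds into a few seconds.

## Degenerate inputs and numerical conventions

* Zero-coverage positions are errors for `conversionFrequency()` and
  simply absent from pileups.
* Thresholds at the boundary: calling uses strict `>`; hotspot
  flagging uses strict `<` 95.
* Empty inputs (no reads, no genes, no sites) yield empty, correctly
  typed results rather than errors, except where an empty sequence is
  meaningless (alignment, folding).
* Ties: multi-allelic sites report the higher-frequency conversion;
  expression ranking breaks RPKM ties by gene name; the folding
  traceback prefers pairing, then the smallest partner.
* All randomness flows through the single configuration seed; repeated
  runs are byte-identical, which the test suite asserts for FASTA,
  GFF3, SAM and report files.

## Known limitations

The caller is a plain threshold rule, not a statistical test — no
binomial error model, no multiple-testing control; this matches the
published procedure it implements. Mitochondrial editing,
transcript-isoform quantification, thermodynamic folding and
reproducing alignment-tool-specific identity values are out of scope.
The gene model ignores introns and trans-splicing, so genes requiring
them must be provided as spliced coordinates.
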