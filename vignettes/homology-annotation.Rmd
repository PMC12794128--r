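---
title: "Homology-based gene annotation: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based gene annotation: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homanno)
```

## The problem and the approach

Most newly sequenced eukaryotic genomes are published without gene models,
and for many species no transcriptome will ever be available. When proteins
from related species exist, spliced protein-to-genome alignment is the
standard source of evidence: an aligner such as miniprot maps each homolog
onto the genome as a chain of exon blocks with a reported identity. Raw
alignment chains, however, are not an annotation — many proteins pile onto
the same locus, chains conflict, and block boundaries need not coincide with
real start and stop codons.

`homanno` turns such alignments into a non-redundant gene set in three
stages:

1. **Locus assembly.** Chains passing an identity filter are clustered by
   single linkage: two chains on the same contig and strand join one locus
   when any pair of their blocks overlaps by at least one base. The linkage
   criterion is deliberately *block-level*, not span-level: a gene nested
   inside another gene's intron shares a span but no aligned bases with its
   host, and must stay a separate locus. The union of a locus's blocks,
   extended outward by a terminal flank, is spliced into a
   *pseudo-transcript* — a UTR-less mRNA stand-in with an exact, bijective
   transcript-to-genome coordinate map.
2. **Coding-region prediction.** Candidate ORFs are enumerated in the three
   forward frames of each pseudo-transcript (the strand is fixed by the
   protein alignment; scanning the reverse frames would only re-admit the
   false positives the design avoids) and scored with a coding-potential
   model trained on the run's own data (below). A greedy pass retains the
   best-scoring, mutually non-overlapping ORFs; a pseudo-transcript that
   retains several ORFs is split into several genes — this is how two
   genuinely overlapping genes that were fused into one locus are separated
   again.
3. **Filtering and deduplication.** Models below a peptide-length or score
   threshold are dropped (each rejection is logged with the criterion that
   failed), identical CDS chains from different reference proteins collapse
   into one gene, and residual same-strand conflicts resolve in favour of
   the higher-scoring, then longer, then leftmost model. The output
   guarantees that no two genes on one strand have overlapping CDS chains.

## The coding-potential model

The score is a frame-periodic Markov log-odds, the model family used by
GeneMark-style coding sensors and by TransDecoder. For a base $x_i$ at
codon position $f \in \{0,1,2\}$ with the $k$ preceding bases as context
($k = 5$ by default, i.e. hexamers),

$$ s(x_i) = \log \frac{P_{\mathrm{cod}}(x_i \mid x_{i-k..i-1},\, f)}
                      {P_{\mathrm{bg}}(x_i \mid x_{i-k..i-1})} , $$

and an ORF's score is the sum over its coding positions (nats). Positions
within the first $k$ bases of a sequence back off to the lower-order tables;
windows touching a non-ACGT character contribute zero.

The model is *self-trained* on each run: the positives are the `train_top_n`
(default 500) longest complete ORFs found across the run's own
pseudo-transcripts, deduplicated by exact sequence, and the background is
the $k$-mer composition of all pseudo-transcript sequence. Two deliberate
exclusions keep the tables clean: the fixed initial ATG and the trailing
stop codon of each training ORF are signals rather than coding composition,
and counting them would visibly distort the conditionals of their contexts
(the stop codons alone would contaminate the frame-2 `TA·`/`TG·` families).
All counts are smoothed with a pseudocount of 1. When fewer than
`min_training_orfs` (default 50) training ORFs exist, the model degrades to
a zero-information state in which every score is exactly zero, so selection
falls back to ranking by length — annotation still proceeds, with a warning.

Because the background is estimated from the pseudo-transcripts themselves —
which are largely coding — the log-odds of true coding sequence sits near
zero and of intergenic sequence clearly below it. That separation is what
the `min_score = 0` default expresses: a retained ORF must look at least as
coding-like as the average of its own run.

## Start placement

ORF enumeration keeps, within each stop-to-stop segment, the longest
ATG-initiated ORF. In an expanded flank this systematically overruns real
starts: any upstream in-frame ATG with no intervening stop extends the ORF,
and because the enumerated form is conditioned on that prefix being
stop-free, the prefix is biased toward coding-like composition — a pure
likelihood comparison of candidate starts under the Markov model therefore
misjudges it surprisingly often. `refine_orf_starts()` instead anchors the
decision in the homology evidence: the start moves to the in-frame ATG
nearest the 5' boundary of the aligned blocks overlapping the ORF, with
ties resolving into the supported region. The flank exists to recover
boundary codons the alignment did not reach, not to claim extra coding
sequence without evidence. For pseudo-transcripts carrying no homology
information (e.g. ORF scanning of a bare sequence), the fallback picks the
candidate start maximizing the ORF's log-odds, which under a
zero-information model reduces to the longest form. `--no-refine-starts`
disables the step.

## Parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `min_identity` | 0.9 | Minimum aligner-reported identity (inclusive). Conservative by default — high precision is the method's point; lower to 0.8 when only distant reference species are available, which admits borderline homologs at some risk of false positives. |
| `terminal_flank` | 300 bp | Outward extension of each locus before ORF search, clipped to contig bounds and never into an adjacent same-strand locus's blocks. 100 codons of slack is enough to recover a start or stop codon lying just outside the homology blocks; internal block boundaries (putative splice junctions) are never moved. |
| `min_orf_aa` | 100 aa | Minimum peptide length at enumeration and at final filtering (the long-ORF convention of TransDecoder-style scanning). Applied to peptide length, the least assembly-dependent of the candidate length measures. |
| `min_score` | 0 nats | ORF log-odds must favour coding. |
| `markov_order` | 5 | Hexamer contexts; the standard order for coding sensors, and the largest the self-training set can support. |
| `train_top_n` | 500 | Longest complete ORFs used as training positives. |
| `pseudocount` | 1 | Additive smoothing of all count tables. |
| `allow_partial` | TRUE | Report ORFs truncated by pseudo-transcript ends (`5prime_partial`, `3prime_partial`, `internal`); homology-supported genes may overhang the finite flanks. Complete ORFs outrank partials at equal score. |

Coordinates are GFF3 throughout: 1-based, inclusive, CDS phases on every
CDS row, and the stop codon included in the CDS of complete models (the
miniprot convention, so evaluation against such annotations is consistent).
Translation uses the standard nuclear code by default and any NCBI table
number via `translation_table`.

## Evaluation and statistics

`compute_stats()` reports gene count, mean CDS segments per gene, mean CDS
segment length, mean summed CDS length per gene and the ratio of mono- to
multi-exonic genes — the fragmentation diagnostics by which over-split
annotations betray themselves. CDS segments stand in for exons because
homology-derived models carry no UTRs. With no multi-exonic genes the ratio
is reported as `Inf` with a warning rather than an arbitrary large number.

`base_level_eval()` compares two annotations at the base level: a genome
base is coding on a strand when covered by at least one CDS on that strand
(bases covered on both strands count once per strand), sensitivity is the
fraction of reference coding bases recovered, specificity (precision) the
fraction of predicted coding bases that are correct, and
$F_1 = 2\,\mathrm{Sn}\,\mathrm{Sp}/(\mathrm{Sn}+\mathrm{Sp})$. The
whole-genome denominator is used — reference loci on contigs absent from
the prediction still count against sensitivity. Exon- and transcript-level
matching codes are out of scope. When nothing is predicted, specificity is
undefined and flagged rather than silently zero; when both Sn and Sp are
zero, $F_1$ is defined as 0 with a warning.

## The synthetic fixture generator

`generate_genome()` plants multi-exon genes in simulated contigs: ATG-to-stop
CDS with codons drawn from a fixed usage-biased table (so coding and
background are statistically distinguishable, as in real genomes), canonical
GT–AG introns, random strands, and at least `intergenic_min` spacing on a
GC-matched iid background. `mutate_proteins()` derives homologs by per-site
substitution at a chosen divergence, recording each realized identity, and
`simulate_alignments()` writes miniprot-style GFF3 with CDS blocks at the
truth coordinates and the realized identity (plus optional Gaussian noise)
in the `Identity` attribute. One seed drives everything; identical specs
give byte-identical files.

Defaults describe a compact vertebrate-like genome: 4–8 exons of 100–300 bp
per gene, introns of 60–500 bp, GC 0.41, ≥1 kb intergenic spacing, identity
noise sd 0.01. What the simulation does *not* emulate is equally important
for reading the test results: there are no repeats or transposons, no
pseudogenes, no alternative splicing, no alignment coordinate error (blocks
sit exactly on the truth), and no non-canonical splice sites. Passing the
planted-gene recovery checks therefore demonstrates that the pipeline's
coordinate arithmetic, ORF logic and conflict resolution are correct — not
that real-genome accuracy will be perfect, which also depends on aligner
behaviour and reference quality.

The test and acceptance problem sizes — 50 planted genes on a 500 kb contig
for recovery, 80 shorter genes (4–6 exons of 75–150 bp, so proteins of
roughly 150–250 aa) for the identity-threshold experiment at divergence
0.25 — were chosen so that each check has the statistical room it needs: at
divergence 0.25 the binomial spread of realized identities across ~200-aa
proteins is what populates the band between the 0.8 and 0.9 thresholds.

## Numerical and degenerate-input choices

* All writers are deterministic: fixed number formatting, fixed ordering
  (genes by contig, start, id), so identical runs are byte-identical.
* Ties break lexicographically or leftmost everywhere they can arise
  (longest-isoform selection, training-ORF ordering, ORF selection,
  deduplication), never by input order.
* Empty inputs: an empty alignment set warns and produces valid empty
  outputs; an empty annotation is an error for statistics (no meaningful
  means) but a flagged, defined result for evaluation.
* A projected CDS that translates with an internal stop is a hard error —
  it can only arise from a coordinate-map defect, not from biology.
* Non-ACGT genome characters survive round trips, translate to `X`, and are
  transparently skipped by the Markov tables.

## Known limitations

* Genes without homology support in the reference set cannot be found; the
  method trades recall for precision and speed by design.
* One isoform per locus: alternative transcripts are neither assembled nor
  reported, and UTRs are absent by construction.
* Splice junctions come exclusively from alignment block boundaries; the
  assembler never re-splices inside a merged block.
* The self-trained background is a coding-rich mixture, which compresses
  the log-odds scale; scores are comparable within a run but not across
  runs or species.
* Scoring ORFs against external protein databases (the natural next
  arbiter for start placement and dubious models) is out of scope.
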