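---
title: "Methods: classification, filtering and profiling of chimeric RNA call sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classification, filtering and profiling of chimeric RNA call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimerascope)
```

## The problem and the model

A split-read fusion caller applied to a large RNA-seq cohort produces one
row per predicted chimera per sample: gene symbols, genomic breakpoints
(one coordinate per parental gene), an assembled junction sequence with the
fusion point at its midpoint, a prediction score in [0, 1], and read-count
based expression estimates for the chimera and both parents. Most of these
predictions are artifacts — template switching during library construction,
multi-mapping reads, homologous loci. The package treats post-detection
cleanup as a deterministic, auditable ladder of filters followed by
descriptive classification, rather than as a statistical model: every
threshold is explicit, every stage reports `kept + removed = input`, and
the labels assigned to a chimera are functions of its breakpoint key alone.

### Coordinates and breakpoints

All coordinates are 1-based inclusive genomic positions, the convention of
the R/Bioconductor interval stack this package builds on; external formats
keep their native dialects and are converted at the I/O boundary. A
breakpoint pair is interpreted as: `pos5` = last genomic base of the 5′
segment, `pos3` = first base of the 3′ segment, each read on its parental
gene's strand. This is the dominant fusion-caller convention; the dialect
object (`call_table_dialect()`) makes the column mapping explicit and
configurable because caller output dialects differ.

### Junction classes

The donor-side role of `pos5` is `exon_end` iff it equals the
transcript-orientation 3′-most base of some exon of some transcript of the
gene (exon end on plus-strand genes, exon start on minus-strand genes); the
acceptor side mirrors this with the 5′-most base. Matching is exact by
default (`tolerance = 0`); the paper trail behind the E/M classes implies
exact coordinate classes, and a tolerance knob exists for noisy callers. A
position strictly inside an exon is `exon_middle`; anything else —
including the *non-qualifying* end of an exon — is `outside` and maps to
the M role, because the four-class scheme has no fifth category. When
transcripts disagree, `exon_end` wins: callers report junctions against
best-matching transcripts, so the permissive union over transcripts is the
faithful reading. Classification is per gene, over the union of all
annotated transcripts, since which transcript set the caller used
internally is not recoverable from its output.

### Pair classes

`inter_chromosomal` is unambiguous. `read_through` requires same
chromosome, same strand, the 5′ gene strictly upstream in transcription
direction, and an intergenic gap of at most `readthrough_max_gap`
(default 100 kb). No published quantification of "proximity" exists for
cis-splicing between adjacent genes; 100 kb covers the known cis-SAGe
pairs while excluding most same-chromosome distal events, and both the gap
and an optional no-intervening-same-strand-gene requirement are exposed in
`pair_class_config()`. Everything else — including overlapping gene spans,
which are flagged — is `intra_other`.

### Frame classes

A chimera is `in_frame` iff *some* pair of coding transcripts places both
breakpoints in CDS with a continuing codon walk:
`(phase(pos5) + 1) mod 3 == phase(pos3)`, where phase is the 0-based CDS
offset mod 3. If at least one pair has both sides coding but no pair is
compatible, it is `frame_shift`; otherwise (UTR, intron, noncoding) `na`.
The any-pair rule is the permissive convention used by fusion annotation
tools; the alternative (one canonical transcript per gene) is not
implemented because no canonical set is implied by the inputs.

### Splice motifs

Donor flag: the two bases ending at `pos5` on the 5′ gene's strand equal
`AG` and the next two equal `GT`; acceptor flag: `AG` immediately before
`pos3` and `G` at `pos3`. Evaluation is on the transcript strand of each
parental gene (reverse complement for minus-strand genes), not the raw plus
strand. Breakpoints within two bases of a contig edge get `NA` flags and
are excluded from percentage denominators.

## The filtering ladder

| stage | rule | default | boundary |
|---|---|---|---|
| score | drop score below cutoff or missing breakpoints | 0.6 | strict `<` (0.6 is kept) |
| identity | drop junctions explainable by one reference transcript | 90% identity | `>=` removes |
| ratio | drop chimera/parent expression ratio exceeding 1 | either parent | strict `>` (1 is kept) |
| non-M/M | drop junction class M/M | — | — |
| recurrence | keep frequency at least 5 | 5 | `>=` keeps |
| tissue recurrence | 2 / 3 / 5 by tissue size | ≤100 / ≤300 / >300 | closed as written |

The identity stage is the one nontrivial algorithm. The original analysis
used a genome-scale aligner with a 90% identity cutoff; here the criterion
is made precise: a call is removed iff some single reference transcript
carries a local alignment to the junction sequence with identity ≥ 0.90
that spans the junction midpoint with ≥ 10 aligned bases on each side —
i.e. the "chimeric" junction is explainable by one annotated transcript.
Candidates are found by exact 11-mer seeding; alignment is local with
match +1 / mismatch −1 / linear gap −2 (Biostrings' dynamic programming is
the engine; the seeding and the span/identity decision are this package's);
identity is matches over alignment columns. `k`, the flank minimum and the
scores are config-exposed. With these scores a spurious removal requires an
alignment that drifts ≥ 10 bases across the junction while holding 90%
identity, which is rare but not impossible on genomic flanks — a property
the synthetic generator accounts for (below).

The expression-ratio filter computes both parents' ratios (a parent at 0
with an expressed chimera yields an infinite ratio; 0/0 yields 0) and
removes on *either* parent exceeding 1 by default; `both`, `five_prime`
and `three_prime` modes exist because the source description names "this
ratio" without fixing the parent. The filter runs per call, before
deduplication; stage ordering is recorded in the pipeline manifest.

Deduplication keys a chimera by the full tuple (gene pair, chromosomes,
breakpoints, strands) — isoform resolution, not gene-pair resolution —
because distinct isoforms of the same gene pair are biologically distinct
events. Frequency counts **distinct samples**, not reads and not donors
(cohorts carry multiple samples per donor). Gene-pair collapsing is
available where database overlap needs it.

## Profiling

Presence/absence matrices are binary by construction; parental-gene
matrices binarize FPKM at ≥ 0.04, the convention of treating a parent as
expressed whenever it reaches the lowest expression observed among the
chimeras themselves. SMC is agreement over positions; its histogram uses
bins 0–0.25 ("dissimilar"), 0.25–0.6, 0.6–1 ("high similarity"),
config-exposed. Tissue-specific chimeras use the strict definition —
recurrent in one tissue and detected in zero samples elsewhere — with a
relaxed `strict = FALSE` alternative (recurrent in exactly one tissue);
the strict reading is the declared default because "specific" claims
should survive single stray detections only by explicit choice. All
matrices and exports are ordered lexicographically so that re-export is
byte-identical.

## Chimeric peptides

Flanks default to 200 bp per side, *genomic* (unspliced) windows, matching
the plain reading of "200 bp upstream and downstream from the breakpoint";
a `spliced` mode that walks exons is provided because breakpoints within
200 bp of an exon boundary make the two readings differ, and which one the
original analysis used is not stated. Translation is three-frame with the
standard code (stops as segment separators, N-containing codons as X);
digestion is tryptic with the proline rule (no cleavage of K/R–P bonds,
the default of standard digestion tools; a flag disables it) and zero
missed cleavages by default (0–2 supported). Per frame, at most one
fragment can span the junction (fragments partition the segment); it is
retained iff it has at least two residues whose codons lie entirely on
each side of the junction boundary. A residue whose codon straddles the
boundary belongs to neither side. PSM acceptance is `q < 0.05` strict with
the same two-residue side minimum; the reference-proteome screen searches
each peptide's fully-5′ and fully-3′ halves as exact substrings.

## Database overlap and normal baseline

Gene-pair matching is ordered (5′/3′ preserved) by default with an
unordered flag, since pair conventions vary across fusion databases; match
provenance records which mode fired. Symbol normalization is uppercase
plus an optional user alias table — no live symbol-service lookups, to
keep runs reproducible offline. Exact-breakpoint matching maps database
mRNA coordinates to genomic positions through the annotated transcript
(`mrna_to_genomic`), and skips (counting them) records whose transcript is
absent from the user's annotation. Eliminated fractions are reported at
one decimal with round-half-even so printed percentages are reproducible.

## The synthetic generator

`make_universe()` lays out random-sequence chromosomes with multi-exon
genes (5–7 exons; 5′UTR, CDS and 3′UTR, CDS divisible by 3), reserving
five adjacent same-strand pairs per chromosome with 3–8 kb gaps as
read-through candidates and spacing all other neighbours beyond 100 kb so
proximity never misclassifies them. `simulate_calls()` plants chimeras
realizing a configured junction × pair × frame class mix by constructing
breakpoints that are unambiguous for the classifiers: E breakpoints at
exon ends, M breakpoints strictly inside exons with a margin, frame
compatibility enforced through candidate phases, frame-NA through UTR
placements. Motif flags are realized by editing the genome around each
breakpoint (writing the canonical context or an anti-motif), with an edit
registry preventing overlapping writes; per-class motif rates default to
the magnitudes reported for large normal cohorts (donor/acceptor: EE
0.42/0.425, EM 0.155/0.10, ME 0.06/0.348, MM 0.017/0.094). Decoys are
100-nt windows copied verbatim from reference transcripts. Because a
genuine chimera's genomic flank can, by chance, extend across the junction
at ≥ 90% identity against a parental transcript, placements that trip the
identity criterion are rejected and re-drawn — the generator's mandate is
unambiguous ground truth, so ambiguity is removed at construction time,
not by weakening the filter.

The default cohort is four tissues of 50, 150, 350 and 20 samples, chosen
to exercise every tissue-recurrence threshold branch. Ten percent of
planted chimeras draw scores below 0.6, ten percent have blank
breakpoints, ten percent violate the ratio bound; recurrence plans give
E/E and read-through chimeras higher sample support so class enrichment
across ladder stages mirrors real cohorts qualitatively. Parental FPKM
profiles are broadly expressed (90% prevalence) and independent of chimera
presence by default, which reproduces the observation that chimera
presence profiles are mostly dissimilar (SMC < 0.25) from parental
expression profiles; `matched` and `anti` profiles exist for targeted
tests.

What the generator does **not** emulate: read-level noise (no FASTQ),
sequence homology between genes (the genome is i.i.d. random, so the
identity filter's hard cases — paralogues — are absent), annotation
ambiguity (one transcript per gene unless fixtures add more), and
realistic expression distributions. Passing end-to-end recovery on this
universe therefore demonstrates correctness of the bookkeeping,
coordinate arithmetic and decision rules, not robustness to the
biological confounders of real data.

## Statistics

The 3′UTR comparison uses the Wilcoxon rank-sum test through the standard
`wilcox.test` implementation (normal approximation with continuity and tie
corrections; exact distribution for combined n < 20 without ties), with
gene-level 3′UTR length defined as the maximum over coding transcripts —
stable under annotation subsetting, unlike the mean. Chromosome-level
gene-count correlation is Pearson's r (the claim being linearity of counts,
not rank agreement), with degenerate inputs flagged rather than coerced.
Empirical CDFs of chimera/parent expression ratios are evaluated on a
fixed 0–1 grid (step 0.05), aggregating per unique chimera by the maximum
supporting call (mean and median available).

## Problem sizes and numerical choices

The test suite runs the full ladder on a small preset (60 planted chimeras
+ 10 decoys) and the acceptance script on the reference preset (300 + 40)
— sizes at which every recovery check is exhaustive and a complete run
takes about two minutes. Determinism is treated as a feature throughout:
seeds fix every draw (the generator evaluates its inputs before seeding,
so argument evaluation order cannot perturb the stream), matrices and
exports sort their keys, and percentage rounding is round-half-even.

## Known limitations

- The identity filter checks the single best local alignment per candidate
  transcript; a suboptimal alignment that satisfies the span/identity
  criterion while the optimal one does not would be missed. With linear
  gap penalties this requires contrived inputs.
- Frame prediction ignores the junction codon itself when frames are
  incompatible mid-codon; it classifies phase compatibility, not peptide
  identity.
- `mrna_to_genomic` trusts the database's transcript version; coordinate
  drift between annotation releases surfaces only as skipped records.
- The spliced flank mode selects the longest transcript containing the
  breakpoint; with deeply nested transcript models a shorter isoform might
  be the biologically correct context.
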