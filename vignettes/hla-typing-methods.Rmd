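---
title: "Predicting HLA class I alleles from shotgun reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting HLA class I alleles from shotgun reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shotgunHLA)
```

## The problem

The HLA class I genes (HLA-A, -B, -C) are the most polymorphic loci in the
human genome, with thousands of catalogued allelic sequences. Standard
reference-based read alignment cannot genotype them from shotgun sequencing
(RNA-Seq, whole-genome, exome) because a single linear reference carries no
representation of that allelic diversity. `shotgunHLA` predicts class I
alleles directly from shotgun reads by *targeted assembly*: it pulls out the
small fraction of reads that look like HLA sequence, assembles them de novo,
and lets the assembled contigs vote among the reference alleles.

HLA nomenclature drives the reporting resolution: in `A*02:01` the field
after the asterisk is the **allele group** (two-digit resolution) and the
next field the **protein-coding allele** (four-digit resolution). A trailing
`P` marks a P group (alleles identical over the antigen-recognition exons);
a trailing `N` marks a null (unexpressed) allele.

## The prediction pipeline

1. **Recruitment.** Every k-length word (default k = 15) of every reference
   allele is hashed. A read is recruited iff its first k bases — or the
   first k bases of its reverse complement — occur in that hash. The
   5'-terminal-word rule is deliberately stringent: it keeps the recruited
   set small and specific at the cost of missing some reads whose HLA
   content starts mid-read. An `internal = TRUE` option relaxes this for
   sensitivity experiments.

2. **Assembly.** Recruited reads are assembled greedily: seeds are taken in
   decreasing order of read multiplicity; a contig is extended at its 3' end
   by the unused read with the longest *exact* suffix–prefix overlap of at
   least `min_overlap` (default 20 nt), then symmetrically at the 5' end.
   Ties break by higher multiplicity, then lexicographic read id, making
   assembly fully deterministic and order-invariant. Reads contained in a
   finished contig are consumed by it; the contig's **depth** is the sum of
   constituent read lengths divided by contig length. Only contigs of at
   least `min_contig` (default 200 nt) survive. Substitution errors are
   tolerated implicitly — an erroneous read simply loses extension
   priority — while indel errors are left to the alignment stage.

3. **Reciprocal alignment.** Each contig is aligned locally (affine-gap
   Smith–Waterman: match +2, mismatch −3, gap open 5, gap extend 2) against
   every allele, keeping all *ex-equo* best hits; each candidate allele is
   aligned back against all contigs to find its own best contig(s). A pair
   that is best in both directions is a **reciprocal best hit**. Alignment
   is delegated to `Biostrings::pairwiseAlignment`; an independent
   full-matrix Gotoh implementation (`local_align_score_ref`) exists solely
   to validate it. As an optimisation, alleles sharing no exact 15-mer with
   a contig are skipped (they cannot tie the best local score in this
   setting); when nothing shares a word, the full scan is used.

4. **Scoring.** A contig supporting allele *x* contributes
   `length × depth × identity` (identity as a fraction over the aligned
   portion, so the score approximates the number of read bases supporting
   the allele), doubled for a reciprocal best hit. The allele score `S_HLA`
   is the sum over supporting contigs. The chance probability that a contig
   characterises one specific allele is `1/N` for a database of `N`
   alleles; a tie across `t` alleles gives the mutually exclusive sum
   `t/N`. The **expect value** multiplies, over supporting contigs, the
   forward probability with a reciprocal-direction analogue, treating
   contigs as independent; **confidence** is `−10·log10(Eval)`. Expect
   values are accumulated in log space so that hundreds of supporting items
   (as in direct-alignment mode) cannot underflow.

5. **Ranking.** Per gene, protein alleles are grouped under their allele
   group; the two top-scoring groups are reported (the diploid expectation;
   configurable). When several contigs characterise a group, the alleles
   common to all of their candidate sets are kept, plus any allele that is
   the unique best of some contig — candidates supported by no contig
   intersection and no distinct contig are dropped. Alleles tying exactly in
   `(S_HLA, Eval)` form an **ambiguity set**, listed together in
   lexicographic order. Null alleles are suppressed unless requested.

### Direct-alignment mode

Reads aligned to the allele FASTA (SAM input) can replace assembly: each
mapped read acts as a degenerate contig (length = aligned length, depth = 1,
identity from the `NM` edit distance), multi-mapping reads contribute tie
probabilities, and scoring/ranking proceed unchanged (without reciprocal
doubling, which has no analogue for single reads). This mode exists for
completeness; with current read lengths it is the weaker of the two.

## Design decisions on under-determined points

Several details of the published procedure are not fully specified; the
package fixes them as follows.

* **Reciprocal-direction probability.** The forward probability has the
  natural denominator `N` (alleles). For the reverse direction the package
  uses `(reciprocal tie multiplicity) / n`, where `n` is the number of
  contigs assigned to the allele's gene, falling back to `1/n` for
  non-reciprocal supporting pairs. This keeps the two directions formally
  analogous (tie multiplicity over the size of the pool being identified).
* **Seed choice and tie-breaks.** Seeding by decreasing multiplicity and
  breaking extension ties by multiplicity, then id, are choices made purely
  to guarantee determinism; the underlying greedy strategy does not define
  them.
* **Floor score.** Contigs whose best alignment scores below 40 (roughly a
  20-base perfect match) are treated as unaligned, as are multi-way ties
  exactly at the floor.
* **Minimum overlap 20.** A conservative exact-overlap threshold for
  100-nt-class reads; configurable.
* **Identity scale.** Identity enters the score as a fraction (0–1), not a
  percentage — required for the magnitudes the score is meant to have
  (length × depth × fraction).

## The simulation benchmark

The spike-in design measures recovery of known alleles. The generator
builds, per gene, a random ancestor and 15 alleles in 5 groups of 3: group
consensus sequences diverge pairwise by ~2% (the scale of real inter-group
distances over the hypervariable exons), and within-group alleles differ by
one or two bases — reproducing the feature that makes four-digit typing
hard, namely protein alleles separated by single substitutions, including
some invisible inside exons 2–3. One allele carries the null suffix `N`.
Benchmarks run on the exon 2+3 concatenated database (~546 nt per allele),
the RNA-Seq-style target unit.

Each benchmark sample draws two alleles per gene (heterozygous by default
in the benchmark harness, since distinct spiked alleles are what the
recovery question is about; the generator itself also supports draws with
replacement, i.e. homozygous samples). Reads are simulated wgsim-style:
fragments of Normal(insert, sd) length, uniform placement, paired 100-nt
reads (or 50–150 in sweeps), independent per-base substitutions at the
requested rate, no indels (the substitution-only regime of the usual
short-read simulators at 0.5–3% error). An HLA-free background — random
sequences scrubbed of any exact 15-mer shared with the database — emulates
the transcriptome bulk; its reads can never be recruited, which the test
suite verifies exhaustively.

Null alleles are excluded from the spiked truth by default: the benchmark
emulates expressed transcripts, and null alleles are transcriptionally
silent (their confounding role belongs to genome/exome data).

**Problem sizes.** The bundled benchmark uses 15 alleles per gene, 20
samples at the reference condition (100 nt, 1% error, 30× per-allele
coverage) and 5 samples × 2 replicates per point in the read-length sweep
{50, 75, 100, 150}. These sizes were chosen so the whole benchmark runs on
a laptop in minutes while keeping ~100–120 distinct truth items per
condition, enough to resolve the trends of interest (sensitivity rising
steeply between 50 and 100 nt; four-digit ambiguity far above two-digit
ambiguity).

### Metrics

With `detected` = distinct truth groups/alleles matched by any reported
prediction, `accurate` = predictions matching truth, and ambiguous
predictions = reported sets in which distinct names share an identical
score and expect value:

* sensitivity = detected / distinct truth chosen,
* specificity = accurate / detected,
* ambiguity = ambiguous predictions / total predictions,

all as percentages. The specificity definition is kept exactly as
published (accurate over *detected*, not over predicted) — an asymmetry
preserved deliberately. At four-digit resolution, P-designated names match
their protein allele (`A*02:01P` ≡ `A*02:01`), and a homozygous truth pair
counts once in the denominator ("distinct"). A truth allele counts as
detected if it appears in any reported slot.

## What the simulations do and do not show

The generator reproduces the *structure* that drives difficulty — many
near-identical alleles, single-base siblings, diploid mixtures, background
dilution, substitution errors — but not everything about real data: allele
databases three orders of magnitude larger (N ≈ 2,000–5,000, which shrinks
every chance probability and stretches confidences), expression imbalance
between haplotypes, coverage unevenness, PCR duplicates, quality decay and
indel errors are all absent. Passing benchmarks here demonstrates that the
method's machinery is implemented correctly and behaves with the right
trends, not that a particular accuracy will be attained on a given cohort.

## Numerical and degenerate-input choices

* Expect values are computed as sums of `log10` factors; `Eval` is
  materialised as `10^log10` only for display.
* Score ties anywhere use an absolute tolerance of 1e-9.
* Reads shorter than k are skipped and counted; reads shorter than
  `min_overlap + 1` cannot extend anything and are dropped by the
  assembler; templates shorter than the read length are skipped with a
  warning by the simulator.
* Empty read sets, empty contig sets and genes without evidence all
  propagate cleanly to empty (zero-row) predictions rather than errors.

## Known limitations

* Class II genes are out of scope; the nomenclature parser is generic, but
  recruitment/scoring have only been exercised on class I style databases.
* Haplotype-frequency or linkage-based reweighting of candidate pairs is
  not implemented.
* The assembler is substitution-tolerant but has no indel handling inside
  contig extension.
* P-group collapsing relies on P markers present in the input names (or an
  optional two-column mapping table); without either, alleles identical
  over the target region simply surface as ambiguity sets.
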