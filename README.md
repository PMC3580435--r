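# shotgunHLA

Predicts HLA class I alleles (genes A, B, C) directly from shotgun
sequencing reads — RNA-Seq, whole-genome or exome — with no HLA-targeted
amplification. It is aimed at anyone holding shotgun data who wants HLA
types as a by-product: immunogenomics analyses, donor–recipient matching
screens, retrospective typing of sequenced cohorts.

## Method

Standard alignment to a linear reference cannot genotype the HLA loci: the
reference carries none of their allelic diversity. `shotgunHLA` instead
runs a targeted-assembly pipeline against a reference allele database
(e.g. IMGT/HLA coding, exon 2+3, or genomic sequences):

1. **Recruit** reads whose 5'-terminal 15-mer (either strand) occurs among
   the k-mers of the allele database.
2. **Assemble** recruited reads into contigs by greedy exact-overlap
   extension (deterministic tie-breaking), keeping contigs ≥ 200 nt with
   their mean read depth.
3. **Align reciprocally**: each contig against every allele (affine-gap
   local alignment; all ex-equo best hits kept) and each candidate allele
   back against the contigs; a pair best in both directions is a
   reciprocal best hit.
4. **Score and rank.** Each supporting contig contributes
   `Score_contig = length × depth × identity` (doubled for reciprocal best
   hits) and `S_HLA = Σ Score_contig`. Chance support is quantified by an
   expect value `Eval = Π (P_contig_is_allele × P_allele_is_contig)` over
   supporting contigs, with `P_contig_is_allele = |tie set| / N` for a
   database of N alleles, and reported as a confidence
   `−10·log10(Eval)`. Per gene, the two top-scoring allele groups
   (two-digit resolution, e.g. `A*02`) are reported with their best
   protein-coding alleles (four-digit, e.g. `A*02:01`); alleles with
   identical score and Eval form ambiguity sets.

A direct-alignment mode (`predict-sam`) consumes SAM records against the
allele FASTA instead of assembling, treating each mapped read as a
depth-1 contig.

The package also ships the full simulation benchmark: a miniature
allele-database generator with known truth, an HLA-free background
generator, a wgsim-style paired-end read simulator, and sensitivity /
specificity / ambiguity metrics at both resolutions.

## Worked example

Simulate one heterozygous sample from a generated 45-allele database
(15 per gene, exon 2+3 targets) and type it:

```r
library(shotgunHLA)

fx <- make_fixture_db(n_per_gene = 15, divergence = 0.02, seed = 7)
db <- fx$exon23_db
picks <- c("A*01:01", "A*03:01", "B*02:01", "B*04:02", "C*01:01", "C*05:01")
tpl <- setNames(as.character(db$seq[picks]), picks)
sim <- simulate_reads(tpl, n_pairs = ceiling(30 * sum(nchar(tpl)) / 200),
                      read_length = 100, error_rate = 0.01, seed = 42)
run <- run_pipeline(db, reads = sim, mode = "assembly")
run$predictions
```

```
HLA-A
  Prediction 1 - A*03
    A*03:01            16592.14  2.96E-30  295.3
    A*03:02            16592.14  2.96E-30  295.3
  Prediction 2 - A*01
    A*01:01             9565.75  1.32E-38  378.8
HLA-B
  Prediction 1 - B*04
    B*04:01            22879.48  1.73E-31  307.6
    B*04:02            22879.48  1.73E-31  307.6
  Prediction 2 - B*02
    B*02:01             6688.90  3.89E-22  214.1
HLA-C
  Prediction 1 - C*01
    C*01:01            10563.80  9.92E-28  270.0
    C*01:02            10563.80  9.92E-28  270.0
    C*01:03            10563.80  9.92E-28  270.0
  Prediction 2 - C*05
    C*05:01             7320.98  8.96E-22  210.5
    C*05:02             7320.98  8.96E-22  210.5
```

Every spiked allele group is recovered in a prediction slot (columns:
allele, `S_HLA` score, expect value, confidence). Rows sharing one slot
with identical score/Eval are ambiguity sets: the simulated 100-nt reads
cannot separate protein alleles whose single-base differences fall outside
the assembled or exonic region — the characteristic four-digit ambiguity
of short-read HLA typing. Scoring against truth:

```r
evaluate(run$predictions, picks, "two_digit")[, 2:4]
#>   sensitivity specificity ambiguity
#> 1         100         100         0
```

A shell wrapper with `predict`, `predict-sam`, `simulate` and `benchmark`
subcommands is installed at `inst/cli/shotgunHLA.R`.

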