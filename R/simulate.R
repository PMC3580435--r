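.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_positions <- function(seq, pos) {
  if (length(pos) == 0L) return(seq)
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(seq, "")[[1L]]
  for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate a miniature reference allele database with known truth
#'
#' Builds, per gene (A, B, C), a random ancestor coding-like sequence and a
#' set of derived alleles organised into allele groups: group consensus
#' sequences diverge from the ancestor so that the expected pairwise
#' divergence between groups is `divergence`, and protein alleles within a
#' group differ from the consensus by one or two point substitutions (so some
#' allele pairs differ by exactly one base, mirroring real protein alleles).
#' The last allele of gene A carries the null suffix `N`. Exon 2 and exon 3
#' coordinates are fixed on every allele, enabling exon-concatenated
#' (RNA-Seq-style) target databases; the generator records the full truth
#' (ancestors, per-allele mutation lists, exon coordinates and exon 2+3
#' sequences).
#'
#' The generator is fully deterministic under `seed`.
#'
#' @param n_per_gene Alleles per gene (>= 2; default 15 = 5 groups x 3).
#' @param divergence Expected pairwise divergence between allele groups
#'   (fraction; must be < 0.2).
#' @param seed Integer RNG seed.
#' @param anc_len Ancestor (CDS-like) length in nt.
#' @return List of class `hla_fixture`: `db` (`hla_ref_db` of kind `"cds"`),
#'   `exon23_db` (`hla_ref_db` of kind `"exon23"`), `exons` (coordinates),
#'   `truth` (ancestors and per-allele mutation positions).
#' @export
make_fixture_db <- function(n_per_gene = 15L, divergence = 0.02, seed = 1L,
                            anc_len = 1101L) {
  if (n_per_gene < 2L) stop("need at least 2 alleles per gene")
  if (divergence >= 0.2) stop("divergence >= 0.2 is unrealistic")
  set.seed(seed)
  exons <- data.frame(number = 2:3, start = c(274L, 544L),
                      end = c(543L, 819L))
  genes <- c("A", "B", "C")
  seqs <- character()
  truth <- list(ancestors = list(), mutations = list())
  for (g in genes) {
    anc <- .rand_dna(anc_len)
    truth$ancestors[[g]] <- anc
    n_groups <- ceiling(n_per_gene / 3)
    made <- 0L
    for (gi in seq_len(n_groups)) {
      n_mut <- max(1L, round(anc_len * divergence / 2))
      gpos <- sort(sample(anc_len, n_mut))
      consensus <- .mutate_positions(anc, gpos)
      n_in_group <- min(3L, n_per_gene - made)
      for (ai in seq_len(n_in_group)) {
        extra <- if (ai == 1L) integer(0)
                 else sort(sample(setdiff(seq_len(anc_len), gpos), ai - 1L))
        s <- .mutate_positions(consensus, extra)
        nm <- sprintf("%s*%02d:%02d", g, gi, ai)
        made <- made + 1L
        if (g == "A" && made == n_per_gene) nm <- paste0(nm, "N")
        seqs[[nm]] <- s
        truth$mutations[[nm]] <- list(group_positions = gpos,
                                      extra_positions = extra)
      }
    }
  }
  db <- .new_ref_db(Biostrings::DNAStringSet(seqs), "cds")
  ex23 <- vapply(seqs, function(s)
    paste0(substring(s, exons$start, exons$end), collapse = ""), "")
  exon23_db <- .new_ref_db(Biostrings::DNAStringSet(ex23), "exon23")
  structure(list(db = db, exon23_db = exon23_db, exons = exons,
                 truth = truth),
            class = "hla_fixture")
}

# map a CDS coordinate onto the exon-concatenated coordinate system
# (NA when the position falls outside the requested exons)
.cds_to_exon23 <- function(pos, exons) {
  exons <- exons[order(exons$number), , drop = FALSE]
  off <- 0L
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(exons))) {
    inside <- pos >= exons$start[i] & pos <= exons$end[i]
    out[inside] <- off + pos[inside] - exons$start[i] + 1L
    off <- off + exons$end[i] - exons$start[i] + 1L
  }
  out
}

#' Write a fixture as an EMBL-style flat file
#'
#' Emits the minimal ID / FT exon / SQ record structure consumed by
#' [read_embl_exons()], for round-trip testing of exon extraction.
#'
#' @param fixture An `hla_fixture`.
#' @param path Output path.
#' @param drop_exon3_for Allele names whose exon 3 feature is omitted (to
#'   exercise the skip-with-warning path).
#' @export
write_fixture_flatfile <- function(fixture, path, drop_exon3_for = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(fixture$db$seq)) {
    s <- as.character(fixture$db$seq[[match(nm, names(fixture$db$seq))]])
    writeLines(sprintf("ID   %s; SV 1; linear; DNA; STD; HUM; %d BP.",
                       nm, nchar(s)), con)
    for (i in seq_len(nrow(fixture$exons))) {
      if (fixture$exons$number[i] == 3L && nm %in% drop_exon3_for) next
      writeLines(sprintf("FT   exon            %d..%d",
                         fixture$exons$start[i], fixture$exons$end[i]), con)
      writeLines(sprintf("FT                   /number=%d",
                         fixture$exons$number[i]), con)
    }
    writeLines(sprintf("SQ   Sequence %d BP;", nchar(s)), con)
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(paste0("     ", substring(s, starts,
                                         pmin(starts + 59L, nchar(s)))), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Generate an HLA-free background
#'
#' Random nucleotide sequences guaranteed to share no exact 15-mer (length
#' `k`) with the reference database: shared words are repaired by
#' re-substituting their central base until none remain. Emulates a
#' transcriptome/exome/genome background from which HLA content has been
#' removed, so background reads are never recruited.
#'
#' @param db `hla_ref_db` whose k-mers must be avoided.
#' @param n_seqs Number of background sequences.
#' @param mean_length Mean sequence length (nt); lengths vary ~20% around it.
#' @param k Word size to exclude (match the recruitment k).
#' @param seed Integer RNG seed.
#' @return Named `DNAStringSet`.
#' @export
make_background <- function(db, n_seqs = 100L, mean_length = 2000L,
                            k = 15L, seed = 1L) {
  set.seed(seed)
  if (n_seqs == 0L) return(Biostrings::DNAStringSet())
  forbidden <- build_kmer_index(db, k)$members
  lens <- pmax(10L * k, round(stats::rnorm(n_seqs, mean_length,
                                           0.2 * mean_length)))
  seqs <- vapply(lens, .rand_dna, "")
  for (i in seq_along(seqs)) {
    for (iter in 1:20) {
      s <- seqs[i]
      n <- nchar(s)
      words <- substring(s, 1:(n - k + 1L), k:n)
      bad <- which(words %in% forbidden)
      if (length(bad) == 0L) break
      ch <- strsplit(s, "")[[1L]]
      for (b in bad) {
        p <- b + k %/% 2L
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      }
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("bg%05d", seq_len(n_seqs))
  out
}

#' Draw spike-in truth sets
#'
#' Draws, per sample, two alleles for each of genes A, B and C (the diploid
#' design: 2xA, 2xB, 2xC). Draws are uniform within gene, with replacement by
#' default (duplicates give homozygous samples); `replace = FALSE` forces
#' heterozygous samples. Null alleles are excluded by default, emulating
#' expressed (RNA-Seq-visible) alleles.
#'
#' @param db `hla_ref_db`.
#' @param n_sets Number of samples (default 20).
#' @param seed Integer RNG seed.
#' @param replace Draw with replacement within gene.
#' @param exclude_null Exclude null (N-suffix) alleles from the draw.
#' @return data.frame of class `hla_truth` with columns `sample`, `gene`,
#'   `allele`.
#' @export
choose_allele_sets <- function(db, n_sets = 20L, seed = 1L, replace = TRUE,
                               exclude_null = TRUE) {
  set.seed(seed)
  nm <- names(db$seq)
  if (exclude_null) nm <- nm[!is_null_allele(nm)]
  genes <- parse_allele_name(nm)$gene
  rows <- list()
  for (s in seq_len(n_sets)) {
    for (g in c("A", "B", "C")) {
      pool <- nm[genes == g]
      if (length(pool) < 2L) stop("gene ", g, " absent (or <2 alleles) in db")
      drawn <- sample(pool, 2L, replace = replace)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene = g, allele = drawn, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hla_truth", "data.frame")
  out
}

#' Simulate substitution-error paired-end reads
#'
#' wgsim-style fragment simulation: fragments are drawn along the templates
#' (template chosen with probability proportional to length times its
#' abundance weight, start uniform), fragment length Normal(`insert_mean`,
#' `insert_sd`) clamped to `[read_length, template length]`; read 1 is the
#' fragment 5' end on the plus strand, read 2 the reverse complement of the
#' fragment 3' end. Each base is substituted independently with probability
#' `error_rate`, uniformly among the three alternatives. No indel errors are
#' introduced. Deterministic under `seed`.
#'
#' @param templates Named character vector or `DNAStringSet`.
#' @param n_pairs Number of read pairs.
#' @param read_length Read length in nt (paper range 50-150).
#' @param error_rate Per-base substitution probability (< 0.25).
#' @param insert_mean,insert_sd Fragment length model (nt).
#' @param weights Optional per-template abundance multipliers (default 1).
#' @param seed Integer RNG seed.
#' @return List of class `sim_reads`: `read1`, `read2` (named character
#'   vectors; ids carry template and pair index).
#' @export
simulate_reads <- function(templates, n_pairs, read_length = 100L,
                           error_rate = 0.01, insert_mean = 300L,
                           insert_sd = 30L, weights = NULL, seed = 1L) {
  if (inherits(templates, "DNAStringSet"))
    templates <- stats::setNames(as.character(templates), names(templates))
  if (error_rate < 0 || error_rate >= 0.25)
    stop("error_rate must be in [0, 0.25)")
  if (read_length > insert_mean)
    stop("read_length must not exceed insert_mean")
  set.seed(seed)
  lens <- nchar(templates)
  short <- lens < read_length
  if (any(short)) {
    warning(sum(short), " template(s) shorter than the read length skipped")
    templates <- templates[!short]; lens <- lens[!short]
  }
  if (length(templates) == 0L) stop("no usable templates")
  if (is.null(weights)) weights <- rep(1, length(templates))
  prob <- lens * weights / sum(lens * weights)

  ti <- sample(length(templates), n_pairs, replace = TRUE, prob = prob)
  frag <- pmin(pmax(round(stats::rnorm(n_pairs, insert_mean, insert_sd)),
                    read_length), lens[ti])
  start <- 1L + floor(stats::runif(n_pairs) * (lens[ti] - frag + 1L))
  fragseq <- substr(templates[ti], start, start + frag - 1L)
  r1 <- substr(fragseq, 1L, read_length)
  r2 <- .revcomp_chr(substr(fragseq, frag - read_length + 1L, frag))

  add_err <- function(rds) {
    nerr <- integer(length(rds))
    if (error_rate == 0)
      return(list(reads = rds, nerr = nerr))
    bases <- c("A", "C", "G", "T")
    for (i in seq_along(rds)) {
      hit <- which(stats::runif(read_length) < error_rate)
      if (length(hit)) {
        ch <- strsplit(rds[i], "")[[1L]]
        for (p in hit) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
        rds[i] <- paste(ch, collapse = "")
        nerr[i] <- length(hit)
      }
    }
    list(reads = rds, nerr = nerr)
  }
  e1 <- add_err(r1); e2 <- add_err(r2)
  r1 <- e1$reads; r2 <- e2$reads
  ids <- sprintf("%s_%06d", names(templates)[ti], seq_len(n_pairs))
  names(r1) <- paste0(ids, "/1")
  names(r2) <- paste0(ids, "/2")
  truth <- data.frame(id = ids, template = names(templates)[ti],
                      start1 = start, start2 = start + frag - read_length,
                      nerr1 = e1$nerr, nerr2 = e2$nerr,
                      stringsAsFactors = FALSE)
  structure(list(read1 = r1, read2 = r2, truth = truth),
            class = "sim_reads")
}

#' Write simulated reads as FASTQ
#'
#' Fixed base qualities; gzip-transparent (use a `.gz` suffix to compress).
#'
#' @param reads A `sim_reads` list.
#' @param prefix Output prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return The two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix) {
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  x1 <- Biostrings::DNAStringSet(unname(reads$read1))
  names(x1) <- names(reads$read1)
  x2 <- Biostrings::DNAStringSet(unname(reads$read2))
  names(x2) <- names(reads$read2)
  Biostrings::writeXStringSet(x1, p1, format = "fastq")
  Biostrings::writeXStringSet(x2, p2, format = "fastq")
  invisible(c(p1, p2))
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path (gzip-transparent).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Write simulated reads as SAM against their source templates
#'
#' Emits one alignment record per read using the simulator's own truth
#' (source template, coordinates and substitution counts are recorded at
#' simulation time), with `NM` set to the number of substituted bases. This
#' produces a synthetic alignment input for the direct-alignment prediction
#' mode without requiring an external aligner; it represents an idealised
#' aligner that always places each read at its true origin.
#'
#' @param reads A `sim_reads` list produced by [simulate_reads()].
#' @param templates The same templates passed to the simulator.
#' @param path Output SAM path.
#' @export
write_truth_sam <- function(reads, templates, path) {
  if (inherits(templates, "DNAStringSet"))
    templates <- stats::setNames(as.character(templates), names(templates))
  tr <- reads$truth
  if (is.null(tr)) stop("reads carry no simulation truth")
  rl <- nchar(reads$read1[[1L]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(templates))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(templates[nm])), con)
  qual <- strrep("I", rl)
  # read 1 maps forward at start1; read 2 is the reverse complement of the
  # fragment 3' end, so its reference-strand sequence is the revcomp
  l1 <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                paste0(tr$id, "/1"), tr$template, tr$start1, rl, unname(reads$read1),
                qual, tr$nerr1)
  l2 <- sprintf("%s\t16\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                paste0(tr$id, "/2"), tr$template, tr$start2, rl,
                .revcomp_chr(unname(reads$read2)), qual, tr$nerr2)
  writeLines(c(l1, l2), con)
  invisible(path)
}
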