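#' Score of one contig for one allele
#'
#' The contribution of a contig to an allele's total score is
#' `length x depth x identity`, where identity is the fraction of identical
#' bases over the aligned portion (0-1 scale), so that the score reflects the
#' number of read bases supporting the allele. A reciprocal best hit — the
#' allele also aligns best to this contig — doubles the contribution.
#'
#' @param length Contig length (nt).
#' @param depth Contig mean depth of coverage (> 0).
#' @param identity Fractional sequence identity over the aligned portion.
#' @param reciprocal Logical; reciprocal best hit doubles the score.
#' @return Numeric score.
#' @examples
#' contig_score(200, 10, 1.0)            # 2000
#' contig_score(200, 10, 1.0, TRUE)      # 4000
#' @export
contig_score <- function(length, depth, identity, reciprocal = FALSE) {
  if (any(depth <= 0)) stop("contig depth must be positive")
  length * depth * identity * ifelse(reciprocal, 2, 1)
}

#' Chance probability that a contig characterises an allele
#'
#' The probability of characterising a single allele by chance is the inverse
#' of the number of alleles in the reference database (1/N). A contig whose
#' best hits tie across several alleles characterises one OR another of them,
#' mutually exclusively, so the probability is summed over the ex-equo set:
#' `|best set| / N`.
#'
#' @param n_best Size of the ex-equo best-hit set containing the allele.
#' @param N Total allele count of the reference database.
#' @return Probability in (0, 1].
#' @examples
#' contig_probability(1, 100)  # 0.01
#' contig_probability(3, 100)  # 0.03
#' @export
contig_probability <- function(n_best, N) {
  if (any(N == 0)) stop("reference database is empty (N = 0)")
  if (any(n_best < 1)) stop("best-hit set must be non-empty")
  n_best / N
}

#' Expect value of an allele's contig support
#'
#' Individual contig probabilities and reciprocal best hits are treated as
#' independent events, so the expect value is the product over supporting
#' contigs of `(P_contig_is_allele x P_allele_is_contig)`. Contigs that do
#' not support the allele contribute no factor.
#'
#' @param p_contig_is_allele Numeric vector of forward-direction
#'   probabilities, one per supporting contig.
#' @param p_allele_is_contig Numeric vector of reciprocal-direction
#'   probabilities, same length.
#' @return The expect value (product of the per-contig probability pairs).
#' @examples
#' expect_value(0.01, 0.01)               # 1e-4
#' expect_value(c(0.01, 0.01), c(0.01, 0.01))  # 1e-8
#' @export
expect_value <- function(p_contig_is_allele, p_allele_is_contig) {
  stopifnot(length(p_contig_is_allele) == length(p_allele_is_contig),
            length(p_contig_is_allele) >= 1L)
  if (any(p_contig_is_allele <= 0) || any(p_allele_is_contig <= 0))
    stop("probabilities must be positive")
  prod(p_contig_is_allele * p_allele_is_contig)
}

#' Confidence of a prediction
#'
#' `-10 * log10(Eval)`, the expect value on a Phred-like log scale; reported
#' to one decimal in text output.
#'
#' @param eval Expect value in (0, 1].
#' @return Numeric confidence (>= 0 for Eval <= 1).
#' @examples
#' round(confidence(1.63e-06), 1)  # 57.9
#' @export
confidence <- function(eval) {
  if (any(eval <= 0)) stop("Eval must be positive")
  -10 * log10(eval)
}

#' Accumulate per-allele evidence from contig alignments
#'
#' Runs best-hit and reciprocal-best alignments for every contig against the
#' reference database and accumulates, per allele: the summed contig score
#' `S_HLA`, the expect value (computed in log space for numerical safety)
#' and the confidence.
#'
#' @param contigs `hla_contigs` data.frame.
#' @param db `hla_ref_db`.
#' @param scoring [scoring_params()].
#' @param floor Best-hit floor score (see [best_hits()]).
#' @return List of class `hla_evidence`: `pairs` (one row per supporting
#'   contig-allele pair, with scores, probabilities and reciprocal flags) and
#'   `alleles` (one row per allele with `S_HLA`, `Eval`, `log10_eval`,
#'   `confidence`, `n_contigs`).
#' @export
score_alleles <- function(contigs, db, scoring = scoring_params(),
                          floor = 40) {
  empty <- structure(list(
    pairs = data.frame(), alleles = data.frame(
      allele = character(), gene = character(), group = character(),
      S_HLA = numeric(), Eval = numeric(), log10_eval = numeric(),
      confidence = numeric(), n_contigs = integer(),
      stringsAsFactors = FALSE)), class = "hla_evidence")
  if (nrow(contigs) == 0L) return(empty)

  allele_map <- .kmer_allele_map(db$seq)
  bh <- lapply(seq_len(nrow(contigs)), function(i)
    best_hits(contigs[i, ], db, scoring, floor, prescreen = allele_map))
  names(bh) <- contigs$id
  pairs <- do.call(rbind, bh[vapply(bh, nrow, 0L) > 0L])
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  rownames(pairs) <- NULL
  tie_size <- vapply(bh, nrow, 0L)
  pairs$tie_size <- tie_size[pairs$query_id]
  pairs$gene <- db$names$gene[match(pairs$subject_id, db$names$raw)]

  # contigs assigned to a gene = contigs with >= 1 best hit in that gene;
  # denominator of the reciprocal-direction probability
  n_contigs_gene <- vapply(split(pairs$query_id, pairs$gene),
                           function(x) length(unique(x)), 0L)

  cand <- sort(unique(pairs$subject_id))
  contig_map <- .kmer_allele_map(contigs$sequence)
  rb <- reciprocal_best(db, contigs, scoring, alleles = cand,
                        prescreen = contig_map)
  rb_tie <- vapply(split(rb$contig_id, rb$allele), length, 0L)

  key <- paste(pairs$subject_id, pairs$query_id)
  rb_key <- paste(rb$allele, rb$contig_id)
  pairs$reciprocal <- key %in% rb_key
  ng <- n_contigs_gene[pairs$gene]
  pairs$p_fwd <- contig_probability(pairs$tie_size, db$N)
  pairs$p_rev <- ifelse(pairs$reciprocal, rb_tie[pairs$subject_id] / ng,
                        1 / ng)
  ci <- match(pairs$query_id, contigs$id)
  pairs$score <- contig_score(contigs$length[ci], contigs$depth[ci],
                              pairs$identity_aln, pairs$reciprocal)

  sp <- split(pairs, pairs$subject_id)
  alleles <- do.call(rbind, lapply(sp, function(p) {
    l10 <- sum(log10(p$p_fwd * p$p_rev))
    data.frame(allele = p$subject_id[1L], gene = p$gene[1L],
               group = group_key(p$subject_id[1L]),
               S_HLA = sum(p$score), Eval = 10^l10, log10_eval = l10,
               confidence = -10 * l10, n_contigs = nrow(p),
               stringsAsFactors = FALSE)
  }))
  rownames(alleles) <- NULL
  structure(list(pairs = pairs, alleles = alleles), class = "hla_evidence")
}

# Overlap rule within one allele group: when several contigs characterise the
# group, keep the alleles common to all of their candidate sets, plus any
# allele that is the sole best hit of some contig; if the intersection is
# empty, keep all members.
.apply_overlap_rule <- function(members, pairs) {
  sub <- pairs[pairs$subject_id %in% members, , drop = FALSE]
  ctgs <- unique(sub$query_id)
  if (length(ctgs) < 2L) return(members)
  sets <- lapply(ctgs, function(cid)
    sub$subject_id[sub$query_id == cid])
  inter <- Reduce(intersect, sets)
  sole <- unique(sub$subject_id[sub$tie_size == 1L])
  keep <- union(inter, sole)
  if (length(keep) == 0L) members else intersect(members, keep)
}

#' Rank allele evidence into per-gene predictions
#'
#' Protein-coding alleles are grouped under their allele group (two-digit
#' key); groups are ranked by decreasing best `S_HLA` and the top `slots`
#' groups per gene (default 2, the diploid expectation) are reported. Within
#' each slot the top-scoring alleles are reported; alleles sharing an
#' identical `(S_HLA, Eval)` form an ambiguity set and are listed together
#' (lexicographic order). Null alleles (expression suffix `N`) are excluded
#' unless `include_null = TRUE`.
#'
#' @param evidence `hla_evidence` from [score_alleles()].
#' @param slots Maximum prediction slots (allele groups) per gene.
#' @param include_null Report null alleles too.
#' @return data.frame of class `hla_predictions`: `gene`, `slot`, `group`,
#'   `allele`, `score`, `eval`, `confidence`, `ambiguous` (one row per
#'   reported allele; rows of one slot share `slot`).
#' @export
rank_and_report <- function(evidence, slots = 2L, include_null = FALSE) {
  al <- evidence$alleles
  out_empty <- data.frame(gene = character(), slot = integer(),
                          group = character(), allele = character(),
                          score = numeric(), eval = numeric(),
                          confidence = numeric(), ambiguous = logical(),
                          stringsAsFactors = FALSE)
  class(out_empty) <- c("hla_predictions", "data.frame")
  if (nrow(al) == 0L) return(out_empty)
  if (!include_null) al <- al[!is_null_allele(al$allele), , drop = FALSE]
  if (nrow(al) == 0L) return(out_empty)

  rows <- list()
  for (g in sort(unique(al$gene))) {
    ag <- al[al$gene == g, , drop = FALSE]
    grp_best <- vapply(split(ag$S_HLA, ag$group), max, 0)
    ord <- names(grp_best)[order(-grp_best, names(grp_best))]
    ord <- ord[seq_len(min(slots, length(ord)))]
    for (si in seq_along(ord)) {
      memb <- ag$allele[ag$group == ord[si]]
      memb <- .apply_overlap_rule(memb, evidence$pairs)
      sub <- ag[ag$allele %in% memb, , drop = FALSE]
      top <- max(sub$S_HLA)
      sub <- sub[sub$S_HLA >= top - 1e-9, , drop = FALSE]
      # ambiguity: distinct protein-allele names sharing identical score
      # and expect value
      amb <- nrow(sub) > 1L &&
        length(unique(round(sub$log10_eval, 9))) == 1L
      sub <- sub[order(sub$allele), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, slot = si, group = ord[si], allele = sub$allele,
        score = sub$S_HLA, eval = sub$Eval, confidence = sub$confidence,
        ambiguous = amb, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hla_predictions", "data.frame")
  out
}

#' @export
print.hla_predictions <- function(x, ...) {
  if (nrow(x) == 0L) { cat("no HLA predictions\n"); return(invisible(x)) }
  for (g in unique(x$gene)) {
    cat("HLA-", g, "\n", sep = "")
    xg <- x[x$gene == g, , drop = FALSE]
    for (s in unique(xg$slot)) {
      xs <- xg[xg$slot == s, , drop = FALSE]
      cat("  Prediction ", s, " - ", xs$group[1L], "\n", sep = "")
      for (i in seq_len(nrow(xs)))
        cat(sprintf("    %-14s %12.2f  %.2E  %.1f\n", xs$allele[i],
                    xs$score[i], xs$eval[i], xs$confidence[i]))
    }
  }
  invisible(x)
}

#' Write a prediction report TSV
#'
#' Columns: gene, prediction slot, allele group, allele, score, expect value,
#' confidence (`-10 x log10(Eval)`, one decimal).
#'
#' @param pred `hla_predictions` data.frame.
#' @param path Output TSV path.
#' @export
write_prediction_report <- function(pred, path) {
  out <- pred
  out$score <- sprintf("%.2f", out$score)
  out$eval <- sprintf("%.2E", out$eval)
  out$confidence <- sprintf("%.1f", out$confidence)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write machine-readable evidence JSON
#'
#' @param evidence `hla_evidence` list.
#' @param path Output JSON path.
#' @export
write_evidence_json <- function(evidence, path) {
  jsonlite::write_json(list(pairs = evidence$pairs,
                            alleles = evidence$alleles),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

.cigar_aligned_len <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  vapply(ops, function(o) {
    n <- as.integer(sub("[MIDNSHP=X]", "", o))
    sum(n[grepl("[M=X]", o)])
  }, 0L)
}

#' Predict alleles directly from read alignments (SAM)
#'
#' The direct-alignment mode: each mapped read is treated as a degenerate
#' contig of depth 1 whose length is its aligned length and whose identity
#' comes from the record's `NM` edit distance when present (1 otherwise).
#' Reads mapping equally well to several alleles contribute tie-set
#' probabilities exactly as multi-allele contigs do; scoring, expect values
#' and ranking then proceed as in assembly mode (no reciprocal doubling).
#'
#' @param sam Path to a SAM (or BAM) file aligned against the allele FASTA
#'   of `db`.
#' @param db `hla_ref_db` whose allele names match the SAM reference names.
#' @param slots,include_null See [rank_and_report()].
#' @return List: `predictions` (`hla_predictions`) and `evidence`.
#' @export
predict_from_alignments <- function(sam, db, slots = 2L,
                                    include_null = FALSE) {
  bam <- if (grepl("\\.bam$", sam, ignore.case = TRUE)) sam
         else Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "cigar"), tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  if (length(rec$qname) == 0L) {
    ev <- score_alleles(
      structure(data.frame(), class = c("hla_contigs", "data.frame")), db)
    return(list(predictions = rank_and_report(ev, slots, include_null),
                evidence = ev))
  }
  rname <- as.character(rec$rname)
  unknown <- setdiff(unique(rname), names(db$seq))
  if (length(unknown))
    stop("SAM reference names not in the allele database: ",
         paste(unknown, collapse = ", "))
  alen <- .cigar_aligned_len(rec$cigar)
  nm <- rec$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(alen))
  ident <- ifelse(is.na(nm), 1, pmax(0, 1 - nm / alen))

  d <- data.frame(qname = rec$qname, allele = rname, alen = alen,
                  ident = ident, prox = alen * ident,
                  stringsAsFactors = FALSE)
  # per-read ex-equo best alignments
  sp <- split(d, d$qname)
  pairs <- do.call(rbind, lapply(sp, function(x) {
    mx <- max(x$prox)
    x <- x[x$prox >= mx - 1e-9, , drop = FALSE]
    x <- x[!duplicated(x$allele), , drop = FALSE]
    x$tie_size <- nrow(x)
    x
  }))
  pairs$gene <- db$names$gene[match(pairs$allele, db$names$raw)]
  n_reads_gene <- vapply(split(pairs$qname, pairs$gene),
                         function(x) length(unique(x)), 0L)
  pairs$p_fwd <- contig_probability(pairs$tie_size, db$N)
  pairs$p_rev <- 1 / n_reads_gene[pairs$gene]
  pairs$score <- pairs$alen * 1 * pairs$ident

  sp2 <- split(pairs, pairs$allele)
  alleles <- do.call(rbind, lapply(sp2, function(x) {
    l10 <- sum(log10(x$p_fwd * x$p_rev))
    data.frame(allele = x$allele[1L], gene = x$gene[1L],
               group = group_key(x$allele[1L]),
               S_HLA = sum(x$score), Eval = 10^l10, log10_eval = l10,
               confidence = -10 * l10, n_contigs = nrow(x),
               stringsAsFactors = FALSE)
  }))
  rownames(alleles) <- NULL
  ev_pairs <- data.frame(query_id = pairs$qname, subject_id = pairs$allele,
                         tie_size = pairs$tie_size, gene = pairs$gene,
                         p_fwd = pairs$p_fwd, p_rev = pairs$p_rev,
                         score = pairs$score, reciprocal = FALSE,
                         stringsAsFactors = FALSE)
  ev <- structure(list(pairs = ev_pairs, alleles = alleles),
                  class = "hla_evidence")
  list(predictions = rank_and_report(ev, slots, include_null),
       evidence = ev)
}
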