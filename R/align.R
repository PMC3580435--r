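#' Alignment scoring parameters
#'
#' Affine-gap local alignment scoring used throughout the pipeline:
#' match +2, mismatch -3, gap open 5, gap extension 2 (a gap of length L
#' costs open + L * extension). These mirror widely used nucleotide
#' local-alignment defaults and are configurable.
#'
#' @param match Match reward (positive).
#' @param mismatch Mismatch penalty (negative).
#' @param gap_open Gap opening cost (positive).
#' @param gap_ext Gap extension cost per gap position (positive).
#' @return A list of class `hla_scoring`.
#' @export
scoring_params <- function(match = 2, mismatch = -3, gap_open = 5,
                           gap_ext = 2) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_ext > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext), class = "hla_scoring")
}

.submat <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = FALSE)
}

.hit_from_pa <- function(pa, query_id, subject_id, query_len) {
  nm <- Biostrings::nmatch(pa)
  al <- nchar(pa)  # alignment length including indels
  data.frame(query_id = query_id, subject_id = subject_id,
             raw_score = as.numeric(BiocGenerics::score(pa)),
             aligned_length = as.integer(al),
             identity_aln = nm / al,
             identity_qry = nm / query_len,
             stringsAsFactors = FALSE)
}

#' Local alignment of two sequences
#'
#' Optimal local (Smith-Waterman) alignment under affine-gap scoring,
#' reporting the raw score, the aligned length, the identity over the aligned
#' portion, and the identity over the full query length.
#'
#' @param query,subject Character scalars (named values give hit ids).
#' @param scoring A [scoring_params()] list.
#' @return One-row data.frame: `query_id`, `subject_id`, `raw_score`,
#'   `aligned_length`, `identity_aln`, `identity_qry`.
#' @export
local_align <- function(query, subject, scoring = scoring_params()) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  qid <- if (!is.null(names(query))) names(query) else "query"
  sid <- if (!is.null(names(subject))) names(subject) else "subject"
  pa <- Biostrings::pairwiseAlignment(
    unname(query), unname(subject), type = "local",
    substitutionMatrix = .submat(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  .hit_from_pa(pa, qid, sid, nchar(query))
}

# score one query against every sequence of a DNAStringSet (fast path)
.scores_vs_set <- function(query, set, scoring) {
  Biostrings::pairwiseAlignment(
    set, query, type = "local", scoreOnly = TRUE,
    substitutionMatrix = .submat(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
}

# kmer -> allele-index lookup used to prescreen alignment candidates; an
# allele sharing no exact k-mer with a query cannot attain the best local
# alignment score in practice, so full dynamic programming is skipped for it
.kmer_allele_map <- function(seqs, k = 15L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  seqs <- as.character(seqs)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    for (w in unique(substring(seqs[i], 1:(n - k + 1L), k:n)))
      assign(w, c(env[[w]], i), envir = env)
  }
  attr(env, "k") <- k
  env
}

.prescreen_alleles <- function(qseq, map) {
  k <- attr(map, "k")
  n <- nchar(qseq)
  if (n < k) return(integer())
  wins <- unique(substring(qseq, 1:(n - k + 1L), k:n))
  sort(unique(unlist(mget(wins, envir = map, ifnotfound = list(NULL)),
                     use.names = FALSE)))
}

#' Ex-equo best database hits of a contig
#'
#' Aligns the contig to every allele of the database and returns all alleles
#' tying the maximal raw score. Queries whose best score falls below the
#' floor — or ties the floor exactly in a multi-way tie — are reported
#' unaligned (zero rows).
#'
#' @param contig One row of an `hla_contigs` data.frame, or a character
#'   scalar (optionally named).
#' @param db An `hla_ref_db`.
#' @param scoring A [scoring_params()] list.
#' @param floor Minimum raw score for a hit to count (default 40).
#' @param prescreen Internal optimisation: restrict the full alignment to
#'   alleles sharing at least one exact 15-mer with the contig (falling back
#'   to all alleles when none shares). Does not change results on real
#'   queries; set `NULL` to disable.
#' @return data.frame of class `best_hit_set` (possibly 0 rows): one row per
#'   ex-equo best allele with identity statistics.
#' @export
best_hits <- function(contig, db, scoring = scoring_params(), floor = 40,
                      prescreen = NULL) {
  if (is.data.frame(contig)) {
    qseq <- contig$sequence[1L]; qid <- contig$id[1L]
  } else {
    qseq <- as.character(contig)[1L]
    qid <- if (!is.null(names(contig))) names(contig)[1L] else "query"
  }
  if (!nzchar(qseq)) stop("empty contig sequence")
  cand <- seq_along(db$seq)
  if (!is.null(prescreen)) {
    hit <- .prescreen_alleles(qseq, prescreen)
    if (length(hit)) cand <- hit
  }
  sc_cand <- .scores_vs_set(qseq, db$seq[cand], scoring)
  sc <- rep(-Inf, length(db$seq))
  sc[cand] <- sc_cand
  mx <- max(sc)
  ties <- which(sc >= mx - 1e-9)
  unaligned <- mx < floor || (abs(mx - floor) <= 1e-9 && length(ties) > 1L)
  if (unaligned) {
    out <- data.frame(query_id = character(), subject_id = character(),
                      raw_score = numeric(), aligned_length = integer(),
                      identity_aln = numeric(), identity_qry = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(rep(qseq, length(ties))), db$seq[ties],
      type = "local", substitutionMatrix = .submat(scoring),
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
    nm <- Biostrings::nmatch(pa)
    al <- nchar(pa)
    out <- data.frame(query_id = qid, subject_id = names(db$seq)[ties],
                      raw_score = as.numeric(BiocGenerics::score(pa)),
                      aligned_length = as.integer(al),
                      identity_aln = nm / al,
                      identity_qry = nm / nchar(qseq),
                      stringsAsFactors = FALSE)
    out <- out[order(out$subject_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("best_hit_set", "data.frame")
  out
}

#' Reciprocal best contigs per allele
#'
#' For each allele (as the query), finds the contig(s) attaining the maximal
#' raw alignment score. A contig-allele pair where the allele also best
#' identifies that contig is a reciprocal best hit, which doubles the
#' contig's score contribution for that allele. The relation is always
#' computed from the allele-as-query direction.
#'
#' @param db An `hla_ref_db`.
#' @param contigs An `hla_contigs` data.frame.
#' @param scoring A [scoring_params()] list.
#' @param alleles Optional character vector restricting which alleles are
#'   evaluated (default: all).
#' @param prescreen Internal optimisation: per allele, align only against
#'   contigs sharing at least one exact 15-mer (all contigs when none
#'   shares); see [best_hits()].
#' @return data.frame with columns `allele`, `contig_id`, `raw_score`; one
#'   row per ex-equo best contig of each allele.
#' @export
reciprocal_best <- function(db, contigs, scoring = scoring_params(),
                            alleles = NULL, prescreen = NULL) {
  if (nrow(contigs) == 0L) stop("no contigs")
  if (is.null(alleles)) alleles <- names(db$seq)
  rows <- lapply(alleles, function(a) {
    aseq <- as.character(db$seq[[match(a, names(db$seq))]])
    ci <- seq_len(nrow(contigs))
    if (!is.null(prescreen)) {
      hit <- .prescreen_alleles(aseq, prescreen)
      if (length(hit)) ci <- hit
    }
    cset <- Biostrings::DNAStringSet(contigs$sequence[ci])
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(rep(aseq, length(ci))), cset,
      type = "local", scoreOnly = TRUE,
      substitutionMatrix = .submat(scoring),
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
    mx <- max(sc)
    ties <- which(sc >= mx - 1e-9)
    data.frame(allele = a, contig_id = contigs$id[ci][ties],
               raw_score = as.numeric(sc[ties]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference full-matrix local alignment score
#'
#' Independent full dynamic-programming (Gotoh) implementation of the local
#' affine-gap alignment score, used to validate the production aligner. Not
#' used by the pipeline itself.
#'
#' @param query,subject Character scalars.
#' @param scoring A [scoring_params()] list.
#' @return The optimal local alignment score (numeric scalar).
#' @export
local_align_score_ref <- function(query, subject,
                                  scoring = scoring_params()) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  sw_score_cpp(query, subject, scoring$match, scoring$mismatch,
               scoring$gap_open, scoring$gap_ext)
}

#' Import pre-computed tabular alignments
#'
#' Accepts 12-column tabular alignment output (query, subject, percent
#' identity, aligned length, mismatches, gap opens, q.start, q.end, s.start,
#' s.end, e-value, bitscore) so externally computed alignments can stand in
#' for the internal aligner bit-for-bit.
#'
#' @param path TSV path.
#' @return data.frame with canonical hit columns (`raw_score` taken from the
#'   bitscore column).
#' @export
read_tabular_alignments <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "aligned_length",
            "mismatches", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("expected 12 tab-separated columns")
  names(tab)[1:12] <- cols
  data.frame(query_id = tab$query_id, subject_id = tab$subject_id,
             raw_score = tab$bitscore,
             aligned_length = tab$aligned_length,
             identity_aln = tab$pident / 100,
             identity_qry = NA_real_, stringsAsFactors = FALSE)
}
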