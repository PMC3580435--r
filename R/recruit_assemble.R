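#' Build an exact k-mer index over a reference database
#'
#' Enumerates every k-length word of every target sequence into a hash-backed
#' membership set. Reads whose 5'-terminal k-mer (on either strand) occurs in
#' this set are candidates for targeted assembly. Words containing `N` are
#' excluded.
#'
#' @param db An `hla_ref_db`.
#' @param k Word length in nucleotides (default 15).
#' @return Object of class `kmer_index`: `list(k, members)` where `members`
#'   is the character vector of distinct k-mers.
#' @export
build_kmer_index <- function(db, k = 15L) {
  k <- as.integer(k)
  w <- Biostrings::width(db$seq)
  if (k < 4L || k > min(w))
    stop("k must be >= 4 and <= the shortest target length (", min(w), ")")
  seqs <- as.character(db$seq)
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  kmers <- unique(kmers[!grepl("N", kmers, fixed = TRUE)])
  structure(list(k = k, members = kmers), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("k-mer index: k =", x$k, "|", length(x$members), "distinct words\n")
  invisible(x)
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Recruit candidate reads by 5' k-mer match
#'
#' A read is recruited iff its first `k` bases, or the first `k` bases of its
#' reverse complement, occur in the target k-mer index. Recruited reads are
#' emitted in target orientation (reverse-complemented when matched on the
#' minus strand). Internal k-mers do not trigger recruitment unless
#' `internal = TRUE`. Reads shorter than `k` are skipped and counted.
#'
#' @param reads Named character vector (or `DNAStringSet`) of read sequences.
#' @param index A `kmer_index` from [build_kmer_index()].
#' @param internal Also recruit on any internal k-mer match (off by default;
#'   the 5'-only rule is the standard behaviour).
#' @return data.frame of class `recruited_reads` with columns `id`,
#'   `sequence` (target orientation) and `strand`; recruitment counts are
#'   attached as attribute `counts`.
#' @export
recruit_reads <- function(reads, index, internal = FALSE) {
  if (inherits(reads, "DNAStringSet")) {
    ids <- names(reads); reads <- as.character(reads)
  } else {
    ids <- names(reads)
  }
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  k <- index$k
  lens <- nchar(reads)
  short <- lens < k
  reads_ok <- reads[!short]
  ids_ok <- ids[!short]
  if (length(reads_ok) == 0L) {
    out <- data.frame(id = character(), sequence = character(),
                      strand = character(), stringsAsFactors = FALSE)
  } else {
    rc <- .revcomp_chr(reads_ok)
    if (internal) {
      hit_fun <- function(s) {
        n <- nchar(s)
        any(substring(s, 1:(n - k + 1L), k:n) %in% index$members)
      }
      plus <- vapply(reads_ok, hit_fun, TRUE, USE.NAMES = FALSE)
      minus <- !plus & vapply(rc, hit_fun, TRUE, USE.NAMES = FALSE)
    } else {
      plus <- substr(reads_ok, 1L, k) %in% index$members
      minus <- !plus & (substr(rc, 1L, k) %in% index$members)
    }
    out <- data.frame(
      id = c(ids_ok[plus], ids_ok[minus]),
      sequence = c(reads_ok[plus], rc[minus]),
      strand = c(rep("+", sum(plus)), rep("-", sum(minus))),
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  attr(out, "counts") <- c(total = length(reads), skipped_short = sum(short),
                           plus = sum(out$strand == "+"),
                           minus = sum(out$strand == "-"))
  class(out) <- c("recruited_reads", "data.frame")
  out
}

# Index distinct read prefixes (or suffixes) of length `w` into an
# environment: key -> integer indices.
.build_window_index <- function(seqs, w, side = c("prefix", "suffix")) {
  side <- match.arg(side)
  keys <- if (side == "prefix") substr(seqs, 1L, w)
          else substr(seqs, nchar(seqs) - w + 1L, nchar(seqs))
  env <- new.env(hash = TRUE, parent = emptyenv())
  sp <- split(seq_along(seqs), keys)
  for (kk in names(sp)) assign(kk, sp[[kk]], envir = env)
  env
}

#' Assemble recruited reads into depth-annotated contigs
#'
#' Greedy seed-and-extend assembly of exact-overlap reads, in the style of
#' short-read greedy assemblers: seeds are taken in order of decreasing read
#' multiplicity (ties by read id); a contig is extended at its 3' end by the
#' unused read with the longest exact suffix-prefix overlap of at least
#' `min_overlap` (ties broken by higher multiplicity, then lexicographic id),
#' then symmetrically at its 5' end. Reads consumed by a contig — including
#' reads wholly contained in it — are marked used and belong to that contig.
#' Per-contig depth is mean per-base read coverage (sum of constituent read
#' lengths / contig length). Contigs shorter than `min_contig` or below
#' `min_depth` are discarded (their reads stay consumed). Output is sorted by
#' decreasing length and is deterministic for identical inputs and
#' parameters.
#'
#' @param reads A `recruited_reads` data.frame (or named character vector of
#'   oriented reads).
#' @param min_overlap Minimum exact suffix-prefix overlap (default 20).
#' @param min_depth Minimum mean depth for an emitted contig (default 1).
#' @param min_contig Minimum contig length in nucleotides (default 200).
#' @return data.frame of class `hla_contigs` with columns `id`, `sequence`,
#'   `length`, `depth`, `n_reads`.
#' @export
assemble <- function(reads, min_overlap = 20L, min_depth = 1,
                     min_contig = 200L) {
  if (is.data.frame(reads)) {
    seqs <- reads$sequence; ids <- reads$id
  } else {
    seqs <- as.character(reads); ids <- names(reads)
  }
  empty <- data.frame(id = character(), sequence = character(),
                      length = integer(), depth = numeric(),
                      n_reads = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("hla_contigs", "data.frame")
  if (length(seqs) == 0L) return(empty)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  keep <- nchar(seqs) > min_overlap
  seqs <- seqs[keep]; ids <- ids[keep]
  if (length(seqs) == 0L) return(empty)

  # collapse to distinct sequences with multiplicities
  u <- unique(seqs)
  idx <- match(seqs, u)
  mult <- tabulate(idx, nbins = length(u))
  rep_id <- vapply(split(ids, idx), min, "")
  lens <- nchar(u)
  maxlen <- max(lens)

  pref_ix <- .build_window_index(u, min_overlap, "prefix")
  suff_ix <- .build_window_index(u, min_overlap, "suffix")

  used <- logical(length(u))
  seed_order <- order(-mult, rep_id)
  rows <- list()

  pick <- function(cand) {
    # highest multiplicity, then lexicographic representative id
    cand[order(-mult[cand], rep_id[cand])][1L]
  }

  for (seed in seed_order) {
    if (used[seed]) next
    contig <- u[seed]
    used[seed] <- TRUE
    members <- seed
    # 3' extension: longest exact suffix-prefix overlap >= min_overlap
    repeat {
      cl <- nchar(contig)
      ext <- FALSE
      for (o in seq.int(min(maxlen - 1L, cl), min_overlap)) {
        w <- substr(contig, cl - o + 1L, cl - o + min_overlap)
        cand <- pref_ix[[w]]
        if (is.null(cand)) next
        cand <- cand[!used[cand] & lens[cand] > o]
        if (length(cand) == 0L) next
        cand <- cand[substr(u[cand], 1L, o) == substr(contig, cl - o + 1L, cl)]
        if (length(cand) == 0L) next
        b <- pick(cand)
        contig <- paste0(contig, substr(u[b], o + 1L, lens[b]))
        used[b] <- TRUE
        members <- c(members, b)
        ext <- TRUE
        break
      }
      if (!ext) break
    }
    # 5' extension: read suffix matches contig prefix
    repeat {
      cl <- nchar(contig)
      ext <- FALSE
      for (o in seq.int(min(maxlen - 1L, cl), min_overlap)) {
        w <- substr(contig, o - min_overlap + 1L, o)
        cand <- suff_ix[[w]]
        if (is.null(cand)) next
        cand <- cand[!used[cand] & lens[cand] > o]
        if (length(cand) == 0L) next
        cand <- cand[substr(u[cand], lens[cand] - o + 1L, lens[cand]) ==
                       substr(contig, 1L, o)]
        if (length(cand) == 0L) next
        b <- pick(cand)
        contig <- paste0(substr(u[b], 1L, lens[b] - o), contig)
        used[b] <- TRUE
        members <- c(members, b)
        ext <- TRUE
        break
      }
      if (!ext) break
    }
    # containment pass: every unused distinct read that is an exact substring
    # of the contig is a constituent (it is covered by the contig's path)
    cl <- nchar(contig)
    for (l in sort(unique(lens[lens <= cl]))) {
      wins <- unique(substring(contig, 1:(cl - l + 1L), l:cl))
      hit <- match(wins, u)
      hit <- hit[!is.na(hit)]
      hit <- hit[lens[hit] == l & !used[hit]]
      if (length(hit)) {
        used[hit] <- TRUE
        members <- c(members, hit)
      }
    }
    members <- unique(members)
    n_reads <- sum(mult[members])
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = contig, length = cl,
      depth = sum(mult[members] * lens[members]) / cl,
      n_reads = as.integer(n_reads), stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, rows)
  out <- out[out$length >= min_contig & out$depth >= min_depth, , drop = FALSE]
  out <- out[order(-out$length, out$sequence), , drop = FALSE]
  out <- cbind(id = if (nrow(out)) sprintf("contig%04d", seq_len(nrow(out)))
               else character(0), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("hla_contigs", "data.frame")
  out
}

#' Contig length and mean depth
#'
#' @param contig One row of an `hla_contigs` data.frame.
#' @return Named numeric vector `c(length, depth)`; depth is the sum of
#'   constituent read lengths divided by contig length.
#' @export
contig_stats <- function(contig) {
  c(length = as.numeric(contig$length), depth = as.numeric(contig$depth))
}

#' Write contigs to FASTA
#'
#' Headers carry `id length=<l> depth=<d> n_reads=<n>`.
#'
#' @param contigs `hla_contigs` data.frame.
#' @param path Output FASTA path.
#' @export
write_contig_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- sprintf("%s length=%d depth=%.3f n_reads=%d", contigs$id,
                      contigs$length, contigs$depth, contigs$n_reads)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
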