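#' @useDynLib shotgunHLA, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import Biostrings
#' @importFrom BiocGenerics score
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils write.table
NULL

#' Parse HLA allele names
#'
#' Splits names written in standard HLA nomenclature (e.g. `A*02:01`,
#' `B*27:05P`, `A*24:09N`, `A*02:01:01:02`) into their fields: the gene
#' (token before `*`), the allele group (first colon-separated field, two-digit
#' resolution), the protein-coding allele (second field, four-digit
#' resolution), and any trailing fields or expression letters, which are kept
#' verbatim in `suffix`. A trailing `P` on the protein field marks a P group
#' (a set of alleles identical over the antigen-recognition exons) and is
#' recorded in `p_group` rather than in `suffix`.
#'
#' @param raw Character vector of allele names.
#' @return A data.frame with one row per name and columns `gene`, `group`,
#'   `protein` (NA for group-only names), `p_group` (logical), `suffix`
#'   (verbatim remainder: either a bare expression letter such as `"N"`, or a
#'   colon-led tail such as `":01:02"`), and `raw`.
#' @examples
#' parse_allele_name(c("A*02:01P", "C*02:21", "B*27"))
#' @export
parse_allele_name <- function(raw) {
  if (!is.character(raw) || length(raw) == 0L)
    stop("allele names must be a non-empty character vector")
  bad <- which(is.na(raw) | !nzchar(raw))
  if (length(bad))
    stop("empty allele name at position ", bad[1L])
  parts <- strsplit(raw, "*", fixed = TRUE)
  n_star <- lengths(parts)
  bad <- which(n_star != 2L | !nzchar(vapply(parts, `[`, "", 1L)))
  if (length(bad))
    stop("cannot parse allele name (need GENE*FIELDS): '", raw[bad[1L]], "'")
  gene <- vapply(parts, `[`, "", 1L)
  rest <- vapply(parts, `[`, "", 2L)

  fields <- strsplit(rest, ":", fixed = TRUE)
  group <- vapply(fields, `[`, "", 1L)
  bad <- which(is.na(group) | !grepl("^[0-9]+$", group))
  if (length(bad))
    stop("cannot parse allele group in '", raw[bad[1L]], "'")

  protein <- rep(NA_character_, length(raw))
  p_group <- rep(FALSE, length(raw))
  suffix <- rep("", length(raw))
  for (i in seq_along(raw)) {
    fs <- fields[[i]]
    if (length(fs) < 2L) next
    f2 <- fs[2L]
    m <- regmatches(f2, regexec("^([0-9]+)([A-Z]*)$", f2))[[1L]]
    if (length(m) == 0L)
      stop("cannot parse protein field in '", raw[i], "'")
    protein[i] <- m[2L]
    tail_letter <- m[3L]
    if (length(fs) == 2L) {
      if (identical(tail_letter, "P")) p_group[i] <- TRUE
      else suffix[i] <- tail_letter
    } else {
      # letters may only trail the final field; keep everything verbatim
      if (nzchar(tail_letter))
        stop("unexpected letter on internal field in '", raw[i], "'")
      suffix[i] <- paste0(":", paste(fs[-(1:2)], collapse = ":"))
    }
  }
  data.frame(gene = gene, group = group, protein = protein,
             p_group = p_group, suffix = suffix, raw = raw,
             stringsAsFactors = FALSE)
}

#' Format parsed allele names
#'
#' Inverse of [parse_allele_name()]: reassembles the original name from the
#' parsed fields.
#'
#' @param x A data.frame as returned by [parse_allele_name()].
#' @return Character vector of names.
#' @export
format_allele_name <- function(x) {
  out <- paste0(x$gene, "*", x$group)
  has_prot <- !is.na(x$protein)
  out[has_prot] <- paste0(out[has_prot], ":", x$protein[has_prot],
                          ifelse(x$p_group[has_prot], "P", ""),
                          x$suffix[has_prot])
  out
}

.as_parsed <- function(x) {
  if (is.data.frame(x)) x else parse_allele_name(x)
}

#' Allele-group and protein-allele keys
#'
#' `group_key()` gives the two-digit resolution key (`A*02`); `protein_key()`
#' gives the four-digit resolution key (`A*02:01`), dropping silent-variant
#' suffix fields and the P marker, so that P-designated names compare equal to
#' their members. `protein_key()` errors on group-only names.
#'
#' @param x Character vector of allele names, or a parsed data.frame.
#' @return Character vector of keys.
#' @examples
#' group_key("A*02:01P")    # "A*02"
#' protein_key("A*02:01:01:02")  # "A*02:01"
#' @export
group_key <- function(x) {
  p <- .as_parsed(x)
  paste0(p$gene, "*", p$group)
}

#' @rdname group_key
#' @export
protein_key <- function(x) {
  p <- .as_parsed(x)
  if (anyNA(p$protein))
    stop("protein_key undefined for group-only name '",
         p$raw[which(is.na(p$protein))[1L]], "'")
  paste0(p$gene, "*", p$group, ":", p$protein)
}

#' Test for null (unexpressed) alleles
#'
#' Null alleles carry the expression suffix `N` in HLA nomenclature: present
#' in the genome but not expressed. They are excluded from ranked predictions
#' by default.
#'
#' @inheritParams group_key
#' @return Logical vector.
#' @export
is_null_allele <- function(x) {
  p <- .as_parsed(x)
  grepl("N$", p$suffix)
}

.new_ref_db <- function(seqs, kind) {
  parsed <- parse_allele_name(names(seqs))
  structure(list(seq = seqs, names = parsed, N = length(seqs), kind = kind),
            class = "hla_ref_db")
}

#' @export
print.hla_ref_db <- function(x, ...) {
  cat("HLA reference allele database (", x$kind, ")\n", sep = "")
  cat("  alleles: ", x$N, " across genes ",
      paste(sort(unique(x$names$gene)), collapse = ", "), "\n", sep = "")
  cat("  lengths: ", min(Biostrings::width(x$seq)), "-",
      max(Biostrings::width(x$seq)), " nt\n", sep = "")
  invisible(x)
}

# Pull a parseable allele name out of a FASTA header. Accepts both
# ">A*02:01 description" and the IMGT dialect ">HLA:HLA00005 A*02:01 1098 bp"
# (name is the second token when the first is an accession without '*').
.header_allele_name <- function(header, i) {
  toks <- strsplit(trimws(header), "[[:space:]]+")[[1L]]
  for (tok in toks[seq_len(min(2L, length(toks)))]) {
    if (grepl("*", tok, fixed = TRUE)) {
      ok <- tryCatch({ parse_allele_name(tok); TRUE }, error = function(e) FALSE)
      if (ok) return(tok)
    }
  }
  stop("record ", i, ": no parseable allele name in FASTA header '",
       header, "'")
}

#' Load a reference allele database from FASTA
#'
#' Reads a FASTA file of reference allele sequences (coding sequences,
#' concatenated exon 2+3 sequences, or genomic sequences) whose headers carry
#' standard HLA nomenclature. Both plain headers (`>A*02:01 ...`) and the
#' IMGT-style dialect (`>HLA:HLA00005 A*02:01 1098 bp`) are accepted.
#'
#' @param path FASTA file (gzip-transparent).
#' @param kind One of `"cds"`, `"exon23"`, `"genomic"`; the sequence kind is
#'   uniform within one database.
#' @param genes Restrict to these genes (default the class I major genes
#'   A, B, C); `NULL` keeps every record.
#' @return An object of class `hla_ref_db`: named `DNAStringSet` `seq`, parsed
#'   `names`, allele count `N` (the denominator of the chance probability of
#'   characterising one allele), and `kind`.
#' @export
load_reference_fasta <- function(path, kind = c("cds", "exon23", "genomic"),
                                 genes = c("A", "B", "C")) {
  kind <- match.arg(kind)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nm <- vapply(seq_along(seqs), function(i)
    .header_allele_name(names(seqs)[i], i), "")
  names(seqs) <- nm
  if (anyDuplicated(nm))
    stop("duplicate allele name in FASTA: ",
         nm[duplicated(nm)][1L])
  parsed <- parse_allele_name(nm)
  if (!is.null(genes)) {
    keep <- parsed$gene %in% genes
    if (!any(keep)) stop("no records left after filtering to genes ",
                         paste(genes, collapse = ","))
    seqs <- seqs[keep]
  }
  if (any(Biostrings::width(seqs) == 0L)) stop("empty sequence in FASTA")
  .new_ref_db(seqs, kind)
}

#' Write a reference database to FASTA
#'
#' @param db An `hla_ref_db`.
#' @param path Output path.
#' @export
write_reference_fasta <- function(db, path) {
  Biostrings::writeXStringSet(db$seq, path)
  invisible(path)
}

#' Read EMBL-style flat-file records (ID / FT exon / SQ only)
#'
#' A minimal reader for EMBL-style flat files as distributed with allele
#' databases, restricted to the parts needed for exon extraction: the `ID`
#' line (allele name, first token), `FT exon` features with 1-based inclusive
#' `from..to` locations and their `/number=` qualifiers, and the sequence
#' block after `SQ`.
#'
#' @param path Flat file path.
#' @return A list of records, each `list(name, sequence, exons)` where `exons`
#'   is a data.frame with columns `number`, `start`, `end`.
#' @export
read_embl_exons <- function(path) {
  lines <- readLines(path)
  recs <- list()
  cur <- NULL
  in_seq <- FALSE
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    cur$sequence <- toupper(gsub("[^A-Za-z]", "", paste0(cur$seqbuf, collapse = "")))
    cur$seqbuf <- NULL
    cur$exons <- do.call(rbind, cur$exons)
    cur
  }
  for (ln in lines) {
    tag <- substr(ln, 1L, 2L)
    if (tag == "ID") {
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- flush(cur)
      nm <- strsplit(trimws(substring(ln, 3L)), "[;[:space:]]+")[[1L]][1L]
      cur <- list(name = nm, seqbuf = character(), exons = list())
      in_seq <- FALSE
    } else if (tag == "FT" && grepl("^FT\\s+exon\\s+[0-9]+\\.\\.[0-9]+", ln)) {
      loc <- regmatches(ln, regexec("([0-9]+)\\.\\.([0-9]+)", ln))[[1L]]
      cur$exons[[length(cur$exons) + 1L]] <-
        data.frame(number = NA_integer_,
                   start = as.integer(loc[2L]), end = as.integer(loc[3L]))
    } else if (tag == "FT" && grepl("/number=", ln, fixed = TRUE)) {
      num <- as.integer(sub(".*?/number=\"?([0-9]+)\"?.*", "\\1", ln))
      k <- length(cur$exons)
      if (k > 0L && is.na(cur$exons[[k]]$number)) cur$exons[[k]]$number <- num
    } else if (tag == "SQ") {
      in_seq <- TRUE
    } else if (tag == "//") {
      recs[[length(recs) + 1L]] <- flush(cur)
      cur <- NULL
      in_seq <- FALSE
    } else if (in_seq) {
      cur$seqbuf <- c(cur$seqbuf, ln)
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- flush(cur)
  recs
}

#' Build an exon-concatenated reference database
#'
#' Extracts the requested exons (1-based inclusive coordinates, ascending exon
#' number) from each flat-file record and concatenates them, producing the
#' exon 2+3 target databases used for RNA-Seq prediction. Records lacking any
#' requested exon are skipped with a warning.
#'
#' @param records List of records from [read_embl_exons()].
#' @param exon_numbers Integer vector of exon numbers (default `c(2, 3)`).
#' @return An `hla_ref_db` of kind `"exon23"`.
#' @export
concat_exons <- function(records, exon_numbers = c(2L, 3L)) {
  out <- character()
  for (rec in records) {
    ex <- rec$exons
    if (is.null(ex) || !all(exon_numbers %in% ex$number)) {
      warning("record '", rec$name, "' lacks exon(s) ",
              paste(setdiff(exon_numbers, ex$number), collapse = ","),
              "; skipped")
      next
    }
    ex <- ex[ex$number %in% exon_numbers, , drop = FALSE]
    ex <- ex[order(ex$number), , drop = FALSE]
    if (any(ex$start < 1L) || any(ex$end > nchar(rec$sequence)) ||
        any(ex$start > ex$end))
      stop("exon coordinates out of range for allele '", rec$name, "'")
    out[[rec$name]] <- paste0(substring(rec$sequence, ex$start, ex$end),
                              collapse = "")
  }
  if (length(out) == 0L) stop("no records with all requested exons")
  .new_ref_db(Biostrings::DNAStringSet(out), "exon23")
}

#' Read an optional P-group mapping table
#'
#' Two-column tab-separated file mapping allele names to P-group names; used
#' to collapse protein alleles that are identical over the antigen-recognition
#' exons when such a table is available.
#'
#' @param path TSV path (allele name, P-group name; no header).
#' @return Named character vector (allele name -> P-group name).
#' @export
read_pgroup_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("P-group table needs two columns")
  stats::setNames(tab[[2L]], tab[[1L]])
}
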