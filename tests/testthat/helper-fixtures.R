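# Shared fixtures and independent oracles used across test files.
# Everything is generated in code under fixed seeds; nothing is read from
# disk except files the tests themselves write to tempdir().

# shared fixture database: 15 alleles per gene (5 groups x 3), 2% divergence
small_fixture <- make_fixture_db(n_per_gene = 15L, divergence = 0.02,
                                 seed = 11L)

# brute-force recruitment oracle: enumerate every k-mer of every target,
# then check the two 5'-terminal words of each read independently of the
# production index
oracle_recruit <- function(reads, db, k = 15L) {
  kmers <- unlist(lapply(as.character(db$seq), function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  kmers <- unique(kmers[!grepl("N", kmers, fixed = TRUE)])
  out <- data.frame(id = character(), sequence = character(),
                    strand = character(), stringsAsFactors = FALSE)
  rc_all <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(unname(reads))))
  for (i in seq_along(reads)) {
    if (nchar(reads[[i]]) < k) next
    if (substr(reads[[i]], 1L, k) %in% kmers) {
      out[nrow(out) + 1L, ] <- c(names(reads)[i], reads[[i]], "+")
    } else if (substr(rc_all[i], 1L, k) %in% kmers) {
      out[nrow(out) + 1L, ] <- c(names(reads)[i], rc_all[i], "-")
    }
  }
  out
}

# uniformly random DNA string
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# reads tiling a template at a fixed step, error-free, 5'->3'
tiling_reads <- function(template, read_len, step) {
  starts <- seq(1L, nchar(template) - read_len + 1L, by = step)
  stats::setNames(substring(template, starts, starts + read_len - 1L),
                  sprintf("t%04d", seq_along(starts)))
}

# minimal hla_predictions constructor for metrics tests
fake_predictions <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r$gene, slot = r$slot, group = r$group,
               allele = r$allele, score = r$score, eval = r$eval,
               confidence = -10 * log10(r$eval), ambiguous = FALSE,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("hla_predictions", "data.frame")
  out
}
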