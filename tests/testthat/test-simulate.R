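test_that("fixture databases are deterministic with the declared structure", {
  fx <- make_fixture_db(n_per_gene = 5, divergence = 0.02, seed = 7)
  expect_equal(fx$db$N, 15L)
  expect_setequal(unique(fx$db$names$gene), c("A", "B", "C"))
  # regenerating under the same seed is byte-identical
  fx2 <- make_fixture_db(n_per_gene = 5, divergence = 0.02, seed = 7)
  expect_identical(as.character(fx$db$seq), as.character(fx2$db$seq))
  f1 <- tempfile(); f2 <- tempfile()
  write_reference_fasta(fx$db, f1); write_reference_fasta(fx2$db, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the sequences
  fx3 <- make_fixture_db(n_per_gene = 5, divergence = 0.02, seed = 8)
  expect_false(identical(as.character(fx$db$seq), as.character(fx3$db$seq)))

  expect_error(make_fixture_db(1), "at least 2")
  expect_error(make_fixture_db(5, divergence = 0.3), "unrealistic")
})

test_that("sibling alleles differ by exactly one base; groups by ~divergence", {
  fx <- small_fixture
  h <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    sum(x != y)
  }
  s <- as.character(fx$db$seq)
  expect_equal(h(s[["A*01:01"]], s[["A*01:02"]]), 1L)
  expect_equal(h(s[["B*02:01"]], s[["B*02:02"]]), 1L)
  # between-group divergence close to the declared 2%
  d <- h(s[["A*01:01"]], s[["A*02:01"]]) / nchar(s[["A*01:01"]])
  expect_gt(d, 0.01)
  expect_lt(d, 0.03)
  # exactly one null allele, in gene A
  nulls <- names(s)[is_null_allele(names(s))]
  expect_length(nulls, 1L)
  expect_equal(parse_allele_name(nulls)$gene, "A")
})

test_that("backgrounds share no recruitment word with the database", {
  db <- small_fixture$exon23_db
  bg <- make_background(db, n_seqs = 30, mean_length = 1000, seed = 3)
  expect_length(bg, 30L)
  dbk <- build_kmer_index(db, 15)$members
  bgk <- unlist(lapply(as.character(bg), function(s) {
    n <- nchar(s)
    substring(s, 1:(n - 15 + 1), 15:n)
  }))
  expect_length(intersect(bgk, dbk), 0L)
  # determinism and the empty case
  bg2 <- make_background(db, n_seqs = 30, mean_length = 1000, seed = 3)
  expect_identical(as.character(bg), as.character(bg2))
  expect_length(make_background(db, n_seqs = 0), 0L)
})

test_that("pure background reads are never recruited", {
  db <- small_fixture$exon23_db
  bg <- make_background(db, n_seqs = 10, mean_length = 1500, seed = 5)
  sim <- simulate_reads(bg, n_pairs = 300, read_length = 100,
                        error_rate = 0, insert_mean = 250, insert_sd = 25,
                        seed = 6)
  rec <- recruit_reads(c(sim$read1, sim$read2), build_kmer_index(db, 15))
  expect_equal(nrow(rec), 0L)
})

test_that("spike-in truth sets have the diploid 2xA 2xB 2xC design", {
  db <- small_fixture$exon23_db
  truth <- choose_allele_sets(db, n_sets = 20, seed = 9)
  expect_equal(nrow(truth), 120L)  # 20 sets x 6 alleles
  counts <- table(truth$sample, truth$gene)
  expect_true(all(counts == 2L))
  expect_equal(parse_allele_name(truth$allele)$gene, truth$gene)
  # seeded rerun identical
  expect_identical(truth, choose_allele_sets(db, n_sets = 20, seed = 9))
  # heterozygous draws have two distinct alleles per gene
  het <- choose_allele_sets(db, n_sets = 20, seed = 9, replace = FALSE)
  per_gene <- tapply(het$allele, paste(het$sample, het$gene),
                     function(a) length(unique(a)))
  expect_true(all(per_gene == 2L))
  # null alleles never drawn by default
  expect_false(any(is_null_allele(truth$allele)))
  # a gene missing from the database is an error
  dbA <- shotgunHLA:::.new_ref_db(db$seq[1:5], "exon23")  # A alleles only
  expect_error(choose_allele_sets(dbA, 2), "gene B")
})

test_that("error-free simulated reads are exact template substrings", {
  db <- small_fixture$exon23_db
  tpl <- stats::setNames(as.character(db$seq[1:2]), names(db$seq)[1:2])
  sim <- simulate_reads(tpl, n_pairs = 200, read_length = 100,
                        error_rate = 0, insert_mean = 250, insert_sd = 25,
                        seed = 11)
  expect_length(sim$read1, 200L)
  expect_length(sim$read2, 200L)
  both <- paste(tpl, collapse = "NNN")
  rc <- shotgunHLA:::.revcomp_chr(c(sim$read1, sim$read2))
  fwd <- c(sim$read1, sim$read2)
  ok <- vapply(seq_along(fwd), function(i)
    grepl(fwd[i], both, fixed = TRUE) || grepl(rc[i], both, fixed = TRUE),
    TRUE)
  expect_true(all(ok))
})

test_that("the observed substitution rate matches the requested rate", {
  db <- small_fixture$exon23_db
  tpl <- stats::setNames(as.character(db$seq[1]), names(db$seq)[1])
  sim <- simulate_reads(tpl, n_pairs = 600, read_length = 100,
                        error_rate = 0.01, insert_mean = 250, insert_sd = 25,
                        seed = 13)
  # recount mismatches independently against the template at truth positions
  t1 <- tpl[[1]]
  mm <- 0L
  for (i in seq_along(sim$read1)) {
    ref1 <- substr(t1, sim$truth$start1[i], sim$truth$start1[i] + 99L)
    mm <- mm + sum(strsplit(sim$read1[[i]], "")[[1]] !=
                     strsplit(ref1, "")[[1]])
    ref2 <- substr(t1, sim$truth$start2[i], sim$truth$start2[i] + 99L)
    r2 <- shotgunHLA:::.revcomp_chr(sim$read2[[i]])
    mm <- mm + sum(strsplit(r2, "")[[1]] != strsplit(ref2, "")[[1]])
  }
  rate <- mm / (1200 * 100)
  expect_gt(rate, 0.008)
  expect_lt(rate, 0.012)
})

test_that("fragment accounting gives the expected mean depth of coverage", {
  db <- small_fixture$exon23_db
  tpl <- stats::setNames(as.character(db$seq[1]), names(db$seq)[1])
  n_pairs <- 500L
  sim <- simulate_reads(tpl, n_pairs = n_pairs, read_length = 100,
                        error_rate = 0, insert_mean = 250, insert_sd = 25,
                        seed = 17)
  # pileup from the recorded truth coordinates
  cov <- integer(nchar(tpl[[1]]))
  for (i in seq_len(n_pairs)) {
    for (st in c(sim$truth$start1[i], sim$truth$start2[i])) {
      idx <- st:(st + 99L)
      cov[idx] <- cov[idx] + 1L
    }
  }
  expected <- n_pairs * 2 * 100 / nchar(tpl[[1]])
  expect_equal(mean(cov), expected, tolerance = 0.1)
  # and the simulator is deterministic
  sim2 <- simulate_reads(tpl, n_pairs = n_pairs, read_length = 100,
                         error_rate = 0, insert_mean = 250, insert_sd = 25,
                         seed = 17)
  expect_identical(sim$read1, sim2$read1)
  expect_identical(sim$read2, sim2$read2)
})

test_that("degenerate simulator inputs are rejected or skipped", {
  tpl <- c(long = rand_seq(600), short = rand_seq(50))
  expect_warning(
    sim <- simulate_reads(tpl, n_pairs = 50, read_length = 100,
                          error_rate = 0, insert_mean = 250, insert_sd = 25,
                          seed = 19),
    "shorter than the read length")
  expect_true(all(grepl("^long_", names(sim$read1))))
  expect_error(simulate_reads(tpl[1], 10, read_length = 300,
                              insert_mean = 250), "insert_mean")
  expect_error(simulate_reads(tpl[1], 10, error_rate = 0.5), "error_rate")
})

test_that("FASTQ round-trips preserve ids and sequences", {
  db <- small_fixture$exon23_db
  tpl <- stats::setNames(as.character(db$seq[1]), names(db$seq)[1])
  sim <- simulate_reads(tpl, n_pairs = 20, read_length = 80,
                        error_rate = 0.01, insert_mean = 200, insert_sd = 20,
                        seed = 23)
  paths <- write_fastq_pair(sim, file.path(tempdir(), "simrt"))
  r1 <- read_fastq(file.path(tempdir(), "simrt_1.fastq"))
  expect_identical(unname(r1), unname(sim$read1))
  expect_identical(names(r1), names(sim$read1))
})
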