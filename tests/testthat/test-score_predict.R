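test_that("contig scores follow size x depth x identity with doubling", {
  expect_equal(contig_score(200, 10, 1.0), 2000)
  expect_equal(contig_score(200, 10, 1.0, reciprocal = TRUE), 4000)
  expect_equal(contig_score(250, 4.0, 0.98), 980)
  expect_error(contig_score(200, 0, 1.0), "depth")
})

test_that("contig probabilities are tie-set sums of 1/N", {
  expect_equal(contig_probability(1, 100), 0.01)
  expect_equal(contig_probability(3, 100), 0.03)
  expect_error(contig_probability(1, 0), "empty")
  expect_error(contig_probability(0, 10), "non-empty")
})

test_that("expect values multiply independent contig probability pairs", {
  expect_equal(expect_value(0.01, 0.01), 1e-4)
  expect_equal(expect_value(c(0.01, 0.01), c(0.01, 0.01)), 1e-8)
  expect_error(expect_value(0, 0.1), "positive")
  expect_error(expect_value(numeric(0), numeric(0)))
})

test_that("confidence is -10 log10 of the expect value", {
  expect_equal(confidence(1.0), 0.0)
  expect_equal(confidence(1e-4), 40)
  expect_error(confidence(0), "positive")
  expect_error(confidence(-1), "positive")
})

test_that("per-allele evidence sums contig scores and multiplies Evals", {
  db <- small_fixture$exon23_db
  tpl <- as.character(db$seq[["C*02:01"]])
  contigs <- data.frame(
    id = c("contig0001", "contig0002"),
    sequence = c(substr(tpl, 1, 300), substr(tpl, 230, 546)),
    length = c(300L, 317L), depth = c(8, 6), n_reads = c(24L, 19L),
    stringsAsFactors = FALSE)
  class(contigs) <- c("hla_contigs", "data.frame")
  ev <- score_alleles(contigs, db)
  expect_gt(nrow(ev$alleles), 0L)
  # additivity: S_HLA equals the sum of the logged per-contig scores
  for (a in ev$alleles$allele) {
    p <- ev$pairs[ev$pairs$subject_id == a, ]
    expect_equal(ev$alleles$S_HLA[ev$alleles$allele == a], sum(p$score))
    expect_equal(ev$alleles$log10_eval[ev$alleles$allele == a],
                 sum(log10(p$p_fwd * p$p_rev)))
  }
  # the spiked allele dominates its gene
  top <- ev$alleles[ev$alleles$gene == "C", ]
  expect_equal(top$allele[which.max(top$S_HLA)], "C*02:01")
  # reciprocal doubling: every reciprocal pair contributes twice the
  # non-reciprocal formula
  ci <- match(ev$pairs$query_id, contigs$id)
  base <- contigs$length[ci] * contigs$depth[ci] * ev$pairs$identity_aln
  expect_equal(ev$pairs$score, base * ifelse(ev$pairs$reciprocal, 2, 1))
})

test_that("adding a supporting contig strictly decreases the expect value", {
  db <- small_fixture$exon23_db
  tpl <- as.character(db$seq[["B*03:01"]])
  one <- data.frame(id = "contig0001", sequence = substr(tpl, 1, 300),
                    length = 300L, depth = 5, n_reads = 15L,
                    stringsAsFactors = FALSE)
  two <- rbind(one, data.frame(id = "contig0002",
                               sequence = substr(tpl, 240, 546),
                               length = 307L, depth = 5, n_reads = 15L,
                               stringsAsFactors = FALSE))
  class(one) <- class(two) <- c("hla_contigs", "data.frame")
  e1 <- score_alleles(one, db)$alleles
  e2 <- score_alleles(two, db)$alleles
  a <- "B*03:01"
  expect_lt(e2$Eval[e2$allele == a], e1$Eval[e1$allele == a])
  expect_gt(e2$confidence[e2$allele == a], e1$confidence[e1$allele == a])
})

test_that("ranking orders groups by score and reports ambiguity sets", {
  db <- small_fixture$exon23_db
  # strong support for A*02:01, weaker for A*04:01: two slots in order
  t1 <- as.character(db$seq[["A*02:01"]])
  t2 <- as.character(db$seq[["A*04:01"]])
  contigs <- data.frame(
    id = c("contig0001", "contig0002"),
    sequence = c(t1, substr(t2, 1, 400)),
    length = c(546L, 400L), depth = c(10, 4), n_reads = c(30L, 12L),
    stringsAsFactors = FALSE)
  class(contigs) <- c("hla_contigs", "data.frame")
  ev <- score_alleles(contigs, db)
  pred <- rank_and_report(ev)
  pa <- pred[pred$gene == "A", ]
  expect_equal(unique(pa$group[pa$slot == 1]), "A*02")
  expect_equal(unique(pa$group[pa$slot == 2]), "A*04")
  # within every gene the slot order is non-increasing in best score
  best_by_slot <- tapply(pa$score, pa$slot, max)
  expect_true(all(diff(best_by_slot) <= 1e-9))
})

test_that("identical-scoring alleles form one lexicographic ambiguity set", {
  fx <- small_fixture
  db <- fx$exon23_db
  # a contig that stops short of the base distinguishing C*04:01 from
  # C*04:02 supports both with identical score and Eval
  cds_diff <- fx$truth$mutations[["C*04:02"]]$extra_positions
  exon_pos <- shotgunHLA:::.cds_to_exon23(cds_diff, fx$exons)
  tpl <- as.character(db$seq[["C*04:01"]])
  end <- if (is.na(exon_pos)) 546L else exon_pos - 1L
  contig <- substr(tpl, max(1L, end - 400L), end)
  contigs <- data.frame(id = "contig0001", sequence = contig,
                        length = nchar(contig), depth = 6,
                        n_reads = 18L, stringsAsFactors = FALSE)
  class(contigs) <- c("hla_contigs", "data.frame")
  pred <- rank_and_report(score_alleles(contigs, db))
  slot1 <- pred[pred$gene == "C" & pred$slot == 1, ]
  expect_true(all(c("C*04:01", "C*04:02") %in% slot1$allele))
  expect_true(all(slot1$ambiguous))
  expect_equal(slot1$allele, sort(slot1$allele))
  expect_equal(length(unique(slot1$score)), 1L)
  expect_equal(length(unique(slot1$eval)), 1L)
})

test_that("homozygous support yields a single prediction slot", {
  db <- small_fixture$exon23_db
  tpl <- as.character(db$seq[["B*05:01"]])
  contigs <- data.frame(id = "contig0001", sequence = tpl,
                        length = 546L, depth = 20, n_reads = 60L,
                        stringsAsFactors = FALSE)
  class(contigs) <- c("hla_contigs", "data.frame")
  pred <- rank_and_report(score_alleles(contigs, db))
  pb <- pred[pred$gene == "B", ]
  expect_equal(unique(pb$slot), 1L)
  expect_equal(unique(pb$group), "B*05")
})

test_that("null alleles are hidden unless requested", {
  fx <- small_fixture
  db <- fx$exon23_db
  null_name <- names(db$seq)[is_null_allele(names(db$seq))]
  expect_length(null_name, 1L)
  tpl <- as.character(db$seq[[null_name]])
  contigs <- data.frame(id = "contig0001", sequence = tpl,
                        length = nchar(tpl), depth = 10, n_reads = 30L,
                        stringsAsFactors = FALSE)
  class(contigs) <- c("hla_contigs", "data.frame")
  ev <- score_alleles(contigs, db)
  pred <- rank_and_report(ev)
  expect_false(null_name %in% pred$allele)
  pred2 <- rank_and_report(ev, include_null = TRUE)
  expect_true(null_name %in% pred2$allele)
})

test_that("direct-alignment mode scores reads as depth-1 contigs", {
  db <- small_fixture$exon23_db
  a <- "A*01:01"
  tpl <- as.character(db$seq[[a]])
  sam <- tempfile(fileext = ".sam")
  con <- file(sam, "w")
  writeLines("@HD\tVN:1.6", con)
  for (nm in names(db$seq))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, 546L), con)
  # 100 perfect unique 100-nt reads
  for (i in 1:100) {
    st <- ((i - 1) %% 440) + 1
    writeLines(sprintf("r%03d\t0\t%s\t%d\t60\t100M\t*\t0\t0\t%s\t%s\tNM:i:0",
                       i, a, st, substr(tpl, st, st + 99), strrep("I", 100)),
               con)
  }
  close(con)
  res <- predict_from_alignments(sam, db)
  ev <- res$evidence$alleles
  expect_equal(ev$S_HLA[ev$allele == a], 100 * (100 * 1 * 1.0))
  expect_equal(res$predictions$group[res$predictions$slot == 1 &
                                       res$predictions$gene == "A"][1], "A*01")

  # a read tying two alleles doubles its tie probability
  sam2 <- tempfile(fileext = ".sam")
  con <- file(sam2, "w")
  writeLines("@HD\tVN:1.6", con)
  for (nm in names(db$seq))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, 546L), con)
  writeLines(sprintf("rr\t0\tA*01:01\t1\t60\t100M\t*\t0\t0\t%s\t%s\tNM:i:0",
                     substr(tpl, 1, 100), strrep("I", 100)), con)
  writeLines(sprintf("rr\t256\tA*01:02\t1\t60\t100M\t*\t0\t0\t%s\t%s\tNM:i:0",
                     substr(tpl, 1, 100), strrep("I", 100)), con)
  close(con)
  res2 <- predict_from_alignments(sam2, db)
  expect_equal(unique(res2$evidence$pairs$p_fwd), 2 / db$N)

  # unresolvable reference names are an error
  sam3 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:X*99:99\tLN:546",
               sprintf("r1\t0\tX*99:99\t1\t60\t100M\t*\t0\t0\t%s\t%s",
                       substr(tpl, 1, 100), strrep("I", 100))), sam3)
  expect_error(predict_from_alignments(sam3, db), "X\\*99:99")
})
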