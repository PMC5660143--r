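test_that("FASTA round-trips, folds case, and rejects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt"), tmp)
  g <- read_fasta(tmp)
  expect_identical(unname(g[["c1"]]), "ACGT")

  g2 <- as_genome(c(a = "ACGTACGTAA", b = "NNACGT"))
  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g2, out)
  g3 <- read_fasta(out)
  expect_identical(as.character(unclass(g3)), as.character(unclass(g2)))

  expect_error(as_genome(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(as_genome(c(a = "")), "empty")
  expect_error(as_genome(c(a = "ACGU")), "non-ACGTN")
})

test_that("GTF and BED12 dialects converge to 0-based half-open internals", {
  w <- tiny_world()
  gtf <- withr::local_tempfile(fileext = ".gtf")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gene_models(w$db, gtf, "gtf")
  write_gene_models(w$db, bed, "bed12")
  db_g <- read_gene_models(gtf, "gtf", genome = w$genome)
  db_b <- read_gene_models(bed, "bed12", genome = w$genome)
  for (db2 in list(db_g, db_b)) {
    for (tid in c("TXP", "TXM")) {
      expect_equal(tx_exons(db2, tid)$start, tx_exons(w$db, tid)$start)
      expect_equal(tx_exons(db2, tid)$end, tx_exons(w$db, tid)$end)
    }
    tr <- db2$transcripts
    expect_equal(tr$strand[match(c("TXP", "TXM"), tr$transcript_id)],
                 c("+", "-"))
    expect_equal(tr$coding[match(c("TXP", "TXM"), tr$transcript_id)],
                 c(TRUE, FALSE))
  }
  # 1-based inclusive GTF line [11,20] must become [10,20)
  gtf2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0("c1\tx\texon\t11\t20\t.\t+\t.\t",
                    'gene_id "g"; transcript_id "t";'), gtf2)
  db1 <- read_gene_models(gtf2, "gtf")
  expect_equal(tx_exons(db1, "t")$start, 10)
  expect_equal(tx_exons(db1, "t")$end, 20)
  # unsorted exons are silently sorted, with a warning
  gtf3 <- withr::local_tempfile(fileext = ".gtf")
  attr9 <- 'gene_id "g"; transcript_id "t";'
  writeLines(c(paste0("c1\tx\texon\t51\t80\t.\t+\t.\t", attr9),
               paste0("c1\tx\texon\t11\t20\t.\t+\t.\t", attr9)), gtf3)
  expect_warning(db3 <- read_gene_models(gtf3, "gtf"), "unsorted")
  expect_equal(tx_exons(db3, "t")$start, c(10, 50))
})

test_that("transcript_db enforces its invariants", {
  tr <- data.frame(transcript_id = "t", gene_id = "g", chrom = "c",
                   strand = "+", coding = FALSE)
  expect_error(transcript_db(tr, data.frame(transcript_id = "t",
                                            start = 5L, end = 5L)), "empty")
  expect_error(
    transcript_db(tr, data.frame(transcript_id = "t",
                                 start = c(0L, 5L), end = c(10L, 15L))),
    "overlapping")
  expect_error(
    transcript_db(tr, data.frame(transcript_id = "t", start = 0L, end = 99L),
                  genome = as_genome(c(c = "ACGT"))),
    "outside chromosome")
})

test_that("catalog writes 14 columns, sorted, and round-trips", {
  cat1 <- data.frame(
    chrom = c("chr2", "chr1"), start = c(5L, 10L), end = c(50L, 90L),
    strand = c("+", "-"), circ_id = c("chr2:5-50:+", "chr1:10-90:-"),
    junction_reads = c(3L, 7L), linear_5p_reads = c(1L, 0L),
    linear_3p_reads = c(2L, 0L), CLR = c(1.5, 7),
    host_transcript = c("tA", NA), orientation = c("sense", "sense"),
    category = c("coding_exon", "intergenic"),
    genomic_length = c(45L, 80L), spliced_length = c(45L, NA),
    stringsAsFactors = FALSE)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat1, tmp)
  back <- read_catalog(tmp)
  expect_equal(names(back), circkit:::.catalog_cols)
  expect_equal(back$chrom, c("chr1", "chr2"))  # deterministic order
  expect_equal(back[back$chrom == "chr2", ]$CLR, 1.5)
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat1[0, ], t2)
  expect_equal(nrow(read_catalog(t2)), 0)
  bad <- cat1; bad$CLR[1] <- NA
  expect_error(write_catalog(bad, tmp), "quantification")
})
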