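test_that("generator is deterministic and introns carry GT/AG", {
  sc <- sim_config(seed = 7, n_genes = 5, depth = 20)
  w1 <- make_genome_and_genes(sc)
  w2 <- make_genome_and_genes(sc)
  expect_identical(w1$genome, w2$genome)
  expect_identical(w1$db$exons, w2$db$exons)
  expect_equal(nrow(w1$db$transcripts), 5)
  # every intron reads GT...AG on the transcript strand
  for (tid in w1$db$transcripts$transcript_id) {
    tr <- w1$db$transcripts[w1$db$transcripts$transcript_id == tid, ]
    ex <- tx_exons(w1$db, tid)
    chr <- w1$genome[[tr$chrom]]
    for (j in seq_len(nrow(ex) - 1)) {
      intr <- substr(chr, ex$end[j] + 1, ex$start[j + 1])
      if (tr$strand == "-") intr <- circkit:::revcomp(intr)
      expect_equal(substr(intr, 1, 2), "GT")
      expect_equal(substr(intr, nchar(intr) - 1, nchar(intr)), "AG")
    }
  }
})

test_that("planted circles record exact junctions and spliced sequences", {
  sc <- sim_config(seed = 3, n_genes = 6, depth = 20)
  w <- make_genome_and_genes(sc)
  tr <- plant_circles(w$db, w$genome, 4, 0.5, seed = 11)
  expect_true(all(tr$acceptor_exon <= tr$donor_exon))
  for (i in seq_len(nrow(tr))) {
    ex_t <- circkit:::.tx_exons_txorder(w$db, tr$transcript_id[i])
    blk <- ex_t[tr$acceptor_exon[i]:tr$donor_exon[i], , drop = FALSE]
    expect_equal(tr$start[i], min(blk$start))
    expect_equal(tr$end[i], max(blk$end))
    # spliced length is additive over exon lengths
    expect_equal(nchar(tr$spliced_seq[i]), sum(blk$end - blk$start))
  }
  expect_error(plant_circles(w$db, w$genome, 100), ">= 3 exons")
})

test_that("circular reads wrap the ring and junction share matches binomial", {
  sc <- sim_config(seed = 5, n_genes = 1, exons_per_gene = c(3, 3),
                   exon_len = c(150, 150), depth = 10000,
                   circular_fraction = 1)
  w <- make_genome_and_genes(sc)
  tr <- plant_circles(w$db, w$genome, 1, 1, seed = 5)
  reads <- simulate_reads(w$genome, w$db, tr, sc)
  circ <- reads[reads$class == "circular", ]
  expect_gt(nrow(circ), 9000)
  L <- nchar(tr$spliced_seq); rl <- sc$read_length
  # error-free junction reads equal suffix+prefix of the truth ring
  doubled <- paste0(tr$spliced_seq, tr$spliced_seq)
  expect_true(all(vapply(circ$seq, function(s)
    grepl(s, doubled, fixed = TRUE), logical(1))))
  # expected junction-read share (rl-1)/L; observed within 3 binomial SD
  p <- (rl - 1) / L
  obs <- sum(circ$junction_overlap)
  expect_lt(abs(obs - nrow(circ) * p), 3 * sqrt(nrow(circ) * p * (1 - p)))
})

test_that("RNase R digestion follows the per-class survival model", {
  reads <- data.frame(read_id = sprintf("r%04d", 1:2000),
                      seq = strrep("A", 40),
                      class = rep(c("linear", "circular"), each = 1000),
                      transcript_id = "t", circ_id = NA,
                      junction_overlap = FALSE, crossings = "",
                      stringsAsFactors = FALSE)
  # boundary cases: (0,1) keeps only circles, (1,1) is the identity
  only_circ <- simulate_rnase_r(reads, 0, 1, seed = 2)
  expect_true(all(only_circ$class == "circular"))
  expect_equal(nrow(only_circ), 1000)
  expect_identical(simulate_rnase_r(reads, 1, 1, seed = 2), reads)
  # survival 0.1 on 1000 linear reads: within 3 SD of Binomial(1000, 0.1)
  kept <- simulate_rnase_r(reads, 0.1, 1, seed = 3)
  n_lin <- sum(kept$class == "linear")
  expect_lt(abs(n_lin - 100), 3 * sqrt(1000 * 0.1 * 0.9))
})

test_that("FASTQ truth tags round-trip", {
  sc <- sim_config(seed = 9, n_genes = 2, depth = 10)
  w <- make_genome_and_genes(sc)
  tr <- plant_circles(w$db, w$genome, 1, 0.5, seed = 9,
                      min_spliced_length = sc$read_length)
  reads <- simulate_reads(w$genome, w$db, tr, sc)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$class, reads$class)
  expect_equal(back$circ_id, reads$circ_id)
  expect_equal(back$junction_overlap, reads$junction_overlap)
  expect_equal(back$crossings, reads$crossings)
})

test_that("Ct simulation encodes fold changes as -log2 shifts", {
  samples <- data.frame(sample = c("a1", "a2", "b1", "b2"),
                        group = c("case", "case", "ctrl", "ctrl"))
  targets <- data.frame(target = c("tg", "spike", "hk"),
                        role = c("assay", "spike_in", "housekeeper"))
  eff <- data.frame(target = "tg", group = "case", fold = 2)
  ct <- simulate_ct_table(samples, targets, eff, n_replicates = 2,
                          noise_sd = 0, seed = 1)
  m <- tapply(ct$ct[ct$target == "tg"], ct$group[ct$target == "tg"], mean)
  expect_equal(unname(m["case"] - m["ctrl"]), -1)  # fold 2 = 1 cycle lower
  expect_error(simulate_ct_table(samples, targets, eff, noise_sd = -1),
               "non-negative")
  bad <- data.frame(target = "spike", group = "case", fold = 2)
  expect_error(simulate_ct_table(samples, targets, bad), "assay")
})
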