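test_that("circular sequence reconstruction respects strand and introns", {
  w <- tiny_world()
  # single-exon circle on the plus strand: ring = exon 2
  candP <- data.frame(chrom = "chr1", start = 170L, end = 230L, strand = "+",
                      host_transcript = "TXP", category = "coding_exon")
  rp <- circular_sequence(candP, w$db, w$genome)
  expect_equal(rp$seq, w$exP[2])
  expect_equal(rp$junction_index, 0L)
  # two-exon circle skips the intron
  cand2 <- data.frame(chrom = "chr1", start = 170L, end = 350L, strand = "+",
                      host_transcript = "TXP", category = "coding_exon")
  expect_equal(circular_sequence(cand2, w$db, w$genome)$seq,
               paste0(w$exP[2], w$exP[3]))
  # minus-strand ring is the reverse complement of the genomic segment
  candM <- data.frame(chrom = "chr1", start = 470L, end = 510L, strand = "-",
                      host_transcript = "TXM", category = "noncoding_gene")
  expect_equal(circular_sequence(candM, w$db, w$genome)$seq, w$exM[2])
  # no spliced model for intronic candidates
  candI <- data.frame(chrom = "chr1", start = 120L, end = 160L, strand = "+",
                      host_transcript = "TXP", category = "intronic")
  expect_error(circular_sequence(candI, w$db, w$genome), "no spliced model")
})

test_that("hand-built rings give the expected junction ORFs", {
  # Met-Lys-stop entirely inside the ring: nothing spans the junction
  expect_equal(nrow(find_junction_orfs("ATGAAATAG")), 0)
  # Met 6 nt before the junction, stop 9 nt past it
  ring <- paste0("CCACCC", "TAAACCACC", "ATGAAA")  # junction after last base
  o <- find_junction_orfs(ring)
  expect_equal(nrow(o), 1)
  expect_equal(o$aa, "MKPP")
  expect_equal(o$start, nchar(ring) - 6)
  expect_false(o$no_stop_in_circle)
  # stop-free ring: truncated at one loop length and flagged
  ring2 <- paste0("AAA", "ATG", strrep("GCT", 9), "CCC")  # 36 nt, no stop
  o2 <- find_junction_orfs(ring2)
  expect_gte(nrow(o2), 1)
  expect_true(all(o2$no_stop_in_circle))
  expect_true(all(o2$nt_end - o2$nt_start <= nchar(ring2)))
  expect_true(all(o2$nt_end > nchar(ring2)))
})

test_that("doubled-string enumeration equals the exhaustive oracle", {
  for (seed in 1:12) {
    ring <- random_ring(300, seed)
    mine <- find_junction_orfs(ring)
    orac <- oracle_junction_orfs(ring)
    rownames(mine) <- rownames(orac) <- NULL
    expect_equal(mine, orac, info = sprintf("seed %d", seed))
  }
  # shorter rings exercise the truncation paths harder
  for (seed in 1:8) {
    ring <- random_ring(40 + seed, seed + 100)
    mine <- find_junction_orfs(ring)
    orac <- oracle_junction_orfs(ring)
    rownames(mine) <- rownames(orac) <- NULL
    expect_equal(mine, orac, info = sprintf("short seed %d", seed))
  }
})

test_that("tryptic digestion cleaves after K/R but not before P", {
  d0 <- tryptic_digest("MKRGT")
  expect_equal(d0$peptide, c("MK", "R", "GT"))
  expect_equal(tryptic_digest("MKPGT")$peptide, "MKPGT")  # K-P: no cut
  d2 <- tryptic_digest("AAKBBRCC", missed_cleavages = 1)
  expect_setequal(d2$peptide, c("AAK", "AAKBBR", "BBR", "BBRCC", "CC"))
})

test_that("every emitted peptide straddles the junction", {
  for (seed in 1:20) {
    ring <- random_ring(120, seed + 500)
    orfs <- find_junction_orfs(ring)
    if (nrow(orfs) == 0) next
    peps <- junction_peptides(orfs, ring, "x", min_len = 1, max_len = 1000)
    L <- nchar(ring)
    d <- strrep(ring, 2)
    for (i in seq_len(nrow(peps))) {
      expect_lt(peps$nt_start[i], L)
      expect_gt(peps$nt_end[i], L)
      # the peptide really is the translation of its doubled-string span
      codons <- substring(d, seq(peps$nt_start[i] + 1, peps$nt_end[i], 3),
                          seq(peps$nt_start[i] + 3, peps$nt_end[i], 3))
      expect_equal(paste(circkit:::translate_codons(codons), collapse = ""),
                   peps$peptide[i])
    }
  }
  # an ORF without K/R yields one peptide: the whole ORF
  ring <- paste0("GGGGGG", "ATGGGA")   # M G G G ... around the junction
  orfs <- find_junction_orfs(ring)
  if (nrow(orfs) > 0) {
    peps <- junction_peptides(orfs, ring, "x", min_len = 1, max_len = 100)
    expect_true(all(vapply(seq_len(nrow(peps)), function(i)
      peps$peptide[i] %in% orfs$aa, logical(1))))
  }
})

test_that("length bounds and junction filter prune the peptide DB", {
  # build a ring whose single junction ORF contains one tryptic site well
  # before the junction: the N-terminal fragment must be discarded
  ring <- paste0(strrep("C", 30), "ATGAAACGT", strrep("GCT", 4))
  # ORF starts 21 nt before junction; peptide after K ("MK" | rest)
  orfs <- find_junction_orfs(ring)
  peps <- junction_peptides(orfs, ring, "x", min_len = 1, max_len = 100)
  expect_true(all(peps$nt_end > nchar(ring)))
  expect_false(any(peps$peptide == "MK"))
  # default 7-35 aa bounds drop short fragments
  peps7 <- junction_peptides(orfs, ring, "x")
  expect_true(all(nchar(peps7$peptide) >= 7 & nchar(peps7$peptide) <= 35))
})

test_that("observed peptides are matched exactly with verdicts", {
  db <- data.frame(circ_id = c("c1", "c2"), frame = 0L, orf_start = 0L,
                   peptide = c("LLGATK", "WWPNQR"), nt_start = 0L,
                   nt_end = 18L, stringsAsFactors = FALSE)
  hits <- filter_hits(c("LLGATK", "AAAAAA"), db)
  expect_equal(hits$verdict,
               c("junction_spanning_match", "non_junction"))
  expect_equal(hits$circ_id, c("c1", NA))
  expect_equal(nrow(filter_hits(character(0), db)), 0)
})
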