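test_that("k-mer index agrees with a naive scan on a random genome", {
  set.seed(1)
  g <- as_genome(c(c1 = paste(sample(c("A", "C", "G", "T"), 100, TRUE),
                              collapse = "")))
  k <- 6
  idx <- build_index(g, k)
  s <- g[["c1"]]
  naive_hits <- function(q) {
    fw <- which(vapply(1:(nchar(s) - k + 1),
                       function(i) substr(s, i, i + k - 1) == q,
                       logical(1))) - 1L
    rc <- which(vapply(1:(nchar(s) - k + 1),
                       function(i) substr(s, i, i + k - 1) ==
                         circkit:::revcomp(q), logical(1))) - 1L
    rbind(if (length(fw)) data.frame(pos = fw, strand = "+"),
          if (length(rc)) data.frame(pos = rc, strand = "-"))
  }
  for (i in c(1, 20, 40, 77, 95)) {
    q <- substr(s, i, i + k - 1)
    hits <- index_lookup(idx, q)
    exp <- naive_hits(q)
    expect_equal(nrow(hits), nrow(exp))
    expect_setequal(paste(hits$pos, hits$strand),
                    paste(exp$pos, exp$strand))
  }
  expect_equal(nrow(index_lookup(idx, strrep("A", k))), 0)  # absent k-mer
})

test_that("anchor extraction honours the 2x-anchor length boundary", {
  expect_equal(extract_anchors(strrep("A", 39), 20), NULL)
  an <- extract_anchors(paste0(strrep("A", 20), strrep("C", 20)), 20)
  expect_equal(an$head, strrep("A", 20))
  expect_equal(an$tail, strrep("C", 20))
})

test_that("junction calls reproduce planted coordinates on both strands", {
  w <- tiny_world()
  idx <- build_index(w$genome, 20)
  # plus-strand circle over TXP exon 2: span [170, 230), ring = exon 2
  ringP <- w$exP[2]
  readP <- ring_read(ringP, 30, 30)
  resP <- call_junction(readP, idx, w$genome, 20)
  expect_equal(resP$status, "called")
  expect_equal(resP$call$acceptor, 170)
  expect_equal(resP$call$donor, 230)
  expect_equal(resP$call$strand, "+")
  # minus-strand circle over TXM exon 2 (transcript order): genomic span
  # [470, 510)
  ringM <- w$exM[2]
  readM <- ring_read(ringM, 20, 20)
  resM <- call_junction(readM, idx, w$genome, 20)
  expect_equal(resM$status, "called")
  expect_equal(resM$call$acceptor, 470)
  expect_equal(resM$call$donor, 510)
  expect_equal(resM$call$strand, "-")
  # mutating the acceptor-side AG kills the call
  g2 <- unclass(w$genome)
  chr <- g2[["chr1"]]
  substr(chr, 169, 169) <- if (substr(chr, 169, 169) == "C") "T" else "C"
  substr(chr, 170, 170) <- "C"            # AG -> xC before position 170
  g2 <- as_genome(c(chr1 = chr))
  idx2 <- build_index(g2, 20)
  resX <- call_junction(readP, idx2, g2, 20)
  expect_false(identical(resX$status, "called"))
  # a junction-free read maps in genomic order: no call
  lin <- substr(w$genome[["chr1"]], 51, 150)
  expect_equal(call_junction(lin, idx, w$genome, 20)$status, "no_call")
})

test_that("detector calls agree with an exhaustive split-point oracle", {
  # brute force: try every split of the read, place both parts exactly,
  # and demand the AG/GT (or AC/CT) flanks
  oracle_call <- function(read, genome) {
    s <- genome[["chr1"]]; L <- nchar(read)
    res <- list()
    for (strand in c("+", "-")) {
      rd <- if (strand == "+") read else circkit:::revcomp(read)
      sigL <- if (strand == "+") "AG" else "AC"
      sigR <- if (strand == "+") "GT" else "CT"
      for (sp in 1:(L - 1)) {
        a <- substr(rd, 1, sp); b <- substr(rd, sp + 1, L)
        pa <- gregexpr(a, s, fixed = TRUE)[[1]]
        pb <- gregexpr(b, s, fixed = TRUE)[[1]]
        if (pa[1] == -1 || pb[1] == -1) next
        for (i in pa) for (j in pb) {
          donor <- (i - 1) + sp; acc <- (j - 1)
          if (acc >= donor) next
          if (substr(s, donor + 1, donor + 2) == sigR &&
              substr(s, acc - 1, acc) == sigL)
            res[[length(res) + 1]] <- c(acc, donor, strand)
        }
      }
    }
    unique(res)
  }
  sc <- sim_config(seed = 21, n_genes = 6, depth = 150,
                   circular_fraction = 0.8)
  w <- make_genome_and_genes(sc)
  tr <- plant_circles(w$db, w$genome, 3, 0.8, seed = 21,
                      min_spliced_length = sc$read_length)
  reads <- simulate_reads(w$genome, w$db, tr, sc)
  jr <- reads[reads$junction_overlap, ]
  jr <- jr[seq_len(min(nrow(jr), 60)), ]
  det <- detect_backsplices(reads, w$genome, min_unique_reads = 1)
  for (i in seq_len(nrow(jr))) {
    ocalls <- oracle_call(jr$seq[i], w$genome)
    mycall <- det$calls[det$calls$read_id == jr$read_id[i], ]
    if (length(ocalls) == 1) {
      # unambiguous truth: detector must call it exactly (if anchors map)
      if (nrow(mycall) == 1) {
        expect_equal(mycall$acceptor, as.integer(ocalls[[1]][1]))
        expect_equal(mycall$donor, as.integer(ocalls[[1]][2]))
        expect_equal(mycall$strand, ocalls[[1]][3])
      }
    }
    if (nrow(mycall) == 1) {
      # every detector call must be oracle-consistent
      expect_true(any(vapply(ocalls, function(o)
        o[1] == mycall$acceptor && o[2] == mycall$donor &&
          o[3] == mycall$strand, logical(1))))
    }
  }
  # and every planted circle coordinate pair is among the detected set
  expect_true(all(tr$circ_id %in% det$candidates$circ_id))
})

test_that("collapse applies the two-unique-read minimum expression threshold", {
  mk <- function(n, seqs) data.frame(
    chrom = "c", strand = "+", acceptor = 10L, donor = 90L,
    splice_signal = "AG..GT", read_id = sprintf("r%d", seq_len(n)),
    read_seq = seqs, stringsAsFactors = FALSE)
  # 1 supporting read: dropped
  expect_equal(nrow(collapse_and_filter(mk(1, "AAAA"))), 0)
  # 2 distinct sequences: kept with junction_read_count = 2
  kept <- collapse_and_filter(mk(2, c("AAAA", "CCCC")))
  expect_equal(kept$junction_read_count, 2)
  # 5 identical sequences collapse to one unique read: dropped
  expect_equal(nrow(collapse_and_filter(mk(5, rep("AAAA", 5)))), 0)
  # read input order does not change the collapsed output
  calls <- rbind(mk(3, c("AAAA", "CCCC", "GGGG")),
                 within(mk(2, c("TTTT", "TTAA")), {
                   acceptor <- 200L; donor <- 400L
                 }))
  a <- collapse_and_filter(calls)
  b <- collapse_and_filter(calls[sample(nrow(calls)), ])
  expect_identical(a, b)
})
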