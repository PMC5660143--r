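# Shared fixtures, all built in code.

# A hand-laid two-gene world on one 600-nt chromosome.
#
# chr1 layout (0-based half-open):
#   [  0, 50)  intergenic
#   [ 50,110)  TXP exon 1 (+)
#   [110,170)  intron 1  GT....AG
#   [170,230)  TXP exon 2
#   [230,290)  intron 2  GT....AG
#   [290,350)  TXP exon 3
#   [350,400)  intergenic
#   [400,580)  TXM, minus strand, 3 exons of 40 nt, introns 30 nt
#   [580,600)  intergenic
tiny_world <- function(seed = 42) {
  set.seed(seed)
  rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  intron <- function(n) paste0("GT", rdna(n - 4), "AG")
  exP <- replicate(3, rdna(60))
  plus_gene <- paste0(exP[1], intron(60), exP[2], intron(60), exP[3])
  # minus gene built on the transcript strand, then reverse-complemented
  exM <- replicate(3, rdna(40))
  minus_tx <- paste0(exM[1], intron(30), exM[2], intron(30), exM[3])
  chr <- paste0(rdna(50), plus_gene, rdna(50),
                circkit:::revcomp(minus_tx), rdna(20))
  genome <- as_genome(c(chr1 = chr))
  tr <- data.frame(
    transcript_id = c("TXP", "TXM"), gene_id = c("GP", "GM"),
    chrom = "chr1", strand = c("+", "-"), coding = c(TRUE, FALSE),
    cds_start = c(50L, NA), cds_end = c(350L, NA),
    stringsAsFactors = FALSE)
  # minus-strand gene occupies [400, 580); transcript exon i (1-based,
  # 5'->3') maps to genomic [400 + 180 - t_end, 400 + 180 - t_start)
  m_t <- rbind(c(0, 40), c(70, 110), c(140, 180))
  m_ex <- data.frame(transcript_id = "TXM",
                     start = 400L + 180L - m_t[, 2],
                     end = 400L + 180L - m_t[, 1])
  ex <- rbind(
    data.frame(transcript_id = "TXP",
               start = c(50L, 170L, 290L), end = c(110L, 230L, 350L)),
    m_ex)
  db <- transcript_db(tr, ex, genome = genome)
  list(genome = genome, db = db,
       exP = exP, exM = exM)
}

# junction read over a planted circle: suffix of the ring then prefix
ring_read <- function(ring, flank5 = 50, flank3 = 50) {
  L <- nchar(ring)
  paste0(substr(ring, L - flank5 + 1, L), substr(ring, 1, flank3))
}

# independent brute-force junction-ORF oracle on the explicit doubled
# string: every start position with ATG in the first copy, earliest-Met
# maximality per (frame, stop), truncation at max_loops*L, junction
# crossing nt_start < L < nt_end.
oracle_junction_orfs <- function(ring, max_loops = 1) {
  L <- nchar(ring)
  d <- strrep(ring, 2)
  cap <- 3 * ((max_loops * L) %/% 3)
  aa1 <- function(codon) {
    a <- unname(Biostrings::GENETIC_CODE[codon])
    if (is.na(a)) "X" else a
  }
  res <- list()
  for (p in 0:(L - 1)) {
    if (substr(d, p + 1, p + 3) != "ATG") next
    # preceded in-frame by another ATG without intervening stop? then not
    # maximal
    maximal <- TRUE
    q <- p - 3
    while (q >= 0) {
      c0 <- substr(d, q + 1, q + 3)
      if (aa1(c0) == "*") break
      if (c0 == "ATG") { maximal <- FALSE; break }
      q <- q - 3
    }
    if (!maximal) next
    aa <- character(0); stopped <- FALSE; q <- p
    while (q + 3 <= 2 * L && (q + 3 - p) <= cap) {
      a <- aa1(substr(d, q + 1, q + 3))
      if (a == "*") { stopped <- TRUE; q <- q + 3; break }
      aa <- c(aa, a)
      q <- q + 3
    }
    nt_end <- if (stopped) q else p + 3 * length(aa)
    trunc <- !stopped
    if (!stopped && q + 3 <= 2 * L && (q + 3 - p) > cap) trunc <- TRUE
    if (p < L && nt_end > L && length(aa) > 0)
      res[[length(res) + 1]] <- data.frame(
        frame = p %% 3, start = p, nt_start = p, nt_end = nt_end,
        aa = paste(aa, collapse = ""), no_stop_in_circle = trunc,
        crosses_junction = TRUE, stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(frame = integer(0), start = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      aa = character(0), no_stop_in_circle = logical(0),
                      crosses_junction = logical(0)))
  out <- do.call(rbind, res)
  out[order(out$frame, out$start), , drop = FALSE]
}

random_ring <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}
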