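#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator. Defaults describe a
#' desk-scale rRNA-depleted total-RNA library: 20 multi-exon genes with
#' canonical GT/AG introns, 100-nt single-end reads, 100 fragments per
#' locus, a 50% circular fraction at planted loci, and RNase R digestion
#' that spares circles (survival 1.0) while degrading linear molecules
#' (survival 0.1).
#'
#' @param seed mandatory integer seed
#' @param n_genes number of genes to synthesize
#' @param exons_per_gene integer range (min, max)
#' @param exon_len,intron_len,intergenic_gap length ranges in nt
#' @param read_length read length in nt
#' @param depth fragments simulated per locus
#' @param circular_fraction share of fragments at a planted locus that are
#'   circular
#' @param error_rate i.i.d. substitution rate per base
#' @param rnase_r_linear_survival,rnase_r_circular_survival per-fragment
#'   survival probabilities under RNase R digestion
#' @param anchor_len detector anchor length (reads must be >= 2x this)
#' @param min_overhang nt required on each side for a linear read to count
#'   as crossing a splice boundary
#' @return list of class \code{"sim_config"}
#' @export
sim_config <- function(seed,
                       n_genes = 20L,
                       exons_per_gene = c(3L, 6L),
                       exon_len = c(80L, 300L),
                       intron_len = c(60L, 400L),
                       intergenic_gap = c(200L, 500L),
                       read_length = 100L,
                       depth = 100L,
                       circular_fraction = 0.5,
                       error_rate = 0,
                       rnase_r_linear_survival = 0.1,
                       rnase_r_circular_survival = 1.0,
                       anchor_len = 20L,
                       min_overhang = 5L) {
  if (missing(seed) || is.na(seed)) .fail("seed is mandatory")
  .check_prob(circular_fraction, "circular_fraction")
  .check_prob(error_rate, "error_rate")
  .check_prob(rnase_r_linear_survival, "rnase_r_linear_survival")
  .check_prob(rnase_r_circular_survival, "rnase_r_circular_survival")
  if (read_length < 2L * anchor_len)
    .fail("read_length must be >= 2 x anchor_len")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 intergenic_gap = as.integer(intergenic_gap),
                 read_length = as.integer(read_length),
                 depth = as.integer(depth),
                 circular_fraction = circular_fraction,
                 error_rate = error_rate,
                 rnase_r_linear_survival = rnase_r_linear_survival,
                 rnase_r_circular_survival = rnase_r_circular_survival,
                 anchor_len = as.integer(anchor_len),
                 min_overhang = as.integer(min_overhang)),
            class = "sim_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Synthesize a toy genome with multi-exon gene models
#'
#' Genes are laid out non-overlapping on one chromosome, strands random.
#' Every intron begins GT and ends AG on the transcript strand (minus-strand
#' genes are inserted as the reverse complement of the transcript-strand
#' construction). Deterministic under the config seed.
#'
#' @param config \code{sim_config}
#' @return list with \code{genome} (named character), \code{db}
#'   (transcript_db) and \code{genes} (per-gene truth table)
#' @export
make_genome_and_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rng <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
  chrom <- "chr1"
  pieces <- character(0)
  offset <- rng(config$intergenic_gap)
  pieces <- c(pieces, .rand_dna(offset))
  tr_rows <- list(); ex_rows <- list()
  for (g in seq_len(config$n_genes)) {
    n_ex <- rng(config$exons_per_gene)
    strand <- sample(c("+", "-"), 1L)
    ex_len <- vapply(seq_len(n_ex), function(i) rng(config$exon_len),
                     integer(1))
    in_len <- if (n_ex > 1L)
      vapply(seq_len(n_ex - 1L), function(i) rng(config$intron_len),
             integer(1)) else integer(0)
    # transcript-strand construction
    seq_parts <- character(0); tpos <- 0L
    t_ex <- matrix(0L, n_ex, 2)
    for (i in seq_len(n_ex)) {
      t_ex[i, ] <- c(tpos, tpos + ex_len[i])
      seq_parts <- c(seq_parts, .rand_dna(ex_len[i]))
      tpos <- tpos + ex_len[i]
      if (i < n_ex) {
        if (in_len[i] < 4L) .fail("intron too short for GT/AG signal")
        intron <- paste0("GT", .rand_dna(in_len[i] - 4L), "AG")
        seq_parts <- c(seq_parts, intron)
        tpos <- tpos + in_len[i]
      }
    }
    gseq <- paste(seq_parts, collapse = "")
    glen <- nchar(gseq)
    if (strand == "+") {
      insert <- gseq
      gstart <- t_ex[, 1] + offset
      gend <- t_ex[, 2] + offset
    } else {
      insert <- revcomp(gseq)
      gstart <- offset + glen - t_ex[, 2]
      gend <- offset + glen - t_ex[, 1]
    }
    tid <- sprintf("TX%02d", g)
    coding <- runif(1) < 0.8
    tr_rows[[g]] <- data.frame(
      transcript_id = tid, gene_id = sprintf("G%02d", g), chrom = chrom,
      strand = strand, coding = coding,
      cds_start = if (coding) min(gstart) else NA_integer_,
      cds_end = if (coding) max(gend) else NA_integer_,
      stringsAsFactors = FALSE)
    ex_rows[[g]] <- data.frame(transcript_id = tid, start = gstart,
                               end = gend, stringsAsFactors = FALSE)
    pieces <- c(pieces, insert)
    offset <- offset + glen
    gap <- rng(config$intergenic_gap)
    pieces <- c(pieces, .rand_dna(gap))
    offset <- offset + gap
  }
  genome <- as_genome(setNames(paste(pieces, collapse = ""), chrom))
  db <- transcript_db(do.call(rbind, tr_rows), do.call(rbind, ex_rows),
                      genome = genome)
  list(genome = genome, db = db,
       genes = do.call(rbind, tr_rows))
}

# exons of a transcript in transcript (5'->3') order
.tx_exons_txorder <- function(db, tid) {
  ex <- tx_exons(db, tid)
  tr <- db$transcripts[db$transcripts$transcript_id == tid, ]
  if (tr$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

# spliced transcript sequence on the transcript strand
.spliced_seq <- function(genome, db, tid) {
  ex <- tx_exons(db, tid)
  tr <- db$transcripts[db$transcripts$transcript_id == tid, ]
  s <- paste(substring(genome[[tr$chrom]], ex$start + 1L, ex$end),
             collapse = "")
  if (tr$strand == "-") revcomp(s) else s
}

#' Plant circRNAs on synthetic transcripts
#'
#' Each circle spans a contiguous exon block (acceptor exon index <= donor
#' exon index in transcript order). The truth record carries the exact
#' genomic junction coordinates and the expected circular spliced sequence.
#'
#' @param db transcript_db from \code{make_genome_and_genes}
#' @param genome matching genome
#' @param n_circles number of circles (distinct host transcripts)
#' @param circular_fraction per-circle share of fragments that are circular
#' @param seed integer seed
#' @param min_spliced_length minimum ring length in nt; pass the intended
#'   read length so ring sampling stays feasible
#' @return data.frame of class \code{"circ_truth"}
#' @export
plant_circles <- function(db, genome, n_circles, circular_fraction = 0.5,
                          seed = 1L, min_spliced_length = 0L) {
  # back-splicing uses real splice sites: the acceptor needs an upstream
  # intron (AG) and the donor a downstream intron (GT), so circles live on
  # internal exon blocks and hosts need >= 3 exons
  eligible_blocks <- function(tid) {
    ex_t <- .tx_exons_txorder(db, tid)
    n_ex <- nrow(ex_t)
    if (n_ex < 3L) return(NULL)
    blocks <- list()
    for (a in 2:(n_ex - 1L)) for (d in a:(n_ex - 1L)) {
      len <- sum(ex_t$end[a:d] - ex_t$start[a:d])
      if (len >= min_spliced_length)
        blocks[[length(blocks) + 1L]] <- c(a, d)
    }
    if (length(blocks)) blocks else NULL
  }
  all_tids <- db$transcripts$transcript_id
  blocks_by_tid <- lapply(setNames(all_tids, all_tids), eligible_blocks)
  tids <- all_tids[!vapply(blocks_by_tid, is.null, logical(1))]
  if (n_circles > length(tids))
    .fail("n_circles exceeds transcripts with >= 3 exons and a block of %d nt",
          min_spliced_length)
  .check_prob(circular_fraction, "circular_fraction")
  set.seed(seed)
  hosts <- sample(tids, n_circles)
  rows <- lapply(hosts, function(tid) {
    tr <- db$transcripts[db$transcripts$transcript_id == tid, ]
    ex_t <- .tx_exons_txorder(db, tid)
    blk_ad <- blocks_by_tid[[tid]][[sample.int(length(blocks_by_tid[[tid]]),
                                               1L)]]
    a <- blk_ad[1]; d <- blk_ad[2]
    block <- ex_t[a:d, , drop = FALSE]
    s <- min(block$start); e <- max(block$end)
    blk_sorted <- block[order(block$start), , drop = FALSE]
    sp <- paste(substring(genome[[tr$chrom]], blk_sorted$start + 1L,
                          blk_sorted$end), collapse = "")
    if (tr$strand == "-") sp <- revcomp(sp)
    data.frame(transcript_id = tid, chrom = tr$chrom, strand = tr$strand,
               acceptor_exon = a, donor_exon = d,
               start = s, end = e,
               circ_id = circ_id(tr$chrom, s, e, tr$strand),
               circular_fraction = circular_fraction,
               spliced_seq = sp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("circ_truth", "data.frame")
  out
}

.inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate single-end reads from linear and circular molecules
#'
#' Linear fragments sample the spliced linear transcript uniformly; circular
#' fragments sample the planted ring with uniform start, wrapping past the
#' head-to-tail junction (no rolling-circle concatemers). Truth is encoded
#' in read names: \code{id:class:transcript:circ_id:juncflag:crossings},
#' where crossings lists the genomic \code{leftEnd-rightStart} splice
#' boundaries the read crosses linearly with >= \code{min_overhang} nt on
#' each side (linear reads only).
#'
#' @param genome,db,circ_truth outputs of the generator stages
#' @param config \code{sim_config}
#' @return data.frame with read_id, seq, class, transcript_id, circ_id,
#'   junction_overlap, crossings
#' @export
simulate_reads <- function(genome, db, circ_truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  rl <- config$read_length
  if (config$depth == 0L) {
    warning("zero depth: empty read set")
    return(data.frame(read_id = character(0), seq = character(0),
                      class = character(0), transcript_id = character(0),
                      circ_id = character(0), junction_overlap = logical(0),
                      crossings = character(0), stringsAsFactors = FALSE))
  }
  out <- list(); ridx <- 0L
  for (tid in db$transcripts$transcript_id) {
    tr <- db$transcripts[db$transcripts$transcript_id == tid, ]
    lin_seq <- .spliced_seq(genome, db, tid)
    if (nchar(lin_seq) < rl)
      .fail("read_length %d exceeds spliced length of %s", rl, tid)
    ex_t <- .tx_exons_txorder(db, tid)
    # spliced coordinate of each internal splice junction + its genomic pair
    jn <- NULL
    if (nrow(ex_t) > 1L) {
      cum <- cumsum(ex_t$end - ex_t$start)
      jn <- data.frame(pos = cum[-length(cum)],
                       left_end = NA_integer_, right_start = NA_integer_)
      for (j in seq_len(nrow(ex_t) - 1L)) {
        up <- ex_t[j, ]; dn <- ex_t[j + 1L, ]
        if (tr$strand == "+") {
          jn$left_end[j] <- up$end; jn$right_start[j] <- dn$start
        } else {
          jn$left_end[j] <- dn$end; jn$right_start[j] <- up$start
        }
      }
    }
    ct <- circ_truth[circ_truth$transcript_id == tid, , drop = FALSE]
    has_circle <- nrow(ct) == 1L
    if (has_circle) {
      ring <- ct$spliced_seq
      if (nchar(ring) < rl)
        .fail("read_length %d exceeds ring length of %s", rl, ct$circ_id)
    }
    n_circ <- if (has_circle)
      rbinom(1L, config$depth, ct$circular_fraction) else 0L
    n_lin <- config$depth - n_circ
    # linear fragments
    if (n_lin > 0L) {
      starts <- sample.int(nchar(lin_seq) - rl + 1L, n_lin, replace = TRUE) - 1L
      cross <- if (is.null(jn)) rep("", n_lin) else
        vapply(starts, function(s0) {
          hit <- jn$pos - config$min_overhang >= s0 &
            jn$pos + config$min_overhang <= s0 + rl
          if (any(hit))
            paste(sprintf("%d-%d", jn$left_end[hit], jn$right_start[hit]),
                  collapse = ";") else ""
        }, character(1))
      out[[length(out) + 1L]] <- data.frame(
        read_id = sprintf("r%06d", ridx + seq_len(n_lin)),
        seq = substring(lin_seq, starts + 1L, starts + rl),
        class = "linear", transcript_id = tid, circ_id = NA_character_,
        junction_overlap = FALSE, crossings = cross,
        stringsAsFactors = FALSE)
      ridx <- ridx + n_lin
    }
    # circular fragments, sampled from the ring
    if (n_circ > 0L) {
      L <- nchar(ring)
      doubled <- paste0(ring, ring)
      starts <- sample.int(L, n_circ, replace = TRUE) - 1L
      out[[length(out) + 1L]] <- data.frame(
        read_id = sprintf("r%06d", ridx + seq_len(n_circ)),
        seq = substring(doubled, starts + 1L, starts + rl),
        class = "circular", transcript_id = tid, circ_id = ct$circ_id,
        junction_overlap = (starts + rl) > L, crossings = "",
        stringsAsFactors = FALSE)
      ridx <- ridx + n_circ
    }
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  reads$seq <- .inject_errors(reads$seq, config$error_rate)
  reads
}

#' Apply in-silico RNase R digestion to tagged reads
#'
#' Linear-tagged reads survive with probability
#' \code{linear_survival}; circular-tagged with \code{circular_survival}.
#'
#' @param reads read table from \code{simulate_reads}
#' @param linear_survival,circular_survival survival probabilities
#' @param seed integer seed
#' @return surviving subset of \code{reads}
#' @export
simulate_rnase_r <- function(reads, linear_survival, circular_survival,
                             seed = 1L) {
  .check_prob(linear_survival, "linear_survival")
  .check_prob(circular_survival, "circular_survival")
  set.seed(seed)
  p <- ifelse(reads$class == "circular", circular_survival, linear_survival)
  keep <- runif(nrow(reads)) < p
  reads[keep, , drop = FALSE]
}

#' Encode truth tags into FASTQ read names and write 4-line FASTQ
#'
#' All base qualities are fixed at Q40 ("I", Phred+33).
#'
#' @param reads read table
#' @param path output FASTQ
#' @return invisibly, \code{path}
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    warning("writing empty FASTQ")
    file.create(path)
    return(invisible(path))
  }
  name <- sprintf("%s:%s:%s:%s:%d:%s",
                  reads$read_id, reads$class, reads$transcript_id,
                  ifelse(is.na(reads$circ_id), ".", reads$circ_id),
                  as.integer(reads$junction_overlap),
                  ifelse(nzchar(reads$crossings), reads$crossings, "."))
  qual <- strrep("I", nchar(reads$seq))
  writeLines(as.vector(rbind(paste0("@", name), reads$seq, "+", qual)), path)
  invisible(path)
}

#' Read a 4-line FASTQ, decoding circkit truth tags when present
#'
#' @param path FASTQ file
#' @return read table in the \code{simulate_reads} layout (truth columns NA
#'   when names carry no tags)
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) == 0L)
    return(data.frame(read_id = character(0), seq = character(0),
                      class = character(0), transcript_id = character(0),
                      circ_id = character(0), junction_overlap = logical(0),
                      crossings = character(0), stringsAsFactors = FALSE))
  if (length(ln) %% 4L != 0L) .fail("truncated FASTQ: %s", path)
  name <- sub("^@", "", ln[seq(1L, length(ln), 4L)])
  seqs <- ln[seq(2L, length(ln), 4L)]
  parts <- strsplit(name, ":", fixed = TRUE)
  tagged <- lengths(parts) >= 6L
  get <- function(i, default = NA_character_)
    vapply(seq_along(parts), function(j)
      if (tagged[j]) parts[[j]][i] else default, character(1))
  # circ ids themselves contain colons; re-join fields 4..(n-2)
  cid <- vapply(seq_along(parts), function(j) {
    if (!tagged[j]) return(NA_character_)
    p <- parts[[j]]
    paste(p[4:(length(p) - 2L)], collapse = ":")
  }, character(1))
  jov <- vapply(seq_along(parts), function(j) {
    if (!tagged[j]) return(NA)
    as.logical(as.integer(parts[[j]][length(parts[[j]]) - 1L]))
  }, logical(1))
  crossings <- vapply(seq_along(parts), function(j) {
    if (!tagged[j]) return(NA_character_)
    parts[[j]][length(parts[[j]])]
  }, character(1))
  data.frame(read_id = vapply(parts, `[`, character(1), 1L),
             seq = seqs,
             class = get(2L),
             transcript_id = get(3L),
             circ_id = ifelse(cid == ".", NA_character_, cid),
             junction_overlap = jov,
             crossings = ifelse(crossings == ".", "", crossings),
             stringsAsFactors = FALSE)
}

#' Count planted truth per circle from tagged reads
#'
#' The conservation oracle: junction reads and the 5'/3' linear boundary
#' crossings of each planted circle, counted directly from truth tags.
#'
#' @param reads tagged read table
#' @param circ_truth planted circle table
#' @return data.frame circ_id, junction_reads, linear_5p, linear_3p
#' @export
truth_counts <- function(reads, circ_truth) {
  do.call(rbind, lapply(seq_len(nrow(circ_truth)), function(i) {
    ct <- circ_truth[i, ]
    jr <- sum(reads$class == "circular" & !is.na(reads$circ_id) &
                reads$circ_id == ct$circ_id & reads$junction_overlap)
    cr <- reads[reads$class == "linear" & nzchar(reads$crossings), , drop = FALSE]
    pairs <- unlist(strsplit(cr$crossings, ";", fixed = TRUE))
    tab <- table(pairs)
    # acceptor boundary: transcript 5' of the circle; donor: transcript 3'
    if (ct$strand == "+") {
      key5 <- names(tab)[endsWith(names(tab), paste0("-", ct$start))]
      key3 <- names(tab)[startsWith(names(tab), paste0(ct$end, "-"))]
    } else {
      key5 <- names(tab)[startsWith(names(tab), paste0(ct$end, "-"))]
      key3 <- names(tab)[endsWith(names(tab), paste0("-", ct$start))]
    }
    data.frame(circ_id = ct$circ_id, junction_reads = jr,
               linear_5p = if (length(key5)) sum(tab[key5]) else 0L,
               linear_3p = if (length(key3)) sum(tab[key3]) else 0L,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a qPCR Ct table with spike-in and housekeeper channels
#'
#' Ct = baseline(target) - log2(fold) + N(0, noise_sd); group effects act on
#' assay targets only. Spike-in, housekeeper and reference-rRNA channels are
#' group-invariant by construction.
#'
#' @param samples data.frame(sample, group)
#' @param targets data.frame(target, role) with role in assay, spike_in,
#'   housekeeper, reference_rRNA
#' @param effects data.frame(target, group, fold); omitted combinations have
#'   fold 1
#' @param n_replicates technical replicates per (sample, target)
#' @param noise_sd Ct noise standard deviation (cycles)
#' @param baseline named numeric of baseline Ct per target (default 22)
#' @param seed integer seed
#' @return data.frame(sample, group, target, role, replicate, ct)
#' @export
simulate_ct_table <- function(samples, targets, effects = NULL,
                              n_replicates = 2L, noise_sd = 0.2,
                              baseline = NULL, seed = 1L) {
  if (noise_sd < 0) .fail("noise_sd must be non-negative")
  roles <- c("assay", "spike_in", "housekeeper", "reference_rRNA")
  if (!all(targets$role %in% roles)) .fail("unknown target role")
  if (!any(targets$role == "spike_in"))
    warning("design has no spike-in channel")
  if (!is.null(effects) &&
      any(effects$target %in% targets$target[targets$role != "assay"])) {
    .fail("group effects are only allowed on assay targets")
  }
  if (is.null(baseline)) baseline <- setNames(rep(22, nrow(targets)),
                                              targets$target)
  set.seed(seed)
  grid <- expand.grid(sample = samples$sample, target = targets$target,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  grid$group <- samples$group[match(grid$sample, samples$sample)]
  grid$role <- targets$role[match(grid$target, targets$target)]
  fold <- rep(1, nrow(grid))
  if (!is.null(effects)) {
    key <- paste(grid$target, grid$group)
    ekey <- paste(effects$target, effects$group)
    hit <- match(key, ekey)
    fold[!is.na(hit)] <- effects$fold[hit[!is.na(hit)]]
  }
  grid$ct <- baseline[grid$target] - log2(fold) +
    rnorm(nrow(grid), 0, noise_sd)
  grid[order(grid$sample, grid$target, grid$replicate),
       c("sample", "group", "target", "role", "replicate", "ct")]
}
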