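#' Read a genome FASTA into a named character vector
#'
#' Sequences are folded to uppercase and restricted to the A/C/G/T/N
#' alphabet. Record names must be unique and sequences non-empty.
#'
#' @param path FASTA file
#' @return named character vector of chromosome sequences (class
#'   \code{"genome"})
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .fail("FASTA not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  as_genome(seqs)
}

#' Construct and validate a genome object
#'
#' @param seqs named character vector, one element per chromosome
#' @return validated genome (named uppercase character vector)
#' @export
as_genome <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    .fail("all chromosomes must be named")
  if (anyDuplicated(names(seqs)))
    .fail("duplicate chromosome name: %s",
          names(seqs)[duplicated(names(seqs))][1])
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) .fail("empty sequence for %s",
                                names(seqs)[!nzchar(seqs)][1])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) .fail("non-ACGTN characters in %s", names(seqs)[bad][1])
  structure(seqs, class = "genome")
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences
#' @param path output file
#' @param width line-wrap width
#' @return invisibly, \code{path}
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models
# ---------------------------------------------------------------------------

#' Build a transcript database
#'
#' Internal gene-model container: coordinates are 0-based half-open on the
#' forward genomic strand, exons sorted by start. Unsorted exon input is
#' sorted with a warning; overlapping exons or a CDS outside the exon union
#' are hard errors.
#'
#' @param transcripts data.frame with columns transcript_id, gene_id, chrom,
#'   strand, coding, cds_start, cds_end (the latter two NA for non-coding)
#' @param exons data.frame with columns transcript_id, start, end
#' @param genome optional genome for bounds checking
#' @return object of class \code{"transcript_db"}
#' @export
transcript_db <- function(transcripts, exons, genome = NULL) {
  need <- c("transcript_id", "gene_id", "chrom", "strand", "coding")
  if (!all(need %in% names(transcripts))) .fail("missing transcript columns")
  if (!all(c("transcript_id", "start", "end") %in% names(exons)))
    .fail("missing exon columns")
  if (!"cds_start" %in% names(transcripts)) transcripts$cds_start <- NA_integer_
  if (!"cds_end" %in% names(transcripts)) transcripts$cds_end <- NA_integer_
  if (anyDuplicated(transcripts$transcript_id)) .fail("duplicate transcript_id")
  if (!all(transcripts$strand %in% c("+", "-"))) .fail("strand must be + or -")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  for (tid in transcripts$transcript_id) {
    ex <- exons[exons$transcript_id == tid, , drop = FALSE]
    if (nrow(ex) == 0L) .fail("transcript %s has no exons", tid)
    if (any(ex$start >= ex$end)) .fail("empty exon in %s", tid)
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)]))
      .fail("overlapping exons in %s", tid)
    tr <- transcripts[transcripts$transcript_id == tid, ]
    if (isTRUE(tr$coding) && !is.na(tr$cds_start)) {
      inside <- any(tr$cds_start >= ex$start & tr$cds_end <= ex$end) ||
        all(vapply(seq_len(2), function(i) {
          p <- if (i == 1) tr$cds_start else tr$cds_end - 1L
          any(p >= ex$start & p < ex$end)
        }, logical(1)))
      if (!inside) .fail("CDS outside exon union in %s", tid)
    }
    if (!is.null(genome)) {
      len <- nchar(genome[[tr$chrom]])
      if (any(ex$start < 0L) || any(ex$end > len))
        .fail("exon outside chromosome %s in %s", tr$chrom, tid)
    }
  }
  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_db")
}

#' Exons of one transcript
#'
#' @param db transcript_db
#' @param transcript_id transcript identifier
#' @return data.frame of exon intervals sorted by start
#' @export
tx_exons <- function(db, transcript_id) {
  ex <- db$exons[db$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0L) .fail("unknown transcript %s", transcript_id)
  ex[order(ex$start), , drop = FALSE]
}

#' Read gene models from GTF or BED12
#'
#' GTF (1-based inclusive) and BED12 (0-based half-open) are both converted
#' to the internal 0-based half-open representation.
#'
#' @param path input file
#' @param format \code{"gtf"} or \code{"bed12"}
#' @param genome optional genome for bounds checking
#' @return transcript_db
#' @export
read_gene_models <- function(path, format = c("gtf", "bed12"), genome = NULL) {
  format <- match.arg(format)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    exons <- data.frame(
      transcript_id = as.character(ex$transcript_id),
      start = GenomicRanges::start(ex) - 1L,
      end = GenomicRanges::end(ex),
      stringsAsFactors = FALSE)
    meta <- unique(data.frame(
      transcript_id = as.character(ex$transcript_id),
      gene_id = as.character(ex$gene_id),
      chrom = as.character(GenomicRanges::seqnames(ex)),
      strand = as.character(GenomicRanges::strand(ex)),
      stringsAsFactors = FALSE))
    cds <- gr[gr$type == "CDS"]
    meta$coding <- meta$transcript_id %in% as.character(cds$transcript_id)
    meta$cds_start <- NA_integer_
    meta$cds_end <- NA_integer_
    if (length(cds)) {
      agg_s <- tapply(GenomicRanges::start(cds) - 1L,
                      as.character(cds$transcript_id), min)
      agg_e <- tapply(GenomicRanges::end(cds),
                      as.character(cds$transcript_id), max)
      idx <- match(meta$transcript_id, names(agg_s))
      meta$cds_start <- as.integer(agg_s[idx])
      meta$cds_end <- as.integer(agg_e[idx])
    }
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    blocks <- gr$blocks
    exons <- do.call(rbind, lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]
      data.frame(transcript_id = gr$name[i],
                 start = GenomicRanges::start(gr)[i] - 1L +
                   GenomicRanges::start(b) - 1L,
                 end = GenomicRanges::start(gr)[i] - 1L +
                   GenomicRanges::end(b),
                 stringsAsFactors = FALSE)
    }))
    thick <- gr$thick
    has_cds <- if (is.null(thick)) rep(FALSE, length(gr)) else
      GenomicRanges::width(thick) > 0
    meta <- data.frame(
      transcript_id = gr$name,
      gene_id = gr$name,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      coding = as.logical(has_cds),
      cds_start = ifelse(has_cds, GenomicRanges::start(thick) - 1L, NA_integer_),
      cds_end = ifelse(has_cds, GenomicRanges::end(thick), NA_integer_),
      stringsAsFactors = FALSE)
  }
  if (any(vapply(split(exons$start, exons$transcript_id), is.unsorted,
                 logical(1))))
    warning("exons were unsorted; sorted by start")
  transcript_db(meta, exons, genome = genome)
}

#' Write gene models to GTF or BED12
#'
#' @param db transcript_db
#' @param path output file
#' @param format \code{"gtf"} or \code{"bed12"}
#' @return invisibly, \code{path}
#' @export
write_gene_models <- function(db, path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  tr <- db$transcripts
  if (format == "gtf") {
    lines <- character(0)
    for (i in seq_len(nrow(tr))) {
      ex <- tx_exons(db, tr$transcript_id[i])
      attr9 <- sprintf('gene_id "%s"; transcript_id "%s";',
                       tr$gene_id[i], tr$transcript_id[i])
      lines <- c(lines,
                 sprintf("%s\tcirckit\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                         tr$chrom[i], min(ex$start) + 1L, max(ex$end),
                         tr$strand[i], attr9),
                 sprintf("%s\tcirckit\texon\t%d\t%d\t.\t%s\t.\t%s",
                         tr$chrom[i], ex$start + 1L, ex$end,
                         tr$strand[i], attr9))
      if (isTRUE(tr$coding[i]) && !is.na(tr$cds_start[i])) {
        cs <- tr$cds_start[i]; ce <- tr$cds_end[i]
        cex <- ex[ex$end > cs & ex$start < ce, , drop = FALSE]
        lines <- c(lines, sprintf(
          "%s\tcirckit\tCDS\t%d\t%d\t.\t%s\t.\t%s",
          tr$chrom[i], pmax(cex$start, cs) + 1L, pmin(cex$end, ce),
          tr$strand[i], attr9))
      }
    }
    writeLines(lines, path)
  } else {
    lines <- vapply(seq_len(nrow(tr)), function(i) {
      ex <- tx_exons(db, tr$transcript_id[i])
      s <- min(ex$start); e <- max(ex$end)
      cs <- if (isTRUE(tr$coding[i]) && !is.na(tr$cds_start[i]))
        tr$cds_start[i] else s
      ce <- if (isTRUE(tr$coding[i]) && !is.na(tr$cds_end[i]))
        tr$cds_end[i] else s
      paste(tr$chrom[i], s, e, tr$transcript_id[i], 0L, tr$strand[i],
            cs, ce, "0,0,0", nrow(ex),
            paste0(paste(ex$end - ex$start, collapse = ","), ","),
            paste0(paste(ex$start - s, collapse = ","), ","),
            sep = "\t")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# circBase-style catalog
# ---------------------------------------------------------------------------

.catalog_cols <- c("chrom", "start", "end", "strand", "circ_id",
                   "junction_reads", "linear_5p_reads", "linear_3p_reads",
                   "CLR", "host_transcript", "orientation", "category",
                   "genomic_length", "spliced_length")

#' Synthetic circRNA identifier
#'
#' \code{"<chrom>:<start>-<end>:<strand>"} with 0-based half-open genomic
#' span; a stand-in for database accessions.
#'
#' @param chrom,start,end,strand candidate coordinates
#' @return character ids
#' @export
circ_id <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' Write the annotated, quantified circRNA catalog
#'
#' Columns: chrom, start, end, strand, circ_id, junction_reads,
#' linear_5p_reads, linear_3p_reads, CLR, host_transcript, orientation,
#' category, genomic_length, spliced_length. Rows sorted by
#' (chrom, start, end, strand). Coordinates are 0-based half-open;
#' \code{start} is the first base of the circle's 5'-most genomic exon and
#' \code{end} one past its 3'-most base, strand carried separately.
#'
#' @param catalog data.frame holding the catalog columns
#' @param path output TSV
#' @return invisibly, \code{path}
#' @export
write_catalog <- function(catalog, path) {
  miss <- setdiff(.catalog_cols, names(catalog))
  if (length(miss)) .fail("catalog missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(is.na(catalog$junction_reads)) || any(is.na(catalog$CLR)))
    .fail("candidate without quantification in catalog")
  catalog <- catalog[.catalog_cols]
  catalog <- catalog[order(catalog$chrom, catalog$start, catalog$end,
                           catalog$strand), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# circkit catalog; coordinates 0-based half-open",
               paste(.catalog_cols, collapse = "\t")), con)
  if (nrow(catalog))
    write.table(catalog, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a catalog written by \code{write_catalog}
#'
#' @param path catalog TSV
#' @return data.frame with the 14 catalog columns
#' @export
read_catalog <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, na.strings = "NA",
                   colClasses = c(chrom = "character", strand = "character",
                                  circ_id = "character",
                                  host_transcript = "character",
                                  orientation = "character",
                                  category = "character"))
  if (!identical(names(df), .catalog_cols)) .fail("malformed catalog header")
  df
}
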