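#' Reconstruct the circular spliced sequence of a candidate
#'
#' Concatenates the host exon segments inside the circle span (intron
#' skipped), reverse-complemented for minus-strand hosts, so that position
#' 0 is the first base of the acceptor exon on the transcript strand and
#' the head-to-tail junction joins the last base back to position 0.
#'
#' @param candidate one-row annotated candidate (needs chrom, start, end,
#'   strand, host_transcript, category)
#' @param db transcript_db
#' @param genome genome
#' @return list(circ_id, seq, junction_index = 0)
#' @export
circular_sequence <- function(candidate, db, genome) {
  if (!candidate$category %in% c("coding_exon", "noncoding_gene") ||
      is.na(candidate$host_transcript))
    .fail("no spliced model for %s candidate", candidate$category)
  ex <- tx_exons(db, candidate$host_transcript)
  seg <- ex[ex$end > candidate$start & ex$start < candidate$end, ,
            drop = FALSE]
  seg$start <- pmax(seg$start, candidate$start)
  seg$end <- pmin(seg$end, candidate$end)
  s <- paste(substring(genome[[candidate$chrom]], seg$start + 1L, seg$end),
             collapse = "")
  if (candidate$strand == "-") s <- revcomp(s)
  list(circ_id = circ_id(candidate$chrom, candidate$start, candidate$end,
                         candidate$strand),
       seq = s, junction_index = 0L)
}

#' Enumerate open reading frames spanning the head-to-tail junction
#'
#' The ring is doubled and translated in three frames; maximal AUG-to-stop
#' ORFs whose nucleotide span covers the junction (index = ring length on
#' the doubled string) are reported. ORFs running further than
#' \code{max_loops} times around the circle are truncated and flagged
#' \code{no_stop_in_circle} (rolling-circle translation is not modeled).
#'
#' @param ring circular spliced sequence (character scalar)
#' @param max_loops cap on ORF length in ring lengths (default 1)
#' @return data.frame: frame (0-2), start (nt offset on the doubled
#'   sequence), nt_start, nt_end, aa, no_stop_in_circle,
#'   crosses_junction (always TRUE)
#' @export
find_junction_orfs <- function(ring, max_loops = 1L) {
  L <- nchar(ring)
  if (L == 0L) .fail("empty ring")
  d <- strrep(ring, 2L)
  cap_nt <- 3L * ((max_loops * L) %/% 3L)
  out <- list()
  for (f in 0:2) {
    starts <- seq(f, 2L * L - 3L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(d, starts + 1L, starts + 3L)
    aa <- translate_codons(codons)
    open_at <- NA_integer_                 # codon index of current ORF start
    for (i in seq_along(codons)) {
      if (aa[i] == "*") {
        if (!is.na(open_at)) {
          p <- starts[open_at]; q_end <- starts[i] + 3L
          trunc <- (q_end - p) > cap_nt && cap_nt > 0L
          if (trunc) q_end <- p + cap_nt
          if (p < L && q_end > L) {
            n_aa <- (q_end - p) %/% 3L - if (trunc) 0L else 1L
            out[[length(out) + 1L]] <- data.frame(
              frame = f, start = p, nt_start = p, nt_end = q_end,
              aa = paste(aa[open_at:(open_at + n_aa - 1L)], collapse = ""),
              no_stop_in_circle = trunc, crosses_junction = TRUE,
              stringsAsFactors = FALSE)
          }
        }
        open_at <- NA_integer_
      } else if (is.na(open_at) && codons[i] == "ATG" && starts[i] < L) {
        open_at <- i
      }
    }
    # no stop found before the doubled string ran out
    if (!is.na(open_at)) {
      p <- starts[open_at]
      q_end <- min(p + cap_nt, starts[length(starts)] + 3L)
      q_end <- p + 3L * ((q_end - p) %/% 3L)
      if (p < L && q_end > L && q_end > p) {
        n_aa <- (q_end - p) %/% 3L
        out[[length(out) + 1L]] <- data.frame(
          frame = f, start = p, nt_start = p, nt_end = q_end,
          aa = paste(aa[open_at:(open_at + n_aa - 1L)], collapse = ""),
          no_stop_in_circle = TRUE, crosses_junction = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), start = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      aa = character(0), no_stop_in_circle = logical(0),
                      crosses_junction = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$frame, res$start), , drop = FALSE]
}

#' In-silico tryptic digest of a peptide
#'
#' Cleaves after K or R except before P; supports missed cleavages.
#'
#' @param aa amino-acid string
#' @param missed_cleavages maximum missed cleavages (default 0)
#' @return data.frame(peptide, aa_start, aa_end) with 0-based half-open
#'   offsets into \code{aa}
#' @export
tryptic_digest <- function(aa, missed_cleavages = 0L) {
  ch <- strsplit(aa, "")[[1]]
  n <- length(ch)
  cut_after <- which(ch %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & ch[pmin(cut_after + 1L, n)] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after, n)
  bounds <- sort(unique(bounds[bounds <= n]))
  nfrag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > nfrag) break
      s <- bounds[i]; e <- bounds[j + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = substr(aa, s + 1L, e), aa_start = s, aa_end = e,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Junction-spanning tryptic peptides of circular ORFs
#'
#' Digests each junction-spanning ORF and keeps peptides whose encoding
#' codons straddle the head-to-tail junction; typical observability bounds
#' of 7-35 aa apply by default.
#'
#' @param orfs output of \code{\link{find_junction_orfs}}
#' @param ring the ring sequence the ORFs came from
#' @param circ_id identifier used in output records
#' @param min_len,max_len peptide length bounds in aa
#' @param missed_cleavages maximum missed cleavages
#' @return data.frame(circ_id, frame, orf_start, peptide, nt_start, nt_end)
#' @export
junction_peptides <- function(orfs, ring, circ_id = "circ",
                              min_len = 7L, max_len = 35L,
                              missed_cleavages = 0L) {
  L <- nchar(ring)
  rows <- list()
  for (i in seq_len(nrow(orfs))) {
    dig <- tryptic_digest(orfs$aa[i], missed_cleavages)
    for (j in seq_len(nrow(dig))) {
      nt_s <- orfs$start[i] + 3L * dig$aa_start[j]
      nt_e <- orfs$start[i] + 3L * dig$aa_end[j]
      if (nt_s < L && nt_e > L &&
          nchar(dig$peptide[j]) >= min_len &&
          nchar(dig$peptide[j]) <= max_len) {
        rows[[length(rows) + 1L]] <- data.frame(
          circ_id = circ_id, frame = orfs$frame[i],
          orf_start = orfs$start[i], peptide = dig$peptide[j],
          nt_start = nt_s, nt_end = nt_e, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(circ_id = character(0), frame = integer(0),
                      orf_start = integer(0), peptide = character(0),
                      nt_start = integer(0), nt_end = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write a junction-peptide search database as FASTA
#'
#' Headers carry circ_id, frame and the peptide's junction offset (aa
#' position of the first residue past the junction).
#'
#' @param peptides output of \code{\link{junction_peptides}} (the ring
#'   length must be recoverable from nt coordinates; pass it explicitly)
#' @param ring_lengths named numeric, ring length per circ_id
#' @param path output FASTA
#' @return invisibly, \code{path}
#' @export
write_peptide_fasta <- function(peptides, ring_lengths, path) {
  lines <- character(0)
  for (i in seq_len(nrow(peptides))) {
    L <- ring_lengths[[peptides$circ_id[i]]]
    off <- ceiling((L - peptides$nt_start[i]) / 3)
    lines <- c(lines, sprintf(">%s|frame=%d|junction_aa_offset=%d",
                              peptides$circ_id[i], peptides$frame[i], off),
               peptides$peptide[i])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Match observed peptides against the junction-peptide database
#'
#' Exact string matching; every observed peptide receives a verdict:
#' \code{"junction_spanning_match"} when present in the database,
#' otherwise \code{"non_junction"} (the outcome class for peptides that
#' match host proteins but not the head-to-tail junction).
#'
#' @param observed character vector of observed peptides
#' @param db junction-peptide table (\code{peptide} column)
#' @return data.frame(peptide, matched, verdict, circ_id)
#' @export
filter_hits <- function(observed, db) {
  if (length(observed) == 0L)
    return(data.frame(peptide = character(0), matched = logical(0),
                      verdict = character(0), circ_id = character(0),
                      stringsAsFactors = FALSE))
  idx <- match(observed, db$peptide)
  data.frame(peptide = observed, matched = !is.na(idx),
             verdict = ifelse(is.na(idx), "non_junction",
                              "junction_spanning_match"),
             circ_id = ifelse(is.na(idx), NA_character_, db$circ_id[idx]),
             stringsAsFactors = FALSE)
}
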