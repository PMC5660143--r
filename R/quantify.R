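#' Count linear reads over a circle's boundary splice sites
#'
#' \code{placements} lists, per read, the linear splice junctions it
#' crosses as genomic (left_end, right_start) boundary pairs. The 5'
#' boundary of a circle is the splice site at its acceptor (transcript 5')
#' junction, the 3' boundary the donor-side site; a read crossing both
#' increments both counts. Junction-spanning circular reads never appear in
#' \code{placements}.
#'
#' @param placements data.frame(read_id, chrom, strand, left_end,
#'   right_start)
#' @param candidate one-row data.frame with chrom, strand, start, end
#' @return c(linear_5p, linear_3p)
#' @export
count_boundary_reads <- function(placements, candidate) {
  p <- placements[placements$chrom == candidate$chrom &
                    placements$strand == candidate$strand, , drop = FALSE]
  if (candidate$strand == "+") {
    n5 <- sum(p$right_start == candidate$start)
    n3 <- sum(p$left_end == candidate$end)
  } else {
    n5 <- sum(p$left_end == candidate$end)
    n3 <- sum(p$right_start == candidate$start)
  }
  c(linear_5p = n5, linear_3p = n3)
}

#' Expand tagged reads into a boundary-crossing placement table
#'
#' @param reads tagged read table from \code{\link{simulate_reads}}
#' @param db transcript_db (for strand lookup)
#' @return placements data.frame for \code{\link{count_boundary_reads}}
#' @export
placements_from_truth <- function(reads, db) {
  lin <- reads[reads$class == "linear" & nzchar(reads$crossings), ,
               drop = FALSE]
  if (nrow(lin) == 0L)
    return(data.frame(read_id = character(0), chrom = character(0),
                      strand = character(0), left_end = integer(0),
                      right_start = integer(0), stringsAsFactors = FALSE))
  tr <- db$transcripts
  rows <- lapply(seq_len(nrow(lin)), function(i) {
    pairs <- strsplit(lin$crossings[i], ";", fixed = TRUE)[[1]]
    m <- do.call(rbind, strsplit(pairs, "-", fixed = TRUE))
    j <- match(lin$transcript_id[i], tr$transcript_id)
    data.frame(read_id = lin$read_id[i], chrom = tr$chrom[j],
               strand = tr$strand[j],
               left_end = as.integer(m[, 1]),
               right_start = as.integer(m[, 2]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Circular-to-linear ratio
#'
#' CLR = circular junction reads / max(linear 5' reads, linear 3' reads),
#' with the denominator replaced by the pseudocount 1 only when both linear
#' counts are zero. Full precision; use \code{\link{round_half_up}} for the
#' printed one-decimal convention.
#'
#' @param reads_circular,reads_linear_5p,reads_linear_3p non-negative
#'   counts (vectorized)
#' @return numeric CLR
#' @export
clr <- function(reads_circular, reads_linear_5p, reads_linear_3p) {
  if (any(c(reads_circular, reads_linear_5p, reads_linear_3p) < 0))
    .fail("counts must be non-negative")
  denom <- pmax(reads_linear_5p, reads_linear_3p)
  denom[denom == 0] <- 1
  reads_circular / denom
}

#' Transcripts-per-million from gene counts and spliced lengths
#'
#' TPM_g = (count_g / length_g) / sum_h(count_h / length_h) * 1e6.
#'
#' @param counts named numeric gene read counts
#' @param lengths named numeric spliced lengths (nt), same genes
#' @return named numeric TPM summing to 1e6
#' @export
host_tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) .fail("zero-length gene")
  lengths <- lengths[names(counts)]
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Quantify candidates: junction counts, boundary counts and CLR
#'
#' @param candidates candidate table with junction_read_count
#' @param placements linear boundary-crossing table
#' @return candidates with linear_5p_reads, linear_3p_reads and CLR added
#' @export
quantify_candidates <- function(candidates, placements) {
  lin <- t(vapply(seq_len(nrow(candidates)), function(i)
    count_boundary_reads(placements, candidates[i, ]), numeric(2)))
  if (nrow(candidates) == 0L)
    lin <- matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("linear_5p", "linear_3p")))
  candidates$linear_5p_reads <- as.integer(lin[, 1])
  candidates$linear_3p_reads <- as.integer(lin[, 2])
  candidates$CLR <- clr(candidates$junction_read_count,
                        candidates$linear_5p_reads,
                        candidates$linear_3p_reads)
  candidates
}
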