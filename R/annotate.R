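#' Classify a circRNA candidate against gene models
#'
#' Priority when several features overlap: (1) both junction boundaries
#' coincide (within \code{tol} nt) with exon boundaries of a same-strand
#' transcript -> \code{coding_exon} if that transcript has a CDS (UTR exons
#' included), else \code{noncoding_gene}; (2) candidate entirely within an
#' intron of a same-strand transcript -> \code{intronic}; (3) overlap only
#' on the opposite strand -> \code{antisense}; (4) no overlap ->
#' \code{intergenic}. A same-strand exonic overlap without boundary
#' coincidence is treated like rule 1 with the maximally overlapping host.
#' When several transcripts satisfy rule 1 the host minimizing spliced
#' length wins, ties broken lexicographically.
#'
#' @param candidate one-row data.frame with chrom, start, end, strand
#' @param db transcript_db
#' @param tol boundary-coincidence tolerance in nt (default 2)
#' @return data.frame: circ_id, host_transcript, orientation, category,
#'   genomic_length, spliced_length (NA when unknown)
#' @export
classify_candidate <- function(candidate, db, tol = 2L) {
  s <- candidate$start; e <- candidate$end
  stopifnot(s < e)
  tr <- db$transcripts[db$transcripts$chrom == candidate$chrom, , drop = FALSE]
  res <- function(host, orientation, category, spliced) {
    data.frame(circ_id = circ_id(candidate$chrom, s, e, candidate$strand),
               host_transcript = host, orientation = orientation,
               category = category, genomic_length = e - s,
               spliced_length = spliced, stringsAsFactors = FALSE)
  }
  tx_span <- function(tid) {
    ex <- tx_exons(db, tid); c(min(ex$start), max(ex$end))
  }
  same <- tr[tr$strand == candidate$strand, , drop = FALSE]
  # rule 1: exon-bounded on a same-strand transcript
  bounded <- character(0); bounded_len <- integer(0)
  for (tid in same$transcript_id) {
    ex <- tx_exons(db, tid)
    if (any(abs(ex$start - s) <= tol) && any(abs(ex$end - e) <= tol)) {
      bounded <- c(bounded, tid)
      bounded_len <- c(bounded_len, spliced_length_in_span(db, tid, s, e))
    }
  }
  if (length(bounded)) {
    o <- order(bounded_len, bounded)
    host <- bounded[o[1]]
    coding <- same$coding[match(host, same$transcript_id)]
    return(res(host, "sense",
               if (isTRUE(coding)) "coding_exon" else "noncoding_gene",
               bounded_len[o[1]]))
  }
  # rule 2: wholly inside an intron of a same-strand transcript
  for (tid in same$transcript_id) {
    ex <- tx_exons(db, tid)
    if (nrow(ex) < 2L) next
    istart <- ex$end[-nrow(ex)]; iend <- ex$start[-1]
    if (any(s >= istart & e <= iend))
      return(res(tid, "sense", "intronic", NA_integer_))
  }
  # rule 1b: same-strand exonic overlap without boundary coincidence
  ex_overlap <- vapply(same$transcript_id, function(tid) {
    ex <- tx_exons(db, tid)
    sum(pmax(0, pmin(ex$end, e) - pmax(ex$start, s)))
  }, numeric(1))
  if (length(ex_overlap) && any(ex_overlap > 0L)) {
    o <- order(-ex_overlap, same$transcript_id)
    host <- same$transcript_id[o[1]]
    coding <- same$coding[o[1]]
    return(res(host, "sense",
               if (isTRUE(coding)) "coding_exon" else "noncoding_gene",
               spliced_length_in_span(db, host, s, e)))
  }
  # same-strand transcript-span overlap (exon-free, not intron-contained)
  span_hit <- vapply(same$transcript_id, function(tid) {
    sp <- tx_span(tid); s < sp[2] && e > sp[1]
  }, logical(1))
  if (length(span_hit) && any(span_hit))
    return(res(same$transcript_id[which(span_hit)[1]], "sense", "intronic",
               NA_integer_))
  # rule 3: overlap only on the opposite strand
  anti <- tr[tr$strand != candidate$strand, , drop = FALSE]
  anti_hit <- vapply(anti$transcript_id, function(tid) {
    sp <- tx_span(tid); s < sp[2] && e > sp[1]
  }, logical(1))
  if (length(anti_hit) && any(anti_hit)) {
    host <- anti$transcript_id[which(anti_hit)[1]]
    return(res(host, "antisense", "antisense", NA_integer_))
  }
  res(NA_character_, "sense", "intergenic", NA_integer_)
}

#' Spliced length of a circle span on a host transcript
#'
#' Sum of host exon lengths intersected with the circle's genomic span.
#'
#' @param db transcript_db
#' @param transcript_id host transcript
#' @param start,end circle genomic span (0-based half-open)
#' @return integer nt
#' @export
spliced_length_in_span <- function(db, transcript_id, start, end) {
  ex <- tx_exons(db, transcript_id)
  sum(pmax(0L, pmin(ex$end, end) - pmax(ex$start, start)))
}

#' Annotate a candidate table
#'
#' @param candidates CircCandidate data.frame from the detector
#' @param db transcript_db
#' @param tol boundary tolerance in nt
#' @return candidates with host_transcript, orientation, category,
#'   genomic_length, spliced_length columns added
#' @export
annotate_candidates <- function(candidates, db, tol = 2L) {
  ann <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(i)
    classify_candidate(candidates[i, ], db, tol)))
  if (is.null(ann))
    ann <- data.frame(circ_id = character(0), host_transcript = character(0),
                      orientation = character(0), category = character(0),
                      genomic_length = integer(0), spliced_length = integer(0))
  cbind(candidates, ann[setdiff(names(ann), "circ_id")])
}

#' Category share summary of an annotated catalog
#'
#' @param catalog annotated catalog with a \code{category} column
#' @return data.frame(category, n, share_percent); shares sum to 100
#' @export
catalog_summary <- function(catalog) {
  cats <- c("coding_exon", "antisense", "intronic", "noncoding_gene",
            "intergenic")
  if (nrow(catalog) == 0L) {
    warning("empty catalog")
    return(data.frame(category = character(0), n = integer(0),
                      share_percent = numeric(0)))
  }
  stopifnot(all(catalog$category %in% cats))
  n <- vapply(cats, function(k) sum(catalog$category == k), integer(1))
  data.frame(category = cats, n = n,
             share_percent = 100 * n / sum(n), row.names = NULL)
}
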