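#' Build an exact-match k-mer index of a genome
#'
#' Stores every forward-strand k-mer with its 0-based start position.
#' \code{\link{index_lookup}} resolves queries on both strands.
#'
#' @param genome named character vector of chromosome sequences
#' @param k k-mer length
#' @return object of class \code{"kmer_index"}
#' @export
build_index <- function(genome, k) {
  tabs <- lapply(names(genome), function(chr) {
    s <- genome[[chr]]
    n <- nchar(s)
    if (n < k) return(NULL)
    data.table::data.table(kmer = substring(s, 1:(n - k + 1L), k:n),
                           chrom = chr, pos = 0:(n - k))
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  structure(list(table = dt, k = k), class = "kmer_index")
}

#' Look up a k-mer on both genomic strands
#'
#' A hit with strand \code{"-"} means the reverse complement of the query
#' occurs at the reported forward-strand position, i.e. the query matches
#' the minus strand there. Palindromic queries yield one hit per
#' (position, strand).
#'
#' @param index \code{kmer_index}
#' @param query character vector of length-k strings
#' @return data.frame(query, chrom, pos, strand)
#' @export
index_lookup <- function(index, query) {
  stopifnot(all(nchar(query) == index$k))
  q <- data.table::data.table(kmer = query, query = query)
  fw <- index$table[q, on = "kmer", nomatch = NULL]
  fw[, "strand" := "+"]
  qr <- data.table::data.table(kmer = revcomp(query), query = query)
  rv <- index$table[qr, on = "kmer", nomatch = NULL]
  rv[, "strand" := "-"]
  out <- rbind(fw, rv)[, c("query", "chrom", "pos", "strand"), with = FALSE]
  as.data.frame(out)
}

#' Split a read into terminal anchors
#'
#' @param read read sequence
#' @param anchor_len anchor length (default 20)
#' @return list(head, tail) or NULL when the read is shorter than
#'   2 x anchor_len
#' @export
extract_anchors <- function(read, anchor_len = 20L) {
  if (nchar(read) < 2L * anchor_len) return(NULL)
  list(head = substr(read, 1L, anchor_len),
       tail = substr(read, nchar(read) - anchor_len + 1L, nchar(read)))
}

# longest common prefix length of two strings (exact match)
.match_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n)); bv <- utf8ToInt(substr(b, 1L, n))
  d <- which(av != bv)
  if (length(d)) d[1] - 1L else n
}

# Attempt a back-splice call for one oriented sequence against the forward
# genome. seq is assumed to read 5'->3' on `strand`; h0/t0 are the forward
# 0-based starts of the head/tail anchor hits. Returns NULL, a one-row
# data.frame, or the string "ambiguous".
.call_oriented <- function(seq, chromseq, h0, t0, anchor_len, max_span,
                           strand) {
  L <- nchar(seq)
  clen <- nchar(chromseq)
  if (t0 >= h0) return(NULL)              # not in reversed order
  # extend head anchor rightwards along read and genome
  e_h <- anchor_len + .match_len(substr(seq, anchor_len + 1L, L),
                                 substr(chromseq, h0 + anchor_len + 1L, clen))
  # extend tail anchor leftwards
  p_t <- L - anchor_len                    # read offset (0-based) of tail hit
  ext <- .match_len(
    paste(rev(strsplit(substr(seq, 1L, p_t), "")[[1]]), collapse = ""),
    paste(rev(strsplit(substr(chromseq, max(1L, t0 - p_t + 1L), t0), "")[[1]]),
          collapse = ""))
  b_t <- p_t - ext                         # leftmost read offset tail covers
  if (b_t > e_h) return(NULL)              # no split point covers the read
  # candidate splits: head covers read[0,s), tail covers read[s,L)
  sig_l <- if (strand == "+") "AG" else "AC"   # upstream flank of circle start
  sig_r <- if (strand == "+") "GT" else "CT"   # downstream flank of circle end
  hits <- list()
  for (s in max(b_t, 1L):min(e_h, L - 1L)) {
    donor_end <- h0 + s
    acc_start <- t0 - (p_t - s)
    if (acc_start < 2L || donor_end > clen - 2L) next
    if (acc_start >= donor_end) next
    if (donor_end - acc_start > max_span) next
    if (substr(chromseq, donor_end + 1L, donor_end + 2L) != sig_r) next
    if (substr(chromseq, acc_start - 1L, acc_start) != sig_l) next
    hits[[length(hits) + 1L]] <- c(acc_start, donor_end)
  }
  if (!length(hits)) return(NULL)
  u <- unique(hits)
  if (length(u) > 1L) return("ambiguous")
  data.frame(acceptor = u[[1]][1], donor = u[[1]][2], strand = strand,
             stringsAsFactors = FALSE)
}

#' Call a head-to-tail junction from one read
#'
#' Anchors must each map uniquely (across both strands); a call is made iff
#' the anchors lie in reversed genomic order on one strand, the span is at
#' most \code{max_span}, and maximal extension of both anchors toward the
#' breakpoint leaves exactly one split point flanked by AG (acceptor side)
#' and GT (donor side) on the transcript strand. Calls consistent on both
#' strands, or with several signal-consistent breakpoints, are rejected as
#' ambiguous.
#'
#' @param read read sequence
#' @param index \code{kmer_index} built with k = anchor_len
#' @param genome genome used to build the index
#' @param anchor_len anchor length
#' @param max_span maximum genomic span of a circle
#' @return list(call = data.frame or NULL, status = one of "called",
#'   "too_short", "no_hit", "not_unique", "no_call", "ambiguous_breakpoint")
#' @export
call_junction <- function(read, index, genome, anchor_len = 20L,
                          max_span = 1e5) {
  an <- extract_anchors(read, anchor_len)
  if (is.null(an)) return(list(call = NULL, status = "too_short"))
  hits <- index_lookup(index, c(an$head, an$tail))
  hh <- hits[hits$query == an$head, , drop = FALSE]
  th <- hits[hits$query == an$tail, , drop = FALSE]
  if (an$head == an$tail) {                    # degenerate: same anchor
    hh <- hits[!duplicated(hits[c("chrom", "pos", "strand")]), , drop = FALSE]
    th <- hh
  }
  if (nrow(hh) == 0L || nrow(th) == 0L)
    return(list(call = NULL, status = "no_hit"))
  if (nrow(hh) > 1L || nrow(th) > 1L)
    return(list(call = NULL, status = "not_unique"))
  results <- list()
  # plus orientation: read as-is, anchors hit on "+"
  if (hh$strand == "+" && th$strand == "+" && hh$chrom == th$chrom) {
    r <- .call_oriented(read, genome[[hh$chrom]], hh$pos, th$pos,
                        anchor_len, max_span, "+")
    if (!is.null(r)) results[[length(results) + 1L]] <-
        list(chrom = hh$chrom, r = r)
  }
  # minus orientation: reverse-complement the read; its head anchor is the
  # reverse complement of the original tail anchor, hitting "-" entries
  if (hh$strand == "-" && th$strand == "-" && hh$chrom == th$chrom) {
    rc <- revcomp(read)
    r <- .call_oriented(rc, genome[[hh$chrom]], th$pos, hh$pos,
                        anchor_len, max_span, "-")
    if (!is.null(r)) results[[length(results) + 1L]] <-
        list(chrom = hh$chrom, r = r)
  }
  if (!length(results)) return(list(call = NULL, status = "no_call"))
  amb <- vapply(results, function(x) identical(x$r, "ambiguous"), logical(1))
  if (any(amb) || length(results) > 1L)
    return(list(call = NULL, status = "ambiguous_breakpoint"))
  r <- results[[1]]
  call <- data.frame(chrom = r$chrom, strand = r$r$strand,
                     acceptor = r$r$acceptor, donor = r$r$donor,
                     splice_signal = "AG..GT", stringsAsFactors = FALSE)
  list(call = call, status = "called")
}

#' Detect back-splice junctions in a read set
#'
#' Runs anchor extraction, unique placement and breakpoint refinement over
#' all reads, then collapses calls per junction.
#'
#' @param reads read table (columns read_id, seq) or character vector
#' @param genome genome
#' @param anchor_len anchor length (default 20 nt, exact match)
#' @param min_unique_reads minimum distinct supporting read sequences
#' @param max_span maximum circle genomic span
#' @return list(candidates, calls, tallies); candidates is a CircCandidate
#'   table (chrom, start, end, strand, circ_id, junction_read_count,
#'   unique_read_ids)
#' @export
detect_backsplices <- function(reads, genome, anchor_len = 20L,
                               min_unique_reads = 2L, max_span = 1e5) {
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("r%06d", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  index <- build_index(genome, anchor_len)
  tallies <- c(called = 0L, too_short = 0L, no_hit = 0L, not_unique = 0L,
               no_call = 0L, ambiguous_breakpoint = 0L)
  calls <- list()
  long <- nchar(reads$seq) >= 2L * anchor_len
  tallies["too_short"] <- sum(!long)
  rr <- reads[long, , drop = FALSE]
  # batch anchor lookup: one keyed join for all distinct anchors
  heads <- substr(rr$seq, 1L, anchor_len)
  tails <- substr(rr$seq, nchar(rr$seq) - anchor_len + 1L, nchar(rr$seq))
  uq <- unique(c(heads, tails))
  hits <- index_lookup(index, uq)
  nhit <- table(factor(hits$query, levels = uq))
  hit1 <- hits[hits$query %in% names(nhit)[nhit == 1L], , drop = FALSE]
  rownames(hit1) <- hit1$query
  h_n <- as.integer(nhit[heads]); t_n <- as.integer(nhit[tails])
  status <- rep("no_call", nrow(rr))
  status[h_n == 0L | t_n == 0L] <- "no_hit"
  status[(h_n > 1L & t_n > 0L) | (t_n > 1L & h_n > 0L)] <- "not_unique"
  cand <- which(status == "no_call" &
                  hit1[heads, "chrom"] == hit1[tails, "chrom"] &
                  hit1[heads, "strand"] == hit1[tails, "strand"])
  for (i in cand) {
    hh <- hit1[heads[i], ]; th <- hit1[tails[i], ]
    if (hh$strand == "+") {
      r <- .call_oriented(rr$seq[i], genome[[hh$chrom]], hh$pos, th$pos,
                          anchor_len, max_span, "+")
    } else {
      r <- .call_oriented(revcomp(rr$seq[i]), genome[[hh$chrom]],
                          th$pos, hh$pos, anchor_len, max_span, "-")
    }
    if (is.null(r)) next
    if (identical(r, "ambiguous")) {
      status[i] <- "ambiguous_breakpoint"
      next
    }
    status[i] <- "called"
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = hh$chrom, strand = r$strand, acceptor = r$acceptor,
      donor = r$donor, splice_signal = "AG..GT", read_id = rr$read_id[i],
      read_seq = rr$seq[i], stringsAsFactors = FALSE)
  }
  for (s in unique(status)) tallies[s] <- tallies[s] + sum(status == s)
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(0), strand = character(0),
               acceptor = integer(0), donor = integer(0),
               splice_signal = character(0), read_id = character(0),
               read_seq = character(0), stringsAsFactors = FALSE)
  list(candidates = collapse_and_filter(calls, min_unique_reads),
       calls = calls, tallies = tallies)
}

#' Collapse junction calls and apply the unique-read threshold
#'
#' Calls are grouped by (chrom, strand, acceptor, donor); support is the
#' number of distinct read sequences ("unique reads"), and groups below
#' \code{min_unique_reads} (default 2, the minimum expression threshold)
#' are dropped. Output order is deterministic.
#'
#' @param calls per-read call table from \code{detect_backsplices}
#' @param min_unique_reads threshold on distinct supporting sequences
#' @return CircCandidate data.frame
#' @export
collapse_and_filter <- function(calls, min_unique_reads = 2L) {
  if (nrow(calls) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      circ_id = character(0), junction_read_count = integer(0),
                      unique_read_ids = character(0), stringsAsFactors = FALSE))
  key <- paste(calls$chrom, calls$strand, calls$acceptor, calls$donor,
               sep = "\r")
  grp <- split(calls, key)
  out <- do.call(rbind, lapply(grp, function(g) {
    uniq <- !duplicated(g$read_seq)
    data.frame(chrom = g$chrom[1], start = g$acceptor[1], end = g$donor[1],
               strand = g$strand[1],
               circ_id = circ_id(g$chrom[1], g$acceptor[1], g$donor[1],
                                 g$strand[1]),
               junction_read_count = sum(uniq),
               unique_read_ids = paste(sort(g$read_id[uniq]), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$junction_read_count >= min_unique_reads, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
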