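#' Assign per-sample expression tiers
#'
#' Three ordinal classes per sample: 0 = not detected, 1 = detected (at
#' least \code{min_reads} unique junction reads), 2 = high (detected and
#' within the top \code{top_fraction} of detected circRNAs by raw junction
#' read count; 10\% in most samples, 5\% for platelets). Exactly
#' \code{ceiling(top_fraction * n_detected)} circRNAs are labeled high;
#' ties at the cutoff are broken by higher CLR, then by circ_id.
#'
#' @param catalog one sample's catalog: circ_id, junction_reads (or
#'   junction_read_count), optionally CLR
#' @param top_fraction fraction in (0, 1]
#' @param min_reads detection threshold (default 2 unique junction reads)
#' @return data.frame(circ_id, tier)
#' @export
tier_sample <- function(catalog, top_fraction = 0.10, min_reads = 2L) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1)
    .fail("top_fraction must be in (0, 1]")
  cnt <- if ("junction_reads" %in% names(catalog))
    catalog$junction_reads else catalog$junction_read_count
  if (is.null(cnt)) .fail("catalog lacks junction read counts")
  clr_col <- if ("CLR" %in% names(catalog)) catalog$CLR else rep(0, nrow(catalog))
  tier <- ifelse(cnt >= min_reads, 1L, 0L)
  det <- which(tier == 1L)
  n_high <- ceiling(top_fraction * length(det))
  if (n_high > 0L) {
    o <- det[order(-cnt[det], -clr_col[det], catalog$circ_id[det])]
    tier[o[seq_len(n_high)]] <- 2L
  }
  data.frame(circ_id = catalog$circ_id, tier = tier,
             stringsAsFactors = FALSE)
}

#' Build the plotted tier matrix across samples
#'
#' Rows are restricted to circRNAs labeled high (2) in at least one sample;
#' a circRNA absent from a sample's catalog scores 0 there. Row and column
#' order are deterministic (sorted ids / given sample order).
#'
#' @param tiered named list of \code{tier_sample} outputs (names = samples)
#' @return integer matrix circ_id x sample
#' @export
build_matrix <- function(tiered) {
  if (length(tiered) < 2L) .fail("need at least two samples")
  ids <- sort(unique(unlist(lapply(tiered, `[[`, "circ_id"))))
  m <- matrix(0L, length(ids), length(tiered),
              dimnames = list(ids, names(tiered)))
  for (s in names(tiered)) {
    t <- tiered[[s]]
    m[t$circ_id, s] <- t$tier
  }
  keep <- apply(m, 1, function(r) any(r == 2L))
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) warning("no circRNA is high in any sample")
  m
}

#' Hierarchically cluster a tier matrix
#'
#' Complete linkage on Manhattan distance over the ordinal codes; input-
#' order invariant up to label permutation.
#'
#' @param m tier matrix from \code{\link{build_matrix}}
#' @return list(row_order, col_order, row_hclust, col_hclust)
#' @export
cluster_matrix <- function(m) {
  if (nrow(m) == 0L) .fail("empty matrix")
  ord1 <- function(x) {
    if (nrow(x) < 2L)
      return(list(order = seq_len(nrow(x)), hc = NULL))
    hc <- hclust(dist(x, method = "manhattan"), method = "complete")
    list(order = hc$order, hc = hc)
  }
  r <- ord1(m); cc <- ord1(t(m))
  list(row_order = rownames(m)[r$order], col_order = colnames(m)[cc$order],
       row_hclust = r$hc, col_hclust = cc$hc)
}

#' Pairwise (and optional multi-way) circRNA set overlaps between samples
#'
#' @param sets named list of circ_id character vectors
#' @param combos optional list of sample-name vectors for multi-way
#'   intersections
#' @return list(pairwise = symmetric count matrix, multi = data.frame of
#'   combo sizes or NULL)
#' @export
overlap_counts <- function(sets, combos = NULL) {
  sets <- lapply(sets, unique)
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  multi <- NULL
  if (!is.null(combos)) {
    multi <- data.frame(
      combo = vapply(combos, paste, character(1), collapse = "&"),
      n = vapply(combos, function(k)
        length(Reduce(intersect, sets[k])), integer(1)),
      stringsAsFactors = FALSE)
  }
  list(pairwise = m, multi = multi)
}
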