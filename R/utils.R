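#' @importFrom stats rbinom rnorm runif sd setNames t.test hclust dist as.dendrogram
#' @importFrom utils write.table read.table head
#' @importFrom data.table data.table setkey rbindlist :=
NULL

# Reverse complement of an A/C/G/T/N character vector (plain strings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half-up to a fixed number of decimals
#'
#' Base \code{round()} rounds half-to-even; printed report columns follow the
#' half-up convention (0.85 -> 0.9) used for one-decimal CLR values.
#'
#' @param x numeric vector
#' @param digits decimals to keep
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stopifnot with a formatted message
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.check_prob <- function(p, what) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    .fail("%s must be a probability in [0,1]", what)
  invisible(p)
}

# Deterministic child seeds derived from one master seed (kept < 2^31).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647L)
}

# Standard genetic code lookup, codon string -> single-letter AA ('*' = stop).
.codon_table <- local({
  aa <- Biostrings::GENETIC_CODE
  setNames(as.character(aa), names(aa))
})

translate_codons <- function(codons) {
  out <- .codon_table[codons]
  out[is.na(out)] <- "X"
  unname(out)
}
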