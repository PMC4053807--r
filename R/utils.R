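# Internal helpers shared across modules.

#' Convert nucleotide strings to the RNA alphabet
#'
#' Uppercases and replaces T with U. Motif definitions in this package are
#' RNA-alphabet (A, C, G, U); DNA input is normalized on ingest.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector in the RNA alphabet.
#' @export
as_rna <- function(x) {
  chartr("Tt", "Uu", toupper(as.character(x)))
}

# Random RNA sequences with a given base composition.
# probs must be named with A, C, G, U.
random_rna <- function(n, len, probs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  stopifnot(all(c("A", "C", "G", "U") %in% names(probs)))
  len <- rep_len(len, n)
  bases <- sample(names(probs), sum(len), replace = TRUE, prob = probs)
  stops <- cumsum(len)
  starts <- stops - len + 1L
  vapply(seq_len(n), function(i) {
    paste(bases[starts[i]:stops[i]], collapse = "")
  }, character(1))
}

# Rank transform with average ties (the rank machinery behind every
# Spearman-type computation here); columns of a data.frame/matrix.
rank_columns <- function(m) {
  m <- as.matrix(m)
  apply(m, 2, rank, ties.method = "average")
}

# Strand-resolved GRanges from the package's 0-based half-open site table.
sites_to_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = sites$strand
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
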