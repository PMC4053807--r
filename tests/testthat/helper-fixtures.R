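# Shared fixtures: a hand-built two-gene transcriptome with known segment
# coordinates, and small-site constructors. All coordinates 0-based
# half-open.

# geneA (+): utr5 [0,100) cds [100,300) intron [300,400) utr3 [400,600)
# geneB (-): genomic ascending utr3 [1000,1200) intron [1200,1300)
#            cds [1300,1500) utr5 [1500,1600)
toy_transcriptome <- function() {
  seg <- rbind(
    data.frame(gene_id = "geneA", chrom = "chr1",
               start = c(0, 100, 300, 400), end = c(100, 300, 400, 600),
               strand = "+", type = c("utr5", "cds", "intron", "utr3"),
               piece = 1L, tx_order = 1:4, stringsAsFactors = FALSE),
    data.frame(gene_id = "geneB", chrom = "chr1",
               start = c(1500, 1300, 1200, 1000),
               end = c(1600, 1500, 1300, 1200),
               strand = "-", type = c("utr5", "cds", "intron", "utr3"),
               piece = 1L, tx_order = 1:4, stringsAsFactors = FALSE)
  )
  seg$length <- seg$end - seg$start
  seg <- seg[, c("gene_id", "chrom", "start", "end", "strand",
                 "type", "piece", "length", "tx_order")]
  structure(list(segments = seg, sequences = NULL, n_genes = 2L),
            class = "areclip_transcriptome")
}

make_site <- function(chrom = "chr1", start = 0L, end = 25L, strand = "+",
                      gene_id = NA_character_, region = "unannotated",
                      read_count = 10L, t2c = 5L, other = 1L,
                      sequence = NA_character_) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, gene_id = gene_id, region = region,
             read_count = as.integer(read_count),
             t2c_read_count = as.integer(t2c),
             other_conv_read_count = as.integer(other),
             sequence = sequence, stringsAsFactors = FALSE)
}

# small fast generator config for tests
small_config <- function(...) {
  areclip_config(n_genes = 200, n_sites = 500, ...)
}

# exhaustive sliding-window motif count, independent of the implementation
brute_count <- function(seqs, motif) {
  k <- nchar(motif)
  occ <- 0L
  for (s in seqs) {
    n <- nchar(s)
    if (n >= k) {
      for (i in 1:(n - k + 1)) {
        if (substr(s, i, i + k - 1) == motif) occ <- occ + 1L
      }
    }
  }
  list(occurrences = occ, total_nt = sum(nchar(seqs)))
}
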