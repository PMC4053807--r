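# Writers/readers for the standard interchange formats: GTF transcript
# models, FASTA sequence sets, TSV expression tables and a JSON manifest of
# generating parameters.

gtf_feature <- c(utr5 = "five_prime_utr", cds = "CDS",
                 intron = "intron", utr3 = "three_prime_utr")

#' Write transcript models as GTF
#'
#' One feature row per segment (five_prime_utr / CDS / intron /
#' three_prime_utr) with gene_id and transcript_id attributes; GTF is
#' 1-based closed, converted from the internal 0-based half-open
#' coordinates by rtracklayer.
#'
#' @param tx an `areclip_transcriptome`.
#' @param path output `.gtf` path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_gtf <- function(tx, path) {
  seg <- tx$segments
  gr <- GenomicRanges::GRanges(
    seqnames = seg$chrom,
    ranges = IRanges::IRanges(seg$start + 1L, seg$end),
    strand = seg$strand,
    type = unname(gtf_feature[seg$type]),
    source = "areclip",
    gene_id = seg$gene_id,
    transcript_id = paste0(seg$gene_id, ".t1")
  )
  # synthetic CDS pieces carry no reading-frame phase; rtracklayer warns
  suppressWarnings(rtracklayer::export(gr, path, format = "gtf"))
  invisible(path)
}

#' Read transcript models from GTF/GFF
#'
#' Inverse of [write_transcriptome_gtf()]: rebuilds the segment table
#' (0-based half-open) from the five_prime_utr / CDS / intron /
#' three_prime_utr features of a GTF or GFF3 file. Sequences are not
#' recoverable from annotation and are left `NULL`.
#'
#' @param path GTF/GFF3 file.
#' @return an `areclip_transcriptome` (without sequences).
#' @export
read_transcriptome_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  inv <- stats::setNames(names(gtf_feature), gtf_feature)
  keep <- as.character(gr$type) %in% names(inv)
  gr <- gr[keep]
  seg <- data.frame(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = unname(inv[as.character(gr$type)]),
    stringsAsFactors = FALSE
  )
  seg$length <- seg$end - seg$start
  # transcript order: genomic order on +, reversed on -
  seg <- seg[order(seg$gene_id, seg$start), ]
  n_per <- table(seg$gene_id)
  seg$tx_order <- unlist(lapply(unique(seg$gene_id), function(g) {
    k <- n_per[[g]]
    if (seg$strand[seg$gene_id == g][1] == "+") seq_len(k) else rev(seq_len(k))
  }), use.names = FALSE)
  seg <- seg[order(seg$gene_id, seg$tx_order), ]
  seg$piece <- stats::ave(seq_len(nrow(seg)), seg$gene_id, seg$type,
                          FUN = seq_along)
  rownames(seg) <- NULL
  seg <- seg[, c("gene_id", "chrom", "start", "end", "strand",
                 "type", "piece", "length", "tx_order")]
  structure(list(segments = seg, sequences = NULL,
                 n_genes = length(unique(seg$gene_id))),
            class = "areclip_transcriptome")
}

#' Write a named sequence set as FASTA
#'
#' @param seqs named character vector (RNA alphabet).
#' @param path output `.fa` path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA sequence set (normalized to RNA alphabet)
#'
#' @param path FASTA file (RNA or DNA alphabet).
#' @return named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  stats::setNames(as_rna(as.character(s)), names(s))
}

#' Write an expression table as TSV
#'
#' @param expression an `areclip_expression` or a data.frame.
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  tab <- if (inherits(expression, "areclip_expression")) {
    cbind(expression$table, expression$replicates)
  } else expression
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a complete dataset and write it to disk
#'
#' Runs the full generator — transcriptome, binding sites, gene summaries,
#' expression changes — and writes GTF transcript models, a FASTA of 3' UTR
#' background sequences, the site CSV, the expression TSV and a JSON
#' manifest of all generating parameters.
#'
#' @param config an [areclip_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tx <- generate_transcriptome(config)
  sites <- generate_sites(tx, config)
  gs <- summarize_genes(sites, tx)
  expr <- generate_expression(gs, config)
  paths <- list(
    gtf = file.path(outdir, "transcriptome.gtf"),
    utr3_fasta = file.path(outdir, "utr3_background.fa"),
    sites = file.path(outdir, "sites.csv"),
    expression = file.path(outdir, "expression.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )
  write_transcriptome_gtf(tx, paths$gtf)
  write_fasta(utr3_sequences(tx), paths$utr3_fasta)
  write_site_table(sites, paths$sites)
  write_expression_tsv(expr, paths$expression)
  manifest <- config
  manifest$positional_bias <- if (is.null(config$positional_bias)) {
    NULL
  } else "custom function (not serialized)"
  class(manifest) <- NULL
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(transcriptome = tx, sites = sites, gene_summaries = gs,
                 expression = expr, paths = paths))
}
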