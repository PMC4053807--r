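# Annotation of binding sites to transcript regions and reduction to
# gene-level summaries.

region_precedence <- c(utr3 = 1L, utr5 = 2L, cds = 3L, intron = 4L)

#' Annotate binding sites with gene and transcript region
#'
#' Strand-aware interval overlap of sites against the transcriptome's
#' segments. Each site is assigned to at most one gene — the gene with the
#' largest total overlap; an exact tie between genes leaves the site
#' `unannotated` to avoid double counting. Within the winning gene the
#' region label is the segment type with the majority of the overlap,
#' ties broken by the precedence utr3 > utr5 > cds > intron. Sites on
#' chromosomes absent from the annotation, or on the opposite strand of
#' every overlapping gene, are labelled `unannotated`. The assignment is
#' deterministic and independent of input row order.
#'
#' @param sites site data.frame (0-based half-open).
#' @param transcriptome an `areclip_transcriptome`.
#' @return `sites` with `gene_id` and `region` (re)assigned.
#' @export
annotate_sites <- function(sites, transcriptome) {
  seg <- transcriptome$segments
  seg_gr <- GenomicRanges::GRanges(
    seg$chrom, IRanges::IRanges(seg$start + 1L, seg$end), strand = seg$strand
  )
  site_gr <- sites_to_granges(sites)
  hits <- GenomicRanges::findOverlaps(site_gr, seg_gr, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)

  gene_id <- rep(NA_character_, nrow(sites))
  region <- rep("unannotated", nrow(sites))

  if (length(q)) {
    ovw <- pmin(sites$end[q], seg$end[s]) -
      pmax(sites$start[q], seg$start[s])
    h <- data.frame(site = q, gene = seg$gene_id[s], type = seg$type[s],
                    w = ovw, stringsAsFactors = FALSE)
    n_hits <- tabulate(h$site, nbins = nrow(sites))

    # common case: a site overlapping exactly one segment
    single <- h[n_hits[h$site] == 1L, , drop = FALSE]
    gene_id[single$site] <- single$gene
    region[single$site] <- single$type

    # sites straddling segment boundaries or multiple genes
    for (si in unique(h$site[n_hits[h$site] > 1L])) {
      rows <- h[h$site == si, , drop = FALSE]
      per_gene <- tapply(rows$w, rows$gene, sum)
      per_gene <- sort(per_gene, decreasing = TRUE)
      if (length(per_gene) > 1 && per_gene[1] == per_gene[2]) next  # gene tie
      win <- names(per_gene)[1]
      tw <- rows[rows$gene == win, , drop = FALSE]
      per_type <- tapply(tw$w, tw$type, sum)
      o <- order(-per_type, region_precedence[names(per_type)])
      gene_id[si] <- win
      region[si] <- names(per_type)[o[1]]
    }
  }
  sites$gene_id <- gene_id
  sites$region <- region
  sites
}

#' Reduce annotated sites to gene-level summaries
#'
#' One row per gene with at least one annotated site: site counts per
#' region, the gene's (longest) 3' UTR length, and the region category —
#' `utr3_only` when every site is in the 3' UTR, `intron_only` when every
#' site is intronic, `both` when the gene has at least one of each, and
#' `other` for the remaining mixtures. Optionally joins a per-gene
#' expression table (columns `gene_id`, `log2fc`, and optionally
#' `significant`).
#'
#' @param sites annotated site data.frame.
#' @param transcriptome an `areclip_transcriptome` (source of 3' UTR lengths).
#' @param expression optional per-gene expression data.frame; duplicate
#'   gene ids are an error.
#' @return data.frame of gene summaries.
#' @export
summarize_genes <- function(sites, transcriptome, expression = NULL) {
  ann <- sites[!is.na(sites$gene_id) & sites$region != "unannotated", ,
               drop = FALSE]
  genes <- sort(unique(ann$gene_id))
  count_region <- function(r) {
    tab <- table(factor(ann$gene_id[ann$region == r], levels = genes))
    as.integer(tab)
  }
  out <- data.frame(
    gene_id = genes,
    n_sites_utr3 = count_region("utr3"),
    n_sites_utr5 = count_region("utr5"),
    n_sites_cds = count_region("cds"),
    n_sites_intron = count_region("intron"),
    stringsAsFactors = FALSE
  )
  total <- out$n_sites_utr3 + out$n_sites_utr5 + out$n_sites_cds +
    out$n_sites_intron
  out$region_category <- ifelse(
    out$n_sites_utr3 == total, "utr3_only",
    ifelse(out$n_sites_intron == total, "intron_only",
           ifelse(out$n_sites_utr3 > 0 & out$n_sites_intron > 0,
                  "both", "other")))
  u3 <- utr3_lengths(transcriptome)
  out$utr3_length <- as.numeric(u3[out$gene_id])

  if (!is.null(expression)) {
    if (anyDuplicated(expression$gene_id)) {
      stop("expression table has duplicate gene ids: ",
           paste(unique(expression$gene_id[duplicated(expression$gene_id)]),
                 collapse = ", "), call. = FALSE)
    }
    m <- match(out$gene_id, expression$gene_id)
    out$log2fc <- expression$log2fc[m]
    if ("significant" %in% names(expression)) {
      out$significant <- expression$significant[m]
    }
  }
  out
}
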