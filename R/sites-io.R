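# Reading, writing and validating binding-site (PARalyzer cluster) tables.
#
# Internal coordinates are 0-based half-open throughout the package. BED
# input is already 0-based half-open; CSV cluster tables use 1-based closed
# coordinates and are converted on read (and back on write).

csv_cols <- c("chrom", "start", "end", "strand", "gene_id", "region",
              "read_count", "t2c_read_count", "other_conv_read_count",
              "sequence")

#' Read a binding-site table
#'
#' Ingests PARalyzer-style cluster tables as CSV (1-based closed
#' coordinates, header `chrom,start,end,strand,gene_id,region,read_count,
#' t2c_read_count,other_conv_read_count,sequence`) or BED6 (0-based
#' half-open). Coordinates are normalized to the package's 0-based half-open
#' convention, sequences to the RNA alphabet. Rows violating the site
#' invariants (start < end; t2c + other <= read_count; sequence length
#' matching the interval when present) are dropped with a row-numbered
#' warning.
#'
#' @param path file to read.
#' @param dialect `"csv_clusters"` or `"bed6"`.
#' @return data.frame of binding sites (0-based half-open).
#' @export
read_site_table <- function(path, dialect = c("csv_clusters", "bed6")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "bed6") {
    gr <- rtracklayer::import(path, format = "BED")
    sites <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_id = NA_character_,
      region = "unannotated",
      read_count = as.integer(gr$score %||% NA_integer_),
      t2c_read_count = NA_integer_,
      other_conv_read_count = NA_integer_,
      sequence = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    missing <- setdiff(csv_cols, names(tab))
    if (length(missing)) {
      stop("csv_clusters table lacks columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    sites <- data.frame(
      chrom = tab$chrom,
      start = as.integer(tab$start) - 1L,  # 1-based closed -> 0-based half-open
      end = as.integer(tab$end),
      strand = tab$strand,
      gene_id = ifelse(tab$gene_id == "" | is.na(tab$gene_id),
                       NA_character_, tab$gene_id),
      region = ifelse(tab$region == "" | is.na(tab$region),
                      "unannotated", tab$region),
      read_count = as.integer(tab$read_count),
      t2c_read_count = as.integer(tab$t2c_read_count),
      other_conv_read_count = as.integer(tab$other_conv_read_count),
      sequence = ifelse(tab$sequence == "" | is.na(tab$sequence),
                        NA_character_, as_rna(tab$sequence)),
      stringsAsFactors = FALSE
    )
  }
  validate_sites(sites)
}

# Drop invariant-violating rows with a row-numbered report.
validate_sites <- function(sites) {
  bad_interval <- !is.na(sites$start) & !is.na(sites$end) &
    sites$start >= sites$end
  bad_counts <- !is.na(sites$read_count) & !is.na(sites$t2c_read_count) &
    !is.na(sites$other_conv_read_count) &
    (sites$t2c_read_count + sites$other_conv_read_count > sites$read_count)
  bad_seq <- !is.na(sites$sequence) &
    nchar(sites$sequence) != (sites$end - sites$start)
  bad <- bad_interval | bad_counts | bad_seq
  if (any(bad)) {
    warning("dropped ", sum(bad), " invalid row(s): ",
            paste(which(bad), collapse = ", "),
            " (start>=end: ", paste(which(bad_interval), collapse = ","),
            "; counts: ", paste(which(bad_counts), collapse = ","),
            "; sequence length: ", paste(which(bad_seq), collapse = ","), ")",
            call. = FALSE)
    sites <- sites[!bad, , drop = FALSE]
    rownames(sites) <- NULL
  }
  sites
}

#' Write a binding-site table as CSV
#'
#' Inverse of [read_site_table()] for the `csv_clusters` dialect:
#' coordinates are emitted 1-based closed.
#'
#' @param sites site data.frame (0-based half-open).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  out <- sites[, intersect(csv_cols, names(sites)), drop = FALSE]
  out$start <- out$start + 1L
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Per-cluster conversion metrics
#'
#' The two PAR-CLIP signal-quality scores per cluster: the fraction of reads
#' carrying a T-to-C conversion, `t2c / read_count`, and the conversion
#' specificity, `log10(t2c / (1 + other))`. When a cluster has no T-to-C
#' reads the specificity is undefined and reported as `NA` with
#' `no_signal = TRUE` (never negative infinity).
#'
#' @param sites site data.frame with read_count, t2c_read_count and
#'   other_conv_read_count; read_count must be positive.
#' @return data.frame with columns conversion_fraction,
#'   conversion_specificity, no_signal.
#' @export
conversion_metrics <- function(sites) {
  if (any(sites$read_count <= 0)) {
    stop("read_count must be positive for conversion metrics", call. = FALSE)
  }
  frac <- sites$t2c_read_count / sites$read_count
  no_signal <- sites$t2c_read_count == 0
  spec <- ifelse(no_signal, NA_real_,
                 log10(sites$t2c_read_count /
                         (1 + sites$other_conv_read_count)))
  data.frame(conversion_fraction = frac,
             conversion_specificity = spec,
             no_signal = no_signal)
}

#' Depth-match a site library
#'
#' Returns the `target_n` sites with the highest read counts, the standard
#' construction for comparing libraries sequenced at different depths (e.g.
#' the "best" subset of a deeper library sized to match a shallower one).
#' Ties in read count are broken by (chrom, start) order so the subset is
#' deterministic.
#'
#' @param sites site data.frame.
#' @param target_n subset size; must not exceed `nrow(sites)`.
#' @return data.frame of `target_n` sites.
#' @export
depth_match <- function(sites, target_n) {
  if (target_n > nrow(sites)) {
    stop("target_n (", target_n, ") exceeds the number of sites (",
         nrow(sites), ")", call. = FALSE)
  }
  o <- order(-sites$read_count, sites$chrom, sites$start)
  out <- sites[o[seq_len(target_n)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
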