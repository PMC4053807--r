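# Motif occurrence counting, signal-to-noise enrichment and RRE
# classification for AU-rich element binding sites.

#' Canonical ZFP36 RNA regulatory elements
#'
#' The four classic tristetraprolin-family recognition elements: the
#' nonamer UUAUUUAUU, the octamer UAUUUAUU (the residues contacted by the
#' tandem zinc-finger domain), the UAUU half-site, and the AUUUA pentamer.
#'
#' @format named character vector of RNA motifs.
#' @export
rre_motifs <- c(
  nonamer = "UUAUUUAUU",
  octamer = "UAUUUAUU",
  halfsite = "UAUU",
  pentamer = "AUUUA"
)

check_rna_motif <- function(motif) {
  if (nchar(motif) < 2) stop("motif must have length >= 2", call. = FALSE)
  if (!all(strsplit(motif, "")[[1]] %in% c("A", "C", "G", "U"))) {
    stop("motif must use the RNA alphabet A/C/G/U: ", motif, call. = FALSE)
  }
  invisible(motif)
}

#' Count motif occurrences in a sequence set
#'
#' Overlapping mode (the default) counts every start position of a match,
#' so tandem, overlapping AU-rich elements are all counted; non-overlapping
#' mode consumes matched nucleotides left to right. Matching is exact
#' (no ambiguity codes) via [Biostrings::vcountPattern()].
#'
#' @param sequences character vector of RNA-alphabet sequences (DNA input
#'   is converted).
#' @param motif motif string over A/C/G/U.
#' @param count_mode `"overlapping"` or `"non_overlapping"`.
#' @return list with `occurrences` (total match count) and `total_nt`
#'   (summed sequence length).
#' @export
count_motif <- function(sequences, motif,
                        count_mode = c("overlapping", "non_overlapping")) {
  count_mode <- match.arg(count_mode)
  if (length(sequences) == 0) {
    stop("empty sequence set: nothing to count", call. = FALSE)
  }
  sequences <- as_rna(sequences)
  check_rna_motif(motif)
  total_nt <- sum(nchar(sequences))
  if (count_mode == "overlapping") {
    occ <- sum(Biostrings::vcountPattern(motif,
                                         Biostrings::RNAStringSet(sequences)))
  } else {
    # gregexpr(fixed = TRUE) returns left-to-right non-overlapping matches
    occ <- sum(vapply(gregexpr(motif, sequences, fixed = TRUE),
                      function(m) sum(m > 0), numeric(1)))
  }
  list(occurrences = as.integer(occ), total_nt = as.integer(total_nt))
}

#' Motif signal-to-noise ratio between sites and background
#'
#' The SNR of a motif is its number of occurrences per nucleotide in the
#' binding-site sequences divided by its occurrences per nucleotide in the
#' background set (canonically the longest annotated 3' UTR sequence per
#' gene). No pseudocounts are applied: when the motif never occurs in the
#' background the SNR is undefined and flagged rather than infinite.
#'
#' @param site_seqs character vector of site sequences.
#' @param background_seqs character vector of background sequences.
#' @param motif motif string over A/C/G/U.
#' @param count_mode passed to [count_motif()].
#' @return one-row data.frame: motif, site_occurrences, site_nt,
#'   bg_occurrences, bg_nt, site_rate, bg_rate, snr, undefined.
#' @export
compute_snr <- function(site_seqs, background_seqs, motif,
                        count_mode = "overlapping") {
  sc <- count_motif(site_seqs, motif, count_mode)
  bc <- count_motif(background_seqs, motif, count_mode)
  site_rate <- sc$occurrences / sc$total_nt
  bg_rate <- bc$occurrences / bc$total_nt
  undefined <- bc$occurrences == 0
  data.frame(
    motif = motif,
    site_occurrences = sc$occurrences, site_nt = sc$total_nt,
    bg_occurrences = bc$occurrences, bg_nt = bc$total_nt,
    site_rate = site_rate, bg_rate = bg_rate,
    snr = if (undefined) NA_real_ else site_rate / bg_rate,
    undefined = undefined,
    stringsAsFactors = FALSE
  )
}

#' Classify sequences by ZFP36 RRE content
#'
#' Non-exclusive substring containment flags for the nonamer, octamer,
#' half-site and pentamer. By construction the flags nest: a nonamer
#' implies an octamer, which implies a half-site; a nonamer also implies
#' a pentamer.
#'
#' @param site_sequence character vector of RNA-alphabet sequences.
#' @return data.frame of logicals has_nonamer, has_octamer, has_halfsite,
#'   has_pentamer.
#' @export
classify_rre <- function(site_sequence) {
  s <- as_rna(site_sequence)
  data.frame(
    has_nonamer = grepl(rre_motifs[["nonamer"]], s, fixed = TRUE),
    has_octamer = grepl(rre_motifs[["octamer"]], s, fixed = TRUE),
    has_halfsite = grepl(rre_motifs[["halfsite"]], s, fixed = TRUE),
    has_pentamer = grepl(rre_motifs[["pentamer"]], s, fixed = TRUE)
  )
}

#' RRE composition of a site set
#'
#' Fraction (and count) of sites containing each RRE and any RRE, overall
#' or split by region.
#'
#' @param sites site data.frame with a `sequence` column.
#' @param by_region split by the `region` column?
#' @return data.frame with one row per (subset, flag) carrying n, count and
#'   fraction; empty subsets yield `NA` fractions flagged by `undefined`.
#' @export
rre_composition <- function(sites, by_region = FALSE) {
  if (any(is.na(sites$sequence))) {
    stop("sites lacking sequences (rows ",
         paste(which(is.na(sites$sequence)), collapse = ", "),
         "): cannot classify", call. = FALSE)
  }
  flags <- classify_rre(sites$sequence)
  flags$has_any <- Reduce(`|`, flags)
  groups <- if (by_region) split(flags, sites$region) else list(all = flags)
  do.call(rbind, lapply(names(groups), function(g) {
    f <- groups[[g]]
    n <- nrow(f)
    data.frame(
      subset = g,
      flag = names(f),
      n = n,
      count = vapply(f, sum, integer(1)),
      fraction = if (n == 0) NA_real_ else vapply(f, mean, numeric(1)),
      undefined = n == 0,
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  }))
}

#' Compare SNR profiles across site sets
#'
#' One SNR per (site set, motif) against a shared background — the layout
#' used to contrast motif enrichment between two RBP libraries (optionally
#' depth-matched subsets).
#'
#' @param site_sets named list of character vectors of site sequences.
#' @param background_seqs shared background sequence set.
#' @param motifs character vector of motifs.
#' @return data.frame with columns set, motif, snr (plus the full
#'   [compute_snr()] columns).
#' @export
compare_snr_profiles <- function(site_sets, background_seqs, motifs) {
  if (length(site_sets) < 2 || is.null(names(site_sets))) {
    stop("`site_sets` must be a named list of >= 2 sequence sets",
         call. = FALSE)
  }
  if (missing(background_seqs) || length(background_seqs) == 0) {
    stop("a shared background sequence set is required", call. = FALSE)
  }
  do.call(rbind, lapply(names(site_sets), function(nm) {
    rows <- do.call(rbind, lapply(motifs, function(m) {
      compute_snr(site_sets[[nm]], background_seqs, m)
    }))
    cbind(set = nm, rows, stringsAsFactors = FALSE)
  }))
}
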