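# Synthetic data generator: transcriptomes, binding sites, expression changes
# and probe affinity tables with the statistical structure the downstream
# analyses assume.

# Log-normal draws parameterized by arithmetic mean and coefficient of
# variation; lengths are rounded and kept >= 1 nt.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(round(mean), n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  pmax(1, round(stats::rlnorm(n, meanlog, sdlog)))
}

utr_comp <- c(A = 0.3, C = 0.2, G = 0.2, U = 0.3)
cds_comp <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)

#' Generate a synthetic transcriptome
#'
#' Builds `n_genes` single-transcript genes, each with contiguous
#' non-overlapping segments in transcript order 5' UTR, CDS pieces
#' interleaved with `n_introns` introns, then 3' UTR. Genes are laid out
#' sequentially on one synthetic chromosome with fixed intergenic gaps and
#' alternate between strands, so both strands are represented. Coordinates
#' are 0-based half-open; on the minus strand the genomic order of segments
#' is reversed while transcript order is preserved.
#'
#' Segment lengths are drawn log-normally from `config$segment_length_params`
#' (CDS parameters apply per CDS piece). UTR sequences use a mildly AU-rich
#' base composition; CDS and introns are uniform.
#'
#' @param config an [areclip_config()].
#' @param sequences generate per-segment sequences (RNA alphabet)? Set to
#'   `FALSE` to skip sequence generation when only coordinates are needed.
#' @return an object of class `areclip_transcriptome`: a list with
#'   `segments` (data.frame: gene_id, chrom, start, end, strand, type,
#'   piece, length, tx_order) and `sequences` (named character vector keyed
#'   by `gene_id|type|piece`, or `NULL`).
#' @export
generate_transcriptome <- function(config, sequences = TRUE) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  slp <- config$segment_length_params

  # transcript-order segment template
  types <- c("utr5",
             as.vector(rbind(rep("cds", config$n_introns + 1),
                             c(rep("intron", config$n_introns), NA)))[
               seq_len(2 * config$n_introns + 1)],
             "utr3")
  n_seg <- length(types)

  seg <- data.frame(
    gene_id = rep(sprintf("gene%04d", seq_len(n)), each = n_seg),
    type = rep(types, n),
    tx_order = rep(seq_len(n_seg), n),
    stringsAsFactors = FALSE
  )
  seg$piece <- stats::ave(seq_len(nrow(seg)),
                          seg$gene_id, seg$type, FUN = seq_along)
  for (tp in unique(types)) {
    idx <- seg$type == tp
    p <- slp[[tp]]
    seg$length[idx] <- rlnorm_mean_cv(sum(idx), p[["mean"]], p[["cv"]])
  }

  strand <- rep(c("+", "-"), length.out = n)
  gene_span <- tapply(seg$length, seg$gene_id, sum)[unique(seg$gene_id)]
  gap <- 1000L
  gene_start <- cumsum(c(0, utils::head(gene_span + gap, -1)))
  names(gene_start) <- unique(seg$gene_id)

  seg$strand <- strand[match(seg$gene_id, unique(seg$gene_id))]
  # genomic layout: transcript order runs left-to-right on +, right-to-left
  # on -, so the 3' UTR of a minus-strand gene sits leftmost genomically
  csum <- stats::ave(seg$length, seg$gene_id, FUN = cumsum)
  span <- stats::ave(seg$length, seg$gene_id, FUN = sum)
  gs <- gene_start[seg$gene_id]
  seg$start <- as.integer(ifelse(seg$strand == "+",
                                 gs + csum - seg$length,
                                 gs + span - csum))
  seg$end <- seg$start + seg$length
  seg$chrom <- "chrS"

  seqs <- NULL
  if (sequences) {
    comp <- ifelse(seg$type %in% c("utr5", "utr3"), "utr", "cds")
    seqs <- character(nrow(seg))
    for (cc in c("utr", "cds")) {
      idx <- comp == cc
      seqs[idx] <- random_rna(sum(idx), seg$length[idx],
                              if (cc == "utr") utr_comp else cds_comp)
    }
    names(seqs) <- paste(seg$gene_id, seg$type, seg$piece, sep = "|")
  }

  seg <- seg[, c("gene_id", "chrom", "start", "end", "strand",
                 "type", "piece", "length", "tx_order")]
  structure(list(segments = seg, sequences = seqs, n_genes = n),
            class = "areclip_transcriptome")
}

#' @export
print.areclip_transcriptome <- function(x, ...) {
  cat("<areclip_transcriptome> ", x$n_genes, " genes, ",
      nrow(x$segments), " segments",
      if (is.null(x$sequences)) " (no sequences)" else "", "\n", sep = "")
  invisible(x)
}

#' 3' UTR lengths of a transcriptome
#'
#' One value per gene; with a single transcript per gene this is also the
#' longest annotated 3' UTR of the gene.
#'
#' @param tx an `areclip_transcriptome`.
#' @return named numeric vector of 3' UTR lengths (nt), keyed by gene.
#' @export
utr3_lengths <- function(tx) {
  u <- tx$segments[tx$segments$type == "utr3", ]
  stats::setNames(u$length, u$gene_id)
}

#' 3' UTR sequences of a transcriptome
#'
#' The background set for SNR computation: the (longest) 3' UTR sequence per
#' gene, RNA alphabet.
#'
#' @param tx an `areclip_transcriptome` generated with `sequences = TRUE`.
#' @return named character vector keyed by gene.
#' @export
utr3_sequences <- function(tx) {
  if (is.null(tx$sequences)) {
    stop("transcriptome was generated without sequences", call. = FALSE)
  }
  u <- tx$segments[tx$segments$type == "utr3", ]
  stats::setNames(tx$sequences[paste(u$gene_id, "utr3", u$piece, sep = "|")],
                  u$gene_id)
}

#' Generate synthetic binding sites on a transcriptome
#'
#' Draws `config$n_sites` PARalyzer-style clusters. Each site picks a host
#' gene uniformly, a region from `config$region_probs`, a log-normal length
#' (default mean 25 nt), and a position uniform within the host segment
#' (optionally weighted by `config$positional_bias` for 3' UTR sites). Site
#' sequences are AU-rich random RNA with one motif from `config$motif_mix`
#' planted at a uniform offset when planting fires. Read counts are negative
#' binomial; T-to-C and other-conversion read counts are binomial thinnings,
#' so `t2c + other <= read_count` always holds. Generating model parameters
#' are recorded in the `generator_params` attribute.
#'
#' @param transcriptome an `areclip_transcriptome`.
#' @param config an [areclip_config()].
#' @return data.frame of sites with 0-based half-open coordinates and
#'   columns chrom, start, end, strand, gene_id, region, read_count,
#'   t2c_read_count, other_conv_read_count, sequence, planted_motif.
#' @export
generate_sites <- function(transcriptome, config) {
  validate_config(config)
  if (nrow(transcriptome$segments) == 0) {
    stop("transcriptome is empty", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  n <- config$n_sites
  seg <- transcriptome$segments
  genes <- unique(seg$gene_id)

  motifs <- names(config$motif_mix)
  max_motif <- if (length(motifs)) max(nchar(motifs)) else 0L
  if (max_motif > 0 && config$site_length_mean < max_motif) {
    stop("configured site length (", config$site_length_mean,
         ") cannot accommodate the longest motif (", max_motif, " nt)",
         call. = FALSE)
  }

  rp <- config$region_probs
  if (config$n_introns == 0L && "intron" %in% names(rp) && rp[["intron"]] > 0) {
    rp <- rp[names(rp) != "intron"]
    rp <- rp / sum(rp)
  }

  gene_id <- sample(genes, n, replace = TRUE)
  region <- sample(names(rp), n, replace = TRUE, prob = rp)
  site_len <- rlnorm_mean_cv(n, config$site_length_mean, config$site_length_cv)
  site_len <- pmax(site_len, max_motif)

  # choose one host segment per site (uniform among pieces of the region)
  seg_key <- paste(seg$gene_id, seg$type)
  seg_split <- split(seq_len(nrow(seg)), seg_key)
  pick <- vapply(paste(gene_id, region), function(k) {
    rows <- seg_split[[k]]
    if (length(rows) == 1L) rows else rows[sample.int(length(rows), 1L)]
  }, integer(1))
  seg_len <- seg$length[pick]
  site_len <- pmin(site_len, seg_len)

  # offset of the site start within the segment, in transcript orientation
  max_off <- seg_len - site_len
  bias <- config$positional_bias
  off <- integer(n)
  for (i in seq_len(n)) {
    if (max_off[i] <= 0) {
      off[i] <- 0L
    } else if (is.null(bias) || region[i] != "utr3") {
      off[i] <- sample.int(max_off[i] + 1L, 1L) - 1L
    } else {
      cand <- 0:max_off[i]
      u <- (cand + site_len[i] / 2) / seg_len[i]
      w <- pmax(bias(u), 0)
      if (all(w == 0)) w <- rep(1, length(w))
      off[i] <- cand[sample.int(length(cand), 1L, prob = w)]
    }
  }

  plus <- seg$strand[pick] == "+"
  start <- ifelse(plus,
                  seg$start[pick] + off,
                  seg$end[pick] - off - site_len)
  end <- start + site_len

  # strand-resolved site sequences with motif planting
  sequence <- random_rna(n, site_len, utr_comp)
  planted <- rep(NA_character_, n)
  if (length(motifs)) {
    p <- config$motif_mix
    choice <- sample(c(motifs, ".none"), n, replace = TRUE,
                     prob = c(p, 1 - sum(p)))
    for (i in which(choice != ".none")) {
      m <- choice[i]
      ml <- nchar(m)
      pos <- sample.int(site_len[i] - ml + 1L, 1L)
      substr(sequence[i], pos, pos + ml - 1L) <- m
      planted[i] <- m
    }
  }

  read_count <- pmax(1L, stats::rnbinom(n, mu = config$read_mu,
                                        size = config$read_size))
  t2c <- stats::rbinom(n, read_count, config$p_t2c)
  other <- stats::rbinom(n, read_count - t2c, config$p_other)

  sites <- data.frame(
    chrom = seg$chrom[pick],
    start = as.integer(start),
    end = as.integer(end),
    strand = seg$strand[pick],
    gene_id = gene_id,
    region = region,
    read_count = as.integer(read_count),
    t2c_read_count = as.integer(t2c),
    other_conv_read_count = as.integer(other),
    sequence = sequence,
    planted_motif = planted,
    stringsAsFactors = FALSE
  )
  attr(sites, "generator_params") <- list(
    read_model = c(mu = config$read_mu, size = config$read_size),
    conversion_model = c(p_t2c = config$p_t2c, p_other = config$p_other),
    motif_mix = config$motif_mix,
    region_probs = rp,
    seed = config$seed
  )
  sites
}

#' Generate synthetic expression changes
#'
#' Per-gene log2 fold changes follow the linear model
#' `log2FC_g = beta_sites * n_sites_utr3_g + beta_len * (utr3_length_g / 1000)
#' + eps_g`, `eps_g ~ N(0, noise_sd^2)`, with per-replicate values equal to a
#' gene baseline plus the fold change plus replicate noise. The generating
#' parameters are stored alongside the table.
#'
#' @param gene_summaries data.frame with columns `gene_id`, `n_sites_utr3`
#'   and `utr3_length` (e.g. from [summarize_genes()], or any per-gene table).
#' @param config an [areclip_config()] supplying `beta_sites`, `beta_len`,
#'   `noise_sd`, `n_replicates`, `replicate_sd` and the seed.
#' @return list of class `areclip_expression` with `table` (gene_id, log2fc),
#'   `replicates` (genes x 2*n_replicates matrix, control then treated) and
#'   `params`.
#' @export
generate_expression <- function(gene_summaries, config) {
  validate_config(config)
  need <- c("gene_id", "n_sites_utr3", "utr3_length")
  if (!all(need %in% names(gene_summaries))) {
    stop("`gene_summaries` must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed + 2L)
  g <- gene_summaries
  n <- nrow(g)
  eps <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
  log2fc <- config$beta_sites * g$n_sites_utr3 +
    config$beta_len * (g$utr3_length / 1000) + eps

  k <- config$n_replicates
  baseline <- stats::rnorm(n, mean = 8, sd = 2)
  reps <- cbind(
    matrix(baseline, n, k) +
      matrix(stats::rnorm(n * k, 0, config$replicate_sd), n, k),
    matrix(baseline + log2fc, n, k) +
      matrix(stats::rnorm(n * k, 0, config$replicate_sd), n, k)
  )
  dimnames(reps) <- list(g$gene_id,
                         c(paste0("ctrl_", seq_len(k)),
                           paste0("trt_", seq_len(k))))
  structure(list(
    table = data.frame(gene_id = g$gene_id, log2fc = log2fc,
                       stringsAsFactors = FALSE),
    replicates = reps,
    params = list(beta_sites = config$beta_sites, beta_len = config$beta_len,
                  noise_sd = config$noise_sd,
                  replicate_sd = config$replicate_sd, seed = config$seed)
  ), class = "areclip_expression")
}

#' Generate a synthetic probe affinity table
#'
#' Emulates an in-vitro binding panel: `n` probes whose dissociation
#' constants follow a power law in the reciprocal SNR,
#' `Kd_i = a * (1/SNR_i)^b * 10^eta_i`, `eta_i ~ N(0, noise_sd_log^2)`.
#' SNR values are log-spaced over three decades. The association constant
#' `K` is reported as `1/Kd`.
#'
#' @param a power-law scale (nM); must be positive.
#' @param b power-law exponent.
#' @param noise_sd_log standard deviation of the multiplicative log10 noise.
#' @param n number of probes (>= 3).
#' @param seed RNG seed.
#' @return data.frame with columns sequence, K, Kd, snr.
#' @export
generate_affinity_probes <- function(a = 100, b = 0.8, noise_sd_log = 0.1,
                                     n = 50, seed = 1L) {
  if (a <= 0) stop("`a` must be positive", call. = FALSE)
  if (n < 3) stop("too few points to fit: need n >= 3", call. = FALSE)
  if (noise_sd_log < 0) stop("`noise_sd_log` must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  snr <- 10^seq(-0.5, 2.5, length.out = n)
  eta <- if (noise_sd_log > 0) stats::rnorm(n, 0, noise_sd_log) else 0
  kd <- a * (1 / snr)^b * 10^eta
  data.frame(
    sequence = random_rna(n, 13, utr_comp),
    K = 1 / kd,
    Kd = kd,
    snr = snr,
    stringsAsFactors = FALSE
  )
}

#' Generate a second RBP's site set with controlled overlap
#'
#' Emulates a companion library (e.g. an ELAVL1 set alongside a ZFP36 set):
#' each generated site overlaps a randomly chosen anchor site with
#' probability `overlap_prob` (placed to share at least one nucleotide,
#' clamped to the anchor's host segment and inheriting its gene and
#' region), and is otherwise placed independently like [generate_sites()].
#'
#' @param anchor_sites annotated site data.frame to overlap with.
#' @param transcriptome an `areclip_transcriptome`.
#' @param config an [areclip_config()] for the new set.
#' @param overlap_prob probability in \[0,1\] that a site is anchored.
#' @return data.frame of sites (same schema as [generate_sites()]) with an
#'   extra logical column `anchored`.
#' @export
generate_overlapping_sites <- function(anchor_sites, transcriptome, config,
                                       overlap_prob = 0.84) {
  if (overlap_prob < 0 || overlap_prob > 1) {
    stop("`overlap_prob` must lie in [0,1]", call. = FALSE)
  }
  sites <- generate_sites(transcriptome, config)
  set.seed(config$seed + 3L)
  n <- nrow(sites)
  anchored <- stats::runif(n) < overlap_prob
  host <- host_segment(anchor_sites, transcriptome)
  ok <- which(!is.na(host))
  if (length(ok) == 0 && any(anchored)) {
    stop("no anchor site lies within an annotated segment", call. = FALSE)
  }
  seg <- transcriptome$segments
  for (i in which(anchored)) {
    j <- ok[sample.int(length(ok), 1L)]
    len <- sites$end[i] - sites$start[i]
    a_start <- anchor_sites$start[j]
    a_end <- anchor_sites$end[j]
    # any start in (a_start - len, a_end) shares >= 1 nt with the anchor
    lo <- a_start - len + 1L
    hi <- a_end - 1L
    s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    # keep the site inside the anchor's host segment
    hs <- seg$start[host[j]]; he <- seg$end[host[j]]
    s <- min(max(s, hs), he - len)
    sites$start[i] <- as.integer(s)
    sites$end[i] <- as.integer(s + len)
    sites$chrom[i] <- anchor_sites$chrom[j]
    sites$strand[i] <- anchor_sites$strand[j]
    sites$gene_id[i] <- anchor_sites$gene_id[j]
    sites$region[i] <- anchor_sites$region[j]
  }
  sites$anchored <- anchored
  sites
}
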