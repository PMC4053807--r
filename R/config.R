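#' Configuration for the synthetic PAR-CLIP data generator
#'
#' Bundles every tunable of the synthetic transcriptome / binding-site /
#' expression generator and validates it once. Defaults emulate the scale and
#' structure of a ZFP36-style PAR-CLIP experiment in a human cell line:
#' a few thousand genes, ~25-nt clusters concentrated in 3' UTRs with a
#' smaller intronic fraction, AU-rich element motifs planted at realistic
#' per-site frequencies, overdispersed read counts with T-to-C conversion
#' evidence, and per-gene expression changes that are a linear function of
#' 3' UTR site count and 3' UTR length plus Gaussian noise.
#'
#' @param n_genes number of genes (one transcript each).
#' @param segment_length_params named list with entries `utr5`, `cds`,
#'   `intron`, `utr3`, each `c(mean, cv)`: mean segment length in nucleotides
#'   and coefficient of variation of the log-normal length distribution.
#' @param n_introns introns per gene (interleaved with CDS pieces).
#' @param n_sites total number of binding sites to generate.
#' @param site_length_mean,site_length_cv log-normal parameters of site
#'   (cluster) length in nucleotides; the default mean of 25 nt matches a
#'   typical PARalyzer cluster-length distribution.
#' @param motif_mix named numeric vector mapping motif (RNA alphabet) to the
#'   probability that a generated site has that motif planted; probabilities
#'   must sum to at most 1 (the remainder of sites receive no planted motif).
#' @param region_probs named probability vector over `utr3`, `utr5`, `cds`,
#'   `intron`; must sum to 1.
#' @param positional_bias optional function of relative 3' UTR position in
#'   \[0,1\] returning a nonnegative sampling weight; `NULL` means uniform.
#' @param read_mu,read_size negative-binomial mean and size of per-cluster
#'   aligned read counts.
#' @param p_t2c per-read probability of carrying a T-to-C conversion.
#' @param p_other per-read probability (among reads without T-to-C) of a
#'   non-T-to-C conversion.
#' @param beta_sites effect on log2 fold change per 3' UTR site.
#' @param beta_len effect on log2 fold change per kilobase of 3' UTR length.
#' @param noise_sd standard deviation of the gene-level Gaussian expression
#'   noise (log2 units).
#' @param n_replicates replicates per condition for the expression matrix.
#' @param replicate_sd standard deviation of replicate-level noise.
#' @param seed RNG seed; a fixed seed makes every generator byte-reproducible.
#'
#' @return an object of class `areclip_config` (a validated list).
#' @export
areclip_config <- function(n_genes = 2000,
                           segment_length_params = list(
                             utr5 = c(mean = 200, cv = 0.5),
                             cds = c(mean = 1500, cv = 0.5),
                             intron = c(mean = 2000, cv = 0.8),
                             utr3 = c(mean = 1000, cv = 0.8)
                           ),
                           n_introns = 1,
                           n_sites = 4000,
                           site_length_mean = 25,
                           site_length_cv = 0.3,
                           motif_mix = c(
                             UUAUUUAUU = 0.08,
                             UAUUUAUU = 0.10,
                             AUUUA = 0.30,
                             UAUU = 0.35
                           ),
                           region_probs = c(
                             utr3 = 0.70, intron = 0.26,
                             cds = 0.03, utr5 = 0.01
                           ),
                           positional_bias = NULL,
                           read_mu = 50, read_size = 2,
                           p_t2c = 0.7, p_other = 0.05,
                           beta_sites = -0.5,
                           beta_len = -0.3,
                           noise_sd = 0.5,
                           n_replicates = 5,
                           replicate_sd = 0.2,
                           seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    segment_length_params = segment_length_params,
    n_introns = as.integer(n_introns),
    n_sites = as.integer(n_sites),
    site_length_mean = site_length_mean,
    site_length_cv = site_length_cv,
    motif_mix = motif_mix,
    region_probs = region_probs,
    positional_bias = positional_bias,
    read_mu = read_mu, read_size = read_size,
    p_t2c = p_t2c, p_other = p_other,
    beta_sites = beta_sites, beta_len = beta_len,
    noise_sd = noise_sd,
    n_replicates = as.integer(n_replicates),
    replicate_sd = replicate_sd,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "areclip_config"
  cfg
}

validate_config <- function(cfg) {
  if (is.na(cfg$n_genes) || cfg$n_genes < 1L) {
    stop("`n_genes` must be a positive integer", call. = FALSE)
  }
  need <- c("utr5", "cds", "intron", "utr3")
  if (!all(need %in% names(cfg$segment_length_params))) {
    stop("`segment_length_params` needs entries for ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (r in need) {
    p <- cfg$segment_length_params[[r]]
    if (p[["mean"]] <= 0 || p[["cv"]] < 0) {
      stop("segment lengths must be positive with nonnegative cv (", r, ")",
           call. = FALSE)
    }
  }
  if (cfg$n_introns < 0L) stop("`n_introns` must be >= 0", call. = FALSE)
  if (cfg$n_sites < 0L) stop("`n_sites` must be >= 0", call. = FALSE)
  if (cfg$site_length_mean <= 0) stop("site length mean must be > 0", call. = FALSE)
  if (length(cfg$motif_mix)) {
    if (any(cfg$motif_mix < 0 | cfg$motif_mix > 1) || sum(cfg$motif_mix) > 1 + 1e-12) {
      stop("`motif_mix` probabilities must lie in [0,1] and sum to <= 1",
           call. = FALSE)
    }
    if (!all(strsplit(paste(names(cfg$motif_mix), collapse = ""), "")[[1]] %in%
               c("A", "C", "G", "U"))) {
      stop("`motif_mix` motifs must use the RNA alphabet A/C/G/U", call. = FALSE)
    }
  }
  rp <- cfg$region_probs
  if (any(rp < 0 | rp > 1) || abs(sum(rp) - 1) > 1e-9) {
    stop("`region_probs` must be probabilities summing to 1", call. = FALSE)
  }
  if (!all(names(rp) %in% c("utr3", "utr5", "cds", "intron"))) {
    stop("`region_probs` names must be among utr3, utr5, cds, intron",
         call. = FALSE)
  }
  if (!is.null(cfg$positional_bias) && !is.function(cfg$positional_bias)) {
    stop("`positional_bias` must be NULL or a function", call. = FALSE)
  }
  if (cfg$p_t2c < 0 || cfg$p_t2c > 1 || cfg$p_other < 0 || cfg$p_other > 1) {
    stop("conversion probabilities must lie in [0,1]", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (cfg$replicate_sd < 0) stop("`replicate_sd` must be >= 0", call. = FALSE)
  if (cfg$read_mu <= 0 || cfg$read_size <= 0) {
    stop("read-count parameters must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.areclip_config <- function(x, ...) {
  cat("<areclip_config>\n")
  cat("  genes:", x$n_genes, " sites:", x$n_sites,
      " introns/gene:", x$n_introns, "\n")
  cat("  region probs:",
      paste(sprintf("%s=%.2f", names(x$region_probs), x$region_probs),
            collapse = " "), "\n")
  cat("  motif mix:",
      paste(sprintf("%s=%.2f", names(x$motif_mix), x$motif_mix),
            collapse = " "), "\n")
  cat("  expression: beta_sites=", x$beta_sites, " beta_len=", x$beta_len,
      " noise_sd=", x$noise_sd, "\n", sep = "")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
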