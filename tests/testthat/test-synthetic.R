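test_that("transcriptome layout follows the configured segment template", {
  cfg <- areclip_config(
    n_genes = 2, n_sites = 0,
    segment_length_params = list(utr5 = c(mean = 100, cv = 0),
                                 cds = c(mean = 100, cv = 0),
                                 intron = c(mean = 100, cv = 0),
                                 utr3 = c(mean = 100, cv = 0)),
    n_introns = 1, seed = 1
  )
  tx <- generate_transcriptome(cfg, sequences = FALSE)
  seg <- tx$segments

  # 1 intron splits the CDS: utr5, cds, intron, cds, utr3 = 5 segments
  expect_equal(as.vector(table(seg$gene_id)), c(5L, 5L))
  for (g in unique(seg$gene_id)) {
    s <- seg[seg$gene_id == g, ]
    expect_equal(sum(s$length), 500)
    expect_equal(s$type[order(s$tx_order)],
                 c("utr5", "cds", "intron", "cds", "utr3"))
    # contiguous, non-overlapping in genomic order
    s <- s[order(s$start), ]
    expect_equal(s$start[-1], s$end[-nrow(s)])
    expect_true(all(s$end - s$start == s$length))
  }
  expect_setequal(unique(seg$strand), c("+", "-"))
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_config(seed = 42)
  tx1 <- generate_transcriptome(cfg)
  tx2 <- generate_transcriptome(cfg)
  expect_identical(tx1, tx2)
  s1 <- generate_sites(tx1, cfg)
  s2 <- generate_sites(tx2, cfg)
  expect_identical(s1, s2)
  gs <- summarize_genes(s1, tx1)
  e1 <- generate_expression(gs, cfg)
  e2 <- generate_expression(gs, cfg)
  expect_identical(e1, e2)
  expect_identical(generate_affinity_probes(seed = 9),
                   generate_affinity_probes(seed = 9))
})

test_that("segment lengths match the configured distribution", {
  cfg <- areclip_config(n_genes = 500, seed = 11)
  tx <- generate_transcriptome(cfg, sequences = FALSE)
  u3 <- utr3_lengths(tx)
  m <- cfg$segment_length_params$utr3[["mean"]]
  cv <- cfg$segment_length_params$utr3[["cv"]]
  se <- m * cv / sqrt(length(u3))
  expect_lt(abs(mean(u3) - m), 3 * se)
})

test_that("motif planting and region assignment follow configured probabilities", {
  cfg <- small_config(motif_mix = c(UAUU = 1.0), seed = 2)
  tx <- generate_transcriptome(cfg)
  sites <- generate_sites(tx, cfg)
  expect_true(all(grepl("UAUU", sites$sequence, fixed = TRUE)))

  cfg2 <- small_config(region_probs = c(utr3 = 1.0), seed = 2)
  sites2 <- generate_sites(tx, cfg2)
  expect_true(all(sites2$region == "utr3"))

  # planting probability 0.5 at n = 2000: observed fraction in binomial 99% CI
  cfg3 <- areclip_config(n_genes = 300, n_sites = 2000,
                         motif_mix = c(AUUUA = 0.5), seed = 3)
  tx3 <- generate_transcriptome(cfg3, sequences = FALSE)
  # sequence generation for sites is independent of transcriptome sequences
  sites3 <- generate_sites(tx3, cfg3)
  frac <- mean(!is.na(sites3$planted_motif))
  expect_lt(abs(frac - 0.5), qnorm(0.995) * sqrt(0.25 / 2000))

  # read-count invariants
  expect_true(all(sites3$t2c_read_count + sites3$other_conv_read_count <=
                    sites3$read_count))
  expect_true(all(nchar(sites3$sequence) == sites3$end - sites3$start))
})

test_that("sites lie wholly within one segment of their host gene", {
  cfg <- small_config(seed = 5)
  tx <- generate_transcriptome(cfg, sequences = FALSE)
  sites <- generate_sites(tx, cfg)
  seg <- tx$segments
  key <- paste(seg$gene_id, seg$type, seg$piece)
  contained <- vapply(seq_len(nrow(sites)), function(i) {
    rows <- seg[seg$gene_id == sites$gene_id[i] &
                  seg$type == sites$region[i], , drop = FALSE]
    any(rows$start <= sites$start[i] & sites$end[i] <= rows$end)
  }, logical(1))
  expect_true(all(contained))
})

test_that("expression generation is an exact linear model without noise", {
  gs <- data.frame(gene_id = c("g1", "g2", "g3"),
                   n_sites_utr3 = c(4, 0, 2),
                   utr3_length = c(1000, 2000, 500))
  cfg <- small_config(beta_sites = -0.5, beta_len = 0, noise_sd = 0,
                      replicate_sd = 0)
  ex <- generate_expression(gs, cfg)
  expect_equal(ex$table$log2fc, c(-2.0, 0.0, -1.0))

  cfg2 <- small_config(beta_sites = -0.5, beta_len = -0.3, noise_sd = 0)
  ex2 <- generate_expression(gs, cfg2)
  expect_equal(ex2$table$log2fc,
               -0.5 * gs$n_sites_utr3 - 0.3 * gs$utr3_length / 1000)
})

test_that("null expression shows no site-count association", {
  cfg <- areclip_config(n_genes = 400, n_sites = 1000,
                        beta_sites = 0, beta_len = 0, noise_sd = 0.5,
                        seed = 7)
  tx <- generate_transcriptome(cfg, sequences = FALSE)
  gs <- summarize_genes(generate_sites(tx, cfg), tx)
  ex <- generate_expression(gs, cfg)
  obs <- cor(ex$table$log2fc, gs$n_sites_utr3, method = "spearman")
  # permutation null band at 99%
  set.seed(99)
  null <- replicate(1000, cor(sample(ex$table$log2fc), gs$n_sites_utr3,
                              method = "spearman"))
  expect_gt(obs, quantile(null, 0.005))
  expect_lt(obs, quantile(null, 0.995))
})

test_that("configuration validation rejects invalid parameters", {
  expect_error(areclip_config(n_genes = 0), "n_genes")
  expect_error(areclip_config(region_probs = c(utr3 = 0.5, intron = 0.2)),
               "summing to 1")
  expect_error(areclip_config(noise_sd = -1), "noise_sd")
  expect_error(areclip_config(motif_mix = c(UAUT = 0.5)), "RNA alphabet")
  expect_error(areclip_config(motif_mix = c(AUUUA = 0.9, UAUU = 0.9)),
               "sum to <= 1")
  expect_error(
    areclip_config(segment_length_params = list(
      utr5 = c(mean = -5, cv = 0.1), cds = c(mean = 100, cv = 0.1),
      intron = c(mean = 100, cv = 0.1), utr3 = c(mean = 100, cv = 0.1))),
    "positive")
  # motif longer than any achievable site
  cfg <- small_config(site_length_mean = 4,
                      motif_mix = c(UUAUUUAUU = 0.5))
  tx <- generate_transcriptome(small_config(seed = 1), sequences = FALSE)
  expect_error(generate_sites(tx, cfg), "accommodate")
})

test_that("probe tables lie exactly on the power curve when noiseless", {
  p <- generate_affinity_probes(a = 100, b = 0.8, noise_sd_log = 0, n = 20,
                                seed = 4)
  expect_equal(p$Kd, 100 * (1 / p$snr)^0.8, tolerance = 1e-12)
  expect_equal(p$K, 1 / p$Kd)
  # SNR spans at least two decades
  expect_gte(log10(max(p$snr) / min(p$snr)), 2)
  expect_error(generate_affinity_probes(n = 2), "too few")
  expect_error(generate_affinity_probes(a = -1), "positive")
})

test_that("controlled-overlap site sets hit the requested overlap rate", {
  cfg <- areclip_config(n_genes = 400, n_sites = 600,
                        region_probs = c(utr3 = 1.0), seed = 21)
  tx <- generate_transcriptome(cfg, sequences = FALSE)
  anchors <- generate_sites(tx, cfg)
  cfg2 <- areclip_config(n_genes = 400, n_sites = 800,
                         region_probs = c(utr3 = 1.0), seed = 22)
  second <- generate_overlapping_sites(anchors, tx, cfg2, overlap_prob = 0.84)
  frac <- overlap_fraction(second, anchors)
  # anchored sites overlap by construction; unanchored add a little by chance
  expect_gte(frac, 0.84 - qnorm(0.995) * sqrt(0.84 * 0.16 / 800))
  expect_lte(frac, 0.97)
  low <- generate_overlapping_sites(anchors, tx, cfg2, overlap_prob = 0.2)
  expect_lt(overlap_fraction(low, anchors), frac)
})
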