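test_that("site positions project onto segments strand-awarely", {
  tx <- toy_transcriptome()
  sites <- rbind(
    make_site(start = 440, end = 460, gene_id = "geneA", region = "utr3"),
    make_site(start = 599, end = 600, gene_id = "geneA", region = "utr3"),
    make_site(start = 400, end = 401, gene_id = "geneA", region = "utr3"),
    # geneB (-): genomic [1199,1200) is transcript position 0 of its 3' UTR
    make_site(start = 1199, end = 1200, strand = "-", gene_id = "geneB",
              region = "utr3"),
    make_site(start = 1000, end = 1001, strand = "-", gene_id = "geneB",
              region = "utr3")
  )
  pos <- site_positions(sites, tx, "from_3prime_end")
  # geneA utr3 is [400,600): site [440,460) has midpoint index 449 -> pos 49
  expect_equal(pos$pos[1], 49)
  expect_equal(pos$value[1], 200 - 1 - 49)
  # site at the final nucleotide: distance from 3' end is 0
  expect_equal(pos$value[2], 0)
  expect_equal(pos$value[3], 199)
  # minus-strand mirror: genomic first nt of geneB's utr3 is its 3' end
  expect_equal(pos$value[4], 199)
  expect_equal(pos$value[5], 0)

  norm <- site_positions(sites, tx, "normalized")
  expect_equal(norm$value[2], 1)
  expect_equal(norm$value[3], 0)
  # strand symmetry: mirrored constructions give identical positions
  expect_equal(norm$value[4], norm$value[3])
  expect_equal(norm$value[5], norm$value[2])
})

test_that("plus and minus strand genes give mirror-identical positions", {
  cfg <- small_config(region_probs = c(utr3 = 1.0), seed = 37)
  tx <- generate_transcriptome(cfg, sequences = FALSE)
  sites <- generate_sites(tx, cfg)
  pos <- site_positions(sites, tx, "normalized")
  strand <- sites$strand[pos$site]
  # positions on both strands cover the same scale with similar spread
  expect_true(all(pos$value >= 0 & pos$value <= 1))
  expect_lt(abs(mean(pos$value[strand == "+"]) -
                  mean(pos$value[strand == "-"])), 0.06)
})

test_that("density bands are seed-stable, nested and calibrated", {
  cfg <- areclip_config(n_genes = 300, n_sites = 800,
                        region_probs = c(utr3 = 1.0), seed = 43)
  tx <- generate_transcriptome(cfg, sequences = FALSE)
  sites <- generate_sites(tx, cfg)
  pos <- site_positions(sites, tx, "normalized")

  d1 <- density_with_bands(pos, n_perm = 50, seed = 9)
  d2 <- density_with_bands(pos, n_perm = 50, seed = 9)
  expect_identical(d1$bands, d2$bands)

  with(d1$bands, {
    expect_true(all(q10 <= q25 & q25 <= q50 & q50 <= q75 & q75 <= q90))
  })
  # uniform placement: the observed curve sits inside the interdecile band
  # at >= 80% of grid points
  inside <- mean(d1$observed >= d1$bands$q10 & d1$observed <= d1$bands$q90)
  expect_gte(inside, 0.8)

  # all sites stacked at the segment end: observed density exceeds the q90
  # band near 1
  stacked <- pos
  stacked$pos <- stacked$seg_len - 1L
  stacked$value <- 1
  ds <- density_with_bands(stacked, n_perm = 50, seed = 9, mode = "normalized")
  near_end <- ds$grid > 0.95
  expect_true(all(ds$observed[near_end] > ds$bands$q90[near_end]))

  expect_error(density_with_bands(pos[1:5, ], n_perm = 50), ">= 20")
  expect_error(density_with_bands(pos, n_perm = 1), ">= 2")
  expect_warning(density_with_bands(pos, n_perm = 10, seed = 2), "unstable")
})

test_that("terminal enrichment is extreme for planted distal sites", {
  cfg <- areclip_config(n_genes = 200, n_sites = 0,
                        segment_length_params = list(
                          utr5 = c(mean = 100, cv = 0),
                          cds = c(mean = 300, cv = 0),
                          intron = c(mean = 100, cv = 0),
                          utr3 = c(mean = 1000, cv = 0)),
                        seed = 3)
  tx <- generate_transcriptome(cfg, sequences = FALSE)
  u3 <- tx$segments[tx$segments$type == "utr3", ]

  # sites hand-placed in the last 100 nt of every UTR (strand-aware)
  distal <- do.call(rbind, lapply(seq_len(nrow(u3)), function(i) {
    if (u3$strand[i] == "+") {
      st <- u3$end[i] - 40
    } else {
      st <- u3$start[i] + 20
    }
    make_site(start = st, end = st + 20, strand = u3$strand[i],
              gene_id = u3$gene_id[i], region = "utr3")
  }))
  te <- terminal_enrichment(distal, tx, n_perm = 500, seed = 5)
  expect_equal(te$observed, nrow(u3))
  expect_equal(te$p_value, 1 / (1 + 500))
  expect_gt(te$ratio, 5)

  # sites at the 5' end of the UTR: nothing in the window, p ~ 1
  proximal <- distal
  proximal$start <- ifelse(u3$strand == "+", u3$start + 20, u3$end - 40)
  proximal$end <- proximal$start + 20
  tp <- terminal_enrichment(proximal, tx, n_perm = 500, seed = 5)
  expect_equal(tp$observed, 0)
  expect_equal(tp$ratio, 0)
  expect_equal(tp$p_value, 1)

  # all UTRs shorter than the window is degenerate
  cfg_short <- areclip_config(n_genes = 20, n_sites = 50,
                              segment_length_params = list(
                                utr5 = c(mean = 100, cv = 0),
                                cds = c(mean = 300, cv = 0),
                                intron = c(mean = 100, cv = 0),
                                utr3 = c(mean = 60, cv = 0)),
                              region_probs = c(utr3 = 1.0),
                              site_length_mean = 10, seed = 4)
  txs <- generate_transcriptome(cfg_short, sequences = FALSE)
  ss <- generate_sites(txs, cfg_short)
  expect_error(terminal_enrichment(ss, txs, window_nt = 100, n_perm = 50),
               "shorter than the window")
})

test_that("uniform sites are not called terminally enriched", {
  cfg0 <- areclip_config(n_genes = 150, n_sites = 300,
                         region_probs = c(utr3 = 1.0), seed = 0)
  tx <- generate_transcriptome(cfg0, sequences = FALSE)
  ps <- vapply(1:20, function(s) {
    cfg <- areclip_config(n_genes = 150, n_sites = 300,
                          region_probs = c(utr3 = 1.0), seed = 100 + s)
    sites <- generate_sites(tx, cfg)
    terminal_enrichment(sites, tx, n_perm = 199, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(ps >= 0.05), 0.8)
})

test_that("inter-site distances match a brute-force pair enumeration", {
  sites <- rbind(
    make_site(start = 40, end = 60, gene_id = "g1", region = "utr3"),
    make_site(start = 90, end = 110, gene_id = "g1", region = "utr3"),
    make_site(start = 0, end = 20, gene_id = "g2", region = "utr3"),
    make_site(start = 30, end = 50, gene_id = "g2", region = "utr3"),
    make_site(start = 60, end = 80, gene_id = "g2", region = "utr3")
  )
  isd <- intersite_distances(sites, max_gap = 70)
  # midpoints 49 and 99 -> distance 50
  expect_equal(sort(isd$distances$distance[isd$distances$gene_id == "g1"]), 50)
  # three equally spaced sites: one transcript counted once
  expect_equal(isd$n_multi_site, 2L)
  expect_equal(isd$n_within_gap, 2L)

  # random instance vs an independent double loop
  cfg <- small_config(region_probs = c(utr3 = 1.0), seed = 53)
  tx <- generate_transcriptome(cfg, sequences = FALSE)
  rnd <- generate_sites(tx, cfg)
  got <- intersite_distances(rnd, max_gap = 70)
  mids <- (rnd$start + rnd$end - 1) %/% 2
  oracle <- c()
  for (g in unique(rnd$gene_id)) {
    m <- mids[rnd$gene_id == g & rnd$region == "utr3"]
    if (length(m) >= 2) {
      for (i in 1:(length(m) - 1)) for (j in (i + 1):length(m)) {
        oracle <- c(oracle, abs(m[i] - m[j]))
      }
    }
  }
  expect_equal(sort(got$distances$distance), sort(oracle))
})

test_that("clustered sites yield more close pairs than uniform placement", {
  cfg_u <- areclip_config(n_genes = 150, n_sites = 600,
                          region_probs = c(utr3 = 1.0), seed = 57)
  tx <- generate_transcriptome(cfg_u, sequences = FALSE)
  uniform <- generate_sites(tx, cfg_u)
  # clustered: second half of sites duplicated near the first half
  clustered <- uniform
  half <- seq_len(nrow(clustered) / 2)
  clustered[nrow(clustered) / 2 + half, ] <- within(uniform[half, ], {
    start <- start + 30
    end <- end + 30
  })
  n_u <- intersite_distances(uniform, 70)$n_within_gap
  n_c <- intersite_distances(clustered, 70)$n_within_gap
  expect_gt(n_c, n_u)
})

test_that("proximity profiles measure edge-to-edge gaps within shared UTRs", {
  tx <- toy_transcriptome()
  q <- make_site(start = 440, end = 460, gene_id = "geneA", region = "utr3")
  t10 <- make_site(start = 470, end = 490, gene_id = "geneA", region = "utr3")
  pp <- proximity_profile(q, t10, tx, n_perm = 10, seed = 1)
  expect_equal(pp$nearest_distances, 10)
  expect_equal(pp$n_shared_utr3, 1L)

  # identical sets: all distances zero
  cfg <- small_config(region_probs = c(utr3 = 1.0), seed = 59)
  txg <- generate_transcriptome(cfg, sequences = FALSE)
  s <- generate_sites(txg, cfg)
  self <- proximity_profile(s, s, txg, n_perm = 3, seed = 1)
  expect_true(all(self$nearest_distances == 0))

  # planted adjacency beats the permutation background
  targets <- s
  targets$start <- pmin(s$start + 30, s$start + 30)
  targets$end <- targets$start + (s$end - s$start)
  pl <- proximity_profile(s, targets, txg, n_perm = 20, seed = 2)
  expect_lt(median(pl$nearest_distances), median(pl$background_distances))

  # disjoint gene sets produce an empty profile with a report
  other <- s
  other$gene_id <- paste0("x_", other$gene_id)
  expect_warning(pe <- proximity_profile(s, other, txg, n_perm = 2, seed = 1),
                 "no 3' UTRs shared")
  expect_equal(pe$n_in_window, 0L)
})

test_that("overlap fractions equal a brute-force all-pairs oracle", {
  s <- make_site(start = 100, end = 125)
  expect_equal(overlap_fraction(s, s), 1.0)
  expect_equal(overlap_fraction(s, make_site(chrom = "chr2", start = 100,
                                             end = 125)), 0.0)
  expect_equal(overlap_fraction(s, make_site(start = 125, end = 150)), 0.0)
  expect_equal(overlap_fraction(s, make_site(start = 124, end = 150)), 1.0)
  # strand-aware
  expect_equal(overlap_fraction(s, make_site(start = 100, end = 125,
                                             strand = "-")), 0.0)

  set.seed(63)
  q <- do.call(rbind, lapply(1:100, function(i) {
    st <- sample(0:2000, 1)
    make_site(start = st, end = st + sample(10:40, 1),
              strand = sample(c("+", "-"), 1))
  }))
  t <- do.call(rbind, lapply(1:80, function(i) {
    st <- sample(0:2000, 1)
    make_site(start = st, end = st + sample(10:40, 1),
              strand = sample(c("+", "-"), 1))
  }))
  oracle <- mean(vapply(seq_len(nrow(q)), function(i) {
    any(q$strand[i] == t$strand & q$chrom[i] == t$chrom &
          q$start[i] < t$end & t$start < q$end[i])
  }, logical(1)))
  expect_equal(overlap_fraction(q, t), oracle)
})
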