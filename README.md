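# areclip

Downstream analysis of PAR-CLIP binding sites for AU-rich element (ARE)
binding proteins.

RNA-binding proteins of the ZFP36/tristetraprolin family destabilize mRNAs
by binding AU-rich elements in 3′ UTRs, while ELAVL1/HuR binds overlapping
U-rich sequences and stabilizes the same transcripts. PAR-CLIP experiments
resolve their binding sites as PARalyzer clusters — short genomic intervals
supported by T-to-C conversion evidence. `areclip` provides the
computational stages that turn such cluster tables into quantitative
biology, for analysts working with CLIP-style binding-site data:

- **Sites I/O and annotation** — read/write cluster tables (CSV, BED6),
  strand-aware annotation to transcript regions (3′ UTR, 5′ UTR, CDS,
  intron) with majority-overlap and precedence rules, per-cluster
  conversion metrics, gene-level summaries, and depth-matching of
  libraries sequenced at different depths.
- **Motif enrichment** — per-nucleotide signal-to-noise ratios:
  `SNR(m) = (occurrences of m per nt in sites) / (occurrences of m per nt
  in background)`, where the background is the longest annotated 3′ UTR per
  gene; overlapping occurrence counting; classification of sites by the
  canonical ZFP36 recognition elements (nonamer `UUAUUUAUU`, octamer
  `UAUUUAUU`, half-site `UAUU`, pentamer `AUUUA`).
- **Affinity calibration** — least-squares power-law fit
  `Kd = a · (1/SNR)^b` in log10–log10 space linking in-vivo enrichment to
  in-vitro dissociation constants, Kd prediction for arbitrary sequences,
  and an in-silico spacer-disruption scan of `UAUU⟨spacer⟩UAUU` variants.
- **Association statistics** — Spearman partial correlation
  `ρ_{XY·Z}` by three mutually validating routes (regression residuals on
  ranks, the recursive order-reduction formula, and correlation-matrix
  inversion), correlation/partial-correlation networks, 2×2 contingency
  enrichment, stratified empirical CDFs with KS distances, a two-sample
  Hotelling T², and a Welch-t differential-expression stand-in.
- **Spatial patterns** — positional densities along transcript segments
  with within-segment permutation bands, distal-end (last 100 nt)
  enrichment with permutation p-values, intra-UTR inter-site spacing, and
  cross-RBP proximity/overlap statistics.
- **Synthetic data** — a seeded generator for transcriptomes, binding-site
  sets (with planted motifs, read/conversion counts, and controlled
  overlap with a second RBP's sites), probe affinity panels, and expression
  changes following `log2FC = β_sites·n_sites + β_len·len/1000 + ε`, so
  every stage is testable without external downloads.

## Worked example

```r
library(areclip)

cfg   <- areclip_config(n_genes = 500, n_sites = 1200, seed = 42)
tx    <- generate_transcriptome(cfg)
sites <- generate_sites(tx, cfg)
gs    <- summarize_genes(sites, tx)
expr  <- generate_expression(gs, cfg)

# 1. motif enrichment in 3' UTR sites vs the longest-3'UTR background
bg  <- utr3_sequences(tx)
u3  <- sites[sites$region == "utr3", ]
snr <- do.call(rbind, lapply(rre_motifs, function(m)
  compute_snr(u3$sequence, bg, m)))
snr[, c("motif", "site_occurrences", "site_rate", "bg_rate", "snr")]
#>              motif site_occurrences site_rate  bg_rate    snr
#> nonamer  UUAUUUAUU               99   0.00474 2.38e-05 199.08
#> octamer   UAUUUAUU              169   0.00810 7.94e-05 101.96
#> halfsite      UAUU              799   0.03828 7.93e-03   4.83
#> pentamer     AUUUA              502   0.02405 2.34e-03  10.28

# 2. SNR -> Kd calibration and prediction
cal <- fit_power_curve(generate_affinity_probes(a = 100, b = 0.8, seed = 42))
cal
#> <areclip_calibration> Kd = 105.3 * (1/SNR)^0.826  (r_log = 0.989, n = 50)
predict_kd(cal, snr[c("nonamer", "octamer"), "snr"])
#> [1] 1.33 2.31     # a 2x SNR gap compresses to a small Kd difference

# 3. does the site-count effect on expression survive controlling UTR length?
fm <- cbind(n_sites_utr3 = gs$n_sites_utr3, utr3_length = gs$utr3_length,
            log2fc = expr$table$log2fc)
partial_correlation(fm, "n_sites_utr3", "log2fc", "utr3_length")
#> <areclip_pcor> rho(n_sites_utr3, log2fc) = -0.729;  given {utr3_length}: -0.756  [residual, n = 453]
partial_correlation(fm, "utr3_length", "log2fc", "n_sites_utr3")
#> <areclip_pcor> rho(utr3_length, log2fc) = -0.221;  given {n_sites_utr3}: -0.36  [residual, n = 453]

# 4. positional bias: are sites enriched in the last 100 nt of the 3' UTR?
te <- terminal_enrichment(sites, tx, n_perm = 1000, seed = 1)
sprintf("ratio %.2f, permutation p = %.3f", te$ratio, te$p_value)
#> [1] "ratio 0.96, permutation p = 0.730"   # uniform placement: no bias
```

The SNR table says each recognition element occurs tens to hundreds of
times more often per nucleotide inside binding sites than in background
3′ UTR sequence. The calibration maps those enrichments onto predicted
dissociation constants, compressing large SNR differences into small Kd
differences at the high-affinity end. The two partial correlations show
that site count and UTR length each retain an independent negative
association with expression change when the other is controlled. The
terminal-enrichment test, run here on uniformly placed synthetic sites,
correctly reports no distal bias.

## Package layout

- `R/` — implementation (config + generators, sites I/O, annotation,
  motif/SNR, affinity, partial correlation, association stats, spatial
  stats, format writers)
- `tests/testthat/` — unit, property and end-to-end statistical tests
- `vignettes/areclip-methods.Rmd` — models, assumptions, parameter
  choices and limitations
- `scripts/acceptance.R` — full pipeline run with JSON output
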