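---
title: "Methods and models behind areclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind areclip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`areclip` analyzes PAR-CLIP binding-site (PARalyzer cluster) tables for
AU-rich element binding proteins: where the sites fall on transcripts, which
sequence elements they enrich, how enrichment relates to binding affinity,
and how binding relates to expression changes once confounding transcript
features are controlled. This vignette documents the models, the parameter
choices, and what the synthetic data generator does and does not emulate.

## Coordinates, alphabets and containers

All internal coordinates are 0-based half-open. BED input is taken as
already 0-based; CSV cluster tables and GTF use 1-based closed coordinates
and are converted at the boundary. All sequences are handled in the RNA
alphabet (A, C, G, U); DNA input is converted on ingest, because the motif
definitions of this field (pentamer `AUUUA`, nonamer `UUAUUUAUU`) are RNA
strings. Sites and transcript segments live in plain data frames;
GenomicRanges is used internally for all interval-overlap operations,
Biostrings for motif matching and FASTA, rtracklayer for GTF.

## Annotation of sites to genes and regions

A cluster may straddle segment boundaries or overlapping genes. The
assignment rule is: (1) a site goes to the gene with the largest total
same-strand overlap, and an exact tie between genes leaves it unannotated
rather than double-counted; (2) within the winning gene the region label is
the segment type holding the majority of the overlap, with ties broken by
the fixed precedence `utr3 > utr5 > cds > intron`. The precedence order
reflects where ARE-binding-protein function is concentrated and makes the
region labels mutually exclusive, which the gene-category reduction
(`utr3_only` / `intron_only` / `both` / `other`) requires. The annotation
hierarchies used by published CLIP pipelines differ in detail and are often
only cited, not restated; this rule is therefore declared explicitly and
tested for determinism and row-order invariance rather than assumed to
match any particular external pipeline.

Gene summaries use the longest annotated 3′ UTR per gene as the gene's UTR
length (with the generator's single transcript per gene, the only one).

## Conversion metrics

Per cluster: the conversion fraction `t2c / read_count` and the conversion
specificity `log10(t2c / (1 + other))`, where `other` counts reads whose
conversions are not T-to-C. A cluster with no T-to-C reads has undefined
specificity; it is reported as `NA` with a `no_signal` flag, never as
negative infinity, so downstream summaries cannot silently absorb an
infinite value.

## Motif SNR

The enrichment of a motif is its occurrence rate per nucleotide in the site
sequences divided by its rate in a background set:
`SNR = (occ_sites / nt_sites) / (occ_bg / nt_bg)`. The background is the
longest annotated 3′ UTR sequence of every gene in the annotation (not only
expressed or bound genes — a config-level choice surfaced through which
sequences the caller passes). Occurrences are counted at every start
position (overlapping mode) by default: AU-rich elements tile and overlap,
and a per-nucleotide rate implies positional scanning. Counting is
restricted to within-site sequence; flanking context is not scanned. No
pseudocounts are used anywhere: a motif absent from the background yields a
flagged undefined SNR rather than an infinity, and a motif absent from the
sites yields SNR 0, which is likewise excluded from any Kd mapping.

## SNR-to-Kd calibration

In-vitro binding panels report dissociation constants `Kd` (nM) for probe
sequences; the same sequences have measurable SNRs in vivo. The calibration
fits `log10(Kd) = log10(a) + b · log10(1/SNR)` by ordinary least squares,
i.e. a power law `Kd = a · (1/SNR)^b` with multiplicative (log-normal)
error — the standard error model for a quantity spanning decades; the
reported correlation `r_log` is Pearson on the log-transformed pairs.
Probes with nonpositive or undefined SNR or Kd are excluded with a warning.
Duplicated probe rows reweight the regression; this is documented rather
than deduplicated, since replicate measurements are legitimate weights.
With `b > 0` the predicted Kd is strictly decreasing in SNR, so large SNR
differences at the high-enrichment end compress into small Kd differences —
the nonlinearity that motivates mapping to the Kd scale at all.

The spacer scan builds `UAUU⟨spacer⟩UAUU` variants for spacer lengths 0–4
over the alphabets `{U}` and `{V = A, C, G}`. The length-0 variant is the
octamer `UAUUUAUU` itself (the two half-sites abut), which pins the scan to
the calibration's octamer prediction. V-variant Kd is the mean of the three
per-base predictions. Variants never observed in the sites or absent from
the background are flagged undefined instead of extrapolated.

## Spearman partial correlation

The central statistical tool is the partial correlation on ranks,
`ρ_{XY·Z}`: the association between X and Y that remains after the control
set Z is regressed out. Each column is rank-transformed once
(average-rank ties), and then three routes compute the same quantity:

1. **residual** — regress the ranked x and y on the ranked controls (with
   intercept, via QR), then apply the product-moment estimator
   `(NΣr_x r_y − Σr_x Σr_y) / sqrt((NΣr_x² − (Σr_x)²)(NΣr_y² − (Σr_y)²))`
   to the residual vectors; the regression weights and residuals are
   returned as intermediates.
2. **recursive** — reduce the nth-order coefficient to three (n−1)th-order
   ones, `ρ_{XY·Z} = (ρ_{XY·Z\z0} − ρ_{Xz0·Z\z0} ρ_{z0Y·Z\z0}) /
   sqrt((1−ρ²_{Xz0·Z\z0})(1−ρ²_{z0Y·Z\z0}))`, eliminating controls in the
   order given (the result is order-invariant; a test asserts it).
3. **matrix** — invert the Spearman correlation matrix of (x, y, Z) and
   read `−P_xy / sqrt(P_xx P_yy)` off the precision matrix.

The three routes agree to numerical precision on nondegenerate data (the
test suite checks 200 random datasets with n = 20–100 rows and 3–6
variables at 1e-10), which guards each against implementation error in the
others. Rank transformation makes every result invariant under strictly
monotone transforms of any variable — the property that lets site counts,
lengths and fold changes be mixed without distributional assumptions.

Degenerate inputs error loudly: collinear controls (QR rank check, or a
singular correlation matrix), a y identical to a control (zero residual
variance), and fewer than |Z| + 3 rows. Genes with any missing variable are
dropped listwise by `feature_matrix()`, which records how many were
dropped.

The network view computes, for every variable pair, the marginal Spearman
correlation alongside the partial correlation given all remaining listed
variables — the side-by-side layout that separates direct effects from
mediated ones (e.g. a passenger RBP whose sites track a driver RBP's sites
shows a positive marginal and a null partial association with the driver's
expression response; both the tests and the acceptance script construct
exactly this scenario).

## Contingency, CDF, Hotelling and the DE stand-in

The 2×2 enrichment of expression direction versus site presence reports a
Haldane-corrected odds ratio (0.5 added to every cell only when a cell is
zero) with a two-sided Fisher exact p, plus the ratio of downregulated
proportions. Stratified CDFs are empirical distribution tables per group
with tie-safe two-sample KS statistics against a reference group, computed
as the sup-distance on the pooled support (site counts produce heavy ties,
so the continuity-assuming test machinery is avoided). The two-sample
Hotelling T² uses the pooled covariance and the exact transform
`F = (n1+n2−p−1)/(p(n1+n2−2)) · T²` on `(p, n1+n2−p−1)` degrees of freedom,
with a caller-supplied Bonferroni divisor when run across several gene
categories. Differential expression is a deliberately simple per-gene Welch
t-test with Bonferroni correction — a stand-in for array-processing
pipelines that are out of scope — flagging zero-variance genes as undefined
rather than producing spurious zeros.

## Positional statistics and the permutation scheme

A site's position is the midpoint of its interval, measured in transcript
orientation: `(w−1)/2` nucleotides from the site's transcript 5′ end,
identically on both strands. (An earlier genomic-floor convention shifted
minus-strand even-width sites one nucleotide 3′-ward relative to the
permutation background — a strand asymmetry the strand-symmetry tests now
pin down.) `normalized` mode divides by segment length − 1, so 0 is the
segment's 5′ end and 1 its 3′ end; `from_3prime_end` counts nucleotides
back from the segment's 3′ end, so a site at the final nucleotide is at 0.

The permutation background re-places each site — with its own width —
uniformly along its own host segment, preserving segment assignment and
length, and redraws all sites per permutation. Density bands are pointwise
10/25/50/75/90 permutation quantiles of Gaussian kernel densities on a
fixed 512-point grid, reusing the observed curve's Silverman bandwidth so
band and curve are comparable. Distal enrichment counts midpoints within
the last 100 nt of the 3′ UTR and reports
`p = (1 + #{perm ≥ obs}) / (1 + n_perm)` — the add-one estimator, which is
never zero and is super-uniform under the null (the suite verifies ≤5%
rejections at α = 0.05 empirically). Windows: 100 nt for distal enrichment,
70 nt for intra-UTR site pairs, 200 nt for cross-RBP proximity — the scales
at which deadenylation-proximal positioning, ZFP36 multimerization and
ZFP36/ELAVL1 co-occurrence operate.

Cross-RBP proximity uses the edge-to-edge gap (0 for overlapping
intervals) rather than midpoint distance: with overlap fractions above
80%, midpoint distances would report tens of nucleotides of spurious
separation for sites that physically coincide. The choice is declared in
the function documentation.

## The synthetic generator: what it emulates, and what it does not

The generator exists so that every analysis stage has input with known
ground truth. Its defaults are the package's study conditions:

- 2,000 genes, one transcript each, segment lengths log-normal with means
  5′ UTR 200 nt, CDS 1,500 nt, intron 2,000 nt, 3′ UTR 1,000 nt
  (CV 0.5–0.8) — typical mammalian transcript scales with realistic
  right-skew; one intron splitting the CDS.
- 4,000 sites of log-normal length (mean 25 nt, the typical PARalyzer
  cluster length), placed 70% in 3′ UTRs, 26% in introns and the rest in
  CDS/5′ UTR — the regional split characteristic of a ZFP36-class library.
- Motif planting probabilities (nonamer 0.08, octamer 0.10, pentamer 0.30,
  half-site 0.35) chosen so that planted plus chance occurrences in the
  AU-rich site background put the per-element and any-element fractions in
  the ranges reported for ZFP36 libraries; the exact realized fractions are
  whatever the acceptance script computes, not targets.
- Read counts negative binomial (mean 50, size 2) for realistic
  overdispersion; T-to-C conversions binomial thinnings (p = 0.7, other
  conversions 0.05 of the remainder), so count invariants hold by
  construction. All generating parameters are recorded in an attribute so
  tests can be distribution-aware.
- Expression: `log2FC = β_sites·n_sites_utr3 + β_len·(len/1000) + ε` with
  β_sites = −0.5 per site, β_len = −0.3 per kb, ε ~ N(0, 0.5²), plus
  replicate-level noise (SD 0.2, 5 replicates per condition) around a
  gene baseline — the linear confound structure (site count and UTR
  length both negatively associated with fold change, and with each
  other through gene sampling) that the partial-correlation analyses are
  designed to disentangle.
- A second RBP's library is generated by re-placing a configurable
  fraction (default 0.84) of sites to overlap an anchor set, emulating
  two proteins competing for the same element pool.

Sequences are generated per segment and per site (mildly AU-rich in UTRs
and sites, uniform in CDS/introns); site sequences are *not* cut from the
segment sequences, so coordinate-level and sequence-level analyses are
statistically consistent but not base-identical — adequate for motif-rate
statistics, not for variant calling. The generator does not emulate raw
reads, alignment error, cross-link-induced mutation profiles beyond
per-cluster counts, multi-isoform structure, expression-dependent site
discovery, or non-linear regulation. Consequently, passing tests
demonstrate that the *estimators* are correct and calibrated under the
stated generative model; they do not certify performance on real libraries
with annotation errors, isoform ambiguity or coverage-dependent biases.

## Determinism and numerics

Every stochastic function takes or derives a seed; fixed seed means
byte-identical output. The generator's sub-stages offset the configured
seed (+1 sites, +2 expression, +3 overlap placement) so stages draw from
distinct streams while remaining reproducible. Ties are broken
deterministically everywhere (depth matching by read count then
coordinates; annotation by precedence; average ranks in correlations).
Equality tolerances in tests: 1e-10 for the three-route partial-correlation
agreement (QR vs recursion vs inversion accumulate rounding differently),
1e-9 relative for noiseless power-law recovery, exact identity for counting
oracles. Statistical assertions use 99% binomial/permutation bands at the
stated n; Monte-Carlo pass-rate checks over 100 seeds allow the binomial
3σ band around the nominal rate. Problem sizes in the routine suite —
2,000-gene recovery runs over 100 seeds, 200 random datasets for route
agreement, 1,000 permutations for positional tests — were chosen as the
smallest sizes at which the checked effects are unambiguous.

## Known limitations

- The annotation precedence rule is a declared stand-in for pipeline-
  specific hierarchies; real-data region fractions will shift slightly
  under different precedence choices.
- The SNR background (all genes' longest 3′ UTRs) can be made
  expression-restricted only by passing a restricted sequence set.
- The power-law calibration extrapolates outside the probe panel's SNR
  range without warning; predictions far above the largest training SNR
  are pure extrapolation.
- Library-size normalization is implemented as depth-matched subsetting
  (top sites by read count), not rate rescaling; the two disagree when
  read-count distributions differ in shape between libraries.
- `simple_de` ignores probe-level structure and inter-gene variance
  shrinkage; it is a test harness, not a replacement for limma/DESeq2.
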