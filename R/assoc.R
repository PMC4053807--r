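# Stratified and contingency statistics relating binding-site features to
# expression changes, plus a two-sample Hotelling T-squared and a stand-in
# differential-expression test.

#' Contingency enrichment of expression direction vs site presence
#'
#' 2x2 association between having binding sites and the direction of a
#' significant expression change (the mosaic-plot summary). Reports the
#' odds ratio (Haldane-corrected by adding 0.5 to every cell when any cell
#' is zero), a two-sided Fisher exact p value, and the ratio of
#' downregulated proportions between genes with and without sites.
#'
#' @param has_sites logical vector per gene.
#' @param direction factor/character per gene, `"down"` or `"up"`.
#' @return list with `table`, `odds_ratio`, `p_value`,
#'   `prop_down_with_sites`, `prop_down_without_sites`, `prop_ratio`.
#' @export
contingency_enrichment <- function(has_sites, direction) {
  direction <- as.character(direction)
  if (!all(direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'", call. = FALSE)
  }
  tab <- table(factor(has_sites, levels = c(TRUE, FALSE)),
               factor(direction, levels = c("down", "up")),
               dnn = c("has_sites", "direction"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in the 2x2 table", call. = FALSE)
  }
  t2 <- tab
  if (any(t2 == 0)) t2 <- t2 + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  pd_with <- tab[1, 1] / sum(tab[1, ])
  pd_without <- tab[2, 1] / sum(tab[2, ])
  list(table = tab, odds_ratio = unname(or), p_value = p,
       prop_down_with_sites = unname(pd_with),
       prop_down_without_sites = unname(pd_without),
       prop_ratio = unname(pd_with / pd_without))
}

#' Two-sample Hotelling T-squared test
#'
#' Tests equality of two bivariate group means (e.g. the joint response to
#' overexpressing one RBP and knocking down another) using the pooled
#' covariance matrix and the exact F transform
#' `F = (n1 + n2 - p - 1) / (p (n1 + n2 - 2)) * T2` on `(p, n1 + n2 - p - 1)`
#' degrees of freedom.
#'
#' @param group_a,group_b numeric matrices with 2 columns (paired values),
#'   each >= 3 rows.
#' @param n_comparisons Bonferroni divisor applied by the caller when the
#'   test is run across several categories (default 1 = no correction).
#' @return list with `t2`, `f_stat`, `df1`, `df2`, `p_value`,
#'   `p_bonferroni`, `n_a`, `n_b`.
#' @export
hotelling_t2 <- function(group_a, group_b, n_comparisons = 1) {
  a <- as.matrix(group_a)
  b <- as.matrix(group_b)
  p <- ncol(a)
  if (ncol(b) != p || p != 2) {
    stop("both groups must be two-dimensional", call. = FALSE)
  }
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 < 3 || n2 < 3) stop("each group needs >= 3 points", call. = FALSE)
  d <- colMeans(a) - colMeans(b)
  S <- ((n1 - 1) * stats::cov(a) + (n2 - 1) * stats::cov(b)) / (n1 + n2 - 2)
  Sinv <- tryCatch(solve(S), error = function(e) {
    stop("singular pooled covariance matrix", call. = FALSE)
  })
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% Sinv %*% d)
  df1 <- p
  df2 <- n1 + n2 - p - 1
  f_stat <- df2 / (p * (n1 + n2 - 2)) * t2
  pval <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  list(t2 = t2, f_stat = f_stat, df1 = df1, df2 = df2,
       p_value = pval, p_bonferroni = min(1, pval * n_comparisons),
       n_a = n1, n_b = n2)
}

# sup-distance between two empirical CDFs, evaluated on the pooled support
# (tie-safe, unlike the continuity-assuming test machinery)
ks_statistic <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(grid)
  fb <- stats::ecdf(b)(grid)
  max(abs(fa - fb))
}

#' Stratified empirical CDFs with KS distances
#'
#' Empirical cumulative distribution per group (e.g. log2 fold changes
#' stratified by 3' UTR site count) and the two-sample Kolmogorov-Smirnov
#' statistic of every group against the reference group. Empty groups are
#' dropped with a warning.
#'
#' @param values numeric vector.
#' @param groups group labels (same length); the first factor level is the
#'   reference.
#' @param reference reference group label (default: first level).
#' @return list with `cdf` (data.frame: group, value, cdf) and `ks`
#'   (data.frame: group, ks_vs_reference, n).
#' @export
stratified_cdf <- function(values, groups, reference = NULL) {
  if (!is.factor(groups)) groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  sizes <- table(groups)
  if (any(sizes == 0)) {
    warning("dropping empty group(s): ",
            paste(names(sizes)[sizes == 0], collapse = ", "), call. = FALSE)
    groups <- droplevels(groups)
    sizes <- table(groups)
  }
  if (nlevels(groups) < 2) stop("need >= 2 nonempty groups", call. = FALSE)
  if (any(sizes < 5)) {
    warning("group(s) with < 5 values: ",
            paste(names(sizes)[sizes < 5], collapse = ", "), call. = FALSE)
  }
  reference <- reference %||% levels(groups)[1]
  split_vals <- split(values, groups)
  cdf <- do.call(rbind, lapply(names(split_vals), function(g) {
    v <- sort(split_vals[[g]])
    data.frame(group = g, value = v, cdf = seq_along(v) / length(v),
               stringsAsFactors = FALSE)
  }))
  ks <- data.frame(
    group = names(split_vals),
    ks_vs_reference = vapply(names(split_vals), function(g) {
      ks_statistic(split_vals[[g]], split_vals[[reference]])
    }, numeric(1)),
    n = as.integer(sizes[names(split_vals)]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  list(cdf = cdf, ks = ks, reference = reference)
}

#' Per-gene differential expression by Welch t-test
#'
#' A deliberately simple two-group comparison of a (log2-scale) expression
#' matrix: per-gene mean difference, Welch t statistic and Bonferroni
#' corrected p value. Genes with zero variance in both groups have an
#' undefined test and are flagged.
#'
#' @param replicate_matrix genes x samples numeric matrix (log2 scale).
#' @param group_labels character/factor per column with exactly 2 levels;
#'   each group needs >= 2 replicates. log2FC is level2 - level1.
#' @return data.frame with gene_id, log2fc, t_stat, df, p_value,
#'   p_bonferroni, undefined.
#' @export
simple_de <- function(replicate_matrix, group_labels) {
  m <- as.matrix(replicate_matrix)
  g <- factor(group_labels)
  if (nlevels(g) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("need >= 2 replicates per group", call. = FALSE)
  a <- m[, g == levels(g)[1], drop = FALSE]
  b <- m[, g == levels(g)[2], drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  lfc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  undefined <- se2 == 0
  t_stat <- ifelse(undefined, NA_real_, lfc / sqrt(se2))
  df <- ifelse(undefined, NA_real_,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p <- ifelse(undefined, NA_real_, 2 * stats::pt(abs(t_stat), df,
                                                 lower.tail = FALSE))
  data.frame(
    gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    log2fc = lfc, t_stat = t_stat, df = df, p_value = p,
    p_bonferroni = pmin(1, p * nrow(m)),
    undefined = undefined,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
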