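# Positional analysis of binding sites along transcript segments with
# within-segment permutation backgrounds, inter-site spacing, and
# cross-RBP proximity/overlap.

# 0-based index of the midpoint nucleotide of a 0-based half-open interval
midpoint_index <- function(start, end) (start + end - 1L) %/% 2L

# host segment (containing the site midpoint) for annotated sites;
# returns row indices into transcriptome$segments, NA when absent
host_segment <- function(sites, transcriptome) {
  seg <- transcriptome$segments
  mid <- midpoint_index(sites$start, sites$end)
  key <- paste(sites$gene_id, sites$region)
  seg_key <- paste(seg$gene_id, seg$type)
  idx <- rep(NA_integer_, nrow(sites))
  by_key <- split(seq_len(nrow(seg)), seg_key)
  for (k in unique(key[!is.na(sites$gene_id)])) {
    rows <- by_key[[k]]
    if (is.null(rows)) next
    here <- which(key == k)
    for (i in here) {
      j <- rows[seg$start[rows] <= mid[i] & mid[i] < seg$end[rows]]
      if (length(j)) idx[i] <- j[1]
    }
  }
  idx
}

#' Positions of sites along their host transcript segments
#'
#' Projects each annotated site's midpoint onto its host segment, measured
#' in transcript orientation (strand-aware): position 0 is the 5' end of
#' the segment. `normalized` mode scales to \[0,1\] (position divided by
#' segment length - 1); `from_3prime_end` reports nucleotides from the
#' segment's 3' end, so a site at the final nucleotide is at 0. Sites whose
#' midpoint falls outside every segment of their annotated gene/region are
#' skipped with a warning.
#'
#' @param sites annotated site data.frame.
#' @param transcriptome an `areclip_transcriptome`.
#' @param mode `"normalized"` or `"from_3prime_end"`.
#' @return data.frame with columns site (row index into `sites`), gene_id,
#'   region, pos (0-based nt within segment, transcript orientation),
#'   seg_len, value (per `mode`).
#' @export
site_positions <- function(sites, transcriptome,
                           mode = c("normalized", "from_3prime_end")) {
  mode <- match.arg(mode)
  idx <- host_segment(sites, transcriptome)
  skipped <- which(is.na(idx) &
                     !is.na(sites$gene_id) & sites$region != "unannotated")
  if (length(skipped)) {
    warning("skipped ", length(skipped),
            " site(s) not contained in any segment: rows ",
            paste(utils::head(skipped, 10), collapse = ", "), call. = FALSE)
  }
  keep <- which(!is.na(idx))
  seg <- transcriptome$segments
  j <- idx[keep]
  width <- sites$end[keep] - sites$start[keep]
  # midpoint measured in transcript orientation: (w-1)/2 nucleotides from
  # the site's transcript 5' end, identically on both strands
  off5 <- ifelse(seg$strand[j] == "+",
                 sites$start[keep] - seg$start[j],
                 seg$end[j] - sites$end[keep])
  pos <- as.integer(off5 + (width - 1L) %/% 2L)
  seg_len <- seg$length[j]
  value <- position_value(pos, seg_len, mode)
  data.frame(site = keep, gene_id = sites$gene_id[keep],
             region = sites$region[keep],
             pos = pos, seg_len = seg_len, width = width,
             value = value,
             stringsAsFactors = FALSE)
}

# redraw the midpoint of a site of the same width placed uniformly along
# its segment (the permutation scheme: a random site along the segment)
redraw_pos <- function(seg_len, width) {
  w <- pmin(width, seg_len)
  o <- floor(stats::runif(length(seg_len)) * (seg_len - w + 1))
  as.integer(o + (w - 1L) %/% 2L)
}

position_value <- function(pos, seg_len, mode) {
  if (mode == "normalized") {
    ifelse(seg_len > 1, pos / (seg_len - 1), 0.5)
  } else {
    seg_len - 1L - pos
  }
}

#' Positional density with permutation bands
#'
#' Kernel density of observed site positions on a fixed 512-point grid,
#' against pointwise quantile bands (10/25/50/75/90) of `n_perm`
#' permutations in which every site is redrawn uniformly along its own
#' host segment (segment assignment and length preserved). The observed
#' bandwidth (Silverman) is reused for all permutations so band and curve
#' are comparable.
#'
#' @param positions output of [site_positions()] (>= 20 rows).
#' @param n_perm number of permutations (default 100; < 20 warns, < 2
#'   errors).
#' @param seed RNG seed.
#' @param mode axis of `positions` (`"normalized"` or `"from_3prime_end"`);
#'   defaults to normalized when values lie in \[0,1\].
#' @return object of class `areclip_density`: list with `grid`, `observed`,
#'   `bands` (data.frame q10, q25, q50, q75, q90), `n_perm`, `seed`.
#' @export
density_with_bands <- function(positions, n_perm = 100, seed = 1L,
                               mode = NULL) {
  if (nrow(positions) < 20) stop("need >= 20 positions", call. = FALSE)
  if (n_perm < 2) stop("need >= 2 permutations", call. = FALSE)
  if (n_perm < 20) warning("bands are unstable with < 20 permutations",
                           call. = FALSE)
  mode <- mode %||%
    (if (all(positions$value >= 0 & positions$value <= 1)) "normalized"
     else "from_3prime_end")
  from <- 0
  to <- if (mode == "normalized") 1 else max(positions$seg_len) - 1
  obs_d <- stats::density(positions$value, n = 512, from = from, to = to)
  bw <- obs_d$bw
  set.seed(as.integer(seed))
  width <- positions$width %||% rep(1L, nrow(positions))
  perm <- matrix(NA_real_, n_perm, 512)
  for (p in seq_len(n_perm)) {
    pos <- redraw_pos(positions$seg_len, width)
    v <- position_value(pos, positions$seg_len, mode)
    perm[p, ] <- stats::density(v, bw = bw, n = 512, from = from, to = to)$y
  }
  qs <- apply(perm, 2, stats::quantile, probs = c(0.1, 0.25, 0.5, 0.75, 0.9))
  structure(list(
    grid = obs_d$x,
    observed = obs_d$y,
    bands = data.frame(q10 = qs[1, ], q25 = qs[2, ], q50 = qs[3, ],
                       q75 = qs[4, ], q90 = qs[5, ]),
    n_perm = n_perm, seed = seed, mode = mode
  ), class = "areclip_density")
}

#' Enrichment of sites at the distal end of 3' UTRs
#'
#' Counts 3' UTR sites whose midpoint lies within the last `window_nt`
#' nucleotides of their UTR and compares against `n_perm` permutations that
#' redraw each site uniformly along its own UTR. The enrichment ratio is
#' observed / mean permuted count; the permutation p value is
#' `(1 + #permutations >= observed) / (1 + n_perm)`.
#'
#' @param sites annotated site data.frame (3' UTR sites are used).
#' @param transcriptome an `areclip_transcriptome`.
#' @param window_nt distal window size in nucleotides (default 100).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `observed`, `expected`, `ratio`, `p_value`, `n_sites`,
#'   `window_nt`, `n_perm`.
#' @export
terminal_enrichment <- function(sites, transcriptome, window_nt = 100,
                                n_perm = 1000, seed = 1L) {
  pos <- site_positions(sites[sites$region == "utr3", , drop = FALSE],
                        transcriptome, mode = "from_3prime_end")
  if (nrow(pos) == 0) stop("no 3' UTR sites", call. = FALSE)
  if (all(pos$seg_len <= window_nt)) {
    stop("all 3' UTRs are shorter than the window (", window_nt, " nt)",
         call. = FALSE)
  }
  observed <- sum(pos$value < window_nt)
  n <- nrow(pos)
  set.seed(as.integer(seed))
  perm <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    draw <- redraw_pos(pos$seg_len, pos$width)
    perm[p] <- sum((pos$seg_len - 1L - draw) < window_nt)
  }
  expected <- mean(perm)
  list(observed = observed,
       expected = expected,
       ratio = if (expected > 0) observed / expected else NA_real_,
       p_value = (1 + sum(perm >= observed)) / (1 + n_perm),
       n_sites = n, window_nt = window_nt, n_perm = n_perm)
}

#' Inter-site distances within 3' UTRs
#'
#' Midpoint-to-midpoint distances between all pairs of 3' UTR sites of the
#' same gene, and the number of transcripts having at least two sites
#' within `max_gap` nucleotides (each transcript counted once regardless of
#' how many pairs qualify).
#'
#' @param sites annotated site data.frame.
#' @param max_gap proximity threshold in nucleotides (default 70).
#' @return list with `distances` (data.frame gene_id, distance),
#'   `n_multi_site` (genes with >= 2 3' UTR sites), `n_within_gap` (genes
#'   with a pair closer than or equal to `max_gap`), `max_gap`.
#' @export
intersite_distances <- function(sites, max_gap = 70) {
  u <- sites[sites$region == "utr3" & !is.na(sites$gene_id), , drop = FALSE]
  mids <- midpoint_index(u$start, u$end)
  by_gene <- split(mids, u$gene_id)
  by_gene <- by_gene[lengths(by_gene) >= 2]
  dist_list <- lapply(by_gene, function(m) {
    d <- as.vector(stats::dist(m))
    d
  })
  distances <- data.frame(
    gene_id = rep(names(dist_list), lengths(dist_list)),
    distance = unlist(dist_list, use.names = FALSE) %||% numeric(0),
    stringsAsFactors = FALSE
  )
  list(distances = distances,
       n_multi_site = length(by_gene),
       n_within_gap = sum(vapply(dist_list,
                                 function(d) any(d <= max_gap), logical(1))),
       max_gap = max_gap)
}

# edge-to-edge gap between one interval and a set (0 when overlapping)
edge_gaps <- function(qs, qe, ts, te) {
  pmax(0, pmax(ts - qe, qs - te))
}

#' Proximity of one RBP's sites to another's within shared 3' UTRs
#'
#' For every query site in a 3' UTR that also carries target sites, the
#' distance to the nearest target site in the same UTR (edge-to-edge gap;
#' 0 when the intervals overlap), retained when within `window`
#' nucleotides. The background redraws each query site's position uniformly
#' along its own UTR (width preserved) `n_perm` times and pools the
#' resulting nearest distances.
#'
#' @param query_sites,target_sites annotated site data.frames.
#' @param transcriptome an `areclip_transcriptome` (UTR bounds for the
#'   permutations).
#' @param window maximum distance retained, in nucleotides (default 200).
#' @param n_perm background permutations (default 100).
#' @param seed RNG seed.
#' @return object of class `areclip_proximity`: list with
#'   `nearest_distances`, `background_distances`, `n_in_window`,
#'   `n_shared_utr3`, `window`, `n_perm`, `seed`.
#' @export
proximity_profile <- function(query_sites, target_sites, transcriptome,
                              window = 200, n_perm = 100, seed = 1L) {
  q <- query_sites[query_sites$region == "utr3" &
                     !is.na(query_sites$gene_id), , drop = FALSE]
  t <- target_sites[target_sites$region == "utr3" &
                      !is.na(target_sites$gene_id), , drop = FALSE]
  shared <- intersect(unique(q$gene_id), unique(t$gene_id))
  if (length(shared) == 0) {
    warning("no 3' UTRs shared between query and target sets", call. = FALSE)
    return(structure(list(nearest_distances = numeric(0),
                          background_distances = numeric(0),
                          n_in_window = 0L, n_shared_utr3 = 0L,
                          window = window, n_perm = n_perm, seed = seed),
                     class = "areclip_proximity"))
  }
  q <- q[q$gene_id %in% shared, , drop = FALSE]
  t_by_gene <- split(t[, c("start", "end")], t$gene_id)

  nearest <- function(qs, qe, gene) {
    tt <- t_by_gene[[gene]]
    if (is.null(tt)) return(NA_real_)
    min(edge_gaps(qs, qe, tt$start, tt$end))
  }
  obs <- vapply(seq_len(nrow(q)),
                function(i) nearest(q$start[i], q$end[i], q$gene_id[i]),
                numeric(1))

  # permutation background: move each query site uniformly within its UTR
  seg <- transcriptome$segments
  u3 <- seg[seg$type == "utr3", , drop = FALSE]
  m <- match(q$gene_id, u3$gene_id)
  utr_start <- u3$start[m]; utr_end <- u3$end[m]
  width <- q$end - q$start
  max_off <- pmax(0L, (utr_end - utr_start) - width)
  set.seed(as.integer(seed))
  bg <- numeric(0)
  for (p in seq_len(n_perm)) {
    off <- floor(stats::runif(nrow(q)) * (max_off + 1L))
    ns <- utr_start + pmin(off, max_off)
    ne <- ns + width
    d <- vapply(seq_len(nrow(q)),
                function(i) nearest(ns[i], ne[i], q$gene_id[i]),
                numeric(1))
    bg <- c(bg, d[!is.na(d) & d <= window])
  }
  keep <- !is.na(obs) & obs <= window
  structure(list(nearest_distances = obs[keep],
                 background_distances = bg,
                 n_in_window = sum(keep),
                 n_shared_utr3 = length(shared),
                 window = window, n_perm = n_perm, seed = seed),
            class = "areclip_proximity")
}

#' Fraction of query sites overlapping any target site
#'
#' Strand-aware interval overlap (>= 1 shared nucleotide, same chromosome
#' and strand).
#'
#' @param query_sites,target_sites site data.frames (0-based half-open).
#' @return fraction in \[0,1\] of query sites with at least one overlap.
#' @export
overlap_fraction <- function(query_sites, target_sites) {
  if (nrow(query_sites) == 0) return(NA_real_)
  if (nrow(target_sites) == 0) return(0)
  qg <- sites_to_granges(query_sites)
  tg <- sites_to_granges(target_sites)
  # sets on entirely different chromosomes are a legitimate zero-overlap
  # comparison, not a user error
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(qg, tg, minoverlap = 1L,
                                 ignore.strand = FALSE))
  mean(hits > 0)
}
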