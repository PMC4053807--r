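# Power-law calibration between PAR-CLIP SNR and in-vitro dissociation
# constants, Kd prediction, and the in-silico spacer-disruption scan.

#' Fit the SNR-to-Kd power curve
#'
#' Ordinary least squares in log10-log10 space:
#' `log10(Kd) = log10(a) + b * log10(1/SNR)`, i.e. `Kd = a * (1/SNR)^b`.
#' A multiplicative (log-normal) error model is the standard reading of a
#' power-curve fit; the reported correlation `r_log` is the Pearson
#' coefficient between `log10(Kd)` and `log10(1/SNR)`. Probes with
#' nonpositive Kd or SNR (e.g. sequences never observed in the binding
#' sites, whose SNR is undefined) are excluded with a warning.
#'
#' @param probes data.frame with columns `Kd` and `snr` (a `sequence`
#'   column is carried through if present).
#' @return object of class `areclip_calibration`: list with `a`, `b`,
#'   `r_log`, `n_points`, and the fitted probe table.
#' @export
fit_power_curve <- function(probes) {
  if (!all(c("Kd", "snr") %in% names(probes))) {
    stop("`probes` must have columns Kd and snr", call. = FALSE)
  }
  usable <- !is.na(probes$Kd) & !is.na(probes$snr) &
    probes$Kd > 0 & probes$snr > 0
  if (any(!usable)) {
    warning("excluded ", sum(!usable),
            " probe(s) with nonpositive/undefined Kd or SNR: rows ",
            paste(which(!usable), collapse = ", "), call. = FALSE)
  }
  p <- probes[usable, , drop = FALSE]
  if (nrow(p) < 3) {
    stop("insufficient data: need >= 3 usable probes, have ", nrow(p),
         call. = FALSE)
  }
  x <- log10(1 / p$snr)
  y <- log10(p$Kd)
  fit <- stats::lm(y ~ x)
  structure(list(
    a = 10^unname(stats::coef(fit)[1]),
    b = unname(stats::coef(fit)[2]),
    r_log = if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
            else stats::cor(x, y),
    n_points = nrow(p),
    probes = p
  ), class = "areclip_calibration")
}

#' @export
print.areclip_calibration <- function(x, ...) {
  cat("<areclip_calibration> Kd = ", format(x$a, digits = 4),
      " * (1/SNR)^", format(x$b, digits = 4),
      "  (r_log = ", format(x$r_log, digits = 3),
      ", n = ", x$n_points, ")\n", sep = "")
  invisible(x)
}

#' Predict Kd from SNR
#'
#' `Kd = a * (1/snr)^b`; strictly decreasing in SNR whenever `b > 0`,
#' so stronger in-vivo enrichment maps to tighter predicted binding.
#'
#' @param calibration an `areclip_calibration`.
#' @param snr positive SNR value(s).
#' @return predicted Kd (same units as the training Kd, typically nM).
#' @export
predict_kd <- function(calibration, snr) {
  if (any(is.na(snr)) || any(snr <= 0)) {
    stop("snr must be positive to predict Kd", call. = FALSE)
  }
  calibration$a * (1 / snr)^calibration$b
}

#' In-silico spacer-disruption scan
#'
#' Builds the half-site variants `UAUU<spacer>UAUU` for spacer lengths 0-4
#' with spacers of uridylates (`U...U`) or non-uridylates (`V = A/C/G`,
#' averaged over the three bases), measures each variant's SNR in the given
#' site/background sequence sets, and maps it to a predicted Kd through the
#' calibration. The length-0 row is the octamer UAUUUAUU itself. Variants
#' absent from the background have undefined SNR and are flagged.
#'
#' @param calibration an `areclip_calibration`.
#' @param site_seqs binding-site sequences (RNA alphabet).
#' @param background_seqs background sequences.
#' @param max_spacer maximum spacer length (default 4).
#' @return data.frame with columns spacer_len, spacer_kind ("U" or "V"),
#'   variants, snr (V rows: mean over A/C/G), kd_pred, undefined.
#' @export
spacer_scan <- function(calibration, site_seqs, background_seqs,
                        max_spacer = 4) {
  half <- "UAUU"
  one <- function(variant) {
    r <- compute_snr(site_seqs, background_seqs, variant)
    # Kd is undefined both when the background lacks the variant (SNR
    # undefined) and when the sites lack it (SNR = 0, outside the power law)
    list(snr = r$snr, undefined = r$undefined || r$site_occurrences == 0)
  }
  rows <- list()
  for (len in 0:max_spacer) {
    if (len == 0) {
      v <- paste0(half, half)
      r <- one(v)
      rows[[length(rows) + 1]] <- data.frame(
        spacer_len = 0L, spacer_kind = "none", variants = v,
        snr = r$snr,
        kd_pred = if (r$undefined) NA_real_ else predict_kd(calibration, r$snr),
        undefined = r$undefined, stringsAsFactors = FALSE
      )
      next
    }
    # uridylate spacer
    vU <- paste0(half, strrep("U", len), half)
    rU <- one(vU)
    rows[[length(rows) + 1]] <- data.frame(
      spacer_len = len, spacer_kind = "U", variants = vU,
      snr = rU$snr,
      kd_pred = if (rU$undefined) NA_real_ else predict_kd(calibration, rU$snr),
      undefined = rU$undefined, stringsAsFactors = FALSE
    )
    # non-uridylate spacer, averaged over homopolymer A/C/G spacers
    vV <- paste0(half, strrep(c("A", "C", "G"), len), half)
    rV <- lapply(vV, one)
    snrs <- vapply(rV, function(r) r$snr, numeric(1))
    undef <- vapply(rV, function(r) r$undefined, logical(1))
    kd <- rep(NA_real_, length(vV))
    kd[!undef] <- predict_kd(calibration, snrs[!undef])
    rows[[length(rows) + 1]] <- data.frame(
      spacer_len = len, spacer_kind = "V",
      variants = paste(vV, collapse = ","),
      snr = if (all(undef)) NA_real_ else mean(snrs[!undef]),
      kd_pred = if (all(undef)) NA_real_ else mean(kd[!undef]),
      undefined = all(undef), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
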