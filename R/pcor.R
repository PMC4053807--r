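# Spearman partial correlation: residual, recursive and matrix-inversion
# routes. All three operate on the same rank transform (average ties) so
# they estimate the same quantity and agree to numerical precision on
# nondegenerate data.

#' Assemble a feature matrix
#'
#' Numeric per-gene variables (site counts, 3' UTR length, log2 fold
#' change, ...) as one matrix-backed object; genes with any missing value
#' are dropped listwise and the number dropped is recorded.
#'
#' @param df data.frame with a `gene_id` column (or rownames) and numeric
#'   variable columns.
#' @param variables which columns to keep (default: all numeric columns).
#' @return object of class `areclip_features`: numeric matrix with gene
#'   rownames and an `n_dropped` attribute.
#' @export
feature_matrix <- function(df, variables = NULL) {
  ids <- if ("gene_id" %in% names(df)) df$gene_id else rownames(df)
  num <- df[, setdiff(names(df), "gene_id"), drop = FALSE]
  num <- num[, vapply(num, is.numeric, logical(1)), drop = FALSE]
  if (!is.null(variables)) num <- num[, variables, drop = FALSE]
  m <- as.matrix(num)
  rownames(m) <- ids
  keep <- stats::complete.cases(m)
  out <- m[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("areclip_features", class(out))
  out
}

#' Spearman correlation matrix
#'
#' Average-rank transform per column followed by Pearson correlation:
#' symmetric with unit diagonal. Constant columns have undefined
#' correlations (`NA`, with a warning).
#'
#' @param fm numeric matrix / `areclip_features` with >= 3 rows.
#' @return correlation matrix.
#' @export
spearman_matrix <- function(fm) {
  m <- unclass(fm)
  if (nrow(m) < 3) stop("need >= 3 rows for correlation", call. = FALSE)
  const <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("constant column(s) have undefined correlations: ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
  }
  suppressWarnings(stats::cor(m, method = "spearman"))
}

# The product-moment estimator applied to residual vectors; written in the
# N*sum(xy) - sum(x)*sum(y) form so the residual route matches the printed
# estimator rather than delegating to cor().
pearson_sums <- function(rx, ry) {
  n <- length(rx)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}

# Recursive reduction: rho_{XY.Z} from the three (|Z|-1)-order partial
# correlations, eliminating controls in the order given.
pcor_recursive <- function(R, x, y, controls) {
  if (length(controls) == 0) return(R[x, y])
  z0 <- controls[1]
  rest <- controls[-1]
  rxy <- pcor_recursive(R, x, y, rest)
  rxz <- pcor_recursive(R, x, z0, rest)
  rzy <- pcor_recursive(R, z0, y, rest)
  (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
}

#' Spearman partial correlation
#'
#' The correlation between X and Y after removing the contribution of the
#' control set Z, on ranks. Three routes are provided and agree to
#' numerical precision:
#' \describe{
#'   \item{residual}{regress the rank-transformed x and y on the
#'     rank-transformed controls (with intercept) and apply the
#'     product-moment estimator to the residual vectors;}
#'   \item{recursive}{reduce the nth-order coefficient to three
#'     (n-1)th-order ones via
#'     `(r_xy.rest - r_xz0.rest * r_z0y.rest) / sqrt((1-r_xz0.rest^2)(1-r_z0y.rest^2))`;}
#'   \item{matrix}{invert the Spearman correlation matrix of
#'     (x, y, controls) and read the coefficient off the precision matrix.}
#' }
#'
#' @param fm numeric matrix / `areclip_features`.
#' @param x,y variable names; must not be controls.
#' @param controls character vector of control variable names (may be
#'   empty, in which case the plain Spearman correlation is returned).
#' @param method `"residual"`, `"recursive"` or `"matrix"`.
#' @return object of class `areclip_pcor`: list with `x`, `y`, `controls`,
#'   `rho_xy` (marginal Spearman), `rho_xy_given_z`, `method`, `n`, and for
#'   the residual route `intermediates` (regression weights and residual
#'   vectors).
#' @export
partial_correlation <- function(fm, x, y, controls = character(0),
                                method = c("residual", "recursive", "matrix")) {
  method <- match.arg(method)
  m <- unclass(fm)
  vars <- c(x, y, controls)
  if (!all(vars %in% colnames(m))) {
    stop("unknown variable(s): ",
         paste(setdiff(vars, colnames(m)), collapse = ", "), call. = FALSE)
  }
  if (x %in% controls || y %in% controls) {
    stop("x and y must not be members of the control set", call. = FALSE)
  }
  n <- nrow(m)
  if (n <= length(controls) + 2) {
    stop("need n > |controls| + 2 rows (have ", n, ")", call. = FALSE)
  }
  rk <- rank_columns(m[, vars, drop = FALSE])
  R <- suppressWarnings(stats::cor(rk))  # Pearson on ranks == Spearman
  rho_xy <- R[x, y]
  intermediates <- NULL

  if (method == "residual") {
    if (length(controls)) {
      Z <- cbind(`(intercept)` = 1, rk[, controls, drop = FALSE])
      qr_z <- qr(Z)
      if (qr_z$rank < ncol(Z)) {
        stop("collinear control set: ", paste(controls, collapse = ", "),
             call. = FALSE)
      }
      wx <- qr.coef(qr_z, rk[, x])
      wy <- qr.coef(qr_z, rk[, y])
      rx <- rk[, x] - drop(Z %*% wx)
      ry <- rk[, y] - drop(Z %*% wy)
    } else {
      wx <- wy <- NULL
      rx <- rk[, x]
      ry <- rk[, y]
    }
    if (sum(rx^2) < 1e-20 || sum(ry^2) < 1e-20) {
      stop("degenerate control set: a variable is fully determined by ",
           "the controls", call. = FALSE)
    }
    rho <- pearson_sums(rx, ry)
    intermediates <- list(w_x = wx, w_y = wy, r_x = rx, r_y = ry)
  } else if (method == "recursive") {
    rho <- pcor_recursive(R, x, y, controls)
  } else {
    sub <- R[vars, vars]
    P <- tryCatch(solve(sub), error = function(e) {
      stop("singular correlation matrix (collinear variables among ",
           paste(vars, collapse = ", "), ")", call. = FALSE)
    })
    rho <- -P[x, y] / sqrt(P[x, x] * P[y, y])
  }

  structure(list(x = x, y = y, controls = controls,
                 rho_xy = rho_xy, rho_xy_given_z = rho,
                 method = method, n = n,
                 intermediates = intermediates),
            class = "areclip_pcor")
}

#' @export
print.areclip_pcor <- function(x, ...) {
  ctrl <- if (length(x$controls)) paste(x$controls, collapse = ", ") else "-"
  cat("<areclip_pcor> rho(", x$x, ", ", x$y, ") = ",
      format(x$rho_xy, digits = 3),
      ";  given {", ctrl, "}: ", format(x$rho_xy_given_z, digits = 3),
      "  [", x$method, ", n = ", x$n, "]\n", sep = "")
  invisible(x)
}

#' Correlation / partial-correlation network
#'
#' For every variable pair: the pairwise Spearman correlation and the
#' partial correlation controlling for all remaining listed variables —
#' the side-by-side layout used to separate direct from mediated
#' associations among site counts, transcript features and expression
#' changes.
#'
#' @param fm numeric matrix / `areclip_features`.
#' @param variables >= 3 variable names (default: all columns).
#' @param method partial-correlation route (default `"matrix"`).
#' @return object of class `areclip_network`: data.frame of edges with
#'   columns x, y, rho, pcor, sign.
#' @export
pcor_network <- function(fm, variables = NULL, method = "matrix") {
  m <- unclass(fm)
  variables <- variables %||% colnames(m)
  if (length(variables) < 3) stop("need >= 3 variables", call. = FALSE)
  edges <- utils::combn(variables, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(edges)), function(i) {
    x <- edges[1, i]; y <- edges[2, i]
    pc <- partial_correlation(fm, x, y,
                              controls = setdiff(variables, c(x, y)),
                              method = method)
    data.frame(x = x, y = y, rho = pc$rho_xy, pcor = pc$rho_xy_given_z,
               sign = sign(pc$rho_xy_given_z), stringsAsFactors = FALSE)
  }))
  class(out) <- c("areclip_network", class(out))
  out
}
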