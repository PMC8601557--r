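# Covariate-adjusted partial Spearman correlations and the feature x
# clinical-parameter screen.

#' @include utils.R
NULL

# Expand a covariate data frame: categorical columns become one-hot dummies
# (first level dropped); numeric columns pass through. Returns a numeric
# matrix (possibly 0 columns).
expandCovariates <- function(Z) {
  if (is.null(Z) || (is.data.frame(Z) && ncol(Z) == 0L))
    return(matrix(numeric(0), nrow = if (is.null(Z)) 0 else nrow(Z), ncol = 0))
  if (!is.data.frame(Z)) Z <- as.data.frame(Z)
  cols <- list()
  for (nm in names(Z)) {
    v <- Z[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- v
    } else {
      f <- factor(v)
      for (lev in levels(f)[-1])
        cols[[paste(nm, lev, sep = ".")]] <- as.numeric(f == lev)
    }
  }
  do.call(cbind, cols)
}

# Rank-transform a numeric matrix column-wise with average ranks for ties;
# binary (0/1 or two-valued dummy) columns pass through unchanged.
rankColumns <- function(M) {
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (length(unique(v)) > 2L) M[, j] <- rank(v)
  }
  M
}

#' Partial Spearman correlation via the precision matrix
#'
#' `x`, `y` and each non-binary covariate column are rank-transformed
#' (average ranks for ties; binary and one-hot columns pass through); the
#' partial correlation of the ranks given the covariates is read off the
#' inverse of their correlation matrix,
#' `rho_xy.Z = -P_xy / sqrt(P_xx P_yy)`; the two-sided p-value comes from
#' `t = rho sqrt((n - 2 - q) / (1 - rho^2))` with `n - 2 - q` degrees of
#' freedom, `q` the number of (expanded) covariate columns. With no
#' covariates this reduces to ordinary Spearman correlation.
#'
#' Incomplete cases are dropped; at least `q + 3` complete cases are
#' required. Zero variance in `x` or `y` after ranking gives an `NA`
#' estimate flagged by `undefined = TRUE`; a singular rank-correlation
#' matrix raises an error naming the collinear columns.
#'
#' @param x,y numeric vectors.
#' @param Z optional covariate data.frame/matrix (categorical columns are
#'   one-hot encoded, first level dropped).
#' @return list with `rho`, `p_value`, `n_used`, `q`, `covariates`,
#'   `undefined`.
#' @export
partialSpearman <- function(x, y, Z = NULL) {
  n0 <- length(x)
  if (length(y) != n0) stop("x and y length mismatch")
  Zm <- expandCovariates(if (is.null(Z)) NULL else Z)
  if (is.null(Z)) Zm <- matrix(numeric(0), n0, 0)
  if (nrow(Zm) && nrow(Zm) != n0) stop("covariate rows mismatch")
  cc <- stats::complete.cases(x, y, if (ncol(Zm)) Zm else NULL)
  x <- x[cc]; y <- y[cc]
  Zm <- Zm[cc, , drop = FALSE]
  q <- ncol(Zm)
  n <- length(x)
  if (n < q + 3)
    stop("need at least q + 3 = ", q + 3, " complete cases, got ", n)
  covnames <- colnames(Zm)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n_used = n, q = q,
                covariates = covnames, undefined = TRUE))
  M <- rankColumns(cbind(x = x, y = y, Zm))
  keep <- apply(M, 2, stats::sd) > 0
  if (!keep[1] || !keep[2])
    return(list(rho = NA_real_, p_value = NA_real_, n_used = n, q = q,
                covariates = covnames, undefined = TRUE))
  M <- M[, keep, drop = FALSE]
  q <- ncol(M) - 2L
  R <- stats::cor(M)
  df <- n - 2 - q
  if (abs(R["x", "y"]) >= 1 - 1e-12) {
    # perfectly rank-correlated pair: residuals coincide given any Z
    rho <- sign(R["x", "y"])
    return(list(rho = rho, p_value = 0, n_used = n, q = q,
                covariates = covnames, undefined = FALSE))
  }
  P <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(P)) {
    qr_ <- qr(R)
    bad <- if (qr_$rank < ncol(R))
      colnames(R)[qr_$pivot[seq(qr_$rank + 1L, ncol(R))]] else colnames(R)
    stop("singular rank-correlation matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  rho <- -P["x", "y"] / sqrt(P["x", "x"] * P["y", "y"])
  rho <- max(-1, min(1, rho))
  df <- n - 2 - q
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(rho = rho, p_value = p, n_used = n, q = q,
       covariates = covnames, undefined = FALSE)
}

#' Screen features against clinical parameters
#'
#' Computes covariate-adjusted partial Spearman correlations between every
#' feature (column of `features`) and every named clinical parameter, on
#' pairwise-complete cases per (feature, parameter) cell, and reports the
#' rows passing the significance and magnitude filters. No multiple-testing
#' correction is applied in this screen (raw `p < p_max`), unlike the
#' differential-abundance module; the fungal-profile convention adds
#' `min_abs_rho = 0.65`.
#'
#' Feature-matrix rows are matched to clinical rows by `sample_id`, or by
#' `patient_id` (post-surgery row) for per-patient change tables.
#'
#' @param features an [AbundanceTable] or plain matrix (e.g. from
#'   [changeTable()]), rows samples or patients.
#' @param clinical a [ClinicalTable].
#' @param parameters clinical parameter (column) names to test.
#' @param covariates clinical covariate names to adjust for (default COPD
#'   and cancer type).
#' @param p_max report rows with `p_value < p_max` (default 0.05).
#' @param min_abs_rho report rows with `|rho| > min_abs_rho` (default 0;
#'   0.65 for the fungal convention).
#' @return data.frame with columns `feature_id`, `parameter`, `rho`,
#'   `p_value`, `n_used`, `covariates`.
#' @export
correlationScreen <- function(features, clinical, parameters,
                              covariates = c("COPD", "cancer_type"),
                              p_max = 0.05, min_abs_rho = 0) {
  m <- if (is(features, "AbundanceTable")) abundances(features) else
    as.matrix(features)
  cd <- clinicalData(clinical)
  unknown <- setdiff(c(parameters, covariates), names(cd))
  if (length(unknown))
    stop("unknown clinical column(s): ", paste(unknown, collapse = ", "))
  rows <- match(rownames(m), cd$sample_id)
  if (anyNA(rows)) {
    byPatient <- match(rownames(m),
                       cd$patient_id[cd$timepoint == "post"])
    rows2 <- which(cd$timepoint == "post")[byPatient]
    if (anyNA(rows2))
      stop("feature rows do not match clinical sample or patient ids")
    rows <- rows2
  }
  cd <- cd[rows, , drop = FALSE]
  for (p in parameters)
    if (all(is.na(cd[[p]]))) stop("parameter '", p, "' entirely missing")
  Z <- if (length(covariates)) cd[, covariates, drop = FALSE] else NULL
  out <- list()
  for (p in parameters) {
    yv <- cd[[p]]
    for (j in seq_len(ncol(m))) {
      res <- tryCatch(partialSpearman(m[, j], yv, Z),
                      error = function(e) NULL)
      if (is.null(res) || res$undefined || is.na(res$p_value)) next
      if (res$p_value < p_max && abs(res$rho) > min_abs_rho)
        out[[length(out) + 1L]] <- data.frame(
          feature_id = colnames(m)[j], parameter = p,
          rho = res$rho, p_value = res$p_value, n_used = res$n_used,
          covariates = paste(res$covariates, collapse = ";"),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(feature_id = character(), parameter = character(),
                      rho = numeric(), p_value = numeric(),
                      n_used = integer(), covariates = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-patient post/pre log2 change matrix
#'
#' `log2((post + eps) / (pre + eps))` per feature, with the shared
#' pseudo-fraction `eps` of the table, so zeros stay finite.
#'
#' @param table an [AbundanceTable].
#' @param pairs a [PairedDesign].
#' @return matrix patients x features of log2 fold-changes.
#' @export
changeTable <- function(table, pairs) {
  m <- abundances(table)
  pr <- designPairs(pairs)
  eps <- pseudoFraction(table)
  ch <- log2((m[pr$post, , drop = FALSE] + eps) /
               (m[pr$pre, , drop = FALSE] + eps))
  rownames(ch) <- pr$patient_id
  ch
}
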