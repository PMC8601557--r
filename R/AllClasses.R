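# Core S4 containers. All abundance matrices are stored samples x features,
# closed to sum 1 per sample (fractions); closure happens in the constructor.

#' AbundanceTable: closed compositional samples x features matrix
#'
#' Holds a relative-abundance matrix with unique sample (row) and feature
#' (column) identifiers. Rows are always stored as fractions summing to 1;
#' percent input is rescaled at construction. Feature identifiers may be
#' full pipe-separated lineage strings (MetaPhlAn style) or bare names.
#'
#' @slot abund numeric matrix, samples x features, non-negative, each row
#'   summing to 1 within `1e-6`.
#' @export
setClass("AbundanceTable", representation(abund = "matrix"))

setValidity("AbundanceTable", function(object) {
  m <- object@abund
  if (!is.numeric(m)) return("abundance matrix must be numeric")
  if (nrow(m) == 0L || ncol(m) == 0L) return("abundance matrix is empty")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("sample and feature identifiers are required")
  if (anyDuplicated(rownames(m))) return("duplicate sample identifiers")
  if (anyDuplicated(colnames(m))) return("duplicate feature identifiers")
  if (anyNA(m)) return("abundances must not contain NA")
  if (any(m < 0)) return("abundances must be non-negative")
  if (any(abs(rowSums(m) - 1) > 1e-6))
    return("rows must be closed compositions (sum 1 within 1e-6)")
  TRUE
})

#' ClinicalTable: per-patient, per-timepoint covariates and outcomes
#'
#' Wraps a data frame with one row per (patient, timepoint). Required
#' columns are `patient_id` and `timepoint` (`"pre"`/`"post"`); a
#' `sample_id` column links rows to abundance-table samples (defaulting to
#' `<patient_id>_<timepoint>`). Binary covariates/outcomes (`COPD`,
#' `recurrence`) must be coded 0/1; missing numeric entries stay `NA` and
#' are handled pairwise-complete downstream, never imputed.
#'
#' @slot data data.frame of clinical records.
#' @export
setClass("ClinicalTable", representation(data = "data.frame"))

setValidity("ClinicalTable", function(object) {
  d <- object@data
  req <- c("patient_id", "timepoint", "sample_id")
  miss <- setdiff(req, names(d))
  if (length(miss))
    return(paste("missing required columns:", paste(miss, collapse = ", ")))
  if (!all(d$timepoint %in% c("pre", "post")))
    return("timepoint values must be 'pre' or 'post'")
  if (anyDuplicated(d[, c("patient_id", "timepoint")]))
    return("at most one row per patient and timepoint")
  if (anyDuplicated(d$sample_id)) return("duplicate sample_id")
  for (bc in intersect(c("COPD", "recurrence"), names(d))) {
    v <- d[[bc]]
    if (!is.numeric(v) || !all(v %in% c(0, 1) | is.na(v)))
      return(sprintf("binary column '%s' must be coded 0/1", bc))
  }
  TRUE
})

#' PairedDesign: patient to (pre-sample, post-sample) mapping
#'
#' @slot pairs data.frame with columns `patient_id`, `pre`, `post`; each
#'   sample id appears in exactly one pair and pre != post.
#' @export
setClass("PairedDesign", representation(pairs = "data.frame"))

setValidity("PairedDesign", function(object) {
  p <- object@pairs
  if (!all(c("patient_id", "pre", "post") %in% names(p)))
    return("pairs need columns patient_id, pre, post")
  if (nrow(p) == 0L) return("no complete pairs")
  if (anyDuplicated(p$patient_id)) return("duplicate patient in pairs")
  ids <- c(p$pre, p$post)
  if (anyDuplicated(ids)) return("a sample id appears in more than one pair")
  if (any(p$pre == p$post)) return("pre and post sample must differ")
  TRUE
})

#' CorrelationNetwork: SparCC basis correlations with permutation pseudo-p
#'
#' @slot featureIds character vector of features.
#' @slot rho symmetric correlation matrix in \[-1, 1\], unit diagonal.
#' @slot pseudoP symmetric matrix of permutation pseudo p-values (empty
#'   until [sparccPseudoP()] has been run); diagonal `NA`.
#' @slot nIterations number of SparCC inference iterations averaged.
#' @slot nPermutations permutations used for pseudo p-values (0 if none).
#' @export
setClass("CorrelationNetwork",
  representation(featureIds = "character", rho = "matrix",
                 pseudoP = "matrix", nIterations = "integer",
                 nPermutations = "integer"))

setValidity("CorrelationNetwork", function(object) {
  D <- length(object@featureIds)
  r <- object@rho
  if (!all(dim(r) == D)) return("rho dimension mismatch")
  if (any(abs(r) > 1 + 1e-8)) return("|rho| must be <= 1")
  if (max(abs(r - t(r))) > 1e-8) return("rho must be symmetric")
  if (any(abs(diag(r) - 1) > 1e-8)) return("rho diagonal must be 1")
  if (length(object@pseudoP) && !all(dim(object@pseudoP) == D))
    return("pseudoP dimension mismatch")
  TRUE
})

#' PermanovaResult: one-factor distance-based pseudo-F test
#'
#' @slot pseudoF observed pseudo-F statistic.
#' @slot R2 between-group fraction of the total sum of squares.
#' @slot pValue permutation p-value, `(1 + exceedances) / (1 + permutations)`.
#' @slot nPermutations number of label permutations drawn.
#' @export
setClass("PermanovaResult",
  representation(pseudoF = "numeric", R2 = "numeric", pValue = "numeric",
                 nPermutations = "integer"))

setValidity("PermanovaResult", function(object) {
  # semi-metric distances (e.g. Bray-Curtis) can push the between-group
  # share of the SS partition marginally below zero, as in adonis
  if (object@R2 < -0.25 || object@R2 > 1)
    return("R2 must be a proportion of the total sum of squares")
  if (object@pValue <= 0 || object@pValue > 1) return("p must be in (0, 1]")
  if (object@pValue < 1 / (object@nPermutations + 1) - 1e-12)
    return("p cannot be below 1/(permutations + 1)")
  TRUE
})

#' Balance: a log-contrast between two disjoint feature sets
#'
#' B = (1/k+) sum(log X_i, i in plus) - (1/k-) sum(log X_j, j in minus),
#' optionally scaled by sqrt(k+ k- / (k+ + k-)) (`"normalized"`, the
#' isometric log-ratio convention). Zeros are replaced by a pseudo-fraction
#' before taking logs.
#'
#' @slot plus,minus character vectors of feature ids (disjoint, non-empty).
#' @slot normalization `"proportional"` or `"normalized"`.
#' @slot values named numeric per-sample balance values.
#' @export
setClass("Balance",
  representation(plus = "character", minus = "character",
                 normalization = "character", values = "numeric"))

setValidity("Balance", function(object) {
  if (length(object@plus) < 1L || length(object@minus) < 1L)
    return("both feature sets must be non-empty")
  if (length(intersect(object@plus, object@minus)))
    return("plus and minus sets must be disjoint")
  if (!object@normalization %in% c("proportional", "normalized"))
    return("normalization must be 'proportional' or 'normalized'")
  if (any(!is.finite(object@values))) return("balance values must be finite")
  TRUE
})

#' BalanceSelectionResult: cross-validated forward balance selection
#'
#' @slot COpt selected number of components (1-SE rule).
#' @slot globalBalance [Balance] refit on all samples with COpt components.
#' @slot cvScores data.frame with columns `C`, `mean`, `se` of held-out fit.
#' @slot componentFrequency named numeric, proportion of CV balances (at
#'   COpt) containing each feature.
#' @slot balanceFrequency data.frame of distinct CV balances and their
#'   relative frequencies.
#' @slot fit list with the association of the global balance with the
#'   response (in-sample) and the cross-validated fit at COpt.
#' @export
setClass("BalanceSelectionResult",
  representation(COpt = "integer", globalBalance = "Balance",
                 cvScores = "data.frame", componentFrequency = "numeric",
                 balanceFrequency = "data.frame", fit = "list"))

#' SyntheticSpec: ground-truth description of a simulated paired cohort
#'
#' Defines the log-normal basis model from which paired compositions are
#' drawn: per-feature log means/sds, per-timepoint basis correlation
#' matrices, planted post-surgery log2 effects, a planted balance driving
#' the outcomes, and the covariate model. The `seed` makes generation fully
#' reproducible.
#'
#' @slot nPatients number of patients (each contributes a pre and post sample).
#' @slot features feature identifiers.
#' @slot logBasisMean,logSd per-feature log-basis mean and sd.
#' @slot corPre,corPost basis correlation matrices (PSD, unit diagonal).
#' @slot differential data.frame `feature`, `delta` (log2 shift at post).
#' @slot balanceTruth list(plus, minus, beta, sigma) or empty list for a
#'   null outcome model.
#' @slot covariateModel list(copd_prev, cancer_probs, gamma_copd,
#'   gamma_cancer).
#' @slot seed integer seed.
#' @export
setClass("SyntheticSpec",
  representation(nPatients = "integer", features = "character",
                 logBasisMean = "numeric", logSd = "numeric",
                 corPre = "matrix", corPost = "matrix",
                 differential = "data.frame", balanceTruth = "list",
                 covariateModel = "list", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  D <- length(object@features)
  if (object@nPatients < 2L) return("need at least 2 patients")
  if (length(object@logBasisMean) != D || length(object@logSd) != D)
    return("logBasisMean/logSd length must match features")
  if (any(object@logSd <= 0)) return("logSd must be positive")
  for (nm in c("corPre", "corPost")) {
    R <- slot(object, nm)
    if (!all(dim(R) == D)) return(sprintf("%s dimension mismatch", nm))
    if (max(abs(R - t(R))) > 1e-8) return(sprintf("%s must be symmetric", nm))
    if (any(abs(diag(R) - 1) > 1e-8))
      return(sprintf("%s must have unit diagonal", nm))
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      return(sprintf("%s is not positive semi-definite", nm))
  }
  if (nrow(object@differential)) {
    if (!all(object@differential$feature %in% object@features))
      return("differential features must be in the feature set")
    if (any(!is.finite(object@differential$delta)))
      return("differential effects must be finite")
  }
  bt <- object@balanceTruth
  if (length(bt)) {
    if (length(intersect(bt$plus, bt$minus)))
      return("balance truth sets must be disjoint")
    if (!all(c(bt$plus, bt$minus) %in% object@features))
      return("balance truth features must be in the feature set")
  }
  TRUE
})

#' SyntheticDataset: generated data plus the truth that produced it
#'
#' @slot abundance [AbundanceTable] of all pre and post samples.
#' @slot clinical [ClinicalTable] with covariates, outcomes and CPET values.
#' @slot pairs [PairedDesign].
#' @slot truth the [SyntheticSpec] used, retained for scoring recovery.
#' @export
setClass("SyntheticDataset",
  representation(abundance = "AbundanceTable", clinical = "ClinicalTable",
                 pairs = "PairedDesign", truth = "SyntheticSpec"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d samples x %d features (fractions)\n",
              nrow(object@abund), ncol(object@abund)))
})

setMethod("show", "ClinicalTable", function(object) {
  d <- object@data
  cat(sprintf("ClinicalTable: %d rows, %d patients, columns: %s\n",
              nrow(d), length(unique(d$patient_id)),
              paste(names(d), collapse = ", ")))
})

setMethod("show", "PairedDesign", function(object) {
  cat(sprintf("PairedDesign: %d complete pre/post pairs\n",
              nrow(object@pairs)))
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat(sprintf("CorrelationNetwork: %d features, %d iterations",
              length(object@featureIds), object@nIterations))
  if (object@nPermutations > 0L)
    cat(sprintf(", pseudo-p from %d permutations", object@nPermutations))
  cat("\n")
})

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.3f, p = %.4g (%d permutations)\n",
              object@pseudoF, object@R2, object@pValue, object@nPermutations))
})

setMethod("show", "Balance", function(object) {
  cat(sprintf("Balance (%s): %d plus vs %d minus features\n",
              object@normalization, length(object@plus), length(object@minus)))
  cat("  plus: ", paste(object@plus, collapse = ", "), "\n", sep = "")
  cat("  minus:", paste(object@minus, collapse = ", "), "\n")
})

setMethod("show", "BalanceSelectionResult", function(object) {
  cat(sprintf("BalanceSelectionResult: C_opt = %d\n", object@COpt))
  show(object@globalBalance)
  f <- object@fit
  if (identical(f$kind, "continuous"))
    cat(sprintf("  in-sample Pearson r = %.3f, CV fit (r^2) = %.3f\n",
                f$estimate, f$cv_estimate))
  else
    cat(sprintf("  in-sample AUC = %.3f, CV-AUC = %.3f\n",
                f$estimate, f$cv_estimate))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d patients, %d features, %d planted effects, seed %d\n",
    object@nPatients, length(object@features), nrow(object@differential),
    object@seed))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset\n")
  show(object@abundance)
  show(object@pairs)
})
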