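# Prevalence filtering, paired Wilcoxon differential abundance with BH-FDR,
# fold-change ranking, and aggregate oxygen-class comparisons.

#' @include utils.R
NULL

#' Prevalence filter
#'
#' Retains features with non-zero abundance in at least `min_prevalence` of
#' all samples (pre and post pooled). The boundary is inclusive: a feature
#' present in exactly 10% of samples survives a 0.10 threshold.
#'
#' @param table an [AbundanceTable].
#' @param min_prevalence fraction in (0, 1].
#' @return the filtered [AbundanceTable].
#' @export
prevalenceFilter <- function(table, min_prevalence = 0.10) {
  if (min_prevalence <= 0 || min_prevalence > 1)
    stop("min_prevalence must be in (0, 1]")
  m <- abundances(table)
  prev <- colMeans(m > 0)
  keep <- prev >= min_prevalence - 1e-12
  if (!any(keep)) stop("no feature passes the prevalence filter")
  table[, keep]
}

#' Paired Wilcoxon signed-rank differential abundance
#'
#' One two-sided signed-rank test per feature on the per-patient post - pre
#' differences: the exact distribution for up to 25 non-zero differences
#' without ties, otherwise the normal approximation with continuity and tie
#' correction. Benjamini-Hochberg q-values are computed across all testable
#' features of the table. A feature whose differences are all zero is
#' flagged untestable with p = 1.
#'
#' @param table an [AbundanceTable].
#' @param pairs a [PairedDesign].
#' @param min_pairs minimum non-zero pairs required for a feature to be
#'   testable (default 5).
#' @return data.frame with columns `feature_id`, `W`, `p_value`, `q_value`,
#'   `direction` (`up_post`/`down_post`), `log2_fold_change`, `prevalence`,
#'   `untestable`.
#' @export
pairedWilcoxon <- function(table, pairs, min_pairs = 5) {
  m <- abundances(table)
  pr <- designPairs(pairs)
  missing <- setdiff(c(pr$pre, pr$post), rownames(m))
  if (length(missing))
    stop("samples missing from table: ", paste(missing, collapse = ", "))
  pre <- m[pr$pre, , drop = FALSE]
  post <- m[pr$post, , drop = FALSE]
  eps <- pseudoFraction(table)
  feats <- colnames(m)

  one <- function(j) {
    d <- post[, j] - pre[, j]
    d[abs(d) < 1e-12] <- 0  # closure round-off is not a real change
    nz <- sum(d != 0)
    if (nz == 0L)
      return(data.frame(W = NA_real_, p_value = 1, untestable = TRUE))
    if (nz < min_pairs)
      return(data.frame(W = NA_real_, p_value = 1, untestable = TRUE))
    ties <- anyDuplicated(abs(d[d != 0])) > 0L
    exact <- nz <= 25 && !ties
    ht <- suppressWarnings(
      stats::wilcox.test(post[, j], pre[, j], paired = TRUE,
                         exact = exact, correct = TRUE))
    data.frame(W = unname(ht$statistic), p_value = ht$p.value,
               untestable = FALSE)
  }
  res <- do.call(rbind, lapply(seq_along(feats), one))
  res$feature_id <- feats
  res$direction <- ifelse(
    apply(post - pre, 2, stats::median) >= 0, "up_post", "down_post")
  res$log2_fold_change <-
    log2((colMeans(post) + eps) / (colMeans(pre) + eps))
  res$prevalence <- colMeans(m > 0)
  res$q_value <- NA_real_
  testable <- !res$untestable
  res$q_value[testable] <- stats::p.adjust(res$p_value[testable],
                                           method = "BH")
  res[, c("feature_id", "W", "p_value", "q_value", "direction",
          "log2_fold_change", "prevalence", "untestable")]
}

#' Significant features of a differential result
#'
#' With `use_fdr = TRUE` (default) significance means `q < alpha`; setting
#' `use_fdr = FALSE` reproduces the raw `P < alpha` reading.
#'
#' @param results data.frame from [pairedWilcoxon()].
#' @param alpha significance level.
#' @param use_fdr use BH q-values (default) or raw p-values.
#' @return character vector of significant feature ids.
#' @export
significantFeatures <- function(results, alpha = 0.05, use_fdr = TRUE) {
  p <- if (use_fdr) results$q_value else results$p_value
  results$feature_id[!results$untestable & !is.na(p) & p < alpha]
}

#' Rank significant features by log2 fold-change
#'
#' @param results data.frame from [pairedWilcoxon()].
#' @param alpha,use_fdr significance rule, see [significantFeatures()].
#' @return the significant rows ordered by `log2_fold_change`, descending.
#' @export
foldChangeRank <- function(results, alpha = 0.05, use_fdr = TRUE) {
  if (nrow(results) == 0L) stop("empty differential result")
  sig <- results[results$feature_id %in%
                   significantFeatures(results, alpha, use_fdr), ,
                 drop = FALSE]
  sig[order(-sig$log2_fold_change, sig$feature_id), , drop = FALSE]
}

#' Aggregate oxygen-class comparison with matched-pairs effect size
#'
#' Sums the relative abundance of all features of class `cls` per sample,
#' runs a paired signed-rank test on the per-patient sums, and reports the
#' matched-pairs effect size `r = |Z| / sqrt(n_pairs)` from the
#' tie-corrected normal-approximation Z. Subgroup variants (e.g. recurrent
#' patients only) are obtained by filtering `pairs` first.
#'
#' @param table an [AbundanceTable].
#' @param pairs a [PairedDesign] (>= 5 pairs).
#' @param annotation named character vector feature -> class; matched onto
#'   the table features via [matchAnnotation()].
#' @param cls class to aggregate (`"anaerobe"` or `"aerobe"`).
#' @return list with `r`, `Z`, `p_value`, `n_pairs`, `direction`, and the
#'   per-sample aggregate abundances.
#' @export
aggregateClassTest <- function(table, pairs, annotation, cls = "anaerobe") {
  pr <- designPairs(pairs)
  if (nrow(pr) < 5L) stop("need at least 5 pairs")
  ann <- matchAnnotation(annotation, table)
  sel <- names(ann)[ann == cls]
  if (!length(sel)) stop("class '", cls, "' absent from annotation")
  m <- abundances(table)
  agg <- rowSums(m[, sel, drop = FALSE])
  d <- agg[pr$post] - agg[pr$pre]
  d[abs(d) < 1e-12] <- 0  # closure round-off is not a real change
  sr <- signedRankZ(d)
  if (sr$n == 0L) {
    p <- 1
  } else {
    ties <- anyDuplicated(abs(d[d != 0])) > 0L
    exact <- sr$n <= 25 && !ties
    p <- suppressWarnings(
      stats::wilcox.test(d[d != 0], exact = exact, correct = TRUE)$p.value)
  }
  list(r = abs(sr$Z) / sqrt(nrow(pr)), Z = sr$Z, p_value = p,
       n_pairs = nrow(pr),
       direction = if (stats::median(d) >= 0) "up_post" else "down_post",
       aggregate = agg)
}

#' Restrict a paired design to a subset of patients
#'
#' @param pairs a [PairedDesign].
#' @param patient_ids patients to keep.
#' @return a [PairedDesign].
#' @export
filterPairs <- function(pairs, patient_ids) {
  pr <- designPairs(pairs)
  keep <- pr[pr$patient_id %in% patient_ids, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no pairs left after filtering")
  new("PairedDesign", pairs = keep)
}
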