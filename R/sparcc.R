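# SparCC basis-correlation inference from compositions, permutation pseudo
# p-values, and differential co-abundance (sign-flip) edge extraction.
#
# SparCC estimates correlations of the unobserved absolute ("basis")
# abundances from the variation matrix t_ij = Var(log(x_i / x_j)) under a
# sparsity assumption: basis variances omega_i^2 solve the linear system
# obtained by setting the summed covariance terms to zero, and
# rho_ij = (omega_i^2 + omega_j^2 - t_ij) / (2 omega_i omega_j). Strongly
# correlated pairs violate the sparsity assumption and are excluded from
# the system iteratively.

#' @include utils.R
NULL

# Basis-variance solve with iterative pair exclusion, for one variation
# matrix. Returns the clipped correlation matrix plus clipping flags.
basisCorrelation <- function(Tmat, exclusion_threshold, exclusion_rounds) {
  D <- nrow(Tmat)
  active <- matrix(TRUE, D, D)
  diag(active) <- FALSE
  negVar <- FALSE
  excluded <- 0L
  repeat {
    A <- matrix(0, D, D)
    A[active] <- 1
    diag(A) <- rowSums(active)
    ti <- rowSums(Tmat * active)
    w <- solve(A, ti)
    if (any(w <= 0)) {
      negVar <- TRUE
      w[w <= 0] <- 1e-6
    }
    rho <- (outer(w, w, "+") - Tmat) / (2 * sqrt(outer(w, w)))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    if (excluded >= exclusion_rounds) break
    cand <- abs(rho)
    cand[!active] <- 0
    diag(cand) <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    idx <- which(cand == mx, arr.ind = TRUE)[1, ]
    active[idx[1], idx[2]] <- active[idx[2], idx[1]] <- FALSE
    excluded <- excluded + 1L
  }
  list(rho = rho, negVar = negVar)
}

# One full SparCC estimate on a fraction matrix (samples x features):
# average over n_iterations Dirichlet-posterior resamples. The inner loop
# is compiled (src/sparcc.cpp); basisCorrelation() above is the reference
# implementation it is tested against.
sparccRho <- function(frac, n_iterations, exclusion_threshold,
                      exclusion_rounds, depth) {
  counts <- frac * depth + 1  # pseudo-counts with +1 prior
  res <- .sparccRhoCpp(counts, as.integer(n_iterations),
                       exclusion_threshold, as.integer(exclusion_rounds))
  rho <- res$rho
  attr(rho, "negVar") <- isTRUE(res$negvar)
  rho
}

#' SparCC basis correlations
#'
#' Per inference iteration, compositions are resampled by a
#' Dirichlet-posterior draw from pseudo-counts (relative abundance x
#' `depth`, +1 prior) — the zero-replacement scheme that makes averaging
#' over iterations meaningful — the variation matrix is formed, the
#' basis-variance linear system is solved, and up to `exclusion_rounds`
#' strongly correlated pairs (|rho| above `exclusion_threshold`) are
#' excluded from the system one at a time. The reported correlation matrix
#' is the element-wise mean over `n_iterations` iterations, clipped to
#' \[-1, 1\].
#'
#' @param table an [AbundanceTable] with at least 4 features (the
#'   basis-variance system is degenerate below that).
#' @param n_iterations inference iterations to average (default 20).
#' @param exclusion_threshold correlation magnitude above which a pair is
#'   excluded from the basis-variance system (default 0.1).
#' @param exclusion_rounds maximum number of excluded pairs (default 10).
#' @param depth pseudo-count depth for the Dirichlet resampling.
#' @param seed optional integer seed.
#' @return a [CorrelationNetwork] (rho only; see [sparccPseudoP()]).
#' @export
sparcc <- function(table, n_iterations = 20, exclusion_threshold = 0.1,
                   exclusion_rounds = 10, depth = 10000, seed = NULL) {
  m <- abundances(table)
  if (ncol(m) < 4L) stop("SparCC needs at least 4 features")
  if (!is.null(seed)) set.seed(seed)
  rho <- sparccRho(m, n_iterations, exclusion_threshold, exclusion_rounds,
                   depth)
  if (isTRUE(attr(rho, "negVar")))
    warning("negative solved basis variance clipped to a small positive value")
  if (max(abs(rho[upper.tri(rho)])) > 0.999)
    warning("near-perfect dependence between features detected")
  attr(rho, "negVar") <- NULL
  dimnames(rho) <- list(colnames(m), colnames(m))
  new("CorrelationNetwork", featureIds = colnames(m), rho = rho,
      pseudoP = matrix(numeric(0), 0, 0),
      nIterations = as.integer(n_iterations), nPermutations = 0L)
}

#' Permutation pseudo p-values for a SparCC network
#'
#' Each permutation shuffles every feature's values across samples
#' independently (destroying all dependence while keeping marginals),
#' recomputes the SparCC correlation matrix with the same number of
#' iterations, and counts exceedances:
#' `pseudo_p = (1 + #(|rho_perm| >= |rho_obs|)) / (1 + n_permutations)`,
#' two-sided. The add-one rule means a pseudo p-value is never 0.
#'
#' @param table the [AbundanceTable] the network was computed from.
#' @param network a [CorrelationNetwork] from [sparcc()].
#' @param n_permutations number of permutations (>= 19, so that 0.05 is
#'   attainable; default 100).
#' @param seed optional integer seed.
#' @inheritParams sparcc
#' @return the network with the `pseudoP` matrix filled in.
#' @export
sparccPseudoP <- function(table, network, n_permutations = 100,
                          exclusion_threshold = 0.1, exclusion_rounds = 10,
                          depth = 10000, seed = NULL) {
  m <- abundances(table)
  if (!identical(colnames(m), featureIds(network)))
    stop("network features do not match the table")
  if (n_permutations < 19) stop("need at least 19 permutations to reach 0.05")
  if (!is.null(seed)) set.seed(seed)
  obs <- abs(networkRho(network))
  n <- nrow(m)
  exceed <- matrix(0L, ncol(m), ncol(m))
  for (b in seq_len(n_permutations)) {
    perm <- apply(m, 2, function(col) col[sample.int(n)])
    rho <- sparccRho(perm, network@nIterations, exclusion_threshold,
                     exclusion_rounds, depth)
    exceed <- exceed + (abs(rho) >= obs)
  }
  p <- (1 + exceed) / (1 + n_permutations)
  p <- (p + t(p)) / 2
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(obs)
  network@pseudoP <- p
  network@nPermutations <- as.integer(n_permutations)
  validObject(network)
  network
}

#' Edges whose significant correlation flips sign between conditions
#'
#' Returns feature pairs that are significant (pseudo-p below `alpha`) in
#' both networks with opposite correlation signs, restricted to pairs whose
#' endpoints are both in `restrict_to` (typically the differentially
#' abundant features).
#'
#' @param net_pre,net_post [CorrelationNetwork]s over the identical feature
#'   universe, both with pseudo p-values.
#' @param restrict_to feature ids edges must connect (default: all).
#' @param alpha pseudo-p significance level (default 0.05).
#' @return data.frame with columns `feature_a`, `feature_b`, `rho_pre`,
#'   `rho_post`, `flip` (`pos_to_neg`/`neg_to_pos`); the flip counts are in
#'   attribute `"counts"`.
#' @export
signFlipEdges <- function(net_pre, net_post, restrict_to = NULL,
                          alpha = 0.05) {
  feats <- featureIds(net_pre)
  if (!identical(feats, featureIds(net_post)))
    stop("networks must share an identical feature universe")
  restrict_to <- restrict_to %||% feats
  rpre <- networkRho(net_pre)
  rpost <- networkRho(net_post)
  mask <- significantEdges(net_pre, alpha) &
    significantEdges(net_post, alpha) &
    (sign(rpre) * sign(rpost) < 0) &
    outer(feats %in% restrict_to, feats %in% restrict_to, "&")
  mask[lower.tri(mask, diag = TRUE)] <- FALSE
  idx <- which(mask, arr.ind = TRUE)
  edges <- data.frame(
    feature_a = feats[idx[, 1]], feature_b = feats[idx[, 2]],
    rho_pre = rpre[idx], rho_post = rpost[idx],
    stringsAsFactors = FALSE)
  edges$flip <- ifelse(edges$rho_pre > 0, "pos_to_neg", "neg_to_pos")
  edges <- edges[order(edges$feature_a, edges$feature_b), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "counts") <- c(
    pos_to_neg = sum(edges$flip == "pos_to_neg"),
    neg_to_pos = sum(edges$flip == "neg_to_pos"))
  edges
}

#' Rank features by incident sign-flip edges
#'
#' @param edges data.frame from [signFlipEdges()].
#' @return named integer vector of flip-edge counts, descending, ties
#'   broken lexicographically by feature id.
#' @export
degreeRanking <- function(edges) {
  if (nrow(edges) == 0L) return(stats::setNames(integer(0), character(0)))
  counts <- table(c(edges$feature_a, edges$feature_b))
  counts <- counts[order(-counts, names(counts))]
  stats::setNames(as.integer(counts), names(counts))
}
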