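# Alpha diversity, Bray-Curtis beta diversity, PCoA and PERMANOVA.

#' @include utils.R
NULL

#' Per-sample alpha diversity
#'
#' Shannon (`-sum p log p`, natural log) and Simpson (Gini-Simpson form,
#' `1 - sum p^2`) are computed on the stored fractions via
#' [vegan::diversity()]. Chao1 needs counts: relative abundances are
#' multiplied by `depth` and rounded to pseudo-counts first (richness from
#' relative data is inherently approximate; a caveat message is emitted
#' once per call). The classic estimator is used:
#' `S_obs + F1^2 / (2 F2)` when `F2 > 0`, else `S_obs + F1 (F1 - 1) / 2`.
#'
#' @param table an [AbundanceTable].
#' @param index `"shannon"`, `"simpson"` or `"chao1"`.
#' @param depth library-size constant used to form pseudo-counts for chao1.
#' @return named numeric vector, one value per sample.
#' @export
alphaDiversity <- function(table, index = c("shannon", "simpson", "chao1"),
                           depth = 10000) {
  index <- match.arg(index)
  m <- abundances(table)
  if (index == "shannon") return(vegan::diversity(m, index = "shannon"))
  if (index == "simpson") return(vegan::diversity(m, index = "simpson"))
  message("chao1 from relative abundances: using pseudo-counts at depth ",
          depth, "; richness estimates are approximate")
  counts <- round(m * depth)
  apply(counts, 1, chao1)
}

#' Classic Chao1 richness estimator on a count vector
#'
#' @param counts non-negative integer counts for one sample.
#' @return Chao1 estimate.
#' @export
chao1 <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all-zero sample")
  S <- length(counts)
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / 2
}

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = 1 - 2 sum min(x_i, y_i) / sum (x_i + y_i)` on the closed
#' fractions, via [vegan::vegdist()].
#'
#' @param table an [AbundanceTable].
#' @return a `dist` object with sample labels.
#' @export
brayCurtis <- function(table) {
  vegan::vegdist(abundances(table), method = "bray")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the double-centred squared distance matrix.
#' Coordinates are ordered by descending eigenvalue; negative eigenvalues
#' (non-Euclidean distances) are reported, not silently dropped. If `k`
#' exceeds the number of axes with positive eigenvalue, the returned axes
#' are truncated with a warning.
#'
#' @param dm a `dist` object or symmetric distance matrix.
#' @param k number of requested axes (>= 1).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   descending) and `explained` (proportion of positive eigenvalue sum).
#' @export
pcoa <- function(dm, k = 2) {
  if (k < 1) stop("k must be >= 1")
  d <- as.matrix(dm)
  n <- nrow(d)
  res <- stats::cmdscale(d, k = min(k, n - 1), eig = TRUE)
  eig <- res$eig
  npos <- sum(eig > max(eig) * 1e-8)
  if (k > npos) {
    warning("only ", npos, " axes with positive eigenvalue; truncating")
    k <- npos
  }
  coords <- res$points[, seq_len(min(k, ncol(res$points))), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       explained = pmax(eig, 0) / sum(pmax(eig, 0)))
}

#' One-factor PERMANOVA
#'
#' Distance-based partition of the total sum of squares
#' (`SS_total = sum(d_ij^2) / n`, within-group SS summed per group) into
#' between and within components; pseudo-F with `a - 1` and `n - a` degrees
#' of freedom; the p-value is `(1 + #(F_perm >= F_obs)) / (1 + n_permutations)`
#' over seeded label permutations. With `strata`, permutations are
#' restricted to swaps within each stratum (e.g. within patient for a
#' paired pre/post design).
#'
#' @param dm a `dist` object or symmetric distance matrix.
#' @param grouping factor-like group labels, one per sample.
#' @param n_permutations number of label permutations (>= 99).
#' @param seed optional integer seed for the permutation stream.
#' @param strata optional blocking factor restricting permutations.
#' @return a [PermanovaResult].
#' @export
permanova <- function(dm, grouping, n_permutations = 999, seed = NULL,
                      strata = NULL) {
  D2 <- as.matrix(dm)^2
  n <- nrow(D2)
  grouping <- droplevels(as.factor(grouping))
  if (length(grouping) != n) stop("grouping length must match samples")
  if (nlevels(grouping) < 2L)
    stop("PERMANOVA needs at least 2 groups")
  if (n_permutations < 99) stop("need at least 99 permutations")
  a <- nlevels(grouping)

  ssWithin <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1L)
        s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  SSt <- sum(D2) / (2 * n)
  SSw <- ssWithin(grouping)
  SSb <- SSt - SSw
  Fobs <- (SSb / (a - 1)) / (SSw / (n - a))

  if (!is.null(seed)) set.seed(seed)
  permIdx <- function() {
    if (is.null(strata)) return(sample.int(n))
    idx <- seq_len(n)
    for (s in unique(strata)) {
      block <- which(strata == s)
      idx[block] <- block[sample.int(length(block))]
    }
    idx
  }
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    g <- grouping[permIdx()]
    SSwp <- ssWithin(g)
    Fp <- ((SSt - SSwp) / (a - 1)) / (SSwp / (n - a))
    if (Fp >= Fobs - 1e-12) exceed <- exceed + 1L
  }
  new("PermanovaResult",
      pseudoF = Fobs, R2 = SSb / SSt,
      pValue = (1 + exceed) / (1 + n_permutations),
      nPermutations = as.integer(n_permutations))
}
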