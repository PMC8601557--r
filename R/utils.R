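# Internal helpers shared across modules.

#' @include AllGenerics.R
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pseudo-fraction used for zero replacement
#'
#' Half the smallest non-zero value of the table: one shared constant per
#' table so fold-changes and balances are comparable across operations.
#'
#' @param table an [AbundanceTable] (or plain non-negative matrix).
#' @return a single positive number.
#' @export
pseudoFraction <- function(table) {
  m <- if (is(table, "AbundanceTable")) abundances(table) else table
  pos <- m[m > 0]
  if (!length(pos)) stop("table has no positive values")
  min(pos) / 2
}

# Terminal species token of a lineage id: last pipe-separated segment with
# any single-letter rank prefix ("s__", "g__", ...) stripped.
speciesToken <- function(ids) {
  last <- vapply(strsplit(ids, "|", fixed = TRUE),
                 function(x) x[[length(x)]], character(1))
  sub("^[A-Za-z]__", "", last)
}

# Rank token (e.g. "p" for phylum) from a pipe-separated lineage; NA when
# the rank is absent.
lineageRank <- function(ids, rank = "p") {
  pat <- paste0("^", rank, "__")
  vapply(strsplit(ids, "|", fixed = TRUE), function(parts) {
    hit <- grep(pat, parts, value = TRUE)
    if (length(hit)) sub(pat, "", hit[[1]]) else NA_character_
  }, character(1))
}

# TRUE for species-level lineage rows (species rank present, no strain rank).
isSpeciesRow <- function(ids) {
  grepl("(^|\\|)s__", ids) & !grepl("(^|\\|)t__", ids)
}

# Signed-rank statistic with normal approximation: drops zero differences,
# average ranks for ties, tie-corrected variance, continuity correction.
# Used for the matched-pairs effect size r = |Z| / sqrt(n).
signedRankZ <- function(d) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(W = NA_real_, Z = 0, n = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  dev <- W - mu
  cc <- sign(dev) * 0.5
  Z <- if (sigma2 > 0) (dev - cc) / sqrt(sigma2) else 0
  list(W = W, Z = Z, n = n)
}

# Mann-Whitney AUC of `score` for predicting label == 1 (exact rank form,
# ties handled by average ranks). Returns NA if a class is absent.
rankAUC <- function(score, label) {
  pos <- label == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  (sum(rank(score)[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Accuracy at the Youden-optimal threshold of `score` for label == 1.
youdenAccuracy <- function(score, label) {
  cand <- sort(unique(score))
  thr <- c(-Inf, (cand[-1] + cand[-length(cand)]) / 2, Inf)
  best <- -Inf; bestAcc <- NA_real_; bestThr <- NA_real_
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  for (t in thr) {
    pred <- as.integer(score > t)
    sens <- sum(pred == 1 & label == 1) / n1
    spec <- sum(pred == 0 & label == 0) / n0
    j <- sens + spec - 1
    if (j > best + 1e-12) {
      best <- j
      bestAcc <- mean(pred == label)
      bestThr <- t
    }
  }
  list(threshold = bestThr, accuracy = bestAcc, youden = best)
}

# Deterministic sub-seed for a pipeline stage, derived from the run seed and
# the stage name, kept inside the 32-bit integer range.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Project a symmetric matrix to the nearest correlation-like PSD matrix:
# eigenvalue clipping at `eps`, then rescaling to unit diagonal.
psdProject <- function(R, eps = 1e-8) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, eps)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / outer(d, d)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  dimnames(M) <- dimnames(R)
  M
}

# Write a data frame as TSV with full numeric precision (round-trippable).
writeTsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) formatC(x, digits = 17, format = "g"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
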