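# Log-contrast microbial balances and selbal-style cross-validated forward
# selection.
#
# A balance over disjoint feature sets I+ (k+ parts) and I- (k- parts) is
#   B = (1/k+) sum_{i in I+} log X_i - (1/k-) sum_{j in I-} log X_j,
# the difference of log geometric means; it is invariant to the closure
# constant. Forward selection starts from the best single pair and greedily
# adds the feature (to either side) that most improves the association with
# the response; cross-validation over the resulting sequence of balances
# picks the number of components.

#' @include utils.R
NULL

replaceZeros <- function(m, eps) {
  m[m == 0] <- eps
  m
}

#' Compute a balance for given feature sets
#'
#' @param table an [AbundanceTable].
#' @param plus_set,minus_set disjoint, non-empty feature-id sets.
#' @param normalization `"proportional"` returns the formula exactly;
#'   `"normalized"` multiplies by `sqrt(k+ k- / (k+ + k-))` (isometric
#'   log-ratio scaling).
#' @return a [Balance].
#' @export
computeBalance <- function(table, plus_set, minus_set,
                           normalization = c("proportional", "normalized")) {
  normalization <- match.arg(normalization)
  m <- abundances(table)
  absent <- setdiff(c(plus_set, minus_set), colnames(m))
  if (length(absent))
    stop("features not in table: ", paste(absent, collapse = ", "))
  if (length(intersect(plus_set, minus_set)))
    stop("plus and minus sets must be disjoint")
  if (!length(plus_set) || !length(minus_set))
    stop("both sets must be non-empty")
  L <- log(replaceZeros(m, pseudoFraction(table)))
  B <- rowMeans(L[, plus_set, drop = FALSE]) -
    rowMeans(L[, minus_set, drop = FALSE])
  if (normalization == "normalized") {
    kp <- length(plus_set); km <- length(minus_set)
    B <- B * sqrt(kp * km / (kp + km))
  }
  new("Balance", plus = as.character(plus_set),
      minus = as.character(minus_set), normalization = normalization,
      values = B)
}

#' Association of a balance with a response
#'
#' Continuous responses: Pearson correlation of the balance values with the
#' response (two-sided p). Dichotomous (0/1) responses: AUC of the balance
#' as a ranking score, plus accuracy at the Youden-optimal threshold.
#'
#' @param balance a [Balance].
#' @param response numeric (continuous) or 0/1 (dichotomous) vector,
#'   aligned with the balance samples (or named by sample).
#' @param kind `"continuous"` or `"dichotomous"`.
#' @return list with `kind`, `estimate` (r or AUC), and for continuous
#'   `p_value`, for dichotomous `accuracy` and `threshold`.
#' @export
evaluateBalance <- function(balance, response,
                            kind = c("continuous", "dichotomous")) {
  kind <- match.arg(kind)
  B <- balanceValues(balance)
  if (!is.null(names(response))) response <- response[names(B)]
  if (length(response) != length(B))
    stop("response length must match balance samples")
  if (anyNA(response)) stop("response must be complete")
  if (kind == "dichotomous") {
    if (!all(response %in% c(0, 1)))
      stop("dichotomous response must be coded 0/1")
    if (length(unique(response)) < 2L)
      stop("dichotomous response has a single class")
    yj <- youdenAccuracy(B, response)
    return(list(kind = kind, estimate = rankAUC(B, response),
                accuracy = yj$accuracy, threshold = yj$threshold))
  }
  if (all(response %in% c(0, 1)) && length(unique(response)) <= 2L)
    stop("response looks dichotomous; pass kind = 'dichotomous'")
  if (stats::sd(response) == 0) stop("response has zero variance")
  ct <- stats::cor.test(B, response)
  list(kind = kind, estimate = unname(ct$estimate),
       p_value = ct$p.value)
}

# Forward-selection path on log-abundance matrix L (samples x features).
# Returns list of (plus, minus) index sets for C = 2 .. C_max.
# Continuous fit = squared Pearson correlation (computed from running
# covariance aggregates); dichotomous fit = AUC of the balance as a score.
forwardBalancePath <- function(L, y, kind, C_max) {
  D <- ncol(L)
  n <- nrow(L)
  feats <- colnames(L)
  C_max <- min(C_max, D)
  ord <- order(feats)  # lexicographic tie-break order

  if (kind == "continuous") {
    Cv <- stats::cov(L)
    cy <- as.vector(stats::cov(L, y))
    vy <- stats::var(y)
    v <- diag(Cv)
    # best pair: r^2 of L_i - L_j with y over all unordered pairs
    num <- outer(cy, cy, "-")^2
    den <- vy * (outer(v, v, "+") - 2 * Cv)
    r2 <- num / den
    r2[!is.finite(r2)] <- -Inf
    diag(r2) <- -Inf
    r2[outer(cy, cy, "-") < 0] <- -Inf  # orientation: plus side correlates +
    mx <- max(r2)
    if (is.finite(mx)) {
      hits <- which(r2 >= mx - 1e-12, arr.ind = TRUE)
      hits <- hits[order(feats[hits[, 1]], feats[hits[, 2]]), , drop = FALSE]
      bi <- hits[1, 1]; bj <- hits[1, 2]
    } else { bi <- ord[1]; bj <- ord[2] }
    plus <- bi; minus <- bj
    path <- list(list(plus = plus, minus = minus))
    # running aggregates for var/cov of the balance
    sy <- function(set) sum(cy[set])
    vSS <- function(s1, s2) sum(Cv[s1, s2])
    while (length(plus) + length(minus) < C_max) {
      kp <- length(plus); km <- length(minus)
      rest <- setdiff(seq_len(D), c(plus, minus))
      if (!length(rest)) break
      aP <- colSums(Cv[plus, , drop = FALSE])   # sum_i in plus C[i, ]
      aM <- colSums(Cv[minus, , drop = FALSE])
      vPP <- vSS(plus, plus); vMM <- vSS(minus, minus)
      vPM <- vSS(plus, minus)
      syP <- sy(plus); syM <- sy(minus)
      # candidate on plus side
      covP <- (syP + cy[rest]) / (kp + 1) - syM / km
      varP <- (vPP + 2 * aP[rest] + v[rest]) / (kp + 1)^2 +
        vMM / km^2 - 2 * (vPM + aM[rest]) / ((kp + 1) * km)
      fitP <- covP^2 / (vy * varP)
      # candidate on minus side
      covM <- syP / kp - (syM + cy[rest]) / (km + 1)
      varM <- vPP / kp^2 + (vMM + 2 * aM[rest] + v[rest]) / (km + 1)^2 -
        2 * (vPM + aP[rest]) / (kp * (km + 1))
      fitM <- covM^2 / (vy * varM)
      fitP[!is.finite(fitP) | varP <= 0] <- -Inf
      fitM[!is.finite(fitM) | varM <= 0] <- -Inf
      cand <- data.frame(f = rep(rest, 2),
                         side = rep(c("plus", "minus"), each = length(rest)),
                         fit = c(fitP, fitM))
      cand <- cand[order(-cand$fit, feats[cand$f],
                         match(cand$side, c("plus", "minus"))), ]
      pick <- cand[1, ]
      if (!is.finite(pick$fit)) break
      if (pick$side == "plus") plus <- c(plus, pick$f) else
        minus <- c(minus, pick$f)
      path[[length(path) + 1L]] <- list(plus = plus, minus = minus)
    }
    return(path)
  }

  # dichotomous: direct evaluation with rank AUC
  bal <- function(plus, minus)
    rowMeans(L[, plus, drop = FALSE]) - rowMeans(L[, minus, drop = FALSE])
  best <- -Inf; bi <- bj <- NA_integer_
  for (io in ord) for (jo in ord) {
    if (io == jo) next
    a <- rankAUC(L[, io] - L[, jo], y)
    if (is.na(a) || a < 0.5) next  # orientation fixed by the pair order
    if (a > best + 1e-12) { best <- a; bi <- io; bj <- jo }
  }
  if (is.na(bi)) { bi <- ord[1]; bj <- ord[2] }
  plus <- bi; minus <- bj
  path <- list(list(plus = plus, minus = minus))
  while (length(plus) + length(minus) < C_max) {
    rest <- setdiff(seq_len(D), c(plus, minus))
    if (!length(rest)) break
    bestFit <- -Inf; pickF <- NA_integer_; pickSide <- NA_character_
    for (f in rest[order(feats[rest])]) {
      for (side in c("plus", "minus")) {
        a <- if (side == "plus") rankAUC(bal(c(plus, f), minus), y) else
          rankAUC(bal(plus, c(minus, f)), y)
        if (!is.na(a) && a > bestFit + 1e-12) {
          bestFit <- a; pickF <- f; pickSide <- side
        }
      }
    }
    if (is.na(pickF)) break
    if (pickSide == "plus") plus <- c(plus, pickF) else
      minus <- c(minus, pickF)
    path[[length(path) + 1L]] <- list(plus = plus, minus = minus)
  }
  path
}

balanceKey <- function(feats, sets) {
  paste(paste(sort(feats[sets$plus]), collapse = ","),
        paste(sort(feats[sets$minus]), collapse = ","), sep = " | ")
}

#' Cross-validated forward selection of a predictive balance
#'
#' Forward selection builds a sequence of balances with C = 2 .. `C_max`
#' components (fit: squared Pearson correlation with a continuous response,
#' AUC for a dichotomous one). Repeated k-fold cross-validation evaluates
#' the held-out fit of each C; the selected `C_opt` is the smallest C whose
#' mean held-out fit is within one standard error of the best (1-SE rule,
#' favouring parsimony). The global balance is refit on all samples with
#' `C_opt` components, and the CV balances at `C_opt` yield robustness
#' frequencies: how often each feature, and each distinct balance, was
#' selected. Folds are stratified by class for dichotomous responses.
#'
#' @param table an [AbundanceTable] (typically restricted to the
#'   significantly changed features first).
#' @param response complete numeric response, aligned with (or named by)
#'   the table samples; 0/1 responses are treated as dichotomous.
#' @param kind `"auto"`, `"continuous"` or `"dichotomous"`.
#' @param C_max largest number of components considered (default 20).
#' @param n_folds,n_repeats cross-validation geometry (default 5 x 10).
#' @param seed optional integer seed.
#' @param normalization passed to [computeBalance()] for the global balance.
#' @param log_response log-transform a positive continuous response (for
#'   survival-as-continuous use); censoring indicators are not modelled.
#' @return a [BalanceSelectionResult].
#' @export
selectBalanceCV <- function(table, response, kind = c("auto", "continuous",
                                                      "dichotomous"),
                            C_max = 20, n_folds = 5, n_repeats = 10,
                            seed = NULL,
                            normalization = c("proportional", "normalized"),
                            log_response = FALSE) {
  kind <- match.arg(kind)
  normalization <- match.arg(normalization)
  m <- abundances(table)
  if (C_max < 2) stop("C_max must be at least 2")
  if (ncol(m) < 2L) stop("need at least 2 features")
  C_max <- min(C_max, ncol(m))
  y <- response
  if (!is.null(names(y))) y <- y[rownames(m)]
  y <- unname(y)
  if (length(y) != nrow(m)) stop("response length must match samples")
  if (anyNA(y)) stop("response must be complete for all samples used")
  if (kind == "auto")
    kind <- if (all(y %in% c(0, 1))) "dichotomous" else "continuous"
  if (kind == "dichotomous") {
    if (!all(y %in% c(0, 1))) stop("dichotomous response must be coded 0/1")
    if (length(unique(y)) < 2L)
      stop("dichotomous response has a single class")
  } else {
    if (log_response) {
      if (any(y <= 0)) stop("log_response needs a positive response")
      y <- log(y)
    }
    if (stats::sd(y) == 0) stop("response has zero variance")
  }
  L <- log(replaceZeros(m, pseudoFraction(table)))
  feats <- colnames(L)
  n <- nrow(L)
  if (!is.null(seed)) set.seed(seed)

  foldAssign <- function() {
    f <- integer(n)
    if (kind == "dichotomous") {
      for (cl in c(0, 1)) {
        idx <- sample(which(y == cl))
        f[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      f[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
    f
  }
  heldBalance <- function(sets, test)
    rowMeans(L[test, sets$plus, drop = FALSE]) -
      rowMeans(L[test, sets$minus, drop = FALSE])

  Cs <- 2:C_max
  nRows <- n_folds * n_repeats
  cvFit <- matrix(NA_real_, nRows, length(Cs))      # per-fold held-out fit
  cvPred <- matrix(NA_real_, n, length(Cs))         # held-out B, per repeat
  repFit <- matrix(NA_real_, n_repeats, length(Cs)) # pooled fit per repeat
  cvSets <- vector("list", nRows)
  row <- 0L
  for (r in seq_len(n_repeats)) {
    fa <- foldAssign()
    cvPred[] <- NA_real_
    for (k in seq_len(n_folds)) {
      row <- row + 1L
      test <- which(fa == k)
      train <- which(fa != k)
      if (length(test) == 0L || length(train) < 4L) next
      if (kind == "dichotomous" && length(unique(y[train])) < 2L) next
      path <- forwardBalancePath(L[train, , drop = FALSE], y[train], kind,
                                 C_max)
      cvSets[[row]] <- path
      for (ci in seq_along(path)) {
        B <- heldBalance(path[[ci]], test)
        cvPred[test, ci] <- B
        cvFit[row, ci] <- if (kind == "continuous") {
          if (stats::sd(B) == 0 || stats::sd(y[test]) == 0) NA_real_
          else stats::cor(B, y[test])^2
        } else rankAUC(B, y[test])
      }
    }
    # pooled held-out scores of this repeat (stable at small n, where
    # per-fold AUC over a handful of samples is heavily quantised)
    for (ci in seq_along(Cs)) {
      have <- !is.na(cvPred[, ci])
      if (!any(have)) next
      repFit[r, ci] <- if (kind == "continuous") {
        if (stats::sd(cvPred[have, ci]) == 0) NA_real_
        else stats::cor(cvPred[have, ci], y[have])^2
      } else rankAUC(cvPred[have, ci], y[have])
    }
  }
  scores <- if (kind == "dichotomous") repFit else cvFit
  means <- colMeans(scores, na.rm = TRUE)
  ses <- apply(scores, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2L) return(NA_real_)
    stats::sd(col) / sqrt(length(col))
  })
  bestIdx <- which.max(means)
  thr <- means[bestIdx] - (if (is.na(ses[bestIdx])) 0 else ses[bestIdx])
  COptIdx <- which(means >= thr - 1e-12)[1]
  COpt <- Cs[COptIdx]

  globalPath <- forwardBalancePath(L, y, kind, C_max)
  gIdx <- min(COptIdx, length(globalPath))
  gSets <- globalPath[[gIdx]]
  global <- computeBalance(table, feats[gSets$plus], feats[gSets$minus],
                           normalization)

  atOpt <- lapply(cvSets, function(p)
    if (!is.null(p) && length(p) >= COptIdx) p[[COptIdx]] else NULL)
  atOpt <- atOpt[!vapply(atOpt, is.null, logical(1))]
  compFreq <- stats::setNames(numeric(length(feats)), feats)
  if (length(atOpt)) {
    sel <- table(unlist(lapply(atOpt, function(s)
      unique(feats[c(s$plus, s$minus)]))))
    compFreq[names(sel)] <- as.numeric(sel) / length(atOpt)
  }
  keys <- vapply(atOpt, function(s) balanceKey(feats, s), character(1))
  balFreq <- if (length(keys)) {
    tb <- sort(table(keys), decreasing = TRUE)
    data.frame(balance = names(tb),
               frequency = as.numeric(tb) / length(keys),
               stringsAsFactors = FALSE)
  } else data.frame(balance = character(), frequency = numeric())

  inFit <- evaluateBalance(global, y, kind)
  fit <- list(kind = kind, estimate = inFit$estimate,
              cv_estimate = means[COptIdx])
  if (kind == "continuous") fit$p_value <- inFit$p_value
  else { fit$accuracy <- inFit$accuracy; fit$threshold <- inFit$threshold }

  new("BalanceSelectionResult",
      COpt = as.integer(COpt), globalBalance = global,
      cvScores = data.frame(C = Cs, mean = means, se = ses),
      componentFrequency = compFreq,
      balanceFrequency = balFreq, fit = fit)
}

#' Log-ratio of summed phylum abundances
#'
#' `log((sum numerator phyla + eps) / (sum denominator phyla + eps))` per
#' sample, with phyla parsed from the `p__` rank of the lineage ids.
#'
#' @param table an [AbundanceTable] with lineage feature ids.
#' @param numerator,denominator character vectors of phylum names.
#' @return named numeric vector, one log-ratio per sample.
#' @export
phylumRatio <- function(table, numerator, denominator) {
  m <- abundances(table)
  phyla <- lineageRank(colnames(m), "p")
  numF <- which(phyla %in% numerator)
  denF <- which(phyla %in% denominator)
  if (!length(numF))
    stop("numerator phyla absent: ", paste(numerator, collapse = ", "))
  if (!length(denF))
    stop("denominator phyla absent: ", paste(denominator, collapse = ", "))
  eps <- pseudoFraction(table)
  numS <- rowSums(m[, numF, drop = FALSE])
  denS <- rowSums(m[, denF, drop = FALSE])
  if (any(numS == 0) || any(denS == 0))
    warning("zero phylum sum in some sample(s); pseudo-fraction applied")
  log((numS + eps) / (denS + eps))
}
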