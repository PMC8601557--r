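# Independent dense-solve oracle for the basis-variance system without
# exclusions: for each i, sum_{j != i} (w_i + w_j) = sum_{j != i} t_ij.
basisOracle <- function(Tmat) {
  D <- nrow(Tmat)
  A <- matrix(1, D, D)
  diag(A) <- D - 1
  w <- solve(A, rowSums(Tmat))
  rho <- (outer(w, w, "+") - Tmat) / (2 * sqrt(outer(w, w)))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}

test_that("basis-variance solution equals an independent dense solve", {
  set.seed(1)
  # D = 4 toy variation matrix from a known basis
  S <- crossprod(matrix(rnorm(16, sd = 0.4), 4)) + diag(4)
  v <- diag(S)
  Tmat <- outer(v, v, "+") - 2 * S
  res <- gutbalance:::basisCorrelation(Tmat, exclusion_threshold = 1.1,
                                       exclusion_rounds = 0)
  expect_equal(res$rho, basisOracle(Tmat), tolerance = 1e-10)
})

test_that("compiled iteration loop matches the reference R implementation", {
  tab <- randomTable(n = 20, D = 6, seed = 9)
  frac <- abundances(tab)
  counts <- frac * 10000 + 1
  nIter <- 5
  set.seed(101)
  cppRho <- gutbalance:::.sparccRhoCpp(counts, nIter, 0.1, 10)$rho
  set.seed(101)
  acc <- matrix(0, 6, 6)
  for (it in seq_len(nIter)) {
    g <- matrix(rgamma(20 * 6, shape = counts), 20, 6)
    L <- log(g / rowSums(g))
    cv <- cov(L)
    v <- diag(cv)
    Tmat <- outer(v, v, "+") - 2 * cv
    acc <- acc + gutbalance:::basisCorrelation(Tmat, 0.1, 10)$rho
  }
  refRho <- acc / nIter
  refRho <- (refRho + t(refRho)) / 2
  diag(refRho) <- 1
  expect_equal(cppRho, refRho, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sparcc is invariant to per-sample scaling before closure", {
  set.seed(4)
  m <- matrix(rgamma(15 * 6, 2), 15, 6,
              dimnames = list(sprintf("S%02d", 1:15), sapply(1:6, lineageId)))
  t1 <- suppressMessages(abundanceTable(m))
  t2 <- suppressMessages(abundanceTable(m * runif(15, 0.5, 50)))
  expect_equal(abundances(t1), abundances(t2), tolerance = 1e-12)
  r1 <- networkRho(suppressWarnings(sparcc(t1, n_iterations = 3, seed = 7)))
  r2 <- networkRho(suppressWarnings(sparcc(t2, n_iterations = 3, seed = 7)))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("duplicated features give near-unit correlation with a warning", {
  set.seed(12)
  base <- exp(rnorm(30, 0, 1))
  m <- cbind(dupA = base, dupB = base, f3 = exp(rnorm(30)),
             f4 = exp(rnorm(30)), f5 = exp(rnorm(30)))
  rownames(m) <- sprintf("S%02d", 1:30)
  tab <- suppressMessages(abundanceTable(m))
  expect_warning(net <- sparcc(tab, seed = 5), "dependence")
  expect_gt(networkRho(net)["dupA", "dupB"], 0.95)
})

test_that("input contracts are enforced", {
  tab <- randomTable(n = 10, D = 3, seed = 2)
  expect_error(sparcc(tab), "4 features")
  tab4 <- randomTable(n = 10, D = 5, seed = 2)
  net <- sparcc(tab4, n_iterations = 2, seed = 1)
  expect_error(sparccPseudoP(tab4, net, n_permutations = 10), "19")
  expect_error(networkPseudoP(net), "pseudo")
  tab5 <- randomTable(n = 10, D = 5, seed = 3,
                      ids = paste0("other", 1:5))
  expect_error(sparccPseudoP(tab5, net, 20), "match")
})

test_that("a planted basis correlation is recovered with calibrated pseudo-p", {
  spec <- plantCorrelation(specWithAbundantPair(77, n_patients = 100,
                                                n_features = 20), 1, 2, 0.8)
  ds <- generateDataset(spec)
  net <- sparcc(ds@abundance, seed = 78)
  expect_lt(abs(networkRho(net)[1, 2] - 0.8), 0.15)
  net <- sparccPseudoP(ds@abundance, net, 100, seed = 79)
  p <- networkPseudoP(net)
  expect_equal(p[1, 2], 1 / 101)              # minimum attainable
  expect_gte(min(p, na.rm = TRUE), 1 / 101)   # add-one rule: never 0
})

test_that("sign-flip extraction filters on significance, sign and endpoints", {
  feats <- paste0("f", 1:4)
  mkNet <- function(rho12, p12) {
    rho <- diag(4)
    rho[1, 2] <- rho[2, 1] <- rho12
    rho[3, 4] <- rho[4, 3] <- 0.5
    p <- matrix(0.5, 4, 4)
    p[1, 2] <- p[2, 1] <- p12
    p[3, 4] <- p[4, 3] <- 0.01
    diag(p) <- NA
    dimnames(rho) <- dimnames(p) <- list(feats, feats)
    new("CorrelationNetwork", featureIds = feats, rho = rho, pseudoP = p,
        nIterations = 20L, nPermutations = 100L)
  }
  pre <- mkNet(0.8, 0.01)
  postFlip <- mkNet(-0.7, 0.01)
  # identical networks: no flips
  expect_equal(nrow(signFlipEdges(pre, pre)), 0)
  # flip present and significant on both sides
  e <- signFlipEdges(pre, postFlip)
  expect_equal(nrow(e), 1)
  expect_equal(e$flip, "pos_to_neg")
  expect_equal(attr(e, "counts")[["pos_to_neg"]], 1)
  # excluded when an endpoint is outside restrict_to
  expect_equal(nrow(signFlipEdges(pre, postFlip,
                                  restrict_to = c("f1", "f3"))), 0)
  # not significant post: excluded
  expect_equal(nrow(signFlipEdges(pre, mkNet(-0.7, 0.2))), 0)
  # mismatched universes: error
  other <- new("CorrelationNetwork", featureIds = paste0("g", 1:4),
               rho = diag(4), pseudoP = matrix(0.5, 4, 4),
               nIterations = 20L, nPermutations = 100L)
  expect_error(signFlipEdges(pre, other), "universe")
})

test_that("degree ranking counts incident flips with lexicographic ties", {
  expect_length(degreeRanking(data.frame(feature_a = character(),
                                         feature_b = character())), 0)
  star <- data.frame(feature_a = c("hub", "hub", "hub"),
                     feature_b = c("a", "b", "c"))
  r <- degreeRanking(star)
  expect_equal(r[["hub"]], 3)
  expect_equal(unname(r[c("a", "b", "c")]), c(1, 1, 1))
  tied <- data.frame(feature_a = c("b", "a"), feature_b = c("z", "z"))
  expect_equal(names(degreeRanking(tied)), c("z", "a", "b"))
})
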