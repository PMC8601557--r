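# Build a paired 2-feature table where feature 1's post - pre differences
# are fully controlled (feature 2 absorbs the remainder).
pairedTableFromDiffs <- function(pre1, diffs) {
  n <- length(pre1)
  pid <- sprintf("P%03d", seq_len(n))
  rows <- c(
    setNames(lapply(seq_len(n), function(i) c(f1 = pre1[i],
                                              f2 = 1 - pre1[i])),
             paste0(pid, "_pre")),
    setNames(lapply(seq_len(n), function(i) c(f1 = pre1[i] + diffs[i],
                                              f2 = 1 - pre1[i] - diffs[i])),
             paste0(pid, "_post")))
  tableFromRows(rows)
}

test_that("prevalence filter boundary is inclusive", {
  n <- 30
  m <- matrix(0.5, n, 3,
              dimnames = list(sprintf("S%02d", 1:n), c("keep", "edge", "rare")))
  m[, "edge"] <- c(rep(0.2, 3), rep(0, n - 3))   # 3/30 = 10%
  m[, "rare"] <- c(rep(0.2, 2), rep(0, n - 2))   # 2/30 < 10%
  tab <- suppressMessages(abundanceTable(m))
  filt <- prevalenceFilter(tab, 0.10)
  expect_setequal(featureIds(filt), c("keep", "edge"))
  expect_error(prevalenceFilter(tab, 0), "0, 1")
  # no feature everywhere-present: full-prevalence filter empties the table
  tab2 <- tableFromRows(list(s1 = c(1, 0), s2 = c(0, 1)))
  expect_error(prevalenceFilter(tab2, 1), "no feature")
})

test_that("all-positive differences over five pairs give exact p = 0.0625", {
  tab <- pairedTableFromDiffs(pre1 = seq(0.10, 0.14, by = 0.01),
                              diffs = c(0.011, 0.022, 0.033, 0.044, 0.055))
  res <- pairedWilcoxon(tab, pairsFor(5))
  r1 <- res[res$feature_id == "f1", ]
  expect_equal(r1$p_value, 0.0625)
  expect_equal(r1$direction, "up_post")
  expect_false(r1$untestable)
  # the complementary feature moves down with the same p
  r2 <- res[res$feature_id == "f2", ]
  expect_equal(r2$p_value, 0.0625)
  expect_equal(r2$direction, "down_post")
})

test_that("constant features are flagged untestable with p = 1", {
  n <- 6
  pid <- sprintf("P%03d", 1:n)
  m <- matrix(1 / 3, 2 * n, 3,
              dimnames = list(c(paste0(pid, "_pre"), paste0(pid, "_post")),
                              c("flat", "f2", "f3")))
  set.seed(2)
  jitter <- runif(2 * n, -0.05, 0.05)
  m[, "f2"] <- 1 / 3 + jitter
  m[, "f3"] <- 1 / 3 - jitter
  tab <- suppressMessages(abundanceTable(m))
  res <- pairedWilcoxon(tab, pairsFor(n))
  flat <- res[res$feature_id == "flat", ]
  expect_true(flat$untestable)
  expect_equal(flat$p_value, 1)
  expect_true(is.na(flat$q_value))
})

test_that("benjamini-hochberg q-values never reorder p-values", {
  set.seed(33)
  p <- runif(40)^2
  q <- p.adjust(p, "BH")
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p))
})

test_that("log2 fold changes use means with the shared pseudo-fraction", {
  tab <- pairedTableFromDiffs(pre1 = rep(0.2, 6),
                              diffs = rep(0.2, 6))  # post mean = 2x pre mean
  res <- pairedWilcoxon(tab, pairsFor(6))
  lfc <- res$log2_fold_change[res$feature_id == "f1"]
  # eps = 0.1 shifts the ratio: log2(0.5/0.3)
  expect_equal(lfc, log2((0.4 + 0.1) / (0.2 + 0.1)))
  rank <- foldChangeRank(res, alpha = 1, use_fdr = FALSE)
  expect_equal(rank$feature_id[1], "f1")
  expect_true(all(diff(rank$log2_fold_change) <= 0))
})

test_that("pipeline type-I error is controlled under the global null", {
  reps <- 200
  hits <- 0L
  tested <- 0L
  for (r in seq_len(reps)) {
    spec <- syntheticSpec(n_patients = 15, n_features = 30, seed = 4000 + r)
    ds <- generateDataset(spec)
    res <- pairedWilcoxon(ds@abundance, ds@pairs)
    hits <- hits + length(significantFeatures(res))
    tested <- tested + sum(!res$untestable)
  }
  expect_lte(hits / tested, 0.05)
})

test_that("differential results are equivariant to sample order", {
  spec <- demoSyntheticSpec(seed = 5, n_features = 30, n_up = 6, n_down = 6)
  ds <- generateDataset(spec)
  tab <- ds@abundance
  m <- abundances(tab)
  perm <- sample(nrow(m))
  tab2 <- suppressMessages(abundanceTable(m[perm, ]))
  r1 <- pairedWilcoxon(prevalenceFilter(tab, 0.1), ds@pairs)
  r2 <- pairedWilcoxon(prevalenceFilter(tab2, 0.1), ds@pairs)
  expect_equal(r1, r2)
})

test_that("aggregate class test sums abundance and reports effect size r", {
  # all features one class: aggregate is exactly 1, nothing to test
  tab <- randomTable(n = 10, D = 4, seed = 6,
                     ids = sapply(1:4, lineageId))
  rownames(tab@abund) <- c(sprintf("P%03d_pre", 1:5),
                           sprintf("P%03d_post", 1:5))
  ann <- setNames(rep("anaerobe", 4), featureIds(tab))
  res <- aggregateClassTest(tab, pairsFor(5), ann, "anaerobe")
  expect_equal(unname(res$aggregate), rep(1, 10), tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_equal(res$r, 0)
  expect_error(aggregateClassTest(tab, pairsFor(5), ann, "aerobe"),
               "absent")

  # r = |Z| / sqrt(n) against an independent hand computation
  spec <- demoSyntheticSpec(seed = 8, n_features = 40, n_up = 6, n_down = 6)
  ds <- generateDataset(spec)
  ann2 <- plantedAnnotation(spec)
  out <- aggregateClassTest(ds@abundance, ds@pairs, ann2, "anaerobe")
  pr <- designPairs(ds@pairs)
  agg <- out$aggregate
  d <- (agg[pr$post] - agg[pr$pre])
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  s2 <- n * (n + 1) * (2 * n + 1) / 24
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(s2)
  expect_equal(out$r, abs(z) / sqrt(nrow(pr)), tolerance = 1e-12)
  expect_equal(out$n_pairs, 15)
})

test_that("a planted anaerobe decrease is detected across seeds", {
  detected <- vapply(1:50, function(s) {
    spec <- demoSyntheticSpec(seed = 6000 + s, n_patients = 50,
                              n_features = 40, n_up = 6, n_down = 6,
                              delta = 2)
    ds <- generateDataset(spec)
    dn <- spec@differential
    # the anaerobes are exactly the planted decreasing features
    ann <- setNames(
      ifelse(featureIds(spec) %in% dn$feature[dn$delta < 0],
             "anaerobe", "aerobe"),
      featureIds(spec))
    res <- aggregateClassTest(ds@abundance, ds@pairs, ann, "anaerobe")
    res$p_value < 0.05 && res$direction == "down_post"
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})
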