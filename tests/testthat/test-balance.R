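twoFeatureTable <- function() {
  tableFromRows(list(s1 = c(a = 0.8, b = 0.2),
                     s2 = c(a = 0.8, b = 0.2)))
}

test_that("balance values match hand-computed log contrasts", {
  tab <- twoFeatureTable()
  b <- computeBalance(tab, "a", "b")
  expect_equal(unname(balanceValues(b)), rep(log(4), 2))
  bn <- computeBalance(tab, "a", "b", normalization = "normalized")
  expect_equal(unname(balanceValues(bn)), rep(sqrt(1 / 2) * log(4), 2))

  # equal parts: balance identically zero
  tab0 <- tableFromRows(list(s1 = c(a = 0.3, b = 0.3, c = 0.4),
                             s2 = c(a = 0.1, b = 0.1, c = 0.8)))
  expect_equal(unname(balanceValues(computeBalance(tab0, "a", "b"))),
               c(0, 0))

  # swapping the sets negates the balance exactly
  tab2 <- randomTable(n = 8, D = 5, seed = 21)
  f <- featureIds(tab2)
  b1 <- balanceValues(computeBalance(tab2, f[1:2], f[3:5]))
  b2 <- balanceValues(computeBalance(tab2, f[3:5], f[1:2]))
  expect_equal(b1, -b2)

  expect_error(computeBalance(tab2, f[1:2], f[2:3]), "disjoint")
  expect_error(computeBalance(tab2, character(), f[1]), "non-empty")
  expect_error(computeBalance(tab2, "missing_feature", f[1]), "not in table")
})

test_that("balances are invariant to the closure constant", {
  set.seed(22)
  basis <- matrix(rgamma(10 * 6, 2), 10, 6,
                  dimnames = list(paste0("s", 1:10), paste0("f", 1:6)))
  tab <- suppressMessages(abundanceTable(basis))
  # hand computation straight from the unclosed basis
  L <- log(basis)
  manual <- rowMeans(L[, 1:2]) - rowMeans(L[, 3:4])
  b <- balanceValues(computeBalance(tab, paste0("f", 1:2), paste0("f", 3:4)))
  expect_equal(unname(b), unname(manual), tolerance = 1e-12)
})

test_that("forward selection at C = 2 matches exhaustive best-pair search", {
  set.seed(23)
  n <- 40; D <- 10
  m <- matrix(rgamma(n * D, 2), n, D,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:D)))
  tab <- suppressMessages(abundanceTable(m))
  L <- log(abundances(tab))
  y <- L[, 3] - L[, 7] + rnorm(n, sd = 0.4)

  path <- gutbalance:::forwardBalancePath(L, y, "continuous", 4)
  got <- path[[1]]
  # oracle: all ordered pairs, squared correlation
  best <- -Inf; oi <- oj <- NA
  for (i in 1:D) for (j in 1:D) {
    if (i == j) next
    r <- cor(L[, i] - L[, j], y)
    if (r >= 0 && r^2 > best) { best <- r^2; oi <- i; oj <- j }
  }
  expect_equal(got$plus, oi)
  expect_equal(got$minus, oj)
  expect_equal(c(oi, oj), c(3, 7))

  # dichotomous flavour, AUC oracle
  yb <- as.integer(L[, 2] - L[, 5] + rnorm(n, sd = 0.4) > 0)
  pathB <- gutbalance:::forwardBalancePath(L, yb, "dichotomous", 2)
  bestA <- -Inf; ai <- aj <- NA
  for (i in 1:D) for (j in 1:D) {
    if (i == j) next
    a <- gutbalance:::rankAUC(L[, i] - L[, j], yb)
    if (a >= 0.5 && a > bestA) { bestA <- a; ai <- i; aj <- j }
  }
  expect_equal(pathB[[1]]$plus, ai)
  expect_equal(pathB[[1]]$minus, aj)
})

test_that("rank AUC and Youden accuracy agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(24)
  score <- rnorm(60)
  label <- rbinom(60, 1, plogis(score))
  auc <- gutbalance:::rankAUC(score, label)
  ref <- as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc, ref, tolerance = 1e-12)
  yj <- gutbalance:::youdenAccuracy(score, label)
  co <- pROC::coords(pROC::roc(label, score, quiet = TRUE, direction = "<"),
                     "best", best.method = "youden")
  expect_equal(yj$threshold, co$threshold[1], tolerance = 1e-9)
})

test_that("evaluateBalance reports r and AUC with sane degenerate handling", {
  tab <- randomTable(n = 30, D = 5, seed = 25)
  f <- featureIds(tab)
  b <- computeBalance(tab, f[1], f[2])
  B <- balanceValues(b)
  expect_equal(evaluateBalance(b, B, "continuous")$estimate, 1)
  expect_equal(evaluateBalance(b, -B, "continuous")$estimate, -1)
  # independent score on a balanced binary response: AUC near 0.5
  set.seed(26)
  yb <- rep(c(0, 1), 1000)
  expect_lt(abs(gutbalance:::rankAUC(rnorm(2000), yb) - 0.5), 0.05)
  expect_error(evaluateBalance(b, rep(1, 30), "dichotomous"), "single class")
  expect_error(evaluateBalance(b, rep(2, 30), "continuous"), "zero variance")
})

test_that("a planted two-feature balance is recovered by CV selection", {
  spec <- demoSyntheticSpec(seed = 41, n_patients = 50, n_features = 15,
                            n_up = 3, n_down = 3, beta = 3, sigma = 0.8)
  ds <- generateDataset(spec)
  pr <- designPairs(ds@pairs)
  post <- ds@abundance[pr$post, ]
  cd <- clinicalData(ds)
  y <- setNames(cd$VO2[match(pr$post, cd$sample_id)], pr$post)
  sel <- selectBalanceCV(post, y, C_max = 8, seed = 42)
  truth <- c(spec@balanceTruth$plus, spec@balanceTruth$minus)
  chosen <- c(sel@globalBalance@plus, sel@globalBalance@minus)
  expect_gt(length(intersect(chosen, truth)), 0)
  expect_gte(max(sel@componentFrequency[truth]), 0.5)
  expect_gt(sel@fit$estimate, 0.5)
  expect_equal(length(chosen), sel@COpt)
  expect_true(all(sel@cvScores$C == 2:8))
})

test_that("selection contracts reject degenerate input", {
  tab <- randomTable(n = 20, D = 6, seed = 27)
  y <- rnorm(20)
  expect_error(selectBalanceCV(tab, y, C_max = 1), "C_max")
  expect_error(selectBalanceCV(tab, rep(1, 20)), "single class")
  expect_error(selectBalanceCV(tab, rep(1.5, 20)), "zero variance")
  expect_error(selectBalanceCV(tab, y[1:10]), "length")
  yna <- y; yna[3] <- NA
  expect_error(selectBalanceCV(tab, yna), "complete")
})

test_that("held-out fit does not beat the in-sample fit on average", {
  diffs <- vapply(1:8, function(s) {
    spec <- demoSyntheticSpec(seed = 500 + s, n_patients = 30,
                              n_features = 12, n_up = 3, n_down = 3,
                              beta = 2, sigma = 1.5)
    ds <- generateDataset(spec)
    pr <- designPairs(ds@pairs)
    post <- ds@abundance[pr$post, ]
    cd <- clinicalData(ds)
    y <- setNames(cd$VO2[match(pr$post, cd$sample_id)], pr$post)
    sel <- selectBalanceCV(post, y, C_max = 6, n_repeats = 3,
                           seed = 600 + s)
    sel@fit$estimate^2 - sel@fit$cv_estimate
  }, numeric(1))
  expect_gte(mean(diffs), -0.02)
})

test_that("phylum ratios follow the summed log-ratio definition", {
  ids <- c(lineageId(1, "Proteobacteria"), lineageId(2, "Actinobacteria"),
           lineageId(3, "Euryarchaeota"), lineageId(4, "Firmicutes"))
  tab <- tableFromRows(list(
    s1 = setNames(c(0.2, 0.1, 0.1, 0.6), ids),
    s2 = setNames(c(0.4, 0.1, 0.1, 0.4), ids)))
  r <- phylumRatio(tab, "Proteobacteria",
                   c("Euryarchaeota", "Actinobacteria"))
  eps <- pseudoFraction(tab)
  expect_equal(unname(r["s1"]), log((0.2 + eps) / (0.2 + eps)))
  expect_equal(unname(r["s2"]), log((0.4 + eps) / (0.2 + eps)))
  expect_error(phylumRatio(tab, "Bacteroidetes", "Firmicutes"), "absent")

  # zero denominator in one sample: finite with a warning
  tab2 <- tableFromRows(list(
    s1 = setNames(c(0.5, 0, 0, 0.5), ids),
    s2 = setNames(c(0.4, 0.1, 0.1, 0.4), ids)))
  expect_warning(r2 <- phylumRatio(tab2, "Proteobacteria", "Actinobacteria"),
                 "zero")
  expect_true(all(is.finite(r2)))
})
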