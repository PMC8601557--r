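# Brute-force oracle: regress ranks on the covariate ranks, correlate the
# residuals (equivalent route to the precision-matrix formula).
residualOracle <- function(x, y, Zm) {
  rx <- rank(x); ry <- rank(y)
  RZ <- apply(Zm, 2, function(col)
    if (length(unique(col)) > 2) rank(col) else col)
  ex <- resid(lm(rx ~ RZ))
  ey <- resid(lm(ry ~ RZ))
  cor(ex, ey)
}

test_that("no covariates reduces to ordinary Spearman", {
  set.seed(1)
  x <- rnorm(40)
  y <- x + rnorm(40)
  res <- partialSpearman(x, y)
  expect_equal(res$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(res$q, 0)
  # strictly increasing relation: rho = 1
  expect_equal(partialSpearman(x, exp(x))$rho, 1)
})

test_that("rank basis makes the estimate invariant to monotone transforms", {
  set.seed(2)
  x <- rexp(30)
  y <- rnorm(30)
  z <- data.frame(z = rnorm(30))
  r0 <- partialSpearman(x, y, z)$rho
  expect_equal(partialSpearman(log(x), y, z)$rho, r0, tolerance = 1e-12)
  expect_equal(partialSpearman(x, y^3, z)$rho,
               partialSpearman(x, y, z)$rho, tolerance = 1e-12)
  # symmetry in (x, y)
  expect_equal(partialSpearman(y, x, z)$rho, r0, tolerance = 1e-12)
})

test_that("precision-matrix route agrees with the rank-residual oracle", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(15:60, 1)
    q <- sample(1:3, 1)
    Z <- matrix(rnorm(n * q), n)
    x <- rnorm(n) + Z %*% rnorm(q)
    y <- rnorm(n) + Z %*% rnorm(q)
    res <- partialSpearman(as.vector(x), as.vector(y), as.data.frame(Z))
    expect_equal(res$rho, residualOracle(as.vector(x), as.vector(y), Z),
                 tolerance = 1e-6)
  }
})

test_that("adjustment removes a confounded association", {
  set.seed(4)
  n <- 200
  z <- rnorm(n)
  x <- z + rnorm(n, sd = 0.3)   # x tracks the confounder
  y <- z + rnorm(n, sd = 0.1)   # y is driven by the confounder
  expect_gt(abs(cor(x, y, method = "spearman")), 0.6)
  expect_lt(abs(partialSpearman(x, y, data.frame(z = z))$rho), 0.15)
})

test_that("categorical covariates are one-hot encoded and degenerate input flagged", {
  set.seed(5)
  n <- 40
  x <- rnorm(n)
  y <- rnorm(n)
  Z <- data.frame(cancer_type = sample(c("ADC", "SCC", "other"), n, TRUE),
                  COPD = rbinom(n, 1, 0.4))
  res <- partialSpearman(x, y, Z)
  expect_equal(res$q, 3)  # two dummies + one binary
  expect_setequal(res$covariates,
                  c("cancer_type.other", "cancer_type.SCC", "COPD"))

  flat <- partialSpearman(rep(1, n), y, Z)
  expect_true(flat$undefined)
  expect_true(is.na(flat$rho))

  # collinear covariates are named in the error
  Z2 <- data.frame(a = x, b = x)
  expect_error(partialSpearman(rnorm(n), y, Z2), "collinear")

  # too few complete cases
  expect_error(partialSpearman(c(1, 2, 3), c(2, 1, 4),
                               data.frame(z = c(1, 5, 2))), "complete cases")
})

test_that("screen reports planted associations and applies both filters", {
  spec <- demoSyntheticSpec(seed = 31, n_patients = 50, n_features = 30,
                            n_up = 5, n_down = 5, beta = 3, sigma = 1)
  ds <- generateDataset(spec)
  pr <- designPairs(ds@pairs)
  post <- ds@abundance[pr$post, ]
  hits <- correlationScreen(post, ds@clinical, parameters = "VO2")
  planted <- c(spec@balanceTruth$plus, spec@balanceTruth$minus)
  expect_true(any(hits$feature_id %in% planted))
  expect_true(all(hits$p_value < 0.05))
  expect_true(all(hits$covariates == "COPD;cancer_type.SCC;cancer_type.other"))

  # magnitude filter: |rho| <= 0.65 rows disappear
  strict <- correlationScreen(post, ds@clinical, parameters = "VO2",
                              min_abs_rho = 0.65)
  expect_true(all(abs(strict$rho) > 0.65))
  expect_lte(nrow(strict), nrow(hits))

  expect_error(correlationScreen(post, ds@clinical, parameters = "nope"),
               "unknown")
  cd <- clinicalData(ds@clinical)
  cd$Watt <- NA_real_
  expect_error(correlationScreen(post, clinicalTable(cd),
                                 parameters = "Watt"), "missing")
})

test_that("change table is the per-patient log2 ratio with pseudo-fraction", {
  n <- 5
  pid <- sprintf("P%03d", 1:n)
  tiny <- 1e-6
  pre <- cbind(f1 = rep(0.2, n), f2 = rep(0.8 - tiny, n), f3 = tiny)
  post <- cbind(f1 = rep(0.4, n), f2 = rep(0.6 - tiny, n), f3 = tiny)
  m <- rbind(pre, post)
  rownames(m) <- c(paste0(pid, "_pre"), paste0(pid, "_post"))
  tab <- suppressMessages(abundanceTable(m))
  ch <- changeTable(tab, pairsFor(n))
  expect_equal(rownames(ch), pid)
  expect_equal(unname(ch[, "f1"]), rep(1, n), tolerance = 1e-5)
  expect_equal(unname(ch[, "f3"]), rep(0, n), tolerance = 1e-9)

  # pre = 0, post > 0 stays finite through the pseudo-fraction
  pre0 <- cbind(f1 = c(0, 0.3), f2 = c(1, 0.7))
  post0 <- cbind(f1 = c(0.5, 0.3), f2 = c(0.5, 0.7))
  m0 <- rbind(pre0, post0)
  rownames(m0) <- c("P001_pre", "P002_pre", "P001_post", "P002_post")
  tab0 <- suppressMessages(abundanceTable(m0))
  ch0 <- changeTable(tab0, pairsFor(2))
  expect_true(all(is.finite(ch0)))
  expect_gt(ch0["P001", "f1"], 0)
})
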