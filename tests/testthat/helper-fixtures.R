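# Fixtures built in code; no data files.

lineageId <- function(i, phylum = "Firmicutes") {
  sprintf("k__Bacteria|p__%s|g__G%02d|s__G%02d_sp", phylum, i, i)
}

# Small closed table: `n` samples x `D` features, seeded, no zeros.
randomTable <- function(n = 6, D = 5, seed = 1, ids = NULL) {
  set.seed(seed)
  m <- matrix(rgamma(n * D, shape = 2), n, D)
  rownames(m) <- sprintf("S%02d", seq_len(n))
  colnames(m) <- ids %||% sapply(seq_len(D), lineageId)
  suppressMessages(abundanceTable(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Paired table built from explicit fraction rows (list of named vectors).
tableFromRows <- function(rows) {
  m <- do.call(rbind, rows)
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  suppressMessages(abundanceTable(m))
}

# A paired design over samples P<i>_pre / P<i>_post.
pairsFor <- function(n) {
  pid <- sprintf("P%03d", seq_len(n))
  new("PairedDesign",
      pairs = data.frame(patient_id = pid, pre = paste0(pid, "_pre"),
                         post = paste0(pid, "_post"),
                         stringsAsFactors = FALSE))
}

# Synthetic spec with planted features at typical (median) abundance, so
# log-scale correlation recovery is not attenuated by sampling-depth noise.
specWithAbundantPair <- function(seed, n_patients = 100, n_features = 50,
                                 pair = c(1, 2)) {
  set.seed(seed)
  mu <- rnorm(n_features, 0, 2)
  sdv <- runif(n_features, 0.5, 1.5)
  mu[pair] <- 0
  sdv[pair] <- 1
  syntheticSpec(n_patients = n_patients, n_features = n_features,
                seed = seed, log_basis_mean = mu, log_sd = sdv)
}
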