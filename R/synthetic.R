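# Synthetic paired compositional cohorts with planted ground truth.
#
# The generative model is the one SparCC itself assumes: feature "basis"
# abundances are log-normal with a specified log-scale correlation
# structure, and only their closure (relative abundances) is observed.
# Planted post-surgery shifts, planted (possibly sign-flipping) basis
# correlations and a planted outcome-driving balance give every downstream
# stage a recoverable truth.

#' @include io.R
NULL

#' Describe a synthetic paired cohort
#'
#' Defaults emulate the study design the package targets: 15 patients with
#' paired pre/post stool samples and a few hundred compositional features.
#' Per-feature log-basis means and sds are drawn once, deterministically
#' from `seed`, unless supplied: means N(0, 2^2) and sds U(0.5, 1.5), giving
#' abundances spanning several orders of magnitude as in real gut
#' metagenomes. Correlation matrices default to the identity.
#'
#' @param n_patients number of patients (each contributes a pre and a post
#'   sample).
#' @param n_features number of compositional features.
#' @param seed integer seed driving all draws for this spec.
#' @param log_basis_mean,log_sd optional per-feature log-basis parameters.
#' @param cor_pre,cor_post optional basis correlation matrices (PSD, unit
#'   diagonal).
#' @param differential optional data.frame with columns `feature` and
#'   `delta`: log2 shifts applied to the post log-means.
#' @param balance_truth optional list `plus`, `minus`, `beta`, `sigma`
#'   defining the balance that drives the outcomes; `NULL` plants no signal
#'   (beta = 0).
#' @param covariate_model list of COPD prevalence, cancer-type category
#'   probabilities and confounding weights on the outcomes.
#' @return a [SyntheticSpec].
#' @export
syntheticSpec <- function(n_patients = 15, n_features = 200, seed = 1,
                          log_basis_mean = NULL, log_sd = NULL,
                          cor_pre = NULL, cor_post = NULL,
                          differential = NULL, balance_truth = NULL,
                          covariate_model = list()) {
  D <- as.integer(n_features)
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Euryarchaeota")
  features <- sprintf("k__Bacteria|p__%s|g__Genus%03d|s__Genus%03d_species",
                      phyla[(seq_len(D) - 1L) %% length(phyla) + 1L],
                      seq_len(D), seq_len(D))
  if (is.null(log_basis_mean) || is.null(log_sd)) {
    set.seed(as.integer(seed))
    if (is.null(log_basis_mean)) log_basis_mean <- stats::rnorm(D, 0, 2)
    if (is.null(log_sd)) log_sd <- stats::runif(D, 0.5, 1.5)
  }
  ident <- diag(D)
  dimnames(ident) <- list(features, features)
  fixCor <- function(R) {
    if (is.null(R)) return(ident)
    R <- as.matrix(R)
    dimnames(R) <- list(features, features)
    R
  }
  if (is.null(differential))
    differential <- data.frame(feature = character(), delta = numeric(),
                               stringsAsFactors = FALSE)
  else
    differential <- data.frame(feature = as.character(differential$feature),
                               delta = as.numeric(differential$delta),
                               stringsAsFactors = FALSE)
  cm <- utils::modifyList(list(
    copd_prev = 0.4,
    cancer_probs = c(ADC = 0.5, SCC = 0.35, other = 0.15),
    gamma_copd = -2,
    gamma_cancer = c(ADC = 0, SCC = -1, other = -0.5),
    vo2_intercept = 16,
    null_sigma = 1.5,
    os_scale = 24, os_shrink = 0.3, os_sigma = 0.2,
    recurrence_slope = 4
  ), covariate_model)
  bt <- if (is.null(balance_truth)) list() else balance_truth
  new("SyntheticSpec",
      nPatients = as.integer(n_patients), features = features,
      logBasisMean = as.numeric(log_basis_mean), logSd = as.numeric(log_sd),
      corPre = fixCor(cor_pre), corPost = fixCor(cor_post),
      differential = differential, balanceTruth = bt,
      covariateModel = cm, seed = as.integer(seed))
}

resolveFeature <- function(spec, f) {
  feats <- featureIds(spec)
  if (is.numeric(f)) {
    if (f < 1 || f > length(feats)) stop("feature index out of range")
    return(as.integer(f))
  }
  i <- match(f, feats)
  if (is.na(i)) i <- match(f, speciesToken(feats))
  if (is.na(i)) stop("unknown feature: ", f)
  i
}

#' Plant a basis correlation between two features
#'
#' Sets the requested log-scale correlation in the pre and/or post basis
#' correlation matrix, then projects the modified matrix to the nearest
#' positive semi-definite correlation matrix (eigenvalue clipping at 1e-8,
#' rescaled to unit diagonal).
#'
#' @param spec a [SyntheticSpec].
#' @param feature_a,feature_b feature ids or indices (distinct).
#' @param rho target correlation, |rho| < 1.
#' @param timepoint `"both"`, `"pre"` or `"post"`.
#' @return the modified [SyntheticSpec].
#' @export
plantCorrelation <- function(spec, feature_a, feature_b, rho,
                             timepoint = c("both", "pre", "post")) {
  timepoint <- match.arg(timepoint)
  a <- resolveFeature(spec, feature_a)
  b <- resolveFeature(spec, feature_b)
  if (a == b) stop("feature_a and feature_b must differ")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (timepoint %in% c("both", "pre")) {
    spec@corPre[a, b] <- spec@corPre[b, a] <- rho
    spec@corPre <- psdProject(spec@corPre)
  }
  if (timepoint %in% c("both", "post")) {
    spec@corPost[a, b] <- spec@corPost[b, a] <- rho
    spec@corPost <- psdProject(spec@corPost)
  }
  validObject(spec)
  spec
}

#' Plant a sign-flipping basis correlation
#'
#' Sets the pre-surgery basis correlation of the pair to `+rho` and the
#' post-surgery one to `-rho`, projecting each matrix to the nearest PSD
#' correlation matrix.
#'
#' @inheritParams plantCorrelation
#' @param rho magnitude of the flip, |rho| <= 0.9.
#' @return the modified [SyntheticSpec].
#' @export
plantSignFlip <- function(spec, feature_a, feature_b, rho) {
  if (abs(rho) > 0.9) stop("|rho| must be <= 0.9 for a sign flip")
  a <- resolveFeature(spec, feature_a)
  b <- resolveFeature(spec, feature_b)
  if (a == b) stop("feature_a and feature_b must differ")
  spec@corPre[a, b] <- spec@corPre[b, a] <- rho
  spec@corPost[a, b] <- spec@corPost[b, a] <- -rho
  spec@corPre <- psdProject(spec@corPre)
  spec@corPost <- psdProject(spec@corPost)
  validObject(spec)
  spec
}

#' Oxygen-tolerance annotation consistent with the planted effects
#'
#' A synthetic annotation map: features planted to decrease post-surgery
#' are labelled anaerobe, features planted to increase aerobe, and the
#' remaining (null) features are `unknown`, so the aggregate class test has
#' a clean planted decrease to recover.
#'
#' @param spec a [SyntheticSpec].
#' @return named character vector feature -> class.
#' @export
plantedAnnotation <- function(spec) {
  feats <- featureIds(spec)
  cls <- stats::setNames(rep("unknown", length(feats)), feats)
  if (nrow(spec@differential)) {
    dn <- spec@differential
    cls[dn$feature[dn$delta < 0]] <- "anaerobe"
    cls[dn$feature[dn$delta > 0]] <- "aerobe"
  }
  cls
}

#' Generate a paired synthetic dataset
#'
#' Pre and post log-basis abundances are drawn multivariate-normally with
#' the spec's per-timepoint correlation matrices; planted log2 effects are
#' added to the post log-means; compositions arise by closure. Outcomes are
#' generated from the planted balance computed on the post composition:
#' a continuous VO2-like response `beta * B + gamma * covariates + noise`,
#' `recurrence ~ Bernoulli(logistic(...))` and a positive overall-survival
#' time `os_scale * exp(...)`. CPET and lung-function parameters other than
#' VO2 are independent noise on plausible clinical scales and exist only on
#' post rows (measured at follow-up). Fully reproducible from the spec seed.
#'
#' @param spec a [SyntheticSpec].
#' @return a [SyntheticDataset].
#' @export
generateDataset <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nPatients
  D <- length(spec@features)
  sdv <- spec@logSd
  mu_pre <- spec@logBasisMean
  mu_post <- mu_pre
  if (nrow(spec@differential)) {
    idx <- match(spec@differential$feature, spec@features)
    mu_post[idx] <- mu_post[idx] + spec@differential$delta * log(2)
  }
  Spre <- (sdv %o% sdv) * spec@corPre
  Spost <- (sdv %o% sdv) * spec@corPost
  Lpre <- MASS::mvrnorm(n, mu_pre, Spre)
  Lpost <- MASS::mvrnorm(n, mu_post, Spost)
  if (n == 1L) { Lpre <- rbind(Lpre); Lpost <- rbind(Lpost) }
  pid <- sprintf("P%03d", seq_len(n))
  basis <- rbind(exp(Lpre), exp(Lpost))
  rownames(basis) <- c(paste0(pid, "_pre"), paste0(pid, "_post"))
  colnames(basis) <- spec@features
  abund <- suppressMessages(abundanceTable(basis))  # closure

  cm <- spec@covariateModel
  copd <- stats::rbinom(n, 1, cm$copd_prev)
  ctype <- sample(names(cm$cancer_probs), n, replace = TRUE,
                  prob = cm$cancer_probs)
  covEff <- cm$gamma_copd * copd + unname(cm$gamma_cancer[ctype])

  post_frac <- abundances(abund)[paste0(pid, "_post"), , drop = FALSE]
  bt <- spec@balanceTruth
  if (length(bt)) {
    lp <- log(post_frac)
    B <- rowMeans(lp[, bt$plus, drop = FALSE]) -
      rowMeans(lp[, bt$minus, drop = FALSE])
    beta <- bt$beta
    sigma <- bt$sigma
  } else {
    B <- rep(0, n)
    beta <- 0
    sigma <- cm$null_sigma
  }
  eta <- beta * B + covEff
  vo2 <- cm$vo2_intercept + eta + stats::rnorm(n, 0, sigma)
  etaC <- eta - mean(eta)
  recurrence <- stats::rbinom(n, 1, stats::plogis(cm$recurrence_slope * etaC))
  os <- cm$os_scale * exp(cm$os_shrink * etaC +
                            stats::rnorm(n, 0, cm$os_sigma))

  noise <- function(m, s) stats::rnorm(n, m, s)
  perPatient <- data.frame(
    patient_id = pid, COPD = copd, cancer_type = ctype,
    recurrence = recurrence, OS = os, stringsAsFactors = FALSE)
  cpet <- data.frame(
    FEV1pct = noise(75, 15), TLCpct = noise(95, 12), RVpct = noise(110, 25),
    sGawpct = noise(80, 20), Watt = noise(100, 25), VE = noise(60, 12),
    VO2 = vo2, O2HR = noise(10, 2), VEVCO2 = noise(32, 4),
    VEVO2 = noise(35, 5))
  pre_rows <- cbind(perPatient, timepoint = "pre",
                    cpet[rep(NA_integer_, n), , drop = FALSE])
  post_rows <- cbind(perPatient, timepoint = "post", cpet)
  clin <- rbind(pre_rows, post_rows)
  rownames(clin) <- NULL
  clin$sample_id <- paste(clin$patient_id, clin$timepoint, sep = "_")
  clinical <- clinicalTable(clin)

  pairs <- new("PairedDesign",
               pairs = data.frame(patient_id = pid,
                                  pre = paste0(pid, "_pre"),
                                  post = paste0(pid, "_post"),
                                  stringsAsFactors = FALSE))
  new("SyntheticDataset", abundance = abund, clinical = clinical,
      pairs = pairs, truth = spec)
}

#' Write a synthetic dataset as the TSV inputs the readers consume
#'
#' Writes `abundance.tsv` (features x samples), `clinical.tsv`,
#' `annotation.tsv` (planted oxygen classes) and `truth.json` (planted
#' ground truth) into `dir`.
#'
#' @param dataset a [SyntheticDataset].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAbundanceTable(dataset@abundance, file.path(dir, "abundance.tsv"))
  writeTsv(clinicalData(dataset), file.path(dir, "clinical.tsv"))
  ann <- plantedAnnotation(dataset@truth)
  utils::write.table(
    data.frame(feature_id = names(ann), class = unname(ann)),
    file.path(dir, "annotation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- dataset@truth
  truth <- list(
    seed = spec@seed, n_patients = spec@nPatients,
    n_features = length(spec@features),
    differential = spec@differential, balance_truth = spec@balanceTruth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
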