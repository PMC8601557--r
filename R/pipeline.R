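# End-to-end orchestration: (simulate | ingest) -> diversity -> differential
# -> co-abundance networks -> clinical correlations -> balance selection,
# from a single config with one top-level seed.

#' @include balance.R
NULL

#' Demo synthetic cohort specification
#'
#' The planted scenario the demo pipeline analyses: 15 patients, 200
#' species-level features, 32 planted post-surgery shifts (17 up, 15 down,
#' 4-fold on the basis scale), a planted 2-vs-3 species balance driving
#' VO2, recurrence and overall survival, and three sign-flipping basis
#' correlations between differential features.
#'
#' @param seed integer seed.
#' @param n_patients,n_features cohort dimensions.
#' @param n_up,n_down number of planted increased/decreased features.
#' @param delta planted |log2| effect size.
#' @param beta,sigma planted balance coefficient and outcome noise sd.
#' @param flip_rho magnitude of the planted sign-flip correlations.
#' @return a [SyntheticSpec].
#' @export
demoSyntheticSpec <- function(seed = 1, n_patients = 15, n_features = 200,
                              n_up = 17, n_down = 15, delta = 2,
                              beta = 3, sigma = 1.5, flip_rho = 0.8) {
  if (n_up + n_down > n_features)
    stop("n_up + n_down cannot exceed n_features")
  spec <- syntheticSpec(n_patients = n_patients, n_features = n_features,
                        seed = seed)
  feats <- featureIds(spec)
  up <- feats[seq_len(n_up)]
  down <- feats[n_up + seq_len(n_down)]
  nd <- n_up + n_down
  # planted features sit at typical abundance (log-mean spread halved) so
  # that recovery reflects method behaviour, not abundance extremes
  mu <- spec@logBasisMean
  mu[seq_len(nd)] <- mu[seq_len(nd)] / 2
  spec <- syntheticSpec(
    n_patients = n_patients, n_features = n_features, seed = seed,
    log_basis_mean = mu, log_sd = spec@logSd,
    differential = data.frame(feature = c(up, down),
                              delta = c(rep(delta, n_up),
                                        rep(-delta, n_down))),
    balance_truth = list(plus = up[1:2], minus = down[1:3],
                         beta = beta, sigma = sigma))
  nflip <- min(6L, n_up, n_down)
  for (k in seq_len(nflip))
    spec <- plantSignFlip(spec, up[k], down[k],
                          flip_rho * c(1, -1)[k %% 2 + 1] *
                            (1 - 0.05 * (k - 1)))
  spec
}

defaultConfig <- function() {
  list(
    thresholds = list(min_prevalence = 0.10, alpha = 0.05,
                      pseudo_p_alpha = 0.05, min_abs_rho = 0,
                      network_restrict_no_fdr = FALSE),
    permutations = list(permanova = 999, sparcc = 100,
                        sparcc_iterations = 20),
    c_max = 20,
    cv = list(folds = 5, repeats = 10),
    parameters = c("FEV1pct", "TLCpct", "RVpct", "sGawpct", "Watt", "VE",
                   "VO2", "O2HR", "VEVCO2", "VEVO2"),
    covariates = c("COPD", "cancer_type"),
    responses = list(continuous = "VO2", dichotomous = "recurrence",
                     survival = "OS")
  )
}

loadConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  cfg <- utils::modifyList(defaultConfig(), config)
  if (is.null(cfg$seed)) stop("config must specify a seed")
  thr <- cfg$thresholds
  stopifnot(thr$min_prevalence > 0, thr$min_prevalence <= 1,
            thr$alpha > 0, thr$alpha < 1,
            thr$pseudo_p_alpha > 0, thr$pseudo_p_alpha < 1,
            cfg$permutations$permanova >= 99,
            cfg$permutations$sparcc >= 19, cfg$c_max >= 2)
  cfg$parameters <- unlist(cfg$parameters)
  cfg$covariates <- unlist(cfg$covariates)
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing one TSV per analysis
#' plus a `manifest.json` (config echo, seed, package version, per-stage
#' wall time) into `out_dir`. All randomness derives from the single config
#' seed through deterministic per-stage sub-seeds, so rerunning with the
#' same config reproduces every analysis output byte-identically. Any stage
#' error aborts with the stage name.
#'
#' @param config a list or path to a YAML file. Must contain `seed`, plus
#'   either `synthetic:` (arguments of [demoSyntheticSpec()]) or `input:`
#'   with `abundance`, `layout`, `clinical` and optionally `annotation`
#'   paths. Thresholds, permutation counts, CV geometry, parameter and
#'   covariate lists have the package defaults (10% prevalence, alpha 0.05,
#'   999 PERMANOVA permutations, 20 SparCC iterations, 100 SparCC
#'   permutations, C up to 20, 5 x 10 CV).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config, out_dir) {
  cfg <- loadConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  results <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  data <- stage("data", function() {
    if (!is.null(cfg$synthetic)) {
      args <- cfg$synthetic
      args$seed <- stageSeed(cfg$seed, "data")
      spec <- do.call(demoSyntheticSpec, args)
      ds <- generateDataset(spec)
      list(table = ds@abundance, clinical = ds@clinical, pairs = ds@pairs,
           annotation = plantedAnnotation(spec))
    } else if (!is.null(cfg$input)) {
      inp <- cfg$input
      table <- readAbundanceTable(inp$abundance,
                                  layout = inp$layout %||% "taxa_merged")
      clinical <- readClinical(inp$clinical)
      ann <- if (!is.null(inp$annotation)) readAnnotation(inp$annotation)
      list(table = table, clinical = clinical,
           pairs = buildPairs(clinical, table), annotation = ann)
    } else stop("config needs either 'synthetic' or 'input'")
  })
  tab <- data$table
  clin <- clinicalData(data$clinical)
  pairs <- data$pairs
  pr <- designPairs(pairs)
  tp <- ifelse(sampleIds(tab) %in% pr$post, "post", "pre")

  results$diversity <- stage("diversity", function() {
    alpha <- data.frame(
      sample_id = sampleIds(tab), timepoint = tp,
      shannon = alphaDiversity(tab, "shannon"),
      simpson = alphaDiversity(tab, "simpson"),
      chao1 = suppressMessages(alphaDiversity(tab, "chao1")))
    writeTsv(alpha, file.path(out_dir, "alpha_diversity.tsv"))
    dm <- brayCurtis(tab)
    pv <- permanova(dm, tp, n_permutations = cfg$permutations$permanova,
                    seed = stageSeed(cfg$seed, "diversity"))
    writeTsv(data.frame(term = "timepoint", pseudo_F = pv@pseudoF,
                        R2 = pv@R2, p_value = pv@pValue,
                        n_permutations = pv@nPermutations),
             file.path(out_dir, "permanova.tsv"))
    ord <- pcoa(dm, k = 2)
    writeTsv(data.frame(sample_id = rownames(ord$coordinates),
                        timepoint = tp, ord$coordinates),
             file.path(out_dir, "pcoa.tsv"))
    list(alpha = alpha, permanova = pv, pcoa = ord)
  })

  results$differential <- stage("differential", function() {
    filt <- prevalenceFilter(tab, cfg$thresholds$min_prevalence)
    res <- pairedWilcoxon(filt, pairs)
    writeTsv(res, file.path(out_dir, "differential.tsv"))
    agg <- NULL
    if (!is.null(data$annotation)) {
      rowsOf <- function(prs, cls)
        tryCatch({
          a <- aggregateClassTest(tab, prs, data$annotation, cls)
          data.frame(class = cls, r = a$r, Z = a$Z, p_value = a$p_value,
                     n_pairs = a$n_pairs, direction = a$direction)
        }, error = function(e) NULL)
      sub <- list(all = pairs)
      if ("recurrence" %in% names(clin)) {
        rec <- unique(clin$patient_id[clin$recurrence == 1])
        nonrec <- unique(clin$patient_id[clin$recurrence == 0])
        sub$recurrent <- tryCatch(filterPairs(pairs, rec),
                                  error = function(e) NULL)
        sub$non_recurrent <- tryCatch(filterPairs(pairs, nonrec),
                                      error = function(e) NULL)
      }
      agg <- do.call(rbind, unlist(lapply(names(sub), function(s) {
        if (is.null(sub[[s]])) return(NULL)
        lapply(c("anaerobe", "aerobe"), function(cl) {
          d <- rowsOf(sub[[s]], cl)
          if (!is.null(d)) cbind(subgroup = s, d)
        })
      }), recursive = FALSE))
      if (!is.null(agg))
        writeTsv(agg, file.path(out_dir, "aggregate_class.tsv"))
    }
    list(filtered = filt, results = res, aggregate = agg,
         significant = significantFeatures(res, cfg$thresholds$alpha))
  })
  filt <- results$differential$filtered
  sig <- results$differential$significant

  results$network <- stage("network", function() {
    it <- cfg$permutations$sparcc_iterations
    np <- cfg$permutations$sparcc
    sd1 <- stageSeed(cfg$seed, "network_pre")
    sd2 <- stageSeed(cfg$seed, "network_post")
    tabPre <- filt[pr$pre, ]
    tabPost <- filt[pr$post, ]
    netPre <- sparccPseudoP(tabPre, sparcc(tabPre, it, seed = sd1),
                            n_permutations = np, seed = sd1 + 1L)
    netPost <- sparccPseudoP(tabPost, sparcc(tabPost, it, seed = sd2),
                             n_permutations = np, seed = sd2 + 1L)
    for (nm in c("pre", "post")) {
      net <- if (nm == "pre") netPre else netPost
      writeTsv(data.frame(feature_id = featureIds(net), networkRho(net),
                          check.names = FALSE),
               file.path(out_dir, sprintf("network_%s_rho.tsv", nm)))
      writeTsv(data.frame(feature_id = featureIds(net), networkPseudoP(net),
                          check.names = FALSE),
               file.path(out_dir, sprintf("network_%s_pseudop.tsv", nm)))
    }
    restrict <- if (isTRUE(cfg$thresholds$network_restrict_no_fdr))
      significantFeatures(results$differential$results,
                          cfg$thresholds$alpha, use_fdr = FALSE)
    else sig
    edges <- signFlipEdges(netPre, netPost, restrict_to = restrict,
                           alpha = cfg$thresholds$pseudo_p_alpha)
    writeTsv(edges, file.path(out_dir, "flip_edges.tsv"))
    deg <- degreeRanking(edges)
    writeTsv(data.frame(feature_id = names(deg), flip_edges = deg),
             file.path(out_dir, "flip_degree.tsv"))
    list(pre = netPre, post = netPost, edges = edges,
         counts = attr(edges, "counts"), degree = deg)
  })

  results$correlation <- stage("correlation", function() {
    if (!length(sig)) return(NULL)
    postTab <- filt[pr$post, sig]
    hits <- correlationScreen(
      postTab, data$clinical,
      parameters = intersect(cfg$parameters, names(clin)),
      covariates = intersect(cfg$covariates, names(clin)),
      p_max = cfg$thresholds$alpha,
      min_abs_rho = cfg$thresholds$min_abs_rho)
    writeTsv(hits, file.path(out_dir, "correlations.tsv"))
    hits
  })

  results$balance <- stage("balance", function() {
    if (length(sig) < 2L) return(NULL)
    postTab <- filt[pr$post, sig]
    postClin <- clin[match(pr$post, clin$sample_id), ]
    runOne <- function(respName, kind, log_response = FALSE) {
      y <- stats::setNames(postClin[[respName]], pr$post)
      if (anyNA(y)) return(NULL)
      if (kind == "dichotomous" && length(unique(y)) < 2L) return(NULL)
      sel <- selectBalanceCV(
        postTab, y, kind = kind, C_max = cfg$c_max,
        n_folds = cfg$cv$folds, n_repeats = cfg$cv$repeats,
        seed = stageSeed(cfg$seed, paste0("balance_", respName)),
        log_response = log_response)
      g <- sel@globalBalance
      writeTsv(data.frame(
        feature_id = c(g@plus, g@minus),
        side = rep(c("plus", "minus"), c(length(g@plus), length(g@minus)))),
        file.path(out_dir, sprintf("balance_%s_features.tsv", respName)))
      writeTsv(sel@cvScores,
               file.path(out_dir, sprintf("balance_%s_cv.tsv", respName)))
      writeTsv(data.frame(feature_id = names(sel@componentFrequency),
                          frequency = sel@componentFrequency),
               file.path(out_dir,
                         sprintf("balance_%s_compfreq.tsv", respName)))
      sel
    }
    resp <- cfg$responses
    sels <- list()
    if (!is.null(resp$continuous))
      sels[[resp$continuous]] <- runOne(resp$continuous, "continuous")
    if (!is.null(resp$dichotomous))
      sels[[resp$dichotomous]] <- runOne(resp$dichotomous, "dichotomous")
    if (!is.null(resp$survival))
      sels[[resp$survival]] <- runOne(resp$survival, "continuous",
                                      log_response = TRUE)
    sels <- sels[!vapply(sels, is.null, logical(1))]
    summ <- do.call(rbind, lapply(names(sels), function(nm) {
      s <- sels[[nm]]
      data.frame(response = nm, kind = s@fit$kind, C_opt = s@COpt,
                 fit_in_sample = s@fit$estimate,
                 fit_cv = s@fit$cv_estimate)
    }))
    if (!is.null(summ))
      writeTsv(summ, file.path(out_dir, "balance_summary.tsv"))
    sels
  })

  manifest <- list(
    package = "gutbalance",
    version = as.character(utils::packageVersion("gutbalance")),
    seed = cfg$seed,
    config = cfg,
    stage_seconds = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Human-readable summary of a pipeline result directory
#'
#' Builds a markdown summary from the stage TSVs: PERMANOVA table, counts
#' of enriched features pre/post, aggregate class effects, flip-edge counts
#' by direction, top correlation hits, and selected balances with fit
#' statistics. Missing stages are flagged as gaps rather than errors.
#'
#' @param dir a directory written by [runPipeline()].
#' @param path optional file to write the summary to.
#' @return the summary, invisibly, as a character vector of lines.
#' @export
pipelineReport <- function(dir, path = NULL) {
  rd <- function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) return(NULL)
    utils::read.delim(fp, check.names = FALSE, stringsAsFactors = FALSE)
  }
  lines <- c("# Pipeline summary", "")
  any_stage <- FALSE

  pv <- rd("permanova.tsv")
  if (!is.null(pv)) {
    any_stage <- TRUE
    lines <- c(lines, "## Community composition",
               sprintf("- PERMANOVA (%s): pseudo-F = %.3f, R2 = %.1f%%, p = %.4g",
                       pv$term[1], pv$pseudo_F[1], 100 * pv$R2[1],
                       pv$p_value[1]), "")
  } else lines <- c(lines, "## Community composition", "- (stage missing)", "")

  dd <- rd("differential.tsv")
  if (!is.null(dd)) {
    any_stage <- TRUE
    sig <- dd[!is.na(dd$q_value) & dd$q_value < 0.05, ]
    lines <- c(lines, "## Differential abundance",
               sprintf("- %d of %d features significant (q < 0.05): %d enriched post, %d enriched pre",
                       nrow(sig), nrow(dd),
                       sum(sig$direction == "up_post"),
                       sum(sig$direction == "down_post")), "")
  } else lines <- c(lines, "## Differential abundance", "- (stage missing)", "")

  ag <- rd("aggregate_class.tsv")
  if (!is.null(ag)) {
    lines <- c(lines, "## Aggregate oxygen-class shifts",
               sprintf("- %s / %s: r = %.1f%%, p = %.3g (%s)",
                       ag$subgroup, ag$class, 100 * ag$r, ag$p_value,
                       ag$direction), "")
  }

  fe <- rd("flip_edges.tsv")
  if (!is.null(fe)) {
    any_stage <- TRUE
    lines <- c(lines, "## Differential co-abundance network",
               sprintf("- %d sign-flip edges: %d positive-to-negative, %d negative-to-positive",
                       nrow(fe), sum(fe$flip == "pos_to_neg"),
                       sum(fe$flip == "neg_to_pos")), "")
  } else lines <- c(lines, "## Differential co-abundance network",
                    "- (stage missing)", "")

  co <- rd("correlations.tsv")
  if (!is.null(co) && nrow(co)) {
    co <- co[order(co$p_value), ]
    top <- utils::head(co, 5)
    lines <- c(lines, "## Clinical correlations",
               sprintf("- %d significant feature-parameter pairs; top hits:",
                       nrow(co)),
               sprintf("  - %s ~ %s: rho = %.2f, p = %.3g",
                       top$feature_id, top$parameter, top$rho, top$p_value),
               "")
  } else lines <- c(lines, "## Clinical correlations",
                    "- none significant or stage missing", "")

  bs <- rd("balance_summary.tsv")
  if (!is.null(bs)) {
    any_stage <- TRUE
    lines <- c(lines, "## Predictive balances",
               sprintf("- %s (%s): C_opt = %d, in-sample fit = %.3f, CV fit = %.3f",
                       bs$response, bs$kind, bs$C_opt, bs$fit_in_sample,
                       bs$fit_cv), "")
  } else lines <- c(lines, "## Predictive balances", "- (stage missing)", "")

  if (!any_stage) lines <- c("# Pipeline summary", "", "no stages completed")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
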