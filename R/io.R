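# Reading/writing abundance tables, clinical metadata and annotation maps.

#' @include utils.R
NULL

#' Construct an AbundanceTable from a samples x features matrix
#'
#' Rows are renormalized to fractions. Percent-scale input (rows summing to
#' 100) is rescaled silently; anything else deviating from closure by more
#' than `1e-6` (relative) is flagged non-closed via a message and
#' renormalized explicitly. Renormalization is idempotent.
#'
#' @param mat non-negative numeric matrix, samples in rows, features in
#'   columns, with row and column names.
#' @param unit_scale `"fraction"` or `"percent"`; the scale the input is
#'   expected on (only used to decide whether to flag the table as
#'   non-closed).
#' @return an [AbundanceTable] (fractions).
#' @export
abundanceTable <- function(mat, unit_scale = c("fraction", "percent")) {
  unit_scale <- match.arg(unit_scale)
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("abundance values must be numeric")
  if (anyNA(mat)) stop("abundance values must not be NA")
  if (any(mat < 0)) stop("negative abundance value")
  rs <- rowSums(mat)
  if (any(rs == 0)) stop("all-zero sample row(s): ",
                         paste(rownames(mat)[rs == 0], collapse = ", "))
  target <- if (unit_scale == "percent") 100 else 1
  if (any(abs(rs / target - 1) > 1e-6))
    message("table not closed to ", target, "; renormalizing rows")
  new("AbundanceTable", abund = mat / rs)
}

#' Read an abundance table from a tab-separated file
#'
#' Expects features in rows: first column feature id, remaining columns one
#' per sample (MetaPhlAn-merged / HUMAnN2-pathabundance style). The matrix
#' is transposed to samples x features and rows are closed to fractions.
#'
#' @param path file path.
#' @param layout `"taxa_merged"` keeps only species-level lineage rows
#'   (species rank present, no strain rank); `"pathway"` drops stratified
#'   (taxon-attributed, `|`-containing) rows, keeping community totals;
#'   `"none"` keeps all rows (used e.g. for round-tripping written tables).
#' @param unit_scale expected input scale, see [abundanceTable()].
#' @return an [AbundanceTable].
#' @export
readAbundanceTable <- function(path, layout = c("taxa_merged", "pathway", "none"),
                               unit_scale = c("fraction", "percent")) {
  layout <- match.arg(layout)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty abundance table: ", path)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric abundance values in ", path)
  if (any(vals < 0)) stop("negative abundance value in ", path)
  rownames(vals) <- ids
  keep <- switch(layout,
    taxa_merged = isSpeciesRow(ids),
    pathway = !grepl("|", ids, fixed = TRUE),
    none = rep(TRUE, length(ids)))
  vals <- vals[keep, , drop = FALSE]
  if (nrow(vals) == 0L)
    stop("no rows retained under layout '", layout, "'")
  abundanceTable(t(vals), unit_scale = match.arg(unit_scale))
}

#' Write an abundance table as TSV (features in rows)
#'
#' Inverse of [readAbundanceTable()] with `layout = "none"`: values are
#' written as fractions at full precision, so a read/write round trip
#' reproduces values to 1e-12 and ordering exactly.
#'
#' @param table an [AbundanceTable].
#' @param path output file path.
#' @export
writeAbundanceTable <- function(table, path) {
  m <- t(abundances(table))
  d <- data.frame(feature_id = rownames(m),
                  formatC(m, digits = 17, format = "g"),
                  check.names = FALSE, stringsAsFactors = FALSE)
  colnames(d) <- c("feature_id", colnames(m))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a ClinicalTable from a data frame
#'
#' @param d data.frame with at least `patient_id` and `timepoint`
#'   (`"pre"`/`"post"`). A `sample_id` column is added as
#'   `<patient_id>_<timepoint>` when absent. Binary columns (`COPD`,
#'   `recurrence`) must be 0/1; blanks in numeric columns become `NA`.
#' @return a [ClinicalTable].
#' @export
clinicalTable <- function(d) {
  req <- c("patient_id", "timepoint")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  d$patient_id <- as.character(d$patient_id)
  d$timepoint <- as.character(d$timepoint)
  bad <- setdiff(unique(d$timepoint), c("pre", "post"))
  if (length(bad))
    stop("invalid timepoint value(s): ", paste(bad, collapse = ", "))
  if (is.null(d$sample_id))
    d$sample_id <- paste(d$patient_id, d$timepoint, sep = "_")
  d$sample_id <- as.character(d$sample_id)
  for (bc in intersect(c("COPD", "recurrence"), names(d))) {
    v <- d[[bc]]
    if (is.character(v)) {
      if (!all(v %in% c("0", "1", "", NA)))
        stop("binary column '", bc, "' must be coded 0/1")
      v <- suppressWarnings(as.numeric(v))
    }
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop("binary column '", bc, "' must be coded 0/1")
    d[[bc]] <- v
  }
  new("ClinicalTable", data = d)
}

#' Read clinical metadata from a tab-separated file
#'
#' Unknown columns are preserved as extra parameters; missing numeric
#' entries are recorded as `NA` (never zero) and excluded pairwise per
#' analysis downstream.
#'
#' @param path file path.
#' @return a [ClinicalTable].
#' @export
readClinical <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  clinicalTable(d)
}

#' Read an oxygen-tolerance (or other feature class) annotation map
#'
#' Two-column TSV `feature_id<TAB>class`. Classes other than `aerobe` /
#' `anaerobe` are mapped to `unknown`.
#'
#' @param path file path.
#' @return named character vector, feature id -> class.
#' @export
readAnnotation <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("annotation map needs two columns")
  cls <- as.character(d[[2]])
  cls[!cls %in% c("aerobe", "anaerobe")] <- "unknown"
  stats::setNames(cls, as.character(d[[1]]))
}

#' Match an annotation map onto a table's features
#'
#' Matching is exact on the terminal species token after stripping rank
#' prefixes (deterministic, no fuzzy matching); unmatched features are
#' `unknown`.
#'
#' @param annotation named character vector from [readAnnotation()] (or
#'   built in code).
#' @param table an [AbundanceTable].
#' @return named character vector over all features of `table`.
#' @export
matchAnnotation <- function(annotation, table) {
  feats <- featureIds(table)
  tok <- speciesToken(feats)
  atok <- speciesToken(names(annotation))
  out <- annotation[match(tok, atok)]
  out[is.na(out)] <- "unknown"
  stats::setNames(unname(out), feats)
}

#' Build the paired pre/post design
#'
#' Returns only patients having both timepoints present as samples of the
#' abundance table, in deterministic order by patient id. Patients with an
#' incomplete pair are dropped with a warning naming them.
#'
#' @param clinical a [ClinicalTable].
#' @param table an [AbundanceTable].
#' @return a [PairedDesign].
#' @export
buildPairs <- function(clinical, table) {
  d <- clinicalData(clinical)
  samp <- sampleIds(table)
  pats <- sort(unique(d$patient_id))
  rows <- lapply(pats, function(p) {
    pre <- d$sample_id[d$patient_id == p & d$timepoint == "pre"]
    post <- d$sample_id[d$patient_id == p & d$timepoint == "post"]
    ok <- length(pre) == 1L && length(post) == 1L &&
      pre %in% samp && post %in% samp
    if (!ok) return(NULL)
    data.frame(patient_id = p, pre = pre, post = post,
               stringsAsFactors = FALSE)
  })
  dropped <- pats[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("dropping patients without a complete pre/post pair: ",
            paste(dropped, collapse = ", "))
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no patient has a complete pre/post pair in the abundance table")
  new("PairedDesign", pairs = pairs)
}
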