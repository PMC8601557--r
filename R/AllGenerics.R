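# Accessor generics. Slot access stays internal to the package.

#' @include AllClasses.R
NULL

#' Abundance matrix (samples x features, fractions)
#' @param x an [AbundanceTable] or [SyntheticDataset].
#' @return numeric matrix.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' Sample identifiers
#' @param x an object with samples.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Feature identifiers
#' @param x an object with features.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' Clinical records as a data frame
#' @param x a [ClinicalTable] or [SyntheticDataset].
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' Paired design as a data frame (patient_id, pre, post)
#' @param x a [PairedDesign] or [SyntheticDataset].
#' @export
setGeneric("designPairs", function(x) standardGeneric("designPairs"))

#' Correlation estimates of a network
#' @param x a [CorrelationNetwork].
#' @export
setGeneric("networkRho", function(x) standardGeneric("networkRho"))

#' Permutation pseudo p-values of a network
#' @param x a [CorrelationNetwork].
#' @export
setGeneric("networkPseudoP", function(x) standardGeneric("networkPseudoP"))

#' Significance mask of a network (pseudo-p below alpha, diagonal excluded)
#' @param x a [CorrelationNetwork].
#' @param alpha significance level for the pseudo p-value (default 0.05).
#' @export
setGeneric("significantEdges",
           function(x, alpha = 0.05) standardGeneric("significantEdges"))

#' Per-sample balance values
#' @param x a [Balance].
#' @export
setGeneric("balanceValues", function(x) standardGeneric("balanceValues"))

#' @rdname abundances
#' @export
setMethod("abundances", "AbundanceTable", function(x) x@abund)
#' @rdname abundances
#' @export
setMethod("abundances", "SyntheticDataset", function(x) x@abundance@abund)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "AbundanceTable", function(x) rownames(x@abund))
#' @rdname featureIds
#' @export
setMethod("featureIds", "AbundanceTable", function(x) colnames(x@abund))
#' @rdname featureIds
#' @export
setMethod("featureIds", "CorrelationNetwork", function(x) x@featureIds)
#' @rdname featureIds
#' @export
setMethod("featureIds", "SyntheticSpec", function(x) x@features)

#' @rdname clinicalData
#' @export
setMethod("clinicalData", "ClinicalTable", function(x) x@data)
#' @rdname clinicalData
#' @export
setMethod("clinicalData", "SyntheticDataset", function(x) x@clinical@data)

#' @rdname designPairs
#' @export
setMethod("designPairs", "PairedDesign", function(x) x@pairs)
#' @rdname designPairs
#' @export
setMethod("designPairs", "SyntheticDataset", function(x) x@pairs@pairs)

#' @rdname networkRho
#' @export
setMethod("networkRho", "CorrelationNetwork", function(x) x@rho)

#' @rdname networkPseudoP
#' @export
setMethod("networkPseudoP", "CorrelationNetwork", function(x) {
  if (!length(x@pseudoP))
    stop("no pseudo p-values: run sparccPseudoP() first")
  x@pseudoP
})

#' @rdname significantEdges
#' @export
setMethod("significantEdges", "CorrelationNetwork", function(x, alpha = 0.05) {
  p <- networkPseudoP(x)
  sig <- p < alpha
  sig[is.na(sig)] <- FALSE
  diag(sig) <- FALSE
  sig
})

#' @rdname balanceValues
#' @export
setMethod("balanceValues", "Balance", function(x) x@values)

#' Subset an abundance table by samples and/or features
#'
#' Subsetting keeps the stored fractions as-is (no re-closure): a feature
#' subset is a sub-composition and downstream log-ratio machinery is
#' invariant to the closure constant.
#'
#' @param x an [AbundanceTable].
#' @param i sample selector (names, indices or logical).
#' @param j feature selector.
#' @param ... ignored.
#' @param drop ignored; always returns an [AbundanceTable].
#' @export
setMethod("[", "AbundanceTable", function(x, i, j, ..., drop = FALSE) {
  m <- x@abund
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  new("AbundanceTable", abund = m / rowSums(m))
})

#' Number of samples in an abundance table
#' @param x an [AbundanceTable].
#' @export
nSamples <- function(x) nrow(abundances(x))

#' Number of features in an abundance table
#' @param x an [AbundanceTable].
#' @export
nFeatures <- function(x) ncol(abundances(x))
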