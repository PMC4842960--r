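#' @include AllClasses.R
NULL

#' Accessors for panomap classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a panomap object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dataType", function(x) standardGeneric("dataType"))
#' @rdname accessors
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))
#' @rdname accessors
#' @export
setGeneric("chromosomeOf", function(x) standardGeneric("chromosomeOf"))
#' @rdname accessors
#' @export
setGeneric("normStages", function(x) standardGeneric("normStages"))
#' @rdname accessors
#' @export
setGeneric("omicsDatasets", function(x) standardGeneric("omicsDatasets"))
#' @rdname accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))
#' @rdname accessors
#' @export
setGeneric("mapCoords", function(x) standardGeneric("mapCoords"))
#' @rdname accessors
#' @export
setGeneric("klDivergence", function(x) standardGeneric("klDivergence"))
#' @rdname accessors
#' @export
setGeneric("mapCombination", function(x) standardGeneric("mapCombination"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("noiseFraction", function(x) standardGeneric("noiseFraction"))
#' @rdname accessors
#' @export
setGeneric("silhouetteWidth", function(x) standardGeneric("silhouetteWidth"))
#' @rdname accessors
#' @export
setGeneric("overlapMatrix", function(x) standardGeneric("overlapMatrix"))
#' @rdname accessors
#' @export
setGeneric("profileLabels", function(x) standardGeneric("profileLabels"))

#' @rdname accessors
#' @export
setMethod("dataType", "OmicsDataset", function(x) x@dataType)
#' @rdname accessors
#' @export
setMethod("omicsValues", "OmicsDataset", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("sampleIDs", "OmicsDataset", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("featureIDs", "OmicsDataset", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("chromosomeOf", "OmicsDataset", function(x) x@chromosome)
#' @rdname accessors
#' @export
setMethod("normStages", "OmicsDataset", function(x) x@stages)

#' @rdname accessors
#' @export
setMethod("omicsDatasets", "MultiOmicsCohort", function(x) x@datasets)
#' @rdname accessors
#' @export
setMethod("clinicalData", "MultiOmicsCohort", function(x) x@clinical)
#' @rdname accessors
#' @export
setMethod("sampleIDs", "MultiOmicsCohort",
          function(x) rownames(x@datasets[[1L]]@values))

#' @rdname accessors
#' @export
setMethod("mapCoords", "EmbeddingMap", function(x) x@coordinates)
#' @rdname accessors
#' @export
setMethod("klDivergence", "EmbeddingMap", function(x) x@klDivergence)
#' @rdname accessors
#' @export
setMethod("mapCombination", "EmbeddingMap", function(x) x@combination)
#' @rdname accessors
#' @export
setMethod("sampleIDs", "EmbeddingMap", function(x) rownames(x@coordinates))

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("noiseFraction", "ClusterAssignment", function(x) x@noiseFraction)
#' @rdname accessors
#' @export
setMethod("silhouetteWidth", "ClusterAssignment", function(x) x@silhouette)

#' @rdname accessors
#' @export
setMethod("overlapMatrix", "OverlapProfile", function(x) x@overlap)
#' @rdname accessors
#' @export
setMethod("profileLabels", "OverlapProfile", function(x) x@profileLabels)
#' @rdname accessors
#' @export
setMethod("sampleIDs", "OverlapProfile", function(x) rownames(x@overlap))

setMethod("show", "OmicsDataset", function(object) {
  cat(sprintf("OmicsDataset [%s]: %d samples x %d features\n",
              object@dataType, nrow(object@values), ncol(object@values)))
  nMiss <- sum(is.na(object@values))
  cat(sprintf("  missing cells: %d; stages: %s\n", nMiss,
              if (length(object@stages)) paste(object@stages, collapse = " -> ")
              else "(raw)"))
})

setMethod("show", "MultiOmicsCohort", function(object) {
  cat(sprintf("MultiOmicsCohort: %d samples, %d data types (%s)\n",
              nrow(object@clinical), length(object@datasets),
              paste(names(object@datasets), collapse = ", ")))
})

setMethod("show", "ReducedBlock", function(object) {
  cat(sprintf(
    "ReducedBlock [%s]: %d samples x %d components (total variance %.4g)\n",
    object@dataType, nrow(object@scores), ncol(object@scores),
    sum(apply(object@scores, 2L, stats::var))))
})

setMethod("show", "IntegratedMatrix", function(object) {
  cat(sprintf("IntegratedMatrix: %d samples x %dD (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(sprintf("%s:%d", names(object@blockSpans),
                            lengths(object@blockSpans)), collapse = " ")))
})

setMethod("show", "EmbeddingMap", function(object) {
  cat(sprintf(
    "EmbeddingMap [%s]: %d samples in %dD, KL = %.4f (seed %s, perplexity %g)\n",
    paste(object@combination, collapse = "+"), nrow(object@coordinates),
    ncol(object@coordinates), object@klDivergence,
    format(object@seed), object@perplexity))
})

setMethod("show", "ClusterAssignment", function(object) {
  k <- length(setdiff(unique(object@labels), 0L))
  cat(sprintf(
    "ClusterAssignment: %d clusters, %.1f%% noise (eps %.4g, minSamples %d, silhouette %.3f)\n",
    k, 100 * object@noiseFraction, object@eps, object@minSamples,
    object@silhouette))
})

setMethod("show", "OverlapProfile", function(object) {
  cat(sprintf("OverlapProfile: %d samples x %d combinations (k = %d)\n",
              nrow(object@overlap), ncol(object@overlap), object@k))
  if (length(object@profileLabels))
    cat(sprintf("  %d genomic profiles assigned\n",
                length(unique(object@profileLabels))))
})
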