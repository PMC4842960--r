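#' @import methods
NULL

OMIC_TYPES <- c("GE", "ME", "CN", "MIR")

#' OmicsDataset: one molecular data type for a set of samples
#'
#' Container for a single data type's sample-by-gene matrix together with its
#' normalization state. Samples are rows, features (gene symbols, or miRNA
#' IDs for the MIR type) are columns. The `stages` slot records which
#' normalization steps have been applied, in order.
#'
#' Expected raw value ranges per type: GE (RSEM) and MIR (reads per million)
#' are non-negative; ME beta values lie in \[0, 1\]; CN gene copy numbers are
#' positive and near 2 for diploid loci.
#'
#' @slot dataType one of `"GE"`, `"ME"`, `"CN"`, `"MIR"`.
#' @slot values numeric matrix, samples x features; `NA` marks missing cells.
#' @slot chromosome named character vector mapping feature -> chromosome
#'   (e.g. `"1"`, `"X"`); may be empty when no annotation is available.
#' @slot stages character vector of applied processing stages.
#'
#' @seealso [loadOmicsMatrix()], [normalizeOmics()], [filterAndImpute()]
#' @export
setClass("OmicsDataset",
  representation(
    dataType   = "character",
    values     = "matrix",
    chromosome = "character",
    stages     = "character"
  ),
  prototype(chromosome = character(0), stages = character(0))
)

setValidity("OmicsDataset", function(object) {
  msg <- character(0)
  if (length(object@dataType) != 1L || !object@dataType %in% OMIC_TYPES)
    msg <- c(msg, sprintf("dataType must be one of %s",
                          paste(OMIC_TYPES, collapse = ", ")))
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have sample rownames and feature colnames")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, sprintf("duplicate sample ID: %s",
                            rownames(v)[duplicated(rownames(v))][1L]))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, sprintf("duplicate feature ID: %s",
                            colnames(v)[duplicated(colnames(v))][1L]))
  }
  if (object@dataType == "ME" && !("normalized" %in% object@stages)) {
    rng <- range(v, na.rm = TRUE)
    if (is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 1))
      msg <- c(msg, "ME beta values must lie in [0, 1] before normalization")
  }
  if (length(msg)) msg else TRUE
})

#' MultiOmicsCohort: aligned multi-type datasets plus clinical data
#'
#' Holds one [OmicsDataset] per included data type, all sharing an identical,
#' identically ordered sample set, together with a per-sample clinical table
#' (tissue label, sex, age, overall survival). This same-sample alignment is
#' the precondition for integration.
#'
#' @slot datasets named list of [OmicsDataset] objects (names are data types).
#' @slot clinical data.frame with one row per sample, rownames = sample IDs.
#'   Recognised columns: `tissue`, `sex`, `age`, `osDays`, `osEvent`.
#'
#' @seealso [alignSamples()], [runIntegration()]
#' @export
setClass("MultiOmicsCohort",
  representation(datasets = "list", clinical = "data.frame")
)

setValidity("MultiOmicsCohort", function(object) {
  msg <- character(0)
  if (!length(object@datasets))
    msg <- c(msg, "at least one dataset is required")
  if (!all(vapply(object@datasets, is, logical(1), "OmicsDataset")))
    msg <- c(msg, "all datasets must be OmicsDataset objects")
  else {
    ids <- lapply(object@datasets, function(d) rownames(d@values))
    if (length(unique(vapply(ids, paste, character(1), collapse = "\r"))) != 1L)
      msg <- c(msg, "all datasets must share an identical, ordered sample set")
    else if (!identical(ids[[1L]], rownames(object@clinical)))
      msg <- c(msg, "clinical rownames must equal the datasets' sample IDs")
  }
  if (length(msg)) msg else TRUE
})

#' ReducedBlock: per-type principal-component scores
#'
#' The scores of one data type on its top principal axes, with the component
#' variances (eigenvalues, non-increasing) and the variance-balancing scale
#' factor applied so far.
#'
#' @slot dataType the data type the block came from.
#' @slot scores numeric matrix, samples x components.
#' @slot eigenvalues component variances, decreasing.
#' @slot scaleFactor positive scalar already applied to `scores` (1 = none).
#'
#' @seealso [reduceBlock()], [scaleBlock()]
#' @export
setClass("ReducedBlock",
  representation(
    dataType    = "character",
    scores      = "matrix",
    eigenvalues = "numeric",
    scaleFactor = "numeric"
  ),
  prototype(scaleFactor = 1)
)

setValidity("ReducedBlock", function(object) {
  msg <- character(0)
  ev <- object@eigenvalues
  if (length(ev) != ncol(object@scores))
    msg <- c(msg, "one eigenvalue per score column is required")
  if (length(ev) > 1L && any(diff(ev) > 1e-8 * max(ev)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (object@scaleFactor <= 0)
    msg <- c(msg, "scaleFactor must be positive")
  if (length(msg)) msg else TRUE
})

#' IntegratedMatrix: concatenated, variance-balanced component scores
#'
#' @slot values numeric matrix, samples x D where D is the summed block width.
#' @slot blockSpans named list mapping data type -> integer column indices.
#'
#' @seealso [concatenateBlocks()], [integrateCohort()]
#' @export
setClass("IntegratedMatrix",
  representation(values = "matrix", blockSpans = "list")
)

setValidity("IntegratedMatrix", function(object) {
  n <- sum(lengths(object@blockSpans))
  if (n != ncol(object@values))
    return("blockSpans must tile the columns of values")
  TRUE
})

#' EmbeddingMap: low-dimensional sample coordinates
#'
#' Coordinates of samples embedded from a chosen data-type combination,
#' with the Kullback-Leibler divergence and seed of the selected restart.
#' Map axes carry no intrinsic meaning; only inter-sample distances do.
#'
#' @slot combination character vector, subset of the data types.
#' @slot coordinates numeric matrix, samples x dims (rownames = sample IDs).
#' @slot klDivergence final KL divergence of the selected restart.
#' @slot seed seed of the selected restart.
#' @slot perplexity perplexity used.
#'
#' @seealso [embedMap()], [runIntegration()]
#' @export
setClass("EmbeddingMap",
  representation(
    combination  = "character",
    coordinates  = "matrix",
    klDivergence = "numeric",
    seed         = "numeric",
    perplexity   = "numeric"
  )
)

setValidity("EmbeddingMap", function(object) {
  if (length(object@klDivergence) == 1L && object@klDivergence < 0)
    return("klDivergence must be non-negative")
  TRUE
})

#' ClusterAssignment: density-based clustering of a map
#'
#' Per-sample cluster labels from density-reachability clustering; label 0
#' marks non-clustering ("noise") samples. The silhouette is computed on
#' clustered samples only.
#'
#' @slot labels named integer vector; 0 = noise.
#' @slot eps density radius used.
#' @slot minSamples minimum neighbourhood occupancy for a core point.
#' @slot silhouette mean silhouette width over clustered samples (NA if < 2
#'   clusters).
#' @slot noiseFraction fraction of samples labelled noise.
#'
#' @seealso [dbscanCluster()], [selectEps()]
#' @export
setClass("ClusterAssignment",
  representation(
    labels        = "integer",
    eps           = "numeric",
    minSamples    = "integer",
    silhouette    = "numeric",
    noiseFraction = "numeric"
  )
)

setValidity("ClusterAssignment", function(object) {
  if (object@noiseFraction < 0 || object@noiseFraction > 1)
    return("noiseFraction must lie in [0, 1]")
  TRUE
})

#' OverlapProfile: per-sample neighbourhood overlap across combinations
#'
#' For each sample and each proper non-empty data-type combination, the
#' percentage of the sample's k nearest neighbours in that combination's map
#' that are also among its k nearest neighbours in the full map. Ward
#' clustering of the rows yields "genomic profile" labels.
#'
#' @slot overlap numeric matrix, samples x combinations, values in \[0, 100\].
#' @slot combinations list of character vectors, the combination per column.
#' @slot k neighbourhood size.
#' @slot profileLabels named integer vector of profile labels (may be empty
#'   until [profileClusters()] is run).
#'
#' @seealso [contributionAnalysis()], [profileClusters()]
#' @export
setClass("OverlapProfile",
  representation(
    overlap       = "matrix",
    combinations  = "list",
    k             = "integer",
    profileLabels = "integer"
  ),
  prototype(profileLabels = integer(0))
)

setValidity("OverlapProfile", function(object) {
  msg <- character(0)
  if (length(object@combinations) != ncol(object@overlap))
    msg <- c(msg, "one combination per overlap column is required")
  rng <- range(object@overlap)
  if (is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 100))
    msg <- c(msg, "overlap percentages must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})
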