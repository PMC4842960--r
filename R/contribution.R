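#' @include AllClasses.R AllGenerics.R
NULL

#' Enumerate data-type combinations
#'
#' All non-empty proper subsets of the input types, in canonical order:
#' singletons first, then pairs, then triples, lexicographic within each
#' size with respect to the canonical type order (GE, ME, CN, MIR). Four
#' types give the 14 alternative combinations.
#'
#' @param types character vector of data types (default all four).
#' @return list of character vectors.
#' @examples
#' length(enumerateCombinations())  # 14
#' @export
enumerateCombinations <- function(types = OMIC_TYPES) {
  types <- types[order(match(types, OMIC_TYPES))]
  T <- length(types)
  out <- list()
  for (size in seq_len(T - 1L)) {
    idx <- utils::combn(T, size)
    for (j in seq_len(ncol(idx)))
      out[[length(out) + 1L]] <- types[idx[, j]]
  }
  out
}

combinationName <- function(combo) paste(combo, collapse = "+")

#' Per-sample k-nearest-neighbour overlap between two maps
#'
#' For each sample, the percentage of its `k` nearest neighbours in one map
#' that are also among its `k` nearest neighbours in the other
#' (`100 * |NN_k(i; A) ∩ NN_k(i; B)| / k`). Symmetric in the two maps.
#'
#' @param mapA,mapB [EmbeddingMap-class] objects or coordinate matrices over
#'   the same ordered samples.
#' @param k neighbourhood size (default 20); must be below the sample count.
#' @return named numeric vector of percentages in \[0, 100\].
#' @export
perSampleOverlap <- function(mapA, mapB, k = 20) {
  asRanks <- function(x) {
    if (is.matrix(x) && nrow(x) == ncol(x) && anyNA(diag(x))) x
    else neighborRanks(x)
  }
  ra <- asRanks(mapA)
  rb <- asRanks(mapB)
  n <- nrow(ra)
  if (!identical(dim(ra), dim(rb)))
    stop("maps must cover the same sample set")
  if (k >= n) stop("k must be below the sample count")
  out <- vapply(seq_len(n), function(i)
    100 * sum(ra[i, ] <= k & rb[i, ] <= k, na.rm = TRUE) / k, numeric(1))
  names(out) <- rownames(ra)
  out
}

#' Contribution analysis over all data-type combinations
#'
#' Embeds every proper non-empty combination of the cohort's data types
#' (14 for four types) with the same restart budget and perplexity as the
#' reference full-combination map, and records each sample's k-NN overlap
#' with the reference. Rows of the resulting matrix are per-sample
#' "genomic profiles" of which data types drive the sample's neighbourhood.
#'
#' @param cohort a normalized [MultiOmicsCohort-class].
#' @param referenceMap optional precomputed full-combination
#'   [EmbeddingMap-class]; built if absent.
#' @param k neighbourhood size (default 20).
#' @param nComponents,nRestarts,perplexity,seed,maxIter embedding settings,
#'   applied identically to every combination (each with its own seed
#'   fan-out) so comparisons are like-for-like.
#' @return an [OverlapProfile-class] (profile labels not yet assigned).
#' @export
contributionAnalysis <- function(cohort, referenceMap = NULL, k = 20,
                                 nComponents = 50, nRestarts = 1,
                                 perplexity = NULL, seed = 0,
                                 maxIter = 1000) {
  types <- names(omicsDatasets(cohort))
  if (is.null(referenceMap))
    referenceMap <- runIntegration(cohort, types, nComponents = nComponents,
                                   nRestarts = nRestarts,
                                   perplexity = perplexity, seed = seed,
                                   maxIter = maxIter)
  combos <- enumerateCombinations(types)
  refRanks <- neighborRanks(referenceMap)
  cols <- vapply(seq_along(combos), function(ci) {
    m <- runIntegration(cohort, combos[[ci]], nComponents = nComponents,
                        nRestarts = nRestarts, perplexity = perplexity,
                        seed = seed + ci * 1000L, maxIter = maxIter)
    perSampleOverlap(neighborRanks(m), refRanks, k = k)
  }, numeric(nrow(mapCoords(referenceMap))))
  colnames(cols) <- vapply(combos, combinationName, character(1))
  rownames(cols) <- sampleIDs(referenceMap)
  new("OverlapProfile", overlap = cols, combinations = combos,
      k = as.integer(k))
}

#' Cluster samples into genomic profiles
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) of the
#' per-sample overlap rows, cut into `nProfiles` flat clusters.
#'
#' @param op an [OverlapProfile-class].
#' @param nProfiles number of profiles (default 5).
#' @return the profile with `profileLabels` assigned.
#' @export
profileClusters <- function(op, nProfiles = 5) {
  m <- overlapMatrix(op)
  if (nProfiles > nrow(m)) stop("nProfiles exceeds the sample count")
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  op@profileLabels <- stats::cutree(hc, k = nProfiles)
  op
}

#' Hypergeometric enrichment of labels within genomic profiles
#'
#' @param op an [OverlapProfile-class] with profiles assigned.
#' @param labels per-sample categories.
#' @param alpha significance level (default 0.001).
#' @return data.frame as from [enrichClusters()].
#' @export
profileEnrichment <- function(op, labels, alpha = 0.001) {
  if (!length(profileLabels(op)))
    stop("run profileClusters() first")
  enrichClusters(profileLabels(op), labels, alpha = alpha)
}

#' Map stability over random restarts
#'
#' Re-embeds the full combination `nRuns` times with seeds `seed + 1` ...
#' `seed + nRuns` and reports each sample's mean k-NN overlap with the
#' reference map; samples whose mean overlap falls below `threshold`
#' percent are flagged as having no consistent neighbourhood.
#'
#' @param cohort a normalized [MultiOmicsCohort-class].
#' @param referenceMap the reference [EmbeddingMap-class]; built if absent.
#' @param nRuns number of reruns (default 100, >= 2).
#' @param k neighbourhood size (default 20).
#' @param threshold consistency threshold in percent (default 20).
#' @param seed base seed; run `r` uses `seed + r`.
#' @param ... embedding settings passed to [runIntegration()].
#' @return list with `meanOverlap` (per sample, percent), `consistent`
#'   (logical), `nRuns` and the overall `averageOverlap`.
#' @export
mapStability <- function(cohort, referenceMap = NULL, nRuns = 100, k = 20,
                         threshold = 20, seed = 0, ...) {
  if (nRuns < 2) stop("nRuns must be at least 2")
  types <- names(omicsDatasets(cohort))
  if (is.null(referenceMap))
    referenceMap <- runIntegration(cohort, types, seed = seed, ...)
  refRanks <- neighborRanks(referenceMap)
  acc <- matrix(0, nrow(refRanks), nRuns)
  for (r in seq_len(nRuns)) {
    m <- runIntegration(cohort, types, seed = seed + r, nRestarts = 1, ...)
    acc[, r] <- perSampleOverlap(neighborRanks(m), refRanks, k = k)
  }
  mo <- rowMeans(acc)
  names(mo) <- rownames(refRanks)
  list(meanOverlap = mo, consistent = mo >= threshold, nRuns = nRuns,
       averageOverlap = mean(mo))
}
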