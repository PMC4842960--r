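#' @include AllClasses.R AllGenerics.R
NULL

#' Specification for a synthetic multi-omic cohort
#'
#' Describes a cohort with known ground truth: latent sample clusters whose
#' separation is planted only in configurable subsets of the data types
#' ("drivers"), type-appropriate marginals, sex-linked features, scattered
#' missing values, planted out-of-tissue samples, and cluster-linked
#' survival.
#'
#' @param nClusters number of latent clusters (default 3).
#' @param samplesPerCluster samples per cluster; scalar or per-cluster
#'   vector (default 50).
#' @param featureCounts named vector of features per data type (default
#'   `c(GE = 300, ME = 200, CN = 200, MIR = 60)`).
#' @param drivers list, one non-empty character vector of data types per
#'   cluster; a cluster is separated from the common center only in its
#'   driver types (default: all types drive every cluster).
#' @param effectSize between-cluster mean shift, in within-cluster standard
#'   deviation units, applied on the latent scale of driver types
#'   (default 4).
#' @param missingRate fraction of cells set missing, in \[0, 1)
#'   (default 0.02).
#' @param sexFeatureFraction fraction of features placed on chromosome X/Y
#'   with a sex-linked latent shift (default 0.05).
#' @param sexShift latent mean shift of male samples on sex-chromosome
#'   features (default 2).
#' @param nCOPs planted out-of-tissue samples (default 0): members of
#'   `copSource` that carry `copTarget`'s latent signal in every data type
#'   while keeping the source tissue label.
#' @param copSource,copTarget source and target clusters for planted COPs.
#' @param eventRates per-cluster exponential event rates (1/days); default
#'   `1 / (300 * cluster index)` so later clusters survive longer.
#' @param censorWindow uniform censoring window in days (default 1825).
#' @param seed RNG seed (default 0).
#' @return a validated spec (list) for [generateCohort()].
#' @export
synthSpec <- function(nClusters = 3, samplesPerCluster = 50,
                      featureCounts = c(GE = 300, ME = 200, CN = 200,
                                        MIR = 60),
                      drivers = NULL, effectSize = 4, missingRate = 0.02,
                      sexFeatureFraction = 0.05, sexShift = 2,
                      nCOPs = 0, copSource = 1, copTarget = 2,
                      eventRates = NULL, censorWindow = 1825, seed = 0) {
  if (length(samplesPerCluster) == 1L)
    samplesPerCluster <- rep(samplesPerCluster, nClusters)
  stopifnot(length(samplesPerCluster) == nClusters,
            all(names(featureCounts) %in% OMIC_TYPES),
            effectSize >= 0, missingRate >= 0, missingRate < 1)
  if (is.null(drivers))
    drivers <- rep(list(names(featureCounts)), nClusters)
  stopifnot(length(drivers) == nClusters, all(lengths(drivers) > 0),
            all(unlist(drivers) %in% names(featureCounts)))
  if (is.null(eventRates)) eventRates <- 1 / (300 * seq_len(nClusters))
  stopifnot(length(eventRates) == nClusters, all(eventRates > 0))
  if (nCOPs > 0) {
    stopifnot(copSource != copTarget, copSource <= nClusters,
              copTarget <= nClusters)
    if (nCOPs > samplesPerCluster[copSource])
      stop("more planted COPs than samples in the source cluster")
  }
  list(nClusters = nClusters, samplesPerCluster = samplesPerCluster,
       featureCounts = featureCounts, drivers = drivers,
       effectSize = effectSize, missingRate = missingRate,
       sexFeatureFraction = sexFeatureFraction, sexShift = sexShift,
       nCOPs = nCOPs, copSource = copSource, copTarget = copTarget,
       eventRates = eventRates, censorWindow = censorWindow, seed = seed)
}

#' Generate a synthetic multi-omic cohort with ground truth
#'
#' Latent per-type Gaussian signals (unit within-cluster SD) are shifted by
#' cluster centers drawn only in each cluster's driver types (non-driver
#' types share a common center, i.e. carry no separation), then emitted on
#' each type's natural scale: GE and MIR as exponentiated counts (>= 0,
#' `2^(baseline + signal) - 1`), ME as logistic-squashed values in (0, 1),
#' CN as `2 * 2^(0.3 * signal)` (positive, centered near diploid). A
#' fraction of features is placed on chromosome X/Y with a sex-linked
#' shift; cells go missing at the configured rate; planted COP samples copy
#' the target cluster's latent signal in every type while keeping the
#' source tissue label; survival times are exponential per true cluster
#' with uniform censoring.
#'
#' @param spec a [synthSpec()].
#' @return list with `cohort` (a raw, un-normalized
#'   [MultiOmicsCohort-class]) and `truth` (data.frame: `sample`,
#'   `trueCluster` — the cluster whose signal the sample carries,
#'   `labelCluster` — the annotated tissue's cluster, `plantedCOP`,
#'   `sourceCluster`; attribute `drivers` holds the per-cluster driver
#'   sets).
#' @examples
#' gen <- generateCohort(synthSpec(nClusters = 2, samplesPerCluster = 10,
#'                                 featureCounts = c(GE = 40, MIR = 20)))
#' gen$cohort
#' @export
generateCohort <- function(spec) {
  set.seed(spec$seed)
  nc <- spec$nClusters
  nPer <- spec$samplesPerCluster
  n <- sum(nPer)
  labelCluster <- rep(seq_len(nc), nPer)
  trueCluster <- labelCluster
  plantedCOP <- rep(FALSE, n)
  if (spec$nCOPs > 0) {
    copIdx <- which(labelCluster == spec$copSource)[seq_len(spec$nCOPs)]
    trueCluster[copIdx] <- spec$copTarget
    plantedCOP[copIdx] <- TRUE
  }
  ids <- sprintf("S%03d", seq_len(n))
  sex <- sample(c("male", "female"), n, replace = TRUE)

  datasets <- list()
  for (type in names(spec$featureCounts)) {
    F <- spec$featureCounts[[type]]
    feats <- sprintf("%s_%04d", tolower(type), seq_len(F))
    nSex <- round(F * spec$sexFeatureFraction)
    chrom <- c(
      if (nSex > 0) sample(c("X", "Y"), nSex, replace = TRUE,
                           prob = c(0.8, 0.2)),
      as.character(sample(1:22, F - nSex, replace = TRUE)))
    names(chrom) <- feats
    # cluster centers: drawn only where this type drives the cluster
    mu <- matrix(0, nc, F)
    for (c in seq_len(nc))
      if (type %in% spec$drivers[[c]])
        mu[c, ] <- spec$effectSize * stats::rnorm(F)
    G <- mu[trueCluster, , drop = FALSE] +
      matrix(stats::rnorm(n * F), n, F)
    sexFeat <- which(chrom[feats] %in% c("X", "Y"))
    if (length(sexFeat))
      G[sex == "male", sexFeat] <- G[sex == "male", sexFeat] + spec$sexShift
    v <- switch(type,
      GE  = pmax(2^(matrix(stats::runif(F, 5, 10), n, F, byrow = TRUE) + G) - 1, 0),
      MIR = pmax(2^(matrix(stats::runif(F, 3, 8), n, F, byrow = TRUE) + G) - 1, 0),
      ME  = stats::plogis(matrix(stats::runif(F, -2, 2), n, F, byrow = TRUE) + G),
      CN  = 2 * 2^(0.3 * G))
    if (spec$missingRate > 0) {
      miss <- matrix(stats::runif(n * F) < spec$missingRate, n, F)
      # never blank out a whole sample
      full <- rowSums(!miss) == 0L
      miss[full, 1L] <- FALSE
      v[miss] <- NA_real_
    }
    dimnames(v) <- list(ids, feats)
    datasets[[type]] <- OmicsDataset(v, type, chromosome = chrom)
  }

  rate <- spec$eventRates[trueCluster]
  eventTime <- stats::rexp(n, rate)
  censTime <- stats::runif(n, 0, spec$censorWindow)
  clinical <- data.frame(
    sample_id = ids,
    tissue = paste0("T", labelCluster),
    sex = sex,
    age = round(stats::runif(n, 40, 80)),
    osDays = pmin(eventTime, censTime),
    osEvent = eventTime <= censTime,
    row.names = ids)
  truth <- data.frame(sample = ids, trueCluster = trueCluster,
                      labelCluster = labelCluster, plantedCOP = plantedCOP,
                      sourceCluster = ifelse(plantedCOP, spec$copSource, NA),
                      row.names = NULL)
  attr(truth, "drivers") <- spec$drivers
  list(cohort = new("MultiOmicsCohort", datasets = datasets,
                    clinical = clinical),
       truth = truth)
}

#' Deterministic worked example
#'
#' A fixed 8-sample toy with two 2D maps plus 6-subject survival data, small
#' enough that every derived quantity can be checked by hand: the neighbour
#' ranks of map X, the local-similarity score between the two maps at
#' `kx = ky = 2`, the upper-tail hypergeometric p for a 4-sample cluster
#' containing 3 of the cohort's 4 label-A samples, and the two-group
#' log-rank statistic. All values are recomputed from the inputs at call
#' time; the construction is deterministic, so repeated calls are
#' identical.
#'
#' @return list with `mapX`, `mapY`, `ranksX`, `similarity`,
#'   `hypergeometricP`, `logrank`, `survivalToy`.
#' @export
workedExample <- function() {
  ids <- paste0("s", 1:8)
  mapX <- matrix(c(0, 0,  0, 1,  1, 0,  1, 1,
                   10, 0, 10, 1, 11, 0, 11, 1),
                 ncol = 2, byrow = TRUE, dimnames = list(ids, c("x", "y")))
  # map Y swaps s4 and s5 across the two blobs
  mapY <- mapX
  mapY[c(4, 5), ] <- mapX[c(5, 4), ]
  sim <- localSimilarity(mapX, mapY, kx = 2, ky = 2)
  # cluster of 4 holding 3 of the 4 label-A samples in a cohort of 8
  hg <- stats::phyper(3 - 1, 4, 4, 4, lower.tail = FALSE)
  survivalToy <- data.frame(
    time = c(1, 2, 3, 4, 5, 6),
    event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    group = c("a", "a", "a", "b", "b", "b"))
  lr <- kmLogrank(survivalToy, survivalToy$group)
  list(mapX = mapX, mapY = mapY, ranksX = neighborRanks(mapX),
       similarity = sim, hypergeometricP = hg,
       logrank = list(chisq = lr$chisq, p = lr$p),
       survivalToy = survivalToy)
}
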