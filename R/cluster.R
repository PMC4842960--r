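#' @include AllClasses.R AllGenerics.R
NULL

#' Density-based clustering of a map
#'
#' Classic density-reachability clustering: points with at least
#' `minSamples` neighbours (self included) within radius `eps` are core
#' points; clusters are grown by expanding density-reachable core points,
#' border points join the first cluster that reaches them, and everything
#' else is noise (label 0). Suited to embedding and component maps because
#' it follows sample density rather than imposing cluster shape. The mean
#' silhouette width over clustered samples and the noise fraction are
#' recorded on the result.
#'
#' @param coords samples x m coordinate matrix or [EmbeddingMap-class].
#' @param eps density radius (> 0).
#' @param minSamples minimum neighbourhood occupancy for a core point
#'   (default 5).
#' @return a [ClusterAssignment-class].
#' @export
dbscanCluster <- function(coords, eps, minSamples = 5) {
  coords <- asCoords(coords)
  if (eps <= 0) stop("eps must be positive")
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # incl. self
  core <- lengths(nbrs) >= minSamples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nbrs[[i]]
    while (length(frontier)) {
      j <- frontier[1L]; frontier <- frontier[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- c(frontier, nbrs[[j]][labels[nbrs[[j]]] == 0L])
      }
    }
  }
  names(labels) <- rownames(coords)
  clustered <- labels != 0L
  sil <- NA_real_
  if (length(unique(labels[clustered])) >= 2L)
    sil <- mean(cluster::silhouette(labels[clustered],
                                    stats::dist(coords[clustered, , drop = FALSE]))[, 3L])
  new("ClusterAssignment", labels = labels, eps = eps,
      minSamples = as.integer(minSamples), silhouette = sil,
      noiseFraction = mean(!clustered))
}

#' Davies-Bouldin index
#'
#' Diagnostic cluster-quality index (lower is better): the mean over
#' clusters of the worst ratio of summed within-cluster scatter to centroid
#' separation.
#'
#' @param coords coordinate matrix.
#' @param labels integer cluster labels; 0 (noise) is ignored.
#' @return the index, or `NA` with fewer than two clusters.
#' @export
daviesBouldin <- function(coords, labels) {
  coords <- asCoords(coords)
  keep <- labels != 0L
  coords <- coords[keep, , drop = FALSE]; labels <- labels[keep]
  cls <- sort(unique(labels))
  if (length(cls) < 2L) return(NA_real_)
  cent <- t(vapply(cls, function(c)
    colMeans(coords[labels == c, , drop = FALSE]), numeric(ncol(coords))))
  scat <- vapply(seq_along(cls), function(ci) {
    pts <- coords[labels == cls[ci], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2L, cent[ci, ])^2)))
  }, numeric(1))
  dbi <- vapply(seq_along(cls), function(i) {
    max(vapply(seq_along(cls)[-i], function(j) {
      (scat[i] + scat[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }, numeric(1))
  mean(dbi)
}

#' Select the density radius by silhouette under a noise cap
#'
#' Scans a grid of `eps` values; among those yielding at least two clusters
#' and at most `maxNoise` non-clustering samples, returns the one maximizing
#' the mean silhouette width of clustered samples. Exact ties go to the
#' smaller `eps`. The default grid is 50 log-spaced values between the 1st
#' and 50th percentile of pairwise distances.
#'
#' @param coords coordinate matrix or [EmbeddingMap-class].
#' @param epsGrid candidate radii (default as described).
#' @param minSamples core-point occupancy (default 5).
#' @param maxNoise maximum admissible noise fraction (default 0.10).
#' @return list with `eps`, the winning [ClusterAssignment-class]
#'   (`assignment`), and the scanned `grid` diagnostics (eps, nClusters,
#'   noiseFraction, silhouette, daviesBouldin).
#' @export
selectEps <- function(coords, epsGrid = NULL, minSamples = 5,
                      maxNoise = 0.10) {
  coords <- asCoords(coords)
  if (is.null(epsGrid)) {
    d <- stats::dist(coords)
    qs <- stats::quantile(d, c(0.01, 0.50))
    if (qs[1L] <= 0) qs[1L] <- min(d[d > 0])
    epsGrid <- exp(seq(log(qs[1L]), log(qs[2L]), length.out = 50))
  }
  if (!length(epsGrid)) stop("epsGrid must be non-empty")
  epsGrid <- sort(epsGrid)
  rows <- lapply(epsGrid, function(e) {
    a <- dbscanCluster(coords, e, minSamples)
    data.frame(eps = e,
               nClusters = length(setdiff(unique(clusterLabels(a)), 0L)),
               noiseFraction = noiseFraction(a),
               silhouette = silhouetteWidth(a),
               daviesBouldin = daviesBouldin(coords, clusterLabels(a)))
  })
  grid <- do.call(rbind, rows)
  ok <- grid$nClusters >= 2L & grid$noiseFraction <= maxNoise &
        !is.na(grid$silhouette)
  if (!any(ok)) {
    bi <- which.max(ifelse(is.na(grid$silhouette), -Inf, grid$silhouette))
    stop(sprintf(
      paste0("no eps in the grid yields >= 2 clusters within the noise cap; ",
             "best candidate: eps = %.4g, noise = %.3f, silhouette = %.3f"),
      grid$eps[bi], grid$noiseFraction[bi], grid$silhouette[bi]))
  }
  cand <- grid[ok, ]
  best <- cand$eps[which.max(cand$silhouette)]  # first max -> smallest eps
  list(eps = best, assignment = dbscanCluster(coords, best, minSamples),
       grid = grid)
}

#' Cluster-label enrichment by the hypergeometric test
#'
#' For every (cluster, label) pair, the upper-tail hypergeometric
#' probability of observing at least the seen overlap, given the cluster
#' size, the label's cohort total and the cohort size. Noise (label 0) is
#' never treated as a cluster.
#'
#' @param assignment a [ClusterAssignment-class] (or integer label vector,
#'   0 = noise).
#' @param labels per-sample categories covering all samples.
#' @param alpha significance level for the `significant` flag
#'   (default 0.001).
#' @return data.frame with columns `cluster`, `label`, `overlap`,
#'   `clusterSize`, `labelTotal`, `cohortSize`, `p`, `significant`.
#' @export
enrichClusters <- function(assignment, labels, alpha = 0.001) {
  cl <- if (is(assignment, "ClusterAssignment")) clusterLabels(assignment)
        else as.integer(assignment)
  labels <- as.character(labels)
  if (length(cl) != length(labels))
    stop("labels must cover all samples")
  N <- length(cl)
  out <- list()
  for (c in sort(setdiff(unique(cl), 0L))) {
    inC <- cl == c
    for (lb in sort(unique(labels))) {
      inL <- labels == lb
      q <- sum(inC & inL)
      p <- stats::phyper(q - 1, sum(inL), N - sum(inL), sum(inC),
                         lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        cluster = c, label = lb, overlap = q, clusterSize = sum(inC),
        labelTotal = sum(inL), cohortSize = N, p = p,
        significant = p < alpha)
    }
  }
  do.call(rbind, out)
}

#' Detect samples outside their tissue-of-origin cluster
#'
#' A sample is called a COP ("cancer outside primary") when its own tissue
#' label is not among the significantly enriched labels of its assigned
#' cluster. Noise samples are COPs by definition (they sit outside every
#' cluster) and are attributed to the nearest cluster centroid for typing.
#' A COP whose (attributed) cluster has at least one enriched label -- some
#' other tissue's cluster -- is type I; a COP in a cluster with no enriched
#' label is a type II candidate (see [dissectCOP2()]).
#'
#' @param assignment a [ClusterAssignment-class].
#' @param enrichment output of [enrichClusters()] at the configured alpha.
#' @param labels per-sample tissue labels.
#' @param coords optional coordinates, required to attribute noise samples
#'   to their nearest cluster centroid.
#' @return data.frame with columns `sample`, `tissue`, `cluster`
#'   (0 = noise), `attributedCluster`, `enrichedLabels`
#'   (comma-separated), `copType` (`NONE`, `COP_I`, `COP_II`).
#' @export
detectCOPs <- function(assignment, enrichment, labels, coords = NULL) {
  cl <- clusterLabels(assignment)
  labels <- as.character(labels)
  enr <- split(enrichment$label[enrichment$significant],
               enrichment$cluster[enrichment$significant])
  attributed <- cl
  if (any(cl == 0L)) {
    if (is.null(coords))
      stop("coords are required to attribute noise samples to a cluster")
    coords <- asCoords(coords)
    cls <- sort(setdiff(unique(cl), 0L))
    cent <- t(vapply(cls, function(c)
      colMeans(coords[cl == c, , drop = FALSE]), numeric(ncol(coords))))
    for (i in which(cl == 0L)) {
      dd <- sqrt(rowSums(sweep(cent, 2L, coords[i, ])^2))
      attributed[i] <- cls[which.min(dd)]
    }
  }
  copType <- character(length(cl))
  for (i in seq_along(cl)) {
    own <- cl[i]
    enrichedOwn <- if (own == 0L) character(0)
                   else enr[[as.character(own)]]
    if (own != 0L && labels[i] %in% enrichedOwn) {
      copType[i] <- "NONE"
    } else {
      enrichedAttr <- enr[[as.character(attributed[i])]]
      copType[i] <- if (length(enrichedAttr)) "COP_I" else "COP_II"
    }
  }
  data.frame(
    sample = if (!is.null(names(cl))) names(cl) else seq_along(cl),
    tissue = labels, cluster = cl, attributedCluster = attributed,
    enrichedLabels = vapply(attributed, function(c) {
      e <- enr[[as.character(c)]]
      if (length(e)) paste(e, collapse = ",") else ""
    }, character(1)),
    copType = copType, row.names = NULL)
}

#' Dissect COP samples in isolation
#'
#' Reruns the full integration pipeline on the COP samples alone, clusters
#' the resulting map, and re-tests tissue enrichment: clusters of COPs with
#' no single enriched tissue are confirmed type II groups. With fewer than
#' ten COPs the dissection is skipped with a warning and the input calls are
#' returned unchanged.
#'
#' @param cohort the normalized [MultiOmicsCohort-class].
#' @param copCalls output of [detectCOPs()].
#' @param minSamples,maxNoise clustering parameters (see [selectEps()]).
#' @param alpha enrichment significance level (default 0.001).
#' @param ... passed to [runIntegration()] (e.g. `nRestarts`, `seed`).
#' @return list with `calls` (copCalls with a `confirmedType` column) and,
#'   when run, `assignment` and `enrichment` of the isolation rerun.
#' @export
dissectCOP2 <- function(cohort, copCalls, minSamples = 5, maxNoise = 0.10,
                        alpha = 0.001, ...) {
  copIdx <- copCalls$copType != "NONE"
  copIDs <- copCalls$sample[copIdx]
  calls <- copCalls
  calls$confirmedType <- calls$copType
  if (sum(copIdx) < 10L) {
    warning("fewer than 10 COP samples; isolation rerun skipped")
    return(list(calls = calls))
  }
  sub <- subsetCohort(cohort, as.character(copIDs))
  map <- runIntegration(sub, ...)
  sel <- selectEps(mapCoords(map), minSamples = minSamples,
                   maxNoise = maxNoise)
  tissues <- clinicalData(sub)$tissue
  enr <- enrichClusters(sel$assignment, tissues, alpha = alpha)
  enrBy <- split(enr$significant, enr$cluster)
  cl <- clusterLabels(sel$assignment)
  at <- match(sampleIDs(sub), calls$sample)
  confirmed <- vapply(seq_along(cl), function(i) {
    # non-clustering samples keep their prior candidate call
    if (cl[i] == 0L) return(calls$copType[at[i]])
    if (any(enrBy[[as.character(cl[i])]])) "COP_I" else "COP_II"
  }, character(1))
  calls$confirmedType[at] <- confirmed
  list(calls = calls, assignment = sel$assignment, enrichment = enr)
}

#' Subset a cohort by sample IDs
#'
#' @param cohort a [MultiOmicsCohort-class].
#' @param ids sample IDs to keep, in the requested order.
#' @return the subsetted cohort.
#' @export
subsetCohort <- function(cohort, ids) {
  stopifnot(all(ids %in% sampleIDs(cohort)))
  ds <- lapply(omicsDatasets(cohort), function(d) {
    d@values <- d@values[ids, , drop = FALSE]
    d
  })
  new("MultiOmicsCohort", datasets = ds,
      clinical = clinicalData(cohort)[ids, , drop = FALSE])
}
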