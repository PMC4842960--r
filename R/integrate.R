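#' @include AllClasses.R AllGenerics.R
NULL

#' Reduce one data type to its top principal components
#'
#' Projects the feature-centered matrix onto its leading principal axes and
#' records the component variances (eigenvalues) in decreasing order.
#' Alternatively, `retainVariance` selects the smallest number of components
#' whose cumulative variance fraction reaches the given level.
#'
#' @param ds a normalized [OmicsDataset-class].
#' @param nComponents number of components to retain (default 50); must not
#'   exceed `min(samples - 1, features)`.
#' @param retainVariance if non-`NULL`, a fraction in (0, 1\]; overrides
#'   `nComponents`.
#' @return a [ReducedBlock-class].
#' @export
reduceBlock <- function(ds, nComponents = 50, retainVariance = NULL) {
  v <- omicsValues(ds)
  if (anyNA(v)) stop("matrix contains missing values; impute first")
  dmax <- min(nrow(v) - 1L, ncol(v))
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (!is.null(retainVariance)) {
    stopifnot(retainVariance > 0, retainVariance <= 1)
    nComponents <- which(cumsum(ev) / sum(ev) >= retainVariance)[1L]
  } else if (nComponents > dmax) {
    stop("nComponents = ", nComponents,
         " exceeds the rank bound; admissible maximum is ", dmax)
  }
  d <- min(nComponents, dmax)
  new("ReducedBlock", dataType = dataType(ds),
      scores = pc$x[, seq_len(d), drop = FALSE],
      eigenvalues = ev[seq_len(d)], scaleFactor = 1)
}

#' Balance a block's variance
#'
#' Divides the scores by the square root of the total retained variance, so
#' every block contributes total variance exactly 1 to the integrated space
#' regardless of its original feature count -- no data type can dominate.
#'
#' @param block a [ReducedBlock-class].
#' @return the scaled block; `scaleFactor` records the division.
#' @export
scaleBlock <- function(block) {
  tot <- sum(block@eigenvalues)
  if (tot <= 0) stop("block has zero total variance")
  f <- 1 / sqrt(tot)
  block@scores <- block@scores * f
  block@eigenvalues <- block@eigenvalues * f^2
  block@scaleFactor <- block@scaleFactor * f
  block
}

#' Concatenate scaled blocks into the integrated space
#'
#' Columns are appended in the canonical data-type order GE, ME, CN, MIR
#' (blocks of other orders are reordered), and each block's column span is
#' recorded.
#'
#' @param blocks list of [ReducedBlock-class] objects over the same samples.
#' @return an [IntegratedMatrix-class].
#' @export
concatenateBlocks <- function(blocks) {
  types <- vapply(blocks, function(b) b@dataType, character(1))
  blocks <- blocks[order(match(types, OMIC_TYPES))]
  types <- types[order(match(types, OMIC_TYPES))]
  ids <- rownames(blocks[[1L]]@scores)
  for (b in blocks)
    if (!identical(rownames(b@scores), ids))
      stop("blocks do not share an identical, ordered sample set")
  vals <- do.call(cbind, lapply(blocks, function(b) b@scores))
  spans <- list(); at <- 0L
  for (i in seq_along(blocks)) {
    w <- ncol(blocks[[i]]@scores)
    spans[[types[i]]] <- at + seq_len(w)
    at <- at + w
  }
  colnames(vals) <- unlist(lapply(seq_along(blocks), function(i)
    paste0(types[i], ".PC", seq_len(ncol(blocks[[i]]@scores)))))
  new("IntegratedMatrix", values = vals, blockSpans = spans)
}

#' Build the integrated matrix for a data-type combination
#'
#' Composes [reduceBlock()] and [scaleBlock()] over the requested types of a
#' normalized cohort and concatenates the results. With all four types at
#' the default 50 components this yields a 200-dimensional space.
#'
#' @param cohort a normalized [MultiOmicsCohort-class].
#' @param combination character vector of data types (default: all present).
#' @param nComponents components per type (default 50); silently capped at
#'   each type's rank bound `min(samples - 1, features)`.
#' @param retainVariance optional variance fraction overriding `nComponents`.
#' @return an [IntegratedMatrix-class].
#' @export
integrateCohort <- function(cohort, combination = names(omicsDatasets(cohort)),
                            nComponents = 50, retainVariance = NULL) {
  if (!length(combination)) stop("combination must be non-empty")
  missing <- setdiff(combination, names(omicsDatasets(cohort)))
  if (length(missing))
    stop("data types not in cohort: ", paste(missing, collapse = ", "))
  blocks <- lapply(omicsDatasets(cohort)[combination], function(d) {
    dmax <- min(nrow(omicsValues(d)) - 1L, ncol(omicsValues(d)))
    scaleBlock(reduceBlock(d, nComponents = min(nComponents, dmax),
                           retainVariance = retainVariance))
  })
  concatenateBlocks(blocks)
}

#' Embed samples into a low-dimensional map
#'
#' Runs `nRestarts` independent t-SNE embeddings with seeds `seed`,
#' `seed + 1`, ... and keeps the restart with the lowest final
#' Kullback-Leibler divergence. The embedding uses exact gradients with the
#' standard early-exaggeration and momentum schedule.
#'
#' @param x an [IntegratedMatrix-class] or a numeric samples x D matrix with
#'   sample rownames.
#' @param dims output dimensionality (default 2).
#' @param nRestarts number of random restarts (default 1).
#' @param perplexity Gaussian neighbourhood size; default 30, or `n / 10`
#'   for cohorts under 100 samples; must be below `n / 3`.
#' @param seed integer seed of the first restart.
#' @param maxIter gradient iterations per restart (default 1000).
#' @param eta learning rate (default 200).
#' @param combination data types recorded on the map (taken from `x` when it
#'   is an [IntegratedMatrix-class]).
#' @return an [EmbeddingMap-class] carrying the winning restart's
#'   coordinates, KL divergence and seed.
#' @export
embedMap <- function(x, dims = 2, nRestarts = 1, perplexity = NULL,
                     seed = 0, maxIter = 1000, eta = 200,
                     combination = NULL) {
  if (is(x, "IntegratedMatrix")) {
    if (is.null(combination)) combination <- names(x@blockSpans)
    x <- x@values
  }
  if (is.null(combination)) combination <- "custom"
  n <- nrow(x)
  if (is.null(perplexity))
    perplexity <- if (n < 100) max(2, n / 10) else 30
  if (perplexity >= n / 3)
    stop("perplexity must be below n/3 = ", n / 3)
  if (nRestarts < 1) stop("nRestarts must be at least 1")
  best <- NULL
  for (r in seq_len(nRestarts)) {
    s <- seed + r - 1
    set.seed(s)
    Y0 <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
    fit <- .tsneCpp(x, Y0, perplexity = perplexity, maxIter = maxIter,
                    eta = eta, exaggeration = 12,
                    stopLying = min(250L, maxIter %/% 3L),
                    momSwitch = min(250L, maxIter %/% 3L),
                    thetaMomStart = 0.5, thetaMomFinal = 0.8)
    if (is.null(best) || fit$kl < best$kl) best <- c(fit, seed = s)
  }
  coords <- best$Y
  rownames(coords) <- rownames(x)
  colnames(coords) <- paste0("dim", seq_len(dims))
  new("EmbeddingMap", combination = combination, coordinates = coords,
      klDivergence = best$kl, seed = best$seed, perplexity = perplexity)
}

#' Run the full integration pipeline
#'
#' Composes per-type PCA reduction, variance balancing, concatenation and
#' multi-restart embedding over exactly the requested data types, returning
#' the map of the lowest-KL restart.
#'
#' @inheritParams integrateCohort
#' @inheritParams embedMap
#' @return an [EmbeddingMap-class] with the combination recorded.
#' @export
runIntegration <- function(cohort, combination = names(omicsDatasets(cohort)),
                           nComponents = 50, retainVariance = NULL,
                           dims = 2, nRestarts = 1, perplexity = NULL,
                           seed = 0, maxIter = 1000) {
  im <- integrateCohort(cohort, combination, nComponents = nComponents,
                        retainVariance = retainVariance)
  embedMap(im, dims = dims, nRestarts = nRestarts, perplexity = perplexity,
           seed = seed, maxIter = maxIter, combination = combination)
}
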