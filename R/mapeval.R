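#' @include AllClasses.R AllGenerics.R
NULL

asCoords <- function(x) {
  if (is(x, "EmbeddingMap")) return(mapCoords(x))
  if (is(x, "IntegratedMatrix")) return(x@values)
  as.matrix(x)
}

#' Per-sample distance ranks
#'
#' For every sample `i`, ranks all other samples by Euclidean distance:
#' the nearest neighbour has rank 1, the second nearest rank 2, and so on.
#' Ties are broken by ascending sample index, so ranks are deterministic.
#'
#' @param coords samples x m coordinate matrix (or an
#'   [EmbeddingMap-class] / [IntegratedMatrix-class]).
#' @return an n x n integer matrix of ranks with `NA` on the diagonal; each
#'   off-diagonal row is a permutation of `1..n-1`.
#' @export
neighborRanks <- function(coords) {
  coords <- asCoords(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least two samples")
  d <- as.matrix(stats::dist(coords))
  r <- matrix(NA_integer_, n, n, dimnames = dimnames(d))
  for (i in seq_len(n)) {
    di <- d[i, -i]
    r[i, -i] <- rank(di, ties.method = "first")
  }
  r
}

#' Local-similarity score between two maps
#'
#' A scale-dependent measure of how well two embeddings of the same samples
#' agree locally. With \eqn{r^x_{ij}} the rank of sample `j`'s distance to
#' sample `i` in map X (nearest = 1) and analogously \eqn{r^y_{ij}} in map Y,
#' the score is
#' \deqn{s_{x,y}(k_x, k_y) = \frac{1}{n\,\min(k_x, k_y)} \sum_i \sum_{j \ne i}
#'   \mathbf{1}[r^x_{ij} \le k_x \wedge r^y_{ij} \le k_y],}
#' which lies in \[0, 1\] and equals 1 exactly when, for every sample, its
#' \eqn{k_x} nearest neighbours in X are among its \eqn{k_y} nearest in Y or
#' vice versa. It is symmetric under exchanging (X, kx) with (Y, ky).
#'
#' @param X,Y coordinate matrices over the same ordered samples (or
#'   [EmbeddingMap-class] objects), or precomputed [neighborRanks()]
#'   matrices.
#' @param kx,ky neighbourhood sizes, `1 <= k <= n - 1` (default 20).
#' @return list with `value` (the score), `kx`, `ky` and `n`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20)
#' localSimilarity(X, X, 5, 5)$value  # exactly 1
#' @export
localSimilarity <- function(X, Y, kx = 20, ky = 20) {
  isRanks <- function(m) is.matrix(m) && nrow(m) == ncol(m) && anyNA(diag(m))
  rx <- if (isRanks(X)) X else neighborRanks(X)
  ry <- if (isRanks(Y)) Y else neighborRanks(Y)
  n <- nrow(rx)
  if (!identical(dim(rx), dim(ry)) ||
      (!is.null(rownames(rx)) && !is.null(rownames(ry)) &&
       !identical(rownames(rx), rownames(ry))))
    stop("the two maps must cover the same ordered sample set")
  if (kx < 1 || ky < 1 || kx > n - 1 || ky > n - 1)
    stop("kx and ky must lie in [1, n - 1]")
  hits <- sum(rx <= kx & ry <= ky, na.rm = TRUE)
  list(value = hits / (n * min(kx, ky)), kx = kx, ky = ky, n = n)
}

#' Tissue-cohesion permutation test
#'
#' Tests, per label, whether samples sharing that label sit closer together
#' on the map than randomly chosen sample subsets of the same size. The
#' statistic is the mean pairwise within-label Euclidean distance; the null
#' is the same statistic over `nPerm` random subsets, and
#' `p = (1 + #\{null <= observed\}) / (1 + nPerm)` (add-one estimator, never
#' exactly zero).
#'
#' @param map an [EmbeddingMap-class] or coordinate matrix.
#' @param labels per-sample categories, same order as the map.
#' @param nPerm number of random subsets (default 999).
#' @param seed RNG seed.
#' @return data.frame with columns `label`, `n`, `observed`, `p`; labels
#'   with fewer than two samples are skipped with a warning.
#' @export
tissueCohesionTest <- function(map, labels, nPerm = 999, seed = 0) {
  coords <- asCoords(map)
  labels <- as.character(labels)
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  meanPairDist <- function(idx) mean(d[idx, idx][upper.tri(diag(length(idx)))])
  set.seed(seed)
  out <- lapply(unique(labels), function(lb) {
    idx <- which(labels == lb)
    if (length(idx) < 2L) {
      warning("label ", lb, " has fewer than two samples; skipped")
      return(NULL)
    }
    obs <- meanPairDist(idx)
    null <- replicate(nPerm, meanPairDist(sample.int(n, length(idx))))
    data.frame(label = lb, n = length(idx), observed = obs,
               p = (1 + sum(null <= obs)) / (1 + nPerm))
  })
  do.call(rbind, out)
}

#' Leave-one-out nearest-neighbour label prediction AUC
#'
#' Assesses how well sample labels can be predicted from the label of each
#' sample's closest neighbour. For every label, a one-vs-rest ROC curve is
#' built over all samples, scored by the margin
#' `d(i, nearest other-class) - d(i, nearest same-class)` (positive when the
#' nearest neighbour matches the class); the reported value is the macro
#' average of the per-label areas. Labels with a single sample are excluded
#' from their own curve (no same-class neighbour exists).
#'
#' @param coords coordinate matrix or [EmbeddingMap-class].
#' @param labels per-sample categories; at least two distinct labels.
#' @return list with `auc` (macro average), `perLabel` (named vector) and
#'   `construction` (a description of the scoring rule, so results are
#'   self-describing).
#' @export
nnLabelAUC <- function(coords, labels) {
  coords <- asCoords(coords)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("at least two distinct labels are required")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  n <- nrow(coords)
  aucOf <- function(score, positive) {
    # Mann-Whitney form: P(score_pos > score_neg) with ties counted 1/2
    r <- rank(score)
    n1 <- sum(positive); n0 <- sum(!positive)
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  labs <- unique(labels)
  per <- vapply(labs, function(lb) {
    inCls <- labels == lb
    if (sum(inCls) < 2L) return(NA_real_)
    dSame <- vapply(seq_len(n), function(i) {
      j <- which((labels == lb) & seq_len(n) != i)
      if (!length(j)) return(NA_real_)
      min(d[i, j])
    }, numeric(1))
    dOther <- vapply(seq_len(n), function(i)
      min(d[i, labels != lb]), numeric(1))
    margin <- dOther - dSame
    ok <- !is.na(margin)
    aucOf(margin[ok], inCls[ok])
  }, numeric(1))
  per <- per[!is.na(per)]
  list(auc = mean(per), perLabel = per,
       construction = paste(
         "macro-averaged one-vs-rest AUC; per-sample score =",
         "d(nearest other-class) - d(nearest same-class), leave-one-out"))
}

#' Cophenetic agreement between a map and its source space
#'
#' Hierarchically clusters both representations (Euclidean distance, Ward
#' linkage by default) and returns the Pearson correlation of the two
#' cophenetic-distance vectors.
#'
#' @param space samples x D matrix or [IntegratedMatrix-class].
#' @param map [EmbeddingMap-class] or coordinate matrix over the same
#'   samples.
#' @param linkage `hclust` agglomeration method (default `"ward.D2"`).
#' @return the correlation, in \[-1, 1\].
#' @export
copheneticComparison <- function(space, map, linkage = "ward.D2") {
  a <- asCoords(space); b <- asCoords(map)
  if (nrow(a) < 3L) stop("need at least three samples")
  if (nrow(a) != nrow(b)) stop("representations must share samples")
  ca <- stats::cophenetic(stats::hclust(stats::dist(a), method = linkage))
  cb <- stats::cophenetic(stats::hclust(stats::dist(b), method = linkage))
  stats::cor(as.vector(ca), as.vector(cb))
}
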