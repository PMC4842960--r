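# Independent oracles and fixture builders used across the suite.

# Adjusted Rand index, computed from the contingency table.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- sum(choose(tab, 2))
  sr <- sum(choose(rowSums(tab), 2))
  sl <- sum(choose(colSums(tab), 2))
  ex <- sr * sl / choose(n, 2)
  (sc - ex) / ((sr + sl) / 2 - ex)
}

# Brute-force local similarity: explicit double loop over ordered pairs,
# with ranks recomputed from scratch (ties by ascending index).
bruteSimilarity <- function(X, Y, kx, ky) {
  n <- nrow(X)
  rankRow <- function(M, i) {
    d <- sqrt(colSums((t(M) - M[i, ])^2))
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    r <- integer(n)
    r[ord] <- seq_len(n)
    r
  }
  hits <- 0L
  for (i in seq_len(n)) {
    rx <- rankRow(X, i)
    ry <- rankRow(Y, i)
    for (j in seq_len(n)) {
      if (j == i) next
      if (rx[j] <= kx && ry[j] <= ky) hits <- hits + 1L
    }
  }
  hits / (n * min(kx, ky))
}

# Exhaustive upper-tail hypergeometric probability by subset enumeration:
# P(overlap >= q) when drawing k samples from N of which m carry the label.
enumHyper <- function(q, m, N, k) {
  sum(vapply(q:min(m, k), function(x)
    choose(m, x) * choose(N - m, k - x), numeric(1))) / choose(N, k)
}

# Manual log-rank statistic from the observed-minus-expected table.
logrankOracle <- function(time, event, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L)
  ts <- sort(unique(time[event]))
  U <- 0; V <- 0
  for (t in ts) {
    atRisk <- time >= t
    d <- sum(event & time == t)
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == levels(group)[1L])
    d1 <- sum(event & time == t & group == levels(group)[1L])
    U <- U + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# Breslow partial log-likelihood for a single binary covariate.
breslowLoglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event]))) {
    ev <- which(event & time == t)
    atRisk <- which(time >= t)
    ll <- ll + sum(x[ev]) * beta -
      length(ev) * log(sum(exp(x[atRisk] * beta)))
  }
  ll
}

# Two well-separated 2D Gaussian blob layouts with ground-truth labels.
makeBlobs <- function(nPer, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(c)
    cbind(rnorm(nPer, centers[c, 1], sd), rnorm(nPer, centers[c, 2], sd))))
  rownames(coords) <- sprintf("b%03d", seq_len(nrow(coords)))
  list(coords = coords, labels = rep(seq_len(nrow(centers)), each = nPer))
}

# One small normalized synthetic cohort shared by several tests.
sharedCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generateCohort(synthSpec(
        nClusters = 3, samplesPerCluster = 20,
        featureCounts = c(GE = 80, ME = 60, CN = 60, MIR = 30),
        effectSize = 4, missingRate = 0.01, seed = 11))
      cache <<- list(cohort = normalizeCohort(gen$cohort), truth = gen$truth)
    }
    cache
  }
})
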