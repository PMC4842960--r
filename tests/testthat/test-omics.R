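mkds <- function(m, type = "GE", chrom = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%d", seq_len(ncol(m)))
  OmicsDataset(m, type,
               chromosome = if (is.null(chrom)) character(0)
                            else stats::setNames(chrom, colnames(m)))
}

test_that("matrix loading round-trips shape, rejects duplicates, keeps NA", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ge.tsv")
  writeLines(c("gene\tsampA\tsampB",
               "g1\t1\t2", "g2\t3\t4", "g3\t5\t"), f)
  ds <- loadOmicsMatrix(f, "GE")
  expect_identical(dim(omicsValues(ds)), c(2L, 3L))  # samples x features
  expect_identical(sampleIDs(ds), c("sampA", "sampB"))
  expect_identical(sum(is.na(omicsValues(ds))), 1L)

  writeLines(c("gene\tsampA\tsampB", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(loadOmicsMatrix(f, "GE"), "g1")

  writeLines(c("sample_id\tg1\tg2", "sampA\t1\t2", "sampB\t3\t4"), f)
  expect_identical(sampleIDs(loadOmicsMatrix(f, "GE")), c("sampA", "sampB"))

  writeLines(c("gene\tsampA\tsampB", "g1\t1\t2", "g2\t3"), f)
  expect_error(loadOmicsMatrix(f, "GE"), "non-rectangular")
})

test_that("expression-style normalization does exact log2(v+1) centering", {
  for (type in c("GE", "MIR")) {
    ds <- mkds(cbind(c(0, 0), c(1, 3), c(7, 7)), type)
    out <- omicsValues(normalizeOmics(ds))
    expect_equal(unname(out[, 1]), c(0, 0))
    expect_equal(unname(out[, 2]), c(-0.5, 0.5))  # log2 -> (1,2), centered
    expect_equal(unname(out[, 3]), c(0, 0))
    expect_error(normalizeOmics(mkds(cbind(c(-1, 2)), type)), "non-negative")
  }
})

test_that("copy-number normalization is log2(v/2) then centering", {
  ds <- mkds(cbind(c(2, 2, 2), c(2, 4, 4)), "CN")
  out <- omicsValues(normalizeCN(ds))
  expect_equal(unname(out[, 1]), c(0, 0, 0))
  expect_equal(unname(out[, 2]), c(-2 / 3, 1 / 3, 1 / 3))
  expect_error(normalizeCN(mkds(cbind(c(0, 2)), "CN")), "positive")
})

test_that("methylation probes collapse to TSS-windowed gene means", {
  probes <- matrix(c(0.2, 0.4, 0.6,
                     0.4, 0.6, 0.8), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("p1", "p2", "p3")))
  ann <- data.frame(probe = c("p1", "p2", "p3"),
                    gene = c("gA", "gA", "gB"),
                    tss_distance = c(-100L, 200L, 500L))
  ds <- collapseMethylation(probes, ann)
  expect_equal(unname(omicsValues(ds)[, "gA"]), c(0.3, 0.5))
  expect_equal(unname(omicsValues(ds)[, "gB"]), c(0.6, 0.8))  # identity

  # a probe exactly one bp beyond the window is excluded
  ann$tss_distance[2] <- 1501L
  ds2 <- collapseMethylation(probes, ann)
  expect_equal(unname(omicsValues(ds2)[, "gA"]), c(0.2, 0.4))

  ann$tss_distance <- c(2000L, 2000L, 2000L)
  expect_error(collapseMethylation(probes, ann), "no probe")
})

test_that("methylation normalization: quantile step, PC removal, guards", {
  set.seed(4)
  m <- matrix(runif(60), 6, 10)
  ds <- mkds(m, "ME")
  # quantile normalization makes sorted sample vectors identical
  q <- quantileNormalize(m)
  sorted <- apply(q, 1, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-8)
  outQ <- omicsValues(normalizeME(ds, removePCs = 0))
  expect_equal(unname(outQ), unname(sweep(q, 2, colMeans(q))),
               tolerance = 1e-12)
  expect_lt(max(abs(colMeans(outQ))), 1e-8)

  # two samples with identical value multisets are unchanged by the
  # quantile step
  perm <- m[1, sample(10)]
  expect_equal(unname(quantileNormalize(rbind(m[1, ], perm))),
               unname(rbind(m[1, ], perm)), tolerance = 1e-12)

  # rank-1 centered matrix is annihilated by removing one component,
  # matching a full singular decomposition
  u <- rnorm(8); v <- runif(5)
  r1 <- outer(u - mean(u), v) / 10 + 0.5
  ds3 <- mkds(r1, "ME")
  out3 <- omicsValues(normalizeME(ds3, removePCs = 1))
  expect_lt(max(abs(out3)), 1e-8)

  expect_error(normalizeME(mkds(matrix(runif(4), 2, 2), "ME"),
                           removePCs = 2), "samples")
})

test_that("sex-chromosome features are dropped, others kept in order", {
  ds <- mkds(matrix(runif(8), 2, 4), "GE",
             chrom = c("1", "chrX", "2", "Y"))
  out <- dropSexChromosomes(ds)
  expect_identical(featureIDs(out), c("g1", "g3"))
  expect_identical(normStages(out), "sexFiltered")

  dsAuto <- mkds(matrix(runif(4), 2, 2), "GE", chrom = c("3", "7"))
  expect_identical(featureIDs(dropSexChromosomes(dsAuto)), c("g1", "g2"))

  dsY <- mkds(matrix(runif(4), 2, 2), "GE", chrom = c("Y", "Y"))
  expect_error(dropSexChromosomes(dsY), "empty")
})

test_that("imputation drops all-missing features and matches the
           hand-computed 3-nearest-neighbour mean", {
  m <- rbind(c(1, 10, 5), c(2, 20, NA), c(3, 30, 7),
             c(50, 60, 8), c(51, 61, 9))
  dimnames(m) <- list(paste0("s", 1:5), paste0("g", 1:3))
  out <- omicsValues(filterAndImpute(mkds(m), k = 3))
  # exhaustive RMS distances from s2 on shared observed features:
  # s1 and s3 are nearest, then s4 or s5; 3-NN donors are s1, s3, s4
  d <- sapply(c(1, 3, 4, 5), function(j)
    sqrt(mean((m[2, 1:2] - m[j, 1:2])^2)))
  donors <- c(1, 3, 4, 5)[order(d)][1:3]
  expect_equal(out["s2", "g3"], mean(m[donors, 3]))

  mAllMiss <- cbind(m, g4 = NA_real_)
  expect_identical(colnames(omicsValues(filterAndImpute(mkds(mAllMiss)))),
                   paste0("g", 1:3))

  expect_identical(omicsValues(filterAndImpute(mkds(m[, 1:2]))), m[, 1:2])

  mBad <- m; mBad[1, ] <- NA
  expect_error(filterAndImpute(mkds(mBad)), "s1")
})

test_that("a duplicated sample donates its value to its twin's gaps", {
  m <- rbind(c(1, 2, 3), c(1, 2, NA), c(9, 9, 9), c(8, 8, 8), c(7, 7, 7))
  dimnames(m) <- list(paste0("s", 1:5), paste0("g", 1:3))
  out <- omicsValues(filterAndImpute(mkds(m), k = 3))
  expect_identical(out["s2", "g3"], 3)
})

test_that("centering is idempotent across all normalizations", {
  center <- function(x) sweep(x, 2, colMeans(x))
  set.seed(9)
  m <- matrix(rexp(40), 8, 5)
  for (type in c("GE", "MIR")) {
    out <- omicsValues(normalizeOmics(mkds(m, type)))
    expect_lt(max(abs(out - center(out))), 1e-8)
  }
  outCN <- omicsValues(normalizeCN(mkds(m + 0.5, "CN")))
  expect_lt(max(abs(outCN - center(outCN))), 1e-8)
})

test_that("sample alignment intersects datasets and clinical, in order", {
  a <- mkds(matrix(1:6, 3, 2,
                   dimnames = list(c("s1", "s2", "s3"), c("g1", "g2"))), "GE")
  b <- mkds(matrix(1:4, 2, 2,
                   dimnames = list(c("s3", "s1"), c("m1", "m2"))), "MIR")
  clin <- data.frame(tissue = c("x", "y", "z"),
                     row.names = c("s1", "s2", "s3"))
  suppressMessages(coh <- alignSamples(list(a, b), clin))
  expect_identical(sampleIDs(coh), c("s1", "s3"))
  expect_identical(rownames(clinicalData(coh)), c("s1", "s3"))

  suppressMessages(cohAll <- alignSamples(
    list(a, mkds(matrix(1:6, 3, 2,
      dimnames = list(c("s1", "s2", "s3"), c("m1", "m2"))), "MIR")), clin))
  expect_identical(sampleIDs(cohAll), c("s1", "s2", "s3"))

  c2 <- mkds(matrix(1:4, 2, 2,
                    dimnames = list(c("t1", "t2"), c("m1", "m2"))), "MIR")
  expect_error(alignSamples(list(a, c2), clin), "no sample")
})

test_that("sex filtering and imputation commute on autosomal values when
           no sex feature informs a neighbour", {
  set.seed(2)
  m <- matrix(runif(24), 4, 6,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:6)))
  m[2, 3] <- NA
  chrom <- c("1", "2", "3", "4", "X", "Y")
  # make the sex-linked columns uninformative: identical across samples
  m[, 5:6] <- 1
  ds <- mkds(m, "GE", chrom = chrom)
  a <- omicsValues(filterAndImpute(dropSexChromosomes(ds), k = 2))
  b <- omicsValues(dropSexChromosomes(filterAndImpute(ds, k = 2)))
  expect_equal(a, b)
})
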