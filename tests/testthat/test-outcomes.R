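test_that("log-rank: identical groups give statistic 0, the 6-subject toy
           matches the observed-minus-expected table, labels commute", {
  recs <- data.frame(time = rep(c(1, 2, 3), 2),
                     event = rep(c(TRUE, FALSE, TRUE), 2))
  same <- kmLogrank(recs, rep(c("a", "b"), each = 3))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  toy <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                    event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
                    group = c("a", "a", "a", "b", "b", "b"))
  lr <- kmLogrank(toy, toy$group)
  expect_equal(lr$chisq,
               logrankOracle(toy$time, toy$event, toy$group),
               tolerance = 1e-9)
  lrSwap <- kmLogrank(toy, c("b", "b", "b", "a", "a", "a"))
  expect_equal(lr$chisq, lrSwap$chisq, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(lr$chisq, 1, lower.tail = FALSE))

  # survival curve steps only at event times of its own group
  km <- kmLogrank(data.frame(time = c(1, 1, 2, 2),
                             event = c(TRUE, TRUE, FALSE, FALSE)),
                  c("g1", "g1", "g2", "g2"))
  sm <- summary(km$fit)
  expect_true(all(sm$time == 1))

  expect_error(kmLogrank(data.frame(time = 1:4, event = rep(FALSE, 4)),
                         rep(c("a", "b"), 2)), "no events")
})

test_that("Kaplan-Meier curves are non-increasing step functions from 1", {
  set.seed(81)
  recs <- data.frame(time = rexp(40, 0.1),
                     event = runif(40) < 0.7)
  km <- kmLogrank(recs, rep(c("a", "b"), 20))
  expect_true(all(km$fit$surv <= 1 + 1e-12))
  for (s in split(km$fit$surv, rep(seq_along(km$fit$strata),
                                   km$fit$strata)))
    expect_true(all(diff(s) <= 1e-12))
})

test_that("Cox fit matches a Breslow partial-likelihood grid search and
           recovers a planted hazard ratio", {
  toy <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                    event = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                    grp = c("x", "y", "x", "y", "x", "y"))
  fit <- coxPH(toy, "grp")
  grid <- seq(-4, 4, by = 5e-4)
  x <- as.integer(toy$grp == "y")
  ll <- vapply(grid, breslowLoglik, numeric(1),
               time = toy$time, event = toy$event, x = x)
  expect_equal(fit$coef, grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(fit$hr, exp(fit$coef), tolerance = 1e-12)

  set.seed(82)
  n <- 500
  g <- rep(0:1, each = n / 2)
  t <- rexp(n, rate = 0.01 * exp(log(2) * g))
  cens <- runif(n, 0, 150)
  recs <- data.frame(time = pmin(t, cens), event = t <= cens,
                     grp = factor(g), age = runif(n, 40, 80),
                     sex = sample(c("m", "f"), n, TRUE))
  est <- coxPH(recs, "grp", covariates = c("age", "sex"))
  expect_gt(est$hr, 1.6)
  expect_lt(est$hr, 2.5)
  expect_identical(attr(est, "ties"), "breslow")
})

test_that("a null group effect keeps the confidence interval on 1 in most
           replicates", {
  set.seed(83)
  cover <- vapply(1:25, function(i) {
    n <- 200
    recs <- data.frame(time = rexp(n, 0.02), event = runif(n) < 0.8,
                       grp = rep(c("a", "b"), n / 2))
    fit <- coxPH(recs, "grp")
    fit$lower95 <= 1 && fit$upper95 >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("annotation tests: rank-sum for continuous, one-sided exact for
           categorical with enumerated reference values", {
  g <- rep(c("a", "b"), each = 3)
  expect_gt(annotationTest(rep(c(1, 2, 3), 2), g), 0.5)

  # 2x2 table (3,0 / 0,3): one-sided p = 1/choose(6,3) = 1/20
  vals <- c("p", "p", "p", "q", "q", "q")
  expect_equal(annotationTest(vals, g), 1 / 20, tolerance = 1e-12)

  # a 2x2 table with an empty row (zero margin): p = 1
  allP <- factor(rep("p", 6), levels = c("p", "q"))
  expect_equal(annotationTest(allP, g), 1)

  expect_error(annotationTest(1:3, factor(c("a", "a", "a"))), "two levels")
})

test_that("gene-set enrichment: hypergeometric tails plus a hand-checked
           Benjamini-Yekutieli step-up", {
  bg <- paste0("g", 1:50)
  sets <- list(inside = paste0("g", 1:10),
               disjoint = paste0("g", 41:50))
  hits <- paste0("g", 1:5)
  res <- pathwayEnrichment(hits, bg, sets)
  expect_equal(res$p[res$set == "inside"],
               enumHyper(5, 10, 50, 5), tolerance = 1e-12)
  expect_equal(res$p[res$set == "disjoint"], 1)

  # degenerate: background equals the single set, all hits inside
  deg <- pathwayEnrichment(paste0("g", 1:3), paste0("g", 1:6),
                           list(s = paste0("g", 1:6)))
  expect_equal(deg$p, 1)

  # BY on raw p (0.01, 0.02, 0.9) with harmonic factor 1 + 1/2 + 1/3
  expect_equal(p.adjust(c(0.01, 0.02, 0.9), method = "BY"),
               c(0.055, 0.055, 1), tolerance = 1e-12)
  expect_error(pathwayEnrichment("z", character(0), sets), "background|subset")
})

test_that("multiple-testing adjustments are ordered as theory demands", {
  set.seed(84)
  for (i in 1:5) {
    p <- runif(20)
    holm <- p.adjust(p, "holm"); bonf <- p.adjust(p, "bonferroni")
    by <- p.adjust(p, "BY")
    expect_true(all(holm <= bonf + 1e-15))
    expect_true(all(holm >= p - 1e-15))
    expect_true(all(by >= p - 1e-15))
    expect_true(all(diff(by[order(p)]) >= -1e-15))  # monotone in raw p
  }
})

test_that("differential expression: identical groups are null, a planted
           shift survives Holm, and the step-down matches hand values", {
  set.seed(85)
  expr <- matrix(rnorm(40 * 30), 40, 30,
                 dimnames = list(paste0("s", 1:40), paste0("g", 1:30)))
  expr[21:40, 7] <- expr[21:40, 7] + 5   # 5 SD shift in gene 7
  de <- differentialExpression(expr, 1:20, 21:40)
  expect_lt(de$pHolm[7], 0.05)
  expect_identical(de$gene[which.min(de$p)], "g7")

  sameHalf <- matrix(rnorm(20 * 5), 20, 5,
                     dimnames = list(paste0("s", 1:20), paste0("g", 1:5)))
  deNull <- differentialExpression(rbind(sameHalf, sameHalf),
                                   1:20, 21:40)
  expect_equal(deNull$p, rep(c(1), 5))  # identical groups, zero difference

  # Holm on (0.01, 0.04) with m = 2 -> (0.02, 0.04)
  expect_equal(p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))

  # zero variance in both groups: statistic NA, p = 1
  flat <- matrix(1, 8, 2, dimnames = list(paste0("s", 1:8), c("gA", "gB")))
  deFlat <- differentialExpression(flat, 1:4, 5:8)
  expect_true(all(is.na(deFlat$statistic)))
  expect_equal(deFlat$p, c(1, 1))

  # within-category centering removes category-level shifts
  expr2 <- matrix(rnorm(40 * 4), 40, 4,
                  dimnames = list(paste0("s", 1:40), paste0("g", 1:4)))
  tissue <- rep(c("t1", "t2"), each = 20)
  expr2[tissue == "t2", ] <- expr2[tissue == "t2", ] + 10
  deC <- differentialExpression(expr2, which(tissue == "t1"),
                                which(tissue == "t2"),
                                centerWithin = tissue)
  expect_true(all(deC$p > 0.001))

  expect_error(differentialExpression(expr, 1, 2:5), "two samples")
})

test_that("co-expression network: exact-duplicate triangle, unattainable
           threshold, planted modules, and a pruning fixed point", {
  set.seed(86)
  base <- rnorm(30)
  tri <- cbind(a = base, b = base, c = base)
  rownames(tri) <- paste0("s", 1:30)
  net <- coexpressionNetwork(tri)
  expect_identical(nrow(net$edges), 3L)
  expect_identical(unique(net$nodes$module), 1L)

  none <- coexpressionNetwork(tri, rThreshold = 1.01)
  expect_identical(nrow(none$nodes), 0L)

  # two planted correlated triples plus isolated genes
  u <- rnorm(60); v <- rnorm(60)
  expr <- cbind(u1 = u, u2 = u + rnorm(60, 0, 0.3), u3 = -u + rnorm(60, 0, 0.3),
                v1 = v, v2 = v + rnorm(60, 0, 0.3), v3 = v + rnorm(60, 0, 0.3),
                w = rnorm(60))
  rownames(expr) <- paste0("s", 1:60)
  net2 <- coexpressionNetwork(expr, rThreshold = 0.6, minPartners = 2)
  expect_identical(sort(unique(net2$nodes$module)), c(1L, 2L))
  expect_false("w" %in% net2$nodes$gene)
  expect_true(any(net2$edges$r < 0))   # the anticorrelated member keeps edges

  # pruning fixed point: rebuilding from the surviving genes changes nothing
  net3 <- coexpressionNetwork(expr[, net2$nodes$gene], rThreshold = 0.6,
                              minPartners = 2)
  expect_identical(net3$nodes$gene, net2$nodes$gene)
  expect_equal(net3$edges, net2$edges)
})
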