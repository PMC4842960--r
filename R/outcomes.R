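#' @include AllClasses.R AllGenerics.R
NULL

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival estimates per group and the standard log-rank
#' chi-square statistic over pooled event times, with the p-value from the
#' chi-square tail on (groups - 1) degrees of freedom.
#'
#' @param records data.frame with columns `time` (non-negative, days) and
#'   `event` (logical or 0/1; death observed).
#' @param groups per-record group labels (at least two groups, at least one
#'   event overall).
#' @return list with `fit` (a [survival::survfit] object), `chisq`, `df`
#'   and `p`.
#' @export
kmLogrank <- function(records, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (sum(records$event) == 0) stop("no events observed")
  s <- survival::Surv(records$time, as.integer(records$event))
  fit <- survival::survfit(s ~ groups)
  sd <- survival::survdiff(s ~ groups)
  df <- nlevels(droplevels(groups)) - 1L
  list(fit = fit, chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards comparison with covariate correction
#'
#' Partial-likelihood fit with Breslow tie handling. The hazard ratio, Wald
#' 95% confidence interval and p-value are reported for each non-reference
#' level of the group variable.
#'
#' @param records data.frame with columns `time`, `event` plus any
#'   covariates named below.
#' @param groupVar name of the group column in `records`.
#' @param covariates character vector drawn from
#'   `c("age", "sex", "tissue")` to adjust for (default none).
#' @return data.frame with `term`, `coef`, `hr`, `lower95`, `upper95`, `p`;
#'   the attribute `ties` records the tie-handling method.
#' @export
coxPH <- function(records, groupVar, covariates = character(0)) {
  stopifnot(groupVar %in% names(records))
  bad <- setdiff(covariates, names(records))
  if (length(bad)) stop("covariates missing from records: ",
                        paste(bad, collapse = ", "))
  grp <- as.factor(records[[groupVar]])
  if (nlevels(droplevels(grp)) < 2L) stop("group variable needs >= 2 levels")
  if (sum(records$event) < length(covariates) + 1L)
    stop("too few events for the requested covariates")
  fm <- stats::as.formula(paste(
    "survival::Surv(time, as.integer(event)) ~",
    paste(c(groupVar, covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fm, data = records, ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite|Loglik", conditionMessage(w)))
        stop("model did not converge (possible complete separation): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  keep <- grepl(paste0("^", groupVar), rownames(sm$coefficients))
  co <- sm$coefficients[keep, , drop = FALSE]
  ci <- sm$conf.int[keep, , drop = FALSE]
  out <- data.frame(term = rownames(co), coef = co[, "coef"],
                    hr = co[, "exp(coef)"],
                    lower95 = ci[, "lower .95"], upper95 = ci[, "upper .95"],
                    p = co[, "Pr(>|z|)"], row.names = NULL)
  attr(out, "ties") <- "breslow"
  out
}

#' Two-group annotation tests
#'
#' Compares a sample annotation between two groups: the Mann-Whitney U
#' (Wilcoxon rank-sum) test for continuous annotations, and the one-sided
#' Fisher exact test (alternative: over-representation in the first group)
#' for categorical ones.
#'
#' @param values per-sample annotation, numeric or categorical.
#' @param group two-level factor over the same samples.
#' @return the p-value.
#' @export
annotationTest <- function(values, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (any(table(group) == 0L)) stop("empty group")
  if (is.numeric(values)) {
    stats::wilcox.test(values ~ group, exact = FALSE)$p.value
  } else {
    tab <- table(as.factor(values), group)
    if (nrow(tab) != 2L)
      stop("categorical annotation must have exactly two levels")
    stats::fisher.test(tab, alternative = "greater")$p.value
  }
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then the member gene symbols. Duplicate symbols within a set are
#' dropped.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  sets[lengths(sets) > 0L]
}

#' Gene-set enrichment with Benjamini-Yekutieli correction
#'
#' Per set, the upper-tail hypergeometric probability of the observed
#' overlap between the hit genes and the set, within the measured
#' background; p-values are adjusted by the Benjamini-Yekutieli step-up
#' procedure (valid under arbitrary dependence) and sets are selected at
#' adjusted p below `alpha`.
#'
#' @param hitGenes character vector of significant genes (must be a subset
#'   of `backgroundGenes`).
#' @param backgroundGenes the measured gene universe.
#' @param geneSets named list of character vectors (see [readGMT()]).
#' @param alpha selection level on the adjusted p (default 0.05).
#' @return data.frame with `set`, `setSize` (within background), `hits`,
#'   `p`, `pBY`, `selected`, ordered by `pBY`.
#' @export
pathwayEnrichment <- function(hitGenes, backgroundGenes, geneSets,
                              alpha = 0.05) {
  if (!length(backgroundGenes)) stop("empty background")
  if (!all(hitGenes %in% backgroundGenes))
    stop("hitGenes must be a subset of backgroundGenes")
  N <- length(unique(backgroundGenes))
  nHit <- length(unique(hitGenes))
  rows <- lapply(names(geneSets), function(nm) {
    inBg <- intersect(geneSets[[nm]], backgroundGenes)
    q <- length(intersect(hitGenes, inBg))
    p <- stats::phyper(q - 1, length(inBg), N - length(inBg), nHit,
                       lower.tail = FALSE)
    data.frame(set = nm, setSize = length(inBg), hits = q, p = p)
  })
  out <- do.call(rbind, rows)
  out$pBY <- stats::p.adjust(out$p, method = "BY")
  out$selected <- out$pBY < alpha
  out[order(out$pBY, out$p), ]
}

#' Per-gene differential expression between two groups
#'
#' Welch's two-sample t test per gene with Holm step-down adjustment.
#' Optionally, expression is first mean-centered within a category (e.g.
#' tissue) so that category-specific baselines do not drive the
#' comparison. Genes with zero variance in both groups get statistic `NA`
#' and p = 1.
#'
#' @param expr samples x genes numeric matrix.
#' @param groupA,groupB row indices or sample IDs of the two groups (each
#'   of size >= 2).
#' @param centerWithin optional per-sample categories; expression is
#'   mean-centered within each category first.
#' @return data.frame with `gene`, `statistic`, `meanA`, `meanB`, `p`,
#'   `pHolm`; the attribute `method` records the test used.
#' @export
differentialExpression <- function(expr, groupA, groupB,
                                   centerWithin = NULL) {
  if (is.character(groupA)) groupA <- match(groupA, rownames(expr))
  if (is.character(groupB)) groupB <- match(groupB, rownames(expr))
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("both groups need at least two samples")
  if (!is.null(centerWithin)) {
    for (cat in unique(centerWithin)) {
      idx <- which(centerWithin == cat)
      expr[idx, ] <- sweep(expr[idx, , drop = FALSE], 2L,
                           colMeans(expr[idx, , drop = FALSE]))
    }
  }
  a <- expr[groupA, , drop = FALSE]
  b <- expr[groupB, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2L, stats::var); vb <- apply(b, 2L, stats::var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  t[degenerate] <- NA_real_
  p[degenerate] <- 1
  p[is.na(p) & !degenerate] <- 1
  out <- data.frame(gene = colnames(expr), statistic = t, meanA = ma,
                    meanB = mb, p = p,
                    pHolm = stats::p.adjust(p, method = "holm"),
                    row.names = NULL)
  attr(out, "method") <- "Welch two-sample t test, Holm adjustment"
  out
}

#' Thresholded co-expression network
#'
#' Builds a gene graph with an edge wherever the absolute pairwise Pearson
#' correlation exceeds `rThreshold` (both signs kept, with the sign
#' recorded), then iteratively drops genes with fewer than `minPartners`
#' incident edges until the pruning reaches a fixed point. Modules are the
#' connected components of the surviving graph.
#'
#' @param expr samples x genes numeric matrix (>= 3 samples).
#' @param genes genes to include (default: all columns).
#' @param rThreshold absolute-correlation threshold (default 0.6).
#' @param minPartners minimum surviving degree (default 2).
#' @return list with `nodes` (data.frame: `gene`, `degree`, `module`),
#'   `edges` (data.frame: `geneA`, `geneB`, `r`) and the [igraph] `graph`;
#'   all empty when nothing survives.
#' @export
coexpressionNetwork <- function(expr, genes = colnames(expr),
                                rThreshold = 0.6, minPartners = 2) {
  stopifnot(all(genes %in% colnames(expr)))
  if (nrow(expr) < 3L) stop("need at least three samples")
  cm <- stats::cor(expr[, genes, drop = FALSE])
  cm[is.na(cm)] <- 0
  adj <- abs(cm) > rThreshold
  diag(adj) <- FALSE
  keep <- rep(TRUE, length(genes))
  repeat {
    deg <- rowSums(adj[keep, keep, drop = FALSE])
    drop <- deg < minPartners
    if (!any(drop)) break
    keep[which(keep)[drop]] <- FALSE
    if (!any(keep)) break
  }
  empty <- list(nodes = data.frame(gene = character(0), degree = integer(0),
                                   module = integer(0)),
                edges = data.frame(geneA = character(0),
                                   geneB = character(0), r = numeric(0)),
                graph = igraph::make_empty_graph(0, directed = FALSE))
  if (!any(keep)) return(empty)
  g <- genes[keep]
  sub <- adj[keep, keep, drop = FALSE]
  idx <- which(sub & upper.tri(sub), arr.ind = TRUE)
  edges <- data.frame(geneA = g[idx[, 1L]], geneB = g[idx[, 2L]],
                      r = cm[keep, keep, drop = FALSE][idx])
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = data.frame(name = g))
  comp <- igraph::components(graph)
  nodes <- data.frame(gene = g,
                      degree = as.integer(igraph::degree(graph)[g]),
                      module = as.integer(comp$membership[g]))
  list(nodes = nodes, edges = edges, graph = graph)
}
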