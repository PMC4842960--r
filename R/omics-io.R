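#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an OmicsDataset
#'
#' @param values numeric matrix, samples x features, with sample rownames and
#'   feature colnames. `NA` marks missing cells.
#' @param dataType one of `"GE"`, `"ME"`, `"CN"`, `"MIR"`.
#' @param chromosome optional named character vector, feature -> chromosome.
#' @param stages processing stages already applied (normally empty).
#' @return an [OmicsDataset-class] object.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
#' OmicsDataset(m, "GE")
#' @export
OmicsDataset <- function(values, dataType,
                         chromosome = character(0), stages = character(0)) {
  storage.mode(values) <- "double"
  new("OmicsDataset", dataType = dataType, values = values,
      chromosome = chromosome, stages = stages)
}

#' Read a delimited omics matrix
#'
#' Reads a rectangular tab-separated table into an un-normalized
#' [OmicsDataset-class]. Orientation is auto-detected from the first header
#' field: if it is one of `sample`, `sample_id` or `barcode`
#' (case-insensitive), rows are taken as samples; any other header (the TCGA
#' convention, e.g. `gene`) means rows are features and the table is
#' transposed on load. Empty cells and `NA` become missing values.
#'
#' @param path path to a delimited text file.
#' @param dataType one of `"GE"`, `"ME"`, `"CN"`, `"MIR"`.
#' @param sep field separator (default tab).
#' @return an [OmicsDataset-class] with samples in rows.
#' @export
loadOmicsMatrix <- function(path, dataType, sep = "\t") {
  nf <- utils::count.fields(path, sep = sep, quote = "", blank.lines.skip = TRUE)
  if (length(unique(nf)) != 1L)
    stop("non-rectangular table: rows have between ", min(nf), " and ",
         max(nf), " fields")
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, na.strings = c("NA", ""),
                           stringsAsFactors = FALSE, quote = "")
  rowEntity <- tolower(names(tab)[1L])
  ids <- as.character(tab[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate row ID in ", basename(path), ": ", dup[1L])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  cdup <- colnames(m)[duplicated(colnames(m))]
  if (length(cdup))
    stop("duplicate column ID in ", basename(path), ": ", cdup[1L])
  if (!rowEntity %in% c("sample", "sample_id", "barcode"))
    m <- t(m)
  OmicsDataset(m, dataType)
}

#' Read a probe-to-gene annotation table
#'
#' Expects columns `probe`, `gene` and `tss_distance` (signed base pairs from
#' the probe to the gene's transcription start site).
#'
#' @param path path to a tab-separated file.
#' @return data.frame with one row per probe-gene pair.
#' @export
readProbeAnnotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe", "gene", "tss_distance")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  ann$tss_distance <- as.integer(ann$tss_distance)
  ann
}

#' Summarize probe-level methylation to gene level
#'
#' Averages beta values gene-wise over probes lying within `window` base
#' pairs of the transcription start site; genes with no qualifying probe are
#' absent from the result.
#'
#' @param probeValues numeric matrix, samples x probes.
#' @param annotation data.frame with columns `probe`, `gene`, `tss_distance`.
#' @param window maximum |distance to TSS| in base pairs (default 1500).
#' @return an [OmicsDataset-class] of type `"ME"` with gene columns.
#' @export
collapseMethylation <- function(probeValues, annotation, window = 1500) {
  keep <- annotation[abs(annotation$tss_distance) <= window, , drop = FALSE]
  keep <- keep[keep$probe %in% colnames(probeValues), , drop = FALSE]
  if (!nrow(keep))
    stop("no probe lies within ", window, " bp of a TSS for any gene")
  genes <- sort(unique(keep$gene))
  out <- vapply(genes, function(g) {
    pr <- keep$probe[keep$gene == g]
    rowMeans(probeValues[, pr, drop = FALSE], na.rm = FALSE)
  }, numeric(nrow(probeValues)))
  out <- matrix(out, nrow = nrow(probeValues),
                dimnames = list(rownames(probeValues), genes))
  OmicsDataset(out, "ME")
}

centerColumns <- function(m) sweep(m, 2L, colMeans(m, na.rm = TRUE), "-")

#' Quantile-normalize samples to a common distribution
#'
#' Forces every sample (row) to the same value distribution: the mean of
#' the per-sample sorted vectors, with ties averaged. After this step every
#' sample's sorted value vector is identical.
#'
#' @param m numeric matrix, samples x features.
#' @return the normalized matrix, same dimnames.
#' @export
quantileNormalize <- function(m) {
  q <- t(limma::normalizeQuantiles(t(m), ties = TRUE))
  dimnames(q) <- dimnames(m)
  q
}

#' Platform-appropriate normalization of one data type
#'
#' Applies the transform prescribed for each data type, then gene-wise
#' mean-centering:
#' \describe{
#'   \item{GE}{RSEM values: `log2(v + 1)`, then per-gene zero-mean.}
#'   \item{MIR}{RPM values: `log2(v + 1)`, then per-gene zero-mean.}
#'   \item{CN}{gene copy numbers: `log2(v / 2)`, then per-gene zero-mean.}
#'   \item{ME}{gene-level beta values: per-sample quantile normalization to
#'     the mean of the sorted sample vectors, per-gene zero-mean, then
#'     removal of the top `removePCs` principal components of the centered
#'     matrix (reconstruction subtracted) to strip technical variation.}
#' }
#'
#' `normalizeGE()`, `normalizeME()`, `normalizeCN()` and `normalizeMIR()` are
#' type-checked wrappers around the same transforms.
#'
#' @param ds an [OmicsDataset-class] (missing cells allowed; centering and
#'   quantile steps ignore them).
#' @param removePCs for ME only: number of leading principal components to
#'   remove (default 1; 0 disables the step).
#' @return the normalized [OmicsDataset-class]; the stage is recorded.
#' @examples
#' m <- matrix(c(1, 3, 0, 0), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("g1", "g2")))
#' omicsValues(normalizeGE(OmicsDataset(m, "GE")))  # g1 -> -0.5, +0.5
#' @export
normalizeOmics <- function(ds, removePCs = 1) {
  switch(dataType(ds),
         GE  = normalizeGE(ds),
         MIR = normalizeMIR(ds),
         CN  = normalizeCN(ds),
         ME  = normalizeME(ds, removePCs = removePCs))
}

#' @rdname normalizeOmics
#' @export
normalizeGE <- function(ds) {
  stopifnot(dataType(ds) == "GE")
  v <- ds@values
  if (any(v < 0, na.rm = TRUE)) stop("GE values must be non-negative")
  ds@values <- centerColumns(log2(v + 1))
  ds@stages <- c(ds@stages, "normalized")
  validObject(ds)
  ds
}

#' @rdname normalizeOmics
#' @export
normalizeMIR <- function(ds) {
  stopifnot(dataType(ds) == "MIR")
  v <- ds@values
  if (any(v < 0, na.rm = TRUE)) stop("MIR values must be non-negative")
  ds@values <- centerColumns(log2(v + 1))
  ds@stages <- c(ds@stages, "normalized")
  validObject(ds)
  ds
}

#' @rdname normalizeOmics
#' @export
normalizeCN <- function(ds) {
  stopifnot(dataType(ds) == "CN")
  v <- ds@values
  if (any(v <= 0, na.rm = TRUE)) stop("CN values must be positive")
  ds@values <- centerColumns(log2(v / 2))
  ds@stages <- c(ds@stages, "normalized")
  validObject(ds)
  ds
}

#' @rdname normalizeOmics
#' @export
normalizeME <- function(ds, removePCs = 1) {
  stopifnot(dataType(ds) == "ME")
  v <- ds@values
  if (nrow(v) < removePCs + 1L)
    stop("need at least removePCs + 1 = ", removePCs + 1L, " samples")
  q <- centerColumns(quantileNormalize(v))
  if (removePCs > 0) {
    if (anyNA(q))
      stop("PC removal requires a complete matrix; run filterAndImpute first")
    sv <- svd(q, nu = removePCs, nv = removePCs)
    recon <- sv$u %*% (diag(sv$d[seq_len(removePCs)], removePCs) %*% t(sv$v))
    q <- q - recon
  }
  ds@values <- q
  ds@stages <- c(ds@stages, "normalized")
  validObject(ds)
  ds
}

#' Remove sex-chromosome features
#'
#' Drops every feature annotated to chromosome X or Y (avoiding sex-driven
#' grouping in downstream maps); all other features are kept in order.
#' Features with no chromosome annotation are kept with a warning.
#'
#' @param ds an [OmicsDataset-class] with a chromosome annotation.
#' @return the filtered dataset; stage `"sexFiltered"` recorded.
#' @export
dropSexChromosomes <- function(ds) {
  chrom <- ds@chromosome
  if (!length(chrom)) stop("dataset has no chromosome annotation")
  feats <- featureIDs(ds)
  known <- feats %in% names(chrom)
  if (!all(known))
    warning(sum(!known), " features lack chromosome annotation; kept")
  chr <- sub("^chr", "", chrom[feats[known]])
  sexFeat <- feats[known][chr %in% c("X", "Y")]
  keep <- setdiff(feats, sexFeat)
  if (!length(keep))
    stop("all features lie on chromosome X or Y; empty dataset")
  ds@values <- ds@values[, keep, drop = FALSE]
  ds@chromosome <- chrom[names(chrom) %in% keep]
  ds@stages <- c(ds@stages, "sexFiltered")
  ds
}

#' Drop all-missing features and impute the rest by nearest neighbours
#'
#' Features missing in every sample are removed. Each remaining missing cell
#' is replaced by the mean of that feature over the `k` nearest samples
#' (root-mean-square Euclidean distance over features observed in both
#' samples, i.e. scaled by the number of shared observed features) among
#' samples observing the feature. Samples at distance zero (exact duplicates
#' on the shared features), when present, take precedence: the imputed value
#' is their mean.
#'
#' @param ds an [OmicsDataset-class].
#' @param k number of nearest neighbours (default 3).
#' @return a complete [OmicsDataset-class]; stage `"imputed"` recorded.
#' @export
filterAndImpute <- function(ds, k = 3) {
  v <- ds@values
  allMissSample <- rowSums(!is.na(v)) == 0L
  if (any(allMissSample))
    stop("sample with all values missing: ",
         rownames(v)[allMissSample][1L])
  allMiss <- colSums(!is.na(v)) == 0L
  v <- v[, !allMiss, drop = FALSE]
  if (anyNA(v)) {
    missRows <- which(rowSums(is.na(v)) > 0L)
    for (i in missRows) {
      obs_i <- !is.na(v[i, ])
      # RMS distance over features observed in both samples
      d <- vapply(seq_len(nrow(v)), function(j) {
        if (j == i) return(Inf)
        shared <- obs_i & !is.na(v[j, ])
        if (!any(shared)) return(Inf)
        sqrt(mean((v[i, shared] - v[j, shared])^2))
      }, numeric(1))
      for (f in which(is.na(v[i, ]))) {
        dj <- d
        dj[is.na(v[, f])] <- Inf
        if (!any(is.finite(dj)))
          stop("cannot impute ", colnames(v)[f], " for ", rownames(v)[i])
        zero <- which(dj == 0)
        donors <- if (length(zero)) zero
                  else order(dj)[seq_len(min(k, sum(is.finite(dj))))]
        v[i, f] <- mean(v[donors, f])
      }
    }
  }
  ds@values <- v
  ds@chromosome <- ds@chromosome[names(ds@chromosome) %in% colnames(v)]
  ds@stages <- c(ds@stages, "imputed")
  ds
}

#' Align datasets and clinical data into a cohort
#'
#' Restricts all datasets and the clinical table to their common samples, in
#' the order of the first dataset, and reports how many samples were dropped.
#'
#' @param datasets named list of [OmicsDataset-class] objects; names default
#'   to the data types.
#' @param clinical data.frame with rownames = sample IDs (or a `sample_id`
#'   column).
#' @return a [MultiOmicsCohort-class].
#' @export
alignSamples <- function(datasets, clinical) {
  if (length(datasets) < 2L) stop("need at least two datasets")
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, dataType, character(1))
  if (!is.null(clinical$sample_id) &&
      !identical(rownames(clinical), as.character(clinical$sample_id)))
    rownames(clinical) <- clinical$sample_id
  common <- Reduce(intersect, c(lapply(datasets, sampleIDs),
                                list(rownames(clinical))))
  if (!length(common)) stop("no sample is shared by all datasets")
  ord <- sampleIDs(datasets[[1L]])
  common <- ord[ord %in% common]
  nAll <- length(unique(unlist(lapply(datasets, sampleIDs))))
  if (nAll > length(common))
    message(nAll - length(common), " samples dropped during alignment; ",
            length(common), " retained")
  datasets <- lapply(datasets, function(d) {
    d@values <- d@values[common, , drop = FALSE]
    d
  })
  new("MultiOmicsCohort", datasets = datasets,
      clinical = clinical[common, , drop = FALSE])
}

#' Run the standard preprocessing over a whole cohort
#'
#' Convenience wrapper applying, per data type: sex-chromosome removal (when
#' a chromosome annotation is present), all-missing-feature removal with
#' nearest-neighbour imputation, and the type-appropriate normalization.
#'
#' @param cohort a [MultiOmicsCohort-class] of raw datasets.
#' @param k imputation neighbours (default 3).
#' @param removePCs leading components removed from ME (default 1).
#' @return the cohort with every dataset normalized.
#' @export
normalizeCohort <- function(cohort, k = 3, removePCs = 1) {
  cohort@datasets <- lapply(cohort@datasets, function(d) {
    if (length(d@chromosome)) d <- dropSexChromosomes(d)
    d <- filterAndImpute(d, k = k)
    normalizeOmics(d, removePCs = removePCs)
  })
  cohort
}
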