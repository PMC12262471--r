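## Per-feature quantification: multi-overlap counting of pooled single +
## chimeric fragments, median-of-ratios size factors, fold-change ratios
## against a reference strain, and IP/Total enrichment ratios.

#' Count fragments per feature with multi-overlap semantics
#'
#' Pools single and chimeric fragment loci (each chimeric locus counts once)
#' and increments every feature sharing at least one same-strand base with a
#' locus, so a fragment overlapping k features increments all k. Loci
#' overlapping no feature are tallied in the `"unassigned"` attribute.
#'
#' @param frags a [FragmentSet-class].
#' @param annotation a [FeatureSet-class].
#' @return Named integer vector of per-feature counts (names are feature
#'   names), with attribute `unassigned`.
#' @export
countFeatures <- function(frags, annotation) {
  feats <- features(annotation)
  loci <- suppressWarnings(c(granges0(frags@singles), granges0(frags@rna1),
                             granges0(frags@rna2)))
  cnt <- countOverlaps(feats, loci)
  names(cnt) <- mcols(feats)$name
  attr(cnt, "unassigned") <- sum(countOverlaps(loci, feats) == 0)
  cnt
}

#' Build a counts matrix across samples
#'
#' @param fragsList named list of [FragmentSet-class] objects (one per
#'   sample).
#' @param annotation a [FeatureSet-class].
#' @return Integer matrix, features x samples.
#' @export
countMatrix <- function(fragsList, annotation) {
  cols <- lapply(fragsList, countFeatures, annotation = annotation)
  m <- do.call(cbind, lapply(cols, as.integer))
  rownames(m) <- names(cols[[1]])
  colnames(m) <- names(fragsList)
  m
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (restricted
#' to features with non-zero counts in every sample) of the ratio of the
#' sample's count to the feature's geometric mean across samples. Samples
#' that are exact scalar multiples of each other recover those scalars up to
#' a common constant.
#'
#' @param mat counts matrix, features x samples.
#' @return Named numeric vector of positive size factors.
#' @export
medianOfRatios <- function(mat) {
  if (is.null(dim(mat)) || ncol(mat) < 1) stop("mat must be a matrix")
  keep <- rowSums(mat > 0) == ncol(mat)
  if (!any(keep))
    stop("no feature has non-zero counts in all samples; ",
         "add a pseudocount before normalisation")
  lg <- log(mat[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - geo)))
  sf
}

#' Normalise counts by size factors
#'
#' @param mat counts matrix.
#' @param sizeFactors per-sample factors; computed with [medianOfRatios()]
#'   when missing.
#' @return Numeric matrix of normalised values with attribute `sizeFactors`.
#' @export
normalizeCounts <- function(mat, sizeFactors = medianOfRatios(mat)) {
  norm <- sweep(mat, 2, sizeFactors, "/")
  attr(norm, "sizeFactors") <- sizeFactors
  norm
}

#' Fold-change ratios against a reference sample group
#'
#' `ratio_f = (mean(norm[f, samples]) + pseudocount) /
#' (mean(norm[f, reference]) + pseudocount)`; a sample group identical to the
#' reference gives ratios of exactly 1, and zero counts are guarded by the
#' pseudocount.
#'
#' @param norm normalised matrix (features x samples).
#' @param samples column names of the contrasted group.
#' @param reference column names of the reference group.
#' @param pseudocount positive guard added to both means.
#' @return Named numeric vector of per-feature ratios.
#' @export
foldChangeVsReference <- function(norm, samples, reference, pseudocount = 1) {
  if (!length(reference)) stop("reference group is empty")
  m <- rowMeans(norm[, samples, drop = FALSE])
  r <- rowMeans(norm[, reference, drop = FALSE])
  (m + pseudocount) / (r + pseudocount)
}

#' IP/Total enrichment ratios
#'
#' `log2((ip + pseudocount) / (total + pseudocount))` per feature; positive
#' values indicate that most of the RNA is associated with the
#' immunoprecipitated protein. The linear ratio is reported alongside.
#'
#' @param ip normalised IP column (named numeric).
#' @param total matched normalised total-RNA column.
#' @param pseudocount positive guard.
#' @return data.frame with columns `ratio` and `log2_ratio`, rownames are
#'   feature names.
#' @export
enrichmentRatio <- function(ip, total, pseudocount = 1) {
  if (length(ip) != length(total) ||
      (!is.null(names(ip)) && !is.null(names(total)) &&
       !identical(names(ip), names(total))))
    stop("ip and total must cover the same features in the same order")
  lin <- (ip + pseudocount) / (total + pseudocount)
  data.frame(ratio = lin, log2_ratio = log2(lin),
             row.names = names(ip))
}
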