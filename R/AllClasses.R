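## S4 containers shared across the pipeline stages.

FEATURE_TYPES <- c("gene", "CDS", "sRNA", "tRNA", "rRNA",
                   "5UTR", "3UTR", "EST5UTR", "EST3UTR",
                   "AS", "IGR", "TU")

#' FeatureSet: a typed, stranded genome annotation
#'
#' Wraps a [GenomicRanges::GRanges] whose metadata columns carry
#' `feature_id` (unique), `ftype` (one of gene, CDS, sRNA, tRNA, rRNA, 5UTR,
#' 3UTR, EST5UTR, EST3UTR, AS, IGR, TU), `name` and optional `description`.
#' Genome lengths travel as `seqlengths` on the ranges.
#'
#' @slot anno `GRanges` with the metadata columns above.
#' @export
setClass("FeatureSet", slots = c(anno = "GRanges"))

setValidity("FeatureSet", function(object) {
  gr <- object@anno
  mc <- mcols(gr)
  need <- c("feature_id", "ftype", "name")
  if (!all(need %in% colnames(mc)))
    return(paste("missing metadata columns:",
                 paste(setdiff(need, colnames(mc)), collapse = ", ")))
  if (anyDuplicated(mc$feature_id))
    return("feature_id values must be unique")
  if (length(gr)) {
    if (any(!as.character(strand(gr)) %in% c("+", "-")))
      return("all features must be stranded (+ or -)")
    if (any(width(gr) < 1))
      return("all features must have width >= 1")
    if (any(!mc$ftype %in% FEATURE_TYPES))
      return(paste("unknown ftype:",
                   paste(unique(setdiff(mc$ftype, FEATURE_TYPES)), collapse = ", ")))
    sl <- seqlengths(gr)[as.character(seqnames(gr))]
    bad <- !is.na(sl) & (end(gr) > sl | start(gr) < 1)
    if (any(bad))
      return(paste("feature beyond genome bounds:", mc$feature_id[which(bad)[1]]))
  }
  TRUE
})

#' Construct a FeatureSet
#'
#' @param anno `GRanges` with metadata columns `feature_id`, `ftype`, `name`
#'   and optionally `description`. A `description` column is added if absent.
#' @param genomeLengths optional named vector of chromosome lengths; copied
#'   onto the seqinfo of the ranges.
#' @return A [FeatureSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 100), "+",
#'   feature_id = "g1", ftype = "gene", name = "g1")
#' FeatureSet(gr)
#' @export
FeatureSet <- function(anno = GRanges(), genomeLengths = NULL) {
  if (length(anno) && is.null(mcols(anno)$description))
    mcols(anno)$description <- NA_character_
  if (!length(anno) && is.null(mcols(anno)$feature_id)) {
    mcols(anno)$feature_id <- character(0)
    mcols(anno)$ftype <- character(0)
    mcols(anno)$name <- character(0)
    mcols(anno)$description <- character(0)
  }
  if (!is.null(genomeLengths)) {
    sl <- names(genomeLengths)
    anno <- GRanges(seqnames(anno), IRanges(start(anno), end(anno)),
                    strand = strand(anno),
                    seqinfo = Seqinfo(sl, unname(genomeLengths)),
                    mcols(anno))
  }
  new("FeatureSet", anno = anno)
}

#' AnalysisParams: tunable parameters of S-chimera calling
#'
#' @slot window window size in nucleotides for binning chimera loci.
#' @slot minChimeras minimum chimeric fragments per significant region pair.
#' @slot alpha significance level for the one-sided Fisher test.
#' @slot assignRatio read-share above which a single gene is assigned
#'   exclusively to a region.
#' @slot maxGap maximum inter-mate gap for a pair to count as a single
#'   (non-chimeric) fragment.
#' @export
setClass("AnalysisParams",
         slots = c(window = "numeric", minChimeras = "numeric",
                   alpha = "numeric", assignRatio = "numeric",
                   maxGap = "numeric"))

setValidity("AnalysisParams", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  if (object@assignRatio <= 0 || object@assignRatio >= 1)
    return("assignRatio must be in (0,1)")
  if (object@minChimeras < 1) return("minChimeras must be >= 1")
  if (object@window < 1) return("window must be >= 1")
  if (object@maxGap < 0) return("maxGap must be >= 0")
  TRUE
})

#' Construct analysis parameters
#'
#' Defaults reproduce the published S-chimera thresholds: >= 5 chimeric
#' fragments and p < 0.05 (one-sided Fisher's exact test), 100-nt windows,
#' exclusive gene assignment at read-share > 0.7.
#'
#' @param window window size (nt).
#' @param minChimeras chimera count floor per S-chimera.
#' @param alpha Fisher significance level.
#' @param assignRatio exclusive-assignment read share.
#' @param maxGap maximum inter-mate gap for single fragments (nt).
#' @return An [AnalysisParams-class] object.
#' @export
analysisParams <- function(window = 100, minChimeras = 5, alpha = 0.05,
                           assignRatio = 0.7, maxGap = 1000) {
  new("AnalysisParams", window = window, minChimeras = minChimeras,
      alpha = alpha, assignRatio = assignRatio, maxGap = maxGap)
}

#' MatePairs: mapped paired-end records
#'
#' Two parallel `GRanges` (one per mate) with aligned strands as reported by
#' the mapper. `libraryReverse` records whether the library is
#' reverse-stranded (the sequenced strand is the reverse complement of the
#' transcript), in which case [transcriptStrand()] flips aligned strands to
#' transcript strands.
#'
#' @slot mate1,mate2 `GRanges`, one range per record.
#' @slot readId character read identifiers.
#' @slot libraryReverse logical flag for reverse-stranded libraries.
#' @export
setClass("MatePairs",
         slots = c(mate1 = "GRanges", mate2 = "GRanges",
                   readId = "character", libraryReverse = "logical"))

setValidity("MatePairs", function(object) {
  if (length(object@mate1) != length(object@mate2) ||
      length(object@mate1) != length(object@readId))
    return("mate1, mate2 and readId must have equal length")
  if (length(object@libraryReverse) != 1)
    return("libraryReverse must be a single flag")
  if (length(object@mate1)) {
    if (any(width(object@mate1) < 1) || any(width(object@mate2) < 1))
      return("zero-length mate")
  }
  TRUE
})

#' Construct MatePairs from coordinate vectors
#'
#' Coordinates are 1-based inclusive (use [readBedpe()] for 0-based
#' half-open BEDPE input).
#'
#' @param readId read identifiers.
#' @param chrom1,start1,end1,strand1 first mate locus.
#' @param chrom2,start2,end2,strand2 second mate locus.
#' @param libraryReverse whether the library is reverse-stranded.
#' @param genomeLengths optional named chromosome lengths.
#' @return A [MatePairs-class] object.
#' @export
matePairs <- function(readId, chrom1, start1, end1, strand1,
                      chrom2, start2, end2, strand2,
                      libraryReverse = FALSE, genomeLengths = NULL) {
  si <- if (is.null(genomeLengths)) NULL else
    Seqinfo(names(genomeLengths), unname(genomeLengths))
  mk <- function(chrom, s, e, st) {
    if (any(e < s)) stop("zero-length mate: end < start")
    if (is.null(si)) GRanges(chrom, IRanges(s, e), strand = st)
    else GRanges(chrom, IRanges(s, e), strand = st, seqinfo = si)
  }
  new("MatePairs",
      mate1 = mk(chrom1, start1, end1, strand1),
      mate2 = mk(chrom2, start2, end2, strand2),
      readId = as.character(readId),
      libraryReverse = libraryReverse)
}

#' FragmentSet: classified single and chimeric fragments
#'
#' @slot singles `GRanges` of merged single-fragment loci (mcol `read_id`).
#' @slot rna1,rna2 parallel `GRanges` of chimeric loci in RNA1/RNA2 order
#'   (RNA1 is the ligation-upstream partner; mcol `read_id` on `rna1`).
#' @export
setClass("FragmentSet",
         slots = c(singles = "GRanges", rna1 = "GRanges", rna2 = "GRanges"))

setValidity("FragmentSet", function(object) {
  if (length(object@rna1) != length(object@rna2))
    return("rna1 and rna2 must be parallel")
  TRUE
})

#' SChimeraSet: significant interacting region pairs
#'
#' One row per S-chimera (a distinct pair of interacting RNA regions):
#' ordered RNA1/RNA2 region coordinates, the supporting chimera count
#' (`interactions`), the Fisher odds ratio and p-value, and assigned gene
#' names (comma-separated when a region keeps several genes).
#'
#' @slot table `DataFrame` with one row per S-chimera.
#' @slot params the [AnalysisParams-class] used for calling.
#' @slot totalChimeras total chimeric fragments in the library.
#' @export
setClass("SChimeraSet",
         slots = c(table = "DataFrame", params = "AnalysisParams",
                   totalChimeras = "numeric"))

#' GuideSet: DASH sgRNA candidates
#'
#' @slot table `DataFrame` with one row per candidate protospacer and its
#'   filter metrics and flags.
#' @export
setClass("GuideSet", slots = c(table = "DataFrame"))

#' SimulationConfig: generative model of chaperone-mediated RNA capture
#'
#' Parameters of the miniature-genome and library simulator. Per captured
#' fragment, a planted chimera is emitted with probability
#' `pLig * rho * (1 - epsilon)` (pair chosen proportionally to `lambda`), a
#' background chimera joining two abundance-weighted random loci with
#' probability `pLig * epsilon`, and a single fragment otherwise. `rho` is the
#' strain-dependent chimera retention probability (scaled down in rim-mutant
#' scenarios), `pLig` the protocol-dependent ligation efficiency; the
#' `ripseq` protocol forces `pLig = 0`.
#'
#' @slot genomeLength genome size (nt).
#' @slot nMrna,nSrna,nTrna,nRrna feature counts.
#' @slot plantedPairs data.frame with columns `srna_id`, `target_id`,
#'   `lambda` (relative interaction intensity).
#' @slot rho chimera retention probability (strain effect).
#' @slot epsilon background random-ligation probability.
#' @slot pLig protocol ligation efficiency.
#' @slot nFragments library size.
#' @slot fragLenMean,fragLenSd mate length distribution (nt).
#' @slot protocol one of `rilseq`, `irilseq`, `ripseq`.
#' @slot libraryReverse emit aligned strands as reverse-complemented.
#' @slot seed integer random seed.
#' @export
setClass("SimulationConfig",
         slots = c(genomeLength = "numeric",
                   nMrna = "numeric", nSrna = "numeric",
                   nTrna = "numeric", nRrna = "numeric",
                   plantedPairs = "data.frame",
                   rho = "numeric", epsilon = "numeric", pLig = "numeric",
                   nFragments = "numeric",
                   fragLenMean = "numeric", fragLenSd = "numeric",
                   protocol = "character", libraryReverse = "logical",
                   seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  pr <- c(rho = object@rho, epsilon = object@epsilon, pLig = object@pLig)
  if (any(pr < 0 | pr > 1))
    return("rho, epsilon and pLig must be probabilities in [0,1]")
  if (!object@protocol %in% c("rilseq", "irilseq", "ripseq"))
    return("protocol must be rilseq, irilseq or ripseq")
  if (object@nFragments < 0) return("nFragments must be >= 0")
  pp <- object@plantedPairs
  if (nrow(pp)) {
    if (!all(c("srna_id", "target_id", "lambda") %in% names(pp)))
      return("plantedPairs needs columns srna_id, target_id, lambda")
    if (any(pp$lambda < 0)) return("lambda must be >= 0")
  }
  TRUE
})

setMethod("show", "FeatureSet", function(object) {
  gr <- object@anno
  cat("FeatureSet with", length(gr), "features\n")
  if (length(gr)) {
    tab <- table(mcols(gr)$ftype)
    cat("  types:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
  sl <- seqlengths(gr)
  if (length(sl) && !all(is.na(sl)))
    cat("  genome:", paste(names(sl), sl, sep = "=", collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "MatePairs", function(object) {
  cat("MatePairs with", length(object@mate1), "records;",
      if (object@libraryReverse) "reverse-stranded" else "forward-stranded",
      "library\n")
  invisible(object)
})

setMethod("show", "FragmentSet", function(object) {
  n1 <- length(object@singles); n2 <- length(object@rna1)
  cat("FragmentSet:", n1, "single,", n2, "chimeric fragments")
  if (n1 + n2 > 0)
    cat(sprintf(" (%.1f%% chimeric)", 100 * n2 / (n1 + n2)))
  cat("\n")
  invisible(object)
})

setMethod("show", "SChimeraSet", function(object) {
  cat("SChimeraSet with", nrow(object@table), "S-chimeras",
      sprintf("(>= %d chimeras, p < %g) from %d total chimeras\n",
              object@params@minChimeras, object@params@alpha,
              as.integer(object@totalChimeras)))
  invisible(object)
})

setMethod("show", "GuideSet", function(object) {
  tab <- object@table
  cat("GuideSet with", nrow(tab), "candidates")
  if ("pass" %in% colnames(tab)) cat(";", sum(tab$pass), "passing filters")
  cat("\n")
  invisible(object)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %s protocol, genome %d nt, %d fragments\n",
              object@protocol, as.integer(object@genomeLength),
              as.integer(object@nFragments)))
  cat(sprintf("  rho=%g epsilon=%g pLig=%g, %d planted pairs, seed %d\n",
              object@rho, object@epsilon, object@pLig,
              nrow(object@plantedPairs), as.integer(object@seed)))
  invisible(object)
})

#' @describeIn FeatureSet number of features
#' @param x a FeatureSet
#' @export
setMethod("length", "FeatureSet", function(x) length(x@anno))

#' @describeIn MatePairs number of mate-pair records
#' @param x a MatePairs object
#' @export
setMethod("length", "MatePairs", function(x) length(x@mate1))
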