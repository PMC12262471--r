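## Comprehensive feature annotation construction: known genes plus predicted
## UTRs, antisense, intergenic (IGR) and transcription-unit (TU) features,
## with the period-delimited naming convention used throughout the pipeline.

#' Load a feature annotation from GFF3
#'
#' GFF3 coordinates are 1-based inclusive; they are stored unchanged on the
#' internal `GRanges`. The feature type is taken from column 3, the feature
#' identifier from the `ID` attribute (falling back to `Name`, then to an
#' autogenerated id), the name from `Name` (falling back to `ID`).
#'
#' @param path GFF3 file.
#' @param genomeLengths optional named vector of chromosome lengths; records
#'   extending beyond a length raise a bounds error.
#' @return A [FeatureSet-class].
#' @export
loadAnnotation <- function(path, genomeLengths = NULL) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body)) {
    nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
    if (any(nf < 8))
      stop("malformed GFF3 record at line ", body[which(nf < 8)[1]])
  }
  if (!length(body)) return(FeatureSet(genomeLengths = genomeLengths))
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- mcols(gr)
  id <- if ("ID" %in% colnames(mc)) as.character(mc$ID) else
    rep(NA_character_, length(gr))
  nm <- if ("Name" %in% colnames(mc)) as.character(mc$Name) else
    rep(NA_character_, length(gr))
  id <- ifelse(is.na(id), nm, id)
  id <- ifelse(is.na(id), sprintf("feature_%05d", seq_along(gr)), id)
  nm <- ifelse(is.na(nm), id, nm)
  desc <- if ("description" %in% colnames(mc)) as.character(mc$description)
          else rep(NA_character_, length(gr))
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand = strand(gr))
  mcols(out)$feature_id <- id
  mcols(out)$ftype <- as.character(mc$type)
  mcols(out)$name <- nm
  mcols(out)$description <- desc
  if (!is.null(genomeLengths)) {
    sl <- genomeLengths[as.character(seqnames(out))]
    bad <- which(is.na(sl) | end(out) > sl | start(out) < 1)
    if (length(bad))
      stop("feature beyond genome length: ", id[bad[1]])
  }
  FeatureSet(out, genomeLengths = genomeLengths)
}

#' Write a FeatureSet as GFF3
#'
#' @param fs a [FeatureSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(fs, path) {
  gr <- features(fs)
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand = strand(gr))
  mcols(out)$type <- mcols(gr)$ftype
  mcols(out)$ID <- mcols(gr)$feature_id
  mcols(out)$Name <- mcols(gr)$name
  d <- mcols(gr)$description
  if (!is.null(d) && any(!is.na(d))) mcols(out)$description <- d
  mcols(out)$source <- "rilseqr"
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

## Largest end among same-chrom/strand features strictly left of pos,
## and smallest start strictly right of pos. Used for UTR truncation.
.nearestBoundaries <- function(gr) {
  key <- paste(as.character(seqnames(gr)), as.character(strand(gr)))
  split(seq_along(gr), key)
}

#' Predict untranslated regions by fixed extension
#'
#' For each coding gene (ftype `gene` or `CDS`) an `EST5UTR` is emitted
#' upstream of the start codon and an `EST3UTR` downstream of the stop codon
#' on the same strand, each of length `min(utrLen, gap)` where the gap is the
#' feature-free distance to the nearest same-strand annotated feature. Minus
#' strand genes extend in mirrored directions. Zero-length extensions are
#' omitted. When `skipIfKnown` is set, no prediction is made at a gene end
#' that already abuts or overlaps a curated (`5UTR`/`3UTR`) or previously
#' predicted UTR.
#'
#' @param fs base [FeatureSet-class].
#' @param utrLen maximum extension (nt).
#' @param skipIfKnown skip ends with an existing UTR annotation.
#' @return A [FeatureSet-class] holding only the predicted UTR features.
#' @export
buildPredictedUTRs <- function(fs, utrLen = 100, skipIfKnown = TRUE) {
  gr <- features(fs)
  if (!length(gr)) return(FeatureSet(genomeLengths = genomeLengths(fs)))
  coding <- which(mcols(gr)$ftype %in% c("gene", "CDS"))
  if (!length(coding)) return(FeatureSet(genomeLengths = genomeLengths(fs)))
  groups <- .nearestBoundaries(gr)
  sl <- seqlengths(gr)

  res <- list()
  for (i in coding) {
    chr <- as.character(seqnames(gr))[i]
    st <- as.character(strand(gr))[i]
    idx <- groups[[paste(chr, st)]]
    others <- setdiff(idx, i)
    s <- start(gr)[i]; e <- end(gr)[i]
    nm <- mcols(gr)$name[i]
    cl <- sl[chr]

    leftLim <- if (length(others)) {
      ends <- end(gr)[others][end(gr)[others] < s]
      if (length(ends)) max(ends) else 0L
    } else 0L
    rightLim <- if (length(others)) {
      starts <- start(gr)[others][start(gr)[others] > e]
      if (length(starts)) min(starts) else NA_integer_
    } else NA_integer_
    if (is.na(rightLim)) rightLim <- if (!is.na(cl)) cl + 1L else e + utrLen + 1L

    utrTypes <- mcols(gr)$ftype %in% c("5UTR", "3UTR", "EST5UTR", "EST3UTR")
    knownAt <- function(pos) {
      if (!skipIfKnown) return(FALSE)
      j <- setdiff(idx[utrTypes[idx]], i)
      any(start(gr)[j] <= pos & end(gr)[j] >= pos)
    }

    gapL <- s - leftLim - 1L
    gapR <- rightLim - e - 1L
    if (length(others)) {
      ## another same-strand feature covering the flanking base => no room
      if (any(start(gr)[others] <= s - 1L & end(gr)[others] >= s - 1L))
        gapL <- 0L
      if (any(start(gr)[others] <= e + 1L & end(gr)[others] >= e + 1L))
        gapR <- 0L
    }
    lenL <- min(utrLen, max(gapL, 0L))
    lenR <- min(utrLen, max(gapR, 0L))

    mk <- function(a, b, type) {
      GRanges(chr, IRanges(a, b), strand = st,
              feature_id = paste(nm, type, sep = "."),
              ftype = type, name = paste(nm, type, sep = "."),
              description = NA_character_)
    }
    if (st == "+") {
      if (lenL > 0 && !knownAt(s - 1L))
        res[[length(res) + 1L]] <- mk(s - lenL, s - 1L, "EST5UTR")
      if (lenR > 0 && !knownAt(e + 1L))
        res[[length(res) + 1L]] <- mk(e + 1L, e + lenR, "EST3UTR")
    } else {
      if (lenR > 0 && !knownAt(e + 1L))
        res[[length(res) + 1L]] <- mk(e + 1L, e + lenR, "EST5UTR")
      if (lenL > 0 && !knownAt(s - 1L))
        res[[length(res) + 1L]] <- mk(s - lenL, s - 1L, "EST3UTR")
    }
  }
  if (!length(res)) return(FeatureSet(genomeLengths = genomeLengths(fs)))
  out <- suppressWarnings(do.call(c, res))
  out <- .resolveUtrCollisions(out)
  id <- mcols(out)$feature_id
  if (anyDuplicated(id))
    mcols(out)$feature_id <- make.unique(id, sep = "_")
  FeatureSet(out, genomeLengths = .slVector(sl))
}

## Two predicted UTRs extending into the same short inter-feature gap can
## collide; split the contested space evenly. Each UTR is anchored at the
## gene boundary it extends from: left-anchored UTRs (EST3UTR on +, EST5UTR
## on -) shrink from their right edge, right-anchored ones from their left.
.resolveUtrCollisions <- function(utrs) {
  if (length(utrs) < 2) return(utrs)
  anchorLeft <- (mcols(utrs)$ftype == "EST3UTR" &
                   as.character(strand(utrs)) == "+") |
                (mcols(utrs)$ftype == "EST5UTR" &
                   as.character(strand(utrs)) == "-")
  hits <- findOverlaps(utrs, drop.self = TRUE, drop.redundant = TRUE)
  drop <- logical(length(utrs))
  for (h in seq_along(hits)) {
    i <- queryHits(hits)[h]; j <- subjectHits(hits)[h]
    li <- if (anchorLeft[i]) i else j   # left-anchored member
    ri <- if (anchorLeft[i]) j else i
    ov <- end(utrs)[li] - start(utrs)[ri] + 1L
    if (ov <= 0) next
    dl <- as.integer(ceiling(ov / 2)); dr <- ov - dl
    newEndL <- end(utrs)[li] - dl
    newStartR <- start(utrs)[ri] + dr
    if (newEndL < start(utrs)[li]) drop[li] <- TRUE else end(utrs)[li] <- newEndL
    if (newStartR > end(utrs)[ri]) drop[ri] <- TRUE else start(utrs)[ri] <- newStartR
  }
  utrs[!drop]
}

.slVector <- function(sl) {
  if (!length(sl) || all(is.na(sl))) NULL else sl[!is.na(sl)]
}

#' Build antisense features
#'
#' Each coding region yields one `AS` feature with identical coordinates on
#' the opposite strand, named `<gene>.AS`. Overlapping genes yield separate,
#' unmerged AS features, matching the per-gene naming scheme.
#'
#' @param fs base [FeatureSet-class].
#' @return A [FeatureSet-class] of AS features.
#' @export
buildAntisense <- function(fs) {
  gr <- features(fs)
  coding <- gr[mcols(gr)$ftype %in% c("gene", "CDS")]
  if (!length(coding)) return(FeatureSet(genomeLengths = genomeLengths(fs)))
  flip <- ifelse(as.character(strand(coding)) == "+", "-", "+")
  out <- GRanges(seqnames(coding), IRanges(start(coding), end(coding)),
                 strand = flip, seqinfo = seqinfo(coding))
  nm <- paste(mcols(coding)$name, "AS", sep = ".")
  mcols(out)$feature_id <- make.unique(nm, sep = "_")
  mcols(out)$ftype <- "AS"
  mcols(out)$name <- nm
  mcols(out)$description <- NA_character_
  FeatureSet(out)
}

#' Build intergenic (IGR) and transcription-unit (TU) features
#'
#' Strand-specifically, each maximal gap between the merged footprints of
#' consecutive same-strand features becomes one feature: `TU` when the gap is
#' strictly shorter than `tuMax` nucleotides, `IGR` otherwise. Features are
#' named `gene1.gene2.IGR` / `gene1.gene2.TU` from the flanking feature names
#' in genomic order. Gaps between a chromosome end and the first/last feature
#' are not emitted (they have a single flanking feature).
#'
#' @param fs [FeatureSet-class] whose same-strand inter-feature space is to be
#'   tiled.
#' @param tuMax gap length below which the feature is a TU (strictly less
#'   than).
#' @return A [FeatureSet-class] of IGR/TU features.
#' @export
buildIgrsTus <- function(fs, tuMax = 100) {
  gr <- features(fs)
  if (!length(gr)) return(FeatureSet(genomeLengths = genomeLengths(fs)))
  res <- list()
  for (chr in unique(as.character(seqnames(gr)))) {
    for (st in c("+", "-")) {
      sub <- gr[as.character(seqnames(gr)) == chr & as.character(strand(gr)) == st]
      if (length(sub) < 2) next
      red <- reduce(sub, ignore.strand = FALSE)
      red <- red[order(start(red))]
      if (length(red) < 2) next
      gapStart <- end(red)[-length(red)] + 1L
      gapEnd <- start(red)[-1L] - 1L
      keep <- gapEnd >= gapStart
      if (!any(keep)) next
      gapStart <- gapStart[keep]; gapEnd <- gapEnd[keep]
      leftName <- vapply(gapStart, function(p) {
        cand <- which(end(sub) == p - 1L)
        if (!length(cand)) cand <- which.max(end(sub)[end(sub) < p])
        mcols(sub)$name[cand[1]]
      }, character(1))
      rightName <- vapply(gapEnd, function(p) {
        cand <- which(start(sub) == p + 1L)
        mcols(sub)$name[cand[1]]
      }, character(1))
      w <- gapEnd - gapStart + 1L
      type <- ifelse(w < tuMax, "TU", "IGR")
      nm <- paste(leftName, rightName, type, sep = ".")
      res[[length(res) + 1L]] <- GRanges(
        chr, IRanges(gapStart, gapEnd), strand = st,
        feature_id = nm, ftype = type, name = nm,
        description = NA_character_)
    }
  }
  if (!length(res)) return(FeatureSet(genomeLengths = genomeLengths(fs)))
  out <- suppressWarnings(do.call(c, res))
  mcols(out)$feature_id <- make.unique(mcols(out)$feature_id, sep = "_")
  FeatureSet(out, genomeLengths = .slVector(seqlengths(gr)))
}

#' Compose the comprehensive annotation
#'
#' Union of the base annotation, predicted UTRs (truncated at neighbouring
#' same-strand transcripts), per-gene antisense features, and IGR/TU features
#' tiling the same-strand gaps of the base + predicted-UTR footprint. Output
#' is deterministically ordered by (chrom, start, strand). Base gene names
#' containing a period are rejected: the period is the naming delimiter of
#' derived features.
#'
#' @param base base [FeatureSet-class] (genes, sRNAs, tRNAs, rRNAs, curated
#'   UTRs).
#' @param utrLen maximum predicted-UTR extension (nt).
#' @param tuMax TU/IGR gap-length boundary (strictly-less-than rule).
#' @param skipIfKnown passed to [buildPredictedUTRs()].
#' @return A [FeatureSet-class] with all base and derived features.
#' @export
composeAnnotation <- function(base, utrLen = 100, tuMax = 100,
                              skipIfKnown = TRUE) {
  gr <- features(base)
  if (!length(gr)) return(base)
  if (any(grepl(".", mcols(gr)$name, fixed = TRUE)))
    stop("base feature names must not contain '.' (naming delimiter)")
  utrs <- buildPredictedUTRs(base, utrLen = utrLen, skipIfKnown = skipIfKnown)
  as_ <- buildAntisense(base)
  withUtrs <- FeatureSet(suppressWarnings(c(gr, features(utrs))),
                         genomeLengths = .slVector(seqlengths(gr)))
  igr <- buildIgrsTus(withUtrs, tuMax = tuMax)
  all_ <- suppressWarnings(c(gr, features(utrs), features(as_), features(igr)))
  if (anyDuplicated(mcols(all_)$feature_id))
    stop("duplicate feature_id in composed annotation: ",
         mcols(all_)$feature_id[duplicated(mcols(all_)$feature_id)][1])
  o <- order(as.character(seqnames(all_)), start(all_),
             as.character(strand(all_)))
  FeatureSet(all_[o], genomeLengths = .slVector(seqlengths(gr)))
}
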