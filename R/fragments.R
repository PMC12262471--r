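## Classification of mapped paired-end records into single and chimeric RNA
## fragments, library summary statistics, and strand-specific coverage.

#' Read mapped mate pairs from BEDPE
#'
#' Accepts standard 10-column BEDPE (`chrom1 start1 end1 chrom2 start2 end2
#' name score strand1 strand2`, 0-based half-open) or a minimal 9-column TSV
#' (`read_id chrom1 start1 end1 strand1 chrom2 start2 end2 strand2`).
#' Coordinates are converted to 1-based inclusive.
#'
#' @param path BEDPE/TSV file.
#' @param libraryReverse whether the library is reverse-stranded.
#' @param genomeLengths optional named chromosome lengths.
#' @return A [MatePairs-class].
#' @export
readBedpe <- function(path, libraryReverse = FALSE, genomeLengths = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) >= 10) {
    matePairs(readId = df[[7]],
              chrom1 = df[[1]], start1 = df[[2]] + 1L, end1 = df[[3]],
              strand1 = df[[9]],
              chrom2 = df[[4]], start2 = df[[5]] + 1L, end2 = df[[6]],
              strand2 = df[[10]],
              libraryReverse = libraryReverse, genomeLengths = genomeLengths)
  } else if (ncol(df) == 9) {
    matePairs(readId = df[[1]],
              chrom1 = df[[2]], start1 = df[[3]] + 1L, end1 = df[[4]],
              strand1 = df[[5]],
              chrom2 = df[[6]], start2 = df[[7]] + 1L, end2 = df[[8]],
              strand2 = df[[9]],
              libraryReverse = libraryReverse, genomeLengths = genomeLengths)
  } else stop("unrecognised mate-pair table: expected 9 or 10+ columns")
}

#' Write mate pairs as BEDPE
#'
#' @param mp a [MatePairs-class].
#' @param path output file (0-based half-open BEDPE).
#' @return `path`, invisibly.
#' @export
writeBedpe <- function(mp, path) {
  m1 <- mp@mate1; m2 <- mp@mate2
  df <- data.frame(
    chrom1 = as.character(seqnames(m1)), start1 = start(m1) - 1L, end1 = end(m1),
    chrom2 = as.character(seqnames(m2)), start2 = start(m2) - 1L, end2 = end(m2),
    name = mp@readId, score = 0L,
    strand1 = as.character(strand(m1)), strand2 = as.character(strand(m2)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname transcriptStrand
#' @export
setMethod("transcriptStrand", "MatePairs", function(x) {
  if (!x@libraryReverse) return(x)
  flip <- function(gr) {
    s <- as.character(strand(gr))
    strand(gr) <- ifelse(s == "+", "-", ifelse(s == "-", "+", s))
    gr
  }
  x@mate1 <- flip(x@mate1)
  x@mate2 <- flip(x@mate2)
  x
})

#' Classify mate pairs into single and chimeric fragments
#'
#' Aligned strands are first resolved to transcript strands (reverse-stranded
#' libraries are flipped). A pair is a *single* fragment iff both mates map to
#' the same chromosome and the same transcript strand with an inter-mate gap
#' of at most `maxGap` nucleotides; its locus is the merged interval.
#' Otherwise the pair is *chimeric*: RNA1 is the ligation-upstream locus
#' (taken from mate 1, the 5' side of the sequencing construct after strand
#' resolution) and RNA2 the other.
#'
#' @param mp a [MatePairs-class].
#' @param maxGap maximum inter-mate gap for single fragments (nt).
#' @return A [FragmentSet-class].
#' @export
classifyFragments <- function(mp, maxGap = 1000) {
  mp <- transcriptStrand(mp)
  m1 <- mp@mate1; m2 <- mp@mate2
  if (!length(m1))
    return(new("FragmentSet", singles = GRanges(), rna1 = GRanges(),
               rna2 = GRanges()))
  sameChrom <- as.character(seqnames(m1)) == as.character(seqnames(m2))
  sameStrand <- as.character(strand(m1)) == as.character(strand(m2))
  gap <- pmax(start(m1), start(m2)) - pmin(end(m1), end(m2)) - 1L
  isSingle <- sameChrom & sameStrand & gap <= maxGap

  si <- seqinfo(m1)
  singles <- GRanges(seqnames(m1)[isSingle],
                     IRanges(pmin(start(m1), start(m2))[isSingle],
                             pmax(end(m1), end(m2))[isSingle]),
                     strand = strand(m1)[isSingle], seqinfo = si)
  mcols(singles)$read_id <- mp@readId[isSingle]
  rna1 <- m1[!isSingle]; rna2 <- m2[!isSingle]
  mcols(rna1)$read_id <- mp@readId[!isSingle]
  mcols(rna2)$read_id <- mp@readId[!isSingle]
  new("FragmentSet", singles = singles, rna1 = rna1, rna2 = rna2)
}

#' Exclude fragments overlapping masked features
#'
#' Removes single fragments overlapping a mask (e.g. rRNA loci) and chimeras
#' with either locus overlapping it, mirroring the up-front exclusion of
#' ribosomal reads in depleted libraries. Overlap is same-strand unless
#' `ignoreStrand` is set.
#'
#' @param frags a [FragmentSet-class].
#' @param mask `GRanges` of loci to exclude (e.g. rRNA genes).
#' @param ignoreStrand mask regardless of strand (default TRUE: rRNA reads
#'   are excluded wherever they map).
#' @return A filtered [FragmentSet-class].
#' @export
maskFeatures <- function(frags, mask, ignoreStrand = TRUE) {
  dropS <- overlapsAny(frags@singles, mask, ignore.strand = ignoreStrand)
  dropC <- overlapsAny(frags@rna1, mask, ignore.strand = ignoreStrand) |
    overlapsAny(frags@rna2, mask, ignore.strand = ignoreStrand)
  new("FragmentSet", singles = frags@singles[!dropS],
      rna1 = frags@rna1[!dropC], rna2 = frags@rna2[!dropC])
}

#' Library-level fragment statistics
#'
#' @param frags a [FragmentSet-class].
#' @return A list with `nSingle`, `nChimeric` and `chimeraFraction`
#'   (`nChimeric / (nSingle + nChimeric)`; 0 with a warning for an empty
#'   library).
#' @export
libraryStats <- function(frags) {
  ns <- length(frags@singles); nc <- length(frags@rna1)
  if (ns + nc == 0) {
    warning("empty library: chimera fraction undefined, reporting 0")
    frac <- 0
  } else frac <- nc / (ns + nc)
  list(nSingle = ns, nChimeric = nc, chimeraFraction = frac)
}

#' Per-strand coverage of fragment loci
#'
#' Position-wise count of fragment loci overlapping each base, separately per
#' strand. Chimeric fragments contribute both loci.
#'
#' @param frags a [FragmentSet-class].
#' @param genomeLengths named chromosome lengths; fragments beyond bounds
#'   raise an error.
#' @return A list of two `RleList` coverage vectors, named `"+"` and `"-"`.
#' @export
coverageTrack <- function(frags, genomeLengths) {
  loci <- suppressWarnings(c(granges0(frags@singles), granges0(frags@rna1),
                             granges0(frags@rna2)))
  sl <- genomeLengths[as.character(seqnames(loci))]
  if (any(is.na(sl)) || any(end(loci) > sl) || any(start(loci) < 1))
    stop("fragment beyond genome bounds")
  si <- Seqinfo(names(genomeLengths), unname(genomeLengths))
  loci <- GRanges(as.character(seqnames(loci)),
                  IRanges(start(loci), end(loci)),
                  strand = strand(loci), seqinfo = si)
  lapply(setNames(c("+", "-"), c("+", "-")), function(st)
    coverage(loci[as.character(strand(loci)) == st]))
}

## strip mcols so GRanges concatenate cleanly
granges0 <- function(gr) {
  GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand = strand(gr))
}

#' Write coverage as fixed-step wiggle tracks
#'
#' One file per strand (`<prefix>_plus.wig`, `<prefix>_minus.wig`), fixedStep
#' with step 1 from position 1.
#'
#' @param track output of [coverageTrack()].
#' @param prefix output path prefix.
#' @return The two file paths, invisibly.
#' @export
writeWiggle <- function(track, prefix) {
  paths <- c(paste0(prefix, "_plus.wig"), paste0(prefix, "_minus.wig"))
  for (k in 1:2) {
    cov <- track[[c("+", "-")[k]]]
    con <- file(paths[k], "w")
    for (chr in names(cov)) {
      writeLines(sprintf("fixedStep chrom=%s start=1 step=1", chr), con)
      writeLines(as.character(as.integer(as.vector(cov[[chr]]))), con)
    }
    close(con)
  }
  invisible(paths)
}
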