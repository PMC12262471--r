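## S-chimera calling: binning of chimeras over ordered window pairs,
## one-sided Fisher's exact enrichment, merging of adjacent significant
## window pairs into maximal region pairs, filtering of non-specific
## chimeras, and gene assignment with the >0.7 read-share rule.

#' Bin chimeric fragments over ordered window pairs
#'
#' The genome is partitioned per strand into fixed windows of
#' `params@window` nucleotides; each chimera is assigned to the ordered
#' window pair containing the midpoints of its RNA1 and RNA2 loci. Marginal
#' totals (`n_a`: chimeras whose RNA1 midpoint falls in the RNA1-side window,
#' `n_b`: likewise for RNA2) and the library total `total` accompany each
#' pair count `n_ab`.
#'
#' @param frags a [FragmentSet-class].
#' @param params an [AnalysisParams-class].
#' @return A data.frame with one row per observed ordered window pair:
#'   `chrom1, strand1, win1, chrom2, strand2, win2, n_ab, n_a, n_b, total`
#'   (window indices are 0-based multiples of the window size).
#' @export
binChimeras <- function(frags, params = analysisParams()) {
  r1 <- frags@rna1; r2 <- frags@rna2
  W <- params@window
  if (!length(r1))
    return(data.frame(chrom1 = character(), strand1 = character(),
                      win1 = integer(), chrom2 = character(),
                      strand2 = character(), win2 = integer(),
                      n_ab = integer(), n_a = integer(), n_b = integer(),
                      total = integer()))
  mid <- function(gr) (start(gr) + end(gr)) %/% 2L
  dt <- data.table(
    chrom1 = as.character(seqnames(r1)), strand1 = as.character(strand(r1)),
    win1 = as.integer((mid(r1) - 1L) %/% W),
    chrom2 = as.character(seqnames(r2)), strand2 = as.character(strand(r2)),
    win2 = as.integer((mid(r2) - 1L) %/% W))
  bins <- dt[, list(n_ab = .N),
             by = c("chrom1", "strand1", "win1", "chrom2", "strand2", "win2")]
  bins[, n_a := sum(n_ab), by = c("chrom1", "strand1", "win1")]
  bins[, n_b := sum(n_ab), by = c("chrom2", "strand2", "win2")]
  bins[, "total" := length(r1)]
  setorder(bins, chrom1, strand1, win1, chrom2, strand2, win2)
  as.data.frame(bins)
}

#' One-sided Fisher's exact test for window-pair enrichment
#'
#' For the 2x2 table `a = nAB`, `b = nA - nAB`, `c = nB - nAB`,
#' `d = total - nA - nB + nAB`, returns the upper-tail hypergeometric
#' probability `P(X >= a)` for a population of `total` chimeras with `nA`
#' successes and `nB` draws, together with the sample odds ratio
#' `(a d)/(b c)` (by convention `Inf` when `b c = 0` and `a d > 0`, `NaN`
#' when both products are 0).
#'
#' All arguments are vectorised.
#'
#' @param nAB chimeras joining the RNA1 window to the RNA2 window.
#' @param nA total chimeras with RNA1 in the RNA1-side window.
#' @param nB total chimeras with RNA2 in the RNA2-side window.
#' @param total total chimeras in the library.
#' @return data.frame with columns `odds_ratio` and `p_value`.
#' @export
fisherOneSided <- function(nAB, nA, nB, total) {
  a <- nAB; b <- nA - nAB; c_ <- nB - nAB; d <- total - nA - nB + nAB
  if (any(c(a, b, c_, d) < 0)) stop("negative contingency cell")
  p <- phyper(a - 1, nA, total - nA, nB, lower.tail = FALSE)
  num <- a * d; den <- b * c_
  or <- ifelse(den == 0, ifelse(num > 0, Inf, NaN), num / den)
  data.frame(odds_ratio = or, p_value = p)
}

## Union-find merge of significant window pairs: two significant pairs touch
## when they share strands/chroms and their window indices differ by at most
## one in BOTH dimensions (8-neighbourhood, so diagonally touching runs of
## signal merge into one region pair).
.mergeComponents <- function(sig) {
  n <- nrow(sig)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  key <- paste(sig$chrom1, sig$strand1, sig$chrom2, sig$strand2)
  for (g in split(seq_len(n), key)) {
    if (length(g) < 2) next
    for (ii in seq_along(g)[-1]) {
      i <- g[ii]
      for (j in g[seq_len(ii - 1)]) {
        if (abs(sig$win1[i] - sig$win1[j]) <= 1 &&
            abs(sig$win2[i] - sig$win2[j]) <= 1) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[ri] <- rj
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Call significant interacting region pairs (S-chimeras)
#'
#' Window pairs with at least `params@minChimeras` chimeras and a one-sided
#' Fisher p-value below `params@alpha` are significant; touching significant
#' window pairs (adjacent in both dimensions, same strands and chromosomes)
#' are merged into maximal region pairs. Each merged region pair is one
#' S-chimera; its `interactions` count is the number of chimeras whose locus
#' midpoints fall inside the merged region pair, and its p-value is the
#' minimum over the merged windows. When an annotation is supplied, genes are
#' assigned to each region with [assignGenes()].
#'
#' @param frags a [FragmentSet-class].
#' @param annotation optional [FeatureSet-class] for gene assignment.
#' @param params an [AnalysisParams-class].
#' @param pAdjust `"none"` (default, matching the published thresholds) or
#'   `"BH"` for optional Benjamini-Hochberg adjustment of the window-pair
#'   p-values before thresholding.
#' @param chromosomes optional chromosome whitelist; chimeras with either
#'   locus outside it are ignored.
#' @return An [SChimeraSet-class].
#' @export
callSChimeras <- function(frags, annotation = NULL,
                          params = analysisParams(),
                          pAdjust = c("none", "BH"),
                          chromosomes = NULL) {
  pAdjust <- match.arg(pAdjust)
  if (!is.null(chromosomes)) {
    keep <- as.character(seqnames(frags@rna1)) %in% chromosomes &
      as.character(seqnames(frags@rna2)) %in% chromosomes
    frags <- new("FragmentSet", singles = frags@singles,
                 rna1 = frags@rna1[keep], rna2 = frags@rna2[keep])
  }
  bins <- binChimeras(frags, params)
  W <- params@window
  empty <- DataFrame(chrom1 = character(), strand1 = character(),
                     start1 = integer(), end1 = integer(),
                     chrom2 = character(), strand2 = character(),
                     start2 = integer(), end2 = integer(),
                     interactions = integer(), odds_ratio = numeric(),
                     p_value = numeric(), rna1_name = character(),
                     rna2_name = character())
  if (!nrow(bins))
    return(new("SChimeraSet", table = empty, params = params,
               totalChimeras = 0))
  ft <- fisherOneSided(bins$n_ab, bins$n_a, bins$n_b, bins$total)
  bins$odds_ratio <- ft$odds_ratio
  bins$p_value <- if (pAdjust == "BH") p.adjust(ft$p_value, "BH") else
    ft$p_value
  sig <- bins[bins$n_ab >= params@minChimeras & bins$p_value < params@alpha, ]
  if (!nrow(sig))
    return(new("SChimeraSet", table = empty, params = params,
               totalChimeras = bins$total[1]))
  comp <- .mergeComponents(sig)
  rows <- lapply(split(seq_len(nrow(sig)), comp), function(idx) {
    s <- sig[idx, ]
    w1a <- min(s$win1); w1b <- max(s$win1)
    w2a <- min(s$win2); w2b <- max(s$win2)
    inside <- bins$chrom1 == s$chrom1[1] & bins$strand1 == s$strand1[1] &
      bins$chrom2 == s$chrom2[1] & bins$strand2 == s$strand2[1] &
      bins$win1 >= w1a & bins$win1 <= w1b &
      bins$win2 >= w2a & bins$win2 <= w2b
    best <- which.min(s$p_value)
    data.frame(chrom1 = s$chrom1[1], strand1 = s$strand1[1],
               start1 = as.integer(w1a * W + 1), end1 = as.integer((w1b + 1) * W),
               chrom2 = s$chrom2[1], strand2 = s$strand2[1],
               start2 = as.integer(w2a * W + 1), end2 = as.integer((w2b + 1) * W),
               interactions = sum(bins$n_ab[inside]),
               odds_ratio = s$odds_ratio[best], p_value = s$p_value[best],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$p_value, tab$chrom1, tab$start1, tab$start2), ]
  rownames(tab) <- NULL

  tab$rna1_name <- NA_character_
  tab$rna2_name <- NA_character_
  if (!is.null(annotation)) {
    for (i in seq_len(nrow(tab))) {
      reads <- .regionChimeras(frags, tab[i, ], W)
      r1 <- GRanges(tab$chrom1[i], IRanges(tab$start1[i], tab$end1[i]),
                    strand = tab$strand1[i])
      r2 <- GRanges(tab$chrom2[i], IRanges(tab$start2[i], tab$end2[i]),
                    strand = tab$strand2[i])
      tab$rna1_name[i] <- paste(
        assignGenes(r1, reads$rna1, annotation, params@assignRatio),
        collapse = ",")
      tab$rna2_name[i] <- paste(
        assignGenes(r2, reads$rna2, annotation, params@assignRatio),
        collapse = ",")
    }
  }
  new("SChimeraSet", table = DataFrame(tab), params = params,
      totalChimeras = bins$total[1])
}

## chimeric loci whose midpoints fall in a merged region pair
.regionChimeras <- function(frags, row, W) {
  r1 <- frags@rna1; r2 <- frags@rna2
  m1 <- (start(r1) + end(r1)) %/% 2L
  m2 <- (start(r2) + end(r2)) %/% 2L
  keep <- as.character(seqnames(r1)) == row$chrom1 &
    as.character(strand(r1)) == row$strand1 &
    as.character(seqnames(r2)) == row$chrom2 &
    as.character(strand(r2)) == row$strand2 &
    m1 >= row$start1 & m1 <= row$end1 &
    m2 >= row$start2 & m2 <= row$end2
  list(rna1 = r1[keep], rna2 = r2[keep])
}

#' Filter chimeras outside significant region pairs
#'
#' Chimeras outside statistically significant regions are treated as
#' non-specific: a chimera is retained iff the midpoints of both of its loci
#' fall within the region pair of some single S-chimera, respecting the
#' RNA1/RNA2 orientation. Single fragments are untouched.
#'
#' @param frags a [FragmentSet-class].
#' @param schimeras an [SChimeraSet-class].
#' @return A [FragmentSet-class] with only the retained chimeras.
#' @export
filterNonsignificant <- function(frags, schimeras) {
  tab <- schimeras@table
  r1 <- frags@rna1; r2 <- frags@rna2
  if (!length(r1) || !nrow(tab))
    return(new("FragmentSet", singles = frags@singles,
               rna1 = r1[integer(0)], rna2 = r2[integer(0)]))
  m1 <- (start(r1) + end(r1)) %/% 2L
  m2 <- (start(r2) + end(r2)) %/% 2L
  keep <- logical(length(r1))
  for (i in seq_len(nrow(tab))) {
    keep <- keep | (
      as.character(seqnames(r1)) == tab$chrom1[i] &
        as.character(strand(r1)) == tab$strand1[i] &
        as.character(seqnames(r2)) == tab$chrom2[i] &
        as.character(strand(r2)) == tab$strand2[i] &
        m1 >= tab$start1[i] & m1 <= tab$end1[i] &
        m2 >= tab$start2[i] & m2 <= tab$end2[i])
  }
  new("FragmentSet", singles = frags@singles,
      rna1 = r1[keep], rna2 = r2[keep])
}

#' Assign genes to an interacting region
#'
#' Overlapping-read counts are tallied per annotated feature (same-strand
#' overlap of at least one base). If the top feature accounts for strictly
#' more than `assignRatio` of the reads overlapping any feature, it is
#' assigned exclusively; otherwise all overlapping features are retained,
#' ordered by decreasing read share. A region whose reads overlap no feature
#' is labelled by the nearest same-strand feature with a `.near` suffix.
#'
#' @param region a single-range `GRanges` (the interacting region).
#' @param reads `GRanges` of the region's chimeric fragment loci.
#' @param annotation a [FeatureSet-class].
#' @param assignRatio exclusive-assignment threshold (strict `>`).
#' @return Character vector of assigned feature names.
#' @export
assignGenes <- function(region, reads, annotation, assignRatio = 0.7) {
  feats <- features(annotation)
  hits <- findOverlaps(reads, feats)
  if (!length(hits)) {
    d <- suppressWarnings(distance(region, feats, ignore.strand = FALSE))
    d[is.na(d)] <- Inf
    if (all(is.infinite(d))) return("unassigned.near")
    return(paste0(mcols(feats)$name[which.min(d)], ".near"))
  }
  denom <- length(unique(queryHits(hits)))
  cnt <- table(subjectHits(hits))
  share <- as.numeric(cnt) / denom
  o <- order(share, decreasing = TRUE)
  nm <- mcols(feats)$name[as.integer(names(cnt))][o]
  share <- share[o]
  if (share[1] > assignRatio) nm[1] else nm
}

#' Write the S-chimera interaction table
#'
#' TSV with RNA1/RNA2 region coordinates, assigned names, supporting chimera
#' count (`interactions`), odds ratio and p-value; one row per S-chimera.
#'
#' @param schimeras an [SChimeraSet-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeInteractionTable <- function(schimeras, path) {
  df <- as.data.frame(schimeras@table)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction table written by [writeInteractionTable()]
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readInteractionTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write Circos-style link records
#'
#' One line per S-chimera: `chrom start end chrom start end count`.
#'
#' @param schimeras an [SChimeraSet-class].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
circosLinks <- function(schimeras, path) {
  tab <- schimeras@table
  df <- data.frame(tab$chrom1, tab$start1, tab$end1,
                   tab$chrom2, tab$start2, tab$end2, tab$interactions)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
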