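## Generative model of chaperone-mediated RNA capture: miniature genomes
## with non-overlapping stranded features, and IP'd sequencing libraries with
## planted sRNA-mRNA chimeras, abundance-driven background ligation and
## single-fragment capture, plus a ground-truth table for recovery testing.

#' Default planted sRNA-mRNA interaction pairs
#'
#' Pairs `srnaNN` with `mrnaNN` using the deterministic feature names emitted
#' by [simulateGenome()]. Relative intensities are spread geometrically over
#' \[0.5, 2\] so recovery tests exercise both strong and weak pairs.
#'
#' @param n number of pairs.
#' @return data.frame with columns `srna_id`, `target_id`, `lambda`.
#' @export
defaultPlantedPairs <- function(n = 20) {
  if (n == 0)
    return(data.frame(srna_id = character(), target_id = character(),
                      lambda = numeric()))
  data.frame(srna_id = sprintf("srna%02d", seq_len(n)),
             target_id = sprintf("mrna%02d", seq_len(n)),
             lambda = 2^seq(-1, 1, length.out = n))
}

#' Construct a simulation configuration
#'
#' Defaults emulate a wild-type RIL-seq capture regime: with
#' `pLig = 0.5`, `rho = 0.3` and `epsilon = 0.02` the expected chimera
#' fraction `pLig (rho (1 - epsilon) + epsilon)` is about 15% of captured
#' fragments, matching wild-type libraries; the `irilseq` protocol default
#' (`pLig = 0.055`) gives about 1.7%. Rim-mutant regimes are derived with
#' [strainScenarios()].
#'
#' @param genomeLength genome size (nt).
#' @param nMrna,nSrna,nTrna,nRrna feature counts.
#' @param plantedPairs data.frame of planted interactions; defaults to
#'   [defaultPlantedPairs()] over `min(nSrna, nMrna, 20)` pairs.
#' @param rho chimera retention probability (strain effect).
#' @param epsilon background random-ligation probability.
#' @param pLig protocol ligation efficiency; default 0.5 for `rilseq`,
#'   0.055 for `irilseq`, 0 for `ripseq`.
#' @param nFragments number of captured fragments.
#' @param fragLenMean,fragLenSd mate length distribution (truncated at
#'   15 nt).
#' @param protocol `rilseq`, `irilseq` or `ripseq`.
#' @param libraryReverse emit aligned strands reverse-complemented
#'   (reverse-stranded library design).
#' @param seed integer seed; the genome and the library draw from streams
#'   derived from it.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(genomeLength = 150000,
                             nMrna = 40, nSrna = 20, nTrna = 6, nRrna = 3,
                             plantedPairs = NULL,
                             rho = 0.3, epsilon = 0.02, pLig = NULL,
                             nFragments = 20000,
                             fragLenMean = 30, fragLenSd = 8,
                             protocol = "rilseq",
                             libraryReverse = TRUE, seed = 1) {
  if (is.null(pLig))
    pLig <- switch(protocol, rilseq = 0.5, irilseq = 0.055, ripseq = 0,
                   stop("unknown protocol: ", protocol))
  if (is.null(plantedPairs))
    plantedPairs <- defaultPlantedPairs(min(nSrna, nMrna, 20))
  new("SimulationConfig", genomeLength = genomeLength,
      nMrna = nMrna, nSrna = nSrna, nTrna = nTrna, nRrna = nRrna,
      plantedPairs = plantedPairs, rho = rho, epsilon = epsilon,
      pLig = pLig, nFragments = nFragments,
      fragLenMean = fragLenMean, fragLenSd = fragLenSd,
      protocol = protocol, libraryReverse = libraryReverse, seed = seed)
}

#' Derive wild-type and rim-mutant strain scenarios
#'
#' The rim-mutant (R16A-like) scenario scales the chimera retention
#' probability `rho` by a protocol-dependent factor — by default 1/100 under
#' `rilseq` and 1/10 under `irilseq` — expressing dissociation of paired RNAs
#' from the mutant chaperone during capture, which the in-vitro-heavy
#' protocol suffers more.
#'
#' @param base a [SimulationConfig-class].
#' @param factor retention scaling for the mutant; defaults by protocol.
#' @return list with elements `WT` and `R16A`.
#' @export
strainScenarios <- function(base, factor = NULL) {
  if (is.null(factor))
    factor <- switch(base@protocol, rilseq = 1 / 100, irilseq = 1 / 10, 1)
  mut <- base
  mut@rho <- base@rho * factor
  list(WT = base, R16A = mut)
}

#' Simulate a miniature annotated genome
#'
#' Places non-overlapping stranded features with realistic length ranges
#' (mRNAs 300-3000 nt, sRNAs 50-300 nt, tRNAs 70-90 nt, rRNAs 1400-2900 nt)
#' along a random-sequence chromosome named `chr`, separated by
#' lognormal-distributed gaps (median ~150 nt, so both sub-100-nt TU gaps and
#' long intergenic gaps occur). Deterministic given the config seed.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `genome` (`DNAStringSet`) and `annotation`
#'   ([FeatureSet-class]).
#' @export
simulateGenome <- function(config) {
  set.seed(as.integer(config@seed))
  n <- c(mrna = config@nMrna, srna = config@nSrna,
         trna = config@nTrna, rrna = config@nRrna)
  lens <- c(
    if (n["mrna"]) sample(300:3000, n["mrna"], replace = TRUE),
    if (n["srna"]) sample(50:300, n["srna"], replace = TRUE),
    if (n["trna"]) sample(70:90, n["trna"], replace = TRUE),
    if (n["rrna"]) sample(1400:2900, n["rrna"], replace = TRUE))
  types <- rep(c("gene", "sRNA", "tRNA", "rRNA"), times = n)
  nms <- c(
    if (n["mrna"]) sprintf("mrna%02d", seq_len(n["mrna"])),
    if (n["srna"]) sprintf("srna%02d", seq_len(n["srna"])),
    if (n["trna"]) sprintf("trna%02d", seq_len(n["trna"])),
    if (n["rrna"]) sprintf("rrna%02d", seq_len(n["rrna"])))
  total <- length(lens)
  if (total == 0) {
    genome <- DNAStringSet(paste(sample(c("A", "C", "G", "T"),
                                        config@genomeLength, replace = TRUE),
                                 collapse = ""))
    names(genome) <- "chr"
    return(list(genome = genome,
                annotation = FeatureSet(
                  genomeLengths = c(chr = config@genomeLength))))
  }
  ord <- sample(total)
  gaps <- pmax(20, round(rlnorm(total + 1, meanlog = log(150), sdlog = 1)))
  if (sum(lens) + sum(gaps) > config@genomeLength)
    stop("features cannot be placed: increase genomeLength (need >= ",
         sum(lens) + sum(gaps), " nt)")
  starts <- integer(total)
  pos <- 0L
  for (i in seq_len(total)) {
    pos <- pos + gaps[i]
    starts[ord[i]] <- pos + 1L
    pos <- pos + lens[ord[i]]
  }
  strands <- sample(c("+", "-"), total, replace = TRUE)
  gr <- GRanges("chr", IRanges(starts, width = lens), strand = strands,
                seqinfo = Seqinfo("chr", config@genomeLength))
  mcols(gr)$feature_id <- nms
  mcols(gr)$ftype <- types
  mcols(gr)$name <- nms
  mcols(gr)$description <- NA_character_
  gr <- gr[order(start(gr))]
  seqchars <- sample(c("A", "C", "G", "T"), config@genomeLength,
                     replace = TRUE)
  genome <- DNAStringSet(paste(seqchars, collapse = ""))
  names(genome) <- "chr"
  list(genome = genome, annotation = FeatureSet(gr))
}

.truncLen <- function(n, mean, sd) pmax(15L, as.integer(round(rnorm(n, mean, sd))))

## an interval of length len placed around center, clipped into [lo, hi]
.clipInterval <- function(center, len, lo, hi) {
  len <- pmin(len, hi - lo + 1L)
  s <- as.integer(round(center - len / 2))
  s <- pmax(lo, pmin(s, hi - len + 1L))
  cbind(s, s + len - 1L)
}

#' Simulate an IP'd sequencing library
#'
#' For each of `nFragments` captured events: with probability
#' `pLig * rho * (1 - epsilon)` a planted pair is drawn proportionally to its
#' intensity `lambda` and a chimeric mate pair is emitted, one mate per
#' partner, positioned around a fixed per-pair interaction site (uniform
#' scatter of +/-30 nt) with truncated-normal lengths; with probability
#' `pLig * epsilon` a background chimera joins two abundance-weighted random
#' transcript loci; otherwise a single fragment (two inward mates within one
#' feature chosen proportionally to log-uniform expression weights) is
#' emitted. Planted chimeras follow the mRNA-first convention: the target
#' mRNA is RNA1 (mate 1), the sRNA is RNA2 (mate 2). The `ripseq` protocol
#' forces the ligation efficiency to zero (no chimeras). Aligned strands are
#' reverse-complemented when `libraryReverse` is set.
#'
#' @param config a [SimulationConfig-class].
#' @param genome `DNAStringSet` from [simulateGenome()] (unused by the
#'   positional model but kept for interface symmetry).
#' @param annotation [FeatureSet-class] from [simulateGenome()].
#' @return list with `matePairs` ([MatePairs-class]) and `truth` (list with
#'   `origin` — per-fragment `"single"`, `"planted"` or `"background"` — and
#'   `pairs` — per planted pair `expected` and `realized` chimera counts).
#' @export
simulateLibrary <- function(config, genome, annotation) {
  set.seed(as.integer(config@seed) + 1L)
  feats <- features(annotation)
  nf <- length(feats)
  if (!nf) stop("annotation has no features")
  fnames <- mcols(feats)$name
  weights <- exp(runif(nf, log(1), log(100)))

  pp <- config@plantedPairs
  if (nrow(pp)) {
    miss <- setdiff(c(pp$srna_id, pp$target_id), fnames)
    if (length(miss))
      stop("planted pair references unknown feature: ", miss[1])
  }
  siteIn <- function(idx) {
    s <- start(feats)[idx]; e <- end(feats)[idx]
    lo <- pmin(s + 40L, (s + e) %/% 2L)
    hi <- pmax(e - 40L, (s + e) %/% 2L)
    as.integer(round(runif(length(idx), lo, hi)))
  }
  if (nrow(pp)) {
    iSrna <- match(pp$srna_id, fnames)
    iMrna <- match(pp$target_id, fnames)
    siteSrna <- siteIn(iSrna)
    siteMrna <- siteIn(iMrna)
  }

  pLig <- if (config@protocol == "ripseq") 0 else config@pLig
  pChim <- pLig * config@rho * (1 - config@epsilon) * (nrow(pp) > 0)
  pBg <- pLig * config@epsilon
  nFrag <- as.integer(config@nFragments)
  cat_ <- sample(c("planted", "background", "single"), nFrag, replace = TRUE,
                 prob = c(pChim, pBg, 1 - pChim - pBg))

  chrom <- "chr"
  m1s <- integer(nFrag); m1e <- integer(nFrag); m1st <- character(nFrag)
  m2s <- integer(nFrag); m2e <- integer(nFrag); m2st <- character(nFrag)

  ## planted chimeras
  ip <- which(cat_ == "planted")
  realized <- integer(nrow(pp))
  if (length(ip)) {
    k <- sample.int(nrow(pp), length(ip), replace = TRUE, prob = pp$lambda)
    realized <- tabulate(k, nbins = nrow(pp))
    lenM <- .truncLen(length(ip), config@fragLenMean, config@fragLenSd)
    lenS <- .truncLen(length(ip), config@fragLenMean, config@fragLenSd)
    cM <- siteMrna[k] + as.integer(round(runif(length(ip), -30, 30)))
    cS <- siteSrna[k] + as.integer(round(runif(length(ip), -30, 30)))
    im <- iMrna[k]; is_ <- iSrna[k]
    xm <- .clipInterval(cM, lenM, start(feats)[im], end(feats)[im])
    xs <- .clipInterval(cS, lenS, start(feats)[is_], end(feats)[is_])
    m1s[ip] <- xm[, 1]; m1e[ip] <- xm[, 2]
    m1st[ip] <- as.character(strand(feats))[im]
    m2s[ip] <- xs[, 1]; m2e[ip] <- xs[, 2]
    m2st[ip] <- as.character(strand(feats))[is_]
  }

  ## background chimeras: independent abundance-weighted loci
  ib <- which(cat_ == "background")
  if (length(ib)) {
    f1 <- sample.int(nf, length(ib), replace = TRUE, prob = weights)
    f2 <- sample.int(nf, length(ib), replace = TRUE, prob = weights)
    len1 <- .truncLen(length(ib), config@fragLenMean, config@fragLenSd)
    len2 <- .truncLen(length(ib), config@fragLenMean, config@fragLenSd)
    c1 <- as.integer(round(runif(length(ib), start(feats)[f1], end(feats)[f1])))
    c2 <- as.integer(round(runif(length(ib), start(feats)[f2], end(feats)[f2])))
    x1 <- .clipInterval(c1, len1, start(feats)[f1], end(feats)[f1])
    x2 <- .clipInterval(c2, len2, start(feats)[f2], end(feats)[f2])
    m1s[ib] <- x1[, 1]; m1e[ib] <- x1[, 2]
    m1st[ib] <- as.character(strand(feats))[f1]
    m2s[ib] <- x2[, 1]; m2e[ib] <- x2[, 2]
    m2st[ib] <- as.character(strand(feats))[f2]
  }

  ## single fragments: two inward mates within one feature
  isg <- which(cat_ == "single")
  if (length(isg)) {
    f <- sample.int(nf, length(isg), replace = TRUE, prob = weights)
    lenA <- .truncLen(length(isg), config@fragLenMean, config@fragLenSd)
    lenB <- .truncLen(length(isg), config@fragLenMean, config@fragLenSd)
    gap <- as.integer(round(runif(length(isg), 0, 150)))
    span <- lenA + gap + lenB
    fs <- start(feats)[f]; fe <- end(feats)[f]
    span <- pmin(span, fe - fs + 1L)
    a <- as.integer(round(runif(length(isg), fs, pmax(fs, fe - span + 1L))))
    b <- a + span - 1L
    lenA2 <- pmin(lenA, span); lenB2 <- pmax(pmin(lenB, span - lenA2), 1L)
    m1s[isg] <- a; m1e[isg] <- a + lenA2 - 1L
    m2s[isg] <- b - lenB2 + 1L; m2e[isg] <- b
    st <- as.character(strand(feats))[f]
    m1st[isg] <- st; m2st[isg] <- st
  }

  t1 <- m1st; t2 <- m2st
  if (config@libraryReverse) {
    t1 <- ifelse(t1 == "+", "-", "+")
    t2 <- ifelse(t2 == "+", "-", "+")
  }
  mp <- matePairs(readId = sprintf("frag%07d", seq_len(nFrag)),
                  chrom1 = rep(chrom, nFrag), start1 = m1s, end1 = m1e,
                  strand1 = t1,
                  chrom2 = rep(chrom, nFrag), start2 = m2s, end2 = m2e,
                  strand2 = t2,
                  libraryReverse = config@libraryReverse,
                  genomeLengths = genomeLengths(annotation))
  pairs <- if (nrow(pp)) {
    data.frame(srna_id = pp$srna_id, target_id = pp$target_id,
               lambda = pp$lambda,
               expected = nFrag * pChim * pp$lambda / sum(pp$lambda),
               realized = realized)
  } else data.frame(srna_id = character(), target_id = character(),
                    lambda = numeric(), expected = numeric(),
                    realized = integer())
  list(matePairs = mp, truth = list(origin = cat_, pairs = pairs))
}

#' Write a simulation config as JSON
#'
#' @param config a [SimulationConfig-class].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeSimulationConfig <- function(config, path) {
  sl <- methods::slotNames(class(config))
  lst <- lapply(sl, function(s) methods::slot(config, s))
  names(lst) <- sl
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
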