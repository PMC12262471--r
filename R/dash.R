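## DASH sgRNA pool design: PAM scanning over target regions, composition and
## thermodynamic filters, exact-match off-target discard, and oligo emission
## as T7 promoter + protospacer + scaffold.

#' Fixed affixes of DASH sgRNA template oligos
#'
#' Each 60-nt template oligo is `T7_PROMOTER + protospacer + SGRNA_SCAFFOLD`
#' (5' to 3').
#'
#' @format 20-character strings.
#' @name oligo-affixes
NULL

#' @rdname oligo-affixes
#' @export
T7_PROMOTER <- "TTCTAATACGACTCACTATA"

#' @rdname oligo-affixes
#' @export
SGRNA_SCAFFOLD <- "GTTTTAGAGCTAGAAATAGC"

.asGenome <- function(genome) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  if (is(genome, "DNAString")) genome <- DNAStringSet(genome)
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    names(genome) <- paste0("chr", seq_along(genome))
  names(genome) <- sub("\\s.*", "", names(genome))
  genome
}

.asTargets <- function(targets) {
  if (is.character(targets)) {
    targets <- rtracklayer::import(targets, format = "bed")
  }
  if (is.null(names(targets)) && !is.null(mcols(targets)$name))
    names(targets) <- mcols(targets)$name
  if (is.null(names(targets)))
    names(targets) <- sprintf("target_%03d", seq_along(targets))
  targets
}

#' Scan target regions for Cas9 PAM-adjacent protospacers
#'
#' Every position where a 3-mer matches NGG on either strand, with at least
#' 20 nt available 5' of the PAM on that strand, yields one candidate whose
#' 20-nt protospacer overlaps a target region. Reverse-strand protospacers
#' are reported as reverse complements; protospacers containing ambiguous
#' bases (N) are skipped.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param targets `GRanges` of regions to deplete, or BED path (0-based
#'   half-open).
#' @return A [GuideSet-class] with one row per candidate.
#' @export
scanPamSites <- function(genome, targets) {
  genome <- .asGenome(genome)
  targets <- .asTargets(targets)
  rows <- list()
  for (chr in names(genome)) {
    subject <- genome[[chr]]
    len <- length(subject)
    tchr <- targets[as.character(seqnames(targets)) == chr]
    if (!length(tchr)) next

    ## plus strand: PAM = [q, q+2] with GG at q+1; protospacer [q-20, q-1]
    gg <- start(matchPattern("GG", subject))
    q <- gg - 1L
    q <- q[q >= 21L & q + 2L <= len]
    if (length(q)) {
      ps <- q - 20L; pe <- q - 1L
      keep <- overlapsAny(IRanges(ps, pe), IRanges(start(tchr), end(tchr)))
      for (k in which(keep)) {
        proto <- as.character(subseq(subject, ps[k], pe[k]))
        if (grepl("[^ACGT]", proto)) next
        pam <- as.character(subseq(subject, q[k], q[k] + 2L))
        if (grepl("[^ACGT]", pam)) next
        hit <- which(start(tchr) <= pe[k] & end(tchr) >= ps[k])[1]
        rows[[length(rows) + 1L]] <- data.frame(
          target_region_id = names(tchr)[hit], chrom = chr, strand = "+",
          proto_start = ps[k], proto_end = pe[k],
          protospacer = proto, pam = pam, stringsAsFactors = FALSE)
      }
    }

    ## minus strand: plus-coords CCN at [p, p+2]; protospacer [p+3, p+22]
    cc <- start(matchPattern("CC", subject))
    p <- cc[cc + 22L <= length(subject)]
    if (length(p)) {
      ps <- p + 3L; pe <- p + 22L
      keep <- overlapsAny(IRanges(ps, pe), IRanges(start(tchr), end(tchr)))
      for (k in which(keep)) {
        fwd <- subseq(subject, ps[k], pe[k])
        proto <- as.character(reverseComplement(fwd))
        if (grepl("[^ACGT]", proto)) next
        pam <- as.character(reverseComplement(subseq(subject, p[k], p[k] + 2L)))
        if (grepl("[^ACGT]", pam)) next
        hit <- which(start(tchr) <= pe[k] & end(tchr) >= ps[k])[1]
        rows[[length(rows) + 1L]] <- data.frame(
          target_region_id = names(tchr)[hit], chrom = chr, strand = "-",
          proto_start = ps[k], proto_end = pe[k],
          protospacer = proto, pam = pam, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_region_id = character(), chrom = character(),
               strand = character(), proto_start = integer(),
               proto_end = integer(), protospacer = character(),
               pam = character(), stringsAsFactors = FALSE)
  tab <- tab[order(tab$target_region_id, tab$chrom, tab$proto_start,
                   tab$strand), , drop = FALSE]
  rownames(tab) <- NULL
  new("GuideSet", table = DataFrame(tab))
}

## SantaLucia (unified) nearest-neighbour parameters:
## dH in kcal/mol, dS in cal/(mol K), 5'->3' top-strand dinucleotides.
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

#' Nearest-neighbour duplex melting temperature
#'
#' Two-state melting temperature of a perfect DNA duplex under the unified
#' nearest-neighbour model, with terminal initiation terms, an entropic salt
#' correction of `0.368 N ln[Na+]` and `Tm = 1000 dH / (dS + R ln(Ct/4)) -
#' 273.15`. Sequences shorter than 2 nt return `-Inf`.
#'
#' @param seq duplex top-strand sequence(s), 5'->3'.
#' @param ct total strand concentration (mol/L).
#' @param na monovalent cation concentration (mol/L).
#' @return Melting temperature(s) in degrees Celsius.
#' @export
nearestNeighborTm <- function(seq, ct = 2.5e-7, na = 0.05) {
  vapply(toupper(seq), function(s) {
    n <- nchar(s)
    if (n < 2) return(-Inf)
    nn <- substring(s, 1:(n - 1), 2:n)
    dh <- sum(.NN_DH[nn])
    ds <- sum(.NN_DS[nn])
    for (term in c(substr(s, 1, 1), substr(s, n, n))) {
      if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (n - 1) * log(na)
    1000 * dh / (ds + 1.987 * log(ct / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

## longest common substring (simple DP; inputs are short oligos)
.lcsub <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0 || nb == 0) return("")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0L; besti <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    for (j in seq_len(nb)) {
      if (av[i] == bv[j]) {
        cur[j] <- if (j > 1) prev[j - 1] + 1L else 1L
        if (cur[j] > best) { best <- cur[j]; besti <- i }
      }
    }
    prev <- cur
  }
  if (best == 0) "" else substr(a, besti - best + 1L, besti)
}

#' Heterodimer melting temperature against a primer
#'
#' The longest stretch of the candidate that is perfectly complementary to
#' the primer defines the potential heterodimer duplex; its
#' nearest-neighbour Tm is returned (`-Inf` when no duplex of at least 2 bp
#' exists).
#'
#' @param protospacer candidate sequence(s).
#' @param primer the amplification primer sequence.
#' @param ... passed to [nearestNeighborTm()].
#' @return Tm in degrees Celsius.
#' @export
heterodimerTm <- function(protospacer, primer, ...) {
  rcPrimer <- as.character(reverseComplement(DNAString(toupper(primer))))
  vapply(toupper(protospacer), function(p) {
    duplex <- .lcsub(p, rcPrimer)
    nearestNeighborTm(duplex, ...)
  }, numeric(1), USE.NAMES = FALSE)
}

#' 3'-end stability melting temperature
#'
#' Nearest-neighbour Tm of the duplex formed by the 3'-terminal
#' `endLen` nucleotides with their perfect complement; a proxy for the
#' propensity of the 3' end to prime extension.
#'
#' @param protospacer candidate sequence(s).
#' @param endLen number of 3'-terminal bases considered.
#' @param ... passed to [nearestNeighborTm()].
#' @return Tm in degrees Celsius.
#' @export
endStabilityTm <- function(protospacer, endLen = 5, ...) {
  ends <- substring(toupper(protospacer),
                    pmax(1L, nchar(protospacer) - endLen + 1L),
                    nchar(protospacer))
  nearestNeighborTm(ends, ...)
}

#' Filter guide candidates by composition and thermodynamics
#'
#' A candidate passes iff `gcMin < GC fraction < gcMax` (strict bounds), its
#' heterodimer Tm against `primer` is at most `heterodimerTmMax`, and its
#' 3'-end stability Tm is at most `endStabilityTmMax`. Per-filter flags are
#' recorded in the returned table together with the metrics.
#'
#' @param guides a [GuideSet-class] from [scanPamSites()].
#' @param primer amplification primer sequence the heterodimer Tm is
#'   evaluated against.
#' @param gcMin,gcMax GC-fraction bounds (strict).
#' @param heterodimerTmMax maximum heterodimer Tm (degrees C).
#' @param endStabilityTmMax maximum 3'-end stability Tm (degrees C).
#' @return A [GuideSet-class] with metric, flag and `pass` columns.
#' @export
filterGuides <- function(guides, primer, gcMin = 0.30, gcMax = 0.80,
                         heterodimerTmMax = 40, endStabilityTmMax = 30) {
  tab <- as.data.frame(guides@table)
  if (!nrow(tab)) {
    tab$gc_fraction <- numeric(0); tab$heterodimer_tm <- numeric(0)
    tab$end_stability_tm <- numeric(0)
    tab$pass_gc <- logical(0); tab$pass_heterodimer <- logical(0)
    tab$pass_end_stability <- logical(0); tab$pass <- logical(0)
    return(new("GuideSet", table = DataFrame(tab)))
  }
  seqs <- DNAStringSet(tab$protospacer)
  tab$gc_fraction <- as.numeric(
    letterFrequency(seqs, "GC", as.prob = TRUE))
  tab$heterodimer_tm <- heterodimerTm(tab$protospacer, primer)
  tab$end_stability_tm <- endStabilityTm(tab$protospacer)
  tab$pass_gc <- tab$gc_fraction > gcMin & tab$gc_fraction < gcMax
  tab$pass_heterodimer <- tab$heterodimer_tm <= heterodimerTmMax
  tab$pass_end_stability <- tab$end_stability_tm <= endStabilityTmMax
  tab$pass <- tab$pass_gc & tab$pass_heterodimer & tab$pass_end_stability
  new("GuideSet", table = DataFrame(tab))
}

#' Subset a GuideSet to candidates passing all filters
#'
#' @param guides a [GuideSet-class] annotated by [filterGuides()].
#' @return A [GuideSet-class].
#' @export
passingGuides <- function(guides) {
  tab <- guides@table
  if (!"pass" %in% colnames(tab)) stop("run filterGuides() first")
  new("GuideSet", table = tab[tab$pass, , drop = FALSE])
}

## exact genomic occurrences of protospacer+NGG, both strands, as
## plus-strand protospacer intervals
.protoOccurrences <- function(proto, genome) {
  occ <- list()
  rc <- as.character(reverseComplement(DNAString(proto)))
  for (chr in names(genome)) {
    subject <- genome[[chr]]
    len <- length(subject)
    ## plus strand: proto at [s, s+19], PAM NGG at [s+20, s+22]
    m <- start(matchPattern(proto, subject))
    m <- m[m + 22L <= len]
    m <- m[vapply(m, function(s)
      as.character(subseq(subject, s + 21L, s + 22L)) == "GG", logical(1))]
    if (length(m))
      occ[[length(occ) + 1L]] <- data.frame(chrom = chr, start = m,
                                            end = m + 19L, strand = "+")
    ## minus strand: revcomp(proto) at [s, s+19], CCN at [s-3, s-1]
    m <- start(matchPattern(rc, subject))
    m <- m[m - 3L >= 1L]
    m <- m[vapply(m, function(s)
      as.character(subseq(subject, s - 3L, s - 2L)) == "CC", logical(1))]
    if (length(m))
      occ[[length(occ) + 1L]] <- data.frame(chrom = chr, start = m,
                                            end = m + 19L, strand = "-")
  }
  if (!length(occ))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  do.call(rbind, occ)
}

#' Discard guides with off-target genomic occurrences
#'
#' Exact-match search of each protospacer followed by an NGG PAM on both
#' genome strands; a candidate is retained iff every occurrence lies fully
#' within a target region. Repeated occurrences inside target regions (e.g.
#' rRNA operon copies) are allowed.
#'
#' @param guides a [GuideSet-class].
#' @param genome `DNAStringSet` or FASTA path.
#' @param targets `GRanges` or BED path of the regions to deplete.
#' @return A [GuideSet-class] of retained candidates with an
#'   `off_target_hits` column (0 for all retained rows).
#' @export
offTargetFilter <- function(guides, genome, targets) {
  genome <- .asGenome(genome)
  targets <- .asTargets(targets)
  tab <- as.data.frame(guides@table)
  if (!nrow(tab)) {
    tab$off_target_hits <- integer(0)
    return(new("GuideSet", table = DataFrame(tab)))
  }
  uniq <- unique(tab$protospacer)
  hitsOutside <- vapply(uniq, function(p) {
    occ <- .protoOccurrences(p, genome)
    if (!nrow(occ)) return(0L)
    inside <- vapply(seq_len(nrow(occ)), function(i) {
      tchr <- targets[as.character(seqnames(targets)) == occ$chrom[i]]
      any(start(tchr) <= occ$start[i] & end(tchr) >= occ$end[i])
    }, logical(1))
    sum(!inside)
  }, integer(1))
  tab$off_target_hits <- hitsOutside[tab$protospacer]
  keep <- tab$off_target_hits == 0L
  new("GuideSet", table = DataFrame(tab[keep, , drop = FALSE]))
}

#' Emit the final oligo pool
#'
#' Deduplicates protospacers (deterministic order by target region and
#' coordinate) and assembles each 60-nt oligo as T7 promoter + protospacer +
#' scaffold.
#'
#' @param guides a [GuideSet-class] of retained candidates.
#' @return data.frame with columns `oligo_id`, `target_region_id`, `chrom`,
#'   `strand`, `proto_start`, `proto_end`, `protospacer`, `oligo`.
#' @export
emitOligos <- function(guides) {
  tab <- as.data.frame(guides@table)
  if (!nrow(tab))
    return(data.frame(oligo_id = character(), target_region_id = character(),
                      chrom = character(), strand = character(),
                      proto_start = integer(), proto_end = integer(),
                      protospacer = character(), oligo = character(),
                      stringsAsFactors = FALSE))
  tab <- tab[order(tab$target_region_id, tab$chrom, tab$proto_start,
                   tab$strand), , drop = FALSE]
  tab <- tab[!duplicated(tab$protospacer), , drop = FALSE]
  out <- data.frame(
    oligo_id = sprintf("sgRNA_%04d", seq_len(nrow(tab))),
    target_region_id = tab$target_region_id, chrom = tab$chrom,
    strand = tab$strand, proto_start = tab$proto_start,
    proto_end = tab$proto_end, protospacer = tab$protospacer,
    oligo = paste0(T7_PROMOTER, tab$protospacer, SGRNA_SCAFFOLD),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write an oligo pool as FASTA
#'
#' @param oligos data.frame from [emitOligos()].
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
writeOligoFasta <- function(oligos, path) {
  seqs <- DNAStringSet(oligos$oligo)
  names(seqs) <- oligos$oligo_id
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Write an oligo pool as TSV
#'
#' @param oligos data.frame from [emitOligos()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeOligoTsv <- function(oligos, path) {
  write.table(oligos, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' End-to-end DASH guide design
#'
#' Scans target regions for PAM-adjacent protospacers, applies the
#' composition/thermodynamic filters, discards candidates with off-target
#' occurrences and emits the deduplicated oligo pool.
#'
#' @inheritParams scanPamSites
#' @inheritParams filterGuides
#' @return list with `candidates` (annotated [GuideSet-class]), `retained`
#'   ([GuideSet-class]) and `oligos` (data.frame).
#' @export
designDashGuides <- function(genome, targets, primer,
                             gcMin = 0.30, gcMax = 0.80,
                             heterodimerTmMax = 40, endStabilityTmMax = 30) {
  genome <- .asGenome(genome)
  targets <- .asTargets(targets)
  cand <- scanPamSites(genome, targets)
  cand <- filterGuides(cand, primer, gcMin = gcMin, gcMax = gcMax,
                       heterodimerTmMax = heterodimerTmMax,
                       endStabilityTmMax = endStabilityTmMax)
  retained <- offTargetFilter(passingGuides(cand), genome, targets)
  list(candidates = cand, retained = retained, oligos = emitOligos(retained))
}
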