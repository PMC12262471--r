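## chimera-only FragmentSet built from explicit loci
chimFrags <- function(m1start, m2start, strand1 = "+", strand2 = "+",
                      width = 31) {
  n <- length(m1start)
  mp <- matePairs(sprintf("c%04d", seq_len(n)),
                  "chr", m1start, m1start + width, strand1,
                  "chr", m2start, m2start + width, strand2)
  ## loci 50 kb apart on the same strand are always chimeric
  classifyFragments(mp, maxGap = 0)
}

test_that("one-sided Fisher matches hand-computable tables", {
  ## a = 0: the upper tail is everything
  expect_equal(fisherOneSided(0, 3, 4, 50)$p_value, 1.0)
  ## single most-extreme table: a=2, nA=nB=2, T=5 -> 1/C(5,2)
  ft <- fisherOneSided(2, 2, 2, 5)
  expect_equal(ft$p_value, 0.1, tolerance = 1e-12)
  expect_equal(ft$odds_ratio, Inf)
  ## a=5, b=5, c=5, d=85 against the enumeration oracle
  expect_equal(fisherOneSided(5, 10, 10, 100)$p_value,
               fisherEnumOracle(5, 10, 10, 100), tolerance = 1e-12)
  ## odds ratio conventions
  expect_true(is.nan(fisherOneSided(0, 0, 0, 10)$odds_ratio))
  expect_equal(fisherOneSided(2, 4, 4, 20)$odds_ratio, (2 * 14) / (2 * 2))
  expect_error(fisherOneSided(5, 3, 10, 100), "negative")
})

test_that("Fisher p equals the enumeration oracle over a margin grid", {
  worst <- 0
  for (total in c(17, 60, 143)) {
    for (nA in unique(round(seq(0, total, length.out = 7)))) {
      for (nB in unique(round(seq(0, total, length.out = 7)))) {
        amin <- max(0, nA + nB - total)  # feasibility of cell d
        a <- amin:min(nA, nB)
        p <- fisherOneSided(a, nA, nB, total)$p_value
        oracle <- fisherEnumOracleAll(nA, nB, total)[a + 1]
        worst <- max(worst, max(abs(p - oracle)))
        ## monotone: p never increases as the joint count grows
        if (length(p) > 1 && any(diff(p) > 1e-15))
          fail(sprintf("non-monotone p at nA=%d nB=%d T=%d", nA, nB, total))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("binning conserves chimera counts and collapses shared windows", {
  f <- chimFrags(c(105, 130, 390), c(50105, 50105, 52000))
  bins <- binChimeras(f, analysisParams(window = 100))
  expect_equal(sum(bins$n_ab), 3)
  expect_equal(unique(bins$total), 3)
  ## first two chimeras share both midpoint windows
  expect_equal(nrow(bins), 2)
  expect_equal(max(bins$n_ab), 2)
  ## marginals bounded by totals
  expect_true(all(bins$n_ab <= pmin(bins$n_a, bins$n_b)))

  ## single chimera: count 1, marginals 1
  b1 <- binChimeras(chimFrags(100, 50100), analysisParams())
  expect_equal(b1$n_ab, 1)
  expect_equal(b1$n_a, 1)
  expect_equal(b1$n_b, 1)
  expect_equal(b1$total, 1)
})

test_that("the count floor forbids S-chimeras below five chimeras", {
  ## 4 chimeras in one window pair within a large library: p is tiny but the
  ## floor rejects
  set.seed(2)
  m1 <- c(rep(110, 4), sample(seq(1000, 20000, by = 37), 96))
  m2 <- c(rep(50110, 4), sample(seq(60000, 90000, by = 41), 96))
  f <- chimFrags(m1, m2)
  ss <- callSChimeras(f, params = analysisParams())
  tab <- schimeraTable(ss)
  expect_false(any(tab$start1 <= 110 & tab$end1 >= 110 &
                     tab$start2 <= 50110 & tab$end2 >= 50110))
  ## with the floor at 4 the same pair is called
  ss4 <- callSChimeras(f, params = analysisParams(minChimeras = 4))
  tab4 <- schimeraTable(ss4)
  expect_true(any(tab4$start1 <= 110 & tab4$end1 >= 110 &
                    tab4$start2 <= 50110 & tab4$end2 >= 50110))
})

test_that("a concentrated pair in a sparse library is significant", {
  set.seed(9)
  ## 50 chimeras in one window pair over a T=10^4 library of scattered pairs
  m1 <- c(rep(110, 50), sample(seq(1000, 480000, by = 7), 9950))
  m2 <- c(rep(50110, 50), sample(seq(500000, 990000, by = 7), 9950))
  f <- chimFrags(m1, m2)
  ss <- callSChimeras(f, params = analysisParams())
  tab <- schimeraTable(ss)
  hit <- tab$start1 <= 110 & tab$end1 >= 110 &
    tab$start2 <= 50110 & tab$end2 >= 50110
  expect_true(any(hit))
  expect_lt(tab$p_value[which(hit)[1]], 1e-50)
  expect_gte(min(tab$interactions), 5)
  expect_true(all(tab$p_value < 0.05))
})

test_that("adjacent significant window pairs merge into one region pair", {
  set.seed(4)
  ## signal straddles a window boundary on the RNA1 side, over a scattered
  ## background that keeps the margins informative
  m1 <- c(rep(180, 6), rep(210, 6), sample(seq(100000, 300000, by = 11), 88))
  m2 <- c(rep(50110, 12), sample(seq(500000, 900000, by = 13), 88))
  f <- chimFrags(m1, m2)
  ss <- callSChimeras(f, params = analysisParams())
  tab <- schimeraTable(ss)
  hit <- which(tab$start2 <= 50110 & tab$end2 >= 50110)
  expect_equal(length(hit), 1)
  expect_equal(tab$interactions[hit], 12)
  expect_equal(tab$start1[hit], 101)
  expect_equal(tab$end1[hit], 300)
})

test_that("filtering retains exactly the chimeras inside S-chimera regions", {
  cfg <- smallConfig(seed = 21)
  sim <- simulateGenome(cfg)
  lib <- simulateLibrary(cfg, sim$genome, sim$annotation)
  f <- classifyFragments(lib$matePairs)
  ss <- callSChimeras(f)
  kept <- filterNonsignificant(f, ss)
  expect_equal(length(chimeras(kept)$rna1),
               sum(schimeraTable(ss)$interactions))
  ## no S-chimeras -> no retained chimeras
  emptySS <- callSChimeras(chimFrags(100, 50100))
  expect_equal(nrow(schimeraTable(emptySS)), 0)
  kept0 <- filterNonsignificant(f, emptySS)
  expect_equal(length(chimeras(kept0)$rna1), 0)
  expect_equal(length(singles(kept0)), length(singles(f)))
})

test_that("gene assignment follows the strict 0.7 read-share rule", {
  gr <- GRanges("chr", IRanges(c(1, 201), c(100, 300)), strand = "+",
                feature_id = c("geneA", "geneB"), ftype = "gene",
                name = c("geneA", "geneB"))
  anno <- FeatureSet(gr, genomeLengths = c(chr = 1000))
  region <- GRanges("chr", IRanges(1, 300), strand = "+")
  reads <- function(kA, kB) {
    GRanges("chr", IRanges(c(rep(10, kA), rep(210, kB)), width = 20),
            strand = "+")
  }
  expect_equal(assignGenes(region, reads(80, 20), anno), "geneA")
  expect_equal(assignGenes(region, reads(60, 40), anno),
               c("geneA", "geneB"))
  ## boundary share of exactly 0.70 keeps both (rule is strict >)
  expect_equal(assignGenes(region, reads(70, 30), anno),
               c("geneA", "geneB"))
  expect_equal(assignGenes(region, reads(71, 29), anno), "geneA")
  ## region with no overlapping feature: nearest-feature fallback
  far <- GRanges("chr", IRanges(500, 600), strand = "+")
  farReads <- GRanges("chr", IRanges(550, 570), strand = "+")
  expect_equal(assignGenes(far, farReads, anno), "geneB.near")
})

test_that("interaction tables roundtrip and links match S-chimera count", {
  cfg <- smallConfig(seed = 31)
  sim <- simulateGenome(cfg)
  lib <- simulateLibrary(cfg, sim$genome, sim$annotation)
  ss <- callSChimeras(classifyFragments(lib$matePairs),
                      annotation = composeAnnotation(sim$annotation))
  expect_gt(nrow(schimeraTable(ss)), 0)
  tsv <- tempfile(fileext = ".tsv")
  writeInteractionTable(ss, tsv)
  back <- readInteractionTable(tsv)
  expect_equal(nrow(back), nrow(schimeraTable(ss)))
  expect_equal(back$interactions, schimeraTable(ss)$interactions)
  expect_equal(back$p_value, schimeraTable(ss)$p_value)

  links <- tempfile(fileext = ".txt")
  circosLinks(ss, links)
  expect_equal(length(readLines(links)), nrow(schimeraTable(ss)))

  ## empty set gives a header-only TSV
  ss0 <- callSChimeras(chimFrags(100, 50100))
  tsv0 <- tempfile(fileext = ".tsv")
  writeInteractionTable(ss0, tsv0)
  expect_equal(length(readLines(tsv0)), 1)
})

test_that("BH adjustment and chromosome whitelisting restrict calls", {
  set.seed(6)
  ## borderline pair: marginally significant raw p can fail after BH
  m1 <- c(rep(110, 5), sample(seq(1000, 480000, by = 7), 995))
  m2 <- c(rep(50110, 5), sample(seq(500000, 990000, by = 7), 995))
  f <- chimFrags(m1, m2)
  raw <- callSChimeras(f)
  bh <- callSChimeras(f, pAdjust = "BH")
  expect_lte(nrow(schimeraTable(bh)), nrow(schimeraTable(raw)))

  ## whitelist excluding the only chromosome removes all chimeras
  none <- callSChimeras(f, chromosomes = "chrOther")
  expect_equal(nrow(schimeraTable(none)), 0)
  same <- callSChimeras(f, chromosomes = "chr")
  expect_equal(nrow(schimeraTable(same)), nrow(schimeraTable(raw)))
})

test_that("null libraries are rarely called significant", {
  sim <- simulateGenome(nullConfig(seed = 1))
  rates <- vapply(1:3, function(s) {
    lib <- simulateLibrary(nullConfig(seed = 100 + s, nChimeras = 2000),
                           sim$genome, sim$annotation)
    f <- classifyFragments(lib$matePairs)
    bins <- binChimeras(f, analysisParams())
    ss <- callSChimeras(f, params = analysisParams())
    nrow(schimeraTable(ss)) / nrow(bins)
  }, numeric(1))
  expect_true(all(rates <= 0.05))
})
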