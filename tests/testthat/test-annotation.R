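test_that("GFF3 I/O preserves 1-based inclusive coordinates and types", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1;Name=g1"), gff)
  fs <- loadAnnotation(gff, genomeLengths = c(chr = 1000))
  gr <- features(fs)
  expect_equal(start(gr), 1)
  expect_equal(end(gr), 100)
  expect_equal(width(gr), 100)
  expect_equal(as.character(mcols(gr)$ftype), "gene")

  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(length(loadAnnotation(empty)), 0)

  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr\tonly three\tfields"), bad)
  expect_error(loadAnnotation(bad), "line 2")

  oob <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tgene\t900\t1200\t.\t+\t.\tID=g9;Name=g9"), oob)
  expect_error(loadAnnotation(oob, genomeLengths = c(chr = 1000)),
               "beyond genome length")
})

test_that("write -> read roundtrip is the identity on a FeatureSet", {
  fs <- randomFeatureSet(seed = 3)
  path <- tempfile(fileext = ".gff3")
  writeAnnotation(fs, path)
  back <- loadAnnotation(path, genomeLengths = c(chr = 20000))
  a <- features(fs); b <- features(back)
  expect_equal(length(a), length(b))
  expect_equal(start(a), start(b))
  expect_equal(end(a), end(b))
  expect_equal(as.character(strand(a)), as.character(strand(b)))
  expect_equal(mcols(a)$feature_id, mcols(b)$feature_id)
  expect_equal(mcols(a)$ftype, mcols(b)$ftype)
  expect_equal(mcols(a)$name, mcols(b)$name)
})

test_that("predicted UTRs extend up to 100 nt and truncate at neighbours", {
  mk <- function(upEnd) {
    ## upstream neighbour is non-coding so it emits no competing UTR
    gr <- GRanges("chr",
                  IRanges(c(upEnd - 99, 1001), c(upEnd, 2000)),
                  strand = "+",
                  feature_id = c("up", "g"),
                  ftype = c("sRNA", "gene"),
                  name = c("up", "g"))
    FeatureSet(gr, genomeLengths = c(chr = 10000))
  }
  utr5 <- function(fs) {
    u <- features(buildPredictedUTRs(fs))
    u[mcols(u)$ftype == "EST5UTR" & grepl("^g\\.", mcols(u)$name)]
  }
  ## ample gap: full 100-nt extension
  u <- utr5(mk(750))
  expect_equal(start(u), 901)
  expect_equal(end(u), 1000)
  ## short gap: truncated to 60
  u <- utr5(mk(940))
  expect_equal(start(u), 941)
  expect_equal(width(u), 60)
  ## abutting neighbour: no extension
  expect_equal(length(utr5(mk(1000))), 0)
})

test_that("minus-strand genes extend UTRs in mirrored directions", {
  gr <- GRanges("chr", IRanges(1001, 2000), strand = "-",
                feature_id = "g", ftype = "gene", name = "g")
  fs <- FeatureSet(gr, genomeLengths = c(chr = 10000))
  u <- features(buildPredictedUTRs(fs))
  u5 <- u[mcols(u)$ftype == "EST5UTR"]
  u3 <- u[mcols(u)$ftype == "EST3UTR"]
  expect_equal(start(u5), 2001)  # 5' of a minus gene is its right end
  expect_equal(end(u5), 2100)
  expect_equal(start(u3), 901)
  expect_equal(end(u3), 1000)
  expect_equal(as.character(strand(u5)), "-")
})

test_that("antisense features mirror coding regions without merging", {
  gr <- GRanges("chr", IRanges(c(100, 150, 400), c(200, 260, 500)),
                strand = c("+", "+", "-"),
                feature_id = c("a", "b", "c"), ftype = "gene",
                name = c("a", "b", "c"))
  fs <- FeatureSet(gr, genomeLengths = c(chr = 1000))
  as_ <- features(buildAntisense(fs))
  expect_equal(length(as_), 3)  # overlapping a/b stay separate
  expect_equal(as.character(strand(as_)), c("-", "-", "+"))
  expect_equal(start(as_), start(gr))
  expect_equal(end(as_), end(gr))
  expect_equal(mcols(as_)$name, c("a.AS", "b.AS", "c.AS"))
})

test_that("gap length strictly below 100 gives TU, otherwise IGR", {
  mk <- function(gap) {
    gr <- GRanges("chr", IRanges(c(1, 101 + gap), c(100, 300 + gap)),
                  strand = "+",
                  feature_id = c("a", "b"), ftype = "gene",
                  name = c("a", "b"))
    features(buildIgrsTus(FeatureSet(gr, genomeLengths = c(chr = 5000))))
  }
  g50 <- mk(50)
  expect_equal(mcols(g50)$ftype, "TU")
  expect_equal(width(g50), 50)
  expect_equal(mcols(g50)$name, "a.b.TU")
  expect_equal(mcols(mk(150))$ftype, "IGR")
  expect_equal(mcols(mk(100))$ftype, "IGR")  # boundary: strictly less than
  expect_equal(mcols(mk(99))$ftype, "TU")
})

test_that("composition of the 3-gene toy matches hand enumeration", {
  fs <- toyFeatureSet()
  comp <- composeAnnotation(fs)
  gr <- features(comp)
  ## 3 genes + 6 predicted UTRs + 3 AS + 1 IGR (plus-strand gap 2101-2400)
  expect_equal(length(gr), 13)
  tab <- table(mcols(gr)$ftype)
  expect_equal(unname(tab[c("gene", "EST5UTR", "EST3UTR", "AS", "IGR")]),
               array(c(3L, 3L, 3L, 3L, 1L)))
  igr <- gr[mcols(gr)$ftype == "IGR"]
  expect_equal(start(igr), 2101)
  expect_equal(end(igr), 2400)
  expect_equal(as.character(strand(igr)), "+")
  expect_equal(mcols(igr)$name, "g1.EST3UTR.g2.EST5UTR.IGR")

  ## deterministic: composing again gives the identical result
  comp2 <- composeAnnotation(fs)
  expect_identical(as.data.frame(features(comp)),
                   as.data.frame(features(comp2)))

  ## empty base passes through
  expect_equal(length(composeAnnotation(FeatureSet())), 0)

  ## period in a base gene name is rejected (naming delimiter)
  bad <- FeatureSet(GRanges("chr", IRanges(1, 50), "+",
                            feature_id = "x.1", ftype = "gene",
                            name = "x.1"),
                    genomeLengths = c(chr = 5000))
  expect_error(composeAnnotation(bad), "period|\\.")
})

test_that("annotation invariants hold on random genomes", {
  for (seed in 1:10) {
    cfg <- simulationConfig(genomeLength = 50000, nMrna = 10, nSrna = 5,
                            nTrna = 2, nRrna = 1,
                            plantedPairs = defaultPlantedPairs(0),
                            seed = seed)
    base <- simulateGenome(cfg)$annotation
    utrs <- features(buildPredictedUTRs(base))
    expect_true(all(width(utrs) <= 100))
    ## predicted UTRs never overlap same-strand base features
    expect_equal(length(findOverlaps(utrs, features(base))), 0)
    ## nor each other
    expect_equal(length(findOverlaps(utrs, drop.self = TRUE)), 0)

    comp <- composeAnnotation(base)
    gr <- features(comp)
    ## IGR+TU exactly tile the same-strand inter-feature space of the
    ## transcript footprint (base + predicted UTRs)
    foot <- gr[!mcols(gr)$ftype %in% c("AS", "IGR", "TU")]
    igrtu <- gr[mcols(gr)$ftype %in% c("IGR", "TU")]
    for (st in c("+", "-")) {
      red <- reduce(foot[strand(foot) == st])
      red <- red[order(start(red))]
      gapSum <- if (length(red) < 2) 0L else
        sum(pmax(start(red)[-1] - end(red)[-length(red)] - 1L, 0L))
      expect_equal(sum(width(igrtu[strand(igrtu) == st])), gapSum)
      ## and IGR/TU never overlap the footprint
      expect_equal(length(findOverlaps(igrtu[strand(igrtu) == st], red)), 0)
    }
    ## every AS feature mirrors an opposite-strand coding feature exactly
    as_ <- gr[mcols(gr)$ftype == "AS"]
    coding <- gr[mcols(gr)$ftype %in% c("gene", "CDS")]
    if (length(as_)) {
      m <- match(paste(start(as_), end(as_)),
                 paste(start(coding), end(coding)))
      expect_false(any(is.na(m)))
      expect_true(all(as.character(strand(as_)) !=
                        as.character(strand(coding))[m]))
    }
  }
})
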