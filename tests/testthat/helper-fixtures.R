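## Shared fixtures and independent oracles.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## Independent exhaustive oracle for the one-sided Fisher test: direct
## enumeration of the hypergeometric upper tail via binomial coefficients,
## kept free of phyper()/dhyper().
fisherEnumOracle <- function(a, nA, nB, total) {
  kmax <- min(nA, nB)
  if (a > kmax) return(0)
  k <- a:kmax
  sum(exp(lchoose(nA, k) + lchoose(total - nA, nB - k) - lchoose(total, nB)))
}

## all upper-tail probabilities P(X >= a), a = 0..min(nA,nB), by reverse
## cumulative sum of enumerated point masses
fisherEnumOracleAll <- function(nA, nB, total) {
  kmax <- min(nA, nB)
  k <- 0:kmax
  pm <- exp(lchoose(nA, k) + lchoose(total - nA, nB - k) - lchoose(total, nB))
  rev(cumsum(rev(pm)))
}

## three-gene toy genome used by hand-enumerated annotation tests
toyFeatureSet <- function() {
  gr <- GRanges("chr",
                IRanges(c(1001, 2501, 3500), c(2000, 3200, 4000)),
                strand = c("+", "+", "-"),
                feature_id = c("g1", "g2", "g3"),
                ftype = "gene",
                name = c("g1", "g2", "g3"))
  FeatureSet(gr, genomeLengths = c(chr = 5000))
}

## deterministic 20-feature annotation for roundtrip tests
randomFeatureSet <- function(seed = 1, n = 20, glen = 20000) {
  set.seed(seed)
  w <- sample(50:400, n, TRUE)
  s <- sort(sample(seq_len(glen - 500), n))
  s <- s + cumsum(rep(0, n))  # starts may overlap; that is fine here
  gr <- GRanges("chr", IRanges(s, width = w),
                strand = sample(c("+", "-"), n, TRUE),
                feature_id = sprintf("f%02d", 1:n),
                ftype = sample(c("gene", "sRNA", "tRNA"), n, TRUE),
                name = sprintf("f%02d", 1:n))
  FeatureSet(gr, genomeLengths = c(chr = glen))
}

## small fast simulation scenario for unit tests
smallConfig <- function(seed = 11, ...) {
  simulationConfig(genomeLength = 60000, nMrna = 15, nSrna = 8, nTrna = 3,
                   nRrna = 1, plantedPairs = defaultPlantedPairs(8),
                   nFragments = 4000, seed = seed, ...)
}

## null-model scenario: every captured fragment is a background chimera
## joining two independently drawn loci (independent-pairing null)
nullConfig <- function(seed, nChimeras = 5000) {
  simulationConfig(rho = 0, epsilon = 1, pLig = 1, nFragments = nChimeras,
                   seed = seed)
}
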