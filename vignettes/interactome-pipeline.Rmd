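---
title: "Calling RNA-RNA interactions from proximity-ligation sequencing"
author: "rilseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling RNA-RNA interactions from proximity-ligation sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilseqr)
library(GenomicRanges)
```

# The problem

Bacterial small regulatory RNAs (sRNAs) act by base-pairing with target
mRNAs, usually on the chaperone Hfq. Proximity-ligation protocols (RIL-seq
and its in-vivo-ligation variant iRIL-seq) capture these pairings: RNAs
co-bound on the immunoprecipitated protein are ligated into chimeric
fragments, so each sequenced mate pair is either a *single* fragment (both
mates from one RNA) or a *chimera* whose two mates map to distinct loci —
direct evidence that the two RNAs sat together on the protein. This package
implements the downstream analysis of such experiments: building the feature
annotation, classifying mapped mate pairs, calling statistically supported
interacting region pairs (S-chimeras), quantifying and contrasting strains,
designing the DASH guide pool used to deplete rRNA from the libraries, and
simulating the whole capture process so that every stage can be validated
against a known ground truth.

# The statistical model of S-chimera calling

Chimeric fragments are binned over ordered window pairs: the genome is
partitioned per strand into fixed windows (default 100 nt) and each chimera
is assigned by the midpoints of its RNA1 and RNA2 loci. For a window pair
with `a` joining chimeras, RNA1-side marginal `n_a`, RNA2-side marginal
`n_b` and library total `T`, the 2x2 table

|            | RNA2 in window | RNA2 elsewhere |
|------------|----------------|----------------|
| RNA1 in window | `a`        | `n_a - a`      |
| RNA1 elsewhere | `n_b - a`  | `T - n_a - n_b + a` |

is tested one-sided for over-representation: the p-value is the
hypergeometric upper tail `P(X >= a)` with population `T`, `n_a` successes
and `n_b` draws. A window pair is significant when `a >= 5` **and**
`p < 0.05`; touching significant window pairs (adjacent in both dimensions)
are merged into one maximal region pair, which is one S-chimera. Chimeras
outside every S-chimera's region pair are treated as non-specific ligation
products and can be removed with `filterNonsignificant()`.

Numerical notes: the tail probability is computed with `phyper()`, and the
test suite verifies it against an exhaustive enumeration of every feasible
table with totals up to 40 (and a stratified grid to 200) to within 1e-12,
together with monotonicity of the p-value in `a` at fixed margins. The odds
ratio uses the convention `Inf` when `b*c = 0` with `a*d > 0` and `NaN` when
both products vanish. No multiple-testing correction is applied by default —
the published thresholds are a raw p-value with a count floor — but
`callSChimeras(pAdjust = "BH")` is available. Ordered pairs are not
symmetrised: (A,B) and (B,A) are distinct interactions, matching the
RNA1/RNA2 orientation convention in which the sRNA appears as RNA2 and its
target as RNA1.

## Gene assignment

Each region of an S-chimera is assigned genes from per-feature
overlapping-read counts (same-strand, >= 1 shared base, computed with
`findOverlaps`): if one feature holds strictly more than 70% of the reads
that overlap any feature, it is assigned exclusively; otherwise all
overlapping features are kept in decreasing read-share order. A region whose
reads overlap nothing is labelled by the nearest same-strand feature with a
`.near` suffix — a fallback we invented so that no called region is silently
nameless; it is recognisable in output by the suffix.

# Annotation construction

`composeAnnotation()` extends a base gene annotation with:

* **Predicted UTRs** (`EST5UTR`/`EST3UTR`): 100 nt beyond each coding gene's
  ends, truncated at the nearest same-strand transcript feature, omitted when
  no room remains, and mirrored on the minus strand. When two predicted UTRs
  compete for one short inter-gene gap, the contested space is split evenly
  between them so that predicted UTRs never overlap anything on their own
  strand; when a curated UTR already abuts a gene end, no prediction is made
  there (`skipIfKnown`, default on).
* **Antisense** (`AS`): one feature per coding gene with identical
  coordinates on the opposite strand, named `<gene>.AS`. Overlapping genes
  yield separate AS features because the naming is per gene.
* **IGR/TU**: strand-specific gaps between the merged footprint of the
  transcript features (base + predicted UTRs). Gaps strictly shorter than
  100 nt become `TU` (likely within one transcription unit), all others
  `IGR`; names are `left.right.TU`/`left.right.IGR` from the flanking
  features in genomic order.

Design choices made where the construction rules were open: AS features are
*not* part of the footprint against which IGR/TU gaps are computed —
including them would blanket both strands wherever genes exist and leave
essentially no intergenic space, contradicting the intended meaning of the
features; gaps between a chromosome end and the first/last feature are not
emitted (they lack a second flanking gene to name them by); chromosomes are
treated as linear (no origin-spanning gap feature); and base gene names
containing a period are rejected, since the period is the naming delimiter.
Internally all features live in `GRanges` (1-based, closed intervals, the
Bioconductor convention); GFF3 I/O is native, and BED/BEDPE input is
converted from 0-based half-open coordinates at the boundary.

# Fragment classification

Libraries are reverse-stranded by default (the sequenced strand is the
reverse complement of the transcript), handled by `transcriptStrand()`. A
mate pair is a single fragment iff both mates map to the same chromosome and
transcript strand with an inter-mate gap of at most `maxGap` (default
1000 nt, exposed in `AnalysisParams`); its locus is the merged interval.
Everything else is chimeric, with RNA1 taken from mate 1 — the 5' side of
the sequencing construct after strand resolution. The published
chimera-calling tool does not document its exact rule; this operational
definition reproduces the meaning of "two proximal RNA molecules ligated"
and its one knob is exposed rather than hard-coded. rRNA reads can be
excluded up front with `maskFeatures()`, mirroring depleted-library
processing; multi-mapped records are out of scope (input is one best mapping
per mate).

# Quantification

`countFeatures()` pools single and chimeric loci and counts them per feature
with multi-overlap semantics (a fragment overlapping k features increments
all k), the behaviour of overlap-tolerant feature counting. Across-sample
normalisation uses hand-rolled median-of-ratios size factors
(`medianOfRatios()`, verified in the tests against DESeq2's reference
implementation) followed by pseudocount-guarded fold changes
(`foldChangeVsReference()`, pseudocount 1 on the normalised scale) and
IP/Total enrichment ratios (`enrichmentRatio()`, log2, positive = bound to
the protein). Negative-binomial differential expression is deliberately out
of scope: the package's claims concern the interactome pipeline, not
dispersion modelling.

# DASH guide design

`designDashGuides()` scans the regions to deplete for Cas9 PAM sites (NGG)
on both strands, takes the 20 nt 5' of each PAM as a candidate protospacer,
and filters on composition and thermodynamics: GC fraction strictly between
0.30 and 0.80, heterodimer melting temperature against the library
amplification primer at most 40 °C, and 3'-end stability Tm at most 30 °C.
Thermodynamics use a standard unified nearest-neighbour model (terminal
initiation terms, entropic salt correction, two-state Tm at 0.25 µM strand
and 50 mM Na+); the heterodimer duplex is the longest perfectly
complementary stretch between candidate and primer, and end stability is the
Tm of the 3'-terminal 5-bp duplex. The primer is a required input — designs
are only meaningful against the primer actually used for amplification — and
the threshold direction is "metric at most threshold passes". Off-target
filtering is an exact-match search of protospacer+NGG over both genome
strands: a candidate is retained only if every occurrence lies fully within
a target region, so repeated rRNA operon copies are fine while any external
copy discards the guide. Mismatch-tolerant off-target search is deliberately
omitted. Emitted oligos are `T7 promoter + protospacer + scaffold`, 60 nt,
deduplicated deterministically.

# The synthetic capture model

`simulateGenome()` places non-overlapping stranded features (mRNAs
300–3000 nt, sRNAs 50–300 nt, tRNAs 70–90 nt, rRNAs 1400–2900 nt) separated
by lognormal gaps (median ~150 nt, so both sub-100-nt TU gaps and long IGRs
occur) on a 150 kb random chromosome. `simulateLibrary()` then draws each of
`nFragments` captured events from a three-way mixture:

* a **planted chimera** with probability `pLig * rho * (1 - epsilon)`,
  choosing a planted sRNA–mRNA pair proportionally to its intensity
  `lambda` and emitting one mate per partner, scattered ±30 nt around a
  fixed per-pair interaction site (so the signal mostly stays within one
  100-nt calling window without modelling secondary structure), with
  truncated-normal mate lengths (mean 30, sd 8, min 15 nt);
* a **background chimera** with probability `pLig * epsilon`, joining two
  loci drawn independently proportionally to log-uniform expression weights
  (abundance-driven ligation noise, the regime in which chimeras involve
  abundant tRNA/rRNA species);
* otherwise a **single fragment** within one abundance-weighted feature.

`rho` is the strain-dependent chimera retention probability and `pLig` the
protocol ligation efficiency; `ripseq` forces `pLig = 0` (binding without
ligation). The defaults (`pLig = 0.5`, `rho = 0.3`, `epsilon = 0.02` for
RIL-seq; `pLig = 0.055` for iRIL-seq) were fixed so the expected chimera
fraction `pLig (rho (1 - epsilon) + epsilon)` is ~15% for wild-type RIL-seq,
~1% for the rim-mutant RIL-seq regime and ~1.7% for wild-type iRIL-seq —
the fractions such libraries actually show. `strainScenarios()` derives the
rim-mutant (R16A-like) config by scaling `rho` by 1/100 under RIL-seq and
1/10 under iRIL-seq, expressing the interpretation that paired RNAs
dissociate from the mutant during capture and that the in-vitro-heavy
protocol loses more of them. The mutant effect is modelled purely as
retention scaling, not altered pair preference; per-pair `lambda` overrides
are available for modelling shifted specificity but are not the default.
The default 20 planted pairs carry intensities spread geometrically over
[0.5, 2], giving every pair an expected chimera yield comfortably above the
5-fragment calling floor at the default library size of 20,000 fragments
(library total T ≈ 3,100 chimeras); the iRIL-seq mutant-contrast runs use
100,000 fragments so the 10-fold-reduced regime stays recoverable. These
sizes are the package's validation conditions, chosen to keep each pair's
expected support ≥ 15 chimeras as the recovery tests require.

What the simulator does *not* emulate: sequence-dependent pairing
energetics, read-level sequencing errors, multi-mapping, operonic
co-transcription structure, or growth-condition-dependent expression. Tests
passing on these simulations therefore demonstrate the correctness of the
pipeline's logic and statistics under its own generative assumptions, not
the biological fidelity of any particular real library.

# A worked run

```{r, eval = FALSE}
cfg <- simulationConfig(seed = 7)
sim <- simulateGenome(cfg)
anno <- composeAnnotation(sim$annotation)
lib <- simulateLibrary(cfg, sim$genome, sim$annotation)
frags <- classifyFragments(lib$matePairs)
libraryStats(frags)
ss <- callSChimeras(frags, annotation = anno)
head(as.data.frame(schimeraTable(ss)))
```

`runPipeline()` wraps the same stages for a sample sheet of strain/protocol
combinations, writes per-sample fragments, interaction tables, Circos link
files, a counts matrix and a summary JSON, and is deterministic given its
root seed.

# Known limitations

* The exact decision rules of the original processing scripts are not
  published in full; the classification gap rule, the window size, the
  contingency construction and the region-merging strategy here are
  documented reconstructions with their parameters exposed, not bit-for-bit
  reimplementations.
* Headline counts from deep-sequenced libraries (thousands of S-chimeras,
  specific guide counts) depend on genome builds, sequencing depth and
  curated annotations and are not reproduction targets at simulation scale;
  the package's guarantees are the property-based ones its tests compute.
* Circular chromosomes are treated as linear; origin-spanning features are
  not generated.
* The nearest-neighbour thermodynamic engine covers perfect duplexes only;
  dangling ends and internal mismatches are ignored.
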