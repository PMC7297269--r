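---
title: "Predicting m6A sites on lncRNA: model, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting m6A sites on lncRNA: model, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncm6A)
```

## The problem

N6-methyladenosine (m6A) is the most abundant internal modification of
eukaryotic RNA. It is deposited almost exclusively on adenosines inside the
DRACH consensus (D = A/G/U, R = A/G, then the methylated A, C, H = A/C/U; 18
distinct 5-mers), but only a small minority of DRACH adenosines are actually
methylated, so motif matching alone is a weak predictor. Long non-coding RNAs
are a particular blind spot: they are often non-polyadenylated and
under-captured by standard library preparations, and base-resolution m6A
experiments yield far fewer lncRNA sites than mRNA sites. `lncm6A` addresses
this with a supervised classifier over candidate DRACH adenosines that is
aware of the lncRNA/mRNA distinction.

## The model

Each candidate site is described by 144 features:

* **84 sequence features.** The 21-nt window centred on the candidate A
  (10 nt of flank each side) is encoded position by position as 4 values: the
  chemical-property triple (x, y, z) with x = 1 for purines, y = 1 for
  amino-group bases, z = 1 for weak hydrogen bonding — so A = (1,1,1),
  C = (0,1,0), G = (1,0,0), U = (0,0,1) — plus the cumulative frequency of
  the position's base, d~i~/i, counting occurrences within positions 1..i of
  the window.
* **60 genomic features**, in a frozen catalog: 10 transcript-topology
  dummies (exon/intron, first/internal/last exon, 5'/3' half, start/end
  proximity, long-exon containment); distances to the nearest 5' and 3'
  splice junctions capped at 2,000 nt; log2 lengths of the containing region
  and the mature transcript; an 18-way one-hot of the DRACH motif identity;
  4 candidate-clustering statistics (neighbour counts within 50/500/2,000 nt
  and capped nearest-neighbour distance); mean conservation over the window
  for four score tracks (two PhastCons-role, two fitCons-role); two
  secondary-structure values (site paired; paired fraction of the 101-nt
  window); 13 configurable interval-overlap dummies for m6A-biology
  annotations plus a miRNA-target dummy; and 4 population z-scores (isoform
  count, exon count, gene GC, window GC).

A probability random forest (500 trees, $\sqrt p$ candidate features per
split, seeded) is trained separately on mRNA-derived and lncRNA-derived
balanced site sets. Because the two RNA classes carry different methylation
characteristics but the mRNA set is far larger, the final predictor blends
both members:

$$ P_{en} = \alpha P_m + (1 - \alpha) P_{lnc}, \qquad \alpha \in [0, 1], $$

with $\alpha$ selected by grid search over $\{0, 0.1, \ldots, 1\}$. All
features of a dataset are computed under a single coordinate mode: the
*full-transcript* mode works on the unspliced pre-RNA (introns included),
the *mature-RNA* mode on the spliced exon chain.

## Dataset construction

Positives are adenosines called at the same genomic coordinate and strand in
at least two replicate base-resolution experiments, restricted to DRACH
context and excluding any site mappable to more than one gene. Per gene, the
transcript with the greatest mature length represents the gene (ties broken
by smallest transcript id), avoiding isoform ambiguity. Negatives are drawn
uniformly, without replacement and in equal number, from the remaining DRACH
adenosines on the transcripts that carry positives; by default every site
reported in *any* replicate is excluded from the negative pool (the stricter
reading of "non-positive"; a flag restores the looser one). Four fifths of
the sites, stratified by label, form the training split. The mature-mode
dataset is the full-mode dataset restricted to exonic sites and re-projected
onto spliced coordinates.

## Design choices made where the design was open

* **Window centring.** Windows are centred on the methylated A (motif
  position 3), 10 nt each side — the symmetric convention of
  chemical-property encoders. Windows overrunning a transcript end are
  padded with `N`, encoded (0,0,0) with frequency 0, under a warning.
* **Cumulative frequency scope.** Frequencies are computed within the 21-nt
  window, not the whole transcript: the encoding's worked examples operate
  on standalone short sequences, and window-local counting keeps the feature
  independent of transcript length.
* **DRACH context is genomic.** Candidate enumeration and motif identity are
  evaluated on the pre-mRNA context in both modes; mature mode re-projects
  exonic candidates. A spliced 5-mer spanning an exon junction therefore
  never creates or destroys a candidate — base-resolution calls are anchored
  on the genome, and the alternative would make the candidate set depend on
  the coordinate mode in hard-to-interpret ways.
* **Splice distances.** Full-transcript mode measures distances to both the
  donor and acceptor boundaries of each intron in pre-RNA coordinates (not
  genomic coordinates; the two differ only in exotic multi-exon layouts);
  the 2,000-nt cap follows the `_p2000` convention of the feature names.
  A junction between transcript positions j and j+1 is at distance `p - j`
  upstream of a site p and `j - p + 1` when downstream; single-exon
  transcripts report the cap.
* **Region dummies.** The catalog fixes the 10 topology dummies as exon,
  intron, first/internal/last exon, 5'-half, 3'-half, within 100 nt of the
  transcript start/end, and containment in an exon of at least 400 nt. The
  5'/3'-half and start/end-proximity dummies are evaluated in the active
  mode's coordinates so they remain defined for intronic sites in full mode.
* **Secondary structure.** An in-package maximum base-pairing folder
  (Nussinov-style dynamic programming; Watson-Crick plus G-U wobble, hairpin
  loops of at least 3 nt, deterministic 5'-most traceback, 200-nt guard)
  folds the 101-nt window. The two derived features — paired flag and paired
  fraction — are coarse enough that a maximum-pairing model carries the same
  information as a thermodynamic folder; precomputed dot-bracket strings can
  be supplied instead and take precedence when configured.
* **Conservation aggregation.** The window mean over 21 nt, with missing
  track values imputed as 0 and counted in a message. In mature mode the
  window follows the spliced transcript, so its genomic footprint may be
  discontiguous.
* **z-scores.** Population (n) standard deviation, not sample (n − 1),
  frozen for reproducibility; a zero-variance population yields z = 0.
  Gene-level values standardise against the dataset's genes, the window GC
  against the extraction call's sites.
* **Alpha selection hygiene.** The blend weight is chosen on a validation
  subset carved from the lncRNA *training* data (a seeded stratified fifth),
  never on test data; the lncRNA member is refit on the full training set
  afterwards. Because the grid contains 0 and 1, the selected blend can
  never lose to either member alone on the selection set (ties resolve to
  the smaller alpha). Selecting alpha on the independent test set would
  leak test information and is deliberately avoided.
* **Feature selection.** "Importance" is the single-feature 10-fold CV AUC
  (classifier-agnostic; forest impurity importance is available behind a
  flag), and the greedy stage evaluates every prefix of the ranked list,
  keeping the shortest prefix attaining the maximal CV AUC.
* **Classification threshold.** A site is called positive iff its
  probability is strictly greater than 0.5, so exactly 0.5 is a negative
  call.
* **MCC convention.** A zero denominator yields 0.

## The synthetic fixture generator

Real six-experiment base-resolution compendia cannot be bundled, so every
test runs on seeded synthetic fixtures that emulate their statistical
structure: a random genome over four chromosomes; lncRNA-like genes (few
exons, shorter) and mRNA-like genes (many exons, longer), each with
occasional shorter extra isoforms so longest-transcript selection matters;
true sites drawn from the DRACH candidates with class-specific motif
preferences, a 3'-end positional bias (weight $e^{b \cdot relpos}$, b = 1),
and a conservation elevation of 0.35 within ±10 nt of true sites on all four
score tracks; and six replicate call sets, each the truth thinned by 15%
dropout plus 5% false calls at non-true DRACH positions. The default scale
is 2,000 planted positives per RNA class (about 4,000 labeled sites per
balanced dataset); `class_imbalance_config()` instead produces roughly 1,291
lncRNA positives against a 25-fold larger mRNA class, the imbalance
regime typical of base-resolution compendia. A structure-pairing bias is supported but
disabled by default: folding every candidate during generation is costly and
the remaining effects already span sequence, topology and track features.

What the fixtures do *not* emulate: real conservation autocorrelation along
the genome, genuine biological coupling between motif, structure and
methylation state, peak-level antibody artefacts, or hg19-scale
transcriptome composition. Passing fixture tests therefore demonstrates that
the machinery — encoding, projection, dataset rules, training, blending,
evaluation — is correct and that planted signal of realistic strength is
recovered; it does not certify accuracies on real cell-line data, which
depend on those data's properties.

## Numerical and degenerate-input conventions

* Genomic coordinates are 1-based inclusive internally (GTF convention);
  BED output is 0-based half-open.
* T is accepted everywhere and treated as U; `N` is legal only as window
  padding (never pairs, frequency 0, excluded from GC).
* Intronic genomic positions have no mature image and raise an explicit
  error; projection is bijective between mature and exonic genomic
  coordinates and order-preserving within a transcript.
* Ties in ranking and selection resolve deterministically (catalog order for
  features, smaller alpha, shortest prefix, lexicographic transcript id).
* ROC/AUC uses trapezoidal integration over distinct thresholds, equal to
  the Mann-Whitney pair statistic with ties counted 1/2.
* All sampling (negatives, splits, folds, fixtures, forests) flows from
  named integer seeds; rerunning with the same seeds reproduces outputs
  exactly, including trained forests.

## Problem sizes used by the test-suite

The acceptance checks run the default fixture (2,000 positives per class) for
the 10-fold cross-validation properties — planted-signal AUC at least 0.85,
label-independent AUC within [0.45, 0.55] — and small fixtures (tens of
genes, hundreds of sites) for the blend, consensus and file round-trip
checks. The exhaustive folding oracle enumerates all pairings for sequences
up to 12 nt on a seeded random sample of sequences (enumerating *every*
sequence up to that length is combinatorially out of reach); legality of the
emitted dot-bracket structures is additionally verified at 80 nt.

## Known limitations

* The 13 m6A-biology overlap tracks and the two conservation track pairs
  are configurable registries with empty defaults: their real-data content
  (specific annotation sets; PhastCons/fitCons builds) must be supplied by
  the analyst; no particular annotation compendium is bundled or
  reconstructed here.
* The maximum-pairing folder ignores thermodynamics; its two features are
  deliberately coarse.
* The full-transcript mode measures distances on pre-RNA coordinates;
  analyses that want genomic-gap distances must project externally.
* Single-feature CV ranking scores features marginally; strongly
  interacting feature pairs may rank low individually.
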