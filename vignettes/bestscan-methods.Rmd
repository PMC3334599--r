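---
title: "Detecting bidirectional expression of short transcripts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bidirectional expression of short transcripts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bestscan)
```

# The problem and the model

Nascent-transcription assays (GRO-seq and kin) read out the positions of
transcriptionally engaged RNA polymerase as stranded sequencing reads.
Promoter-proximal pausing produces a distinctive local pattern: a dense
spike of sense-strand reads just downstream of the TSS, and a divergent
antisense spike immediately upstream — bidirectional expression of short
transcripts (BEST). The same transcriptomic signature at non-promoter
loci is a footprint of polymerase recruited to active regulatory elements
such as enhancers. `bestscan` formalises the signature as a supervised
classification problem: learn what BEST looks like at a cell type's own
active promoters, then scan all non-promoter 2-kb windows for it.

## Density statistic

Everything is built on one statistic: read density in **reads / kb /
mapability**. For a window of length $L$ bp with $n$ read anchors on the
resolved strand and length-weighted mean mapability $m$,

$$d = \frac{n}{(L/1000)\, m}.$$

Each read contributes to exactly one window, through a single anchor
position — by default its 5′ end on its own strand, the natural choice for
a polymerase-position signal (the midpoint is available as an option).
This keeps counts exactly additive over window partitions, which the test
suite asserts as an invariant. When $m$ is at or below a floor (default
0.05) the density is *undefined* rather than arbitrarily inflated; such
windows are excluded from training and scanning instead of dominating
them. Uncovered bases in the mapability track default to 0, the
conservative reading of missing annotation; window mapability is the
length-weighted mean of the piecewise-constant values over the window.

## Active-gene calling

The level of transcription of a transcript is the sense density over its
*body*, defined as 1 kb downstream of the TSS to the annotated gene end;
transcripts of 3 kb or less carry no body and are not scored. The
activity cutoff is calibrated against externally labelled expressed /
non-expressed genes by the maximal-accuracy rule: every observed density
(plus one value above the maximum, so the all-negative rule is reachable)
is tried as a threshold for "density ≥ cutoff means expressed", and the
cutoff maximising $(TP + TN)/(P + N)$ is kept, ties resolved to the
smallest cutoff. The search is exhaustive and finite by construction, and
a brute-force re-scan is the oracle in the tests. The boundary is
inclusive (`≥`), and when several transcripts share a gene symbol the
longest active transcript represents the symbol.

## The classifier

Each stranded 2-kb window yields six features: sense density $f_1$,
antisense density $f_2$, and the four ratios of $f_1, f_2$ to the sense /
antisense densities of the 2-kb windows immediately 3′ and 5′
(strand-relative, so the directions flip on the minus strand). Ratios are
regularised with a symmetric pseudocount (default 0.1 reads/kb/mapability)
in numerator and denominator: a window with no reads anywhere gets ratios
of exactly 1 rather than 0/0.

Training windows are centred at active TSSs (class B), active-transcript
midpoints (class E), and midpoints of seeded random intergenic regions
matched to the active-transcript length distribution and overlapping no
annotated transcript (class N). Intergenic windows get a random strand:
background is strand-symmetric, and fixing a strand would bias the N
feature distributions.

The class-conditional distribution of each feature is a quantile-binned
histogram (default 20 bins) of log1p-transformed values, with bin edges
computed on the *pooled* values of all three classes so every class is
measured on the same grid, and Laplace smoothing
$(\text{count} + \alpha)/(n + k\alpha)$ with $\alpha = 1$ so every bin
has positive mass and every log-likelihood is finite. Quantile binning on
the log scale is robust to the heavy right tails of read densities;
values outside the training range are clamped into the open edge bins.
Priors are uniform. Posteriors are evaluated in log space and normalised
by log-sum-exp; the tests require agreement with a direct-product
implementation to 1e-9. Exact posterior ties resolve in the fixed order N,
then E, then B — the conservative direction, biased against false BEST
calls. The LOD score is the log odds of B against the *better* of E and N
(priors included), so with equal priors a window is called B exactly when
LOD > 0; the high-confidence rule is the strict LOD > 2.5.

## Scanning

Chromosomes are tiled with non-overlapping 2-kb windows from coordinate 0,
with no offset sweep: one prediction per genomic window, evaluated on both
strands and reported once with the max-LOD strand, which keeps the
"one or both strands" counting rule unambiguous. A window is skipped when
it, or either flanking window, intersects the exclusion mask or has
undefined density. The mask is the union of ±7 kb around every TSS *and
annotated gene end* plus ±7 kb around every H3K4me3 peak — the fuller of
the two plausible readings of the exclusion rule (gene ends included),
chosen because gene ends show a dampened pausing-like signal that would
otherwise contaminate non-promoter calls. Skipped-window counts are
reported per chromosome in the scan log.

## Enrichment statistics

Overlap of predictions with a peak set is compared against seeded random
background windows drawn from the same non-overlapping tiling the scan
uses, avoiding the same exclusion mask (plus any extra exclusions).
Overlap means an intersection of at least 1 bp under half-open
coordinates; abutting intervals do not overlap. The test is a two-tailed
Pearson chi-squared on the 2×2 table without continuity correction —
appropriate in the large-count regime these comparisons live in — and
errors on degenerate margins. Chromatin-mark representation at loci is
the pooled (not per-region averaged) reads/bp of the mark at loci over
background, divided by the same ratio for input:
$\ln\!\big[(t_\text{loci}/t_\text{bg})\,/\,(i_\text{loci}/i_\text{bg})\big]$,
with per-replicate values and their SD when replicates are supplied, and
a flagged undefined result when any pooled density is zero.

## Proportional-distance profiles

To aggregate read patterns over peaks of very different sizes, genomic
offsets are converted to proportional distance: offset from the peak
start divided by peak length, so every peak interior maps to $[0, 1]$ and
flanks extend below 0 and above 1. Bins of 150 bp tile outward from the
peak boundaries across 5-kb flanks; for a 300-bp peak the first interior
bin spans 0–0.5, the first upstream bin −0.5–0, the first downstream bin
1–1.5. Peaks whose 5-kb-extended span comes within 2 kb of a TSS, gene
end, or H3K4me3 peak are discarded first. Per region and strand, bin
densities are divided by the average density over the whole peak + flank
extent, making the length-weighted mean of relative density exactly 1 —
an identity the tests check — and regions with no signal on either strand
are skipped and counted. Region profiles are averaged onto a fixed
proportional grid (bins of 0.1 over $[-2, 3]$): each 150-bp bin
contributes to the grid bin containing its midpoint, and short peaks
(whose flanks reach far in proportional units) simply contribute to more
flank bins than long peaks. Unstranded peaks use plus-strand reads as
"sense". Gene metaprofiles use the same machinery with strand-aware
coordinates (TSS = 0, gene end = 1, flanks of half a gene length).

The pausing index of a transcript is the sense density in
$[\mathrm{TSS}, \mathrm{TSS}+1\,\mathrm{kb})$ divided by the body density
(TSS + 1 kb to the gene end). The window sizes are a design choice — the
index is conventionally defined only up to such windows — and are
configurable; the scientifically testable property is the inverse rank
correlation with gene-body expression, which the suite asserts on
simulated cohorts.

# The synthetic-data generator

The generator emulates exactly the structure the method exploits, as a
seeded Poisson process:

* **Genome**: 10 Mb as two 5-Mb chromosomes — large enough for ~2,500
  scannable windows and stable rate estimates, small enough that the full
  train + scan cycle runs in seconds.
* **Genes**: 200 non-overlapping genes of 3.5–12 kb (all above the 3-kb
  body filter), 60% expressed. Expressed bodies get
  $8 + \mathrm{Exp}(\text{mean }10)$ reads/kb of sense-strand elongation;
  non-expressed $\mathrm{Unif}(0, 0.8)$ — an order-of-magnitude
  separation, as in real nascent data, with truth labels split at
  5 reads/kb.
* **Pause spikes**: each expressed promoter gets Poisson(50) sense reads
  in [TSS, TSS+150) and Poisson(35) antisense reads in [TSS−200, TSS):
  the antisense spike sits immediately upstream, as divergent initiation
  does.
* **Planted loci**: 50 intergenic loci carry the identical bidirectional
  spike shape on a random strand. They are kept ≥ 7 kb from every gene
  TSS/end, mutually separated, and — including the ±5-kb flank context
  the classifier needs — inside the scannable search space and within
  mappable sequence: truth planted where the scanner cannot look would
  measure placement rather than recovery.
* **Background**: 0.2 reads/kb on each strand, uniform.
* **Mapability**: piecewise-constant 50-kb segments, mostly 1.0 with ~5%
  at 0.8 and ~2% at 0.02, exercising the undefined-density path.
* **Reads** are thinned by local mapability after placement, so the
  reads/kb/mapability estimator is unbiased for the simulated rates.
* **Peak sets**: per mark, a peak is planted over each truth locus with
  probability $q$ (default 0.8) and over each of 2,000 control windows
  with probability $r$ (default 0.1). Control windows are 2-kb tiles
  sampled *without replacement* away from truth loci, so each window's
  overlap indicator is an independent Bernoulli and the recovered fold
  converges to $q/r$; H3K4me3-like peaks are additionally placed at 90%
  of expressed promoters to exercise the exclusion machinery.

Reads are independent positions, not fragments: sufficient for a method
that only consumes anchor densities. The generator deliberately does not
model sequence content, PCR/nucleotide bias, fragment-length effects, or
spatial autocorrelation of chromatin state. Passing the recovery tests
therefore shows the statistical machinery is correct under the stated
model — not that real data meet that model; on real data, mapability
error, unannotated transcripts, and amplification artefacts will all cost
accuracy.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; strand is `+`, `-` or `*`.
* The density engine returns `NA` (never an exception) for
  below-floor mapability; feature extraction refuses windows with any
  undefined constituent density or missing flank, and callers skip them.
* Quantile bin edges are deduplicated, so a feature whose pooled values
  are heavily tied gets fewer than the nominal bins; the effective count
  is what the Laplace denominator uses, and edges/masses are serialised
  with the model (versioned JSON) so a reloaded model scores identically.
* Random placements (intergenic training regions, background windows,
  planted loci) are rejection-sampled with bounded retries and fail
  loudly with the shortfall rather than silently degrading.
* All seeded stages save and restore the caller's RNG state, and
  regenerating any dataset from the same config is byte-identical.

# Problem sizes

The test suite and the reference simulation are sized for interactive
use: the full suite (including three complete train + scan cycles at
decreasing spike amplitude, oracle sweeps of 1,000 classifier evaluations
and 200 ROC datasets of up to 1,000 genes) completes in well under a
minute on one core.

# Known limitations

* Adjacent high-confidence windows are not merged into loci, and the
  2-kb tiling is not swept across offsets, so a BEST event straddling a
  tile boundary can split its signature between two windows and be
  missed; this is the dominant (and understood) source of sensitivity
  loss in the planted-truth tests.
* Posterior probabilities are not calibrated; only their ordering and the
  LOD scale are meaningful.
* SAM/BAM input is not parsed; reads are consumed as BED6/bedGraph text
  behind the read-track contract.
* Peak calling, coordinate lift-over and expression-array preprocessing
  are upstream of this package: peaks and labels are consumed as files.
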