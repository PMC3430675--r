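---
title: "Methods: peak calling, grading and binding-site length prediction for afSELEX-seq"
author: "afselex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak calling, grading and binding-site length prediction for afSELEX-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afselex)
```

## The experiment and the analysis problem

Aptamer-free SELEX-seq (afSELEX-seq) selects sheared genomic dsDNA
fragments for binding to a protein of interest over several competitive
cycles, sequencing every cycle including the unselected input library.
After aligning each cycle back to the source genome, a genuine binding
site appears as a coverage peak that sharpens and grows with every round,
while unbound regions are counter-selected toward zero coverage. The
analysis tasks are: build comparable per-cycle coverage tracks, find peaks
in the final cycle, decide which peaks behaved like true binding sites
across cycles, estimate the length of the bound site from peak geometry,
and hand well-chosen sequences (plus a null model) to a motif-discovery
tool.

## Frequency tracks

Each cycle's alignments (SAM or BLASTn 12-column tabular) are reduced to
`(start, span, strand)` triples; only mapped primary alignments are used
and the reference span is computed from the CIGAR. Because library
fragments are sequenced from one end, a read shorter than the mean library
fragment length $L$ is extended 3'-ward on its strand to length $L$; every
position of the resulting occupied interval receives +1 coverage. Coverage
of the *fragment footprint* (rather than counting 5' tag starts) is what
makes the peak-width model below valid. Both strands contribute to the same
track, since dsDNA binding is strand-agnostic. The genome is treated as
linear; fragments are truncated at its ends (for a circular bacterial
chromosome this produces at most one boundary artifact).

Cycles are sequenced to different depths, so every cycle is first
subsampled to the same number of aligned reads -- uniformly, without
replacement, under a caller-supplied seed, after sorting reads into a
canonical order so the selection does not depend on input file order. No
further between-cycle normalization is applied.

Coordinates are 1-based and inclusive throughout, matching SAM convention
and every written report.

## Peak identification

Peaks are called on the final enrichment cycle with a sliding-window scan
of total width $2L$ advancing one nucleotide at a time. A position
qualifies as an apex iff it strictly exceeds every count in the left
half-window, weakly exceeds the right half-window, and strictly exceeds
the window minimum. The asymmetric tie rule reports an extended run of
tied values once, at its leftmost position (a strict-maximum rule would
silently drop flat-topped peaks); the window-minimum clause makes a
perfectly flat window yield nothing.

An apex is kept only if its final-cycle count exceeds the local control
threshold
$$ \mu_c + k\,\sigma_c, $$
the mean plus $k$ (default 2) population standard deviations of the
*control-cycle* counts over a window of radius `statRange` (default
1000 bp) around the apex. Two SDs corresponds to the upper edge of the 95%
band of control variation. Counter-selection can drive the local control
to all zeros, which would make the threshold 0 and admit single-read
noise; `minApex` (default 10 counts) floors the threshold in that case.
The threshold is tested at the apex only.

Retained apexes closer together than one fragment length are merged into a
single peak (the higher apex survives), with two exceptions under which
both stand as separate peaks: a *deep valley* -- the minimum track value
between them falls below 50% of the smaller apex -- or *comparable
heights* -- the smaller apex is at least 75% of the larger. "Adjacent peak
value" in the valley rule is read as the smaller of the two apexes.
Merging proceeds left to right, the surviving apex being compared with the
next maximum. Each retained peak's support finally extends from its apex
outwards to the nearest zero-coverage position, clipped at the midpoint to
each retained neighbor, so supports are disjoint.

## Peak grading

Apex frequencies are compared across all cycles at the final-cycle apex
position. A peak earns the weight $w_t$ of every transition $t$ (control
to cycle 2, cycle 2 to cycle 3, ...) in which its apex frequency strictly
increased (fold-change threshold configurable via `enrichFactor`):
$$ \mathrm{score} = \sum_t w_t\,[f_{t+1} > f_t]. $$
Weights should be proportional to the bulk affinity of each cycle's
library, so that enrichment under the harsher competition of later rounds
counts more; without affinity measurements the default doubles per round
(1, 2, 4, ...), which preserves the property that later rounds dominate
and additionally makes every achievable score distinct. Distinct achieved
scores, sorted descending, define ordinal quality classes; class 1
("Best") holds the peaks with the maximal achieved score. With a single
transition every enriching peak lands in class 1 -- grading needs multiple
cycles to discriminate, which is the method's central point.

Each peak is annotated with its area (sum of final-cycle counts over the
support), its fraction of the total area over all peaks, its 99%-area
width, the predicted binding-site length, and the genomic sequence
centered on its apex (`seqRange` bp, default 200, sized for
motif-discovery input). The report is ordered by class, then score, then
area, then position.

## Binding-site length from peak width

A fragment binds specifically only if it contains the whole site, so
fragments of mean length $L$ over a site of length $b$ tile a footprint of
full width $W = 2L - b$; inverting gives $b = 2L - W$. Width is measured
as the *range along the chromosome containing the central 99% of the
peak's area*: the 0.5% and 99.5% quantiles of the cumulative count
distribution across the support are located by linear interpolation
(position $j$ occupying the unit interval $(j-1, j]$), and the interval is
expanded to whole-bp bounds, $W = \lceil q_{0.995}\rceil - \lfloor
q_{0.005}\rfloor$.

This whole-bp convention is a deliberate numerical choice. For a flat
footprint of width $F \le 199$ bp it returns exactly $F$ -- so the
predictor recovers $b$ *exactly* on idealized fragment-union coverage,
which the test suite verifies for $L \in \{30, 50, 100\}$ and all
$b \in \{10, \dots, L-5\}$ -- while for a dense Gaussian of SD $\sigma$ it
returns $2 \times 2.576\,\sigma \approx 5.15\,\sigma$ up to at most 1 bp
of expansion per side. A pure interpolated quantile range would instead
return $0.99F$ on flat footprints and bias $\hat b$ upward by
$\mathrm{round}(0.01F)$. The residual cost of the whole-bp convention is a
$-1$ bp bias on Gaussian peaks whose footprint width is even; it is
visible in simulation as sparse datasets whose few identical best peaks
all predict $b - 1$ (see *Known limitations*).

Predictions at or below zero (peak wider than $2L$, e.g. merged or
support-truncated peaks) are clamped to 0 and flagged indeterminate.

## Spoof peaks and the background model

Motif discovery benefits from a background (null) base-composition model.
`generateSpoofs()` draws seeded uniform random positions -- by default as
many as there are real peaks, avoiding real peak supports and the genome
ends -- and extracts sequences of the grading `seqRange`, so the null
sample is size- and width-matched to the real peak sequences.
`zeroOrderModel()` tallies single-base frequencies (ignoring N) and
`writeBackground()` serializes them in the background-file dialect that
motif-discovery tools consume. Negative peaks are deliberately not
produced: counter-selection leaves near-zero background between peaks, so
local control dips reflect sequencing variation, not weak binding.

## The synthetic-data generator

`simulateDataset()` builds a complete synthetic experiment with ground
truth:

1. a uniform random genome of `genomeSize` bp (default 5e6);
2. a motif: a random genome substring with length drawn uniformly from
   `motifLenRange` (default 15--30 bp). Its similarity model is the
   deterministic matrix (probability 1 on the motif base per position), so
   similarity reduces to the match count times the scale factor;
3. a similarity profile over every genome window, on both strands (the
   larger of the forward and reverse-complement scores);
4. per enrichment cycle, a Gaussian peak at every above-cutoff site with
   amplitude $\propto \exp(k_c\, s/s_{\max})$, the steepness $k_c$
   strictly increasing over cycles (default 4, 6, 8), truncated at
   $\pm 4\sigma$; the whole track is then scaled so its total mass equals
   `totalReads` $\times L$, the coverage equivalent of a fixed per-cycle
   read total (default 2e7 reads). Scaling after truncation makes the
   normalization exact;
5. a control track of uniform random integer coverage with mean
   `controlDepth` (default 20), independent of similarity -- in the
   unselected library frequency carries no affinity signal;
6. the Gaussian SD is $\sigma = (2L - b)/(2 \times 2.576)$, so the central
   99% of each peak's area spans exactly the fragment footprint $2L - b$
   of the true site -- the geometry the length predictor assumes.

**Enrichment cutoff.** Sites scoring below `cutoffFrac` of the maximum
similarity do not enrich at all. The default is 0.625: the halfway point
between the similarity of a random sequence and a perfect match. Under the
deterministic matrix a random n-mer already matches 25% of positions
(the analogous baseline on a bit-score similarity axis is the
random-sequence score, not zero), so "half of maximal identity" sits at
$0.25 + 0.5 \times 0.75 = 0.625$ of the raw maximum. This calibration
keeps above-cutoff sites in the tens-to-thousands per half-megabase,
comparable to real afSELEX-seq peak sets. Cutting at 0.5 of the raw
maximum instead admits $P(\mathrm{Bin}(n, 0.25) \ge n/2)$ of all genome
positions -- 2--3% for short motifs, a site every ~30 bp -- tiling the
genome with overlapping footprints that no peak caller could separate and
that no real selection experiment resembles. The parameter is fully
exposed for users who want a different regime.

**What the generator emulates, and what it does not.** It reproduces the
features the analysis depends on: enrichment proportional to an
exponential function of motif similarity with round-over-round steepening,
Gaussian peak shape with footprint-encoded width, fixed per-cycle mass,
and an affinity-blind control. It does not simulate sequencing error,
mappability or GC bias, fragment-length dispersion (all peaks share one
$\sigma$), read-level sampling noise (amplitudes are deterministic;
Poisson noise would be a straightforward extension), or biological
cooperativity between sites. Passing tests therefore demonstrate that the
pipeline inverts the generator's (paper-shaped) data model, not that it is
robust to every artifact of real sequencing data.

## Validation analyses

`gaussianFitR2()` measures peak normality: a Gaussian is parameterized by
the profile's own maximum, mean position and positional SD, and the
least-squares $r^2$ between profile and Gaussian is reported (1.0 for an
exact Gaussian; undefined, with a warning, for zero-variance profiles).

`binnedSimilarityFrequency()` ranks all sites by descending similarity,
bins them in groups of 100 (trailing partial group dropped) and averages
similarity and track frequency per bin; `fitExponential()` fits
$\mathrm{freq} = a\,e^{k\,\mathrm{sim}}$ by least squares on log
frequency over positive-frequency bins, reporting the log-scale $r^2$.
When judging the simulator's own response, bins are used only if they lie
fully inside the enriching similarity range (mean bin similarity at or
above the first match level above the cutoff): a boundary bin averages
enriching sites with zero-expectation ones, and its mean frequency is
meaningless on the log scale. Fit quality also requires site footprints
not to overlap much -- frequency read at a site otherwise includes
spillover from neighboring peaks -- so the property is demonstrated on a
sparse-site configuration (3e5 bp genome, 29 bp motif, 30 bp fragments,
cutoff 0.5 pinned to widen the enriching range).

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at reduced scale,
chosen to exercise the same regimes at desk cost: the length-recovery
study uses 20 datasets of 5e5 bp (fragment length 100 bp, 2e6
reads-equivalent per cycle, seeds 1..20), unit fixtures use genomes of
1--100 kb, and oracle suites use exhaustive small cases. Other choices:
population (not sample) SD for the control threshold; strict inequality
for enrichment; ties in report order broken by class, score, area, then
position; all randomness flows from caller-supplied seeds through a
restore-on-exit RNG scope, so identical configurations reproduce
byte-identical outputs.

## Known limitations

* **Crowded sites.** When binding-site footprints overlap (site spacing
  below $\approx 4\sigma$), peak supports truncate at inter-peak midpoints
  and predicted lengths shrink toward 0; the per-dataset SD then widens,
  which is honest but uninformative. This is a property of the data
  regime, not fixable by the caller.
* **Even-width footprints.** The whole-bp width measure predicts $b - 1$
  for isolated Gaussian peaks whose footprint $2L - b$ is even; datasets
  with very few best-class peaks can therefore miss the truth with SD 0.
* **Single sequence, linear genome.** Multi-contig references are
  rejected; circularity is ignored.
* **No statistical peak model.** The caller is deliberately
  threshold-based (local control mean + 2 SD); it estimates no FDR and
  models no local rate, by design.
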