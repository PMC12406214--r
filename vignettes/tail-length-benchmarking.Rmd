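---
title: "Benchmarking poly(A) tail length inference from raw nanopore signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking poly(A) tail length inference from raw nanopore signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailbench)
```

## The problem

Direct RNA nanopore sequencing records the ionic current of a single
molecule threading a pore 3'-to-5'. Each read therefore begins with the
sequencing adapter, then the reverse-transcription adapter (RTA, whose ten
poly(T) bases anneal to the tail during library preparation), then the
poly(A) tail, then the transcript body. The tail appears as a long,
low-variance stretch of signal, and its length in nucleotides is

$$ L = \frac{e - s}{r}, $$

where $[s, e)$ is the tail's span in raw samples and $r$ is the
read-specific translocation rate in samples per nucleotide, estimated here
as transcript-region samples divided by the known transcript length.
Different tools disagree mainly in how they find $[s, e)$; `tailbench`
implements the three archetypal strategies as peers over a shared
simulator so that their behavior can be compared against exact ground
truth:

* **HMM** (`hmm_segment()`): a four-state linear-chain hidden Markov model
  (adapter, RTA, poly(A), transcript) with Gaussian emissions, decoded by
  Viterbi. Minimum state durations are enforced by state expansion, and an
  exhaustive-enumeration oracle (`oracle_segment()`) certifies on small
  reads that the decoder returns the global maximum-likelihood tiling.
* **Sliding window** (`window_segment()`): two passes -- a smoothed signal
  is thresholded inside a band around the poly(A) level, then 25-sample
  bin means shrink the rough boundaries until the bin-to-bin slope falls
  under a limit.
* **Anchor-and-grow** (`anchor_segment()`): the adapter is taken as the
  initial high-level segment; the first trailing window whose mean sits in
  the poly(A) band with variance under a ceiling anchors the region, which
  then grows while samples stay near the anchor level. Regions shorter
  than a minimum length are discarded, making this the conservative
  method: it drops short tails the HMM still calls, which reproduces the
  real-world phenomenon of one tool filtering out reads another keeps.

## Group-level averaging: median versus maxpeak

Per-read estimates from real read sets are multimodal: a main peak near
the true length plus an over-represented short-tail population. A median
over such a mixture is pulled toward the contaminant. The package's
central statistic is therefore the **maxpeak** -- the tail length
maximizing a Gaussian-kernel density estimate (`density_estimate()`,
Silverman's rule-of-thumb bandwidth, 512-point grid, ties to the smallest
grid value). The main peak's spread is summarized by its full width at
half-maximum: `fwhm_sd()` interpolates the two half-height crossings
nearest the highest peak and reports $\mathrm{FWHM} / (2\sqrt{2\ln 2})$,
the standard deviation of a Gaussian of that width; minor peaks elsewhere
are ignored.

Accuracy is scored by the windowed mean absolute error: reads are cut, in
input order, into non-overlapping windows of $N$ reads (incomplete
trailing window dropped), each window is summarized by its median or
maxpeak, and the MAE is the mean absolute deviation of those summaries
from the known length. Uncertainty comes from a percentile bootstrap
(resample reads with replacement within the known-length category, then
re-window; $B = 1000$), and tool differences are tested two-sidedly
against the mean-centered bootstrap distribution of the MAE difference.
With $B$ resamples the smallest reportable nonzero p-value is $1/B$; a
zero exceedance count is reported as $p < 1/B$, never as zero. Tool
comparisons are restricted to reads detected by every tool
(`common_reads()`) so that detection differences do not masquerade as
accuracy differences.

Design choices in this area that the literature leaves open, decided here
once: percentile (not BCa) intervals as the simplest defensible choice;
resampling happens *before* windowing; windows follow input order rather
than any sort; the p-value uses the symmetric two-sided exceedance of the
centered difference.

## The synthetic-data generator

`simulate_dataset()` draws molecules under a `sim_config()`:

* **Geometry.** Region lengths in nucleotides (adapter 30, RTA 14 --
  including the ten poly(T) positions that set the ~10 nt detection floor
  -- and a 300 nt transcript by default) are converted to samples by a
  per-read translocation rate drawn from a normal truncated below at 1
  sample/nt. Presets mirror the two chemistry generations:
  `rna002_config()` (~70 nt/s at 3012 Hz, about 43 samples/nt) and
  `rna004_config()` (~130 nt/s at 4000 Hz, about 31 samples/nt).
* **Emissions.** Each region has a Gaussian level (defaults, in arbitrary
  units: adapter 120 +/- 5, RTA 95 +/- 3, poly(A) 105 +/- 1.5); the
  transcript resamples one level per nucleotide from a stationary
  distribution (85, between-level sd 8, within-level sd 2), giving it the
  high level-switching variance that the low-variance poly(A) detectors
  exploit.
* **Artifacts**, applied with precedence mispriming > fragmentation >
  degradation so each configured probability is exactly the marginal rate
  of its label when enabled alone: *degradation* shortens the tail by a
  geometric-like draw (mean 30 nt, capped at the tail length) and leaves
  the 3' end intact; *fragmentation* removes the tail and truncates the
  body, pushing the mapped end more than 20 nt from the reference 3' end;
  *mispriming* starts the read at an internal A-rich site planted in each
  simulated reference (a decamer with a five-adenine run), with an
  apparent tail of 0-10 nt; *split reads* emit one molecule as two
  consecutive reads on the same channel whose sample counts sum to the
  parent's. Default artifact rates (degradation 0.15, fragmentation 0.08,
  mispriming 0.04, split 0.01) are plausible magnitudes for a degraded
  library, chosen once and exposed in the config, since no quantitative
  model for them exists to copy.
* **Metadata.** Channels, start times, and per-read mean quality scores
  (normal with mean 25, sd 2.4, so that ~98% of reads exceed Q20) support
  the split-read and quality analyses.

What the generator deliberately does **not** emulate: pore k-mer models
and sequence-dependent current (transcript levels are sequence-agnostic),
basecalling and its errors, RNA modifications, or dwell-time
autocorrelation. Passing tests therefore certify the estimators'
statistical machinery against a faithful *structural* model of direct-RNA
reads, not their robustness to every idiosyncrasy of real pores; on real
data the segmentation parameters would need calibrating against the
observed level distributions rather than derived from a known generative
config.

## Short-tail diagnostics

`short_tail_report()` reproduces the forensic workflow for reads called
with sub-threshold tails (< 10 nt by default): a read whose mapped 3' end
lies within 20 nt (inclusive) of the reference 3' end is
degradation-consistent (`full_length`); farther ends are `truncated` and
are screened for mispriming by examining the 10 nt downstream of the
mapped end -- a longest adenine run of at least 4, or adenine content
above 50%, flags a plausible internal priming site. The 50% content
default follows the threshold stated for the screen in the literature;
a stricter 60% variant appears in some figure annotations, so the
threshold is exposed as a parameter. Split pairs are recovered from
acquisition metadata by greedy earliest-first pairing of consecutive
same-channel reads within a gap threshold. Spearman correlation (average
ranks for ties) quantifies any relationship between tail length and read
quality; degenerate rank situations are reported as not-applicable rather
than as a number.

## Numerical choices and degenerate inputs

* Signals are standardized per read by median/MAD before segmentation, so
  every boundary call is invariant to affine rescaling of the current.
  Parameters derived from a config (`hmm_params_for()` and friends)
  account for this by solving the config's four-component mixture CDF for
  its analytic median and MAD; emission sds are further inflated by a term
  proportional to each level's magnitude, absorbing the ~10% per-read
  error of the MAD estimate itself.
* Viterbi ties break toward the earlier region switch; the enumeration
  oracle breaks ties to the lexicographically earliest boundary triple.
* The KDE grid density is renormalized so its trapezoidal integral is
  exactly 1; a zero-variance sample short-circuits to a point-mass summary
  whose maxpeak is the repeated value.
* A tail call with undetected boundaries is a status (`no_tail`), not an
  error; a missing or non-positive translocation rate yields
  `rate_unavailable`. Density summaries refuse fewer than 10 reads,
  maxpeak windows require at least 10 reads per window, and the FWHM
  estimator raises an "unbounded peak" error when the density never drops
  below half-maximum inside the grid.
* The anchor grower confirms a level change with 3 of the next 5 samples
  before stopping, so single outlying samples cannot truncate a tail.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data at sizes chosen to make every stochastic check stable: 200 reads for
the decoder-vs-oracle certificate, six datasets of 500 reads
(RNA002-like preset, tails 10-150 nt) for maxpeak recovery, 100
replicates of 2,000-read contaminated populations for the windowed-MAE
properties, 10,000 draws for FWHM calibration, and 1,000 reads for the
diagnostics mixture. Bootstrap routines default to $B = 1000$.

## Known limitations

* Segmentation parameters are derived from the generating config; there
  is no blind re-estimation of levels from a single read, so applying the
  segmenters to real squiggles requires a calibration step.
* The window and anchor methods report no likelihood score, only
  detection status and boundaries.
* The known overestimation-adjustment step some production basecallers
  apply to their tail calls is unspecified upstream and is deliberately
  not imitated.
* Split-read pairing is greedy earliest-first; molecules split into three
  or more reads would be paired only partially.
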