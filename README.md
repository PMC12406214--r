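# tailbench

Poly(A) tail length inference and benchmarking from nanopore raw signal.

Direct RNA nanopore sequencing reads a molecule 3'-to-5', so every read's
current trace contains, in order: sequencing adapter, reverse-transcription
adapter (RTA), poly(A) tail, transcript body. The tail's length in
nucleotides is `L = (e - s) / r`, where `[s, e)` is the tail's sample span
and `r` the read-specific translocation rate (samples per nucleotide).
Estimating `L` well matters because tail length feeds into mRNA stability,
translation-efficiency and differential-polyadenylation analyses — and the
tools that estimate it disagree, mainly in how they segment the raw
signal.

`tailbench` is for method developers and analysts who want to study that
disagreement under exact ground truth. It provides:

* **a squiggle simulator** (`simulate_dataset()`) producing four-region
  direct-RNA reads with known tails (presets for the ~70 nt/s and
  ~130 nt/s chemistries), plus the artifact processes that create
  spuriously short tails: tail degradation, fragmentation, internal-site
  mispriming, and split-read glitches;
* **three segmenters** spanning the design space of published tools: a
  linear-chain HMM decoded by Viterbi (C++ core, certified against an
  exhaustive-enumeration oracle), a two-pass sliding-window method
  (25-sample bin averaging with slope-limited boundary shrinking), and a
  conservative anchor-and-grow method that discards short tails;
* **tail estimation** with QC statuses (`estimate_tails()`), converting
  sample spans to nucleotides via the translocation rate;
* **benchmark statistics**: kernel-density **maxpeak** averaging (the mode
  of the tail-length density — robust to the short-tail contaminant
  population that drags medians down), FWHM-derived peak widths, windowed
  MAE with percentile-bootstrap confidence intervals and two-sided
  bootstrap tests (p-value floor `1/B`), and common-read filtering for
  direct tool comparisons;
* **short-tail diagnostics**: degradation-vs-truncation classification at
  the mapped 3' end, an A-run/A-content mispriming screen on the
  downstream decamer, split-pair detection from channel metadata, and
  quality–length correlation;
* a **CLI** (`run_cli()`, also installed as `inst/scripts/tailbench`) with
  `simulate | segment | estimate | evaluate | diagnose | all` subcommands,
  YAML configs, TSV/FASTA interchange and seeded, byte-reproducible runs.

## Worked example

Simulate a 60 nt-tail library with realistic artifact rates, run the HMM
pipeline, and summarize:

```r
library(tailbench)

cfg <- rna002_config(tail_population = list(c(60, 1)))
ds  <- simulate_dataset(cfg, n_reads = 300, seed = 42)
ds
#> <sim_dataset> 302 reads (seed 42)
#>   artifact reads: 40 degraded, 24 fragmented, 9 misprimed, 4 split parts

est  <- estimate_tails(ds, method = "hmm", rate_source = "transcript")
density_estimate(est$tail_nt[est$qc == "pass"])
#> <density_summary> n = 302, bandwidth = 0.155 nt
#>   maxpeak 59.98 nt | median 60.00 nt | FWHM-derived sd 0.18 nt
```

The maxpeak sits on the known 60 nt tail even though ~24% of reads carry
an artifact. Two reads were emitted as split pairs (302 reads from 300
molecules); `find_split_pairs(signal_metadata(ds), 0.5)` recovers them,
and `short_tail_report(est, stubs, ds$references)` classifies the
sub-10 nt calls into degradation-consistent versus truncated reads with a
mispriming screen.

Where maxpeak earns its keep is a *contaminated* population. With 35% of
reads carrying short tails (the mixture real libraries show), the median
of each 100-read window is dragged down while the density mode is not:

```r
set.seed(1)
tails <- sample(c(rnorm(1300, 60, 6), pmax(0, rnorm(700, 8, 3))))
windowed_mae(tails, truth = 60, window_n = 100, statistic = "maxpeak")
#> <benchmark_result> -, known 60 nt: MAE = 0.700 nt (maxpeak, window 100, 20 windows)
windowed_mae(tails, truth = 60, window_n = 100, statistic = "median")
#> <benchmark_result> -, known 60 nt: MAE = 4.594 nt (median, window 100, 20 windows)
```

`bootstrap_ci()` wraps either statistic with a 95% resampling interval and
`bootstrap_test()` compares two tools' MAEs (smallest reportable nonzero
p with `B = 1000` is 0.001; a zero exceedance count prints as
`P < 0.001`).

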