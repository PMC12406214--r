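#' Simulation configuration for synthetic direct-RNA squiggles
#'
#' Defines the generative model for four-region reads (sequencing adapter,
#' reverse-transcription adapter (RTA), poly(A) tail, transcript body), the
#' per-read translocation rate, the tail-length population, and the artifact
#' processes that produce spuriously short tails: tail degradation,
#' fragmentation of the read body, internal-site mispriming, and split-read
#' glitches.
#'
#' Current levels are in arbitrary units; only their relative separation
#' matters because segmentation standardizes each read by median/MAD. The
#' poly(A) region has deliberately low variance relative to the transcript
#' body, whose per-nucleotide levels are resampled from a stationary
#' distribution with large between-level spread -- the signature that
#' low-variance anchor-style detectors rely on.
#'
#' @param sampling_rate samples per second of the acquisition.
#' @param translocation_rate_mean,translocation_rate_sd mean and sd of the
#'   per-read translocation rate in samples per nucleotide. One rate is drawn
#'   per read from a normal truncated below at 1 sample/nt.
#' @param adapter_nt,rta_nt,transcript_len_nt region lengths in nucleotides.
#'   The RTA default of 14 nt includes the 10 poly(T) positions that set the
#'   nominal 10 nt detection floor for tails.
#' @param adapter_mean,adapter_sd,rta_mean,rta_sd,polya_mean,polya_sd
#'   Gaussian emission parameters per region (arbitrary current units).
#' @param transcript_mean,transcript_within_sd,transcript_between_sd
#'   transcript emissions: per-nucleotide level means are drawn iid from
#'   Normal(`transcript_mean`, `transcript_between_sd`) and samples within a
#'   level add Normal(0, `transcript_within_sd`) noise.
#' @param tail_population list of `c(length_nt, weight)` pairs (or a
#'   two-column matrix/data frame); weights must be positive and are
#'   normalized to sum to 1.
#' @param degradation_prob probability a read's tail is enzymatically
#'   shortened; `degradation_scale` is the mean shortening in nt
#'   (geometric-like draw, capped at the tail length).
#' @param fragmentation_prob probability the read body is 3'-truncated with
#'   the tail removed entirely (mapped end > 20 nt from the reference 3'
#'   end).
#' @param mispriming_prob probability the poly(T) adapter anneals to an
#'   internal A-rich site instead of the tail, yielding a 0-10 nt apparent
#'   tail and a truncated alignment.
#' @param split_prob probability a molecule is emitted as two consecutive
#'   reads on the same channel; `split_gap_s` is the inter-read gap in
#'   seconds.
#' @param n_refs number of reference transcripts to simulate against.
#' @param n_channels,run_duration_s flow-cell geometry used for channel and
#'   start-time metadata.
#' @param qscore_mean,qscore_sd per-read mean quality score distribution.
#' @param noise_seed optional integer seed recorded in the config; dataset
#'   generation always seeds explicitly via [simulate_dataset()].
#'
#' @return an object of class `sim_config`.
#' @seealso [rna002_config()], [rna004_config()], [simulate_dataset()]
#' @export
sim_config <- function(sampling_rate = 3012,
                       translocation_rate_mean = sampling_rate / 70,
                       translocation_rate_sd = 0.05 * translocation_rate_mean,
                       adapter_nt = 30, rta_nt = 14, transcript_len_nt = 300,
                       adapter_mean = 120, adapter_sd = 5,
                       rta_mean = 95, rta_sd = 3,
                       polya_mean = 105, polya_sd = 1.5,
                       transcript_mean = 85, transcript_within_sd = 2,
                       transcript_between_sd = 8,
                       tail_population = list(c(60, 1)),
                       degradation_prob = 0.15, degradation_scale = 30,
                       fragmentation_prob = 0.08, mispriming_prob = 0.04,
                       split_prob = 0.01, split_gap_s = 0.25,
                       n_refs = 4, n_channels = 512, run_duration_s = 20000,
                       qscore_mean = 25, qscore_sd = 2.4,
                       noise_seed = NULL) {
  pop <- normalize_tail_population(tail_population)
  cfg <- structure(list(
    sampling_rate = sampling_rate,
    translocation_rate_mean = translocation_rate_mean,
    translocation_rate_sd = translocation_rate_sd,
    adapter_nt = adapter_nt, rta_nt = rta_nt,
    transcript_len_nt = transcript_len_nt,
    adapter_mean = adapter_mean, adapter_sd = adapter_sd,
    rta_mean = rta_mean, rta_sd = rta_sd,
    polya_mean = polya_mean, polya_sd = polya_sd,
    transcript_mean = transcript_mean,
    transcript_within_sd = transcript_within_sd,
    transcript_between_sd = transcript_between_sd,
    tail_population = pop,
    degradation_prob = degradation_prob,
    degradation_scale = degradation_scale,
    fragmentation_prob = fragmentation_prob,
    mispriming_prob = mispriming_prob,
    split_prob = split_prob, split_gap_s = split_gap_s,
    n_refs = n_refs, n_channels = n_channels,
    run_duration_s = run_duration_s,
    qscore_mean = qscore_mean, qscore_sd = qscore_sd,
    noise_seed = noise_seed), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

normalize_tail_population <- function(pop) {
  if (is.data.frame(pop) || is.matrix(pop)) {
    pop <- lapply(seq_len(nrow(pop)), function(i) as.numeric(pop[i, 1:2]))
  }
  if (!is.list(pop) || length(pop) == 0)
    stop("invalid `tail_population`: must be a nonempty list of (length_nt, weight) pairs")
  m <- do.call(rbind, lapply(pop, function(p) {
    p <- as.numeric(p)
    if (length(p) != 2 || anyNA(p))
      stop("invalid `tail_population`: each entry needs (length_nt, weight)")
    p
  }))
  if (any(m[, 1] < 0))
    stop("invalid `tail_population`: tail lengths must be >= 0")
  if (any(m[, 2] <= 0) || sum(m[, 2]) <= 0)
    stop("invalid `tail_population`: weights must be positive and sum to a positive value")
  data.frame(length_nt = m[, 1], weight = m[, 2] / sum(m[, 2]))
}

validate_sim_config <- function(cfg) {
  num_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("invalid `%s`: must be a single positive number", field))
  }
  num_nonneg <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop(sprintf("invalid `%s`: must be a single nonnegative number", field))
  }
  prob01 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(sprintf("invalid `%s`: must be a probability in [0, 1]", field))
  }
  for (f in c("sampling_rate", "translocation_rate_mean", "adapter_nt",
              "rta_nt", "transcript_len_nt", "degradation_scale",
              "split_gap_s", "n_refs", "n_channels", "run_duration_s",
              "qscore_sd"))
    num_pos(f)
  for (f in c("translocation_rate_sd", "adapter_sd", "rta_sd", "polya_sd",
              "transcript_within_sd", "transcript_between_sd"))
    num_nonneg(f)
  for (f in c("degradation_prob", "fragmentation_prob", "mispriming_prob",
              "split_prob"))
    prob01(f)
  if (cfg$transcript_len_nt < 20)
    stop("invalid `transcript_len_nt`: references need at least 20 nt")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  sampling rate: %g Hz; translocation rate: %.1f +/- %.1f samples/nt\n",
              x$sampling_rate, x$translocation_rate_mean, x$translocation_rate_sd))
  cat(sprintf("  regions (nt): adapter %g, RTA %g, transcript %g\n",
              x$adapter_nt, x$rta_nt, x$transcript_len_nt))
  cat(sprintf("  tail population: %s\n",
              paste(sprintf("%gnt(%.2f)", x$tail_population$length_nt,
                            x$tail_population$weight), collapse = ", ")))
  cat(sprintf("  artifacts: degradation %.2f (scale %g nt), fragmentation %.2f, mispriming %.2f, split %.2f\n",
              x$degradation_prob, x$degradation_scale, x$fragmentation_prob,
              x$mispriming_prob, x$split_prob))
  invisible(x)
}

#' Kit-like presets for the simulator
#'
#' `rna002_config()` mimics the older chemistry: ~70 nt/s at a 3012 Hz
#' sampling rate (~43 samples/nt). `rna004_config()` mimics the newer
#' chemistry: ~130 nt/s at 4000 Hz (~31 samples/nt). All other parameters
#' are shared defaults and can be overridden.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
rna002_config <- function(...) {
  args <- list(...)
  defaults <- list(sampling_rate = 3012,
                   translocation_rate_mean = 3012 / 70)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

#' @rdname rna002_config
#' @export
rna004_config <- function(...) {
  args <- list(...)
  defaults <- list(sampling_rate = 4000,
                   translocation_rate_mean = 4000 / 130)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}
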