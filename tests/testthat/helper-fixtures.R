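# Small, fast configurations used across the suite. Scaled-down rates keep
# reads short (hundreds of samples) so whole datasets simulate in
# milliseconds; levels and artifact machinery are the package defaults.

tiny_config <- function(...) {
  defaults <- list(sampling_rate = 100, translocation_rate_mean = 4,
                   translocation_rate_sd = 0.2, adapter_nt = 10, rta_nt = 5,
                   transcript_len_nt = 60, tail_population = list(c(30, 1)),
                   degradation_prob = 0, fragmentation_prob = 0,
                   mispriming_prob = 0, split_prob = 0, n_refs = 2)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(sim_config, defaults)
}

# zero within-region noise (transcript levels still switch between nt)
zero_noise_config <- function(...) {
  tiny_config(adapter_sd = 0, rta_sd = 0, polya_sd = 0,
              transcript_within_sd = 0, translocation_rate_sd = 0, ...)
}

tiny_hmm <- function(cfg) hmm_params_for(cfg, min_duration = rep(8L, 4))

# exact two-sided binomial 99% acceptance interval for a count
binom99 <- function(n, p) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p))
}

expect_in_interval <- function(count, interval) {
  expect_gte(count, interval[1])
  expect_lte(count, interval[2])
}

# mixture of a true-length peak and a short-tail contaminant, emulating the
# multimodal tail distributions real read sets show
contaminated_tails <- function(n, truth = 60, sd_main = 6,
                               contamination = 0.35) {
  short <- rbinom(n, 1, contamination) == 1
  x <- numeric(n)
  x[!short] <- rnorm(sum(!short), truth, sd_main)
  x[short] <- pmax(0, rnorm(sum(short), 8, 3))
  x
}
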