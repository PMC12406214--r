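# shared raw-unit parameters for plateau-style constructions
plateau_params <- hmm_params(means = c(4, 1, 2.5, 0),
                             sds = c(0.3, 0.3, 0.2, 1),
                             self_trans = rep(0.99, 4),
                             min_duration = rep(5L, 4))

plateau_read <- function(lens, means = c(4, 1, 2.5, 0)) {
  squiggle("plateau", rep(means, times = lens), sampling_rate = 100)
}

test_that("HMM boundaries land exactly at zero-noise plateau joins", {
  lens <- c(30L, 20L, 40L, 50L)
  b <- hmm_segment(plateau_read(lens), plateau_params, standardize = FALSE)
  expect_identical(b$starts, c(0L, 30L, 50L, 90L))
  expect_identical(b$polya_start, 50L)
  expect_identical(b$polya_end, 90L)
  expect_true(b$detected)
})

test_that("reads shorter than the summed minimum durations are refused", {
  short <- squiggle("s", rnorm(3), 100)
  p <- hmm_params(c(4, 1, 2.5, 0), rep(0.5, 4), min_duration = rep(10L, 4))
  expect_error(hmm_segment(short, p), "signal too short")
  expect_error(oracle_segment(short, p), "signal too short")
})

test_that("the oracle refuses reads above its length bound", {
  long <- squiggle("l", rnorm(400), 100)
  expect_error(oracle_segment(long, plateau_params, max_len = 300),
               "too long")
})

test_that("a read of exactly the minimum total duration has the unique tiling", {
  lens <- c(5L, 5L, 5L, 5L)
  b <- oracle_segment(plateau_read(lens), plateau_params, standardize = FALSE)
  expect_identical(b$starts, c(0L, 5L, 10L, 15L))
  v <- hmm_segment(plateau_read(lens), plateau_params, standardize = FALSE)
  expect_identical(v$starts, b$starts)
})

test_that("Viterbi equals the exhaustive-enumeration oracle on random reads", {
  cfg <- tiny_config(translocation_rate_mean = 2, translocation_rate_sd = 0.1,
                     adapter_nt = 8, rta_nt = 5, transcript_len_nt = 25,
                     tail_population = list(c(10, 1), c(20, 1)))
  hp <- hmm_params_for(cfg, min_duration = rep(5L, 4))
  ds <- simulate_dataset(cfg, 200, seed = 2024)
  for (sq in ds$reads) {
    v <- hmm_segment(sq, hp)
    o <- oracle_segment(sq, hp, max_len = 300)
    expect_equal(v$score, o$score, tolerance = 1e-10)
    expect_identical(as.integer(v$starts), as.integer(o$starts))
  }
})

test_that("window segmentation brackets a clean plateau within one bin", {
  set.seed(8)
  x <- c(rnorm(300, 4, 1.5), rep(2.5, 2500), rnorm(1000, 0, 1.5))
  sq <- squiggle("p", x, 100)
  wp <- window_params(polya_level = 2.5, band = 0.5)
  b <- window_segment(sq, wp, standardize = FALSE)
  expect_true(b$detected)
  expect_lte(abs(b$polya_start - 300), 25 + wp$smooth %/% 2 + 1)
  expect_lte(abs(b$polya_end - 2800), 25 + wp$smooth %/% 2 + 1)
})

test_that("window segmentation recovers a simulated tail span within two bins", {
  cfg <- tiny_config(translocation_rate_mean = 30, translocation_rate_sd = 0,
                     tail_population = list(c(60, 1)), transcript_len_nt = 80)
  ds <- simulate_dataset(cfg, 10, seed = 3)
  wp <- window_params_for(cfg)
  spans <- vapply(ds$reads, function(sq) {
    b <- window_segment(sq, wp)
    expect_true(b$detected)
    b$polya_end - b$polya_start
  }, numeric(1))
  expect_true(all(abs(spans - 1800) <= 2 * wp$bin))
})

test_that("pure high-variance noise yields no window detection", {
  set.seed(10)
  sq <- squiggle("noise", rnorm(5000, 0, 3), 100)
  b <- window_segment(sq, window_params(polya_level = 2.5, band = 0.4),
                      standardize = FALSE)
  expect_false(b$detected)
})

test_that("anchor segmentation is exact on zero-noise reads", {
  cfg <- zero_noise_config(tail_population = list(c(40, 1)))
  ds <- simulate_dataset(cfg, 10, seed = 4)
  ap <- anchor_params_for(cfg, window = 10L, min_len = 40L)
  for (id in names(ds$reads)) {
    b <- anchor_segment(ds$reads[[id]], ap)
    ann <- ds$annotations[[id]]
    expect_true(b$detected)
    expect_equal(b$polya_start, ann$polya[1])
    expect_equal(b$polya_end, ann$polya[2])
  }
})

test_that("anchor segmentation drops tails shorter than its minimum length", {
  cfg <- zero_noise_config(tail_population = list(c(5, 1)))
  ds <- simulate_dataset(cfg, 5, seed = 6)
  ap <- anchor_params_for(cfg, window = 10L, min_len = 40L)  # 5 nt * 4 = 20 < 40
  for (sq in ds$reads)
    expect_false(anchor_segment(sq, ap)$detected)
})

test_that("anchor detection is more conservative than the HMM on a benchmark", {
  cfg <- tiny_config(tail_population = list(c(8, 2), c(40, 8)),
                     degradation_prob = 0.2, fragmentation_prob = 0.1)
  ds <- simulate_dataset(cfg, 200, seed = 17)
  hp <- tiny_hmm(cfg)
  ap <- anchor_params_for(cfg)
  n_hmm <- sum(vapply(ds$reads, function(sq)
    tryCatch(hmm_segment(sq, hp)$detected, error = function(e) FALSE),
    logical(1)))
  n_anchor <- sum(vapply(ds$reads, function(sq)
    anchor_segment(sq, ap)$detected, logical(1)))
  expect_lte(n_anchor, n_hmm)
  expect_gt(n_anchor, 0)
})

test_that("boundary error grows with emission noise, in expectation", {
  # one fixed decoder, increasingly noisy data
  hp <- tiny_hmm(tiny_config(tail_population = list(c(20, 1))))
  noise_err <- function(noise_mult) {
    cfg <- tiny_config(adapter_sd = 5 * noise_mult, rta_sd = 3 * noise_mult,
                       polya_sd = 1.5 * noise_mult,
                       transcript_within_sd = 2 * noise_mult,
                       tail_population = list(c(20, 1)))
    ds <- simulate_dataset(cfg, 100, seed = 55)
    mean(vapply(names(ds$reads), function(id) {
      b <- hmm_segment(ds$reads[[id]], hp)
      ann <- ds$annotations[[id]]
      abs(b$polya_start - ann$polya[1]) + abs(b$polya_end - ann$polya[2])
    }, numeric(1)))
  }
  errs <- vapply(c(1, 2, 4), noise_err, numeric(1))
  expect_true(all(diff(errs) >= 0))
})

test_that("boundary calls are invariant to rescaling the current", {
  cfg <- tiny_config()
  ds <- simulate_dataset(cfg, 5, seed = 77)
  hp <- tiny_hmm(cfg)
  wp <- window_params_for(cfg)
  ap <- anchor_params_for(cfg)
  for (sq in ds$reads) {
    scaled <- squiggle(sq$read_id, sq$samples * 7.3 + 11, sq$sampling_rate)
    for (f in list(function(s) hmm_segment(s, hp),
                   function(s) window_segment(s, wp),
                   function(s) anchor_segment(s, ap))) {
      b1 <- f(sq); b2 <- f(scaled)
      expect_identical(b1$polya_start, b2$polya_start)
      expect_identical(b1$polya_end, b2$polya_end)
    }
  }
})
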