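test_that("3' end classification uses an inclusive 20 nt threshold", {
  expect_identical(classify_end(0), "full_length")
  expect_identical(classify_end(20), "full_length")
  expect_identical(classify_end(21), "truncated")
  expect_identical(classify_end(500), "truncated")
  expect_identical(classify_end(c(0, 20, 21)),
                   c("full_length", "full_length", "truncated"))
  expect_error(classify_end(-1), "ref_end_offset_nt")
})

test_that("the mispriming screen enumerates runs and adenine content", {
  r <- mispriming_screen("AAAAAAAAAA", 0)
  expect_identical(r$longest_a_run, 10L)
  expect_equal(r$a_fraction, 1)
  expect_true(r$mispriming_flag)

  r <- mispriming_screen("CGCGCGCGCG", 0)
  expect_identical(r$longest_a_run, 0L)
  expect_equal(r$a_fraction, 0)
  expect_false(r$mispriming_flag)

  # flagged by content only: longest run 3 < 4, but 7/10 adenines
  r <- mispriming_screen("AATAAAGCAA", 0)
  expect_identical(r$longest_a_run, 3L)
  expect_equal(r$a_fraction, 0.7)
  expect_true(r$mispriming_flag)
})

test_that("the screen records shortfall near the reference end and checks coordinates", {
  ref <- "CCCCCCCCCCAAAA"
  r <- mispriming_screen(ref, 10)   # only 4 nt remain
  expect_identical(r$shortfall, 6)
  expect_identical(r$longest_a_run, 4L)
  expect_true(r$mispriming_flag)
  r2 <- mispriming_screen(ref, 14)  # at the very end: nothing downstream
  expect_identical(r2$downstream_seq, "")
  expect_false(r2$mispriming_flag)
  expect_error(mispriming_screen(ref, 15), "coordinate error")
  expect_error(mispriming_screen(ref, -1), "coordinate error")
})

test_that("the mispriming flag is monotone in both thresholds", {
  set.seed(201)
  mers <- replicate(200, paste(sample(c("A", "C", "G", "T"), 10,
                                      replace = TRUE, prob = c(.4, .2, .2, .2)),
                               collapse = ""))
  for (m in mers) {
    flags_run <- vapply(1:8, function(rt)
      mispriming_screen(m, 0, run_threshold = rt)$mispriming_flag, logical(1))
    flags_ct <- vapply(c(.2, .4, .6, .8), function(ct)
      mispriming_screen(m, 0, content_threshold = ct)$mispriming_flag,
      logical(1))
    # lowering a threshold never unflags
    expect_true(all(diff(flags_run) <= 0))
    expect_true(all(diff(flags_ct) <= 0))
  }
})

test_that("split-pair detection pairs adjacent same-channel reads greedily", {
  md <- data.frame(read_id = c("a", "b", "c", "d"),
                   channel = c(1, 1, 2, 3),
                   start_time = c(0, 10.1, 0, 5),
                   duration = c(10, 5, 5, 5))
  p <- find_split_pairs(md, max_gap_s = 0.5)
  expect_identical(nrow(p), 1L)
  expect_identical(p$first_id, "a")
  expect_identical(p$second_id, "b")

  md$channel <- c(1, 2, 3, 4)
  expect_identical(nrow(find_split_pairs(md, 0.5)), 0L)

  # three consecutive close reads: greedy earliest-first pairs the first two
  md3 <- data.frame(read_id = c("x", "y", "z"), channel = 1,
                    start_time = c(0, 10.1, 15.3), duration = c(10, 5, 5))
  p3 <- find_split_pairs(md3, 0.5)
  expect_identical(nrow(p3), 1L)
  expect_identical(p3$first_id, "x")
})

test_that("simulated split pairs are recovered exactly from metadata", {
  cfg <- tiny_config(split_prob = 0.08)
  ds <- simulate_dataset(cfg, 300, seed = 202)
  truth_pairs <- sum(grepl("split_first", ds$truth$artifact_labels))
  p <- find_split_pairs(signal_metadata(ds), max_gap_s = cfg$split_gap_s * 2)
  expect_identical(nrow(p), truth_pairs)
  expect_true(all(grepl("_p1$", p$first_id)))
  expect_true(all(grepl("_p2$", p$second_id)))
})

test_that("quality-length correlation handles monotone, null and degenerate inputs", {
  tails <- 1:50
  expect_equal(quality_length_correlation(tails, tails^2 + 5)$rho, 1)

  set.seed(203)
  nulls <- vapply(1:100, function(i)
    quality_length_correlation(rnorm(1000), rnorm(1000))$rho, numeric(1))
  expect_gte(sum(abs(nulls) < 0.1), 95)

  r <- quality_length_correlation(rep(5, 20), rnorm(20))
  expect_identical(r$status, "not_applicable")
  expect_true(is.na(r$rho))
  expect_error(quality_length_correlation(1:5, 1:5), "insufficient reads")
})

test_that("short-tail reports recover simulated degraded/fragmented fractions", {
  # all molecules carry short tails: 40% fragmented, the rest degraded
  cfg <- tiny_config(tail_population = list(c(6, 1)), degradation_prob = 1,
                     fragmentation_prob = 0.4)
  ds <- simulate_dataset(cfg, 1000, seed = 204)
  est <- data.frame(read_id = ds$truth$read_id, method = "truth", qc = "pass",
                    tail_nt = ds$truth$true_tail_nt, polya_start = 0,
                    polya_end = 1, rate = 1)
  stubs <- ds$truth[, c("read_id", "ref_id", "ref_end_offset_nt",
                        "mean_qscore")]
  rep <- short_tail_report(est, stubs, ds$references)
  s <- rep$summary
  expect_identical(s$status, "ok")
  expect_identical(s$n_short, 1000L)
  # partition property
  expect_equal(s$full_length + s$truncated, 1)
  n_frag <- sum(grepl("fragmented", ds$truth$artifact_labels))
  expect_equal(round(s$truncated * 1000), n_frag, ignore_attr = TRUE)
  expect_in_interval(n_frag, binom99(1000, 0.4))
  # degraded reads keep an intact 3' end
  expect_in_interval(round(s$full_length * 1000), binom99(1000, 0.6))
})

test_that("the screen flags misprimed reads more often than fragmented ones", {
  cfg <- tiny_config(tail_population = list(c(5, 1)), mispriming_prob = 0.5,
                     fragmentation_prob = 1)  # precedence: misprime first
  ds <- simulate_dataset(cfg, 400, seed = 205)
  est <- data.frame(read_id = ds$truth$read_id, method = "truth", qc = "pass",
                    tail_nt = pmin(ds$truth$true_tail_nt, 9), polya_start = 0,
                    polya_end = 1, rate = 1)
  stubs <- ds$truth[, c("read_id", "ref_id", "ref_end_offset_nt",
                        "mean_qscore")]
  rep <- short_tail_report(est, stubs, ds$references)
  rec <- merge(rep$records, ds$truth[, c("read_id", "artifact_labels")],
               by = "read_id")
  mis <- grepl("misprimed", rec$artifact_labels)
  frag <- grepl("^fragmented", rec$artifact_labels)
  expect_gt(mean(rec$mispriming_flag[mis]), mean(rec$mispriming_flag[frag]))
  expect_gt(mean(rec$mispriming_flag[mis]), 0.9)
})

test_that("empty short-tail sets and missing references degrade gracefully", {
  refs <- Biostrings::DNAStringSet(c(ref_01 = paste(rep("ACGT", 25),
                                                    collapse = "")))
  est <- data.frame(read_id = "r1", method = "m", qc = "pass", tail_nt = 50,
                    polya_start = 0, polya_end = 1, rate = 1)
  stubs <- data.frame(read_id = "r1", ref_id = "ref_01",
                      ref_end_offset_nt = 0, mean_qscore = 25)
  rep <- short_tail_report(est, stubs, refs)
  expect_identical(rep$summary$status, "not_applicable")
  expect_identical(rep$summary$n_short, 0L)

  est$tail_nt <- 3
  stubs$ref_id <- "missing_ref"
  expect_warning(rep2 <- short_tail_report(est, stubs, refs), "missing reference")
  expect_identical(rep2$summary$status, "not_applicable")
})
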