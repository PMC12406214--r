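test_that("density summaries handle degenerate and small samples", {
  s <- density_estimate(rep(42, 25))
  expect_equal(s$maxpeak, 42)
  expect_equal(s$median, 42)
  expect_error(density_estimate(rnorm(9)), "insufficient reads")
})

test_that("the KDE mode tracks a known normal mode and integrates to 1", {
  set.seed(101)
  s <- density_estimate(rnorm(5000, 50, 3))
  expect_lt(abs(s$maxpeak - 50), 1)
  expect_lt(abs(trapezoid(s$grid, s$density) - 1), 1e-3)
  expect_equal(s$maxpeak, s$grid[which.max(s$density)])
})

test_that("maxpeak resists short-tail contamination where the median does not", {
  set.seed(102)
  x <- c(rnorm(700, 60, 5), rnorm(300, 8, 3))
  s <- density_estimate(x)
  expect_gte(s$maxpeak, 55)
  expect_lte(s$maxpeak, 65)
  expect_lt(s$median, s$maxpeak)
  # brute-force grid scan as an independent mode oracle
  h <- s$bandwidth
  grid <- s$grid
  kde <- vapply(grid, function(g) mean(dnorm((g - x) / h)) / h, numeric(1))
  expect_equal(s$maxpeak, grid[which.max(kde)], tolerance = 1e-8)
})

test_that("maxpeak and median agree on symmetric unimodal samples", {
  set.seed(103)
  for (rep in 1:5) {
    # an explicit moderate bandwidth keeps the mode estimate stable
    s <- density_estimate(rnorm(2000, 40, 6), bandwidth = 2)
    expect_lte(abs(s$maxpeak - s$median), s$bandwidth)
  }
})

test_that("FWHM-derived sd is calibrated on an analytic normal density", {
  grid <- seq(60 - 25, 60 + 25, length.out = 801)
  s <- density_summary(grid, dnorm(grid, 60, 5))
  expect_equal(fwhm_sd(s), 5, tolerance = 0.01)

  set.seed(104)
  x <- rnorm(10000, 60, 10)
  s2 <- density_estimate(x)
  expect_lt(abs(fwhm_sd(s2) - sd(x)) / sd(x), 0.1)
})

test_that("FWHM ignores minor peaks and flags unbounded ones", {
  grid <- seq(-20, 120, length.out = 2001)
  y <- 0.8 * dnorm(grid, 30, 4) + 0.2 * dnorm(grid, 90, 4)
  s <- density_summary(grid, y / trapezoid(grid, y))
  expect_equal(fwhm_sd(s), 4, tolerance = 0.4)

  flat <- density_summary(seq(0, 10, length.out = 101),
                          rep(0.1, 101))
  expect_error(fwhm_sd(flat), "unbounded peak")
})

test_that("peak width grows with tail length under constant sample noise", {
  set.seed(105)
  widths <- vapply(c(10, 30, 60, 100, 150), function(L) {
    rates <- pmax(1, rnorm(400, 40, 3))
    spans <- L * rates + rnorm(400, 0, 20)
    # population-average rate stands in for the unknown per-read rate
    est <- pmax(0, spans / 40)
    fwhm_sd(density_estimate(est))
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("windowed MAE reproduces hand-computed examples", {
  r <- windowed_mae(c(28, 32, 20, 40), truth = 30, window_n = 2,
                    statistic = "median")
  expect_equal(r$mae, 0)
  expect_equal(r$n_windows, 2L)
  expect_equal(windowed_mae(c(32, 32, 40, 40), 30, 1, "median")$mae, 6)
  expect_equal(windowed_mae(rep(60, 37), 60, 5, "median")$mae, 0)
  # incomplete trailing window dropped
  expect_equal(windowed_mae(c(10, 50, 99), 30, 2, "median")$mae, 0)
  expect_error(windowed_mae(c(1, 2), 30, 5, "median"), "complete window")
  expect_error(windowed_mae(rnorm(50), 30, 5, "maxpeak"), "window_n >= 10")
})

test_that("bootstrap CIs degenerate correctly and are reproducible", {
  r <- bootstrap_ci(rep(60, 40), 60, 10, "median", B = 200, seed = 1)
  expect_equal(c(r$ci_low, r$mae, r$ci_high), c(0, 0, 0))
  set.seed(42)
  x <- rnorm(100, 60, 10)
  r1 <- bootstrap_ci(x, 60, 10, "median", B = 200, seed = 7)
  r2 <- bootstrap_ci(x, 60, 10, "median", B = 200, seed = 7)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  expect_lte(r1$ci_low, r1$mae)
  expect_gte(r1$ci_high, r1$mae)
})

test_that("bootstrap CIs cover the generating process MAE", {
  set.seed(106)
  # independent oracle: the true windowed-median MAE of the process by
  # large-scale direct simulation
  true_mae <- mean(abs(apply(matrix(rnorm(10 * 20000, 60, 10), nrow = 10),
                             2, median) - 60))
  hits <- 0
  for (i in 1:100) {
    x <- rnorm(200, 60, 10)
    r <- bootstrap_ci(x, 60, 10, "median", B = 400, seed = 1000 + i)
    if (r$ci_low <= true_mae && true_mae <= r$ci_high) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("the bootstrap test reports the 1/B floor on separated groups", {
  a <- rep(90, 50); b <- rep(60, 50)
  r <- bootstrap_test(a, b, truth = 60, window_n = 10, statistic = "median",
                      B = 1000, seed = 1)
  expect_equal(r$p_value, 0.001)
  expect_true(r$floor)
  expect_equal(r$observed_diff, 30)
})

test_that("identical groups have zero observed MAE difference", {
  set.seed(107)
  x <- rnorm(60, 60, 5)
  r <- bootstrap_test(x, x, 60, 10, "median", B = 100, seed = 3)
  expect_equal(r$observed_diff, 0)
  expect_false(r$floor)
})

test_that("a large dispersion difference is declared significant", {
  set.seed(108)
  a <- rnorm(500, 60, 3); b <- rnorm(500, 60, 30)
  r <- bootstrap_test(a, b, 60, 10, "median", B = 1000, seed = 5)
  expect_lte(r$p_value, 0.01)
})

test_that("common-read filtering intersects QC-passing ids", {
  t1 <- data.frame(read_id = c("a", "b", "c"), qc = "pass",
                   tail_nt = 1:3)
  t2 <- data.frame(read_id = c("a", "b", "c"), qc = c("pass", "pass",
                                                      "no_tail"),
                   tail_nt = 1:3)
  cr <- common_reads(list(x = t1, y = t2))
  expect_setequal(cr$read_ids, c("a", "b"))
  expect_identical(unname(cr$detection_counts), c(3L, 2L))
  expect_identical(nrow(cr$tables$x), 2L)
  # nested drops: intersection size equals the smallest detection count
  expect_identical(length(cr$read_ids), min(cr$detection_counts))

  t3 <- data.frame(read_id = c("a", "b"), qc = "no_tail", tail_nt = 1:2)
  expect_warning(cr2 <- common_reads(list(t1 = t1, t3 = t3)),
                 "empty intersection")
  expect_length(cr2$read_ids, 0)
  expect_identical(nrow(cr2$tables$t1), 0L)

  expect_error(common_reads(list(t1)), "at least 2")
  expect_error(common_reads(list(a = t1, b = t1[, "read_id", drop = FALSE])),
               "qc")
})

test_that("maxpeak windows beat median windows under heavy contamination", {
  set.seed(109)
  x <- contaminated_tails(2000)
  mp <- windowed_mae(x, 60, 100, "maxpeak")$mae
  md <- windowed_mae(x, 60, 100, "median")$mae
  expect_lt(mp, md)
})

test_that("evaluate_tables assembles benchmark and density tables", {
  set.seed(110)
  truth <- data.frame(read_id = sprintf("r%03d", 1:200),
                      true_tail_nt = rep(c(30, 60), each = 100))
  est <- data.frame(read_id = truth$read_id, method = "hmm", qc = "pass",
                    tail_nt = rnorm(200, truth$true_tail_nt, 4),
                    polya_start = 0, polya_end = 1, rate = 1)
  ev <- evaluate_tables(list(hmm = est), truth, window_ns = c(10, 50),
                        statistic = "median", B = 50, seed = 9)
  expect_identical(nrow(ev$benchmark), 4L)   # 2 lengths x 2 windows
  expect_identical(nrow(ev$density), 2L)
  expect_true(all(ev$benchmark$ci_low <= ev$benchmark$mae + 1e-12))
  expect_true(all(ev$benchmark$mae >= 0))
})
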