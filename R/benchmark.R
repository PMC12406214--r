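#' Windowed mean absolute error against a known tail length
#'
#' Reads are partitioned, in input order, into non-overlapping windows of
#' `window_n`; the incomplete trailing window is dropped. Each window is
#' summarized by its median or its maxpeak (KDE mode; windows must then
#' hold at least 10 reads) and the MAE is the mean over windows of the
#' absolute difference between the window summary and the known length.
#'
#' @param estimates per-read tail estimates in nt (input order preserved).
#' @param truth known tail length in nt.
#' @param window_n reads per window.
#' @param statistic `"median"` or `"maxpeak"`.
#' @param bandwidth optional bandwidth forwarded to [density_estimate()].
#' @return an object of class `benchmark_result`: list with tool,
#'   known_length_nt, window_n, statistic, mae, ci_low, ci_high, n_windows,
#'   detection_count.
#' @export
windowed_mae <- function(estimates, truth, window_n,
                         statistic = c("median", "maxpeak"),
                         bandwidth = NULL) {
  statistic <- match.arg(statistic)
  mae <- windowed_mae_value(estimates, truth, window_n, statistic, bandwidth)
  structure(list(tool = NA_character_, known_length_nt = truth,
                 window_n = as.integer(window_n), statistic = statistic,
                 mae = mae, ci_low = NA_real_, ci_high = NA_real_,
                 n_windows = length(estimates) %/% window_n,
                 detection_count = length(estimates)),
            class = "benchmark_result")
}

windowed_mae_value <- function(estimates, truth, window_n, statistic,
                               bandwidth = NULL) {
  estimates <- as.numeric(estimates)
  n <- length(estimates)
  k <- n %/% window_n
  if (k < 1) stop("no complete window: need at least `window_n` reads")
  if (statistic == "maxpeak" && window_n < 10)
    stop("maxpeak windows require window_n >= 10")
  w <- matrix(estimates[seq_len(k * window_n)], nrow = window_n)
  stat_w <- if (statistic == "median") {
    apply(w, 2, median)
  } else {
    apply(w, 2, function(v) density_estimate(v, bandwidth = bandwidth)$maxpeak)
  }
  mean(abs(stat_w - truth))
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %s, known %g nt: MAE = %.3f nt (%s, window %d, %d windows)\n",
              ifelse(is.na(x$tool), "-", x$tool), x$known_length_nt, x$mae,
              x$statistic, x$window_n, x$n_windows))
  if (!is.na(x$ci_low))
    cat(sprintf("  95%% bootstrap CI [%.3f, %.3f]\n", x$ci_low, x$ci_high))
  invisible(x)
}

#' Bootstrap confidence interval for the windowed MAE
#'
#' Resamples reads with replacement within the known-length category
#' (resample first, then window), recomputes the MAE `B` times, and takes
#' the 2.5/97.5 percentile interval.
#'
#' @inheritParams windowed_mae
#' @param B number of bootstrap resamples.
#' @param seed optional seed for the resampling.
#' @return a `benchmark_result` with `ci_low`/`ci_high` filled in.
#' @export
bootstrap_ci <- function(estimates, truth, window_n,
                         statistic = c("median", "maxpeak"), B = 1000,
                         seed = NULL, bandwidth = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- windowed_mae(estimates, truth, window_n, statistic, bandwidth)
  n <- length(estimates)
  maes <- vapply(seq_len(B), function(b) {
    windowed_mae_value(sample(estimates, n, replace = TRUE), truth, window_n,
                       statistic, bandwidth)
  }, numeric(1))
  ci <- unname(quantile(maes, c(0.025, 0.975)))
  res$ci_low <- ci[1]; res$ci_high <- ci[2]
  res
}

#' Bootstrap significance test for an MAE difference between two tools
#'
#' Both groups are resampled with replacement `B` times within the
#' known-length category; the two-sided p-value is the fraction of the
#' mean-centered bootstrap MAE differences at least as extreme in absolute
#' value as the observed difference. With a finite number of resamples the
#' smallest reportable nonzero p is `1/B`; a zero count is reported as
#' `p < 1/B` (flagged via `floor`).
#'
#' @param estimates_a,estimates_b per-read estimates for the two tools.
#' @inheritParams bootstrap_ci
#' @return an object of class `bootstrap_test`: list with p_value, floor
#'   (TRUE when the exceedance count was zero), observed_diff, mae_a,
#'   mae_b, B.
#' @export
bootstrap_test <- function(estimates_a, estimates_b, truth, window_n,
                           statistic = c("median", "maxpeak"), B = 1000,
                           seed = NULL, bandwidth = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mae_a <- windowed_mae_value(estimates_a, truth, window_n, statistic, bandwidth)
  mae_b <- windowed_mae_value(estimates_b, truth, window_n, statistic, bandwidth)
  obs <- mae_a - mae_b
  na <- length(estimates_a); nb <- length(estimates_b)
  d <- vapply(seq_len(B), function(b) {
    windowed_mae_value(sample(estimates_a, na, replace = TRUE), truth,
                       window_n, statistic, bandwidth) -
      windowed_mae_value(sample(estimates_b, nb, replace = TRUE), truth,
                         window_n, statistic, bandwidth)
  }, numeric(1))
  centered <- d - mean(d)
  count <- sum(abs(centered) >= abs(obs))
  structure(list(p_value = max(count, 1) / B, floor = count == 0,
                 observed_diff = obs, mae_a = mae_a, mae_b = mae_b, B = B),
            class = "bootstrap_test")
}

#' @export
print.bootstrap_test <- function(x, ...) {
  p <- if (x$floor) sprintf("P < %g", 1 / x$B) else sprintf("P = %g", x$p_value)
  cat(sprintf("<bootstrap_test> MAE %.3f vs %.3f (diff %.3f): %s (B = %d)\n",
              x$mae_a, x$mae_b, x$observed_diff, p, x$B))
  invisible(x)
}

#' Restrict per-tool estimate tables to commonly detected reads
#'
#' Tool comparisons are only direct when every tool calls the same reads,
#' so tables are filtered to the intersection of read ids with `qc ==
#' "pass"` across all tools. Per-tool detection counts are reported for
#' sensitivity accounting.
#'
#' @param tables named list (>= 2) of estimate data frames with `read_id`
#'   and `qc` columns.
#' @return list with `read_ids` (the intersection), `tables` (filtered),
#'   `detection_counts`; warns on an empty intersection.
#' @export
common_reads <- function(tables) {
  if (!is.list(tables) || length(tables) < 2)
    stop("need at least 2 estimate tables")
  for (nm in names(tables)) {
    miss <- setdiff(c("read_id", "qc"), names(tables[[nm]]))
    if (length(miss))
      stop(sprintf("table `%s` is missing column(s): %s", nm,
                   paste(miss, collapse = ", ")))
  }
  pass_ids <- lapply(tables, function(t) t$read_id[t$qc == "pass"])
  counts <- vapply(pass_ids, length, integer(1))
  ids <- Reduce(intersect, pass_ids)
  if (length(ids) == 0)
    warning("empty intersection: no read passed QC in every table")
  list(read_ids = ids,
       tables = lapply(tables, function(t) t[t$read_id %in% ids, ,
                                             drop = FALSE]),
       detection_counts = counts)
}
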