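#' Standardize a raw signal by median/MAD
#'
#' Raw current scale and offset are arbitrary across reads, so all
#' segmenters operate (by default) on `(x - median(x)) / mad(x)`. This makes
#' every boundary call invariant to affine rescaling of the current.
#'
#' @param x numeric vector of current samples.
#' @return standardized numeric vector.
#' @export
standardize_signal <- function(x) {
  s <- mad(x)
  if (!is.finite(s) || s == 0) s <- sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  (x - median(x)) / s
}

#' Parameters of the linear-chain segmentation HMM
#'
#' Four states in fixed signal order (adapter, RTA, poly(A), transcript),
#' linked by linear-chain transitions with no skips. Each state has a
#' Gaussian emission; the transcript state's sd should be inflated to absorb
#' per-nucleotide level switching. Minimum durations are enforced by state
#' expansion in the decoder.
#'
#' @param means,sds length-4 numeric: emission mean and sd per state, in the
#'   units of the (typically standardized) signal.
#' @param self_trans length-4 numeric in (0,1): self-transition probability
#'   of each state's terminal duration copy.
#' @param min_duration length-4 integer: minimum state durations in samples.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(means, sds, self_trans = rep(0.999, 4),
                       min_duration = rep(25L, 4)) {
  stopifnot(length(means) == 4, length(sds) == 4, length(self_trans) == 4,
            length(min_duration) == 4)
  if (any(sds <= 0)) stop("invalid `sds`: must be > 0")
  if (any(self_trans <= 0 | self_trans >= 1))
    stop("invalid `self_trans`: must be in (0, 1)")
  if (any(min_duration < 1)) stop("invalid `min_duration`: must be >= 1")
  structure(list(means = as.numeric(means), sds = as.numeric(sds),
                 self_trans = as.numeric(self_trans),
                 min_duration = as.integer(min_duration)),
            class = "hmm_params")
}

# Expected standardized level of each region given a simulator config.
# A read's samples follow a four-component normal mixture with weights
# proportional to the expected region durations; the per-read median/MAD
# standardization is approximated by the mixture's analytic median and MAD
# (solved from the mixture CDF), so derived parameters track any region
# geometry, not just transcript-dominated reads.
std_levels <- function(config) {
  w <- c(config$adapter_nt, config$rta_nt,
         sum(config$tail_population$length_nt * config$tail_population$weight),
         config$transcript_len_nt)
  w <- w / sum(w)
  mu <- c(config$adapter_mean, config$rta_mean, config$polya_mean,
          config$transcript_mean)
  s <- pmax(c(config$adapter_sd, config$rta_sd, config$polya_sd,
              sqrt(config$transcript_between_sd^2 +
                     config$transcript_within_sd^2)), 1e-6)
  Fm <- function(q) sum(w * stats::pnorm(q, mu, s))
  lo <- min(mu - 6 * s); hi <- max(mu + 6 * s)
  med <- stats::uniroot(function(q) Fm(q) - 0.5, c(lo, hi), tol = 1e-9)$root
  madv <- 1.4826 * stats::uniroot(
    function(t) Fm(med + t) - Fm(med - t) - 0.5,
    c(1e-9, hi - lo), tol = 1e-9)$root
  lv <- (mu - med) / madv
  list(means = lv, sds = s / madv, scale = madv,
       # half the gap from the poly(A) level to its nearest neighbour level
       polya_halfgap = min(abs(lv[3] - lv[2]), abs(lv[3] - lv[4])) / 2)
}

#' Derive segmenter parameters from a simulator configuration
#'
#' Converts the generator's emission model to the standardized scale the
#' segmenters operate on (per-read median/MAD standardization is
#' approximated by the transcript level mean and total spread). sd floors
#' keep the states tolerant of per-read standardization jitter.
#'
#' @param config a [sim_config()].
#' @param min_duration minimum state durations in samples.
#' @return an `hmm_params`.
#' @export
hmm_params_for <- function(config, min_duration = rep(25L, 4)) {
  lv <- std_levels(config)
  # inflate emission sds to absorb per-read standardization jitter: the
  # per-read MAD estimate has ~10-15% relative error, which shifts every
  # standardized level in proportion to its magnitude
  sds <- sqrt((1.3 * lv$sds)^2 + (0.12 * abs(lv$means))^2 + 0.05^2)
  exp_nt <- c(config$adapter_nt, config$rta_nt,
              sum(config$tail_population$length_nt *
                    config$tail_population$weight) + 1,
              config$transcript_len_nt)
  self_p <- 1 - 1 / pmax(exp_nt * config$translocation_rate_mean, 2)
  hmm_params(lv$means, sds, self_p, min_duration)
}

new_boundaries <- function(read_id, method, detected, polya_start = NA_integer_,
                           polya_end = NA_integer_, score = NA_real_,
                           starts = NULL, n = NA_integer_) {
  structure(list(read_id = read_id, method = method, detected = detected,
                 polya_start = polya_start, polya_end = polya_end,
                 score = score, starts = starts, n = n),
            class = "polya_boundaries")
}

#' @export
print.polya_boundaries <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<polya_boundaries> %s [%s]: poly(A) at [%d, %d) of %d samples\n",
                x$read_id, x$method, x$polya_start, x$polya_end, x$n))
  else
    cat(sprintf("<polya_boundaries> %s [%s]: not detected\n", x$read_id,
                x$method))
  invisible(x)
}

#' Segment a read with the linear-chain HMM (Viterbi decoding)
#'
#' Finds the maximum-probability four-region state path; the poly(A)
#' boundaries are the third state's span. Ties are broken toward the
#' earlier region switch.
#'
#' @param squiggle a [squiggle()].
#' @param params an [hmm_params()].
#' @param standardize standardize the signal by median/MAD first (the
#'   default); pass `FALSE` when `params` are given in raw signal units.
#' @return a `polya_boundaries` with the decoded region `starts` (0-based)
#'   and the path log-probability as `score`.
#' @export
hmm_segment <- function(squiggle, params, standardize = TRUE) {
  x <- squiggle$samples
  if (standardize) x <- standardize_signal(x)
  if (length(x) < sum(params$min_duration)) stop("signal too short")
  v <- .viterbi_polya(x, params$means, params$sds, params$self_trans,
                      params$min_duration)
  new_boundaries(squiggle$read_id, "hmm", TRUE,
                 polya_start = v$starts[3], polya_end = v$starts[4],
                 score = v$log_prob, starts = v$starts, n = length(x))
}

#' Exhaustive maximum-likelihood segmentation (test oracle)
#'
#' Enumerates every valid boundary triple (subject to the minimum state
#' durations) and returns the highest-scoring four-region tiling under the
#' same path-probability objective as [hmm_segment()]. Quadratic-cubic in
#' read length, so it refuses reads longer than `max_len`; it exists to
#' certify the Viterbi decoder on small reads, not for production use.
#' Ties go to the lexicographically earliest boundary triple.
#'
#' @inheritParams hmm_segment
#' @param max_len refusal bound on read length in samples.
#' @return a `polya_boundaries` (method `"oracle"`).
#' @export
oracle_segment <- function(squiggle, params, standardize = TRUE,
                           max_len = 300L) {
  x <- squiggle$samples
  if (length(x) > max_len)
    stop("read too long for the exhaustive oracle (", length(x), " > ",
         max_len, " samples)")
  if (standardize) x <- standardize_signal(x)
  T_ <- length(x)
  m <- params$min_duration
  if (T_ < sum(m)) stop("signal too short")
  ll <- vapply(1:4, function(i)
    c(0, cumsum(dnorm(x, params$means[i], params$sds[i], log = TRUE))),
    numeric(T_ + 1))
  lp <- log(params$self_trans); lq <- log1p(-params$self_trans)

  score_triple <- function(b1, b2, b3) {
    ll[b1 + 1, 1] + (ll[b2 + 1, 2] - ll[b1 + 1, 2]) +
      (ll[b3 + 1, 3] - ll[b2 + 1, 3]) + (ll[T_ + 1, 4] - ll[b3 + 1, 4]) +
      (b1 - m[1]) * lp[1] + lq[1] +
      (b2 - b1 - m[2]) * lp[2] + lq[2] +
      (b3 - b2 - m[3]) * lp[3] + lq[3]
  }

  best <- -Inf; best_b <- c(NA, NA, NA)
  for (b1 in m[1]:(T_ - m[2] - m[3] - m[4])) {
    b2s <- (b1 + m[2]):(T_ - m[3] - m[4])
    for (b2 in b2s) {
      b3s <- (b2 + m[3]):(T_ - m[4])
      v <- score_triple(b1, b2, b3s)
      j <- which.max(v)              # first max: earliest b3 wins ties
      if (v[j] > best) { best <- v[j]; best_b <- c(b1, b2, b3s[j]) }
    }
  }
  new_boundaries(squiggle$read_id, "oracle", TRUE,
                 polya_start = best_b[2], polya_end = best_b[3],
                 score = best, starts = c(0L, best_b), n = T_)
}
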