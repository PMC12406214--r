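#' Parameters of the two-pass sliding-window segmenter
#'
#' Pass 1 thresholds a smoothed signal inside a level band around the
#' poly(A) level and takes the longest surviving run as the rough region.
#' Pass 2 clips the rough region (plus one smoothing window on each side),
#' averages consecutive `bin`-sample bins, and shrinks the boundaries from
#' both ends until the bin-to-bin slope magnitude falls under `slope_limit`.
#'
#' @param polya_level expected poly(A) signal level (standardized units).
#' @param band half-width of the pass-1 level band.
#' @param smooth smoothing window in samples (running mean).
#' @param bin pass-2 bin size in samples (default 25).
#' @param slope_limit maximum bin-to-bin slope magnitude inside the tail.
#' @param min_run minimum pass-1 run length in samples to count as a
#'   candidate region.
#' @return an object of class `window_params`.
#' @export
window_params <- function(polya_level, band = 0.5, smooth = 51L, bin = 25L,
                          slope_limit = 0.15, min_run = 50L) {
  if (bin < 1) stop("invalid `bin`: must be >= 1")
  if (smooth < 1) stop("invalid `smooth`: must be >= 1")
  structure(list(polya_level = polya_level, band = band,
                 smooth = as.integer(smooth), bin = as.integer(bin),
                 slope_limit = slope_limit, min_run = as.integer(min_run)),
            class = "window_params")
}

#' @rdname window_params
#' @param config a [sim_config()] from which to derive the standardized
#'   poly(A) level.
#' @param ... overrides forwarded to `window_params()`.
#' @export
window_params_for <- function(config, ...) {
  lv <- std_levels(config)
  band <- min(max(lv$polya_halfgap, 0.15), 0.8)
  slope <- max(0.04, min(1.5 * lv$sds[3], 0.6 * band))
  args <- list(polya_level = lv$means[3], band = band, slope_limit = slope)
  over <- list(...)
  args[names(over)] <- over
  do.call(window_params, args)
}

running_mean <- function(x, w) {
  if (w <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

longest_true_run <- function(b) {
  r <- rle(b)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  i <- which(r$values)
  j <- i[which.max(r$lengths[i])]
  c(start = ends[j] - r$lengths[j] + 1L, end = ends[j])  # 1-based inclusive
}

#' Segment a read with the two-pass sliding-window method
#'
#' An undetected tail is a status (`detected = FALSE`), not an error.
#' Boundary quantization is one pass-2 bin (default 25 samples).
#'
#' @inheritParams hmm_segment
#' @param params a [window_params()].
#' @return a `polya_boundaries` (method `"window"`).
#' @export
window_segment <- function(squiggle, params, standardize = TRUE) {
  x <- squiggle$samples
  if (length(x) == 0) stop("signal too short")
  if (standardize) x <- standardize_signal(x)
  n <- length(x)
  sm <- running_mean(x, params$smooth)
  in_band <- !is.na(sm) & abs(sm - params$polya_level) <= params$band
  run <- longest_true_run(in_band)
  if (is.null(run) || (run["end"] - run["start"] + 1L) < params$min_run)
    return(new_boundaries(squiggle$read_id, "window", FALSE, n = n))

  # pass 2: clip rough region +/- one smoothing window, bin, shrink
  clip_lo <- max(1L, run[["start"]] - params$smooth)
  clip_hi <- min(n, run[["end"]] + params$smooth)
  nb <- (clip_hi - clip_lo + 1L) %/% params$bin
  if (nb < 1)
    return(new_boundaries(squiggle$read_id, "window", FALSE, n = n))
  idx <- clip_lo + seq_len(nb * params$bin) - 1L
  bm <- colMeans(matrix(x[idx], nrow = params$bin))
  lo <- 1L; hi <- nb
  while (lo < hi && abs(bm[lo + 1L] - bm[lo]) > params$slope_limit)
    lo <- lo + 1L
  while (hi > lo && abs(bm[hi] - bm[hi - 1L]) > params$slope_limit)
    hi <- hi - 1L
  # surviving edge bins must still sit in the level band
  while (lo <= hi && abs(bm[lo] - params$polya_level) > params$band)
    lo <- lo + 1L
  while (hi >= lo && abs(bm[hi] - params$polya_level) > params$band)
    hi <- hi - 1L
  if (hi < lo)
    return(new_boundaries(squiggle$read_id, "window", FALSE, n = n))
  start0 <- (clip_lo - 1L) + (lo - 1L) * params$bin   # 0-based half-open
  end0 <- (clip_lo - 1L) + hi * params$bin
  new_boundaries(squiggle$read_id, "window", TRUE, polya_start = start0,
                 polya_end = end0, score = NA_real_, n = n)
}
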