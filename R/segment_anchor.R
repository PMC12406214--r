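#' Parameters of the anchor-and-grow segmenter
#'
#' The adapter is modeled as the initial high-level segment; the anchor is
#' the first position where a trailing window's mean falls inside the
#' poly(A) level band with variance at or below `var_ceiling` (windows
#' straddling region switches have inflated variance and are rejected, so
#' the anchor lands at the start of the low-variance poly(A) stretch). The
#' region is then grown sample-by-sample while each next sample stays
#' within `mean_tol` of the running region mean, and refined backwards the
#' same way. Regions shorter than `min_len` are discarded
#' (`detected = FALSE`), which makes this the conservative method of the
#' three: short tails that the HMM still calls are dropped here.
#'
#' @param polya_level expected poly(A) level (standardized units).
#' @param band half-width of the anchor level band.
#' @param window trailing-window width in samples (> 0).
#' @param var_ceiling maximum trailing-window variance at the anchor (> 0).
#' @param mean_tol growth tolerance around the running region mean.
#' @param min_len minimum accepted region length in samples.
#' @return an object of class `anchor_params`.
#' @export
anchor_params <- function(polya_level, band = 0.6, window = 40L,
                          var_ceiling = 0.15, mean_tol = 0.75,
                          min_len = 300L) {
  if (window <= 0) stop("invalid `window`: must be > 0")
  if (var_ceiling <= 0) stop("invalid `var_ceiling`: must be > 0")
  structure(list(polya_level = polya_level, band = band,
                 window = as.integer(window), var_ceiling = var_ceiling,
                 mean_tol = mean_tol, min_len = as.integer(min_len)),
            class = "anchor_params")
}

#' @rdname anchor_params
#' @param config a [sim_config()]; the level comes from the emission model
#'   and the window/minimum length scale with the translocation rate
#'   (window ~ 1 nt of dwell, minimum length ~ 5 nt of tail).
#' @param ... overrides forwarded to `anchor_params()`.
#' @export
anchor_params_for <- function(config, ...) {
  lv <- std_levels(config)
  r <- config$translocation_rate_mean
  band <- min(max(lv$polya_halfgap, 0.15), 0.8)
  args <- list(polya_level = lv$means[3], band = band,
               window = max(20L, as.integer(round(r))),
               var_ceiling = max(0.01, (2.5 * max(lv$sds[3], 0.03))^2),
               mean_tol = min(max(4 * lv$sds[3], 0.25), 1.2 * band),
               min_len = max(50L, as.integer(round(5 * r))))
  over <- list(...)
  args[names(over)] <- over
  do.call(anchor_params, args)
}

#' Segment a read by anchoring on the adapter end and growing
#'
#' @inheritParams hmm_segment
#' @param params an [anchor_params()].
#' @return a `polya_boundaries` (method `"anchor"`).
#' @export
anchor_segment <- function(squiggle, params, standardize = TRUE) {
  x <- squiggle$samples
  if (length(x) == 0) stop("signal too short")
  if (standardize) x <- standardize_signal(x)
  n <- length(x)
  w <- params$window
  if (n < w) return(new_boundaries(squiggle$read_id, "anchor", FALSE, n = n))

  cs <- cumsum(x); cs2 <- cumsum(x * x)
  rmean <- (cs[w:n] - c(0, cs)[ (w:n) - w + 1L]) / w
  rvar <- pmax(0, (cs2[w:n] - c(0, cs2)[(w:n) - w + 1L]) / w - rmean^2)
  ok <- abs(rmean - params$polya_level) <= params$band & rvar <= params$var_ceiling
  if (!any(ok)) return(new_boundaries(squiggle$read_id, "anchor", FALSE, n = n))
  i <- (w:n)[which(ok)[1]]          # 1-based last index of the anchor window
  start <- i - w + 1L

  # fixed reference level: the anchor window is pure poly(A), and a frozen
  # reference keeps isolated transcript levels from dragging the region mean
  ref <- (cs[i] - c(0, cs)[start]) / w
  # a single outlying sample must not truncate the region: stop only when a
  # true level change is confirmed by 3 of the next 5 samples deviating
  confirmed <- function(j, step) {
    idx <- seq(j, by = step, length.out = 5L)
    idx <- idx[idx >= 1L & idx <= n]
    sum(abs(x[idx] - ref) > params$mean_tol) >= 3L
  }
  # refine start backwards against the reference level
  while (start > 1L) {
    if (abs(x[start - 1L] - ref) > params$mean_tol &&
        confirmed(start - 1L, -1L)) break
    start <- start - 1L
  }
  # grow the end forward
  e <- i
  while (e < n) {
    if (abs(x[e + 1L] - ref) > params$mean_tol &&
        confirmed(e + 1L, 1L)) break
    e <- e + 1L
  }
  span <- e - start + 1L
  if (span < params$min_len)
    return(new_boundaries(squiggle$read_id, "anchor", FALSE, n = n))
  new_boundaries(squiggle$read_id, "anchor", TRUE, polya_start = start - 1L,
                 polya_end = e, score = NA_real_, n = n)
}
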