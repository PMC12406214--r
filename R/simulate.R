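#' Construct a squiggle (raw-signal read)
#'
#' @param read_id opaque read identifier.
#' @param samples numeric vector of current values (arbitrary units).
#' @param sampling_rate samples per second.
#' @param channel flow-cell channel number.
#' @param start_time acquisition start time in seconds.
#' @return an object of class `squiggle`.
#' @export
squiggle <- function(read_id, samples, sampling_rate, channel = 1L,
                     start_time = 0) {
  if (length(samples) == 0) stop("invalid `samples`: must be nonempty")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("invalid `sampling_rate`: must be > 0")
  structure(list(read_id = as.character(read_id),
                 samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 channel = as.integer(channel),
                 start_time = as.numeric(start_time)),
            class = "squiggle")
}

#' @export
print.squiggle <- function(x, ...) {
  cat(sprintf("<squiggle> %s: %d samples @ %g Hz (channel %d, t0 = %.2f s)\n",
              x$read_id, length(x$samples), x$sampling_rate, x$channel,
              x$start_time))
  invisible(x)
}

#' Duration of a squiggle in seconds
#' @param x a `squiggle`.
#' @return numeric seconds.
#' @export
squiggle_duration <- function(x) length(x$samples) / x$sampling_rate

new_annotation <- function(read_id, breaks, true_tail_nt, rate,
                           artifact_labels = character()) {
  # breaks: 0-based region starts c(adapter, rta, polya, transcript) plus
  # total length as 5th element; regions are half-open and tile the read
  structure(list(read_id = read_id,
                 adapter = c(breaks[1], breaks[2]),
                 rta = c(breaks[2], breaks[3]),
                 polya = c(breaks[3], breaks[4]),
                 transcript = c(breaks[4], breaks[5]),
                 true_tail_nt = true_tail_nt,
                 rate = rate,
                 artifact_labels = artifact_labels),
            class = "segment_annotation")
}

#' @export
print.segment_annotation <- function(x, ...) {
  cat(sprintf("<segment_annotation> %s: tail %.1f nt @ %.1f samples/nt%s\n",
              x$read_id, x$true_tail_nt, x$rate,
              if (length(x$artifact_labels))
                paste0(" [", paste(x$artifact_labels, collapse = ","), "]")
              else ""))
  for (r in c("adapter", "rta", "polya", "transcript"))
    cat(sprintf("  %-10s [%d, %d)\n", r, x[[r]][1], x[[r]][2]))
  invisible(x)
}

#' Simulate reference transcripts with a planted internal A-rich site
#'
#' Each reference gets one internal decamer with a 5-adenine run and 80%
#' adenine content at a recorded distance from the 3' end; misprimed reads
#' terminate there, so the mispriming screen has a true positive signal to
#' find. Consumes the current RNG stream.
#'
#' @param config a [sim_config()].
#' @return list with `sequences` (a [Biostrings::DNAStringSet]) and
#'   `misprime_sites` (data frame `ref_id`, `offset_nt` giving the planted
#'   site's distance from the 3' end).
#' @export
sim_references <- function(config) {
  L <- as.integer(config$transcript_len_nt)
  n <- as.integer(config$n_refs)
  site <- "AAAAACAAAT"  # run 5, A-fraction 0.8: passes both screen rules
  seqs <- character(n)
  offs <- integer(n)
  for (i in seq_len(n)) {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(0.22, 0.28, 0.28, 0.22))
    # site offset from the 3' end: internal (>= 10 nt in, so the decamer
    # fits before the reference end) but not right at the 5' end either
    lo <- min(max(10L, ceiling(L * 0.2)), L - 10L)
    hi <- max(lo, min(floor(L * 0.7), L - 10L))
    d <- if (hi > lo) sample(lo:hi, 1L) else lo
    pos <- L - d + 1L            # 1-based start of the downstream decamer
    s[pos:(pos + 9L)] <- strsplit(site, "")[[1]]
    seqs[i] <- paste(s, collapse = "")
    offs[i] <- d
  }
  ids <- sprintf("ref_%02d", seq_len(n))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  list(sequences = dss,
       misprime_sites = data.frame(ref_id = ids, offset_nt = offs,
                                   stringsAsFactors = FALSE))
}

# Draw one molecule (no split): squiggle pieces + annotation + stub fields.
# Uses the current RNG stream.
simulate_molecule <- function(config, refs, read_id) {
  rate <- max(1, rnorm(1, config$translocation_rate_mean,
                       config$translocation_rate_sd))
  pop <- config$tail_population
  tail_nt <- pop$length_nt[sample.int(nrow(pop), 1L, prob = pop$weight)]
  iref <- sample.int(length(refs$sequences), 1L)
  ref_id <- names(refs$sequences)[iref]
  L <- Biostrings::width(refs$sequences)[iref]

  labels <- character()
  offset <- 0L
  transcript_nt <- L
  if (runif(1) < config$mispriming_prob) {
    labels <- "misprimed"
    offset <- refs$misprime_sites$offset_nt[iref]
    transcript_nt <- L - offset
    tail_nt <- sample(0:10, 1L)  # apparent tail = internal As under the poly(T)
  } else if (runif(1) < config$fragmentation_prob) {
    labels <- "fragmented"
    offset <- min(L - 20L, 21L + rgeom(1, 1 / 80))
    transcript_nt <- L - offset
    tail_nt <- 0
  } else if (runif(1) < config$degradation_prob) {
    labels <- "degraded"
    delta <- 1L + rgeom(1, 1 / config$degradation_scale)
    tail_nt <- max(0, tail_nt - delta)
  }

  n_adapter <- round(config$adapter_nt * rate)
  n_rta <- round(config$rta_nt * rate)
  n_polya <- round(tail_nt * rate)
  n_transcript <- max(1L, round(transcript_nt * rate))

  x_adapter <- rnorm(n_adapter, config$adapter_mean, config$adapter_sd)
  x_rta <- rnorm(n_rta, config$rta_mean, config$rta_sd)
  x_polya <- if (n_polya > 0)
    rnorm(n_polya, config$polya_mean, config$polya_sd) else numeric()
  # transcript: one level per nucleotide; per-nt dwell times partition the
  # span exactly (cumulative rounding, so sum(dwell) == n_transcript)
  dwell <- diff(round((0:transcript_nt) * (n_transcript / transcript_nt)))
  levels <- rnorm(transcript_nt, config$transcript_mean,
                  config$transcript_between_sd)
  x_transcript <- rep(levels, times = dwell) +
    rnorm(n_transcript, 0, config$transcript_within_sd)

  samples <- c(x_adapter, x_rta, x_polya, x_transcript)
  breaks <- cumsum(c(0L, n_adapter, n_rta, n_polya, n_transcript))
  list(read_id = read_id, samples = samples, breaks = breaks,
       tail_nt = tail_nt, rate = rate, labels = labels,
       ref_id = ref_id, offset = offset, transcript_nt = transcript_nt,
       qscore = rnorm(1, config$qscore_mean, config$qscore_sd))
}

stub_row <- function(read_id, ref_id, offset, qscore) {
  data.frame(read_id = read_id, ref_id = ref_id,
             ref_end_offset_nt = as.numeric(offset),
             mean_qscore = qscore, stringsAsFactors = FALSE)
}

#' Simulate a single read
#'
#' Draws one molecule from the configured generative model (using the
#' current RNG stream) and returns its squiggle, ground-truth segment
#' annotation, and an alignment stub standing in for a mapper: the stub's
#' `ref_end_offset_nt` is positive exactly when the molecule was fragmented
#' or misprimed. Split-read glitches are an acquisition-level artifact of
#' consecutive reads and only arise from [simulate_dataset()].
#'
#' @param config a [sim_config()].
#' @param references optional result of [sim_references()]; generated on the
#'   fly (consuming RNG draws) when omitted.
#' @param read_id identifier for the read.
#' @param channel,start_time acquisition metadata; drawn randomly if `NULL`.
#' @return list with elements `squiggle`, `annotation`, `stub`.
#' @export
simulate_read <- function(config, references = NULL, read_id = "read_000001",
                          channel = NULL, start_time = NULL) {
  validate_sim_config(config)
  refs <- references %||% sim_references(config)
  m <- simulate_molecule(config, refs, read_id)
  ch <- channel %||% sample.int(config$n_channels, 1L)
  t0 <- start_time %||% runif(1, 0, config$run_duration_s)
  list(squiggle = squiggle(read_id, m$samples, config$sampling_rate, ch, t0),
       annotation = new_annotation(read_id, m$breaks, m$tail_nt, m$rate,
                                   m$labels),
       stub = stub_row(read_id, m$ref_id, m$offset, m$qscore))
}

#' Simulate a dataset of reads with ground truth
#'
#' Generates `n_reads` molecules under `config`. A molecule hit by a
#' split-read glitch is emitted as two consecutive reads on the same
#' channel (suffixes `_p1`/`_p2`, labels `split_first`/`split_second`)
#' whose sample counts sum to the unsplit molecule's; the split point falls
#' inside the transcript region, so the first part keeps the tail and the
#' second is a tail-less 5' fragment. Identical seeds give bit-identical
#' output.
#'
#' @param config a [sim_config()].
#' @param n_reads number of molecules to draw (>= 0).
#' @param seed integer seed controlling all randomness.
#' @return an object of class `sim_dataset`: list with `reads` (named list
#'   of `squiggle`), `annotations` (named list of `segment_annotation`),
#'   `truth` (data frame: read_id, true_tail_nt, rate, artifact_labels,
#'   ref_id, ref_end_offset_nt, mean_qscore), `references`,
#'   `misprime_sites`, `config`, `seed`.
#' @export
simulate_dataset <- function(config, n_reads, seed = 1L) {
  validate_sim_config(config)
  if (!is.numeric(n_reads) || length(n_reads) != 1 || n_reads < 0)
    stop("invalid `n_reads`: must be >= 0")
  n_reads <- as.integer(n_reads)
  set.seed(as.integer(seed))
  refs <- sim_references(config)

  reads <- list(); anns <- list(); truth_rows <- list()
  emit <- function(sq, ann, stub) {
    reads[[sq$read_id]] <<- sq
    anns[[ann$read_id]] <<- ann
    truth_rows[[ann$read_id]] <<- data.frame(
      read_id = ann$read_id, true_tail_nt = ann$true_tail_nt,
      rate = ann$rate,
      artifact_labels = paste(ann$artifact_labels, collapse = ","),
      ref_id = stub$ref_id, ref_end_offset_nt = stub$ref_end_offset_nt,
      mean_qscore = stub$mean_qscore, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_reads)) {
    base_id <- sprintf("m%06d", i)
    m <- simulate_molecule(config, refs, base_id)
    ch <- sample.int(config$n_channels, 1L)
    t0 <- runif(1, 0, config$run_duration_s)
    n_total <- length(m$samples)
    tr_start <- m$breaks[4]
    do_split <- runif(1) < config$split_prob && (n_total - tr_start) >= 2
    if (!do_split) {
      emit(squiggle(base_id, m$samples, config$sampling_rate, ch, t0),
           new_annotation(base_id, m$breaks, m$tail_nt, m$rate, m$labels),
           stub_row(base_id, m$ref_id, m$offset, m$qscore))
    } else {
      # split point strictly inside the transcript region
      k <- sample((tr_start + 1L):(n_total - 1L), 1L)
      id1 <- paste0(base_id, "_p1"); id2 <- paste0(base_id, "_p2")
      b1 <- c(m$breaks[1:4], k)
      b2 <- c(0L, 0L, 0L, 0L, n_total - k)
      nt_in_first <- round((k - tr_start) / m$rate)
      t1 <- t0
      t2 <- t0 + k / config$sampling_rate + config$split_gap_s
      emit(squiggle(id1, m$samples[seq_len(k)], config$sampling_rate, ch, t1),
           new_annotation(id1, b1, m$tail_nt, m$rate,
                          c(m$labels, "split_first")),
           stub_row(id1, m$ref_id, m$offset, m$qscore))
      emit(squiggle(id2, m$samples[(k + 1L):n_total], config$sampling_rate,
                    ch, t2),
           new_annotation(id2, b2, 0, m$rate, c(m$labels, "split_second")),
           stub_row(id2, m$ref_id, m$offset + nt_in_first, m$qscore))
    }
  }

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(read_id = character(), true_tail_nt = numeric(),
               rate = numeric(), artifact_labels = character(),
               ref_id = character(), ref_end_offset_nt = numeric(),
               mean_qscore = numeric(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  structure(list(reads = reads, annotations = anns, truth = truth,
                 references = refs$sequences,
                 misprime_sites = refs$misprime_sites,
                 config = config, seed = as.integer(seed)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d reads (seed %d)\n", length(x$reads), x$seed))
  if (nrow(x$truth)) {
    lab <- x$truth$artifact_labels
    cat(sprintf("  artifact reads: %d degraded, %d fragmented, %d misprimed, %d split parts\n",
                sum(grepl("degraded", lab)), sum(grepl("fragmented", lab)),
                sum(grepl("misprimed", lab)), sum(grepl("split", lab))))
  }
  invisible(x)
}

#' Per-read acquisition metadata table
#'
#' @param dataset a `sim_dataset`, or a list of `squiggle` objects.
#' @return data frame: read_id, channel, start_time, duration, sampling_rate.
#' @export
signal_metadata <- function(dataset) {
  reads <- if (inherits(dataset, "sim_dataset")) dataset$reads else dataset
  if (length(reads) == 0)
    return(data.frame(read_id = character(), channel = integer(),
                      start_time = numeric(), duration = numeric(),
                      sampling_rate = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(unname(reads), function(s) data.frame(
    read_id = s$read_id, channel = s$channel, start_time = s$start_time,
    duration = squiggle_duration(s), sampling_rate = s$sampling_rate,
    stringsAsFactors = FALSE)))
}
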