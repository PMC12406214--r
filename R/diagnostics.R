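#' Classify a read's 3' end as full length or truncated
#'
#' A read whose mapped 3' end lies within `threshold_nt` (inclusive) of the
#' reference transcript's 3' end is degradation-consistent
#' (`"full_length"`); farther ends are `"truncated"`.
#'
#' @param ref_end_offset_nt distance(s) from the mapped 3' end to the
#'   reference 3' end in nt (>= 0); an alignment-stub data frame with this
#'   column is also accepted.
#' @param threshold_nt inclusive full-length threshold (default 20 nt).
#' @return character vector of `"full_length"` / `"truncated"`.
#' @export
classify_end <- function(ref_end_offset_nt, threshold_nt = 20) {
  if (is.data.frame(ref_end_offset_nt))
    ref_end_offset_nt <- ref_end_offset_nt$ref_end_offset_nt
  if (any(ref_end_offset_nt < 0, na.rm = TRUE))
    stop("invalid `ref_end_offset_nt`: must be >= 0")
  ifelse(ref_end_offset_nt <= threshold_nt, "full_length", "truncated")
}

#' Screen the sequence downstream of a mapped end for mispriming signal
#'
#' Examines the 10 nt immediately 3' of the mapped end on the reference.
#' The read is flagged as potentially misprimed when the longest adenine
#' run reaches `run_threshold` or the adenine fraction exceeds
#' `content_threshold` (the poly(T) adapter could have annealed there).
#' When fewer than 10 nt remain before the reference end, the available
#' stretch is used and the shortfall recorded.
#'
#' @param reference_seq reference sequence (character or
#'   [Biostrings::DNAString]).
#' @param mapped_end_pos 0-based position of the first base downstream of
#'   the mapped end.
#' @param run_threshold minimum adenine run length that flags (default 4).
#' @param content_threshold adenine fraction above which the read flags
#'   (default 0.5; strict `>`).
#' @param window_nt downstream window, fixed at 10 nt to match the
#'   adapter's 10 poly(T) bases.
#' @return list with longest_a_run, a_fraction, mispriming_flag,
#'   downstream_seq, shortfall.
#' @export
mispriming_screen <- function(reference_seq, mapped_end_pos,
                              run_threshold = 4, content_threshold = 0.5,
                              window_nt = 10) {
  s <- toupper(as.character(reference_seq))
  L <- nchar(s)
  if (mapped_end_pos < 0 || mapped_end_pos > L)
    stop(sprintf("coordinate error: mapped_end_pos %d outside reference [0, %d]",
                 mapped_end_pos, L))
  down <- substr(s, mapped_end_pos + 1, min(L, mapped_end_pos + window_nt))
  avail <- nchar(down)
  if (avail == 0) {
    return(list(longest_a_run = 0L, a_fraction = NA_real_,
                mispriming_flag = FALSE, downstream_seq = "",
                shortfall = window_nt))
  }
  chars <- strsplit(down, "")[[1]]
  r <- rle(chars == "A")
  longest <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  frac <- sum(chars == "A") / avail
  list(longest_a_run = as.integer(longest), a_fraction = frac,
       mispriming_flag = longest >= run_threshold || frac > content_threshold,
       downstream_seq = down, shortfall = window_nt - avail)
}

#' Detect split-read pairs from acquisition metadata
#'
#' A sequencer glitch can write one molecule as two consecutive reads on
#' the same channel. Candidate pairs are consecutive same-channel reads
#' whose inter-read gap (next start minus current end) is at most
#' `max_gap_s`; pairing is greedy earliest-first and each read joins at
#' most one pair.
#'
#' @param metadata data frame with read_id, channel, start_time, duration.
#' @param max_gap_s maximum inter-read gap in seconds.
#' @return data frame: first_id, second_id, gap_s.
#' @export
find_split_pairs <- function(metadata, max_gap_s) {
  need <- c("read_id", "channel", "start_time", "duration")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  empty <- data.frame(first_id = character(), second_id = character(),
                      gap_s = numeric(), stringsAsFactors = FALSE)
  if (nrow(metadata) < 2) return(empty)
  o <- order(metadata$channel, metadata$start_time)
  md <- metadata[o, ]
  same <- md$channel[-1] == md$channel[-nrow(md)]
  gap <- md$start_time[-1] - (md$start_time[-nrow(md)] +
                                md$duration[-nrow(md)])
  cand <- which(same & gap <= max_gap_s)
  if (!length(cand)) return(empty)
  used <- logical(nrow(md))
  first <- character(); second <- character(); gaps <- numeric()
  for (i in cand) {   # cand is increasing: greedy earliest-first
    if (used[i] || used[i + 1]) next
    used[i] <- used[i + 1] <- TRUE
    first <- c(first, md$read_id[i])
    second <- c(second, md$read_id[i + 1])
    gaps <- c(gaps, gap[i])
  }
  data.frame(first_id = first, second_id = second, gap_s = gaps,
             stringsAsFactors = FALSE)
}

#' Synthetic acquisition metadata with a known number of split pairs
#'
#' Builds a flow-cell metadata table (round-robin channels, evenly spaced
#' reads) in which exactly `n_pairs` disjoint read pairs are adjacent
#' within `gap_s` seconds on their channel -- every other inter-read gap is
#' `spacing_s - duration_s`, far above any sensible pairing threshold. A
#' synthetic stand-in for a basecalling summary, used to exercise
#' [find_split_pairs()] at scale with known ground truth.
#'
#' @param n_reads total number of reads.
#' @param n_pairs number of engineered split pairs (needs one channel
#'   each).
#' @param gap_s intra-pair gap in seconds.
#' @param spacing_s start-to-start spacing of ordinary reads per channel.
#' @param duration_s read duration in seconds.
#' @param n_channels number of channels.
#' @return metadata data frame (read_id, channel, start_time, duration).
#' @export
synthetic_split_metadata <- function(n_reads, n_pairs, gap_s = 0.2,
                                     spacing_s = 30, duration_s = 10,
                                     n_channels = 512) {
  if (2 * n_pairs > n_reads) stop("need n_reads >= 2 * n_pairs")
  if (n_pairs > n_channels) stop("need one channel per engineered pair")
  ch <- rep(seq_len(n_channels), length.out = n_reads)
  start <- numeric(n_reads)
  idx_by_ch <- split(seq_len(n_reads), ch)
  for (ids in idx_by_ch) start[ids] <- (seq_along(ids) - 1) * spacing_s
  done <- 0L
  for (ids in idx_by_ch) {
    if (done >= n_pairs) break
    if (length(ids) < 2) next
    start[ids[2]] <- start[ids[1]] + duration_s + gap_s
    done <- done + 1L
  }
  data.frame(read_id = sprintf("r%06d", seq_len(n_reads)), channel = ch,
             start_time = start, duration = duration_s,
             stringsAsFactors = FALSE)
}

#' Spearman correlation between tail length and read quality
#'
#' @param tails per-read tail lengths in nt.
#' @param qscores paired mean quality scores.
#' @return list with rho, p_value, n, status (`"ok"` or
#'   `"not_applicable"` when ranks are degenerate).
#' @export
quality_length_correlation <- function(tails, qscores) {
  keep <- is.finite(tails) & is.finite(qscores)
  tails <- tails[keep]; qscores <- qscores[keep]
  n <- length(tails)
  if (n < 10) stop("insufficient reads: need >= 10 paired observations")
  if (length(unique(tails)) < 2 || length(unique(qscores)) < 2)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                status = "not_applicable"))
  ct <- suppressWarnings(cor.test(tails, qscores, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n, status = "ok")
}

#' Diagnose the origin of short tail calls
#'
#' Restricts to reads with `tail_nt < tail_cutoff` and classifies each:
#' degradation-consistent (3'-intact) versus truncated, with the
#' mispriming screen applied at the mapped end, optional split-pair
#' partners, and read quality. Summarizes the fractions the read set
#' splits into.
#'
#' @param estimates per-read estimates data frame (read_id, tail_nt,
#'   optionally qc -- non-`"pass"` rows are dropped).
#' @param stubs alignment-stub data frame (read_id, ref_id,
#'   ref_end_offset_nt, mean_qscore).
#' @param reference reference sequences: a [Biostrings::DNAStringSet] or a
#'   FASTA path.
#' @param tail_cutoff short-tail threshold in nt (default 10, strict `<`).
#' @param end_threshold_nt full-length threshold for [classify_end()].
#' @param run_threshold,content_threshold forwarded to
#'   [mispriming_screen()].
#' @param qscore_threshold quality threshold for the summary fraction.
#' @param split_pairs optional result of [find_split_pairs()].
#' @return list of class `short_tail_report` with `records` (one
#'   diagnostic row per short-tail read) and `summary` (fractions:
#'   full_length, truncated, truncated_misprimed, high_quality_unexplained;
#'   `status` is `"not_applicable"` for an empty short-tail set).
#' @export
short_tail_report <- function(estimates, stubs, reference, tail_cutoff = 10,
                              end_threshold_nt = 20, run_threshold = 4,
                              content_threshold = 0.5, qscore_threshold = 20,
                              split_pairs = NULL) {
  if (is.character(reference) && length(reference) == 1)
    reference <- Biostrings::readDNAStringSet(reference)
  if ("qc" %in% names(estimates))
    estimates <- estimates[estimates$qc == "pass", , drop = FALSE]
  df <- merge(estimates[, c("read_id", "tail_nt")], stubs, by = "read_id")
  df <- df[!is.na(df$tail_nt) & df$tail_nt < tail_cutoff, , drop = FALSE]

  empty_summary <- list(n_short = 0L, full_length = NA_real_,
                        truncated = NA_real_,
                        truncated_misprimed = NA_real_,
                        high_quality_unexplained = NA_real_,
                        status = "not_applicable")
  rec_cols <- c("read_id", "tail_nt", "end_class", "downstream_10mer",
                "longest_a_run", "a_fraction", "mispriming_flag",
                "split_partner", "mean_qscore")
  if (nrow(df) == 0) {
    records <- as.data.frame(setNames(rep(list(character(0)), length(rec_cols)),
                                      rec_cols), stringsAsFactors = FALSE)
    return(structure(list(records = records, summary = empty_summary),
                     class = "short_tail_report"))
  }

  ref_len <- setNames(Biostrings::width(reference), names(reference))
  partner_of <- character(0)
  if (!is.null(split_pairs) && nrow(split_pairs)) {
    partner_of <- setNames(c(split_pairs$second_id, split_pairs$first_id),
                           c(split_pairs$first_id, split_pairs$second_id))
  }

  rows <- vector("list", nrow(df))
  skipped <- character()
  for (i in seq_len(nrow(df))) {
    rid <- df$read_id[i]; ref_id <- df$ref_id[i]
    if (!ref_id %in% names(reference)) {
      skipped <- c(skipped, rid)
      next
    }
    L <- ref_len[[ref_id]]
    pos <- L - round(df$ref_end_offset_nt[i])
    scr <- mispriming_screen(reference[[ref_id]], pos, run_threshold,
                             content_threshold)
    rows[[i]] <- data.frame(
      read_id = rid, tail_nt = df$tail_nt[i],
      end_class = classify_end(df$ref_end_offset_nt[i], end_threshold_nt),
      downstream_10mer = scr$downstream_seq,
      longest_a_run = scr$longest_a_run, a_fraction = scr$a_fraction,
      mispriming_flag = scr$mispriming_flag,
      split_partner = if (rid %in% names(partner_of)) partner_of[[rid]]
                      else NA_character_,
      mean_qscore = df$mean_qscore[i], stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped ", length(skipped),
            " read(s) with missing reference sequence: ",
            paste(head(skipped, 5), collapse = ", "))
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(records) || nrow(records) == 0)
    return(structure(list(records = NULL, summary = empty_summary),
                     class = "short_tail_report"))
  rownames(records) <- NULL

  trunc <- records$end_class == "truncated"
  unexplained <- trunc & !records$mispriming_flag
  summary <- list(
    n_short = nrow(records),
    full_length = mean(!trunc),
    truncated = mean(trunc),
    truncated_misprimed = if (any(trunc)) mean(records$mispriming_flag[trunc])
                          else NA_real_,
    high_quality_unexplained = if (any(unexplained))
      mean(records$mean_qscore[unexplained] > qscore_threshold) else NA_real_,
    status = "ok")
  structure(list(records = records, summary = summary),
            class = "short_tail_report")
}

#' @export
print.short_tail_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<short_tail_report> %d short-tail reads\n", s$n_short))
  if (s$status == "ok") {
    cat(sprintf("  full length (degradation-consistent): %.1f%%\n",
                100 * s$full_length))
    cat(sprintf("  truncated: %.1f%% (of which misprime-flagged: %s)\n",
                100 * s$truncated,
                ifelse(is.na(s$truncated_misprimed), "-",
                       sprintf("%.1f%%", 100 * s$truncated_misprimed))))
    if (!is.na(s$high_quality_unexplained))
      cat(sprintf("  unexplained truncated reads with qscore > threshold: %.1f%%\n",
                  100 * s$high_quality_unexplained))
  } else cat("  (no short-tail reads)\n")
  invisible(x)
}
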