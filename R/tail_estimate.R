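#' Estimate the read-specific translocation rate
#'
#' The rate (samples per nucleotide) normalizes a tail's sample span into
#' nucleotides. In benchmark mode it comes from the transcript region's
#' sample count divided by the known transcript length.
#'
#' @param transcript_span transcript-region sample count (from a decoded
#'   four-region path, or ground truth).
#' @param transcript_len_nt known transcript length in nucleotides.
#' @return rate in samples/nt, or `NA_real_` ("rate unavailable") when the
#'   transcript region is empty or the length is not positive.
#' @export
estimate_rate <- function(transcript_span, transcript_len_nt) {
  if (!is.numeric(transcript_span) || !is.numeric(transcript_len_nt) ||
      is.na(transcript_span) || is.na(transcript_len_nt) ||
      transcript_span <= 0 || transcript_len_nt <= 0)
    return(NA_real_)
  transcript_span / transcript_len_nt
}

#' Convert poly(A) boundaries to a nucleotide tail length
#'
#' `tail_nt = (polya_end - polya_start) / rate`. The length is reported as a
#' float (not rounded) for downstream density estimation. QC status:
#' `"pass"` for a converted call, `"no_tail"` when boundaries were not
#' detected, `"rate_unavailable"` when no positive rate exists.
#'
#' @param boundaries a `polya_boundaries`.
#' @param rate samples per nucleotide (e.g. from [estimate_rate()]).
#' @return an object of class `tail_estimate`: list with read_id, method,
#'   qc, tail_nt, polya_start, polya_end, rate.
#' @export
estimate_tail <- function(boundaries, rate) {
  if (!isTRUE(boundaries$detected)) {
    return(structure(list(read_id = boundaries$read_id,
                          method = boundaries$method, qc = "no_tail",
                          tail_nt = NA_real_, polya_start = NA_integer_,
                          polya_end = NA_integer_, rate = NA_real_),
                     class = "tail_estimate"))
  }
  if (is.na(rate) || !is.numeric(rate) || rate <= 0) {
    return(structure(list(read_id = boundaries$read_id,
                          method = boundaries$method, qc = "rate_unavailable",
                          tail_nt = NA_real_,
                          polya_start = boundaries$polya_start,
                          polya_end = boundaries$polya_end, rate = NA_real_),
                     class = "tail_estimate"))
  }
  span <- boundaries$polya_end - boundaries$polya_start
  structure(list(read_id = boundaries$read_id, method = boundaries$method,
                 qc = "pass", tail_nt = span / rate,
                 polya_start = boundaries$polya_start,
                 polya_end = boundaries$polya_end, rate = rate),
            class = "tail_estimate")
}

#' @export
print.tail_estimate <- function(x, ...) {
  if (x$qc == "pass")
    cat(sprintf("<tail_estimate> %s [%s]: %.2f nt (span %d @ %.2f samples/nt)\n",
                x$read_id, x$method, x$tail_nt,
                x$polya_end - x$polya_start, x$rate))
  else
    cat(sprintf("<tail_estimate> %s [%s]: %s\n", x$read_id, x$method, x$qc))
  invisible(x)
}

estimate_to_row <- function(e) {
  data.frame(read_id = e$read_id, method = e$method, qc = e$qc,
             tail_nt = e$tail_nt,
             polya_start = as.numeric(e$polya_start),
             polya_end = as.numeric(e$polya_end), rate = e$rate,
             stringsAsFactors = FALSE)
}

#' Run segmentation and tail estimation over a simulated dataset
#'
#' Segments every read with the chosen method and converts spans to
#' nucleotides. The translocation rate comes either from the ground-truth
#' annotation (`rate_source = "annotation"`, the benchmark default) or, for
#' the HMM which decodes a full four-region path, from the transcript
#' region span and the known transcript length
#' (`rate_source = "transcript"`).
#'
#' @param dataset a `sim_dataset`.
#' @param method one of `"hmm"`, `"window"`, `"anchor"`.
#' @param params method parameters; derived from `dataset$config` when
#'   `NULL`.
#' @param rate_source `"annotation"` or `"transcript"` (HMM only).
#' @return a per-read estimates data frame (read_id, method, qc, tail_nt,
#'   polya_start, polya_end, rate).
#' @export
estimate_tails <- function(dataset, method = c("hmm", "window", "anchor"),
                           params = NULL,
                           rate_source = c("annotation", "transcript")) {
  method <- match.arg(method)
  rate_source <- match.arg(rate_source)
  cfg <- dataset$config
  if (is.null(params))
    params <- switch(method, hmm = hmm_params_for(cfg),
                     window = window_params_for(cfg),
                     anchor = anchor_params_for(cfg))
  truth <- dataset$truth
  ref_len <- stats::setNames(Biostrings::width(dataset$references),
                             names(dataset$references))
  rows <- vector("list", length(dataset$reads))
  for (k in seq_along(dataset$reads)) {
    sq <- dataset$reads[[k]]
    tr <- truth[truth$read_id == sq$read_id, , drop = FALSE]
    b <- switch(method,
      hmm = tryCatch(hmm_segment(sq, params),
                     error = function(e) new_boundaries(sq$read_id, "hmm",
                                                        FALSE,
                                                        n = length(sq$samples))),
      window = window_segment(sq, params),
      anchor = anchor_segment(sq, params))
    rate <- if (rate_source == "annotation" || method != "hmm" ||
                !isTRUE(b$detected)) {
      tr$rate[1]
    } else {
      tn <- ref_len[[tr$ref_id[1]]] - tr$ref_end_offset_nt[1]
      estimate_rate(b$n - b$starts[4], tn)
    }
    rows[[k]] <- estimate_to_row(estimate_tail(b, rate))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    empty_estimates_table()
  rownames(out) <- NULL
  out
}

empty_estimates_table <- function() {
  data.frame(read_id = character(), method = character(), qc = character(),
             tail_nt = numeric(), polya_start = numeric(),
             polya_end = numeric(), rate = numeric(),
             stringsAsFactors = FALSE)
}
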