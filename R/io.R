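# Tabular exchange is TSV with fixed headers; floats are written with 17
# significant digits so write-then-read is the identity on all fields.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_precise <- function(df, path, numeric_cols) {
  out <- df
  for (cc in intersect(numeric_cols, names(out))) out[[cc]] <- fmt_num(out[[cc]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

read_tsv_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  miss <- setdiff(required, header)
  if (length(miss))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  bad <- which(nf != length(header))
  if (length(bad))
    stop("malformed row at line ", bad[1], " of ", basename(path),
         ": expected ", length(header), " fields, found ", nf[bad[1]])
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  for (cc in intersect(numeric_cols, names(df)))
    df[[cc]] <- as.numeric(df[[cc]])
  df
}

estimates_schema <- c("read_id", "method", "qc", "tail_nt", "polya_start",
                      "polya_end", "rate")
truth_schema <- c("read_id", "true_tail_nt", "rate", "artifact_labels",
                  "ref_id", "ref_end_offset_nt", "mean_qscore")
boundaries_schema <- c("read_id", "method", "detected", "polya_start",
                       "polya_end", "score")

#' Read and write per-read estimate tables
#'
#' TSV with header `read_id, method, qc, tail_nt, polya_start, polya_end,
#' rate`; third-party tool outputs mapped onto these columns can be
#' ingested the same way. Floats round-trip at full precision.
#'
#' @param estimates estimates data frame.
#' @param path file path.
#' @return `read_estimates()` returns the data frame; writers return the
#'   path invisibly.
#' @export
write_estimates <- function(estimates, path) {
  write_tsv_precise(estimates[, estimates_schema, drop = FALSE], path,
                    c("tail_nt", "polya_start", "polya_end", "rate"))
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  read_tsv_checked(path, estimates_schema,
                   c("tail_nt", "polya_start", "polya_end", "rate"))
}

#' Read and write ground-truth tables
#'
#' TSV with header `read_id, true_tail_nt, rate, artifact_labels, ref_id,
#' ref_end_offset_nt, mean_qscore`.
#'
#' @param truth ground-truth data frame.
#' @param path file path.
#' @return `read_truth()` returns the data frame; writers return the path
#'   invisibly.
#' @export
write_truth <- function(truth, path) {
  write_tsv_precise(truth[, truth_schema, drop = FALSE], path,
                    c("true_tail_nt", "rate", "ref_end_offset_nt",
                      "mean_qscore"))
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read_tsv_checked(path, truth_schema,
                   c("true_tail_nt", "rate", "ref_end_offset_nt",
                     "mean_qscore"))
}

#' Write segmentation boundaries to TSV
#'
#' @param boundaries list of `polya_boundaries` (or a data frame already in
#'   schema).
#' @param path file path.
#' @return the path, invisibly; `read_boundaries()` returns the data frame.
#' @export
write_boundaries <- function(boundaries, path) {
  df <- if (is.data.frame(boundaries)) boundaries else
    do.call(rbind, lapply(boundaries, function(b) data.frame(
      read_id = b$read_id, method = b$method, detected = b$detected,
      polya_start = as.numeric(b$polya_start),
      polya_end = as.numeric(b$polya_end), score = b$score,
      stringsAsFactors = FALSE)))
  write_tsv_precise(df[, boundaries_schema, drop = FALSE], path,
                    c("polya_start", "polya_end", "score"))
}

#' @rdname write_boundaries
#' @export
read_boundaries <- function(path) {
  df <- read_tsv_checked(path, boundaries_schema,
                         c("polya_start", "polya_end", "score"))
  df$detected <- as.logical(df$detected)
  df
}

#' Read and write the dataset signal container
#'
#' One self-describing text file per dataset: a magic first line, a header
#' line, then one row per read carrying the squiggle metadata and the raw
#' samples as a comma-joined field. Samples round-trip bit-exactly (17
#' significant digits).
#'
#' @param reads a `sim_dataset` or list of `squiggle` objects.
#' @param path file path.
#' @return `read_signals()` returns a named list of `squiggle`; the writer
#'   returns the path invisibly.
#' @export
write_signals <- function(reads, path) {
  if (inherits(reads, "sim_dataset")) reads <- reads$reads
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#tailbench-signal-container\tv1",
               "read_id\tchannel\tstart_time\tsampling_rate\tn_samples\tsamples"),
             con)
  for (s in reads) {
    writeLines(paste(s$read_id, s$channel, fmt_num(s$start_time),
                     fmt_num(s$sampling_rate), length(s$samples),
                     paste(fmt_num(s$samples), collapse = ","),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "#tailbench-signal-container"))
    stop("schema error in ", basename(path),
         ": not a tailbench signal container")
  header <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  need <- c("read_id", "channel", "start_time", "sampling_rate", "n_samples",
            "samples")
  miss <- setdiff(need, header)
  if (length(miss))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  out <- list()
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop("malformed row at line ", k + 2, " of ", basename(path))
    v <- setNames(as.list(f), header)
    samples <- as.numeric(strsplit(v$samples, ",", fixed = TRUE)[[1]])
    if (length(samples) != as.integer(v$n_samples))
      stop("malformed row at line ", k + 2, " of ", basename(path),
           ": sample count mismatch")
    out[[v$read_id]] <- squiggle(v$read_id, samples,
                                 as.numeric(v$sampling_rate),
                                 as.integer(v$channel),
                                 as.numeric(v$start_time))
  }
  out
}

#' Write reference sequences to FASTA
#'
#' @param sequences a [Biostrings::DNAStringSet].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_references <- function(sequences, path) {
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}
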