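#' Dynamically trim reads to their longest passing segment
#'
#' Cuts each read down to its longest contiguous run of bases whose error
#' probability beats the threshold, trimming from either or both ends as
#' needed. Uses the same strict-inequality pass rule and leftmost tie-break
#' as [longest_passing_segment()], so the maximized-read-length histogram
#' exactly predicts trimmed lengths. Reads where no base passes become
#' zero-length reads.
#'
#' @param reads A `fastq_reads` data.frame (or any data.frame with `id`,
#'   `sequence`, `quality` columns).
#' @param threshold A [threshold_spec()].
#' @param encoding A [quality_encoding()]; taken from `reads` when present.
#' @return The trimmed data.frame, same columns and row count.
#' @export
dynamic_trim <- function(reads, threshold = threshold_spec(),
                         encoding = NULL) {
  threshold <- threshold_spec(threshold)
  enc <- attr(reads, "encoding")
  if (is.null(enc)) enc <- encoding
  if (is.null(enc)) stop("reads carry no encoding; supply `encoding`")
  enc <- quality_encoding(enc)
  seg <- .segment_table(reads$quality, enc, threshold)
  out <- reads
  out$sequence <- substr(reads$sequence, seg$start + 1L,
                         seg$start + seg$length)
  out$quality <- substr(reads$quality, seg$start + 1L,
                        seg$start + seg$length)
  attr(out, "encoding") <- enc
  out
}

#' Trim a FASTQ file (DynamicTrim)
#'
#' Streams a FASTQ file, trims every read to its longest passing segment,
#' and writes a standard FASTQ file in the input's encoding. Zero-length
#' reads are dropped by default (`keep_empty = TRUE` writes them as records
#' with empty sequence and quality lines).
#'
#' @param in_path Input FASTQ path.
#' @param out_path Output FASTQ path (default `<in_path>.trimmed.fastq`).
#' @param threshold A [threshold_spec()]; default p = 0.05.
#' @param encoding `"auto"` or a [quality_encoding()].
#' @param keep_empty Keep zero-length reads.
#' @param chunk_size Records per streamed chunk.
#' @return A list of class `trim_summary`: `reads_in`, `reads_out`,
#'   `bases_in`, `bases_out`, `mean_trimmed_length` (mean over all input
#'   reads, counting dropped reads as length 0 — the mean of the
#'   [length_histogram()] at the same threshold), `out_path`, `threshold`.
#' @export
trim_file <- function(in_path, out_path = paste0(in_path, ".trimmed.fastq"),
                      threshold = threshold_spec(), encoding = "auto",
                      keep_empty = FALSE, chunk_size = 5000L) {
  threshold <- threshold_spec(threshold)
  if (!file.exists(in_path)) stop("no such file: ", in_path)
  enc <- .detect_file_encoding(in_path, encoding)
  reads_in <- 0L; reads_out <- 0L
  bases_in <- 0; bases_out <- 0
  first <- TRUE
  fastq_apply(in_path, function(chunk, n_before) {
    trimmed <- dynamic_trim(`attr<-`(chunk, "encoding", enc), threshold)
    reads_in <<- reads_in + nrow(chunk)
    bases_in <<- bases_in + sum(nchar(chunk$sequence))
    if (!keep_empty)
      trimmed <- trimmed[nchar(trimmed$sequence) > 0L, , drop = FALSE]
    reads_out <<- reads_out + nrow(trimmed)
    bases_out <<- bases_out + sum(nchar(trimmed$sequence))
    write_fastq(trimmed, out_path, append = !first)
    first <<- FALSE
    NULL  # never request early stream termination
  }, chunk_size = chunk_size, parse_headers = FALSE)
  if (first) write_fastq(data.frame(), out_path)  # empty input -> empty file
  structure(list(reads_in = reads_in, reads_out = reads_out,
                 bases_in = bases_in, bases_out = bases_out,
                 mean_trimmed_length = if (reads_in > 0)
                   bases_out / reads_in else NA_real_,
                 out_path = out_path, encoding = enc, threshold = threshold),
            class = "trim_summary")
}

#' @export
print.trim_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<trim_summary> %d/%d reads kept; %s/%s bases kept; ",
           "mean trimmed length %.2f (threshold p < %.4g)\n"),
    x$reads_out, x$reads_in, format(x$bases_out, big.mark = ","),
    format(x$bases_in, big.mark = ","), x$mean_trimmed_length,
    x$threshold$p_cutoff))
  invisible(x)
}
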