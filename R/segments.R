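#' Trimming threshold specification
#'
#' A base passes the threshold when its error probability is strictly below
#' `p`; equivalently, its Phred quality strictly exceeds -10 log10(p). The
#' default is p = 0.05 (Q ~= 13; one expected base-call error every 20
#' nucleotides). Exactly one of `p` or `q` may be given; a Phred cutoff `q`
#' is converted exactly to p = 10^(-q/10), with no rounding.
#'
#' @param p Error-probability cutoff in (0, 1).
#' @param q Phred-score cutoff (converted to a probability cutoff).
#' @return A `threshold_spec` object with fields `p_cutoff` and `origin`.
#' @examples
#' threshold_spec()            # p = 0.05
#' threshold_spec(q = 13)      # p = 10^-1.3 = 0.0501...
#' @export
threshold_spec <- function(p = NULL, q = NULL) {
  if (inherits(p, "threshold_spec")) return(p)
  if (!is.null(p) && !is.null(q))
    stop("give a probability cutoff or a Phred cutoff, not both")
  if (is.null(p) && is.null(q)) p <- 0.05
  if (!is.null(q)) {
    if (q < 0) stop("Phred cutoff must be >= 0")
    out <- list(p_cutoff = phred_to_error_prob(q), origin = "phred")
  } else {
    if (!is.numeric(p) || p <= 0 || p >= 1)
      stop("probability cutoff must lie in (0, 1)")
    out <- list(p_cutoff = p, origin = "probability")
  }
  class(out) <- "threshold_spec"
  out
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> pass if p < %.6g (Q > %.4g), set as %s\n",
              x$p_cutoff, error_prob_to_phred(x$p_cutoff), x$origin))
  invisible(x)
}

#' Longest contiguous segment of bases passing a quality threshold
#'
#' Scans a read's per-base error probabilities once and returns its longest
#' run of consecutive bases with error probability strictly below the
#' cutoff. Among equal-length maximal runs the leftmost wins, preserving
#' 5' bases. This segment defines both the maximized read length and the
#' slice kept by [dynamic_trim()].
#'
#' @param error_probs Numeric vector of per-base error probabilities in
#'   (0, 1].
#' @param threshold A [threshold_spec()] (or probability cutoff).
#' @return A list with `start` (0-based offset of the segment) and `length`
#'   (0 when no base passes).
#' @examples
#' longest_passing_segment(c(0.01, 0.01, 0.2, 0.01), threshold_spec(0.05))
#' @export
longest_passing_segment <- function(error_probs, threshold = threshold_spec()) {
  threshold <- threshold_spec(threshold)
  n <- length(error_probs)
  if (n == 0L) return(list(start = 0L, length = 0L))
  r <- rle(error_probs < threshold$p_cutoff)
  pass <- which(r$values)
  if (length(pass) == 0L) return(list(start = 0L, length = 0L))
  best <- pass[which.max(r$lengths[pass])]  # which.max -> leftmost tie-break
  start <- if (best == 1L) 0L else sum(r$lengths[seq_len(best - 1L)])
  list(start = as.integer(start), length = as.integer(r$lengths[best]))
}

# Vectorized maximized read lengths (and starts) for a chunk of reads.
.segment_table <- function(qual, enc, threshold) {
  probs <- decode_quality(qual, enc)
  segs <- lapply(probs, longest_passing_segment, threshold = threshold)
  data.frame(start = vapply(segs, `[[`, integer(1), "start"),
             length = vapply(segs, `[[`, integer(1), "length"))
}

#' Histogram of maximized read lengths
#'
#' For every read in a file (not just the per-tile sample), computes the
#' longest-passing-segment length and tabulates the distribution. This
#' histogram is one representation of the usable information content of a
#' dataset: it exactly predicts the read lengths [trim_file()] produces at
#' the same threshold.
#'
#' @param reads A FASTQ path or a `fastq_reads` data.frame.
#' @param threshold A [threshold_spec()].
#' @param encoding `"auto"` or a [quality_encoding()] (ignored when `reads`
#'   carries one).
#' @return A data.frame of class `length_histogram` with columns `length`
#'   and `count` (lengths with zero count omitted), and attributes
#'   `total_reads`, `threshold`.
#' @export
length_histogram <- function(reads, threshold = threshold_spec(),
                             encoding = "auto") {
  threshold <- threshold_spec(threshold)
  counts <- integer(0)  # counts[k] = number of reads with length k - 1
  bump <- function(lens) {
    if (length(lens) == 0L) return()
    tab <- tabulate(lens + 1L)
    if (length(tab) > length(counts))
      counts <<- c(counts, integer(length(tab) - length(counts)))
    counts[seq_along(tab)] <<- counts[seq_along(tab)] + tab
  }
  if (is.character(reads)) {
    enc <- .detect_file_encoding(reads, encoding)
    fastq_apply(reads, function(chunk, n_before) {
      bump(.segment_table(chunk$quality, enc, threshold)$length)
    }, parse_headers = FALSE)
  } else {
    enc <- attr(reads, "encoding")
    if (is.null(enc)) enc <- quality_encoding(encoding)
    bump(.segment_table(reads$quality, enc, threshold)$length)
  }
  nz <- which(counts > 0L)
  hist <- data.frame(length = nz - 1L, count = counts[nz])
  attr(hist, "total_reads") <- sum(counts)
  attr(hist, "threshold") <- threshold
  class(hist) <- c("length_histogram", "data.frame")
  hist
}

#' Write the maximized-read-length histogram as TSV
#'
#' @param hist A [length_histogram()].
#' @param path Output path (conventionally `<prefix>.hist.tsv`).
#' @return Invisibly, `path`.
#' @export
write_histogram <- function(hist, path) {
  utils::write.table(as.data.frame(hist)[c("length", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
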