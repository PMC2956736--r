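#' Quality-score encodings
#'
#' FASTQ files from the Illumina platform historically used three ASCII
#' dialects for per-base quality scores: Sanger/Phred+33 (offset 33, Phred
#' scale), Illumina 1.3+/Phred+64 (offset 64, Phred scale) and the original
#' Solexa+64 (offset 64, odds scale, scores as low as -5). A
#' `quality_encoding` object records which dialect applies and how to decode
#' it.
#'
#' @param name One of `"sanger"`, `"illumina"`, `"solexa"` (long forms
#'   `"sanger33"`, `"illumina64"`, `"solexa64"` are accepted). An existing
#'   `quality_encoding` object is returned unchanged.
#' @return A `quality_encoding` object: a list with elements `name`,
#'   `offset` (33 or 64), `scale` (`"phred"` or `"solexa-odds"`),
#'   `min_ascii` and `max_ascii`.
#' @examples
#' quality_encoding("sanger")
#' quality_encoding("solexa")$min_ascii  # 59, i.e. ';' encodes Qs = -5
#' @export
quality_encoding <- function(name = c("sanger", "illumina", "solexa")) {
  if (inherits(name, "quality_encoding")) return(name)
  name <- sub("(33|64)$", "", tolower(name[1]))
  name <- match.arg(name, c("sanger", "illumina", "solexa"))
  enc <- switch(name,
    sanger   = list(name = "sanger33",   offset = 33L, scale = "phred"),
    illumina = list(name = "illumina64", offset = 64L, scale = "phred"),
    solexa   = list(name = "solexa64",   offset = 64L, scale = "solexa-odds"))
  enc$min_ascii <- if (enc$name == "solexa64") 59L else enc$offset
  enc$max_ascii <- 126L
  class(enc) <- "quality_encoding"
  enc
}

#' @export
print.quality_encoding <- function(x, ...) {
  cat(sprintf("<quality_encoding> %s (ASCII offset %d, %s scale, Q range %d..%d)\n",
              x$name, x$offset, x$scale, encoding_q_range(x)[1],
              encoding_q_range(x)[2]))
  invisible(x)
}

#' Legal integer quality-score range of an encoding
#'
#' @param enc A [quality_encoding()].
#' @return Integer vector `c(min, max)` of legal scores (Phred scores for the
#'   Phred-scale dialects, Solexa odds scores for `solexa64`).
#' @export
encoding_q_range <- function(enc) {
  enc <- quality_encoding(enc)
  c(enc$min_ascii, enc$max_ascii) - enc$offset
}

#' Convert between Phred scores and error probabilities
#'
#' Phred quality is Q = -10 log10(p), where p is the probability that the
#' base call is wrong; Q = 30 corresponds to p = 0.001 and the default
#' trimming threshold p = 0.05 corresponds to Q ~= 13 (one error per 20
#' bases).
#'
#' @param p Error probabilities in (0, 1].
#' @param q Phred quality scores (>= 0; need not be integer).
#' @return `error_prob_to_phred` returns real-valued Phred scores;
#'   `phred_to_error_prob` returns probabilities in (0, 1].
#' @examples
#' error_prob_to_phred(0.05)   # 13.0103
#' phred_to_error_prob(30)     # 0.001
#' @export
error_prob_to_phred <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("error probabilities must lie in (0, 1]")
  -10 * log10(p)
}

#' @rdname error_prob_to_phred
#' @export
phred_to_error_prob <- function(q) {
  if (any(!is.finite(q)) || any(q < 0))
    stop("Phred scores must be finite and >= 0")
  10^(-q / 10)
}

#' Convert Solexa odds scores to error probabilities
#'
#' The pre-1.3 Solexa pipeline scored bases as Qs = -10 log10(p / (1 - p)),
#' which can be negative (minimum -5). Inverting gives
#' p = 10^(-Qs/10) / (1 + 10^(-Qs/10)).
#'
#' @param qs Solexa odds scores (>= -5).
#' @return Error probabilities in (0, 1).
#' @export
solexa_to_error_prob <- function(qs) {
  t <- 10^(-qs / 10)
  t / (1 + t)
}

#' Decode quality strings to error probabilities
#'
#' Converts ASCII quality strings into per-base error probabilities under a
#' given encoding. All downstream statistics in this package operate on the
#' probability scale, not on log-based quality scores.
#'
#' @param qual Character vector of quality strings.
#' @param enc A [quality_encoding()] or its name.
#' @return A list of numeric vectors, one per input string, each value in
#'   (0, 1].
#' @examples
#' decode_quality("^^", "illumina")[[1]]  # c(0.001, 0.001)
#' @export
decode_quality <- function(qual, enc) {
  enc <- quality_encoding(enc)
  lapply(qual, function(s) {
    ints <- utf8ToInt(s)
    if (length(ints) && min(ints) < enc$min_ascii) {
      bad <- intToUtf8(ints[which.min(ints)])
      stop(sprintf("quality character '%s' (ASCII %d) below minimum for %s",
                   bad, min(ints), enc$name))
    }
    if (enc$scale == "phred") {
      phred_to_error_prob(ints - enc$offset)
    } else {
      solexa_to_error_prob(ints - enc$offset)
    }
  })
}

#' Encode integer quality scores as an ASCII quality string
#'
#' Inverse of [decode_quality()] for integer scores: maps scores to ASCII
#' characters under the encoding's offset.
#'
#' @param q Integer quality scores within [encoding_q_range()].
#' @param enc A [quality_encoding()] or its name.
#' @return A single quality string of `length(q)` characters.
#' @export
encode_quality <- function(q, enc) {
  enc <- quality_encoding(enc)
  q <- as.integer(round(q))
  rng <- encoding_q_range(enc)
  if (length(q) && (min(q) < rng[1] || max(q) > rng[2]))
    stop(sprintf("quality score outside legal range [%d, %d] for %s",
                 rng[1], rng[2], enc$name))
  if (!length(q)) return("")
  intToUtf8(q + enc$offset)
}

#' Detect the quality encoding of a FASTQ file from its quality strings
#'
#' Applies the standard ASCII-range heuristic: any character below ASCII 59
#' implies Sanger/Phred+33; otherwise any character in ASCII 59..63 implies
#' Solexa+64 (those codes are legal only as negative Solexa scores);
#' otherwise Illumina/Phred+64 is assumed, with a warning because high-Q
#' Sanger data cannot be excluded. A user-supplied encoding always overrides
#' detection.
#'
#' @param quality_strings Character vector of quality lines (a sample of the
#'   file; [read_fastq()] scans up to its first 10,000 records).
#' @return A [quality_encoding()].
#' @export
detect_encoding <- function(quality_strings) {
  quality_strings <- quality_strings[nzchar(quality_strings)]
  if (length(quality_strings) == 0L)
    stop("cannot detect encoding: no non-empty quality strings supplied")
  for (i in seq_along(quality_strings)) {
    ints <- utf8ToInt(quality_strings[i])
    if (min(ints) < 33L || max(ints) > 126L)
      stop(sprintf(
        "record %d has quality character outside printable ASCII [33, 126]", i))
  }
  codes <- utf8ToInt(paste(quality_strings, collapse = ""))
  if (any(codes < 59L)) return(quality_encoding("sanger"))
  if (any(codes < 64L)) return(quality_encoding("solexa"))
  warning("quality characters all >= ASCII 64: assuming illumina64 ",
          "(sanger33 cannot be excluded); pass `encoding` to override",
          call. = FALSE)
  quality_encoding("illumina")
}
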