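#' Parse a pre-CASAVA-1.8 FASTQ header
#'
#' Headers of the form `@instrument:lane:tile:x:y#index/mate` carry the
#' lane and tile of origin of each read. Headers that do not match the
#' colon-delimited convention are accepted gracefully: they yield `NA` lane
#' and tile, and downstream statistics treat the whole file as a single
#' pseudo-tile labelled 0.
#'
#' @param line Header line(s), with or without the leading `@`.
#' @return A data.frame with one row per header: `instrument`, `lane`,
#'   `tile`, `x`, `y` (integer, `NA` when unparseable) and
#'   `index_and_mate` (character or `NA`).
#' @examples
#' parse_header("@HWUSI-EAS100R:6:73:941:1973#0/1")  # lane 6, tile 73
#' parse_header("@read_0001")                        # pseudo-tile marker
#' @export
parse_header <- function(line) {
  line <- sub("^@", "", line)
  line <- sub("[ \t].*$", "", line)  # drop description after whitespace
  parts <- strsplit(line, ":", fixed = TRUE)
  out <- data.frame(instrument = NA_character_, lane = NA_integer_,
                    tile = NA_integer_, x = NA_integer_, y = NA_integer_,
                    index_and_mate = NA_character_,
                    stringsAsFactors = FALSE)[rep(1L, length(line)), ,
                                              drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < 5L) next
    tail5 <- f[2:5]
    ylast <- f[5]
    ymain <- sub("#.*$", "", ylast)
    if (!all(grepl("^-?[0-9]+$", c(f[2:4], ymain)))) next
    out$instrument[i] <- f[1]
    out$lane[i] <- as.integer(f[2])
    out$tile[i] <- as.integer(f[3])
    out$x[i] <- as.integer(f[4])
    out$y[i] <- as.integer(ymain)
    if (grepl("#", ylast, fixed = TRUE))
      out$index_and_mate[i] <- sub("^[^#]*#", "", ylast)
  }
  out
}

# Convert a block of raw FASTQ lines (multiple of 4) into a read data.frame.
# `offset` is the number of records already consumed, for error messages.
.parse_fastq_block <- function(lines, offset = 0L, parse_headers = TRUE) {
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("truncated FASTQ record at record %d",
                 offset + n %/% 4L + 1L))
  idx <- seq(1L, n, by = 4L)
  head <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(head, "@"))
  if (length(bad))
    stop(sprintf("record %d: header does not start with '@'",
                 offset + bad[1]))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("record %d: '+' separator line missing", offset + bad[1]))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop(sprintf("record %d: sequence and quality lengths differ (%d vs %d)",
                 offset + bad[1], nchar(seqs[bad[1]]), nchar(qual[bad[1]])))
  reads <- data.frame(id = sub("^@", "", head), sequence = seqs,
                      quality = qual, stringsAsFactors = FALSE)
  if (parse_headers) {
    hf <- parse_header(head)
    reads$lane <- hf$lane
    reads$tile <- hf$tile
  }
  reads
}

#' Stream a FASTQ file in chunks
#'
#' Applies a function to successive chunks of records so that memory use is
#' independent of file size. Each chunk is the data.frame produced by
#' [read_fastq()] (columns `id`, `sequence`, `quality`, `lane`, `tile`).
#'
#' @param path Path to a FASTQ file (plain text or gzip).
#' @param fun Function called as `fun(chunk, n_before)` where `n_before` is
#'   the number of records already streamed; returning `FALSE` stops the
#'   stream early.
#' @param chunk_size Records per chunk.
#' @param parse_headers Parse lane/tile from headers (skip for speed when
#'   tile identity is not needed).
#' @return Invisibly, the total number of records streamed.
#' @export
fastq_apply <- function(path, fun, chunk_size = 5000L, parse_headers = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "r")  # transparently handles plain text too
  on.exit(close(con))
  total <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0L) break
    chunk <- .parse_fastq_block(lines, offset = total,
                                parse_headers = parse_headers)
    res <- fun(chunk, total)
    total <- total + nrow(chunk)
    if (identical(res, FALSE)) break
    if (length(lines) < 4L * chunk_size) break
  }
  invisible(total)
}

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records into a data.frame, detecting the quality
#' encoding from up to the first 10,000 records unless one is supplied.
#' Reads missing a parseable lane/tile header are assigned pseudo-tile 0
#' (one notice per file).
#'
#' @param path Path to a FASTQ file.
#' @param encoding `"auto"` (default) or a [quality_encoding()]/name.
#' @param n_max Maximum number of records to read (default all).
#' @return A data.frame of class `fastq_reads` with columns `id`,
#'   `sequence`, `quality`, `lane`, `tile`, and attribute `encoding`.
#' @export
read_fastq <- function(path, encoding = "auto", n_max = Inf) {
  chunks <- list()
  fastq_apply(path, function(chunk, n_before) {
    if (n_before < n_max) {
      keep <- min(nrow(chunk), n_max - n_before)
      chunks[[length(chunks) + 1L]] <<- chunk[seq_len(keep), , drop = FALSE]
    }
    n_before + nrow(chunk) < n_max
  })
  reads <- if (length(chunks)) do.call(rbind, chunks) else
    data.frame(id = character(0), sequence = character(0),
               quality = character(0), lane = integer(0), tile = integer(0),
               stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  if (identical(encoding, "auto")) {
    encoding <- detect_encoding(utils::head(reads$quality[nzchar(reads$quality)],
                                            10000L))
  } else {
    encoding <- quality_encoding(encoding)
  }
  if (anyNA(reads$tile) && nrow(reads)) {
    message("headers without tile information: using single pseudo-tile 0")
    reads$tile[is.na(reads$tile)] <- 0L
  }
  attr(reads, "encoding") <- encoding
  class(reads) <- c("fastq_reads", "data.frame")
  reads
}

#' Write reads to a FASTQ file
#'
#' Writes 4-line records. Writing then re-reading reproduces id, sequence
#' and quality byte-for-byte. Zero-length reads are written as records with
#' empty sequence and quality lines.
#'
#' @param reads A data.frame with columns `id`, `sequence`, `quality`.
#' @param path Output path.
#' @param append Append to an existing file.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, append = FALSE) {
  n <- nrow(reads)
  if (n == 0L) {
    if (!append) {
      ok <- file.create(path)
      if (!ok) stop("cannot write to ", path)
    }
    return(invisible(path))
  }
  lines <- character(4L * n)
  idx <- seq(1L, 4L * n, by = 4L)
  lines[idx] <- paste0("@", reads$id)
  lines[idx + 1L] <- reads$sequence
  lines[idx + 2L] <- "+"
  lines[idx + 3L] <- reads$quality
  con <- if (append) file(path, "a") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Detect encoding by scanning up to the first 10,000 records of a file.
.detect_file_encoding <- function(path, encoding = "auto") {
  if (!identical(encoding, "auto")) return(quality_encoding(encoding))
  quals <- character(0)
  fastq_apply(path, function(chunk, n_before) {
    quals <<- c(quals, chunk$quality)
    length(quals) < 10000L
  }, chunk_size = 10000L, parse_headers = FALSE)
  detect_encoding(utils::head(quals[nzchar(quals)], 10000L))
}
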