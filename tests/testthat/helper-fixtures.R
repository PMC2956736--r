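# Fixtures are built in code: small FASTQ files, random reads, and the
# brute-force segment oracle used against the linear scan.

write_fastq_lines <- function(ids, seqs, quals, path = tempfile(fileext = ".fastq")) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", quals))
  writeLines(lines, path)
  path
}

# n random reads with lengths in len_range and integer qualities uniform in
# q_range, encoded under `enc`; returns a fastq_reads-style data.frame.
random_reads <- function(n, len_range = c(0L, 150L), q_range = c(0L, 40L),
                         enc = quality_encoding("sanger"), tile = 1L) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  make <- function(len) {
    if (len == 0L) return(c(seq = "", qual = ""))
    q <- sample(q_range[1]:q_range[2], len, replace = TRUE)
    c(seq = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = ""),
      qual = encode_quality(q, enc))
  }
  m <- vapply(lens, make, c(seq = "", qual = ""))
  reads <- data.frame(id = sprintf("T:1:%d:%d:%d#0/1", tile, seq_len(n), 1L),
                      sequence = m["seq", ], quality = m["qual", ],
                      lane = 1L, tile = tile, stringsAsFactors = FALSE)
  attr(reads, "encoding") <- enc
  reads
}

# O(L^2) oracle: checks every contiguous substring; leftmost maximal run.
brute_force_segment <- function(p, cutoff) {
  n <- length(p)
  best <- list(start = 0L, length = 0L)
  if (n == 0L) return(best)
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(p[s:e] < cutoff)) {
        len <- e - s + 1L
        if (len > best$length) best <- list(start = s - 1L, length = len)
      }
    }
  }
  best
}

# Small simulated flow cell reused by several tests.
sim_flowcell <- function(path = tempfile(fileext = ".fastq"), ...) {
  prof <- flowcell_profile(...)
  res <- simulate_flowcell(prof, path)
  list(profile = prof, path = path, truth = res$truth)
}
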