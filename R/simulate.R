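#' Per-cycle baseline quality profile
#'
#' A linear Phred decay from `q_start` to `q_end` across the read. Because
#' Q is -10 log10(p), a linear decay in Q is an exponential growth in error
#' probability along the read — the error profile characteristic of the
#' platform.
#'
#' @param read_length Number of cycles.
#' @param q_start,q_end Phred quality at the first and last cycle.
#' @return Integer vector of length `read_length`.
#' @export
quality_profile <- function(read_length, q_start = 34, q_end = 20) {
  as.integer(round(seq(q_start, q_end, length.out = read_length)))
}

#' Flow-cell defects
#'
#' Constructors for the defect classes the simulator can inject:
#' `tile_failure` (a whole tile emits no reads, or is uniformly degraded),
#' `cycle_failure` (specific cycles of one tile lose quality, as caused by
#' tile-specific air bubbles), and `gradient` (adds to the U-shaped
#' spatial penalty, see [ushape_penalty()]).
#'
#' @param tile Tile identifier the defect applies to.
#' @param dropout If `TRUE`, the tile emits zero reads.
#' @param severity Phred-score penalty subtracted from affected bases
#'   (clamped at the encoding minimum), or U-shape amplitude for
#'   `gradient`.
#' @param cycles Integer vector of affected cycles (for `cycle_failure`).
#' @return A `flowcell_defect` object.
#' @export
tile_failure <- function(tile, dropout = TRUE, severity = 20) {
  structure(list(kind = "tile_failure", tile = tile, dropout = dropout,
                 severity = severity), class = "flowcell_defect")
}

#' @rdname tile_failure
#' @export
cycle_failure <- function(tile, cycles, severity = 20) {
  structure(list(kind = "cycle_failure", tile = tile,
                 cycles = as.integer(cycles), severity = severity),
            class = "flowcell_defect")
}

#' @rdname tile_failure
#' @export
gradient_defect <- function(severity) {
  structure(list(kind = "gradient", severity = severity),
            class = "flowcell_defect")
}

#' U-shaped spatial quality penalty
#'
#' Tiles on the Genome Analyzer-era flow cell are laid out in a U: tiles 1
#' and `n` sit together at one end, `n/2` and `n/2 + 1` at the other, and
#' `n/4` and `3n/4` together in the middle of the flow cell. A quality
#' erosion at mid-flow-cell therefore shows up at tiles around `n/4` and
#' `3n/4` in tile-ordered plots. The model: map tile `t` to its physical
#' arm coordinate u(t) = t - 1/2 (first arm) or n + 1/2 - t (return arm),
#' then apply a triangular penalty peaking at the arm midpoint n/4:
#' penalty = amplitude * max(0, 1 - |u - n/4| / (n/4)). The penalty is
#' exactly end-symmetric (`penalty(1) == penalty(n)`) and maximal at tiles
#' n/4 and 3n/4.
#'
#' @param tile_index Tile index (1..`n_tiles`), vectorized.
#' @param n_tiles Number of tiles.
#' @param amplitude Peak penalty in Phred units (>= 0).
#' @return Numeric penalty (Phred units) per tile.
#' @export
ushape_penalty <- function(tile_index, n_tiles, amplitude) {
  stopifnot(all(tile_index >= 1), all(tile_index <= n_tiles), amplitude >= 0)
  u <- ifelse(tile_index <= n_tiles / 2, tile_index - 0.5,
              n_tiles + 0.5 - tile_index)
  mid <- n_tiles / 4
  amplitude * pmax(0, 1 - abs(u - mid) / mid)
}

#' Simulated flow-cell run parameterization
#'
#' Defines the geometry, per-cycle baseline quality, spatial gradient,
#' defect list and encoding of a synthetic run. Defaults mirror a 100-tile,
#' 75-cycle Genome Analyzer II lane in Phred+64 encoding with a linear
#' Phred decay and small per-base jitter.
#'
#' @param n_tiles Number of tiles.
#' @param reads_per_tile Reads emitted per (non-failed) tile.
#' @param read_length Cycles per read.
#' @param baseline_q Integer per-cycle quality profile, length
#'   `read_length`.
#' @param ushape_amplitude Peak Phred penalty of the U-shaped gradient
#'   (0 = flat flow cell).
#' @param defects List of [tile_failure()]/[cycle_failure()]/
#'   [gradient_defect()] objects.
#' @param encoding A [quality_encoding()] or name.
#' @param jitter Half-width j of the uniform integer per-base quality
#'   jitter on {-j, ..., +j}; exercises variance/min/max statistics.
#' @param seed Integer seed making the run fully deterministic.
#' @return A `flowcell_profile` object.
#' @export
flowcell_profile <- function(n_tiles = 100L, reads_per_tile = 1000L,
                             read_length = 75L,
                             baseline_q = quality_profile(read_length),
                             ushape_amplitude = 0, defects = list(),
                             encoding = "illumina", jitter = 2L,
                             seed = 1L) {
  stopifnot(n_tiles >= 1, reads_per_tile >= 1, read_length >= 1,
            jitter >= 0, ushape_amplitude >= 0)
  if (length(baseline_q) != read_length)
    stop("baseline_q must have one quality per cycle")
  if (inherits(defects, "flowcell_defect")) defects <- list(defects)
  for (d in defects) {
    if (!inherits(d, "flowcell_defect")) stop("defects must be flowcell_defect objects")
    if (d$kind == "gradient") ushape_amplitude <- ushape_amplitude + d$severity
  }
  structure(list(n_tiles = as.integer(n_tiles),
                 reads_per_tile = as.integer(reads_per_tile),
                 read_length = as.integer(read_length),
                 baseline_q = as.integer(baseline_q),
                 ushape_amplitude = ushape_amplitude,
                 defects = Filter(function(d) d$kind != "gradient", defects),
                 encoding = quality_encoding(encoding),
                 jitter = as.integer(jitter), seed = as.integer(seed)),
            class = "flowcell_profile")
}

# Pre-jitter quality Q0(t, c) for every tile x cycle, NA for dropout tiles.
.base_quality_grid <- function(profile) {
  q <- matrix(rep(profile$baseline_q, each = profile$n_tiles),
              nrow = profile$n_tiles)
  pen <- round(ushape_penalty(seq_len(profile$n_tiles), profile$n_tiles,
                              profile$ushape_amplitude))
  q <- q - pen
  for (d in profile$defects) {
    if (d$kind == "tile_failure") {
      if (isTRUE(d$dropout)) q[d$tile, ] <- NA_integer_
      else q[d$tile, ] <- q[d$tile, ] - d$severity
    } else if (d$kind == "cycle_failure") {
      q[d$tile, d$cycles] <- q[d$tile, d$cycles] - d$severity
    }
  }
  q
}

# Exact mean and sd of the per-base error probability at one cell, over the
# uniform jitter support after clamping to the encoding's legal range.
.cell_truth <- function(q0, jitter, enc) {
  rng <- encoding_q_range(enc)
  qs <- pmin(pmax(q0 + seq(-jitter, jitter), rng[1]), rng[2])
  p <- if (enc$scale == "phred") phred_to_error_prob(qs) else
    solexa_to_error_prob(qs)
  # population sd over the (uniform) jitter support
  sd <- if (length(p) > 1)
    stats::sd(p) * sqrt((length(p) - 1) / length(p)) else 0
  c(mean = mean(p), sd = sd)
}

#' Truth record for a simulated flow cell
#'
#' The exact per-(tile, cycle) mean and standard deviation of the per-base
#' error probability implied by a [flowcell_profile()] (enumerating the
#' jitter support after clamping). Rows for dropout tiles carry `NA`.
#'
#' @param profile A `flowcell_profile`.
#' @return A data.frame with columns `tile`, `cycle`, `mean_p`, `sd_p`.
#' @export
flowcell_truth <- function(profile) {
  q <- .base_quality_grid(profile)
  grid <- expand.grid(tile = seq_len(profile$n_tiles),
                      cycle = seq_len(profile$read_length))
  stats <- t(vapply(seq_len(nrow(grid)), function(i) {
    q0 <- q[grid$tile[i], grid$cycle[i]]
    if (is.na(q0)) c(mean = NA_real_, sd = NA_real_)
    else .cell_truth(q0, profile$jitter, profile$encoding)
  }, c(mean = 0, sd = 0)))
  data.frame(grid, mean_p = stats[, "mean"], sd_p = stats[, "sd"])
}

#' Simulate a flow-cell FASTQ file with injected defects
#'
#' Writes a FASTQ file emulating one lane: reads carry pre-CASAVA-1.8
#' headers (`@SIM:1:<tile>:<x>:<y>#0/1`), bases are uniform over ACGT, and
#' per-base quality is the deterministic per-(tile, cycle) baseline minus
#' the U-shape and defect penalties, plus uniform integer jitter, clamped
#' to the encoding's legal range. A machine-readable truth table
#' ([flowcell_truth()]) is written alongside for recovery tests. Fully
#' deterministic given `profile$seed`.
#'
#' @param profile A [flowcell_profile()].
#' @param path Output FASTQ path.
#' @param truth_path Truth TSV path (`NULL` to skip writing it).
#' @return Invisibly, a list with `path`, `truth` (data.frame) and
#'   `truth_path`.
#' @export
simulate_flowcell <- function(profile, path,
                              truth_path = paste0(path, ".truth.tsv")) {
  stopifnot(inherits(profile, "flowcell_profile"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(profile$seed)
  enc <- profile$encoding
  rng <- encoding_q_range(enc)
  qgrid <- .base_quality_grid(profile)
  n <- profile$reads_per_tile
  L <- profile$read_length
  bases <- c("A", "C", "G", "T")
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (t in seq_len(profile$n_tiles)) {
    if (anyNA(qgrid[t, ])) next  # total tile failure: zero reads
    base_m <- matrix(bases[sample.int(4L, n * L, replace = TRUE)], n, L)
    jit <- if (profile$jitter > 0)
      matrix(sample.int(2L * profile$jitter + 1L, n * L, replace = TRUE) -
               profile$jitter - 1L, n, L)
    else matrix(0L, n, L)
    qm <- sweep(jit, 2L, qgrid[t, ], `+`)
    qm <- pmin(pmax(qm, rng[1]), rng[2])
    chr <- c(intToUtf8(seq(rng[1], rng[2]) + enc$offset, multiple = TRUE))
    qc <- matrix(chr[qm - rng[1] + 1L], n, L)
    seqs <- do.call(paste0, as.data.frame(base_m, stringsAsFactors = FALSE))
    quals <- do.call(paste0, as.data.frame(qc, stringsAsFactors = FALSE))
    ids <- sprintf("@SIM:1:%d:%d:%d#0/1", t, seq_len(n), t)
    lines <- character(4L * n)
    idx <- seq(1L, 4L * n, by = 4L)
    lines[idx] <- ids
    lines[idx + 1L] <- seqs
    lines[idx + 2L] <- "+"
    lines[idx + 3L] <- quals
    writeLines(lines, con)
  }
  truth <- flowcell_truth(profile)
  if (!is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(path = path, truth = truth, truth_path = truth_path))
}
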