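#' Sample reads per tile by single-pass reservoir sampling
#'
#' Draws a uniform random sample without replacement of up to `n` reads
#' from every tile in one streaming pass, so memory scales with tiles x
#' sample size, never with file size. One shared sample per tile serves all
#' cycles (a read spans every cycle it covers). Tiles with fewer than 5,000
#' reads trigger a warning: the accuracy of the summary statistics erodes
#' quickly below that sample size.
#'
#' @param reads A FASTQ path or a `fastq_reads` data.frame.
#' @param n Sample size per tile (default 10,000 reads).
#' @param seed Integer seed; fixing it makes the sample reproducible (for a
#'   fixed chunk size).
#' @param encoding `"auto"` or a [quality_encoding()].
#' @param chunk_size Records per streamed chunk.
#' @return A list of class `tile_samples`: `samples` (named list, tile ->
#'   data.frame of sampled reads), `n_seen` (reads per tile in the input),
#'   `encoding`, `n_requested`.
#' @export
sample_per_tile <- function(reads, n = 10000L, seed = NULL,
                            encoding = "auto", chunk_size = 5000L) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  store <- new.env(parent = emptyenv())   # tile -> list(id=, sequence=, quality=)
  seen <- new.env(parent = emptyenv())    # tile -> reads seen so far
  take_chunk <- function(chunk, n_before) {
    for (t in unique(chunk$tile)) {
      rows <- which(chunk$tile == t)
      key <- as.character(t)
      prev <- if (is.null(seen[[key]])) 0L else seen[[key]]
      if (is.null(store[[key]]))
        store[[key]] <- list(id = character(0), sequence = character(0),
                             quality = character(0))
      m <- length(rows)
      pos <- prev + seq_len(m)            # 1-based index of each read in its tile
      fill <- rows[pos <= n]
      if (length(fill)) {
        sl <- store[[key]]
        sl$id <- c(sl$id, chunk$id[fill])
        sl$sequence <- c(sl$sequence, chunk$sequence[fill])
        sl$quality <- c(sl$quality, chunk$quality[fill])
        store[[key]] <- sl
      }
      repl <- rows[pos > n]
      if (length(repl)) {
        # classic reservoir step: read i replaces a random slot with prob n/i
        j <- floor(stats::runif(length(repl)) * pos[pos > n]) + 1
        hit <- which(j <= n)
        if (length(hit)) {
          sl <- store[[key]]
          sl$id[j[hit]] <- chunk$id[repl[hit]]
          sl$sequence[j[hit]] <- chunk$sequence[repl[hit]]
          sl$quality[j[hit]] <- chunk$quality[repl[hit]]
          store[[key]] <- sl
        }
      }
      seen[[key]] <- prev + m
    }
  }
  if (is.character(reads)) {
    enc <- .detect_file_encoding(reads, encoding)
    fastq_apply(reads, function(chunk, n_before) {
      if (anyNA(chunk$tile)) chunk$tile[is.na(chunk$tile)] <- 0L
      take_chunk(chunk, n_before)
    }, chunk_size = chunk_size)
  } else {
    enc <- attr(reads, "encoding")
    if (is.null(enc)) enc <- quality_encoding(encoding)
    tiles <- reads$tile
    if (anyNA(tiles)) reads$tile[is.na(tiles)] <- 0L
    nr <- nrow(reads)
    starts <- seq(1L, max(nr, 1L), by = chunk_size)
    if (nr > 0L) for (s in starts) {
      e <- min(s + chunk_size - 1L, nr)
      take_chunk(reads[s:e, , drop = FALSE], s - 1L)
    }
  }
  keys <- ls(store)
  ord <- order(suppressWarnings(as.numeric(keys)), keys)
  keys <- keys[ord]
  samples <- lapply(keys, function(k)
    data.frame(store[[k]], stringsAsFactors = FALSE))
  names(samples) <- keys
  n_seen <- vapply(keys, function(k) seen[[k]], integer(1))
  low <- n_seen[pmin(n_seen, n) < 5000L]
  if (length(low))
    warning(sprintf(
      "tile(s) %s have fewer than 5,000 reads sampled; summary statistics lose accuracy below 5,000 reads per cycle and tile",
      paste(names(low), collapse = ", ")), call. = FALSE)
  structure(list(samples = samples, n_seen = n_seen, encoding = enc,
                 n_requested = as.integer(n)),
            class = "tile_samples")
}

#' Tile x cycle error-probability statistics
#'
#' Aggregates the per-tile samples into a tiles x cycles grid of
#' error-probability statistics: the substrate of the quality heat map and
#' per-cycle line graph. All statistics are on the probability scale (a
#' run at constant Q = 30 yields mean 0.001, never 30). Cell (t, c)
#' aggregates the error probability at cycle c over sampled reads of tile t
#' long enough to cover cycle c; tiles absent from the integer tile range
#' (e.g. a failed tile that emitted no reads) appear as all-missing rows.
#'
#' @param samples A `tile_samples` object from [sample_per_tile()].
#' @param variance Also compute the (n - 1)-denominator sample variance.
#' @param minmax Also compute per-cell minima and maxima.
#' @return A list of class `tile_cycle_matrix`: `tiles`, `cycles`, matrices
#'   `mean_p`, `n_obs` (reads contributing per cell) and optionally
#'   `variance_p`, `min_p`, `max_p`; `n_sampled` per tile.
#' @export
compute_tile_matrix <- function(samples, variance = FALSE, minmax = FALSE) {
  stopifnot(inherits(samples, "tile_samples"))
  enc <- samples$encoding
  obs_tiles <- names(samples$samples)
  C <- 0L
  probs_by_tile <- lapply(samples$samples, function(df) {
    p <- decode_quality(df$quality, enc)
    len <- lengths(p)
    C <<- max(C, if (length(len)) max(len) else 0L)
    p
  })
  if (C == 0L) stop("no usable reads: maximum read length is 0")
  num <- suppressWarnings(as.numeric(obs_tiles))
  tiles <- if (!anyNA(num) && all(num == round(num)) && length(num))
    as.character(seq(min(num), max(num))) else obs_tiles
  empty <- matrix(NA_real_, nrow = length(tiles), ncol = C,
                  dimnames = list(tiles, paste0("cycle", seq_len(C))))
  out <- list(tiles = tiles, cycles = C, mean_p = empty,
              n_obs = matrix(0L, nrow(empty), C, dimnames = dimnames(empty)))
  if (variance) out$variance_p <- empty
  if (minmax) { out$min_p <- empty; out$max_p <- empty }
  for (t in obs_tiles) {
    p <- probs_by_tile[[t]]
    if (length(p) == 0L) next
    m <- matrix(NA_real_, length(p), C)
    for (i in seq_along(p)) if (length(p[[i]])) m[i, seq_along(p[[i]])] <- p[[i]]
    n_c <- as.integer(colSums(!is.na(m)))
    mean_c <- ifelse(n_c > 0, colMeans(m, na.rm = TRUE), NA_real_)
    out$mean_p[t, ] <- mean_c
    out$n_obs[t, ] <- n_c
    if (variance)
      out$variance_p[t, ] <- ifelse(n_c > 1,
                                    apply(m, 2, stats::var, na.rm = TRUE),
                                    ifelse(n_c == 1, 0, NA_real_))
    if (minmax) {
      out$min_p[t, ] <- suppressWarnings(apply(m, 2, min, na.rm = TRUE))
      out$max_p[t, ] <- suppressWarnings(apply(m, 2, max, na.rm = TRUE))
      out$min_p[t, n_c == 0] <- NA_real_
      out$max_p[t, n_c == 0] <- NA_real_
    }
  }
  out$n_sampled <- stats::setNames(
    vapply(tiles, function(t)
      if (t %in% obs_tiles) nrow(samples$samples[[t]]) else 0L, integer(1)),
    tiles)
  out$encoding <- enc
  class(out) <- "tile_cycle_matrix"
  out
}

#' @export
print.tile_cycle_matrix <- function(x, ...) {
  cat(sprintf("<tile_cycle_matrix> %d tiles x %d cycles; mean error probability %.4g\n",
              length(x$tiles), x$cycles,
              mean(x$mean_p, na.rm = TRUE)))
  invisible(x)
}

#' Global per-cycle and whole-dataset mean error probabilities
#'
#' Collapses a [compute_tile_matrix()] result across tiles, weighting each
#' tile's per-cycle mean by the number of sampled reads contributing at
#' that cycle — so the global mean equals the plain mean over all sampled
#' base observations. Cycles with no observations yield `NA` and are
#' excluded from the global mean.
#'
#' @param matrix A `tile_cycle_matrix`.
#' @return A list of class `global_cycle_stats`: `mean_p_per_cycle`
#'   (length-`cycles` vector) and `global_mean_p`.
#' @export
compute_global <- function(matrix) {
  stopifnot(inherits(matrix, "tile_cycle_matrix"))
  w <- matrix$n_obs
  mp <- matrix$mean_p
  num <- colSums(w * ifelse(is.na(mp), 0, mp))
  den <- colSums(w)
  per_cycle <- ifelse(den > 0, num / den, NA_real_)
  structure(list(mean_p_per_cycle = unname(per_cycle),
                 global_mean_p = sum(num) / sum(den)),
            class = "global_cycle_stats")
}

#' Write tile x cycle statistics tables as TSV
#'
#' One matrix file per computed statistic (`<prefix>.quality.tsv` for the
#' means, `.variance.tsv`, `.min.tsv`, `.max.tsv` when present; rows are
#' tiles in ascending order, columns cycles 1..C, missing cells `NA`), plus
#' `<prefix>.cycles.tsv` holding the global per-cycle means.
#'
#' @param matrix A `tile_cycle_matrix`.
#' @param global A [compute_global()] result (computed if `NULL`).
#' @param prefix Output path prefix.
#' @return Invisibly, a character vector of the files written.
#' @export
write_stats_tables <- function(matrix, global = NULL, prefix) {
  stopifnot(inherits(matrix, "tile_cycle_matrix"))
  if (is.null(global)) global <- compute_global(matrix)
  write_one <- function(m, path) {
    df <- data.frame(tile = matrix$tiles, m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- write_one(matrix$mean_p, paste0(prefix, ".quality.tsv"))
  if (!is.null(matrix$variance_p))
    files <- c(files, write_one(matrix$variance_p, paste0(prefix, ".variance.tsv")))
  if (!is.null(matrix$min_p))
    files <- c(files, write_one(matrix$min_p, paste0(prefix, ".min.tsv")))
  if (!is.null(matrix$max_p))
    files <- c(files, write_one(matrix$max_p, paste0(prefix, ".max.tsv")))
  gpath <- paste0(prefix, ".cycles.tsv")
  utils::write.table(
    data.frame(cycle = seq_len(matrix$cycles),
               mean_p = global$mean_p_per_cycle),
    gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, gpath))
}
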