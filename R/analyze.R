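#' At-a-glance quality assessment of one or more FASTQ files
#'
#' The full pipeline behind the `analyze` subcommand: for each input file,
#' detect the quality encoding, reservoir-sample reads per tile, compute
#' the tile x cycle error-probability matrix and global per-cycle means,
#' compute the maximized-read-length histogram over all reads, write the
#' TSV tables (and optionally plots), and write a one-page text summary.
#' Multiple files are processed independently, each with its own output
#' prefix.
#'
#' @param paths FASTQ input path(s).
#' @param output_prefix Output prefix per file (default: the input path).
#' @param sample_size Reads sampled per tile (default 10,000).
#' @param encoding `"auto"` or a [quality_encoding()] applied to all files.
#' @param variance,minmax Also compute variance / min and max matrices.
#' @param threshold [threshold_spec()] for the length histogram.
#' @param plots Write heat map, per-cycle line graph and histogram plots.
#' @param plot_format `"png"`, `"pdf"` or `"svg"`.
#' @param seed Seed for the per-tile sampling.
#' @return Invisibly, a list of `fastq_qc` objects (one per file), each
#'   holding `matrix`, `global`, `histogram`, `samples`, `files`,
#'   `summary`.
#' @export
analyze_fastq <- function(paths, output_prefix = paths,
                          sample_size = 10000L, encoding = "auto",
                          variance = FALSE, minmax = FALSE,
                          threshold = threshold_spec(), plots = FALSE,
                          plot_format = "png", seed = NULL) {
  stopifnot(length(output_prefix) == length(paths))
  threshold <- threshold_spec(threshold)
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    path <- paths[i]
    prefix <- output_prefix[i]
    if (!file.exists(path)) stop("no such file: ", path)
    warnings_seen <- character(0)
    samples <- withCallingHandlers(
      sample_per_tile(path, n = sample_size, seed = seed,
                      encoding = encoding),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    tcm <- compute_tile_matrix(samples, variance = variance, minmax = minmax)
    glob <- compute_global(tcm)
    hist <- length_histogram(path, threshold = threshold,
                             encoding = samples$encoding)
    files <- write_stats_tables(tcm, glob, prefix)
    hfile <- write_histogram(hist, paste0(prefix, ".hist.tsv"))
    files <- c(files, hfile)
    if (plots) {
      pfiles <- c(paste0(prefix, ".heatmap.", plot_format),
                  paste0(prefix, ".cycles.", plot_format),
                  paste0(prefix, ".hist.", plot_format))
      plot_heatmap(tcm, pfiles[1])
      plot_cycle_lines(tcm, glob, pfiles[2])
      plot_length_histogram(hist, threshold, pfiles[3])
      files <- c(files, pfiles)
    }
    summary_text <- .qc_summary_text(path, samples, tcm, glob, hist,
                                     threshold, warnings_seen)
    writeLines(summary_text, paste0(prefix, ".summary.txt"))
    files <- c(files, paste0(prefix, ".summary.txt"))
    res <- structure(list(path = path, matrix = tcm, global = glob,
                          histogram = hist, samples = samples,
                          threshold = threshold, files = files,
                          summary = summary_text),
                     class = "fastq_qc")
    out[[i]] <- res
  }
  names(out) <- paths
  invisible(if (length(out) == 1L) out[[1]] else out)
}

.qc_summary_text <- function(path, samples, tcm, glob, hist, threshold,
                             warnings_seen) {
  n_reads <- sum(samples$n_seen)
  hist_mean <- sum(hist$length * hist$count) / sum(hist$count)
  lines <- c(
    sprintf("FASTQ quality summary: %s", path),
    sprintf("  encoding            : %s", samples$encoding$name),
    sprintf("  reads               : %d", n_reads),
    sprintf("  tiles               : %d (%s..%s)", length(tcm$tiles),
            tcm$tiles[1], tcm$tiles[length(tcm$tiles)]),
    sprintf("  cycles              : %d", tcm$cycles),
    sprintf("  global mean P(error): %.6g  (Q = %.3g)", glob$global_mean_p,
            error_prob_to_phred(glob$global_mean_p)),
    sprintf("  threshold           : P < %.4g (Q > %.3g)",
            threshold$p_cutoff, error_prob_to_phred(threshold$p_cutoff)),
    sprintf("  mean maximized len  : %.2f nt", hist_mean))
  low <- samples$n_seen[pmin(samples$n_seen, samples$n_requested) < 5000L]
  if (length(low))
    lines <- c(lines, sprintf(
      "  WARNING: tile(s) %s sampled below 5,000 reads; statistics lose accuracy",
      paste(names(low), collapse = ", ")))
  for (w in setdiff(warnings_seen, character(0)))
    if (!grepl("fewer than 5,000", w))
      lines <- c(lines, paste0("  WARNING: ", w))
  lines
}

#' @export
print.fastq_qc <- function(x, ...) {
  writeLines(x$summary)
  invisible(x)
}
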