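# Graphics are a view over the TSV tables: every plotting function is a
# pure consumer that renders exactly the numbers handed to it and returns
# them invisibly, so plotted data can be checked against the tables.

.open_device <- function(path, width = 800, height = 600) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height),
    pdf = grDevices::pdf(path, width = width / 100, height = height / 100),
    svg = grDevices::svg(path, width = width / 100, height = height / 100),
    stop("unsupported plot format: ", ext))
}

.heat_palette <- function(n = 256) {
  grDevices::hcl.colors(n, "YlOrRd", rev = TRUE)
}

#' Heat map of mean error probability per tile and cycle
#'
#' Cycles run left to right on the x-axis; tiles are ranked top to bottom
#' on the y-axis. Cell colour is proportional to the mean probability of a
#' base-call error; tiles with no reads render as a neutral grey horizontal
#' bar. The colour scale spans [0, `color_scale_max`] (defaulting to the
#' matrix maximum; fix it to compare runs).
#'
#' @param matrix A `tile_cycle_matrix`.
#' @param path Output file; format chosen by extension (png/pdf/svg).
#' @param color_scale_max Upper end of the colour scale, or `NULL` for the
#'   matrix maximum.
#' @param width,height Device size in pixels.
#' @return Invisibly, the matrix of values rendered (tiles x cycles).
#' @export
plot_heatmap <- function(matrix, path, color_scale_max = NULL,
                         width = 800, height = 600) {
  stopifnot(inherits(matrix, "tile_cycle_matrix"))
  m <- matrix$mean_p
  if (all(is.na(m))) stop("matrix has no non-missing cells")
  zmax <- if (is.null(color_scale_max)) max(m, na.rm = TRUE) else
    color_scale_max
  if (zmax <= 0) zmax <- 1e-6
  .open_device(path, width, height)
  on.exit(grDevices::dev.off())
  graphics::layout(t(c(1, 2)), widths = c(5, 1))
  graphics::par(mar = c(4, 4, 2, 1))
  nt <- nrow(m); nc <- ncol(m)
  # image() draws row 1 at the bottom; flip so tile 1 is at the top
  z <- t(m[rev(seq_len(nt)), , drop = FALSE])
  graphics::plot(NA, xlim = c(0.5, nc + 0.5), ylim = c(0.5, nt + 0.5),
                 xaxs = "i", yaxs = "i", xlab = "cycle", ylab = "tile",
                 yaxt = "n", main = "Mean probability of base-call error")
  graphics::rect(0.5, 0.5, nc + 0.5, nt + 0.5, col = "grey70", border = NA)
  graphics::image(x = seq_len(nc), y = seq_len(nt), z = z,
                  zlim = c(0, zmax), col = .heat_palette(), add = TRUE)
  at <- pretty(seq_len(nt))
  at <- at[at >= 1 & at <= nt]
  graphics::axis(2, at = nt + 1 - at, labels = matrix$tiles[at])
  graphics::par(mar = c(4, 1, 2, 3))
  ramp <- seq(0, zmax, length.out = 256)
  graphics::image(x = 1, y = ramp, z = t(ramp), zlim = c(0, zmax),
                  col = .heat_palette(), xaxt = "n", xlab = "",
                  ylab = "", yaxt = "n")
  graphics::axis(4, las = 1)
  graphics::mtext("P(error)", side = 3, line = 0.5, cex = 0.8)
  invisible(m)
}

#' Per-cycle mean error probability: one line per tile plus global overlay
#'
#' Dotted black lines trace each tile's mean error probability across
#' cycles; filled red circles overlay the count-weighted global per-cycle
#' mean of the whole dataset. The y-axis is probability, never a log
#' score.
#'
#' @param matrix A `tile_cycle_matrix`.
#' @param global A [compute_global()] result (computed if `NULL`).
#' @inheritParams plot_heatmap
#' @return Invisibly, a list with `per_tile` (matrix) and `global`
#'   (numeric vector), exactly as rendered.
#' @export
plot_cycle_lines <- function(matrix, global = NULL, path,
                             width = 800, height = 600) {
  stopifnot(inherits(matrix, "tile_cycle_matrix"))
  if (is.null(global)) global <- compute_global(matrix)
  .open_device(path, width, height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::matplot(t(matrix$mean_p), type = "l", lty = 3, col = "black",
                    xlab = "cycle (nucleotide position)",
                    ylab = "mean probability of base-call error",
                    main = "Per-tile quality by cycle")
  graphics::points(seq_len(matrix$cycles), global$mean_p_per_cycle,
                   col = "red", pch = 19)
  invisible(list(per_tile = matrix$mean_p,
                 global = global$mean_p_per_cycle))
}

#' Histogram of maximized read lengths
#'
#' Bar chart of the distribution of longest contiguous read segments
#' passing the quality threshold, over lengths 0..max; the threshold is
#' annotated in the title as both a probability and its Phred equivalent.
#'
#' @param hist A [length_histogram()].
#' @param threshold A [threshold_spec()]; taken from `hist` when absent.
#' @inheritParams plot_heatmap
#' @return Invisibly, the full counts vector over lengths `0..max`.
#' @export
plot_length_histogram <- function(hist, threshold = NULL, path,
                                  width = 800, height = 600) {
  stopifnot(nrow(hist) > 0)
  if (is.null(threshold)) threshold <- attr(hist, "threshold")
  threshold <- threshold_spec(threshold)
  max_len <- max(hist$length)
  counts <- integer(max_len + 1L)
  counts[hist$length + 1L] <- hist$count
  .open_device(path, width, height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::barplot(counts, names.arg = 0:max_len, space = 0,
                    xlab = "maximized read length (nt)", ylab = "reads",
                    main = sprintf(
                      "Longest segments passing P < %.4g (Q > %.3g)",
                      threshold$p_cutoff,
                      error_prob_to_phred(threshold$p_cutoff)))
  invisible(counts)
}
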