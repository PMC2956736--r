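make_tile_samples <- function(tile_dfs, enc = quality_encoding("sanger"),
                              n_requested = 10000L) {
  structure(list(samples = tile_dfs,
                 n_seen = vapply(tile_dfs, nrow, integer(1)),
                 encoding = enc, n_requested = n_requested),
            class = "tile_samples")
}

reads_df <- function(quals, tile = 1L, enc = quality_encoding("sanger")) {
  df <- data.frame(id = sprintf("T:1:%d:%d:1#0/1", tile, seq_along(quals)),
                   sequence = vapply(quals, function(q)
                     paste(rep("A", nchar(q)), collapse = ""), ""),
                   quality = quals, lane = 1L, tile = tile,
                   stringsAsFactors = FALSE)
  attr(df, "encoding") <- enc
  df
}

test_that("reservoir sampling keeps small tiles whole and is deterministic", {
  set.seed(3)
  reads <- rbind(random_reads(500, c(20L, 20L), tile = 1L),
                 random_reads(700, c(20L, 20L), tile = 2L))
  attr(reads, "encoding") <- quality_encoding("sanger")
  s <- suppressWarnings(sample_per_tile(reads, n = 10000L, seed = 9))
  expect_identical(vapply(s$samples, nrow, integer(1)),
                   c(`1` = 500L, `2` = 700L))
  expect_identical(unname(s$n_seen), c(500L, 700L))
  # population exceeding n: exactly n kept, identical set on rerun
  s1 <- suppressWarnings(sample_per_tile(reads, n = 300L, seed = 42))
  s2 <- suppressWarnings(sample_per_tile(reads, n = 300L, seed = 42))
  expect_identical(nrow(s1$samples[["1"]]), 300L)
  expect_identical(s1$samples, s2$samples)
  s3 <- suppressWarnings(sample_per_tile(reads, n = 300L, seed = 43))
  expect_false(identical(s1$samples[["1"]]$id, s3$samples[["1"]]$id))
})

test_that("an undersized per-tile sample triggers the accuracy warning", {
  reads <- random_reads(200, c(10L, 10L))
  expect_warning(sample_per_tile(reads, n = 10000L),
                 "fewer than 5,000 reads")
  # requesting a small sample from a big tile warns too
  big <- random_reads(6000, c(5L, 5L))
  expect_warning(sample_per_tile(big, n = 400L), "5,000")
  expect_silent(sample_per_tile(big, n = 5000L))
})

test_that("reservoir sample is uniform (binomial inclusion frequencies)", {
  set.seed(21)
  pop <- random_reads(10000, c(1L, 1L))
  n <- 100L
  n_rep <- 1000L
  counts <- integer(10000)
  for (r in seq_len(n_rep)) {
    s <- suppressWarnings(sample_per_tile(pop, n = n, seed = 100000L + r))
    idx <- as.integer(sub("^T:1:1:(\\d+):.*", "\\1", s$samples[["1"]]$id))
    counts[idx] <- counts[idx] + 1L
  }
  p0 <- n / 10000
  se <- sqrt(p0 * (1 - p0) / n_rep)
  frac_ok <- mean(abs(counts / n_rep - p0) <= 3 * se)
  expect_gte(frac_ok, 0.99)
})

test_that("matrix cells are per-cell means/variances/extrema of probabilities", {
  enc <- quality_encoding("sanger")
  # p = 0.1 is Q10 = '+'; p ~= 0.3 has no integer Q, use Q5/Q7 instead:
  # decode anchors: '5' = Q20 -> 0.01, '+' = Q10 -> 0.1, '&' = Q5 -> 10^-0.5
  q1 <- encode_quality(c(10, 20), enc)   # p = 0.1, 0.01
  q2 <- encode_quality(c(5, 20), enc)    # p = 10^-0.5, 0.01
  ts <- make_tile_samples(list(`1` = reads_df(c(q1, q2))))
  m <- compute_tile_matrix(ts, variance = TRUE, minmax = TRUE)
  p1 <- c(0.1, 0.01); p2 <- c(10^-0.5, 0.01)
  expect_equal(unname(m$mean_p["1", ]), c(mean(c(p1[1], p2[1])), 0.01))
  expect_equal(unname(m$variance_p["1", ]),
               c(stats::var(c(p1[1], p2[1])), 0))
  expect_equal(unname(m$min_p["1", ]), c(0.1, 0.01))
  expect_equal(unname(m$max_p["1", ]), c(10^-0.5, 0.01))
  expect_identical(unname(m$n_obs["1", ]), c(2L, 2L))

  # identical quality strings everywhere: zero variance, min == mean == max
  same <- make_tile_samples(list(`1` = reads_df(rep("55555", 4))))
  ms <- compute_tile_matrix(same, variance = TRUE, minmax = TRUE)
  expect_true(all(ms$variance_p == 0))
  expect_equal(ms$min_p, ms$mean_p)
  expect_equal(ms$max_p, ms$mean_p)

  # mixed-length reads: denominators are per cell
  mix <- make_tile_samples(list(`1` = reads_df(c("++", "+"))))
  mm <- compute_tile_matrix(mix)
  expect_identical(unname(mm$n_obs["1", ]), c(2L, 1L))
  expect_equal(unname(mm$mean_p["1", ]), c(0.1, 0.1))
})

test_that("statistics are probabilities, never log scores", {
  const <- make_tile_samples(
    list(`1` = reads_df(rep("^^^", 3), enc = quality_encoding("illumina"))),
    enc = quality_encoding("illumina"))
  m <- compute_tile_matrix(const)
  expect_true(all(m$mean_p == 0.001))  # Q30 run -> 0.001 everywhere, not 30
})

test_that("global means are count-weighted over contributing cells", {
  enc <- quality_encoding("sanger")
  t1 <- reads_df(rep(encode_quality(10, enc), 100), tile = 1L)  # p 0.1
  t2 <- reads_df(rep(encode_quality(5, enc), 300), tile = 2L)   # p 10^-0.5
  ts <- make_tile_samples(list(`1` = t1, `2` = t2))
  m <- compute_tile_matrix(ts)
  g <- compute_global(m)
  expect_equal(g$mean_p_per_cycle,
               (100 * 0.1 + 300 * 10^-0.5) / 400)
  # single tile: per-cycle means equal that tile's row
  g1 <- compute_global(compute_tile_matrix(make_tile_samples(list(`1` = t1))))
  expect_equal(g1$mean_p_per_cycle, unname(m$mean_p["1", ]))
  # hand-computed weighted mean with counts 100 and 300 at p 0.1 and 0.2
  expect_equal((100 * 0.1 + 300 * 0.2) / 400, 0.175)

  # brute-force consistency: global mean == mean over all base observations
  set.seed(5)
  rr <- list(`1` = random_reads(40, c(3L, 12L), tile = 1L),
             `2` = random_reads(25, c(3L, 12L), tile = 2L))
  ts2 <- make_tile_samples(rr)
  g2 <- compute_global(compute_tile_matrix(ts2))
  all_p <- unlist(decode_quality(c(rr[["1"]]$quality, rr[["2"]]$quality),
                                 "sanger"))
  expect_equal(g2$global_mean_p, mean(all_p))
  expect_true(g2$global_mean_p >= min(g2$mean_p_per_cycle, na.rm = TRUE) &&
              g2$global_mean_p <= max(g2$mean_p_per_cycle, na.rm = TRUE))
})

test_that("written TSV tables round-trip the matrix values", {
  set.seed(6)
  ts <- make_tile_samples(list(`1` = random_reads(10, c(4L, 4L), tile = 1L),
                               `3` = random_reads(12, c(4L, 4L), tile = 3L)))
  m <- compute_tile_matrix(ts, variance = TRUE)
  g <- compute_global(m)
  prefix <- tempfile()
  files <- write_stats_tables(m, g, prefix)
  qt <- utils::read.delim(paste0(prefix, ".quality.tsv"), check.names = FALSE)
  expect_identical(nrow(qt), 3L)           # tiles 1..3, gap tile 2 included
  expect_identical(as.character(qt$tile), c("1", "2", "3"))
  expect_true(all(is.na(qt[qt$tile == 2, -1])))  # missing tile -> NA row
  expect_equal(unname(as.matrix(qt[, -1])), unname(m$mean_p),
               tolerance = 1e-6)
  ct <- utils::read.delim(paste0(prefix, ".cycles.tsv"))
  expect_equal(ct$mean_p, g$mean_p_per_cycle, tolerance = 1e-6)
})
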