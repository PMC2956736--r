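test_that("analyze_fastq emits all tables, plots and a summary", {
  fc <- sim_flowcell(n_tiles = 5, reads_per_tile = 300, read_length = 20,
                     seed = 23)
  prefix <- tempfile()
  qc <- analyze_fastq(fc$path, output_prefix = prefix, sample_size = 300,
                      encoding = "illumina", variance = TRUE, minmax = TRUE,
                      plots = TRUE, plot_format = "pdf", seed = 1)
  expected <- paste0(prefix, c(".quality.tsv", ".variance.tsv", ".min.tsv",
                               ".max.tsv", ".cycles.tsv", ".hist.tsv",
                               ".heatmap.pdf", ".cycles.pdf", ".hist.pdf",
                               ".summary.txt"))
  expect_true(all(file.exists(expected)))
  expect_true(all(file.size(expected) > 0))
  summary <- readLines(paste0(prefix, ".summary.txt"))
  expect_true(any(grepl("reads\\s+: 1500", summary)))
  expect_true(any(grepl("cycles\\s+: 20", summary)))
  expect_true(any(grepl("global mean P\\(error\\)", summary)))
  # per-tile samples of 300 reads are below the 5,000-read guidance
  expect_true(any(grepl("WARNING.*5,000", summary)))
})

test_that("two input files yield two independent output sets", {
  fc1 <- sim_flowcell(n_tiles = 2, reads_per_tile = 100, read_length = 10,
                      seed = 1)
  fc2 <- sim_flowcell(n_tiles = 3, reads_per_tile = 100, read_length = 12,
                      seed = 2)
  p1 <- tempfile(); p2 <- tempfile()
  res <- analyze_fastq(c(fc1$path, fc2$path), output_prefix = c(p1, p2),
                       sample_size = 100, encoding = "illumina", seed = 1)
  expect_length(res, 2)
  expect_identical(res[[1]]$matrix$cycles, 10L)
  expect_identical(res[[2]]$matrix$cycles, 12L)
  expect_true(file.exists(paste0(p1, ".quality.tsv")))
  expect_true(file.exists(paste0(p2, ".quality.tsv")))
})

test_that("identical configuration reproduces byte-identical tables", {
  fc <- sim_flowcell(n_tiles = 4, reads_per_tile = 500, read_length = 15,
                     seed = 31)
  p1 <- tempfile(); p2 <- tempfile()
  analyze_fastq(fc$path, p1, sample_size = 200, encoding = "illumina",
                seed = 77)
  analyze_fastq(fc$path, p2, sample_size = 200, encoding = "illumina",
                seed = 77)
  for (suffix in c(".quality.tsv", ".cycles.tsv", ".hist.tsv"))
    expect_identical(readLines(paste0(p1, suffix)),
                     readLines(paste0(p2, suffix)))
})

test_that("probability and Phred cutoffs differ only at the rounded boundary", {
  # Q = 13 converts to p = 10^-1.3 ~= 0.0501, slightly looser than p = 0.05:
  # only bases with p in [0.05, 0.0501) change fate
  fc <- sim_flowcell(n_tiles = 2, reads_per_tile = 400, read_length = 30,
                     seed = 41)
  o1 <- tempfile(); o2 <- tempfile()
  s1 <- trim_file(fc$path, o1, threshold_spec(p = 0.05), encoding = "illumina")
  s2 <- trim_file(fc$path, o2, threshold_spec(q = 13), encoding = "illumina")
  expect_gte(s2$bases_out, s1$bases_out)
  # integer qualities never land inside the sliver, so outputs coincide here
  expect_identical(readLines(o1), readLines(o2))
})

test_that("the command-line entry point runs end to end", {
  exe <- system.file("exec", "fqcell", package = "fqcell")
  skip_if(exe == "", "exec script not installed")
  tdir <- tempfile(); dir.create(tdir)
  prefix <- file.path(tdir, "run")
  st <- system2("Rscript", c(exe, "simulate", "--tiles", "3",
                             "--reads-per-tile", "80", "--read-length", "12",
                             "--seed", "5", "-o", prefix),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(paste0(prefix, ".fastq")))
  out <- system2("Rscript", c(exe, "analyze", paste0(prefix, ".fastq"),
                              "--sample-size", "80", "--encoding",
                              "illumina", "--seed", "1"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(paste0(prefix, ".fastq.quality.tsv")))
  out2 <- system2("Rscript", c(exe, "trim", paste0(prefix, ".fastq"),
                               "--phredcutoff", "13", "--encoding",
                               "illumina"),
                  stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(paste0(prefix, ".fastq.trimmed.fastq")))
  # missing input exits non-zero
  bad <- system2("Rscript", c(exe, "trim", file.path(tdir, "ghost.fastq")),
                 stdout = FALSE, stderr = FALSE)
  expect_gt(bad, 0)
})
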