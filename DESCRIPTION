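Package: fqcell
Title: Tile- and Cycle-Level Quality Assessment and Dynamic Trimming of
    Illumina FASTQ Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: At-a-glance quality assessment of Illumina short-read data.
    Reads FASTQ files in the Sanger/Phred+33, Illumina/Phred+64 and
    Solexa+64 quality encodings, samples reads per flow-cell tile, and
    summarizes per-tile per-cycle base-call error probabilities as tables,
    heat maps and line graphs, together with a histogram of maximized read
    lengths. Includes a dynamic trimmer that cuts each read to its longest
    contiguous segment passing an error-probability threshold, and a
    deterministic flow-cell simulator with injectable quality defects for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
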