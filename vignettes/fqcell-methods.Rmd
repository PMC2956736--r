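---
title: "Quality assessment and dynamic trimming of Illumina reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment and dynamic trimming of Illumina reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqcell)
```

## The problem

An Illumina run produces millions of short reads, each base annotated with
a quality score encoding the base caller's estimated probability that the
call is wrong. Quality is not homogeneous: it decays along the read
(chemistry degrades with each cycle), and it varies spatially across the
flow cell — a lane is subdivided into tiles, and tiles fail wholesale, or
only at specific cycles (air bubbles), or along smooth spatial gradients.
Users who outsource sequencing rarely see the vendor's diagnostics, so
fqcell reconstructs them from nothing but the FASTQ file: per-tile
per-cycle error-probability summaries, and a trimmer that salvages the
high-quality core of every read.

## Quality scores and the probability scale

Three ASCII dialects are in circulation. Sanger/Phred+33 and
Illumina 1.3+/Phred+64 both store the Phred score $Q = -10\log_{10} p$
(so $Q=30 \iff p=0.001$; the character `^` under offset 64); the original
Solexa pipeline stored the odds score $Q_s = -10\log_{10}\!\frac{p}{1-p}$,
which reaches $-5$ (ASCII `;` under offset 64) and needs the distinct
inverse $p = 10^{-Q_s/10}/(1+10^{-Q_s/10})$. Detection uses the standard
ASCII-range heuristic over up to the first 10,000 records: any code below
59 implies Phred+33; otherwise a code in 59–63 implies Solexa+64 (legal
only as a negative odds score); otherwise Phred+64 is assumed with a
warning, because a uniformly high-quality Phred+33 file is
indistinguishable — the warning exists precisely because the heuristic
cannot exclude it, and an explicit `encoding` argument always overrides
detection. The two scales agree closely where it matters: the relative
gap between the odds and Phred probabilities at the same numeric score is
$10^{-Q/10}/(1+10^{-Q/10})$ — about 9% at $Q=10$, under 6% from $Q=12$,
vanishing thereafter.

Every downstream statistic is computed and reported on the probability
scale, never as a log score. Means, variances and sums of log scores are
at best unintuitive and at worst misleading; probabilities average
meaningfully. One design consequence: `N` bases get whatever probability
their quality character encodes — the quality string is authoritative, and
no special-casing is applied.

## Tile × cycle statistics

For each tile the package draws a uniform sample without replacement of up
to `sample_size` reads (default 10,000) by single-pass reservoir sampling
(Algorithm R: read $i$ enters a full reservoir with probability $n/i$),
so a file of any size is processed in one streaming pass with memory
proportional to tiles × sample size. One reservoir per tile is reused
across all cycles: a read spans every cycle it covers, so a shared
per-tile sample realizes per-cycle-and-tile sampling without a second
pass; this is our reading of the sampling description, and it is
documented here because an independent sample per cycle would also have
been defensible. Sampling is reproducible given a seed (and the fixed
default chunking of 5,000 records).

Cell $(t, c)$ of the matrix is the arithmetic mean (optionally the
$n-1$-denominator sample variance, minimum and maximum) of the decoded
error probabilities at cycle $c$ over sampled reads of tile $t$ that are
at least $c$ bases long — denominators are per cell, so mixed-length input
is handled correctly. When tile identifiers are integers, the matrix spans
the full integer range between the smallest and largest observed tile, so
a tile that emitted no reads (a total failure) appears as an all-`NA` row
rather than silently vanishing; statistics are never fabricated for empty
cells. Global per-cycle means weight each tile by the number of sampled
reads contributing at that cycle, which makes the global mean identical to
the plain mean over all sampled base observations.

Below roughly 5,000 reads per tile the cell estimates visibly degrade, so
any tile whose sample (requested or available) falls below 5,000 raises a
warning that is also echoed in the run summary. Headers without a
parseable pre-CASAVA `instrument:lane:tile:x:y#index/mate` structure
degrade to a single pseudo-tile 0 with one notice per file — the analysis
still runs, it just loses spatial resolution.

## Maximized read lengths and dynamic trimming

A base *passes* a threshold $p_0$ iff its error probability is strictly
below $p_0$ (equivalently $Q > -10\log_{10} p_0$); a base exactly at the
cutoff fails. Strictness at the boundary is a convention, chosen and
documented so results are exactly reproducible; a Phred-specified cutoff
is converted exactly via $p_0 = 10^{-Q/10}$ with no rounding, so
`--phredcutoff 13` is a slightly looser cutoff (0.0501…) than
`--probcutoff 0.05` — with integer input qualities the two nearly always
coincide. The default is $p_0 = 0.05$: $Q \approx 13$, one expected error
per 20 bases.

Each read's *maximized length* is the length of its longest contiguous run
of passing bases, found by a single linear scan over the run-length
encoding of the pass/fail vector; among equal-length maxima the leftmost
wins, a deterministic tie-break that favours the 5′ end, which is
typically the higher-quality end on this platform. The histogram of these
lengths is computed over **all** reads, not the per-tile sample — it is
cheap in the same streaming pass and it must exactly predict what the
trimmer does. The trimmer slices each read (sequence and quality string
alike) to exactly that segment, through the same shared implementation, so
the histogram mean equals the trim summary's mean trimmed length by
construction, with dropped reads counting as length zero. Reads with no
passing base become zero-length and are dropped by default
(`keep_empty = TRUE` writes them as records with empty lines 2 and 4);
dropping is the default because empty records break many downstream
assemblers. No minimum-length filter beyond that is applied — users
wanting one can post-filter. Trimming at a fixed threshold is idempotent:
every retained base already passes.

## The flow-cell simulator

The simulator is the package's ground truth, not an afterthought: it emits
a FASTQ file plus an exact table of the per-(tile, cycle) mean and
standard deviation of the error probability it generated. Per-base quality
at (tile $t$, cycle $c$) is a deterministic integer
$Q_0(t,c) = \text{baseline}(c) - \text{ushape}(t) - \text{defects}(t,c)$
plus uniform integer jitter on $\{-j,\dots,j\}$ (default $j=2$, enough to
exercise the variance/min/max paths), clamped to the encoding's legal
range; the truth table enumerates the jitter support after clamping, so
recovery tests compare against exact moments. Bases are uniform over
ACGT — base identities drive nothing in scope, only quality strings do.

Defaults mirror the Genome Analyzer II-era run geometry: 100 tiles, 75
cycles, Phred+64 encoding, and a linear Phred decay from 34 to 20 across
the read — linear in $Q$ is exponential in error probability, the
platform's characteristic profile. The default of 1,000 reads per tile is
a desk-scale choice for a realistic but fast fixture; tests that probe
estimator accuracy raise it to 10,000 (and the validation runs described
below use 10 × 2,000 × 75 for trimmer properties, 6 × 10,000 × 40 for
truth recovery, and 100 × 400 × 75 for the end-to-end acceptance run).

Three defect classes reproduce what real runs show: `tile_failure`
(dropout: the tile emits zero reads, surfacing as the all-`NA` matrix
row), `cycle_failure` (a Phred penalty on chosen cycles of one tile,
surfacing as isolated dark cells), and the U-shaped gradient. Tiles are
physically laid out in a U: tiles 1 and $n$ sit together at one flow-cell
end, $n/2$ and $n/2{+}1$ at the other, $n/4$ and $3n/4$ together in the
middle. We model a mid-flow-cell erosion by mapping tile $t$ to its arm
coordinate $u(t) = t - \tfrac12$ (first arm) or $n + \tfrac12 - t$
(return arm) and applying a triangular penalty peaked at the arm midpoint
$n/4$:
$\text{penalty}(t) = A\,\max\!\left(0,\, 1 - \frac{|u(t) - n/4|}{n/4}\right)$.
The half-offset makes the penalty exactly end-symmetric
($\text{penalty}(1) = \text{penalty}(n)$) and maximal at tiles $n/4$ and
$3n/4$ (tied, by the layout's symmetry, with their physical partners
$n/4{+}1$ and $3n/4{+}1$); it is small but not exactly zero at the
flow-cell ends, the price of exact symmetry under a triangular shape.
Defect severities are not calibrated to any particular real run — they
are chosen for testability (clearly separable from the baseline at the
simulated sample sizes), not realism.

What the simulator does **not** emulate: base-call errors correlated with
quality, chastity filtering, optical duplicates, adapter read-through,
cluster-density effects, or realistic quality *distributions* (real
per-cell quality is not uniform-jittered around a deterministic mean). A
green validation suite therefore shows that the statistics, defect
detection and trimming machinery are correct for data whose quality
strings mean what they claim — it does not show that quality strings from
any given pipeline version are well calibrated, which can only be checked
by mapping reads to a reference.

## Numerical and interface choices

* Integer rounding of scores (e.g. $Q \approx 13$ for $p = 0.05$) rounds
  half away from zero.
* Cycles are 1-based everywhere users see them; internal segment
  arithmetic is 0-based half-open, converted at the boundary.
* Tile rows are ordered ascending numerically, preserving the adjacency
  that makes U-shaped gradients legible (tiles $n/4$ and $3n/4$ mid-run).
* Renderers are pure consumers: each plot function draws exactly the
  matrix/vector it is handed and returns it invisibly, so the graphics can
  never disagree with the TSV tables, and a headless installation without
  a PNG device still produces every tabular product. Graphics use base R
  devices (png/pdf/svg by file extension) with a perceptually ordered
  sequential palette and a reserved grey for missing tiles; the colour
  scale defaults to the matrix maximum and can be fixed for cross-run
  comparison.
* The estimator-degradation check (that 500-read sampling is visibly
  worse than 10,000-read sampling) is defined against a fixed absolute
  error band — one standard error at $n = 10{,}000$ — because each
  estimator's own $\pm1$ SE band is hit ~68% of the time regardless of
  $n$.
* `analyze`, `trim` and `simulate` are exposed both as R functions and
  through the thin `exec/fqcell` Rscript wrapper; identical configuration
  (including seed) yields byte-identical TSV output.

## Limitations

CASAVA ≥ 1.8 headers are accepted only via the pseudo-tile fallback (no
tile resolution); paired-end mates are trimmed independently, which can
orphan mates; gzip input is read transparently but is a convenience, not a
contract; and no windowed/mean-quality trimming variants are offered —
only the contiguous-segment definition, because the histogram, the
trimmer and the summary statistics are deliberately one consistent system.
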