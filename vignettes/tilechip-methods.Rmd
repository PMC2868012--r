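---
title: "tilechip: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tilechip: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical methods, the modelling
assumptions and the design decisions behind `tilechip`. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The problem

ChIP-chip measures protein–DNA interaction by hybridizing an
immunoprecipitated chromatin fraction to a tiling microarray: 25-mer
oligonucleotide probes ("reporters") cover the genome at roughly regular
spacing, each with a physical (x, y) position on the array. Three
complications dominate the analysis:

1. **Annotation drift.** Probe annotation files map probe sequences to
   genomic coordinates of the assembly that was current when the array
   was designed. Against a newer assembly some probes match nowhere,
   others at several loci; all downstream positional analysis depends on
   correcting this.
2. **Sequence-driven hybridization bias.** A probe's intensity depends
   on its sequence — most visibly on its GC-content and on which base
   occupies each of the 25 positions — independent of actual binding.
3. **Spatial correlation of signal.** Sheared chromatin fragments are
   longer than the probe spacing, so neighbouring probes measure
   overlapping fragment populations and their scores are serially
   correlated; peak detection must model that correlation or its error
   rates are wrong.

## Coordinates

All coordinates are 0-based, half-open inside the package. External
conventions are converted at the I/O boundary only: GFF3 (1-based
inclusive) on read, WIG (1-based starts) on write. A minus-strand match
covering the forward interval `[s, s + L)` is stored as `start = s`,
`strand = "-"`, keeping a single coordinate system for windowing. The
TSS of a minus-strand feature is its rightmost base (`end − 1`); the
TTS is the opposite end.

## Probe remapping

Exact multi-pattern matching uses an Aho-Corasick automaton built over
the probe sequences (compiled C++: keyword trie, breadth-first failure
links, dense goto function, merged output sets). Each chromosome is
streamed once; every character costs exactly one state transition, which
an instrumentation counter exposes for testing. Design choices:

* **Reverse strand by pattern augmentation.** The pattern set is doubled
  with reverse complements instead of scanning a reverse-complemented
  genome: one pass, half the memory traffic, provably identical results
  (the equivalence is exercised against a naive k-mer oracle in the test
  suite).
* **Any probe with more than one match in total is "multiple".** That
  includes a probe hitting once on each strand, and the edge case of a
  palindromic probe whose single genomic occurrence is hit on both
  strands. The alternative (counting per strand) would silently keep
  probes with ambiguous placement.
* **Probes containing N are excluded up front** and counted as `none`;
  exact matching over an ambiguity code is undefined. In the genome, `N`
  matches nothing and resets the automaton, so matches never span
  assembly gaps.
* **Duplicate probe sequences** each receive the full match list (probes
  are identified by id, not sequence): two probes sharing a sequence
  that occurs once are both unique.
* Matching is exact and case-insensitive (the genome is uppercased on
  read; soft-masking is ignored).

## Normalization

The package's recommended route normalizes an IP array against a
reference (mock) immunoprecipitation, which captures unspecific antibody
binding and shares the sequence biases of the IP:

1. `log2` transform (zeros replaced by the array's smallest positive
   value, counted). Ranking is invariant under monotone transforms, so
   this step matters only for the intensity-scale diagnostics, but it
   keeps the documented scale progression explicit:
   `raw → log2 → percentile → enrichment`.
2. Rank-percentile per array: `percentile = rank / n`, ties averaged.
   The definition with `rank/n` (rather than `(rank − 0.5)/n`) makes the
   maximum exactly 1 and the output lie in `(0, 1]`.
3. Subtraction per (IP, reference) pair; several pairs are averaged per
   probe. Enrichment therefore lies in `[−1, 1]` and is
   scale-free across arrays.

The Buck–Lieb median-rank-percentile summary (median of within-array
ranks across replicates, divided by probe count) is available both as a
replicate combiner and as an alternative enrichment route
(`mrp(IP) − mrp(ref)`).

Missing values propagate as NA with counts; they are excluded from ranks
and from all downstream statistics.

## Hybridization-bias diagnostics

`gc_bias_summary()` groups probes by GC count (N contributes zero) and
summarizes each group with mean and quartiles; quartiles and all other
quantiles in the package use linear interpolation between order
statistics (`stats::quantile` type 7). `position_nucleotide_bias()`
reports the mean intensity of probes carrying base b at position p,
with counts. Probes containing N are excluded from *both* diagnostics —
not just at the N position — so every position's counts sum to the same
probe total and the conservation identity (count-weighted column mean =
global mean) is exact. The diagnostics run on whatever scale their input
has; the before/after-normalization comparison is produced by running
the same functions on raw and on normalized values, with the scale
recorded alongside each table.

## Peak calling

Per-probe enrichment is standardized genome-wide
(`z = (x − mean)/sd`, sample sd; a median/MAD variant is available).
For probe i, the moving-average statistic over the window of `2w + 1`
probes (shrunk at chromosome ends to the m available probes) is

```
S_i  = mean(z in window)
Var(S_i) = [m + 2 · Σ_{k=1}^{m−1} (m − k) ρ_k] / m²
S*_i = S_i / sqrt(Var(S_i))
```

with `ρ_k` the lag-k autocorrelation of z in probe order, treated as 0
beyond `max_lag` (default `2w`; bounded estimation noise). `S*` is
referred to the standard normal upper tail (one-sided: ChIP enrichment
is directional), adjusted by Benjamini–Hochberg across the genome, and
probes with `p_adj ≤ fdr_q` are merged into regions while the gap
between probe *intervals* (`next_start − (prev_start + L)`) is at most
`max_gap`; regions with fewer than `min_probes` probes are dropped. The
reported interval is `[first_start, last_start + L)`.

Numerical guards and choices:

* **Edge policy**: windows shrink at chromosome ends and the variance is
  recomputed for the actual window size, keeping one statistic per probe
  deterministically.
* **Variance floor**: wild autocorrelation estimates can drive the
  bracket non-positive; the variance is floored at `1/(4m²)` with a
  warning rather than producing non-finite statistics.
* **Autocorrelation estimation**: per chromosome when a chromosome has
  at least `10 · max_lag` probes, pooled across chromosomes by
  length-weighted averaging; short chromosomes use the pooled value.
* **Two-pass refinement** (`refine_acf = TRUE` in `cmarrt_run()`):
  enriched regions carry genuine serial correlation that is *signal*,
  not noise; estimating ρ on all probes therefore inflates the variance
  correction and costs power (with a few percent of probes in enriched
  blocks, lag-1 estimates around 0.1 arise from the blocks alone). The
  second pass excises provisionally significant windows (seeds ±w),
  splits each chromosome into the remaining segments, and pools segment
  autocorrelations by length. Under the null the two passes coincide, so
  calibration is unaffected.

Default parameters (`w = 4`, `fdr_q = 0.05`, `max_gap = 250` bp,
`min_probes = 4`) suit a 20–40 bp tiling density where a nucleosomal or
transcription-factor footprint spans several probes; all are exposed as
parameters, not constants.

## Binding profiles and expression correlation

`align_profiles()` assigns each probe a strand-oriented relative
coordinate (`start − anchor` on `+` features, `anchor − start` on `−`),
so "downstream" always points into the transcript, and averages probes
within fixed-width bins over `[−upstream, downstream)`. Probe-to-bin
assignment uses the probe *start* (not midpoint): simple, deterministic,
and documented so users can compare conventions. Windows beyond
chromosome bounds are simply empty bins rather than dropped features,
keeping gene sets comparable.

`quantile_profiles()` computes, per bin, a ladder of quantiles (default
0.05…0.95 in steps of 0.05) — the distributional alternative to a mean
profile. The motivating phenomenon: if a few features carry very strong
anchor-proximal signal, the mean profile shows a peak that the median
profile does not; the quantile ladder makes that distinction visible.
The test suite reproduces this on a mixture in which 5% of features
carry a spike ten times the profile's dynamic range on an otherwise
near-zero enrichment background — note the mean-vs-median divergence is
only expressible when the background level is small against the spike.
`outlier_profiles()` flags features whose non-missing bins lie outside
the central quantile band more than half the time.

Transcript-relative regions (`region_spec`) resolve anchors at TSS
(oriented offset 0) or TTS (offset `length − 1`) plus signed offsets in
transcription-direction bp; features where a region resolves to
non-positive length are skipped and counted. A default region set
(upstream, promoter, early, elongation, termination, downstream) ships
as an editable table in `inst/extdata/regions_default.tsv` rather than
being hard-coded — region boundaries are a scientific choice, not a
constant. `region_expression_correlation()` reports the Pearson
correlation between per-region mean occupancy and expression, joined by
exact feature-id match with unmatched ids counted, requiring at least 3
complete pairs.

## Synthetic data

The generator fabricates every input with known ground truth:

* `generate_genome()`: iid bases at a configurable GC fraction (default
  0.39, a yeast-like composition).
* `plant_probes()`: probes as genome substrings at fixed spacing;
  a configurable fraction duplicated into an extra chromosome (copies
  separated by N runs, making them expected-`multiple`) and a fraction
  replaced by sequences verified absent from the final genome on both
  strands (expected-`none`).
* `simulate_intensities()`: log2-scale model
  `baseline + gc_slope·GC + position effects + peak shift (IP only) +
  N(0, noise_sd²)`, exponentiated to a raw-scale matrix. Reference
  arrays share all sequence biases but no peak signal — the premise of
  mock-IP normalization.
* `simulate_expression()`: `slope · occupancy(region) + noise`.

One master seed fans out to per-component child seeds by fixed offsets,
so adding a generator never perturbs existing fixtures; the whole
fixture regenerates byte-identically from its seed. The default scale —
one 200 kb chromosome, 25-mers every 20 bp (9,999 probes), 2 IP + 1
reference array, 25 planted 300 bp binding sites at +2 log2 shift, 60
genes — runs the full pipeline in a few seconds and is the scale used by
the end-to-end tests; the statistical validations (calibration, power)
use 20,000-probe tracks with 50 replicates.

What the generator deliberately does **not** model: fragment-size
physics (enrichment shoulders decay as boxcars, not triangles),
dye-bias of two-color platforms, spatial array artifacts, and
non-Gaussian intensity noise. Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not performance
on any particular laboratory dataset.

## Pipeline

`run_pipeline()` chains remap → normalize → qc → callpeaks → profile →
correlate from a YAML/list configuration; any suffix of stages can be
rerun from the intermediates of a previous run. Every stage writes its
outputs plus a JSON report (counts, parameters, package version — no
timestamps), and all writers serialize numbers with `%.15g`, so
identical configurations produce byte-identical artifact trees. Schema
violations are reported with field paths (`inputs$probes`). The
`exec/tilechip` script exposes the same stages as shell subcommands.

## Known limitations

* Exact matching only: probes with as little as one mismatch against
  the current assembly are classified `none`, which is the conservative
  choice but discards probes a mismatch-tolerant mapper would rescue.
* The normal-tail p-values for `S*` rest on the standardized-score null
  being approximately Gaussian; heavy-tailed enrichment distributions
  make the calls conservative near the center and optimistic in the
  extreme tail. The robust (median/MAD) standardization mitigates but
  does not remove this.
* Depletion (negative enrichment) is deliberately out of scope; the
  test is one-sided.
* Quantile profiles treat bins independently; no smoothing across bins
  is applied.
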