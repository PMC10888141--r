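---
title: "Methods: NET-seq occupancy and pause-site analysis with netpause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NET-seq occupancy and pause-site analysis with netpause}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpause)
```

## The measurement and its model

Native elongating transcript sequencing (NET-seq) immunoprecipitates the
elongating polymerase and sequences the nascent RNA it carries. The 3' end of
each aligned read — the last incorporated nucleotide (LNT) — marks the
position of the polymerase active site at the moment of capture. Counting
read 3' ends therefore yields a per-nucleotide polymerase occupancy profile:
under steady-state transcription, occupancy at a position is proportional to
the polymerase dwell time there, so high occupancy is read as pausing and low
occupancy as rapid elongation. `netpause` analyzes such profiles over a
single transcription unit, the motivating case being the RNA polymerase I
35S pre-rRNA unit of budding yeast (ETS1–18S–ITS1–5.8S–ITS2–25S–ETS2), with
two strains compared in replicate.

Three properties of Pol I NET-seq shape the pipeline:

* **One template, one strand.** The 35S unit is transcribed in a single
  direction; the template is stored 5'→3' in the direction of transcription
  and no reverse-strand arithmetic exists downstream. Opposite-strand and
  out-of-template reads are filtered with logged counts.
* **Mature-rRNA contamination.** Libraries carry fragments of mature 18S,
  5.8S and 25S rRNA that are indistinguishable from nascent signal inside
  mature regions. The transcribed spacers (ETS1, ITS1, ITS2, ETS2) are the
  only regions with pure nascent signal, so the pause-site and
  distribution-comparison analyses restrict to them.
* **PCR duplication.** Each molecule carries a unique molecular identifier
  (UMI). A read is kept once per molecular key `(start, end, strand, UMI)`;
  the key includes coordinates so that distinct positions sharing a UMI are
  never collapsed, while biological coincidences (same position, different
  UMI) survive.

## The pipeline

For each replicate: deduplicate → count LNTs per position → normalize by the
sample's total count, so each track is a probability vector over template
positions. Replicate agreement is summarized by the pairwise Spearman
correlation matrix of normalized tracks and by a sample-level PCA (samples
as observations, positions as features, centered, unscaled, via singular
value decomposition). Per condition, the position-wise **median** of the
replicate tracks is the working profile (the median of three replicates is
robust to a single outlying library); for an even replicate number the two
central order statistics are averaged.

Differential analysis between the two strains:

* **Per-position Student's t-test.** At every position, a two-sided
  pooled-variance two-sample t-test on the normalized replicate values
  (df = n₁+n₂−2). Positions with `p < α` (default 0.05) are called `up` or
  `down` by the sign of the perturbed-minus-reference mean difference,
  mirroring the green/black significance bar convention of occupancy
  histograms. No multiple-testing correction is applied by default — the
  calls reproduce a raw per-position significance bar — and
  Benjamini–Hochberg is available (`adjust = "BH"`). Welch's form is
  available (`var_equal = FALSE`). The test operates on normalized values,
  not raw counts: the compared quantity is occupancy share, which is what a
  library-size-free comparison requires.
* **Per-spacer Kolmogorov–Smirnov test.** For each spacer region, a
  two-sample KS test compares the *distributions of per-position median
  occupancy values* of the two conditions (each condition contributes
  region-length observations). This is the value-distribution reading of
  "comparing distribution patterns"; a positionally weighted variant (KS on
  cumulative occupancy along the coordinate) is a noted alternative that is
  not implemented. The p-value is asymptotic with the standard two-sample
  effective n; region-length samples make the exact computation unnecessary.
* **Smoothing for display.** A centered boxcar moving average, default 200 nt
  for whole-unit profiles and 75 nt within spacers. At edges the window
  shrinks to the available positions, preserving output length; for even
  windows the center is offset floor((w−1)/2) left, floor(w/2) right. The
  smoother is display-level only; no test consumes smoothed values.

Pause analysis:

* **Pause calling.** Within spacers, positions with nonzero median occupancy
  are ranked by median descending (ties broken by ascending coordinate, so
  selection is deterministic) and the top `q` fraction is selected,
  `ceil(q · n_eligible)` positions with q = 0.025 by default. Zero-median
  positions are excluded from the eligible set: they carry no occupancy
  evidence and would otherwise dilute the quantile. Calling operates on the
  per-condition median profile; per-replicate calling with intersection is a
  conceivable variant not taken, as the median already absorbs
  replicate-level noise.
* **Sequence contexts and the difference logo.** Around each pause LNT a
  W = 21 nt sense-strand window (LNT ± 10) is extracted; windows overrunning
  a template end are dropped and counted. Per condition, a base-frequency
  matrix with a per-cell pseudocount of 0.5 guards against zero columns on
  small pause sets. The difference logo compares the perturbed and reference
  matrices column-wise by Jensen–Shannon divergence in bits
  (JSD = H(m) − (H(p)+H(r))/2, m the mid-distribution; bounded by [0,1] for
  two distributions), and partitions each column's JSD into signed per-base
  heights proportional to |p_b − r_b|, positive meaning perturbed-enriched.
  By construction Σ_b |height_b| = JSD per column, and swapping the two
  matrices negates every height.

## The synthetic generator

`simulate_reads()` produces data with the statistical structure the analysis
assumes, so every stage is testable without sequencing data. The generative
model, per replicate:

1. Per-position 3'-end weight `w(i) = 1 + A·(1 + sin(2πi/period))/2` — a
   smooth periodic baseline emulating the quasi-periodic peak/valley
   occupancy of real Pol I profiles — times `base_pause_boost` at planted
   motif LNTs, times `condition_multiplier` additionally in the perturbed
   condition; normalized to a probability vector.
2. Planted pause motifs are T-runs directly followed by G-runs (default
   T₄G₄, 20 motifs) placed in spacer regions with ≥ 25 nt separation; the
   motif LNT is the last G. Chance background occurrences of the motif string
   are disrupted so the planted set is exact.
3. Read 3' ends are drawn multinomially from the condition's distribution; a
   `contamination_fraction` of reads instead get 3' ends uniform over mature
   positions (contamination maps only to mature rRNA, which is the rationale
   for spacer-restricted analysis). Read starts are 3' end − length + 1
   (uniform length), clipped at 0. Each unique read gets a random UMI, then
   `pcr_duplicate_rate` of the final list are verbatim copies of
   already-emitted reads, which UMI deduplication can provably remove; any
   chance molecular-key collision among unique reads is recorded in the
   truth bookkeeping.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `template_length` | 7000 | ~35S scale (≈6.9 kb) |
| region layout | ETS1 10%, 18S 25%, ITS1 5%, 5.8S 3%, ITS2 7%, 25S 40%, ETS2 10% | approximate 35S proportions; spacers ≈ 32% |
| `period`, `amplitude` | 200 nt, 9 | quasi-periodic baseline with ~10-fold peak-to-trough range, the order of magnitude real profiles span |
| `base_pause_boost`, `condition_multiplier` | 5, 5 | strong-effect fixture: pause recovery near-certain at desk scale |
| `n_replicates`, `reads_per_replicate` | 3, 2×10⁵ | triplicate design; depth at which replicate rank correlation is high |
| `contamination_fraction` | 0.3 | no quantitative estimate exists for mature-rRNA contamination; 0.3 is an arbitrary, documented fixture choice |
| `pcr_duplicate_rate`, `umi_length` | 0.1, 8 | modest duplication, UMI space (4⁸) large enough that collisions are rare and logged |
| `read_length_range` | 20–60 nt | typical aligned NET-seq fragment lengths |

All randomness flows from one integer seed; identical seeds give
byte-identical read sets and written files.

**What the generator does not emulate.** Sequencing errors and quality
scores; alignment artifacts (reads are born aligned); UMI errors (no
directional clustering is needed or implemented); reproducible
position-specific biases (ligation or RT preference); and real pause-site
statistics — real occupancy is heavy-tailed and sequence-driven everywhere,
not a smooth sinusoid plus isolated planted motifs. Tests passing on
synthetic data therefore validate the pipeline's arithmetic, bookkeeping and
statistical calibration, not biological discovery performance on real
libraries.

## Numerical choices and degenerate inputs

* Normalization of an all-zero track returns zeros with a `degenerate` flag
  rather than NaN.
* t-test positions where both groups have zero variance: p = 1 when the
  means are equal, p = 0 otherwise, flagged `degenerate`; positions all-zero
  in both conditions are additionally flagged untestable and excluded from
  calibration summaries.
* A constant track makes Spearman undefined for its pairs; these are
  reported `NA` with a warning rather than an error, so one degenerate
  library does not abort QC.
* JSD values are clamped at 0 against floating-point rounding; per-base
  heights are all zero when a column's JSD is 0.
* The normalization denominator is the total over the analyzed template.
  When upstream processing retains reads outside the unit, totals over the
  whole library differ; this implementation takes the template universe,
  consistent with a per-unit data frame, and the choice is deliberately
  explicit here because either reading of "total counts for the sample" is
  defensible.

## Known limitations

* **Difference logos need separated pause sets.** When both conditions pause
  at largely the same positions — as happens whenever the reference
  condition also has elevated occupancy at the same motifs — the two context
  matrices share most of their contexts and the per-column JSD is small
  (order 0.01 bits at 56-context pause sets), with per-base height signs
  unstable under resampling. The logo is informative when the perturbation
  *repositions* pausing, not when it merely scales shared pauses. The
  synthetic strong-effect fixture, in which the reference condition carries
  the same motif boost at 1/5 strength, sits in exactly this shared-pause
  regime: its perturbed pause set recovers all planted motifs and its
  reference set recovers most of them, so its difference logo is
  correspondingly shallow.
* With three replicates per group on discrete counts, per-position t-test
  p-values are only approximately t-distributed; the null rejection fraction
  at α = 0.05 lands near but not exactly on 0.05 (the suite checks a wide
  calibration band over ≥ 5000 positions).
* The KS p-value is asymptotic and the per-position median values within a
  region are spatially autocorrelated, so it should be read as a descriptive
  comparison of value distributions, not an exact test of independent
  samples.
* Analysis sizes in the test suite and acceptance script (2×10⁵ reads per
  replicate over a 7 kb template) are the package's desk-scale study
  conditions; all stages are linear in reads and positions and run unchanged
  at higher depth.
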