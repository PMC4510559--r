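---
title: "Family-based benchmarking of CNV call sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based benchmarking of CNV call sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvtrio)
```

## Overview

`cnvtrio` benchmarks copy-number variant (CNV) call sets produced by
different detection tools on parent-offspring trios. The guiding idea is
that the overwhelming majority of CNVs in a genome are inherited, so a
genuine offspring CNV should be re-detectable in at least one parent by
the same (or, in a relaxed mode, any) caller. The package standardizes
caller output, measures class-aware coverage overlap between offspring
and parental calls, quantifies the chance component of that validation by
permuting parent-offspring assignments, and compares callers to each
other through asymmetric concordance and multi-tool consensus regions. A
simulator generates trio cohorts and noisy call sets so that every stage
has a ground truth to be tested against.

## The segment model

All callers are reduced to one representation: a data frame of segments
with 0-based half-open coordinates (BED convention on disk and in
memory), an autosome number 1–22, a CN class in {loss, normal, gain},
and provenance (`sample_id`, `tool_id`). Integer CN genotypes 0–6, as
reported by HMM-based callers, collapse onto classes as 0,1 → loss, 2 →
normal, ≥3 → gain: the class records how the diploid copy number
deviates, the genotype by how much. Marker-level output (one CN state per
array marker) becomes segments by taking maximal runs of consecutive
same-state markers per chromosome; a run spans the first marker position
to the last marker position + 1, since markers are points and no
breakpoint information exists between markers. This conservative
convention, and the 0-based half-open coordinate choice, are design
decisions: callers do not agree on a convention, so the package fixes
one and converts on ingest.

`standardize_calls()` then drops normal-class segments (a CNV is a gain
or a loss), restricts to autosomes (sex chromosomes are unsupported by
several callers and excluded from the benchmark), and merges overlapping
*or book-ended* same-class segments within one (sample, tool) into their
union. Merging is required for the validation rule to be well defined
("one or more segments" covering an offspring CNV presumes a computable
union) and makes standardization idempotent. Sub-kilobase calls are
retained: short outliers are part of a caller's output spectrum and
excluding them would silently favor tools that fragment less. Adjacent
same-state marker runs separated by an intervening different-state
marker are never merged; runs separated only by a marker gap are merged
exactly when they touch (book-ended), and remain separate otherwise.

## Interval arithmetic

Every benchmark measure reduces to one primitive: the number of bases of
a query segment covered by the union of a set of subject segments
sharing chromosome, CN class, and possibly sample or tool. Because this
primitive runs inside permutation loops (hundreds of thousands of
query/subject group pairs per replicate set), it is implemented as a
single vectorized sweep: each grouping key is assigned a block offset on
one numeric axis (offset 2^34, far above any base-pair coordinate, with
all encoded values exact in doubles), subjects are merged into maximal
runs by a cumulative-maximum scan over the sorted encoded intervals, and
per-query covered widths are obtained from two binary searches against
the merged runs plus a cumulative-width lookup. Consensus depth uses the
same encoding with a +1/−1 boundary-event sweep. The test suite checks
this arithmetic two independent ways: exhaustive per-base counting on
small random instances (exact equality, including 1000 instances in the
acceptance tests) and `IRanges` reductions/intersections on larger ones.

## Trio validation

For each offspring CNV `c` of length `L`, the package computes the
fraction of its bases covered by the union of same-class segments of the
father and of the mother, **each parent separately** — parents are never
pooled into one union, because "found in at least one parent" is a
per-parent statement and pooling could assemble a spurious union from
two half-covering parents. The CNV is validated when either parent's
coverage passes the threshold (default `t = 0.9`).

Two comparison modes exist deliberately:

* **same-tool** mode requires coverage strictly greater than `t` and
  parental calls from the caller under evaluation;
* **extended** mode admits any caller's parental calls, each (parent,
  tool) union evaluated separately, with comparison `≥ t`.

The strict/non-strict asymmetry mirrors the two phrasings such a rule is
commonly given ("more than 90%" vs "at least 90%"); both comparisons are
arguments, so users can harmonize them. At the default threshold the
difference only matters for coverage fractions exactly equal to 0.9.
Matching is at class granularity (gain/loss), not genotype: requiring
identical integer copy numbers would punish callers for disagreeing on
a quantity (the genotype) that segmentation tools do not even report.
Multiple offspring segments validate independently; no attempt is made
to phase or to match one parental segment to one offspring segment, and
fragmented parental calls count through their union — only covered
sequence matters, not continuity.

Summaries per (sample, tool) report the validated percentage overall and
by class, the deletions-to-duplications ratio (DDR) among validated
CNVs, and the validated cumulative sequence (validated bp / total CNV
bp). Percentages are computed per sample first and then summarized over
samples as median and inter-quartile range, so that samples with many
calls do not dominate.

## The permutation null

Population-frequent CNVs inflate family validation: a common variant is
present in unrelated "parents" too. `pseudo_validation()` estimates this
chance component by rebuilding the pedigree with randomly reassigned
parents and re-running the validation, by default 10 replicates. Three
design choices are exposed because the procedure admits variants:

* **Parent pairs travel as units** (`keep_pairs = TRUE` default): a
  father-mother couple from one trio is reassigned together, preserving
  within-couple CNV correlation; splitting pairs is available.
* **Self-assignment is excluded** (`exclude_self = TRUE` default): the
  permutation is a derangement, since a "random" parent equal to the
  true parent would leak genuine inheritance into the null.
* **Scope** is pooled across populations or within population; the
  within-population null is the more conservative reference when CNV
  frequencies differ between populations.

For loci at allele frequency `f`, a random parent carries with
probability `1 − (1 − f)²` and a random pair validates with probability
`1 − (1 − f)⁴`; the acceptance tests verify the simulated null against
this closed form at `f ∈ {0.05, 0.2, 0.5}` within three Monte Carlo
standard errors. The Monte Carlo variance has two parts — the finite
number of replicate evaluations and the finite simulated parent pool,
whose carrier states are fixed across replicates — and both are included
in that standard error. Reported rates are the median over replicates of
the per-sample median validated percentage (with IQR), plus the pooled
validated fraction over all evaluations, which is the quantity the
closed form predicts. When a seed is given, replicate *i* uses
`seed + i − 1`, making replicate streams reproducible and extensible.

## Concordance, consensus, reference verification

Pairwise concordance is directional: the *predictor*'s calls are
measured against the *verifier*'s same-class call union. Three measures
are reported per ordered pair, each as a median over shared samples:
the per-sample median per-CNV concordant fraction, the percentage of
predictor CNVs whose fraction passes the threshold, and the percentage
of the predictor's cumulated called sequence covered by the verifier.
The median cascade (per CNV → per sample → across samples) is a design
decision; pooling CNVs across samples would weight samples unequally.
Concordance can be restricted to family-validated CNVs by passing the
validation records; the filter applies to both sides.

Consensus regions are defined by base-pair stacking depth: per sample
and class, each tool contributes its merged track (so one tool counts
once per base) and maximal runs with depth ≥ k (default 3) are emitted.
Depth stacking is the unambiguous region-level reading of "called by at
least k tools"; call-level reciprocal-overlap chains would depend on
fragmentation. Consensus sets are nested in k, and summing bases over
k = 1..n_tools reproduces the total merged called bases — both are
tested invariants.

`verify_against_reference()` applies the same coverage rule against an
external variant set; `class_aware = FALSE` supports references without
gain/loss annotation.

## Signal transforms

The marker-level formula layer is exposed for users preprocessing
intensity data: θ = 2/π·arctan of the two-channel ratio, the piecewise
linear B-allele fraction against genotype cluster medians
θ_AA < θ_AB < θ_BB (0 below θ_AA; 0 → 0.5 linearly to θ_AB; 0.5 → 1
linearly to θ_BB; 1 above), and the log R ratio log2(R_obs) −
log2(R_exp). Two choices deserve note. First, the printed form of the θ
ratio (A-channel over B-channel) *increases with the A allele*, while
the BAF interpolation requires θ to increase with the B allele; the
transform is therefore exposed with an `orientation` argument rather
than silently corrected, and the conventional `B_over_A` orientation is
one flag away. Second, the piecewise BAF cases are naturally written
with strict inequalities, leaving the boundaries undefined; the package
assigns boundaries by continuity (the linear branches attain 0, 0.5, 1
there), which the tests check to machine precision.

## Descriptive features

Per (sample, tool): CNV count, deletion and duplication counts, median
and cumulative length (bp), median markers per CNV, median inter-marker
distance, and the DDR. The inter-marker distance of one CNV is defined
as its mean marker gap, length/(n_markers − 1), with CNVs of fewer than
two markers excluded from the median — a per-CNV-then-median reading;
pooling all gaps of a sample is the natural alternative and can be
recovered from the raw calls. DDR with zero duplications is reported as
missing rather than infinity. Quantiles use linear interpolation between
order statistics (R type 7) package-wide, and the MAD uses the 1.4826
consistency constant by default; both are conventions, both
configurable.

## Group comparisons

The HMM vs segmentation comparison takes, per sample, the median of the
statistic over the tools of each class, then compares the paired
per-sample vectors with a two-sided Wilcoxon signed-rank test
(`stats::wilcox.test`; exact for small untied samples, normal
approximation with continuity correction otherwise; the all-zero case
is reported as undefined). Between-class dispersion differences use a
label-permutation test on |MAD_A − MAD_B|: with 6 tools split 3/3 there
are only 20 distinct assignments, so the null is enumerated exhaustively
by default and random sampling (with add-one correction) is a fallback
for larger tool panels. No multiple-testing correction is applied to the
reported p-values; users comparing many features should adjust.

## What the simulator emulates — and what it does not

`simulate_panel()` places CNV loci on the 22 hg19-length autosomes with
log-normal lengths (meanlog log(1e4), sdlog 1: median 10 kb, matching
the kb-scale medians typical of array callers), a loss probability of
ddr/(1+ddr) with default DDR 4 (array callers report 2.8–5.5), and
per-population allele frequencies drawn uniformly from [0.01, 0.2] with
a logit-normal population perturbation (sd 0.5) emulating
population-specific CNV spectra. `simulate_trios()` draws parental
carrier copies Binomial(2, f) — modeling carrier chromosomes makes
Mendelian transmission well defined even though the benchmark itself
only uses presence/absence — transmits each variant copy with
probability 1/2, and appends de novo offspring events at fresh genomic
positions (never on panel loci, so they cannot validate) at a configured
expected fraction, default 0.01 in line with the "up to 99% inherited"
regime. `simulate_calls()` applies a tool profile: per-CNV detection
probability, Gaussian breakpoint jitter (clamped to keep segments
well-formed, falling back to true breakpoints when a draw degenerates),
fragmentation into two sub-segments with a gap, class confusion, and
Poisson false positives along the genome. The default six-profile panel
(three "hmm-like": higher sensitivity, few false positives, no
fragmentation; three "segmentation-like": more false positives and
fragmentation) is calibrated to reproduce the *direction* of the
differences reported for real caller families — more calls and lower
validation for segmentation-type callers — with no claim of quantitative
fidelity to any real tool.

The simulator works at the call level. It does not generate probe
intensities, LRR/BAF tracks along chromosomes, marker-density-dependent
detection, linkage between loci, multi-allelic or overlapping-locus
structure, or genotyping batch effects. Passing tests therefore
demonstrate that the *benchmark machinery* is correct (coverage
arithmetic, validation logic, null calibration, consensus stacking),
not that any particular real caller will achieve similar rates on real
arrays.

## Problem sizes and numerical choices

The test and acceptance workloads use 30 trios × 200 loci × 6 tools
(about 40 000 standardized calls) for the noisy end-to-end checks, 10
permutation replicates for the null, and 1000 random instances for the
per-base oracle equivalence; these sizes give the closed-form
comparisons sub-percent Monte Carlo error while keeping a full run in
tens of seconds. Degenerate inputs are defined behavior: empty call
sets validate vacuously and produce no summary row; a permutation scope
with a single trio is an error (pooled) or skipped with a message
(within-population inside the orchestrator); k above the number of
tools yields an empty consensus with a warning; an empty reference
verifies nothing, with a warning. `de_novo_rate` must be below 0.5
(the appended-events construction targets an expected *fraction*, which
becomes ill-defined beyond that).

## Known limitations

Family-based validation cannot detect unusual inheritance at
multi-allelic CNV loci, treats validation as a proxy for specificity
only (real sensitivity is unmeasurable without ground truth), and
inherits the marker-density dependence of the underlying callers. The
permutation null is an empirical resampling null, not an analytic model
of CNV sharing. Sex chromosomes are out of scope throughout.
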