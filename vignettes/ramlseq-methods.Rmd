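---
title: "Regional methylation from limited-deamination sequencing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional methylation from limited-deamination sequencing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramlseq)
```

## The signal model

A limited heat-alkaline deamination step applied during library preparation
converts a small fraction of 5-methylcytosine (and, indistinguishably,
5-hydroxymethylcytosine) to thymine-read bases, while deaminated
unmethylated cytosines are excised before amplification. The sequencing
readout is therefore an ordinary genome library in which methylation is
encoded as a small excess of C-to-T transitions at methylated CpG sites:

* at a methylated CpG cytosine, each read observation is a transition with
  probability `d` ~ 0.01 (the protocol tunes the deamination duration to
  about 1 percent);
* at any unmethylated cytosine, a transition is seen only at the sequencing
  background `e` ~ 1e-5;
* the ratio `d / e` ~ 1000 is the working signal-to-noise window: large
  enough to quantify methylation regionally, small enough to leave variant
  calling untouched.

At ~1 percent conversion and 30-fold coverage the per-site signal is a
handful of events, so the package never calls methylation per base.
Instead it pools all CpG sites of a region (a CpG island, promoter, exon,
or window) into a *regional aggregated methylation level* (RAML). With
about 100 combined CpG sites at 30-fold coverage a region carries an
expected ~30 deamination events, which is the scale at which regional
estimates become stable — hence the default of 100 CpG per simulated
region and the `low_confidence` flag on estimates pooled from fewer sites.

### Read orientation

The deamination signature is read-oriented: it appears as C-to-T at
reference-C positions in Read1 and as G-to-A at reference-G positions in
Read2 (the bottom-strand cytosine seen in reverse complement), while the
mirror channels (Read2 C-to-T, Read1 G-to-A) carry only symmetric
sequencing error. Counting therefore uses the two signal channels, pooled
per region by default, and `compute_imbalance()` uses the Read1-minus-Read2
C-to-T excess to isolate deamination from shared error. The simulator
implements this signature directly: per fragment, deamination events are
drawn independently for the top-strand cytosine (rendered in Read1) and
the bottom-strand cytosine (rendered in Read2). This is a phenomenological
model of the protocol's orientation asymmetry, chosen because it
reproduces exactly the channels the counting scheme reads; it does not
attempt to model the underlying strand chemistry.

## Counting and its filters

`count_transitions()` walks each alignment against the reference. At a
reference C (Read1) an observed C increments `total`, an observed T
increments `error` and `total`; other bases are sequencing errors out of
the C/T channel and are excluded from the denominator, so `total` is the
count of cytosine-informative observations (C + C-to-T). Context is
assigned on the cytosine's own strand: the CpN partner of a Read1
reference-C is the base at position + 1; for a Read2 reference-G it is the
complement of the base at position - 1. The trinucleotide upstream base is
recorded the same way (the ApCpG context shows slightly depressed
conversion in practice; stratified calibration is possible by filtering
the site table on `upstream`).

Default filters (all configurable via `counting_filters()`):

| filter | default | reason |
|---|---|---|
| `min_mapq` | 10 | mapping-quality cutoff that maximises methylation-call accuracy for short-read aligners |
| `min_baseq` | 30 | drops low-confidence base calls; also how overlap-masked Read2 bases (Q0) are excluded |
| `exclude_cycles` | 2 head, 2 tail | the first and last two sequencing cycles under-report conversion at fully methylated sites |
| `snp_mask` | none | genuine C>T variants masquerade as full conversion; positions from a depth-filtered VCF (DP >= 5) are removed |
| indel adjacency | always | bases aligned next to an insertion or deletion are skipped |

Mate overlaps would count the same molecule position twice.
`trim_overlap_sam()` masks the overlapping Read2 bases to Q0 (below any
counting threshold) rather than rewriting CIGARs: the SAM stays valid, the
operation is idempotent, and the decision remains local to counting.
Trimming is always taken from Read2, never Read1.

## Calibration and RAML

Because run-to-run conversion varies, every dataset is calibrated
internally from two kinds of control observations:

* `estimate_R0()`: the pooled C-to-T rate at **non-CpG cytosines** inside
  stably hypermethylated control regions — unmethylated by assumption, so
  this is the pure background;
* `estimate_R100()`: the pooled CpG rate in those control regions,
  adjusted for their true methylation `WM` (their mean methylation across
  public WGBS compendia, usually slightly below 1):
  `R100 = sum(Error_n / WM_n) / sum(Total_n)`. Only the numerator is
  WM-adjusted, matching the published form of the estimator.

A regional estimate is then the clamped linear interpolation

```
Meth = min(1, max(0, (Error - Total * R0) / ((R100 - R0) * Total)))
```

with a binomial standard error `sqrt(R(1-R)/Total) / (R100 - R0)`
attached. The division by `R100 - R0` ~ 0.01 is worth pausing on: it
amplifies counting noise roughly 100-fold from the rate scale to the
methylation scale. This is intrinsic to the low-conversion design and is
why estimates need large pooled totals and why fully methylated regions
show the widest spread.

## Benchmarking across technologies and the linear model

To compare against (or integrate) WGBS, enzymatic-conversion and Nanopore
measurements, per-region levels from three methods are reduced to a
benchmarked consensus `BM`: coverage-derived weights
(`method_weights()`: per-method normalisation over regions, then
per-region renormalisation), then the weighted average of the **two
closest** of the three measurements (`benchmark_methylation()`), which
discounts the one outlying technology per region. Regions first pass
per-method coverage minima (50 for the two short-read methods, 20 for
Nanopore, via `coverage_pass()`).

`bin_and_pool()` groups regions into 10 equal-width methylation bins
(membership `[LB, UB)`, final bin closed so BM = 1 is kept; a strict-
inequality reading would silently drop boundary values) and pools counts
*before* dividing, so each bin's rate is coverage-weighted.
`fit_linear_model()` then fits `R_k = alpha + beta * ABM_k` by OLS; on
data generated under the signal model the fit recovers `beta` ~ `d` = 0.01
and `alpha` ~ `e` with R-squared above 0.99, which is what licenses the
two-point internal calibration above. Ties in the closest-pair argmin go
to the pair with the larger combined weight; both choices are
deterministic and documented.

`quadrant_consistency()` complements correlation: both axes are cut at
0.3 and 0.7 (the conventional hypomethylation boundary; configurable) and
the statistic is the fraction of regions in the same cell on both axes.

## Differential methylation

Replicates within a condition are pooled like the cross-technology
benchmark: closest pair of the three per-region estimates, weighted
average, totals summed (`pool_replicates()`; ties go to the pair holding
the highest-coverage replicate). Between two conditions,
`dmr_z_test()` asks whether the difference exceeds a margin `delta` = 0.1
in either direction, using one-sided two-proportion z-statistics with the
coverage-weighted pooled proportion `mean_bm()` in the variance and
`p = min(1 - phi(z_greater), phi(z_less))`. The variance term carries a
square root — a standard error, as the use of the normal CDF requires.
No multiple-testing correction is applied by default (`adjust = "BH"` is
available). `classify_confusion()` scores calls against an external
reference label set over an explicit evaluable filter.

A known limitation, visible in the simulations: the z-test takes the
pooled `Total` as a binomial denominator, but a calibrated RAML is not a
binomial proportion of `Total` — its true variance is larger by the
calibration amplification, plus any molecule-pool resampling between
replicates. The test is therefore anticonservative for borderline
differences at moderate depth, and conservative mainly through its margin.
Deep pooled totals (tens of thousands) restore its nominal behaviour;
intermediate methylation differences near the margin are where both false
negatives and the occasional false positive concentrate.

## The simulator: what it emulates, and what it does not

`simulate_reference()` builds one chromosome of regions with exactly
`cpg_per_region` CpG dinucleotides separated by {A, C, T} spacers —
spacers contribute the non-CpG cytosines needed for background
calibration and, by construction, no accidental CpG. Per-site methylation
status is Bernoulli with the region's assigned level; control regions are
appended fully methylated with a WM table. Two observation paths share
one schema: `simulate_pileup_counts()` draws per-site, per-channel
binomial counts (fast; most tests), and `simulate_sam_reads()` emits
proper overlapping read pairs with constant Q37 qualities (optionally
degraded read ends), exercising trimming, filtering and counting end to
end. `simulate_paired_conditions()` shifts a designated fraction of
analysis regions — never the control regions, which anchor calibration —
and resamples site status per replicate.

Defaults are the study conditions of the protocol: `d` = 0.01,
`e` = 1e-5, read length 100, fragment length 160 (40 bp mate overlap),
100 CpG per region, seeds mandatory. Problem sizes used by the test suite
and the acceptance script — 1000 pileup replicates for the expected-event
check, ~1.4e8 observations for the fold-ratio check, 500 regions at
50-fold for the regression — were chosen so each statistic's Monte-Carlo
error sits well inside its assertion band while the whole suite runs in
well under a minute of simulation time.

What the simulator does **not** emulate: real genome composition and
mappability (alignment is taken as given), PCR duplicates, quality-score
error profiles beyond the flat model, molecule-shared deamination between
overlapping mates (events are drawn per mate, so overlap trimming is
exercised positionally, not chemically), and 5hmC as a distinct signal
(flagged in the truth, identical in the observations — the chemistry does
not discriminate). Passing tests therefore demonstrate the correctness of
the counting, calibration and testing machinery under the stated signal
model, not robustness to alignment artifacts in real data.

## Numerical conventions

All internal coordinates are 0-based half-open; conversion happens only at
format boundaries (VCF and SAM text are 1-based). Region aggregation uses
interval overlap of the cytosine position (strand-specific, so the C and
G of one CpG are two sites). Rates of uncovered regions are `NA`, never 0.
Degenerate inputs are handled explicitly: constant-rate bins fit with zero
slope and zero R-squared, zero-variance DMR regions are flagged
`untestable` rather than producing infinite statistics, and calibration
with `R100 <= R0` is an error rather than a sign flip.
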