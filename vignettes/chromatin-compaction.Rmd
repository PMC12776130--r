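---
title: "Measuring sub-kilobase chromatin compaction with chromfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sub-kilobase chromatin compaction with chromfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromfold)
```

## The measurement problem

Chromatin fiber compaction at the scale of a few nucleosomes — the scale at
which regulatory proteins encounter DNA — leaves quantitative fingerprints in
two orthogonal sequencing readouts:

* **Correlated-cleavage fragment length distributions (FLDs).** Ionizing
  radiation produces pairs of single-stranded breaks at points where DNA
  passes close to itself, so the lengths of the released ssDNA fragments
  report three-dimensional proximity. In human fibroblasts the FLD carries a
  quartet of peaks: ~78 nt (one DNA wrap around a nucleosome), ~180 nt (a
  full nucleosome unit) and ~270 / ~360 nt (contacts between the DNA gyres
  of stacked alternating nucleosomes). The height of the fourth peak tracks
  zig-zag stacking and hence fiber compaction; its position tracks
  nucleosome spacing.
* **Short-range proximity-ligation contacts.** Below ~1.5 kb, Micro-C
  contact probability versus genomic distance is a comb with maxima at
  integer multiples of the nucleosome repeat length (NRL). The mean spacing
  of the comb estimates the NRL, and the relative heights of odd versus even
  steps — the odd/even ratio `(h_{N+3} + h_{N+5}) / (h_{N+2} + h_{N+4})` —
  quantify the zig-zag (two-start) stacking signature: two-start folding
  brings nucleosome N close to N+2, producing a staircase in which odd and
  even peaks pair up rather than decaying smoothly.

A third, coarser readout — per-bin Hi-C compartment scores — is consumed,
not computed, by this package: scores are oriented against an active-mark
reference track and per-bin shifts between conditions are classified.

Because all three analyses operate downstream of alignment, every input is a
small text table (length histograms, `.pairs` records, BED intervals,
bedGraph tracks). The package ships a synthetic-data generator that emulates
the statistical structure of each input, which is how the whole chain is
tested.

## The FLD processing chain

Raw fragment-length counts are not comparable across samples: library
preparation and PCR impose a sample-specific, length-dependent capture
loss, and sequencing depth varies. The chain applied by this package is:

1. **Spike-in depth scaling** (`spikein_scale()`). Each sample carries an
   exogenous MNase-ladder spike-in of known pre-sequencing length
   distribution. Within a biological replicate, every sample's counts are
   multiplied by `REF_b / D_i`, where `D_i` is that sample's spike-in read
   depth and `REF_b` the mean spike-in depth over the technical replicates.
   After scaling, all spike-in totals equal `REF_b`; the operation is
   idempotent.
2. **Length-bias fit** (`fit_length_bias()`). The log-ratio of the
   post-sequencing to pre-sequencing spike-in distributions is fitted by
   ordinary least squares on lengths ≥ 300 nt, where the ladder's own
   structure has decayed, giving `a·exp(k·(L − 300))`. The fit is
   extrapolated back over the full grid. Weighting by counts is deliberately
   omitted: the fit region has broadly comparable counts across rungs and
   OLS keeps the estimator transparent.
3. **Correction, interpolation, smoothing, normalization**
   (`correct_normalize()`). Counts are divided by the bias model, linearly
   interpolated onto a common 55–450 nt integer grid, smoothed with a
   centered rolling mean (10 nt default; 5 nt for spike-in diagnostics,
   30 nt for sparse region subsets; windows shrink at the grid boundaries),
   and divided by the value at 180 nt so the mononucleosome signal is
   exactly 1. Normalizing to the *value at* 180 nt rather than the local
   peak maximum is the default because it is deterministic under noise; a
   `peak_max` mode (maximum within ±40 nt of 180) is available.
4. **gDNA contrast** (`gdna_ratio()`). Dividing the cell curve by the
   matched irradiated genomic-DNA curve cancels the uncorrelated-break
   background. A pseudocount of `1e-6` of the larger curve maximum keeps
   ratios finite without masking bins and makes the ratio invariant to
   common rescaling of both inputs.
5. **Replicate aggregation and comparison** (`aggregate_condition()`,
   `compare_conditions()`). Condition means carry a Student t interval,
   `mean ± t_{0.975, n−1}·SD/√n`. Between conditions, a two-sided Welch
   t-test is run at every grid position across the smoothed replicate
   curves, and only maximal contiguous significant stretches of ≥ 5 nt are
   reported. The run filter (rather than a test on 5-nt-windowed means) is
   the default reading of "significance within 5 nt windows"; the per-bp
   test plus run filter is simpler, and its null behavior is checked
   directly (below).

Fragment and pair subsetting by region sets uses one rule everywhere: a
record is retained iff its full genomic span overlaps at least 1 bp of any
region, with 0-based half-open coordinates on both sides. Subsetting over a
disjoint exhaustive partition therefore conserves totals up to fragments
that straddle partition boundaries (which match both flanking parts).

## Short-range contact analysis

Ligation pairs are classified by strand orientation on position-ordered
records: `+/−` inward, `−/+` outward, same-strand tandem. Orientation
matters because read positions mark nucleosome entry or exit points, so
inward and outward distances include or exclude the wrapped-nucleosome
lengths; the generator models this as a ±147 bp offset. NRL and the
odd/even ratio are computed from the **tandem** curve by default, precisely
because tandem distances carry no such offset.

Peaks are called where the second difference of the smoothed curve is
negative: each maximal negative-curvature run contributes the position of
the curve maximum within it (`call_curve_peaks()`). Two filters suppress
noise artifacts:

* a **height floor**, by default the larger of the smoothed-curve median
  (tracking the baseline of ratio-style curves, which sit near 1 between
  peaks) and 5% of the curve maximum (suppressing counting-noise bumps on
  the near-zero valleys of sparse distance histograms — the median alone is
  useless there because more than half of all bins *are* valley bins);
* a **minimum separation** of three smoothing windows, keeping the higher
  of any two closer candidates. Counting noise flips the sign of the second
  difference near the inflection points of a genuine bump, fragmenting it
  into several runs; the separation rule (the distance filter familiar from
  standard peak finders) collapses these to one call. Real spacings in this
  domain (≥ ~90 nt between FLD quartet peaks, ≥ ~160 bp between contact
  comb peaks) are far above the default 45-unit separation.

Maxima falling where the smoothing window is truncated (the first and last
window of the curve) are not called, since curvature is undefined there.
Step labels N+1, N+2, … are assigned from the mean peak spacing;
`estimate_nrl()` is the mean of successive peak distances, which on an even
comb equals both the comb spacing and the least-squares slope of position
against step index. Peak "height" defaults to the smoothed-curve value at
the called maximum; an integrated ±window mode is available
(`odd_even_ratio(..., window = 10)`).

## What the generator emulates — and what it does not

`simulate_ricc_fragments()` draws lengths from a Gaussian-mixture quartet
(centers 78/180/270/360 nt, SD 12 nt) over a uniform 50–700 nt background of
uncorrelated breaks, then thins with probability `exp(−k·L)`. The uniform
background is a deliberate maximal-ignorance choice: no length law for
random radiation breaks is established, and a flat background is exactly
what the gDNA-ratio step is designed to cancel. `simulate_spikein()` returns
the analytic ladder mixture (the "known before sequencing" distribution,
default rung spacing 154 nt — a typical fission-yeast repeat) together with
a sampled, thinned realization. `simulate_microc_pairs()` draws distances
from the truncated comb `w_n ∝ n^{−γ}(1 + A·[n odd, n ≥ 3])` with Gaussian
peaks at `n·NRL`; the odd-step amplitude `A` is the zig-zag dial, and
orientation proportions default to equal thirds (the real mixture is not
documented). `simulate_cscore_tracks()` builds reference tracks through a
Gaussian copula so the realized rank correlation matches its target.
Relative quartet-peak weights are free parameters (no quantitative model for
them exists); the defaults split mass equally.

These are phenomenological models. They contain no 3D fiber geometry, no
radical-diffusion physics, no sequence or GC bias, no MNase accessibility
bias, and no read-level artifacts. Passing tests therefore demonstrate that
the *processing chain* recovers the structural constants it was built to
measure from data with the assumed statistical structure — not that those
assumptions exhaust real data.

## Numerical choices and calibration checks

* **Desk-scale problem sizes.** The recovery analyses use 2×10⁵ fragments
  per FLD sample (with matched gDNA and spike-in sets, bias k = 0.005/nt,
  50% background) and 5×10⁵ ligation pairs per contact curve; at these
  depths the quartet centers are recovered within a few nt and the NRL
  within a fraction of a bp at repeats 163/186/212 bp.
* **Null calibration.** With both conditions drawn from one generator
  configuration (4 vs 4 replicates, 50 trials), the per-position significant
  fraction stays within three standard errors of α = 0.05 and the median
  number of ≥ 5 nt runs is 0. Smoothing correlates neighboring positions,
  so occasional runs do arise in single trials; the median-zero behavior is
  what the run filter is for.
* **Zig-zag monotonicity.** The odd/even ratio is checked at
  `A ∈ {0, 0.25, 0.5}` with a near-flat step decay (γ = 0.1). With the
  steeper default decay γ = 1.2 the unmodulated ratio is analytically
  `(3^{−γ} + 5^{−γ})/(2^{−γ} + 4^{−γ}) ≈ 0.66`, not 1 — the power-law trend
  and the zig-zag signature are confounded in the raw ratio. The weak-decay
  setting isolates the zig-zag dial: the ratio is ≈ 0.97 at `A = 0` and
  strictly increases with `A`.
* **Degenerate inputs.** Zero-variance positions in the Welch test return
  p = 1 when means agree; zero gDNA bins are handled by the pseudocount;
  a curve with no concave stretch yields an empty peak set (not an error);
  single-replicate aggregation flags its undefined interval; chromosomes
  with fewer than 5 bins are an error in orientation, and an exactly-zero
  compartment score counts as the A side in shift labels.
* **Compartment thresholds.** The shift threshold defaults to 0.25 in
  c-score units, with 0.2 also in published use for the same statistic —
  both are exposed via `threshold`. Chromosome exclusion uses the Spearman
  t-approximation p-value at 0.01; excluded chromosomes are dropped from
  the shift census and listed in the orientation report.

## Worked example

```{r example}
# one condition's worth of synthetic data, processed end to end
cell <- histogram_from_fragments(
  simulate_ricc_fragments(fld_sim_config(depth = 2e5, bias_rate = 0.005,
                                         seed = 1)))
gdna <- histogram_from_fragments(
  simulate_gdna_fragments(fld_sim_config(depth = 2e5, bias_rate = 0.005,
                                         seed = 2)),
  source = "gdna")
spike <- simulate_spikein(spike_sim_config(depth = 2e5, bias_rate = 0.005,
                                           seed = 3))
bias <- fit_length_bias(spike$post, spike$pre)
bias
ratio <- gdna_ratio(correct_normalize(cell, bias),
                    correct_normalize(gdna, bias))
call_curve_peaks(ratio$grid, ratio$values, smooth_window = 9)

# tandem contact curve -> NRL and zig-zag ratio
pairs <- simulate_microc_pairs(
  microc_sim_config(nrl = 186, depth = 2e5, zigzag_amplitude = 0.4,
                    decay_exponent = 0.1, seed = 4))
zigzag_summary(contact_curve(pairs, "tandem"))
```

## Known limitations

* The generators place fragments and pairs uniformly; positional structure
  (phasing, domains) is absent, so region subsetting is exercised only as a
  counting operation.
* The exponential bias model is single-parameter; real capture bias can be
  non-log-linear at the extremes of the length range.
* Peak-height comparisons across conditions inherit the normalization
  choice (value at 180 nt); curves whose mononucleosome peak shifts
  materially away from 180 nt should use `norm_mode = "peak_max"`.
* The odd/even ratio confounds step-decay shape with zig-zag amplitude; it
  is a contrast statistic between matched conditions, not an absolute
  measure of fiber geometry.
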