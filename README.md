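# chromfold

Direct, quantitative readouts of chromatin fiber compaction at the
sub-kilobase scale — the scale of a few nucleosomes, where linker histone
H1 and histone marks shape the accessibility of regulatory DNA.

`chromfold` is for epigenomics analysts working downstream of alignment. It
implements three complementary analyses as composable R functions:

1. **Correlated-cleavage fragment length distributions (FLDs).** Ionizing
   radiation cleaves DNA in pairs at self-contact points; the released
   single-stranded fragment lengths report 3D proximity. Fibroblast FLDs
   carry a quartet of peaks at ~78 nt (one nucleosomal DNA wrap), ~180 nt
   (a full nucleosome unit) and ~270/~360 nt (stacked-gyre contacts of
   alternating nucleosomes). The package runs the full comparative chain:
   spike-in depth scaling (`REF_b / D_i`), exponential length-bias fit on
   a spike-in ladder (`a·e^{k(L-300)}`, extrapolated back), correction,
   interpolation to a common 55–450 nt grid, 10 nt rolling-mean smoothing,
   normalization to the mononucleosome signal at 180 nt, cell/gDNA
   background ratios, Student-*t* replicate intervals
   (`mean ± t₀.₉₇₅,ₙ₋₁·SD/√n`) and per-position Welch tests with a ≥ 5 nt
   significant-run filter.
2. **Short-range Micro-C contacts (< 1.5 kb).** Cis ligation pairs are
   split by strand orientation (`+/−` inward, `−/+` outward, same-strand
   tandem), turned into contact probability curves, and summarized by
   second-derivative peak calls: the nucleosome repeat length (NRL) is the
   mean spacing of the N+k contact peaks, and the odd/even ratio
   `(h_{N+3}+h_{N+5})/(h_{N+2}+h_{N+4})` quantifies the zig-zag
   (two-start) stacking signature.
3. **Hi-C compartment scores.** Per-chromosome c-scores are oriented
   against an active-mark reference by Spearman correlation (flip when
   negative, exclude when p ≥ 0.01) and per-bin shifts between conditions
   are classified (`B_to_A`, `A_to_B`, `A_shifted`, `B_shifted`, `stable`
   at |Δc-score| ≤ 0.25).

A first-class synthetic-data generator (`simulate_ricc_fragments()`,
`simulate_spikein()`, `simulate_microc_pairs()`, `simulate_state_regions()`,
`simulate_cscore_tracks()`) emulates every input class with the statistical
structure these analyses assume, so the entire chain is testable at desk
scale. Parsers/writers cover the formats involved: histogram TSVs
(including Picard CollectInsertSizeMetrics logs), 4DN `.pairs`,
BED/gappedPeak, bedGraph, and curve TSVs with JSON provenance sidecars.

## Worked example

Simulate one fibroblast-like condition and process it end to end:

```r
library(chromfold)

cell <- histogram_from_fragments(
  simulate_ricc_fragments(fld_sim_config(depth = 2e5, bias_rate = 0.005,
                                         seed = 1)))
gdna <- histogram_from_fragments(
  simulate_gdna_fragments(fld_sim_config(depth = 2e5, bias_rate = 0.005,
                                         seed = 2)),
  source = "gdna")
spike <- simulate_spikein(spike_sim_config(depth = 2e5, bias_rate = 0.005,
                                           seed = 3))

(bias <- fit_length_bias(spike$post, spike$pre))
#> <bias_model> a = 0.2233, k = -0.004847 /nt (fit on L >= 300)

ratio <- gdna_ratio(correct_normalize(cell, bias),
                    correct_normalize(gdna, bias))
call_curve_peaks(ratio$grid, ratio$values, smooth_window = 9)
#> <peak_set> 4 peak(s)
#>  position height step
#>        77 1.0330   NA
#>       181 0.9995   NA
#>       269 1.0320   NA
#>       359 1.1030   NA
```

The fitted decay rate recovers the simulated capture bias (k = 0.005/nt
was injected), and the four ratio-curve peaks land on the injected quartet
centers 78/180/270/360 nt. Peak heights are on the normalized scale where
the mononucleosome signal is 1; the background ratio is flat near its
baseline between peaks.

The contact-curve side, with a zig-zag amplitude of 0.4 boosting odd steps:

```r
pairs <- simulate_microc_pairs(
  microc_sim_config(nrl = 186, depth = 2e5, zigzag_amplitude = 0.4,
                    decay_exponent = 0.1, seed = 4))
zigzag_summary(contact_curve(pairs, "tandem"))
#> <zigzag_summary> NRL = 186.3 bp, odd/even ratio = 1.365 (7 peaks)
```

The estimator recovers the simulated 186 bp repeat length, and the
odd/even ratio rises above 1 as expected when alternating-nucleosome
stacking is present (it sits near 1 for an unmodulated comb).

See the vignette (`vignettes/chromatin-compaction.Rmd`) for the model
assumptions, parameter defaults and numerical choices.

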