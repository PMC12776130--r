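# Properties of the synthetic-data generators: seed determinism, the
# statistical structure each generator promises, and thinning bookkeeping.

test_that("every generator is deterministic given its config and seed", {
  fcfg <- fld_sim_config(depth = 2000, bias_rate = 0.004, seed = 5)
  expect_identical(simulate_ricc_fragments(fcfg), simulate_ricc_fragments(fcfg))
  expect_identical(simulate_gdna_fragments(fcfg), simulate_gdna_fragments(fcfg))

  scfg <- spike_sim_config(depth = 2000, bias_rate = 0.004, seed = 6)
  expect_identical(simulate_spikein(scfg), simulate_spikein(scfg))

  mcfg <- microc_sim_config(depth = 2000, seed = 7)
  expect_identical(simulate_microc_pairs(mcfg), simulate_microc_pairs(mcfg))

  tr <- simulate_cscore_tracks(50, 0.8, seed = 8)
  expect_identical(tr, simulate_cscore_tracks(50, 0.8, seed = 8))

  # seeding does not clobber the caller's RNG stream
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_ricc_fragments(fcfg))
  expect_identical(runif(1), before)
})

test_that("background-only fragment lengths are uniform on the background range", {
  cfg <- fld_sim_config(peak_weights = rep(0, 4), background_fraction = 1,
                        depth = 1e5, seed = 42)
  frags <- simulate_ricc_fragments(cfg)
  expect_equal(nrow(frags), 1e5)
  # GOF against uniform on interior lengths (rounding halves the edge bins)
  len <- frags$length[frags$length >= 51 & frags$length <= 699]
  bins <- cut(len, breaks = seq(50.5, 699.5, length.out = 21))
  gof <- suppressWarnings(stats::chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.01)
})

test_that("default quartet mixture puts empirical modes at the configured centers", {
  cfg <- fld_sim_config(bias_rate = 0, depth = 2e5, seed = 31)
  frags <- simulate_ricc_fragments(cfg)
  modes <- c(window_mode(frags$length, 60, 100),
             window_mode(frags$length, 160, 200),
             window_mode(frags$length, 250, 290),
             window_mode(frags$length, 340, 380))
  expect_true(all(abs(modes - c(78, 180, 270, 360)) <= 4))
})

test_that("length-bias thinning acceptance rate matches the analytic expectation", {
  k <- 0.006
  cfg <- fld_sim_config(bias_rate = k, depth = 1e5, seed = 17)
  frags <- simulate_ricc_fragments(cfg)
  # E[exp(-kL)] over the mixture: Gaussian components via the normal MGF,
  # uniform background in closed form
  p_gauss <- exp(-k * cfg$peak_centers + k^2 * cfg$peak_widths^2 / 2)
  a <- cfg$background_range[1]
  b <- cfg$background_range[2]
  p_unif <- (exp(-k * a) - exp(-k * b)) / (k * (b - a))
  p <- sum(cfg$peak_weights * p_gauss) + cfg$background_fraction * p_unif
  expect_lt(abs(nrow(frags) - cfg$depth * p),
            3 * sqrt(cfg$depth * p * (1 - p)))
})

test_that("unbiased background-free FLD converges to the analytic mixture with depth", {
  max_dev <- vapply(c(2e4, 2e5), function(depth) {
    cfg <- fld_sim_config(peak_weights = c(0.25, 0.25, 0.25, 0.25),
                          background_fraction = 0, depth = depth, seed = 91)
    frags <- simulate_ricc_fragments(cfg)
    support <- 40:420
    emp <- tabulate(frags$length, nbins = 420)[support] / nrow(frags)
    ana <- rowSums(vapply(1:4, function(j) {
      cfg$peak_weights[j] * dnorm(support, cfg$peak_centers[j],
                                  cfg$peak_widths[j])
    }, numeric(length(support))))
    max(abs(emp - ana))
  }, numeric(1))
  expect_lt(max_dev[2], max_dev[1])
  expect_lt(max_dev[2], 1e-3)
})

test_that("gDNA control carries no contact peaks and matches the cell background", {
  cfg <- fld_sim_config(depth = 1e5, seed = 3)
  gdna <- simulate_gdna_fragments(cfg)
  tab <- rolling_mean(tabulate(gdna$length, nbins = 700), 10)
  pk <- call_curve_peaks(55:450, tab[55:450], smooth_window = 10)
  # no called mode rises meaningfully above the flat background
  expect_true(length(pk$positions) == 0 ||
                max(pk$heights) < 1.25 * median(tab[55:450]))
})

test_that("spike-in pre/post pair recovers the injected exponential bias", {
  # unbiased ladder: fitted slope indistinguishable from zero
  s0 <- simulate_spikein(spike_sim_config(depth = 1e6, bias_rate = 0, seed = 4))
  expect_lt(abs(fit_length_bias(s0$post, s0$pre)$rate), 1e-3)
  # biased ladder: log-linear fit recovers k within 10%
  s1 <- simulate_spikein(spike_sim_config(depth = 1e6, bias_rate = 0.01,
                                          seed = 5))
  expect_lt(abs(fit_length_bias(s1$post, s1$pre)$rate - (-0.01)),
            0.1 * 0.01)
  # pre-sequencing histogram is exact and analytic: identical across seeds
  s2 <- simulate_spikein(spike_sim_config(depth = 1e6, bias_rate = 0.01,
                                          seed = 99))
  expect_identical(s1$pre$counts, s2$pre$counts)
})

test_that("ligation pairs respect the strand convention and comb structure", {
  cfg <- microc_sim_config(depth = 2e5, zigzag_amplitude = 0, seed = 11)
  pairs <- simulate_microc_pairs(cfg)
  expect_equal(nrow(pairs), cfg$depth)
  expect_false(any(duplicated(pairs$read_id)))
  ori <- classify_orientation(pairs$strand1, pairs$strand2)
  # strand columns partition into exactly the three orientation classes
  expect_setequal(unique(ori), c("tandem", "inward", "outward"))
  expect_equal(sum(table(ori)), nrow(pairs))
  # tandem curve modes sit at integer multiples of the repeat length
  cv <- contact_curve(pairs, orientation = "tandem")
  for (n in 1:3) {
    win <- which(abs(cv$distances - n * cfg$nrl) <= 40)
    mode_d <- cv$distances[win][which.max(rolling_mean(cv$probabilities, 9)[win])]
    expect_lte(abs(mode_d - n * cfg$nrl), 3)
  }
  # unmodulated comb: called peak heights strictly decreasing in step
  pk <- call_contact_peaks(cv)
  expect_true(all(diff(pk$heights) < 0))
})

test_that("orientation shift moves inward and outward curves in opposite directions", {
  cfg <- microc_sim_config(depth = 2e5, n_peaks = 5, seed = 12)
  pairs <- simulate_microc_pairs(cfg)
  d_in <- contact_curve(pairs, "inward", min_d = 1)
  d_out <- contact_curve(pairs, "outward", min_d = 1)
  mode_of <- function(cv) cv$distances[which.max(rolling_mean(cv$probabilities, 9))]
  expect_lte(abs(mode_of(d_in) - (cfg$nrl + cfg$orientation_shift)), 5)
  expect_lte(abs(mode_of(d_out) - (cfg$nrl - cfg$orientation_shift)), 5)
})

test_that("state regions confine their data and transmit per-state compaction", {
  states <- list(
    list(label = "open", n_intervals = 15, interval_length = 2e4,
         microc = microc_sim_config(nrl = 163, n_peaks = 6, depth = 6e4,
                                    seed = 1)),
    list(label = "compact", n_intervals = 15, interval_length = 2e4,
         microc = microc_sim_config(nrl = 212, n_peaks = 6, depth = 6e4,
                                    seed = 1),
         fld = fld_sim_config(depth = 5000, seed = 1))
  )
  sim <- simulate_state_regions(state_region_config(states, seed = 2))
  # intervals non-overlapping
  r <- sim$regions[order(sim$regions$chrom, sim$regions$start), ]
  same <- r$chrom[-1] == r$chrom[-nrow(r)]
  expect_true(all(r$start[-1][same] >= r$end[-nrow(r)][same]))
  # all fragments of a state fall inside that state's intervals
  fr <- sim$fragments
  regs <- sim$regions[sim$regions$state == "compact", ]
  inside <- vapply(seq_len(nrow(fr)), function(i) {
    any(fr$chrom[i] == regs$chrom & fr$start[i] >= regs$start &
          fr$end[i] <= regs$end)
  }, logical(1))
  expect_true(all(inside))
  # per-state NRL estimates separate in the correct direction
  nrl_of <- function(state) {
    p <- sim$pairs[sim$pairs$state == state, ]
    estimate_nrl(call_contact_peaks(contact_curve(p, "tandem")))
  }
  n_open <- nrl_of("open")
  n_compact <- nrl_of("compact")
  expect_lt(n_open, n_compact)
  expect_lt(abs(n_open - 163), 8)
  expect_lt(abs(n_compact - 212), 8)
  # empty state list gives empty outputs
  empty <- simulate_state_regions(state_region_config(list(), seed = 1))
  expect_equal(nrow(empty$regions), 0)
})

test_that("cscore track generator controls correlation sign and shift structure", {
  tr <- simulate_cscore_tracks(200, 1, seed = 3, chroms = c("chr1", "chr2"),
                               chrom_signs = c(1, -1),
                               shifts = rep(c(0, 0.5), each = 200))
  # rho_target 1: reference is an exact (anti)monotone copy per chromosome
  c1 <- tr$cscore$chrom == "chr1"
  expect_equal(cor(tr$cscore$value[c1], tr$reference$value[c1],
                   method = "spearman"), 1)
  expect_equal(cor(tr$cscore$value[!c1], tr$reference$value[!c1],
                   method = "spearman"), -1)
  # orientation flips the negatively correlated chromosome
  or <- orient_cscores(tr$cscore, tr$reference)
  expect_equal(or$report$decision, c("keep", "flip"))
  expect_equal(or$track$value[or$track$chrom == "chr2"],
               -tr$cscore$value[!c1])
  # second condition is first plus the configured shifts
  expect_equal(tr$cscore_b$value - tr$cscore$value, rep(c(0, 0.5), each = 200))
})
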