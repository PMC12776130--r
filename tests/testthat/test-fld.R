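# FLD processing chain: subsetting, spike-in scaling, bias fit/correction,
# normalization, gDNA contrast, replicate aggregation and Welch comparison.

test_that("histograms count fragments under the half-open span-overlap rule", {
  frags <- data.frame(chrom = "chr1", start = c(100, 100), end = c(200, 200))
  counted <- histogram_from_fragments(frags[1, ],
                                      data.frame(chrom = "chr1", start = 150,
                                                 end = 300))
  expect_equal(hist_total(counted), 1)
  abutting <- histogram_from_fragments(frags[1, ],
                                       data.frame(chrom = "chr1", start = 200,
                                                  end = 300))
  expect_equal(hist_total(abutting), 0)
  expect_error(histogram_from_fragments(
    data.frame(chrom = "chr1", start = 10, end = 10)), "greater than")
})

test_that("span-overlap subsetting matches a brute-force interval scan", {
  set.seed(201)
  frags <- data.frame(
    chrom = sample(c("chr1", "chr2"), 2000, replace = TRUE),
    start = sample.int(5000, 2000, replace = TRUE))
  frags$end <- frags$start + sample.int(400, 2000, replace = TRUE)
  regions <- data.frame(
    chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
    start = sample.int(5000, 30, replace = TRUE))
  regions$end <- regions$start + sample.int(500, 30, replace = TRUE)
  expect_identical(
    fragments_in_regions(frags$chrom, frags$start, frags$end, regions),
    brute_overlap(frags, regions))
})

test_that("subset totals over a disjoint exhaustive partition conserve the FLD", {
  cfg <- fld_sim_config(depth = 2e4, seed = 77)
  frags <- simulate_ricc_fragments(cfg, genome = c(simchr = 2e6))
  cuts <- c(0, 5e5, 1.2e6, 2e6)
  parts <- lapply(1:3, function(i) {
    data.frame(chrom = "simchr", start = cuts[i], end = cuts[i + 1])
  })
  totals <- vapply(parts, function(r) {
    hist_total(histogram_from_fragments(frags, r))
  }, numeric(1))
  # fragments straddling a boundary are counted in both flanking parts
  straddle <- sum(vapply(cuts[2:3], function(x) {
    sum(frags$start < x & frags$end > x)
  }, numeric(1)))
  expect_equal(sum(totals), nrow(frags) + straddle)
})

test_that("spike-in scaling applies REF_b/D_i and is idempotent", {
  mk <- function(total, id) {
    fld_histogram(100:102, c(total / 2, total / 4, total / 4),
                  sample_id = id, source = "spikein_post")
  }
  hists <- list(a = fld_histogram(100, 10, "a"), b = fld_histogram(100, 10, "b"),
                c = fld_histogram(100, 10, "c"))
  spikes <- list(a = mk(100, "a"), b = mk(200, "b"), c = mk(300, "c"))
  sc <- spikein_scale(hists, spikes)
  expect_equal(unname(sc$factors), c(2, 1, 2 / 3))
  expect_equal(sc$ref_depth, 200)
  expect_true(all(vapply(sc$spike_histograms, hist_total, numeric(1)) == 200))
  # second application is a no-op
  sc2 <- spikein_scale(sc$histograms, sc$spike_histograms)
  expect_equal(unname(sc2$factors), rep(1, 3))
  # single technical replicate: factor 1
  one <- spikein_scale(hists["a"], spikes["a"])
  expect_equal(unname(one$factors), 1)
  expect_error(spikein_scale(list(), list()), "empty")
})

test_that("length-bias fit is exact on closed-form inputs", {
  lens <- 100:700
  base <- 1000 * exp(-((lens - 300) / 150)^2) + 5
  pre <- fld_histogram(lens, base, source = "spikein_pre")
  # post identical to pre: zero rate
  post0 <- fld_histogram(lens, base, source = "spikein_post")
  expect_lt(abs(fit_length_bias(post0, pre)$rate), 1e-6)
  # post = pre * exp(-0.01 L): slope recovered to machine precision
  post1 <- fld_histogram(lens, base * exp(-0.01 * lens),
                         source = "spikein_post")
  fit <- fit_length_bias(post1, pre)
  expect_equal(fit$rate, -0.01, tolerance = 1e-10)
  expect_equal(predict(fit, 300), exp(-0.01 * 300), tolerance = 1e-8)
  expect_error(fit_length_bias(fld_histogram(300:305, rep(1, 6)), pre),
               "10 usable")
})

test_that("correction chain inverts a known bias up to normalization", {
  k <- 0.002
  cfg <- fld_sim_config(depth = 4e6, bias_rate = k, seed = 55)
  hb <- histogram_from_fragments(simulate_ricc_fragments(cfg))
  model <- bias_model(amplitude = exp(-k * 300), rate = -k)
  corr <- correct_normalize(hb, model)
  expect_equal(corr$values[corr$grid == 180], 1)
  # exact oracle: the analytic unbiased mixture, smoothed and normalized the
  # same way
  g <- corr$grid
  dens <- cfg$background_fraction / diff(cfg$background_range) +
    rowSums(vapply(seq_along(cfg$peak_centers), function(j) {
      cfg$peak_weights[j] * dnorm(g, cfg$peak_centers[j], cfg$peak_widths[j])
    }, numeric(length(g))))
  ana <- rolling_mean(dens, 10)
  ana <- ana / ana[g == 180]
  expect_true(all(abs(corr$values / ana - 1) < 0.05))
})

test_that("identity bias with unit window reproduces the renormalized input", {
  h <- fld_histogram(55:450, 100 + (55:450 %% 7))
  cc <- correct_normalize(h, bias_model(1, 0), smooth_window = 1)
  expect_equal(cc$values, h$counts / h$counts[h$lengths == 180])
})

test_that("gDNA ratio is exact, finite and scale-invariant", {
  g <- 55:450
  cell <- corrected_curve(g, rep(2, length(g)))
  expect_equal(gdna_ratio(cell, cell)$values, rep(1, length(g)))
  # zero gDNA bin stays finite via the pseudocount
  gd <- corrected_curve(g, c(0, rep(2, length(g) - 1)))
  expect_true(all(is.finite(gdna_ratio(cell, gd)$values)))
  # invariant under common positive rescaling of both inputs
  a <- corrected_curve(g, 1 + dnorm(g, 180, 12) * 50)
  b <- corrected_curve(g, 1 + dnorm(g, 300, 30) * 20)
  scale_curve <- function(cv, f) corrected_curve(cv$grid, cv$values * f)
  expect_equal(gdna_ratio(scale_curve(a, 37), scale_curve(b, 37))$values,
               gdna_ratio(a, b)$values, tolerance = 1e-12)
  expect_error(gdna_ratio(cell, corrected_curve(56:451, rep(1, length(g)))),
               "grids")
})

test_that("matched cell/gDNA simulations give ratio peaks at injected centers", {
  cell_cfg <- fld_sim_config(depth = 5e5, seed = 61)
  gdna_cfg <- fld_sim_config(depth = 5e5, seed = 62)
  cc <- correct_normalize(histogram_from_fragments(
    simulate_ricc_fragments(cell_cfg)))
  gc_ <- correct_normalize(histogram_from_fragments(
    simulate_gdna_fragments(gdna_cfg)))
  rat <- gdna_ratio(cc, gc_)
  # ratio ~ flat outside the peak windows
  flat <- rat$grid > 390 & rat$grid < 450
  expect_lt(diff(range(rat$values[flat])) / mean(rat$values[flat]), 0.35)
  pk <- call_curve_peaks(rat$grid, rat$values, smooth_window = 5)
  for (ctr in c(78, 180, 270, 360)) {
    expect_lte(min(abs(pk$positions - ctr)), 4)
  }
})

test_that("replicate aggregation reproduces the Student t interval", {
  g <- 1:10
  mk <- function(v) corrected_curve(g, rep(v, 10))
  agg <- aggregate_condition(list(mk(1), mk(2), mk(3)))
  expect_equal(agg$values, rep(2, 10))
  half <- agg$ci_upper - agg$values
  expect_equal(half, rep(qt(0.975, 2) / sqrt(3), 10), tolerance = 1e-9)
  expect_equal(half[1], 2.484, tolerance = 1e-3)
  # n = 2 uses t_{0.975,1} = 12.706
  agg2 <- aggregate_condition(list(mk(0), mk(1)))
  expect_equal(agg2$ci_upper - agg2$values,
               rep(12.706 * sd(c(0, 1)) / sqrt(2), 10), tolerance = 1e-4)
  # identical replicates: zero-width interval
  agg3 <- aggregate_condition(list(mk(1), mk(1), mk(1)))
  expect_equal(agg3$ci_upper, agg3$ci_lower)
  # single replicate: interval undefined and flagged
  agg4 <- aggregate_condition(list(mk(1)))
  expect_false(agg4$info$ci_defined)
  expect_true(all(is.na(agg4$ci_upper)))
})

test_that("run calling matches the brute-force scan and honors min_run", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(50:300, 1)
    p <- runif(n)
    alpha <- runif(1, 0.05, 0.5)
    min_run <- sample(2:6, 1)
    got <- find_significant_runs(p, alpha, min_run)
    want <- brute_runs(p, alpha, min_run)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
  # a 4-long sub-alpha stretch is filtered at min_run = 5
  p <- rep(1, 20)
  p[8:11] <- 0.001
  expect_equal(nrow(find_significant_runs(p, 0.05, 5)), 0)
})

test_that("Welch comparison agrees with stats::t.test and recovers planted signal", {
  set.seed(31)
  g <- 55:450
  mk <- function(mult = 1, window = NULL) {
    v <- 1 + rnorm(length(g), sd = 0.005)
    if (!is.null(window)) v[g %in% window] <- v[g %in% window] * mult
    corrected_curve(g, v)
  }
  a <- replicate(4, mk(), simplify = FALSE)
  b <- replicate(4, mk(2, 250:279), simplify = FALSE)
  cmp <- compare_conditions(a, b)
  # cross-check a few positions against the reference Welch implementation
  am <- do.call(rbind, lapply(a, `[[`, "values"))
  bm <- do.call(rbind, lapply(b, `[[`, "values"))
  for (j in c(1, 100, 230)) {
    expect_equal(cmp$p_values[j],
                 stats::t.test(bm[, j], am[, j])$p.value, tolerance = 1e-10)
  }
  # planted 30 nt two-fold window: exactly one run covering >= 80% of it
  expect_equal(nrow(cmp$significant_runs), 1)
  run <- cmp$significant_runs[1, ]
  covered <- length(intersect(seq(run$start, run$end), 250:279))
  expect_gte(covered, 24)
  expect_gt(mean(cmp$mean_ratio[g %in% 250:279]), 1.8)
  expect_error(compare_conditions(a[1], b), "two replicate")
})
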