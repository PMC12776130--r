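# Generators for every input class the pipeline consumes. All generators are
# deterministic given (config, seed): identical calls yield identical tables.

# draw thinned fragment lengths from a Gaussian-mixture + uniform-background
# model; no RNG management here, callers seed the stream
draw_fld_lengths <- function(cfg) {
  k <- length(cfg$peak_centers)
  probs <- c(cfg$peak_weights, cfg$background_fraction)
  if (sum(probs) <= 0) {
    stop("all mixture weights are zero; nothing to simulate", call. = FALSE)
  }
  n <- cfg$depth
  comp <- sample.int(k + 1L, n, replace = TRUE, prob = probs)
  len <- numeric(n)
  draw_one <- function(j, m) {
    if (j == k + 1L) {
      runif(m, cfg$background_range[1], cfg$background_range[2])
    } else {
      rnorm(m, cfg$peak_centers[j], cfg$peak_widths[j])
    }
  }
  for (j in seq_len(k + 1L)) {
    idx <- which(comp == j)
    if (length(idx)) len[idx] <- draw_one(j, length(idx))
  }
  len <- round(len)
  # negative or zero draws (deep Gaussian tails) are rejected and resampled
  bad <- which(len < 1)
  guard <- 0L
  while (length(bad)) {
    for (j in unique(comp[bad])) {
      idx <- bad[comp[bad] == j]
      len[idx] <- round(draw_one(j, length(idx)))
    }
    bad <- which(len < 1)
    guard <- guard + 1L
    if (guard > 1000L) stop("cannot draw positive fragment lengths", call. = FALSE)
  }
  if (cfg$bias_rate > 0) {
    len <- len[runif(n) < exp(-cfg$bias_rate * len)]
  }
  as.integer(len)
}

place_on_genome <- function(len, genome) {
  if (is.null(names(genome)) || any(genome <= 0)) {
    stop("`genome` must be a named vector of positive chromosome sizes",
         call. = FALSE)
  }
  if (length(len) && max(len) > min(genome)) {
    stop("a simulated fragment is longer than the smallest chromosome",
         call. = FALSE)
  }
  chrom <- sample(names(genome), length(len), replace = TRUE,
                  prob = genome / sum(genome))
  start <- floor(runif(length(len), 0, unname(genome[chrom]) - len + 1))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), length = len,
             stringsAsFactors = FALSE)
}

#' Simulate correlated-cleavage single-stranded fragments
#'
#' Draws fragment lengths from the configured Gaussian-mixture-plus-background
#' model, thins them with probability `exp(-bias_rate * length)` (length-
#' dependent capture loss), and places them uniformly on a synthetic genome.
#'
#' @param cfg An [fld_sim_config()].
#' @param genome Named vector of chromosome sizes (bp) for uniform placement.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `length` (nt). Row count is `cfg$depth` minus fragments
#'   lost to thinning.
#' @examples
#' frags <- simulate_ricc_fragments(fld_sim_config(depth = 1000))
#' head(frags)
#' @export
simulate_ricc_fragments <- function(cfg, genome = c(simchr = 2e6)) {
  stopifnot(inherits(cfg, "fld_sim_config"))
  with_seed(cfg$seed, place_on_genome(draw_fld_lengths(cfg), genome))
}

#' Simulate an irradiated genomic-DNA control
#'
#' Identical to [simulate_ricc_fragments()] but with all contact-peak weights
#' forced to zero: purified genomic DNA carries only uncorrelated background
#' breaks, which is what the cell/gDNA ratio normalizes against.
#'
#' @inheritParams simulate_ricc_fragments
#' @return Fragment data frame as in [simulate_ricc_fragments()].
#' @export
simulate_gdna_fragments <- function(cfg, genome = c(simchr = 2e6)) {
  stopifnot(inherits(cfg, "fld_sim_config"))
  cfg$peak_weights[] <- 0
  cfg$background_fraction <- 1
  simulate_ricc_fragments(cfg, genome)
}

#' Simulate an MNase spike-in ladder before and after sequencing
#'
#' Returns the pair of histograms the length-bias fit consumes: `pre`, the
#' exact analytic rung mixture evaluated per integer nt (the ladder as
#' quantified by capillary electrophoresis before library preparation), and
#' `post`, a sampled histogram after `exp(-bias_rate * L)` thinning (the
#' ladder as recovered from sequencing). Both are produced under one seed.
#'
#' @param cfg A [spike_sim_config()].
#' @return List with elements `pre` and `post`, both [fld_histogram()]
#'   objects on a common integer support (sources `spikein_pre` /
#'   `spikein_post`).
#' @seealso [fit_length_bias()]
#' @export
simulate_spikein <- function(cfg) {
  stopifnot(inherits(cfg, "spike_sim_config"))
  with_seed(cfg$seed, {
    centers <- cfg$ladder_repeat * seq_len(cfg$n_rungs)
    support <- seq_len(ceiling(max(centers) + 5 * max(cfg$rung_widths)))
    dens <- rep(0, length(support))
    for (j in seq_len(cfg$n_rungs)) {
      dens <- dens + cfg$rung_weights[j] *
        dnorm(support, centers[j], cfg$rung_widths[j])
    }
    pre_counts <- dens / sum(dens) * cfg$depth

    comp <- sample.int(cfg$n_rungs, cfg$depth, replace = TRUE,
                       prob = cfg$rung_weights)
    len <- round(rnorm(cfg$depth, centers[comp], cfg$rung_widths[comp]))
    bad <- which(len < 1 | len > max(support))
    guard <- 0L
    while (length(bad)) {
      len[bad] <- round(rnorm(length(bad), centers[comp[bad]],
                              cfg$rung_widths[comp[bad]]))
      bad <- which(len < 1 | len > max(support))
      guard <- guard + 1L
      if (guard > 1000L) stop("cannot draw ladder lengths", call. = FALSE)
    }
    if (cfg$bias_rate > 0) {
      len <- len[runif(length(len)) < exp(-cfg$bias_rate * len)]
    }
    post_counts <- tabulate(len, nbins = max(support))
    list(
      pre = fld_histogram(support, pre_counts, sample_id = "spikein",
                          source = "spikein_pre"),
      post = fld_histogram(support, as.numeric(post_counts),
                           sample_id = "spikein", source = "spikein_post")
    )
  })
}

# draw truncated comb distances plus orientation/strand assignment
draw_pair_distances <- function(cfg) {
  w <- microc_step_weights(cfg)
  centers <- cfg$nrl * seq_len(cfg$n_peaks)
  mass <- sum(w * (pnorm(cfg$max_distance, centers, cfg$peak_width) -
                     pnorm(cfg$min_distance, centers, cfg$peak_width)))
  if (mass / sum(w) < 1e-9) {
    stop("distance truncation empties the comb support", call. = FALSE)
  }
  n <- cfg$depth
  step <- sample.int(cfg$n_peaks, n, replace = TRUE, prob = w)
  d <- rnorm(n, centers[step], cfg$peak_width)
  orientation <- sample(c("tandem", "inward", "outward"), n, replace = TRUE,
                        prob = cfg$orientation_mix)
  shift <- ifelse(orientation == "inward", cfg$orientation_shift,
                  ifelse(orientation == "outward", -cfg$orientation_shift, 0))
  final <- round(d + shift)
  bad <- which(d < cfg$min_distance | d > cfg$max_distance | final < 1)
  guard <- 0L
  while (length(bad)) {
    step[bad] <- sample.int(cfg$n_peaks, length(bad), replace = TRUE, prob = w)
    d[bad] <- rnorm(length(bad), centers[step[bad]], cfg$peak_width)
    final[bad] <- round(d[bad] + shift[bad])
    bad <- which(d < cfg$min_distance | d > cfg$max_distance | final < 1)
    guard <- guard + 1L
    if (guard > 1000L) {
      stop("distance truncation empties the comb support", call. = FALSE)
    }
  }
  tandem_minus <- orientation == "tandem" & runif(n) < 0.5
  strand1 <- ifelse(orientation == "inward", "+",
                    ifelse(orientation == "outward", "-",
                           ifelse(tandem_minus, "-", "+")))
  strand2 <- ifelse(orientation == "inward", "-",
                    ifelse(orientation == "outward", "+",
                           ifelse(tandem_minus, "-", "+")))
  data.frame(distance = as.integer(final), orientation = orientation,
             strand1 = strand1, strand2 = strand2, stringsAsFactors = FALSE)
}

#' Simulate short-range cis ligation pairs
#'
#' Contact distances are drawn from the truncated nucleosome-comb mixture of
#' the configuration (see [microc_sim_config()]); ligation orientation is
#' assigned per `orientation_mix`, inward/outward distances receive the
#' orientation offset, and strands follow the convention inward `+/-`,
#' outward `-/+`, tandem `+/+` or `-/-`. Pairs are placed uniformly in cis.
#'
#' @param cfg A [microc_sim_config()].
#' @return Data frame with columns `read_id`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `strand1`, `strand2` (positions 0-based, `pos1 <= pos2`).
#' @examples
#' pairs <- simulate_microc_pairs(microc_sim_config(depth = 1000))
#' table(classify_orientation(pairs$strand1, pairs$strand2))
#' @export
simulate_microc_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "microc_sim_config"))
  with_seed(cfg$seed, {
    dd <- draw_pair_distances(cfg)
    sizes <- cfg$chrom_sizes
    if (max(dd$distance) >= min(sizes)) {
      stop("chromosomes too small for the simulated contact distances",
           call. = FALSE)
    }
    chrom <- sample(names(sizes), nrow(dd), replace = TRUE,
                    prob = sizes / sum(sizes))
    pos1 <- floor(runif(nrow(dd), 0, unname(sizes[chrom]) - dd$distance))
    data.frame(read_id = sprintf("pair%07d", seq_len(nrow(dd))),
               chrom1 = chrom, pos1 = as.integer(pos1),
               chrom2 = chrom, pos2 = as.integer(pos1 + dd$distance),
               strand1 = dd$strand1, strand2 = dd$strand2,
               stringsAsFactors = FALSE)
  })
}

#' Simulate labeled epigenetic-state regions with state-specific data
#'
#' Places non-overlapping intervals for each state on the synthetic genome,
#' then generates fragments and/or ligation pairs inside those intervals
#' using each state's override configurations (e.g. a different nucleosome
#' repeat length or peak weights per chromatin state). All randomness comes
#' from the master `cfg$seed`; seeds inside the per-state override configs
#' are ignored.
#'
#' @param cfg A [state_region_config()].
#' @return List with elements `regions` (data frame `chrom`, `start`, `end`,
#'   `state`), `fragments` (per-state fragment table with a `state` column)
#'   and `pairs` (per-state pair table with a `state` column). Empty state
#'   lists give empty outputs.
#' @export
simulate_state_regions <- function(cfg) {
  stopifnot(inherits(cfg, "state_region_config"))
  empty_regions <- data.frame(chrom = character(), start = integer(),
                              end = integer(), state = character(),
                              stringsAsFactors = FALSE)
  if (!length(cfg$states)) {
    return(list(regions = empty_regions,
                fragments = data.frame(), pairs = data.frame()))
  }
  with_seed(cfg$seed, {
    sizes <- cfg$chrom_sizes
    occupied <- lapply(sizes, function(s) IRanges::IRanges())
    regions <- list()
    for (s in cfg$states) {
      for (i in seq_len(s$n_intervals)) {
        placed <- FALSE
        for (try in seq_len(2000L)) {
          ch <- sample(names(sizes), 1L, prob = sizes / sum(sizes))
          if (sizes[[ch]] <= s$interval_length) next
          st <- floor(runif(1, 0, sizes[[ch]] - s$interval_length))
          cand <- IRanges::IRanges(st + 1L, st + s$interval_length)
          if (!IRanges::overlapsAny(cand, occupied[[ch]])) {
            occupied[[ch]] <- c(occupied[[ch]], cand)
            regions[[length(regions) + 1L]] <-
              data.frame(chrom = ch, start = as.integer(st),
                         end = as.integer(st + s$interval_length),
                         state = s$label, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop(sprintf("cannot place intervals for state '%s' without overlap",
                       s$label), call. = FALSE)
        }
      }
    }
    regions <- do.call(rbind, regions)

    # place each span of length len[i] inside one of the state's intervals;
    # spans longer than every interval are dropped (reported via `kept`)
    place_in_intervals <- function(len, ivs) {
      widths <- ivs$end - ivs$start
      fits <- outer(len, widths, `<=`)
      kept <- which(rowSums(fits) > 0)
      len <- len[kept]
      fits <- fits[kept, , drop = FALSE]
      pick <- vapply(seq_along(len), function(i) {
        ok <- which(fits[i, ])
        if (length(ok) == 1L) ok else sample(ok, 1L)
      }, integer(1))
      st <- floor(runif(length(len), ivs$start[pick],
                        ivs$end[pick] - len + 1))
      list(placed = data.frame(chrom = ivs$chrom[pick], start = as.integer(st),
                               end = as.integer(st + len),
                               stringsAsFactors = FALSE),
           kept = kept)
    }

    fragments <- list()
    pairs <- list()
    for (s in cfg$states) {
      ivs <- regions[regions$state == s$label, , drop = FALSE]
      if (!is.null(s$fld)) {
        len <- draw_fld_lengths(s$fld)
        res <- place_in_intervals(len, ivs)
        fr <- res$placed
        if (nrow(fr)) {
          fr$length <- fr$end - fr$start
          fr$state <- s$label
          fragments[[length(fragments) + 1L]] <- fr
        }
      }
      if (!is.null(s$microc)) {
        dd <- draw_pair_distances(s$microc)
        res <- place_in_intervals(dd$distance, ivs)
        dd <- dd[res$kept, , drop = FALSE]
        pl <- res$placed
        if (nrow(pl)) {
          pairs[[length(pairs) + 1L]] <-
            data.frame(read_id = sprintf("%s_pair%06d", s$label,
                                         seq_len(nrow(pl))),
                       chrom1 = pl$chrom, pos1 = pl$start,
                       chrom2 = pl$chrom, pos2 = pl$end,
                       strand1 = dd$strand1, strand2 = dd$strand2,
                       state = s$label, stringsAsFactors = FALSE)
        }
      }
    }
    list(regions = regions,
         fragments = if (length(fragments)) do.call(rbind, fragments)
         else data.frame(),
         pairs = if (length(pairs)) do.call(rbind, pairs) else data.frame())
  })
}

#' Simulate paired compartment-score and reference bin tracks
#'
#' Generates, per chromosome, a compartment-score track, a reference
#' active-mark track whose rank correlation with the scores approximates
#' `rho_target` (with configurable sign per chromosome), and a
#' second-condition score track equal to the first plus configurable per-bin
#' shifts. The reference is built through a Gaussian copula, so the realized
#' Spearman correlation matches `rho_target` up to sampling noise;
#' `rho_target = 1` gives an exact monotone copy.
#'
#' @param n_bins Bins per chromosome, `>= 10`.
#' @param rho_target Target magnitude of the rank correlation in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @param chroms Chromosome names.
#' @param bin_width Bin width (bp); default 100 kb.
#' @param chrom_signs Sign (+1/-1) of the reference correlation per
#'   chromosome; recycled.
#' @param shifts Per-bin additive shifts applied to the second condition;
#'   scalar or vector of length `n_bins * length(chroms)`. Default 0.
#' @return List of bin-track data frames (`chrom`, `start`, `end`, `value`):
#'   `cscore`, `reference`, `cscore_b`.
#' @seealso [orient_cscores()], [classify_shifts()]
#' @export
simulate_cscore_tracks <- function(n_bins, rho_target, seed = 1L,
                                   chroms = "chr1", bin_width = 1e5,
                                   chrom_signs = 1, shifts = 0) {
  if (n_bins < 10) stop("`n_bins` must be >= 10", call. = FALSE)
  if (rho_target < 0 || rho_target > 1) {
    stop("`rho_target` must be in [0, 1]", call. = FALSE)
  }
  chrom_signs <- rep_len(sign(chrom_signs), length(chroms))
  if (any(chrom_signs == 0)) stop("`chrom_signs` must be +-1", call. = FALSE)
  shifts <- rep_len(shifts, n_bins * length(chroms))
  # Pearson rho on normal scores that yields the requested Spearman rho
  r <- 2 * sin(pi * rho_target / 6)
  with_seed(seed, {
    out_c <- out_r <- out_b <- list()
    for (i in seq_along(chroms)) {
      x <- rnorm(n_bins)
      z <- rnorm(n_bins)
      y <- chrom_signs[i] * (r * x + sqrt(max(0, 1 - r^2)) * z)
      start <- as.integer((seq_len(n_bins) - 1L) * bin_width)
      bins <- data.frame(chrom = chroms[i], start = start,
                         end = as.integer(start + bin_width),
                         stringsAsFactors = FALSE)
      sh <- shifts[(i - 1L) * n_bins + seq_len(n_bins)]
      out_c[[i]] <- cbind(bins, value = x)
      out_r[[i]] <- cbind(bins, value = y)
      out_b[[i]] <- cbind(bins, value = x + sh)
    }
    list(cscore = do.call(rbind, out_c),
         reference = do.call(rbind, out_r),
         cscore_b = do.call(rbind, out_b))
  })
}
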