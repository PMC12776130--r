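#' Configuration for simulated correlated-cleavage fragment lengths
#'
#' Describes the phenomenological model behind simulated single-stranded
#' fragment length distributions: a Gaussian mixture of contact peaks (one
#' DNA wrap at ~78 nt, the mononucleosome at ~180 nt, and stacked-gyre
#' contacts near 270 and 360 nt) over a uniform background of uncorrelated
#' breaks, followed by exponential length-dependent capture loss
#' `exp(-bias_rate * length)`.
#'
#' @param peak_centers Numeric vector of peak centers (nt).
#' @param peak_widths Gaussian SD per peak (nt); recycled to the number of
#'   peaks.
#' @param peak_weights Nonnegative mixture fraction per peak.
#' @param background_fraction Fraction of fragments drawn from the uniform
#'   background of uncorrelated breaks. `peak_weights` and
#'   `background_fraction` must sum to 1.
#' @param background_range Length-2 vector, support of the uniform background
#'   (nt). Uncorrelated radiation breaks have no documented length law, so a
#'   maximally uninformative uniform is used.
#' @param bias_rate Exponential capture-loss rate per nt, `>= 0`.
#' @param depth Number of fragments drawn before length-bias thinning.
#' @param seed Integer RNG seed.
#' @return An object of class `fld_sim_config`.
#' @seealso [simulate_ricc_fragments()], [simulate_gdna_fragments()]
#' @export
fld_sim_config <- function(peak_centers = c(78, 180, 270, 360),
                           peak_widths = 12,
                           peak_weights = rep(0.125, 4),
                           background_fraction = 0.5,
                           background_range = c(50, 700),
                           bias_rate = 0,
                           depth = 1e5,
                           seed = 1L) {
  k <- length(peak_centers)
  peak_widths <- rep_len(peak_widths, k)
  if (length(peak_weights) != k) {
    stop("`peak_weights` must have one entry per peak center", call. = FALSE)
  }
  if (any(peak_weights < 0) || background_fraction < 0 ||
      background_fraction > 1) {
    stop("mixture weights must be nonnegative and background_fraction in [0,1]",
         call. = FALSE)
  }
  if (abs(sum(peak_weights) + background_fraction - 1) > 1e-9) {
    stop("`peak_weights` + `background_fraction` must sum to 1", call. = FALSE)
  }
  if (length(background_range) != 2L ||
      background_range[1] >= background_range[2] || background_range[1] <= 0) {
    stop("`background_range` must be an increasing positive pair", call. = FALSE)
  }
  if (bias_rate < 0) stop("`bias_rate` must be >= 0", call. = FALSE)
  if (depth <= 0) stop("`depth` must be > 0", call. = FALSE)
  structure(list(peak_centers = peak_centers, peak_widths = peak_widths,
                 peak_weights = peak_weights,
                 background_fraction = background_fraction,
                 background_range = background_range, bias_rate = bias_rate,
                 depth = as.integer(depth), seed = as.integer(seed)),
            class = "fld_sim_config")
}

#' Configuration for a simulated MNase spike-in ladder
#'
#' The spike-in emulates an MNase-digested chromatin ladder of known
#' pre-sequencing length distribution: Gaussian rungs at integer multiples of
#' `ladder_repeat`. The default repeat of 154 nt corresponds to a typical
#' fission-yeast nucleosome repeat length.
#'
#' @param ladder_repeat Rung spacing (nt), `> 0`.
#' @param n_rungs Number of ladder rungs, `>= 2`.
#' @param rung_widths Gaussian SD per rung (nt); recycled.
#' @param rung_weights Optional mixture weight per rung; defaults to equal.
#' @param depth Fragments drawn before thinning.
#' @param bias_rate Exponential capture-loss rate per nt.
#' @param seed Integer RNG seed.
#' @return An object of class `spike_sim_config`.
#' @seealso [simulate_spikein()], [fit_length_bias()]
#' @export
spike_sim_config <- function(ladder_repeat = 154, n_rungs = 4,
                             rung_widths = 15, rung_weights = NULL,
                             depth = 1e5, bias_rate = 0, seed = 1L) {
  if (ladder_repeat <= 0) stop("`ladder_repeat` must be > 0", call. = FALSE)
  if (n_rungs < 2) stop("`n_rungs` must be >= 2", call. = FALSE)
  rung_widths <- rep_len(rung_widths, n_rungs)
  if (is.null(rung_weights)) rung_weights <- rep(1 / n_rungs, n_rungs)
  if (length(rung_weights) != n_rungs || any(rung_weights <= 0)) {
    stop("`rung_weights` must be positive, one per rung", call. = FALSE)
  }
  rung_weights <- rung_weights / sum(rung_weights)
  if (bias_rate < 0) stop("`bias_rate` must be >= 0", call. = FALSE)
  if (depth <= 0) stop("`depth` must be > 0", call. = FALSE)
  structure(list(ladder_repeat = ladder_repeat, n_rungs = as.integer(n_rungs),
                 rung_widths = rung_widths, rung_weights = rung_weights,
                 depth = as.integer(depth), bias_rate = bias_rate,
                 seed = as.integer(seed)),
            class = "spike_sim_config")
}

#' Configuration for simulated short-range cis ligation pairs
#'
#' Cis contact distances follow a nucleosome "comb": a mixture of Gaussians at
#' integer multiples `n * nrl` of the nucleosome repeat length, with per-step
#' weight `w_n = n^-decay_exponent * (1 + zigzag_amplitude * [n odd, n >= 3])`,
#' truncated to `[min_distance, max_distance]`. The odd-step boost emulates
#' the enrichment of N/N+odd contacts produced by zig-zag (two-start)
#' alternating-nucleosome stacking. Ligation orientation is assigned
#' tandem/inward/outward; inward distances are shifted by `+orientation_shift`
#' and outward by `-orientation_shift`, reflecting that read positions mark
#' nucleosome entry or exit points depending on orientation (the default 147
#' bp is one nucleosome of wrapped DNA).
#'
#' @param nrl Nucleosome repeat length (bp).
#' @param peak_width Gaussian SD of each comb peak (bp).
#' @param n_peaks Number of comb steps simulated.
#' @param decay_exponent Power-law decay exponent `gamma > 0` of step weights.
#' @param zigzag_amplitude Nonnegative boost `A` applied to odd steps
#'   `n >= 3`.
#' @param orientation_shift Offset (bp) added to inward and subtracted from
#'   outward distances.
#' @param min_distance,max_distance Truncation bounds (bp) of the base
#'   distance distribution.
#' @param orientation_mix Named proportions for tandem/inward/outward;
#'   defaults to equal thirds.
#' @param depth Number of pairs drawn.
#' @param chrom_sizes Named vector of chromosome sizes (bp) used for placement.
#' @param seed Integer RNG seed.
#' @return An object of class `microc_sim_config`.
#' @seealso [simulate_microc_pairs()], [zigzag_summary()]
#' @export
microc_sim_config <- function(nrl = 186, peak_width = 12, n_peaks = 7,
                              decay_exponent = 1.2, zigzag_amplitude = 0,
                              orientation_shift = 147,
                              min_distance = 50, max_distance = 1500,
                              orientation_mix = c(tandem = 1 / 3,
                                                  inward = 1 / 3,
                                                  outward = 1 / 3),
                              depth = 1e5,
                              chrom_sizes = c(simchr = 3e6),
                              seed = 1L) {
  if (nrl <= 0) stop("`nrl` must be > 0", call. = FALSE)
  if (n_peaks < 1) stop("`n_peaks` must be >= 1", call. = FALSE)
  if (decay_exponent <= 0) stop("`decay_exponent` must be > 0", call. = FALSE)
  if (zigzag_amplitude < 0) stop("`zigzag_amplitude` must be >= 0", call. = FALSE)
  if (min_distance >= max_distance) {
    stop("`min_distance` must be smaller than `max_distance`", call. = FALSE)
  }
  if (min_distance < 1) stop("`min_distance` must be >= 1", call. = FALSE)
  nm <- c("tandem", "inward", "outward")
  if (!all(nm %in% names(orientation_mix)) || any(orientation_mix < 0) ||
      sum(orientation_mix) <= 0) {
    stop("`orientation_mix` needs nonnegative tandem/inward/outward entries",
         call. = FALSE)
  }
  orientation_mix <- orientation_mix[nm] / sum(orientation_mix[nm])
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("`chrom_sizes` must be a named vector of positive sizes", call. = FALSE)
  }
  if (depth <= 0) stop("`depth` must be > 0", call. = FALSE)
  structure(list(nrl = nrl, peak_width = peak_width,
                 n_peaks = as.integer(n_peaks),
                 decay_exponent = decay_exponent,
                 zigzag_amplitude = zigzag_amplitude,
                 orientation_shift = orientation_shift,
                 min_distance = min_distance, max_distance = max_distance,
                 orientation_mix = orientation_mix,
                 depth = as.integer(depth), chrom_sizes = chrom_sizes,
                 seed = as.integer(seed)),
            class = "microc_sim_config")
}

#' Per-step comb weights of a ligation-pair configuration
#'
#' `w_n = n^-gamma * (1 + A * [n odd, n >= 3])`. For `A = 0` the weights are
#' strictly decreasing in `n`.
#'
#' @param cfg A [microc_sim_config()].
#' @return Numeric vector of length `cfg$n_peaks`.
#' @export
microc_step_weights <- function(cfg) {
  n <- seq_len(cfg$n_peaks)
  odd <- (n %% 2L == 1L) & n >= 3L
  n^(-cfg$decay_exponent) * (1 + cfg$zigzag_amplitude * odd)
}

#' Configuration for labeled epigenetic-state regions
#'
#' Each state is a list with fields `label`, `n_intervals`, `interval_length`
#' (bp) and optional `fld` ([fld_sim_config()]) and `microc`
#' ([microc_sim_config()]) overrides describing the state's compaction
#' parameters. Generated intervals are non-overlapping (0-based half-open)
#' and per-state fragments/pairs are placed inside them.
#'
#' @param states List of state descriptions (may be empty).
#' @param chrom_sizes Named vector of chromosome sizes (bp).
#' @param seed Integer RNG seed.
#' @return An object of class `state_region_config`.
#' @seealso [simulate_state_regions()]
#' @export
state_region_config <- function(states, chrom_sizes = c(simchr = 5e6),
                                seed = 1L) {
  stopifnot(is.list(states))
  for (s in states) {
    if (!all(c("label", "n_intervals", "interval_length") %in% names(s))) {
      stop("each state needs `label`, `n_intervals`, `interval_length`",
           call. = FALSE)
    }
    if (s$n_intervals < 1 || s$interval_length < 1) {
      stop("state interval counts and lengths must be positive", call. = FALSE)
    }
  }
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("`chrom_sizes` must be a named vector of positive sizes", call. = FALSE)
  }
  structure(list(states = states, chrom_sizes = chrom_sizes,
                 seed = as.integer(seed)),
            class = "state_region_config")
}
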