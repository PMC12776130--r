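# Orientation-aware short-range contact analysis: contact probability
# curves, second-derivative peak calls, nucleosome repeat length and the
# odd/even zig-zag contact ratio.

#' Classify ligation orientation from strand information
#'
#' For a position-ordered pair (`pos1 <= pos2`): `+/-` is an inward ligation,
#' `-/+` outward, and same-strand pairs (`+/+` or `-/-`) are tandem. Inward
#' and outward contact distances include or exclude the lengths of the two
#' nucleosomes, because read positions mark nucleosome entry or exit points;
#' tandem distances carry no such offset.
#'
#' @param strand1,strand2 Character vectors over `{+, -}`.
#' @return Character vector over `{inward, outward, tandem}`.
#' @examples
#' classify_orientation(c("+", "-", "+", "-"), c("-", "+", "+", "-"))
#' @export
classify_orientation <- function(strand1, strand2) {
  ok <- c("+", "-")
  if (!all(strand1 %in% ok) || !all(strand2 %in% ok)) {
    stop("strands must be '+' or '-'", call. = FALSE)
  }
  ifelse(strand1 == "+" & strand2 == "-", "inward",
         ifelse(strand1 == "-" & strand2 == "+", "outward", "tandem"))
}

# order each pair by position, swapping strands along with positions so the
# orientation convention (defined on pos1 <= pos2) applies
order_pairs <- function(pairs) {
  swap <- pairs$pos1 > pairs$pos2
  if (any(swap)) {
    tmp <- pairs$pos1[swap]
    pairs$pos1[swap] <- pairs$pos2[swap]
    pairs$pos2[swap] <- tmp
    tmp <- pairs$strand1[swap]
    pairs$strand1[swap] <- pairs$strand2[swap]
    pairs$strand2[swap] <- tmp
  }
  pairs
}

#' Span-overlap subsetting of ligation pairs
#'
#' Keeps cis pairs whose span `[min(pos1, pos2), max(pos1, pos2))` overlaps
#' at least 1 bp of the region set (same span rule as fragment subsetting);
#' trans pairs are dropped.
#'
#' @param pairs Pair data frame (`read_id`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `strand1`, `strand2`).
#' @param regions Region data frame (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @return The retained rows of `pairs` (possibly none).
#' @export
subset_pairs_by_regions <- function(pairs, regions) {
  cis <- pairs[pairs$chrom1 == pairs$chrom2, , drop = FALSE]
  if (!nrow(cis)) return(cis)
  lo <- pmin(cis$pos1, cis$pos2)
  hi <- pmax(cis$pos1, cis$pos2)
  same <- hi == lo
  hi[same] <- hi[same] + 1L  # zero-length span: treat as a 1 bp point
  cis[fragments_in_regions(cis$chrom1, lo, hi, regions), , drop = FALSE]
}

#' Short-range contact probability curve
#'
#' Drops trans pairs, computes cis contact distances `|pos2 - pos1|`,
#' retains the requested ligation orientation and distance window, optionally
#' subsets by a region set (span-overlap rule), and normalizes the distance
#' histogram to sum to one over `[min_d, max_d]`.
#'
#' @param pairs Pair data frame.
#' @param orientation `"tandem"`, `"inward"`, `"outward"` or `"all"`.
#' @param min_d,max_d Distance window (bp). The 50 bp default floor excludes
#'   self-ligation-scale artifacts; 1500 bp is the short-range ceiling.
#' @param regions Optional region set for subsetting.
#' @param subset Optional label recorded on the curve.
#' @return An object of class `contact_curve`: `distances` (`min_d:max_d`),
#'   `probabilities` (summing to 1), `orientation`, `n_pairs`, `subset`.
#' @examples
#' pairs <- simulate_microc_pairs(microc_sim_config(depth = 5000))
#' curve <- contact_curve(pairs, orientation = "tandem")
#' curve
#' @export
contact_curve <- function(pairs, orientation = c("all", "tandem", "inward",
                                                 "outward"),
                          min_d = 50, max_d = 1500, regions = NULL,
                          subset = NA_character_) {
  orientation <- match.arg(orientation)
  if (min_d < 1) stop("`min_d` must be >= 1", call. = FALSE)
  if (min_d >= max_d) stop("`min_d` must be below `max_d`", call. = FALSE)
  pairs <- pairs[pairs$chrom1 == pairs$chrom2, , drop = FALSE]
  pairs <- order_pairs(pairs)
  if (!is.null(regions)) pairs <- subset_pairs_by_regions(pairs, regions)
  if (nrow(pairs)) {
    ori <- classify_orientation(pairs$strand1, pairs$strand2)
    if (orientation != "all") pairs <- pairs[ori == orientation, , drop = FALSE]
  }
  d <- abs(pairs$pos2 - pairs$pos1)
  d <- d[d >= min_d & d <= max_d]
  if (!length(d)) {
    stop("no pairs survive the orientation/distance/region filters",
         call. = FALSE)
  }
  counts <- tabulate(d - min_d + 1L, nbins = max_d - min_d + 1L)
  structure(list(distances = as.integer(min_d:max_d),
                 probabilities = counts / sum(counts),
                 orientation = orientation, n_pairs = length(d),
                 subset = subset),
            class = "contact_curve")
}

#' @export
print.contact_curve <- function(x, ...) {
  cat(sprintf("<contact_curve> %s: %d pairs on [%d, %d] bp\n",
              x$orientation, x$n_pairs, min(x$distances), max(x$distances)))
  invisible(x)
}

#' Call peaks on a curve by negative second-derivative runs
#'
#' Smooths the curve with a centered rolling mean, computes the discrete
#' second difference, finds maximal runs where it is negative (concave
#' stretches), and reports the position of the smoothed-curve maximum within
#' each run. Two filters then suppress noise artifacts: candidates below a
#' height floor are discarded, and of any two candidates closer than
#' `min_separation` only the higher is kept (highest-first greedy selection,
#' as in distance-filtered peak finders). The default floor is the larger of
#' the smoothed-curve median (which tracks the baseline of ratio-style
#' curves) and 5% of the curve maximum (which suppresses counting-noise
#' bumps on near-zero valleys of sparse histograms); `"median"` uses the
#' median alone.
#'
#' @param positions Strictly increasing coordinates.
#' @param values Curve values, parallel to `positions`.
#' @param smooth_window Rolling-mean width; curve length must be at least
#'   three windows.
#' @param height_floor `"auto"` (default), `"median"`, `"none"`, or a
#'   numeric threshold.
#' @param min_separation Minimum distance between retained peaks, in
#'   coordinate units; `NULL` defaults to three times the smoothing window,
#'   0 disables the filter.
#' @return An object of class `peak_set` with `positions`, `heights`
#'   (smoothed-curve values at the maxima) and `steps` (unassigned, `NA`);
#'   empty (zero peaks) when the curve has no concave stretch.
#' @seealso [call_contact_peaks()] for contact curves with step labels.
#' @export
call_curve_peaks <- function(positions, values, smooth_window = 15,
                             height_floor = "auto", min_separation = NULL) {
  n <- length(values)
  stopifnot(length(positions) == n)
  if (n < 3 * smooth_window || n < 3) {
    stop("curve shorter than three smoothing windows", call. = FALSE)
  }
  if (is.null(min_separation)) min_separation <- 3 * smooth_window
  y <- rolling_mean(values, smooth_window)
  d2 <- diff(y, differences = 2)       # d2[j] is curvature at index j + 1
  neg <- d2 < 0
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- numeric(0)
  height <- numeric(0)
  # curvature is only meaningful where the smoothing window is complete, so
  # maxima inside the shrink-window boundary zones are not called
  hl <- (as.integer(smooth_window) - 1L) %/% 2L
  hr <- as.integer(smooth_window) - 1L - hl
  lo_ok <- 2L + hl       # curvature at i uses y[i - 1]; keep windows complete
  hi_ok <- n - hr - 1L
  for (i in which(r$values)) {
    idx <- (starts[i] + 1L):(ends[i] + 1L)   # map run back to curve indices
    top <- idx[which.max(y[idx])]
    if (top < lo_ok || top > hi_ok) next
    pos <- c(pos, positions[top])
    height <- c(height, y[top])
  }
  floor_val <- if (identical(height_floor, "auto")) {
    max(median(y), 0.05 * max(y))
  } else if (identical(height_floor, "median")) {
    median(y)
  } else if (identical(height_floor, "none")) {
    -Inf
  } else if (is.numeric(height_floor)) {
    height_floor
  } else stop("invalid `height_floor`", call. = FALSE)
  keep <- which(height >= floor_val)
  pos <- pos[keep]
  height <- height[keep]
  if (min_separation > 0 && length(pos) > 1) {
    accept <- logical(0)
    acc_pos <- numeric(0)
    for (i in order(height, decreasing = TRUE)) {
      if (!length(acc_pos) || all(abs(acc_pos - pos[i]) >= min_separation)) {
        accept <- c(accept, i)
        acc_pos <- c(acc_pos, pos[i])
      }
    }
    accept <- sort(accept)
    pos <- pos[accept]
    height <- height[accept]
  }
  structure(list(positions = pos, heights = height,
                 steps = rep(NA_integer_, length(pos)),
                 smooth_window = smooth_window, height_floor = floor_val,
                 min_separation = min_separation),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s)\n", length(x$positions)))
  if (length(x$positions)) {
    print(data.frame(position = x$positions, height = signif(x$heights, 4),
                     step = x$steps), row.names = FALSE)
  }
  invisible(x)
}

#' Call nucleosome-step peaks on a contact curve
#'
#' Applies [call_curve_peaks()] to the contact probability curve and assigns
#' consecutive integer step labels (N+1, N+2, ...): the mean spacing of the
#' called maxima estimates one nucleosome step, the first peak's label is its
#' position in units of that spacing, and subsequent peaks increment by one.
#'
#' @param curve A [contact_curve()].
#' @inheritParams call_curve_peaks
#' @return A `peak_set` with `steps` filled (integer `n` meaning the N+n
#'   contact) when at least two peaks are called.
#' @export
call_contact_peaks <- function(curve, smooth_window = 15,
                               height_floor = "auto",
                               min_separation = NULL) {
  stopifnot(inherits(curve, "contact_curve"))
  ps <- call_curve_peaks(curve$distances, curve$probabilities,
                         smooth_window = smooth_window,
                         height_floor = height_floor,
                         min_separation = min_separation)
  k <- length(ps$positions)
  if (k >= 2) {
    spacing <- mean(diff(ps$positions))
    first <- max(1L, as.integer(round(ps$positions[1] / spacing)))
    ps$steps <- first + seq_len(k) - 1L
  }
  ps
}

#' Nucleosome repeat length from called contact peaks
#'
#' The NRL estimate is the mean distance between successive called peak
#' maxima. On an evenly spaced comb this equals the comb spacing exactly and
#' coincides with the least-squares slope of position against step index.
#'
#' @param peaks A `peak_set` with at least two peaks.
#' @param max_peaks Optional cap on the number of leading peaks used.
#' @return NRL in bp.
#' @examples
#' pk <- structure(list(positions = c(186, 372, 558), heights = rep(1, 3),
#'                      steps = 1:3), class = "peak_set")
#' estimate_nrl(pk)
#' @export
estimate_nrl <- function(peaks, max_peaks = Inf) {
  stopifnot(inherits(peaks, "peak_set"))
  k <- min(length(peaks$positions), max_peaks)
  if (k < 2) stop("need at least two called peaks to estimate NRL",
                  call. = FALSE)
  mean(diff(peaks$positions[seq_len(k)]))
}

#' Odd/even (zig-zag) contact ratio
#'
#' `(h_{N+3} + h_{N+5}) / (h_{N+2} + h_{N+4})`, where `h` is the contact
#' signal at each labeled peak. A ratio near or above 1 indicates enrichment
#' of N/N+odd contacts, the signature of zig-zag (two-start) stacking of
#' alternating nucleosomes; a smoothly decaying curve gives a lower ratio.
#' By default `h` is the peak height recorded by the caller (the smoothed
#' curve value at the maximum); `window > 0` instead integrates the raw
#' probabilities within `+-window` bp of each peak.
#'
#' @param curve The [contact_curve()] the peaks were called on.
#' @param peaks A `peak_set` with step labels covering N+2 .. N+5.
#' @param window Half-width (bp) for integrated heights; 0 uses the recorded
#'   peak heights.
#' @return Positive ratio.
#' @export
odd_even_ratio <- function(curve, peaks, window = 0) {
  stopifnot(inherits(curve, "contact_curve"), inherits(peaks, "peak_set"))
  need <- 2:5
  idx <- match(need, peaks$steps)
  if (any(is.na(idx))) {
    stop("peaks must include labeled steps N+2 through N+5", call. = FALSE)
  }
  h <- if (window > 0) {
    vapply(idx, function(i) {
      sel <- abs(curve$distances - peaks$positions[i]) <= window
      sum(curve$probabilities[sel])
    }, numeric(1))
  } else {
    peaks$heights[idx]
  }
  (h[2] + h[4]) / (h[1] + h[3])
}

#' One-call zig-zag summary of a contact curve
#'
#' Calls peaks, estimates the nucleosome repeat length, and computes the
#' odd/even contact ratio.
#'
#' @param curve A [contact_curve()] (the tandem-orientation curve is the
#'   recommended input, since tandem distances carry no nucleosome-length
#'   offset).
#' @inheritParams call_curve_peaks
#' @param max_peaks Cap on peaks entering the NRL average.
#' @return Object of class `zigzag_summary`: list with `nrl`,
#'   `odd_even_ratio`, `peaks`.
#' @export
zigzag_summary <- function(curve, smooth_window = 15, height_floor = "auto",
                           max_peaks = Inf) {
  peaks <- call_contact_peaks(curve, smooth_window = smooth_window,
                              height_floor = height_floor)
  structure(list(nrl = estimate_nrl(peaks, max_peaks = max_peaks),
                 odd_even_ratio = odd_even_ratio(curve, peaks),
                 peaks = peaks),
            class = "zigzag_summary")
}

#' @export
print.zigzag_summary <- function(x, ...) {
  cat(sprintf("<zigzag_summary> NRL = %.1f bp, odd/even ratio = %.3f (%d peaks)\n",
              x$nrl, x$odd_even_ratio, length(x$peaks$positions)))
  invisible(x)
}
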