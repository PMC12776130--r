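#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the previous RNG state, so simulation calls are reproducible
#' without disturbing the caller's random stream.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Centered rolling mean with shrinking edge windows
#'
#' Rolling average of width `window` centered on each element. At the
#' boundaries the window shrinks so the first and last elements are averaged
#' over whatever part of the window lies inside the vector; no values are
#' dropped and the output has the same length as the input. For even window
#' widths the extra position is taken on the right.
#'
#' @param x Numeric vector.
#' @param window Integer window width; `window <= 1` returns `x` unchanged.
#' @return Numeric vector, same length as `x`.
#' @examples
#' rolling_mean(c(1, 2, 3, 4, 5), 3)
#' @export
rolling_mean <- function(x, window) {
  window <- as.integer(window)
  n <- length(x)
  if (window <= 1L || n == 0L) return(as.numeric(x))
  hl <- (window - 1L) %/% 2L
  hr <- window - 1L - hl
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - hl)
  hi <- pmin(n, i + hr)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Span-overlap membership of fragments in a region set
#'
#' A fragment is considered inside the region set iff its full genomic span
#' `[start, end)` (0-based, half-open) overlaps at least 1 bp of any region.
#' This is the span-overlap rule used for both fragment and ligation-pair
#' subsetting.
#'
#' @param chrom,start,end Parallel vectors describing fragment spans
#'   (0-based half-open).
#' @param regions Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Logical vector, `TRUE` where the span overlaps the region set.
#' @examples
#' regs <- data.frame(chrom = "chr1", start = 150, end = 300)
#' fragments_in_regions("chr1", 100, 200, regs)  # TRUE, 50 bp overlap
#' fragments_in_regions("chr1", 100, 150, regs)  # FALSE, half-open abutment
#' @export
fragments_in_regions <- function(chrom, start, end, regions) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(end <= start)) {
    stop("fragment `end` must be greater than `start` (0-based half-open)",
         call. = FALSE)
  }
  if (any(regions$end <= regions$start)) {
    stop("region `end` must be greater than `start`", call. = FALSE)
  }
  keep <- logical(length(chrom))
  for (ch in unique(regions$chrom)) {
    idx <- which(chrom == ch)
    if (!length(idx)) next
    r <- regions[regions$chrom == ch, , drop = FALSE]
    q <- IRanges::IRanges(start = start[idx] + 1L, end = end[idx])
    s <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    keep[idx] <- IRanges::overlapsAny(q, s)
  }
  keep
}

# shared input check for bin tracks (chrom/start/end/value data frames)
check_bin_track <- function(x, arg = deparse(substitute(x))) {
  need <- c("chrom", "start", "end", "value")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop(sprintf("`%s` must be a data frame with columns %s", arg,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
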