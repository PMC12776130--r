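# Independent brute-force oracles used to check the package's vectorized /
# library-backed implementations. These stay deliberately naive (explicit
# loops, no shared code paths with the package internals).

# per-fragment interval scan: span [start, end) overlaps >= 1 bp of a region
brute_overlap <- function(fragments, regions) {
  vapply(seq_len(nrow(fragments)), function(i) {
    any(fragments$chrom[i] == regions$chrom &
          fragments$start[i] < regions$end &
          fragments$end[i] > regions$start)
  }, logical(1))
}

# explicit scan for maximal sub-alpha runs of length >= min_run
brute_runs <- function(p, alpha, min_run) {
  out <- list()
  i <- 1L
  n <- length(p)
  while (i <= n) {
    if (!is.na(p[i]) && p[i] < alpha) {
      j <- i
      while (j < n && !is.na(p[j + 1L]) && p[j + 1L] < alpha) j <- j + 1L
      if (j - i + 1L >= min_run) out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(data.frame(start = numeric(), end = numeric()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# exhaustive local-maximum search within negative second-difference runs of
# the (naively) smoothed curve; mirrors the peak-caller definition (including
# the exclusion of maxima in the truncated-window boundary zones) without
# floors or separation filtering
brute_peaks <- function(positions, values, smooth_window) {
  n <- length(values)
  hl <- (smooth_window - 1L) %/% 2L
  hr <- smooth_window - 1L - hl
  y <- vapply(seq_len(n), function(i) {
    mean(values[max(1L, i - hl):min(n, i + hr)])
  }, numeric(1))
  d2 <- vapply(2:(n - 1L), function(i) y[i + 1L] - 2 * y[i] + y[i - 1L],
               numeric(1))
  pos <- numeric(0)
  h <- numeric(0)
  i <- 1L
  while (i <= length(d2)) {
    if (d2[i] < 0) {
      j <- i
      while (j < length(d2) && d2[j + 1L] < 0) j <- j + 1L
      idx <- (i + 1L):(j + 1L)
      best <- idx[1]
      for (k in idx) if (y[k] > y[best]) best <- k
      if (best >= 2L + hl && best <= n - hr - 1L) {
        pos <- c(pos, positions[best])
        h <- c(h, y[best])
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(positions = pos, heights = h)
}

# random noiseless multi-bump curve on 1..n (Gaussian bumps over a gently
# curved baseline; a nonzero-curvature baseline avoids sign-of-zero
# ambiguities in the second difference)
random_smooth_curve <- function(n = 300, k = NULL) {
  if (is.null(k)) k <- sample(2:5, 1)
  centers <- sort(runif(k, 0.1 * n, 0.9 * n))
  widths <- runif(k, 8, 20)
  amps <- runif(k, 0.5, 2)
  x <- seq_len(n)
  y <- 0.3 + 0.1 * sin(x / runif(1, 25, 60))
  for (j in seq_len(k)) y <- y + amps[j] * dnorm(x, centers[j], widths[j])
  y
}

# empirical mode of a fragment-length vector inside a window, after light
# smoothing of the raw tabulation
window_mode <- function(lengths, lo, hi, smooth = 5) {
  tab <- tabulate(lengths, nbins = max(lengths))
  sm <- chromfold::rolling_mean(tab, smooth)
  win <- lo:hi
  win[which.max(sm[win])]
}
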