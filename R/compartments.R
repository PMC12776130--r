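# Compartment-score orientation against an active-mark reference and
# per-bin shift classification between two conditions.

# Spearman rank correlation with average ranks for ties; p-value from the
# large-sample t approximation with n - 2 degrees of freedom
spearman_stats <- function(x, y) {
  n <- length(x)
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_))
  p <- if (abs(rho) >= 1 - 1e-12) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

align_tracks <- function(a, b, name_a = "a", name_b = "b") {
  check_bin_track(a, name_a)
  check_bin_track(b, name_b)
  key_a <- paste(a$chrom, a$start, a$end)
  key_b <- paste(b$chrom, b$start, b$end)
  if (!setequal(key_a, key_b)) {
    stop(sprintf("`%s` and `%s` are not on the same binning", name_a, name_b),
         call. = FALSE)
  }
  b <- b[match(key_a, key_b), , drop = FALSE]
  list(a = a, b = b)
}

#' Orient compartment scores against a reference active-mark track
#'
#' Compartment scores from contact data carry an arbitrary sign per
#' chromosome. For each chromosome this computes the Spearman rank
#' correlation (average ranks for ties; p from the t approximation with
#' n - 2 df) between the c-scores and a reference signal of the active
#' compartment (e.g. H3K36me3 ChIP), flips the sign of negatively correlated
#' chromosomes so positive scores consistently denote the gene-dense A
#' compartment, and excludes chromosomes whose correlation is not significant
#' at `p_cut`.
#'
#' @param cscore Bin track data frame (`chrom`, `start`, `end`, `value`) of
#'   compartment scores.
#' @param reference Reference bin track on the same binning.
#' @param p_cut Exclusion threshold; chromosomes with `p >= p_cut` (default
#'   0.01) are dropped from the oriented track.
#' @return List with `track` (oriented scores, excluded chromosomes removed)
#'   and `report` (data frame `chrom`, `n`, `rho`, `p`,
#'   `decision` in keep/flip/exclude).
#' @export
orient_cscores <- function(cscore, reference, p_cut = 0.01) {
  al <- align_tracks(cscore, reference, "cscore", "reference")
  cscore <- al$a
  reference <- al$b
  chroms <- unique(cscore$chrom)
  report <- lapply(chroms, function(ch) {
    sel <- cscore$chrom == ch
    n <- sum(sel)
    if (n < 5) {
      stop(sprintf("chromosome %s has fewer than 5 bins", ch), call. = FALSE)
    }
    st <- spearman_stats(cscore$value[sel], reference$value[sel])
    decision <- if (is.na(st$p) || st$p >= p_cut) {
      "exclude"
    } else if (st$rho < 0) "flip" else "keep"
    data.frame(chrom = ch, n = n, rho = st$rho, p = st$p,
               decision = decision, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, report)
  oriented <- cscore
  for (i in seq_len(nrow(report))) {
    sel <- oriented$chrom == report$chrom[i]
    if (report$decision[i] == "flip") {
      oriented$value[sel] <- -oriented$value[sel]
    }
  }
  keep_chrom <- report$chrom[report$decision != "exclude"]
  oriented <- oriented[oriented$chrom %in% keep_chrom, , drop = FALSE]
  list(track = oriented, report = report)
}

#' Classify per-bin compartment shifts between two conditions
#'
#' For oriented score tracks of conditions A and B on a shared binning, the
#' per-bin difference `delta = B - A` is labeled: `stable` when
#' `|delta| <= threshold`; a sign change negative-to-positive is `B_to_A`
#' and positive-to-negative `A_to_B`; within the same compartment sign, an
#' increase is `A_shifted` and a decrease `B_shifted`. An exactly-zero score
#' counts as nonnegative (A side). Bins missing a value in either track are
#' dropped and counted.
#'
#' @param a,b Oriented bin tracks (`chrom`, `start`, `end`, `value`).
#' @param threshold Minimum `|delta|` for a non-stable call (default 0.25;
#'   0.2 is also in published use for the same statistic, so the threshold is
#'   exposed).
#' @return List with `calls` (data frame `chrom`, `start`, `end`, `value_a`,
#'   `value_b`, `delta`, `label`) and `n_missing` (bins dropped for missing
#'   values).
#' @examples
#' a <- data.frame(chrom = "chr1", start = 0, end = 1e5, value = -0.5)
#' b <- data.frame(chrom = "chr1", start = 0, end = 1e5, value = 0.5)
#' classify_shifts(a, b)$calls$label  # "B_to_A"
#' @export
classify_shifts <- function(a, b, threshold = 0.25) {
  al <- align_tracks(a, b, "a", "b")
  a <- al$a
  b <- al$b
  va <- a$value
  vb <- b$value
  miss <- is.na(va) | is.na(vb)
  calls <- data.frame(chrom = a$chrom, start = a$start, end = a$end,
                      value_a = va, value_b = vb, delta = vb - va,
                      stringsAsFactors = FALSE)[!miss, , drop = FALSE]
  lab <- character(nrow(calls))
  da <- calls$value_a
  db <- calls$value_b
  dd <- calls$delta
  stable <- abs(dd) <= threshold
  lab[stable] <- "stable"
  chg <- !stable
  lab[chg & da < 0 & db >= 0] <- "B_to_A"
  lab[chg & da >= 0 & db < 0] <- "A_to_B"
  same <- chg & ((da >= 0 & db >= 0) | (da < 0 & db < 0))
  lab[same & dd > 0] <- "A_shifted"
  lab[same & dd < 0] <- "B_shifted"
  calls$label <- lab
  list(calls = calls, n_missing = sum(miss))
}
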