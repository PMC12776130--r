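# Parsers and writers for the text formats the pipeline touches: fragment
# length histograms (plain two-column TSV and the HISTOGRAM section of Picard
# CollectInsertSizeMetrics logs), 4DN .pairs, BED / gappedPeak region sets,
# bedGraph bin tracks, BED3+length fragment tables, and corrected-curve TSVs
# with a JSON metadata sidecar. Every writer emits files its parser
# round-trips.

hist_meta_fields <- c("sample_id", "condition", "bio_rep", "tech_rep",
                      "source", "subset")

#' Parse a fragment length histogram file
#'
#' Accepts either a plain two-column table (`insert_size`, `count`; `#` lines
#' are metadata, an optional non-numeric first row is a header) or a Picard
#' CollectInsertSizeMetrics metrics log, from which the table following the
#' `## HISTOGRAM` marker is extracted. Metadata lines of the form
#' `# key=value` populate the histogram's metadata fields.
#'
#' @param path File to read.
#' @return An [fld_histogram()].
#' @export
parse_histogram <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hidx <- grep("^## HISTOGRAM", lines)
  meta <- list()
  if (length(hidx)) {
    block <- lines[seq.int(hidx[1] + 1L, length(lines))]
    stop_at <- which(!nzchar(trimws(block)) | grepl("^##", block))
    if (length(stop_at)) block <- block[seq_len(min(stop_at) - 1L)]
    tab <- block
  } else {
    meta_lines <- grep("^#", lines, value = TRUE)
    kv <- regmatches(meta_lines,
                     regexec("^#\\s*([A-Za-z_]+)=(.*)$", meta_lines))
    for (m in kv) {
      if (length(m) == 3 && m[2] %in% hist_meta_fields) meta[[m[2]]] <- m[3]
    }
    tab <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  }
  if (length(tab)) {
    first <- strsplit(trimws(tab[1]), "[ \t]+")[[1]]
    has_header <- is.na(suppressWarnings(as.numeric(first[1])))
    if (has_header) tab <- tab[-1]
  }
  if (!length(tab)) stop("histogram table is empty", call. = FALSE)
  df <- read.table(text = paste(tab, collapse = "\n"),
                   col.names = c("length", "count"),
                   colClasses = c("numeric", "numeric"))
  if (any(df$length != round(df$length)) || any(df$length < 1)) {
    stop("histogram lengths must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(df$length)) {
    stop("duplicate lengths in histogram", call. = FALSE)
  }
  if (any(diff(df$length) <= 0)) {
    stop("histogram lengths must be increasing", call. = FALSE)
  }
  args <- c(list(lengths = as.integer(df$length), counts = df$count), meta)
  # parse NA placeholders written by write_histogram back to NA
  for (f in hist_meta_fields) {
    if (!is.null(args[[f]]) && args[[f]] == "NA") args[[f]] <- NA_character_
  }
  do.call(fld_histogram, args)
}

#' Write a fragment length histogram
#'
#' Two-column TSV with `# key=value` metadata lines; [parse_histogram()]
#' round-trips the output.
#'
#' @param hist An [fld_histogram()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "fld_histogram"))
  meta <- vapply(hist_meta_fields, function(f) {
    sprintf("# %s=%s", f, as.character(hist[[f]]))
  }, character(1))
  body <- sprintf("%d\t%.10g", hist$lengths, hist$counts)
  writeLines(c(meta, "insert_size\tcount", body), path)
  invisible(path)
}

#' Parse a 4DN .pairs file
#'
#' Reads the text pairs format (`## pairs format v1.0` header, `#` comment
#' lines, columns readID chrom1 pos1 chrom2 pos2 strand1 strand2). Malformed
#' records (wrong column count, non-numeric or negative positions, invalid
#' strand symbols) are skipped with a warning; more than 10% malformed lines
#' is an error. A header-only file yields an empty table.
#'
#' @param path File to read.
#' @return Data frame with columns `read_id`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `strand1`, `strand2`.
#' @export
parse_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  empty <- data.frame(read_id = character(), chrom1 = character(),
                      pos1 = integer(), chrom2 = character(),
                      pos2 = integer(), strand1 = character(),
                      strand2 = character(), stringsAsFactors = FALSE)
  if (!length(data)) return(empty)
  parts <- strsplit(trimws(data), "[ \t]+")
  nfld <- lengths(parts)
  ok <- nfld >= 7L
  get <- function(i) vapply(parts[ok], `[[`, character(1), i)
  p1 <- suppressWarnings(as.numeric(get(3)))
  p2 <- suppressWarnings(as.numeric(get(5)))
  s1 <- get(6)
  s2 <- get(7)
  good <- !is.na(p1) & !is.na(p2) & p1 >= 0 & p2 >= 0 &
    s1 %in% c("+", "-") & s2 %in% c("+", "-")
  n_bad <- sum(!ok) + sum(!good)
  if (n_bad > 0.1 * length(data)) {
    stop(sprintf("%d of %d pair records malformed (> 10%%)", n_bad,
                 length(data)), call. = FALSE)
  }
  if (n_bad > 0) {
    warning(sprintf("skipped %d malformed pair record(s)", n_bad),
            call. = FALSE)
  }
  if (!any(good)) return(empty)
  data.frame(read_id = get(1)[good], chrom1 = get(2)[good],
             pos1 = as.integer(p1[good]), chrom2 = get(4)[good],
             pos2 = as.integer(p2[good]), strand1 = s1[good],
             strand2 = s2[good], stringsAsFactors = FALSE)
}

#' Write a 4DN .pairs file
#'
#' @param pairs Pair data frame (see [parse_pairs()] for columns).
#' @param path Output file.
#' @param chrom_sizes Optional named vector written as `#chromsize:` lines.
#' @param seed Optional seed recorded in the header for provenance.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, chrom_sizes = NULL, seed = NULL) {
  header <- c("## pairs format v1.0",
              "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2")
  if (!is.null(chrom_sizes)) {
    header <- c(header, sprintf("#chromsize: %s %d", names(chrom_sizes),
                                as.integer(chrom_sizes)))
  }
  if (!is.null(seed)) header <- c(header, sprintf("#seed: %d", as.integer(seed)))
  body <- sprintf("%s\t%s\t%d\t%s\t%d\t%s\t%s", pairs$read_id, pairs$chrom1,
                  pairs$pos1, pairs$chrom2, pairs$pos2, pairs$strand1,
                  pairs$strand2)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Parse a BED or gappedPeak region set
#'
#' Reads at least `chrom`, `start`, `end` (0-based half-open); a fourth
#' column, when present, is kept as the region name / state label. Extra
#' columns (scores, strand, the block structure of 15-column gappedPeak
#' records) are ignored: only coordinates and names are retained. Overlapping
#' intervals are merged only when `merge = TRUE` (names are dropped by
#' merging).
#'
#' @param path File to read.
#' @param merge Merge overlapping intervals per chromosome.
#' @return Data frame `chrom`, `start`, `end`, `name`.
#' @export
parse_regions <- function(path, merge = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(parts) < 3)) {
    stop("region records need at least 3 columns", call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, character(1), 1)
  start <- as.integer(vapply(parts, `[[`, character(1), 2))
  end <- as.integer(vapply(parts, `[[`, character(1), 3))
  if (any(is.na(start)) || any(is.na(end))) {
    stop("non-numeric region coordinates", call. = FALSE)
  }
  if (any(start >= end)) {
    stop("region `start` must be below `end` (0-based half-open)",
         call. = FALSE)
  }
  name <- vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_,
                 character(1))
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    stringsAsFactors = FALSE)
  if (merge) {
    merged <- lapply(split(out, out$chrom), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir), name = NA_character_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, merged)
    rownames(out) <- NULL
  }
  out
}

#' Write a region set as BED
#'
#' BED3 when no names are present, otherwise BED6 with the name field (score
#' 0, strand `.`).
#'
#' @param regions Data frame `chrom`, `start`, `end` and optionally `name`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  has_name <- "name" %in% names(regions) && any(!is.na(regions$name))
  body <- if (has_name) {
    sprintf("%s\t%d\t%d\t%s\t0\t.", regions$chrom, as.integer(regions$start),
            as.integer(regions$end), ifelse(is.na(regions$name), ".",
                                            regions$name))
  } else {
    sprintf("%s\t%d\t%d", regions$chrom, as.integer(regions$start),
            as.integer(regions$end))
  }
  writeLines(body, path)
  invisible(path)
}

#' Read a bedGraph bin track
#'
#' @param path File to read (`track` and `#` lines are skipped).
#' @return Data frame `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  df <- read.table(text = paste(lines, collapse = "\n"),
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer",
                                  "numeric"))
  df
}

#' Write a bedGraph bin track
#'
#' @param track Data frame `chrom`, `start`, `end`, `value`.
#' @param path Output file.
#' @param name Optional track name emitted as a `track` line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, name = NULL) {
  check_bin_track(track)
  header <- if (!is.null(name)) {
    sprintf("track type=bedGraph name=\"%s\"", name)
  } else character(0)
  body <- sprintf("%s\t%d\t%d\t%.10g", track$chrom, as.integer(track$start),
                  as.integer(track$end), track$value)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a BED3+length fragment table
#'
#' @param path File to read; a fourth column is taken as the fragment length
#'   (nt), otherwise `end - start` is used.
#' @return Data frame `chrom`, `start`, `end`, `length`.
#' @export
read_fragments_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  if (!length(parts)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  chrom <- vapply(parts, `[[`, character(1), 1)
  start <- as.integer(vapply(parts, `[[`, character(1), 2))
  end <- as.integer(vapply(parts, `[[`, character(1), 3))
  len <- vapply(parts, function(p) {
    if (length(p) >= 4) as.integer(p[4]) else NA_integer_
  }, integer(1))
  len[is.na(len)] <- (end - start)[is.na(len)]
  data.frame(chrom = chrom, start = start, end = end, length = len,
             stringsAsFactors = FALSE)
}

#' Write a BED3+length fragment table
#'
#' @param fragments Data frame `chrom`, `start`, `end` and optionally
#'   `length`.
#' @param path Output file.
#' @param seed Optional seed recorded as a `#` header line.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path, seed = NULL) {
  len <- if ("length" %in% names(fragments)) fragments$length
  else fragments$end - fragments$start
  header <- if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed))
  else character(0)
  body <- sprintf("%s\t%d\t%d\t%d", fragments$chrom,
                  as.integer(fragments$start), as.integer(fragments$end),
                  as.integer(len))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a corrected curve as TSV with a JSON metadata sidecar
#'
#' The TSV holds the grid, values and (when defined) confidence bounds; the
#' sidecar `<path>.json` records sample metadata, replicate count and the
#' processing parameters stored in `info` (scaling factors, bias parameters,
#' windows), so outputs carry full provenance.
#'
#' @param curve A [corrected_curve()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_corrected_curve <- function(curve, path) {
  stopifnot(inherits(curve, "corrected_curve"))
  df <- data.frame(position = curve$grid, value = curve$values)
  if (!is.null(curve$ci_lower)) {
    df$ci_lower <- curve$ci_lower
    df$ci_upper <- curve$ci_upper
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  info <- curve$info
  info$bias <- if (!is.null(info$bias)) unclass(info$bias)
  meta <- list(sample_id = curve$sample_id, condition = curve$condition,
               source = curve$source, subset = curve$subset,
               n_replicates = curve$n_replicates, info = info)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read a corrected curve written by [write_corrected_curve()]
#'
#' @param path TSV path (the `<path>.json` sidecar is read when present).
#' @return A [corrected_curve()].
#' @export
read_corrected_curve <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  corrected_curve(df$position, df$value,
                  n_replicates = meta$n_replicates %||% 1L,
                  ci_lower = df$ci_lower, ci_upper = df$ci_upper,
                  sample_id = meta$sample_id %||% basename(path),
                  condition = meta$condition %||% NA_character_,
                  source = meta$source %||% "cell",
                  subset = meta$subset %||% NA_character_,
                  info = meta$info %||% list())
}
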