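# Genomic interval algebra and BED I/O.
#
# Intervals are plain data.frames with columns chrom (character), start, end
# (numeric, 0-based half-open) and an optional label column. Coordinates are
# stored as doubles: genome positions exceed what is comfortable for
# 32-bit-integer products, and all arithmetic here is exact below 2^53.

#' Construct a set of genomic intervals
#'
#' Builds the interval data.frame used throughout the package: chromosome
#' label, 0-based inclusive start, exclusive end. Size in bp is `end - start`.
#'
#' @param chrom Chromosome labels (character); a `"chr"` prefix is stripped so
#'   `"chr10"` and `"10"` compare equal.
#' @param start,end Coordinates, `start < end`, `start >= 0`.
#' @param label Optional name per interval.
#' @return A data.frame with columns `chrom`, `start`, `end` and, when given,
#'   `label`.
#' @examples
#' gi("10", 134492316, 134941539, label = "case5")
#' @export
gi <- function(chrom, start, end, label = NULL) {
  x <- data.frame(chrom = normalize_chrom(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  if (!is.null(label)) x$label <- as.character(label)
  validate_gi(x)
  x
}

#' @rdname gi
#' @param x A candidate interval data.frame.
#' @export
validate_gi <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop("interval coordinates must not be NA", call. = FALSE)
  if (any(x$start < 0))
    stop("interval start must be >= 0", call. = FALSE)
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop(sprintf("malformed interval (start >= end) at row %d: %s:%s-%s",
                 bad[1], x$chrom[bad[1]],
                 format(x$start[bad[1]], scientific = FALSE),
                 format(x$end[bad[1]], scientific = FALSE)), call. = FALSE)
  invisible(x)
}

#' Normalize chromosome labels
#'
#' Strips any `"chr"` prefix so both BED dialects compare equal.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector without `"chr"` prefixes.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

#' Interval width in bp
#' @param x Interval data.frame.
#' @return Numeric vector of `end - start`.
#' @export
gi_width <- function(x) {
  x$end - x$start
}

#' Intersect two genomic intervals
#'
#' Same-chromosome intervals yield `[max(starts), min(ends))` when that span
#' is non-empty; disjoint intervals or different chromosomes yield `NULL`
#' (the empty marker).
#'
#' @param a,b Single-row interval data.frames (see [gi()]).
#' @return A one-row interval data.frame, or `NULL` when the intersection is
#'   empty.
#' @examples
#' a <- gi("10", 134492316, 134941539)
#' b <- gi("10", 134543728, 134955025)
#' gi_intersect(a, b) # 134,543,728-134,941,539
#' @export
gi_intersect <- function(a, b) {
  validate_gi(a); validate_gi(b)
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (a$chrom != b$chrom) return(NULL)
  s <- max(a$start, b$start)
  e <- min(a$end, b$end)
  if (s >= e) return(NULL)
  gi(a$chrom, s, e)
}

#' Reciprocal overlap fraction of two intervals
#'
#' The standard CNV-matching criterion: `min(|a n b| / |a|, |a n b| / |b|)`.
#' Returns 0 for disjoint intervals or different chromosomes; symmetric in
#' its arguments. `b` may hold several intervals; `a` must be a single one,
#' and the result is one fraction per row of `b`.
#'
#' @param a Single-row interval data.frame.
#' @param b Interval data.frame (any number of rows).
#' @return Numeric vector in `[0, 1]`, length `nrow(b)`.
#' @export
reciprocal_overlap <- function(a, b) {
  validate_gi(a); validate_gi(b)
  stopifnot(nrow(a) == 1L)
  if (nrow(b) == 0L) return(numeric(0))
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  ov <- pmax(ov, 0)
  ov[b$chrom != a$chrom] <- 0
  ifelse(ov == 0, 0, pmin(ov / (a$end - a$start), ov / (b$end - b$start)))
}

#' Format a size in bp the way CNV tables print it
#'
#' Below 1 Mb: `floor(bp / 1000)` with unit `"Kb"`. At or above 1 Mb:
#' `floor(bp / 1e4) / 100` with unit `"Mb"` (two decimals, floored). Flooring
#' (never rounding up) is deliberate: it is the convention that reproduces
#' published size cells such as 182,706 bp -> "182 Kb".
#'
#' @param bp Non-negative sizes in bp (vectorized).
#' @return Character vector of size labels.
#' @examples
#' format_size(c(536879, 1672881, 999))
#' @export
format_size <- function(bp) {
  bp <- as.numeric(bp)
  if (any(is.na(bp)) || any(bp < 0)) stop("bp must be >= 0", call. = FALSE)
  ifelse(bp < 1e6,
         sprintf("%d Kb", as.integer(floor(bp / 1000))),
         sprintf("%.2f Mb", floor(bp / 1e4) / 100))
}

#' Read / write BED interval files
#'
#' Tab-separated, 3+ columns; column 4, when present, is kept as `label`.
#' Output is always sorted by (chrom, start, end). `write_bed()` then
#' `read_bed()` round-trips exactly.
#'
#' @param path File path.
#' @return `read_bed`: an interval data.frame with columns `chrom`, `start`,
#'   `end` and `label` (NA when absent).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gi_empty())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3))
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 which(n < 3)[1]), call. = FALSE)
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 bad[1]), call. = FALSE)
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: start >= end", bad[1]),
         call. = FALSE)
  label <- vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
  x <- data.frame(chrom = normalize_chrom(chrom), start = start, end = end,
                  label = label, stringsAsFactors = FALSE)
  gi_sort(x)
}

#' @rdname read_bed
#' @param x Interval data.frame.
#' @export
write_bed <- function(x, path) {
  validate_gi(x)
  x <- gi_sort(x)
  label <- if ("label" %in% names(x)) x$label else rep(NA_character_, nrow(x))
  lines <- ifelse(is.na(label),
                  sprintf("%s\t%s\t%s", x$chrom,
                          format(x$start, scientific = FALSE, trim = TRUE),
                          format(x$end, scientific = FALSE, trim = TRUE)),
                  sprintf("%s\t%s\t%s\t%s", x$chrom,
                          format(x$start, scientific = FALSE, trim = TRUE),
                          format(x$end, scientific = FALSE, trim = TRUE), label))
  writeLines(lines, path)
  invisible(path)
}

#' Sort intervals by (chrom, start, end)
#' @param x Interval data.frame.
#' @return The sorted data.frame, row names reset.
#' @export
gi_sort <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

# Empty interval set with the canonical columns.
gi_empty <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

#' Total length covered by the union of intervals on one chromosome
#'
#' Overlapping intervals are merged before measuring, so double-covered bases
#' count once. All intervals must share `chrom`.
#'
#' @param x Interval data.frame (possibly empty).
#' @return Total covered bases (numeric scalar).
#' @export
gi_union_length <- function(x) {
  if (nrow(x) == 0L) return(0)
  stopifnot(length(unique(x$chrom)) == 1L)
  x <- x[order(x$start, x$end), , drop = FALSE]
  total <- 0
  cur_s <- x$start[1]; cur_e <- x$end[1]
  if (nrow(x) > 1L) for (i in 2:nrow(x)) {
    if (x$start[i] <= cur_e) {
      cur_e <- max(cur_e, x$end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- x$start[i]; cur_e <- x$end[i]
    }
  }
  total + (cur_e - cur_s)
}
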