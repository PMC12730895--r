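#' Genomic interval sets
#'
#' An `interval_set` is a normalized tibble of 0-based half-open genomic
#' intervals (`chrom`, `start`, `end`), the BED convention. Normalization
#' sorts intervals and merges overlapping *and book-ended* intervals, so
#' region-size arithmetic is unambiguous. Interval algebra is delegated to
#' IRanges/GenomicRanges; the 0-based half-open (BED) to 1-based closed
#' (GRanges/VCF) conversion is centralized in two internal helpers.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-ish vectors; 0-based half-open coordinates with
#'   `start < end`.
#' @return A tibble of class `interval_set` with columns `chrom`, `start`,
#'   `end`, sorted and disjoint.
#' @examples
#' interval_set(c("chr1", "chr1"), c(10, 15), c(20, 30))
#' @export
interval_set <- function(chrom = character(), start = integer(), end = integer()) {
  as_interval_set(tibble(chrom = as.character(chrom),
                         start = as.numeric(start), end = as.numeric(end)))
}

#' Coerce a data frame to a normalized interval set
#'
#' @param x A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return An `interval_set` tibble.
#' @export
as_interval_set <- function(x) {
  require_columns(x, c("chrom", "start", "end"), "interval table")
  x <- as_tibble(x)[, c("chrom", "start", "end")]
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  bad <- which(!is.finite(x$start) | !is.finite(x$end) | x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    abort_format(sprintf(
      "invalid interval%s at row%s %s: need 0 <= start < end",
      if (length(bad) > 1) "s" else "", if (length(bad) > 1) "s" else "",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  out <- gr_to_iv(GenomicRanges::reduce(iv_to_gr(x)))
  class(out) <- c("interval_set", class(out))
  out
}

# BED half-open [start, end) -> GRanges 1-based closed [start+1, end]
iv_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

# GRanges 1-based closed -> BED half-open
gr_to_iv <- function(gr) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
}

restore_iv <- function(df) {
  class(df) <- unique(c("interval_set", class(df)))
  df
}

#' Read a BED file into an interval set
#'
#' Reads BED3+ (extra columns ignored), skipping `track`/`browser`/comment
#' lines. Intervals are validated (`start < end`, with offending line
#' numbers reported), then sorted and merged.
#'
#' @param path Path to a BED file.
#' @return An `interval_set` tibble.
#' @export
read_intervals <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(interval_set())
  }
  fields <- strsplit(lines[keep], "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort_format(sprintf("BED line %d has fewer than 3 fields",
                         which(keep)[which(nf < 3)[1]]))
  }
  df <- tibble(
    chrom = map_chr(fields, 1),
    start = suppressWarnings(as.numeric(map_chr(fields, 2))),
    end = suppressWarnings(as.numeric(map_chr(fields, 3)))
  )
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$start < 0 | df$start >= df$end)
  if (length(bad) > 0) {
    abort_format(sprintf("invalid BED interval (need 0 <= start < end) at line %d of %s",
                         which(keep)[bad[1]], path))
  }
  as_interval_set(df)
}

#' Write an interval set as BED3
#'
#' @param x An `interval_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  readr::write_tsv(as_tibble(x)[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Total bases covered by an interval set
#'
#' @param x An `interval_set`.
#' @return Total width in bases (intervals are disjoint after normalization).
#' @export
interval_total_bases <- function(x) {
  x <- as_interval_set(x)
  sum(x$end - x$start)
}

#' Intersect two interval sets
#'
#' @param x,y `interval_set` objects (or coercible data frames).
#' @return The `interval_set` covering bases present in both inputs.
#' @export
intersect_intervals <- function(x, y) {
  gr <- GenomicRanges::intersect(iv_to_gr(as_interval_set(x)),
                                 iv_to_gr(as_interval_set(y)))
  restore_iv(gr_to_iv(gr))
}

#' Pad every interval by a fixed number of bases on each side
#'
#' Starts are clipped at 0. Used for the exon +/- 2 bp padding when building
#' target regions.
#'
#' @param x An `interval_set`.
#' @param pad Non-negative number of bases added to each side.
#' @return A padded, re-normalized `interval_set`.
#' @export
pad_intervals <- function(x, pad) {
  x <- as_interval_set(x)
  if (nrow(x) == 0) return(x)
  as_interval_set(mutate(x, start = pmax(0, start - pad), end = end + pad))
}

#' Test 1-based positions for membership in an interval set
#'
#' @param chrom,pos Parallel vectors of chromosome names and 1-based
#'   positions (the VCF convention for variant coordinates).
#' @param region An `interval_set` (0-based half-open).
#' @return Logical vector.
#' @export
in_intervals <- function(chrom, pos, region) {
  region <- as_interval_set(region)
  if (length(chrom) == 0) return(logical(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, end = pos))
  GenomicRanges::countOverlaps(q, iv_to_gr(region)) > 0
}

#' Common target region across studies
#'
#' Exact base-wise intersection of study-specific target regions; the result
#' never exceeds the smallest input.
#'
#' @param study_regions A list of `interval_set` objects (at least one).
#' @return The intersection `interval_set`.
#' @export
common_target_region <- function(study_regions) {
  if (!is.list(study_regions) || length(study_regions) == 0 ||
      is.data.frame(study_regions)) {
    abort_config("`study_regions` must be a non-empty list of interval sets")
  }
  Reduce(intersect_intervals, study_regions)
}
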