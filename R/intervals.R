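#' Genomic interval helpers
#'
#' All coordinates in this package are 1-based and inclusive, matching the
#' HGVS g. convention used for genomic loci and breakpoints. BED input/output
#' converts to and from the 0-based half-open convention at the file boundary.
#'
#' @name lr-intervals
NULL

#' Length of a 1-based inclusive interval
#'
#' @param start,end 1-based inclusive positions (vectorised).
#' @return Integer vector of lengths, `end - start + 1`.
#' @examples
#' interval_length(100, 200) # 101
#' @export
interval_length <- function(start, end) {
  check_interval(start, end)
  as.integer(end - start + 1)
}

check_interval <- function(start, end, what = "interval") {
  if (any(is.na(start)) || any(is.na(end))) {
    rlang::abort(paste0("NA coordinates in ", what))
  }
  if (any(start < 1)) {
    rlang::abort(paste0(what, ": start must be >= 1 (1-based inclusive)"))
  }
  if (any(end < start)) {
    rlang::abort(paste0(what, ": end < start"))
  }
  invisible(TRUE)
}

#' Parse a region string
#'
#' Accepts `"contig:start-end"` (1-based inclusive). Also tolerates an
#' en-dash and thousands separators, so printed locus coordinates can be
#' pasted directly.
#'
#' @param region Region string, e.g. `"chr1:100-200"`.
#' @return A one-row tibble with columns `contig`, `start`, `end`.
#' @export
parse_region <- function(region) {
  stopifnot(is.character(region), length(region) == 1L)
  x <- gsub(",", "", region)
  x <- gsub("–", "-", x) # en-dash
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L) {
    rlang::abort(sprintf("cannot parse region '%s' (expected contig:start-end)", region))
  }
  start <- as.integer(m[3])
  end <- as.integer(m[4])
  check_interval(start, end, what = sprintf("region '%s'", region))
  tibble::tibble(contig = m[2], start = start, end = end)
}

# Coerce a region given as string or data frame to a one-row tibble.
as_region_tbl <- function(region) {
  if (is.character(region)) {
    return(parse_region(region))
  }
  stopifnot(is.data.frame(region), nrow(region) == 1L)
  stopifnot(all(c("contig", "start", "end") %in% names(region)))
  check_interval(region$start, region$end)
  tibble::as_tibble(region)[, c("contig", "start", "end")]
}

# IRanges bridge: tibble with start/end -> IRanges
as_iranges <- function(df) {
  IRanges::IRanges(start = df$start, end = df$end)
}

iranges_to_tbl <- function(ir) {
  tibble::tibble(
    start = BiocGenerics::start(ir),
    end = BiocGenerics::end(ir)
  )
}
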