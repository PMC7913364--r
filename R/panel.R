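#' Read a long-range amplicon panel definition
#'
#' A panel file is a BED-derived TSV: one row per amplicon with columns
#' `contig`, `start`, `end` (BED 0-based half-open), `locus`, `amplicon`,
#' an ignored `score` placeholder, and optional forward/reverse primer-site
#' spans written as `"start-end"` (1-based inclusive). Lines beginning with
#' `#` are comments. Coordinates are converted to the package's 1-based
#' inclusive convention on load.
#'
#' Validation enforced at load: `end >= start` for every amplicon, unique
#' `(locus, amplicon)` names, primer sites (when given) lying at and within
#' the two ends of their amplicon, and loci that do not overlap one another
#' on the same contig (loci are disjoint accounting units).
#'
#' @param path Path to the panel TSV.
#' @return An `lr_panel`: a tibble with one row per amplicon, columns
#'   `locus`, `amplicon`, `contig`, `start`, `end`, `product_size_bp`,
#'   `fwd_start`, `fwd_end`, `rev_start`, `rev_end` (primer columns are `NA`
#'   when the file omits them), sorted by locus then start.
#' @seealso [write_panel()], [locus_target_size()], [find_gaps()]
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(new_panel(empty_panel_tbl()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 5L)) {
    bad <- which(n < 5L)[1]
    rlang::abort(sprintf("malformed panel row %d: expected >= 5 tab-separated fields", bad))
  }
  rows <- purrr::imap(fields, function(f, i) {
    start0 <- suppressWarnings(as.integer(f[2]))
    end0 <- suppressWarnings(as.integer(f[3]))
    if (is.na(start0) || is.na(end0)) {
      rlang::abort(sprintf("malformed panel row %d: non-numeric coordinates", i))
    }
    tibble::tibble(
      locus = f[4], amplicon = f[5], contig = f[1],
      start = start0 + 1L, end = end0,
      fwd = if (length(f) >= 7L) f[7] else NA_character_,
      rev = if (length(f) >= 8L) f[8] else NA_character_
    )
  })
  tbl <- dplyr::bind_rows(rows)
  if (any(tbl$end < tbl$start)) {
    bad <- which(tbl$end < tbl$start)[1]
    rlang::abort(sprintf("panel row %d: end < start", bad))
  }
  tbl <- dplyr::bind_cols(tbl, parse_primer_span(tbl$fwd, "fwd"), parse_primer_span(tbl$rev, "rev"))
  tbl$fwd <- tbl$rev <- NULL
  tbl$product_size_bp <- interval_length(tbl$start, tbl$end)
  tbl <- tbl[, c("locus", "amplicon", "contig", "start", "end", "product_size_bp",
                 "fwd_start", "fwd_end", "rev_start", "rev_end")]
  tbl <- dplyr::arrange(tbl, .data$locus, .data$start)
  new_panel(tbl)
}

parse_primer_span <- function(x, prefix) {
  x[!is.na(x) & (x == "." | x == "")] <- NA_character_
  m <- regmatches(x, regexec("^([0-9]+)-([0-9]+)$", x))
  start <- vapply(m, function(g) if (length(g) == 3L) as.integer(g[2]) else NA_integer_, integer(1))
  end <- vapply(m, function(g) if (length(g) == 3L) as.integer(g[3]) else NA_integer_, integer(1))
  bad <- !is.na(x) & is.na(start)
  if (any(bad)) {
    rlang::abort(sprintf("malformed %s primer span '%s'", prefix, x[which(bad)[1]]))
  }
  out <- tibble::tibble(start, end)
  names(out) <- paste0(prefix, c("_start", "_end"))
  out
}

empty_panel_tbl <- function() {
  tibble::tibble(
    locus = character(), amplicon = character(), contig = character(),
    start = integer(), end = integer(), product_size_bp = integer(),
    fwd_start = integer(), fwd_end = integer(),
    rev_start = integer(), rev_end = integer()
  )
}

new_panel <- function(tbl) {
  validate_panel(tbl)
  class(tbl) <- c("lr_panel", class(tbl))
  tbl
}

#' Build a panel from an amplicon tibble
#'
#' Programmatic constructor mirroring [read_panel()]: takes 1-based inclusive
#' coordinates directly.
#'
#' @param amplicons Tibble with columns `locus`, `amplicon`, `contig`,
#'   `start`, `end` and optional `fwd_start`, `fwd_end`, `rev_start`,
#'   `rev_end`.
#' @return An `lr_panel` tibble.
#' @export
as_panel <- function(amplicons) {
  tbl <- tibble::as_tibble(amplicons)
  need <- c("locus", "amplicon", "contig", "start", "end")
  if (!all(need %in% names(tbl))) {
    rlang::abort(paste("panel needs columns:", paste(need, collapse = ", ")))
  }
  for (col in c("fwd_start", "fwd_end", "rev_start", "rev_end")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_integer_
  }
  tbl$start <- as.integer(tbl$start)
  tbl$end <- as.integer(tbl$end)
  tbl$product_size_bp <- interval_length(tbl$start, tbl$end)
  tbl <- tbl[, names(empty_panel_tbl())]
  tbl <- dplyr::arrange(tbl, .data$locus, .data$start)
  new_panel(tbl)
}

validate_panel <- function(tbl) {
  if (nrow(tbl) == 0L) {
    return(invisible(TRUE))
  }
  check_interval(tbl$start, tbl$end, what = "amplicon")
  key <- paste(tbl$locus, tbl$amplicon, sep = "\r")
  if (anyDuplicated(key)) {
    rlang::abort("duplicate (locus, amplicon) names in panel")
  }
  # one contig per locus
  per <- dplyr::summarise(dplyr::group_by(tbl, .data$locus),
    ncontig = dplyr::n_distinct(.data$contig), .groups = "drop")
  if (any(per$ncontig > 1L)) {
    rlang::abort("a locus spans multiple contigs")
  }
  # primer sites must sit at and within the amplicon ends
  has_p <- !is.na(tbl$fwd_start)
  if (any(has_p)) {
    p <- tbl[has_p, ]
    ok <- p$fwd_start == p$start & p$fwd_end <= p$end & p$fwd_end >= p$fwd_start &
      p$rev_end == p$end & p$rev_start >= p$start & p$rev_start <= p$rev_end
    if (any(!ok)) {
      rlang::abort("primer sites must lie at the two ends of, and within, their amplicon")
    }
  }
  # loci on the same contig must not overlap each other
  spans <- dplyr::summarise(dplyr::group_by(tbl, .data$locus),
    contig = .data$contig[1], start = min(.data$start), end = max(.data$end),
    .groups = "drop")
  for (ctg in unique(spans$contig)) {
    s <- dplyr::arrange(spans[spans$contig == ctg, ], .data$start)
    if (nrow(s) > 1L && any(s$start[-1] <= s$end[-nrow(s)])) {
      rlang::abort(sprintf("loci overlap on contig %s (loci must be disjoint)", ctg))
    }
  }
  invisible(TRUE)
}

#' Write a panel back to BED-derived TSV
#'
#' Inverse of [read_panel()]; coordinates are converted back to BED 0-based
#' half-open, so `read_panel(write_panel(p))` round-trips exactly.
#'
#' @param panel An `lr_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  span <- function(s, e) ifelse(is.na(s), ".", paste0(s, "-", e))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t0\t%s\t%s",
    panel$contig, panel$start - 1L, panel$end, panel$locus, panel$amplicon,
    span(panel$fwd_start, panel$fwd_end), span(panel$rev_start, panel$rev_end))
  writeLines(c("# contig\tstart\tend\tlocus\tamplicon\tscore\tfwd_primer\trev_primer", lines), path)
  invisible(path)
}

#' Per-locus genomic target size
#'
#' The genomic target of a locus is the union of its amplicon intervals;
#' overlapping stretches between adjacent amplicons are counted once.
#'
#' @param panel An `lr_panel` (or compatible tibble).
#' @return Tibble with columns `locus`, `n_amplicons`, `target_bp`.
#' @export
locus_target_size <- function(panel) {
  panel %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::summarise(
      n_amplicons = dplyr::n(),
      target_bp = sum(BiocGenerics::width(IRanges::reduce(as_iranges(dplyr::pick(dplyr::everything()))))),
      .groups = "drop"
    )
}

#' Total genomic target of a panel
#'
#' Sum of per-locus target sizes. Loci are validated to be mutually
#' disjoint, so the sum equals the size of the union of all amplicons.
#'
#' @param panel An `lr_panel`.
#' @return Integer, total target in bp.
#' @export
panel_target_size <- function(panel) {
  if (nrow(panel) == 0L) {
    return(0L)
  }
  as.integer(sum(locus_target_size(panel)$target_bp))
}

#' Panel summary
#'
#' One-row accounting summary: number of loci, number of amplicons (= number
#' of PCRs), and the total genomic target in bp.
#'
#' @param panel An `lr_panel`.
#' @return One-row tibble with `n_loci`, `n_amplicons`, `total_target_bp`.
#' @export
panel_stats <- function(panel) {
  tibble::tibble(
    n_loci = dplyr::n_distinct(panel$locus),
    n_amplicons = nrow(panel),
    total_target_bp = panel_target_size(panel)
  )
}

# Per-locus target intervals: explicit `targets` tibble or the amplicon span.
locus_targets <- function(panel, targets = NULL) {
  if (!is.null(targets)) {
    t <- tibble::as_tibble(targets)
    stopifnot(all(c("locus", "contig", "start", "end") %in% names(t)))
    check_interval(t$start, t$end, what = "locus target")
    return(t[, c("locus", "contig", "start", "end")])
  }
  dplyr::summarise(dplyr::group_by(panel, .data$locus),
    contig = .data$contig[1], start = min(.data$start), end = max(.data$end),
    .groups = "drop")
}

#' Uncovered stretches within locus targets
#'
#' Reports the maximal intervals inside each locus target that no amplicon
#' covers — the regions that could not be amplified and will show no
#' coverage. By default the target of a locus is the span of its amplicons
#' (in which case interior gaps between amplicons are reported); pass
#' explicit `targets` to audit against the intended design.
#'
#' @param panel An `lr_panel`.
#' @param targets Optional tibble `locus`, `contig`, `start`, `end` giving
#'   the intended target interval per locus.
#' @return Tibble `locus`, `contig`, `start`, `end`, `length`, sorted and
#'   disjoint within each locus; zero rows when the tiling is complete.
#' @export
find_gaps <- function(panel, targets = NULL) {
  tgt <- locus_targets(panel, targets)
  out <- purrr::pmap(tgt, function(locus, contig, start, end) {
    amps <- panel[panel$locus == locus, ]
    gap <- BiocGenerics::setdiff(
      IRanges::IRanges(start, end),
      IRanges::reduce(as_iranges(amps))
    )
    g <- iranges_to_tbl(gap)
    if (nrow(g) == 0L) return(NULL)
    tibble::tibble(locus = locus, contig = contig, start = g$start, end = g$end)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble::tibble(locus = character(), contig = character(),
      start = integer(), end = integer(), length = integer()))
  }
  out$length <- interval_length(out$start, out$end)
  dplyr::arrange(out, .data$locus, .data$start)
}

#' Regions covered by two or more amplicons
#'
#' Multi-PCR loci are designed so adjacent amplicons overlap; these overlaps
#' show up as a depth step in coverage plots. Reports the maximal intervals
#' covered by at least two amplicons of the same locus, each interval once
#' regardless of how many amplicons stack on it.
#'
#' @param panel An `lr_panel`.
#' @return Tibble `locus`, `contig`, `start`, `end`, `length`.
#' @export
overlap_regions <- function(panel) {
  out <- panel %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::group_map(function(amps, key) {
      cov <- IRanges::coverage(as_iranges(amps))
      hi <- iranges_to_tbl(IRanges::slice(cov, lower = 2L, rangesOnly = TRUE))
      if (nrow(hi) == 0L) return(NULL)
      tibble::tibble(locus = key$locus, contig = amps$contig[1],
        start = hi$start, end = hi$end)
    }) %>%
    dplyr::bind_rows()
  if (nrow(out) == 0L) {
    return(tibble::tibble(locus = character(), contig = character(),
      start = integer(), end = integer(), length = integer()))
  }
  out$length <- interval_length(out$start, out$end)
  dplyr::arrange(out, .data$locus, .data$start)
}

#' Allele-dropout risk of a deletion against a panel
#'
#' PCR-based assays cannot detect a deletion that removes a primer-binding
#' site: the affected allele fails to amplify (allele dropout, ADO) and the
#' locus appears homozygous for the remaining allele. Given a candidate
#' deletion, classifies every amplicon that intersects it:
#' `primer_site_hit` (deletion intersects a primer site — ADO risk),
#' `contained_in_deletion` (whole amplicon deleted — no product from that
#' allele), or `detectable` (deletion strictly internal, breakpoints
#' sequenceable). When the panel has no primer-site columns, amplicon ends
#' stand in for primer sites and a warning notes the approximation.
#'
#' @param panel An `lr_panel`.
#' @param deletion Deletion interval: `"contig:start-end"` string or a
#'   one-row data frame with `contig`, `start`, `end`.
#' @param primer_end_bp Width of the surrogate primer site used when primer
#'   columns are absent (default 30 bp at each amplicon end).
#' @return Tibble `locus`, `amplicon`, `status`, `ado_risk` (logical),
#'   `note`; one row per amplicon intersecting the deletion. The returned
#'   tibble carries attribute `any_ado_risk`.
#' @export
ado_risk <- function(panel, deletion, primer_end_bp = 30L) {
  del <- as_region_tbl(deletion)
  amps <- panel[panel$contig == del$contig, ]
  if (nrow(amps) == 0L) {
    rlang::abort(sprintf("deletion contig '%s' not present in panel", del$contig))
  }
  hit <- amps$start <= del$end & amps$end >= del$start
  amps <- amps[hit, ]
  missing_primers <- nrow(amps) > 0L && all(is.na(amps$fwd_start))
  if (missing_primers) {
    rlang::warn("panel has no primer-site spans; using amplicon ends as surrogate primer sites")
    amps$fwd_start <- amps$start
    amps$fwd_end <- pmin(amps$start + primer_end_bp - 1L, amps$end)
    amps$rev_end <- amps$end
    amps$rev_start <- pmax(amps$end - primer_end_bp + 1L, amps$start)
  }
  isect <- function(s, e) !is.na(s) & s <= del$end & e >= del$start
  contained <- amps$start >= del$start & amps$end <= del$end
  primer_hit <- isect(amps$fwd_start, amps$fwd_end) | isect(amps$rev_start, amps$rev_end)
  status <- dplyr::case_when(
    contained ~ "contained_in_deletion",
    primer_hit ~ "primer_site_hit",
    TRUE ~ "detectable"
  )
  out <- tibble::tibble(
    locus = amps$locus, amplicon = amps$amplicon, status = status,
    ado_risk = contained | primer_hit,
    note = dplyr::case_when(
      contained ~ "amplicon fully within deletion: no product from deleted allele",
      primer_hit ~ "deletion removes a primer-binding site: allele dropout likely",
      TRUE ~ "deletion internal to amplicon: breakpoints sequenceable, no ADO risk"
    )
  )
  for (i in which(out$ado_risk)) {
    rlang::warn(sprintf("ADO risk: %s/%s — %s", out$locus[i], out$amplicon[i], out$note[i]))
  }
  attr(out, "any_ado_risk") <- any(out$ado_risk)
  out
}

#' @export
print.lr_panel <- function(x, ...) {
  s <- panel_stats(x)
  cat(sprintf("<lr_panel> %d loci, %d amplicons, total target %s bp\n",
    s$n_loci, s$n_amplicons, format(s$total_target_bp, big.mark = ",")))
  NextMethod()
}
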