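#' Deletion breakpoint characterization
#'
#' Sequencing a junction-spanning amplicon and comparing it to the
#' reference resolves a deletion's breakpoints at nucleotide resolution.
#' When a short identical sequence (microhomology) flanks both breakpoints,
#' the deletion placement is ambiguous over `microhomology + 1` equivalent
#' positions, all deleting the same number of bases; HGVS then prescribes
#' either the 3'-most placement or the explicit ambiguous
#' `g.(a_b)_(c_d)del` form.
#'
#' @name lr-breakpoints
NULL

#' Deletion length from breakpoint coordinates
#'
#' Inclusive length of a deleted interval: `end - start + 1`.
#'
#' @param start,end 1-based inclusive first and last deleted positions.
#' @return Integer length in bp.
#' @examples
#' deletion_length(2716981, 2787016) # 70036
#' @export
deletion_length <- function(start, end) {
  if (any(end < start)) rlang::abort("end < start")
  interval_length(start, end)
}

#' Microhomology length from a pair of printed intervals
#'
#' The microhomology at a deletion junction is reported as two equal-length
#' genomic intervals (the copy retained on the 5' side and the copy
#' retained on the 3' side); its length is the shared interval length.
#'
#' @param i1,i2 Intervals as `"start-end"` strings, region strings, or
#'   one-row data frames with `start`/`end`.
#' @return Integer microhomology length in bp.
#' @examples
#' microhomology_from_intervals("94507690-94507699", "94511701-94511710") # 10
#' @export
microhomology_from_intervals <- function(i1, i2) {
  as_se <- function(x) {
    if (is.character(x)) {
      x <- gsub(",", "", gsub("–", "-", x))
      if (!grepl(":", x)) x <- paste0("seq:", x)
      return(parse_region(x))
    }
    as_region_tbl(x)
  }
  a <- as_se(i1)
  b <- as_se(i2)
  la <- interval_length(a$start, a$end)
  lb <- interval_length(b$start, b$end)
  if (la != lb) {
    rlang::abort(sprintf("microhomology intervals have unequal lengths (%d vs %d)", la, lb))
  }
  la
}

# Longest common prefix/suffix lengths with N treated as a mismatch
# (conservative: an ambiguous base must not extend a microhomology).
lcp_len <- function(x, y) {
  a <- charToRaw(x)
  b <- charToRaw(y)
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  eq <- a[seq_len(n)] == b[seq_len(n)] & a[seq_len(n)] != charToRaw("N")
  mis <- which(!eq)
  if (length(mis) == 0L) n else mis[1] - 1L
}

lcs_len <- function(x, y) {
  a <- rev(charToRaw(x))
  b <- rev(charToRaw(y))
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  eq <- a[seq_len(n)] == b[seq_len(n)] & a[seq_len(n)] != charToRaw("N")
  mis <- which(!eq)
  if (length(mis) == 0L) n else mis[1] - 1L
}

#' Infer a deletion and its microhomology from sequence comparison
#'
#' Compares an observed breakpoint-spanning sequence (amplicon consensus or
#' assembled contig) to the corresponding reference segment, assuming they
#' differ by exactly one contiguous deletion. With `P` the longest common
#' prefix and `S` the longest common suffix, the placement slack
#' `P + S - |observed|` equals the microhomology length: the deletion can
#' be placed at `microhomology + 1` equivalent start positions, every
#' placement deleting `|reference| - |observed|` bases. `N` bases never
#' extend a match.
#'
#' @param reference Reference segment (character, A/C/G/T/N, uppercase).
#' @param observed Observed sequence with the deletion (character).
#' @param contig Contig/accession label for reporting (default `"seq"`).
#' @param offset 1-based genomic position of `substr(reference, 1, 1)`,
#'   so toy sub-references report genomic coordinates (default 1).
#' @param report_mode `"ambiguous"` (default) or `"shifted"`; see
#'   [format_hgvs()].
#' @return An `lr_deletion_call`: one-row tibble with `contig`,
#'   `five_start`, `five_end` (interval of possible first deleted
#'   positions), `three_start`, `three_end` (corresponding last deleted
#'   positions), `deletion_length`, `microhomology_len`,
#'   `microhomology_seq`, `hgvs`.
#' @examples
#' infer_deletion("AAAACCTGGGGCCTTTTT", "AAAACCTTTTT")
#' @export
infer_deletion <- function(reference, observed, contig = "seq", offset = 1L,
                           report_mode = c("ambiguous", "shifted")) {
  report_mode <- match.arg(report_mode)
  reference <- toupper(reference)
  observed <- toupper(observed)
  if (!grepl("^[ACGTN]*$", reference) || !grepl("^[ACGTN]*$", observed)) {
    rlang::abort("sequences must contain only A/C/G/T/N")
  }
  nr <- nchar(reference)
  no <- nchar(observed)
  if (no >= nr) {
    rlang::abort("observed sequence is not shorter than the reference: not a deletion")
  }
  del_len <- nr - no
  p <- lcp_len(reference, observed)
  s <- lcs_len(reference, observed)
  slack <- p + s - no
  if (slack < 0L) {
    rlang::abort("not a clean deletion: sequences differ by more than one contiguous deletion")
  }
  mh <- slack
  left_start <- no - s + 1L # leftmost possible first deleted position (local)
  right_start <- p + 1L # rightmost
  mh_seq <- if (mh > 0L) substr(reference, left_start, left_start + mh - 1L) else ""
  call <- tibble::tibble(
    contig = contig,
    five_start = left_start + offset - 1L,
    five_end = right_start + offset - 1L,
    three_start = left_start + del_len + offset - 2L,
    three_end = right_start + del_len + offset - 2L,
    deletion_length = del_len,
    microhomology_len = mh,
    microhomology_seq = mh_seq
  )
  class(call) <- c("lr_deletion_call", class(call))
  call$hgvs <- format_hgvs(call, mode = report_mode)
  call
}

#' Render a deletion call as HGVS g. notation
#'
#' With no microhomology the placement is unique:
#' `contig:g.start_enddel` (or `g.posdel` for a single base). With
#' microhomology, `mode = "ambiguous"` (the default) writes the explicit
#' uncertainty form `contig:g.(a_b)_(c_d)del` using the equivalent
#' placement intervals — repetitive flanks genuinely preclude picking one
#' breakpoint — while `mode = "shifted"` applies the HGVS 3' rule and
#' reports the 3'-most placement as an exact interval.
#'
#' @param call An `lr_deletion_call`.
#' @param mode `"ambiguous"` or `"shifted"`.
#' @return HGVS string.
#' @export
format_hgvs <- function(call, mode = c("ambiguous", "shifted")) {
  mode <- match.arg(mode)
  if (call$microhomology_len == 0L || mode == "shifted") {
    start <- call$five_end # 3'-most placement
    end <- call$three_end
    if (call$microhomology_len == 0L) {
      start <- call$five_start
      end <- call$three_start
    }
    if (start == end) {
      return(sprintf("%s:g.%ddel", call$contig, start))
    }
    return(sprintf("%s:g.%d_%ddel", call$contig, start, end))
  }
  sprintf("%s:g.(%d_%d)_(%d_%d)del", call$contig,
    call$five_start, call$five_end, call$three_start, call$three_end)
}

#' Parse an HGVS deletion string back to intervals
#'
#' Inverse of [format_hgvs()] for exact and ambiguous deletion forms.
#'
#' @param hgvs HGVS string such as `"chr1:g.100_200del"` or
#'   `"chr1:g.(95_98)_(195_198)del"`.
#' @return One-row tibble `contig`, `five_start`, `five_end`,
#'   `three_start`, `three_end`.
#' @export
parse_hgvs_del <- function(hgvs) {
  m <- regmatches(hgvs,
    regexec("^(.+):g\\.\\(([0-9]+)_([0-9]+)\\)_\\(([0-9]+)_([0-9]+)\\)del$", hgvs))[[1]]
  if (length(m) == 6L) {
    return(tibble::tibble(contig = m[2],
      five_start = as.integer(m[3]), five_end = as.integer(m[4]),
      three_start = as.integer(m[5]), three_end = as.integer(m[6])))
  }
  m <- regmatches(hgvs, regexec("^(.+):g\\.([0-9]+)(?:_([0-9]+))?del$", hgvs))[[1]]
  if (length(m) >= 3L) {
    s <- as.integer(m[3])
    e <- if (length(m) == 4L && nzchar(m[4])) as.integer(m[4]) else s
    return(tibble::tibble(contig = m[2], five_start = s, five_end = s,
      three_start = e, three_end = e))
  }
  rlang::abort(sprintf("cannot parse HGVS deletion '%s'", hgvs))
}

#' Annotate repeats flanking a deletion call
#'
#' Large deletions are often mediated by flanking repetitive elements (for
#' example Alu pairs). Reports the repeats intersecting a window around the
#' breakpoint ambiguity intervals, labelled by their position relative to
#' the deletion: `5prime` (ends at or before the first possibly deleted
#' base), `3prime` (starts at or after the last possibly deleted base), or
#' `internal`.
#'
#' @param call An `lr_deletion_call`.
#' @param repeats Tibble with `contig`, `start`, `end`, `family`.
#' @param window Window in bp around the breakpoint intervals (default 100).
#' @return Tibble `family`, `contig`, `start`, `end`, `side`.
#' @export
annotate_flanking_repeats <- function(call, repeats, window = 100L) {
  r <- tibble::as_tibble(repeats)
  if (nrow(r) == 0L) {
    return(tibble::tibble(family = character(), contig = character(),
      start = integer(), end = integer(), side = character()))
  }
  stopifnot(all(c("contig", "start", "end", "family") %in% names(r)))
  r <- r[r$contig == call$contig, ]
  lo <- call$five_start - window
  hi <- call$three_end + window
  r <- r[r$start <= hi & r$end >= lo, ]
  side <- dplyr::case_when(
    r$end <= call$five_end ~ "5prime",
    r$start >= call$three_start ~ "3prime",
    TRUE ~ "internal"
  )
  tibble::tibble(family = r$family, contig = r$contig, start = r$start,
    end = r$end, side = side)
}

#' Majority-rule consensus over aligned reads
#'
#' Naive per-position majority consensus across an alignment tibble,
#' intended for turning the simulator's junction-spanning reads into the
#' observed sequence [infer_deletion()] consumes. Positions with no
#' aligned base are reported as `N`. This is not an assembler: reads must
#' already be aligned to the coordinate system of interest.
#'
#' @param alignments Alignment tibble.
#' @param region Region string or one-row data frame (`contig`, `start`,
#'   `end`).
#' @return Character consensus sequence of the region's length.
#' @export
consensus_sequence <- function(alignments, region) {
  reg <- as_region_tbl(region)
  len <- interval_length(reg$start, reg$end)
  counts <- matrix(0L, nrow = 5L, ncol = len,
    dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  aln <- alignments[alignments$rname == reg$contig, ]
  for (i in seq_len(nrow(aln))) {
    walk <- cigar_walk(aln$pos[i], aln$cigar[i])
    keep <- walk$ref_pos >= reg$start & walk$ref_pos <= reg$end
    if (!any(keep)) next
    bases <- substring(aln$seq[i], walk$read_idx[keep], walk$read_idx[keep])
    cols <- walk$ref_pos[keep] - reg$start + 1L
    for (k in seq_along(cols)) {
      b <- bases[k]
      if (!b %in% rownames(counts)) b <- "N"
      counts[b, cols[k]] <- counts[b, cols[k]] + 1L
    }
  }
  covered <- colSums(counts) > 0L
  base <- rep("N", len)
  if (any(covered)) {
    base[covered] <- rownames(counts)[apply(counts[, covered, drop = FALSE], 2, which.max)]
  }
  paste(base, collapse = "")
}

#' Deletion call as a symbolic VCF-style record
#'
#' One-row tibble in VCF column layout with a symbolic `<DEL>` ALT and
#' `SVLEN`/`CIPOS`/`CIEND`-style ambiguity fields in INFO. `POS` is the
#' base before the leftmost placement, per VCF convention for symbolic
#' alleles.
#'
#' @param call An `lr_deletion_call`.
#' @return One-row tibble `CHROM`, `POS`, `ID`, `REF`, `ALT`, `QUAL`,
#'   `FILTER`, `INFO`.
#' @export
deletion_vcf_record <- function(call) {
  mh <- call$microhomology_len
  pos <- call$five_start - 1L
  info <- sprintf("SVTYPE=DEL;SVLEN=-%d;END=%d;CIPOS=0,%d;CIEND=0,%d;HOMLEN=%d%s",
    call$deletion_length, call$three_start, mh, mh, mh,
    if (mh > 0L) paste0(";HOMSEQ=", call$microhomology_seq) else "")
  tibble::tibble(CHROM = call$contig, POS = pos, ID = ".", REF = "N",
    ALT = "<DEL>", QUAL = ".", FILTER = ".", INFO = info)
}

#' @export
print.lr_deletion_call <- function(x, ...) {
  cat(sprintf("<lr_deletion_call> %s: %s bp deleted, microhomology %d bp%s\n  %s\n",
    x$contig, format(x$deletion_length, big.mark = ","), x$microhomology_len,
    if (x$microhomology_len > 0L) sprintf(" ('%s')", x$microhomology_seq) else "",
    x$hgvs))
  invisible(x)
}

#' Tidiers for deletion calls
#'
#' `tidy()` returns the call as a plain tibble; `glance()` a one-row
#' summary (length, microhomology, number of equivalent placements).
#'
#' @param x An `lr_deletion_call`.
#' @param ... Unused.
#' @name lr_deletion_call-tidiers
#' @method tidy lr_deletion_call
#' @export
tidy.lr_deletion_call <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "lr_deletion_call")
  tibble::as_tibble(out)
}

#' @rdname lr_deletion_call-tidiers
#' @method glance lr_deletion_call
#' @export
glance.lr_deletion_call <- function(x, ...) {
  tibble::tibble(
    deletion_length = x$deletion_length,
    microhomology_len = x$microhomology_len,
    n_placements = x$microhomology_len + 1L,
    hgvs = x$hgvs
  )
}
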