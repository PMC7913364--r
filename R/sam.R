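#' Alignment tables
#'
#' Aligned reads are carried as a tibble with SAM-convention columns:
#' `qname`, `flag`, `rname`, `pos` (1-based leftmost aligned position),
#' `mapq`, `cigar`, `seq`, `qual` (ASCII Phred+33). The simulator emits
#' this table directly; [read_alignments()] fills it from a SAM file on
#' disk.
#'
#' @name lr-alignments
NULL

ALN_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")

empty_alignments <- function() {
  tibble::tibble(
    qname = character(), flag = integer(), rname = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    seq = character(), qual = character()
  )
}

#' Read a coordinate-style alignment file (SAM) into a tibble
#'
#' Uses Rsamtools to convert and parse the file, then returns the plain
#' alignment tibble used throughout the package. Secondary and
#' supplementary alignments are dropped (flags 0x100/0x800): phasing and
#' depth both reason about one placement per read.
#'
#' @param path Path to a SAM (text) or BAM file.
#' @return Alignment tibble (see [lr-alignments]).
#' @export
read_alignments <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
      overwrite = TRUE, indexDestination = FALSE))
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")))[[1]]
  tbl <- tibble::tibble(
    qname = res$qname,
    flag = as.integer(res$flag),
    rname = as.character(res$rname),
    pos = as.integer(res$pos),
    mapq = as.integer(res$mapq),
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual)
  )
  tbl <- tbl[!is.na(tbl$pos), ]
  drop <- bitwAnd(tbl$flag, bitwOr(256L, 2048L)) != 0L
  tbl[!drop, ]
}

#' Write an alignment tibble as SAM text
#'
#' Emits a minimal valid SAM file (`@HD`, one `@SQ` line per reference)
#' suitable for `samtools` or for [read_alignments()] round-trips.
#'
#' @param alignments Alignment tibble.
#' @param ref_lengths Named integer vector: reference name -> length.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, ref_lengths, path) {
  stopifnot(!is.null(names(ref_lengths)))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths)))
  a <- dplyr::arrange(alignments, .data$rname, .data$pos)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
    a$qname, a$flag, a$rname, a$pos, a$mapq, a$cigar,
    "*", 0L, 0L, a$seq, a$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# --- CIGAR machinery -------------------------------------------------------

# Parse a CIGAR string into op/length vectors.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(list(op = character(), len = integer()))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) rlang::abort(sprintf("bad CIGAR '%s'", cigar))
  list(op = ops, len = lens)
}

# Walk one read's CIGAR. Returns:
#   ref_pos / read_idx: parallel vectors of aligned (M/=/X) positions
#   dels: tibble(start, end) of reference intervals deleted in the read
#   ins: tibble(after_ref, read_start, len) insertions (after_ref = ref base
#        preceding the inserted sequence)
cigar_walk <- function(pos, cigar) {
  cg <- parse_cigar(cigar)
  rp <- pos
  qp <- 1L
  ref_pos <- integer(0)
  read_idx <- integer(0)
  dels <- list()
  ins <- list()
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]
    l <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      ref_pos <- c(ref_pos, rp:(rp + l - 1L))
      read_idx <- c(read_idx, qp:(qp + l - 1L))
      rp <- rp + l
      qp <- qp + l
    } else if (op == "D" || op == "N") {
      if (op == "D") dels[[length(dels) + 1L]] <- c(rp, rp + l - 1L)
      rp <- rp + l
    } else if (op == "I") {
      ins[[length(ins) + 1L]] <- c(rp - 1L, qp, l)
      qp <- qp + l
    } else if (op == "S") {
      qp <- qp + l
    } # H, P consume nothing we track
  }
  dels <- if (length(dels)) {
    m <- do.call(rbind, dels)
    tibble::tibble(start = m[, 1], end = m[, 2])
  } else tibble::tibble(start = integer(), end = integer())
  ins <- if (length(ins)) {
    m <- do.call(rbind, ins)
    tibble::tibble(after_ref = m[, 1], read_start = m[, 2], len = m[, 3])
  } else tibble::tibble(after_ref = integer(), read_start = integer(), len = integer())
  list(ref_pos = ref_pos, read_idx = read_idx, dels = dels, ins = ins)
}

# Reference positions covered by aligned read bases (M/=/X only); deletions
# do not contribute depth at the deleted bases.
cigar_covered <- function(pos, cigar) {
  cg <- parse_cigar(cigar)
  out <- integer(0)
  rp <- pos
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]
    l <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      out <- c(out, rp:(rp + l - 1L))
      rp <- rp + l
    } else if (op %in% c("D", "N")) {
      rp <- rp + l
    }
  }
  out
}

phred_from_qual <- function(qual_string) {
  if (is.na(qual_string) || qual_string == "*") {
    return(integer(0))
  }
  as.integer(charToRaw(qual_string)) - 33L
}
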