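#' Per-base depth over a region
#'
#' CIGAR-aware pileup depth: each aligned read base (M/=/X operations)
#' contributes one to the depth at its reference position; bases deleted in
#' a read contribute nothing at the deleted positions. Duplicates are kept
#' if present — amplicon libraries are PCR-derived, so duplicate reads are
#' expected and informative.
#'
#' @param alignments Alignment tibble (see [lr-alignments]).
#' @param region Region string `"contig:start-end"` or one-row data frame.
#' @param min_mapq Minimum mapping quality for a read to contribute
#'   (default 0).
#' @return An `lr_depth_profile`: tibble `contig`, `pos`, `depth` with one
#'   row per base of the region.
#' @export
depth_profile <- function(alignments, region, min_mapq = 0L) {
  reg <- as_region_tbl(region)
  if (nrow(alignments) > 0L && !reg$contig %in% alignments$rname) {
    rlang::abort(sprintf("contig '%s' absent from alignments", reg$contig))
  }
  len <- interval_length(reg$start, reg$end)
  depth <- integer(len)
  aln <- alignments[alignments$rname == reg$contig &
                    !is.na(alignments$mapq) & alignments$mapq >= min_mapq, ]
  for (i in seq_len(nrow(aln))) {
    cov <- cigar_covered(aln$pos[i], aln$cigar[i])
    cov <- cov[cov >= reg$start & cov <= reg$end]
    if (length(cov)) {
      idx <- cov - reg$start + 1L
      depth[idx] <- depth[idx] + 1L
    }
  }
  out <- tibble::tibble(contig = reg$contig, pos = seq(reg$start, reg$end),
    depth = depth)
  class(out) <- c("lr_depth_profile", class(out))
  out
}

#' Low-depth intervals of a depth profile
#'
#' Maximal intervals where depth falls below a threshold — the coverage
#' gaps a diagnostic run must flag before interpreting "no variant found".
#'
#' @param profile An `lr_depth_profile` (or tibble `contig`, `pos`,
#'   `depth`).
#' @param min_depth Depth threshold (default 20): positions with
#'   `depth < min_depth` are gap positions.
#' @return Tibble `contig`, `start`, `end`, `length`, `mean_depth`.
#' @export
gap_report <- function(profile, min_depth = 20L) {
  p <- tibble::as_tibble(profile)
  empty <- tibble::tibble(contig = character(), start = integer(),
    end = integer(), length = integer(), mean_depth = numeric())
  if (nrow(p) == 0L) return(empty)
  low <- p$depth < min_depth
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L) return(empty)
  tibble::tibble(
    contig = p$contig[1],
    start = p$pos[starts[keep]],
    end = p$pos[ends[keep]],
    length = r$lengths[keep],
    mean_depth = vapply(keep, function(k) {
      mean(p$depth[starts[k]:ends[k]])
    }, numeric(1))
  )
}

#' Warn on suspicious all-homozygous regions
#'
#' A region where every variant call appears homozygous may in truth be
#' hemizygous: a deletion spanning a primer-binding site drops one allele
#' out of the PCR entirely, and the assay shows no sign of the event other
#' than exclusively homozygous-appearing calls. Emits a warning when a
#' region has at least `min_sites` calls and all of them are homozygous.
#'
#' @param variants Variant tibble (from [read_variants()] or with a `gt`
#'   column).
#' @param region Region string or one-row data frame.
#' @param min_sites Minimum number of calls before the pattern is
#'   reportable (default 5).
#' @return One-row tibble `n_sites`, `n_hom`, `all_homozygous`, `warning`
#'   (logical); warns (and sets `warning = TRUE`) when triggered.
#' @export
homozygosity_warning <- function(variants, region, min_sites = 5L) {
  reg <- as_region_tbl(region)
  v <- tibble::as_tibble(variants)
  v <- v[v$contig == reg$contig & v$pos >= reg$start & v$pos <= reg$end, ]
  if (!"is_het" %in% names(v)) {
    gt <- gsub("\\|", "/", v$gt)
    v$is_het <- gt %in% c("0/1", "1/0")
  }
  n <- nrow(v)
  n_hom <- sum(!v$is_het)
  trig <- n >= min_sites && n_hom == n
  if (trig) {
    rlang::warn(sprintf(
      "region %s:%d-%d: all %d variant calls homozygous — possible allele dropout or hemizygous deletion",
      reg$contig, reg$start, reg$end, n))
  }
  tibble::tibble(n_sites = n, n_hom = n_hom,
    all_homozygous = n > 0L && n_hom == n, warning = trig)
}

#' Plot a depth profile
#'
#' @param object An `lr_depth_profile`.
#' @param min_depth Optional threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lr_depth_profile
#' @export
autoplot.lr_depth_profile <- function(object, min_depth = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
    ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = sprintf("position on %s", object$contig[1]),
      y = "depth (aligned bases)") +
    ggplot2::theme_minimal()
  if (!is.null(min_depth)) {
    p <- p + ggplot2::geom_hline(yintercept = min_depth, linetype = "dashed",
      colour = "firebrick")
  }
  p
}

#' Plot pool-plan volumes
#'
#' @param object An `lr_pool_plan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lr_pool_plan
#' @export
autoplot.lr_pool_plan <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
    ggplot2::aes(x = stats::reorder(.data$name, .data$volume_uL),
      y = .data$volume_uL)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "volume (uL)") +
    ggplot2::theme_minimal()
}
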