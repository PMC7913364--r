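#' Diagnostic yield from cohort counts
#'
#' Percentage of probands with an identified molecular diagnosis, computed
#' from diagnosed/total counts and rounded to one decimal, the convention
#' diagnostic cohort tables use.
#'
#' @param counts Tibble with columns `diagnosed` and `total` (and any
#'   identifying columns, which are passed through).
#' @return The input with a `yield_pct` column appended.
#' @examples
#' diagnostic_yield(tibble::tibble(cohort = "validation", diagnosed = 108, total = 108))
#' @export
diagnostic_yield <- function(counts) {
  c <- tibble::as_tibble(counts)
  stopifnot(all(c("diagnosed", "total") %in% names(c)))
  if (any(c$total <= 0) || any(c$diagnosed < 0) || any(c$diagnosed > c$total)) {
    rlang::abort("need 0 <= diagnosed <= total and total > 0")
  }
  dplyr::mutate(c, yield_pct = round(100 * .data$diagnosed / .data$total, 1))
}

#' Build a panel from per-locus target sizes
#'
#' Turns a per-locus size table (locus name, number of PCRs, genomic
#' target size) into an `lr_panel` in which each locus is one synthetic
#' single-interval amplicon of the stated size on its own contig. Useful
#' for panel-level accounting when only the published per-locus sizes are
#' available, not the amplicon coordinates.
#'
#' @param sizes Tibble with columns `locus` and `target_bp` (an `n_pcr`
#'   column, if present, is carried into the summary attribute).
#' @return An `lr_panel`.
#' @export
panel_from_locus_sizes <- function(sizes) {
  s <- tibble::as_tibble(sizes)
  stopifnot(all(c("locus", "target_bp") %in% names(s)))
  as_panel(tibble::tibble(
    locus = s$locus,
    amplicon = paste0(s$locus, "_full"),
    contig = paste0("locus_", s$locus),
    start = 1L,
    end = as.integer(s$target_bp)
  ))
}

#' Bundled example tables
#'
#' Paths to the plain-text tables shipped with the package: the
#' IRD panel per-locus target sizes (`"ird_locus_sizes.tsv"`) and the
#' diagnostic cohort counts (`"cohort_yields.tsv"`).
#'
#' @param file File name under `extdata`; with no argument, lists the
#'   available files.
#' @return A path (or vector of file names).
#' @export
lr_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "lrpanel")))
  }
  p <- system.file("extdata", file, package = "lrpanel", mustWork = TRUE)
  p
}
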