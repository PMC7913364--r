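#' Read proband variant calls from a VCF
#'
#' Loads CHROM/POS/REF/ALT and the genotype of one sample into a tibble.
#' Multiallelic records are decomposed into one row per alternate allele;
#' the per-row genotype dose is recorded so heterozygosity can be assessed
#' downstream. Genotypes made of two different alternate alleles (e.g.
#' `1/2`) cannot be expressed as a REF/ALT observation pair and are dropped
#' with a warning.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param sample Sample name; defaults to the first sample column.
#' @return Tibble with columns `contig`, `pos`, `ref`, `alt`, `gt`,
#'   `is_het` (logical: genotype is ref/alt heterozygous for this allele).
#' @export
read_variants <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) {
    return(tibble::tibble(contig = character(), pos = integer(), ref = character(),
      alt = character(), gt = character(), is_het = logical()))
  }
  gt_mat <- vcfR::extract.gt(v, element = "GT")
  if (is.null(sample)) sample <- colnames(gt_mat)[1]
  if (!sample %in% colnames(gt_mat)) {
    rlang::abort(sprintf("sample '%s' not in VCF", sample))
  }
  fix <- tibble::as_tibble(v@fix[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE])
  fix$gt <- unname(gt_mat[, sample])
  out <- fix %>%
    dplyr::mutate(pos = as.integer(.data$POS)) %>%
    tidyr::separate_rows("ALT", sep = ",") %>%
    dplyr::group_by(.data$CHROM, .data$pos, .data$REF) %>%
    dplyr::mutate(alt_index = dplyr::row_number()) %>%
    dplyr::ungroup()
  alleles <- strsplit(gsub("\\|", "/", out$gt %||% ""), "/", fixed = TRUE)
  dose <- mapply(function(al, idx) sum(al == as.character(idx)), alleles, out$alt_index)
  has_ref <- vapply(alleles, function(al) any(al == "0"), logical(1))
  mixed_alt <- vapply(alleles, function(al) {
    al <- al[al != "." & al != "0"]
    length(unique(al)) > 1L
  }, logical(1))
  if (any(mixed_alt & dose > 0)) {
    rlang::warn("dropping genotypes composed of two different ALT alleles (not REF/ALT phasable)")
  }
  keep <- dose > 0 & !mixed_alt
  tibble::tibble(
    contig = out$CHROM[keep],
    pos = out$pos[keep],
    ref = out$REF[keep],
    alt = out$ALT[keep],
    gt = out$gt[keep],
    is_het = dose[keep] == 1 & has_ref[keep]
  )
}
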