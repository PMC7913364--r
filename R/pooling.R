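#' Simple dilution plan (C1 V1 = C2 V2)
#'
#' Computes the stock and diluent volumes needed to bring a stock at
#' `stock_conc` to `target_conc` in a final volume `final_volume`. The
#' protocol dilutes every amplicon to a common 10 ng/uL working
#' concentration before pooling; this calculator is unit-agnostic as long as
#' both concentrations share a unit.
#'
#' @param stock_conc Stock concentration (e.g. ng/uL); must be >= `target_conc`.
#' @param target_conc Desired concentration, > 0.
#' @param final_volume Final volume (uL), > 0.
#' @return One-row tibble with `stock_uL`, `diluent_uL`, `final_volume_uL`.
#' @examples
#' dilution_plan(100, 10, 50) # 5 uL stock + 45 uL diluent
#' @export
dilution_plan <- function(stock_conc, target_conc, final_volume) {
  if (target_conc <= 0 || final_volume <= 0) {
    rlang::abort("target_conc and final_volume must be > 0")
  }
  if (stock_conc < target_conc) {
    rlang::abort("cannot dilute upward: stock concentration below target")
  }
  v1 <- target_conc * final_volume / stock_conc
  tibble::tibble(
    stock_uL = v1,
    diluent_uL = final_volume - v1,
    final_volume_uL = final_volume
  )
}

# Round volumes to `round_to` and push the residue onto the largest
# component so the total is exact (pipettable plans must still sum right).
round_volumes <- function(v, round_to) {
  if (is.null(round_to)) {
    return(v)
  }
  total <- sum(v)
  r <- round(v / round_to) * round_to
  i <- which.max(v)
  r[i] <- total - sum(r[-i])
  r
}

new_pool_plan <- function(tbl, total, meta = list()) {
  attr(tbl, "total_volume_uL") <- total
  attr(tbl, "meta") <- meta
  class(tbl) <- c("lr_pool_plan", class(tbl))
  tbl
}

#' Size-proportional amplicon pool volumes
#'
#' After dilution to a common working concentration (mass/volume), pooling
#' volumes proportional to amplicon size makes the pool equimolar per
#' amplicon copy: the mass of amplicon i is proportional to its size, so
#' moles (mass / size) are equal and every base position of the panel is
#' represented equally. The pool must reach a minimum total volume (the
#' shearing input, default 130 uL); a per-amplicon floor (default 1 uL,
#' pipettable) can force a proportionally larger pool.
#'
#' @param measurements Tibble with columns `amplicon_name` (or `name`) and
#'   `size_bp`; a `concentration` column, if present, is checked to be a
#'   single common working concentration.
#' @param min_total Minimum pool volume in uL (default 130).
#' @param min_volume Per-component volume floor in uL (default 1).
#' @param round_to Pipetting resolution in uL (default 0.1); `NULL` for
#'   exact volumes.
#' @return An `lr_pool_plan` tibble: `name`, `size_bp`, `volume_uL`, with
#'   attributes `total_volume_uL` and scaling metadata.
#' @export
amplicon_pool_volumes <- function(measurements, min_total = 130, min_volume = 1,
                                  round_to = 0.1) {
  m <- tibble::as_tibble(measurements)
  if (nrow(m) == 0L) {
    rlang::abort("no amplicon measurements supplied")
  }
  if (!"name" %in% names(m) && "amplicon_name" %in% names(m)) {
    m$name <- m$amplicon_name
  }
  stopifnot(all(c("name", "size_bp") %in% names(m)))
  if (any(m$size_bp <= 0)) rlang::abort("size_bp must be > 0")
  if ("concentration" %in% names(m)) {
    if (any(m$concentration <= 0)) rlang::abort("concentration must be > 0")
    if (length(unique(m$concentration)) > 1L) {
      rlang::warn("amplicons are not at a common working concentration; volumes assume they are")
    }
  }
  # scale factor: proportionality constant uL per bp
  f <- max(min_total / sum(m$size_bp), min_volume / min(m$size_bp))
  v <- round_volumes(m$size_bp * f, round_to)
  floored <- f > min_total / sum(m$size_bp) + 1e-12
  if (floored) {
    rlang::inform(sprintf(
      "per-amplicon floor of %g uL raises the pool to %.1f uL (above min_total %g uL)",
      min_volume, sum(v), min_total))
  }
  new_pool_plan(
    tibble::tibble(name = m$name, size_bp = m$size_bp, volume_uL = v),
    total = sum(v),
    meta = list(rule = "volume proportional to amplicon size",
                scale_uL_per_bp = f, min_total_uL = min_total,
                min_volume_uL = min_volume, floor_applied = floored)
  )
}

#' Library molarity from mass concentration
#'
#' Converts a dsDNA library's mass concentration to molarity using the
#' standard 660 g/mol per base pair:
#' `nM = concentration[ng/uL] * 1e6 / (660 * mean_fragment_bp)`.
#' Libraries are normalised to a 4 nM working concentration before index
#' pooling and denaturation.
#'
#' @param libraries Tibble with columns `concentration` (ng/uL) and
#'   `mean_fragment_bp`.
#' @return The input tibble with a `molarity_nM` column appended.
#' @examples
#' library_molarity(tibble::tibble(name = "L1", concentration = 10, mean_fragment_bp = 400))
#' @export
library_molarity <- function(libraries) {
  libs <- tibble::as_tibble(libraries)
  stopifnot(all(c("concentration", "mean_fragment_bp") %in% names(libs)))
  if (any(libs$concentration <= 0) || any(libs$mean_fragment_bp <= 0)) {
    rlang::abort("concentration and mean_fragment_bp must be > 0")
  }
  dplyr::mutate(libs, molarity_nM = .data$concentration * 1e6 / (660 * .data$mean_fragment_bp))
}

#' Target-size-proportional index pool volumes
#'
#' Libraries normalised to a common molarity (4 nM in the protocol) and
#' sequenced together under different indexes are pooled proportionally to
#' their total genomic target size, so each library's target receives the
#' same expected per-base read depth.
#'
#' @param libraries Tibble with columns `name` and `target_size_bp`; a
#'   `molarity_nM` column, if present, is checked for a common value.
#' @param total_volume Total pool volume in uL.
#' @param round_to Pipetting resolution (default 0.1 uL); rounding residue is
#'   assigned to the largest component so the total is exact. `NULL` for
#'   exact volumes.
#' @return An `lr_pool_plan` tibble: `name`, `target_size_bp`, `volume_uL`.
#' @export
index_pool_volumes <- function(libraries, total_volume, round_to = 0.1) {
  libs <- tibble::as_tibble(libraries)
  stopifnot(all(c("name", "target_size_bp") %in% names(libs)))
  if (nrow(libs) == 0L || sum(libs$target_size_bp) <= 0) {
    rlang::abort("total target size is zero: nothing to pool")
  }
  if ("molarity_nM" %in% names(libs) &&
      diff(range(libs$molarity_nM)) > 1e-9 * max(libs$molarity_nM)) {
    rlang::warn("libraries are not at a common molarity; proportional volumes assume they are")
  }
  v <- round_volumes(total_volume * libs$target_size_bp / sum(libs$target_size_bp), round_to)
  new_pool_plan(
    tibble::tibble(name = libs$name, target_size_bp = libs$target_size_bp, volume_uL = v),
    total = sum(v),
    meta = list(rule = "volume proportional to genomic target size",
                total_volume_uL = total_volume)
  )
}

#' Spike-in amount for extending an exome library
#'
#' A finalized targeted library spiked into a whole-exome pool should be
#' added in proportion to the ratio of its target size to the exome target
#' size, so the extra regions reach comparable depth:
#' `amount = wes_library_amount * lr_target_bp / wes_target_bp`.
#' The amount is unit-agnostic (attomoles, ng, or a library fraction).
#'
#' @param lr_target_bp Total target of the spiked-in LR library, bp.
#' @param wes_target_bp Exome target size, bp (> 0).
#' @param wes_library_amount Amount of exome library in the pool.
#' @return Spike-in amount in the same unit as `wes_library_amount`.
#' @examples
#' spikein_amount(137748, 45e6, 100) # ~0.31
#' @export
spikein_amount <- function(lr_target_bp, wes_target_bp, wes_library_amount) {
  if (wes_target_bp <= 0) rlang::abort("wes_target_bp must be > 0")
  if (lr_target_bp < 0) rlang::abort("lr_target_bp must be >= 0")
  wes_library_amount * lr_target_bp / wes_target_bp
}

#' @export
print.lr_pool_plan <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<lr_pool_plan> %d components, total %.1f uL (%s)\n",
    nrow(x), attr(x, "total_volume_uL"), meta$rule))
  NextMethod()
}

#' @rdname lr_pool_plan-tidiers
#' @method tidy lr_pool_plan
#' @export
tidy.lr_pool_plan <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out
}

#' Tidiers for pool plans
#'
#' `tidy()` returns the component table; `glance()` returns a one-row
#' summary with the total volume and scaling metadata.
#'
#' @param x An `lr_pool_plan`.
#' @param ... Unused.
#' @name lr_pool_plan-tidiers
#' @method glance lr_pool_plan
#' @export
glance.lr_pool_plan <- function(x, ...) {
  meta <- attr(x, "meta")
  tibble::tibble(
    n_components = nrow(x),
    total_volume_uL = attr(x, "total_volume_uL"),
    rule = meta$rule %||% NA_character_
  )
}
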