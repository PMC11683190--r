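#' Build the full factorial experimental design
#'
#' Crosses pea accession, rhizobial inoculum and aphid exposure, replicating
#' every cell once per block (a randomized complete block design).  The default
#' factor sets give the 3 x 5 x 3 x 6 = 270-plant layout of the study the
#' package emulates.
#'
#' Plant identifiers follow the pattern `B<block>_<accession>_<inoculum>_<aphid>`.
#' Co-inoculation version A (`co_A`) labels the Fix+ strain red and the Fix-
#' strain green; version B (`co_B`) is the reciprocal labeling.
#'
#' @param n_blocks Number of complete blocks (>= 1).
#' @param accessions,inocula,aphids Character vectors of factor levels; any
#'   subset of the defaults is allowed.
#' @return A tibble with one row per plant: `plant_id`, `block`, `accession`,
#'   `inoculum`, `aphid`, ordered by (block, accession, inoculum, aphid).
#' @examples
#' build_design(n_blocks = 1)
#' @export
build_design <- function(n_blocks = 6L,
                         accessions = c("wild", "domesticated", "non_nodulating"),
                         inocula = c("none", "fix_plus", "fix_minus", "co_A", "co_B"),
                         aphids = c("none", "pemv_minus", "pemv_plus")) {
  n_blocks <- as.integer(n_blocks)
  if (length(n_blocks) != 1L || is.na(n_blocks) || n_blocks < 1L) {
    stop("invalid design: n_blocks must be a single integer >= 1", call. = FALSE)
  }
  for (nm in c("accessions", "inocula", "aphids")) {
    v <- get(nm)
    if (!is.character(v) || length(v) == 0L || anyNA(v) || anyDuplicated(v)) {
      stop("invalid design: ", nm, " must be a non-empty character vector ",
           "without duplicates", call. = FALSE)
    }
  }
  design <- tidyr::expand_grid(
    block = seq_len(n_blocks),
    accession = accessions,
    inoculum = inocula,
    aphid = aphids
  )
  design |>
    dplyr::mutate(
      plant_id = paste0("B", .data$block, "_", .data$accession, "_",
                        .data$inoculum, "_", .data$aphid)
    ) |>
    dplyr::select("plant_id", "block", "accession", "inoculum", "aphid") |>
    dplyr::arrange(.data$block, match(.data$accession, accessions),
                   match(.data$inoculum, inocula), match(.data$aphid, aphids))
}

#' Which strains does an inoculum carry, and in which color?
#'
#' Resolves the reciprocal red/green labeling scheme: 1-strain inocula carry
#' the same strain under both fluorophores (so marker effects cannot mimic
#' occupant effects), `co_A` carries red Fix+ / green Fix-, and `co_B` the
#' reciprocal pair.
#'
#' @param inoculum One of `"none"`, `"fix_plus"`, `"fix_minus"`, `"co_A"`, `"co_B"`.
#' @return A list with `red` and `green` strain labels (`"fix_plus"`,
#'   `"fix_minus"` or `"none"`) and `both_strains` (logical).
#' @export
inoculum_colors <- function(inoculum) {
  switch(inoculum,
    none      = list(red = "none",      green = "none",      both_strains = FALSE),
    fix_plus  = list(red = "fix_plus",  green = "fix_plus",  both_strains = FALSE),
    fix_minus = list(red = "fix_minus", green = "fix_minus", both_strains = FALSE),
    co_A      = list(red = "fix_plus",  green = "fix_minus", both_strains = TRUE),
    co_B      = list(red = "fix_minus", green = "fix_plus",  both_strains = TRUE),
    stop("unknown inoculum: ", inoculum, call. = FALSE)
  )
}

#' Convert an optical density to a cell titer
#'
#' Uses the study's spectrophotometric calibration: CFU per mL =
#' OD600 x 5.8e7.
#'
#' @param od600 Non-negative optical density at 600 nm (vectorized).
#' @return Estimated colony-forming units per mL.
#' @examples
#' od600_to_cfu(1.0)   # 5.8e7
#' @export
od600_to_cfu <- function(od600) {
  if (!is.numeric(od600) || any(is.na(od600)) || any(od600 < 0)) {
    stop("od600 must be non-negative and non-missing", call. = FALSE)
  }
  od600 * 5.8e7
}
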