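#' Fatty-acid composition of seven argan oils
#'
#' The published fatty-acid composition (percent of total FAME peak area) of
#' seven argan oil samples differing in geographic origin and extraction
#' procedure. Four acids dominate the profile: palmitic (C16:0), stearic
#' (C18:0), oleic (C18:1) and linoleic (C18:2). These seven profiles are the
#' reference input for the correlation screen and the network build.
#'
#' @return A data frame with one row per oil sample and columns `sample_id`,
#'   `region`, `extraction`, `palmitic`, `stearic`, `oleic`, `linoleic`
#'   (percent).
#' @seealso [derive_indices()], [argan_reference_indices()]
#' @export
#' @examples
#' oils <- argan_oils()
#' derive_indices(as_profile(oils[1, ]))
argan_oils <- function() {
  data.frame(
    sample_id = c(
      "TUN-SOL", "MAR-CP-COSM", "MAR-SOL", "MAR-CP-ED",
      "ALG-TIN-SOL", "ALG-TIN-CP", "ALG-MOS-SOL"
    ),
    region = c(
      "Tunisia", "Morocco", "Morocco", "Morocco",
      "Algeria-Tindouf", "Algeria-Tindouf", "Algeria-Mostaganem"
    ),
    extraction = c(
      "solvent", "cold pressing", "solvent", "cold pressing",
      "solvent", "cold pressing", "solvent"
    ),
    palmitic = c(16.13, 14.43, 12.79, 13.5, 13.84, 13, 12.28),
    stearic = c(7.10, 6.17, 5.35, 5.5, 5.68, 5.2, 4.72),
    oleic = c(52.53, 47.17, 45.53, 47, 50.30, 44.3, 45.02),
    linoleic = c(24.24, 32.22, 34.64, 33, 28.99, 35.8, 36.80),
    stringsAsFactors = FALSE
  )
}

#' Published derived nutritional indices for the seven reference oils
#'
#' The derived index rows as printed in the source tables: total saturated and
#' unsaturated fatty acids, P/S index and UFA/SFA ratio, at two-decimal
#' presentation precision. Kept separate from [argan_oils()] so that
#' recomputation via [derive_indices()] can be checked against the printed
#' values.
#'
#' @return A data frame with columns `sample_id`, `total_sfa`, `total_ufa`,
#'   `ps_index`, `ufa_sfa_ratio`.
#' @export
argan_reference_indices <- function() {
  data.frame(
    sample_id = argan_oils()$sample_id,
    total_sfa = c(23.23, 20.60, 18.14, 19, 19.52, 18.2, 17),
    total_ufa = c(76.77, 79.39, 80.17, 80, 79.29, 80.1, 81.82),
    ps_index = c(1.04, 1.56, 1.91, 1.74, 1.48, 1.97, 2.16),
    ufa_sfa_ratio = c(3.30, 3.85, 4.42, 4.21, 4.06, 4.40, 4.81),
    stringsAsFactors = FALSE
  )
}

#' Published physicochemical quality row for six argan oils
#'
#' Free acidity (% oleic acid) and the published quality-grade labels for the
#' six oils whose physicochemical parameters were tabulated. Used to check the
#' default grade bands of [classify_grade()].
#'
#' @return A data frame with columns `sample_id`, `region`, `extraction`,
#'   `free_acidity`, `grade`.
#' @export
argan_quality_table <- function() {
  data.frame(
    sample_id = c(
      "TUN-SOL", "MAR-CP", "MAR-SOL",
      "ALG-TIN-SOL", "ALG-TIN-CP", "ALG-MOS-SOL"
    ),
    region = c(
      "Tunisia", "Morocco", "Morocco",
      "Algeria-Tindouf", "Algeria-Tindouf", "Algeria-Mostaganem"
    ),
    extraction = c(
      "solvent", "cold pressing", "solvent",
      "solvent", "cold pressing", "solvent"
    ),
    free_acidity = c(0.90, 1.05, 1.3, 0.12, 0.8, 0.11),
    grade = c(
      "extra virgin", "virgin", "virgin",
      "refined", "extra virgin", "refined"
    ),
    stringsAsFactors = FALSE
  )
}

#' Published extraction yields by origin
#'
#' Yield percentages by processing stage (nut per fruit, kernel per nut,
#' kernel per fruit, oil per kernel) for the tabulated origins; `NA` where the
#' source reports no value or only a range (the mechanically pressed Moroccan
#' oil/kernel yield is reported as 30-50%). Values are stored as printed, not
#' re-derived.
#'
#' @return A data frame with columns `sample_id`, `nut_per_fruit`,
#'   `kernel_per_nut`, `kernel_per_fruit`, `oil_per_kernel`, `extraction`.
#' @export
argan_yield_table <- function() {
  data.frame(
    sample_id = c(
      "TUN", "MAR-SOL", "MAR-MECH", "MAR-HAND", "ALG-TIN", "ALG-MOS"
    ),
    nut_per_fruit = c(25, NA, 27, NA, NA, NA),
    kernel_per_nut = c(10, NA, 10.8, NA, NA, NA),
    kernel_per_fruit = c(2.5, NA, 3, 2.7, NA, NA),
    oil_per_kernel = c(61.3, 58, NA, 20, 55.9, 66.5),
    extraction = c(
      "solvent", "solvent", "mechanical pressing", "hand pressing",
      "solvent", "solvent"
    ),
    stringsAsFactors = FALSE
  )
}
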