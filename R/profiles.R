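# Fatty-acid profiles: normalisation from GC peak areas, compositional
# validation, yield ratios and the derived nutritional indices.

#' Convert GC peak areas to a fatty-acid percentage profile
#'
#' Each fatty acid's percentage is its peak area divided by the sum of all
#' peak areas, times 100 — the standard percent-of-total-FAME-area convention
#' for gas-chromatographic composition reporting.
#'
#' @param areas Named numeric vector of non-negative peak areas; at least one
#'   must be positive.
#' @return A named numeric vector of percentages summing to 100, of class
#'   `fatty_acid_profile`.
#' @export
#' @examples
#' normalize_peak_areas(c(oleic = 2, linoleic = 1, palmitic = 1))
normalize_peak_areas <- function(areas) {
  if (length(areas) == 0 || is.null(names(areas)) || any(!nzchar(names(areas)))) {
    stop("'areas' must be a non-empty named numeric vector", call. = FALSE)
  }
  nms <- names(areas)
  areas <- stats::setNames(as.numeric(areas), nms)
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("peak areas must be finite and non-negative", call. = FALSE)
  }
  total <- sum(areas)
  if (total <= 0) {
    stop("all peak areas are zero; cannot normalize", call. = FALSE)
  }
  structure(100 * areas / total, class = "fatty_acid_profile")
}

#' Validate the compositional closure of a fatty-acid profile
#'
#' A percentage profile must have every component in \[0, 100\] and sum to
#' 100 within a closure tolerance. Published compositions are rounded to two
#' decimals, so small deviations from exact closure are expected; the default
#' tolerance of 1 percentage point accommodates them.
#'
#' @param profile Named numeric vector of percentages (a full profile or the
#'   four major acids).
#' @param tol Allowed absolute deviation of the sum from 100 (percentage
#'   points).
#' @return The profile (classed `fatty_acid_profile`) with attribute
#'   `closure_dev`, the signed deviation of its sum from 100.
#' @export
validate_profile <- function(profile, tol = 1.0) {
  vals <- unclass(profile)
  if (length(vals) == 0 || is.null(names(vals))) {
    stop("profile must be a named numeric vector of percentages", call. = FALSE)
  }
  bad <- names(vals)[!is.finite(vals) | vals < 0 | vals > 100]
  if (length(bad) > 0) {
    stop(
      "profile component(s) out of [0, 100]: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  dev <- sum(vals) - 100
  if (abs(dev) > tol) {
    stop(
      sprintf(
        "closure violation: components sum to %.4f (tolerance 100 ± %g)",
        sum(vals), tol
      ),
      call. = FALSE
    )
  }
  structure(vals, class = "fatty_acid_profile", closure_dev = dev)
}

#' Coerce a sample-table row to a fatty-acid profile
#'
#' Extracts the fatty-acid columns of a one-row data frame (as returned by
#' [argan_oils()] or [read_samples()]) into a named profile vector.
#'
#' @param row One-row data frame containing at least the columns in `acids`.
#' @param acids Character vector of fatty-acid column names.
#' @return A named numeric `fatty_acid_profile`.
#' @export
as_profile <- function(row, acids = c("palmitic", "stearic", "oleic", "linoleic")) {
  missing <- setdiff(acids, names(row))
  if (length(missing) > 0) {
    stop("missing fatty-acid column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    stats::setNames(as.numeric(row[1, acids]), acids),
    class = "fatty_acid_profile"
  )
}

#' Derived nutritional indices of a fatty-acid profile
#'
#' Computes the standard nutritional quality indices of an edible oil from
#' its fatty-acid composition: total saturated fatty acids (SFA), total
#' unsaturated fatty acids (UFA), the P/S index (polyunsaturated, here
#' linoleic, over total saturated) and the UFA/SFA ratio. Values are kept at
#' full precision; rounding to two decimals is a presentation concern.
#'
#' @param profile Named numeric percentage profile.
#' @param sfa_names Names of the saturated acids summed into total SFA.
#' @param ufa_names Names of the unsaturated acids summed into total UFA.
#' @param pufa_names Names of the polyunsaturated acids forming the P of P/S.
#' @return A list of class `derived_indices` with elements `total_sfa`,
#'   `total_ufa`, `ps_index`, `ufa_sfa_ratio`.
#' @export
#' @examples
#' tun <- c(palmitic = 16.13, stearic = 7.10, oleic = 52.53, linoleic = 24.24)
#' derive_indices(tun)
derive_indices <- function(profile,
                           sfa_names = c("palmitic", "stearic"),
                           ufa_names = c("oleic", "linoleic"),
                           pufa_names = "linoleic") {
  vals <- unclass(profile)
  needed <- unique(c(sfa_names, ufa_names, pufa_names))
  missing <- setdiff(needed, names(vals))
  if (length(missing) > 0) {
    stop("acid(s) absent from profile: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  total_sfa <- sum(vals[sfa_names])
  total_ufa <- sum(vals[ufa_names])
  if (total_sfa == 0) {
    stop("total SFA is zero; P/S index and UFA/SFA ratio undefined",
      call. = FALSE
    )
  }
  structure(
    list(
      total_sfa = total_sfa,
      total_ufa = total_ufa,
      ps_index = sum(vals[pufa_names]) / total_sfa,
      ufa_sfa_ratio = total_ufa / total_sfa
    ),
    class = "derived_indices"
  )
}

#' @export
print.derived_indices <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Total SFA %.*f%%  Total UFA %.*f%%  P/S %.*f  UFA/SFA %.*f\n",
    digits, x$total_sfa, digits, x$total_ufa,
    digits, x$ps_index, digits, x$ufa_sfa_ratio
  ))
  invisible(x)
}

#' Append derived indices to a sample table
#'
#' Row-wise application of [derive_indices()] to a sample table, adding the
#' columns `total_sfa`, `total_ufa`, `ps_index` and `ufa_sfa_ratio`.
#'
#' @inheritParams derive_indices
#' @param samples Data frame with one row per oil and fatty-acid columns.
#' @return `samples` with four index columns appended.
#' @export
add_derived_indices <- function(samples,
                                sfa_names = c("palmitic", "stearic"),
                                ufa_names = c("oleic", "linoleic"),
                                pufa_names = "linoleic") {
  idx <- lapply(seq_len(nrow(samples)), function(i) {
    di <- derive_indices(
      as_profile(samples[i, , drop = FALSE], unique(c(sfa_names, ufa_names))),
      sfa_names, ufa_names, pufa_names
    )
    as.data.frame(unclass(di))
  })
  cbind(samples, do.call(rbind, idx))
}

#' Processing-stage yield ratios
#'
#' Computes the standard fruit-processing yields of argan oil production from
#' stage masses: nut per fruit, kernel per nut, kernel per fruit and oil per
#' kernel, each as 100 x child mass / parent mass. Stages not supplied yield
#' `NA`.
#'
#' @param fruit,nut,kernel,oil Stage masses (same unit); non-negative, and a
#'   parent mass must be positive for any ratio drawn from it.
#' @return A list of class `yield_record` with elements `nut_per_fruit`,
#'   `kernel_per_nut`, `kernel_per_fruit`, `oil_per_kernel` (percent).
#' @export
#' @examples
#' yield_ratios(fruit = 100, nut = 25, kernel = 2.5)
yield_ratios <- function(fruit = NULL, nut = NULL, kernel = NULL, oil = NULL) {
  masses <- c(fruit = fruit, nut = nut, kernel = kernel, oil = oil)
  if (any(!is.finite(masses)) || any(masses < 0)) {
    stop("stage masses must be finite and non-negative", call. = FALSE)
  }
  ratio <- function(child, parent, stage) {
    if (is.null(child) || is.null(parent)) {
      return(NA_real_)
    }
    if (parent == 0) {
      stop("zero ", stage, " mass: ratio undefined", call. = FALSE)
    }
    100 * child / parent
  }
  structure(
    list(
      nut_per_fruit = ratio(nut, fruit, "fruit"),
      kernel_per_nut = ratio(kernel, nut, "nut"),
      kernel_per_fruit = ratio(kernel, fruit, "fruit"),
      oil_per_kernel = ratio(oil, kernel, "kernel")
    ),
    class = "yield_record"
  )
}
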