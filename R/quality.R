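# Physicochemical quality indices from titration and absorbance readings,
# and the quality-grade classifier.

#' Free acidity of an oil from NaOH titration
#'
#' Free acidity, expressed as mass percent of oleic acid, from the volume of
#' NaOH solution needed to neutralise the free fatty acids in an oil sample:
#' `V * C * M / (10 * m)`.
#'
#' @param V Titrant volume at the equivalence point, ml.
#' @param C NaOH concentration, mol/L.
#' @param m Oil sample mass, g; must be positive.
#' @param M Molar mass used to express the acidity, g/mol; oleic acid
#'   (282.46) by default.
#' @return Free acidity in percent oleic acid.
#' @export
#' @examples
#' free_acidity(V = 0.9001, C = 0.177, m = 5)
free_acidity <- function(V, C, m, M = 282.46) {
  check_nonneg(V = V, C = C, M = M)
  if (!is.finite(m) || m <= 0) {
    stop("oil mass 'm' must be positive", call. = FALSE)
  }
  V * C * M / (10 * m)
}

#' Acid index of an oil from KOH titration
#'
#' The acid index (acid value) is the mass of potassium hydroxide, in mg,
#' needed to neutralise the free acids in one gram of oil:
#' `V * 56.1 * N / m`, with 56.1 g/mol the molar mass of KOH.
#'
#' @param V Titrant volume at the equivalence point, ml.
#' @param N KOH normality, eq/L.
#' @param m Oil sample mass, g; must be positive.
#' @return Acid index in mg KOH per g oil.
#' @export
acid_index <- function(V, N, m) {
  check_nonneg(V = V, N = N)
  if (!is.finite(m) || m <= 0) {
    stop("oil mass 'm' must be positive", call. = FALSE)
  }
  V * 56.1 * N / m
}

#' Total polyphenol content from Folin-Ciocalteu absorbance
#'
#' Total polyphenols in ppm (mg gallic-acid equivalent per kg oil) from the
#' absorbance at 725 nm of the Folin-Ciocalteu reaction mixture, using the
#' fixed protocol calibration `403.68 * A725` valid for a 10 g oil take.
#'
#' @param A725 Absorbance at 725 nm; non-negative.
#' @return Polyphenol content, ppm.
#' @export
total_polyphenols <- function(A725) {
  check_nonneg(A725 = A725)
  403.68 * A725
}

#' Chlorophyll content from three-wavelength absorbance
#'
#' Chlorophyll pigments in ppm by the baseline-corrected single-peak method:
#' the 670 nm absorbance minus the mean of the flanking 630 and 710 nm
#' readings, divided by `0.1086 * L`. Noisy baselines can drive the corrected
#' absorbance slightly negative; since a content cannot be negative the
#' result is then floored at zero with a warning.
#'
#' @param A670,A630,A710 Absorbances at the stated wavelengths; non-negative.
#' @param L Spectrophotometer cell path length, cm; positive (default 1).
#' @return Chlorophyll content, ppm.
#' @export
chlorophyll_content <- function(A670, A630, A710, L = 1) {
  check_nonneg(A670 = A670, A630 = A630, A710 = A710)
  if (!is.finite(L) || L <= 0) {
    stop("path length 'L' must be positive", call. = FALSE)
  }
  value <- (A670 - (A630 + A710) / 2) / (0.1086 * L)
  if (value < 0) {
    warning(
      sprintf("negative chlorophyll reading (%.4g ppm) floored to 0", value),
      call. = FALSE
    )
    value <- 0
  }
  value
}

#' Carotenoid content from 470 nm absorbance
#'
#' Carotenoids in ppm from the absorbance at 470 nm of the oil dissolved in
#' cyclohexane (7.5 ml oil made up to 25 ml), via the specific extinction
#' method: `A470 * 25 * 10000 / (2000 * 7.5)`.
#'
#' @param A470 Absorbance at 470 nm; non-negative.
#' @return Carotenoid content, ppm.
#' @export
carotenoid_content <- function(A470) {
  check_nonneg(A470 = A470)
  A470 * 25 * 10000 / (2000 * 7.5)
}

#' Default quality-grade bands on free acidity
#'
#' The default classification bands mapping free acidity (% oleic acid) to a
#' commercial quality grade. Very low acidity indicates a refined (chemically
#' deacidified) oil, so the bands are deliberately non-monotone: \[0, 0.2)
#' refined, \[0.2, 1.0\] extra virgin, (1.0, 2.0\] virgin, (2.0, Inf)
#' lampante.
#'
#' @return A data frame with columns `lower`, `upper`, `lower_closed`,
#'   `upper_closed`, `label`, one row per band.
#' @export
grade_bands <- function() {
  data.frame(
    lower = c(0, 0.2, 1, 2),
    upper = c(0.2, 1, 2, Inf),
    lower_closed = c(TRUE, TRUE, FALSE, FALSE),
    upper_closed = c(FALSE, TRUE, TRUE, FALSE),
    label = c("refined", "extra virgin", "virgin", "lampante"),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands) {
  required <- c("lower", "upper", "lower_closed", "upper_closed", "label")
  if (!all(required %in% names(bands))) {
    stop("grade bands need columns: ", paste(required, collapse = ", "),
      call. = FALSE
    )
  }
  bands <- bands[order(bands$lower), , drop = FALSE]
  if (bands$lower[1] != 0 || !bands$lower_closed[1]) {
    stop("grade bands must start with a band closed at 0", call. = FALSE)
  }
  if (is.finite(bands$upper[nrow(bands)])) {
    stop("grade bands must extend to Inf", call. = FALSE)
  }
  if (any(bands$upper <= bands$lower)) {
    stop("each grade band needs upper > lower", call. = FALSE)
  }
  for (i in seq_len(nrow(bands) - 1)) {
    if (bands$upper[i] != bands$lower[i + 1]) {
      stop(
        sprintf(
          "grade bands have a gap or overlap between %g and %g",
          bands$upper[i], bands$lower[i + 1]
        ),
        call. = FALSE
      )
    }
    if (bands$upper_closed[i] == bands$lower_closed[i + 1]) {
      stop(
        sprintf(
          "boundary %g belongs to %s of the adjacent bands",
          bands$upper[i], if (bands$upper_closed[i]) "both" else "neither"
        ),
        call. = FALSE
      )
    }
  }
  bands
}

#' Classify an oil's quality grade from its free acidity
#'
#' Assigns each free-acidity value to the grade band containing it. Bands are
#' configuration: they must tile \[0, Inf) without gap or overlap, each
#' boundary belonging to exactly one of its two adjacent bands.
#'
#' @param free_acidity Numeric vector of free acidities, % oleic acid;
#'   non-negative.
#' @param bands Band table as produced by [grade_bands()].
#' @return Character vector of grade labels.
#' @export
#' @examples
#' classify_grade(c(0.90, 1.05, 0.12))
classify_grade <- function(free_acidity, bands = grade_bands()) {
  bands <- validate_bands(bands)
  check_nonneg(free_acidity = free_acidity)
  vapply(free_acidity, function(v) {
    for (i in seq_len(nrow(bands))) {
      above <- if (bands$lower_closed[i]) v >= bands$lower[i] else v > bands$lower[i]
      below <- if (bands$upper_closed[i]) v <= bands$upper[i] else v < bands$upper[i]
      if (above && below) {
        return(bands$label[i])
      }
    }
    stop("no grade band contains ", v, call. = FALSE) # unreachable after validation
  }, character(1))
}

# shared guard: every named argument finite and >= 0
check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("'", nm, "' must be finite and non-negative", call. = FALSE)
    }
  }
  invisible(TRUE)
}
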