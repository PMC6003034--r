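# Variable encoding of the ten study variables and the Pearson correlation
# screen with two-sided p-values.

#' Default numeric coding of the categorical study variables
#'
#' Region and extraction procedure enter the correlation and network analyses
#' as integer-coded variables. No canonical coding exists for such labels, so
#' the coding is explicit configuration and every correlation involving a
#' coded variable is interpretable only together with it. The defaults order
#' regions Tunisia (1), Morocco (2), Algeria (3) — both Algerian provenances
#' share code 3 — and extraction procedures solvent (1), mechanical
#' pressing (2), cold or hand pressing (3).
#'
#' @return A list with named numeric vectors `region` and `extraction`
#'   mapping label to code.
#' @export
default_encoding <- function() {
  list(
    region = c(
      "Tunisia" = 1, "Morocco" = 2, "Algeria" = 3,
      "Algeria-Tindouf" = 3, "Algeria-Mostaganem" = 3
    ),
    extraction = c(
      "solvent" = 1, "mechanical pressing" = 2,
      "cold pressing" = 3, "hand pressing" = 3
    )
  )
}

#' The ten analysis variables, in canonical order
#' @return Character vector of variable names.
#' @export
analysis_variables <- function() {
  c(
    "region", "extraction", "palmitic", "stearic", "oleic", "linoleic",
    "total_sfa", "total_ufa", "ps_index", "ufa_sfa_ratio"
  )
}

#' Encode a sample table as a numeric sample-by-variable matrix
#'
#' Maps categorical labels to numeric codes, appends the derived nutritional
#' indices when absent, and assembles the ten analysis variables into a
#' numeric matrix (rows = samples, columns = variables) ready for the
#' correlation screen and the network build.
#'
#' @param samples Sample table with `region`, `extraction` and the four
#'   fatty-acid columns (see [argan_oils()], [read_samples()]).
#' @param encoding Label-to-code maps, as [default_encoding()].
#' @param variables Column order of the result.
#' @return Numeric matrix with `rownames` from `sample_id` (if present) and
#'   attribute `encoding`.
#' @export
#' @examples
#' X <- encode_samples(argan_oils())
#' dim(X)
encode_samples <- function(samples,
                           encoding = default_encoding(),
                           variables = analysis_variables()) {
  if (is.null(samples) || nrow(samples) == 0) {
    stop("empty sample table", call. = FALSE)
  }
  derived <- c("total_sfa", "total_ufa", "ps_index", "ufa_sfa_ratio")
  if (!all(derived %in% names(samples)) && any(derived %in% variables)) {
    samples <- add_derived_indices(samples)
  }
  out <- matrix(NA_real_,
    nrow = nrow(samples), ncol = length(variables),
    dimnames = list(samples$sample_id, variables)
  )
  for (v in variables) {
    if (v %in% names(encoding)) {
      labels <- as.character(samples[[v]])
      unseen <- setdiff(unique(labels), names(encoding[[v]]))
      if (length(unseen) > 0) {
        stop(
          "label(s) not covered by the ", v, " coding: ",
          paste(unseen, collapse = ", "),
          call. = FALSE
        )
      }
      out[, v] <- unname(encoding[[v]][labels])
    } else {
      if (!v %in% names(samples)) {
        stop("variable '", v, "' absent from the sample table", call. = FALSE)
      }
      out[, v] <- as.numeric(samples[[v]])
    }
  }
  attr(out, "encoding") <- encoding
  out
}

#' Pearson correlation matrix with two-sided p-values
#'
#' Pairwise product-moment correlations over the columns of a numeric matrix,
#' with two-sided p-values from the exact small-sample transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution on
#' `n - 2` degrees of freedom. Raw p-values are the default, matching the
#' conventional two-sided p < 0.05 screen; Benjamini-Hochberg adjustment over
#' the distinct pairs is available via `adjust = "BH"`.
#'
#' @param X Numeric matrix, rows = samples (n >= 3), columns = variables.
#'   Zero-variance columns are dropped with a warning.
#' @param alpha Significance levels for the star flags, largest first.
#' @param adjust P-value adjustment over the distinct pairs: `"none"`
#'   (default) or any method of [stats::p.adjust()].
#' @return An object of class `correlation_result`: list with the `r` matrix,
#'   `p` matrix (diagonal `NA`), `sig` character matrix of stars, sample size
#'   `n`, `alpha` and `adjust`.
#' @export
#' @examples
#' cr <- pearson_with_pvalues(encode_samples(argan_oils()))
#' round(cr$r["oleic", "ps_index"], 3)
pearson_with_pvalues <- function(X, alpha = c(0.05, 0.01), adjust = "none") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) {
    stop("need at least 3 samples for a correlation p-value", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(
      "dropping zero-variance column(s): ",
      paste(colnames(X)[sds == 0], collapse = ", "),
      call. = FALSE
    )
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2) {
    stop("fewer than 2 variable columns with positive variance", call. = FALSE)
  }
  r <- stats::cor(X)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(p) <- NA_real_
  if (!identical(adjust, "none")) {
    low <- lower.tri(p)
    p[low] <- stats::p.adjust(p[low], method = adjust)
    p[upper.tri(p)] <- t(p)[upper.tri(p)]
  }
  alpha <- sort(alpha, decreasing = TRUE)
  stars <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  for (k in seq_along(alpha)) {
    stars[!is.na(p) & p < alpha[k]] <- strrep("*", k)
  }
  structure(
    list(r = r, p = p, sig = stars, n = n, alpha = alpha, adjust = adjust),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Pearson correlation over %d variables, n = %d (adjust = %s)\n",
    ncol(x$r), x$n, x$adjust
  ))
  shown <- matrix(
    paste0(formatC(x$r, digits = digits, format = "f"), x$sig),
    nrow(x$r),
    dimnames = dimnames(x$r)
  )
  print(shown, quote = FALSE)
  cat(
    "significance:", paste(
      sprintf("%s p < %g", strrep("*", seq_along(x$alpha)), x$alpha),
      collapse = ", "
    ), "\n"
  )
  invisible(x)
}

#' Flatten a correlation result to one row per variable pair
#'
#' @param cr A `correlation_result`.
#' @return Data frame with columns `var1`, `var2`, `r`, `p`, `sig`, one row
#'   per unordered pair (`var1` before `var2` in column order).
#' @export
correlation_tidy <- function(cr) {
  stopifnot(inherits(cr, "correlation_result"))
  idx <- which(upper.tri(cr$r), arr.ind = TRUE)
  vars <- colnames(cr$r)
  data.frame(
    var1 = vars[idx[, 1]],
    var2 = vars[idx[, 2]],
    r = cr$r[idx],
    p = cr$p[idx],
    sig = cr$sig[idx],
    stringsAsFactors = FALSE
  )
}
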