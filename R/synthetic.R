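# Seeded generators: linear-Gaussian SEM data for network recovery tests,
# synthetic oil cohorts with compositional closure, and exact inversion
# fixtures for the quality formulas.

#' Specify a linear-Gaussian structural equation model
#'
#' A SEM over named nodes: each node is a linear combination of its parents
#' plus independent Gaussian noise. The parent map must be acyclic; nodes are
#' simulated in topological order.
#'
#' @param parents Named list: for each node, a character vector of its
#'   parents (empty or `NULL` for root nodes). Every node must be named;
#'   parents not named as nodes are an error.
#' @param coefficients Named list parallel to `parents`: numeric vector of
#'   one weight per parent (recycled scalar allowed). Defaults to weight 1
#'   for every parent.
#' @param noise_sd Per-node Gaussian noise standard deviation; scalar or
#'   named vector. Must be positive.
#' @param n Number of samples; at least 1.
#' @param seed Integer seed; the simulation is deterministic given the spec.
#' @return An object of class `sem_spec`.
#' @export
#' @examples
#' spec <- sem_spec(parents = list(x = NULL, y = "x"), n = 100, seed = 1)
#' head(simulate_sem(spec))
sem_spec <- function(parents, coefficients = NULL, noise_sd = 1, n, seed) {
  nodes <- names(parents)
  if (is.null(nodes) || any(!nzchar(nodes))) {
    stop("every node in 'parents' must be named", call. = FALSE)
  }
  unknown <- setdiff(unique(unlist(parents)), nodes)
  if (length(unknown) > 0) {
    stop("parent(s) not declared as nodes: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  order <- topological_order(parents)
  if (is.null(coefficients)) {
    coefficients <- lapply(parents, function(p) rep(1, length(p)))
  }
  coefficients <- lapply(stats::setNames(nodes, nodes), function(v) {
    b <- coefficients[[v]]
    np <- length(parents[[v]])
    if (is.null(b)) b <- rep(1, np)
    if (length(b) == 1 && np > 1) b <- rep(b, np)
    if (length(b) != np) {
      stop("node '", v, "': ", np, " parent(s) but ", length(b),
        " coefficient(s)",
        call. = FALSE
      )
    }
    b
  })
  if (length(noise_sd) == 1) {
    noise_sd <- stats::setNames(rep(noise_sd, length(nodes)), nodes)
  }
  if (any(!is.finite(noise_sd)) || any(noise_sd <= 0)) {
    stop("'noise_sd' must be positive", call. = FALSE)
  }
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  structure(
    list(
      nodes = nodes, parents = parents, coefficients = coefficients,
      noise_sd = noise_sd[nodes], n = as.integer(n),
      seed = as.integer(seed), order = order
    ),
    class = "sem_spec"
  )
}

# Layered topological sort; errors on a cyclic parent map.
topological_order <- function(parents) {
  nodes <- names(parents)
  order <- character(0)
  pending <- nodes
  while (length(pending) > 0) {
    ready <- pending[vapply(
      pending,
      function(v) all(parents[[v]] %in% order), logical(1)
    )]
    if (length(ready) == 0) {
      stop("parent map contains a cycle involving: ",
        paste(pending, collapse = ", "),
        call. = FALSE
      )
    }
    order <- c(order, ready)
    pending <- setdiff(pending, ready)
  }
  order
}

#' Simulate data from a linear-Gaussian SEM
#'
#' Generates `n` samples: in topological order, each node equals the weighted
#' sum of its parents plus `N(0, noise_sd^2)` noise. Column order follows the
#' node order of the spec.
#'
#' @param spec A [sem_spec()].
#' @return Numeric n x p matrix with node names as column names.
#' @export
simulate_sem <- function(spec) {
  stopifnot(inherits(spec, "sem_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  X <- matrix(0, spec$n, length(spec$nodes),
    dimnames = list(NULL, spec$nodes)
  )
  for (v in spec$order) {
    mu <- 0
    pa <- spec$parents[[v]]
    if (length(pa) > 0) {
      mu <- X[, pa, drop = FALSE] %*% spec$coefficients[[v]]
    }
    X[, v] <- mu + stats::rnorm(spec$n, 0, spec$noise_sd[[v]])
  }
  X
}

#' Default group means for the synthetic oil cohort
#'
#' Six provenance-by-procedure groups (Tunisia, Morocco, Algeria crossed with
#' solvent and cold-pressing extraction) with mean fatty-acid profiles taken
#' from the reference compositions of [argan_oils()], renormalized to exact
#' closure (several published columns omit minor acids and sum slightly below
#' 100). No Tunisian cold-pressed composition has been published, so that
#' group reuses the Tunisian solvent mean.
#'
#' @return Data frame with `region`, `extraction` and the four mean acid
#'   percentages.
#' @export
default_oil_groups <- function() {
  ref <- argan_oils()
  pick <- function(id) ref[ref$sample_id == id, c("palmitic", "stearic", "oleic", "linoleic")]
  means <- rbind(
    pick("TUN-SOL"), pick("TUN-SOL"), pick("MAR-SOL"),
    pick("MAR-CP-COSM"), pick("ALG-MOS-SOL"), pick("ALG-TIN-CP")
  )
  means <- 100 * means / rowSums(means)
  cbind(
    data.frame(
      region = c("Tunisia", "Tunisia", "Morocco", "Morocco", "Algeria", "Algeria"),
      extraction = c(
        "solvent", "cold pressing", "solvent",
        "cold pressing", "solvent", "cold pressing"
      ),
      stringsAsFactors = FALSE
    ),
    means
  )
}

#' Simulate a synthetic oil cohort
#'
#' Draws per-sample fatty-acid profiles as group mean plus independent
#' Gaussian noise, then (by default) renormalizes each profile to exact
#' compositional closure (sum 100). Negative draws are rejected and resampled
#' up to `max_retries` times. The default cohort — 3 regions x 2 extraction
#' procedures x 5 replicates, n = 30 — is the package's standard desk-scale
#' test population.
#'
#' Group means whose components do not close within 1 point (published
#' compositions with minor acids omitted) are accepted with a warning;
#' with `renormalize = FALSE` and `noise_sd = 0` such means are reproduced
#' verbatim, which is useful for checking derived indices against published
#' rows.
#'
#' @param groups Group table as [default_oil_groups()]: one row per
#'   region-by-extraction group with mean acid percentages.
#' @param reps Samples per group.
#' @param noise_sd Trait noise standard deviation (percentage points).
#' @param seed Integer seed.
#' @param max_retries Resampling attempts before a negative profile is an
#'   error.
#' @param renormalize Rescale every drawn profile to sum exactly 100.
#' @return Sample table (data frame) with `sample_id`, `region`,
#'   `extraction` and the four acid columns.
#' @export
#' @examples
#' cohort <- simulate_oil_table(seed = 42)
#' range(rowSums(cohort[, c("palmitic", "stearic", "oleic", "linoleic")]))
simulate_oil_table <- function(groups = default_oil_groups(), reps = 5,
                               noise_sd = 1, seed, max_retries = 100,
                               renormalize = TRUE) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  acids <- c("palmitic", "stearic", "oleic", "linoleic")
  open <- character(0)
  for (i in seq_len(nrow(groups))) {
    prof <- stats::setNames(as.numeric(groups[i, acids]), acids)
    validate_profile(prof, tol = Inf) # range check
    if (abs(sum(prof) - 100) > 1) {
      open <- c(open, sprintf("group %d (sum %.2f)", i, sum(prof)))
    }
  }
  if (length(open) > 0) {
    warning("group mean(s) not closed within 100 ± 1: ",
      paste(open, collapse = ", "),
      call. = FALSE
    )
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  rows <- vector("list", nrow(groups) * reps)
  k <- 0
  for (i in seq_len(nrow(groups))) {
    mean_prof <- as.numeric(groups[i, acids])
    for (r in seq_len(reps)) {
      prof <- NULL
      for (try in seq_len(max_retries)) {
        cand <- mean_prof + stats::rnorm(length(acids), 0, noise_sd)
        if (all(cand >= 0)) {
          prof <- cand
          break
        }
      }
      if (is.null(prof)) {
        stop("could not draw a non-negative profile for group ", i,
          " after ", max_retries, " attempts; reduce 'noise_sd'",
          call. = FALSE
        )
      }
      if (renormalize) {
        prof <- 100 * prof / sum(prof)
      }
      k <- k + 1
      rows[[k]] <- data.frame(
        sample_id = sprintf("%s-%s-%02d", groups$region[i],
          gsub(" ", "", groups$extraction[i]), r),
        region = groups$region[i],
        extraction = groups$extraction[i],
        palmitic = prof[1], stearic = prof[2],
        oleic = prof[3], linoleic = prof[4],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Invert the quality formulas into instrument readings
#'
#' Produces titration and absorbance readings that, fed back through
#' [free_acidity()], [acid_index()], [total_polyphenols()],
#' [chlorophyll_content()] and [carotenoid_content()], recover the target
#' contents exactly. The chlorophyll baseline (equal absorbances at 630 and
#' 710 nm) is drawn uniformly from \[0, 0.05\] under the seed so the
#' round-trip exercises the baseline correction, not just zero baselines.
#'
#' @param free_acidity,acid_index,polyphenol,chlorophyll,carotenoid Target
#'   contents (units as in the corresponding formulas); non-negative.
#' @param C NaOH concentration (mol/L) for the free-acidity titration.
#' @param m Oil mass (g) for the free-acidity titration.
#' @param M Molar mass (g/mol) expressing the acidity.
#' @param N KOH normality for the acid-index titration.
#' @param m_acid Oil mass (g) for the acid-index titration.
#' @param L Cell path length, cm.
#' @param seed Integer seed for the chlorophyll baseline.
#' @return List with `titration_naoh` (V, C, m, M), `titration_koh`
#'   (V, N, m), `absorbance` (A630, A670, A710, A470, A725, L).
#' @export
absorbance_fixtures <- function(free_acidity = 0.90, acid_index = 1.85,
                                polyphenol = 55, chlorophyll = 0.009,
                                carotenoid = 1.8,
                                C = 0.177, m = 5, M = 282.46,
                                N = 0.1, m_acid = 1, L = 1, seed = 1) {
  check_nonneg(
    free_acidity = free_acidity, acid_index = acid_index,
    polyphenol = polyphenol, chlorophyll = chlorophyll,
    carotenoid = carotenoid
  )
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  baseline <- stats::runif(1, 0, 0.05)
  list(
    titration_naoh = list(
      V = free_acidity * 10 * m / (C * M), C = C, m = m, M = M
    ),
    titration_koh = list(
      V = acid_index * m_acid / (56.1 * N), N = N, m = m_acid
    ),
    absorbance = list(
      A630 = baseline,
      A670 = chlorophyll * 0.1086 * L + baseline,
      A710 = baseline,
      A470 = carotenoid * 2000 * 7.5 / (25 * 10000),
      A725 = polyphenol / 403.68,
      L = L
    )
  )
}
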