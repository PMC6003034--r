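---
title: "Quality indices and partial-correlation networks for argan oil panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality indices and partial-correlation networks for argan oil panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arganet)
```

## The problem

An argan oil panel is a small table: a handful of oils, each with a
provenance (region, extraction procedure), a fatty-acid composition from gas
chromatography, and a set of physicochemical quality readings. Three
analytical layers sit on top of it:

1. **Quality indices** computed from raw instrument readings — titration
   volumes and absorbances — via fixed protocol formulas.
2. **Nutritional indices** derived from the fatty-acid composition.
3. **Association structure**: which traits co-vary (Pearson screen), and
   which associations survive conditioning on everything else (a Gaussian
   graphical model), with a heuristic orientation of the resulting edges.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic generators do and do not emulate.

## Quality indices

Each content formula is an affine-free, degree-1 map from its driving
reading, so the package also ships exact inverses
(`absorbance_fixtures()`) used to verify the round trip to 1e-9:

| quantity | formula | units |
|---|---|---|
| free acidity | `V·C·M / (10·m)` | % oleic acid |
| acid index | `V·56.1·N / m` | mg KOH / g |
| polyphenols | `403.68 · A725` | ppm |
| chlorophyll | `[A670 − (A630+A710)/2] / (0.1086·L)` | ppm |
| carotenoids | `A470·25·10000 / (2000·7.5)` | ppm |

Two deliberate choices:

* **Negative chlorophyll floors to zero with a warning.** The three-point
  baseline correction can go slightly negative under noise; a content
  cannot, and silently negative values would poison downstream summaries.
* **The polyphenol constant 403.68 is treated as a fixed protocol
  calibration** (valid for the stated 10 g oil take); the underlying
  gallic-acid curve is not modelled.

Grade classification is configuration, not chemistry: bands must tile
\[0, ∞) with every boundary owned by exactly one adjacent band, and the
*defaults* are deliberately non-monotone — very low acidity (< 0.2 %)
indicates a refined, chemically deacidified oil, then \[0.2, 1\] extra
virgin, (1, 2\] virgin, and above 2 % lampante. They reproduce all six
published grade labels from the published free-acidity row:

```{r grades}
q <- argan_quality_table()
data.frame(q, recomputed = classify_grade(q$free_acidity))
```

## Fatty-acid profiles and derived indices

Compositions are percent of total FAME peak area
(`normalize_peak_areas()`), so they are *compositional*: the closure
constraint (sum 100) is checked by `validate_profile()` with a default
tolerance of ±1 point, which absorbs two-decimal presentation rounding.
Published literature columns often list only the four major acids; their
sums can fall 1–2 points short of 100. `read_samples()` therefore treats a
closure violation as a warning by default (`closure = "error"` restores
strictness) — otherwise the package could not ingest the very tables the
field publishes.

The indices are plain arithmetic on the four major acids — total SFA
(palmitic + stearic), total UFA (oleic + linoleic), P/S = linoleic/SFA,
UFA/SFA — kept at full precision internally and rounded to two decimals
only in reports. Recomputation matches the published reference rows at
their printed two-decimal granularity; one published P/S entry (the
Tindouf solvent oil, 28.99/19.52 = 1.485) appears truncated rather than
rounded in print, which is why the test tolerance is one unit in the last
printed digit rather than strict round-half-up equality.

```{r indices}
add_derived_indices(argan_oils())[, c(1, 8:11)]
```

## The correlation screen

`pearson_with_pvalues()` computes product-moment correlations and exact
two-sided p-values from the `t` transform on `n − 2` degrees of freedom.
Conventions follow the field: raw p-values at α = 0.05 and 0.01
(Benjamini–Hochberg is available but off by default, matching the usual
uncorrected screen of small oil panels). Categorical provenance variables
enter as integer codes (`default_encoding()`: Tunisia 1, Morocco 2,
Algeria 3; solvent 1, mechanical 2, cold/hand pressing 3). There is no
canonical such coding, so any correlation involving region or extraction is
meaningful only relative to the declared encoding, which is attached to the
encoded matrix and echoed in run logs.

A caution specific to compositional data: closure alone induces negative
correlations among components (a percentage that rises forces others down),
and the derived indices are deterministic functions of the acids. Strong
SFA–SFA and SFA↔PUFA correlations are therefore partly structural, which is
precisely why the network layer conditions each pair on all other
variables.

## The network model

The network layer assumes the encoded variables are approximately jointly
Gaussian, so that zero partial correlation encodes conditional
independence.

**Shrinkage precision.** With n samples and p variables, the sample
correlation matrix `S` of the standardized data is shrunk toward the
identity, `S* = (1−λ)S + λI`. When `λ` is not supplied it is set to the
analytic intensity — the summed estimated variances of the off-diagonal
correlations over their summed squares, clipped to \[0, 1\]. Any λ > 0
makes `S*` positive definite even when n ≤ p or when variables are exact
linear combinations of others. Both situations are real here: a
seven-sample panel has n < p = 10, and the ten analysis variables contain
built-in dependencies (total SFA is the sum of two acids; closure ties the
acids together), so the unshrunk matrix is singular *by construction* at
any sample size. `lambda = 0` is accordingly only usable on variable
subsets free of exact dependencies, and `estimate_precision()` fails
loudly otherwise. A pseudo-inverse backend was considered and rejected:
shrinkage yields a proper positive-definite precision with an
interpretable tuning parameter, while a pseudo-inverse silently changes
the estimand on singular input.

**Edges.** Partial correlations `ρᵢⱼ = −ωᵢⱼ/√(ωᵢᵢωⱼⱼ)` with magnitude at
least τ become edges. τ defaults to 0.3 — a conventional "moderate
association" cut — and is configuration, not inference: no p-value is
attached to shrunk partial correlations here.

**Orientation.** Node k's score is its standardized partial variance
`gₖ = 1/ωₖₖ` (equivalently `σₖₖ/ωₖₖ` with `σₖₖ = 1` after
standardization — the two readings of the score coincide exactly on the
standardized scale, which is why standardization is mandatory rather than
optional; an unstandardized reading via `use_raw_variances = TRUE` is
exposed for completeness but ties orientation to measurement units). An
edge orients from the higher score ("more exogenous": little of its
variance explained by the rest) to the lower; the ratio `Bᵢⱼ = gᵢ/gⱼ`
satisfies `Bᵢⱼ·Bⱼᵢ = 1` identically, and `|B − 1| ≤ tie_eps` (default
1e-9; exact floating-point ties essentially never occur, so the tolerance
honours the conceptual "B = 1" case) leaves an edge undirected. Since
every arc points strictly downhill in a single node ordering, the directed
graph cannot contain a cycle; `is_acyclic()` re-verifies this through an
independent graph library on every build anyway.

**What orientation does — and does not — mean.** The heuristic is an
ordering device, not a causal discovery method. On a simulated causal
chain X1 → X2 → X3 the middle node has the *smallest* standardized partial
variance (it is the best explained), so both edges orient into it — the
recovered arrows need not coincide with the generative ones even when the
skeleton is recovered perfectly. Skeleton recovery is the property one can
actually expect, and it is strong: on chain and fork structural equation
models with coefficient 0.8 and n = 500, thresholding at τ = 0.2 recovers
100 % of true skeleton edges across 100 seeded replicates (recomputed in
the acceptance script). Arrows should be read as "relatively exogenous →
relatively endogenous", nothing more.

**The reference panel is an honest edge case.** With n = 7 on ten highly
collinear variables the analytic λ is ≈ 0.39; that much shrinkage flattens
every partial correlation below 0.3, so the default build returns an empty
(trivially acyclic) DAG. This is the method stating that seven samples
cannot support conditional-dependence claims over ten variables — lowering
τ or forcing a small λ will produce edges, but they are configuration
artefacts, which is why both knobs are explicit and echoed in every
report.

```{r network}
net <- build_network(encode_samples(argan_oils()))
net
```

On a larger panel the same pipeline yields a populated graph:

```{r network30}
cohort <- simulate_oil_table(seed = 1)
build_network(encode_samples(cohort))
```

## Synthetic generators

`simulate_sem()` draws from linear-Gaussian structural equation models in
topological order — the exact distributional family under which partial
correlations encode conditional independence — with every run fully
determined by an integer seed (the generators save and restore the global
RNG state, so they do not perturb a surrounding analysis). Closed forms
anchor the tests: a single edge with coefficient β and unit noise implies
corr = β/√(β²+1), and a chain's implied covariance is computed
analytically and compared entrywise.

`simulate_oil_table()` emulates a provenance-structured panel: group mean
profile + Gaussian trait noise, renormalized to exact closure (the noise
model a multivariate-normal partial-correlation analysis presumes, applied
to compositional data the way the field treats it — renormalize after
perturbation). Negative draws are rejected with bounded retries rather
than truncated, avoiding a distorted noise distribution near zero. The
default cohort is 3 regions × 2 extraction procedures × 5 replicates
(n = 30), group means taken from the published reference compositions
(renormalized to closure; Tunisia lacks a published cold-pressed column,
so that group reuses the Tunisian solvent mean). With `renormalize =
FALSE` and zero noise the generator reproduces published (non-closing)
columns verbatim, which is how the derived-index rows are checked
end-to-end.

What the generators do **not** emulate: GC chromatograms and peak
identification, non-Gaussian or heteroscedastic trait noise,
batch/instrument effects, and any dependence of the noise on the mean.
Passing tests on this synthetic family therefore demonstrate correctness
of the *computations* and recoverability under the model's own
assumptions — not robustness of the network step to real-world
departures from Gaussianity.

## Numerical choices, in one place

* Closure tolerance 1 point (`validate_profile`); closure violations in
  file input warn by default.
* Shrinkage target: identity on the correlation scale; λ clipped to
  \[0, 1\]; Cholesky-based inversion with an explicit error if `S*` is not
  positive definite.
* τ = 0.3 default edge threshold; `tie_eps = 1e-9` orientation tie band.
* Presentation rounding: 2 decimals for percentages/indices, 3 for r and
  p; full precision everywhere internally.
* Grade bands validated for gap/overlap/boundary-ownership before use.
* Problem sizes used in the shipped checks: the 7-oil reference panel, the
  n = 30 default cohort, SEMs at n = 500 (recovery, 100 seeds) and
  n = 2000 (closed-form correlation, 20 seeds) — small enough to run at a
  desk, large enough for the stochastic checks' tolerances.

## Known limitations

* Orientation is a total-order heuristic (see above); equal scores produce
  undirected edges, and no conditional-probability tables are estimated —
  the output is a graph, not a fitted Bayesian network.
* Correlations involving region/extraction depend on the integer coding of
  those labels; alternative codings permute signs and magnitudes.
* Several published pairwise correlations for this panel are not
  reproducible from the published two-decimal compositions (the package
  documents the two recomputable discrepancies in its tests rather than
  asserting the published values).
* The Pearson screen at n = 7 has very low power, and with ten variables
  the raw-p convention implies a non-trivial false-positive burden; the BH
  option exists for users who want it.
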