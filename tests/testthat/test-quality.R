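test_that("titration and absorbance formulas give the hand-computed values", {
  expect_equal(free_acidity(V = 0, C = 0.177, m = 5), 0)
  expect_equal(free_acidity(V = 0.9001, C = 0.177, m = 5), 0.90, tolerance = 1e-3)
  # doubling the oil mass halves the acidity
  expect_equal(
    free_acidity(V = 0.9, C = 0.177, m = 10),
    free_acidity(V = 0.9, C = 0.177, m = 5) / 2
  )

  expect_equal(acid_index(V = 0, N = 0.1, m = 1), 0)
  expect_equal(acid_index(V = 1, N = 0.1, m = 1), 5.61)
  expect_equal(acid_index(V = 0.3298, N = 0.1, m = 1), 1.85, tolerance = 1e-3)

  expect_equal(total_polyphenols(0), 0)
  expect_equal(total_polyphenols(1.0), 403.68)
  expect_equal(total_polyphenols(55 / 403.68), 55)

  expect_equal(chlorophyll_content(A670 = 0.3, A630 = 0.3, A710 = 0.3), 0)
  expect_equal(chlorophyll_content(A670 = 0.1086, A630 = 0, A710 = 0), 1.0)
  expect_equal(
    chlorophyll_content(A670 = 0.2172, A630 = 0, A710 = 0, L = 2), 1.0
  )

  expect_equal(carotenoid_content(0), 0)
  expect_equal(carotenoid_content(0.06), 1.0)
  expect_equal(carotenoid_content(0.108), 1.8)
})

test_that("content formulas are homogeneous of degree 1 in their driving reading", {
  for (s in c(0.5, 2, 7)) {
    expect_equal(
      free_acidity(V = s * 0.9, C = 0.177, m = 5),
      s * free_acidity(V = 0.9, C = 0.177, m = 5)
    )
    expect_equal(acid_index(V = s, N = 0.1, m = 1), s * acid_index(1, 0.1, 1))
    expect_equal(total_polyphenols(s * 0.2), s * total_polyphenols(0.2))
    expect_equal(carotenoid_content(s * 0.05), s * carotenoid_content(0.05))
    expect_equal(
      chlorophyll_content(A670 = s * 0.2, A630 = 0, A710 = 0),
      s * chlorophyll_content(A670 = 0.2, A630 = 0, A710 = 0)
    )
  }
})

test_that("degenerate readings error and negative chlorophyll floors to zero", {
  expect_error(free_acidity(V = 1, C = 0.1, m = 0), "positive")
  expect_error(acid_index(V = 1, N = 0.1, m = 0), "positive")
  expect_error(total_polyphenols(-0.1), "non-negative")
  expect_error(carotenoid_content(-1), "non-negative")
  expect_error(chlorophyll_content(0.1, 0.1, 0.1, L = 0), "positive")
  expect_warning(
    out <- chlorophyll_content(A670 = 0.01, A630 = 0.05, A710 = 0.05),
    "floored"
  )
  expect_equal(out, 0)
})

test_that("round-trip inversion fixtures recover every target content", {
  targets <- list(
    free_acidity = 0.90, acid_index = 1.85, polyphenol = 55,
    chlorophyll = 1.3, carotenoid = 0.74
  )
  fx <- do.call(absorbance_fixtures, c(targets, seed = 5))
  expect_equal(do.call(free_acidity, fx$titration_naoh),
    targets$free_acidity,
    tolerance = 1e-9
  )
  expect_equal(do.call(acid_index, fx$titration_koh),
    targets$acid_index,
    tolerance = 1e-9
  )
  expect_equal(total_polyphenols(fx$absorbance$A725),
    targets$polyphenol,
    tolerance = 1e-9
  )
  expect_equal(
    with(fx$absorbance, chlorophyll_content(A670, A630, A710, L)),
    targets$chlorophyll,
    tolerance = 1e-9
  )
  expect_equal(carotenoid_content(fx$absorbance$A470),
    targets$carotenoid,
    tolerance = 1e-9
  )

  # zero chlorophyll target: peak equals the baseline mean
  fx0 <- absorbance_fixtures(chlorophyll = 0, seed = 9)
  expect_equal(
    fx0$absorbance$A670,
    (fx0$absorbance$A630 + fx0$absorbance$A710) / 2
  )
})

test_that("default grade bands reproduce the published quality labels", {
  q <- argan_quality_table()
  expect_equal(classify_grade(q$free_acidity), q$grade)
  expect_equal(classify_grade(2.5), "lampante")
  # band edges: 0.2 belongs to extra virgin, 1.0 to extra virgin, 2.0 to virgin
  expect_equal(classify_grade(c(0.2, 1.0, 2.0)),
    c("extra virgin", "extra virgin", "virgin")
  )
})

test_that("malformed grade bands are rejected", {
  bands <- grade_bands()
  gap <- bands
  gap$upper[1] <- 0.15
  expect_error(classify_grade(0.5, gap), "gap or overlap")

  both <- bands
  both$lower_closed[2] <- FALSE # boundary 0.2 claimed by neither band
  expect_error(classify_grade(0.5, both), "neither")

  open_start <- bands
  open_start$lower_closed[1] <- FALSE
  expect_error(classify_grade(0.5, open_start), "closed at 0")

  finite_end <- bands[1:3, ]
  expect_error(classify_grade(0.5, finite_end), "Inf")
})
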