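test_that("correction matrix reduces to identity without natural abundance", {
  ab0 <- list(C = 1, H = 1, N = 1, O = 1)
  C <- build_correction_matrix("C3H7NO2", abundances = ab0)
  expect_equal(unclass(C), diag(4), ignore_attr = TRUE)
})

test_that("1-carbon correction column matches the direct binomial", {
  C <- build_correction_matrix("C1", abundances = list(C = c(0.989, 0.011)))
  expect_equal(C[, 1], c(0.989, 0.011))
  expect_equal(C[, 2], c(0, 1))  # fully labeled molecule has no unlabeled C
})

test_that("correction columns are probability masses (sum <= 1)", {
  for (f in c("C6H12O6", "C9H13N3O4", "C5H9NO2", "C10H16N5O13P3")) {
    C <- build_correction_matrix(f)
    expect_true(all(colSums(C) <= 1 + 1e-12), info = f)
    expect_true(all(C >= 0 & C <= 1), info = f)
    # lower-triangular in the labeled contribution
    expect_true(all(C[upper.tri(C)] == 0), info = f)
  }
  expect_error(build_correction_matrix("C2Xx3"), "unknown element")
  expect_error(build_correction_matrix("H2O"), "no C atoms")
})

test_that("correct_natural_abundance inverts forward convolution", {
  set.seed(7)
  formulas <- c("C3H4O3", "C6H12O6", "C12H22O11", "C9H13N3O4", "C4H6O4")
  for (f in formulas) {
    C <- build_correction_matrix(f)
    x_true <- runif(nrow(C)) * 1e5
    raw <- as.numeric(C %*% x_true)
    expect_equal(correct_natural_abundance(raw, C), x_true, tolerance = 1e-8)
  }
  C <- build_correction_matrix("C3H4O3")
  expect_equal(correct_natural_abundance(rep(0, 4), C), rep(0, 4))
  Cid <- build_correction_matrix("C3", abundances = list(C = 1))
  raw <- c(3, 2, 1, 4)
  expect_equal(correct_natural_abundance(raw, Cid), raw)
  # noisy input never yields negative intensities
  set.seed(8)
  C <- build_correction_matrix("C6H12O6")
  for (i in 1:10) {
    raw <- pmax(as.numeric(C %*% runif(7)) + rnorm(7, 0, 0.01), 0)
    x <- correct_natural_abundance(raw, C)
    expect_true(all(x >= 0))
  }
})

test_that("relative_amount follows the normalisation formula", {
  expect_equal(relative_amount(c(2, 1, 1), 2, 2), 1)
  expect_equal(relative_amount(2 * c(2, 1, 1), 2, 2), 2)  # homogeneity
  expect_equal(relative_amount(c(0, 0), 5, 10), 0)
  expect_error(relative_amount(c(1, 1), 0, 2), "> 0")
  expect_error(relative_amount(c(1, 1), 1, -1), "> 0")
})

test_that("fractional_contribution endpoints, formulas and invariances", {
  expect_equal(fractional_contribution(c(1, 0, 0, 0)), 0)
  expect_equal(fractional_contribution(c(1, 0, 0, 0), mode = "one_minus_m0"), 0)
  expect_equal(fractional_contribution(c(0, 0, 0, 1)), 1)
  expect_equal(fractional_contribution(c(0, 0, 0, 1), mode = "one_minus_m0"), 1)
  expect_equal(fractional_contribution(c(0.5, 0, 0, 0.5)), 0.5)
  expect_equal(fractional_contribution(c(0.5, 0, 0, 0.5), mode = "one_minus_m0"), 0.5)
  expect_error(fractional_contribution(c(0, 0, 0)), "zero total")
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    mid <- runif(n + 1)
    fc <- fractional_contribution(mid)
    expect_gte(fc, 0); expect_lte(fc, 1)
    # invariant to overall intensity scaling
    expect_equal(fractional_contribution(mid * 37.5), fc)
    # moving mass from a lower to a higher isotopologue never decreases FC
    lo <- sample(n, 1)
    hi <- if (lo == n) n + 1L else sample((lo + 1L):(n + 1L), 1)
    moved <- mid
    delta <- mid[lo] / 2
    moved[lo] <- moved[lo] - delta; moved[hi] <- moved[hi] + delta
    expect_gte(fractional_contribution(moved), fc - 1e-12)
  }
})

test_that("normalize_tracer_enrichment divides and clips", {
  expect_equal(normalize_tracer_enrichment(0.25, 0.5), 0.5)
  expect_equal(normalize_tracer_enrichment(0.33, 1), 0.33)
  expect_warning(out <- normalize_tracer_enrichment(0.52, 0.5), "clipping")
  expect_equal(out, 1)
  expect_error(normalize_tracer_enrichment(0.2, 0), "enrichment")
})

test_that("panel-level correction and labeling index round-trip the truth", {
  mets <- data.frame(metabolite = c("pyr", "glc"),
                     formula = c("C3H4O3", "C6H12O6"))
  fc <- matrix(c(0.3, 0.1), 2, 1, dimnames = list(mets$metabolite, "all"))
  truth <- flux_truth(mets, fc, tracer_enrichment = 0.5, noise_sd = 0,
                      seed = 3)
  panel <- correct_panel(gen_mid_panel(truth, 2))
  idx <- labeling_index(panel)
  expect_equal(unname(idx["pyr", ]), rep(0.3, 2), tolerance = 1e-6)
  expect_equal(unname(idx["glc", ]), rep(0.1, 2), tolerance = 1e-6)
  # enrichment normalisation rescales to nutrient-derived fraction
  idx_n <- labeling_index(panel, normalize_enrichment = TRUE)
  expect_equal(unname(idx_n["pyr", ]), rep(0.6, 2), tolerance = 1e-6)
  # relative amounts are finite and positive for a non-empty panel
  amt <- relative_amounts(panel)
  expect_true(all(amt > 0))
})

test_that("missing isotopologue rows are zero-filled with a warning", {
  mets <- data.frame(metabolite = "pyr", formula = "C3H4O3")
  data <- data.frame(metabolite = "pyr", isotopologue = c(0, 3),
                     sample = "s1", intensity = c(50, 50))
  samples <- data.frame(sample = "s1", group = "all",
                        internal_standard = 1e5, cell_count = 1e6)
  panel <- mid_panel(mets, data, samples)
  expect_warning(idx <- labeling_index(panel), "missing isotopologue")
  expect_equal(unname(idx["pyr", "s1"]), 0.5)
  expect_error(mid_panel(mets, transform(data, intensity = c(-1, 1)), samples),
               ">= 0")
})
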