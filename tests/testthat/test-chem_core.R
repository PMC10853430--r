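test_that("exact neutral mass matches hand-summed monoisotopic values", {
  expect_equal(exact_neutral_mass(formula_frame(0, 0, 0, 0, 0)), 0)
  expect_equal(exact_neutral_mass(formula_frame(6, 12, 6)), 180.063388,
               tolerance = 1e-8)
  expect_equal(exact_neutral_mass(formula_frame(1, 4)), 16.031300,
               tolerance = 1e-7)
})

test_that("mass is additive over element-wise formula sums", {
  set.seed(1)
  for (i in 1:25) {
    f1 <- formula_frame(sample(1:30, 1), sample(1:50, 1), sample(0:15, 1),
                        sample(0:3, 1), sample(0:1, 1))
    f2 <- formula_frame(sample(1:30, 1), sample(1:50, 1), sample(0:15, 1),
                        sample(0:3, 1), sample(0:1, 1))
    expect_equal(exact_neutral_mass(f1 + f2),
                 exact_neutral_mass(f1) + exact_neutral_mass(f2),
                 tolerance = 1e-9)
  }
})

test_that("DBE follows the CHNOS valence model", {
  expect_equal(dbe(formula_frame(6, 6)), 4)        # benzene
  expect_equal(dbe(formula_frame(6, 12, 6)), 1)    # glucose
  expect_equal(dbe(formula_frame(2, 6, 0, 1)), 0.5)  # half-integer radical
  # saturated alkanes CnH2n+2 have DBE 0 for all n
  n <- 1:20
  expect_equal(dbe(formula_frame(n, 2 * n + 2)), rep(0, 20))
})

test_that("elemental ratios are H/C and O/C, undefined without carbon", {
  expect_equal(elemental_ratios(formula_frame(10, 15, 2, 1)),
               data.frame(h_c = 1.5, o_c = 0.2))
  expect_equal(elemental_ratios(formula_frame(1, 0, 0)),
               data.frame(h_c = 0, o_c = 0))
  r <- elemental_ratios(formula_frame(18, 34, 2))
  expect_equal(round(r$h_c, 4), 1.8889)
  expect_equal(round(r$o_c, 4), 0.1111)
  expect_error(elemental_ratios(formula_frame(0, 4)), "C = 0")
})

test_that("element groups partition formulas by N/S content", {
  f <- formula_frame(C = c(6, 5, 8, 6), H = c(12, 9, 11, 10),
                     O = c(6, 3, 2, 4), N = c(0, 1, 2, 0), S = c(0, 1, 0, 1))
  expect_equal(as.character(element_group(f)),
               c("CHO", "CHONS", "CHON", "CHOS"))
  # partition property: group counts sum to the set size
  set.seed(2)
  g <- random_valid_formulas(500)
  expect_false(anyNA(element_group(g)))
  expect_equal(sum(table(element_group(g))), 500)
})

test_that("[M-H]- ion/neutral conversion round-trips and validates input", {
  expect_equal(neutral_mass_from_mz(179.056112), 180.063388,
               tolerance = 1e-6)
  expect_equal(neutral_mass_from_mz(1.0072765), 2.014553, tolerance = 1e-6)
  expect_error(neutral_mass_from_mz(0), "positive")
  expect_error(neutral_mass_from_mz(200, mode = "[M+H]+"), "unsupported")
  m <- exact_neutral_mass(formula_frame(20, 24, 8, 1))
  expect_equal(neutral_mass_from_mz(mz_from_neutral_mass(m)), m,
               tolerance = 1e-9)
})

test_that("formula keys encode exact elemental identity", {
  f <- formula_frame(c(6, 6), c(12, 12), c(6, 6), c(0, 1))
  k <- formula_key(f)
  expect_equal(k[1], "C6H12O6N0S0")
  expect_false(k[1] == k[2])
})
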