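test_that("peak filtering applies the S/N cutoff and instrument window", {
  pk <- data.frame(mz = c(300, 300, 150, 1200), intensity = 1,
                   snr = c(5, 3.9, 10, 10))
  kept <- filter_peaks(pk)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$snr, 5)
  expect_equal(nrow(filter_peaks(pk[0, ])), 0)
})

test_that("the validity screen enforces ratio, heteroatom and DBE rules", {
  expect_false(formula_is_valid(formula_frame(10, 25, 2, 1)))  # H/C 2.5
  expect_false(formula_is_valid(formula_frame(5, 10, 7)))      # O/C 1.4
  expect_true(formula_is_valid(formula_frame(6, 12, 6)))
  expect_false(formula_is_valid(formula_frame(7, 11, 2)))      # DBE 2.5
  expect_false(formula_is_valid(formula_frame(10, 14, 2, 4)))  # N > 3
  expect_false(formula_is_valid(formula_frame(10, 14, 2, 0, 2)))  # S > 1
  expect_false(formula_is_valid(formula_frame(0, 2, 0)))  # no CH backbone
})

test_that("candidate enumeration finds the true formula and nothing below CH2", {
  cand <- enumerate_candidates(180.063388)
  expect_true("C6H12O6N0S0" %in% formula_key(cand))
  expect_lt(min(abs(cand$error_ppm)), 0.01)
  expect_true(all(formula_is_valid(cand)))
  expect_true(all(diff(abs(cand$error_ppm)) >= 0))  # sorted by |error|
  expect_equal(nrow(enumerate_candidates(11.0)), 0)
})

test_that("enumeration agrees with the nested-loop oracle", {
  set.seed(4)
  masses <- runif(30, 200, 1000)
  for (M in masses) {
    expect_identical(candidate_keys(enumerate_candidates(M)),
                     candidate_keys(oracle_candidates(M)))
  }
})

test_that("widening the tolerance never shrinks the candidate set", {
  set.seed(5)
  for (M in runif(10, 200, 1000)) {
    k1 <- candidate_keys(enumerate_candidates(M, assignment_params(tol_ppm = 0.5)))
    k2 <- candidate_keys(enumerate_candidates(M, assignment_params(tol_ppm = 1)))
    k3 <- candidate_keys(enumerate_candidates(M, assignment_params(tol_ppm = 2)))
    expect_true(all(k1 %in% k2))
    expect_true(all(k2 %in% k3))
  }
})

test_that("formula selection minimises |error| with deterministic tie-breaks", {
  expect_null(select_formula(enumerate_candidates(11.0)))
  cand <- data.frame(C = c(10, 12), H = c(16, 20), O = c(4, 2),
                     N = c(0, 1), S = c(0, 0),
                     error_ppm = c(0.2, -0.8))
  expect_equal(select_formula(cand)$C, 10)
  tie <- data.frame(C = c(9, 10), H = c(14, 16), O = c(3, 4),
                    N = c(2, 0), S = c(1, 0),
                    error_ppm = c(0.5, -0.5))
  expect_equal(select_formula(tie)$N + select_formula(tie)$S, 0)
})

test_that("assignment composes the stages and reports unassigned peaks", {
  p <- assignment_params(mz_window = c(150, 1000))
  a <- assign_peaklist(peaks_for(formula_frame(6, 12, 6)), p, quiet = TRUE)
  expect_equal(nrow(a), 1)
  expect_equal(a$C, 6); expect_equal(a$H, 12); expect_equal(a$O, 6)
  expect_lt(abs(a$error_ppm), 0.01)

  low <- data.frame(mz = c(300, 400), intensity = 1, snr = c(1, 2))
  expect_equal(nrow(assign_peaklist(low, quiet = TRUE)), 0)

  # determinism: identical input, identical output
  set.seed(6)
  pk <- peaks_for(random_valid_formulas(50))
  expect_identical(assign_peaklist(pk, quiet = TRUE),
                   assign_peaklist(pk, quiet = TRUE))
})

test_that("exact-mass round trip always contains the true formula", {
  set.seed(7)
  f <- random_valid_formulas(200)
  m <- exact_neutral_mass(f)
  keep <- m >= 201.1 & m <= 1000
  f <- f[keep, ]; m <- m[keep]
  a <- assign_peaklist(peaks_for(f), quiet = TRUE)
  expect_equal(nrow(a), nrow(f))
  # containment: every true formula is among the candidates (n_candidates
  # counts them; the true formula has error 0 so it is always selected or
  # tied at zero error)
  expect_true(all(a$n_candidates >= 1))
  expect_true(all(abs(a$error_ppm) < 1e-6))
})

test_that("perturbed peaks recover the truth within the unambiguous regime", {
  set.seed(8)
  cfg <- small_scenario()
  f <- rbind(
    sample_formula_in_class("lignin_cram", 60, window = c(210, 490)),
    sample_formula_in_class("tannins", 40, n_atoms = rep(0:1, 20),
                            window = c(210, 490)))
  mz <- mz_from_neutral_mass(exact_neutral_mass(f))
  mzp <- mz * (1 + runif(nrow(f), -0.3, 0.3) * 1e-6)
  a <- assign_peaklist(data.frame(mz = mzp, intensity = 1, snr = 10),
                       quiet = TRUE)
  exact <- a$C == f$C & a$H == f$H & a$O == f$O & a$N == f$N & a$S == f$S
  expect_gte(sum(exact, na.rm = TRUE), 99)
})
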