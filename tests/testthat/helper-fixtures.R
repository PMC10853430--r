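# Small fixtures built in code.

# Interior-point formulas, one per van Krevelen class, hand-placed well
# inside each box.
interior_formulas <- function() {
  formula_frame(
    C = c(18, 10, 10, 10, 20, 20, 10),
    H = c(34, 18, 10, 18,  20,  8, 10),
    O = c( 2,  4,  3,  8,   1,  2,  8))
  # lipids, aliphatic_proteins, lignin_cram, carbohydrates,
  # unsaturated_hc, condensed_aromatics, tannins
}

# Peak list for a formula table: exact [M-H]- m/z, fixed intensity/snr.
peaks_for <- function(f, snr = 10) {
  data.frame(mz = mz_from_neutral_mass(exact_neutral_mass(f)),
             intensity = 1e6, snr = snr)
}

# Random valid formulas drawn uniformly from the enumerable space.
random_valid_formulas <- function(n, params = assignment_params()) {
  sp <- domforge:::formula_space(params)
  sp[sample.int(nrow(sp), n, replace = TRUE), c("C", "H", "O", "N", "S")]
}

# A tiny fast scenario for smoke tests.
small_scenario <- function(seed = 1L, n = 400L) {
  scenario_config(formulas_per_sample = n, seed = seed)
}
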