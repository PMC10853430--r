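# Exact-mass chemistry primitives for CHNOS formulas.
#
# Monoisotopic masses: IUPAC/CODATA values, >= 7 decimal places.  12C is
# exactly 12 by definition of the unified atomic mass unit.

.MASS <- list(
  C = 12.0,
  H = 1.0078250319,
  O = 15.9949146221,
  N = 14.0030740052,
  S = 31.9720707300,
  proton   = 1.0072764666,
  electron = 0.0005485799
)

#' Monoisotopic mass constants
#'
#' Monoisotopic masses (Da) of the five elements considered in DOM formula
#' assignment (12C, 1H, 16O, 14N, 32S) plus the proton and electron masses.
#' 12C is exactly 12 Da by definition; the remaining values are IUPAC/CODATA
#' monoisotopic masses at >= 7 decimal places.
#'
#' @return Named list of masses in Da.
#' @export
#' @examples
#' mass_constants()$H
mass_constants <- function() .MASS

#' Construct a table of molecular formulas
#'
#' A formula set is represented throughout the package as a data frame with
#' integer columns `C`, `H`, `O`, `N`, `S`.  A single formula is a one-row
#' table.  Two formulas are identical iff all five counts are equal; this
#' elemental identity is the unit of all chemodiversity accounting
#' (FT-ICR-MS cannot distinguish structural isomers).
#'
#' @param C,H,O,N,S Non-negative integer vectors (recycled to a common
#'   length).
#' @return A `data.frame` with columns `C`, `H`, `O`, `N`, `S`.
#' @export
#' @examples
#' formula_frame(6, 12, 6)          # glucose
#' formula_frame(C = c(6, 18), H = c(6, 34), O = c(0, 2))
formula_frame <- function(C, H, O = 0L, N = 0L, S = 0L) {
  len <- lengths(list(C, H, O, N, S))
  n <- if (any(len == 0L)) 0L else max(len)
  f <- data.frame(C = rep_len(as.integer(C), n), H = rep_len(as.integer(H), n),
                  O = rep_len(as.integer(O), n), N = rep_len(as.integer(N), n),
                  S = rep_len(as.integer(S), n))
  if (any(is.na(f)))
    stop("formula counts must be non-missing integers")
  if (any(f < 0L))
    stop("formula counts must be >= 0")
  f
}

.check_formula <- function(f) {
  need <- c("C", "H", "O", "N", "S")
  if (!is.data.frame(f) || !all(need %in% names(f)))
    stop("expected a formula table with columns C, H, O, N, S")
  f
}

#' Canonical formula identity key
#'
#' A string key encoding the exact (C, H, O, N, S) tuple; used for set
#' algebra (union, intersection, difference) on formula populations.
#'
#' @param f Formula table (see [formula_frame()]).
#' @return Character vector of keys, one per row.
#' @export
formula_key <- function(f) {
  f <- .check_formula(f)
  sprintf("C%dH%dO%dN%dS%d", f$C, f$H, f$O, f$N, f$S)
}

#' Exact neutral monoisotopic mass
#'
#' Sum over elements of count times monoisotopic mass.  Deterministic and
#' additive: `exact_neutral_mass(f1 + f2)` equals the sum of the parts.
#'
#' @param f Formula table.
#' @return Numeric vector of neutral masses in Da.
#' @export
#' @examples
#' exact_neutral_mass(formula_frame(6, 12, 6))  # 180.063388
exact_neutral_mass <- function(f) {
  f <- .check_formula(f)
  f$C * .MASS$C + f$H * .MASS$H + f$O * .MASS$O + f$N * .MASS$N + f$S * .MASS$S
}

#' Double bond equivalents
#'
#' Rings plus pi bonds of a neutral CHNOS formula under the standard valence
#' model (C tetravalent, N trivalent, O and S divalent, H monovalent):
#' DBE = 1 + C - H/2 + N/2.  The value may be half-integer; half-integer DBE
#' is used downstream to reject radical (electron-parity-violating) neutral
#' compositions.
#'
#' @param f Formula table.
#' @return Numeric vector of DBE values (possibly half-integer).
#' @export
#' @examples
#' dbe(formula_frame(6, 6))       # benzene: 4
#' dbe(formula_frame(6, 12, 6))   # glucose: 1
dbe <- function(f) {
  f <- .check_formula(f)
  1 + f$C - f$H / 2 + f$N / 2
}

#' H/C and O/C elemental ratios
#'
#' The two coordinates of the van Krevelen diagram.
#'
#' @param f Formula table; every row must have `C >= 1`.
#' @return A `data.frame` with columns `h_c` and `o_c`.
#' @export
#' @examples
#' elemental_ratios(formula_frame(18, 34, 2))  # oleic acid: 1.889, 0.111
elemental_ratios <- function(f) {
  f <- .check_formula(f)
  if (any(f$C < 1L))
    stop("elemental ratios undefined for formulas with C = 0")
  data.frame(h_c = f$H / f$C, o_c = f$O / f$C)
}

#' Element-group membership (CHO / CHON / CHOS / CHONS)
#'
#' Partitions formulas by heteroatom content: CHO if no N and no S, CHON if
#' N only, CHOS if S only, CHONS if both.  The assignment is total and
#' unique for any CH-containing formula.
#'
#' @param f Formula table.
#' @return Factor with levels `CHO`, `CHON`, `CHOS`, `CHONS`.
#' @export
#' @examples
#' element_group(formula_frame(c(6, 5), c(12, 9), c(6, 3), c(0, 1), c(0, 1)))
element_group <- function(f) {
  f <- .check_formula(f)
  g <- ifelse(f$N > 0L,
              ifelse(f$S > 0L, "CHONS", "CHON"),
              ifelse(f$S > 0L, "CHOS", "CHO"))
  factor(g, levels = c("CHO", "CHON", "CHOS", "CHONS"))
}

#' Neutral mass from a measured m/z
#'
#' Converts a singly deprotonated negative-mode ion (\[M-H\]-) m/z to the
#' neutral mass: M = m/z + proton mass.  This is the only ion convention
#' supported; DOM electrospray studies in negative mode are dominated by
#' \[M-H\]- ions.
#'
#' @param mz Positive numeric vector of measured m/z values.
#' @param mode Ionization mode; only `"[M-H]-"` is supported.
#' @return Neutral masses in Da.
#' @export
#' @examples
#' neutral_mass_from_mz(179.056112)  # glucose [M-H]- : 180.063388
neutral_mass_from_mz <- function(mz, mode = "[M-H]-") {
  if (!identical(mode, "[M-H]-"))
    stop("unsupported ionization mode: ", mode,
         " (only \"[M-H]-\" is supported)")
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("m/z values must be positive")
  mz + .MASS$proton
}

#' m/z of the \[M-H\]- ion of a neutral mass
#'
#' Inverse of [neutral_mass_from_mz()]; used by the synthetic peak
#' generator.
#'
#' @param mass Neutral monoisotopic masses in Da.
#' @param mode Ionization mode; only `"[M-H]-"` is supported.
#' @return m/z values in Da.
#' @export
mz_from_neutral_mass <- function(mass, mode = "[M-H]-") {
  if (!identical(mode, "[M-H]-"))
    stop("unsupported ionization mode: ", mode,
         " (only \"[M-H]-\" is supported)")
  mass - .MASS$proton
}

# Rounding used for reported percentages: half away from zero (so 0.125 at
# 2 d.p. is 0.13), unlike base round()'s round-half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
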