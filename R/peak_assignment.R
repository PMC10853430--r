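# CHNOS molecular formula assignment by exhaustive enumeration within a
# ppm tolerance.

#' Assignment parameters
#'
#' Filters and element bounds for formula assignment.  Defaults follow
#' standard negative-mode FT-ICR-MS DOM practice: peaks with S/N >= 4
#' inside the m/z 200-1,000 instrument window; elemental combinations
#' C/H/O unbounded in practice (generous caps), N 0-3, S 0-1; elemental
#' ratio screens H/C < 2.4 and O/C < 1.2; integer, non-negative DBE and
#' the valence cap H <= 2C + N + 2.
#'
#' @param tol_ppm Mass tolerance in parts-per-million (> 0).  15 T
#'   instruments routinely achieve sub-ppm accuracy; default 1.
#' @param snr_min Minimum signal-to-noise ratio; default 4.
#' @param mz_window Instrument window (length-2, Da); default c(200, 1000).
#' @param max_c,max_h,max_o Upper element bounds; the defaults (60, 122,
#'   40) cover any valid formula below 1,000 Da with margin.
#' @param max_n,max_s Heteroatom caps; defaults 3 and 1.
#' @param hc_max,oc_max Elemental ratio caps (exclusive); defaults 2.4 and
#'   1.2.
#' @return A list of class `assignment_params`.
#' @export
assignment_params <- function(tol_ppm = 1.0, snr_min = 4,
                              mz_window = c(200, 1000),
                              max_c = 60L, max_h = 122L, max_o = 40L,
                              max_n = 3L, max_s = 1L,
                              hc_max = 2.4, oc_max = 1.2) {
  stopifnot(tol_ppm > 0, snr_min >= 0, length(mz_window) == 2L,
            mz_window[1] < mz_window[2],
            max_c >= 1, max_h >= 1, max_o >= 0, max_n >= 0, max_s >= 0,
            hc_max > 0, oc_max > 0)
  structure(list(tol_ppm = tol_ppm, snr_min = snr_min,
                 mz_window = as.numeric(mz_window),
                 max_c = as.integer(max_c), max_h = as.integer(max_h),
                 max_o = as.integer(max_o), max_n = as.integer(max_n),
                 max_s = as.integer(max_s),
                 hc_max = hc_max, oc_max = oc_max),
            class = "assignment_params")
}

.check_peaks <- function(peaks) {
  need <- c("mz", "intensity", "snr")
  if (!is.data.frame(peaks) || !all(need %in% names(peaks)))
    stop("peak table needs columns: ", paste(need, collapse = ", "))
  peaks
}

#' Filter peaks by signal-to-noise and instrument window
#'
#' Retains exactly the peaks with `snr >= snr_min` and m/z inside the
#' configured window (inclusive); row order is preserved.
#'
#' @param peaks Data frame with columns `mz`, `intensity`, `snr`.
#' @param params See [assignment_params()].
#' @return The retained rows of `peaks`.
#' @export
filter_peaks <- function(peaks, params = assignment_params()) {
  peaks <- .check_peaks(peaks)
  keep <- peaks$snr >= params$snr_min &
    peaks$mz >= params$mz_window[1] & peaks$mz <= params$mz_window[2]
  peaks[keep, , drop = FALSE]
}

#' Chemical validity screen for a candidate formula
#'
#' TRUE iff H/C < `hc_max`, O/C < `oc_max`, N <= `max_n`, S <= `max_s`,
#' DBE is a non-negative integer (electron-parity screen for even-electron
#' \[M-H\]- neutrals) and H <= 2C + N + 2 (valence feasibility).  Requires
#' C >= 1 and H >= 1 (CH backbone).
#'
#' @param f Formula table.
#' @param params See [assignment_params()].
#' @return Logical vector, one per row.
#' @export
#' @examples
#' formula_is_valid(formula_frame(10, 25, 2))  # H/C = 2.5 -> FALSE
#' formula_is_valid(formula_frame(6, 12, 6))   # glucose  -> TRUE
formula_is_valid <- function(f, params = assignment_params()) {
  f <- .check_formula(f)
  d <- dbe(f)
  f$C >= 1L & f$H >= 1L &
    f$H / f$C < params$hc_max &
    f$O / f$C < params$oc_max &
    f$N <= params$max_n & f$S <= params$max_s &
    d >= 0 & d == floor(d) &
    f$H <= 2L * f$C + f$N + 2L
}

# Memoised table of every valid formula within the element bounds, sorted
# by exact neutral mass.  Built once per parameter set; candidate lookup
# is then a binary search.  Constraints folded into construction:
#   * H has the parity of N (integer DBE) and H <= 2C + N + 2 (DBE >= 0,
#     identical to the valence cap);
#   * H/C < hc_max, O/C < oc_max.
.space_cache <- new.env(parent = emptyenv())

formula_space <- function(params = assignment_params()) {
  key <- paste(params$max_c, params$max_h, params$max_o, params$max_n,
               params$max_s, params$hc_max, params$oc_max, sep = "|")
  hit <- .space_cache[[key]]
  if (!is.null(hit)) return(hit)

  g <- expand.grid(C = seq_len(params$max_c), O = 0:params$max_o,
                   N = 0:params$max_n, S = 0:params$max_s,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$O / g$C < params$oc_max, , drop = FALSE]
  h_lo <- ifelse(g$N %% 2L == 1L, 1L, 2L)
  h_hi <- pmin(params$max_h, 2L * g$C + g$N + 2L,
               ceiling(params$hc_max * g$C) - 1L)
  n_h <- pmax(0L, (h_hi - h_lo) %/% 2L + 1L)
  keep <- n_h > 0L
  g <- g[keep, , drop = FALSE]
  h_lo <- h_lo[keep]; n_h <- n_h[keep]
  idx <- rep.int(seq_len(nrow(g)), n_h)
  sp <- data.frame(C = g$C[idx],
                   H = h_lo[idx] + 2L * (sequence(n_h) - 1L),
                   O = g$O[idx], N = g$N[idx], S = g$S[idx])
  sp$mass <- exact_neutral_mass(sp)
  sp <- sp[order(sp$mass), , drop = FALSE]
  rownames(sp) <- NULL
  .space_cache[[key]] <- sp
  sp
}

# Signed mass error in ppm of a theoretical mass against an observed
# neutral mass: (observed - theoretical) / observed * 1e6.
.error_ppm <- function(observed, theoretical) {
  (observed - theoretical) / observed * 1e6
}

# Deterministic candidate ordering: |error| ascending, then fewer N+S
# atoms, then lower DBE, then lexicographic element counts.
.candidate_order <- function(cand) {
  order(abs(cand$error_ppm), cand$N + cand$S, dbe(cand),
        cand$C, cand$H, cand$O, cand$N, cand$S)
}

#' Enumerate all candidate formulas for a neutral mass
#'
#' Every formula passing [formula_is_valid()] whose exact neutral mass
#' lies within `tol_ppm` of `neutral_mass` (|mass - M| <= tol * 1e-6 * M),
#' and no others; sorted by absolute mass error ascending.
#'
#' @param neutral_mass Positive neutral mass in Da (scalar).
#' @param params See [assignment_params()].
#' @return A `data.frame` with columns `C`, `H`, `O`, `N`, `S`,
#'   `error_ppm`; zero rows if no formula matches.
#' @export
#' @examples
#' enumerate_candidates(180.063388)  # contains C6H12O6 at ~0 ppm
enumerate_candidates <- function(neutral_mass, params = assignment_params()) {
  stopifnot(length(neutral_mass) == 1L, is.finite(neutral_mass),
            neutral_mass > 0)
  sp <- formula_space(params)
  tol <- params$tol_ppm * 1e-6 * neutral_mass
  lo <- findInterval(neutral_mass - tol - 1e-9, sp$mass)
  hi <- findInterval(neutral_mass + tol + 1e-9, sp$mass)
  cand <- if (hi > lo) sp[(lo + 1L):hi, , drop = FALSE] else sp[0L, , drop = FALSE]
  cand <- cand[abs(cand$mass - neutral_mass) <= tol, , drop = FALSE]
  cand$error_ppm <- .error_ppm(neutral_mass, cand$mass)
  cand$mass <- NULL
  cand <- cand[.candidate_order(cand), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Select the best candidate formula
#'
#' The candidate with the smallest absolute mass error; ties broken
#' deterministically by fewer N+S atoms, then lower DBE, then
#' lexicographic element counts.
#'
#' @param candidates Candidate table from [enumerate_candidates()].
#' @return A one-row formula table (with `error_ppm`), or `NULL` if the
#'   candidate list is empty.
#' @export
select_formula <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  best <- candidates[.candidate_order(candidates)[1L], , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Assign molecular formulas to a peak list
#'
#' The composition filter -> ion-to-neutral conversion -> candidate
#' enumeration -> selection, applied per peak.  Output rows correspond
#' one-to-one to the peaks surviving [filter_peaks()]; unassigned peaks
#' are retained with NA element counts so assignment rates are
#' reportable.
#'
#' @param peaks Data frame with columns `mz`, `intensity`, `snr` (and
#'   optionally `sample_id`, carried through).
#' @param params See [assignment_params()].
#' @param mode Ionization mode; only `"[M-H]-"` is supported.
#' @param quiet Suppress the assigned/unassigned count message.
#' @return A `data.frame` of class `assigned_peaks` with columns `mz`,
#'   `intensity`, `snr`, `C`, `H`, `O`, `N`, `S`, `error_ppm`,
#'   `n_candidates`.
#' @export
assign_peaklist <- function(peaks, params = assignment_params(),
                            mode = "[M-H]-", quiet = FALSE) {
  peaks <- filter_peaks(peaks, params)
  n <- nrow(peaks)
  out <- peaks
  out$C <- out$H <- out$O <- out$N <- out$S <- rep(NA_integer_, n)
  out$error_ppm <- rep(NA_real_, n)
  out$n_candidates <- rep(0L, n)

  if (n > 0L) {
    sp <- formula_space(params)
    M <- neutral_mass_from_mz(peaks$mz, mode)
    tol <- params$tol_ppm * 1e-6 * M
    lo <- findInterval(M - tol - 1e-9, sp$mass)
    hi <- findInterval(M + tol + 1e-9, sp$mass)
    nwin <- hi - lo
    has <- which(nwin > 0L)
    if (length(has)) {
      row <- sequence(nwin[has], from = lo[has] + 1L)
      pk <- rep.int(has, nwin[has])
      ok <- abs(sp$mass[row] - M[pk]) <= tol[pk]
      row <- row[ok]; pk <- pk[ok]
      if (length(row)) {
        cand <- sp[row, , drop = FALSE]
        cand$error_ppm <- .error_ppm(M[pk], cand$mass)
        ord <- order(pk, abs(cand$error_ppm), cand$N + cand$S, dbe(cand),
                     cand$C, cand$H, cand$O, cand$N, cand$S)
        pk <- pk[ord]; cand <- cand[ord, , drop = FALSE]
        ncand <- tabulate(pk, nbins = n)
        first <- !duplicated(pk)
        sel <- pk[first]
        out$C[sel] <- cand$C[first]; out$H[sel] <- cand$H[first]
        out$O[sel] <- cand$O[first]; out$N[sel] <- cand$N[first]
        out$S[sel] <- cand$S[first]
        out$error_ppm[sel] <- cand$error_ppm[first]
        out$n_candidates <- ncand
      }
    }
  }
  if (!quiet)
    message("assigned ", sum(!is.na(out$C)), " of ", n, " peaks (",
            n - sum(!is.na(out$C)), " unassigned)")
  rownames(out) <- NULL
  class(out) <- c("assigned_peaks", "data.frame")
  out
}

#' @export
print.assigned_peaks <- function(x, ...) {
  n <- nrow(x)
  cat("Assigned peak table: ", n, " peaks, ",
      sum(!is.na(x$C)), " with a formula\n", sep = "")
  NextMethod()
}
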