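# Independent oracles used to cross-check the implementation.

# Exhaustive candidate enumeration by solving the integer-H window inside
# nested loops over (S, N, O), vectorised over C.  A deliberately
# different strategy from the package's pre-built sorted formula table.
oracle_candidates <- function(M, params = assignment_params()) {
  ms <- mass_constants()
  tol <- params$tol_ppm * 1e-6 * M
  acc <- vector("list", 0L)
  for (S in 0:params$max_s) for (N in 0:params$max_n) for (O in 0:params$max_o) {
    C <- seq_len(params$max_c)
    C <- C[O / C < params$oc_max]
    if (!length(C)) next
    base <- C * ms$C + O * ms$O + N * ms$N + S * ms$S
    hlo <- ceiling((M - tol - base) / ms$H)
    hhi <- floor((M + tol - base) / ms$H)
    keep <- which(hhi >= hlo & hhi >= 1L)
    for (i in keep) {
      for (H in max(1L, hlo[i]):hhi[i]) {
        if (H > params$max_h) next
        if (H %% 2L != N %% 2L) next              # integer DBE
        if (H > 2L * C[i] + N + 2L) next          # DBE >= 0 / valence
        if (H / C[i] >= params$hc_max) next
        mass <- C[i] * ms$C + H * ms$H + O * ms$O + N * ms$N + S * ms$S
        if (abs(mass - M) <= tol)
          acc[[length(acc) + 1L]] <- c(C[i], H, O, N, S)
      }
    }
  }
  if (!length(acc))
    return(formula_frame(integer(0), integer(0)))
  m <- do.call(rbind, acc)
  formula_frame(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
}

# Spearman rho and two-sided permutation p computed by brute force:
# ranks via order statistics and the full permutation set generated
# through repeated sampling-free recursion on index vectors.
oracle_spearman <- function(x, y) {
  n <- length(x)
  rk <- function(v) {
    # average ranks without rank(): mean position among sorted values
    sapply(v, function(vi) mean(which(sort(v) == vi)))
  }
  rx <- rk(x); ry <- rk(y)
  pears <- function(a, b) {
    ca <- a - mean(a); cb <- b - mean(b)
    sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
  }
  rho <- pears(rx, ry)
  all_perm <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_perm(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  rho_null <- vapply(all_perm(seq_len(n)),
                     function(p) pears(rx, ry[p]), numeric(1))
  list(rho = rho, p_value = mean(abs(rho_null) >= abs(rho) - 1e-12))
}

# Sorted key strings for comparing candidate sets.
candidate_keys <- function(f) sort(formula_key(f))
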