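# Seeded synthetic study generator: DOM formula populations and peak
# lists, soil-chemistry trends, and genus tables with planted monotone
# couplings.  Ground truth is emitted alongside every dataset so each
# pipeline stage can be scored.

#' Default per-condition compound-class mixture (percent)
#'
#' Class mixtures for the four continuous-cropping conditions,
#' interpolating linearly between the study-start and study-end
#' endpoints of the emulated field trends: tannins 18.13 -> 13.95 %,
#' aliphatic/proteins 2.73 -> 8.85 %, lignin/CRAM 56.83 -> 53.20 %.
#' The remaining four classes share the residual, with condensed
#' aromatics shrinking and the high-H/C classes (lipids, carbohydrates,
#' unsaturated hydrocarbons) growing toward the late conditions.
#' Each row sums to 100.
#'
#' @return 4 x 7 matrix (conditions x classes), percentages.
#' @export
default_class_mixture <- function() {
  m <- rbind(
    CC1Y = c(lipids = 5.00, aliphatic_proteins = 2.73, lignin_cram = 56.83,
             carbohydrates = 3.00, unsaturated_hc = 2.31,
             condensed_aromatics = 12.00, tannins = 18.13),
    CC3Y = c(5.40, 4.77, 55.62, 3.50, 2.57, 11.40, 16.74),
    CC5Y = c(5.80, 6.81, 54.41, 4.00, 2.84, 10.80, 15.34),
    CC7Y = c(6.32, 8.85, 53.20, 4.50, 2.98, 10.20, 13.95))
  colnames(m) <- .VK_CLASSES
  m
}

#' Default per-condition element-group mixture (percent)
#'
#' CHO / CHON / CHOS / CHONS shares per condition, interpolating the
#' emulated endpoints: CHON 52.24 -> 46.10 %, CHOS 5.81 -> 11.10 %,
#' CHONS 5.51 -> 8.14 %, CHO taking the residual (34-37 %).  Rows sum to
#' 100.
#'
#' @return 4 x 4 matrix (conditions x groups), percentages.
#' @export
default_group_mixture <- function() {
  m <- rbind(
    CC1Y = c(CHO = 36.44, CHON = 52.24, CHOS = 5.81, CHONS = 5.51),
    CC3Y = c(35.85, 50.19, 7.57, 6.39),
    CC5Y = c(35.25, 48.15, 9.34, 7.26),
    CC7Y = c(34.66, 46.10, 11.10, 8.14))
  colnames(m) <- c("CHO", "CHON", "CHOS", "CHONS")
  m
}

#' Default soil-chemistry trends
#'
#' Per-variable condition means plus Gaussian noise s.d., shaped like the
#' emulated field study: pH flat (~7), total carbon (TC, g/kg), total
#' nitrogen (TN, g/kg) and organic matter (OM, g/kg) decreasing, C/N
#' increasing in the later conditions, and dissolved organic carbon
#' (DOC, mg/kg) V-shaped (early decrease, late recovery).
#'
#' @return Named list; each element is `list(means = <4 values>, sd = )`.
#' @export
default_chemistry_trends <- function() {
  list(
    pH  = list(means = c(7.05, 7.00, 6.98, 6.95), sd = 0.08),
    TC  = list(means = c(12.0, 10.2, 9.8, 9.5),   sd = 0.35),
    TN  = list(means = c(1.30, 1.10, 0.92, 0.78), sd = 0.04),
    CN  = list(means = c(9.2, 9.3, 10.7, 12.2),   sd = 0.30),
    OM  = list(means = c(22.0, 19.5, 17.2, 15.0), sd = 0.70),
    DOC = list(means = c(85, 70, 62, 75),          sd = 3.0))
}

#' Default planted genus couplings
#'
#' Genera whose abundances are tied to a designated feature through a
#' Gaussian copula at a configured true Spearman correlation: a
#' methanotroph-like genus tracking aliphatic/proteins, a
#' sulfur-oxidiser-like genus tracking CHOS, a nitrate-reducer-like
#' genus tracking TN, and one genus anti-tracking tannins.
#'
#' @return Data frame with columns `genus`, `feature`, `rho`.
#' @export
default_couplings <- function() {
  data.frame(
    genus   = c("Methylobacter", "Thiobacillus", "wb1_P19", "Aquabacterium"),
    feature = c("aliphatic_proteins", "CHOS", "TN", "tannins"),
    rho     = c(0.95, 0.95, 0.90, -0.90),
    stringsAsFactors = FALSE)
}

#' Synthetic-study scenario configuration
#'
#' The generator's defaults are the emulated study conditions: 4
#' continuous-cropping durations x 3 biological replicates, 5,000
#' formulas per sample drawn from the per-condition class and group
#' mixtures, \[M-H\]- peaks in the m/z 200-1,000 instrument window with
#' Gaussian mass error (s.d. 0.3 ppm, sub-ppm as on a 15 T instrument),
#' 5 % unassignable noise peaks, 5 % of signal peaks below the S/N = 4
#' cutoff, the default chemistry trends and planted genus couplings.
#' The seed fully determines all outputs.
#'
#' @param conditions Condition labels, in temporal order.
#' @param replicates Replicates per condition.
#' @param formulas_per_sample Unique formulas drawn per sample.
#' @param class_mixture Conditions x 7-classes percentage matrix; rows
#'   must sum to 100 (to 1e-6).
#' @param group_mixture Conditions x 4-groups percentage matrix; rows
#'   must sum to 100.
#' @param n_probs Probabilities of N = 1, 2, 3 within N-containing
#'   groups.
#' @param mz_window Instrument m/z window.
#' @param mass_error_sd_ppm Gaussian m/z perturbation s.d. in ppm.
#' @param noise_fraction Unassignable noise peaks as a fraction of the
#'   signal-peak count.
#' @param low_snr_fraction Fraction of signal peaks given S/N below 4.
#' @param chemistry See [default_chemistry_trends()].
#' @param couplings See [default_couplings()].
#' @param n_noise_genera Uncoupled (independent) genera in the panel, in
#'   addition to one abundant uncoupled core genus.
#' @param n_only_first,n_only_last Uncoupled genera present (non-zero)
#'   only in the first / only in the last condition, giving the genus
#'   Venn partition between end conditions a non-trivial structure.
#' @param seed Integer seed; same seed, same study.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(conditions = c("CC1Y", "CC3Y", "CC5Y", "CC7Y"),
                            replicates = 3L,
                            formulas_per_sample = 5000L,
                            class_mixture = default_class_mixture(),
                            group_mixture = default_group_mixture(),
                            n_probs = c(0.5, 0.3, 0.2),
                            mz_window = c(200, 1000),
                            mass_error_sd_ppm = 0.3,
                            noise_fraction = 0.05,
                            low_snr_fraction = 0.05,
                            chemistry = default_chemistry_trends(),
                            couplings = default_couplings(),
                            n_noise_genera = 8L,
                            n_only_first = 2L,
                            n_only_last = 3L,
                            seed = 1L) {
  nc <- length(conditions)
  class_mixture <- as.matrix(class_mixture)
  group_mixture <- as.matrix(group_mixture)
  stopifnot(nrow(class_mixture) == nc, nrow(group_mixture) == nc,
            ncol(class_mixture) == 7L, ncol(group_mixture) == 4L,
            replicates >= 1L, formulas_per_sample >= 1L,
            length(n_probs) == 3L, all(n_probs > 0),
            mass_error_sd_ppm >= 0, noise_fraction >= 0,
            low_snr_fraction >= 0, low_snr_fraction <= 1)
  if (any(abs(rowSums(class_mixture) - 100) > 1e-6))
    stop("class mixture rows must sum to 100")
  if (any(abs(rowSums(group_mixture) - 100) > 1e-6))
    stop("group mixture rows must sum to 100")
  vars <- vapply(chemistry, function(v) length(v$means) == nc, logical(1))
  if (!all(vars)) stop("each chemistry variable needs one mean per condition")
  structure(list(conditions = conditions, replicates = as.integer(replicates),
                 formulas_per_sample = as.integer(formulas_per_sample),
                 class_mixture = class_mixture, group_mixture = group_mixture,
                 n_probs = n_probs / sum(n_probs),
                 mz_window = as.numeric(mz_window),
                 mass_error_sd_ppm = mass_error_sd_ppm,
                 noise_fraction = noise_fraction,
                 low_snr_fraction = low_snr_fraction,
                 chemistry = chemistry, couplings = couplings,
                 n_noise_genera = as.integer(n_noise_genera),
                 n_only_first = as.integer(n_only_first),
                 n_only_last = as.integer(n_only_last),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Rejection-sample formulas inside a van Krevelen class box
#'
#' Draws integer CHNOS compositions whose exact mass lies in `window`,
#' that pass [formula_is_valid()], whose (O/C, H/C) point lies inside the
#' class box shrunk by `margin` on every side (avoiding edge ambiguity),
#' and that [classify_formula()] maps back to `cls` under the given
#' precedence.  N and S counts are fixed per draw via `n_atoms` /
#' `s_atoms` (recycled), so group membership is exact by construction.
#'
#' @param cls A class name from [vk_classes()] (not `"unclassified"`).
#' @param n Number of formulas to draw.
#' @param n_atoms,s_atoms Heteroatom counts per draw (recycled).
#' @param window Neutral-mass window in Da.
#' @param margin Box shrink margin on O/C and H/C; default 0.01.
#' @param table Boundary table; see [vk_classes()].
#' @param params Validity screen parameters.
#' @param max_tries Rejection rounds before an infeasible-configuration
#'   error.
#' @return Formula table with `n` rows (duplicates possible; callers
#'   wanting unique sets should deduplicate and redraw).
#' @export
sample_formula_in_class <- function(cls, n = 1L, n_atoms = 0L, s_atoms = 0L,
                                    window = c(200, 1000), margin = 0.01,
                                    table = vk_classes(),
                                    params = assignment_params(),
                                    max_tries = 200L) {
  row <- table[table$class == cls, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown compound class: ", cls)
  oc_lo <- row$o_c_low + margin; oc_hi <- row$o_c_high - margin
  hc_lo <- row$h_c_low + margin; hc_hi <- row$h_c_high - margin
  if (oc_lo >= oc_hi || hc_lo >= hc_hi)
    stop("margin leaves an empty box for class ", cls)
  nat <- rep_len(as.integer(n_atoms), n)
  sat <- rep_len(as.integer(s_atoms), n)
  C <- H <- O <- integer(n)
  need <- seq_len(n)
  for (try in seq_len(max_tries)) {
    k <- length(need)
    oc <- stats::runif(k, oc_lo, oc_hi)
    hc <- stats::runif(k, hc_lo, hc_hi)
    unit <- .MASS$C + hc * .MASS$H + oc * .MASS$O
    base <- nat[need] * .MASS$N + sat[need] * .MASS$S
    cmin <- pmax(1, ceiling((window[1] - base) / unit))
    cmax <- pmin(params$max_c, pmax(0, floor((window[2] - base) / unit)))
    feasible <- cmax >= cmin
    Ck <- ifelse(feasible,
                 cmin + floor(stats::runif(k) * (cmax - cmin + 1)), 1)
    Ok <- round(oc * Ck)
    Hk <- round(hc * Ck)
    wrong <- (Hk - nat[need]) %% 2 != 0
    up_ok <- (Hk + 1) / Ck <= hc_hi
    Hk[wrong] <- ifelse(up_ok[wrong], Hk[wrong] + 1, Hk[wrong] - 1)
    mass <- Ck * .MASS$C + Hk * .MASS$H + Ok * .MASS$O + base
    good <- feasible & Hk >= 1 & Ok >= 0 &
      Ck <= params$max_c & Hk <= params$max_h & Ok <= params$max_o &
      Ok / Ck >= oc_lo & Ok / Ck <= oc_hi &
      Hk / Ck >= hc_lo & Hk / Ck <= hc_hi &
      Hk <= 2 * Ck + nat[need] + 2 &
      mass >= window[1] & mass <= window[2]
    if (any(good)) {
      cand <- formula_frame(Ck[good], Hk[good], Ok[good],
                            nat[need][good], sat[need][good])
      good[good] <- formula_is_valid(cand, params) &
        as.character(classify_formula(cand, table)) == cls
    }
    slot <- need[good]
    C[slot] <- Ck[good]; H[slot] <- Hk[good]; O[slot] <- Ok[good]
    need <- need[!good]
    if (!length(need)) break
  }
  if (length(need))
    stop("infeasible configuration: could not sample ", length(need),
         " formula(s) in class ", cls, " within ", max_tries, " tries")
  formula_frame(C, H, O, nat, sat)
}

# Draw `k` *unique* formulas for one class, with per-draw heteroatom
# counts; duplicates are redrawn.
.sample_unique_in_class <- function(cls, nat, sat, window, table, params,
                                    max_rounds = 100L) {
  k <- length(nat)
  f <- sample_formula_in_class(cls, k, nat, sat, window = window,
                               table = table, params = params)
  for (round in seq_len(max_rounds)) {
    dup <- duplicated(formula_key(f))
    if (!any(dup)) return(f)
    f[dup, ] <- sample_formula_in_class(cls, sum(dup), nat[dup], sat[dup],
                                        window = window, table = table,
                                        params = params)
  }
  stop("could not draw ", k, " unique formulas in class ", cls)
}

#' Generate one synthetic sample (peak list plus ground truth)
#'
#' Draws `formulas_per_sample` unique formulas from the condition's class
#' and group mixtures, converts each to its \[M-H\]- m/z, perturbs it by
#' Gaussian ppm error, attaches log-normal intensities and S/N values
#' (a configured fraction below 4), and appends unassignable noise peaks
#' at uniform m/z guaranteed to have no valid formula within 2 ppm.
#' Peaks are returned shuffled.  Uses the current RNG state; seed via
#' [generate_study()] or `set.seed()`.
#'
#' @param cond_index Condition row (1-based) into the mixtures.
#' @param cfg A [scenario_config()].
#' @param boundaries Boundary table; see [vk_classes()].
#' @param params Validity parameters for the generated formulas.
#' @return List with `peaks` (data frame `mz`, `intensity`, `snr`) and
#'   `truth` (formula table with `compound_class`, `element_group`, plus
#'   `n_noise`).
#' @export
generate_sample <- function(cond_index, cfg = scenario_config(),
                            boundaries = vk_classes(),
                            params = assignment_params()) {
  n <- cfg$formulas_per_sample
  neutral_window <- c(cfg$mz_window[1] + .MASS$proton, cfg$mz_window[2])

  cls <- sample(colnames(cfg$class_mixture), n, replace = TRUE,
                prob = cfg$class_mixture[cond_index, ])
  grp <- sample(colnames(cfg$group_mixture), n, replace = TRUE,
                prob = cfg$group_mixture[cond_index, ])
  nat <- ifelse(grp %in% c("CHON", "CHONS"),
                sample(1:3, n, replace = TRUE, prob = cfg$n_probs), 0L)
  sat <- ifelse(grp %in% c("CHOS", "CHONS"), 1L, 0L)

  f <- formula_frame(integer(n), rep(1L, n))
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    f[idx, ] <- .sample_unique_in_class(cl, nat[idx], sat[idx],
                                        neutral_window, boundaries, params)
  }
  truth <- f
  truth$compound_class <- factor(cls, levels = c(boundaries$class, "unclassified"))
  truth$element_group <- factor(grp, levels = c("CHO", "CHON", "CHOS", "CHONS"))

  mz <- mz_from_neutral_mass(exact_neutral_mass(f))
  mz_obs <- mz * (1 + stats::rnorm(n, 0, cfg$mass_error_sd_ppm) * 1e-6)
  low <- stats::runif(n) < cfg$low_snr_fraction
  snr <- ifelse(low, stats::runif(n, 0.5, 3.9),
                4 + stats::rexp(n, rate = 1 / 20))
  peaks <- data.frame(mz = mz_obs,
                      intensity = stats::rlnorm(n, log(1e6), 1),
                      snr = snr)

  n_noise <- round(cfg$noise_fraction * n)
  if (n_noise > 0L) {
    noise_mz <- .draw_noise_mz(n_noise, cfg$mz_window, params)
    peaks <- rbind(peaks,
                   data.frame(mz = noise_mz,
                              intensity = stats::rlnorm(n_noise, log(2e5), 0.8),
                              snr = stats::runif(n_noise, 1, 8)))
  }
  peaks <- peaks[sample.int(nrow(peaks)), , drop = FALSE]
  rownames(peaks) <- NULL
  list(peaks = peaks, truth = truth, n_noise = n_noise)
}

# Noise m/z values whose neutral mass has NO valid formula within 2 ppm,
# so "unassigned" has unambiguous truth.
.draw_noise_mz <- function(k, mz_window, params, guard_ppm = 2,
                           max_rounds = 200L) {
  sp <- formula_space(params)
  out <- numeric(0)
  for (round in seq_len(max_rounds)) {
    mz <- stats::runif(k - length(out), mz_window[1], mz_window[2])
    M <- neutral_mass_from_mz(mz)
    tol <- guard_ppm * 1e-6 * M
    nhit <- findInterval(M + tol, sp$mass) - findInterval(M - tol, sp$mass)
    out <- c(out, mz[nhit == 0L])
    if (length(out) >= k) return(out[seq_len(k)])
  }
  stop("could not place ", k, " noise peaks clear of valid formula masses")
}

#' Generate a full synthetic study
#'
#' Seeds the RNG from `cfg$seed` and emits one peak list per
#' condition-replicate sample, a soil-chemistry table following the
#' configured linear trends plus noise, and a genus-abundance table in
#' which coupled genera track their designated feature through a
#' Gaussian copula (so the planted Spearman correlation is exact by
#' construction) and the remaining genera are independent log-normal
#' noise.  Ground truth (true formulas with classes, true chemistry
#' means, planted edges) is returned alongside.
#'
#' @param cfg A [scenario_config()].
#' @param boundaries Boundary table; see [vk_classes()].
#' @param params Validity parameters.
#' @return Object of class `dom_study`: list with `config`, `samples`
#'   (sample metadata), `peaks` (named list of peak tables), `truth`
#'   (named list of true formula tables + `edges`), `chemistry`,
#'   `genus`, and `features` (samples x features truth matrix + `meta`).
#' @export
generate_study <- function(cfg = scenario_config(),
                           boundaries = vk_classes(),
                           params = assignment_params()) {
  set.seed(cfg$seed)
  conds <- cfg$conditions
  samples <- expand.grid(replicate = seq_len(cfg$replicates),
                         condition = conds, KEEP.OUT.ATTRS = FALSE)
  samples <- samples[, c("condition", "replicate")]
  samples$sample_id <- paste0(samples$condition, "_R", samples$replicate)
  ns <- nrow(samples)

  peaks <- truth <- stats::setNames(vector("list", ns), samples$sample_id)
  for (i in seq_len(ns)) {
    ci <- match(samples$condition[i], conds)
    g <- generate_sample(ci, cfg, boundaries, params)
    peaks[[i]] <- g$peaks
    truth[[i]] <- g$truth
  }

  chem <- data.frame(sample_id = samples$sample_id,
                     condition = as.character(samples$condition),
                     replicate = samples$replicate)
  for (v in names(cfg$chemistry)) {
    spec <- cfg$chemistry[[v]]
    ci <- match(samples$condition, conds)
    chem[[v]] <- spec$means[ci] + stats::rnorm(ns, 0, spec$sd)
  }

  # truth feature matrix: per-sample class/group percentages + chemistry
  cls_pct <- t(vapply(truth, function(tt)
    100 * as.numeric(table(tt$compound_class)[.VK_CLASSES]) / nrow(tt),
    numeric(7)))
  colnames(cls_pct) <- .VK_CLASSES
  grp_pct <- t(vapply(truth, function(tt)
    100 * as.numeric(table(tt$element_group)) / nrow(tt), numeric(4)))
  colnames(grp_pct) <- c("CHO", "CHON", "CHOS", "CHONS")
  feat <- cbind(cls_pct, grp_pct,
                as.matrix(chem[, names(cfg$chemistry), drop = FALSE]))
  rownames(feat) <- samples$sample_id

  genus_names <- c(cfg$couplings$genus, "Nocardioides",
                   sprintf("Genus%02d", seq_len(cfg$n_noise_genera)))
  gm <- matrix(NA_real_, ns, length(genus_names),
               dimnames = list(samples$sample_id, genus_names))
  for (j in seq_len(nrow(cfg$couplings))) {
    fname <- cfg$couplings$feature[j]
    if (!fname %in% colnames(feat))
      stop("coupling target not a feature: ", fname)
    gm[, cfg$couplings$genus[j]] <-
      couple_to_feature(feat[, fname], cfg$couplings$rho[j])
  }
  gm[, "Nocardioides"] <- stats::rlnorm(ns, log(500), 0.5)
  for (g in sprintf("Genus%02d", seq_len(cfg$n_noise_genera)))
    gm[, g] <- stats::rlnorm(ns, log(100), 1)

  # genera detected only in the first / last condition (zero elsewhere),
  # so the end-condition genus Venn has all three compartments
  gm_extra <- NULL
  restricted <- function(labels, cond) {
    block <- matrix(0, ns, length(labels),
                    dimnames = list(samples$sample_id, labels))
    sel <- samples$condition == cond
    for (g in labels) block[sel, g] <- stats::rlnorm(sum(sel), log(50), 0.5)
    block
  }
  if (cfg$n_only_first > 0L)
    gm_extra <- cbind(gm_extra,
                      restricted(sprintf("OnlyEarly%02d",
                                         seq_len(cfg$n_only_first)),
                                 conds[1L]))
  if (cfg$n_only_last > 0L)
    gm_extra <- cbind(gm_extra,
                      restricted(sprintf("OnlyLate%02d",
                                         seq_len(cfg$n_only_last)),
                                 conds[length(conds)]))
  if (!is.null(gm_extra)) {
    gm <- cbind(gm, gm_extra)
    genus_names <- colnames(gm)
  }

  genus <- data.frame(genus = genus_names,
                      t(gm), check.names = FALSE, row.names = NULL)

  full <- cbind(feat, gm)
  meta <- data.frame(
    feature = colnames(full),
    category = c(rep("compound_class", 7), rep("element_group", 4),
                 rep("chemistry", length(cfg$chemistry)),
                 rep("genus", length(genus_names))),
    stringsAsFactors = FALSE)

  out <- list(config = cfg, samples = samples, peaks = peaks,
              truth = list(formulas = truth,
                           edges = cfg$couplings,
                           chemistry_means = cfg$chemistry),
              chemistry = chem, genus = genus,
              features = list(x = full, meta = meta))
  class(out) <- "dom_study"
  out
}

#' @export
print.dom_study <- function(x, ...) {
  cat("Synthetic DOM study: ", length(x$config$conditions), " conditions x ",
      x$config$replicates, " replicates, ",
      x$config$formulas_per_sample, " formulas/sample (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Couple a log-normal abundance to a feature via a Gaussian copula
#'
#' Returns a log-normal abundance vector whose rank correlation with `x`
#' is `rho_s` by construction: the normal scores of `x` are mixed with
#' independent Gaussian noise at the copula correlation
#' `rho_z = 2 sin(pi rho_s / 6)` (the exact Spearman-to-Pearson relation
#' for the bivariate Gaussian copula), then exponentiated.
#'
#' @param x Feature vector (any continuous scale; only its ranks are
#'   used).
#' @param rho_s Target Spearman correlation in (-1, 1).
#' @param meanlog,sdlog Log-normal marginal parameters.
#' @return Numeric abundance vector, same length as `x`.
#' @export
couple_to_feature <- function(x, rho_s, meanlog = log(100), sdlog = 1) {
  stopifnot(abs(rho_s) < 1)
  n <- length(x)
  rho_z <- 2 * sin(pi * rho_s / 6)
  zx <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
  zx <- zx / stats::sd(zx)
  z <- rho_z * zx + sqrt(1 - rho_z^2) * stats::rnorm(n)
  exp(meanlog + sdlog * z)
}
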