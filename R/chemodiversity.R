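# Per-sample composition summaries, two-condition degraded / remaining /
# produced comparison, and Venn partition percentages.
#
# All accounting is on unique formulas (exact CHNOS identity, set
# semantics), never on peaks: FT-ICR-MS resolves elemental composition,
# not structure, so the formula is the natural unit.

# Unique-formula slice of an annotated table: one row per distinct
# formula, keeping class and group.
.unique_formulas <- function(annotated) {
  need <- c("C", "H", "O", "N", "S", "compound_class", "element_group")
  if (!is.data.frame(annotated) || !all(need %in% names(annotated)))
    stop("expected a class-annotated table (see classify_table)")
  ok <- !is.na(annotated$C)
  f <- annotated[ok, need, drop = FALSE]
  if (nrow(f) == 0L) return(f)
  key <- formula_key(f)
  f <- f[!duplicated(key), , drop = FALSE]
  rownames(f) <- NULL
  f
}

#' Per-sample DOM composition summary
#'
#' Deduplicates formulas within a sample and tabulates counts and
#' percentages over the seven van Krevelen compound classes (plus
#' `unclassified`) and the four element groups.  Percentages are kept at
#' full precision internally; `print` and the writers round to 2 d.p.
#' (half away from zero).
#'
#' @param annotated A class-annotated table (from [classify_table()]);
#'   rows without a formula are ignored.
#' @param sample_id Optional sample label stored in the result.
#' @return An object of class `dom_composition`: a list with
#'   `sample_id`, `n_formulas`, `class_counts`, `class_pct`,
#'   `group_counts`, `group_pct`.
#' @export
composition <- function(annotated, sample_id = NA_character_) {
  f <- .unique_formulas(annotated)
  n <- nrow(f)
  if (n == 0L)
    warning("sample ", sample_id, " has no assigned formulas")
  class_counts <- table(f$compound_class)
  group_counts <- table(f$element_group)
  pct <- function(cnt) if (n > 0L) 100 * as.numeric(cnt) / n
                       else rep(0, length(cnt))
  out <- list(sample_id = sample_id, n_formulas = n,
              class_counts = stats::setNames(as.integer(class_counts),
                                             names(class_counts)),
              class_pct = stats::setNames(pct(class_counts),
                                          names(class_counts)),
              group_counts = stats::setNames(as.integer(group_counts),
                                             names(group_counts)),
              group_pct = stats::setNames(pct(group_counts),
                                          names(group_counts)))
  class(out) <- "dom_composition"
  out
}

#' @export
print.dom_composition <- function(x, ...) {
  cat("DOM composition", if (!is.na(x$sample_id)) paste0(" [", x$sample_id, "]"),
      ": ", x$n_formulas, " unique formulas\n", sep = "")
  cat("Compound classes (%):\n")
  print(round_half_up(x$class_pct, 2))
  cat("Element groups (%):\n")
  print(round_half_up(x$group_pct, 2))
  invisible(x)
}

#' Compositions as a tidy table
#'
#' Binds a list of [composition()] results into one long data frame,
#' ready to write or to feed the network stage.
#'
#' @param comps List of `dom_composition` objects.
#' @return Data frame with columns `sample_id`, `feature`, `category`
#'   (`compound_class` or `element_group`), `count`, `pct`.
#' @export
composition_table <- function(comps) {
  do.call(rbind, lapply(comps, function(cp) {
    rbind(
      data.frame(sample_id = cp$sample_id, feature = names(cp$class_pct),
                 category = "compound_class",
                 count = cp$class_counts, pct = cp$class_pct,
                 row.names = NULL),
      data.frame(sample_id = cp$sample_id, feature = names(cp$group_pct),
                 category = "element_group",
                 count = cp$group_counts, pct = cp$group_pct,
                 row.names = NULL)
    )
  }))
}

#' Degraded / remaining / produced comparison of two conditions
#'
#' Exact set algebra on canonical formula identities between an earlier
#' condition A and a later condition B: *degraded* formulas occur only in
#' A, *remaining* formulas in both, *produced* formulas only in B.  The
#' three overall percentages are fractions of the union; per-class and
#' per-group percentages are computed within the pooled membership of
#' each class/group.
#'
#' @param a,b Class-annotated tables (see [classify_table()]) for the two
#'   conditions; replicate tables should be row-bound first (formula sets
#'   are unioned within a condition).
#' @param labels Length-2 condition labels, used in printing.
#' @return An object of class `dom_comparison`: a list with `counts` and
#'   `overall_pct` (degraded / remaining / produced), `per_class` and
#'   `per_group` data frames, and the three formula sets.
#' @export
#' @examples
#' a <- classify_table(formula_frame(c(10, 12, 14), c(12, 16, 20), c(5, 6, 7)))
#' b <- classify_table(formula_frame(c(12, 14, 16, 18), c(16, 20, 24, 30),
#'                                   c(6, 7, 8, 4)))
#' compare_two(a, b)
compare_two <- function(a, b, labels = c("A", "B")) {
  fa <- .unique_formulas(a)
  fb <- .unique_formulas(b)
  if (nrow(fa) == 0L && nrow(fb) == 0L)
    stop("both conditions are empty; nothing to compare")
  ka <- formula_key(fa)
  kb <- formula_key(fb)
  pool <- rbind(fa, fb[!(kb %in% ka), , drop = FALSE])
  kp <- formula_key(pool)
  status <- ifelse(kp %in% ka,
                   ifelse(kp %in% kb, "remaining", "degraded"),
                   "produced")
  status <- factor(status, levels = c("degraded", "remaining", "produced"))
  counts <- table(status)
  total <- nrow(pool)
  overall_pct <- 100 * as.numeric(counts) / total
  names(overall_pct) <- names(counts)

  drp_by <- function(fac) {
    tab <- table(fac, status)
    data.frame(feature = rownames(tab),
               n_total = as.integer(rowSums(tab)),
               n_degraded = as.integer(tab[, "degraded"]),
               n_remaining = as.integer(tab[, "remaining"]),
               n_produced = as.integer(tab[, "produced"]),
               pct_degraded = 100 * tab[, "degraded"] / pmax(1L, rowSums(tab)),
               pct_remaining = 100 * tab[, "remaining"] / pmax(1L, rowSums(tab)),
               pct_produced = 100 * tab[, "produced"] / pmax(1L, rowSums(tab)),
               row.names = NULL)
  }

  out <- list(labels = labels,
              counts = stats::setNames(as.integer(counts), names(counts)),
              overall_pct = overall_pct,
              per_class = drp_by(pool$compound_class),
              per_group = drp_by(pool$element_group),
              degraded = pool[status == "degraded", , drop = FALSE],
              remaining = pool[status == "remaining", , drop = FALSE],
              produced = pool[status == "produced", , drop = FALSE])
  class(out) <- "dom_comparison"
  out
}

#' @export
print.dom_comparison <- function(x, ...) {
  cat("DOM comparison ", x$labels[1], " vs ", x$labels[2], ": ",
      sum(x$counts), " formulas in the union\n", sep = "")
  tab <- data.frame(n = x$counts, pct = round_half_up(x$overall_pct, 1))
  print(tab)
  invisible(x)
}

#' Venn-partition percentages
#'
#' Percentages of a two-set Venn partition (only-A, shared, only-B) of
#' its total, rounded to 2 d.p. (half away from zero).
#'
#' @param only_a,shared,only_b Non-negative counts; total must be > 0.
#' @return Named numeric vector `pct_only_a`, `pct_shared`, `pct_only_b`.
#' @export
#' @examples
#' venn_percentages(56, 613, 97)  # 7.31, 80.03, 12.66
venn_percentages <- function(only_a, shared, only_b) {
  if (any(c(only_a, shared, only_b) < 0))
    stop("Venn counts must be >= 0")
  total <- only_a + shared + only_b
  if (total <= 0)
    stop("Venn partition is empty; percentages undefined")
  stats::setNames(round_half_up(100 * c(only_a, shared, only_b) / total, 2),
                  c("pct_only_a", "pct_shared", "pct_only_b"))
}

#' Venn partition of taxa between two abundance tables
#'
#' A taxon is present in a condition iff its total abundance there
#' exceeds `presence_threshold` (default 0).  The two tables share a
#' taxon identifier in their first column; remaining columns are numeric
#' sample abundances (summed across replicates).
#'
#' @param a,b Data frames: first column taxon id, remaining columns
#'   numeric abundances.  Duplicated taxon ids are an error.
#' @param presence_threshold Presence cutoff on the summed abundance.
#' @return Named integer vector `only_a`, `shared`, `only_b`.
#' @export
build_venn_from_tables <- function(a, b, presence_threshold = 0) {
  tot <- function(tab, nm) {
    if (!is.data.frame(tab) || ncol(tab) < 2L)
      stop("abundance table ", nm, " needs a taxon column plus >= 1 numeric column")
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
      stop("duplicated taxon identifiers in table ", nm, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric abundances in table ", nm)
    stats::setNames(rowSums(vals), ids)
  }
  ta <- tot(a, "A"); tb <- tot(b, "B")
  pa <- names(ta)[ta > presence_threshold]
  pb <- names(tb)[tb > presence_threshold]
  c(only_a = length(setdiff(pa, pb)),
    shared = length(intersect(pa, pb)),
    only_b = length(setdiff(pb, pa)))
}
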