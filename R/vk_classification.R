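# Van Krevelen compound-class boundaries and classification.

.VK_CLASSES <- c("lipids", "aliphatic_proteins", "lignin_cram",
                 "carbohydrates", "unsaturated_hc", "condensed_aromatics",
                 "tannins")
.CLASS_LEVELS <- c(.VK_CLASSES, "unclassified")

#' Default van Krevelen class-boundary table
#'
#' The seven biochemical compound classes of soil DOM and their O/C x H/C
#' boxes: lipids (O/C 0-0.3, H/C 1.5-2.0), aliphatic/proteins (0.3-0.67,
#' 1.5-2.2), lignin/CRAM-like (0.1-0.67, 0.7-1.5), carbohydrates
#' (0.67-1.2, 1.5-2.3), unsaturated hydrocarbons (0-0.1, 0.5-1.5),
#' condensed aromatics (0-0.67, 0.1-0.7) and tannins (0.67-1.2, 0.5-1.5).
#'
#' The printed boxes overlap (e.g. unsaturated hydrocarbons and condensed
#' aromatics share O/C < 0.1, H/C 0.5-0.7), so classification applies the
#' rows in table order, first match wins.  The default order is the order
#' the classes are conventionally listed; supply a reordered or edited
#' table to [classify_formula()] to change the convention.  Each box is
#' half-open, `[low, high)` on both axes, which removes double assignment
#' on shared edges such as O/C = 0.3 or H/C = 1.5.
#'
#' @return A `data.frame` with columns `class`, `o_c_low`, `o_c_high`,
#'   `h_c_low`, `h_c_high`, in precedence order.
#' @export
#' @examples
#' vk_classes()
vk_classes <- function() {
  data.frame(
    class    = .VK_CLASSES,
    o_c_low  = c(0.00, 0.30, 0.10, 0.67, 0.00, 0.00, 0.67),
    o_c_high = c(0.30, 0.67, 0.67, 1.20, 0.10, 0.67, 1.20),
    h_c_low  = c(1.50, 1.50, 0.70, 1.50, 0.50, 0.10, 0.50),
    h_c_high = c(2.00, 2.20, 1.50, 2.30, 1.50, 0.70, 1.50)
  )
}

.check_boundary_table <- function(table) {
  need <- c("class", "o_c_low", "o_c_high", "h_c_low", "h_c_high")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("boundary table needs columns: ", paste(need, collapse = ", "))
  if (any(table$o_c_low >= table$o_c_high) ||
      any(table$h_c_low >= table$h_c_high))
    stop("boundary table has empty boxes (low >= high)")
  table
}

#' Classify formulas into van Krevelen compound classes
#'
#' Maps each formula to the first class in `table` order whose half-open
#' O/C x H/C box `[low, high)` contains its elemental ratios;
#' `"unclassified"` if no box matches.  Classification depends only on the
#' element counts, never on intensity or m/z, and is total and unique:
#' every CH-containing formula receives exactly one class.
#'
#' @param f Formula table with `C >= 1` in every row.
#' @param table Boundary table in precedence order; see [vk_classes()].
#' @return Factor with the seven class levels plus `"unclassified"`.
#' @export
#' @examples
#' classify_formula(formula_frame(18, 34, 2))   # oleic acid -> lipids
#' classify_formula(formula_frame(10, 12, 7))   # -> tannins
classify_formula <- function(f, table = vk_classes()) {
  f <- .check_formula(f)
  table <- .check_boundary_table(table)
  r <- elemental_ratios(f)
  cls <- rep("unclassified", nrow(f))
  open <- rep(TRUE, nrow(f))
  for (i in seq_len(nrow(table))) {
    hit <- open &
      r$o_c >= table$o_c_low[i]  & r$o_c < table$o_c_high[i] &
      r$h_c >= table$h_c_low[i]  & r$h_c < table$h_c_high[i]
    cls[hit] <- table$class[i]
    open <- open & !hit
  }
  factor(cls, levels = c(table$class, "unclassified"))
}

#' Annotate an assigned-peak table with class and element group
#'
#' Appends `compound_class` and `element_group` columns to a table of
#' assigned peaks (see [assign_peaklist()]).  Rows without a formula
#' (unassigned peaks) receive class `"unclassified"` and group `NA`.
#' Annotation never changes the row count.
#'
#' @param assigned Data frame with formula columns `C`, `H`, `O`, `N`, `S`
#'   (NA in `C` marks an unassigned peak), e.g. from [assign_peaklist()],
#'   or any formula table.
#' @param table Boundary table; see [vk_classes()].
#' @return The input with `compound_class` and `element_group` appended.
#' @export
classify_table <- function(assigned, table = vk_classes()) {
  if (nrow(assigned) == 0L) {
    assigned$compound_class <- factor(character(),
                                      levels = c(table$class, "unclassified"))
    assigned$element_group <- factor(character(),
                                     levels = levels(element_group(formula_frame(1, 1))))
    return(assigned)
  }
  has <- !is.na(assigned$C) & assigned$C >= 1L
  cls <- factor(rep("unclassified", nrow(assigned)),
                levels = c(table$class, "unclassified"))
  grp <- factor(rep(NA_character_, nrow(assigned)),
                levels = c("CHO", "CHON", "CHOS", "CHONS"))
  if (any(has)) {
    fsub <- assigned[has, c("C", "H", "O", "N", "S")]
    cls[has] <- classify_formula(fsub, table)
    grp[has] <- element_group(fsub)
  }
  assigned$compound_class <- cls
  assigned$element_group <- grp
  assigned
}

#' Van Krevelen diagram
#'
#' Scatter of H/C against O/C for a set of formulas, coloured by compound
#' class, with the default class boxes drawn.  A basic diagnostic plot.
#'
#' @param f Formula table (rows with `C >= 1`).
#' @param table Boundary table; see [vk_classes()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the ratios and classes plotted.
#' @export
vk_plot <- function(f, table = vk_classes(), ...) {
  f <- .check_formula(f)
  r <- elemental_ratios(f)
  cls <- classify_formula(f, table)
  cols <- grDevices::hcl.colors(nrow(table) + 1, "Dark 3")
  graphics::plot(r$o_c, r$h_c, col = cols[as.integer(cls)], pch = 16,
                 cex = 0.5, xlab = "O/C", ylab = "H/C",
                 xlim = c(0, 1.2), ylim = c(0, 2.4), ...)
  graphics::rect(table$o_c_low, table$h_c_low, table$o_c_high,
                 table$h_c_high, border = "grey40", lty = 2)
  invisible(data.frame(r, compound_class = cls))
}
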