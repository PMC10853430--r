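# Readers, writers and the end-to-end pipeline driver.
#
# Delimited text everywhere: FT-ICR peak exports are vendor CSVs in
# practice, and plain text keeps fixtures human-readable.  All writes go
# through a temp-file-plus-rename so output files are never partial.

.sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

# Atomic delimited write: temp file in the same directory, then rename.
write_delim_atomic <- function(x, path, sep = .sep_for(path)) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(x, tmp, sep = sep, quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

#' Read a peak list
#'
#' Delimited text (comma for `.csv`, tab otherwise) with a header and
#' columns `mz`, `intensity`, `snr`.  Malformed rows are rejected with
#' the offending row number.
#'
#' @param path File path.
#' @return Data frame with columns `mz`, `intensity`, `snr` (extra
#'   columns carried through).
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                         stringsAsFactors = FALSE)
  need <- c("mz", "intensity", "snr")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("peak list ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in need) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric or missing '", col, "' in ", path, " at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    x[[col]] <- v
  }
  bad <- which(x$mz <= 0 | x$intensity < 0 | x$snr < 0)
  if (length(bad))
    stop("negative or zero mz/intensity/snr in ", path, " at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  x
}

#' Write a peak list
#'
#' @param peaks Data frame with columns `mz`, `intensity`, `snr`.
#' @param path Output path (`.csv` writes comma-separated, else tabs).
#' @return Invisibly, `path`.
#' @export
write_peaklist <- function(peaks, path) {
  .check_peaks(peaks)
  write_delim_atomic(peaks, path)
}

#' Read a taxa x samples abundance table
#'
#' First column: taxon identifier; remaining columns: numeric
#' abundances.  Duplicated taxa, negative abundances and empty data
#' sections are errors.
#'
#' @param path File path (comma for `.csv`, tab otherwise).
#' @return Data frame, taxon identifiers in the first column.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(x) == 0L) stop("abundance table ", path, " has no data rows")
  if (ncol(x) < 2L) stop("abundance table ", path, " has no sample columns")
  ids <- as.character(x[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated taxon identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (j in 2:ncol(x)) {
    v <- suppressWarnings(as.numeric(x[[j]]))
    if (anyNA(v))
      stop("non-numeric abundance in ", path, ", column ", names(x)[j])
    if (any(v < 0))
      stop("negative abundance in ", path, ", column ", names(x)[j])
    x[[j]] <- v
  }
  x
}

#' Assemble the samples x features matrix for network inference
#'
#' Binds per-sample compound-class and element-group percentages (from
#' [composition()] results), soil chemistry values and genus abundances
#' into one numeric matrix plus feature metadata, the input contract of
#' [build_network()].
#'
#' @param comps Named list of `dom_composition` objects (names =
#'   sample ids).
#' @param chemistry Data frame with `sample_id` plus numeric chemistry
#'   columns (others ignored).
#' @param genus Taxa x samples data frame (first column genus, sample
#'   columns named by sample id).
#' @return List with `x` (samples x features matrix) and `meta`
#'   (feature, category).
#' @export
build_feature_matrix <- function(comps, chemistry = NULL, genus = NULL) {
  ids <- names(comps)
  if (is.null(ids)) stop("comps must be a named list of compositions")
  cls <- t(vapply(comps, function(cp) cp$class_pct[.VK_CLASSES], numeric(7)))
  grp <- t(vapply(comps, function(cp) {
    g <- cp$group_pct[c("CHO", "CHON", "CHOS", "CHONS")]
    g[is.na(g)] <- 0
    g
  }, numeric(4)))
  colnames(cls) <- .VK_CLASSES
  colnames(grp) <- c("CHO", "CHON", "CHOS", "CHONS")
  x <- cbind(cls, grp)
  meta <- data.frame(feature = colnames(x),
                     category = c(rep("compound_class", 7),
                                  rep("element_group", 4)),
                     stringsAsFactors = FALSE)
  if (!is.null(chemistry)) {
    i <- match(ids, chemistry$sample_id)
    if (anyNA(i)) stop("chemistry table missing sample(s): ",
                       paste(ids[is.na(i)], collapse = ", "))
    num <- vapply(chemistry, is.numeric, logical(1)) &
      !(names(chemistry) %in% c("replicate"))
    cm <- as.matrix(chemistry[i, num, drop = FALSE])
    x <- cbind(x, cm)
    meta <- rbind(meta, data.frame(feature = colnames(cm),
                                   category = "chemistry"))
  }
  if (!is.null(genus)) {
    gm <- t(as.matrix(genus[, -1L, drop = FALSE]))
    colnames(gm) <- as.character(genus[[1L]])
    if (!all(ids %in% rownames(gm)))
      stop("genus table missing sample(s): ",
           paste(setdiff(ids, rownames(gm)), collapse = ", "))
    gm <- gm[ids, , drop = FALSE]
    x <- cbind(x, gm)
    meta <- rbind(meta, data.frame(feature = colnames(gm),
                                   category = "genus"))
  }
  rownames(x) <- ids
  list(x = x, meta = meta)
}

#' Run the full pipeline on a synthetic scenario
#'
#' Generates the study from `cfg`, then runs assignment ->
#' classification -> per-sample composition -> first-versus-last
#' condition comparison -> genus Venn -> co-occurrence network, writing
#' each stage's table into `out_dir` together with a config echo and a
#' deterministic run log.  Idempotent for a fixed seed: rerunning
#' produces byte-identical outputs.
#'
#' @param cfg A [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @param params Assignment parameters.
#' @param alpha Edge significance level for the network stage.
#' @param bh Apply Benjamini-Hochberg correction in the network stage.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(cfg = scenario_config(), out_dir,
                         params = assignment_params(), alpha = 0.05,
                         bh = FALSE, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  say("generating synthetic study (seed ", cfg$seed, ")")
  study <- generate_study(cfg, params = params)
  ids <- study$samples$sample_id

  say("assigning formulas")
  assigned <- lapply(ids, function(id) {
    a <- assign_peaklist(study$peaks[[id]], params, quiet = TRUE)
    a$sample_id <- id
    a
  })
  names(assigned) <- ids
  all_assigned <- do.call(rbind, assigned)
  annotated <- lapply(assigned, classify_table)

  say("summarising composition")
  comps <- lapply(ids, function(id) composition(annotated[[id]], id))
  names(comps) <- ids
  comp_tab <- composition_table(comps)
  comp_tab$pct <- round_half_up(comp_tab$pct, 2)

  say("comparing first and last condition")
  first <- study$samples$condition == cfg$conditions[1]
  last <- study$samples$condition == cfg$conditions[length(cfg$conditions)]
  cmp <- compare_two(do.call(rbind, annotated[first]),
                     do.call(rbind, annotated[last]),
                     labels = c(cfg$conditions[1],
                                cfg$conditions[length(cfg$conditions)]))

  gen_cond <- function(sel) study$genus[, c(TRUE, sel), drop = FALSE]
  venn <- build_venn_from_tables(gen_cond(first), gen_cond(last))
  venn_pct <- venn_percentages(venn["only_a"], venn["shared"], venn["only_b"])

  say("inferring co-occurrence network")
  fm <- build_feature_matrix(comps, study$chemistry, study$genus)
  net <- build_network(fm$x, fm$meta, alpha = alpha, bh = bh)

  paths <- list(
    config = file.path(out_dir, "config.yaml"),
    assigned = file.path(out_dir, "assigned_peaks.tsv"),
    composition = file.path(out_dir, "composition.tsv"),
    comparison = file.path(out_dir, "comparison_overall.tsv"),
    comparison_class = file.path(out_dir, "comparison_by_class.tsv"),
    comparison_group = file.path(out_dir, "comparison_by_group.tsv"),
    venn = file.path(out_dir, "venn_genus.tsv"),
    edges = file.path(out_dir, "network_edges.tsv"),
    graphml = file.path(out_dir, "network.graphml"),
    log = file.path(out_dir, "run_log.txt"))

  yaml::write_yaml(.config_as_list(cfg), paths$config)
  write_delim_atomic(all_assigned, paths$assigned)
  write_delim_atomic(comp_tab, paths$composition)
  write_delim_atomic(
    data.frame(status = names(cmp$counts), n = cmp$counts,
               pct = round_half_up(cmp$overall_pct, 1), row.names = NULL),
    paths$comparison)
  pc <- cmp$per_class
  pg <- cmp$per_group
  for (col in grep("^pct_", names(pc))) pc[[col]] <- round_half_up(pc[[col]], 2)
  for (col in grep("^pct_", names(pg))) pg[[col]] <- round_half_up(pg[[col]], 2)
  write_delim_atomic(pc, paths$comparison_class)
  write_delim_atomic(pg, paths$comparison_group)
  write_delim_atomic(
    data.frame(part = names(venn), count = as.integer(venn),
               pct = as.numeric(venn_pct)),
    paths$venn)
  edges <- net$edges
  edges$rho <- round(edges$rho, 6)
  write_delim_atomic(edges, paths$edges)
  write_graphml(net, paths$graphml)

  log_lines <- c(
    sprintf("samples: %d", length(ids)),
    sprintf("peaks total: %d", nrow(all_assigned)),
    sprintf("peaks assigned: %d", sum(!is.na(all_assigned$C))),
    sprintf("unique formulas (union): %d",
            length(unique(formula_key(all_assigned[!is.na(all_assigned$C),
                                                   c("C", "H", "O", "N", "S")])))),
    sprintf("comparison: degraded %d / remaining %d / produced %d",
            cmp$counts["degraded"], cmp$counts["remaining"],
            cmp$counts["produced"]),
    sprintf("network edges: %d of %d pairs", nrow(net$edges),
            net$n_pairs_tested))
  tmp <- paste0(paths$log, ".tmp")
  writeLines(log_lines, tmp)
  file.rename(tmp, paths$log)

  invisible(list(study = study, assigned = all_assigned, comps = comps,
                 comparison = cmp, venn = venn, venn_pct = venn_pct,
                 network = net, paths = paths))
}

# Plain-list view of a scenario_config for the YAML echo.
.config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$class_mixture <- apply(cfg$class_mixture, 1, as.list, simplify = FALSE)
  out$group_mixture <- apply(cfg$group_mixture, 1, as.list, simplify = FALSE)
  out
}
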