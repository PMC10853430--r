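# Spearman co-occurrence network among DOM classes, element groups, soil
# chemistry variables and bacterial genera.

# All permutations of 1..n as an n! x n integer matrix (recursive
# construction).  Used only for the exact small-n null, so n <= 9.
.perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with a p-value
#'
#' rho is the Pearson correlation of average ranks (ties receive average
#' ranks).  The null p-value is two-sided: for n <= `exact_max` the exact
#' permutation distribution of rho is enumerated in full (this handles
#' ties, which the classical exact tables do not); for larger n the
#' standard t approximation `t = rho * sqrt((n-2) / (1-rho^2))` on n - 2
#' degrees of freedom is used.
#'
#' @param x,y Numeric vectors of equal length n >= 4; neither constant.
#' @param exact_max Largest n for which the exact permutation null is
#'   enumerated; default 9.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
#' @examples
#' spearman_pair(1:5, c(2, 4, 6, 8, 10))   # rho = 1
spearman_pair <- function(x, y, exact_max = 9L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= exact_max) {
    rx <- rank(x); ry <- rank(y)
    perm <- .perms(n)
    # rho for each permutation of y-ranks against fixed x-ranks
    ry_perm <- matrix(ry[perm], nrow(perm), n)
    cx <- rx - mean(rx)
    num <- as.vector(ry_perm %*% cx)
    den <- sqrt(sum(cx^2) * sum((ry - mean(ry))^2))
    rho_null <- num / den
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

.check_feature_matrix <- function(x, meta) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric")
  if (is.null(colnames(x))) stop("feature matrix needs column names")
  if (nrow(x) < 4L)
    stop("need >= 4 samples (rows) to compute correlations, got ", nrow(x))
  if (anyNA(x)) stop("feature matrix contains missing values")
  if (!is.null(meta)) {
    if (!all(c("feature", "category") %in% names(meta)))
      stop("feature metadata needs columns 'feature' and 'category'")
    if (!all(colnames(x) %in% meta$feature))
      stop("metadata missing for features: ",
           paste(setdiff(colnames(x), meta$feature), collapse = ", "))
  }
  x
}

#' Build a signed Spearman co-occurrence network
#'
#' Tests every unordered pair of features (columns) with
#' [spearman_pair()] and keeps the edges with p below `alpha`, signed by
#' the direction of the correlation.  Constant features are skipped with
#' a warning (their correlation is undefined).  Edges are returned sorted
#' by |rho| descending.
#'
#' @param x Samples x features numeric matrix (or data frame) with column
#'   names; >= 4 rows.
#' @param meta Optional feature metadata: data frame with columns
#'   `feature` and `category` (e.g. `compound_class`, `element_group`,
#'   `chemistry`, `genus`); carried onto the nodes.
#' @param alpha Significance level for edge retention; default 0.05 (no
#'   multiple-testing correction, matching common practice in
#'   co-occurrence studies).
#' @param bh If TRUE, apply Benjamini-Hochberg correction across all
#'   tested pairs before thresholding at `alpha`.
#' @param exact_max Passed to [spearman_pair()].
#' @return Object of class `dom_network`: list with `edges` (data frame
#'   `node_a`, `node_b`, `rho`, `p_value`, `sign`), `nodes`, `alpha`,
#'   `n_samples`, `n_pairs_tested`.
#' @export
build_network <- function(x, meta = NULL, alpha = 0.05, bh = FALSE,
                          exact_max = 9L) {
  x <- .check_feature_matrix(x, meta)
  keep <- apply(x, 2L, stats::sd) > 0
  if (any(!keep))
    warning("skipping constant feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  x <- x[, keep, drop = FALSE]
  p <- ncol(x)
  pairs <- if (p >= 2L) utils::combn(p, 2L) else matrix(integer(), 2L, 0L)
  m <- ncol(pairs)
  rho <- pval <- numeric(m)
  for (k in seq_len(m)) {
    res <- spearman_pair(x[, pairs[1L, k]], x[, pairs[2L, k]],
                         exact_max = exact_max)
    rho[k] <- res$rho
    pval[k] <- res$p_value
  }
  padj <- if (bh) stats::p.adjust(pval, method = "BH") else pval
  sel <- which(padj < alpha)
  edges <- data.frame(
    node_a = colnames(x)[pairs[1L, sel]],
    node_b = colnames(x)[pairs[2L, sel]],
    rho = rho[sel], p_value = pval[sel],
    sign = ifelse(rho[sel] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  if (bh) edges$p_adjusted <- padj[sel]
  edges <- edges[order(-abs(edges$rho), edges$node_a, edges$node_b), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(feature = colnames(x), stringsAsFactors = FALSE)
  if (!is.null(meta))
    nodes$category <- meta$category[match(nodes$feature, meta$feature)]
  out <- list(edges = edges, nodes = nodes, alpha = alpha,
              n_samples = nrow(x), n_pairs_tested = m, bh = bh)
  class(out) <- "dom_network"
  out
}

#' @export
print.dom_network <- function(x, ...) {
  cat("Spearman co-occurrence network: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (p < ", x$alpha,
      if (x$bh) ", BH-adjusted" else "", ", ",
      x$n_samples, " samples)\n", sep = "")
  if (nrow(x$edges)) print(utils::head(x$edges, 10L))
  invisible(x)
}

# igraph object for a dom_network (positive/negative edge attribute kept).
.as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b", "rho", "p_value", "sign")],
    directed = FALSE,
    vertices = net$nodes)
  g
}

#' @export
plot.dom_network <- function(x, ...) {
  g <- .as_igraph(x)
  ecol <- ifelse(igraph::E(g)$sign == "positive", "firebrick", "forestgreen")
  igraph::plot.igraph(g, edge.color = ecol,
                      edge.width = 1 + 3 * abs(igraph::E(g)$rho),
                      vertex.size = 8, vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' Write a network in GraphML format
#'
#' @param net A `dom_network` from [build_network()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(net, path) {
  if (!inherits(net, "dom_network")) stop("expected a dom_network")
  igraph::write_graph(.as_igraph(net), path, format = "graphml")
  invisible(path)
}
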