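#' Build the signed Pearson co-expression network
#'
#' Computes Pearson correlations between all pairs of the selected genes over
#' all samples (cases and controls pooled, log2 scale) and keeps edges with
#' `|r| >= corr_threshold`. Isolated nodes are retained in the node set; the
#' sign of `r` is kept on every edge, so the network encodes both correlation
#' and anti-correlation.
#'
#' @param mat An [expression_matrix()].
#' @param genes Gene ids to include (must be present in `mat`).
#' @param corr_threshold Minimum `|r|` for an edge, in (0, 1).
#' @return An object of class `coexpression_network`: a list with `nodes`
#'   (character) and `edges` (data.frame `gene_a`, `gene_b`, `r` with
#'   `gene_a < gene_b`).
#' @export
build_network <- function(mat, genes, corr_threshold = 0.7) {
  stopifnot(corr_threshold > 0, corr_threshold < 1)
  if (ncol(mat$values) < 3) {
    stop("building a correlation network needs >= 3 samples", call. = FALSE)
  }
  missing <- setdiff(genes, gene_ids(mat))
  if (length(missing) > 0) {
    stop("genes absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  lg <- values_log2(mat)[genes, , drop = FALSE]
  vars <- apply(lg, 1, stats::var)
  if (any(vars == 0)) {
    stop("zero-variance gene(s) reached network construction: ",
         paste(utils::head(genes[vars == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  cm <- cor(t(lg))
  idx <- which(upper.tri(cm) & abs(cm) >= corr_threshold, arr.ind = TRUE)
  a <- genes[idx[, 1]]
  b <- genes[idx[, 2]]
  swap <- a > b
  edges <- data.frame(
    gene_a = ifelse(swap, b, a),
    gene_b = ifelse(swap, a, b),
    r = cm[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = genes, edges = edges, corr_threshold = corr_threshold),
            class = "coexpression_network")
}

#' Construct a network directly from an edge list
#'
#' Mainly useful for tests and for re-importing exported edge lists.
#'
#' @param nodes Character vector of node ids.
#' @param edges Data.frame with columns `gene_a`, `gene_b`, `r`.
#' @param corr_threshold Threshold recorded on the object.
#' @return A `coexpression_network`.
#' @export
coexpression_network <- function(nodes, edges,
                                 corr_threshold = min(abs(edges$r), 1)) {
  stopifnot(all(c("gene_a", "gene_b", "r") %in% colnames(edges)))
  if (any(edges$gene_a == edges$gene_b)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  bad <- setdiff(c(edges$gene_a, edges$gene_b), nodes)
  if (length(bad) > 0) {
    stop("edge endpoints missing from node set: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  if (anyDuplicated(edges[, c("gene_a", "gene_b")])) {
    stop("duplicate edges", call. = FALSE)
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = as.character(nodes), edges = edges,
                 corr_threshold = corr_threshold),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d nodes, %d edges (|r| >= %.2f)\n",
              length(x$nodes), nrow(x$edges), x$corr_threshold))
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' Edge correlations are stored in the `r` edge attribute; topological
#' computations in this package always treat the graph as unweighted.
#'
#' @param net A `coexpression_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Summary statistics of a co-expression network
#'
#' @param net A `coexpression_network`.
#' @return A list with `n_nodes`, `n_edges`, `density`,
#'   `largest_component_size`, `frac_negative_edges`.
#' @export
network_stats <- function(net) {
  n <- length(net$nodes)
  m <- nrow(net$edges)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  list(
    n_nodes = n,
    n_edges = m,
    density = if (n < 2) 0 else m / (n * (n - 1) / 2),
    largest_component_size = if (n == 0) 0L else max(comp$csize),
    frac_negative_edges = if (m == 0) 0 else mean(net$edges$r < 0)
  )
}

#' Choose a correlation threshold by density
#'
#' Alternative to a fixed `corr_threshold`: scans thresholds
#' 0.50, 0.55, ..., 0.95 and returns the smallest whose resulting edge density
#' is at most `max_density`. Deterministic and logged via the return value;
#' the fixed default of 0.7 remains the standard mode.
#'
#' @param mat An [expression_matrix()].
#' @param genes Gene ids to include.
#' @param max_density Maximum acceptable edge density.
#' @return The selected threshold (numeric scalar).
#' @export
select_corr_threshold <- function(mat, genes, max_density = 0.05) {
  lg <- values_log2(mat)[genes, , drop = FALSE]
  cm <- abs(cor(t(lg)))
  n <- length(genes)
  n_pairs <- n * (n - 1) / 2
  for (th in seq(0.50, 0.95, by = 0.05)) {
    dens <- sum(cm[upper.tri(cm)] >= th) / n_pairs
    if (dens <= max_density) return(th)
  }
  0.95
}

#' Write a network edge list to TSV
#'
#' @param net A `coexpression_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
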